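#' Solve the per-sample-weighted soft-margin SVM dual
#'
#' Maximizes `sum(alpha) - 0.5 * sum_ij alpha_i alpha_j y_i y_j K_ij`
#' subject to `sum(y * alpha) = 0` and the per-sample box constraints
#' `0 <= alpha_i <= s_i * C`, where `s_i` are fuzzy weights. Solved by
#' sequential minimal optimization with second-order working-set selection;
#' deterministic for a fixed input order. The result is a KKT point to the
#' requested gap tolerance.
#'
#' @param K Symmetric positive semidefinite Gram matrix.
#' @param y Label vector over `{+1, -1}`.
#' @param weights Per-sample fuzzy values `s_i` in `[0, 1]` (or a
#'   `"fuzzy_weights"` tibble, whose `weight` column is used).
#' @param C Positive trade-off parameter.
#' @param tol Stopping tolerance on the KKT gap (default `1e-6`).
#' @param max_iter Iteration cap for the pairwise updates.
#' @return A list of class `"dual_solution"`: `alpha`, `b` (bias),
#'   `objective` (dual objective value), `support` (indices with
#'   `alpha > threshold`), `free` (support vectors strictly inside the
#'   box), `upper` (per-sample upper bounds `s_i * C`), `iterations`,
#'   `converged`.
#' @export
solve_weighted_dual <- function(K, y, weights, C, tol = 1e-6,
                                max_iter = 100000L) {
  if (inherits(weights, "fuzzy_weights")) weights <- weights$weight
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n, length(weights) == n)
  if (!all(y %in% c(-1, 1))) abort("labels must be +1 or -1.")
  if (any(weights < 0 | weights > 1)) abort("weights must lie in [0, 1].")
  if (C <= 0) abort("`C` must be positive.")
  ub <- weights * C
  if (all(ub[y == 1] == 0) || all(ub[y == -1] == 0)) {
    abort("no trainable instances in one class (all weights zero).")
  }
  sol <- smo_solve(K, as.numeric(y), ub, tol, as.integer(max_iter))
  if (!sol$converged) {
    warn(sprintf("SMO hit the iteration cap (%d); KKT gap %.2e.",
                 max_iter, sol$gap))
  }
  alpha <- sol$alpha
  sv_tol <- 1e-8 * C * max(weights)
  support <- which(alpha > sv_tol)
  free <- which(alpha > sv_tol & alpha < ub - sv_tol)
  b <- compute_bias(alpha, K, y, ub, fallback = sol$b_interval[1])
  structure(list(alpha = alpha, b = b, objective = sol$objective,
                 support = support, free = free, upper = ub,
                 iterations = sol$iterations, converged = sol$converged),
            class = "dual_solution")
}

#' Recover the bias term of a weighted SVM dual solution
#'
#' Averages `y_i - sum_j alpha_j y_j K_ij` over the free support vectors
#' (those strictly inside their box bound), the robust generalization of
#' reading the bias off a single support vector. When no support vector is
#' free, the midpoint of the feasible interval implied by the bound
#' instances is used.
#'
#' @param alpha Dual coefficients.
#' @param K Training Gram matrix.
#' @param y Labels over `{+1, -1}`.
#' @param upper Per-sample upper bounds `s_i * C`.
#' @param fallback Optional precomputed midpoint used when no support
#'   vector is free; if `NULL` it is derived from the KKT inequalities.
#' @return The bias `b` (a scalar).
#' @export
compute_bias <- function(alpha, K, y, upper, fallback = NULL) {
  sv_tol <- 1e-8 * max(upper)
  if (all(alpha <= sv_tol)) abort("no support vectors: cannot recover bias.")
  u <- as.numeric(K %*% (alpha * y))
  free <- alpha > sv_tol & alpha < upper - sv_tol
  if (any(free)) return(mean(y[free] - u[free]))
  if (!is.null(fallback)) return(fallback)
  # feasible interval: b >= y_i - u_i on I_up, b <= y_i - u_i on I_low
  up <- (y > 0 & alpha < upper) | (y < 0 & alpha > 0)
  low <- (y > 0 & alpha > 0) | (y < 0 & alpha < upper)
  (max(y[up] - u[up]) + min(y[low] - u[low])) / 2
}

#' Fit a fuzzy-weighted SVM (RIFSVM, IFSVM, or plain SVM)
#'
#' End-to-end training: computes per-instance fuzzy weights under the
#' requested scheme, then solves the weighted soft-margin dual and recovers
#' the bias. Scheme `"rif"` is the relative-density intuitionistic weighting
#' ([rif_weights()]); `"ifsvm"` the kernel-centroid intuitionistic baseline
#' ([if_weights()]); `"unit"` sets every weight to 1 and reproduces the
#' standard soft-margin SVM.
#'
#' @param data A labeled training dataset (tibble; features + label column).
#' @param scheme Weighting scheme: `"rif"`, `"ifsvm"`, or `"unit"`.
#' @param C Positive trade-off parameter.
#' @param kernel A [kernel_spec] (default RBF with `h = 1`).
#' @param multiplier Neighbor-policy multiplier for the `"rif"` scheme.
#' @param delta,beta1 IFSVM membership parameters (see [if_weights()]).
#' @param weights Optional explicit weight vector overriding the scheme.
#' @param label_col Name of the label column.
#' @param tol,max_iter Solver controls (see [solve_weighted_dual()]).
#' @return An object of class `"rifsvm"`: the retained support points and
#'   coefficients, bias, kernel spec, weights used, and fit metadata.
#'   Supports [predict()][predict.rifsvm()], [decision_values()],
#'   [tidy()], [glance()], and [autoplot()] (2-D data).
#' @export
#' @examples
#' d <- synth_data2(seed = 7, n_pos = 30, n_neg = 150)
#' fit <- rifsvm(d, scheme = "rif", C = 10, kernel = rbf_kernel(8))
#' table(truth = d$label, pred = predict(fit, d))
rifsvm <- function(data, scheme = c("rif", "ifsvm", "unit"), C = 1,
                   kernel = rbf_kernel(1), multiplier = 1, delta = 1e-4,
                   beta1 = "auto", weights = NULL, label_col = "label",
                   tol = 1e-6, max_iter = 100000L) {
  scheme <- match.arg(scheme)
  X <- feature_matrix(data, label_col)
  y <- label_vector(data, label_col)
  K <- kernel_matrix(X, kernel = kernel)
  w_tbl <- NULL
  if (is.null(weights)) {
    w_tbl <- switch(scheme,
      rif = rif_weights(data, multiplier, label_col),
      ifsvm = if_weights(data, kernel, delta, beta1, label_col),
      unit = NULL)
    weights <- if (is.null(w_tbl)) rep(1, length(y)) else w_tbl$weight
  }
  sol <- solve_weighted_dual(K, y, weights, C, tol, max_iter)
  sv <- sol$support
  structure(list(
    sv_x = X[sv, , drop = FALSE], sv_coef = sol$alpha[sv] * y[sv],
    b = sol$b, kernel = kernel, C = C, scheme = scheme,
    alpha = sol$alpha, weights = weights, weight_table = w_tbl,
    objective = sol$objective, support = sv, free = sol$free,
    iterations = sol$iterations, converged = sol$converged,
    n = length(y), n_pos = sum(y == 1), n_neg = sum(y == -1),
    multiplier = multiplier, feature_names = colnames(X),
    label_col = label_col), class = "rifsvm")
}

#' Decision values of a fitted fuzzy-weighted SVM
#'
#' The pre-sign decision function
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b` over the support points.
#'
#' @param model A fitted [rifsvm()] object.
#' @param newdata A dataset (tibble or matrix of features).
#' @param label_col Name of the label column to drop, if present.
#' @return A numeric vector of decision values.
#' @export
decision_values <- function(model, newdata, label_col = model$label_col) {
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata, label_col)
  if (ncol(X) != ncol(model$sv_x)) abort("dimension mismatch with the model.")
  Kx <- kernel_matrix(X, model$sv_x, model$kernel)
  as.numeric(Kx %*% model$sv_coef + model$b)
}

#' Predict with a fitted fuzzy-weighted SVM
#'
#' @param object A fitted [rifsvm()] object.
#' @param newdata A dataset (tibble or feature matrix).
#' @param type `"class"` for `{+1, -1}` labels (sign of the decision
#'   value), `"decision"` for the continuous decision values.
#' @param ... Unused.
#' @return Integer class labels or numeric decision values.
#' @export
predict.rifsvm <- function(object, newdata, type = c("class", "decision"),
                           ...) {
  type <- match.arg(type)
  f <- decision_values(object, newdata)
  if (type == "decision") f else ifelse(f >= 0, 1L, -1L)
}

#' @export
print.rifsvm <- function(x, ...) {
  cat(sprintf("Fuzzy-weighted SVM (scheme: %s)\n", x$scheme))
  cat(sprintf("  n = %d (%d minority / %d majority), C = %g, %s\n",
              x$n, x$n_pos, x$n_neg, x$C,
              if (x$kernel$kind == "rbf") sprintf("RBF h = %g", x$kernel$h)
              else "linear kernel"))
  cat(sprintf("  support vectors: %d (%d free), dual objective %.6g\n",
              length(x$support), length(x$free), x$objective))
  invisible(x)
}

#' Per-instance summary of a fitted fuzzy-weighted SVM
#'
#' @param x A fitted [rifsvm()] object.
#' @param ... Unused.
#' @return A tibble with one row per training instance: fuzzy `weight`,
#'   dual coefficient `alpha`, and `support` / `bounded` status.
#' @method tidy rifsvm
#' @export
tidy.rifsvm <- function(x, ...) {
  tibble::tibble(
    .row = seq_len(x$n),
    weight = x$weights,
    alpha = x$alpha,
    support = x$alpha > 1e-8 * x$C * max(x$weights),
    bounded = x$alpha >= x$weights * x$C - 1e-8 * x$C * max(x$weights))
}

#' One-row summary of a fitted fuzzy-weighted SVM
#'
#' @param x A fitted [rifsvm()] object.
#' @param ... Unused.
#' @return A one-row tibble: scheme, C, kernel spread, class counts,
#'   imbalance ratio, support-vector count, dual objective, convergence.
#' @method glance rifsvm
#' @export
glance.rifsvm <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, C = x$C, h = x$kernel$h,
                 n = x$n, n_pos = x$n_pos, n_neg = x$n_neg,
                 ir = x$n_pos / x$n_neg, n_sv = length(x$support),
                 objective = x$objective, converged = x$converged)
}

#' Decision-boundary plot for a 2-D fitted model
#'
#' @param object A fitted [rifsvm()] object trained on 2-D data.
#' @param data The training (or any 2-D) dataset to overlay.
#' @param grid_n Resolution of the background decision grid.
#' @param ... Unused.
#' @return A ggplot object showing the sign of the decision function and
#'   the data points.
#' @method autoplot rifsvm
#' @export
autoplot.rifsvm <- function(object, data, grid_n = 120, ...) {
  X <- feature_matrix(data, object$label_col)
  if (ncol(X) != 2) abort("decision plots need 2-D data.")
  rx <- range(X[, 1]); ry <- range(X[, 2])
  gx <- seq(rx[1], rx[2], length.out = grid_n)
  gy <- seq(ry[1], ry[2], length.out = grid_n)
  grid <- as.matrix(expand.grid(gx, gy))
  colnames(grid) <- object$feature_names
  f <- decision_values(object, grid)
  df <- tibble::tibble(x1 = grid[, 1], x2 = grid[, 2], f = f)
  pts <- tibble::tibble(x1 = X[, 1], x2 = X[, 2],
                        class = factor(label_vector(data, object$label_col),
                                       c(-1, 1), c("majority", "minority")))
  ggplot2::ggplot(df, ggplot2::aes(.data$x1, .data$x2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = factor(sign(.data$f))),
                         alpha = 0.25) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$f), breaks = 0,
                          colour = "black") +
    ggplot2::geom_point(data = pts, ggplot2::aes(shape = .data$class),
                        size = 1.3) +
    ggplot2::scale_fill_manual(values = c("-1" = "#b2182b", "1" = "#2166ac"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize a fitted model to JSON
#'
#' Writes everything needed to evaluate the decision function -- kernel
#' spec, support points and coefficients, bias, scheme, weights and `C` --
#' as a portable JSON container. [read_model()] restores a predictable
#' model object.
#'
#' @param model A fitted [rifsvm()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    scheme = model$scheme, C = model$C,
    kernel = list(kind = model$kernel$kind, h = model$kernel$h),
    sv_x = apply(model$sv_x, 1, as.numeric, simplify = FALSE),
    sv_coef = model$sv_coef, b = model$b,
    weights = model$weights, feature_names = model$feature_names,
    n = model$n, n_pos = model$n_pos, n_neg = model$n_neg,
    label_col = model$label_col)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a fitted model from JSON
#'
#' @param path A file written by [write_model()].
#' @return An object of class `"rifsvm"` supporting [predict()] and
#'   [decision_values()].
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  kernel <- if (p$kernel$kind == "rbf") rbf_kernel(p$kernel$h) else
    linear_kernel()
  sv_x <- p$sv_x
  if (is.list(sv_x)) sv_x <- do.call(rbind, lapply(sv_x, as.numeric))
  sv_x <- matrix(as.numeric(sv_x), ncol = length(p$feature_names),
                 dimnames = list(NULL, p$feature_names))
  structure(list(sv_x = sv_x, sv_coef = p$sv_coef, b = p$b,
                 kernel = kernel, C = p$C, scheme = p$scheme,
                 weights = p$weights, feature_names = p$feature_names,
                 n = p$n, n_pos = p$n_pos, n_neg = p$n_neg,
                 support = seq_len(length(p$sv_coef)), free = integer(),
                 alpha = NULL, label_col = p$label_col),
            class = "rifsvm")
}
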