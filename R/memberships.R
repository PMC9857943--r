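#' Exponential-decay membership from a distance
#'
#' The primitive `2 / (1 + exp(d / D))` mapping a non-negative distance
#' onto `(0, 1]`: zero distance gives membership 1, the normalizing
#' distance `D` (the class-wise maximum) gives `2 / (1 + e) ~ 0.538`. A
#' degenerate `D = 0` (all distances zero) yields membership 1 everywhere.
#'
#' @param d Non-negative distance vector.
#' @param D Non-negative normalizing distance (scalar).
#' @return Membership values in `(0, 1]`.
#' @export
exp_decay_membership <- function(d, D) {
  if (D <= 0) return(rep(1, length(d)))
  2 / (1 + exp(d / D))
}

#' Intuitionistic fuzzy score used for the majority class
#'
#' Combines membership and non-membership into a reliability score:
#' `0` where non-membership dominates (`mu < nu`, the noise branch),
#' otherwise `(1 - nu) / (2 - mu - nu)`. Requires `0 <= mu + nu <= 1`, so
#' the denominator is at least 1.
#'
#' @param mu Membership vector in `[0, 1]`.
#' @param nu Non-membership vector in `[0, 1]`.
#' @return Score vector in `[0, 1]`.
#' @export
#' @examples
#' rif_score(c(1, 0.2, 0.6), c(0, 0.3, 0.2))  # 1, 0, 2/3
rif_score <- function(mu, nu) {
  stopifnot(length(mu) == length(nu))
  ifelse(mu < nu, 0, (1 - nu) / (2 - mu - nu))
}

#' Relative-density intuitionistic fuzzy weights (RIF scheme)
#'
#' The core weighting scheme. Majority (negative) instances receive
#' membership from their within-class k-th neighbor distance and
#' non-membership `nu = (1 - mu) * rho`, where the opposite-class affinity
#' `rho` decays with the instance's distance to the minority class; their
#' fuzzy weight is the intuitionistic score scaled by the imbalance ratio
#' `IR = N+ / N-`, which rebalances the aggregate margin penalty of the two
#' classes. Minority (positive) instances are deliberately exempt from the
#' non-membership penalty -- sparsity alone would brand them as noise -- and
#' take their within-class membership directly as the weight.
#'
#' @param data A labeled dataset.
#' @param multiplier Positive scale on the `sqrt(N)` neighbor policy.
#' @param label_col Name of the label column.
#' @param rho_normalizer Normalizer for the majority-class affinity
#'   distance: `"majority_between"` (default) uses the maximum
#'   minority-class k-th neighbor distance over the majority instances
#'   being scored, keeping the decay argument in (0, 1];
#'   `"minority_within"` instead reuses the minority within-class maximum.
#' @param profile Optional precomputed [density_profile()] for `data`.
#' @return A tibble of class `"fuzzy_weights"` with columns `.row`,
#'   `label`, `mu`, `nu`, `rho`, `score`, `weight` and attributes `ir`
#'   (imbalance ratio) and `scheme = "rif"`.
#' @export
#' @examples
#' d <- synth_data2(seed = 1, n_pos = 20, n_neg = 100)
#' w <- rif_weights(d)
#' range(w$weight[w$label == -1])  # bounded by IR = 0.2
rif_weights <- function(data, multiplier = 1, label_col = "label",
                        rho_normalizer = c("majority_between",
                                           "minority_within"),
                        profile = NULL) {
  rho_normalizer <- match.arg(rho_normalizer)
  if (is.null(profile)) profile <- density_profile(data, multiplier, label_col)
  nrm <- attr(profile, "normalizers")
  neg <- profile$label == -1
  pos <- !neg
  ir <- sum(pos) / sum(neg)
  if (ir > 1) {
    warn("positive class is not the minority: majority weights exceed 1 and cannot be used in the weighted dual.")
  }

  mu <- nu <- rho <- score <- weight <- numeric(nrow(profile))
  # majority: membership from own-class density, affinity from minority side
  mu[neg] <- exp_decay_membership(profile$d_within[neg], nrm$within[["neg"]])
  B <- switch(rho_normalizer,
              majority_between = nrm$between[["neg"]],
              minority_within = nrm$within[["pos"]])
  rho[neg] <- exp_decay_membership(profile$d_between[neg], B)
  nu[neg] <- (1 - mu[neg]) * rho[neg]
  score[neg] <- rif_score(mu[neg], nu[neg])
  weight[neg] <- ir * score[neg]
  # minority: membership is the weight; no non-membership penalty
  mu[pos] <- exp_decay_membership(profile$d_within[pos], nrm$within[["pos"]])
  score[pos] <- mu[pos]
  weight[pos] <- mu[pos]

  out <- tibble::tibble(.row = profile$.row, label = profile$label,
                        mu = mu, nu = nu, rho = rho,
                        score = score, weight = weight)
  attr(out, "ir") <- ir
  attr(out, "scheme") <- "rif"
  class(out) <- c("fuzzy_weights", class(out))
  out
}

#' Classic fuzzy membership functions
#'
#' The three standard distance-decay memberships used by earlier fuzzy SVM
#' variants: linear `1 - d / (max(d) + delta)`, exponential
#' `2 / (1 + exp(beta * d))`, and Gaussian `exp(-(d - mu)^2 / (2 sigma^2))`.
#'
#' @param d Non-negative distance vector (to the chosen reference object).
#' @param kind One of `"linear"`, `"exponential"`, `"gaussian"`.
#' @param delta Small positive offset (linear kind).
#' @param beta Decay rate in `[0, 1]` (exponential kind).
#' @param mu,sigma Location and positive scale (Gaussian kind).
#' @return Membership vector in `[0, 1]`.
#' @export
classic_membership <- function(d, kind = c("linear", "exponential", "gaussian"),
                               delta = 1e-4, beta = 0.5, mu = 0, sigma = 1) {
  kind <- match.arg(kind)
  stopifnot(all(d >= 0))
  switch(kind,
    linear = 1 - d / (max(d) + delta),
    exponential = 2 / (1 + exp(beta * d)),
    gaussian = {
      if (sigma <= 0) abort("`sigma` must be positive.")
      exp(-(d - mu)^2 / (2 * sigma^2))
    })
}

#' @export
print.fuzzy_weights <- function(x, ...) {
  cat(sprintf("Fuzzy weights (%s scheme), %d instances, IR = %.4f\n",
              attr(x, "scheme"), nrow(x), attr(x, "ir")))
  NextMethod()
}

#' Scatter plot of fuzzy weights over a 2-D dataset
#'
#' @param object A `"fuzzy_weights"` tibble.
#' @param data The 2-D labeled dataset it was computed from.
#' @param label_col Name of the label column.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fuzzy_weights
#' @export
autoplot.fuzzy_weights <- function(object, data, label_col = "label", ...) {
  X <- feature_matrix(data, label_col)
  if (ncol(X) != 2) abort("weight plots need a 2-D dataset.")
  df <- tibble::tibble(x1 = X[, 1], x2 = X[, 2],
                       class = factor(object$label, c(-1, 1),
                                      c("majority", "minority")),
                       weight = object$weight)
  ggplot2::ggplot(df, ggplot2::aes(.data$x1, .data$x2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$weight,
                                     shape = .data$class), size = 1.6) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, colour = "fuzzy value") +
    ggplot2::theme_minimal()
}
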