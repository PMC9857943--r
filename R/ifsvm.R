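#' Kernel-space distances to the class centroids
#'
#' For each instance, the distance in feature space between `phi(x_i)` and
#' its own class mean, expanded through the Gram matrix:
#' `||phi(x_i) - c||^2 = K_ii + mean(K_cc) - 2 * mean_j K_ij` over the
#' class members `j`. With a linear kernel this reduces to the plain
#' Euclidean distance to the arithmetic class mean.
#'
#' @param data A labeled dataset.
#' @param kernel A [kernel_spec] (see [rbf_kernel()], [linear_kernel()]).
#' @param label_col Name of the label column.
#' @return A list with `dist` (length-n distances to own-class center) and
#'   `radius` (named vector: per-class maximum distance).
#' @export
kernel_center_distances <- function(data, kernel = rbf_kernel(1),
                                    label_col = "label") {
  X <- feature_matrix(data, label_col)
  y <- label_vector(data, label_col)
  K <- kernel_matrix(X, kernel = kernel)
  kernel_center_distances_from_gram(K, y)
}

#' Intuitionistic fuzzy membership from kernel-centroid distances
#'
#' The baseline membership `mu(x_i) = 1 - d_i / (R + delta)` where `d_i` is
#' the kernel-space distance to the instance's class center and `R` that
#' class's radius (the maximum such distance). The small `delta` keeps the
#' boundary instance strictly above zero.
#'
#' @inheritParams kernel_center_distances
#' @param delta Small positive offset (default `1e-4`).
#' @return Membership vector in `(0, 1]`.
#' @export
if_membership <- function(data, kernel = rbf_kernel(1), delta = 1e-4,
                          label_col = "label") {
  if (delta <= 0) abort("`delta` must be positive.")
  cd <- kernel_center_distances(data, kernel, label_col)
  y <- label_vector(data, label_col)
  R <- ifelse(y == 1, cd$radius[["pos"]], cd$radius[["neg"]])
  1 - cd$dist / (R + delta)
}

#' Intuitionistic fuzzy weights (IFSVM baseline scheme)
#'
#' The centroid-based baseline: membership from the kernel-space distance
#' to the class center ([if_membership()]); opposite-class affinity
#' `rho(x_i)` as the fraction of instances within kernel distance `beta1`
#' of `x_i` (the instance itself included in the denominator) that belong
#' to the opposite class; non-membership `nu = (1 - mu) * rho`; and the
#' final weight from the score function with its `nu = 0 -> mu` branch,
#' applied identically to both classes. This is the scheme whose
#' centroid reference mis-weights small disjunct clusters and manifold
#' geometries, motivating the relative-density alternative.
#'
#' @inheritParams if_membership
#' @param beta1 Positive neighborhood radius in kernel space, or `"auto"`
#'   for the conventional `min(R+, R-) / 5`.
#' @return A tibble of class `"fuzzy_weights"` with columns `.row`,
#'   `label`, `mu`, `nu`, `rho`, `score`, `weight`; attributes `ir`,
#'   `scheme = "ifsvm"`, `beta1` (the resolved radius), `radius`.
#' @export
if_weights <- function(data, kernel = rbf_kernel(1), delta = 1e-4,
                       beta1 = "auto", label_col = "label") {
  if (delta <= 0) abort("`delta` must be positive.")
  X <- feature_matrix(data, label_col)
  y <- label_vector(data, label_col)
  K <- kernel_matrix(X, kernel = kernel)
  cd <- kernel_center_distances_from_gram(K, y)
  R <- ifelse(y == 1, cd$radius[["pos"]], cd$radius[["neg"]])
  mu <- 1 - cd$dist / (R + delta)

  if (identical(beta1, "auto")) beta1 <- min(cd$radius) / 5
  if (!is.numeric(beta1) || beta1 <= 0) {
    abort("`beta1` must be positive (or \"auto\").")
  }
  # pairwise kernel-space distances from the Gram matrix
  kd <- sqrt(pmax(outer(diag(K), diag(K), "+") - 2 * K, 0))
  inside <- kd <= beta1
  opposite <- outer(y, y, "!=")
  rho <- rowSums(inside & opposite) / rowSums(inside)
  nu <- (1 - mu) * rho
  score <- ifelse(nu == 0, mu, rif_score(mu, nu))

  out <- tibble::tibble(.row = seq_along(y), label = as.integer(y),
                        mu = mu, nu = nu, rho = rho,
                        score = score, weight = score)
  attr(out, "ir") <- sum(y == 1) / sum(y == -1)
  attr(out, "scheme") <- "ifsvm"
  attr(out, "beta1") <- beta1
  attr(out, "radius") <- cd$radius
  class(out) <- c("fuzzy_weights", class(out))
  out
}

# center distances when the Gram matrix is already available
kernel_center_distances_from_gram <- function(K, y) {
  d <- numeric(length(y))
  radius <- c(pos = 0, neg = 0)
  for (cl in c(1, -1)) {
    rows <- which(y == cl)
    d2 <- diag(K) + mean(K[rows, rows]) - 2 * rowMeans(K[, rows, drop = FALSE])
    d[rows] <- sqrt(pmax(d2[rows], 0))
    radius[[if (cl == 1) "pos" else "neg"]] <- max(d[rows])
  }
  list(dist = d, radius = radius)
}
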