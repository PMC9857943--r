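#' Neighbor count from the square-root policy
#'
#' The relative-density machinery sets the neighbor index `k` to
#' `ceiling(multiplier * sqrt(N))`, clamped to `[1, N - 1]`. The square-root
#' default balances two failure modes: too small a `k` misses noise, too
#' large a `k` marks normal instances as sparse. The `multiplier` supports
#' sensitivity sweeps around the default.
#'
#' @param N Class size (>= 2).
#' @param multiplier Positive scale factor on `sqrt(N)` (default 1).
#' @return An integer `k` in `[1, N - 1]`.
#' @export
#' @examples
#' k_from_multiplier(100)       # 10
#' k_from_multiplier(100, 1 / 2) # 5
k_from_multiplier <- function(N, multiplier = 1) {
  if (!is.numeric(N) || N < 2) abort("`N` must be at least 2.")
  if (!is.numeric(multiplier) || multiplier <= 0) {
    abort("`multiplier` must be positive.")
  }
  k <- ceiling(multiplier * sqrt(N))
  as.integer(min(max(k, 1), N - 1))
}

#' Distance to the k-th nearest neighbor
#'
#' Euclidean distance from `query` to its k-th closest point in
#' `reference` (ascending order, 1-based). With `exclude_self = TRUE`, one
#' zero-distance copy of the query is removed from the reference first --
#' the convention when the query belongs to the reference set, so that an
#' instance is never its own neighbor.
#'
#' @param query Numeric vector (one point).
#' @param reference Numeric matrix of reference points (rows).
#' @param k Neighbor index (1-based).
#' @param exclude_self Drop one zero-distance reference point first?
#' @return The k-th nearest-neighbor distance (a scalar).
#' @export
kth_nn_distance <- function(query, reference, k, exclude_self = FALSE) {
  reference <- as.matrix(reference)
  d <- sqrt(rowSums(sweep(reference, 2, as.numeric(query))^2))
  if (exclude_self) {
    zero <- which(d < 1e-12)
    if (length(zero) > 0) d <- d[-zero[1]]
  }
  if (k < 1 || k > length(d)) {
    abort("`k` exceeds the usable reference count.")
  }
  sort(d, partial = k)[k]
}

#' Per-instance within- and between-class k-th neighbor distances
#'
#' For every instance, computes its within-class relative-density distance
#' (k-th nearest neighbor inside its own class, self excluded, with that
#' class's `k`) and its between-class distance (k-th nearest neighbor in
#' the opposite class, with the opposite class's `k`). The reciprocal of
#' each distance is the KNN-PDE relative density: sparse instances --
#' noise, outliers -- get large distances and hence low density. Distances
#' are Euclidean in the (normalized) input space.
#'
#' @param data A labeled dataset (both classes of size >= 2).
#' @param multiplier Positive scale on the `sqrt(N)` neighbor policy.
#' @param label_col Name of the label column.
#' @return A tibble of class `"density_profile"` with columns `.row`,
#'   `label`, `d_within`, `d_between`, and attributes `k` (named vector
#'   with the realized `k+`, `k-`) and `normalizers` (class-wise maxima of
#'   the stored distances).
#' @export
density_profile <- function(data, multiplier = 1, label_col = "label") {
  X <- feature_matrix(data, label_col)
  y <- label_vector(data, label_col)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == -1)
  if (n_pos < 2 || n_neg < 2) abort("each class needs at least 2 instances.")
  k_pos <- k_from_multiplier(n_pos, multiplier)
  k_neg <- k_from_multiplier(n_neg, multiplier)

  D <- sqrt(pmax(sqdist(X, X), 0))
  pos <- which(y == 1)
  neg <- which(y == -1)
  kth_rows <- function(rows, cols, k, self) {
    sub <- D[rows, cols, drop = FALSE]
    if (self) sub[cbind(seq_along(rows), match(rows, cols))] <- Inf
    apply(sub, 1, function(d) sort(d, partial = k)[k])
  }
  d_within <- d_between <- numeric(length(y))
  d_within[pos] <- kth_rows(pos, pos, k_pos, self = TRUE)
  d_within[neg] <- kth_rows(neg, neg, k_neg, self = TRUE)
  d_between[pos] <- kth_rows(pos, neg, k_neg, self = FALSE)
  d_between[neg] <- kth_rows(neg, pos, k_pos, self = FALSE)

  out <- tibble::tibble(.row = seq_along(y), label = as.integer(y),
                        d_within = d_within, d_between = d_between)
  attr(out, "k") <- c(pos = k_pos, neg = k_neg)
  attr(out, "normalizers") <- list(
    within = c(pos = max(d_within[pos]), neg = max(d_within[neg])),
    between = c(pos = max(d_between[pos]), neg = max(d_between[neg]))
  )
  class(out) <- c("density_profile", class(out))
  out
}

# pairwise squared Euclidean distances (n x m), clipped at 0 downstream
sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  outer(an, bn, "+") - 2 * tcrossprod(A, B)
}
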