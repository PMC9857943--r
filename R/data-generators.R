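#' Specify a Gaussian cluster group
#'
#' One row of a cluster mixture specification: `n` independent draws from an
#' isotropic Gaussian at `center` with per-axis spread `sd`, carrying class
#' label `label`.
#'
#' @param center Numeric vector, the cluster mean (any dimension `d`).
#' @param sd Positive scalar, the per-axis standard deviation.
#' @param n Positive integer, number of points to draw.
#' @param label Class label, `+1` (minority/positive) or `-1`
#'   (majority/negative).
#' @return A one-row tibble with a list-column `center` and columns
#'   `sd`, `n`, `label`. Rows from several calls can be stacked with
#'   [dplyr::bind_rows()] to form a mixture specification.
#' @seealso [gen_clusters()], [synth_data1()]
#' @export
#' @examples
#' spec <- dplyr::bind_rows(
#'   cluster_spec(c(0, 0), 0.1, 50, -1),
#'   cluster_spec(c(1, 1), 0.1, 10, +1)
#' )
#' gen_clusters(spec, seed = 1)
cluster_spec <- function(center, sd, n, label) {
  stopifnot(is.numeric(center), length(center) >= 1)
  if (!is.numeric(sd) || length(sd) != 1 || sd <= 0) {
    abort("`sd` must be a positive scalar.")
  }
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer.")
  }
  if (!label %in% c(-1, 1)) abort("`label` must be +1 or -1.")
  tibble::tibble(center = list(as.numeric(center)), sd = sd,
                 n = as.integer(n), label = as.integer(label))
}

#' Generate an isotropic Gaussian cluster mixture
#'
#' Draws each group of a [cluster_spec()] stack independently and returns a
#' labeled dataset. Deterministic given `seed`.
#'
#' @param spec Tibble of cluster rows, as built by [cluster_spec()].
#' @param seed Integer seed; the global RNG state is restored on exit.
#' @return A tibble with feature columns `x1 ... xd` and an integer `label`
#'   column over `{+1, -1}`.
#' @export
gen_clusters <- function(spec, seed) {
  validate_cluster_spec(spec)
  d <- length(spec$center[[1]])
  withr::with_seed(seed, {
    parts <- purrr::pmap(spec, function(center, sd, n, label) {
      x <- matrix(rnorm(n * d, sd = sd), nrow = n, ncol = d, byrow = TRUE)
      x <- sweep(x, 2, center, "+")
      cbind(x, label)
    })
  })
  mat_to_dataset(do.call(rbind, parts), d)
}

validate_cluster_spec <- function(spec) {
  if (!is.data.frame(spec) || nrow(spec) == 0 ||
      !all(c("center", "sd", "n", "label") %in% names(spec))) {
    abort("`spec` must be a tibble of cluster_spec() rows.")
  }
  dims <- lengths(spec$center)
  if (length(unique(dims)) != 1) abort("all cluster centers must share a dimension.")
  if (any(spec$sd <= 0)) abort("cluster spreads must be positive.")
  if (any(spec$n < 1)) abort("cluster counts must be positive.")
  invisible(spec)
}

#' Specify one ring of a concentric-rings dataset
#'
#' @param inner Positive inner radius of the annulus.
#' @param width Non-negative radial width of the annulus.
#' @param n Positive integer count of points.
#' @param label Class label, `+1` or `-1`.
#' @param center Length-2 numeric ring center (default the origin).
#' @return A one-row tibble; stack rows with [dplyr::bind_rows()].
#' @seealso [gen_rings()], [synth_data2()]
#' @export
ring_spec <- function(inner, width, n, label, center = c(0, 0)) {
  if (!is.numeric(inner) || inner <= 0) abort("`inner` radius must be positive.")
  if (!is.numeric(width) || width < 0) abort("`width` must be non-negative.")
  if (!is.numeric(n) || n < 1 || n != round(n)) abort("`n` must be a positive integer.")
  if (!label %in% c(-1, 1)) abort("`label` must be +1 or -1.")
  stopifnot(length(center) == 2, all(is.finite(center)))
  tibble::tibble(inner = inner, width = width, n = as.integer(n),
                 label = as.integer(label), center = list(as.numeric(center)))
}

#' Generate a concentric-rings dataset
#'
#' For each ring, the angle is uniform on `[0, 2*pi)` and the radius uniform
#' on `[inner, inner + width]` -- the simplest sampling law consistent with a
#' ring of fixed width. Deterministic given `seed`.
#'
#' @param spec Tibble of [ring_spec()] rows.
#' @param seed Integer seed.
#' @return A tibble with columns `x1`, `x2`, `label`.
#' @export
gen_rings <- function(spec, seed) {
  if (!is.data.frame(spec) || nrow(spec) == 0 ||
      !all(c("inner", "width", "n", "label", "center") %in% names(spec))) {
    abort("`spec` must be a tibble of ring_spec() rows.")
  }
  withr::with_seed(seed, {
    parts <- purrr::pmap(spec, function(inner, width, n, label, center) {
      theta <- runif(n, 0, 2 * pi)
      r <- runif(n, inner, inner + width)
      cbind(center[1] + r * cos(theta), center[2] + r * sin(theta), label)
    })
  })
  mat_to_dataset(do.call(rbind, parts), 2L)
}

#' Synthetic preset: three-cluster Gaussian mixture ("Data1")
#'
#' An imbalanced two-class dataset of three isotropic Gaussian groups in 2-D:
#' 800 negative points at (0.4, 0.4) and two positive groups of 50 and 150
#' points at (0.15, 0.15) and (0.7, 0.7), all with per-axis spread 0.1. The
#' positive class (200 points) forms small disjunct clusters, giving a 1:4
#' minority-to-majority ratio with class overlap -- the configuration under
#' which centroid-based fuzzy memberships mis-weight the small cluster.
#'
#' @param seed Integer seed.
#' @return A tibble with columns `x1`, `x2`, `label`.
#' @export
#' @examples
#' d1 <- synth_data1(seed = 1)
#' table(d1$label)
synth_data1 <- function(seed) {
  spec <- dplyr::bind_rows(
    cluster_spec(c(0.40, 0.40), 0.1, 800, -1),
    cluster_spec(c(0.15, 0.15), 0.1, 50, +1),
    cluster_spec(c(0.70, 0.70), 0.1, 150, +1)
  )
  gen_clusters(spec, seed)
}

#' Synthetic preset: concentric rings ("Data2")
#'
#' Two concentric annuli centered at the origin with radial width 0.2: the
#' negative (majority) ring has inner radius 0.6, the positive (minority)
#' ring inner radius 0.3, so the classes are separated by a 0.1 radial gap.
#' Default counts 100 positive / 500 negative give the 1:5 imbalance ratio.
#' A manifold-distributed geometry on which class centroids are
#' uninformative (both fall at the origin).
#'
#' @param seed Integer seed.
#' @param n_pos,n_neg Class counts (kept at a 1:5 ratio by default).
#' @return A tibble with columns `x1`, `x2`, `label`.
#' @export
synth_data2 <- function(seed, n_pos = 100, n_neg = 500) {
  spec <- dplyr::bind_rows(
    ring_spec(inner = 0.6, width = 0.2, n = n_neg, label = -1),
    ring_spec(inner = 0.3, width = 0.2, n = n_pos, label = +1)
  )
  gen_rings(spec, seed)
}

mat_to_dataset <- function(mat, d) {
  colnames(mat) <- c(paste0("x", seq_len(d)), "label")
  out <- tibble::as_tibble(as.data.frame(mat))
  out$label <- as.integer(out$label)
  out
}
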