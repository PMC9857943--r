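# Small data builders shared across tests. Everything is generated in code;
# seeds are fixed so the suite is deterministic.

# two tight, well-separated clusters (gap >> cluster diameter)
separated_clusters <- function(seed = 1, n_pos = 12, n_neg = 30) {
  spec <- dplyr::bind_rows(
    cluster_spec(c(0, 0), 0.05, n_neg, -1),
    cluster_spec(c(5, 5), 0.05, n_pos, +1)
  )
  gen_clusters(spec, seed)
}

# small imbalanced overlapping dataset for property checks
random_dataset <- function(seed, n_pos = 15, n_neg = 45, sd = 0.5) {
  spec <- dplyr::bind_rows(
    cluster_spec(c(0, 0), sd, n_neg, -1),
    cluster_spec(c(1, 1), sd, n_pos, +1)
  )
  gen_clusters(spec, seed)
}

# brute-force k-th NN distance: full pairwise sort, no partial tricks
brute_kth <- function(q, ref, k, exclude_self = FALSE) {
  d <- sort(apply(ref, 1, function(r) sqrt(sum((r - q)^2))))
  if (exclude_self) d <- d[-1]
  d[k]
}

# dual objective value for a candidate alpha
dual_objective <- function(alpha, K, y) {
  sum(alpha) - 0.5 * drop(t(alpha * y) %*% K %*% (alpha * y))
}
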