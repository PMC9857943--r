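#' Read a dataset-by-algorithm score table
#'
#' @param path CSV with one row per dataset: a first `dataset` column of
#'   row labels, then one numeric column per algorithm.
#' @return A tibble with the `dataset` column and algorithm score columns.
#' @export
read_score_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(tab)[1] <- "dataset"
  stopifnot(nrow(tab) >= 2, ncol(tab) >= 3)
  tab
}

#' Packaged benchmark score tables
#'
#' Published percent-scale scores of eight imbalance-learning algorithms
#' (six fuzzy-SVM comparison methods, the IFSVM baseline, and RIFSVM) on
#' twenty KEEL/UCI benchmark datasets, one table per metric. These scores
#' are consumed as fixed inputs by the rank-based comparison machinery;
#' the benchmark runs themselves are not reproduced here.
#'
#' @param metric One of `"gmean"`, `"fmeasure"`, `"auc"`.
#' @return A 20-row tibble with a `dataset` column and eight algorithm
#'   columns.
#' @export
#' @examples
#' colMeans(rank_table(benchmark_scores("gmean")))
benchmark_scores <- function(metric = c("gmean", "fmeasure", "auc")) {
  metric <- match.arg(metric)
  read_score_table(system.file("extdata",
                               paste0("benchmark_", metric, ".csv"),
                               package = "rifsvm", mustWork = TRUE))
}

#' Row-wise ranks of a score table
#'
#' Ranks the algorithms within each dataset row, best = 1 (respecting
#' `higher_better`); tied scores receive the mean of the ranks they span,
#' so every row's ranks sum to `k (k + 1) / 2`.
#'
#' @param scores A score table from [read_score_table()] /
#'   [benchmark_scores()], or a bare numeric matrix (datasets x
#'   algorithms).
#' @param higher_better Is a larger score better?
#' @return A numeric matrix of ranks with the same shape and dimnames.
#' @export
rank_table <- function(scores, higher_better = TRUE) {
  m <- score_matrix(scores)
  sgn <- if (higher_better) -1 else 1
  t(apply(m, 1, function(r) rank(sgn * r, ties.method = "average")))
}

score_matrix <- function(scores) {
  if (is.data.frame(scores)) {
    rn <- if ("dataset" %in% names(scores)) scores$dataset else NULL
    m <- as.matrix(scores[setdiff(names(scores), "dataset")])
    rownames(m) <- rn
  } else {
    m <- as.matrix(scores)
  }
  if (anyNA(m)) abort("score table has missing cells.")
  m
}

#' Friedman test on a rank matrix
#'
#' The chi-square form of the Friedman statistic over `n` datasets and `k`
#' algorithms, `12 n / (k (k + 1)) * (sum r_i^2 - k (k + 1)^2 / 4)` with
#' `r_i` the column mean ranks, and its less conservative F-distributed
#' form `tau_F = (n - 1) chi^2 / (n (k - 1) - chi^2)` with
#' `(k - 1, (k - 1)(n - 1))` degrees of freedom, used to decide whether
#' the algorithms perform equally.
#'
#' @param ranks A rank matrix from [rank_table()] (datasets x algorithms).
#' @param alpha Significance level for the F-test decision.
#' @return A list of class `"friedman_result"`: `avg_ranks`, `chi_sq`,
#'   `tau_f`, `df1`, `df2`, `f_crit`, `reject`, `n`, `k`.
#' @export
friedman_rank_test <- function(ranks, alpha = 0.05) {
  m <- score_matrix(ranks)
  n <- nrow(m)
  k <- ncol(m)
  r <- colMeans(m)
  chi_sq <- 12 * n / (k * (k + 1)) * (sum(r^2) - k * (k + 1)^2 / 4)
  denom <- n * (k - 1) - chi_sq
  if (denom <= 0) {
    abort("degenerate rank matrix: Friedman statistic at its upper limit.")
  }
  tau_f <- (n - 1) * chi_sq / denom
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  f_crit <- qf(1 - alpha, df1, df2)
  structure(list(avg_ranks = r, chi_sq = chi_sq, tau_f = tau_f,
                 df1 = df1, df2 = df2, f_crit = f_crit,
                 reject = tau_f > f_crit, alpha = alpha, n = n, k = k),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman test: chi^2 = %.4f, tau_F = %.4f (F(%d, %d))\n",
              x$chi_sq, x$tau_f, x$df1, x$df2))
  cat(sprintf("  critical value %.4f at alpha = %g -> %s\n", x$f_crit,
              x$alpha,
              if (x$reject) "reject equal performance" else "no rejection"))
  invisible(x)
}

# Nemenyi constants q_alpha (studentized range / sqrt(2)), k = 2..10,
# as tabulated in Demsar's classifier-comparison methodology
q_nemenyi <- list(
  "0.05" = c(1.960, 2.343, 2.569, 2.728, 2.850, 2.949, 3.031, 3.102, 3.164),
  "0.1"  = c(1.645, 2.052, 2.291, 2.459, 2.589, 2.693, 2.780, 2.855, 2.920))

#' Nemenyi critical difference
#'
#' The minimum gap between two algorithms' average ranks declared
#' significant by the Nemenyi post-hoc test:
#' `CD = q_alpha * sqrt(k (k + 1) / (6 n))`.
#'
#' @param k Number of algorithms (2..10, tabulated `q`).
#' @param n Number of datasets.
#' @param alpha Significance level, 0.05 or 0.10.
#' @return The critical difference (scalar).
#' @export
#' @examples
#' nemenyi_cd(k = 8, n = 20)  # 2.3478
nemenyi_cd <- function(k, n, alpha = 0.05) {
  stopifnot(k >= 2, n >= 1)
  qs <- q_nemenyi[[as.character(alpha)]]
  if (is.null(qs) || k > 10) {
    abort("tabulated q values cover alpha in {0.05, 0.1} and k in 2..10.")
  }
  qs[k - 1] * sqrt(k * (k + 1) / (6 * n))
}

#' Pairwise Nemenyi comparison of average ranks
#'
#' @param avg_ranks Named vector of average ranks (one per algorithm).
#' @param n Number of datasets the ranks were averaged over.
#' @param alpha Significance level, 0.05 or 0.10.
#' @return A list of class `"nemenyi_result"`: `cd`, `alpha`, and a
#'   logical `significant` matrix with `|r_i - r_j| > CD`.
#' @export
nemenyi_test <- function(avg_ranks, n, alpha = 0.05) {
  cd <- nemenyi_cd(length(avg_ranks), n, alpha)
  diff <- abs(outer(avg_ranks, avg_ranks, "-"))
  structure(list(cd = cd, alpha = alpha, significant = diff > cd),
            class = "nemenyi_result")
}

#' Full rank-based comparison report
#'
#' For each metric's score table: tie-averaged ranks, the Friedman
#' decision, and the Nemenyi critical difference with the pairwise
#' significance matrix. Use [write_report()] to serialize as JSON.
#'
#' @param tables Named list of score tables (one per metric).
#' @param alpha Significance level.
#' @param higher_better Is a larger score better?
#' @return A list of class `"compare_report"`, one sub-report per metric.
#' @export
#' @examples
#' rep <- compare_report(list(gmean = benchmark_scores("gmean")))
#' rep$gmean$friedman$avg_ranks
compare_report <- function(tables, alpha = 0.05, higher_better = TRUE) {
  out <- lapply(tables, function(tab) {
    ranks <- rank_table(tab, higher_better)
    fr <- friedman_rank_test(ranks, alpha)
    nm <- nemenyi_test(fr$avg_ranks, fr$n, alpha)
    list(avg_ranks = fr$avg_ranks, friedman = fr, nemenyi = nm)
  })
  structure(out, class = "compare_report")
}

#' Serialize a comparison report to JSON
#'
#' @param report A [compare_report()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  ser <- lapply(unclass(report), function(m) {
    list(avg_ranks = as.list(m$friedman$avg_ranks),
         chi_sq = m$friedman$chi_sq, tau_f = m$friedman$tau_f,
         f_crit = m$friedman$f_crit, reject = m$friedman$reject,
         cd = m$nemenyi$cd,
         significant = m$nemenyi$significant)
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
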