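#' Confusion counts with the minority class as positive
#'
#' @param truth True labels over `{+1, -1}` (+1 = minority).
#' @param pred Predicted labels over `{+1, -1}`.
#' @return A one-row tibble with integer columns `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tibble::tibble(
    tp = sum(truth == 1 & pred == 1), fn = sum(truth == 1 & pred == -1),
    tn = sum(truth == -1 & pred == -1), fp = sum(truth == -1 & pred == 1))
}

#' Imbalance-aware classification metrics (percent scale)
#'
#' Sensitivity (minority recall), specificity (majority recall), their
#' geometric mean (G-Mean), and the F-Measure (harmonic mean of minority
#' precision and recall), all on the 0-100 percent scale. An empty
#' predicted-positive set yields precision 0 and hence F-Measure 0.
#'
#' @param truth True labels over `{+1, -1}`; both classes must be present.
#' @param pred Predicted labels over `{+1, -1}`.
#' @return A one-row tibble with columns `se`, `sp`, `g_mean`, `f_measure`.
#' @export
#' @examples
#' classification_metrics(c(1, 1, -1, -1), c(1, -1, -1, -1))
classification_metrics <- function(truth, pred) {
  if (!any(truth == 1) || !any(truth == -1)) {
    abort("both classes must be present in `truth`.")
  }
  cc <- confusion_counts(truth, pred)
  se <- cc$tp / (cc$tp + cc$fn)
  sp <- cc$tn / (cc$tn + cc$fp)
  prec <- if (cc$tp + cc$fp == 0) 0 else cc$tp / (cc$tp + cc$fp)
  f <- if (prec + se == 0) 0 else 2 * prec * se / (prec + se)
  out <- c(se = se, sp = sp, g_mean = sqrt(se * sp), f_measure = f)
  tibble::as_tibble(as.list(100 * out))
}

#' AUC from decision values (percent scale)
#'
#' The Mann-Whitney rank formulation of the area under the ROC curve over
#' continuous decision values, with ties counted one half: the fraction of
#' minority/majority pairs ranked in the correct order. Invariant under
#' any strictly increasing transform of the scores.
#'
#' @param truth True labels over `{+1, -1}`; both classes must be present.
#' @param scores Continuous decision values (higher = more positive).
#' @return The AUC on the 0-100 percent scale.
#' @export
auc_score <- function(truth, scores) {
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == -1)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present in `truth`.")
  r <- rank(scores, ties.method = "average")
  100 * (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
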