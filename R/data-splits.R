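#' Stratified train/test split
#'
#' Randomly partitions row indices at the given training fraction within
#' each class, so both parts preserve the class proportions (per-class
#' rounding). Deterministic given `seed`.
#'
#' @param data A labeled dataset.
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param label_col Name of the label column.
#' @return A list with integer vectors `train` and `test` (a partition of
#'   `1:nrow(data)`), of class `"split_plan"`.
#' @export
stratified_split <- function(data, train_frac = 0.8, seed = 1,
                             label_col = "label") {
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    abort("`train_frac` must lie strictly between 0 and 1.")
  }
  y <- label_vector(data, label_col)
  idx <- withr::with_seed(seed, {
    lapply(c(1, -1), function(cl) {
      rows <- which(y == cl)
      n_tr <- round(length(rows) * train_frac)
      if (n_tr < 1 || n_tr >= length(rows)) {
        abort(paste0("class ", cl, " too small to appear in both parts."))
      }
      sample(rows)[seq_len(n_tr)]
    })
  })
  train <- sort(c(idx[[1]], idx[[2]]))
  structure(list(train = train, test = setdiff(seq_len(nrow(data)), train),
                 seed = seed),
            class = "split_plan")
}

#' Stratified k-fold assignment
#'
#' Assigns each row to one of `folds` cross-validation folds by per-class
#' round-robin after a seeded shuffle, so every fold carries both classes
#' in near-equal proportion. Deterministic given `seed`.
#'
#' @param data A labeled dataset.
#' @param folds Number of folds (>= 2; each class must have at least
#'   `folds` instances).
#' @param seed Integer seed.
#' @param label_col Name of the label column.
#' @return An integer vector of fold ids in `1:folds`, one per row.
#' @export
stratified_kfold <- function(data, folds = 5, seed = 1, label_col = "label") {
  if (folds < 2) abort("`folds` must be at least 2.")
  y <- label_vector(data, label_col)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in c(1, -1)) {
      rows <- which(y == cl)
      if (length(rows) < folds) {
        abort(paste0("class ", cl, " has fewer instances than folds."))
      }
      fold[sample(rows)] <- rep_len(seq_len(folds), length(rows))
    }
  })
  fold
}
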