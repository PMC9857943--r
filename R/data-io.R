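#' Read a delimited labeled dataset and map classes to +1/-1
#'
#' Loads a delimited text file (comma or tab, sniffed from the header line),
#' maps the designated label classes onto the `{+1, -1}` convention used
#' throughout the package (+1 = minority/positive), and drops rows whose
#' label falls in neither set. Mirrors the one-vs-rest groupings commonly
#' used to carve imbalanced binary problems out of multiclass benchmarks.
#'
#' @param path Path to a delimited text file with a header row.
#' @param label_col Name of the label column.
#' @param positive Character/numeric vector of label values mapped to `+1`.
#' @param negative Vector of label values mapped to `-1`, or `"rest"`
#'   (default) to map every non-positive value.
#' @return A tibble with numeric feature columns and an integer `label`
#'   column over `{+1, -1}`.
#' @export
read_labeled_data <- function(path, label_col, positive, negative = "rest") {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!label_col %in% names(raw)) {
    abort(paste0("label column '", label_col, "' not found in ", path))
  }
  lab <- as.character(raw[[label_col]])
  positive <- as.character(positive)
  rest <- !identical(negative, "rest")
  negative <- if (rest) as.character(negative) else setdiff(unique(lab), positive)
  if (length(intersect(positive, negative)) > 0) {
    abort("positive and negative class sets overlap.")
  }
  keep <- lab %in% c(positive, negative)
  features <- raw[keep, setdiff(names(raw), label_col), drop = FALSE]
  bad <- names(features)[!vapply(features, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste("non-numeric feature column(s):", paste(bad, collapse = ", ")))
  }
  y <- ifelse(lab[keep] %in% positive, 1L, -1L)
  if (sum(y == 1) == 0) abort("positive class is empty after mapping.")
  if (sum(y == -1) == 0) abort("negative class is empty after mapping.")
  out <- tibble::as_tibble(features)
  out$label <- y
  out
}

#' Min-max normalize feature columns to [0, 1]
#'
#' Affinely maps each feature column so its minimum becomes 0 and its
#' maximum 1; constant columns map to all zeros. The label column is left
#' untouched. With `params`, applies a previously fitted mapping instead
#' (for fold-safe normalization: fit on training data, apply to test data).
#'
#' @param data A labeled dataset (tibble with a label column).
#' @param label_col Name of the label column.
#' @param params Optional result of [minmax_params()] fitted on other data.
#' @return A tibble of the same shape with rescaled features.
#' @export
#' @examples
#' d <- tibble::tibble(x1 = c(2, 4, 6), label = c(1L, -1L, 1L))
#' minmax_normalize(d)$x1
minmax_normalize <- function(data, label_col = "label", params = NULL) {
  feats <- setdiff(names(data), label_col)
  if (is.null(params)) params <- minmax_params(data, label_col)
  for (f in feats) {
    rng <- params[[f]]
    span <- rng[2] - rng[1]
    data[[f]] <- if (span > 0) (data[[f]] - rng[1]) / span else rep(0, nrow(data))
  }
  data
}

#' Fit a min-max normalization mapping
#'
#' @inheritParams minmax_normalize
#' @return A named list of `c(min, max)` per feature column, for use as the
#'   `params` argument of [minmax_normalize()].
#' @export
minmax_params <- function(data, label_col = "label") {
  feats <- setdiff(names(data), label_col)
  lapply(stats::setNames(feats, feats), function(f) range(data[[f]]))
}

# feature matrix + label vector accessors used across the package
feature_matrix <- function(data, label_col = "label") {
  feats <- setdiff(names(data), label_col)
  m <- as.matrix(data[feats])
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) abort("all feature values must be finite.")
  m
}

label_vector <- function(data, label_col = "label") {
  y <- data[[label_col]]
  if (is.null(y)) abort(paste0("label column '", label_col, "' not found."))
  if (!all(y %in% c(-1, 1))) abort("labels must be +1 or -1.")
  as.numeric(y)
}
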