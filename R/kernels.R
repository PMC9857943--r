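#' Kernel specifications
#'
#' Constructors for the kernels used by the weighted SVM. The Gaussian
#' (RBF) kernel is `K(x, x') = exp(-h * ||x - x'||^2)` with spread
#' parameter `h > 0`; the linear kernel is the plain inner product.
#'
#' @param h Positive RBF spread parameter.
#' @return A list of class `"kernel_spec"`.
#' @name kernel_spec
NULL

#' @rdname kernel_spec
#' @export
rbf_kernel <- function(h = 1) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0) {
    abort("`h` must be a positive scalar.")
  }
  structure(list(kind = "rbf", h = h), class = "kernel_spec")
}

#' @rdname kernel_spec
#' @export
linear_kernel <- function() {
  structure(list(kind = "linear", h = NA_real_), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$kind == "rbf") {
    cat(sprintf("RBF kernel, h = %g\n", x$h))
  } else {
    cat("Linear kernel\n")
  }
  invisible(x)
}

#' Gram matrix between two point sets
#'
#' @param X Numeric matrix of points (rows), or a data frame of features.
#' @param Y Optional second point set; defaults to `X` (square self-Gram).
#' @param kernel A [kernel_spec].
#' @return The `nrow(X) x nrow(Y)` kernel matrix.
#' @export
#' @examples
#' X <- matrix(rnorm(10), 5, 2)
#' diag(kernel_matrix(X, kernel = rbf_kernel(2)))  # all ones
kernel_matrix <- function(X, Y = NULL, kernel = rbf_kernel(1)) {
  X <- as.matrix(X)
  Y <- if (is.null(Y)) X else as.matrix(Y)
  if (ncol(X) != ncol(Y)) abort("point sets differ in dimensionality.")
  switch(kernel$kind,
    rbf = exp(-kernel$h * pmax(sqdist(X, Y), 0)),
    linear = tcrossprod(X, Y),
    abort(paste("unknown kernel kind:", kernel$kind)))
}
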