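# Small numerical helpers shared across modules.

#' Geometric mean
#'
#' @param x numeric vector, all values strictly positive.
#' @return The geometric mean of `x`.
#' @keywords internal
geomMean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

#' Shifted log2 transform
#'
#' `log2(x + offset)`, the transform used throughout the concordance and
#' cell-scoring stages. The default offset of 1 keeps zero counts at zero.
#'
#' @param x numeric vector or matrix of non-negative values.
#' @param offset non-negative shift added before taking logs.
#' @return Transformed values, same shape as `x`.
#' @export
log2p <- function(x, offset = 1) {
  if (offset < 0) stop("offset must be non-negative")
  if (offset == 0 && any(x <= 0)) {
    stop("offset 0 requires strictly positive values")
  }
  log2(x + offset)
}

# counts must be whole numbers >= 0 (stored as numeric for convenience)
checkCountMatrix <- function(m, what = "counts") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix")
  }
  if (anyNA(m)) stop(what, " must not contain NA")
  if (any(m < 0)) stop(what, " must be non-negative")
  if (any(m != round(m))) stop(what, " must be integral")
  invisible(TRUE)
}

# column-wise sample SD (n - 1 denominator) without loops
colSds <- function(m) {
  n <- nrow(m)
  if (n < 2) stop("need at least 2 rows for a sample SD")
  mu <- colMeans(m)
  sqrt(colSums((m - rep(mu, each = n))^2) / (n - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
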