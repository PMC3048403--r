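# Trimmed-mean array scaling: each array is multiplied by a scalar so that
# its trimmed mean equals a fixed target intensity, permitting inter-array
# comparison on the linear fluorescence scale.

#' Trimmed mean of a vector
#'
#' Discards the \code{floor(trim * n)} smallest and largest values and
#' averages the rest (the MAS-style two-sided trim).
#'
#' @param x numeric vector.
#' @param trim proportion removed from each tail, in [0, 0.5).
#' @return The trimmed mean.
#' @export
trimmedMean <- function(x, trim = 0.02) {
  stopifnot(is.numeric(x), length(x) > 0, trim >= 0, trim < 0.5)
  mean(x, trim = trim)
}

#' Scale arrays to a common trimmed mean
#'
#' Each column (array) is independently multiplied by a scalar so that its
#' trimmed mean equals \code{targetMean} intensity units. Because a positive
#' rescaling preserves the order statistics, the set of trimmed observations
#' is unchanged and the post-scaling trimmed mean matches the target to
#' floating-point precision.
#'
#' @param x a \link{StageExpressionSet} or a numeric matrix with arrays in
#'   columns.
#' @param targetMean target trimmed mean in intensity units (default 500).
#' @param trim proportion trimmed from each tail (default 0.02).
#' @return Object of the same class as \code{x} with scaled intensities.
#' @examples
#' m <- matrix(c(1:10, 2 * (1:10)), ncol = 2,
#'             dimnames = list(paste0("p", 1:10), c("a", "b")))
#' colMeans(scaleTrimmedMean(m))  # both columns now share a trimmed mean
#' @export
scaleTrimmedMean <- function(x, targetMean = 500, trim = 0.02) {
  stopifnot(targetMean > 0, trim >= 0, trim < 0.5)
  if (is(x, "StageExpressionSet")) {
    v <- intensities(x)
    scaled <- scaleTrimmedMean(v, targetMean = targetMean, trim = trim)
    SummarizedExperiment::assay(x, "exprs") <- scaled
    return(x)
  }
  v <- as.matrix(x)
  tm <- apply(v, 2, trimmedMean, trim = trim)
  bad <- which(!is.finite(tm) | tm <= 0)
  if (length(bad))
    stop(sprintf("degenerate array '%s': non-positive trimmed mean",
                 colnames(v)[bad[1]] %||% bad[1]))
  sweep(v, 2, targetMean / tm, "*")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
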