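# Statistics for the bench validation assays: delta-delta-Ct relative
# quantification for qPCR, densitometry percent-of-control for western
# blots, and fluorescence-per-cell with quotient propagation of error for
# the filamentous-actin assay.

#' Relative expression fold by the delta-delta-Ct method
#'
#' Given per-sample delta-Ct values (target Ct minus reference-gene Ct),
#' computes \eqn{\Delta\Delta Ct = \overline{\Delta Ct}_{test} -
#' \overline{\Delta Ct}_{control}} and the relative fold
#' \eqn{2^{-\Delta\Delta Ct}}. Significance is a two-sided two-sample
#' t-test on the delta-Ct values (reported only when both groups have at
#' least two values).
#'
#' @param testDcts,controlDcts numeric vectors of delta-Ct values (cycles).
#' @param variant t-test variant passed to \code{\link{tTestTwoSample}}.
#' @return list with \code{ddct}, \code{fold} and \code{p} (NA when a
#'   group has fewer than 2 values).
#' @examples
#' ddctFold(c(4, 4, 4), c(6, 6, 6))$fold  # 4
#' @export
ddctFold <- function(testDcts, controlDcts, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (!length(testDcts) || !length(controlDcts))
    stop("each group needs at least one delta-Ct value")
  if (any(!is.finite(c(testDcts, controlDcts))))
    stop("delta-Ct values must be finite")
  ddct <- mean(testDcts) - mean(controlDcts)
  p <- if (length(testDcts) >= 2 && length(controlDcts) >= 2)
    tTestTwoSample(testDcts, controlDcts, variant) else NA_real_
  list(ddct = ddct, fold = 2^(-ddct), p = p)
}

#' Delta-delta-Ct folds from a Ct table
#'
#' Convenience wrapper taking raw cycle-threshold values: computes
#' per-sample delta-Ct as \code{Ct_target - Ct_reference}, then
#' \code{\link{ddctFold}} per gene between a test and a control group.
#'
#' @param ct data.frame with columns \code{group}, \code{Ct_target},
#'   \code{Ct_reference}, and optionally \code{gene} (one comparison per
#'   gene when present).
#' @param testGroup,controlGroup group labels to compare.
#' @param variant t-test variant.
#' @return data.frame with one row per gene: \code{gene}, \code{ddct},
#'   \code{fold}, \code{p}.
#' @export
ddctFromCt <- function(ct, testGroup, controlGroup,
                       variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  ct <- as.data.frame(ct)
  stopifnot(all(c("group", "Ct_target", "Ct_reference") %in% colnames(ct)))
  if (any(!is.finite(ct$Ct_target)) || any(!is.finite(ct$Ct_reference)) ||
      any(ct$Ct_target <= 0) || any(ct$Ct_reference <= 0))
    stop("Ct values must be positive and finite")
  ct$dct <- ct$Ct_target - ct$Ct_reference
  genes <- if ("gene" %in% colnames(ct)) unique(ct$gene) else NA_character_
  rows <- lapply(genes, function(g) {
    sub <- if (is.na(g)) ct else ct[ct$gene == g, , drop = FALSE]
    res <- ddctFold(sub$dct[sub$group == testGroup],
                    sub$dct[sub$group == controlGroup], variant)
    data.frame(gene = g, ddct = res$ddct, fold = res$fold, p = res$p)
  })
  do.call(rbind, rows)
}

#' Densitometry as percent of the control group
#'
#' Normalizes each band intensity to its loading-control intensity and
#' expresses the ratio as a percentage of the control group's mean ratio,
#' so the control group averages exactly 100.
#'
#' @param bands numeric band intensities (relative optical units).
#' @param loading matched loading-control intensities (must be positive).
#' @param controlIdx logical or integer index selecting the control-group
#'   measurements.
#' @return Numeric vector of percent-of-control values parallel to
#'   \code{bands}.
#' @export
densitometryPercent <- function(bands, loading, controlIdx) {
  if (length(bands) != length(loading))
    stop("band and loading-control intensities must be matched pairs")
  if (any(!is.finite(loading)) || any(loading <= 0))
    stop("loading-control intensities must be positive")
  if (any(!is.finite(bands)) || any(bands <= 0))
    stop("band intensities must be positive")
  ratio <- bands / loading
  ctrl <- ratio[controlIdx]
  if (!length(ctrl)) stop("control group is empty")
  100 * ratio / mean(ctrl)
}

#' Fluorescence per cell with quotient propagation of error
#'
#' For well-level fluorescence readings \code{x} and parallel cell counts
#' \code{y}, reports \eqn{\bar z = \bar x / \bar y} (relative fluorescence
#' units per cell) with uncertainty from the standard quotient
#' propagation-of-error formula
#' \eqn{\sigma_z = \bar z \sqrt{(\sigma_x/\bar x)^2 + (\sigma_y/\bar y)^2}},
#' where \eqn{\sigma} is the sample (n-1) standard deviation.
#'
#' @param fluorValues numeric fluorescence replicate values (RFU), >= 2.
#' @param cellCounts numeric cell-count replicate values, positive, >= 2.
#' @return list with \code{mean} (RFU per cell) and \code{sd}.
#' @examples
#' factinPerCell(c(900, 1000, 1100), c(90, 100, 110))
#' @export
factinPerCell <- function(fluorValues, cellCounts) {
  if (length(fluorValues) < 2 || length(cellCounts) < 2)
    stop("need at least 2 replicate values per input")
  if (any(cellCounts <= 0)) stop("cell counts must be positive")
  xbar <- mean(fluorValues)
  ybar <- mean(cellCounts)
  zbar <- xbar / ybar
  sz <- zbar * sqrt((stats::sd(fluorValues) / xbar)^2 +
                    (stats::sd(cellCounts) / ybar)^2)
  list(mean = zbar, sd = sz)
}
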