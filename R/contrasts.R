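# Pairwise stage statistics per probe: signed fold changes and two-sample
# t-tests on the linear intensity scale, followed by the expression /
# fold-change / significance filter that defines the differentially
# expressed probe set.

#' Signed fold change
#'
#' The published-table convention: the ratio \code{test/ref} when it is at
#' least 1, otherwise the negative reciprocal, so the magnitude is always
#' the fold ratio and the sign the direction (\code{-4} means 4-fold lower).
#'
#' @param meanTest,meanRef positive group means (vectorized).
#' @return Signed fold change with magnitude >= 1.
#' @examples
#' signedFoldChange(800, 400)  # +2
#' signedFoldChange(100, 400)  # -4
#' @export
signedFoldChange <- function(meanTest, meanRef) {
  if (any(!is.finite(meanTest)) || any(!is.finite(meanRef)) ||
      any(meanTest <= 0) || any(meanRef <= 0))
    stop("signed fold change requires positive, finite means")
  r <- meanTest / meanRef
  ifelse(r >= 1, r, -1 / r)
}

#' Two-sample t-test p-value with degenerate-variance convention
#'
#' Two-sided p-value from the pooled (homoscedastic, the default, mirroring
#' a spreadsheet two-sample test) or Welch two-sample t statistic. When the
#' pooled variance is exactly zero the p-value is 1 for equal means and 0
#' otherwise, so constant probes are handled deterministically.
#'
#' @param groupA,groupB numeric vectors with at least 2 values each.
#' @param variant \code{"pooled"} (default) or \code{"welch"}.
#' @return Two-sided p-value.
#' @export
tTestTwoSample <- function(groupA, groupB, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  if (var(groupA) == 0 && var(groupB) == 0)
    return(if (mean(groupA) == mean(groupB)) 1 else 0)
  t.test(groupA, groupB, var.equal = (variant == "pooled"))$p.value
}

# vectorized row-wise two-sample t on summary statistics
.rowTTestP <- function(ma, va, na, mb, vb, nb, variant = "pooled") {
  if (variant == "pooled") {
    s2 <- (va * (na - 1) + vb * (nb - 1)) / (na + nb - 2)
    se <- sqrt(s2 * (1 / na + 1 / nb))
    df <- rep_len(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  p <- 2 * pt(abs(ma - mb) / se, df, lower.tail = FALSE)
  zero <- se == 0 | !is.finite(se)
  if (any(zero)) p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  p
}

#' Per-probe pairwise stage contrasts
#'
#' For every probe set, computes signed fold changes and two-sample t-test
#' p-values for the intermediate-vs-early (\code{IE}), late-vs-early
#' (\code{LE}) and late-vs-intermediate (\code{IL}) comparisons on the
#' linear intensity scale, plus the maximum intensity across all arrays
#' (used by the expression filter).
#'
#' @param x a \link{StageExpressionSet} with at least 2 replicates per stage.
#' @param variant t-test variant, \code{"pooled"} (default) or
#'   \code{"welch"}.
#' @return data.frame with columns \code{probe_id}, \code{fc_IE},
#'   \code{p_IE}, \code{fc_LE}, \code{p_LE}, \code{fc_IL}, \code{p_IL}
#'   (late vs intermediate) and \code{max_intensity}.
#' @seealso \code{\link{deFilter}}, \code{\link{classifyContrasts}}
#' @export
contrastStats <- function(x, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(is(x, "StageExpressionSet"))
  v <- intensities(x)
  idx <- lapply(setNames(.STAGES, .STAGES), function(s) .stageCols(x, s))
  mn <- lapply(idx, function(i) rowMeans(v[, i, drop = FALSE]))
  vr <- lapply(idx, function(i) apply(v[, i, drop = FALSE], 1, var))
  n <- lengths(idx)
  data.frame(
    probe_id = probeIds(x),
    fc_IE = signedFoldChange(mn$I, mn$E),
    p_IE = .rowTTestP(mn$I, vr$I, n["I"], mn$E, vr$E, n["E"], variant),
    fc_LE = signedFoldChange(mn$L, mn$E),
    p_LE = .rowTTestP(mn$L, vr$L, n["L"], mn$E, vr$E, n["E"], variant),
    fc_IL = signedFoldChange(mn$L, mn$I),
    p_IL = .rowTTestP(mn$L, vr$L, n["L"], mn$I, vr$I, n["I"], variant),
    max_intensity = apply(v, 1, max),
    row.names = NULL
  )
}

#' Differential-expression filter
#'
#' A probe is retained iff its maximum intensity across all arrays exceeds
#' \code{intensityFloor} (strictly), the magnitude of its late-vs-early
#' fold change is at least \code{foldThreshold} and the late-vs-early
#' p-value is at most \code{alpha} (both inclusive). Retained probes are
#' split by direction of the late-vs-early change; the three parts
#' partition the input.
#'
#' @param contrasts data.frame from \code{\link{contrastStats}}.
#' @param intensityFloor expression floor in intensity units (default 500).
#' @param foldThreshold minimum |fold change| late vs early (default 2).
#' @param alpha maximum late-vs-early p-value (default 0.05).
#' @return Object of class \code{DEPartition}: list with data.frames
#'   \code{up}, \code{down}, \code{excluded} and the filter settings.
#' @export
deFilter <- function(contrasts, intensityFloor = 500, foldThreshold = 2,
                     alpha = 0.05) {
  stopifnot(intensityFloor > 0, foldThreshold > 0, alpha > 0, alpha <= 1)
  contrasts <- as.data.frame(contrasts)
  keep <- contrasts$max_intensity > intensityFloor &
    abs(contrasts$fc_LE) >= foldThreshold &
    contrasts$p_LE <= alpha
  out <- list(
    up = contrasts[keep & contrasts$fc_LE > 0, , drop = FALSE],
    down = contrasts[keep & contrasts$fc_LE < 0, , drop = FALSE],
    excluded = contrasts[!keep, , drop = FALSE],
    intensityFloor = intensityFloor,
    foldThreshold = foldThreshold,
    alpha = alpha
  )
  class(out) <- "DEPartition"
  out
}

#' @export
print.DEPartition <- function(x, ...) {
  cat(sprintf(
    "DEPartition: %d up, %d down, %d excluded (floor > %g, |FC| >= %g, p <= %g)\n",
    nrow(x$up), nrow(x$down), nrow(x$excluded),
    x$intensityFloor, x$foldThreshold, x$alpha))
  invisible(x)
}

#' Collapse differentially expressed probes to gene symbols
#'
#' Maps each direction's probe list to unique annotated gene symbols.
#' Unmapped probes are counted separately; a gene with probes changing in
#' both directions appears in both lists (with a warning).
#'
#' @param de a \code{DEPartition} from \code{\link{deFilter}}, or a list
#'   with data.frames \code{up} and \code{down} carrying \code{probe_id}.
#' @param probeGeneMap data.frame with columns \code{probe_id} and
#'   \code{gene} (NA / missing probes are unannotated), or a named
#'   character vector probe -> gene.
#' @return list with character vectors \code{up} and \code{down} (gene
#'   symbols), \code{shared} (genes present in both), and
#'   \code{unannotated} (probe ids without a gene symbol).
#' @export
collapseToGenes <- function(de, probeGeneMap) {
  if (is.data.frame(probeGeneMap)) {
    map <- setNames(as.character(probeGeneMap$gene),
                    as.character(probeGeneMap$probe_id))
  } else map <- probeGeneMap
  if (anyDuplicated(names(map)))
    stop("probe-to-gene map has duplicate probe ids")
  lookup <- function(probes) map[as.character(probes)]
  gUp <- lookup(de$up$probe_id)
  gDown <- lookup(de$down$probe_id)
  unannotated <- c(de$up$probe_id[is.na(gUp) | !nzchar(gUp)],
                   de$down$probe_id[is.na(gDown) | !nzchar(gDown)])
  up <- unique(gUp[!is.na(gUp) & nzchar(gUp)])
  down <- unique(gDown[!is.na(gDown) & nzchar(gDown)])
  shared <- intersect(up, down)
  if (length(shared))
    warning(sprintf("%d gene(s) have probes changing in both directions: %s",
                    length(shared), paste(shared, collapse = ", ")))
  list(up = unname(up), down = unname(down), shared = shared,
       unannotated = as.character(unannotated))
}
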