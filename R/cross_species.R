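# Cross-species concordance: score a mouse DE gene list against archived
# reference-platform differential-expression tables via percentile ranks of
# p-values, and summarize the overlap with a cumulative binomial tail
# probability.

#' Percentile rank of a gene in a platform p-value list
#'
#' Position of the query gene when the platform's genes are sorted by
#' increasing p-value (1-based, ties broken by mean rank), divided by the
#' platform size and expressed as a percent.
#'
#' @param pValues numeric vector of platform p-values, named by gene
#'   symbol unless \code{genes} is given.
#' @param query gene symbol to rank (case-insensitive).
#' @param genes optional character vector of gene symbols parallel to
#'   \code{pValues}.
#' @return Percentile rank in (0, 100].
#' @examples
#' percentileRank(c(a = 1e-6, b = 0.2, c = 0.5, d = 0.9), "a")  # 25
#' @export
percentileRank <- function(pValues, query, genes = names(pValues)) {
  if (any(!is.finite(pValues))) stop("p-values must be finite")
  if (is.null(genes)) stop("gene symbols are required to locate the query")
  i <- match(toupper(query), toupper(genes))
  if (anyNA(i))
    stop(sprintf("gene '%s' absent from the platform table",
                 query[which(is.na(i))[1]]))
  r <- rank(pValues, ties.method = "average")
  unname(100 * r[i] / length(pValues))
}

#' Cumulative binomial upper-tail probability
#'
#' \eqn{\sum_{i=k}^{n} \binom{n}{i} p^i (1-p)^{n-i}}, by exact summation:
#' the chance of at least \code{k} successes in \code{n} trials at
#' per-trial null probability \code{pNull}.
#'
#' @param n number of genes compared.
#' @param k observed concordant count.
#' @param pNull per-gene null success probability, in (0, 1).
#' @return Upper-tail probability in (0, 1].
#' @examples
#' binomialUpperTail(3, 2, 0.5)  # 0.5
#' @export
binomialUpperTail <- function(n, k, pNull) {
  stopifnot(length(n) == 1, length(k) == 1, length(pNull) == 1)
  if (k < 0 || k > n || pNull <= 0 || pNull >= 1)
    stop("invalid binomial parameters: need 0 <= k <= n and pNull in (0,1)")
  if (k == 0) return(1)
  sum(stats::dbinom(k:n, n, pNull))
}

#' Score a mouse gene list against a reference platform table
#'
#' Looks up each mouse gene (case-insensitive) in a reference platform's
#' per-gene differential-expression table and records its percentile rank
#' by p-value, fold change and p-value. Genes absent from the platform
#' (not tested or below detection) get \code{NA} entries, the analogue of
#' the printed \code{"x"}.
#'
#' @param mouseGenes character vector of gene symbols with their mouse
#'   directions of change in \code{mouseDirections}.
#' @param platform data.frame with columns \code{gene}, \code{p} and
#'   \code{fold} (signed, cancer vs normal) for every platform gene.
#' @param mouseDirections optional numeric vector of signs (+1/-1) parallel
#'   to \code{mouseGenes}; carried through for direction checking.
#' @return data.frame with one row per mouse gene: \code{gene},
#'   \code{rank} (percent), \code{fold}, \code{p},
#'   \code{mouse_direction}.
#' @seealso \code{\link{summarizeOverlap}}
#' @export
scorePlatform <- function(mouseGenes, platform, mouseDirections = NULL) {
  platform <- as.data.frame(platform)
  stopifnot(all(c("gene", "p", "fold") %in% colnames(platform)))
  i <- match(toupper(mouseGenes), toupper(platform$gene))
  ranks <- rep(NA_real_, length(mouseGenes))
  found <- !is.na(i)
  if (any(found))
    ranks[found] <- percentileRank(platform$p, mouseGenes[found],
                                   genes = platform$gene)
  data.frame(
    gene = mouseGenes,
    rank = ranks,
    fold = ifelse(found, platform$fold[i], NA_real_),
    p = ifelse(found, platform$p[i], NA_real_),
    mouse_direction = if (is.null(mouseDirections)) NA_real_
                      else as.numeric(mouseDirections)
  )
}

#' Summarize cross-platform overlap with a cumulative binomial probability
#'
#' Flags each gene as significant when its platform percentile rank is at
#' or below \code{rankThreshold}, counts concordant genes (\code{k}) among
#' all genes compared (\code{n}; absent genes stay in \code{n} but can
#' never be concordant), and computes the upper-tail cumulative binomial
#' probability of observing at least \code{k} concordant genes at a
#' per-gene null probability \code{pNull}.
#'
#' By default concordance is significance alone, reproducing the printed
#' layout in which an opposite-direction change still counts; set
#' \code{checkDirection = TRUE} to additionally require the platform fold
#' change to share the mouse direction (needs \code{mouse_direction} in
#' \code{geneStats}).
#'
#' @param geneStats per-gene table from \code{\link{scorePlatform}}, or any
#'   data.frame with columns \code{gene}, \code{rank} (percent, NA for
#'   absent), \code{fold} and optionally \code{mouse_direction}.
#' @param rankThreshold maximum percentile rank counted significant
#'   (default 10; the null probability defaults to
#'   \code{rankThreshold/100}).
#' @param pNull per-gene null success probability.
#' @param checkDirection require matching direction of change.
#' @return Object of class \code{OverlapSummary}: list with the annotated
#'   \code{perGene} table (columns \code{significant}, \code{concordant},
#'   \code{display} with \code{"x"} for absent genes), and \code{n},
#'   \code{k}, \code{pNull}, \code{binomP}.
#' @export
summarizeOverlap <- function(geneStats, rankThreshold = 10,
                             pNull = rankThreshold / 100,
                             checkDirection = FALSE) {
  geneStats <- as.data.frame(geneStats)
  if (!nrow(geneStats)) stop("empty gene list")
  stopifnot(all(c("gene", "rank") %in% colnames(geneStats)),
            rankThreshold > 0)
  sig <- !is.na(geneStats$rank) & geneStats$rank <= rankThreshold + 1e-9
  conc <- sig
  if (checkDirection) {
    if (!"mouse_direction" %in% colnames(geneStats) ||
        all(is.na(geneStats$mouse_direction)))
      stop("direction checking needs a 'mouse_direction' column")
    conc <- sig & !is.na(geneStats$fold) &
      sign(geneStats$fold) == sign(geneStats$mouse_direction)
  }
  geneStats$significant <- sig
  geneStats$concordant <- conc
  geneStats$display <- ifelse(is.na(geneStats$rank), "x",
                              sprintf("%.1f%%", geneStats$rank))
  n <- nrow(geneStats)
  k <- sum(conc)
  out <- list(perGene = geneStats, n = n, k = k, pNull = pNull,
              binomP = binomialUpperTail(n, k, pNull))
  class(out) <- "OverlapSummary"
  out
}

#' @export
print.OverlapSummary <- function(x, ...) {
  cat(sprintf(
    "OverlapSummary: %d of %d genes concordant (p_null = %g), binomial P = %.3g\n",
    x$k, x$n, x$pNull, x$binomP))
  invisible(x)
}

#' Read an archived cross-platform comparison table
#'
#' Parses the printed-table layout comparing a mouse gene list against two
#' reference platforms: one row per gene with percentile rank, fold change
#' and p-value per platform, where \code{"x"} marks a gene that was not
#' significant or below detection. A copy of the published comparison ships
#' with the package (\code{system.file("extdata",
#' "archived_human_platform.tsv", package = "tristage")}).
#'
#' @param path path to a tab-delimited table with columns \code{gene},
#'   \code{mouse_direction} and, per platform prefix, \code{<p>_rank},
#'   \code{<p>_fold}, \code{<p>_p}.
#' @return Named list of per-platform gene-stat data.frames suitable for
#'   \code{\link{summarizeOverlap}}.
#' @export
readPlatformComparison <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "x", NA, x)))
  prefixes <- unique(sub("_rank$", "", grep("_rank$", colnames(tab),
                                            value = TRUE)))
  out <- lapply(prefixes, function(p) {
    data.frame(
      gene = tab$gene,
      rank = num(tab[[paste0(p, "_rank")]]),
      fold = num(tab[[paste0(p, "_fold")]]),
      p = num(tab[[paste0(p, "_p")]]),
      mouse_direction = if ("mouse_direction" %in% colnames(tab))
        as.numeric(tab$mouse_direction) else NA_real_
    )
  })
  names(out) <- prefixes
  out
}
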