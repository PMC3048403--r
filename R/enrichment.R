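# Gene-set over-representation of a differentially expressed gene list
# against a background of expressed genes, by the one-sided hypergeometric
# upper tail, with Benjamini-Hochberg adjusted values reported alongside.

#' Hypergeometric upper-tail probability
#'
#' \eqn{P(X \ge k)} for a hypergeometric draw of \code{n} genes from a
#' background of \code{N} of which \code{K} belong to the set, computed by
#' exact summation of the point masses.
#'
#' @param N background size.
#' @param K background members annotated to the set.
#' @param n size of the drawn (differentially expressed) list.
#' @param k observed overlap.
#' @return Upper-tail probability in (0, 1].
#' @examples
#' hypergeomUpperTail(20, 5, 5, 5)  # 1 / choose(20, 5)
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (K > N || n > N || k > min(K, n) || k < 0 || K < 0 || n < 0)
    stop("invalid hypergeometric parameters: need 0 <= k <= min(K, n), K <= N, n <= N")
  if (k == 0) return(1)
  sum(stats::dhyper(k:min(K, n), K, N - K, n))
}

#' Gene-set over-representation analysis
#'
#' Tests each gene set for over-representation in a differentially
#' expressed gene list relative to a background of expressed genes (the
#' genes surviving the expression floor), using the hypergeometric upper
#' tail. Symbol matching is case-insensitive. The significance flag uses
#' the raw p-value at \code{alphaEnrich} (the convention of the published
#' category tables); Benjamini-Hochberg adjusted values are reported
#' alongside.
#'
#' @param deGenes character vector of differentially expressed gene
#'   symbols; members absent from the background are dropped with a
#'   warning.
#' @param background character vector of expressed gene symbols.
#' @param geneSets named list of member-symbol vectors, as returned by
#'   \code{\link{readGeneSets}}.
#' @param alphaEnrich significance level on the raw p-value (default 0.01).
#' @return data.frame sorted by \code{p_hyper} with columns \code{set_id},
#'   \code{description}, \code{N}, \code{K}, \code{n}, \code{k},
#'   \code{p_hyper}, \code{p_adj} and \code{significant}. Sets with no
#'   background member are omitted.
#' @export
runOverrepresentation <- function(deGenes, background, geneSets,
                                  alphaEnrich = 0.01) {
  if (!length(background)) stop("empty background")
  if (!length(geneSets)) stop("no gene sets supplied")
  bg <- unique(toupper(background))
  de <- unique(toupper(deGenes))
  missing <- setdiff(de, bg)
  if (length(missing)) {
    warning(sprintf("%d DE gene(s) absent from the background were dropped",
                    length(missing)))
    de <- intersect(de, bg)
  }
  desc <- attr(geneSets, "descriptions")
  N <- length(bg)
  n <- length(de)
  rows <- lapply(names(geneSets), function(id) {
    members <- unique(toupper(geneSets[[id]]))
    K <- length(intersect(members, bg))
    if (K < 1L) return(NULL)
    k <- length(intersect(members, de))
    data.frame(set_id = id,
               description = if (!is.null(desc) && id %in% names(desc))
                 desc[[id]] else "",
               N = N, K = K, n = n, k = k,
               p_hyper = hypergeomUpperTail(N, K, n, k))
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    stop("no gene set has members in the background")
  res$p_adj <- p.adjust(res$p_hyper, method = "BH")
  res$significant <- res$p_hyper < alphaEnrich
  res <- res[order(res$p_hyper, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
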