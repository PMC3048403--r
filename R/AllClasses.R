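#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats p.adjust pt rlnorm rnorm runif setNames t.test var
#' @importFrom utils read.delim write.table
NULL

.STAGES <- c("E", "I", "L")

#' StageExpressionSet: probe-set intensities across three progression stages
#'
#' An S4 container for probe-set-level expression intensities from a
#' three-stage progression design (early \code{E}, intermediate \code{I},
#' late \code{L}; typically three biological replicates per stage). It
#' extends \linkS4class{SummarizedExperiment}: intensities live in the
#' \code{"exprs"} assay and the stage/replicate design in \code{colData}.
#'
#' Validity requires: a single \code{"exprs"} assay of finite, non-negative
#' intensities on the linear (fluorescence-unit) scale; unique, non-empty
#' probe identifiers as rownames; a \code{stage} column restricted to
#' \code{E}/\code{I}/\code{L}; and unique (stage, replicate) pairs.
#'
#' @param values numeric matrix of non-negative intensities, probes in rows,
#'   samples in columns.
#' @param stage character or factor of per-sample stage labels, each one of
#'   \code{"E"}, \code{"I"}, \code{"L"}.
#' @param replicate integer vector of per-sample replicate indices.
#' @param sampleIds sample identifiers; defaults to \code{colnames(values)}.
#' @param probeIds probe-set identifiers; defaults to \code{rownames(values)}.
#'
#' @return A \code{StageExpressionSet}.
#'
#' @examples
#' m <- matrix(100 * (1:18), nrow = 2,
#'             dimnames = list(c("p1", "p2"), paste0("s", 1:9)))
#' se <- StageExpressionSet(m, stage = rep(c("E", "I", "L"), each = 3),
#'                          replicate = rep(1:3, 3))
#' stages(se)
#' @aliases StageExpressionSet-class
#' @export
StageExpressionSet <- function(values, stage, replicate,
                               sampleIds = colnames(values),
                               probeIds = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probeIds))
    stop("probe identifiers are required (rownames or 'probeIds')")
  if (is.null(sampleIds))
    sampleIds <- paste0(stage, replicate)
  if (length(stage) != ncol(values) || length(replicate) != ncol(values))
    stop("'stage' and 'replicate' must have one entry per sample column")
  cd <- S4Vectors::DataFrame(
    sample_id = as.character(sampleIds),
    stage = factor(as.character(stage), levels = .STAGES),
    replicate = as.integer(replicate),
    row.names = as.character(sampleIds)
  )
  dimnames(values) <- list(as.character(probeIds), as.character(sampleIds))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd)
  new("StageExpressionSet", se)
}

#' @exportClass StageExpressionSet
setClass("StageExpressionSet", contains = "SummarizedExperiment")

setValidity("StageExpressionSet", function(object) {
  msg <- character(0)
  if (!identical(SummarizedExperiment::assayNames(object)[1], "exprs"))
    return("first assay must be named 'exprs'")
  v <- SummarizedExperiment::assay(object, "exprs")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample_id", "stage", "replicate") %in% colnames(cd)))
    return("colData must carry 'sample_id', 'stage' and 'replicate'")
  if (anyNA(cd$stage) || !all(as.character(cd$stage) %in% .STAGES))
    msg <- c(msg, "stage labels must be one of 'E', 'I', 'L'")
  if (anyDuplicated(paste(cd$stage, cd$replicate)))
    msg <- c(msg, "(stage, replicate) pairs must be unique")
  if (is.null(rownames(object)) || any(!nzchar(rownames(object))))
    msg <- c(msg, "probe identifiers must be non-empty")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicate probe id: '%s'",
                          rownames(object)[duplicated(rownames(object))][1]))
  if (any(!is.finite(v)))
    msg <- c(msg, "all intensities must be finite")
  else if (any(v < 0))
    msg <- c(msg, "all intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn StageExpressionSet per-sample stage labels (factor E/I/L).
#' @param x a \code{StageExpressionSet}.
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' @export
setMethod("stages", "StageExpressionSet", function(x)
  SummarizedExperiment::colData(x)$stage)

#' @describeIn StageExpressionSet per-sample replicate indices.
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))

#' @export
setMethod("replicates", "StageExpressionSet", function(x)
  SummarizedExperiment::colData(x)$replicate)

#' @describeIn StageExpressionSet probe-set identifiers.
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @export
setMethod("probeIds", "StageExpressionSet", function(x) rownames(x))

#' @describeIn StageExpressionSet intensity matrix (linear scale).
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @export
setMethod("intensities", "StageExpressionSet", function(x)
  SummarizedExperiment::assay(x, "exprs"))

setMethod("show", "StageExpressionSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("StageExpressionSet:", nrow(object), "probe sets x",
      ncol(object), "arrays\n")
  tab <- table(cd$stage)
  cat("  stages:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  rng <- range(SummarizedExperiment::assay(object, "exprs"))
  cat(sprintf("  intensity range: [%.3g, %.3g]\n", rng[1], rng[2]))
})

# replicate columns of one stage, erroring informatively when absent
.stageCols <- function(x, stage, minReplicates = 2L) {
  idx <- which(as.character(stages(x)) == stage)
  if (length(idx) < minReplicates)
    stop(sprintf("missing stage '%s' (need >= %d replicates, found %d)",
                 stage, minReplicates, length(idx)))
  idx
}
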