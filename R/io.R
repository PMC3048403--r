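# Readers and writers for the external tables the pipeline touches:
# tab-delimited expression matrices, the GEO series-matrix dialect,
# GMT gene sets and printed-table-style result files.

# convert a character matrix of cells to numeric, locating bad cells
.numericCells <- function(chr, probeIds, sampleIds) {
  suppress <- function(x) suppressWarnings(as.numeric(x))
  out <- matrix(NA_real_, nrow(chr), ncol(chr))
  for (j in seq_len(ncol(chr))) {
    num <- suppress(chr[, j])
    bad <- which(is.na(num) & !is.na(chr[, j]) & nzchar(trimws(chr[, j])))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at probe '%s', sample '%s'",
                   chr[bad[1], j], probeIds[bad[1]], sampleIds[j]))
    if (anyNA(num))
      stop(sprintf("missing value at probe '%s', sample '%s'",
                   probeIds[which(is.na(num))[1]], sampleIds[j]))
    out[, j] <- num
  }
  out
}

.applyStageAssignment <- function(values, probeIds, sampleIds,
                                  stageAssignment) {
  stageAssignment <- as.data.frame(stageAssignment)
  need <- c("sample_id", "stage", "replicate")
  if (!all(need %in% colnames(stageAssignment)))
    stop("stageAssignment needs columns 'sample_id', 'stage', 'replicate'")
  m <- match(sampleIds, stageAssignment$sample_id)
  if (anyNA(m))
    stop(sprintf("sample '%s' has no stage assignment",
                 sampleIds[which(is.na(m))[1]]))
  dup <- duplicated(probeIds)
  if (any(dup))
    stop(sprintf("duplicate probe id: '%s'", probeIds[dup][1]))
  dimnames(values) <- list(probeIds, sampleIds)
  StageExpressionSet(values,
                     stage = stageAssignment$stage[m],
                     replicate = stageAssignment$replicate[m],
                     sampleIds = sampleIds, probeIds = probeIds)
}

#' Read a tab-delimited probe-set expression table
#'
#' The expected layout is one header row of sample identifiers, a first
#' column of probe-set identifiers and one numeric intensity column per
#' sample (linear fluorescence units, no missing values). Column order is
#' preserved. Stage labels are supplied explicitly through
#' \code{stageAssignment} rather than guessed from sample titles.
#'
#' @param path path to a tab-delimited file (UTF-8; LF or CRLF).
#' @param stageAssignment data.frame with columns \code{sample_id},
#'   \code{stage} (one of \code{E}/\code{I}/\code{L}) and \code{replicate},
#'   covering every sample in the file.
#' @return A \link{StageExpressionSet}.
#' @seealso \code{\link{readSeriesMatrix}} for the GEO dialect,
#'   \code{\link{writeExpressionTable}} for the inverse operation.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6 * 100, 2, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
#' writeLines(c("probe\ts1\ts2\ts3",
#'              paste(rownames(m), m[, 1], m[, 2], m[, 3], sep = "\t")), tf)
#' sa <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                  stage = c("E", "E", "I"), replicate = c(1, 2, 1))
#' readExpressionTable(tf, sa)
#' @export
readExpressionTable <- function(path, stageAssignment) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE,
                    quote = "\"", comment.char = "")
  if (ncol(tab) < 2L) stop("expression table needs probe ids plus samples")
  probeIds <- trimws(tab[[1]])
  sampleIds <- colnames(tab)[-1]
  values <- .numericCells(as.matrix(tab[, -1, drop = FALSE]),
                          probeIds, sampleIds)
  .applyStageAssignment(values, probeIds, sampleIds, stageAssignment)
}

#' Write a StageExpressionSet as a tab-delimited table
#'
#' Inverse of \code{\link{readExpressionTable}}: full-precision intensities,
#' header row of sample ids, first column of probe ids.
#'
#' @param x a \link{StageExpressionSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(x, path) {
  df <- data.frame(probe_id = probeIds(x), intensities(x),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix in the GEO series-matrix dialect
#'
#' Understands the subset of the series-matrix format needed for deposited
#' probe-set tables: lines starting with \code{"!"} are metadata and are
#' ignored, the data table lies between the
#' \code{!series_matrix_table_begin} and \code{!series_matrix_table_end}
#' markers, and probe identifiers may be double-quoted. Everything else
#' behaves as \code{\link{readExpressionTable}}.
#'
#' @inheritParams readExpressionTable
#' @return A \link{StageExpressionSet}.
#' @export
readSeriesMatrix <- function(path, stageAssignment) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  if (!length(begin)) stop("no data table (missing table-begin marker)")
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  end <- if (length(end)) end[1] else length(lines) + 1L
  body <- lines[seq(begin[1] + 1L, end - 1L)]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop("no data table (empty table body)")
  cells <- strsplit(body, "\t", fixed = TRUE)
  width <- lengths(cells)
  if (length(unique(width)) != 1L)
    stop(sprintf("ragged data table: line %d has %d fields, expected %d",
                 which(width != width[1])[1], width[width != width[1]][1],
                 width[1]))
  unquote <- function(x) gsub('^"|"$', "", trimws(x))
  header <- unquote(cells[[1]])
  mat <- do.call(rbind, cells[-1])
  probeIds <- unquote(mat[, 1])
  sampleIds <- header[-1]
  values <- .numericCells(apply(mat[, -1, drop = FALSE], 2, unquote),
                          probeIds, sampleIds)
  values <- matrix(values, nrow = length(probeIds))
  .applyStageAssignment(values, probeIds, sampleIds, stageAssignment)
}

#' Read gene sets in GMT format
#'
#' One set per line: \code{set_id TAB description TAB member TAB member ...}.
#' Duplicate members within a line are collapsed with a warning; a line with
#' fewer than three fields is an error naming the line.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors of member gene symbols, one per
#'   set, with a named \code{"descriptions"} attribute.
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineNo <- which(keep)
  sets <- vector("list", length(fields))
  ids <- character(length(fields))
  desc <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d fields; need set id, description and at least one member",
                   lineNo[i], length(f)))
    ids[i] <- f[1]
    desc[i] <- f[2]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("gene set '%s': duplicate members collapsed", f[1]))
      members <- unique(members)
    }
    if (!length(members))
      stop(sprintf("GMT line %d: gene set '%s' has no members", lineNo[i], f[1]))
    sets[[i]] <- members
  }
  names(sets) <- ids
  attr(sets, "descriptions") <- setNames(desc, ids)
  sets
}

#' Write a printed-table-style differential-expression result file
#'
#' Renders results in the layout of the published stage-contrast tables:
#' tab-delimited with one header row, signed fold changes with one decimal
#' (\code{-19.3} means 19.3-fold lower) and p-values with four decimals.
#'
#' @param records data.frame with columns \code{gene}, optional
#'   \code{accession}, \code{fc_IE}, \code{p_IE}, \code{fc_LE}, \code{p_LE}
#'   and optional \code{trajectory}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readResultsTable}}
#' @export
writeResultsTable <- function(records, path) {
  records <- as.data.frame(records)
  need <- c("gene", "fc_IE", "p_IE", "fc_LE", "p_LE")
  if (nrow(records) && !all(need %in% colnames(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  out <- data.frame(
    gene = character(0), accession = character(0),
    fc_IE = character(0), p_IE = character(0),
    fc_LE = character(0), p_LE = character(0),
    trajectory = character(0)
  )
  if (nrow(records)) {
    out <- data.frame(
      gene = as.character(records$gene),
      accession = if ("accession" %in% colnames(records))
        as.character(records$accession) else "",
      fc_IE = sprintf("%.1f", records$fc_IE),
      p_IE = sprintf("%.4f", records$p_IE),
      fc_LE = sprintf("%.1f", records$fc_LE),
      p_LE = sprintf("%.4f", records$p_LE),
      trajectory = if ("trajectory" %in% colnames(records))
        as.character(records$trajectory) else ""
    )
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot write results table to '%s'", path)))
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by \code{writeResultsTable}
#'
#' @param path path to a results table.
#' @return data.frame with numeric fold-change and p-value columns at the
#'   rendered precision.
#' @export
readResultsTable <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  for (col in c("fc_IE", "p_IE", "fc_LE", "p_LE"))
    if (col %in% colnames(tab)) tab[[col]] <- as.numeric(tab[[col]])
  tab
}
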