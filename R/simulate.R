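# Synthetic-data generators with known ground truth: a three-stage
# expression matrix with planted trajectory classes, gene sets with one
# planted enriched set, a reference platform with a planted concordant
# subset, and a qPCR Ct table with planted folds. Every generator is
# deterministic under the configuration seed.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic study. Defaults emulate a
#' genome-scale three-stage array experiment: three biological replicates
#' per stage, log-normal multiplicative intensity noise, a small planted
#' differentially expressed fraction split among early / progressive /
#' late trajectory classes in proportions mirroring a typical progression
#' study, 4-fold effects, and multi-probe genes.
#'
#' Pattern semantics: \emph{early} probes carry the full fold effect at
#' both the intermediate and late stages; \emph{progressive} probes carry
#' half the log2 effect at the intermediate stage and the full effect at
#' the late stage; \emph{late} probes change only at the late stage;
#' \emph{null} probes never change.
#'
#' @param nProbes number of probe sets.
#' @param classProps named proportions over \code{early}, \code{progressive},
#'   \code{late}, \code{null}; must sum to 1.
#' @param effectFold planted fold effect at the late stage (default 4).
#' @param upProb probability a planted effect is up rather than down.
#' @param baselineLog2Mean,baselineLog2Sd log2-scale baseline intensity
#'   distribution.
#' @param cv replicate noise coefficient of variation (log-normal).
#' @param replicates biological replicates per stage (default 3).
#' @param probesPerGeneMax probes per gene are drawn uniformly from
#'   1..\code{probesPerGeneMax}.
#' @param unannotatedFrac fraction of probes with no gene symbol.
#' @param nGeneSets number of gene sets to generate (one planted enriched).
#' @param geneSetSize members per gene set.
#' @param enrichmentFactor sampling-weight ratio favouring DE genes in the
#'   planted set.
#' @param platformSize genes on the simulated reference platform.
#' @param concordantFraction fraction of queried mouse genes planted as
#'   concordant on the platform.
#' @param rankThreshold percentile-rank significance threshold emulated by
#'   the platform generator.
#' @param qpcrSd Gaussian noise (cycles) on simulated Ct values.
#' @param qpcrReplicates qPCR replicates per group.
#' @param seed mandatory integer seed; every generator derived from this
#'   configuration is reproducible given the seed.
#' @return list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nProbes = 10000,
                             classProps = c(early = 0.002,
                                            progressive = 0.015,
                                            late = 0.026, null = 0.957),
                             effectFold = 4, upProb = 0.5,
                             baselineLog2Mean = 7, baselineLog2Sd = 1.2,
                             cv = 0.1, replicates = 3,
                             probesPerGeneMax = 3, unannotatedFrac = 0.05,
                             nGeneSets = 20, geneSetSize = 50,
                             enrichmentFactor = 5,
                             platformSize = 2000, concordantFraction = 0.5,
                             rankThreshold = 10,
                             qpcrSd = 0.15, qpcrReplicates = 3,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  need <- c("early", "progressive", "late", "null")
  if (!all(need %in% names(classProps)))
    stop("classProps needs proportions for: ", paste(need, collapse = ", "))
  classProps <- classProps[need]
  if (abs(sum(classProps) - 1) > 1e-8 || any(classProps < 0))
    stop("class proportions must be non-negative and sum to 1")
  stopifnot(nProbes >= 1, effectFold >= 1, cv >= 0, replicates >= 2,
            upProb >= 0, upProb <= 1)
  structure(list(
    nProbes = as.integer(nProbes), classProps = classProps,
    effectFold = effectFold, upProb = upProb,
    baselineLog2Mean = baselineLog2Mean, baselineLog2Sd = baselineLog2Sd,
    cv = cv, replicates = as.integer(replicates),
    probesPerGeneMax = as.integer(probesPerGeneMax),
    unannotatedFrac = unannotatedFrac,
    nGeneSets = as.integer(nGeneSets), geneSetSize = as.integer(geneSetSize),
    enrichmentFactor = enrichmentFactor,
    platformSize = as.integer(platformSize),
    concordantFraction = concordantFraction,
    rankThreshold = rankThreshold,
    qpcrSd = qpcrSd, qpcrReplicates = as.integer(qpcrReplicates),
    seed = as.integer(seed)
  ), class = "SimulationConfig")
}

# deterministic integer class counts honouring the proportions
.classCounts <- function(props, n) {
  counts <- diff(c(0, round(cumsum(props) * n)))
  names(counts) <- names(props)
  counts
}

.lnormNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a three-stage expression matrix with planted trajectories
#'
#' Intensities are \code{baseline x stage effect x multiplicative
#' log-normal noise} on the linear fluorescence scale. Stage effects
#' follow the planted class (see \code{\link{simulationConfig}}); class
#' counts match the configured proportions up to rounding. Probes are
#' grouped into multi-probe genes; a configurable fraction stays
#' unannotated.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{expr} (a \link{StageExpressionSet}),
#'   \code{truth} (data.frame: \code{probe_id}, \code{gene}, \code{class},
#'   \code{direction}, \code{fold_I}, \code{fold_L}) and
#'   \code{probeGeneMap} (data.frame: \code{probe_id}, \code{gene}).
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$nProbes
  counts <- .classCounts(config$classProps, n)
  cls <- sample(rep(names(counts), counts))
  dir <- ifelse(runif(n) < config$upProb, 1, -1)
  dir[cls == "null"] <- 0
  lf <- log2(config$effectFold)
  foldL <- ifelse(cls == "null", 1, config$effectFold)
  foldI <- 2^(lf * (cls == "early") + (lf / 2) * (cls == "progressive"))
  # signed (direction) stage multipliers
  mI <- ifelse(dir >= 0, foldI, 1 / foldI)
  mL <- ifelse(dir >= 0, foldL, 1 / foldL)
  mI[cls == "null"] <- 1
  mL[cls == "null"] <- 1
  baseline <- 2^rnorm(n, config$baselineLog2Mean, config$baselineLog2Sd)
  reps <- config$replicates
  stage <- rep(.STAGES, each = reps)
  repl <- rep(seq_len(reps), times = 3)
  mult <- cbind(matrix(1, n, reps),
                matrix(mI, n, reps),
                matrix(mL, n, reps))
  noise <- matrix(.lnormNoise(n * 3L * reps, config$cv), nrow = n)
  values <- baseline * mult * noise
  probeId <- sprintf("P%06d_at", seq_len(n))
  dimnames(values) <- list(probeId, paste0(stage, repl))
  # gene assignment: runs of 1..probesPerGeneMax probes per gene
  sizes <- sample.int(config$probesPerGeneMax, n, replace = TRUE)
  sizes <- sizes[cumsum(sizes) - sizes < n]
  gene <- rep(sprintf("G%05d", seq_along(sizes)), sizes)[seq_len(n)]
  gene <- gene[sample.int(n)]
  gene[runif(n) < config$unannotatedFrac] <- NA_character_
  truth <- data.frame(probe_id = probeId, gene = gene, class = cls,
                      direction = dir, fold_I = mI, fold_L = mL)
  expr <- StageExpressionSet(values, stage = stage, replicate = repl)
  list(expr = expr, truth = truth,
       probeGeneMap = truth[, c("probe_id", "gene")])
}

#' Simulate gene sets with one planted enriched set
#'
#' Builds \code{nGeneSets} gene sets over the simulated gene universe. The
#' first set (\code{SET01}, the planted set) samples its members with
#' weight \code{enrichmentFactor} on genes whose planted trajectory class
#' is non-null, so it is over-represented in any downstream DE list; the
#' remaining sets sample uniformly.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param truth truth table from \code{\link{simulateExpression}}.
#' @return Named list of member vectors (with \code{"descriptions"}
#'   attribute) plus a \code{"planted"} attribute naming the enriched set.
#' @export
simulateGeneSets <- function(config, truth) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  genes <- unique(truth$gene[!is.na(truth$gene)])
  deGenes <- unique(truth$gene[!is.na(truth$gene) & truth$class != "null"])
  m <- min(config$geneSetSize, length(genes))
  w <- ifelse(genes %in% deGenes, config$enrichmentFactor, 1)
  ids <- sprintf("SET%02d", seq_len(config$nGeneSets))
  sets <- vector("list", config$nGeneSets)
  sets[[1]] <- sample(genes, m, prob = w)
  for (i in seq_len(config$nGeneSets - 1L))
    sets[[i + 1L]] <- sample(genes, m)
  names(sets) <- ids
  attr(sets, "descriptions") <- setNames(
    c("planted enriched set", rep("random set", config$nGeneSets - 1L)), ids)
  attr(sets, "planted") <- ids[1]
  sets
}

#' Simulate a reference-platform differential-expression table
#'
#' Emulates an archived cancer-vs-normal platform table: background genes
#' get uniform p-values and random fold directions; a planted concordant
#' subset of the queried mouse genes receives p-values from the low tail
#' (percentile rank safely below \code{rankThreshold}) with fold changes
#' matching the mouse direction.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param mouseGenes character vector of queried mouse gene symbols.
#' @param mouseDirections numeric signs (+1/-1) parallel to
#'   \code{mouseGenes}.
#' @return data.frame with columns \code{gene}, \code{p}, \code{fold} and
#'   a \code{"concordant"} attribute (logical, parallel to
#'   \code{mouseGenes}).
#' @export
simulatePlatform <- function(config, mouseGenes, mouseDirections) {
  stopifnot(inherits(config, "SimulationConfig"),
            length(mouseGenes) == length(mouseDirections))
  set.seed(config$seed + 2L)
  nm <- length(mouseGenes)
  nbg <- max(config$platformSize - nm, 0L)
  genes <- toupper(c(mouseGenes, sprintf("BGG%05d", seq_len(nbg))))
  p <- runif(length(genes))
  fold <- ifelse(runif(length(genes)) < 0.5, 1, -1) * runif(length(genes), 1, 10)
  conc <- rep(FALSE, nm)
  nConc <- round(config$concordantFraction * nm)
  if (nConc > 0) {
    conc[sample.int(nm, nConc)] <- TRUE
    # low-tail p-values: empirical percentile rank stays below threshold
    p[which(conc)] <- runif(nConc, 0, 0.3 * config$rankThreshold / 100)
    fold[which(conc)] <- sign(mouseDirections[conc]) *
      runif(nConc, 2, 10)
  }
  out <- data.frame(gene = genes, p = p, fold = fold)
  attr(out, "concordant") <- conc
  out
}

#' Simulate a qPCR Ct table with planted folds
#'
#' Generates target and reference cycle-threshold values for a test and a
#' control group such that \code{\link{ddctFromCt}} recovers each planted
#' fold in expectation: the test group's delta-Ct is shifted by
#' \code{-log2(fold)} relative to control, with Gaussian noise of
#' \code{qpcrSd} cycles on the target Ct.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param folds named numeric vector of planted folds (names are genes).
#' @param testGroup,controlGroup group labels to emit.
#' @return data.frame with columns \code{sample}, \code{group},
#'   \code{gene}, \code{Ct_target}, \code{Ct_reference}.
#' @export
simulateQpcr <- function(config, folds, testGroup = "L",
                         controlGroup = "E") {
  stopifnot(inherits(config, "SimulationConfig"), length(folds) >= 1)
  if (is.null(names(folds))) names(folds) <- sprintf("gene%02d",
                                                     seq_along(folds))
  set.seed(config$seed + 3L)
  reps <- config$qpcrReplicates
  ctRef <- 18
  baseDct <- 5
  rows <- lapply(names(folds), function(g) {
    dctCtrl <- baseDct + rnorm(reps, 0, config$qpcrSd)
    dctTest <- baseDct - log2(folds[[g]]) + rnorm(reps, 0, config$qpcrSd)
    data.frame(
      sample = c(paste0(controlGroup, seq_len(reps)),
                 paste0(testGroup, seq_len(reps))),
      group = rep(c(controlGroup, testGroup), each = reps),
      gene = g,
      Ct_target = ctRef + c(dctCtrl, dctTest),
      Ct_reference = ctRef
    )
  })
  do.call(rbind, rows)
}
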