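# Independent brute-force oracles and small fixture builders used across
# the suite.

# P(overlap >= k) by enumerating every n-subset of a background of N in
# which the first K elements are the set members.
bruteHypergeomUpper <- function(N, K, n, k) {
  if (n == 0 || N == 0) return(if (k <= 0) 1 else 0)
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# P(successes >= k) by enumerating all 2^n outcomes with their weights.
bruteBinomialUpper <- function(n, k, p) {
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- apply(grid, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  sum(w[rowSums(grid) >= k])
}

# minimal 3x3-replicate expression set built from an explicit value matrix
makeStageSet <- function(values, probeIds = sprintf("p%d", seq_len(nrow(values)))) {
  rownames(values) <- probeIds
  colnames(values) <- paste0(rep(c("E", "I", "L"), each = 3), 1:3)
  StageExpressionSet(values, stage = rep(c("E", "I", "L"), each = 3),
                     replicate = rep(1:3, 3))
}

stageAssignment9 <- function(ids = paste0(rep(c("E", "I", "L"), each = 3), 1:3)) {
  data.frame(sample_id = ids, stage = rep(c("E", "I", "L"), each = 3),
             replicate = rep(1:3, 3))
}

fixturePath <- function(name) {
  system.file("extdata", name, package = "tristage", mustWork = TRUE)
}

# published-table stage contrasts shipped with the package
readMouseContrasts <- function() {
  read.delim(fixturePath("mouse_stage_contrasts.tsv"))
}
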