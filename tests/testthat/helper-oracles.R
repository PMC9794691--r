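# Independent oracles and small fixture builders shared across tests.

# O(n^2) re-implementation of greedy maximal-score window selection:
# repeatedly take the best-scoring live window (ties: chromosome order,
# then leftmost), kill everything overlapping it.
naiveConsensus <- function(chrom, summit, score, half = 250L) {
  ws <- summit - half
  we <- summit + half - 1L
  chromi <- as.integer(factor(chrom, levels = unique(sort(chrom))))
  alive <- rep(TRUE, length(summit))
  keep <- logical(length(summit))
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[order(-score[cand], chromi[cand], ws[cand])][1]
    keep[best] <- TRUE
    ov <- alive & chrom == chrom[best] & ws <= we[best] & we >= ws[best]
    alive[ov] <- FALSE
  }
  keep
}

# Exhaustive hypergeometric upper-tail oracle: enumerate every draw of
# `target_n` items from a universe with `hits` marked, and count draws with
# at least `obs` marked items.
hyperEnumOracle <- function(universe_n, hits_n, target_n, obs) {
  draws <- utils::combn(universe_n, target_n)
  marked <- seq_len(hits_n)
  tail_hits <- apply(draws, 2, function(d) sum(d %in% marked) >= obs)
  mean(tail_hits)
}

# Sharp-consensus motif: one dominant base (0.85) per column.
sharpMotif <- function(id, seed, width = 8) {
  cons <- withr::with_seed(seed, sample(1:4, width, replace = TRUE))
  M <- matrix(0.05, 4, width)
  M[cbind(cons, seq_len(width))] <- 0.85
  motifModel(id, M)
}

# GRanges of summit calls from parallel vectors.
summitCalls <- function(chrom, summit, score, sample = "s1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(summit, width = 1))
  gr$summit <- summit
  gr$score <- score
  gr$sample <- rep_len(sample, length(summit))
  gr
}

colDataDf <- function(se)
  as.data.frame(SummarizedExperiment::colData(se))

rowDataDf <- function(se)
  as.data.frame(SummarizedExperiment::rowData(se))

countsOf <- function(se) SummarizedExperiment::assay(se, "counts")
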