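revcompChr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s)
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}

# Log2-odds score matrix for a motif: 5 x width, rows A,C,G,T,N with the N
# row fixed at 0 (an N scores as background). The pseudocount floors the
# PFM probabilities so zero entries stay finite while a deterministic
# consensus base keeps probability 1 (and a width-w consensus scores
# exactly w * log2(1 / background)).
motifScoreMatrix <- function(motif, pseudocount = 1e-3) {
  M <- log2(pmax(motif@pfm, pseudocount) / motif@background)
  rbind(M, N = 0)
}

encodeSeq <- function(seq) {
  v <- strsplit(toupper(as.character(seq)), "")[[1]]
  code <- match(v, c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

#' Scan a sequence with a PWM
#'
#' Scores every offset on both strands with the log2-odds of the
#' pseudocount-normalized PFM against the motif's background (N bases score
#' as background) and reports positions at or above the motif's threshold.
#'
#' @param seq A character string or `DNAString` over `A`, `C`, `G`, `T`,
#'   `N`.
#' @param motif A [MotifModel-class].
#' @return `data.frame` with `offset` (1-based start of the window on the
#'   forward strand), `strand`, and `bits`.
#' @export
#' @examples
#' m <- motifModel("ex", diag(4)[, c(1, 2, 3, 4)], threshold = 7.9)
#' motifScan("AAACGTAAA", m)
motifScan <- function(seq, motif) {
  code <- encodeSeq(seq)
  w <- motifWidth(motif)
  L <- length(code)
  if (w > L)
    return(data.frame(offset = integer(), strand = character(),
                      bits = numeric()))
  M <- motifScoreMatrix(motif)
  # Minus-strand hits are equivalent to scanning with the reverse-complement
  # score matrix on the forward sequence.
  Mrc <- M[c(4:1, 5), rev(seq_len(w)), drop = FALSE]
  offs <- seq_len(L - w + 1L)
  scoreWith <- function(mat) {
    s <- numeric(length(offs))
    for (j in seq_len(w)) s <- s + mat[cbind(code[offs + j - 1L], j)]
    s
  }
  fwd <- scoreWith(M)
  rev <- scoreWith(Mrc)
  fsel <- fwd >= motif@threshold
  rsel <- rev >= motif@threshold
  out <- rbind(
    data.frame(offset = offs[fsel], strand = rep("+", sum(fsel)),
               bits = fwd[fsel]),
    data.frame(offset = offs[rsel], strand = rep("-", sum(rsel)),
               bits = rev[rsel]))
  out[order(out$offset, out$strand), , drop = FALSE]
}

# TRUE per sequence when the motif has >= 1 occurrence.
motifHits <- function(seqs, motif) {
  vapply(as.character(seqs), function(s) nrow(motifScan(s, motif)) > 0,
         logical(1), USE.NAMES = FALSE)
}

#' Motif enrichment in target versus background peak sequences
#'
#' A peak is a hit for a motif when it contains at least one occurrence at
#' or above the motif threshold. Enrichment of hits among targets within
#' the universe (targets plus background, disjoint) is scored with the
#' hypergeometric upper tail, BH-adjusted across motifs, and ranked by FDR.
#'
#' @param target_seqs `DNAStringSet` (or character vector) of target peak
#'   sequences (e.g. gained-accessibility peaks).
#' @param background_seqs Background peak sequences.
#' @param motifs List of [MotifModel-class] objects.
#' @return `data.frame` ranked by ascending FDR: `motif`,
#'   `target_hits`, `target_n`, `background_hits`, `background_n`,
#'   `target_fraction`, `background_fraction`, `p`, `fdr`.
#' @export
motifEnrichment <- function(target_seqs, background_seqs, motifs) {
  nT <- length(target_seqs); nB <- length(background_seqs)
  stopifnot2(nT > 0, "empty target set")
  if (inherits(motifs, "MotifModel")) motifs <- list(motifs)
  rows <- lapply(motifs, function(m) {
    hT <- sum(motifHits(target_seqs, m))
    hB <- sum(motifHits(background_seqs, m))
    total <- hT + hB
    p <- stats::phyper(hT - 1, total, nT + nB - total, nT,
                       lower.tail = FALSE)
    data.frame(motif = m@id, target_hits = hT, target_n = nT,
               background_hits = hB, background_n = nB,
               target_fraction = hT / nT,
               background_fraction = if (nB > 0) hB / nB else NA_real_,
               p = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p)
  out <- out[order(out$fdr, out$p, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}
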