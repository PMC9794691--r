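#' Build fixed-width consensus peaks from per-sample summit calls
#'
#' Every summit is expanded to a 500 bp window (summit +/- 250 in 0-based
#' half-open coordinates). The highest-scoring window genome-wide is
#' retained, every window overlapping it is discarded, and the step repeats
#' until no window remains; ties are broken by chromosome order then start.
#' A sample "calls" a consensus peak when any of its windows overlaps it.
#'
#' @param calls A `GRangesList` (one element per sample) or a `GRanges`
#'   with a `sample` mcol; each range carries mcols `summit` (absolute bp)
#'   and `score`.
#' @param width Consensus window width (bp).
#' @return A `GRanges` of non-overlapping fixed-width consensus peaks with
#'   mcols `summit`, `score`, and a logical `called` matrix
#'   (peaks x samples).
#' @export
buildConsensus <- function(calls, width = 500L) {
  if (is(calls, "GRangesList")) {
    samples <- rep(names(calls), lengths(calls))
    calls <- unlist(calls, use.names = FALSE)
    calls$sample <- samples
  }
  stopifnot2(is(calls, "GRanges") &&
               all(c("summit", "score", "sample") %in% names(mcols(calls))),
             "calls need summit, score and sample metadata")
  stopifnot2(all(start(calls) >= 1), "malformed intervals")
  half <- width %/% 2L
  # 0-based half-open [summit0 - half, summit0 + half), summit0 = summit - 1.
  win <- GRanges(seqnames(calls),
                 IRanges(pmax(calls$summit - half, 1L),
                         calls$summit + half - 1L),
                 seqinfo = GenomeInfoDb::seqinfo(calls))
  win$summit <- calls$summit
  win$score <- calls$score
  win$sample <- calls$sample

  chrom <- as.integer(factor(as.character(seqnames(win)),
                             levels = GenomeInfoDb::seqlevels(win)))
  ord <- order(-win$score, chrom, start(win))
  hits <- findOverlaps(win, win)
  nbr <- split(subjectHits(hits), queryHits(hits))
  alive <- rep(TRUE, length(win))
  keep <- logical(length(win))
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[nbr[[as.character(i)]]] <- FALSE
  }
  peaks <- win[keep]
  peaks <- peaks[order(as.integer(factor(as.character(seqnames(peaks)),
                                         levels = GenomeInfoDb::seqlevels(peaks))),
                       start(peaks))]
  all_samples <- unique(win$sample)
  ov <- findOverlaps(peaks, win)
  called <- matrix(FALSE, length(peaks), length(all_samples),
                   dimnames = list(NULL, all_samples))
  called[cbind(queryHits(ov), match(win$sample[subjectHits(ov)],
                                    all_samples))] <- TRUE
  mcols(peaks)$sample <- NULL
  mcols(peaks)$called <- called
  peaks
}

#' Filter consensus peak counts for abundance and reproducibility
#'
#' A peak is retained when its maximum per-group mean log2-CPM is at least
#' `cpm_cut` and it was called in every replicate of at least one group.
#'
#' @param counts Peaks x samples count matrix.
#' @param called Logical peaks x samples call matrix.
#' @param groups Factor (or character) of experimental group per sample.
#' @param cpm_cut Minimum group-mean log2-CPM.
#' @param prior_count Prior count for [normalizeLogCPM()].
#' @return Logical vector: `TRUE` for retained peaks.
#' @export
filterPeakCounts <- function(counts, called, groups, cpm_cut = 2,
                             prior_count = 0.5) {
  stopifnot2(all(dim(counts) == dim(called)),
             "counts and called must have identical dimensions")
  stopifnot2(length(groups) == ncol(counts),
             "one group per sample column required")
  lcpm <- normalizeLogCPM(counts, prior_count)
  groups <- factor(groups)
  gm <- sapply(levels(groups), function(g)
    rowMeans(lcpm[, groups == g, drop = FALSE]))
  rep_called <- sapply(levels(groups), function(g)
    rowSums(called[, groups == g, drop = FALSE]) == sum(groups == g))
  apply(as.matrix(gm), 1, max) >= cpm_cut &
    apply(as.matrix(rep_called), 1, any)
}

#' Annotate peaks to their nearest gene TSS
#'
#' Assigns each peak to the gene with the nearest TSS (by distance from the
#' peak center), leaving peaks further than `max_dist` unassigned. Feature
#' classes: `promoter` when the center lies within `promoter_window` of a
#' TSS, `gene_body` when it falls inside a gene's extent, else
#' `distal_intergenic`. The signed TSS distance is positive downstream of
#' the TSS (strand-aware).
#'
#' @param peaks A `GRanges` of peaks.
#' @param genome A [SyntheticGenome-class] (or any object with `genes()`
#'   providing `gene_id`, `tss` and strand).
#' @param max_dist Maximum TSS distance for gene assignment (bp).
#' @param promoter_window Half-width of the promoter class window (bp).
#' @return The input `GRanges` with mcols `nearest_gene`, `tss_distance`
#'   (signed), and `feature_class`.
#' @export
annotatePeaks <- function(peaks, genome, max_dist = 1e5,
                          promoter_window = 2000) {
  g <- genes(genome)
  stopifnot2(length(g) > 0, "genome has no genes to annotate against")
  center <- (start(peaks) + end(peaks)) %/% 2L
  cgr <- GRanges(seqnames(peaks), IRanges(center, width = 1))
  tss <- GRanges(seqnames(g), IRanges(g$tss, width = 1))
  hits <- distanceToNearest(cgr, tss)
  nearest <- rep(NA_character_, length(peaks))
  dist_signed <- rep(NA_real_, length(peaks))
  cls <- rep("distal_intergenic", length(peaks))
  qi <- queryHits(hits); si <- subjectHits(hits)
  raw <- center[qi] - g$tss[si]
  sgn <- ifelse(as.character(strand(g))[si] == "-", -raw, raw)
  d <- abs(raw)
  assign_ok <- d <= max_dist
  nearest[qi[assign_ok]] <- g$gene_id[si[assign_ok]]
  dist_signed[qi[assign_ok]] <- sgn[assign_ok]
  in_prom <- logical(length(peaks))
  in_prom[qi] <- d <= promoter_window
  in_body <- overlapsAny(cgr, g)
  cls[in_body] <- "gene_body"
  cls[in_prom] <- "promoter"
  mcols(peaks)$nearest_gene <- nearest
  mcols(peaks)$tss_distance <- dist_signed
  mcols(peaks)$feature_class <- cls
  peaks
}

#' Feature-class proportions of an annotated peak set
#'
#' @param peaks Output of [annotatePeaks()].
#' @return `data.frame` with `feature_class`, `n`, `proportion` (sums to 1).
#' @export
featureProportions <- function(peaks) {
  stopifnot2("feature_class" %in% names(mcols(peaks)),
             "peaks must be annotated first")
  classes <- c("promoter", "gene_body", "distal_intergenic")
  n <- vapply(classes, function(cl)
    sum(mcols(peaks)$feature_class == cl), integer(1))
  data.frame(feature_class = classes, n = n,
             proportion = if (length(peaks) > 0) n / length(peaks) else
               rep(0, 3), row.names = NULL)
}

#' Regulatory-element overlap percentages and deltas
#'
#' For each element class and each peak set, the percentage of peaks
#' overlapping at least one element of that class; non-`"all"` sets also
#' report the delta against the `"all"` consensus set.
#'
#' @param peak_sets Named list of `GRanges`; must include `"all"`.
#' @param elements `GRanges` with a `class` mcol (`dELS`, `pELS`, `PLS`).
#' @return `data.frame` with `set`, `class`, `percent`, `delta`.
#' @export
regulatoryOverlapDelta <- function(peak_sets, elements) {
  stopifnot2("all" %in% names(peak_sets), "peak_sets must include 'all'")
  classes <- c("dELS", "pELS", "PLS")
  pct <- function(set, cl) {
    if (length(set) == 0) return(0)
    el <- elements[mcols(elements)$class == cl]
    if (length(el) == 0) return(0)
    100 * mean(overlapsAny(set, el))
  }
  out <- expand.grid(set = names(peak_sets), class = classes,
                     stringsAsFactors = FALSE)
  out$percent <- mapply(function(s, cl) pct(peak_sets[[s]], cl),
                        out$set, out$class)
  base <- out$percent[match(paste("all", out$class),
                            paste(out$set, out$class))]
  out$delta <- ifelse(out$set == "all", 0, out$percent - base)
  out
}
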