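#' Build a synthetic genome
#'
#' Places non-overlapping genes uniformly on equal-length chromosomes and
#' regulatory elements either uniformly or forced near TSSs. Elements are
#' classed by the distance from their midpoint to the nearest TSS:
#' promoter-like (`PLS`) within 200 bp, proximal enhancer-like (`pELS`)
#' within 2 kb, distal enhancer-like (`dELS`) beyond.
#'
#' @param n_chrom Number of chromosomes.
#' @param n_genes Number of genes.
#' @param n_elements Number of regulatory elements.
#' @param chrom_length Length of each chromosome (bp).
#' @param gene_length Gene body length (bp).
#' @param element_width Element width (bp).
#' @param element_max_dist If non-`NULL`, elements are placed uniformly
#'   within this distance of a random TSS instead of uniformly genome-wide.
#' @param seed Integer seed.
#' @return A [SyntheticGenome-class] object.
#' @export
makeGenome <- function(n_chrom = 2, n_genes = 200, n_elements = 300,
                       chrom_length = 1e6, gene_length = 2000,
                       element_width = 200, element_max_dist = NULL,
                       seed = 1L) {
  stopifnot2(n_chrom >= 1 && chrom_length > 0, "need positive genome sizes")
  stopifnot2(n_genes * (gene_length + 1) <= 0.5 * n_chrom * chrom_length,
             "genome too small to place the requested genes")
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  si <- Seqinfo(seqnames = chroms,
                seqlengths = rep(as.integer(chrom_length), n_chrom))
  withSeed(seed, {
    genes <- GRanges(seqinfo = si)
    if (n_genes > 0) {
      per <- rep(seq_len(n_chrom), length.out = n_genes)
      starts <- integer(n_genes); chrom_of <- chroms[per]
      for (ci in seq_len(n_chrom)) {
        idx <- which(per == ci)
        taken <- IRanges()
        pos <- integer(0)
        guard <- 0L
        while (length(pos) < length(idx)) {
          cand <- sample.int(chrom_length - gene_length, 1L)
          ir <- IRanges(cand, cand + gene_length - 1L)
          if (!any(overlapsAny(ir, taken))) {
            taken <- c(taken, ir)
            pos <- c(pos, cand)
          }
          guard <- guard + 1L
          if (guard > 50L * length(idx))
            stop("failed to place non-overlapping genes", call. = FALSE)
        }
        starts[idx] <- pos
      }
      strand <- sample(c("+", "-"), n_genes, replace = TRUE)
      genes <- GRanges(chrom_of, IRanges(starts, width = gene_length),
                       strand = strand, seqinfo = si)
      genes$gene_id <- sprintf("g%04d", seq_len(n_genes))
      genes$tss <- ifelse(strand == "+", start(genes), end(genes))
    }
    elements <- GRanges(seqinfo = si)
    if (n_elements > 0) {
      if (!is.null(element_max_dist) && n_genes > 0) {
        gi <- sample.int(n_genes, n_elements, replace = TRUE)
        centers <- genes$tss[gi] +
          sample(seq(-element_max_dist, element_max_dist), n_elements,
                 replace = TRUE)
        centers <- pmin(pmax(centers, element_width), chrom_length - element_width)
        e_chrom <- as.character(seqnames(genes))[gi]
      } else {
        e_chrom <- sample(chroms, n_elements, replace = TRUE)
        centers <- sample.int(chrom_length - element_width, n_elements,
                              replace = TRUE) + element_width %/% 2
      }
      elements <- GRanges(e_chrom,
                          IRanges(centers - element_width %/% 2,
                                  width = element_width), seqinfo = si)
      if (n_genes > 0) {
        tss <- GRanges(seqnames(genes), IRanges(genes$tss, width = 1),
                       seqinfo = si)
        mid <- GRanges(seqnames(elements),
                       IRanges(start(elements) + element_width %/% 2, width = 1),
                       seqinfo = si)
        hits <- distanceToNearest(mid, tss)
        d <- rep(Inf, n_elements)
        d[queryHits(hits)] <- mcols(hits)$distance
      } else d <- rep(Inf, n_elements)
      elements$class <- ifelse(d <= 200, "PLS",
                               ifelse(d <= 2000, "pELS", "dELS"))
    }
    new("SyntheticGenome", seqinfo = si, genes = genes, elements = elements)
  })
}

#' Study design sheet
#'
#' @param cell_lines Cell-line labels.
#' @param treatments Ordered treatment labels (subset of `DMSO`, `acute`,
#'   `DTP`, `short_washout`, `long_washout`).
#' @param replicates Replicates per (cell line, treatment) group; at least 2
#'   so group variances are estimable.
#' @return `data.frame` with `sample`, `cell_line`, `treatment`, `replicate`.
#' @export
designSpec <- function(cell_lines = c("PC9", "H1975"),
                       treatments = c("DMSO", "acute", "DTP",
                                      "short_washout", "long_washout"),
                       replicates = 3) {
  stopifnot2(replicates >= 2, "need >= 2 replicates per group")
  canonical <- c("DMSO", "acute", "DTP", "short_washout", "long_washout")
  stopifnot2(all(treatments %in% canonical), "unknown treatment label")
  d <- expand.grid(replicate = seq_len(replicates), treatment = treatments,
                   cell_line = cell_lines, stringsAsFactors = FALSE)
  d$sample <- sprintf("%s_%s_r%d", d$cell_line, d$treatment, d$replicate)
  d[, c("sample", "cell_line", "treatment", "replicate")]
}

# Temporal archetype patterns (log2FC vs DMSO per treatment), emulating the
# recurring time-course cluster shapes: (1) acute down with gradual
# recovery, (2) acute-only up, (3) persistent DTP up surviving washout,
# (4) persistent DTP down.
archetypeLibrary <- function(lfc) {
  list("1" = c(DMSO = 0, acute = -lfc, DTP = -lfc / 2,
               short_washout = -lfc / 4, long_washout = 0),
       "2" = c(DMSO = 0, acute = lfc, DTP = 0,
               short_washout = 0, long_washout = 0),
       "3" = c(DMSO = 0, acute = 0, DTP = lfc,
               short_washout = lfc, long_washout = lfc),
       "4" = c(DMSO = 0, acute = 0, DTP = -lfc,
               short_washout = -lfc, long_washout = -lfc))
}

#' Planted differential effects for the count simulator
#'
#' Assigns temporal archetypes (round-robin) to the first `n_diff` genes,
#' log-normal baseline means and a common negative-binomial dispersion, and
#' flags a fraction of the differential genes as concordant (candidates for
#' a same-direction chromatin effect).
#'
#' @param gene_ids Feature identifiers.
#' @param treatments Treatment labels the design will use.
#' @param n_diff Number of differential genes.
#' @param lfc Log2 fold-change magnitude of the archetype patterns.
#' @param dispersion NB dispersion (0 gives Poisson counts).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters.
#' @param concordant_frac Fraction of differential genes flagged concordant.
#' @param seed Integer seed.
#' @return List of class `EffectSpec`: `lfc` (genes x treatments matrix),
#'   `baseline`, `dispersion`, `archetype`, `is_diff`, `concordant`.
#' @export
effectSpec <- function(gene_ids, treatments = c("DMSO", "acute", "DTP",
                                                "short_washout",
                                                "long_washout"),
                       n_diff = 100, lfc = 2, dispersion = 0.1,
                       baseline_meanlog = 5, baseline_sdlog = 1,
                       concordant_frac = 0.5, seed = 1L) {
  stopifnot2(dispersion >= 0, "dispersion must be >= 0")
  stopifnot2(n_diff <= length(gene_ids), "n_diff exceeds the gene count")
  n <- length(gene_ids)
  lib <- archetypeLibrary(lfc)
  withSeed(seed, {
    baseline <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
    archetype <- rep(NA_character_, n)
    lfc_mat <- matrix(0, n, length(treatments),
                      dimnames = list(gene_ids, treatments))
    if (n_diff > 0) {
      archetype[seq_len(n_diff)] <- rep(names(lib), length.out = n_diff)
      for (i in seq_len(n_diff))
        lfc_mat[i, ] <- lib[[archetype[i]]][treatments]
    }
    concordant <- rep(FALSE, n)
    if (n_diff > 0)
      concordant[seq_len(n_diff)] <-
        stats::runif(n_diff) < concordant_frac
    structure(list(lfc = lfc_mat, baseline = baseline,
                   dispersion = dispersion, archetype = archetype,
                   is_diff = !is.na(archetype), concordant = concordant),
              class = "EffectSpec")
  })
}

#' Simulate a gene x sample count matrix
#'
#' Counts are negative-binomial with mean
#' `baseline * 2^lfc(treatment) * size_factor * line_offset`, where
#' log-normal library-size factors (sd 0.1) exercise CPM normalization and
#' per-(gene, cell line) log-normal offsets (sd `line_sd`) reproduce the
#' cell-line-dominant variance structure seen in expression PCA. Dispersion
#' 0 yields Poisson sampling.
#'
#' @param design A [designSpec()] sheet.
#' @param effects An [effectSpec()].
#' @param seed Integer seed.
#' @param line_sd SD of the per-(gene, line) log-normal baseline offset.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, the design as `colData`, the truth as `rowData`, and size
#'   factors in `metadata()$size_factors`.
#' @export
simulateCounts <- function(design, effects, seed = 1L, line_sd = 0.5) {
  stopifnot2(inherits(effects, "EffectSpec"), "effects must come from effectSpec()")
  stopifnot2(all(design$treatment %in% colnames(effects$lfc)),
             "design treatments missing from effects$lfc")
  n <- length(effects$baseline)
  gene_ids <- rownames(effects$lfc)
  lines <- unique(design$cell_line)
  withSeed(seed, {
    sf <- stats::rlnorm(nrow(design), 0, 0.1)
    offs <- matrix(stats::rlnorm(n * length(lines), 0, line_sd), n,
                   dimnames = list(gene_ids, lines))
    mu <- sapply(seq_len(nrow(design)), function(s) {
      effects$baseline * 2^effects$lfc[, design$treatment[s]] *
        sf[s] * offs[, design$cell_line[s]]
    })
    stopifnot2(all(mu >= 0), "negative mean encountered")
    counts <- if (effects$dispersion == 0)
      matrix(stats::rpois(length(mu), mu), nrow = n)
    else
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / effects$dispersion), nrow = n)
    dimnames(counts) <- list(gene_ids, design$sample)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(design, row.names = design$sample),
      rowData = S4Vectors::DataFrame(
        baseline = effects$baseline, dispersion = effects$dispersion,
        archetype = effects$archetype, is_diff = effects$is_diff,
        concordant = effects$concordant, effects$lfc,
        row.names = gene_ids))
    S4Vectors::metadata(se)$size_factors <- sf
    se
  })
}

#' Simulate per-sample peak calls and a peak count matrix
#'
#' True peak locations are shared across samples; each sample reports a
#' variable-width call with a jittered summit and an abundance-derived
#' score. The first `n_diff` peaks gain accessibility in the `DTP`
#' treatment with log2 fold change `lfc`; when `link_truth` is given, a
#' fraction `link_frac` of differential peaks is placed within `link_dist`
#' of the corresponding genes' TSSs with matching effect direction.
#' Per-sample-only noise calls (not reproducible across replicates) are
#' appended to exercise the reproducibility filter.
#'
#' @param genome A [SyntheticGenome-class].
#' @param design A [designSpec()] sheet (typically `DMSO` + `DTP`).
#' @param seed Integer seed.
#' @param n_peaks Number of true peaks.
#' @param n_diff Number of differential (DTP-gained/lost) peaks.
#' @param lfc Log2 fold change of differential peaks in `DTP` (sign taken
#'   from the linked gene where linked).
#' @param dispersion NB dispersion of peak counts.
#' @param link_truth Optional `data.frame` with `gene_id` and `lfc` (the RNA
#'   truth) used to place concordant peaks.
#' @param link_frac Fraction of differential peaks linked to genes.
#' @param link_dist Maximum distance (bp) from a linked peak center to the
#'   gene TSS.
#' @param summit_jitter SD (bp) of per-sample summit jitter.
#' @param n_noise Noise calls per sample.
#' @return A list: `peaks` (truth `GRanges`, fixed 500 bp, with mcols
#'   `peak_id`, `is_diff`, `lfc`, `linked_gene`), `calls` (`GRangesList`
#'   per sample with `summit`, `score`), `counts` (peaks x samples),
#'   `called` (logical matrix), `design`.
#' @export
simulatePeaks <- function(genome, design, seed = 1L, n_peaks = 500,
                          n_diff = 50, lfc = 2, dispersion = 0.1,
                          link_truth = NULL, link_frac = 0.5,
                          link_dist = 5e4, summit_jitter = 5,
                          n_noise = 10) {
  si <- genome@seqinfo
  chroms <- seqlevels(si)
  clen <- seqlengths(si)[1]
  stopifnot2(n_peaks * 600 <= 0.8 * length(chroms) * clen,
             "peak density exceeds genome capacity")
  withSeed(seed, {
    # Linked differential peaks go near their genes' TSSs first.
    centers <- integer(0); chrom_of <- character(0)
    linked_gene <- rep(NA_character_, n_peaks)
    peak_lfc <- rep(0, n_peaks)
    if (n_diff > 0) peak_lfc[seq_len(n_diff)] <- lfc
    n_linked <- 0L
    if (!is.null(link_truth) && n_diff > 0) {
      n_linked <- min(round(link_frac * n_diff), nrow(link_truth), n_diff)
      if (n_linked > 0) {
        g <- genes(genome)
        sel <- match(link_truth$gene_id[seq_len(n_linked)], g$gene_id)
        stopifnot2(all(!is.na(sel)), "link_truth gene absent from genome")
        off <- sample(seq(-link_dist, link_dist), n_linked, replace = TRUE)
        centers <- pmin(pmax(g$tss[sel] + off, 300L), clen - 300L)
        chrom_of <- as.character(seqnames(g))[sel]
        linked_gene[seq_len(n_linked)] <- link_truth$gene_id[seq_len(n_linked)]
        peak_lfc[seq_len(n_linked)] <- abs(lfc) *
          sign(link_truth$lfc[seq_len(n_linked)])
      }
    }
    # Remaining peaks: uniform, min 600 bp separation within chromosome.
    need <- n_peaks - length(centers)
    if (need > 0) {
      ch <- sample(chroms, need, replace = TRUE)
      pos <- integer(need)
      for (ci in unique(ch)) {
        idx <- which(ch == ci)
        avoid <- centers[chrom_of == ci]
        got <- integer(0); guard <- 0L
        while (length(got) < length(idx)) {
          cand <- sample.int(clen - 600L, 1L) + 300L
          if (all(abs(cand - c(avoid, got)) >= 600L)) got <- c(got, cand)
          guard <- guard + 1L
          if (guard > 200L * length(idx))
            stop("failed to place peaks", call. = FALSE)
        }
        pos[idx] <- got
      }
      centers <- c(centers, pos)
      chrom_of <- c(chrom_of, ch)
    }
    peaks <- GRanges(chrom_of, IRanges(centers - 249L, width = 500L),
                     seqinfo = si)
    peaks$peak_id <- sprintf("peak%05d", seq_len(n_peaks))
    peaks$summit <- centers
    peaks$is_diff <- seq_len(n_peaks) <= n_diff
    peaks$lfc <- peak_lfc
    peaks$linked_gene <- linked_gene

    baseline <- stats::rlnorm(n_peaks, 4, 0.6)
    sf <- stats::rlnorm(nrow(design), 0, 0.1)
    mu <- sapply(seq_len(nrow(design)), function(s) {
      l <- if (design$treatment[s] == "DTP") peak_lfc else 0
      baseline * 2^l * sf[s]
    })
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / max(dispersion, 1e-8)),
                     nrow = n_peaks,
                     dimnames = list(peaks$peak_id, design$sample))
    called <- matrix(TRUE, n_peaks, nrow(design),
                     dimnames = dimnames(counts))

    calls <- lapply(seq_len(nrow(design)), function(s) {
      summ <- centers + round(stats::rnorm(n_peaks, 0, summit_jitter))
      half <- sample(150:350, n_peaks, replace = TRUE)
      gr <- GRanges(chrom_of,
                    IRanges(pmax(summ - half, 1L),
                            pmin(summ + half, clen)), seqinfo = si)
      gr$summit <- summ
      gr$score <- unname(log1p(counts[, s]) * 10 +
                           stats::rnorm(n_peaks, 0, 0.5))
      if (n_noise > 0) {
        nc <- sample.int(clen - 600L, n_noise) + 300L
        ng <- GRanges(sample(chroms, n_noise, replace = TRUE),
                      IRanges(nc - 200L, nc + 200L), seqinfo = si)
        ng$summit <- nc
        ng$score <- stats::runif(n_noise, 2, 8)
        gr <- c(gr, ng)
      }
      gr
    })
    names(calls) <- design$sample
    list(peaks = peaks, calls = GRangesList(calls), counts = counts,
         called = called, design = design)
  })
}

#' Embed motif instances in background peak sequences
#'
#' Generates i.i.d. background nucleotides at the stated GC content and
#' inserts one PWM-sampled instance (random offset, random strand) into a
#' stated fraction of sequences.
#'
#' @param n_peaks Number of sequences.
#' @param motif A [MotifModel-class].
#' @param occupancy Fraction of sequences receiving a planted instance.
#' @param gc Background GC fraction.
#' @param width Sequence width (bp); must be at least the motif width.
#' @param seed Integer seed.
#' @param prefix Sequence-name prefix.
#' @return List with `seqs` (a [Biostrings::DNAStringSet]) and `truth`
#'   (`data.frame`: `peak`, `planted`, `offset`, `strand`).
#' @export
embedMotifs <- function(n_peaks, motif, occupancy = 0.5, gc = 0.41,
                        width = 500, seed = 1L, prefix = "peak") {
  stopifnot2(occupancy >= 0 && occupancy <= 1, "occupancy must be in [0, 1]")
  w <- motifWidth(motif)
  stopifnot2(w <= width, "motif longer than peak sequence")
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  withSeed(seed, {
    planted <- stats::runif(n_peaks) < occupancy
    seqs <- character(n_peaks)
    offset <- rep(NA_integer_, n_peaks)
    strand <- rep(NA_character_, n_peaks)
    for (i in seq_len(n_peaks)) {
      s <- sample(bases, width, replace = TRUE, prob = probs)
      if (planted[i]) {
        inst <- vapply(seq_len(w), function(j)
          sample(bases, 1, prob = motif@pfm[, j]), character(1))
        st <- sample(c("+", "-"), 1)
        if (st == "-")
          inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
        o <- sample.int(width - w + 1L, 1L)
        s[o:(o + w - 1L)] <- inst
        offset[i] <- o; strand[i] <- st
      }
      seqs[i] <- paste(s, collapse = "")
    }
    nm <- sprintf("%s%04d", prefix, seq_len(n_peaks))
    list(seqs = stats::setNames(Biostrings::DNAStringSet(seqs), nm),
         truth = data.frame(peak = nm, planted = planted,
                            offset = offset, strand = strand))
  })
}

#' Generate a random signed regulator network with a planted active regulator
#'
#' Builds a bipartite signed regulator-to-target graph. The planted
#' regulator's targets receive observed directions agreeing with
#' `edge sign x planted direction` at the stated concordance rate; every
#' other signature gene's direction is random.
#'
#' @param n_regulators Number of regulators.
#' @param targets_per Targets per regulator.
#' @param sign_mix Probability an edge is activating (+1).
#' @param planted_regulator Identifier of the planted regulator (one of
#'   `R01`, `R02`, ...).
#' @param planted_direction Hypothesized activity direction of the planted
#'   regulator (+1 or -1).
#' @param concordance Fraction of the planted regulator's targets whose
#'   observed direction matches the prediction.
#' @param n_genes Size of the target gene pool.
#' @param n_signature Signature size (planted targets are always included).
#' @param seed Integer seed.
#' @return List with `edges` (`data.frame`: `source`, `target`, `sign`),
#'   `signature` (named vector of observed directions) and `planted`.
#' @export
makeNetwork <- function(n_regulators = 20, targets_per = 50, sign_mix = 0.5,
                        planted_regulator = "R01", planted_direction = 1L,
                        concordance = 1.0, n_genes = 2000,
                        n_signature = 500, seed = 1L) {
  stopifnot2(n_regulators >= 1 && targets_per >= 1, "need positive sizes")
  stopifnot2(n_genes >= targets_per, "gene pool smaller than out-degree")
  regs <- sprintf("R%02d", seq_len(n_regulators))
  stopifnot2(planted_regulator %in% regs, "planted regulator not in network")
  pool <- sprintf("g%04d", seq_len(n_genes))
  withSeed(seed, {
    edges <- do.call(rbind, lapply(regs, function(r) {
      data.frame(source = r,
                 target = sample(pool, targets_per),
                 sign = ifelse(stats::runif(targets_per) < sign_mix, 1L, -1L))
    }))
    planted_targets <- edges$target[edges$source == planted_regulator]
    sig_genes <- unique(c(planted_targets,
                          sample(pool, min(n_signature, n_genes))))
    sig_genes <- utils::head(sig_genes, max(n_signature, length(planted_targets)))
    dirs <- sample(c(-1L, 1L), length(sig_genes), replace = TRUE)
    names(dirs) <- sig_genes
    psign <- edges$sign[edges$source == planted_regulator]
    predicted <- planted_direction * psign
    agree <- stats::runif(length(planted_targets)) < concordance
    dirs[planted_targets] <- ifelse(agree, predicted, -predicted)
    list(edges = edges, signature = dirs,
         planted = list(regulator = planted_regulator,
                        direction = planted_direction))
  })
}
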