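#' Fisher's method for combining p-values
#'
#' `X = -2 * sum(log(p))` compared to the upper tail of a chi-square with
#' `2k` degrees of freedom.
#'
#' @param p Vector of p-values (the study combines BH-adjusted values).
#' @return List with `statistic` (X) and `p` (combined).
#' @export
fisherCombine <- function(p) {
  checkProb(p)
  stopifnot2(length(p) >= 1, "need at least one p-value")
  X <- -2 * sum(log(p))
  list(statistic = X,
       p = stats::pchisq(X, df = 2 * length(p), lower.tail = FALSE))
}

#' Cross-cell-line meta-analysis of differential peaks
#'
#' Intersects per-cell-line differential peak tables (consensus windows) by
#' genomic overlap: a record is emitted for every peak of the first cell
#' line that overlaps a peak in every other line. Contributing log2 fold
#' changes are averaged, direction consistency flagged, and adjusted
#' p-values combined with Fisher's method (chi-square with 2k df).
#'
#' @param tables Named list (one per cell line) of `GRanges` with mcols
#'   `log2fc` and `padj`.
#' @param combine Combine `"padj"` (as the study does; conservative) or raw
#'   `"p"` if present.
#' @return A `GRanges` (intervals of the first line) with per-line
#'   `log2fc.<line>` / `padj.<line>` mcols plus `avg_log2fc`,
#'   `consistent_direction`, `fisher_statistic`, `combined_p`, `k`.
#' @export
metaIntersect <- function(tables, combine = c("padj", "p")) {
  combine <- match.arg(combine)
  stopifnot2(length(tables) >= 1, "need at least one cell line table")
  stopifnot2(!is.null(names(tables)) && all(nzchar(names(tables))),
             "tables must be named by cell line")
  for (tb in tables)
    stopifnot2(is(tb, "GRanges") &&
                 all(c("log2fc", "padj") %in% names(mcols(tb))),
               "each table needs log2fc and padj mcols")
  base <- tables[[1]]
  k <- length(tables)
  idx <- matrix(NA_integer_, length(base), k)
  idx[, 1] <- seq_along(base)
  keep <- rep(TRUE, length(base))
  if (k > 1) for (j in 2:k) {
    hits <- findOverlaps(base, tables[[j]], select = "first")
    idx[, j] <- hits
    keep <- keep & !is.na(hits)
  }
  base <- base[keep]
  idx <- idx[keep, , drop = FALSE]
  lfc <- sapply(seq_len(k), function(j) tables[[j]]$log2fc[idx[, j]])
  lfc <- matrix(lfc, ncol = k)
  pv <- sapply(seq_len(k), function(j) {
    tb <- tables[[j]]
    col <- if (combine == "p" && "p" %in% names(mcols(tb))) tb$p else tb$padj
    col[idx[, j]]
  })
  pv <- matrix(pv, ncol = k)
  mc <- mcols(base)[, character(0)]
  for (j in seq_len(k)) {
    mc[[paste0("log2fc.", names(tables)[j])]] <- lfc[, j]
    mc[[paste0("padj.", names(tables)[j])]] <- pv[, j]
  }
  mc$avg_log2fc <- rowMeans(lfc)
  mc$consistent_direction <- apply(lfc, 1, function(x)
    all(x > 0) || all(x < 0))
  mc$fisher_statistic <- -2 * rowSums(log(pv))
  mc$combined_p <- stats::pchisq(mc$fisher_statistic, df = 2 * k,
                                 lower.tail = FALSE)
  mc$k <- k
  mcols(base) <- mc
  base
}

#' Classify RNA-ATAC concordance per gene
#'
#' Per gene, the chromatin effect is summarized over its linked significant
#' peaks (mean log2 fold change, or the strongest peak). Classes:
#' `concordant_up` / `concordant_down` require at least `lfc_cut` log2
#' change in the same direction in both assays with both FDRs below
#' `fdr_cut`; genes significant in both assays that miss those bounds are
#' `discordant`; genes significant in one assay only are `rna_only` /
#' `atac_only`; the rest are `ns`. The classes partition the gene list.
#'
#' @param rna `data.frame` with `gene`, `log2fc`, `fdr`.
#' @param atac `data.frame` with `peak`, `log2fc`, `fdr`.
#' @param links `data.frame` with `peak`, `gene` (from TSS-distance
#'   annotation).
#' @param fdr_cut,lfc_cut Significance and effect cutoffs (default
#'   FDR < 0.005 and two-fold).
#' @param peak_summary `"mean"` or `"strongest"` linked-peak summary.
#' @return `data.frame` per gene: `gene`, `rna_log2fc`, `rna_fdr`,
#'   `atac_log2fc`, `atac_fdr`, `class`.
#' @export
classifyConcordance <- function(rna, atac, links, fdr_cut = 0.005,
                                lfc_cut = 1,
                                peak_summary = c("mean", "strongest")) {
  peak_summary <- match.arg(peak_summary)
  stopifnot2(!anyDuplicated(rna$gene), "duplicate gene rows in rna table")
  atac_sig <- atac[atac$fdr < fdr_cut, , drop = FALSE]
  li <- merge(links, atac_sig, by = "peak")
  atac_by_gene <- if (nrow(li) > 0) {
    sp <- split(li, li$gene)
    do.call(rbind, lapply(sp, function(d) {
      if (peak_summary == "mean")
        data.frame(gene = d$gene[1], atac_log2fc = mean(d$log2fc),
                   atac_fdr = min(d$fdr))
      else {
        i <- which.max(abs(d$log2fc))
        data.frame(gene = d$gene[1], atac_log2fc = d$log2fc[i],
                   atac_fdr = d$fdr[i])
      }
    }))
  } else data.frame(gene = character(), atac_log2fc = numeric(),
                    atac_fdr = numeric())
  out <- merge(data.frame(gene = rna$gene, rna_log2fc = rna$log2fc,
                          rna_fdr = rna$fdr),
               atac_by_gene, by = "gene", all.x = TRUE)
  rna_sig <- out$rna_fdr < fdr_cut
  atac_sig_g <- !is.na(out$atac_log2fc)
  cls <- rep("ns", nrow(out))
  both <- rna_sig & atac_sig_g
  up <- both & out$rna_log2fc >= lfc_cut & out$atac_log2fc >= lfc_cut
  dn <- both & out$rna_log2fc <= -lfc_cut & out$atac_log2fc <= -lfc_cut
  cls[both] <- "discordant"
  cls[up] <- "concordant_up"
  cls[dn] <- "concordant_down"
  cls[rna_sig & !atac_sig_g] <- "rna_only"
  cls[!rna_sig & atac_sig_g] <- "atac_only"
  out$class <- cls
  out[order(out$gene), , drop = FALSE]
}

#' Merged-evidence pathway enrichment
#'
#' Evidence genes are the union of RNA-passing genes and genes with a
#' linked ATAC-passing peak after the stated filter (at least `lfc_cut`
#' absolute log2 fold change and adjusted p below `p_cut`). Each gene set
#' is scored with the hypergeometric upper tail of its overlap with the
#' evidence list against the universe of tested genes, BH-adjusted across
#' sets.
#'
#' @param rna `data.frame` with `gene`, `log2fc`, `fdr` (the universe is
#'   its gene column).
#' @param atac `data.frame` with `peak`, `log2fc`, `fdr`; may have zero
#'   rows for RNA-only enrichment.
#' @param links `data.frame` with `peak`, `gene`.
#' @param gene_sets Named list of character vectors.
#' @param lfc_cut Absolute log2 fold-change filter (default two-fold).
#' @param p_cut Adjusted-p filter.
#' @return `data.frame` ranked by FDR: `set`, `set_size`, `overlap`,
#'   `evidence_n`, `universe_n`, `p`, `fdr`, `evidence` (per-set gene
#'   labels `gene(rna|atac|both)`).
#' @export
mergedEnrichment <- function(rna, atac, links, gene_sets, lfc_cut = 1,
                             p_cut = 0.005) {
  universe <- unique(rna$gene)
  stopifnot2(length(universe) > 0, "empty gene universe")
  ev_rna <- rna$gene[abs(rna$log2fc) >= lfc_cut & rna$fdr < p_cut]
  atac_pass <- atac[abs(atac$log2fc) >= lfc_cut & atac$fdr < p_cut, ,
                    drop = FALSE]
  ev_atac <- unique(merge(links, atac_pass, by = "peak")$gene)
  ev_atac <- intersect(ev_atac, universe)
  evidence <- union(ev_rna, ev_atac)
  N <- length(universe); E <- length(evidence)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    ov <- intersect(set, evidence)
    p <- stats::phyper(length(ov) - 1, E, N - E, length(set),
                       lower.tail = FALSE)
    lab <- vapply(ov, function(g) {
      src <- c("rna", "atac")[c(g %in% ev_rna, g %in% ev_atac)]
      paste0(g, "(", if (length(src) == 2) "both" else src, ")")
    }, character(1))
    data.frame(set = nm, set_size = length(set), overlap = length(ov),
               evidence_n = E, universe_n = N, p = p,
               evidence = paste(lab, collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p)
  out <- out[order(out$fdr, out$p, out$set),
             c("set", "set_size", "overlap", "evidence_n", "universe_n",
               "p", "fdr", "evidence")]
  rownames(out) <- NULL
  out
}
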