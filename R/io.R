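# Text I/O for the formats the pipeline consumes and emits. All writers are
# deterministic so identical inputs produce byte-identical files.

#' Read / write long-format confluence traces
#'
#' Columns: `cell_line`, `compound`, `arm`, `replicate`, `time_h`,
#' `confluence_pct` (tab-separated, IncuCyte-style export shape).
#'
#' @param traces Trace `data.frame`.
#' @param path File path.
#' @return `readTraces` returns the `data.frame`; `writeTraces` its path,
#'   invisibly.
#' @export
writeTraces <- function(traces, path) {
  utils::write.table(traces, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraces
#' @export
readTraces <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Read / write a count matrix as TSV
#'
#' Feature identifiers in the first column (`feature`), one column per
#' sample.
#'
#' @param counts Numeric matrix with row and column names.
#' @param path File path.
#' @return `readCounts` returns the matrix.
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write narrowPeak files
#'
#' Ten-column BED extension: chrom, chromStart (0-based), chromEnd, name,
#' score, strand, signalValue, pValue, qValue, summit offset from
#' chromStart. Internally ranges are 1-based closed (`GRanges`); the summit
#' is stored as an absolute 1-based position in the `summit` mcol.
#'
#' @param peaks `GRanges` with mcols `summit` and `score`.
#' @param path File path.
#' @return `readNarrowPeak` returns a `GRanges` with `name`, `score`,
#'   `signal`, `p`, `q`, `summit` mcols.
#' @export
writeNarrowPeak <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    chromStart = start(peaks) - 1L,
    chromEnd = end(peaks),
    name = if (!is.null(peaks$peak_id)) peaks$peak_id else
      if (!is.null(peaks$name)) peaks$name else
        sprintf("peak%05d", seq_along(peaks)),
    score = round(pmin(pmax(peaks$score, 0), 1000)),
    strand = ".",
    signalValue = signif(peaks$score, 6),
    pValue = -1, qValue = -1,
    peak = peaks$summit - start(peaks))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeNarrowPeak
#' @export
readNarrowPeak <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "chromStart", "chromEnd",
                                        "name", "score", "strand", "signal",
                                        "p", "q", "peak"))
  gr <- GRanges(df$chrom, IRanges(df$chromStart + 1L, df$chromEnd))
  gr$name <- df$name
  gr$score <- df$signal
  gr$signal <- df$signal
  gr$p <- df$p
  gr$q <- df$q
  gr$summit <- df$chromStart + 1L + df$peak
  gr
}

#' Read / write gene annotation as BED6-like TSV
#'
#' Columns: chrom, start (0-based), end, gene_id, tss (absolute, 1-based),
#' strand.
#'
#' @param genome A [SyntheticGenome-class] (writer) / file path (reader).
#' @param path File path.
#' @return `readGenesBED` returns a `GRanges` with `gene_id`, `tss`.
#' @export
writeGenesBED <- function(genome, path) {
  g <- genes(genome)
  df <- data.frame(chrom = as.character(seqnames(g)), start = start(g) - 1L,
                   end = end(g), gene_id = g$gene_id, tss = g$tss,
                   strand = as.character(strand(g)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeGenesBED
#' @export
readGenesBED <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "gene_id",
                                        "tss", "strand"))
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                strand = df$strand)
  gr$gene_id <- df$gene_id
  gr$tss <- df$tss
  gr
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @return `readGMT` returns a named list.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGMT
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, character(1), 1))
}

#' Read / write motif models in JASPAR PFM format
#'
#' Header line `>ID name`, then four rows `A [ counts... ]` etc.
#'
#' @param motifs List of [MotifModel-class] objects (writer).
#' @param path File path.
#' @param background,threshold Passed to [motifModel()] on read (`NULL`
#'   threshold uses the constructor default).
#' @return `readJASPAR` returns a list of `MotifModel`s.
#' @export
writeJASPAR <- function(motifs, path) {
  if (inherits(motifs, "MotifModel")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m@id, " ", m@id), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m@pfm[b, ], digits = 6),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname writeJASPAR
#' @export
readJASPAR <- function(path, background = rep(0.25, 4), threshold = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  stopifnot2(length(starts) > 0, "no motif headers in file")
  lapply(starts, function(s) {
    id <- strsplit(sub("^>", "", lines[s]), "[ \t]+")[[1]][1]
    rows <- lines[(s + 1):(s + 4)]
    vals <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt][ \t]*\\[?|\\]$", "", trimws(r))
      as.numeric(strsplit(trimws(gsub("\\]", "", r)), "[ \t]+")[[1]])
    })
    mat <- do.call(rbind, vals)
    rownames(mat) <- c("A", "C", "G", "T")
    motifModel(id, mat, background = background, threshold = threshold)
  })
}

#' Read / write signed regulator networks
#'
#' Three-column TSV: source, target, sign (+1 / -1), with a header.
#'
#' @param edges `data.frame` with `source`, `target`, `sign`.
#' @param path File path.
#' @return `readNetwork` returns the edge `data.frame`.
#' @export
writeNetwork <- function(edges, path) {
  utils::write.table(edges[, c("source", "target", "sign")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Read / write FASTA sequence sets
#'
#' Thin wrappers over [Biostrings::writeXStringSet()] /
#' [Biostrings::readDNAStringSet()].
#'
#' @param seqs A `DNAStringSet`.
#' @param path File path.
#' @return `readFASTA` returns a `DNAStringSet`.
#' @export
writeFASTA <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname writeFASTA
#' @export
readFASTA <- function(path) Biostrings::readDNAStringSet(path)
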