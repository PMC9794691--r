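#' @import methods
#' @importFrom GenomicRanges GRanges start end width seqnames strand mcols
#'   mcols<- findOverlaps GRangesList distanceToNearest resize
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors DataFrame queryHits subjectHits metadata metadata<-
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels
NULL

#' SyntheticGenome: a small in-silico genome for pipeline testing
#'
#' Holds chromosome lengths, gene bodies with TSS/strand, and regulatory
#' elements classed by TSS distance (`PLS` promoter-like within 200 bp,
#' `pELS` proximal enhancer-like within 2 kb, `dELS` distal beyond).
#'
#' @slot seqinfo A [GenomeInfoDb::Seqinfo] with chromosome lengths.
#' @slot genes `GRanges` of gene bodies with mcols `gene_id` and `tss`
#'   (absolute TSS position; `start` for `+` genes, `end` for `-`).
#' @slot elements `GRanges` of regulatory elements with mcol `class`.
#'
#' @export
setClass("SyntheticGenome",
         representation(seqinfo = "Seqinfo", genes = "GRanges",
                        elements = "GRanges"))

setValidity("SyntheticGenome", function(object) {
  g <- object@genes
  msg <- character()
  if (length(g) > 0) {
    if (is.null(g$gene_id) || is.null(g$tss))
      msg <- c(msg, "genes need gene_id and tss mcols")
    else if (anyDuplicated(paste(seqnames(g), g$tss)))
      msg <- c(msg, "TSS positions must be unique per gene")
    lens <- seqlengths(object@seqinfo)[as.character(seqnames(g))]
    if (any(end(g) > lens) || any(start(g) < 1))
      msg <- c(msg, "gene outside chromosome bounds")
  }
  e <- object@elements
  if (length(e) > 0) {
    if (is.null(e$class) || !all(e$class %in% c("PLS", "pELS", "dELS")))
      msg <- c(msg, "element class must be PLS, pELS or dELS")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticGenome-class Accessor for the gene annotation.
#' @param x A `SyntheticGenome`.
#' @export
genes <- function(x) x@genes

#' @describeIn SyntheticGenome-class Accessor for the regulatory elements.
#' @export
regulatoryElements <- function(x) x@elements

setMethod("show", "SyntheticGenome", function(object) {
  cat("SyntheticGenome:", length(seqlevels(object@seqinfo)),
      "chromosome(s),", length(object@genes), "gene(s),",
      length(object@elements), "regulatory element(s)\n")
})

#' MotifModel: a position frequency matrix with scan parameters
#'
#' @slot id Motif identifier.
#' @slot pfm 4 x width probability matrix (rows A, C, G, T; columns sum
#'   to 1).
#' @slot background Background nucleotide frequencies (A, C, G, T).
#' @slot threshold Log2-odds score (bits) above which a scan position is an
#'   occurrence.
#'
#' @export
setClass("MotifModel",
         representation(id = "character", pfm = "matrix",
                        background = "numeric", threshold = "numeric"))

setValidity("MotifModel", function(object) {
  msg <- character()
  if (nrow(object@pfm) != 4 ||
      !identical(rownames(object@pfm), c("A", "C", "G", "T")))
    msg <- c(msg, "pfm must have rows A, C, G, T")
  else if (any(abs(colSums(object@pfm) - 1) > 1e-6))
    msg <- c(msg, "pfm columns must sum to 1")
  if (length(object@background) != 4 ||
      abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background must be 4 frequencies summing to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a MotifModel
#'
#' Accepts a count or probability matrix (4 x width, rows A/C/G/T);
#' columns are pseudocount-normalized to probabilities.
#'
#' @param id Motif identifier.
#' @param matrix 4 x width numeric matrix of counts or probabilities.
#' @param background Background frequencies, default uniform.
#' @param threshold Occurrence threshold in bits; defaults to 80% of the
#'   motif's maximum attainable score.
#' @param pseudocount Added to each matrix cell before normalization.
#' @return A `MotifModel`.
#' @export
motifModel <- function(id, matrix, background = rep(0.25, 4),
                       threshold = NULL, pseudocount = 0) {
  stopifnot2(nrow(matrix) == 4, "motif matrix must have 4 rows (A, C, G, T)")
  rownames(matrix) <- c("A", "C", "G", "T")
  pfm <- sweep(matrix + pseudocount, 2, colSums(matrix + pseudocount), "/")
  m <- new("MotifModel", id = id, pfm = pfm,
           background = background / sum(background),
           threshold = 0)
  if (is.null(threshold))
    threshold <- 0.8 * sum(log2(apply(pmax(pfm, 1e-3), 2, max) / min(m@background)))
  m@threshold <- threshold
  validObject(m)
  m
}

#' @describeIn MotifModel-class Motif width in bp.
#' @param x A `MotifModel`.
#' @export
motifWidth <- function(x) ncol(x@pfm)

#' @describeIn MotifModel-class The motif consensus string.
#' @export
motifConsensus <- function(x)
  paste(rownames(x@pfm)[apply(x@pfm, 2, which.max)], collapse = "")

setMethod("show", "MotifModel", function(object) {
  cat("MotifModel", object@id, "- width", ncol(object@pfm),
      "consensus", motifConsensus(object),
      "threshold", round(object@threshold, 2), "bits\n")
})
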