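#' Build an observed expression signature from a differential table
#'
#' Takes the top `n` genes ranked by ascending FDR (ties broken by larger
#' absolute log2 fold change, then identifier); genes with a zero fold
#' change carry no direction and are excluded before ranking, promoting the
#' next gene. Directions are the fold-change signs.
#'
#' @param diff `data.frame` with columns `gene` (or `feature`), `log2fc`,
#'   `fdr`.
#' @param n Signature size (default 500); a smaller table is used whole
#'   with a warning.
#' @return Named integer vector of directions (+1 / -1).
#' @export
buildSignature <- function(diff, n = 500) {
  gene_col <- if ("gene" %in% names(diff)) "gene" else "feature"
  stopifnot2(all(c(gene_col, "log2fc", "fdr") %in% names(diff)),
             "diff needs gene/feature, log2fc and fdr columns")
  d <- diff[diff$log2fc != 0, , drop = FALSE]
  d <- d[order(d$fdr, -abs(d$log2fc), d[[gene_col]]), , drop = FALSE]
  if (nrow(d) < n)
    warning("only ", nrow(d), " directed genes available; using all")
  d <- utils::head(d, n)
  stats::setNames(as.integer(sign(d$log2fc)), d[[gene_col]])
}

# Drop duplicate (source, target) pairs; conflicting-sign duplicates are
# ambiguous regulation and are removed entirely with a warning.
cleanNetwork <- function(network) {
  stopifnot2(all(c("source", "target", "sign") %in% names(network)),
             "network needs source, target, sign columns")
  stopifnot2(all(network$sign %in% c(-1L, 1L)), "edge signs must be +1/-1")
  key <- paste(network$source, network$target)
  nsign <- tapply(network$sign, key, function(s) length(unique(s)))
  amb <- names(nsign)[nsign > 1]
  if (length(amb) > 0) {
    warning(length(amb), " ambiguous (both-sign) edge(s) removed")
    network <- network[!(key %in% amb), , drop = FALSE]
    key <- paste(network$source, network$target)
  }
  network[!duplicated(key), , drop = FALSE]
}

#' Score candidate upstream regulators against an observed signature
#'
#' For regulator R under hypothesized direction h, every edge `R -> g` with
#' sign s predicts direction `h * s` for g. Among signature genes,
#' `n_correct` predictions match the observed direction and `n_incorrect`
#' do not. The analytic p-value is the binomial upper tail of `n_correct`
#' in `n_correct + n_incorrect` trials at the background match rate (the
#' signature's fraction of up genes, per predicted direction, averaged over
#' the regulator's observed edges). The permutation p-value ranks the
#' observed `n_correct - n_incorrect` among `B` random reassignments of the
#' observed directions over signature genes (or the exact full enumeration
#' over the regulator's targets when `exact = TRUE`).
#'
#' @param network `data.frame` with `source`, `target`, `sign` (+1 / -1).
#' @param signature Named direction vector from [buildSignature()].
#' @param B Number of permutations (ignored when `exact = TRUE`).
#' @param seed Seed for the permutations.
#' @param exact Enumerate all direction assignments of each regulator's
#'   observed targets (feasible for small out-degrees) instead of shuffling.
#' @param both_directions Score each regulator under both hypothesized
#'   directions (otherwise only the better-supported one is reported).
#' @return `data.frame` ranked by analytic then permutation p:
#'   `regulator`, `direction`, `n_correct`, `n_incorrect`, `n_unobserved`,
#'   `analytic_p`, `permutation_p`.
#' @export
scoreRegulators <- function(network, signature, B = 1000, seed = 1L,
                            exact = FALSE, both_directions = TRUE) {
  stopifnot2(nrow(network) > 0, "empty network")
  if (!exact) stopifnot2(B >= 1, "B must be >= 1")
  network <- cleanNetwork(network)
  f_up <- mean(signature == 1)

  obs <- network[network$target %in% names(signature), , drop = FALSE]
  obs$observed <- signature[obs$target]
  regs <- unique(network$source)
  hyp <- if (both_directions) c(1L, -1L) else 1L

  rows <- list()
  for (r in regs) {
    er <- obs[obs$source == r, , drop = FALSE]
    outdeg <- sum(network$source == r)
    for (h in hyp) {
      pred <- h * er$sign
      n_ok <- sum(er$observed == pred)
      n_bad <- nrow(er) - n_ok
      m <- nrow(er)
      p0 <- if (m > 0) mean(ifelse(pred == 1, f_up, 1 - f_up)) else NA_real_
      ap <- if (m > 0)
        stats::pbinom(n_ok - 1, m, p0, lower.tail = FALSE) else 1
      rows[[length(rows) + 1L]] <- data.frame(
        regulator = r, direction = h, n_correct = n_ok,
        n_incorrect = n_bad, n_unobserved = outdeg - m,
        analytic_p = ap, permutation_p = NA_real_)
    }
  }
  out <- do.call(rbind, rows)

  if (exact) {
    for (i in seq_len(nrow(out))) {
      r <- out$regulator[i]; h <- out$direction[i]
      er <- obs[obs$source == r, , drop = FALSE]
      m <- nrow(er)
      if (m == 0) { out$permutation_p[i] <- 1; next }
      stopifnot2(m <= 20, "exact enumeration limited to out-degree <= 20")
      pred <- h * er$sign
      stat_obs <- sum(er$observed == pred) - sum(er$observed != pred)
      p <- 0
      for (mask in 0:(2^m - 1)) {
        dirs <- ifelse(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0, 1L, -1L)
        w <- prod(ifelse(dirs == 1, f_up, 1 - f_up))
        stat <- sum(dirs == pred) - sum(dirs != pred)
        if (stat >= stat_obs) p <- p + w
      }
      out$permutation_p[i] <- p
    }
  } else {
    stats_obs <- out$n_correct - out$n_incorrect
    exceed <- integer(nrow(out))
    withSeed(seed, for (b in seq_len(B)) {
      perm <- stats::setNames(sample(unname(signature)), names(signature))
      po <- perm[obs$target]
      for (i in seq_len(nrow(out))) {
        sel <- obs$source == out$regulator[i]
        pred <- out$direction[i] * obs$sign[sel]
        stat <- sum(po[sel] == pred) - sum(po[sel] != pred)
        if (stat >= stats_obs[i]) exceed[i] <- exceed[i] + 1L
      }
    })
    out$permutation_p <- (1 + exceed) / (B + 1)
  }
  out <- out[order(out$analytic_p, out$permutation_p, out$regulator), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-regulator explanation table
#'
#' Expected versus observed direction for every observed target of one
#' regulator, mirroring signed-network node/edge semantics.
#'
#' @param network Edge table (`source`, `target`, `sign`).
#' @param signature Named direction vector.
#' @param regulator Regulator identifier.
#' @param direction Hypothesized direction (+1 / -1).
#' @return `data.frame`: `target`, `edge_sign`, `expected`, `observed`,
#'   `match`.
#' @export
explainRegulator <- function(network, signature, regulator, direction = 1L) {
  network <- cleanNetwork(network)
  er <- network[network$source == regulator &
                  network$target %in% names(signature), , drop = FALSE]
  data.frame(target = er$target, edge_sign = er$sign,
             expected = direction * er$sign,
             observed = unname(signature[er$target]),
             match = direction * er$sign == unname(signature[er$target]))
}
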