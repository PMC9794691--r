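#' Drop features without detectable expression in at least two samples
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @param min_samples Minimum number of samples with a nonzero count.
#' @return The filtered matrix.
#' @export
filterDetectable <- function(counts, min_samples = 2) {
  stopifnot2(is.matrix(counts) && all(counts >= 0),
             "counts must be a non-negative matrix")
  counts[rowSums(counts > 0) >= min_samples, , drop = FALSE]
}

#' Log2 counts-per-million normalization
#'
#' `log2((count + prior) / (library + 2 * prior) * 1e6)` per column, the
#' convention used both for expression matrices and for the accessibility
#' peak-abundance filter.
#'
#' @param counts Count matrix, features x samples.
#' @param prior_count Pseudo-count added to every count (default 0.5).
#' @return Matrix of log2-CPM values.
#' @export
normalizeLogCPM <- function(counts, prior_count = 0.5) {
  lib <- colSums(counts)
  stopifnot2(all(lib > 0), "zero library size column")
  log2(t(t(counts + prior_count) / (lib + 2 * prior_count)) * 1e6)
}

# Newton solve of trigamma(x) = y, vectorized; used by the variance
# moderation hyperparameter fit.
trigammaInv <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(dif / x), na.rm = TRUE) < 1e-12) break
  }
  x
}

# Method-of-moments empirical-Bayes fit of the scaled inverse chi-square
# prior on residual variances (prior variance s2_0, prior df d0). Operates
# on log variances; d0 = Inf when the observed spread is no larger than the
# chi-square sampling spread.
fitVariancePrior <- function(s2, d_res) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(d_res / 2) + log(d_res / 2)
  emean <- mean(e)
  G <- length(e)
  evar <- sum((e - emean)^2) / (G - 1)
  excess <- evar - trigamma(d_res / 2)
  if (excess <= 0)
    return(list(s2_prior = exp(emean), d_prior = Inf))
  d0 <- 2 * trigammaInv(excess)
  list(s2_prior = exp(emean + digamma(d0 / 2) - log(d0 / 2)), d_prior = d0)
}

#' Per-feature linear contrasts with empirical-Bayes moderation
#'
#' Fits ordinary least squares per feature under an intercept-free
#' treatment (+ optional cell-line covariate) design, shrinks residual
#' variances toward an empirical-Bayes prior estimated by method of moments
#' on log residual variances, and tests contrasts with moderated t
#' statistics (df = residual + prior df). A moderated F over the full
#' contrast set is also returned per feature.
#'
#' @param mat Numeric matrix (features x samples), typically log2-CPM.
#' @param samples `data.frame` with one row per column of `mat`, containing
#'   `treatment` and optionally `cell_line`. The design is
#'   `~0 + treatment + cell_line` when `cell_line` has more than one level,
#'   else `~0 + treatment`.
#' @param contrasts Named list; each element `c(level_plus, level_minus)`
#'   names two treatment levels, or is a full numeric contrast vector over
#'   design columns.
#' @param d_prior Override the estimated prior df (`0` forces ordinary t,
#'   `Inf` forces the pooled-prior z-like limit).
#' @return List with `records` (long `data.frame`: `feature`, `contrast`,
#'   `log2fc`, `t`, `p`, `fdr`), `F` (per-feature moderated F over all
#'   contrasts with `p`, `fdr`), and `moderation`
#'   (`s2_prior`, `d_prior`, `d_res`, `s2_posterior`).
#' @export
fitContrasts <- function(mat, samples, contrasts, d_prior = NULL) {
  stopifnot2(is.matrix(mat) && ncol(mat) == nrow(samples),
             "mat columns must match sample sheet rows")
  stopifnot2("treatment" %in% names(samples), "samples needs a treatment column")
  treatment <- factor(samples$treatment)
  has_line <- "cell_line" %in% names(samples) &&
    length(unique(samples$cell_line)) > 1
  design <- if (has_line) {
    cell_line <- factor(samples$cell_line)
    stats::model.matrix(~ 0 + treatment + cell_line)
  } else stats::model.matrix(~ 0 + treatment)

  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    bad <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    stop("design is rank deficient; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(design); p <- ncol(design)
  d_res <- n - p
  stopifnot2(d_res >= 1, "need at least one residual degree of freedom")

  beta <- t(qr.coef(qrX, t(mat)))              # features x p
  fitted <- beta %*% t(design)
  res <- mat - fitted
  s2 <- rowSums(res^2) / d_res
  xtxinv <- chol2inv(qr.R(qrX))

  L <- sapply(contrasts, function(ct) {
    if (is.numeric(ct) && length(ct) == p) return(ct)
    stopifnot2(length(ct) == 2, "contrast must be c(plus, minus) or numeric")
    v <- numeric(p)
    cols <- paste0("treatment", ct)
    stopifnot2(all(cols %in% colnames(design)),
               paste("unknown treatment level in contrast:",
                     paste(ct, collapse = " - ")))
    v[match(cols, colnames(design))] <- c(1, -1)
    v
  })
  L <- matrix(L, nrow = p, dimnames = list(colnames(design), names(contrasts)))

  prior <- fitVariancePrior(s2, d_res)
  if (!is.null(d_prior)) prior$d_prior <- d_prior
  d0 <- prior$d_prior
  s2_post <- if (is.infinite(d0)) rep(prior$s2_prior, length(s2)) else
    (d0 * prior$s2_prior + d_res * s2) / (d0 + d_res)
  df_total <- d_res + d0

  est <- beta %*% L                             # features x q
  u <- diag(t(L) %*% xtxinv %*% L)              # unscaled variances per contrast
  records <- do.call(rbind, lapply(seq_along(contrasts), function(j) {
    se <- sqrt(s2_post * u[j])
    tstat <- est[, j] / se
    pv <- 2 * stats::pt(-abs(tstat), df = df_total)
    data.frame(feature = rownames(mat) %||% as.character(seq_len(nrow(mat))),
               contrast = names(contrasts)[j],
               log2fc = est[, j], t = tstat, p = pv,
               fdr = bhAdjust(pv), row.names = NULL)
  }))

  # Moderated F over the full contrast set.
  V <- t(L) %*% xtxinv %*% L
  Vinv <- solve(V)
  q <- ncol(L)
  quad <- rowSums((est %*% Vinv) * est)
  Fstat <- quad / (q * s2_post)
  Fp <- stats::pf(Fstat, q, df_total, lower.tail = FALSE)
  Ftab <- data.frame(feature = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                     F = Fstat, p = Fp, fdr = bhAdjust(Fp), row.names = NULL)

  list(records = records, F = Ftab,
       moderation = list(s2_prior = prior$s2_prior, d_prior = d0,
                         d_res = d_res, s2_posterior = s2_post))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select features changing in several cell-line models by moderated F
#'
#' Features significant (FDR below `fdr_cut`) in at least `min_models` cell
#' lines are ranked by their best FDR across lines and truncated to `top_n`.
#'
#' @param f_tables Named list (one per cell line) of per-feature F tables as
#'   returned in `fitContrasts()$F`.
#' @param min_models Minimum number of lines a feature must be significant in.
#' @param top_n Maximum number of features returned.
#' @param fdr_cut Per-line significance cutoff.
#' @return `data.frame` with `feature`, `n_models`, `best_fdr`, FDR-sorted.
#' @export
moderatedFSelect <- function(f_tables, min_models = 3, top_n = 2000,
                             fdr_cut = 0.05) {
  stopifnot2(min_models <= length(f_tables),
             "min_models exceeds the number of cell lines")
  long <- do.call(rbind, lapply(names(f_tables), function(cl) {
    data.frame(feature = f_tables[[cl]]$feature, fdr = f_tables[[cl]]$fdr)
  }))
  sig <- long[long$fdr < fdr_cut, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(feature = character(), n_models = integer(),
                      best_fdr = numeric()))
  agg <- stats::aggregate(fdr ~ feature, data = sig,
                          FUN = function(x) c(n = length(x), best = min(x)))
  out <- data.frame(feature = agg$feature,
                    n_models = agg$fdr[, "n"],
                    best_fdr = agg$fdr[, "best"])
  out <- out[out$n_models >= min_models, , drop = FALSE]
  out <- out[order(out$best_fdr, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with input validation; order of the input vector
#' is preserved.
#'
#' @param p P-values in `[0, 1]` (NAs propagate).
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p) {
  checkProb(p[!is.na(p)], "p")
  stats::p.adjust(p, method = "BH")
}

#' Z-score by cell line and cluster expression patterns
#'
#' Each feature is Z-scored within every cell line's samples (zero-variance
#' rows map to 0), patterns are grouped by k-means with a fixed seed and
#' `nstart` restarts, and features within each cluster are ordered by the
#' leaf order of a complete-linkage Euclidean dendrogram.
#'
#' @param mat Features x samples matrix (e.g. log2-CPM or log2-TPM).
#' @param cell_line Cell-line label per column of `mat` (a single label
#'   Z-scores across all samples).
#' @param K Number of clusters.
#' @param seed Seed for the k-means restarts.
#' @param nstart Random restarts.
#' @return List with `z` (the Z-scored matrix), `cluster` (per-feature
#'   assignment) and `order` (row order: by cluster, dendrogram leaves
#'   within).
#' @export
zscoreAndCluster <- function(mat, cell_line = rep("all", ncol(mat)), K = 4,
                             seed = 1L, nstart = 25) {
  stopifnot2(K >= 1, "K must be >= 1")
  stopifnot2(nrow(mat) >= K, "need at least K features")
  z <- mat
  for (cl in unique(cell_line)) {
    idx <- which(cell_line == cl)
    sub <- mat[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sd <- apply(sub, 1, stats::sd)
    zs <- (sub - mu) / ifelse(sd == 0, 1, sd)
    zs[sd == 0, ] <- 0
    z[, idx] <- zs
  }
  km <- withSeed(seed, stats::kmeans(z, centers = K, nstart = nstart))
  ord <- unlist(lapply(sort(unique(km$cluster)), function(k) {
    idx <- which(km$cluster == k)
    if (length(idx) <= 2) return(idx)
    hc <- stats::hclust(stats::dist(z[idx, , drop = FALSE]),
                        method = "complete")
    idx[hc$order]
  }))
  list(z = z, cluster = km$cluster, order = unname(ord))
}

#' Single-sample gene-set score
#'
#' Primary statistic: per-sample mean of feature Z-scores over the set
#' (Z computed per feature across all samples). Alternative: mean rank of
#' set genes minus its expectation, scaled to `[-1, 1]`.
#'
#' @param mat Features x samples matrix.
#' @param gene_set Character vector of feature names.
#' @param method `"meanz"` or `"rank"`.
#' @return Named numeric vector of per-sample scores.
#' @export
scoreSignature <- function(mat, gene_set, method = c("meanz", "rank")) {
  method <- match.arg(method)
  present <- intersect(gene_set, rownames(mat))
  if (length(present) == 0)
    stop("no gene-set members present in the matrix; missing: ",
         paste(utils::head(gene_set, 5), collapse = ", "), call. = FALSE)
  if (method == "meanz") {
    mu <- rowMeans(mat)
    sd <- apply(mat, 1, stats::sd)
    z <- (mat - mu) / ifelse(sd == 0, 1, sd)
    z[sd == 0, ] <- 0
    colMeans(z[present, , drop = FALSE])
  } else {
    n <- nrow(mat); m <- length(present)
    if (n == m) return(stats::setNames(rep(0, ncol(mat)), colnames(mat)))
    apply(mat, 2, function(col) {
      r <- rank(col)
      (mean(r[rownames(mat) %in% present]) - (n + 1) / 2) / ((n - m) / 2)
    })
  }
}
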