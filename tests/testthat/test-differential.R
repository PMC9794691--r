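test_that("detectability filter keeps features nonzero in >= 2 samples", {
  m <- rbind(a = c(1, 2, 0), b = c(5, 0, 0), c = c(0, 0, 0))
  kept <- filterDetectable(m)
  expect_equal(rownames(kept), "a")
  expect_equal(nrow(filterDetectable(matrix(0, 3, 4))), 0)
})

test_that("log-CPM normalization matches its defining formula", {
  m <- matrix(c(100, 999900, 50, 999950), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  lc <- normalizeLogCPM(m, prior_count = 0)
  expect_equal(lc["a", "s1"], log2(100), tolerance = 1e-12)
  # scale invariance: doubling a column leaves its CPM unchanged
  m2 <- m; m2[, 1] <- m2[, 1] * 2
  expect_equal(normalizeLogCPM(m2, 0)[, 1], lc[, 1])
  # prior keeps zeros finite
  expect_true(all(is.finite(normalizeLogCPM(rbind(c(0, 1), c(5, 5)), 0.5))))
  expect_error(normalizeLogCPM(rbind(c(0, 1), c(0, 1))), "zero library")
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  # order invariance
  p <- c(0.04, 0.01, 0.02)
  expect_equal(bhAdjust(p), c(0.04, 0.03, 0.03))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("moderated t interpolates between ordinary t and pooled z", {
  set.seed(20)
  n_feat <- 60
  samples <- data.frame(treatment = rep(c("DMSO", "DTP"), each = 4))
  m <- matrix(rnorm(n_feat * 8), n_feat)
  m[1:10, 5:8] <- m[1:10, 5:8] + 2
  rownames(m) <- paste0("f", 1:n_feat)
  ct <- list(C = c("DTP", "DMSO"))

  f0 <- fitContrasts(m, samples, ct, d_prior = 0)
  ord_t <- apply(m, 1, function(y) unname(stats::t.test(
    y[5:8], y[1:4], var.equal = TRUE)$statistic))
  expect_equal(f0$records$t, unname(ord_t), tolerance = 1e-10)

  finf <- fitContrasts(m, samples, ct, d_prior = Inf)
  est <- rowMeans(m[, 5:8]) - rowMeans(m[, 1:4])
  z <- est / sqrt(finf$moderation$s2_prior * (1 / 4 + 1 / 4))
  expect_equal(finf$records$t, unname(z), tolerance = 1e-10)
})

test_that("moderation hyperparameters agree with the reference EB fit", {
  skip_if_not_installed("limma")
  set.seed(21)
  samples <- data.frame(treatment = rep(c("DMSO", "acute", "DTP"), each = 3),
                        cell_line = rep(c("A", "B", "C"), 3))
  m <- matrix(rnorm(300 * 9, sd = rep(sqrt(rchisq(300, 5) / 5), 9)), 300)
  rownames(m) <- paste0("f", 1:300)
  fit <- fitContrasts(m, samples, list(C = c("DTP", "DMSO")))
  design <- stats::model.matrix(~ 0 + treatment + cell_line, samples)
  lf <- limma::lmFit(m, design)
  cf <- limma::contrasts.fit(lf, limma::makeContrasts(
    treatmentDTP - treatmentDMSO, levels = design))
  eb <- limma::eBayes(cf)
  expect_equal(fit$moderation$d_prior, eb$df.prior, tolerance = 1e-8)
  expect_equal(fit$moderation$s2_prior, eb$s2.prior, tolerance = 1e-8)
  expect_equal(fit$records$t, unname(eb$t[, 1]), tolerance = 1e-10)
  expect_equal(fit$records$p, unname(eb$p.value[, 1]), tolerance = 1e-10)
})

test_that("contrasts absorb constant shifts of a cell line's data", {
  set.seed(22)
  samples <- data.frame(treatment = rep(c("DMSO", "DTP"), 4),
                        cell_line = rep(c("A", "B"), each = 4))
  m <- matrix(rnorm(40 * 8), 40, dimnames = list(paste0("f", 1:40), NULL))
  f1 <- fitContrasts(m, samples, list(C = c("DTP", "DMSO")))
  m2 <- m
  m2[, samples$cell_line == "B"] <- m2[, samples$cell_line == "B"] + 3
  f2 <- fitContrasts(m2, samples, list(C = c("DTP", "DMSO")))
  expect_equal(f1$records$log2fc, f2$records$log2fc, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with named columns", {
  # treatment is perfectly confounded with cell line
  samples <- data.frame(treatment = c("DMSO", "DMSO", "DTP", "DTP"),
                        cell_line = c("A", "A", "B", "B"))
  m <- matrix(rnorm(8), 2)
  expect_error(fitContrasts(m, samples, list(C = c("DTP", "DMSO"))),
               "rank deficient")
})

test_that("moderated F selection applies the m-of-n rule and top-n cap", {
  mk <- function(fdrs) data.frame(feature = paste0("f", seq_along(fdrs)),
                                  F = 1, p = fdrs, fdr = fdrs)
  tabs <- list(L1 = mk(c(0.01, 0.01, 0.2)), L2 = mk(c(0.02, 0.2, 0.2)),
               L3 = mk(c(0.03, 0.01, 0.2)), L4 = mk(c(0.2, 0.01, 0.2)))
  sel <- moderatedFSelect(tabs, min_models = 3, top_n = 10)
  expect_setequal(sel$feature, c("f1", "f2"))
  expect_equal(moderatedFSelect(tabs, min_models = 3, top_n = 1)$feature,
               sel$feature[1])
  expect_equal(nrow(moderatedFSelect(tabs, min_models = 4, top_n = 10)), 0)
  expect_error(moderatedFSelect(tabs, min_models = 5), "exceeds")
})

test_that("z-scoring and k-means recover well-separated archetypes", {
  set.seed(23)
  a <- matrix(rep(c(2, 2, -2, -2), each = 30), 30, byrow = FALSE) +
    rnorm(120, sd = 0.1)
  b <- matrix(rep(c(-2, -2, 2, 2), each = 30), 30, byrow = FALSE) +
    rnorm(120, sd = 0.1)
  m <- rbind(a, b)
  rownames(m) <- paste0("f", 1:60)
  cl <- zscoreAndCluster(m, K = 2, seed = 1)
  expect_equal(length(unique(cl$cluster[1:30])), 1)
  expect_equal(length(unique(cl$cluster[31:60])), 1)
  expect_false(cl$cluster[1] == cl$cluster[31])
  expect_setequal(cl$order, 1:60)
  # degenerate cases
  const <- matrix(5, 3, 4, dimnames = list(letters[1:3], NULL))
  z <- zscoreAndCluster(const, K = 1, seed = 1)
  expect_true(all(z$z == 0))
  expect_true(all(z$cluster == 1))
  expect_error(zscoreAndCluster(m, K = 0), "K must be")
})

test_that("signature scores reduce to feature Z-scores in edge cases", {
  m <- matrix(c(1, 2, 3, 2, 4, 6), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  sc_all <- scoreSignature(m, c("a", "b"))
  z_a <- (m["a", ] - mean(m["a", ])) / sd(m["a", ])
  expect_equal(scoreSignature(m, "a"), z_a)
  expect_equal(sc_all, (z_a + (m["b", ] - mean(m["b", ])) / sd(m["b", ])) / 2)
  expect_error(scoreSignature(m, "nope"), "missing")
  # rank variant is bounded
  r <- scoreSignature(m, "a", method = "rank")
  expect_true(all(abs(r) <= 1))
})

test_that("planted up-signature separates DTP from DMSO samples", {
  des <- designSpec("A", c("DMSO", "DTP"), 4)
  eff <- effectSpec(sprintf("g%03d", 1:300), c("DMSO", "DTP"), n_diff = 40,
                    lfc = 2, dispersion = 0.05, seed = 30)
  se <- simulateCounts(des, eff, seed = 31)
  m <- normalizeLogCPM(countsOf(se))
  rd <- rowDataDf(se)
  up_set <- rownames(rd)[!is.na(rd$archetype) & rd$archetype == "3"]
  sc <- scoreSignature(m, up_set)
  tt <- stats::t.test(sc[colDataDf(se)$treatment == "DTP"],
                      sc[colDataDf(se)$treatment == "DMSO"])
  expect_gt(mean(sc[colDataDf(se)$treatment == "DTP"]),
            mean(sc[colDataDf(se)$treatment == "DMSO"]))
  expect_lt(tt$p.value, 0.05)
})
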