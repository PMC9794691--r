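grWith <- function(start, lfc, padj, chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = 500))
  gr$log2fc <- lfc
  gr$padj <- padj
  gr
}

test_that("Fisher combination matches its chi-square closed form", {
  # single p: identity
  expect_equal(fisherCombine(0.2)$p, 0.2, tolerance = 1e-12)
  # worked case: X = -2(ln .1 + ln .1), survival e^{-X/2}(1 + X/2) at df 4
  fc <- fisherCombine(c(0.1, 0.1))
  expect_equal(fc$statistic, 9.2103, tolerance = 1e-4)
  expect_equal(fc$p, exp(-fc$statistic / 2) * (1 + fc$statistic / 2),
               tolerance = 1e-12)
  # additivity of the statistic
  expect_equal(fisherCombine(c(0.05, 0.3))$statistic,
               fisherCombine(0.05)$statistic + fisherCombine(0.3)$statistic)
  expect_error(fisherCombine(1.5), "\\[0, 1\\]")
})

test_that("meta-analysis over one cell line is the identity", {
  t1 <- grWith(c(1000, 3000), c(1.5, -2), c(0.01, 0.3))
  meta <- metaIntersect(list(A = t1))
  expect_equal(meta$combined_p, t1$padj, tolerance = 1e-12)
  expect_equal(meta$avg_log2fc, t1$log2fc)
  expect_true(all(meta$consistent_direction))
})

test_that("meta-analysis intersects, averages, and flags inconsistency", {
  t1 <- grWith(c(1000, 3000, 6000), c(1, 1, 2), c(0.1, 0.05, 0.2))
  t2 <- grWith(c(1100, 3100), c(1, -1), c(0.1, 0.01))  # third peak absent
  meta <- metaIntersect(list(A = t1, B = t2))
  expect_equal(length(meta), 2)
  expect_equal(meta$avg_log2fc, c(1, 0))
  expect_equal(meta$consistent_direction, c(TRUE, FALSE))
  x <- -2 * (log(0.1) + log(0.1))
  expect_equal(meta$fisher_statistic[1], x)
  expect_equal(meta$combined_p[1],
               stats::pchisq(x, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(metaIntersect(list()), "at least one")
})

test_that("concordance classes follow the two-fold / FDR rules and partition", {
  rna <- data.frame(gene = paste0("g", 1:6),
                    log2fc = c(1.5, 1.5, 1.5, 0.2, -1.4, 2),
                    fdr = c(0.001, 0.001, 0.01, 0.001, 0.002, 0.5))
  atac <- data.frame(peak = paste0("p", 1:5),
                     log2fc = c(1.2, -1.2, 1.2, 1.2, -1.3),
                     fdr = c(0.001, 0.001, 0.001, 0.001, 0.002))
  links <- data.frame(peak = paste0("p", 1:5),
                      gene = c("g1", "g2", "g3", "g4", "g5"))
  cc <- classifyConcordance(rna, atac, links)
  cl <- setNames(cc$class, cc$gene)
  expect_equal(unname(cl["g1"]), "concordant_up")
  expect_equal(unname(cl["g2"]), "discordant")
  expect_equal(unname(cl["g3"]), "atac_only")   # rna fdr 0.01 > 0.005
  expect_equal(unname(cl["g4"]), "discordant")  # both sig, below 2-fold
  expect_equal(unname(cl["g5"]), "concordant_down")
  expect_equal(unname(cl["g6"]), "ns")
  expect_equal(nrow(cc), 6)  # partition: one class per gene
  expect_error(classifyConcordance(rbind(rna, rna[1, ]), atac, links),
               "duplicate")
})

test_that("merged enrichment matches the exhaustive hypergeometric case", {
  # universe 10 genes, 5 evidence genes, set of 4 fully inside evidence
  rna <- data.frame(gene = paste0("g", 1:10),
                    log2fc = c(rep(2, 5), rep(0, 5)),
                    fdr = c(rep(0.001, 5), rep(0.5, 5)))
  atac <- data.frame(peak = character(), log2fc = numeric(), fdr = numeric())
  links <- data.frame(peak = character(), gene = character())
  sets <- list(inside = paste0("g", 1:4), outside = paste0("g", 7:10))
  enr <- mergedEnrichment(rna, atac, links, sets)
  expect_equal(enr$p[enr$set == "inside"], 5 / 210, tolerance = 1e-12)
  expect_equal(enr$p[enr$set == "inside"], hyperEnumOracle(10, 5, 4, 4),
               tolerance = 1e-12)
  expect_equal(enr$overlap[enr$set == "outside"], 0)
  expect_equal(enr$p[enr$set == "outside"], 1)
})

test_that("merged enrichment unions RNA and ATAC evidence with labels", {
  rna <- data.frame(gene = paste0("g", 1:8),
                    log2fc = c(2, 2, rep(0, 6)), fdr = c(0.001, 0.001, rep(1, 6)))
  atac <- data.frame(peak = c("p1", "p2"), log2fc = c(3, 3),
                     fdr = c(0.001, 0.001))
  links <- data.frame(peak = c("p1", "p2"), gene = c("g2", "g3"))
  enr <- mergedEnrichment(rna, atac, links, list(s = paste0("g", 1:3)))
  expect_equal(enr$overlap, 3)
  expect_match(enr$evidence, "g1\\(rna\\)")
  expect_match(enr$evidence, "g2\\(both\\)")
  expect_match(enr$evidence, "g3\\(atac\\)")
  expect_error(mergedEnrichment(rna[0, ], atac, links, list(s = "g1")),
               "empty")
})
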