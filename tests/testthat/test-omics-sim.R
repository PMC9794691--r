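test_that("synthetic genomes are seed-deterministic with valid features", {
  g1 <- makeGenome(2, 50, 80, seed = 5)
  g2 <- makeGenome(2, 50, 80, seed = 5)
  expect_identical(GenomicRanges::start(genes(g1)),
                   GenomicRanges::start(genes(g2)))
  expect_equal(length(genes(g1)), 50)
  # genes non-overlapping within chromosome
  expect_equal(length(GenomicRanges::reduce(genes(g1), ignore.strand = TRUE)),
               50)
  g0 <- makeGenome(1, 0, 10, seed = 1)
  expect_equal(length(genes(g0)), 0)
  expect_true(all(regulatoryElements(g0)$class == "dELS"))
  expect_error(makeGenome(1, 1000, 0, chrom_length = 1e4), "too small")
})

test_that("elements forced near TSSs are classed promoter-like", {
  g <- makeGenome(1, 20, 50, element_max_dist = 100, seed = 2)
  expect_true(all(regulatoryElements(g)$class == "PLS"))
})

test_that("zero-dispersion counts are Poisson-like (variance tracks mean)", {
  des <- designSpec("A", c("DMSO", "DTP"), replicates = 50)
  # small baseline means so the 10% log-normal size-factor spread contributes
  # negligible extra-Poisson variance
  eff <- effectSpec(paste0("g", 1:20), c("DMSO", "DTP"), n_diff = 0,
                    dispersion = 0, baseline_meanlog = 2, baseline_sdlog = 0,
                    seed = 3)
  se <- simulateCounts(des, eff, seed = 4, line_sd = 0)
  cnt <- countsOf(se)
  disp_index <- apply(cnt, 1, stats::var) / rowMeans(cnt)
  expect_lt(median(disp_index), 1.5)
  se2 <- simulateCounts(des, eff, seed = 4, line_sd = 0)
  expect_identical(cnt, countsOf(se2))
})

test_that("null simulations yield nominal false-positive control downstream", {
  des <- designSpec("A", c("DMSO", "DTP"), 3)
  eff <- effectSpec(sprintf("g%04d", 1:800), c("DMSO", "DTP"), n_diff = 0,
                    dispersion = 0.1, seed = 11)
  se <- simulateCounts(des, eff, seed = 12)
  fit <- fitContrasts(normalizeLogCPM(countsOf(se)), colDataDf(se),
                      list(C = c("DTP", "DMSO")))
  expect_lt(mean(fit$records$fdr < 0.05), 0.02)
  expect_lt(mean(abs(fit$records$log2fc) > 1 & fit$records$fdr < 0.05), 0.01)
})

test_that("peak simulation plants reproducible summits and noise calls", {
  genome <- makeGenome(2, 50, 0, seed = 6)
  des <- designSpec("A", c("DMSO", "DTP"), 3)
  pk <- simulatePeaks(genome, des, seed = 7, n_peaks = 100, n_diff = 10,
                      summit_jitter = 0, n_noise = 5)
  # jitter 0: every sample reports identical summits for true peaks
  s1 <- pk$calls[[1]]$summit[1:100]
  for (j in 2:length(pk$calls)) expect_identical(pk$calls[[j]]$summit[1:100], s1)
  expect_equal(length(pk$calls[[1]]), 105)  # 100 true + 5 noise
  expect_true(all(GenomicRanges::width(pk$peaks) == 500))
  pk2 <- simulatePeaks(genome, des, seed = 7, n_peaks = 100, n_diff = 10,
                       summit_jitter = 0, n_noise = 5)
  expect_identical(pk$counts, pk2$counts)
  expect_error(simulatePeaks(genome, des, n_peaks = 1e6), "capacity")
})

test_that("motif embedding respects occupancy extremes", {
  m <- motifModel("det", diag(4), threshold = 7.99)
  none <- embedMotifs(20, m, occupancy = 0, seed = 8)
  expect_true(all(!none$truth$planted))
  all_in <- embedMotifs(20, m, occupancy = 1, seed = 9)
  expect_true(all(all_in$truth$planted))
  expect_true(all(vapply(as.character(all_in$seqs), function(s)
    grepl("ACGT", s) || grepl("ACGT", as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))),
    logical(1))))
  expect_error(embedMotifs(5, m, width = 3), "longer")
})

test_that("network generation is deterministic with the stated concordance", {
  net1 <- makeNetwork(seed = 10)
  net2 <- makeNetwork(seed = 10)
  expect_identical(net1, net2)
  # concordance 1: every planted target direction matches sign * direction
  e <- net1$edges[net1$edges$source == net1$planted$regulator, ]
  expect_true(all(net1$signature[e$target] ==
                    net1$planted$direction * e$sign))
})
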