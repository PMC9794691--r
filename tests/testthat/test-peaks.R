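test_that("greedy consensus keeps the top window and flags the loser's sample", {
  calls <- summitCalls(c("chr1", "chr1"), c(1000, 1200), c(10, 8),
                       sample = c("s1", "s2"))
  cons <- buildConsensus(calls)
  expect_equal(length(cons), 1)
  expect_equal(GenomicRanges::start(cons), 750)
  expect_equal(GenomicRanges::end(cons), 1249)
  expect_true(all(S4Vectors::mcols(cons)$called[1, c("s1", "s2")]))
})

test_that("disjoint summits are both retained", {
  cons <- buildConsensus(summitCalls("chr1", c(1000, 2000), c(10, 8)))
  expect_equal(length(cons), 2)
  expect_true(all(GenomicRanges::width(cons) == 500))
})

test_that("consensus equals the naive oracle, is idempotent and non-overlapping", {
  set.seed(40)
  for (rep in 1:25) {
    n <- sample(20:120, 1)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    summit <- sample(500:50000, n, replace = TRUE)
    score <- round(runif(n, 0, 50), 2)
    cons <- buildConsensus(summitCalls(chrom, summit, score,
                                       sample(c("s1", "s2"), n, TRUE)))
    kp <- naiveConsensus(chrom, summit, score)
    expect_setequal(paste(GenomicRanges::seqnames(cons),
                          GenomicRanges::start(cons)),
                    paste(chrom[kp], summit[kp] - 250))
    # every discarded window overlaps a kept window of >= score
    for (i in which(!kp)) {
      ov <- chrom[kp] == chrom[i] &
        abs(summit[kp] - summit[i]) < 500
      expect_true(any(score[kp][ov] >= score[i]))
    }
    again <- buildConsensus(summitCalls(
      as.character(GenomicRanges::seqnames(cons)), cons$summit, cons$score))
    expect_equal(GenomicRanges::start(again), GenomicRanges::start(cons))
    expect_equal(length(GenomicRanges::reduce(cons, min.gapwidth = 0L)),
                 length(cons))
  }
})

test_that("peak-count filter enforces abundance and triplicate rules", {
  groups <- rep(c("DMSO", "DTP"), each = 3)
  # library ~1e6 so that a count of ~4200 gives log2 CPM just over 2
  counts <- matrix(1000, 250, 6)
  counts[1, ] <- 5000    # abundant
  counts[2, ] <- 5000    # abundant but not reproducible
  counts[3, ] <- 0       # called everywhere but too weak
  called <- matrix(TRUE, 250, 6)
  called[2, ] <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)  # 2 of 3 per group
  keep <- filterPeakCounts(counts, called, groups, cpm_cut = 2)
  expect_true(keep[1])
  expect_false(keep[2])
  expect_false(keep[3])
  expect_error(filterPeakCounts(counts, called[, 1:3], groups), "identical")
})

test_that("peak annotation honors the 100 kb rule and class partition", {
  genome <- makeGenome(1, 3, 0, chrom_length = 1e6, seed = 41)
  g <- genes(genome)
  tss1 <- g$tss[1]
  # odd widths so the peak center is an exact integer position
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(tss1 + 800, tss1 + 150000), width = 401))
  # isolate: place far peak away from all genes
  far_ok <- all(abs(GenomicRanges::start(peaks)[2] + 200 - g$tss) > 1e5)
  ann <- annotatePeaks(peaks, genome)
  expect_equal(ann$nearest_gene[1], g$gene_id[1])
  expect_equal(abs(ann$tss_distance[1]), 1000)
  expect_equal(ann$feature_class[1], "promoter")
  if (far_ok) expect_true(is.na(ann$nearest_gene[2]))
  props <- featureProportions(ann)
  expect_equal(sum(props$proportion), 1)
})

test_that("TSS distance magnitude is strand-symmetric", {
  genome <- makeGenome(1, 10, 0, seed = 42)
  flipped <- genome
  g <- genes(genome)
  GenomicRanges::strand(g) <- ifelse(as.character(
    GenomicRanges::strand(g)) == "+", "-", "+")
  flipped@genes <- g
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    seq(1000, 900000, by = 90000), width = 500))
  a1 <- annotatePeaks(peaks, genome)
  a2 <- annotatePeaks(peaks, flipped)
  expect_equal(abs(a1$tss_distance), abs(a2$tss_distance))
})

test_that("regulatory overlap deltas behave as percent differences", {
  el <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1000, 5000, 9000), width = 200))
  el$class <- c("dELS", "dELS", "PLS")
  all_pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    seq(500, 20000, by = 1950), width = 100))
  up_pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1050, 5050), width = 100))  # both on dELS
  d <- regulatoryOverlapDelta(list(all = all_pk, up = up_pk), el)
  expect_equal(d$delta[d$set == "all"], rep(0, 3))
  up_dels <- d[d$set == "up" & d$class == "dELS", ]
  expect_equal(up_dels$percent, 100)
  base <- d$percent[d$set == "all" & d$class == "dELS"]
  expect_equal(up_dels$delta, 100 - base)
  empty <- regulatoryOverlapDelta(list(all = all_pk, up = up_pk), el[0])
  expect_true(all(empty$percent == 0))
})
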