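test_that("trapezoid AUC is exact on constant and linear traces", {
  grid <- c(0, 13, 50, 120, 200)
  expect_equal(computeAUC(grid, rep(50, 5)), 10000)
  expect_equal(computeAUC(c(0, 25, 60, 100), c(0, 25, 60, 100)), 5000)
  expect_error(computeAUC(0, 10), "two time points")
  expect_error(computeAUC(c(0, 10, 10), c(1, 2, 3)), "strictly increasing")
})

test_that("AUC is invariant to inserting collinear interior points", {
  t0 <- c(0, 50, 100)
  y0 <- c(10, 40, 20)
  t1 <- c(0, 25, 50, 75, 100)
  y1 <- c(10, 25, 40, 30, 20)  # linear interpolants of the same trace
  expect_equal(computeAUC(t1, y1), computeAUC(t0, y0))
})

test_that("replicate summary is the median with even-count convention", {
  expect_equal(summarizeReplicates(c(3, 5, 100)), 5)
  expect_equal(summarizeReplicates(c(4, 8)), 6)
  expect_equal(summarizeReplicates(7), 7)
  expect_error(summarizeReplicates(numeric(0)), "at least one")
})

test_that("combination scoring applies the threshold and 2x monotherapy rule", {
  sc <- scoreCombination(20000, 20000, 20000, 8000, "upfront")
  expect_equal(sc$combination_activity, 12000)
  hit <- scoreCombination(20000, 16000, 20000, 9000, "upfront")
  expect_equal(hit$combination_activity, 11000)
  expect_equal(hit$monotherapy_activity, 4000)
  expect_true(hit$hit)
  expect_false(hit$hit_low_mono_support)
  low <- scoreCombination(20000, 14000, 20000, 9000, "upfront")
  expect_equal(low$monotherapy_activity, 6000)
  expect_false(low$hit)
  expect_true(low$hit_low_mono_support)
  # sequential threshold is 7500
  seq_hit <- scoreCombination(20000, 19000, 20000, 12000, "sequential")
  expect_true(seq_hit$hit)
  expect_false(scoreCombination(20000, 19000, 20000, 12000, "upfront")$hit)
  expect_error(scoreCombination(1, 1, 1, 1, "bogus"))
})

test_that("identical arm AUCs give zero activities and no hit", {
  for (a in c(100, 5000)) for (b in c(200, 30000)) {
    sc <- scoreCombination(a, a, b, b, "upfront")
    expect_equal(sc$combination_activity, 0)
    expect_equal(sc$monotherapy_activity, 0)
    expect_false(sc$hit)
  }
})

test_that("hit calling is monotone in combination-arm AUC", {
  prev_hit <- TRUE
  for (auc_combo in seq(0, 20000, by = 2500)) {
    h <- scoreCombination(20000, 19500, 20000, auc_combo, "upfront")$hit
    expect_true(!h || prev_hit)  # weaker combination never re-enables a hit
    prev_hit <- h
  }
})

test_that("cross-model summary applies the 3-of-n rule", {
  mk <- function(cmp, lines, hits, low = rep(FALSE, length(lines)))
    data.frame(compound = cmp, cell_line = lines, hit = hits,
               hit_low_mono_support = low)
  res <- rbind(mk("a", paste0("L", 1:7), c(rep(TRUE, 3), rep(FALSE, 4))),
               mk("b", paste0("L", 1:7), c(rep(TRUE, 2), rep(FALSE, 5)),
                  c(FALSE, FALSE, TRUE, rep(FALSE, 4))))
  cm <- crossModelSummary(res)
  expect_true(cm$common_hit[cm$compound == "a"])
  expect_false(cm$common_hit[cm$compound == "b"])
  expect_equal(cm$n_models_hit, c(3L, 2L))
  expect_equal(nrow(crossModelSummary(res[0, ])), 0)
  expect_error(crossModelSummary(rbind(res, res[1, ])), "duplicate")
})

test_that("truth evaluation computes confusion rates", {
  res <- data.frame(cell_line = "L", compound = c("a", "b", "c"),
                    hit = c(TRUE, FALSE, FALSE))
  truth <- data.frame(cell_line = "L", compound = c("a", "b", "c"),
                      true_hit = c(TRUE, TRUE, FALSE))
  ev <- evaluateAgainstTruth(res, truth)
  expect_equal(ev$sensitivity, 0.5)
  expect_equal(ev$fpr, 0)
  res$hit <- FALSE
  expect_equal(evaluateAgainstTruth(res, truth)$sensitivity, 0)
  expect_error(evaluateAgainstTruth(res[1:2, ], truth), "different")
})
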