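#' Area under a confluence trace
#'
#' Trapezoidal integral of percent confluence over the full observed window,
#' in percent-hours, with no baseline subtraction.
#'
#' @param time_h Observation times in hours, strictly increasing.
#' @param confluence Percent confluence at each time.
#' @return AUC in percent-hours.
#' @export
#' @examples
#' computeAUC(c(0, 100, 200), c(50, 50, 50))  # 10000
computeAUC <- function(time_h, confluence) {
  stopifnot2(length(time_h) >= 2, "AUC needs at least two time points")
  stopifnot2(length(time_h) == length(confluence),
             "times and confluence must have equal length")
  dt <- diff(time_h)
  stopifnot2(all(dt > 0), "times must be strictly increasing")
  sum(dt * (confluence[-1] + confluence[-length(confluence)]) / 2)
}

#' Summarize replicate AUCs
#'
#' The screen uses the median replicate AUC (mean of the central pair for
#' even replicate counts).
#'
#' @param aucs Numeric vector of replicate AUCs.
#' @return The median AUC.
#' @export
summarizeReplicates <- function(aucs) {
  stopifnot2(length(aucs) >= 1, "need at least one replicate AUC")
  stats::median(aucs)
}

#' Hit-calling rule for the DTP combination screen
#'
#' Defaults mirror the study's screens: combination activity above 10,000
#' percent-hours (upfront format) or 7,500 (sequential), at least twice the
#' monotherapy activity, and a compound must be a hit in at least
#' `min_models` cell lines to count as a common hit.
#'
#' @param threshold_upfront,threshold_sequential Combination-activity
#'   thresholds in percent-hours.
#' @param mono_multiplier Required ratio of combination to monotherapy
#'   activity.
#' @param min_models Minimum number of cell lines for a common hit.
#' @return A validated list of class `HitRule`.
#' @export
hitRule <- function(threshold_upfront = 10000, threshold_sequential = 7500,
                    mono_multiplier = 2, min_models = 3) {
  stopifnot2(threshold_upfront > 0 && threshold_sequential > 0,
             "thresholds must be positive")
  stopifnot2(mono_multiplier >= 1, "mono_multiplier must be >= 1")
  stopifnot2(min_models >= 1, "min_models must be >= 1")
  structure(list(threshold_upfront = threshold_upfront,
                 threshold_sequential = threshold_sequential,
                 mono_multiplier = mono_multiplier,
                 min_models = min_models),
            class = "HitRule")
}

#' Score one compound's combination against the hit rule
#'
#' Combination activity is the AUC difference between the osimertinib-DTP
#' control arm and the combination arm; monotherapy activity is the AUC
#' difference between DMSO and test-compound monotherapy. A hit must exceed
#' the format's combination-activity threshold and be at least
#' `mono_multiplier` times the monotherapy activity. Compounds passing the
#' threshold but failing the multiplier are flagged `hit_low_mono_support`.
#'
#' @param auc_dmso,auc_mono,auc_dtp,auc_combo Median replicate AUCs
#'   (percent-hours) for the DMSO, test-compound monotherapy,
#'   osimertinib-DTP, and combination arms. Vectorized.
#' @param format `"upfront"` or `"sequential"`.
#' @param rule A [hitRule()].
#' @return `data.frame` with activities and `hit` / `hit_low_mono_support`
#'   flags.
#' @export
scoreCombination <- function(auc_dmso, auc_mono, auc_dtp, auc_combo,
                             format = c("upfront", "sequential"),
                             rule = hitRule()) {
  format <- match.arg(format)
  stopifnot2(all(c(auc_dmso, auc_mono, auc_dtp, auc_combo) >= 0),
             "AUCs must be non-negative")
  thr <- if (format == "upfront") rule$threshold_upfront else rule$threshold_sequential
  combination_activity <- auc_dtp - auc_combo
  monotherapy_activity <- auc_dmso - auc_mono
  passes_thr <- combination_activity > thr
  passes_mono <- combination_activity > rule$mono_multiplier * monotherapy_activity
  data.frame(auc_dmso = auc_dmso, auc_mono = auc_mono,
             auc_dtp = auc_dtp, auc_combo = auc_combo,
             combination_activity = combination_activity,
             monotherapy_activity = monotherapy_activity,
             format = format,
             hit = passes_thr & passes_mono,
             hit_low_mono_support = passes_thr & !passes_mono)
}

#' Score a whole simulated or imported screen
#'
#' Computes per-replicate AUCs from long-format traces, takes the median
#' replicate AUC per arm, and applies [scoreCombination()] per (cell line,
#' compound). The combination arm is `C_upfront` for the upfront format and
#' `D_sequential` for the sequential format; DMSO and osimertinib-DTP AUCs
#' come from the shared `"control"` wells. When replicates permit, a Welch
#' two-sided t-test compares replicate combination AUCs to the osimertinib
#' control AUCs (`p_vs_osi`).
#'
#' @param traces Long `data.frame` with columns `cell_line`, `compound`,
#'   `arm`, `replicate`, `time_h`, `confluence_pct` (as written by
#'   [simulateScreen()]).
#' @param format Screen format.
#' @param rule A [hitRule()].
#' @return One row per (cell line, compound) with AUCs, activities, hit
#'   flags and `p_vs_osi`.
#' @export
scoreScreen <- function(traces, format = c("upfront", "sequential"),
                        rule = hitRule()) {
  format <- match.arg(format)
  need <- c("cell_line", "compound", "arm", "replicate", "time_h",
            "confluence_pct")
  stopifnot2(all(need %in% names(traces)), "traces are missing required columns")
  combo_arm <- if (format == "upfront") "C_upfront" else "D_sequential"

  key <- interaction(traces$cell_line, traces$compound, traces$arm,
                     traces$replicate, drop = TRUE)
  well_auc <- do.call(rbind, lapply(split(traces, key), function(w) {
    w <- w[order(w$time_h), ]
    data.frame(cell_line = w$cell_line[1], compound = w$compound[1],
               arm = w$arm[1], replicate = w$replicate[1],
               auc = computeAUC(w$time_h, w$confluence_pct))
  }))
  rownames(well_auc) <- NULL

  medAuc <- function(cl, cmp, arm) {
    x <- well_auc$auc[well_auc$cell_line == cl & well_auc$compound == cmp &
                        well_auc$arm == arm]
    if (length(x) == 0) NA_real_ else summarizeReplicates(x)
  }
  repAuc <- function(cl, cmp, arm)
    well_auc$auc[well_auc$cell_line == cl & well_auc$compound == cmp &
                   well_auc$arm == arm]

  compounds <- setdiff(unique(well_auc$compound), "control")
  lines <- unique(well_auc$cell_line)
  out <- vector("list", length(lines) * length(compounds))
  i <- 0L
  for (cl in lines) for (cmp in compounds) {
    i <- i + 1L
    sc <- scoreCombination(
      auc_dmso = medAuc(cl, "control", "DMSO"),
      auc_mono = medAuc(cl, cmp, "A_mono"),
      auc_dtp = medAuc(cl, "control", "B_osi"),
      auc_combo = medAuc(cl, cmp, combo_arm),
      format = format, rule = rule)
    a <- repAuc(cl, cmp, combo_arm)
    b <- repAuc(cl, "control", "B_osi")
    sc$p_vs_osi <- if (length(a) >= 2 && length(b) >= 2 &&
                         (stats::var(a) + stats::var(b)) > 0)
      endpointTest(a, b)$p.value else NA_real_
    out[[i]] <- cbind(data.frame(cell_line = cl, compound = cmp), sc)
  }
  do.call(rbind, out)
}

#' Summarize hits across a cell-line panel
#'
#' A compound is a common hit when it is a hit in at least `min_models`
#' cell lines. For common hits, cell lines where the compound passed the
#' activity threshold with under-`mono_multiplier` monotherapy support are
#' also reported.
#'
#' @param results Output of [scoreScreen()] (or rows shaped like
#'   [scoreCombination()] plus `cell_line`/`compound`).
#' @param rule A [hitRule()].
#' @return One row per compound: `n_models_hit`, `common_hit`,
#'   `low_mono_models` (comma-separated labels).
#' @export
crossModelSummary <- function(results, rule = hitRule()) {
  if (nrow(results) == 0)
    return(data.frame(compound = character(), n_models_hit = integer(),
                      common_hit = logical(), low_mono_models = character()))
  stopifnot2(!anyDuplicated(results[, c("compound", "cell_line")]),
             "duplicate (compound, cell line) entries")
  sp <- split(results, results$compound)
  out <- do.call(rbind, lapply(sp, function(r) {
    n_hit <- sum(r$hit)
    data.frame(compound = r$compound[1], n_models_hit = n_hit,
               common_hit = n_hit >= rule$min_models,
               low_mono_models = paste(r$cell_line[r$hit_low_mono_support],
                                       collapse = ","))
  }))
  rownames(out) <- NULL
  out[order(out$compound), , drop = FALSE]
}

#' Evaluate called hits against simulator truth
#'
#' @param results Output of [scoreScreen()].
#' @param truth Truth table from [simulateScreen()].
#' @return List with `sensitivity`, `fpr`, and the confusion counts.
#' @export
evaluateAgainstTruth <- function(results, truth) {
  key_r <- paste(results$cell_line, results$compound)
  key_t <- paste(truth$cell_line, truth$compound)
  stopifnot2(setequal(key_r, key_t),
             "results and truth cover different (cell line, compound) pairs")
  called <- results$hit[match(key_t, key_r)]
  tp <- sum(called & truth$true_hit)
  fn <- sum(!called & truth$true_hit)
  fp <- sum(called & !truth$true_hit)
  tn <- sum(!called & !truth$true_hit)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       tp = tp, fn = fn, fp = fp, tn = tn)
}
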