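#' Ellipsoid tumor volume
#'
#' `pi/6 * width^2 * length` in cubic millimetres; if the two calliper
#' measurements arrive unordered the smaller is treated as the width.
#'
#' @param width,length Calliper measurements in mm (vectorized).
#' @return Volume in mm^3.
#' @export
#' @examples
#' tumorVolume(6, 12)  # 72 * pi
tumorVolume <- function(width, length) {
  stopifnot2(all(width > 0) && all(length > 0),
             "tumor dimensions must be positive")
  w <- pmin(width, length)
  l <- pmax(width, length)
  pi / 6 * w^2 * l
}

#' Percent nuclear localization per cell, with a group comparison
#'
#' Computes `100 * nuclear / (nuclear + cytoplasmic)` per cell (cells with
#' zero total signal are dropped with a warning) and, when a two-level
#' `group` is supplied, compares groups with a two-sided Wilcoxon rank-sum
#' test (a paired signed-rank variant is available via `paired = TRUE`).
#'
#' @param nuclear,cytoplasmic Per-cell signal intensities (arbitrary units).
#' @param group Optional factor with two levels.
#' @param paired Use the signed-rank (paired) variant.
#' @return List with `percent_nuclear` per retained cell, the retained
#'   `group`, and `test` (an `htest`, or `NULL` without groups).
#' @export
percentNuclear <- function(nuclear, cytoplasmic, group = NULL,
                           paired = FALSE) {
  stopifnot2(length(nuclear) == length(cytoplasmic),
             "signal vectors must have equal length")
  stopifnot2(all(nuclear >= 0) && all(cytoplasmic >= 0),
             "signals must be non-negative")
  tot <- nuclear + cytoplasmic
  keep <- tot > 0
  if (any(!keep))
    warning(sum(!keep), " cell(s) with zero total signal dropped")
  pct <- 100 * nuclear[keep] / tot[keep]
  g <- if (!is.null(group)) factor(group[keep]) else NULL
  test <- NULL
  if (!is.null(g)) {
    stopifnot2(nlevels(g) == 2, "group must have exactly two levels")
    test <- stats::wilcox.test(pct[g == levels(g)[1]], pct[g == levels(g)[2]],
                               paired = paired, exact = FALSE)
  }
  list(percent_nuclear = pct, group = g, test = test)
}

#' Welch two-sided endpoint comparison
#'
#' Used throughout the screens to compare replicate combination AUCs (or
#' endpoint tumor volumes) against the osimertinib monotherapy control.
#'
#' @param values_a,values_b Endpoint values per group, `n >= 2` each.
#' @return An `htest` from [stats::t.test()] (Welch, two-sided).
#' @export
endpointTest <- function(values_a, values_b) {
  stopifnot2(length(values_a) >= 2 && length(values_b) >= 2,
             "endpoint test needs n >= 2 per group")
  stats::t.test(values_a, values_b, var.equal = FALSE,
                alternative = "two.sided")
}
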