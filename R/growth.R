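#' Simulation parameters for a persister growth model
#'
#' Bundles the kinetic parameters of the two-compartment (sensitive +
#' persister) confluence model. Rates are per hour; confluence is in percent
#' of well area.
#'
#' @param r Growth rate of drug-sensitive cells (h^-1).
#' @param r_p Growth rate of persister cells under EGFR inhibition (h^-1);
#'   much smaller than `r`.
#' @param K Carrying capacity (percent confluence).
#' @param c0 Confluence at seeding (percent).
#' @param f Persister fraction of the inoculum, in `[0, 1]`.
#' @param d Osimertinib kill rate on sensitive cells (h^-1).
#' @param e_drug Test-compound kill multiplier (dimensionless, >= 0) applied
#'   to the persister pool; the persister kill rate under the test compound
#'   is `e_drug * d`.
#' @param lag Regrowth lag (hours) between drug washout and persister
#'   reversion to the sensitive growth rate.
#' @param sigma Log-scale multiplicative measurement noise SD.
#' @param extinction Confluence (percent) below which a compartment is set
#'   to zero; wells cannot hold fractional cells.
#' @param dt Internal Runge-Kutta step (hours).
#'
#' @return A validated list of class `SimParams`.
#' @export
simParams <- function(r = 0.03, r_p = 0.002, K = 100, c0 = 10, f = 0.05,
                      d = 0.05, e_drug = 0, lag = 24, sigma = 0.03,
                      extinction = 1e-6, dt = 0.25) {
  stopifnot2(all(c(r, r_p, d, e_drug, lag, sigma) >= 0),
             "rates, lag and sigma must be non-negative")
  stopifnot2(f >= 0 && f <= 1, "persister fraction f must lie in [0, 1]")
  stopifnot2(c0 > 0 && c0 < K, "need 0 < c0 < K")
  stopifnot2(dt > 0, "dt must be positive")
  structure(list(r = r, r_p = r_p, K = K, c0 = c0, f = f, d = d,
                 e_drug = e_drug, lag = lag, sigma = sigma,
                 extinction = extinction, dt = dt),
            class = "SimParams")
}

#' Dosing regimen for one screen arm
#'
#' Arms follow the DTP screen layout: `DMSO` vehicle control, `A_mono` test
#' compound alone, `B_osi` osimertinib alone, `C_upfront` osimertinib plus
#' test compound co-dosed from day 0, and `D_sequential` osimertinib until
#' the DTP stage then crossover to the test compound.
#'
#' @param arm One of `"DMSO"`, `"A_mono"`, `"B_osi"`, `"C_upfront"`,
#'   `"D_sequential"`.
#' @param dtp_day Day the DTP stage is declared established (crossover day
#'   for the sequential arm).
#' @param washout_day Day drugs are removed for arms A-C.
#' @param horizon Assay length in days.
#' @param sample_interval Imaging interval in hours.
#' @param codose_sequential If `TRUE`, osimertinib is kept on after the
#'   sequential crossover instead of being withdrawn.
#'
#' @return A validated list of class `RegimenSpec`.
#' @export
regimenSpec <- function(arm = c("DMSO", "A_mono", "B_osi", "C_upfront",
                                "D_sequential"),
                        dtp_day = 14, washout_day = 24, horizon = 35,
                        sample_interval = 6, codose_sequential = FALSE) {
  arm <- match.arg(arm)
  stopifnot2(dtp_day > 0 && dtp_day <= washout_day && washout_day <= horizon,
             "need 0 < dtp_day <= washout_day <= horizon")
  stopifnot2(sample_interval > 0, "sample_interval must be positive")
  structure(list(arm = arm, dtp_day = dtp_day, washout_day = washout_day,
                 horizon = horizon, sample_interval = sample_interval,
                 codose_sequential = codose_sequential),
            class = "RegimenSpec")
}

# Exposure windows (hours) for one arm. Returns intervals [on, off) for
# osimertinib and the test compound, plus the persister reversion time.
armSchedule <- function(regimen, params) {
  dtp_h <- regimen$dtp_day * 24
  wash_h <- regimen$washout_day * 24
  hor_h <- regimen$horizon * 24
  osi <- switch(regimen$arm,
    DMSO = c(NA, NA),
    A_mono = c(NA, NA),
    B_osi = c(0, wash_h),
    C_upfront = c(0, wash_h),
    D_sequential = if (regimen$codose_sequential) c(0, hor_h) else c(0, dtp_h))
  test <- switch(regimen$arm,
    DMSO = c(NA, NA),
    A_mono = c(0, wash_h),
    B_osi = c(NA, NA),
    C_upfront = c(0, wash_h),
    D_sequential = c(dtp_h, hor_h))
  # Persisters behave as persisters from first osimertinib exposure until
  # `lag` hours after it is withdrawn; arms never exposed grow sensitively.
  revert <- if (is.na(osi[1])) -Inf else osi[2] + params$lag
  list(osi = osi, test = test, revert = revert, horizon_h = hor_h)
}

inWindow <- function(t, w) !is.na(w[1]) && t >= w[1] && t < w[2]

# Classical fixed-step RK4 from t0 to t1. Dosing state is constant within a
# segment (the caller splits at every event time), so the right-hand side is
# inlined with flags evaluated once at the segment midpoint.
rk4Segment <- function(state, t0, t1, params, sched) {
  span <- t1 - t0
  if (span <= 0) return(state)
  tm <- (t0 + t1) / 2
  osi <- inWindow(tm, sched$osi)
  test <- inWindow(tm, sched$test)
  K <- params$K
  rS <- params$r
  dS_kill <- if (osi) params$d else 0
  p_rate <- if (!is.na(sched$osi[1]) && tm < sched$revert) params$r_p else params$r
  p_kill <- if (test) params$e_drug * params$d else 0

  dS <- function(S, P) if (osi) -dS_kill * S else rS * S * (1 - (S + P) / K)
  dP <- function(S, P) p_rate * P * (1 - (S + P) / K) - p_kill * P

  n <- max(1L, ceiling(span / params$dt))
  h <- span / n
  S <- state[1]; P <- state[2]
  for (i in seq_len(n)) {
    k1S <- dS(S, P);                         k1P <- dP(S, P)
    k2S <- dS(S + h / 2 * k1S, P + h / 2 * k1P); k2P <- dP(S + h / 2 * k1S, P + h / 2 * k1P)
    k3S <- dS(S + h / 2 * k2S, P + h / 2 * k2P); k3P <- dP(S + h / 2 * k2S, P + h / 2 * k2P)
    k4S <- dS(S + h * k3S, P + h * k3P);     k4P <- dP(S + h * k3S, P + h * k3P)
    S <- max(S + h / 6 * (k1S + 2 * k2S + 2 * k3S + k4S), 0)
    P <- max(P + h / 6 * (k1P + 2 * k2P + 2 * k3P + k4P), 0)
  }
  if (S + P < params$extinction) { S <- 0; P <- 0 }
  c(S, P)
}

#' Simulate one well's confluence time course
#'
#' Integrates the deterministic two-compartment persister model with a
#' fixed-step fourth-order Runge-Kutta scheme, splitting at dosing events,
#' then applies multiplicative log-normal measurement noise.
#'
#' Dynamics: without drug, sensitive and persister pools grow logistically at
#' rate `r` toward carrying capacity `K`. Under osimertinib the sensitive
#' pool dies at rate `d` while persisters grow slowly at `r_p`. Test-compound
#' exposure adds a persister kill term `e_drug * d`. After osimertinib
#' washout persisters revert to the sensitive growth rate following a lag.
#'
#' @param params A [simParams()] object.
#' @param regimen A [regimenSpec()] object.
#' @param seed Integer seed for the measurement noise (ignored when
#'   `sigma = 0`).
#'
#' @return A `data.frame` with columns `time_h`, `confluence_pct` (observed,
#'   clipped to `[0, K]`), and noise-free compartment columns `S`, `P`.
#' @export
#' @examples
#' tr <- simulateWell(simParams(sigma = 0), regimenSpec("B_osi"), seed = 1)
#' head(tr)
simulateWell <- function(params, regimen, seed = 1L) {
  stopifnot2(inherits(params, "SimParams"), "params must come from simParams()")
  stopifnot2(inherits(regimen, "RegimenSpec"), "regimen must come from regimenSpec()")
  sched <- armSchedule(regimen, params)
  times <- seq(0, sched$horizon_h, by = regimen$sample_interval)
  events <- sort(unique(c(sched$osi, sched$test, sched$revert)))
  events <- events[is.finite(events) & events > 0 & events < sched$horizon_h]

  S <- params$c0 * (1 - params$f)
  P <- params$c0 * params$f
  out <- numeric(length(times))
  out[1] <- S + P
  for (i in seq_along(times)[-1]) {
    t0 <- times[i - 1]; t1 <- times[i]
    cuts <- c(t0, events[events > t0 & events < t1], t1)
    st <- c(S, P)
    for (j in seq_len(length(cuts) - 1))
      st <- rk4Segment(st, cuts[j], cuts[j + 1], params, sched)
    S <- st[1]; P <- st[2]
    out[i] <- S + P
  }
  noisefree <- out
  if (params$sigma > 0) {
    eps <- withSeed(seed, stats::rnorm(length(times), 0, params$sigma))
    out <- out * exp(eps)
  }
  out <- pmin(pmax(out, 0), params$K)
  data.frame(time_h = times, confluence_pct = out,
             noisefree = pmin(noisefree, params$K))
}

#' Simulate a full DTP combination screen
#'
#' Generates confluence traces for every (cell line, compound, arm,
#' replicate) combination plus shared per-cell-line `DMSO` and `B_osi`
#' control wells (labelled compound `"control"`), and a ground-truth table
#' marking compounds whose planted persister kill multiplier exceeds
#' `truth_cutoff` as true hits.
#'
#' @param panel `data.frame` with columns `compound` and `e_drug` (planted
#'   persister kill multiplier per compound).
#' @param cell_lines Character vector of cell-line labels.
#' @param replicates Replicate wells per condition (>= 1).
#' @param params_by_line Named list of [simParams()] per cell line; a single
#'   `SimParams` is recycled to all lines.
#' @param regimen Base [regimenSpec()]; the `arm` field is overridden per well.
#' @param seed Master seed; per-well seeds are derived deterministically.
#' @param truth_cutoff `e_drug` value at or above which a compound counts as
#'   a planted true hit.
#'
#' @return A list with `traces` (long `data.frame`: `cell_line`, `compound`,
#'   `arm`, `replicate`, `time_h`, `confluence_pct`) and `truth`
#'   (`cell_line`, `compound`, `e_drug`, `true_hit`).
#' @export
simulateScreen <- function(panel, cell_lines, replicates = 3,
                           params_by_line = simParams(),
                           regimen = regimenSpec(), seed = 1L,
                           truth_cutoff = 2) {
  stopifnot2(is.data.frame(panel) && nrow(panel) > 0 &&
               all(c("compound", "e_drug") %in% names(panel)),
             "panel must be a non-empty data.frame with compound and e_drug")
  stopifnot2(!anyDuplicated(panel$compound), "duplicate compounds in panel")
  stopifnot2(replicates >= 1, "replicates must be >= 1")
  if (inherits(params_by_line, "SimParams"))
    params_by_line <- stats::setNames(
      rep(list(params_by_line), length(cell_lines)), cell_lines)
  stopifnot2(all(cell_lines %in% names(params_by_line)),
             "params_by_line must cover every cell line")

  compound_arms <- c("A_mono", "B_osi", "C_upfront", "D_sequential")
  grid <- rbind(
    expand.grid(compound = panel$compound, arm = compound_arms,
                replicate = seq_len(replicates), stringsAsFactors = FALSE),
    expand.grid(compound = "control", arm = c("DMSO", "B_osi"),
                replicate = seq_len(replicates), stringsAsFactors = FALSE))
  traces <- vector("list", length(cell_lines) * nrow(grid))
  idx <- 0L
  for (cl in cell_lines) {
    base <- params_by_line[[cl]]
    for (g in seq_len(nrow(grid))) {
      idx <- idx + 1L
      cmp <- grid$compound[g]
      e <- if (cmp == "control") 0 else panel$e_drug[panel$compound == cmp]
      p <- base
      p$e_drug <- e
      reg <- regimen
      reg$arm <- grid$arm[g]
      tr <- simulateWell(p, reg, seed = childSeed(seed, idx))
      traces[[idx]] <- data.frame(
        cell_line = cl, compound = cmp, arm = grid$arm[g],
        replicate = grid$replicate[g],
        time_h = tr$time_h, confluence_pct = tr$confluence_pct)
    }
  }
  truth <- expand.grid(cell_line = cell_lines, compound = panel$compound,
                       stringsAsFactors = FALSE)
  truth$e_drug <- panel$e_drug[match(truth$compound, panel$compound)]
  truth$true_hit <- truth$e_drug >= truth_cutoff
  list(traces = do.call(rbind, traces), truth = truth)
}

#' Default screen panel with planted hits
#'
#' A 20-compound panel in which a declared subset carries a strong persister
#' kill multiplier (planted true hits) and the remainder carry negligible
#' activity drawn uniformly from `[0, 0.05]` (persister kill rates well
#' below the persister growth rate).
#'
#' @param n_compounds Panel size.
#' @param n_hits Number of planted true hits.
#' @param hit_e_drug Kill multiplier given to planted hits.
#' @param seed Seed for the null compounds' residual activity.
#' @return `data.frame` with `compound` and `e_drug`.
#' @export
defaultPanel <- function(n_compounds = 20, n_hits = 5, hit_e_drug = 6,
                         seed = 1L) {
  e <- withSeed(seed, stats::runif(n_compounds, 0, 0.05))
  e[seq_len(n_hits)] <- hit_e_drug
  data.frame(compound = sprintf("cmpd%02d", seq_len(n_compounds)), e_drug = e)
}

#' Default three-line kinetic panel
#'
#' Kinetic parameters for a small EGFR-mutant cell-line panel: modest
#' variation in growth rate and seeding density around the default model.
#'
#' @return Named list of [simParams()] objects.
#' @export
defaultLineParams <- function() {
  list(PC9 = simParams(r = 0.030, c0 = 10),
       H1975 = simParams(r = 0.032, c0 = 8),
       HCC2935 = simParams(r = 0.034, c0 = 12))
}
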