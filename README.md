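# persisterlab

Drug-tolerant persister (DTP) cells are the slow-cycling, reversibly
resistant subpopulation that survives continuous EGFR-inhibitor
(osimertinib) exposure in EGFR-mutant lung cancer models and regrows after
drug withdrawal. `persisterlab` implements, as a tested R package, the
computational procedures used to find therapeutic vulnerabilities in that
state:

* **Screen scoring** — trapezoid AUCs of IncuCyte-style confluence
  time-courses; *combination activity* = AUC(osimertinib DTP) −
  AUC(combination arm) and *monotherapy activity* = AUC(DMSO) −
  AUC(monotherapy); hit calling at format thresholds (10,000
  percent·hours upfront, 7,500 sequential) with the "at least 2×
  monotherapy" support rule, and 3-of-n cell-line common-hit summaries.
* **Differential analysis** — log2-CPM normalization, per-feature linear
  models under `~ 0 + treatment + cell_line`, empirical-Bayes variance
  moderation (moderated t and F; verified against limma to 1e-10), BH
  FDR, m-of-n moderated-F feature selection, per-line Z-scoring with
  seeded k-means pattern clustering, and single-sample gene-set scores.
* **Chromatin pipeline** — fixed 500 bp consensus peaks by iterative
  maximal-score selection over per-sample summit calls, abundance +
  triplicate-reproducibility filtering, nearest-TSS annotation with a
  100 kb cap, feature-class proportions, and regulatory-element overlap
  deltas (PLS/pELS/dELS).
* **Integration** — cross-cell-line meta-analysis (interval intersection,
  average fold change, Fisher-combined adjusted p at χ²(2k)), RNA–ATAC
  concordance classes at two-fold / FDR < 0.005, and merged-evidence
  hypergeometric pathway enrichment.
* **Motifs** — PWM log2-odds scanning on both strands and hypergeometric
  motif enrichment in gained vs background peaks.
* **Causal reasoning** — upstream-regulator ranking on signed directed
  networks one level above a top-500 differential signature, with
  binomial-tail and permutation significance.
* **Synthetic data** — seed-deterministic generators for every input:
  two-compartment (sensitive + persister) growth curves with washouts and
  planted combination effects; negative-binomial count matrices with
  temporal effect archetypes; peak calls with jittered summits and noise;
  sequences with planted motif instances; signed networks with a planted
  active regulator — each emitting ground truth.

## Worked example

Simulate a small single-line screen with two planted hits among six
compounds, score the upfront format, and check calls against the planted
truth:

```r
library(persisterlab)

panel <- defaultPanel(n_compounds = 6, n_hits = 2)
sim <- simulateScreen(panel, "PC9", replicates = 3,
                      params_by_line = list(PC9 = simParams()), seed = 1)
res <- scoreScreen(sim$traces, format = "upfront")
res[, c("compound", "combination_activity", "monotherapy_activity",
        "hit", "p_vs_osi")]
#>   compound combination_activity monotherapy_activity   hit  p_vs_osi
#> 1   cmpd01              10976.0               138.33  TRUE 6.565e-06
#> 2   cmpd02              10977.3               260.40  TRUE 6.495e-06
#> 3   cmpd03               2757.7               166.78 FALSE 4.317e-06
#> 4   cmpd04               4217.5                49.19 FALSE 3.097e-05
#> 5   cmpd05                949.8                59.39 FALSE 4.016e-05
#> 6   cmpd06               4177.2               114.97 FALSE 3.922e-05

evaluateAgainstTruth(res, sim$truth)[c("sensitivity", "fpr")]
#> $sensitivity
#> [1] 1
#> $fpr
#> [1] 0
```

The two planted compounds clear both the 10,000 percent·hour
combination-activity threshold and the 2× monotherapy rule; the inactive
compounds show activity well below threshold (their small `p_vs_osi`
values reflect tiny but consistent replicate differences, which is exactly
why the screen gates on effect size, not endpoint p-values). Fisher
combination of two adjusted p-values of 0.1 gives
`X = 9.21, p = 0.056` (`fisherCombine(c(0.1, 0.1))`), the χ²(4) upper
tail.

See `vignettes/persister-dtp-methods.Rmd` for the model definitions,
parameter defaults and numerical choices.

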