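---
title: "Methods: persister screening and multi-omics integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: persister screening and multi-omics integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persisterlab)
```

# Scope

`persisterlab` implements the computational backbone of a drug-tolerant
persister (DTP) vulnerability study in EGFR-mutant lung cancer models:
scoring long-term confluence-based combination drug screens, building and
filtering ATAC-seq consensus peaks, moderated differential analysis of
RNA and chromatin count matrices, cross-cell-line meta-analysis, RNA-ATAC
concordance, motif and pathway enrichment, and causal upstream-regulator
inference on signed networks. Each analysis stage is paired with a
seed-deterministic synthetic-data generator that emulates its raw inputs,
so the full pipeline is testable without any external data.

# The confluence growth model

A well holds two populations: drug-sensitive cells $S$ and persisters $P$,
measured jointly as percent confluence. Without drug, both grow
logistically at rate $r$ toward carrying capacity $K$:

$$\frac{dS}{dt} = r\,S\left(1 - \frac{S+P}{K}\right).$$

Under osimertinib, sensitive cells die at rate $d$ ($dS/dt = -dS$) while
persisters grow slowly at $r_p \ll r$. A test compound adds a persister
kill term $e_{\text{drug}}\, d\, P$, where $e_{\text{drug}}$ is a
dimensionless multiplier of the osimertinib kill rate: the screen's planted
effect size. After osimertinib washout, persisters revert to the sensitive
growth rate following a lag. Five arms mirror the screen layout: DMSO,
test-compound monotherapy (A), osimertinib monotherapy (B), upfront
combination (C), and sequential combination (D, crossover at the DTP day).
Arm A applies the persister-directed kill to the (small) persister
fraction of an untreated population, so monotherapy activity is small but
nonzero, which is what the screen's two-fold support rule is designed to
exploit.

Default parameters ($r = 0.03\,h^{-1}$, $r_p = 0.002$, $d = 0.05$,
$K = 100$, $c_0 = 10$, persister fraction $f = 0.05$, 6 h sampling, 35-day
horizon, DTP day 14, washout day 24, log-normal noise SD 0.03) were chosen
once so that the osimertinib arm reaches a persister plateau around two
weeks and regrows to confluence within the horizon, the qualitative shape
of published DTP regrowth curves. The 6 h imaging interval is a
plate-imager convention, not an inferred value.

Two numerical choices matter. Integration is fixed-step classical RK4
(internal step 0.25 h, segments split at every dosing event) — curves are
smooth and slow, and a fixed step makes traces bit-reproducible; against
the closed-form logistic solution the integrator is accurate to about
4e-10 percent confluence, far inside the 1e-6 documentation tolerance.
Populations falling below 1e-6 % confluence are set to zero: wells cannot
hold fractional cells, and this makes "no regrowth without persisters" an
exact property rather than an asymptotic one.

```{r growth-example}
tr <- simulateWell(simParams(sigma = 0), regimenSpec("B_osi"), seed = 1)
tail(tr, 3)
```

# Screen scoring

The screen's effect sizes are AUC differences in percent-hours, computed
by trapezoid over the full assay window with no baseline subtraction
(the original AUCs came from a graphing package that documents neither
baseline nor window, so both are parameters here with these defaults;
replicates are summarized by the median AUC, applied to AUCs, not
traces):

* combination activity = AUC(osimertinib DTP) − AUC(combination arm),
* monotherapy activity = AUC(DMSO) − AUC(test-compound monotherapy).

A hit must exceed the format threshold (10,000 upfront; 7,500 sequential)
*and* be at least twice the monotherapy activity; compounds that clear the
threshold but fail the two-fold rule are reported separately
(`hit_low_mono_support`). A compound is a common hit when it is a hit in
at least 3 cell lines. Endpoint significance (Welch two-sided t of
replicate combination AUCs versus osimertinib controls) is reported
alongside.

The default simulated panel plants five strong hits
($e_{\text{drug}} = 6$) among fifteen inactive compounds
($e_{\text{drug}} \sim U(0, 0.05)$, persister kill rates below the
persister growth rate). The planted kill multipliers were calibrated once
so hit recovery is robust at the default thresholds and then frozen; with
them the three-line screen recovers all planted hits with no false
positives in both formats.

# Count simulation and moderated differential analysis

Counts are negative binomial with variance $\mu + \phi\mu^2$ (Poisson at
$\phi = 0$), mean $= \text{baseline} \times 2^{\text{lfc}} \times
\text{size factor} \times \text{line offset}$. Log-normal size factors
(sd 0.1) exercise CPM normalization; per-(gene, line) log-normal offsets
(sd 0.5) reproduce the cell-line-dominant PCA structure of real panels.
Planted genes follow four temporal archetypes over the treatment course
(acute-down-recovering, acute-only-up, persistent-DTP-up,
persistent-DTP-down), emulating the recurring cluster shapes of DTP
time-course expression data.

Differential analysis fits per-feature least squares on log2-CPM
(`log2((count + 0.5) / (lib + 1) * 1e6)`) under the intercept-free
`~ 0 + treatment + cell_line` design, then shrinks residual variances
toward an empirical-Bayes prior fitted by method of moments on log
variances. Moderated t uses the posterior variance with
$d_{\text{res}} + d_0$ degrees of freedom; a moderated F over the full
contrast set supports the "significant in m of n cell lines" selection
(FDR < 0.05 eligibility, ranked by best FDR, top 2000). The moderation is
implemented in the package and verified in the test suite against the
reference empirical-Bayes implementation to 1e-10, and analytically at
both limits ($d_0 = 0$ gives ordinary t; $d_0 = \infty$ gives a pooled-z).
Precision weights for the count mean-variance trend are deliberately not
layered on top: at desk scale on log-CPM the moderated fit alone is
calibrated (null FDR < 0.05 fraction ~0.001 in the acceptance run), and
the divergence is documented here rather than hidden.

Expression patterns are grouped by per-cell-line Z-scoring and k-means.
`stats::kmeans` (Hartigan–Wong) with 25 seeded restarts is used; with a
fixed seed the restarts make the assignment reproducible, which is what
matters for the heatmap ordering (complete-linkage dendrogram leaves
within cluster). The Z-scores can be computed over all samples or
per cell line via the `cell_line` argument — published figures do not
always state which; both are exposed.

Pathway scores are single-sample mean Z over the set (a rank-based
alternative scaled to $[-1, 1]$ is available); this is a declared stand-in
for kernel-density GSVA, labelled as such, adequate for
direction-of-change comparisons between treatment groups.

# Consensus peaks, annotation and overlap deltas

Summit calls from every sample are expanded to fixed 500 bp windows;
the highest-scoring window genome-wide is kept, overlapping windows
discarded, repeating until exhaustion (ties: chromosome order, then
leftmost — the published procedure does not specify a tie-break, and a
deterministic one is required for reproducibility). A sample "calls" a
retained peak if any of its windows overlaps it. The greedy selection is
verified in the tests against an independent $O(n^2)$ re-implementation
on 1000 random summit sets, along with idempotency and
non-overlap. Peaks are kept when their best group-mean log2-CPM is at
least 2 and they are called in every replicate of at least one group.

Peaks annotate to the gene with the nearest TSS (from the peak center),
unassigned beyond 100 kb. Feature classes: promoter within TSS ± 2 kb (a
declared convention — the class windows are not published), gene body
inside a gene extent, else distal intergenic. Regulatory-element overlap
deltas report, per element class (promoter-like, proximal and distal
enhancer-like), the percentage of a differential peak set overlapping the
class minus the percentage in all consensus peaks.

# Motif scanning and enrichment

Motifs are position frequency matrices scored as log2-odds against
background at every offset on both strands; probabilities are floored at
1e-3 so impossible bases stay finite while a deterministic consensus
scores exactly $w \log_2(1/0.25)$ bits. `N` scores as background. The
default occurrence threshold is 80% of the motif's maximum attainable
score. Enrichment of hit-containing peaks among gained peaks versus
background peaks uses the hypergeometric upper tail (enrichment only, per
the gained-peak framing), BH-adjusted across motifs. The hypergeometric
tail is checked in the tests against exhaustive enumeration of all draws
on small universes and against a 10,000-draw permutation null.

# Meta-analysis, concordance and merged enrichment

Per-cell-line differential peaks are intersected by genomic overlap;
records overlapping in every line carry the mean log2 fold change, a
direction-consistency flag, and Fisher's combination
$X = -2\sum\ln p_i \sim \chi^2_{2k}$ of the *adjusted* p-values — exactly
as the source procedure states. Combining adjusted values is conservative
and nonstandard; a flag switches to raw p-values where available.

Concordance classifies each gene by its RNA effect and the mean log2 fold
change of its linked significant peaks (strongest-peak alternative by
flag): `concordant_up`/`concordant_down` need at least two-fold
same-direction change in both assays at FDR < 0.005 in both;
genes significant in both assays that miss those bounds are `discordant`;
one-assay genes are `rna_only`/`atac_only`; the rest `ns`. The six
classes partition the gene list by construction. In the synthetic
pipeline the planted concordant genes are the persistent-DTP archetypes
flagged concordant; linked peaks are placed within 2 kb of their gene's
TSS so nearest-TSS annotation is almost always unambiguous. Recovery
failures that remain are informative: peaks just above the 0.005 FDR at
n = 3, and occasional annotation to a nearer neighboring TSS.

Merged-evidence enrichment filters both assays at two-fold / adjusted
p < 0.005, unions the gene lists (labelling each gene rna/atac/both), and
scores gene sets by the hypergeometric upper tail against the tested-gene
universe. This is a transparent stand-in for multi-omics rank-combination
enrichment; the Brown's-method refinement of that tool is out of scope
and is not imitated.

# Causal upstream regulators

The observed signature is the top 500 differential genes by ascending FDR
(ties by larger absolute fold change, then identifier; zero-fold-change
genes carry no direction and are excluded before ranking), each carrying
the sign of its fold change. For a regulator under a hypothesized
direction $h$, each signed edge predicts $h \times s$ for its target;
observed targets split into correct and incorrect predictions. Two scores
are reported: a binomial upper tail of the correct count at the
signature's background match rate (adjusted per edge sign), and a
permutation p ranking the observed correct-minus-incorrect statistic
among random reassignments of the signature's directions (exact
enumeration over a regulator's targets for small out-degrees; the
all-correct four-target star gives exactly 1/16 under a balanced
signature). Both hypothesized directions are scored and swap the counts
exactly. Ambiguous both-sign duplicate edges are removed at load time.
The binomial score is a declared, documented stand-in for a proprietary
causal-reasoning score whose formula is not public; no attempt is made to
reproduce that score's values. Inference is one network level up only.

# Problem sizes and determinism

The shipped analyses run at desk scale, chosen as the package's own
defaults: a 20-compound x 3-line x 3-replicate screen (about 740 wells),
2000-gene count matrices with 3 replicates per group, 300-500 peak
universes, 200 + 2000 motif peak sequences with 11 motifs, and
20-regulator x 50-target networks. Every generator and every analysis
stage takes an explicit seed; reruns with the same seed produce
byte-identical output files, which the test suite asserts on the written
TSV/narrowPeak/FASTA artifacts.

# What the synthetic data do and do not show

The generators emulate the *structure* of the real inputs — persister
regrowth kinetics, negative-binomial counts with library-size and
cell-line variance components, reproducible peaks with jittered summits
and non-reproducible noise calls, motif instances at controlled
occupancy, signed networks with a planted active regulator. They do not
emulate read-level artifacts (GC bias, duplication, mappability),
correlated gene programs, chromatin domain structure, or realistic motif
co-occurrence. Passing tests therefore demonstrate that the
implementations compute their definitions correctly and recover planted
structure under honest noise, not that the pipeline's thresholds are
optimal for any particular real dataset.

# Known limitations

* Voom-style precision weights are not implemented; very low-count
  features are handled only through the detectability filter and prior
  count.
* The GSVA kernel and the proprietary causal score are replaced by
  documented simpler statistics, labelled in output headers.
* Consensus windows clipped at chromosome ends are still treated as
  nominal 500 bp in abundance filters.
* Fisher combination of adjusted p-values (as the source procedure
  specifies) is conservative; the raw-p flag exists for standard usage.
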