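---
title: "Reverse-engineering a tumour regulome: methods and design notes"
author: "regmra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-engineering a tumour regulome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`regmra` implements a transcription-factor (TF) centred analysis of tumour
expression cohorts. The analysis graph is:

1. infer one TF-centric regulatory network per expression cohort
   (mutual information, permutation filtering, DPI pruning, signed
   regulons);
2. derive disease gene signatures by contrasting tumour-like samples
   against candidate cell-of-origin samples;
3. run a master regulator analysis (MRA) for every network x signature
   combination and intersect the calls into a consensus MR set;
4. score per-sample regulon activity with a two-tailed enrichment
   statistic, cluster it, and map agonist/antagonist relations between
   regulons;
5. stratify patients by median regulon activity and test survival
   differences with the log-rank test;
6. test regulons for enrichment of differentially methylated genes.

Because the public cohorts this style of analysis runs on are large and
preprocessed elsewhere, the package ships a synthetic-data generator that
plants the statistical structure the analysis assumes. Every stage is
validated against that planted truth in the test suite.

# The synthetic generator

## What it plants

`generate_truth()` creates a universe of TFs and genes. A configurable
number of TFs are master regulators split into two clusters, A and B
(default 2 and 5, with 3 decoy TFs). Each MR regulon has a fixed number of
targets (default 40): a shared pool (default 30% of the regulon) regulated
by *every* MR — with one sign per gene for cluster A and the opposite sign
for cluster B — plus private targets with random signs, disjoint between
MRs. This yields the planted relations the downstream stages look for:
within a cluster all shared targets agree in sign (agonism), between
clusters they always disagree (antagonism). Decoy TFs get regulons below
the size-15 filter, so the filter and MRA specificity are both exercised.

## The expression model

Expression is linear-Gaussian on the log2 scale:

$$ x_{gs} = \sum_t w_{tg} \, a_{ts} + \varepsilon_{gs}, \qquad
   \varepsilon_{gs} \sim N(0, \sigma^2), $$

where $a_{ts}$ is the latent activity of TF $t$ in sample $s$ and
$w_{tg} \in \{-w, 0, +w\}$ the planted weight. MR activities load on a
single shared factor with opposite signs per cluster
($a = \pm\sqrt{r}f + \sqrt{1-r}\,e$, default $r = 0.7$), so each activity
is marginally standard normal, within-cluster activities correlate at
$+r$ and between-cluster activities at $-r$ — the antagonistic structure
seen in regulon-activity heatmaps of real cohorts. This is the simplest
model under which mutual information, correlation sign and two-tailed
enrichment activity are all recoverable and analytically checkable.

A TF's own expression is its activity plus noise with a *smaller*
residual sd (default `noise_sd / 4`). Two reasons. Biologically, the TF
transcript is the proximal readout of the regulator, whereas targets
accumulate downstream noise. Statistically, TF-TF dependence must exceed
indirect TF-target dependence for data-processing-inequality pruning to
be meaningful: if the TF readout carries the same noise as a target, the
paths TF1 → (shared factor) → TF2 and TF1 → (shared factor) → target of
TF2 have *identical* attenuation, DPI decisions degenerate to coin flips
on estimation noise, and no inference method could separate direct from
indirect edges. The generator's role is to produce data in the regime the
method assumes, so the cleaner TF readout is the default and is exposed
as `tf_noise_sd`.

## Survival and methylation

Survival times are exponential with per-sample hazard
$h_s = h_0 \exp(\beta_A \bar a_{A,s} + \beta_B \bar a_{B,s})$ over the
mean cluster activities (defaults $\beta_A = -1$, protective, and
$\beta_B = +1$). Censoring is independent uniform on $(0, \tau)$ with
$\tau$ solved so the expected censoring fraction at baseline hazard
equals `censor_rate` (default 20%). The exponential model has a
closed-form null and an easy external oracle (the `survival` package),
which the tests use.

Methylation is simulated as beta values: per-probe baselines uniform on
0.15–0.85, a planted case-control shift of `delta_beta` (default 0.4,
direction random per gene) on probes of the selected regulons' targets,
Gaussian probe noise (default sd 0.05), clipped to [0, 1]. The default
design is 15 cases versus 9 controls, matching the array comparison the
pipeline emulates.

## What the generator does *not* emulate

No probe-level microarray effects, no RNA-seq counts, no batch or
platform effects, no copy-number confounding, no missing values, and
normally distributed residuals throughout. Passing tests therefore show
that the *statistical machinery* recovers planted structure under the
stated model — not that real cohorts satisfy that model. Effect sizes
(weights, shifts, hazards, beta differences) are calibration choices of
this package, stated above; no published effect magnitudes exist for
them.

# Network inference

**MI estimator.** Values are rank-transformed (average ranks for ties)
and discretised into `n_bins` equal-frequency bins; MI is the plug-in
entropy estimate in nats. For a perfectly monotone pair with `n`
divisible by `B` this gives exactly `log(B)`, which the tests exploit.
The default is the cube-root rule `B = round(n^(1/3))` (5 bins at
n = 120): with `B^2` joint cells, square-root binning would leave most
cells with 0–1 samples, inflating the null variance enough to mask true
edges. Constant genes collapse to one bin (MI 0) and are flagged, not
dropped.

**Permutation filter.** The null is built by permuting the sample labels
of targets and recomputing MI for every TF-target pair; all draws are
pooled (marginals are near-uniform by construction, so pair nulls are
exchangeable), which keeps the permutation count modest. Empirical
p-values use the add-one estimator `(1 + #{null >= mi}) / (1 + total)`;
Benjamini–Hochberg is applied globally across pairs at `alpha = 0.05`
(per-TF adjustment is available behind a flag). Self-pair draws are
excluded from the pool so the denominator matches the tested pairs.

**DPI.** For each triplet (TF1, TF2, g) with all three edges retained,
the TF-g edge with the smallest MI is removed if it is smaller than both
others by more than `dpi_eps` (default 0; `NA` disables pruning). All
removals are decided against the pre-pruning edge set, so the result is
order-independent, and a TF-TF edge is never removed by a triplet it
anchors. Bootstrap consensus (an option in some implementations) is
deliberately out of scope.

**Regulons.** The mode of action is the sign of the Spearman correlation
between TF and target profiles; exact-zero correlations drop the target
with a warning. Regulons under 15 targets are kept in the listing but
flagged, and excluded from MRA, association maps and activity scoring.

# Signatures and master regulator analysis

Signatures come from per-gene Welch t-tests on log2 expression with BH
adjustment; the signature is the set with adjusted p at or below 0.05. A
plain gene list is accepted anywhere a signature is, since MRA consumes
membership only (signed statistics are retained for reporting). The
default synthetic signature contrast uses 20 case versus 20 origin
samples with an activity shift of 3; real studies of this design have
used groups as small as 2 versus 3, which the functions accept, but the
recovery guarantees quoted in the tests are for the default sizes.

MRA is a one-tailed hypergeometric overrepresentation test per
size-filtered regulon. The universe is the intersection of the network
universe and the signature's tested genes — the least arbitrary choice
given that published descriptions leave the universe unstated; the
universe (array genes vs network genes) is switchable by passing a
different signature universe. BH runs across regulons, MRs are calls at
adjusted p <= 0.05, and the consensus is the strict intersection across
all supplied analyses (monotone: adding an analysis can only shrink it).

# Regulon activity

Per cohort, expression is z-scored gene-wise (sample sd, n−1); constant
genes are dropped with a warning. For each sample, genes are ranked by
z (ties broken lexicographically by gene id for determinism) and each
regulon is scored with a weighted Kolmogorov–Smirnov running sum per
tail: hits step up by `|z| / sum(|z| over hits)` (weight exponent 1,
configurable by pre-transforming z), misses step down by
`1 / (N - n_hits)`; the enrichment score is the maximum-magnitude signed
deviation, earliest extreme on ties. The two-tailed activity is
`dES = ES(positive targets) - ES(negative targets)` in [-2, 2]; an empty
tail contributes 0 so one-sided regulons still score. `dES` is reported
raw — no permutation renormalisation and no rescaling to [-1, 1] — because
the raw difference is deterministic and directly testable; this choice is
recorded in the output metadata. When a network is projected onto another
cohort, targets are intersected with the available genes, regulons losing
more than half their targets are flagged, and zero-overlap regulons score
`NA` with a warning.

Association maps report, per regulon pair sharing at least `min_shared`
targets (default 1 — association edges are conventionally drawn without a
floor), the shared count and the fraction regulated in the same
direction; above 0.5 is agonist, below antagonist, exactly 0.5 ambiguous.
Activity clustering is average-linkage agglomeration on
`1 - Pearson` between regulon profiles (Euclidean for samples), with ties
resolved deterministically by item order.

# Survival

Each regulon's activity row is median-split: strictly above the median is
"high", at or below is "low" (published descriptions say "above the
median" for high and leave exact ties open; the at-or-below-goes-low
convention is documented, not inferred). The Kaplan–Meier estimator and
the standard unweighted log-rank test are implemented directly from
their defining formulas — they are first-class objects of this analysis,
and the test suite cross-checks both against the `survival` package to
1e-8 on random cohorts. The prognosis direction ("good" when the
high-activity group survives longer) is taken from KM medians, falling
back to restricted mean survival when both medians are undefined. The
screen reports raw per-regulon p-values (matching how per-regulon
survival results are conventionally reported) alongside BH-adjusted ones.

# Methylation

Probe-wise differential methylation uses Welch t-tests on M-values
`log2(beta / (1 - beta))` with beta clipped to `[1e-3, 1 - 1e-3]`
(variance stabilisation; testing raw beta is both non-standard and
heteroscedastic), Bonferroni-adjusted across probes at a strict 0.01.
An optional QC mask drops failed probes before testing; raw array
processing is out of scope. A gene is differentially methylated if any
of its probes is (the majority rule is available behind a flag; no
published collapsing rule exists for this step). Regulon enrichment
reuses the hypergeometric kernel over the universe of genes covered by
both the probe map and the network, Bonferroni across regulons at 0.01,
run separately per network.

# Pipeline, determinism, numerical notes

`run_pipeline()` executes the full graph — 2 cohorts x 2 signatures ->
4 MRAs -> consensus -> activity/survival per cohort -> methylation per
network — from a single config (YAML-overridable, every parameter
defaulting to the thresholds above). All randomness flows from one master
seed through fixed per-stage offsets; reports carry the config hash and
seed, and identical config + seed reproduces every output byte for byte.
Stages after the consensus can be toggled off in the config; stage-level
disk checkpointing was deliberately not implemented because every stage
runs in seconds at these problem sizes, so a resume mechanism would add
failure modes without saving meaningful time. Plots are optional
artifacts and never on the validated path.

Degenerate inputs are handled explicitly rather than silently: constant
genes (flagged or dropped with warnings, stage-dependent), zero Spearman
correlations (target dropped), all-equal activity rows (no median split,
regulon skipped with a warning), zero log-rank variance (NA with a
warning), empty tails (ES 0), empty edge lists (pass through DPI).

# Validation problem sizes

The shipped tests validate: exact hypergeometric tails against exhaustive
enumeration for every universe up to size 12; KM/log-rank against the
`survival` package on 100 random cohorts (n <= 30, 20% censoring) plus a
hand-derived worked example; MI closed forms and a 20-seed null
calibration of the edge filter (10 TFs x 500 genes, n = 120, 500
permutations); DPI on planted chains; 20-seed end-to-end consensus
recovery at the default configuration; activity fidelity, cluster
recovery and association labels against planted truth; 20-seed survival
direction/power and null calibration; 20-seed methylation enrichment
recovery and null control; and byte-identical reruns. These sizes were
chosen as the smallest at which the planted structure is comfortably
identifiable, keeping the full suite in a few minutes on one core.

# Known limitations

- The linear-Gaussian generator cannot probe robustness to heavy tails,
  nonlinear regulation or batch structure.
- Activity scores are raw `dES`, not permutation-normalised enrichment
  scores; magnitudes are comparable within a cohort, not across cohorts
  with very different regulon sizes.
- DPI assumes indirect dependencies are weaker than direct ones; with
  extremely noisy TF readouts that assumption fails in principle for any
  method of this family.
- The survival screen is univariate (no covariates, no competing risks).
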