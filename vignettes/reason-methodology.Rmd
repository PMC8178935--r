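---
title: "Methods: composite epigenetic and clinicopathologic risk scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite epigenetic and clinicopathologic risk scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Early-stage (AJCC I/II) oral squamous cell carcinoma has poor and highly
variable 5-year survival, and clinicopathologic staging alone discriminates
weakly (c-index well below 0.8). `reasonscore` builds a composite integer
risk score for 5-year disease-specific mortality with two additive
components:

* a **clinicopathologic score**: recursive partitioning over ten factors
  (age, race, sex, tobacco, alcohol, histologic grade, stage, perineural
  invasion, lymphovascular invasion, margin status), with each decision
  node contributing points equal to its death odds ratio rounded to the
  nearest integer;
* a **molecular score**: the count of signature genes whose methylation
  state, discretized from Illumina 450K beta values, has moved from the
  survivor-reference state in the gene's risk direction (one point per
  risk-positive gene).

Discrimination is evaluated with the concordance index (equal to AUROC for
a binary outcome), with tied pairs credited one half; 0.5 is random and
1 perfect concordance.

The package is organised around one fitting function, `fit_reason()`,
returning a classed object with `print`/`summary`/`coef`/`predict`/`plot`
methods; each pipeline stage is also exported for stepwise use, and a thin
command-line wrapper (`inst/scripts/reason`) exposes the stages as
subcommands.

## Probe filtering

The discovery input is a normalized beta matrix with matching detection
p-values and a probe manifest. Seven filters run in a fixed order, each
recorded in an auditable report (`n_in`, `n_removed`, `n_out` chain
exactly):

1. sex-chromosome probes removed;
2. SNP-associated probes removed, then probes mapping to no gene region
   (a probe with both flags is attributed to the SNP stage — the two
   removals are sequential, so the printed arithmetic requires the sets to
   be disjoint, which the bundled generator guarantees by construction);
3. detection filter: keep a probe with detection p < 0.01 in **at least**
   50% of samples (the boundary is inclusive: exactly half passes);
4. cross-reactive / multi-mapping probes removed;
5. uninformative-beta filter: remove a probe only when its beta is below
   0.1 in *all* samples or above 0.9 in *all* samples;
6. top-variance selection: keep the `floor(0.30 * n)` probes with the
   largest unbiased sample variance of beta. The floor is forced by the
   published count (317,016 × 0.30 = 95,104.8 → 95,104); ties at the cut
   break lexicographically by probe id so the retained set is invariant to
   input row order.

Variance is computed on the beta scale (not MAD, not M-value variance);
this is the plainest reading of "most variable" and is configurable. The
predicate filters (1–5) are idempotent; the variance filter is a quantile
selector and deliberately is not (re-applying it keeps shrinking the set).

## Surrogate variables and the 0.2 exclusion rule

Unmodeled structure (processing batches) is captured with a deterministic
surrogate-variable analysis: the candidate SVs are the right singular
vectors of the **row-centered** M-value matrix, the number of SVs is chosen
by parallel analysis (a singular value must exceed the 95th percentile of
its order statistic across 20 row-permuted matrices; the permutation
stream has its own fixed seed so "auto" selection is reproducible), signs
are fixed so each SV's largest-magnitude loading is positive, and SVs whose
|Pearson correlation with the outcome| exceeds 0.2 are excluded from the
downstream design (sign-agnostic threshold; correlation with a binary
outcome is the point-biserial coefficient).

Centering, rather than first regressing each probe on the outcome, is a
deliberate design decision: residuals from a regression on the outcome are
*exactly* orthogonal to it, so surrogate variables built from them could
never trigger the exclusion rule — the rule would be vacuous. With centered
data an SV that absorbs outcome-linked variation (a confounded batch, or
the biological signal itself) shows a real correlation and is excluded,
which is precisely the protection the rule exists to provide. The full
iterative SVA algorithm with empirical null weighting is intentionally
replaced by this deterministic variant: it is testable, seed-free up to
the documented permutation stream, and preserves orthonormality.

## Differential methylation

Modeling happens on M-values, `M = log2(beta / (1 - beta))` with beta
clipped to `[1e-6, 1 - 1e-6]` so boundary values stay finite. Each probe is
fit by ordinary least squares on `[intercept, outcome, retained SVs]`
(no clinical covariates in the probe model). Variances are moderated by
empirical Bayes: the prior degrees of freedom `d0` and prior variance
`s0²` come from closed-form method-of-moments estimators on the log
residual variances (solving `trigamma(d0/2) = var(e) - trigamma(df/2)` by
Newton inversion of the trigamma function), the posterior variance is the
precision-weighted blend `(d0 s0² + df s²)/(d0 + df)`, and two-sided
p-values use `d0 + df` degrees of freedom. When the residual variances are
essentially identical the moment equation has no positive solution and
`d0 = ∞`: shrinkage is total and every probe uses `s0²`. In the `d0 → 0`
limit the statistic is the ordinary t. Zero-variance (constant) probes are
flagged, excluded from the moment fit, and shrunk like any other probe.

Multiplicity is handled by Benjamini–Hochberg; the signature is the set of
CpGs with adjusted p < 0.1 (the lenient discovery threshold reflecting the
exploratory scale of a pilot-size cohort), its gene list is the
deduplicated symbol set, and each gene's risk direction is the sign of its
most significant CpG's effect. Because the effect scale behind a published
"fold change" for methylation is ambiguous, both the M-value difference
(`logFC`) and the mean beta difference (`delta_beta_mean`) are emitted.

## Methylation state transitions

Beta values discretize into three ordered states — unmethylated below 0.3,
hemi-methylated 0.33–0.75 (closed at both ends, forced by the "0.33–0.75"
interval wording), fully methylated strictly above 0.75. Two conventions
close genuine ambiguities and are exposed as configuration rather than
hard-wired:

* the unspecified gap `[0.30, 0.33)` merges into the unmethylated state,
  giving a single operative boundary at 0.33 (`state_thresholds()`);
* the transition baseline, which the state-transition formulation leaves
  unnamed, is the state of the **median beta among 5-year survivors**,
  with the lower-middle order statistic for even counts so the reference
  is always an observed beta. This is the key interpretive choice of the
  molecular component: risk calls are movements away from the typical
  surviving patient.

A patient is risk-positive for a gene when at least one of its CpGs shows
a state *transition* (a change without a state change never counts)
whose direction matches the gene's differential-methylation direction;
multiple CpGs aggregate by OR, maximizing the sensitivity of a
presence/absence call. The molecular score is the count of risk-positive
genes, unweighted (the combination is framed as presence/absence of each
risk factor); `predict()` on new patients carries the *training* reference
states with the model.

## The clinicopathologic score

Continuous features are dichotomized once, at the cut from a
multiples-of-5 grid (a proxy for clinically sensible round cut-offs) that
maximizes the Pearson chi-square of the 2×2 cut-by-outcome table; ties go
to the smaller cut. The tree then splits greedily on the smallest
chi-square p-value over all candidate conditions (one-level-versus-rest
for categoricals). Following the classic chi-square partitioning (CHAID)
tradition, the winning p-value is Bonferroni-adjusted for the number of
candidate splits examined at that node, so `stop_alpha = 0.05` is a
per-node family-wise level; without this, a ten-feature panel generates
roughly twenty candidate tests per node and pure-noise cohorts would split
more often than not. Stopping: adjusted p ≥ 0.05, depth 4, or a child
below 20 patients (defaults; all configurable). A root with no admissible
split is a legitimate single-leaf model scoring everyone zero.

Each decision node becomes a scoring rule: the odds ratio of death for the
risk-side branch (the branch with the higher death rate, guaranteeing
OR ≥ 1) against the other, with the Haldane–Anscombe 0.5 correction when
any cell is zero, rounded to the nearest integer (round-half-even, R's
`round()`). A rule's condition is the conjunction of its node path and the
risk-side condition; a patient's score is the sum of points over satisfied
rules, so adding a satisfied rule can only increase a score. Missing
values in a feature a rule uses make that rule unsatisfiable for that
patient (skipped and counted in a message — the feature contract is < 5%
missingness, so no imputation is attempted); an unseen category level is
an error naming the level.

A known pathology of integer odds-ratio scoring, discussed because the
tests exercise it: a sparse deep node with a zero cell can produce a
Haldane-corrected OR around 20, and its rounded points then dominate the
composite for a subgroup selected by noise. The Bonferroni stop makes such
nodes rare but cannot eliminate them; on synthetic replicates roughly one
cohort in ten fits one, which is why the recovery suite summarizes
held-out discrimination by its median across seeds rather than the mean.

## Combination and evaluation

The composite score is the plain sum of the two components. The
concordance index is computed by exact pair enumeration up to 10⁴ patients
and by a midrank-based O(n log n) route beyond (the two are verified to
agree, concordant/discordant/tied counts included). Bootstrap percentile
intervals (default 2,000 patient-level resamples, seeded; resamples
without both outcome classes are redrawn) accompany panel comparisons.

## Downstream analyses

Expression counts are filtered to genes with ≥ 10 counts in ≥ 90% of
samples. Expression–methylation correlation is Pearson on
`log2(count + 1)` (the transform is configurable to raw scale; a published
correlation of raw "gene counts" in a general-purpose stats package leaves
the scale unstated, and for monotone planted effects the sign is
transform-invariant), with p-values from the t transform of r.
Over-representation uses the one-sided upper-tail hypergeometric test per
GMT gene set with Bonferroni correction over the sets actually tested.
The background universe defaults to **all** genes surviving differential
methylation — the "non-significant genes as background" reading would
exclude the query from its own universe, which breaks the hypergeometric
model; both modes exist (`ora_universe()`), with the query always forced
into the universe.

## The synthetic-data generator

`simulate_bundle()` emulates the study conditions end to end so every
stage is testable offline:

* **cohort**: marginal prevalences follow the published TCGA-like
  early-stage oral-cavity table (60% male, 93% white, mean age 64, 68%
  ever-smokers, 61% alcohol, 57% tongue, 69% stage II, 35% PNI, 6.9% LVI,
  21% positive/close margins); outcome is drawn from a logistic model over
  configurable odds multipliers with the intercept calibrated by root
  finding so the marginal event rate hits the target (default 0.14,
  TCGA-like; 0.37 mirrors an internal-cohort regime);
* **methylation**: per-probe logit-normal mixture (hypo/hyper modes,
  default noise sd 0.4 on the logit scale, clipped), 13 signature CpGs
  over 12 genes with baselines 0.55 (hyper-directed) and 0.45
  (hypo-directed) placed one state-boundary crossing away from a
  ±0.25 beta shift planted in deceased patients (shifts clip into [0,1],
  never error); disjoint X/Y, SNP, unmapped, cross-reactive, and
  uninformative probe classes at published-array fractions; an additive
  logit-scale batch effect with per-probe loadings (sd 0.5, "strong"
  batches) and batch allocation optionally biased to hit a target
  batch–outcome correlation; detection failures per entry plus a set of
  systematically bad probes;
* **expression**: negative-binomial counts whose log2 mean tracks a
  latent variable correlated with the gene's signature-CpG beta at a
  configured signed target;
* **truth**: everything planted is recorded, and the truth file states
  explicitly that joint distributions are invented stand-ins — only
  marginal prevalences and array-class fractions follow published
  summaries.

Reproducibility contract: one top-level seed, stage-derived streams, and a
separate `design_seed` so replicate cohorts can be drawn on an identical
array (same signature probe ids, directions, batch loadings) — this is
what held-out evaluation uses. A fixed seed yields a byte-identical
bundle, and written bundles round-trip bit-exactly (doubles serialized at
17 significant digits).

What the generator does **not** emulate: probe type I/II chemistry, raw
intensities, realistic linkage disequilibrium or co-methylation structure,
informative missingness, censoring. Passing tests therefore demonstrate
the pipeline's arithmetic and its statistical behavior under a clean
generative model, not performance on real cohorts.

## Problem sizes in the stochastic suites

Chosen as the package's own balance of power against runtime, and fixed
by seed: null type-I control of the moderated t at 50 seeds × 2,000
probes × 60 patients; signature recovery at 20 seeds (n = 60, event rate
0.14, shift 0.25); score recovery and ordering at 50 seeds of paired
500-patient cohorts with two planted factors (PNI odds 3.5, stage odds
3.0 at event rate 0.37 — chosen so the Bayes-optimal predictor sits in
the mid-0.6 to low-0.7 c-index regime typical of clinicopathologic
panels); null end-to-end calibration at 50 seeds (n = 60, 300 probes).
The filter-cascade worked example runs at the full published array size
(485,512 probes × 4 samples) in seconds.

## Known limitations

* The reference-state convention (survivor median) and the `[0.30, 0.33)`
  gap closure are interpretive choices; both are configuration-exposed,
  and conclusions sensitive to them should be checked under alternatives.
* Integer OR points are coarse and can be dominated by sparse-node
  estimates (see above).
* The outcome is fixed-horizon binary status; censoring-aware concordance
  (Harrell's C over time-to-event) is out of scope.
* Identifier mapping (Ensembl/Entrez), ontology-graph propagation for GO,
  and figure-grade heatmap/network rendering are out of scope; tabular
  outputs are provided instead.
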