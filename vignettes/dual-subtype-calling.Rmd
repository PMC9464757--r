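---
title: "Calling dual molecular subtypes with correlation-to-centroid signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling dual molecular subtypes with correlation-to-centroid signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualsubtype)
```

## The problem

Eighty-gene molecular subtyping assays score a breast tumor against three
gene signatures — Luminal (58 genes), Basal (28 genes) and HER2 (4 genes) —
and call the subtype as the highest-scoring class. For most tumors the top
score is clearly separated from the rest, but a minority of tumors activate
two (occasionally three) transcriptional programs at once: the top two
scores are then statistically indiscernible, and forcing a single label
hides biology that matters for treatment response (a Luminal-HER2 tumor
does not respond to HER2-directed therapy like a pure HER2 tumor does).

`dualsubtype` implements this analysis end to end: centroid scoring,
single/dual/triple calling, prevalence re-weighting to a clinical
population, four-class triple-negative re-classification, the clinical rule
set and cohort statistics, and a synthetic cohort generator so every stage
is testable without access to a proprietary assay cohort.

## Scoring model

Let $x_c(s)$ be the profile of sample $s$ restricted to class $c$'s gene
set and $\mu_c$ the class centroid over those genes. The subtype score is
the Pearson correlation

$$r_c(s) = \operatorname{cor}\big(x_c(s),\, \mu_c\big) \in [-1, 1],$$

and the standard call is $\arg\max_c r_c(s)$, with exact ties broken in the
fixed order (Luminal, Basal, HER2). Correlation-to-centroid is the
established design of this assay family; the score form is nonetheless
configurable (`method = "spearman"` or `"cosine"`), and gene
standardization before scoring is available but **off** by default — the
assay's own preprocessing is out of scope here, and the default assumes
log-ratio input on a common scale. Missing genes and zero-variance
restrictions are hard errors, never imputed or silently scored 0.

Centroids are trained as per-gene class means over labeled samples
(`train_centroids()`); commercial centroid values are proprietary and are
not shipped.

## Single / dual / triple calling

The statistic of interest is the top difference
$d = r_{(1)} - r_{(2)} \ge 0$. Two complementary pieces of evidence decide
whether the top pair is indiscernible:

1. **Cohort thresholds from multimodality detection**
   (`fit_difference_thresholds()`). For each winning class, the
   distribution of $d$ over the samples that class wins is fitted with 1-
   and 2-component Gaussian mixtures (via `mclust`, BIC selection). If the
   2-component model wins *and* the component means are separated by more
   than the sum of their SDs, the threshold $t_c$ is the density minimum
   between the means (grid search, step $10^{-4}$). Otherwise the fit falls
   back to a low quantile of $d$ (default the 5th percentile), flagged
   `quantile-fallback`. Classes winning fewer than 50 samples are fitted on
   the pooled distribution; classes winning none stay undefined.
2. **Per-sample gene bootstrap** (`bootstrap_scores()`). Each of $B$
   replicates resamples every signature's genes with replacement (keeping
   the signature size) and rescoring. The *flip fraction* for an ordered
   class pair is the share of replicates in which the lower-ranked class
   meets or exceeds the higher one; ties count as flips, so complementary
   flip fractions sum to at least 1.

The top pair is indiscernible when $d < t_c$ **or** the flip fraction
exceeds `alpha` (default 0.05). If it is, the (second, third) pair is
tested by the same rule — reusing the winning class's threshold on
$r_{(2)} - r_{(3)}$ — giving Triple when both pairs are indiscernible, Dual
when only the top pair is, Single otherwise. Dual labels concatenate the
components in descending score order (`"Luminal-Basal-type"`).

Design choices worth stating explicitly, since the combination of bootstrap
and multimodality evidence admits several reasonable constructions:

* **The resampling unit is genes within each signature.** Per-sample
  calling needs a within-sample unit of resampling, and at scoring time
  genes are the only replicated unit available. The procedure is isolated
  behind `bootstrap_scores()` so an alternative (e.g. residual resampling)
  can be swapped in.
* **The two criteria combine by OR**, and either can be disabled
  (`use_threshold`, `use_bootstrap`). The threshold captures cohort-level
  bimodality; the flip fraction captures per-sample score stability; a
  sample flagged by either is not confidently single.
* **The threshold comparison is strict** ($d < t$, not $\le$). With a
  degenerate difference distribution (all $d$ identical, e.g. a noise-free
  all-single cohort) the fallback threshold equals that constant, and a
  non-strict rule would absurdly call the entire cohort dual. A tied top
  pair ($d = 0$) is still never Single: its flip fraction is at least 0.5,
  and $0 < t$ for any positive threshold.
* **Triple testing reuses the winning class's threshold** for the
  (second, third) pair; fitting separate second-order thresholds would need
  far more triples than any cohort provides.
* **Defaults** $B = 1000$, `alpha` $= 0.05$, fallback quantile 5%,
  separation guard = sum of component SDs. These are this package's
  reconstruction defaults, all configurable.

Replicates in which a resampled gene multiset is constant (possible for
tiny signatures) are marked invalid per class; flip fractions use pairwise
valid replicates, and more than `max_invalid` (default 50%) invalid
replicates for any class is an error. For 2-gene toy signatures — where
half of all resamples are degenerate by construction — `max_invalid` must
be raised; the tests use exactly this regime because every valid resample
of a 2-gene signature is a permutation, making exhaustive enumeration an
exact oracle.

### The 4-gene HER2 signature

A Pearson correlation over 4 genes is fragile: under the null (a sample
with no structure on those genes) it is uniform on $(-1, 1)$, and its gene
bootstrap is wide, because a 4-from-4 resample keeps only two distinct
genes about a third of the time (yielding correlations of exactly
$\pm 1$). The expected consequence — more dual calls among HER2-won samples
than among Luminal-won ones — is a documented property of the assay
geometry, not corrected away.

## Synthetic cohorts

`generate_expression_cohort()` emulates a reference-based log-ratio
expression cohort:

* Sample composition is allocated **deterministically** (largest-remainder
  rounding) over kinds (Single/Dual/Triple) and class compositions, so
  fixture sizes are exact; randomness is confined to expression noise and
  clinical draws. Dual pairs are allocated proportionally to the product of
  their class proportions.
* An **active** program shifts its signature genes up by
  `activation_effect` (default 2, log2 units) times per-gene loadings
  spanning 0.25–1.75 with mean exactly 1 — signature genes respond
  heterogeneously in real data, and a uniform shift would leave centroids
  without usable gene-level contrast. When two or more programs are
  co-active, each shift is scaled by `dual_attenuation` (default 0.7),
  emulating the intermediate marker levels dual tumors show.
* An **inactive** program is repressed by `repression_effect` times the
  same loadings (default: mirror of the activation effect). On two-color
  log-ratio platforms the "off" state of a subtype program genuinely sits
  below the reference (ESR1 in basal tumors, the ERBB2 amplicon in
  non-amplified tumors), and without this the chance correlation of a
  non-member sample against the 4-gene HER2 centroid would be uniform
  noise, which no correlation classifier can survive.
* Background genes are pure $\mathcal N(0, \texttt{noise\_sd}^2)$ noise;
  default `noise_sd` 0.3 log2 units.
* Default class proportions (0.85, 0.10, 0.05) reflect an HR+-dominated
  referral population; default `dual_fraction` 0.05 and `triple_fraction`
  0.003 match the order of magnitude of reported dual/triple rates.

Clinical annotations are coupled to the planted classes: ER means ordered
Luminal-single (85%) > Luminal-involved dual (60%) > HR− (< 1%); Ki-67
means ordered Luminal-single (15%) < dual (40%) < HER2-single (65%) <
Basal-single (70%), SD 12, clipped to [0, 100]; HER2 IHC/FISH drawn
consistently with the planted HR/HER2 stratum; HER2+ samples assigned to
the trastuzumab-containing arm. pCR outcomes are Bernoulli per group with
configurable rates; the pipeline default encodes the headline contrast
(61.3% for HER2-single vs 23.8% for Luminal-HER2 under chemotherapy +
trastuzumab).

What the generator does **not** emulate: probe-level microarray structure,
batch effects, correlated gene-gene noise within a signature, assay
normalization, or continuous gradations of pathway activity (activation is
binary per program, modulated only by attenuation). Passing recovery tests
on these cohorts therefore demonstrates the *mechanics* of the classifier
under its design assumptions, not its accuracy on any real cohort.

## Prevalence under a clinical mixture

Cohorts enriched for one clinical subtype misstate the population dual
rate. `estimate_mixture_prevalence()` resamples the cohort to a target
HR/HER2 composition (default 70/13/5/12% for HR+HER2−, HR+HER2+, HR−HER2+,
HR−HER2−): each of `n_iter` iterations draws
$\mathrm{round}(w_k \cdot \texttt{subset\_size})$ samples with replacement
from stratum $k$ and records the dual fraction; the estimate is the mean
and the 95% interval the 2.5/97.5 percentiles across iterations. Because
the per-sample indicator is binary, the with-replacement draw within a
stratum is realized as a binomial draw on the stratum's observed dual rate
— distributionally identical and orders of magnitude faster. Sampling
*with* replacement is forced by the geometry: a 5% stratum of a small
cohort must be over-sampled to fill its quota. Triples are excluded from
the numerator by default, matching the separate accounting of dual and
triple calls. Defaults `n_iter` 1000 and `subset_size` 10000 give
Monte-Carlo error well below 0.1 percentage points; the estimator is
consistent for $\sum_k w_k r_k$.

## TNBC re-classification

`classify_burstein()` applies the same scoring core to a four-class model
(BLIA, BLIS, LAR, MES) over one shared 80-gene panel. Published centroid
values are deliberately not hard-coded: the model ships as a JSON schema
the user populates, plus `synthetic_burstein_model()` — clearly labelled
synthetic — for exercising the mechanics. Cross-tabulation against the
single/dual calls feeds the chi-square machinery; in simulate mode the
pipeline runs a self-contained synthetic demonstration in which
Basal-involved duals are drawn from LAR/MES centroids and singles from
BLIA/BLIS.

## Clinical rules and statistics

* HR+ iff ER ≥ 1% or PR ≥ 1%; if one marker is missing and the other below
  1%, the status is missing rather than guessed.
* HER2+ iff IHC 3+ or IHC 2+/FISH-amplified; IHC 2+ without FISH is
  missing.
* Ki-67 < 30% tags the low-proliferation ("TNLP") range; ER-low-positive
  is 1–10% inclusive.
* Chi-square of independence without continuity correction; two-sample
  *t* defaults to Welch/Satterthwaite (toggleable to pooled); proportions
  carry Wilson score intervals; logistic regression is the standard IRLS
  fit with Wald tests, with quasi-complete separation detected from
  diverging coefficients and flagged unusable rather than reported as
  significant. No multiple-testing adjustment is applied anywhere — raw
  p-values are reported, and that is a deliberate, documented scope
  decision.

## Pipeline and reproducibility

`run_pipeline()` chains simulate/ingest → train/read model → score → fit
thresholds → dual-call → prevalence → TNBC re-classification → statistics
→ summary, driven by one validated configuration (YAML/JSON or list);
unknown keys and missing files fail before any computation. All randomness
derives from the single configured seed, and report files contain no
timestamps, so a rerun of the same configuration is byte-identical. When
the simulated cohort lacks a stratum the prevalence mixture requires
(e.g. an all-single configuration with no HER2+ dual stratum), that stage
is skipped with a message instead of failing the run. A thin command-line
front end (`inst/cli/dualsubtype.R`) exposes the stages as subcommands;
the R functions remain the primary interface.

## Problem sizes and known limitations

The shipped tests and the acceptance script use cohorts of 150–2000
samples, $B$ of 60–1000 and prevalence resampling up to
$1000 \times 10000$, sizes at which every stage's behavior is already
stable and a full run takes well under a minute.

Known limitations:

* With very few duals per winning class (a handful of points), the
  2-component fit can lodge a wide low component across the gap and place
  the valley high, over-calling duals and, through the shared-threshold
  triple rule, triples. The diagnostics recorded per class (`decision`,
  component parameters) make this visible; cohorts of a few hundred
  samples with ≥ 5% duals behave well.
* HER2's 4-gene signature keeps an irreducible chance-correlation floor
  (see above).
* The generator's binary activation model cannot probe graded pathway
  activity; recovery rates on it are upper bounds for messier data.
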