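---
title: "Separating cryptic bumble bees with malar ratios: models and methods"
author: "cryptobee authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating cryptic bumble bees with malar ratios: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptobee)
```

## The identification problem

*Bombus sandersoni*, *B. vagans* and *B. perplexus* are sympatric North
American bumble bees in the subgenus *Pyrobombus* whose hair-colour patterns
overlap so much that field identifications — even by experienced
observers — are wrong roughly 30% of the time. Workers are the main problem:
they show up to ten-fold body-size variation, so any absolute measurement is
useless and qualitative "cheek slightly longer than wide" characters do not
transfer across sizes.

The quantitative way out is a set of three size-invariant ratios measured
under a stereomicroscope with an eyepiece reticle:

* **MRL** = malar length / malar width,
* **MR1** = malar length / flagellomere-1 length,
* **MR3** = malar length / flagellomere-3 length.

Because all four raw measurements of a bee share one reticle scale, the
ratios are unit-free; `cryptobee` never converts reticle units to
millimetres (`compute_ratios()` warns, rather than errors, when MRL ≥ 1,
because "malar length smaller than malar width" is an empirical regularity
of this group, not a definition). Species labels used to train and evaluate
the classifiers come from DNA barcodes (a short diagnostic COI fragment),
which is the package's ground truth throughout.

## The synthetic specimen generator

The raw specimen table behind the published analysis is not public, so the
package ships a generator whose defaults *are* the study conditions, and all
distribution-level results are internal-consistency reproductions on that
calibration:

* **Sample sizes** per species × caste: 19/27/35 workers and 3/22/9 queens
  (perplexus/sandersoni/vagans), 115 bees in total.
* **Cell means** for (MR1, MR3, MRL) are the published model-based marginal
  means (e.g. vagans workers: 1.46, 1.83, 0.92).
* **Cell SDs** are back-derived from the published two-sided 99% predictive
  intervals assuming normality: `sd = (hi − lo) / (2 × qnorm(0.995))`
  (divisor 5.1517). For example the vagans-worker MR1 interval 1.30–1.62
  gives sd = 0.0621. The "99% quantile" wording is read as the *central*
  (0.5%, 99.5%) interval because the published brackets are two-sided.
* **Inter-ratio correlations** use the pooled published values
  (MR1–MR3 0.66, MR1–MRL 0.75, MR3–MRL 0.77) inside every cell, projected to
  the nearest positive semi-definite matrix if needed (the default is
  already positive definite). Reusing pooled correlations within cells is
  conservative for combined-measurement accuracy: within-class correlations
  are, if anything, smaller.
* **Raw measurements** are back-filled from the drawn ratios with the malar
  width anchored at 1 reticle unit; only ratios are identifiable, so the
  anchor is arbitrary and exercised by the scale-invariance tests.
* **Hair traits** are sampled uniformly over each cell's characteristic
  category span (the source prints category spans like "few–many", never
  frequencies); a category that is itself a vocabulary value
  ("dark-light" mesipisternum) is taken literally. Yellow T3 hairs are
  simulated only for light-pleura perplexus (probability 0.7, "often").
* **Visual identifications** are correct with probability 0.704, the
  published field-identification success rate.
* **Region** is assigned 50/50 and has no effect on the ratios, which makes
  its F test a clean null for calibration checks.

What the generator deliberately does **not** emulate: measurement rounding
to reticle divisions, any within-colony correlation structure, real
hair-trait frequencies, region effects, and non-normal tails. Passing tests
therefore demonstrate that the *pipeline* recovers the published
distributional summaries under the published conditions — not that the
published values are correct for real bees.

## Discriminant analysis and its uncertainty

The classifier is two-class Gaussian LDA written in the package (class
means, covariance pooled by degrees of freedom, priors equal to training
class frequencies, maximum log-posterior decision rule). `MASS::lda` and a
brute-force log-posterior oracle serve as independent cross-checks in the
test suite, never as the engine. *B. perplexus* is excluded from LDA: its
hair characters (dark lower pleura in the common form, scattered dark
thoracic hairs even in the light form) already identify it, and its ratios
overlap *B. sandersoni* too much for a ratio-only classifier to be honest.

Evaluation follows a stratified 60/40 train/test design (per-class ceiling
into training, so 27 + 35 workers split 17 + 21 / 10 + 14). Uncertainty is
quantified two ways:

* `bootstrap_accuracy()` — the data-based procedure: 999 replicates of
  class-stratified resampling with replacement (keeping class counts),
  a fresh stratified split per replicate, fit, predict; report the median
  and SD of test accuracy. What exactly is resampled was an open design
  point; resampling the full dataset before splitting keeps class balance
  and yields the non-degenerate accuracy SDs that a split-only scheme
  cannot.
* `simulation_accuracy()` — the parametric counterpart used for the
  headline reproductions: each replicate simulates a fresh calibrated
  dataset before splitting. With no released dataset to resample, this is
  the estimator the calibration supports directly.

Under the default calibration the queen classifiers are perfect for all
three measurements (median 100%), worker MRL is perfect, and worker MR1 and
MR3 land at a median of 23/24 ≈ 95.8% correct — the test set has 24 bees, so
the accuracy distribution is lattice-valued and the median sits on a lattice
point near the published 96%/97%.

## Predictive reference ranges

Reference intervals per species × caste × measurement are built by a
bootstrap-then-simulate scheme: 500 bootstrap replicates of the cell mean,
then a simulated population of 10,000 bees from `Normal(mean, sd)`, reported
as the central 99% interval. Two interpretation points, decided once:

* The population is simulated with the **sample SD**, not the bootstrap SE
  of the mean: reference ranges describe bees, and the published predicted
  intervals are wider than the observed ranges, which is impossible under
  an SE-scale spread.
* The "99% quantile" is the central (0.5%, 99.5%) interval, matching the
  two-sided published brackets.

The predicted interval always contains the cell mean, widens strictly with
sd, and converges to `mean ± 2.576 sd` as the simulated population grows.
One stability caveat found during calibration: at the population parameters
the vagans and sandersoni MRL intervals are disjoint for both castes, but
the gap is only ≈ 0.02, so on any *single* simulated dataset the estimated
bounds can overlap once the cell SDs are themselves estimated. The stable
per-dataset statement — and the published one — is that the *observed* MRL
ranges of the two species never overlap; the tests assert exactly that.

`classify_by_ranges()` combines ranges with hair rules, which only ever
shrink or re-rank the range-based candidate set, with one exception: dark
hairs on the lower mesipisternum are treated as *diagnostic* for
*B. perplexus* (the other two species never show them), so that rule
overrides range filtering. Many black scutum hairs exclude perplexus;
yellow T3 hairs move light-form perplexus to the front. An empty candidate
set is a valid "ambiguous — consider DNA confirmation" answer.

## Species comparisons

Mean ratios are compared with an ordinary least-squares model (a Gaussian
GLM with identity link *is* OLS) of ratio on species, caste and region,
with species:caste and species:region interactions fitted first. Terms are
tested with **Type II** (marginal) F statistics via `car::Anova` — the
design is unbalanced and the published table names only "ANOVA", so the
marginal flavour is the package's documented choice; on balanced data it
coincides with the sequential one. Interactions with p > 0.05 are dropped
and the model refitted, mirroring the published pruning rule (the
calibration simulates no interactions, so pruning removes both terms about
90% of the time and the power tests confirm a 5-SD interaction is
essentially always retained).

Marginal means per species × caste average the region levels with **equal
weight** (the published estimates are explicitly "averaged over region"),
with delta-method SEs and t-based confidence limits. Pairwise species
contrasts are Tukey-adjusted through the studentized-range distribution:
`p = P(q_{k, df} ≥ |t|·√2)` using R's `ptukey`, which the acceptance suite
cross-checks against a 10^6-draw Monte Carlo oracle to within 0.002, and
which the unit tests verify against `emmeans` to 1e-8 and against the plain
t-test at k = 2. With the 115-bee design the main-effects model has 110
residual degrees of freedom, matching the published tables.

## Observer repeatability

Replicated measurements are modelled additively: measured ratio = true
ratio + observer bias + replicate noise. The default replicate SD (0.03
ratio units) and observer-bias SD (0.01) were fixed once so that
within-observer correlations fall around the published 0.86–0.95 band given
the simulated between-bee variance, and per-specimen replicate SDs stay
under the published maximum of 0.11; `within_sd_for_r()` inverts
`R = var_bee / (var_bee + within_sd²)` when a measurement-specific target is
wanted. Correlations are plain Pearson tests (`cor.test`), reported with
t and n − 2 degrees of freedom; between-observer comparisons pair
per-specimen replicate means (whether the original analysis averaged
replicates first is unstated — averaging is the package's documented
choice). The SD-vs-mean association uses the per-specimen mean and SD
across a comparison's replicates; specimens with a single replicate are
excluded with a message, and a comparison whose measurement one observer
never made yields an NA row, as in the published table.

## Barcode analysis

The barcode module works at desk scale on an aligned, ungapped ~150 bp COI
fragment: FASTA I/O through `Biostrings`, haplotype collapse (identical
sequences, deterministic first-appearance naming), pairwise percent
identity (sites with non-ACGT symbols in either sequence are excluded from
numerator and denominator), group-wise mean identities, and a haplotype
network as the minimum-spanning forest over pairwise base-pair differences
with edges above a connection limit removed (Kruskal's algorithm,
name-order tie-breaking, so networks are reproducible). The full
statistical-parsimony connection-probability calculation is deliberately
not re-derived; the limit is an explicit step count defaulting to 10, a
typical parsimony limit for a fragment of this length.

The synthetic barcode preset uses a 140 bp fragment with exact divergences:
6 substitutions between sandersoni and vagans (identity 95.7%) and 8
between perplexus and each other species (94.3%), with perplexus split into
two haplotypes one substitution apart. The published 99.3% within-perplexus
similarity is reproducible as a haplotype-pair identity (1 − 1/140 = 99.3%)
but not as an individual-pair average at n = 22 (the haplotype-pair weight
can never get close enough to 1), so the within-perplexus check asserts
"< 100%, exact under the pair-count formula" rather than the printed value.
The perplexus haplotype split defaults to 50/50; the source does not print
haplotype counts.

## Problem sizes and numerical choices

The reproduction runs use 999 replicates for every accuracy median, 200
simulated datasets for the linear-model summaries, 500 bootstrap replicates
and 10,000 simulated bees per reference-range cell, 10^6 draws for the
Monte Carlo oracles, and 2,000 null simulations for the size checks of the
F and Pearson tests — the same replicate counts as the published procedure
where one is stated, and sizes chosen for stable estimates where not. All
generators take explicit integer seeds and are byte-reproducible;
deterministic tie-breaking is used wherever an order is otherwise
unspecified (equal LDA posteriors take the first class; equal-weight
network edges follow haplotype order). Collinear discriminant measurements
(singular pooled covariance), rank-deficient designs, single-member range
cells, zero-variance correlations and infeasible divergence triangles are
all explicit errors or NA results rather than silent numerics.

## Known limitations

* All distribution-level reproductions are internal-consistency checks
  against the calibrated generator, not against the unreleased specimen
  table; observed min/max columns of the published range table are
  explicitly out of reach.
* The ratio model is normal within cells; real reticle data are rounded to
  grid divisions and may be slightly skewed.
* The barcode module assumes an ungapped alignment of one fragment and does
  not model sequencing error, indels or chromatogram assembly.
* Range-based identification returns candidate sets, not posterior
  probabilities; ambiguity is reported, not resolved.
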