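---
title: "tfpulse: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tfpulse: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfpulse)
```

tfpulse analyzes two-color microarray time courses of treated versus
untreated cultures: per-gene log2 expression ratios at a pre-treatment
reference and several post-treatment time points, with dye-swap technical
replication, interpreted through a known TF→gene wiring diagram. This
vignette explains each stage's model, its assumptions, the tunable
parameters, and the design choices made where more than one reasonable
option existed.

## The experimental design being modelled

The default `array_design()` is six sampling times (0, 10, 20, 40, 60,
120 min; the first is the untreated reference taken just before compound
addition) and four replicates per condition: two biological repeats, each
hybridized twice with the dye assignment of the experimental and control
channels exchanged. Dye swaps exist because Cy3 and Cy5 fluorescence are
not equally efficient, particularly at low intensity; exchanging the
labels lets label-specific bias cancel across a replicate pair and — more
importantly here — lets the per-array normalization be checked against
ground truth in simulation.

The control channel is a fixed pre-treatment reference rather than a
time-matched untreated culture; this is a configuration choice of the
generator (`condition` labels and the design object travel with every
table) and the pipeline itself is agnostic to it.

## Preprocessing

`compute_ratios()` forms, per feature and array,
M = log2(experimental/control) *oriented by the recorded dye assignment*
(so positive M always means induction, whichever dye carried the treated
sample) and A = ½·log2(Cy3·Cy5). Non-positive intensities are a hard
error naming the offending feature, never silently dropped.

`lowess_normalize()` fits a robust locally weighted regression of M on A
separately for each array and subtracts it. Defaults are span 0.3 and 3
robustness iterations — conventional values for expression arrays; the
span is the fraction of features entering each local fit, so it trades
bias-curve flexibility against absorption of real signal. Normalization
is per array ("global" in the sense of one fit across all features of an
array, with no print-tip stratification, which the data model does not
carry). Arrays with fewer than 20 features fall back to median-centering
with a warning. Two properties are worth stating plainly:

* LOWESS assumes most features are unchanged. When many genes carry
  strong signal, the local trend absorbs part of it. The packaged
  normalization checks therefore use genome-scale fixtures (4000
  features) with a quiet transcriptome, which is the regime the method is
  designed for.
* LOWESS is not an exact projection: applying it twice removes a further
  sliver — residual noise smoothing plus span-limited misfit of a steep
  bias curve. The test suite checks that the second pass moves decile
  means by less than 5% of what the first pass removed (the
  median-centering fallback, by contrast, is exactly idempotent).

`assemble_series()` collects normalized arrays into the long
gene × time × replicate series, erroring on duplicate cells and leaving
missing cells absent (never zero-filled); genes missing in more than one
replicate at a time point are flagged, not imputed.

The QC calculators implement the labelling suitability rules: cDNA yield
in ng is A260 × 330 × elution volume (50 µl default), specific activity
is dye pmol/µl divided by cDNA ng/µl times 1000, and a sample passes iff
yield > 825 ng *and* specific activity > 8 pmol/µg, both strict.

## Differential expression

`call_de()` tests, per (gene, condition, time), the replicate log2 ratios
against zero with a two-sided one-sample t-test and calls a gene
significant only if additionally |mean log2 ratio| ≥ log2(fold_cutoff)
(default 2-fold). The one-sample form reflects the hybridization design:
each array is already a treated-versus-control contrast, so "no change"
is a ratio of 1. Testing is per time point, matching how fold changes are
reported per time.

Degenerate replicate sets have explicit policies rather than NaN
propagation: all replicates exactly zero gives p = 1; all replicates
equal but nonzero (zero sample variance) gives the sentinel p = 0 with a
`zero_variance` flag; fewer than two replicates is reported untestable
(p = NA), never silently significant. No multiple-testing correction
gates the calls; a Benjamini–Hochberg column is emitted alongside for
transparency and the number of tests is attached as an attribute.
`summarize_fold_changes()` renders the wide per-gene table of signed fold
changes with an asterisk on cells whose p exceeds the threshold, joined
to user-supplied product/category/regulator annotations with an explicit
"unannotated" fill.

## TF activity inference

The model is log-linear with fixed connectivity:

$$x_{gt} = \sum_f X_{gf}\, b_{gf}\, c_{ft} + \varepsilon, \qquad
\varepsilon \sim \mathcal{N}(0, s^2),$$

with zero-mean Gaussian priors on the weights $b$ (per edge) and the
activities $c$ (per TF and time). Replicates enter as repeated
observations of the same (gene, time) mean by default
(`replicates = "average"` collapses them first). The model is a snapshot
approximation — there is deliberately no temporal prior linking adjacent
time points, no network learning and no nonlinear transcription kinetics.

**Fitting.** Mean-field variational Bayes over the bilinear pair: a full
Gaussian posterior over each time point's activity vector and over each
gene's weight vector, updated in closed form in alternation, with an
EM-style point update of $s^2$. The evidence lower bound is computed each
sweep; every update is a coordinate-ascent step, so the trace is
non-decreasing — a property the test suite asserts on every fixture.

**ARD pruning.** Each TF has its own weight-prior variance
$\tau_f$, re-estimated by empirical Bayes (the mean second moment of the
TF's weight column) and floored at $10^{-4}$ — i.e. a TF whose weights
fall below 1% of the unit weight scale is pruned. This automatic
relevance determination step is what makes the downstream
non-responsiveness filter meaningful. Without it, the bilinear model
exhibits a well-known pathology on uninformative data: the weight
posterior stays at prior scale, the mean-field activity precision counts
that prior-level weight mass as signal power, and the activity posterior
ends up with deceptively tight error bars around noise-fit means. With
ARD, a TF whose targets carry no coherent signal has its weight column
collapse, and its activity posterior reverts to the activity prior:
near-zero means with wide bars, correctly reported as "nothing
inferable". The weight/ARD pair is iterated to its joint fixed point
within each sweep (an inner coordinate-ascent loop, so monotonicity is
preserved) so that borderline TFs are resolved rather than left mid-way
down the slow ARD decay path.

**Error bars.** Reported activity standard deviations come from the
plug-in precision at the weight means — the Bayesian linear-regression
covariance given $b = \mathbb{E}[b]$ — rather than from the raw
mean-field covariance, for the reason above: in the mean-field update the
weight *uncertainty* sharpens the activity precision, which is exactly
backwards for an uncertainty report. The activity means keep their fully
shrunken variational values. (With weights held fixed the two coincide,
which is how the suite checks the update against a brute-force Bayesian
regression oracle to 1e-8.)

**Identifiability.** The likelihood is invariant under jointly rescaling
a TF's weight column and activity row, and under jointly negating them.
The scale gauge is fixed at report time by rescaling each TF to unit mean
squared weight (applied symmetrically to means and sds, so all
downstream quantities — the discard test and |r| are scale-invariant —
are unaffected; rescaling mid-run is not an ascent step and would break
the monotone trace). The sign gauge cannot be fixed from data at all;
`sign_ambiguity_report()` votes inferred weight signs against the signed
network annotation and `flip_profile()` applies the correction, which
provably leaves residuals and |r| unchanged.

**Baselines and convergence.** Gene baselines are absorbed by centering
each gene on its grand mean over all times and replicates
(`center = "mean"`). Centering on the t = 0 replicate mean
(`center = "reference"`, which anchors profiles at zero there) is
available but not the default: with four replicates it injects the
reference-time noise, sd ≈ σ/2, as a shared offset into every later time
point while pinning t = 0 at exactly zero — a spurious step response that
inflates apparent responsiveness. Grand-mean centering spreads the
centering error as a constant offset, which the shift-invariant discard
test and correlation ignore. Convergence is declared when the relative
ELBO change drops below `tol` (1e-7) or when no gauge-fixed activity mean
moves by more than `tol_activity` (1e-6) in a sweep; the second criterion
exists because ARD leaves a quasi-flat scale direction along which the
ELBO creeps long after every reported quantity has stabilized.
Initialization: weights start at the annotated sign (±1) where known,
else at small seeded random values; activities start at zero; the noise
variance starts at half the data variance. Non-convergence is reported
with a warning and a flag, never silently.

## Cross-condition comparison

A TF profile is *non-responsive* if some constant k lies within z
posterior sds of the mean at every time point. This is an exact
interval-intersection test — `max(m − z·sd) ≤ min(m + z·sd)` — needing no
search (the suite confirms agreement with a brute-force grid search over
k on 1000 random profiles). The multiplier defaults to z = 2
(an approximate 95% band on 1-sd bars); z = 1 gives literal error bars.

`compare_conditions()` then scores each TF shared by two runs: discarded
in both → no score (`both_discarded`); discarded in exactly one → the
sentinel score **2**, deliberately outside the correlation range, marking
a condition-specific response; retained in both → |Pearson r| of the two
mean profiles, in [0, 1]. The absolute value is taken because each
profile's sign is a gauge: anti-correlated profiles are as concordant as
correlated ones, and flipping any profile changes nothing. Uncertainty
is not propagated into r — the score uses mean profiles only. The
reference time point is dropped from the correlation by default
(`include_t0 = FALSE`): under reference centering it is structurally near
zero in every profile and would inflate concordance; the discard test, by
contrast, always uses the full profile. The sentinel never enters score
summaries. A retained profile with exactly zero variance cannot arise by
construction (a constant profile is always discarded); if it occurs
numerically the TF is reported with an NA score and a warning.
`rank_tfs()` partitions at configurable thresholds (concordant ≥ 0.8,
discordant ≤ 0.3 by default) with lexicographic TF-id tie-breaking.

## The synthetic-data generator

The generator exists so that every stage can be tested against known
ground truth. It emulates: sparse signed networks (per-gene regulator
count truncated-Poisson with minimum 1, so every gene has a regulator);
smooth activity trajectories — saturating rises `1 − exp(−t/τ)` and
transient pulses `(t/t_p)·exp(1 − t/t_p)`, both zero at the reference
time, peaking near the requested amplitude, with random sign — assigned
to `round(frac_responsive · n_tfs)` TFs; log-linear expression with
weights of magnitude 0.5–1.5 (signs honouring the annotation) and
per-gene baselines; and raw two-channel intensities with
A ~ Uniform(6, 14), channels floored at 1, and a dye-attached
intensity-dependent bias `d(A) = amplitude · exp(−(A − 6)/1.5)` added to
the raw Cy5/Cy3 log-ratio (low-intensity inflation, the classic
"banana"). The bias being dye-attached means dye-swap pairs see it with
opposite orientation — as real Cy-dye nonlinearity does — so pooled
decile means cancel across a swap pair and bias checks are evaluated per
array. `debias_two_color()` inverts the construction exactly when the
amplitude is known, which pins down the bookkeeping to machine precision.

What it does **not** emulate: spot-level image artefacts, background,
print-tip structure, missing features, gene-specific noise variances,
cross-hybridization, or any nonlinearity between TF activity and log
expression. Passing tests therefore demonstrate correctness of the
computations and calibration under the model's own assumptions, not
performance on real arrays.

Every stochastic operation takes an explicit seed; `simulate_dataset()`
derives stage seeds from a run seed by fixed offsets, so end-to-end
output is bit-reproducible.

## Problem sizes used by the packaged checks

Recovery and null-filtering checks run at 10 TFs × 200 genes (6 times,
4 replicates, noise sd 0.2, amplitude 2) — comfortably informative for
the model yet quick to fit; normalization checks use 4000-feature quiet
arrays as above; the DE false-positive check uses 6000 null tests
(5 × 200 genes × 6 times) at noise sd 0.25. The oracle equivalences use
deliberately tiny instances (5 genes, 2 TFs) where brute force is exact.

## Known limitations

* Scores carry no significance measure: |r| between two 5-point profiles
  is noisy, and the package reports it raw, as the method prescribes.
* The discard test treats the per-time bars as independent intervals; it
  ignores posterior correlation across time points.
* Mean-field posteriors remain approximate even with the plug-in bar
  calibration; about 4% of pure-noise TFs still survive the discard test
  at z = 2 in the packaged fixtures (the filter's empirical specificity
  is ~96%, not 100%).
* Per-array LOWESS with strongly responsive, compact transcriptomes (few
  hundred features, many regulated) will absorb real signal into the
  trend; the replicate t-tests and the inference stage are downstream of
  whatever the normalization leaves.
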