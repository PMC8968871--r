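---
title: "Models and design choices in isomerMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in isomerMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomerMS)
```

This vignette is the package's own account of the statistics it
implements: the spectral model behind the synthetic generator, the
selection/normalisation conventions, the three classifier families and
their conclusive/inconclusive decision machinery, the numerical
conventions at the edges, and the places where a genuine design choice
had to be made. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The data model

One *analysis* is one deposition of a compound measured at three
Orifice-1 voltages (30/60/90 V); raising the voltage induces in-source
collision-induced dissociation, so the three channels carry
complementary fragment-ratio information. Centroided peaks are
accumulated into fixed 0.025 Da bins named for their upper limit
(left-open, right-closed: `binPeak(109.031)` is 109.050, and 109.050
itself belongs to the 109.050 bin). Each (bin, voltage) pair is one
variable; the central object is a `BinnedSpectra`
(a `SummarizedExperiment`) of variables × samples with the study
metadata — isomer, week, QuickStrip card, replicate, deposition
volume, batch — as column data.

Conventions at the edges, chosen where the procedure itself is silent:

* several centroids in one bin are **summed** (ion current is
  additive); a `"max"` mode exists for sensitivity analysis;
* background subtraction operates on *binned* representations (blank
  and sample centroid m/z never match exactly) and clamps at zero —
  a blank larger than the sample means "nothing above background",
  not negative ion current;
* the centroid abundance floor (default 120 counts) is **inclusive**:
  the floor is the minimum reportable value.

## 2. The synthetic generator

No spectra are distributed with the reference design, so the generator
is a first-class, tested module that emulates the *variance structure*
the analysis assumes, not the chemistry. For fragment $f$ of sample
$s$:

$$\log A_{sf} = \mu_f + e\,\beta_{c(s)f} + W_{w(s)} + U_{w(s)f}
  + \log v_{d(s)} + \varepsilon_{sf}$$

with $\mu_f$ the reference-class log mean, $\beta$ multiplicative
class effects scaled by a global `class_effect_size` $e$, $W_w$ a
week-level intensity drift shared by all fragments (SD 0.25),
$U_{wf}$ an idiosyncratic per-(fragment, week) drift (SD 0.35),
$v_d$ a deposition-volume factor (1 / 1.8 / 2.6 for 3 / 6 / 10 µL —
sub-proportional, reflecting ionisation saturation), and
$\varepsilon \sim N(0, 0.25^2)$ per-peak noise. All components are
lognormal-multiplicative because ambient-ionisation intensities are
positive and right-skewed. Observed m/z adds a uniform ±0.005 Da
jitter — one fifth of the bin width, so a fragment maps to a stable
bin; catalog m/z values are placed mid-bin, and the jitter bound is
configurable for deliberate bin-edge-splitting experiments.

The default catalog (16 fragments) encodes the qualitative findings
the analysis is meant to recover: an abundant molecular-ion region at
30 V with **zero** class effect (a negative control for ANOVA and
importance screening), strong fragment-ratio effects at 60/90 V, one
**low-abundance diagnostic fragment near the selection threshold**
(class information hidden in minor bins), two trace fragments below
the 1 % selection threshold, and one fragment at the centroid
abundance floor. Effect sizes were fixed once so that the reference
conditions reproduce the headline qualitative behaviours — random
forest out-of-bag error below 5 %, the Welch counting classifier an
order of magnitude worse, LDA in between — and are exposed through
`spectrumModel()` rather than hidden. The week drift makes
accumulating weekly means stabilise after the first few sessions, and
the *shared* component induces the strong positive between-variable
correlations that motivate classifiers tolerant of collinearity.

The external validation batch reuses the catalog with a global
intensity scale (×10: a more concentrated solution), amplified
card-level drift (each of its 11 cards is its own session), and its
own volume pattern (three 10 µL cards, eight 3 µL) — 99 analyses, 33
triplicates. Per-voltage normalisation cancels the global scale
exactly; the drift does transfer and is what makes the external batch
a genuine robustness test.

What the generator does **not** model: profile-mode peak shapes
(spectra are born centroided), isotope patterns, real fragment
chemistry, carry-over, or mass-calibration error beyond the jitter.
Green tests therefore demonstrate that the *pipeline machinery* is
correct under the assumed variance structure, not that any instrument
will achieve these error rates.

## 3. Variable selection and normalisation

Selection temporarily rescales every spectrum to a base peak of 100 %
and retains a bin when at least `min_spectra` (default 50) spectra —
pooled across voltages and classes — reach the percent threshold. The
originating description of this rule is grammatically ambiguous ("any
bin for which at least 50 spectra did not meet the threshold was
discarded" would, read literally, discard nearly everything at 10 %);
both readings are implemented (`rule = "count_meeting"` /
`"count_failing"`) with the sensible one as default. Per-voltage
refinement applies the same threshold/count rule within each voltage
channel; the rule is pluggable (`refine_fun`) because the original
step-by-step refinement figure is not available to pin it more
precisely. Selection is monotone (raising the percent threshold never
adds a bin) and side-effect free: base-peak percentages exist only
inside the selection functions, and raw abundances flow onward.

Both normalisations act per sample *and per voltage*, with only
retained variables in the denominator: ion current divides by the sum
(rows then sum to 1 per voltage), vector length by the Euclidean norm
(unit norm per voltage). Both are invariant to rescaling a sample's
raw intensities — the property that lets a ×10 concentration shift
transfer. An all-zero voltage segment normalises to all-zero with a
warning rather than erroring, so degraded samples flow through to the
classifiers and surface as inconclusives, which is where a forensic
workflow wants them.

## 4. Screening

`multiwayAnova()` fits, per variable, the full factorial
isomer × week × volume model with sequential (Type I) sums of squares;
the reference design is balanced, so the ANOVA types coincide, and
unbalanced input draws a warning. p-values are reported raw — the
screen is descriptive, and correcting across collinear bins would give
a false sense of control. Single-level factors are skipped with a
warning rather than failing the whole screen.

## 5. The classifiers and the decision machinery

All three families end in the same rule (`thresholdConclusion()`):
assign the top-scoring isomer if its score reaches the acceptance
threshold, else *inconclusive*; a tied top score is always
inconclusive. Thresholds are applied after the models run, so sweeping
0.50→0.95 can only convert conclusions into inconclusives — never flip
one isomer into another — and `rateTable()` reports
success/inconclusive/error fractions (summing to 1) across the sweep.
The conclusive boundary is `score >= threshold` (with a `strict` flag)
so that a 0.50 row can be fully conclusive.

**Welch counting.** For a test triplicate against each candidate
isomer's training rows, an unequal-variance t test runs at every
variable; *indistinguishable* means failure to reject,
$p > 1 - \text{confidence}/100$, with $p$ equal to the significance
level counting as distinguishable. Zero-variance on both sides
(reachable with noiseless synthetic triplicates) resolves to $p = 1$
for equal means and $p = 0$ otherwise. The count of indistinguishable
bins is the score; ROC curves sweep an integer count threshold
(extended one step past the maximum count so the curve closes at the
origin), and the replicated analysis draws, per replicate, a
confidence level uniform in [90, 99.999] % and a normalisation scheme
uniform over the two, averaging FPR/TPR pointwise across replicates.
Per-replicate curves are also retained, since pooling before versus
after averaging is a genuine open choice. The decision-rule variant
assigns the max-count isomer only when its margin over the runner-up
exceeds `min_difference`.

**LDA.** Equal priors, common covariance, no further variable
reduction. Variables with pooled within-class variance below 1.0×10⁻⁸
are removed and logged before fitting (they are numerical poison and
carry no information); if the pooled covariance is still effectively
singular the fit *errors with advice* to use the higher
percent-threshold variable set — deliberately surfacing, rather than
silently regularising, the overfitting regime that appears when many
collinear bins meet few samples. Posteriors follow the closed-form
Gaussian rule (verified in tests to 1e-8 against a direct
density-ratio oracle); the likelihood ratio top/second posterior is
reported but flagged indicative-only, because no calibration against
casework-like data is performed here.

**Random forest.** 500 unpruned CART trees on full-size bootstrap
resamples, `mtry = max(1, floor(sqrt(p)))` — the canonical defaults,
kept deliberately untuned. Tree induction is delegated to the
randomForest package; in-bag bookkeeping is retained and out-of-bag
votes are recomputed from per-tree predictions, so the bootstrap/OOB
contract is verified rather than assumed (a test checks the tally
against the fit's own vote matrix). Permutation importance shuffles
one variable at a time, reclassifies the out-of-bag samples with plain
argmax conclusions, and reports the mean decrease in accuracy over 5
repeats by default (1 reproduces the single-pass literal procedure).
The elimination experiment alternates stratified 12-fold
cross-validation with removal of the least-important `floor(p/2)`
variables (keeping `ceiling(p/2)`: p, ⌈p/2⌉, …, 1); importance is
re-ranked after each halving by default, with the initial-ranking mode
available, since either reading is defensible. Triplicate rules
(`all_match`, `majority`, `highest`) compress a card's three vote
profiles into one conclusion; `all_match` conclusive calls are
provably a subset of `majority` calls at the same threshold, and a tie
anywhere yields inconclusive.

## 6. Validation harnesses

Leave-one-card-out treats one QuickStrip card's nine analyses as the
test unit (the card is the natural unit of acquisition nuisance);
same-day folds restrict training to the sibling cards of the same
session, with single-card days skipped and warned; the 80/20 split is
stratified by class with total test size `round(0.2 N)` distributed as
evenly as possible (288 analyses give a 58-sample test set, matching
the reference denominators). "Day" equals "week" in the default
design, since each weekly session was a single acquisition day. All
harnesses are seeded, and fold tests assert the absence of
train/test leakage by id intersection.

## 7. Numerical conventions and problem sizes

Master seeds derive per-replicate/per-permutation substreams by a
fixed counter formula, recorded in outputs; every RNG use is wrapped
so the caller's RNG state is untouched. CSV writers print 17
significant digits, making write→read round trips value-exact.
The test suite runs the full 288-sample design with 500-tree forests
for the study-condition checks (5 seeds), 300-tree forests for the
elimination curves (3 seeds), and reduced designs (2 weeks × 4 cards)
for Monte-Carlo property loops — sizes chosen to keep the whole suite
around a minute on a laptop core while leaving the Monte-Carlo bands
comfortably wider than the observed seed-to-seed spread.

## 8. Known limitations

* The generator's effect sizes are a modelling choice, not a fit to
  instrument data; absolute error rates on real spectra are outside
  what this package can claim.
* Likelihood ratios are uncalibrated by design.
* The per-voltage refinement criterion and the exact historical
  multiple-centroid aggregation are unrecoverable from the available
  description; both are implemented as documented, pluggable choices.
* No mixtures or cutting agents; single-compound depositions only.
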