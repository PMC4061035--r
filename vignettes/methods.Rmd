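---
title: "Models and methods behind ovimetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ovimetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ovimetab re-implements, as a tested pipeline, the plasma ^1^H NMR
metabolomics and muscle-fibre morphometry analysis used to characterise the
ovine Callipyge phenotype: lambs carrying the mutation paternally
(N^mat^C^pat^, "NC") against wild-type (N^mat^N^pat^, "NN") littermates,
sampled at 8 and 12 weeks of age. Because the original spectra are not
required to develop or test the statistics, the package is built around a
seeded synthetic-cohort generator whose defaults encode the study design;
every downstream stage is exercised against planted ground truth.

## The synthetic cohort

**Design.** `build_design()` produces the study roster: 17 NC lambs
(8 male, 9 female) and 22 NN lambs (12 male, 10 female), two sampling
occasions each, two NC samples at 8 weeks unavailable, and three samples
flagged as outliers — both samples of one "diseased" NC animal (no
circulating glucose, tenfold lactate) and one NN 12-week sample carrying a
high level of an unknown compound. That yields 76 present samples and, once
the outliers are excluded, the 73 analysed samples (36 at 8 weeks, 37 at
12 weeks).

**Concentrations.** `sample_concentrations()` draws one relative
concentration (dimensionless, percent-of-total-intensity scale) per sample
and metabolite. The expected value in a cell is
`baseline × age_fc^[12wk] × geno12_fc^[NC at 12wk] × gender_fc^[F]`.
Baselines, SDs and fold changes come from the published group summaries
(`age_reference()`, `genotype_reference()`): for age-affected metabolites
the baseline is the 8-week mean and the age fold change the exact ratio of
the printed means; metabolites only reported in the genotype comparison
take the wild-type 12-week mean as baseline; the genotype effect is planted
at 12 weeks only, and gender carries no effect anywhere — both choices
mirror the study's findings (genotype effects visible only at the later
age, no gender effect). Noise is truncated-normal with the SD scaled
proportionally to the planted mean (constant coefficient of variation);
this is the realistic model for plasma metabolite variability — the
published per-group SDs track their means — and redrawing non-positive
values respects the positivity of concentrations. A lognormal alternative
with exactly matched mean and CV is available for robustness work. The
generator emits a ground-truth manifest (which metabolites carry which
fold changes) that the recovery tests consume, and
`default_effects(null_effects = TRUE)` produces a global-null cohort for
type-I-error work.

**Spectra.** `render_spectrum()` sums unit-area Lorentzian multiplets: each
resonance in the packaged peak library carries a center shift, relative
line offsets and heights, a FWHM in ppm, and a proton-count weight, so the
noise-free integral of a metabolite's signal equals concentration × proton
count. The default axis is 9.5–0.0 ppm in 32,768 points, stored descending;
all operations accept either direction. Lorentzian tails are truncated at
±100 linewidths (≈0.3% of the mass), keeping rendering cost proportional to
the signal-bearing region. A smooth baseline arc, optional broad
macromolecule humps (the NOESY-like condition; the default off-state plays
the role of the CPMG spin-echo filter, whose only downstream consequence is
baseline breadth), and Gaussian noise complete the trace.
`inject_artifacts()` then adds EDTA peaks strictly confined to the five
EDTA exclusion windows (with a 0.002 ppm interior margin so that trapezoid
integration of adjacent buckets picks up none of the artifact), a
residual-water hump inside 5.20–4.68 ppm, a urea signal inside
6.00–5.60 ppm, the outlier transformations, and a per-sample global ppm
miscalibration (SD 0.005 ppm) that the referencing stage must undo.

One rendering detail matters for referencing: the glucose anomeric doublet
is stored with its taller line exactly at 5.233 ppm (a slightly asymmetric
"roof", heights 0.6/0.4). Referencing aligns the *maximum* within the
search window, and with a symmetric doublet that maximum alternates
noise-dependently between the two lines, leaving a ±J/2 residual
miscalibration that smears bucket contents.

**What the generator does not emulate.** No FID-domain effects (phasing,
apodization, field strength), no J-coupling quantum mechanics, no peak
position dependence on pH or ionic strength, no inter-metabolite
correlation beyond the normalization constraint, and a panel of ~22
metabolites instead of the hundreds present in plasma. Consequently the
total spectral intensity is dominated by the modelled panel, which makes
total-intensity normalization slightly conservative: a net planted decrease
in one group inflates that group's remaining buckets by a few percent,
attenuating decreasing fold changes. Passing recovery tests therefore show
that the chain detects effects of the published size under clean,
favourable conditions; they do not certify performance on real spectra with
overlapping resonances and baseline distortions.

## Spectral preprocessing

`reference_spectrum()` shifts the axis so the window maximum sits at
5.233 ppm (window 5.205–5.285 ppm, above the water cutoff so a glucose-free
sample can never lock onto the water hump; a peak must exceed the noise
floor estimated from the signal-free 9.2–9.5 ppm region, otherwise the
spectrum is returned unshifted with a warning — exactly what should happen
for the "diseased" outliers).

`bucket_spectrum()` integrates fixed 0.01 ppm buckets over 9.0–0.5 ppm by
the trapezoid rule on the piecewise-linear spectrum, with interpolation at
bucket bounds (a flat spectrum integrates to exactly height × width, and
contiguous buckets partition the total integral). Buckets are half-open
`[low, low+width)` intervals anchored at 0.5 ppm; a bucket is dropped when
it overlaps an exclusion window with positive length. Under this convention
the counts are exact: 850 buckets before exclusion, 737 after removing the
urea (6.00–5.60), water (5.20–4.68) and five EDTA windows. Exclusion
happens before normalization (the processing-order ambiguity in bucketing
software is resolved this way and recorded here).

`normalize_total()` divides each row by its own sum and multiplies by 100,
so bucket values sit on the percent-of-total-intensity scale on which the
published relative concentrations (glucose ≈ 0.73, i.e. ≈0.73% of total
intensity) are printed. `pareto_scale()` centers each bucket and divides by
the square root of its SD (sample SD, n−1), storing means and SDs for
back-scaling; zero-variance columns become zero.

## Latent-variable models and validation

All decompositions are NIPALS-based and authored in the package. PCA is the
power iteration with deflation (it matches the singular value decomposition
up to sign; the sign convention makes the largest-magnitude loading
positive). PLS-DA is NIPALS PLS2 with unit-norm X-weights against 0/1 class
columns (wild-type 0 / Callipyge 1; 8 weeks 0 / 12 weeks 1). OPLS-DA is the
Trygg–Wold algorithm for a single response, with the predictive weight
recomputed from the deflated matrix after each orthogonal extraction — a
detail that makes every orthogonal score exactly uncorrelated with the
response. Models are labelled `1+n_orth+0` (predictive + X-orthogonal +
Y-orthogonal); Y-orthogonal components are out of scope since all study
models are "+0". The number of orthogonal components is taken from
configuration (3 for the age model, 1 for the genotype and gender models,
as reported for the study's fits); `fit_pls_da()` optimizes its component
count by cross-validation when not given.

**Outlier screen.** Hotelling's T² over the PCA score space with the
F-based 95% bound `A(N²−1)/(N(N−A)) · F(0.95; A, N−A)` (the ellipse
convention of standard chemometrics software; the χ² alternative is less
accurate at these sample sizes). The screen uses 5 components: the diseased
samples dominate the leading components, but a single-bucket alien
metabolite only emerges around the fourth component — consistent with the
study's own inspection of higher-order components. At a 95% bound roughly
5% of genuine samples can exceed the threshold in any given cohort; the
pipeline applies the rule as stated rather than tightening it.

**Cross-validation.** 7-fold (the default of the chemometrics software the
field uses; the fold count is not stated in the study), with deterministic
class-stratified venetian-blinds assignment: samples sorted by class then
id and dealt round-robin. `Q² = 1 − PRESS/SS` with PRESS summed over
held-out predictions and SS the total response sum of squares about the
mean. Folds refit the model from the training rows only (centering included;
the global Pareto scaling is fixed, as scaling is in the emulated software).

**Permutation testing.** The response rows are permuted (identity excluded),
the model refitted and cross-validated per permutation, and the empirical
p-value uses the add-one estimator `(#{Q²_perm ≥ Q²_orig}+1)/(n_perm+1)`,
which cannot return zero. Intercepts of the R²Y and Q² regression lines
against the permutation correlation (through the original model at
correlation 1) are reported for validation plots. The default is 200
permutations, as in the study.

**CV-ANOVA.** The pinned formulation is
`F = [(SS − PRESS)/df₁] / [PRESS/df₂]` with `df₁ = 2A+1` (A = total fitted
components, predictive plus orthogonal), `df₂ = (N−1) − df₁`, and P from
`F(df₁, df₂)`; `PRESS ≥ SS` yields P = 1. This diagnostic is conservative
by construction — on null data the cross-validated PRESS almost always
exceeds SS, so the null rejection rate sits far below the nominal level.
The package reports it as the model-level sanity check it is, alongside the
permutation test, which is the calibrated significance statement.

**VIP and back-scaled loadings.**
`VIP_j = sqrt(p · Σ_a SSY_a w_ja² / Σ_a SSY_a)` with unit-norm weights, so
the mean squared VIP is exactly 1 and VIP > 1 marks above-average influence.
For OPLS-DA the VIP is computed on the predictive component — the part of
the model carrying class information (including orthogonal weights would
reward variables for class-unrelated variance). Loadings are back-scaled by
each bucket's stored SD so the profile resembles a spectrum, with |weight|
as the colour value, ordered by descending shift.

## The univariate stage

Buckets with VIP > 1 are candidates; where several map to one metabolite
the maximal-VIP bucket represents it, and unmapped candidate buckets are
retained as unknowns (U1, U2, …). The bucket→metabolite map assigns every
bucket overlapping a resonance line's core (±1 FWHM), so a multiplet's
"duplicate" buckets collapse onto their metabolite. Per candidate, the
normality-gated test: Shapiro–Wilk per group, and only if *both* groups
pass at α = 0.05 is the pooled-variance Student's t test used, otherwise
the two-sided Mann–Whitney U test (exact for small tie-free samples). The
per-group gate is the stricter reading of the published procedure and is
the one implemented; Welch's t is available by option but pooled variance
is the default, matching the test the study names. Benjamini–Hochberg
correction is applied within each comparison's candidate list (mirroring
per-table adjustment), and the joint significance rule is VIP > 1 ∧ raw
P < 0.05, with the BH-adjusted variant reported alongside. Fold changes are
ratios of group means, printed half-up to 2 decimals with full precision
retained. Tests run on the normalized (unscaled) bucket intensities —
whether the study tested buckets or re-integrated signals is unstated;
buckets are assumed.

## Pathway enrichment

Over-representation is the hypergeometric upper tail `P(X ≥ k)` for k hits
among n matched metabolites in a pathway of size K within a universe of N
compounds; topology impact is the fraction of the pathway's total
out-degree centrality held by hit compounds (normalized by the graph total
so impact lies in [0,1]); the fold-enrichment score is −ln P and the
reporting rule raw P < 0.05 with no cross-pathway correction (BH available
by flag, off by default — matching the emulated tool's reporting). The
universe is the whole compound collection of the selected library, not the
measured panel (again the emulated tool's convention; a measured-panel
background is available by flag). Two packaged toy libraries stand in for
the curated collections: `toy-hsa` with the eleven pathways of the study's
enrichment figure and `toy-bta`, its smaller counterpart lacking three of
them. Both carry a background compound pool so the universe (~90 compounds)
exceeds any single pathway by an order of magnitude, as in real libraries;
compound sets and directed reaction edges are reduced toy versions, so
enrichment p-values are structurally comparable to, but not numerically
reproductions of, the study's.

## Fibre morphometry

Per animal, the prevalence-weighted overall cross-sectional area is
`Σ percentᵢ × CSAᵢ / 100` over the five fibre types (1, 2C, 2A, 2AX, 2X).
Genotype contrasts use per-variable one-way ANOVA with
`s.e.d. = sqrt(MSE(1/n₁+1/n₂))` from the pooled error mean square and the
two-group identity F = t². The published "overall" row for the affected
muscle is not exactly the prevalence-weighted mean of its printed per-type
values, implying per-animal averaging before rounding — so
`analyze_fibre_table()` reports both variants (per-animal, and from group
means as an attribute). `simulate_fibre_tables()` draws per-animal tables
around the published group means with the per-animal SD implied by the
printed s.e.d.; percentages are truncated at zero and renormalized to 100.
One published inconsistency is worth noting: with overall CSA means
1636 vs 3227, s.e.d. 368.4 and n = 3, one-way ANOVA arithmetic gives
P ≈ 0.01, not the printed "<0.001"; the package's tests therefore assert
significance at the study's stated P < 0.05 threshold.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: all-tied univariate data returns
P = 1 with a warning; zero-variance buckets scale to zero; nonpositive row
totals, constant responses, and over-large component counts raise errors
naming the offending sample or dimension. Score/loading signs are fixed so
the largest-magnitude loading is positive. Seeds thread from a single
master seed through every stage (per-sample render seeds are derived
offsets), and identical seeds give bit-identical cohorts, tables and
reports.

The test suite runs the full study-scale pipeline (76 spectra at 32,768
points, 737 buckets, 200 permutations) once; property suites use reduced
sizes chosen for statistical sufficiency rather than fidelity — a 16,384
point axis where only bucket integrals matter (the 0.003 ppm lines remain
resolved at ≥5 points per linewidth), 200-replicate null simulations for
type-I error, 50 label-permutation refits for the null-Q² property, and
small constructed matrices wherever an algebraic identity is being checked.

## Known limitations

The generator's clean conditions flatter every stage: real plasma spectra
carry overlapping multiplets, pH-dependent shifts and imperfect baselines
that erode VIP selectivity and univariate power. Statistical power at the
published effect sizes and group sizes is moderate (per-metabolite
detection probabilities mostly 0.6–0.9), so the recovered fraction of
planted metabolites varies substantially between simulated cohorts; the
recovery checks pin a seed for that reason. CV-ANOVA is conservative, as
noted. The toy pathway libraries support algorithmic validation, not
biological interpretation. And the fibre module ingests per-animal summary
tables — image analysis and fibre classification are upstream of this
package.
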