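---
title: "Screening and response-surface methods for fermentation optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and response-surface methods for fermentation optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermdoe)
```

# The problem

Fermentation media have many candidate components — metal salts,
nitrogen sources, phenolic inducers, solvents — and enzyme yield
responds to them nonlinearly and interactively. The standard two-stage
campaign is (1) a *Plackett–Burman screen*: a saturated two-level
orthogonal design that estimates the main effect of up to N−1 factors
in N runs, used only to rank and shortlist factors; and (2) a *central
composite design* around the promising region, supporting a full
second-order model whose fitted surface is then optimized. `fermdoe`
implements both stages, the surrounding enzyme-activity arithmetic, and
a bundled worked study of laccase production by a *Bacillus* strain.

# Coding of factors

Every factor carries a center and a half-range step in actual units;
coded levels are `z = (x − center)/step`, so the factorial cube is
`±1`. All models are fitted in coded units — this makes the columns of
a CCD orthogonal or near-orthogonal and the coefficients directly
comparable — and predictions are mapped back through the stored coding.
`uncode_value()` is the exact inverse of `code_value()`, and the
round-trip is machine-precision exact (a property the test suite
checks).

# Plackett–Burman screening

Designs are built from the classical cyclic generator rows (orders 4,
8, 12, 16, 20, 24): the generator row, its cyclic shifts, and a final
all-low run. The generating rows are reproduced in the source; any
orthogonal PB design of the same order is statistically equivalent, so
no attempt is made to match the run order of any particular software's
output. Balance and mutual orthogonality are verified exhaustively in
the tests.

The effect estimator divides the high-minus-low response sum by the
total run count N. The classical contrast mean divides by N/2; both
are offered (`divisor` argument) because they differ only by the
constant factor 2 — ranking and signs, which are all a screen is used
for, are identical. The N-divisor form is the default to match the
reporting convention of the bundled study.

**Significance.** The bundled study's screen shows a significant/
nonsignificant split without stating its rule, and its response data
are unpublished, so no numerical reproduction of that figure is
claimed anywhere. For user data the package adopts Lenth's method, the
standard for unreplicated two-level designs: `s0 = 1.5 · median|E|`,
the pseudo standard error is `1.5 · median` of the effects with
`|E| < 2.5 s0`, and the margin of error is the two-sided t quantile at
`d/3` degrees of freedom (d = number of effects). A plain
absolute-threshold rule is available as an alternative. One edge case
is handled explicitly: when a majority of effects are exactly zero
(noiseless synthetic data) the restricted median degenerates, and the
pseudo-SE is taken as zero so that every nonzero effect is flagged.

# The central composite design

For k factors: `2^k` factorial points, `2k` axial points at `±α`, and
`n_center` replicated center points, emitted in that fixed block order
(a seeded shuffle is available, with the seed recorded on the output).
The default axial distance is the rotatable `α = (2^k)^(1/4)` ≈ 1.6818
for k = 3, which equalizes prediction variance on spheres. The bundled
study never states α or the factorial levels in its methods; both are
inferred from its design table — the rotatable α reproduces all six
printed axial actual levels to two decimals (e.g. MnSO₄
650 + 350·2^(3/4) = 1238.63 µM), which is treated as derived, not
quoted, information. Display rounding is two decimals to match that
table; internal computation keeps full precision.

# The quadratic model and its ANOVA

The full second-order model (10 coefficients for k = 3) is fitted by
least squares via QR decomposition; an independent `stats::lm()` fit on
the expanded formula serves as a cross-check oracle in the tests (both
agree to 1e−8 on all fixtures). Rank deficiency raises an error naming
the dependent columns rather than silently dropping terms.

The ANOVA reports partial (Type-III) per-term sums of squares, each on
1 df, computed as `β̂_j² / [(X'X)^{-1}]_jj`. On the orthogonally coded
CCD the linear and interaction columns are mutually orthogonal, so for
those terms partial and sequential SS coincide; the pure-quadratic
columns are correlated with the intercept and each other, so the
per-term SS do **not** sum to the model SS — this is expected and left
as is. The residual is split into *pure error* — within-replicate
variation `Σ_g Σ (y − ȳ_g)²` over groups of identical coded points
(identity after rounding coded values to 6 decimals) — and *lack of
fit*, the remainder. F ratios use the residual mean square for model
terms and the pure-error mean square for lack of fit. Designs without
replicates get no lack-of-fit split, flagged explicitly. p-values
follow the reporting convention of the field's software: four decimals
with `<0.0001` below that, and "Significant" labels at p < 0.05.

Diagnostics: `R²`, `adjusted R² = 1 − (1−R²)(n−1)/(n−p)`, PRESS from
the closed-form leave-one-out residuals `e_i/(1−h_ii)`, predicted
`R² = 1 − PRESS/SS_total`, and `CV% = 100·√MS_res / ȳ`.

# Optimization

The stationary point solves `2Qx = −b` for the canonical form
`Y = β0 + b'x + x'Qx` and is classified by Q's eigenvalues (maximum,
minimum, saddle). Because a stationary point may lie outside the
region the design actually probed, `optimize_in_region()` maximizes
within the axial box `[−α, α]^k` (the default region — it is what the
design covers; a spherical region of radius α is the alternative): the
interior stationary maximum is returned directly when feasible,
otherwise deterministic multi-start L-BFGS-B ascent from a fixed
3-level lattice of starts (box) or an exact trust-region solve by
bisection on the Lagrange multiplier (sphere). Tests compare both
against a brute-force dense grid search.

A noteworthy derived fact about the bundled study: the published fitted
equation's quadratic form has eigenvalues (+1.7, −2962, −3944) — its
small ethanol-squared coefficient and large interactions tip the
smallest curvature slightly positive, so that equation's stationary
point is formally a (near-singular) saddle outside the design region,
and its constrained maximum sits on the region boundary. The refit of
the same design table yields a proper interior maximum at about coded
(0.03, 0.00, 0.85). Both models are therefore reported side by side
and neither is "corrected" into the other.

# The bundled study and its inconsistencies

Three tables are packaged as verbatim transcriptions with checksums:
the stepwise (one-variable-at-a-time) optimization trail, the 20-run
CCD with predicted and measured activities, and the pulp biobleaching
outcomes. Several cells are internally inconsistent, and the package's
policy is to analyse the tables exactly as printed while attaching
machine-readable notes:

* the fitted equation's intercept (16,696.86) disagrees with the
  table's center-point prediction (18,174.66), though all linear and
  interaction coefficients of a fresh refit match the published ones
  to a few parts in 10⁴; which is the transcription error is
  undecidable, so both models are reported;
* two design runs have residual entries inconsistent with their own
  predicted/actual columns (`reproduce_study(apply_errata = TRUE)`
  substitutes the internally consistent values as a sensitivity
  variant — R² moves from 0.9981 to 0.9983, so nothing hinges on it);
* the published pure-error SS is two orders larger than the value
  computed from the printed center replicates (≈1.51×10⁴ on 5 df);
  the package reports the recomputed split and makes no claim to
  reproduce the published lack-of-fit magnitudes;
* one biobleaching percent cell (7.69 %) is inconsistent with its own
  control row (25.00 → 26.00 is 4.00 %); the computed value is
  reported and the printed one noted;
* the text swaps the adjusted and predicted R² labels relative to the
  table; the package computes both and arbitrates nothing.

# Synthetic data and what passing tests show

The generators emulate the statistical structure the two model stages
assume: additive two-level main effects, a smooth second-order surface,
and a linear absorbance ramp, each plus homoscedastic Gaussian noise.
The default noise SD of 50 nkat/mL matches the replicate-SD scale of
the bundled study's activity measurements (25–51 nkat/mL across a
3,000–18,400 range), which justifies a constant-σ model. Each generator
draws from its own seed substream, so adding one never perturbs
fixtures made by another; regeneration with identical parameters and
seed is bit-identical. The screening generator divides planted effects
by two so the classical (half-N) estimator is unbiased for the planted
value.

Zero-noise analysis∘generation recovers planted truth exactly for all
three generators — the module's core contract. Calibration is checked
by simulation at desk scale: 100 seeded refits verify unbiased
coefficient recovery at σ = 50, and 200 seeded fits verify that the
lack-of-fit p-value is approximately uniform (Kolmogorov distance
< 0.15) when the generating model is correct. These sizes keep the full
suite under a minute while leaving Monte-Carlo error well inside the
asserted bounds. What passing does *not* show: robustness to
heteroscedastic or non-Gaussian noise, model misspecification beyond
lack-of-fit power, or anything about wet-lab measurement error — the
generators are statistical emulators, not instrument simulators.

# Assay arithmetic

Activity from absorbance kinetics follows the Beer–Lambert chain:
`ΔC = ΔA/(ε·l)` mol/L, scaled by reaction volume to nmol, by time to
nmol/s (nanokatal), and by dilution per mL of enzyme aliquot. The
bundled study states ε = 14,800 M⁻¹ cm⁻¹ at 470 nm and a 5-min assay
but omits the reaction volume, aliquot and path length; the defaults
(1 mL, 0.1 mL, 1 cm) are ordinary cuvette-assay values and are
configurable parameters — no reported result depends on them. Unit
conversion is definitional: 1 U = 1 µmol/min = 16.667 nkat. Fold
changes and percent metrics are reported at two decimals with
integer-rounded variants, matching the field's reporting style.

# Known limitations

Designs are limited to PB screens and rotatable/face/numeric-α CCDs
(no fractional factorials, Box–Behnken, D-optimal, or blocking).
Optimization is single-response (no desirability functions), and no
Box–Cox response transformation is offered. The screening stage of the
bundled study is demonstrable only on synthetic data, since its
response vector was never published.
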