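---
title: "Methods: vergence-based target engineering and machine-learned IOL power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vergence-based target engineering and machine-learned IOL power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iolml)
```

## The problem

After cataract surgery the eye's refraction is determined by the optical
power of the implanted intraocular lens (IOL) and by where that lens ends
up sitting — the effective lens position (ELP), which cannot be measured
preoperatively. Classical formulas such as SRK/T predict the ELP from
keratometry (K) and axial length (AL) and then solve thin-lens vergence
equations for the lens power that will leave the eye emmetropic. Their
accuracy plateaus around 60–80% of eyes within ±0.50 D of target.

This package implements an alternative: learn the lens power directly
from surgical outcomes. Every operated eye with a known implanted power
and a measured postoperative refraction tells us what power *should* have
been implanted; a regression model trained on many such eyes encodes the
ELP behaviour of a specific lens model implicitly, without an A-constant.

## Target engineering through the reversed vergence chain

The centerpiece is a thin-lens pseudophakic model of the operated eye.
Propagating the vergence required for a retinal focus backwards through
the IOL and cornea to the spectacle plane (vertex distance $V$, in mm):

$$V_3 = \frac{1336}{AL - ELP}, \qquad
\frac{1}{V_1} = \frac{ELP}{1336} + \frac{1}{V_3 - IOL}, \qquad
Rx = \frac{1}{V/1000 - 1/(K - V_1)}$$

with $K$, $IOL$, $V_1$, $V_3$ in diopters and $AL$, $ELP$ in mm; 1336 is
the reduced index of the intraocular media times 1000. Positive $Rx$ is a
hyperopic residual. We implement the spectacle transfer in the
algebraically equivalent form $Rx = e/(Ve/1000 - 1)$ with $e = K - V_1$,
which is continuous through the zero-residual point (the printed form has
a removable singularity there) and singular only where the eye's far
point falls on the spectacle plane.

From this chain three per-eye quantities follow:

* `rx_05iol` — the refraction change produced by a 0.5 D change of lens
  power, $Rx(IOL) - Rx(IOL + 0.5)$. For an average eye a 1.0 D lens
  change moves the spectacle refraction by ≈ 0.69 D, reproducing the
  clinical ≈ 0.7 rule of thumb.
* `iol_ideal` — the power that would have zeroed the residual:
  $IOL_{ideal} = IOL_{impl} + (Rx_{post}/Rx_{05IOL}) \cdot 0.5$. This is
  the training target.
* `rx_predicted` — the residual a *predicted* power would have produced:
  $((IOL_{impl} - IOL_{pred})/0.5)\cdot Rx_{05IOL} + Rx_{post}$. This is
  the evaluation back-calculation; substituting the ideal power cancels
  to zero identically, which the tests verify to $10^{-9}$ D.

The ELP entering the chain is the SRK/T prediction: corneal radius
$r = 337.5/K$, the corrected axial length (quadratic shortening beyond
24.2 mm), computed corneal width and height, and the A-constant offset
$0.62467A - 68.747 - 3.336$. The corneal-height square root clamps its
argument at zero in the steep-cornea degeneracy, as common SRK/T
implementations do. The vergence chain uses AL as printed while SRK/T's
own power formula uses the retinal-thickness-corrected optical length;
the resulting ≈ 0.03 D offset at the emmetropic power is documented
behaviour, not error.

Two genuinely open choices we fixed: the vertex distance is not part of
the study's stated parameters — we default to 12 mm, the standard
phoropter convention, configurable; and a single A-constant (119.1, the
study lens's optimized value) is used for all eyes in target derivation.

## Cohort cleaning

`prepare_cohort()` applies filters in a fixed documented order —
completeness, biometry/demographic ranges, follow-up interval, acuity
consistency, postoperative CDVA ≤ 0.3 logMAR, astigmatism ≤ 3.0 D,
free-text keyword exclusion, fellow-eye AL concordance (> 1 mm difference
excludes both eyes), and a single-pass ±3σ outlier rule over the five
predictors plus the postoperative refraction. The first failing rule is
the recorded reason, so exclusion counts are auditable and the filter is
idempotent. Boundary conventions: a case exactly at mean ± 3σ is
retained (strict inequality); uncorrected acuity equal to corrected is
retained (equality is clinically common; a strict mode is available).
The σ-rule runs once, after the fellow-eye filter — the original order is
not stated, so ours is fixed and configurable.

The 70/30 selection/verification split is uniform at case level.
Normalization is min–max to $[-1, 1]$ fitted on the selection set only,
applied to predictors *and* target (the reported training MSEs ≈ 0.003
are only meaningful on that scale); verification cases outside any
selection-set range are removed rather than extrapolated, with
boundaries kept (closed-interval convention).

Both eyes of a patient are retained by default; with under 10% of
verification data coming from fellow eyes the intra-class correlation is
bounded near 0.1, low enough for conventional paired tests.

## The two models

**SVM-RM** is ε-insensitive support vector regression with a polynomial
kernel $(s\langle x, x'\rangle + 1)^2$, ε = 0.0282 and box constraint
C = 0.0049 (the study's optimum on normalized data; the kernel scale was
not reported — we default $s = 1$). Fitting goes through libsvm
(`e1071`), which solves the same convex objective as sequential minimal
optimization; 30% of the training table is held out for validation MSE.
The degenerate no-support-vector case (every residual inside the tube)
returns the constant bias, the flattest admissible function. The
original Bayesian hyperparameter search is not reproduced — only its
reported optimum is used as the default.

**MLNN-EM** is a median ensemble of ten networks, each
5 inputs → 5 tanh units → 1 linear output (36 parameters), trained by
Levenberg–Marquardt on sum-of-squares loss: one accepted update per
epoch, damping λ divided by 10 on acceptance and multiplied by 10 on
rejection. Initialization is Nguyen–Widrow (hidden rows scaled to
magnitude $0.7 H^{1/n}$, biases spread over $[-\beta, \beta]$ with
alternating sign). Each member draws its own 70:15:15
train/validation/test partition and its own initialization from named
seed substreams — the study wording supports independent per-member
splits, and we chose that reading. Early stopping: training halts after
20 epochs without strict validation improvement ("failed to improve or
remained the same" is read as *no strict decrease*), and the weights at
the validation minimum are returned; the contract is tested against an
adversarially worsening validation curve. `max_epochs` defaults to 1000,
far above the observed stopping epochs (≤ 78 in our runs). When no
damping level yields descent, a vanished gradient is treated as
convergence; otherwise the best-so-far weights are returned with a
warning. A hidden-layer width search (`topology_search`) scores each
candidate by median + 1 SD of the member test MSEs, ties toward fewer
neurons; the default width of 5 is the study's selected topology, so the
search is provided as a utility rather than run in the default pipeline.

## Evaluation

Per eye and method, the signed prediction error is the (back-calculated)
residual refraction, positive = hyperopic. Summaries per axial-length
subgroup (SHORT ≤ 22 mm < MEDIUM < 24 mm ≤ LONG, plus ALL): ME, MAE,
MedAE, sample SD, extremes, and percentages within ±0.25/0.50/0.75/1.00 D
using closed intervals $|e| \le t$.

The paired battery: Wilcoxon signed-rank on absolute errors (zeros
dropped, average ranks; exact null distribution by convolution over
doubled ranks for n ≤ 25 — equivalent to enumerating all $2^n$ sign
assignments and valid under ties — and a tie-corrected normal
approximation without continuity correction above); McNemar with Yates'
correction on within-threshold indicators, the numerator
$(|b-c|-1)^2$ clamped at zero when $|b-c| < 1$ (implementations differ;
ours is documented); and the exact binomial sign test. Bonferroni uses
the per-subgroup table as the family, and the family size m is reported
next to every adjusted p-value since the original family size is not
stated.

An evaluation-only import (`read_refraction_csv`) accepts a deposited
per-eye refraction table (subgroup label plus one refraction column per
method) so outcome summaries and tests can be recomputed without
biometry or trained models.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws biometry from truncated normals matching the
study population's selection-set marginals (age 56.89 ± 7.25 y, K
43.27 ± 1.40 D, ACD 3.10 ± 0.32 mm, AL 23.03 ± 0.92 mm, each truncated
at the observed extremes) and preoperative refraction from a
right-skewed two-component normal mixture (0.85·N(1.60, 1.20²) +
0.15·N(3.30, 2.00²), truncated to [−3.88, 6.63]) whose mean ≈ 1.85 and
SD ≈ 1.48 match the observed non-normal marginal. AL and Rx_pre are
coupled through a Gaussian copula at ρ = −0.50 — the study reports no
covariances, so this encodes only the qualitative myopia–axial-length
association; all other cross-correlations default to zero. About 32% of
patients contribute both eyes, sharing a patient-level latent factor
(copula correlation 0.90) so fellow-eye AL differences are mostly under
1 mm.

Outcomes are generated forward through the same vergence model the
pipeline inverts: the true ELP is the SRK/T prediction at a *true*
A-constant (118.62) plus N(0, 0.25 mm) per-eye scatter; the surgeon
plans emmetropia at the *planning* constant 119.1 by inverting the
vergence model at the planning ELP, rounded to 0.5 D steps (ties toward
the lower power) and clamped to [6, 35] D. The 0.48-unit constant gap
was solved analytically on the mean eye so the simulated clinical
baseline lands at ME ≈ −0.46 D — the study's observed bias, attributed
there to a non-optimized lens constant. Measured refraction adds
N(0, 0.15 D) noise (objective-refractometer repeatability scale) and
0.125 D quantization (consistent with printed outcome values such as
−1.875). The ELP scatter of 0.25 mm is a calibration that places the
baseline near 58% within ±0.50 D; it is documented as such, not claimed
as a measured quantity. With these settings the simulated baseline shows
ME ≈ −0.45, SD ≈ 0.45, ≈ 60% within ±0.50 D.

The generator deliberately does **not** model: device-specific
keratometry/biometry error structure, toric outcomes, per-surgeon
effects, a phakic optical model for Rx_pre (it is sampled, since its
only role is as a predictor), or any joint biometry distribution beyond
the single AL–Rx_pre coupling. Consequently, passing the end-to-end
tests shows that the pipeline *recovers a known forward model under
realistic noise and censoring* — it does not certify clinical accuracy
on real populations, where the ELP process is richer than
SRK/T-plus-Gaussian-scatter.

## Numerical conventions

* Lens rounding ties go toward the lower power (myopic-safe).
* The vergence chain raises domain errors for AL ≤ ELP and for the two
  genuine singularities; the zero-residual point is handled smoothly.
* Normalization refuses constant columns; denormalization round-trips to
  $10^{-12}$.
* All randomness flows from one master seed through named substreams
  (`derive_seed`): split, SVM holdout, per-member init and split,
  generator. Reruns are bit-for-bit identical.

## Problem sizes

The default study-scale run uses 2,194 eyes (≈ 1,500 selection /
≈ 650 verification after filtering), ten ensemble members, and completes
in a few seconds on one core; the test suite exercises reduced cohorts
(200–1,200 eyes, 3–5 members) plus one full-scale end-to-end run, and
the distributional checks use n = 10,000 draws.

## Known limitations

* The study's own trained weights and its 1,539/655 split are not
  reproducible (raw predictors were never deposited); only the split
  fraction and the methodology are honored.
* Eyes longer than 26.3 mm and shorter than 19.9 mm are outside the
  emulated population; the models refuse to extrapolate outside the
  selection-set range by design.
* The σ-filter order relative to the fellow-eye filter, the exact
  Wilcoxon variant, and the Bonferroni family size are unstated in the
  source methodology; our choices are fixed, documented above, and
  configurable where they matter.
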