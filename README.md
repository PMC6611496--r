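# iolml

Machine-learned intraocular lens (IOL) power calculation with
vergence-based target engineering, and the statistical framework to
evaluate it against a clinical baseline.

## What problem this solves

Selecting the power of the lens implanted in cataract surgery is an
inverse problem: the postoperative refraction depends on an unmeasurable
quantity, the effective lens position (ELP). Classical vergence formulas
(SRK/T and relatives) predict ELP from keratometry and axial length and
leave 60–80% of eyes within ±0.50 D of target. An alternative is to
learn the power directly from surgical outcomes: each operated eye with
known implanted power `IOL_impl` and measured postoperative spherical
equivalent `Rx_post` reveals the power that *would have* zeroed the
residual,

```
IOL_ideal = IOL_impl + (Rx_post / Rx_05IOL) * 0.5
```

where `Rx_05IOL` is the eye-specific spectacle-plane refraction change
per 0.5 D of lens power, computed from a reversed thin-lens vergence
chain (V3 = 1336/(AL − ELP); 1/V1 = ELP/1336 + 1/(V3 − IOL);
Rx = 1/(V/1000 − 1/(K − V1)), ELP from SRK/T). `IOL_ideal` is the
training target for two regressors on five routine predictors
(K, ACD, AL, age, preoperative refraction):

* **SVM-RM** — ε-insensitive support vector regression, polynomial
  kernel of order 2, ε = 0.0282, C = 0.0049 on [−1, 1]-normalized data;
* **MLNN-EM** — the median of ten 5-hidden-neuron tanh networks trained
  by Levenberg–Marquardt with Nguyen–Widrow initialization and
  validation early stopping (patience 20).

Evaluation back-calculates each model's residual refraction
(`rx_predicted`), summarizes prediction errors per axial-length subgroup
(SHORT ≤ 22 mm < MEDIUM < 24 mm ≤ LONG), and compares methods with
Wilcoxon signed-rank, McNemar with Yates' correction, the exact sign
test, and Bonferroni correction.

Because no per-eye predictor data is publicly deposited for this kind of
study, the package ships a seeded synthetic cohort generator
(`generate_cohort()`) that emulates the study population's biometry
marginals and produces outcomes through the same forward vergence model,
including a miscalibrated surgeon constant (clinical baseline bias
≈ −0.46 D), ELP scatter, measurement noise and refraction quantization.
Every pipeline stage is testable against known ground truth. See the
methods vignette (`vignettes/iol-power-ml-methods.Rmd`) for the model,
the calibrations and their rationale.

## Worked example

The analysis is organized as numbered drivers over the package API:

```sh
Rscript analysis/01_simulate.R --seed 1     # 2,194-eye synthetic cohort
Rscript analysis/02_prepare.R  --seed 1     # filters, targets, 70/30 split
Rscript analysis/03_train.R    --seed 1     # SVM-RM + MLNN-EM
Rscript analysis/04_evaluate.R --seed 1     # error summaries + paired tests
```

Output of the run above (seed 1):

```
generated 2194 eyes from 1663 patients (seed 1)
clinical outcome: mean Rx_post -0.453 D, SD 0.446 D, 60.5% within ±0.50 D

input 2194 eyes; excluded 47 (sigma:rx_pre_d, fellow-eye AL, ...)
selection 1503 eyes, verification 641 eyes (3 out of trained range)

SVM-RM holdout MSE (normalized): 0.00387
MLNN-EM test MSE (normalized): mean 0.00349, median 0.00351

ALL-eyes prediction errors:
 subgroup  method   n      me   mae medae   std   min   max ±0.25 ±0.50 ±0.75 ±1.00
      ALL      CR 641 -0.4442 0.505 0.500 0.437 -1.75 0.875  34.3  61.5  80.5  91.4
      ALL  SVM-RM 641  0.0689 0.375 0.318 0.476 -1.20 1.933  44.1  70.0  89.1  96.3
      ALL MLNN-EM 641  0.0207 0.334 0.281 0.421 -1.25 1.346  46.0  76.3  93.0  98.0
```

Reading this: the simulated clinical baseline (CR) carries the
calibrated systematic myopic bias (ME −0.44 D) and lands 61.5% of eyes
within ±0.50 D; both learned models remove the bias (|ME| ≤ 0.07 D) and
raise the ±0.50 D rate by 9–15 points, with the ensemble slightly ahead
— the qualitative contrast such studies report. The Wilcoxon tests on
absolute errors (printed by stage 4) put both model-vs-CR comparisons at
p < 1e−13 after Bonferroni.

A minimal programmatic session:

```r
library(iolml)
oc  <- optics_constants(a_constant = 119.1)          # 12 mm vertex default
elp <- srkt_elp(43.3, 23.03, oc)$elp_mm              # 5.312 mm
r05 <- rx_05iol(43.3, 23.03, elp, 23.0, oc)          # 0.346 D per 0.5 D
iol_ideal(23.0, +0.50, r05)                          # 23.72 D
```

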