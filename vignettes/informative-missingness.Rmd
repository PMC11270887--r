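---
title: "Methods: informative missingness, imputation strategies, and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: informative missingness, imputation strategies, and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the generative model
behind the synthetic cohorts, the exact form of each missing-data strategy,
the classifiers and the evaluation stack, and the reasoning behind every
numerical choice that was genuinely open. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The prediction task

The package emulates a ward-level early-warning setting: patient time is cut
into 12-hour blocks (a morning and an evening risk review), a binary outcome
marks deterioration within the following block, and patient time is censored
at 7 days — hence at most 14 blocks per patient. Predictors are demographics
(age, sex, race, admission type), the block index, and twelve laboratory
measures with the plausibility limits and clinical normal ranges of a
standard panel (`lab_config()`). Five labs (WBC, platelets, sodium,
potassium, BUN) are collected routinely; seven (arterial/venous pH, PaO2,
arterial/venous PaCO2, lactate, troponin) only on clinical suspicion.

## 2. The synthetic cohort generator

Real cohorts of this kind cannot be shared, so the generator is a
first-class, tested component rather than a fixture. It is deliberately
minimal: one latent state with three observable consequences.

**Severity.** Each patient carries a latent severity
$s_t = b_i + \rho\,(s_{t-1} - b_i) + \varepsilon_t$, a stationary AR(1) with
persistence $\rho = 0.8$ per block and innovation SD $0.6$, giving a unit
stationary SD. The baseline $b_i$ is a small demographic shift (about
$\pm 0.2$ SD across age, sex and admission type), so demographics are weak
but real predictors. Severity is emitted in a `severity` debug column as
simulation ground truth; it is never used as a predictor.

**Labs.** Each lab's true value is the midpoint of its normal range plus a
severity-driven abnormality plus Gaussian noise, truncated at the
plausibility limits; the loading is 0.8 normal-range half-widths per
severity SD and the noise SD 0.5 half-widths. One-sided labs (BUN up,
platelets down, PaO2 down, lactate up, troponin up) deviate linearly in
severity. Clinically two-sided labs (potassium, sodium, WBC, both pHs, both
PaCO2s) deviate toward a patient-specific tail — hypo- or hyper-, drawn once
per patient — and only while severity is above its typical level. This was a
deliberate design choice: laboratory values have characteristically U-shaped
risk relations (hypo- and hyperkalaemia are both dangerous), and a purely
linear lab model makes clinical cut-point encodings uninformative relative
to the raw value, which misrepresents how such encodings behave on real
data. With the mixed design, coarse "low/high" abnormality carries
information that no single linear term in the raw value can.

**Outcome and stay.** Each block, the patient deteriorates with probability
$\mathrm{logit}^{-1}(-6.38 + 1.5\,s_t)$ (the event ends the stay and is
recorded on that block), otherwise is discharged with constant hazard 0.080
per block, otherwise continues until the 14-block censoring. The intercept
and hazard were calibrated once, by simulation, so that the default
generator reproduces the cohort descriptives it is meant to emulate: a
patient-level event rate near 4.7%, a block-level event rate near 0.6%, and
a median of about 8 blocks (4 hospital days). `scripts/acceptance.R`
re-measures all of these on a fresh 20,000-patient cohort.

**Observation mechanism.** The missingness indicators are Bernoulli with
per-lab log-odds

* MCAR: intercept only;
* MAR: intercept + 0.6 × (absolute standardised deviation of the *last
  observed* value of that lab — clinicians re-test after an abnormal
  result); the dependence is on observed history only;
* NMAR: intercept + severity coefficient × $s_t$ (0.6 for regular labs, 1.0
  for informative ones) — observation depends on the latent state that also
  drives the unobserved values, which is exactly the informative
  missingness mechanism.

Intercepts are calibrated per mechanism so the marginal block-level
missingness sits near 50% for regular and 90% for informative labs. Under
the NMAR defaults the case-vs-control observation contrasts come out close
to the magnitudes typical of ward cohorts (count relative rates ~1.2 for
regular labs; ever/never relative rates ~1.5–1.8 for informative ones) —
the test suite checks the directions, the acceptance script the rates.

**What the generator does not emulate.** Within-block aggregation of
repeated measurements (the simulator emits one value per block; how a
real-data adapter should collapse multiple draws — last, worst — is left to
that adapter); correlated multi-lab panels (labs are conditionally
independent given severity, whereas real orders arrive in panels, which
makes real within-patient observation far more correlated across labs);
time-varying measurement habits; and demographic marginals beyond rough
plausibility. Conclusions from passing tests are therefore about behaviour
under a controlled NMAR mechanism, not about any specific hospital's data.

## 3. Strategies

All strategies obey a fit-on-train / apply-on-test contract
(`fit_imputer` → `apply_imputer`); observed entries are never altered.

* **Mean**: per-lab observed training mean; preserves the completed-column
  mean exactly, distorts correlations; valid under MCAR only.
* **Conditional (PMM)**: chained equations, 10 sweeps by default; each lab
  is linearly regressed on all other predictors — the other labs as
  currently completed plus the demographics; the outcome is excluded (it is
  the label, and conditioning the imputation on it would leak it into the
  features). A missing entry takes the observed
  value of one of the 5 donors with closest predicted mean (donor count
  unstated in the usual presentations; 5 is the conventional default),
  drawn uniformly, seeded. Single imputation, matching deployment use.
  Rank-deficient conditional models fall back to marginal donors and are
  recorded in the state's `notes`.
* **Normal value**: the normal-range midpoint — BUN 13.5, potassium 4.25,
  troponin 0.05, and so on. Encodes "not measured because presumed normal",
  a special NMAR assumption.
* **Categorical**: `unknown` / `low` / `normal` / `high` by the normal-range
  cut points; missingness survives as its own level, so downstream models
  see it.
* **LOCF composition**: with `locf = TRUE`, application carries the last
  observed raw value forward within the patient first, and the base
  strategy resolves the leading blocks that have no earlier observation.
  For categorical encoding the raw value is carried and then re-encoded, so
  abnormality is re-evaluated against the same cut points rather than
  freezing a possibly stale category.
* Values outside the plausibility limits are retained but counted by
  `qc_plausibility` (no winsorisation rule is imposed). Demographics are
  never imputed; race keeps "Missing" as an ordinary category.

## 4. The missingness embedding

Each partially observed lab gets a trainable matrix $W_j \in R^{k\times d}$
over its $k = 2$ missingness states; the one-hot state vector selects a row
($e_j = W_j m_j$), a missing entry uses the "missing" row as is, and an
observed entry scales the "observed" row by the value ($x_j e_j$). The
default dimension follows the fourth-root rule $d = \lceil k^{1/4}\rceil$,
i.e. 2. Observed values are standardised by training-set mean/SD before the
scaling: the raw scales differ by four orders of magnitude across the panel
(platelets vs troponin), and unstandardised scaling would make the learned
rows mere unit compensators. This normalisation is a deliberate package
decision and is flagged here because it is the one place the encoder's
arithmetic goes beyond the bare $x_j e_j$ formula. Weights initialise as
seeded $N(0, 0.1^2)$ draws and train jointly with the downstream network;
fully observed columns bypass the encoder. Categorical demographics can be
embedded the same way (all categorical variables sharing one dimension for
simplicity) or one-hot encoded; unseen levels map to a reserved "(other)"
row.

## 5. Classifiers

No deep-learning framework is part of the package's dependency set; the
package carries its own small neural engine (dense layers, LSTM cell,
hand-derived backpropagation verified against numerical differentiation in
the test suite, Adam, dropout, early stopping). All fits are deterministic
given their seeds.

* **Lasso logistic regression** via glmnet, $\lambda$ by 10-fold
  cross-validated deviance with folds assigned at the patient level.
* **MLP**: ReLU hidden layers (default 32–16), sigmoid output, binary
  cross-entropy. Each patient-block is an independent observation.
* **LSTM**: one recurrent layer (default 16 units) over the patient's
  padded block sequence, a risk emitted at every block from that block's
  hidden state (causal; padding masked out of the loss). Demographics enter
  at every time step — injecting them once at $t=0$ would force the cell to
  memorise them; per-step injection is the cheaper inductive bias. Default
  learning rate 3e-3 (the categorical dummy inputs train too slowly at
  1e-3) and 30 epochs.
* **Class imbalance**: positive blocks are ~0.6% of the data. The loss is
  unweighted by default, with a `pos_weight` option for sensitivity
  studies.
* **Tuner**: a single successive-halving bracket parametrised by the
  maximum epochs per trial $R$ and the elimination factor $\eta$: train all
  sampled candidates at $R/\eta^s$ epochs, keep the best $1/\eta$, multiply
  the budget by $\eta$, repeat to $R$. If the budget admits no halving
  round the tuner degrades to plain random search and says so in its log.
  Ties break by candidate order. Hyperparameters are tuned per experiment
  cell when tuning is used (strategies change the input geometry, so
  sharing one architecture across cells would bias the comparison; the
  cost trade-off is real but secondary at these scales).

## 6. Evaluation

* **AUROC** in Mann–Whitney (midrank) form, ties counted half; the test
  suite pins it to an exhaustive pairwise oracle and to an independent ROC
  implementation.
* **Stratified weighted AUROC**: repeated blocks from one patient are
  correlated, so observations are stratified such that each patient
  contributes at most once per stratum — which holds when strata are the
  block index (time since admission), the default. The aggregate is the
  weight-sum $\sum_s w_s \mathrm{AUROC}_s$ with $w_s$ the stratum's share of
  usable observations. Reading "stratified by length of stay" as grouping
  patients by their total stay is also defensible and available
  (`stratify_by = "patient_los"`), but it puts the same patient in one
  stratum many times, which defeats the independence rationale; the
  block-index reading is the default for exactly that reason. Strata with
  one outcome class carry no ranking information: dropped, weights
  renormalised, reported in the result.
* **Bootstrap**: patients resampled with replacement (blocks travel with
  their patient), basic (reflected) interval
  $(2\hat\theta - q_{0.975},\, 2\hat\theta - q_{0.025})$ — the "basic"
  algorithm by name and form. Resamples with a single outcome class are
  dropped; more than 20% dropped is an error, not a silent answer. The
  basic interval is not forced to contain the point estimate, and no such
  property is asserted.
* **Missingness diagnostics**: for regular labs, quasi-Poisson regression
  of per-patient observed counts on case status with log length-of-stay
  offset (dispersion via Pearson $\chi^2/\mathrm{df}$, the glm default);
  for informative labs, Poisson regression of the ever-observed indicator
  on case status and length of stay with HC0 sandwich variance — the
  standard way to get valid relative-risk CIs from a binary outcome.
  Cohort balance uses standardised mean differences (pooled-SD form for
  continuous variables, the multi-proportion Mahalanobis form for
  categorical ones).

## 7. Study sizes and determinism

The shipped experiment configuration simulates 20,000 patients; the
qualitative strategy-comparison study in the test suite runs five seeds of
5,000 patients with a reduced cell set, sizes at which the directional
contrasts of interest are measurable while a full run stays desk-scale. One
master seed fans out deterministic per-cell seeds, so any cell can be rerun
in isolation; two runs with the same configuration are identical to the
bit.

## 8. Known limitations

* The generator's event log-odds are *exactly* linear in the latent
  severity, and the twelve per-block missingness indicators alone already
  summarise severity well. Two consequences, both visible in the package's
  own directional study: the cross-validated lasso on a completed panel is
  close to the best achievable score, so the LSTM's longitudinal advantage
  — while real against the MLP — does not materialise against the lasso at
  these scales; and LOCF is roughly neutral (rather than harmful) for the
  LSTM with categorical encoding, because the recurrent state already
  performs the carrying that LOCF hard-codes. On real cohorts, with messier
  nonlinearity and two orders of magnitude more patients, both contrasts
  are reported to favour the longitudinal model more clearly.
* PMM uses linear conditional models inside the chained equations; with
  strongly two-sided labs those models are misspecified, which is faithful
  to how the method degrades under informative missingness but means the
  package's PMM is a lower bound on what a richer conditional model could
  do under MAR.
* The missingness embedding is variable-specific and time-constant;
  time-dependent embeddings are out of scope.
* The bootstrap and the stratified AUROC treat the block index as the only
  source of within-patient structure; no calibration metrics are computed.
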