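# ecglyte

Estimating continuous blood electrolyte concentrations — potassium, calcium,
sodium, creatinine — directly from raw multi-lead ECG waveforms, with deep
convolutional regression models and calibratable uncertainty.

Electrolyte imbalances are common in emergency patients and can cause lethal
arrhythmias, but the gold-standard blood test is unavailable in ambulances and
many telehealth settings, where an ECG is easy to obtain. This package
implements the full methodology for studying ECG-based concentration
prediction as a reusable, tested R pipeline:

* **Synthetic cohort generation** with a known, controllable
  electrolyte-to-waveform forward model (Gaussian-wavelet beat templates; the
  T-wave amplitude responds to a potassium-like analyte, the repolarization
  interval to a calcium-like one), emulating the statistical structure of an
  emergency-department registry: concentration moments, multiple ECGs and labs
  per patient inside a time window, admission dates spanning a temporal
  cutoff, and target variance rising with age.
* **Clinical dataset construction**: ECG–lab linking within a closed ±60 min
  window with median target assignment, patient-level 70/10/20 random and
  temporal (2017-01-01 cutoff) splits with post-cutoff leakage removal,
  first-ECG selection for evaluation, target z-scoring.
* **Preprocessing**: polyphase resampling, zero-phase high-pass and mains
  notch filtering, zero-padding to a fixed length, 8-lead reduction
  (III, aVR, aVL, aVF are linear in I and II).
* **The model spectrum**, sharing one 1-D residual convolutional backbone
  (implemented in the package, gradients verified against finite
  differences): direct regression (MSE), heteroscedastic Gaussian regression
  (negative log-likelihood `Σ ½log(2πσ²(x)) + (y−μ(x))²/2σ²(x)`), k-class
  classification (cross-entropy over μ±2σ interval schemes), and
  rank-consistent ordinal regression (k−1 cumulative thresholds, decoded by
  `1 + #{p_j > 0.5}`) — plus five classical baselines (PCA-256 features with
  linear / gradient-boosting / random-forest regressors; batch-wise linear
  and 3-layer MLP on raw traces).
* **Uncertainty**: a 5-member Gaussian ensemble yielding aleatoric
  (mean predicted variance), epistemic-ensemble (variance of member means)
  and epistemic-Laplace estimates (last-layer Gauss–Newton posterior
  `Σ⁻¹ = Σᵢ φᵢφᵢᵀ/σ²ᵢ + τI`, marginal-likelihood τ, linearized predictive
  variance φᵀΣφ).
* **Evaluation**: MSE/MAE/Pearson/Spearman, age- and sex-stratified
  normalized MAE, cumulative ROC families and AUmROC over class counts,
  hypo/hyper binary AUROC, sparsification, central-interval calibration,
  uncertainty–error correlation, and distribution-shift protocols (additive
  noise at exact SNR, trace masking).

## Worked example

```r
library(ecglyte)

an <- analyte_profile("potassium")      # mean 3.99, sd 0.50 mmol/l
co <- sample_cohort(an, n_patients = 900,
                    effect = effect_profile("strong"),
                    lab_noise_sd = 0.25, seed = 11)
cp <- preprocess_cohort(co)             # 128 Hz, 512 samples, filtered
d  <- prepare_model_data(cp, seed = 5)  # link, split, z-score
d
#> <linked_dataset> train 574 / val 52 / random_test 149 / temporal_test 71 ECGs

m <- train_direct(d, backbone_tiny(), train_config(epochs = 20, seed = 1))
regression_metrics(predict(m, d$random_test$x), d$random_test$y)
#> n=149  MSE=0.06702  MAE=0.2034  R=0.864  rho=0.830
```

The strong-effect synthetic cohort is the potassium-like regime: with an
effective label noise of 0.25 mmol/l (assay error plus biological drift
between ECG and blood draw), a tiny residual network recovers the planted
concentration–morphology relationship up to that noise floor (R ≈ 0.86–0.90
depending on cohort size), while the same network on the `"null"` profile
cannot beat the target variance, and classical baselines on PCA features
stay near the variance floor even in the strong regime — the qualitative
ordering that motivates deep models for this task.

The numbered scripts under `analysis/` run the full study at desk scale —
cohort simulation, preprocessing and splits, direct regression versus the
five baselines, the discretization spectrum, ensemble uncertainty, and the
noise/masking stress tests — writing tables to `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_direct_regression.R
Rscript analysis/04_discretization.R
Rscript analysis/05_uncertainty.R
Rscript analysis/06_ood.R
```

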