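# ebmr — event-based modelling of biomarker orderings and patient staging

`ebmr` implements the sporadic-disease **event-based model (EBM)** of disease
progression. The model treats progression as a fixed sequence of *events* at
which individual biomarkers switch from a "normal" to an "abnormal"
distribution, and learns that sequence — together with its uncertainty and a
per-subject disease stage — directly from a cross-sectional table of
continuous biomarker measurements. No biomarker cut points and no a priori
staging by clinical diagnosis are required, which matters in sporadic disease
where the control group is contaminated by presymptomatic cases and the
patient group contains misdiagnoses.

It is aimed at biostatisticians and neuroimaging researchers working with
cohort studies (CSF assays, cognitive test scores, regional MRI volumes,
atrophy rates) who want a data-driven ordering of biomarker abnormality and a
fine-grained staging measure for classification and conversion prediction.

## The model

For subject *j* with measurements *x₁ⱼ…x_Nⱼ* of *N* biomarkers, the EBM
assumes the subject sits at an unknown discrete stage *k* ∈ {0…N} of an
event sequence *S* = (s(1)…s(N)): events at positions ≤ *k* have occurred,
later ones have not. With a uniform stage prior, the data likelihood of a
candidate sequence is

    P(X | S) = Π_j  1/(N+1) Σ_{k=0}^{N}  Π_{i≤k} p(x_{s(i)j} | E_{s(i)})
                                        Π_{i>k} p(x_{s(i)j} | ¬E_{s(i)})

where `p(x|E)` and `p(x|¬E)` are the abnormal / normal measurement densities.
These are modelled per biomarker as the two components of a normal mixture
fitted to **all** subjects, with the weak constraint that each component's
standard deviation may not exceed the sample SD of the CN-labelled
(respectively AD-labelled) group — enough to keep the fit away from
physically unrealistic solutions without trusting the labels.

The package provides:

- `ebm()` — the fitting function: constrained mixtures per biomarker
  (projected EM), maximum-likelihood sequence by multi-start greedy ascent
  over permutations, MCMC over permutations for positional-variance
  uncertainty; with `print`, `summary`, `coef`, `predict` (staging),
  `plot` (positional variance diagram), `simulate` and `logLik` methods.
- `bootstrap_sequences()` — sequence cross-validation on subject resamples.
- `stage_subjects()`, `longitudinal_consistency()` — staging under a fixed
  sequence and its stability across visits.
- `stage_distribution()`, `classify_by_stage()` — stage histograms by
  diagnosis, stage-threshold classification (balanced accuracy,
  sensitivity/specificity, ROC AUC).
- `compute_cutpoint()` — descriptive mixture-equality cut points.
- `simulation_scenario()` / `generate_cohort()` / `generate_followup()` —
  a synthetic-cohort generator with known ground truth (contaminated
  controls, misdiagnosed patients) used throughout the test suite.
- `read_biomarker_table()` and friends — CSV + schema input with log- and
  percent-of-TIV preprocessing and amyloid/APOE4 subgrouping.

## Worked example

Simulate a five-event cohort with a known ordering, fit the model, and use
the stages to classify:

```r
library(ebmr)

sc <- simulation_scenario(
  n_events = 5, separation = 3, n_cn = 40, n_mci = 50, n_ad = 30,
  biomarker_names = c("csf_abeta", "csf_ptau", "atrophy_rate",
                      "memory_score", "hippo_vol"))
cohort <- generate_cohort(sc, seed = 7)

fit <- ebm(cohort$dataset, n_samples = 5000, burn_in = 500, seed = 7)
fit
#> Event-based model: 5 events, 120 subjects
#>   ML sequence: csf_abeta -> csf_ptau -> atrophy_rate -> memory_score -> hippo_vol
#>   logLik: -1041.9061
#>   MCMC: 5000 samples, acceptance 0.0%
```

The recovered ordering equals the generating one
(`sequence_kendall_tau(fit$order, cohort$sequence)` is 1), and the zero MCMC
acceptance tells us the posterior is concentrated on that single ordering at
this separation (every proposed transposition is rejected). `summary(fit)`
shows the fitted mixture for each biomarker and the stage histogram:

```r
summary(fit)
#> Baseline stage distribution:
#> stage
#>  0  1  2  3  4  5
#> 25 27 16 22 18 12
```

Stages separate the diagnostic groups; thresholding them classifies CN
versus AD subjects:

```r
sa  <- predict(fit, type = "assignment")
keep <- cohort$truth$diagnosis != "MCI"
classify_by_stage(sa$stage[keep], cohort$truth$diagnosis[keep] == "AD",
                  n_events = 5)
#> Stage-threshold classification (n+ = 30, n- = 40)
#>   threshold stage 3: balanced accuracy 83.3% (sens 86.7%, spec 80.0%), AUC 0.899
```

Here subjects at stage ≥ 3 are called AD; balanced accuracy is the mean of
sensitivity and specificity, so it does not depend on the CN/AD mix. The
misclassified subjects are mostly contaminated controls and misdiagnosed
patients, which the generator plants by design. `plot(fit)` draws the
positional variance diagram (events × positions, greyscale 0 → white,
1 → black).

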