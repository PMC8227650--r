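# edapain

Objective, near-real-time detection of acute pain from electrodermal
activity (EDA). Skin conductance is driven purely by sympathetic sudomotor
innervation, so a painful stimulus evokes a skin-conductance response (SCR)
within seconds — `edapain` turns a raw wrist-worn conductance stream into
per-sample pain indices, stimulus-locked features, and subject-wise
classifier evaluations.

The package is aimed at biomedical-signal researchers who need a tested,
scriptable reference implementation of this pipeline, including a synthetic
EDA generator with exact ground truth so every stage can be validated
without access to human recordings.

## The method

A raw recording (irregularly sampled, ~15–130 Hz) is preprocessed to a
uniform 2 Hz series `x(t)`: cubic-spline resampling to 4 Hz, a 1-s running
median, decimation to 2 Hz, and a zero-phase 0.01 Hz high-pass. Three
indices are then computed:

* **TVSymp** — variable frequency complex demodulation (VFCDM) splits `x(t)`
  into 12 narrow bands centered at 0.04–0.92 Hz (0.08 Hz steps); components
  2 and 3 (≈0.08–0.24 Hz, where sympathetically mediated EDA dynamics
  concentrate) are summed, normalized to unit variance, and the
  instantaneous amplitude `a(t) = |X'(t) + i H{X'}(t)|` of the analytic
  signal is TVSymp.
* **MTVSymp** — `max(a(t) − mean of the preceding 5 s of a, 0)`, emphasising
  abrupt sympathetic surges over sustained elevation.
* **dPhEDA** — the five-point-stencil derivative of the phasic component
  from a convex tonic/phasic decomposition: `y = M q + B l + C d + res` with
  a nonnegative sparse driver `q` through a Bateman system
  (`tau0 = 2 s, tau1 = 0.7 s`), a spline tonic `B l`, and offset/drift
  `C d`, solved as a quadratic program.

A causal streaming scheme reproduces the on-device computation (55-s /
25-s trailing windows, mean left-padding, 5-s last-value right-padding, 2-s
tail averages emitted every 0.5 s). Around each stimulus, the 5 s before
and after form painless/pain segments; mean and max of each index give six
features per segment, compared by Fisher's ratio
`|mean0 − mean1|/(var0 + var1)`, AUROC with subject-stratified bootstrap
CIs, and a subject-nested permutation rank test. A leave-one-subject-out
harness with nested subject-wise grid search evaluates eight classifier
families. The methods vignette
(`vignettes/eda-pain-detection.Rmd`) documents every model, default and
design decision.

## Worked example

```r
library(edapain)
library(dplyr)

# simulate a small stimulus-locked experiment (5 subjects, 10 stimuli each)
cfg <- sim_config(n_subjects = 5, seed = 42)
ds  <- generate_dataset(cfg)
#> Synthetic EDA dataset: 5 subjects, 10 stimuli/subject, raw rate 120 Hz

# batch pipeline for one subject: preprocess -> indices
rec  <- filter(ds$records, subject_id == "sim01")
prep <- preprocess_eda(rec)                  # uniform 2 Hz, DC removed
idx  <- eda_indices(prep)                    # tvsymp, mtvsymp, dpheda
idx
#> # A tibble: 1,045 × 4
#>    time_s tvsymp mtvsymp   dpheda
#>     <dbl>  <dbl>   <dbl>    <dbl>
#>  1    0   0.0496  0       0.0221
#>  2    0.5 0.0991  0.0495  0.0456
#>  3    1   0.117   0.0430  0.0207
#>  # …

# stimulus-locked 5-s segment features for all subjects
segs <- purrr::map_dfr(unique(ds$records$subject_id), function(sid) {
  rec <- filter(ds$records, subject_id == sid)
  ev  <- filter(ds$events,  subject_id == sid)
  extract_segments(eda_indices(preprocess_eda(rec)), ev)
})

# discriminability of each feature (painless vs pain)
cmp <- compare_segment_features(segs, seed = 1)
tidy(cmp) %>% select(feature, fishers_ratio, auroc, ci_low, ci_high, p_value)
#> # A tibble: 6 × 6
#>   feature      fishers_ratio auroc ci_low ci_high  p_value
#> 1 tvsymp_mean          2.14  0.984  0.974   0.995 0.000500
#> 2 tvsymp_max           0.810 0.836  0.800   0.886 0.000500
#> 3 mtvsymp_mean         3.85  0.912  0.863   0.950 0.000500
#> 4 mtvsymp_max          0.564 0.650  0.619   0.683 0.00400
#> 5 dpheda_mean        106.    0.978  0.955   0.998 0.000500
#> 6 dpheda_max          23.4   1     1       1      0.000500
```

Each row compares painless vs pain segments for one feature: Fisher's ratio
is the scale-free linear separation, AUROC the probability a random pain
segment outscores a random painless one (with its 95% bootstrap CI), and
`p_value` the subject-nested permutation test. Here the evoked response
(0.5 µS, 25× the noise floor) is easily detected; the derivative and mean
features dominate because these are zero-phase batch indices (see the
vignette on pre-echo; max-type features shine on the causal streamed path).

A leave-one-subject-out classifier evaluation:

```r
rf <- evaluate_protocol1(segs, classifier_spec("RandomForest"), seed = 1)
glance(rf)   # mean accuracy / sensitivity / specificity with 95% CIs
```

A command-line interface wraps the same functions
(`inst/cli/edapain simulate|preprocess|indices|stream|segments|evaluate`).

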