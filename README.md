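# exhaustscope

PET radiomics modelling of tumor-infiltrating CD8+ T cell exhaustion.

## The problem

Exhausted CD8+ T cells dominate "cold" tumors and blunt both radiotherapy
and checkpoint blockade, but measuring the exhaustion state of the
infiltrate requires excising the tumor and running flow cytometry. A
candidate non-invasive surrogate is the *texture* of FDG uptake on PET:
heavily exhausted infiltrates are associated with patchier glucose uptake —
suppressed foci decorating a less suppressed background — so local
homogeneity statistics of the lesion should fall as the terminally exhausted
(PD-1^hi, "terminal Tex") fraction of CD8+ T cells rises.

`exhaustscope` implements that analysis end to end for mouse micro-PET/CT
scale data, and, because the underlying animal data are not public, ships a
first-class synthetic phantom generator whose latent immunology drives the
image texture, so every stage of the method can be exercised and tested on
data with known ground truth.

The pipeline:

1. **Simulate** — ellipsoidal tumor phantoms (~200 mm³, 0.5 mm voxels) with
   cold-spot suppression whose extent scales with the subject's latent
   terminal-Tex fraction, drawn from calibrated LLC/B16 treatment
   timecourses (terminal Tex ≈ 40% LLC / ≈ 20% B16 at baseline, peaking near
   70–73% at days 7–14 after ablative irradiation).
2. **Convert to SUV** — `SUV = activity [kBq/mL] × body weight [g] /
   injected dose [kBq]`.
3. **Extract radiomic features** — 61 PET features (first-order on raw SUV
   and on discretized gray levels, GLCM, GLRLM) and 57 CT features (adding
   the 3D shape family), with fixed-bin-count discretization (64 levels over
   the ROI min–max).
4. **Filter by reproducibility** — Lin's concordance correlation coefficient
   (CCC) between paired test–retest extractions; a feature is kept iff
   CCC > 0.65 (PET) or CCC > 0.75 (CT).
5. **Select** — LASSO regression of each exhaustion characteristic (early /
   terminal Tex fraction, E/T ratio, PD-1 MFI, binary high/low label) on the
   robust features, penalty chosen by leave-one-out cross-validation.
6. **Score** — an unpenalized binary logistic model on three features,
   outcome = terminal-Tex fraction above the cohort median. The package also
   ships the fixed reference score

   ```
   T exhaustion score = −297.597 · InverseVariance(GLCM)
                        + 178.689 · Homogeneity2(GLCM)
                        + 1.088 · Kurtosis(IntensityHistogram)
                        + 1.485
   ```

   with `P(high exhaustion) = 1 / (1 + exp(−score))`.
7. **Evaluate** — concordance index (≡ AUC for a binary outcome), Brier
   score and calibration curves, on the training arm (ICI-treated LLC+B16
   surrogate) and an independently seeded validation arm (post-irradiation
   LLC surrogate).

## Worked example

```r
library(exhaustscope)

# one subject, 7 days after ablative irradiation
state   <- sample_exhaustion_state(llc_rt_timecourse(), day = 7, seed = 1)
state
#> <exhaustion_state> LLC day 7: terminal 0.682, early 0.286, E/T 0.42, PD-1 MFI 1144

phantom <- generate_phantom(phantom_spec(seed = 1), state)
suv     <- to_suv(phantom$pet)
fv      <- extract_features(suv, phantom$mask, "pet")
round(fv[c("GLCM_InverseVariance", "GLCM_Homogeneity2", "IH_Kurtosis")], 4)
#> GLCM_InverseVariance    GLCM_Homogeneity2          IH_Kurtosis
#>               0.1429               0.1375               3.2134

t_exhaustion_score(texscore_reference(), fv)
#> $score
#> [1] -12.97779
#> $probability
#> [1] 2.311095e-06
```

This lesion is heavily exhausted (terminal Tex 68%), and its texture shows
it: inverse variance and homogeneity2 are low. The packaged score's absolute
calibration belongs to the original imaging protocol, so on synthetic
phantoms its probabilities are only rank-informative — which is why the
pipeline refits the three-feature logistic model on the synthetic training
arm:

```r
cfg        <- run_config(seed = 42)        # n = 20 train / 20 validation
training   <- run_training_arm(cfg)
training
#> <training_result> n = 20, C-index 1.000, Brier 0.000
#>   score features: GLRLM_RunLengthNonuniformity, ID_MeanAbsoluteDeviation, GLCM_Correlation

validation <- run_validation_arm(cfg, training$model)
validation
#> <validation_result> n = 20, C-index 1.000, Brier 0.439, call rate 0.95
```

Training C-index 1.000 and Brier 0.000 say the synthetic planted signal is
strong enough to separate the median split perfectly; the validation
C-index (here 1.000; 0.92–0.99 across seeds) shows the frozen model ranks an
independently generated post-irradiation cohort correctly. The validation
Brier is large because probabilities from a separable fit saturate — ranking,
not calibration, transfers across arms.

## Package layout

- `R/timecourse.R`, `R/phantom.R` — exhaustion-state simulation and digital
  FDG phantoms (including test–retest pairs and cohorts)
- `R/scan.R`, `R/io.R` — scan/mask containers, SUV conversion, NIfTI + JSON
  sidecar I/O
- `R/discretize.R`, `R/glcm.R`, `R/glrlm.R`, `R/intensity.R`, `R/shape.R`,
  `R/extract.R` — the radiomic feature families and catalog-driven
  extraction
- `R/ccc.R` — Lin's CCC and the test–retest robustness filter
- `R/model.R`, `R/metrics.R` — LASSO selection, the `texscore` S3 model
  (print/summary/coef/predict/fitted/residuals), C-index, Brier,
  calibration
- `R/pipeline.R` — the training and validation arms
- `vignettes/exhaustion-radiomics.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations)
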