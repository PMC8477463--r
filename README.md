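# wholelesion

Whole-lesion histogram and texture analysis of biparametric prostate MRI,
for discriminating prostate cancer (PCa) from benign prostatic hyperplasia
(BPH). The package is aimed at imaging scientists who want a tested,
fully reproducible implementation of this radiomics workflow — from raw
multi-b diffusion signals to ROC operating points — plus a calibrated
synthetic-cohort generator, so that every stage can be exercised and
validated without patient data.

## What it computes

The pipeline mirrors the clinical workflow:

1. **ADC mapping.** Per voxel, the mono-exponential diffusion model
   *S(b) = S(0) e^(−b·ADC)* is fitted by least squares on (b, log S) over
   b ∈ {0, 500, 800, 1000, 1500, 2000} s/mm² (`fit_adc`).
2. **Segmentation.** From foreground/background seed points, the random
   walker algorithm labels each voxel with the probability that a random
   walk on the intensity-weighted lattice graph (edge weights
   w_ij = exp(−β(g_i−g_j)²), β = 130) reaches a lesion seed first — the
   discrete Dirichlet problem (`random_walker`, `segment_lesion`). The mask
   is computed on the b = 1500 s/mm² DWI volume and propagated to the ADC
   map and T2W image (`propagate_mask`).
3. **Features.** Per modality: lesion volume, mean, SD, median, 5th/95th
   percentiles, skewness, kurtosis, and the Haralick GLCM features
   contrast Σ(i−j)²p(i,j), entropy −Σp log p, difference variance and
   difference entropy of p_{x−y}(k) (`extract_features`).
4. **Diagnostics.** Welch/pooled t and Mann–Whitney group tests, the
   Mann–Whitney AUC with DeLong 95% CI and test vs 0.5, Youden-optimal
   cutoffs with their inequality direction, ±likelihood ratios, and
   logistic combination of parameters scored on the probability scale
   (`roc_analysis`, `combine_parameters`, `cohort_report`).
5. **Simulation.** Phantoms (ellipsoidal textured lesions, Rician noise,
   sinh–arcsinh T2W skew) and whole cohorts calibrated to a published
   90-PCa / 112-BPH cohort's class-conditional feature statistics
   (`generate_phantom`, `generate_cohort`, `default_cohort_params`).

See `vignettes/whole-lesion-analysis.Rmd` for the models, conventions and
design decisions.

## Worked example

Simulate the calibrated two-class cohort in fast mode and report the
diagnostics:

```r
library(wholelesion)
cfg <- pipeline_config(mode = "fast", n_pca = 90, n_bph = 112,
                       master_seed = 20260930)
res <- run_pipeline(cfg, "run1")
subset(res$report$roc, feature %in%
       c("ADC_p5", "ADC_mean", "T2W_kurtosis", "ADC_p5 & T2W_kurtosis"))
```

```
               feature   auc ci_low ci_high    p_vs_half      cutoff direction
                ADC_p5 0.898  0.851   0.944 2.963322e-63 665.8849681        <=
              ADC_mean 0.868  0.819   0.916 1.869281e-50 928.2010204        <=
          T2W_kurtosis 0.606  0.525   0.688 1.025596e-02   2.5763183         >
 ADC_p5 & T2W_kurtosis 0.904  0.859   0.948 4.636608e-71   0.4325319         >
 sensitivity_pct specificity_pct youden_j lr_pos lr_neg
            83.3            89.3    0.726   7.78   0.19
            90.0            67.0    0.570   2.72   0.15
            47.8            76.8    0.246   2.06   0.68
            84.4            85.7    0.702   5.91   0.18
```

Reading the first row: in this simulated cohort the ADC 5th percentile
separates the classes with AUC 0.898 (CI excluding 0.5, so the marker is
informative); calling "cancer" when ADC_p5 ≤ 665.9 × 10⁻⁶ mm²/s catches
83.3% of cancers while clearing 89.3% of hyperplasias (Youden J = 0.726); a
positive call multiplies the odds of cancer by 7.78 and a negative call by
0.19. Low ADC indicating cancer is why the cutoff direction is "≤". The
combined ADC_p5 & T2W_kurtosis score reports its cutoff on the logistic
probability scale (0.43).

The same run writes `features.csv`, `report_comparison.csv`,
`report_roc.csv`, the resolved `config.json` and a timing log into the
output directory; rerunning with the same config and master seed reproduces
them byte for byte. Image mode (`mode = "image"`) synthesizes full DWI/T2W
volumes per patient and pushes them through ADC fitting, walker
segmentation and feature extraction instead of drawing features directly.

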