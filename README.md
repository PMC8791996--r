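# hierODR

Inference of cortical hierarchy from the laminar termination patterns of
interareal axonal projections.

## The problem

Feedforward (FF) pathways in visual cortex terminate preferentially in the
middle layers (L2–4) of their target area, while feedback (FB) pathways
favour layer 1. For an anterogradely labeled pathway imaged in a coronal
section, the **optical density ratio**

```
ODR = mean intensity in L2-4 / (mean intensity in L1 + mean intensity in L2-4)
```

is therefore a graded index of how feedforward-like the projection is:
ODR > 0.5 marks FF-like, ODR < 0.5 FB-like termination. `hierODR` turns a
directed area-by-area table of ODRs into a continuous hierarchy of the
areas, for anatomists and systems neuroscientists quantifying interareal
organisation (the built-in catalog is the ten-area mouse visual network —
V1 plus LM, AL, RL, P, LI, PM, AM, A, POR — but any directed network of
proportion-valued pathway indices fits).

## The model

Each observed pathway ODR `y_k` for the directed connection `i -> j` is
modelled as beta-distributed with common precision `phi`,

```
y_k ~ Beta(mu_k * phi, (1 - mu_k) * phi),    logit(mu) = X delta
```

where `X` is the incidence matrix of the connection graph (+1 in the target
column, −1 in the source column of each row) and `delta` the vector of
hierarchical levels. The expected logit ODR of a pathway thus equals the
level difference of its endpoints. Because every row of `X` sums to zero,
the reference column (V1) is dropped, pinning its level at 0. The package
provides:

- **`compute_odr()`** — the imaging pipeline: background subtraction, 1-µm
  disk smoothing, selection of pixels within a fraction of the peak
  intensity, and the L2-4 / (L1 + L2-4) ratio;
- **`fit_reciprocity()`** — OLS of each pathway's logit ODR on its
  reciprocal (slope −1 under a strict hierarchy);
- **`distance_matrix()`** — model-free hierarchical distances as unit-slope
  intercepts of the logit ODRs of two areas toward common targets (or from
  common sources), using the additivity `delta_ip = delta_iq + delta_qp`;
- **`fit_beta_regression()` / `fit_hierarchy()`** — the maximum-likelihood
  beta regression (quasi-Newton on `(delta, log phi)`, analytic gradient,
  observed-information covariance, AIC);
- **`model_search()`** — AIC comparison across partitions that constrain
  areas to share a level (columns of `X` summed);
- **`classify_edges()`** — FF / lateral / FB labels from two-sided Wald
  contrasts on the fitted levels;
- **`fit_gaussian_rf()` / `hierarchy_rf_consistency()`** — elliptical
  Gaussian receptive-field fits, equal-area 2-SD diameters
  (`4 * sqrt(sigma_x * sigma_y)` degrees), and their correlation with the
  fitted levels;
- **`simulate_odr()` / `render_laminar_image()` / `simulate_rf_maps()`** —
  a synthetic-data generator for every input the pipeline consumes.

## Worked example

```r
library(hierODR)

sim    <- simulate_odr(seed = 7)            # 10 areas, 80 of 90 pathways
report <- run_full_analysis(sim$observations, seed = 7)
print(report)
```

```
== Hierarchy analysis report ==
10 areas, 80 observed pathways
Reciprocity fit: slope = -0.848, F(1, 34) = 144.510, p = 8.57e-14 (n = 36 pairs, 72 pathways)
Beta-regression hierarchy fit
  80 pathways, 10 levels, phi = 93.02
  logLik = 130.577, AIC = -241.155
  levels: V1=0.00, RL=0.44, LM=0.53, AL=1.01, P=1.05, A=1.06, PM=1.06, AM=1.49, LI=1.50, POR=2.02
  goodness of fit: r = 0.968, t(78) = 34.11
AIC winner: V1|LM/RL|AL/P/PM/A|LI/AM|POR (5 levels, AIC -249.09)
 class  n      mean         sd        sem
    FF 32 0.6895497 0.10127456 0.01790298
   LAT 14 0.5082735 0.06358681 0.01699429
    FB 34 0.3247199 0.09421611 0.01615793
```

The negative reciprocity slope says that the more FF a pathway is, the more
FB its reciprocal. The fitted levels recover the generating five-level
configuration (V1 at 0, POR on top), the AIC search identifies exactly that
five-level partition, and pathway classes separate cleanly by ODR: FF
pathways average ≈ 0.69, lateral ≈ 0.51, FB ≈ 0.32 on these data.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate_data.R` … `06_rf_consistency.R`); each writes its tables under
`results/`.

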