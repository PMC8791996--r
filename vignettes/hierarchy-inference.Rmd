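---
title: "Inferring a cortical hierarchy from laminar optical density ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a cortical hierarchy from laminar optical density ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierODR)
```

## The measurement and the model

Interareal axonal pathways terminate in characteristic laminar patterns:
feedforward (FF) projections are column-like with strong middle-layer
terminations, feedback (FB) projections favour layer 1. The optical density
ratio of a labeled pathway in a coronal section,

$$\mathrm{ODR} = \frac{\bar I_{L2\text{-}4}}{\bar I_{L1} + \bar I_{L2\text{-}4}},$$

compresses that pattern into a proportion: near 1 for strongly FF, near 0
for strongly FB termination. Deep layers are deliberately excluded from the
ratio because fibers of passage contaminate them.

Given a directed area-by-area matrix of pathway-mean ODRs, the package
estimates a scalar hierarchical level $h_a$ per area under a beta
regression with logit link and constant precision:

$$y_k \sim \mathrm{Beta}(\mu_k\phi,\ (1-\mu_k)\phi), \qquad
  \mathrm{logit}(\mu_k) = h_{\mathrm{target}(k)} - h_{\mathrm{source}(k)}.$$

The design matrix is the incidence matrix of the observed connection graph:
each row has $+1$ in the target area's column and $-1$ in the source's.
Rows sum to zero, so one column — the reference area, V1 by default — is
dropped and its level fixed at 0. Merging columns constrains areas to share
a level; AIC ($-2\log L + 2(p+1)$, one parameter per free level plus
$\phi$) compares such partitions. Three further views complement the
regression: the reciprocity fit (under a strict hierarchy the logit ODRs of
a reciprocal pair are antisymmetric, slope $-1$), the unit-slope pairs
plot (for injected areas $p, q$ and a common target $i$, the identity
$\delta_{ip} = \delta_{iq} + \delta_{qp}$ makes the intercept of a slope-1
line an estimate of $h_p - h_q$), and two-sided Wald contrasts on the
fitted levels that label each pathway FF, lateral, or FB.

## Assumptions worth stating

* **One level per area.** A single scalar per area must explain every
  pathway touching it; systematic target-specific laminar specialisations
  appear as lack of fit, not as extra parameters.
* **Constant precision.** $\phi$ is shared across pathways; there is no
  precision submodel.
* **Independence across pathways.** Section-to-section correlation within
  a pathway is absorbed by averaging sections before the regression.
* **Pathway means, not sections.** The likelihood consumes one value per
  directed pathway (the mean of its 3–5 section ODRs, averaged on the ODR
  scale). A section-level fit is possible by passing per-section rows as
  distinct observations, but the default granularity is the pathway; all
  reported degrees of freedom follow from that choice.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `eps` | 1e-3 | clipping bound for logit and likelihood; keeps transforms finite at ODR 0/1 without distorting interior values (averaged pixel data essentially never reach 0/1) |
| `fraction`, `mode` | 0.7, `"range"` | pixel selection: keep intensities within `fraction` of the band peak ($v \ge (1-f)\,v_{max}$, boundary inclusive). A rank-based mode (top `fraction` by rank) is provided because the phrase "top 70% of the highest value" admits both readings; the choice is recorded per result |
| `exclude_top` | 0 | optionally drop pixels above $(1-e)\,v_{max}$ first (robustness to the saturated projection core) |
| `radius_um` | 1 µm | flat disk-mean smoothing radius, converted to pixels by the image scale; damps outlier/saturated pixels |
| `min_sections` | 3 | pathways with fewer sections are retained with a warning — there is no principled exclusion rule, only a reporting convention |
| `alpha` | 0.05 | two-sided Wald level for FF/FB vs lateral classification, uncorrected; a Holm-corrected variant is available via `holm_bonferroni()` |
| `max_log_phi` | log(1e8) | cap on the precision; zero-residual (noise-free) data push $\phi$ to this cap, which is flagged (`phi_at_bound`) rather than treated as convergence failure |

## Numerical choices

* **Initialisation** is deterministic: $\delta$ from OLS of
  $\mathrm{logit}(y)$ on the design, $\phi$ from the method-of-moments
  estimate on the OLS residual variance.
* **Optimisation** is quasi-Newton (L-BFGS-B) on $(\delta, \log\phi)$ with
  the analytic gradient, a coarse pass followed by a tight restart
  (relative tolerance $\sim 10^{-15}$); convergence is declared on the
  optimizer's own criterion or a gradient max-norm below
  $10^{-6}\max(1, |\log L|)$. The covariance is the inverse observed
  information at the optimum, delta-method-transformed from $\log\phi$ to
  $\phi$.
* **Identifiability.** A rank-deficient design (the observed graph
  disconnects the groups) raises an error naming the unidentified columns.
  The additive indeterminacy of the levels is pinned by the reference
  column; the multiplicative scale of the latent axis is absorbed by the
  logit link and $\phi$, so no further constraint is imposed.
* **Within-group pathways** produce all-zero design rows ($\mu = 0.5$
  fixed). They stay in the likelihood — they inform $\phi$ — with an
  option to drop them.
* **Ties in the AIC ranking** break toward fewer parameters, then the
  lexicographic partition signature.
* **Degenerate inputs**: empty backgrounds, all-zero pixel selections,
  constant response maps, pairs with no common third area, and all-equal
  levels in `scale_levels()` raise explicit errors (or a flagged 0/1 ODR
  with a warning when exactly one band is empty).
* **Order of imaging operations** is fixed as background subtraction →
  smoothing → selection; the source wording does not pin this down, so it
  is fixed once and documented. Selection thresholds are computed per layer
  band by default (`per_section_max = TRUE` switches to a joint peak).

## The partition search

`model_search()` fits one model per candidate partition. `"cumulative_top"`
(merging the top $n$ areas) and `"lm_upward"` (growing a block upward from
the second-lowest area) reproduce staged, nested searches;
`"bracketed"` enumerates all contiguous-block groupings of the
rank-ordered middle areas (the lowest and highest areas stay singleton;
$2^{k-3}$ models for $k$ areas); `"ladder"` — the default — is a staged
eight-model family from two levels to all-singleton. The ladder is the
default because exhaustive enumeration materially inflates the selection
of spurious extra levels: each unnecessary split of a true group survives
with probability $\approx P(\chi^2_1 > 2) \approx 0.16$, so a 128-model
bracketed search accepts at least one spurious split in roughly half of
the replicates, while the ladder keeps the overfitting set small. This is
a property of AIC itself, not of the likelihood; it is why the selection
consistency check below is stated against the ladder.

## What the generator emulates — and what it does not

`simulate_odr()` inverts the analysis model exactly: section ODRs are beta
draws around $\mathrm{logit}^{-1}(h_j - h_i)$ with common $\phi$. The
default configuration fixes the study conditions once: ten areas in five
levels (V1 | LM,RL | A,AL,PM,P | LI,AM | POR) spread over $[0, 2]$,
$\phi = 30$, four sections per pathway, and 10 of the 90 directed pathways
missing (placed at random — the count is a data property, the positions
are not). `render_laminar_image()` builds two-band sections whose
background-subtracted band means realise a target ODR exactly, and
`simulate_rf_maps()` draws elliptical-Gaussian response fields on a
5°-spaced stimulus grid.

Because the ODR generator *is* the fitted model, passing recovery tests
demonstrates correctness of the estimator, not realism of the model: real
sections exhibit within-pathway correlation, uneven illumination,
segmentation error in the layer masks, and laminar patterns that no
single-level-per-area model can represent. The rendered images likewise
have rectangular bands and stationary noise — they exercise the pixel
pipeline's arithmetic, not histological variability. Conclusions about
real tissue rest on the robustness analyses (selection-threshold variants,
raw-ODR reciprocity) rather than on these tests.

## Receptive fields

`fit_gaussian_rf()` fits rate $= b + A\exp(-q(x, y))$ with an oriented
elliptical quadratic form by Levenberg–Marquardt, initialised at the peak
position with moment-based sigmas (both the orientation and the baseline
term can be disabled). The RF diameter is the diameter of the circle with
the same area as the 2-SD ellipse, $4\sqrt{\sigma_x\sigma_y}$ degrees —
the equal-area reading of "transforming the elliptical field into a
circle"; the geometric-mean axis gives the identical value, and taking the
major axis was rejected because it is not an area-preserving transform.
An axis-swap ambiguity ($\sigma_x \leftrightarrow \sigma_y$,
$\theta \to \theta + \pi/2$) is inherent; the diameter is invariant to it.

## Problem sizes used by the checks

The test suite runs the estimator-vs-grid-oracle comparison on 3-area
networks (two seeded instances, five grid refinements), level recovery
over 100 seeded replicates of the 10-area/90-pathway network at
$\phi = 30$, AIC selection consistency over 50 replicates of the
five-level truth, 1000-replicate null calibrations for ANOVA, Tukey and
Holm, and 100 noisy receptive-field recoveries. These sizes were chosen so
each property is measured with useful precision while the whole suite
stays interactive (~half a minute).

## Known limitations

* AIC model selection is not consistent: the probability of preferring a
  spuriously split level does not vanish with more data, so the selected
  level count should be read together with the Wald grouping
  (`classify_edges()`), which is what defines the overlapping levels.
* The per-pathway beta likelihood treats section-mean ODRs as beta
  distributed; the mean of $n$ beta draws is not exactly beta, so the
  fitted $\phi$ reflects an effective, not the generative, precision
  whenever sections are averaged.
* Reciprocity and pairs-plot estimates use OLS with noise in both
  coordinates; attenuation biases slopes toward zero. An antisymmetric
  generating process still yields slope $-1$ in expectation only in the
  noise-free limit (an orthogonal-regression variant would trade this for
  scale sensitivity and is deliberately not the default).
* `hierarchy_rf_consistency()` correlates area *means*; with few units per
  area the per-area SEM dominates and the Pearson test's df is the number
  of areas minus 2, not the unit count.
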