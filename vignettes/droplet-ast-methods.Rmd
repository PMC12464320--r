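---
title: "Methods: single-cell antibiotic susceptibility analysis in droplets"
author: "dropletAST"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell antibiotic susceptibility analysis in droplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletAST)
```

## The problem

In droplet-microfluidics antibiotic susceptibility testing (AST), a dilute
bacterial suspension is emulsified into thousands of nanolitre water-in-oil
droplets together with an antibiotic, so that most occupied droplets carry a
single cell. After incubation, each droplet is a binary readout: the cell
either grew (a *positive* droplet) or it did not. Because every cell is
cultured in isolation, the fraction of positive droplets as a function of
antibiotic concentration traces the *distribution* of single-cell minimum
inhibitory concentrations (individual MICs, iMICs) across the population --
information a bulk broth-dilution MIC cannot provide. The width and shape of
that distribution quantify *heteroresistance*: the presence of
sub-populations with markedly different susceptibilities inside a seemingly
isogenic culture.

dropletAST implements the full analysis chain for such experiments, plus a
synthetic-data generator that emulates both the counting statistics and the
droplet micrographs, so every stage can be validated against known ground
truth without wet-lab data.

## Model

### Poisson encapsulation

With inoculum density $D$ (CFU/mL) and droplet volume $V$ (mL), droplet
occupancy is Poisson with mean $\lambda = DV$. The standard design point,
$10^5$ CFU/mL in 1 nL droplets, gives $\lambda = 0.1$: about 90% empty
droplets, 9% with one cell, and only ~0.5% with two or more, so single-cell
encapsulation dominates among occupied droplets. `poisson_occupancy()`
returns these masses exactly.

### Dose-response and the iMIC distribution

Positive-droplet counts $N_+(c)$ out of $N(c)$ droplets give the positive
fraction $f_+(c) = N_+(c)/N(c)$, normalized to the antibiotic-free control:
$F_R(c) = f_+(c)/f_+(0)$. The dose-response curve is fitted with the
two-parameter survival ("Gompertz-type") function

$$\phi(c) = \exp\{-(c/p_1)^{p_2}\},$$

where $p_1$ is the concentration at maximum slope (the scale) and $p_2$ the
slope parameter at $c = p_1$ (the shape). The corresponding iMIC density is
the negative derivative,

$$p(c) = \frac{p_2\,c^{p_2-1}}{p_1^{p_2}}\,\exp\{-(c/p_1)^{p_2}\},$$

which is exactly a Weibull density with scale $p_1$ and shape $p_2$. This
equivalence is used throughout: closed-form moments come from the Weibull
raw moments $E[c^k] = p_1^k\,\Gamma(1 + k/p_2)$ (evaluated via log-gamma so
extreme shapes do not overflow), and the synthetic generator draws per-cell
iMICs from `rweibull()` so the generator and the fitted model agree by
construction.

The statistic suite per sample (`imic_summary()`):

* **mode** $= p_1(1 - 1/p_2)^{1/p_2}$, the inflection point of $F_R$ and the
  most frequent iMIC;
* **mean, SD, skewness, kurtosis** from the gamma-function closed forms,
  each cross-checked against adaptive quadrature of $p(c)$, with the
  absolute closed-form-vs-quadrature differences reported as numerical
  error estimates for skewness and kurtosis;
* **RMSD** $= \sigma/\text{mode}$ and **CoV** $= \sigma/\mu$, dimensionless
  dispersion measures;
* **threshold concentrations** by inverting the curve,
  $c(\varepsilon) = p_1(-\ln\varepsilon)^{1/p_2}$, at the policy's survival
  levels (below);
* **DoH**, the degree of heteroresistance: the ratio of the
  complete-inhibition concentration to the onset-of-inhibition
  concentration.

### Threshold policy

The fitted curve reaches zero only asymptotically, so "first drop in
growth" and "complete inhibition" require conventions, collected in
`threshold_policy()`:

| level        | default | meaning                                          |
|--------------|---------|--------------------------------------------------|
| `eps_start`  | 0.99    | survival has dropped by 1%: onset of inhibition  |
| `eps_total`  | 0.05    | >95% of droplets inhibited (fixed by definition) |
| `eps_all`    | 0.001   | 99.9% inhibition, treated as complete            |

`eps_total` follows directly from the ">95% inhibited" definition. The
other two are calibrated conventions, deliberately exposed as parameters
rather than hard-coded: on a reference unexposed sample (mode 9.2, mean
8.9 ng/mL) the defaults place the onset concentration near 3.4 ng/mL and
the complete-inhibition concentration near 15 ng/mL. When
$c(\varepsilon_{all})$ exceeds the highest tested concentration the value is
not determinable from the data (status `ND`) -- the heavy-tail regime where
the fitted curve runs almost parallel to the concentration axis -- and the
*experimentally observed* complete-inhibition concentration (`imic_exp()`,
the smallest tested concentration with zero positives in every replicate at
that concentration and all higher ones) substitutes for it in the DoH.

### Recovering parameters from printed summary statistics

`solve_shape_scale()` inverts a (mode, mean) pair back to $(p_1, p_2)$ by
root-finding on the ratio
$\text{mode}/\text{mean} = (1-1/p_2)^{1/p_2}/\Gamma(1+1/p_2)$. This ratio is
*not* injective: it rises above 1, peaks near shape 7, and decays back
towards 1, so a ratio slightly above 1 has two preimages. The function
returns all roots and defaults to the smaller shape -- the wider,
larger-CoV branch, which is the one consistent with a dispersed single-cell
MIC distribution; when an independent dispersion value (SD or CoV) is
printed alongside, it should be used to confirm the branch. A related
subtlety: the mean-mode crossing (shape ~3.31) and the skewness zero
(shape ~3.602) do not coincide, so "mode below mean" and "positive
skewness" are equivalent only away from that narrow near-symmetric window.

## Fitting

`fit_gompertz()` minimizes $\sum_c w(c)\,(F_R(c) - \phi(c))^2$ with the
Levenberg-Marquardt implementation in minpack.lm, from multiple starts:
$p_1^{(0)}$ = the tested concentration whose $F_R$ is nearest 0.5 (fallback:
the median tested concentration) and $p_2^{(0)} \in \{1, 2, 4, 8\}$; the
lowest-RSS solution wins, ties towards the smaller shape. The $c = 0$ point
($F_R = 1$ by construction) is included and the fit is unweighted by
default; inverse-variance weights from replicate SDs are an option. Values
$F_R > 1$ from sampling noise are legitimate inputs and are not clipped.

Degenerate inputs are refused or flagged rather than silently fitted: a
profile with no decline is an error; one that never falls below 0.5, or
whose fitted scale lands beyond the tested range, carries a warning. In
tests the optimizer is checked against an iterated grid search over the same
RSS surface.

Replicates are averaged at the *count* level before normalization (the
pooled-evidence order); per-replicate normalization followed by profile
averaging is available via `order = "normalize_first"` for sensitivity
analysis, and per-point replicate SDs are always retained.

## Image analysis

Bright-field droplet micrographs are classified in four stages:

1. **Detection** (`detect_droplets()`): droplets appear as bright discs on
   a darker background, so Otsu thresholding plus connected-component
   labeling (EBImage) finds them directly; each blob's centroid and
   area-equivalent radius define the droplet, a compactness gate rejects
   merged blobs, and droplets cut by the frame are excluded. We chose this
   over a Hough transform because on disc-like blobs the labeling route is
   simpler, faster, and directly yields the area-equivalent radius; the
   detector is validated against the generator's ground-truth manifest
   (centers within 3 px, radii within 15%).
2. **Texture features** (`droplet_feature_point()`): the axis-aligned
   square inscribed in each droplet interior is tiled with non-overlapping
   16x16 px patches (no background contamination); per patch a grey-level
   co-occurrence matrix (GLCM) is built at offset distance 1 and angles
   {0, $\pi/2$} over 64 grey levels, symmetric and normalized, and
   *dissimilarity* $\sum P(i,j)|i-j|$ and *homogeneity*
   $\sum P(i,j)/(1+(i-j)^2)$ are averaged over offsets and patches. A grown
   microcolony makes the interior granular at pixel scale, which raises
   dissimilarity and lowers homogeneity.
3. **Clustering** (`classify_droplets()`): k-means with $k = 2$ on the
   standardized feature plane; the cluster with higher mean raw
   dissimilarity is labeled growth-positive, making the naming invariant to
   k-means' internal indexing. The GLCM hyperparameters and the
   standardization step are conventions (reasonable texture-analysis
   defaults), all exposed through `glcm_params()`.
4. **Evaluation** (`evaluate_classification()`): against ground truth,
   false negatives and false positives are reported as fractions of the
   *detected-positive* count -- the convention matching a fluorescence
   validation benchmark of this method class, where 9 FN and 10 FP against
   1,447 detected positives give 0.6% and 0.7%; the total-droplet
   denominator is available as an option.

## The synthetic-data generator

`simulate_counts()` emulates the counting experiment: per concentration and
replicate, droplet occupancies are Poisson($\lambda$) draws; each cell gets
a Weibull iMIC; a droplet is positive when its governing iMIC exceeds the
concentration. Under the default `single_only` rule an occupied droplet is
governed by a single cell (the analysis framework's one-cell assumption);
the `max_of_k` rule lets any of $k$ co-encapsulated cells rescue growth,
and exists to probe the (small, at $\lambda = 0.1$) bias from multiple
encapsulation -- pointwise it can only raise the expected survival.

`generate_droplet_images()` emulates the micrographs: droplets are placed
on a jittered grid (guaranteeing non-overlap and full containment --
real chips pack droplets more densely, but overlap handling is a detection
concern, not a statistics concern), rendered as discs with a brighter rim,
with global Gaussian sensor noise; occupied droplets get i.i.d. Gaussian
granular texture over the interior. Amplitudes are stated in 8-bit grey
levels: defaults are background noise SD 2 and texture SD 10, i.e. a 5x
contrast-to-noise ratio. Defaults place 100 droplets of radius 18 +/- 2 px
per 960 x 960 image and 20 images (~2,000 droplets at 9.1% occupancy) --
the scaled-down classifier benchmark used by `scripts/acceptance.R`. The
droplet radius default is chosen so the inscribed square always holds at
least one full texture patch; droplets too small for one patch are flagged
and excluded from clustering.

What the generator does *not* emulate: optics (no point-spread function,
defocus, or illumination gradients), droplet polydispersity beyond a
truncated normal radius, debris, or touching droplets. Passing the
classifier benchmark therefore demonstrates the correctness of the
detection/GLCM/k-means machinery on images with the assumed structure, not
performance on real micrographs -- the latter was established in the
laboratory with fluorescence ground truth, which is exactly the role the
manifest plays here.

Study-condition defaults of `simulation_config()` -- truth
$(p_1, p_2) = (9.8, 4.4)$ (an unexposed-sample parameter pair on a ng/mL
scale), a fine 14-point concentration ladder over 0-20 densifying near the
scale, 5,000 droplets per concentration, three biological replicates,
$\lambda = 0.1$ -- were fixed once from the experimental design they
emulate and are used unchanged by the tests.

## Pipeline and comparisons

`run_pipeline()` composes counts (given or simulated) -> profile -> fit ->
summary per sample, isolates per-sample failures, and reports DoH fold
changes against a designated control; `report_table()` renders the
statistics-by-samples table. Image-derived counts enter via
`classify_droplet_images()` + `tally_droplet_records()`.

The sample-vs-control comparison (`compare_to_control()`) is a paired
two-sided t-test on the two fitted curves evaluated over a shared 50-point
grid spanning the common concentration range. This is a documented
convention: a curve-level test is not uniquely defined by the experimental
design, and published p-values from such tests are not reproducible without
knowing the exact data vectors used; a replicate-level alternative (Welch's
t on per-replicate fitted scales) is provided behind `method =
"replicates"`. Identical curves return $p = 1$ by convention.

## Numerical choices and problem sizes

* Closed forms via `lgamma()`; quadrature cross-checks integrate the
  unit-scale density (substitution $u = c/p_1$) with `rel.tol = 1e-10` and
  a `1e-13` absolute floor, so results are unit-independent and the
  near-cancelling third moment at zero-skew shapes stays integrable.
* Threshold inversion is closed-form and round-trips
  $\phi(c(\varepsilon)) = \varepsilon$ to $10^{-10}$.
* The Poisson occupancy masses sum to 1 exactly in floating point (the
  multi-cell mass is the complement of the rounded empty + single sum).
* Test problem sizes: 50,000 droplets/concentration for convergence
  checks, 100 simulated experiments at the 5,000-droplet default for the
  parameter-recovery benchmark (median relative errors: scale within 2%,
  shape within 8%), ~2,000 droplets across 20 images for the classifier
  benchmark. These sizes make the whole validation suite run in about a
  minute on a laptop while keeping binomial sampling error well below the
  tolerances tested.

## Known limitations

* The binary growth readout cannot see metabolically inactive or very slow
  growers; as in the laboratory method, such cells deflate $F_R$ and bias
  iMIC statistics downward.
* Concentration units are opaque metadata; no conversion between samples.
* The onset/complete-inhibition survival levels are conventions; DoH values
  are comparable only under a fixed policy.
* `solve_shape_scale()` is exact only if the printed mode and mean come
  from the same fitted curve; rounding in the inputs propagates (on the
  reference pair, to about $\pm 0.02$ in skewness).
* The curve-level t-test treats grid points as paired observations; it is
  a ranking/screening device, not a calibrated hypothesis test.
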