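# dropletAST

Single-cell antibiotic susceptibility analysis for droplet microfluidics.

## The problem

In droplet-based antibiotic susceptibility testing (AST), bacteria are
encapsulated one per nanolitre droplet (Poisson loading, λ ≈ 0.1) together
with an antibiotic, incubated, and each droplet scored as growth-positive or
negative. Unlike a bulk MIC, the positive-droplet fraction across an
antibiotic concentration ladder traces the full distribution of *individual*
MICs (iMICs) over the population, and with it the population's
**heteroresistance** — the coexistence of sub-populations with very
different susceptibilities inside one seemingly isogenic culture.

dropletAST is for researchers running (or simulating) such experiments. It
covers the entire chain:

* **Image analysis** — droplet detection in bright-field micrographs,
  grey-level co-occurrence matrix (GLCM) texture features
  (dissimilarity, homogeneity) per droplet interior, and k-means
  classification into growth-positive/negative, with confusion statistics
  against ground truth.
* **Resistance profiles** — positive fractions `f+(c) = N+(c)/N(c)`,
  normalized to the no-antibiotic control, `F_R(c) = f+(c)/f+(0)`, with
  replicate averaging at the count level.
* **Dose–response model** — least-squares fit of the Gompertz survival
  function

  φ(c) = exp{−(c/p₁)^p₂}

  whose negative derivative, p(c) = (p₂ c^(p₂−1)/p₁^p₂) exp{−(c/p₁)^p₂},
  is the iMIC density (a Weibull density with scale p₁, shape p₂).
* **iMIC statistic suite** — mode p₁(1−1/p₂)^(1/p₂); closed-form mean,
  SD, skewness and kurtosis from Γ-function moments; RMSD (SD/mode) and
  CoV (SD/mean); threshold concentrations by curve inversion
  c(ε) = p₁(−ln ε)^(1/p₂); and the **degree of heteroresistance (DoH)** —
  the ratio of the complete-inhibition concentration to the
  onset-of-inhibition concentration — plus DoH fold changes versus an
  unexposed control.
* **Synthetic data** — a generator for count tables (Poisson occupancy ×
  Weibull per-cell iMICs) and for droplet micrographs with a ground-truth
  manifest, so every stage is testable without wet-lab data.

## Worked example

Simulate an experiment at the standard design point (ground truth scale
9.8 ng/mL, shape 4.4; λ = 0.1; 5,000 droplets per concentration; three
replicates), fit it, and summarize:

```r
library(dropletAST)

cfg  <- simulation_config(seed = 42)       # defaults = study conditions
tabs <- simulate_counts(cfg)               # 3 replicate count tables
prof <- resistance_profile(tabs, unit = "ng/mL")
fit  <- fit_gompertz(prof)
fit
#> Gompertz survival fit: phi(c) = exp{-(c/p1)^p2}
#>   p1 (scale) = 9.77 ng/mL   p2 (shape) = 4.375
#>   RSS = 0.001107 over 14 points (c_max = 20), converged: TRUE

imic_summary(fit, tables = tabs)
#> Individual-MIC summary (Gompertz fit: p1 = 9.77  p2 = 4.375 )
#>   mode 9.207 ng/mL   mean 8.901 ng/mL   SD 2.303 ng/mL
#>   RMSD 0.2501   CoV 0.2587   skewness -0.1572   kurtosis 2.792
#>   start 3.414 ng/mL   total 12.56 ng/mL   all 15.2 ng/mL   exp 16 ng/mL
#>   DoH 4.452 (from fitted)
```

Reading the output: the fitted scale and shape recover the simulation truth
(9.8, 4.4) to ~1%. The most frequent iMIC (mode) is 9.2 ng/mL; the
distribution is slightly left-skewed (−0.16), meaning a tail of unusually
*susceptible* cells. Growth first drops at ~3.4 ng/mL (`start`, survival
0.99), >95% of cells are inhibited at 12.6 ng/mL (`total`), 99.9% at
15.2 ng/mL (`all`), and the first tested concentration with zero positive
droplets in all replicates was 16 ng/mL (`exp`). The DoH, 15.2/3.4 ≈ 4.5,
is the distribution-width measure used to compare samples: a sample whose
pre-exposure widens its iMIC distribution shows a DoH fold increase versus
the control (`run_pipeline()` / `fold_change_doh()` automate that
comparison).

For images instead of counts:

```r
gen <- generate_droplet_images(image_config(seed = 7))   # 20 images, ~2000 droplets
rec <- classify_droplet_images(gen$images, gen$manifest, seed = 7)
evaluate_classification(rec)
#> Droplet classification: 1999 droplets in 20 images, 192 detected positive (9.6%)
#>   false negatives: 0 (0.00%)   false positives: 0 (0.00%)
```

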