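# visbrix

Qualitative and quantitative assessment of fruit soluble solid content
(SSC, °Brix) from visible-range absorbance spectra.

## What it does, and for whom

Visible spectroscopy (400–800 nm) is a cheap alternative to NIR for
grading fruit by sugar content: by the Lambert–Beer law, juice absorbance
at the carbohydrate bands (near 461, 469 and 750 nm) is proportional to
SSC in a fixed optical path. `visbrix` is aimed at chemometrics users who
want a complete, testable pipeline from raw spectra to either a 3-grade
quality call or a °Brix prediction:

* **Pretreatment** — SNV, vector normalisation, Savitzky–Golay smoothing,
  first/second finite-difference derivatives, and second-derivative +
  smoothing (SD-SG), all length-preserving on the 81-point grid.
* **Features** — PCA with contribution-rate selection: keep the smallest
  *k* latent variables whose cumulative eigenvalue share
  Φ_k = Σ_{i≤k} λ_i / Σ_j λ_j reaches a threshold (0.95 or 0.99).
* **Balancing** — SMOTE oversampling of minority grades; multipliers
  (3, 1, 4) turn a 22/71/7 cohort into a balanced 66/71/28 = 165-sample
  training table.
* **Models** — a from-scratch three-layer BPNN (sigmoid hidden layer;
  sigmoid or linear head) trained by full-batch gradient descent under one
  of four learning-rate decay laws
  (η₀(1−t/T)^p, 0.5η₀(1+cos tπ/T), η₀e^{−t²/2γ²}, η₀/(1+e^{γ(t−T/2)})),
  optionally preceded by particle swarm optimisation of the whole weight
  vector (v ← ωv + c₁r₁(pbest−x) + c₂r₂(gbest−x)); plus a NIPALS PLS1
  baseline.
* **Metrics** — confusion matrix, accuracy, macro recall/F1, one-vs-rest
  AUC, Pearson r, RMSEC/RMSEP, leave-one-out RMSECV, per-grade
  descriptive statistics.
* **Synthetic data** — a Lambert–Beer generator (Gaussian bands, truncated
  Gaussian SSC population, baseline/scatter/noise corruptions) so the full
  pipeline runs and is tested without instrument data.

## Worked example

```r
library(visbrix)

# a synthetic 100-sample cohort with the realistic grade imbalance
x <- generate_spectra(synthetic_config(seed = 1))
print(x)
#> spectrum_set: 100 samples x 81 wavelengths (400-800 nm)
#> grades: G1=20 G2=76 G3=4

head(grade_statistics(x$ssc, x$grade)[, c("grade", "n", "mean", "variance", "cv")])
#>   grade  n      mean  variance         cv
#> 1     1 20 15.005185 0.6322961 0.05299305
#> 2     2 76 12.436398 1.1115468 0.08477529
#> 3     3  4  9.278003 0.2710229 0.05611106

# 3-grade classification on a clean fixture: SD-SG -> PCA(0.99) -> SMOTE ->
# 8:2 split -> PSO-optimised BPNN with Gaussian learning-rate decay
r <- run_qualitative(pipeline_config(data = make_fixture("clean", seed = 1),
                                     pca = list(threshold = 0.99), seed = 1))
sprintf("accuracy %.2f%%, macro recall %.2f%%, macro F1 %.4f (k = %d LVs)",
        r$accuracy, r$macro_recall, r$macro_f1, r$k)
#> "accuracy 100.00%, macro recall 100.00%, macro F1 1.0000 (k = 1 LVs)"

# quantitative Brix prediction on noise-free spectra
q <- run_quantitative(pipeline_config(
  synthetic = synthetic_config(n_samples = 100, baseline_sd = 0,
                               scatter_sd = 0, noise_sd = 0, seed = 1),
  pca = list(threshold = 0.99), seed = 1))
sprintf("r_cal %.3f RMSEC %.3f | r_pre %.3f RMSEP %.3f",
        q$r_cal, q$rmsec, q$r_pre, q$rmsep)
#> "r_cal 0.999 RMSEC 0.072 | r_pre 0.999 RMSEP 0.074"
```

A clean one-band spectrum set needs a single latent variable, the grading
pipeline separates the grades perfectly, and the regression recovers SSC
to well under 0.1 °Brix. On corrupted spectra the orderings that motivate
the pipeline appear: SD-SG pretreatment beats raw spectra when baseline
and scatter dominate, and the swarm-optimised network beats plain gradient
descent on low-dimensional features (see the methods vignette for where it
does not).

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R` with verbs `generate`, `qualitative`,
`quantitative`, `compare`.

## Documentation

The methods vignette (`vignettes/visbrix-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, the
numerical choices (edge handling, tie-breaks, standardisation,
degenerate inputs), and known limitations.
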