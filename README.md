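# sersga

Genetic-algorithm band selection and LDA classification for two-class serum
SERS (surface-enhanced Raman spectroscopy) diagnostics.

## The problem

Label-free serum SERS measures, per blood sample, a Raman intensity spectrum
over the fingerprint region (400–1800 cm⁻¹, ~1 cm⁻¹ resolution). Disease
shifts the relative intensity of a handful of bands by a few percent,
underneath a large smooth autofluorescence background, strong per-sample
intensity variability and noise. Full-spectrum classifiers (e.g. PCA-LDA)
can separate the classes but yield components with no physical meaning;
selecting a small set of discriminative *bands* gives a simpler model whose
variables are interpretable Raman lines.

`sersga` implements the complete analysis:

* **Preprocessing** — iterative fifth-order polynomial background removal
  (peak-clipping modified polynomial fitting), Savitzky–Golay smoothing,
  normalization to unit area under the curve.
* **Band selection** — the spectrum is tiled into 254 contiguous
  five-variable segments; a genetic algorithm searches 6-segment subsets
  (chromosomes) maximizing leave-one-spectrum-out cross-validated
  Fisher-LDA accuracy

  `fitness(c) = 1/n · Σᵢ 1[ ŷ₍₋ᵢ₎(xᵢ; c) = yᵢ ]`,

  with population 20, single-point crossover (p = 0.70), per-individual
  mutation (p = 0.05), elitist copy of the top 25%, elitism, and 100
  generations; the search is repeated (default 100 runs) and each run's
  best chromosome is cumulatively counted, the top-count segments merging
  into consensus diagnostic bands.
* **Classification** — two-class Fisher LDA, `w ∝ S_w⁻¹(μ₁ − μ₀)`, midpoint
  threshold, LOOCV; plus a PCA-LDA comparator on the leading 20 principal
  components.
* **Evaluation** — sensitivity/specificity/accuracy (cancer positive),
  ROC/AUC from pooled held-out scores, per-band pooled-variance t-tests,
  difference spectra.

Because two-class serum SERS cohorts are rarely public, the package includes
a first-class synthetic generator (91 spectra: 55 cancer + 36 normal by
default) with Lorentzian serum peaks, planted class effects at eight known
bands, per-spectrum polynomial fluorescence baselines, lognormal global
intensity scale and white noise — so the whole pipeline is testable against
known ground truth. See `vignettes/sersga-methods.Rmd` for the model,
parameter choices and limitations.

## Worked example

```r
library(sersga)

cohort <- simulate_dataset(synthetic_config(seed = 42))
cohort
#> <spectra_set> 91 spectra x 1270 variables, 400-1800 cm^-1
#>   labels: normal=36, cancer=55

clean <- preprocess_set(cohort)
idx   <- build_segment_index(length(clean$grid), 5, grid = clean$grid)

ga     <- ga_config(n_runs = 10, seed = 42)   # 100 runs is the analysis default
counts <- consensus_counts(clean, ga, idx)
counts
#> <band_counts> 10 runs x 6 segments (sum 60)
#>   top segments: 52(5) 149(4) 214(4) 14(3) 51(3) 191(3) 55(2) 93(2) 168(2) 188(2)

bands <- top_bands(counts, idx, k = 6)
bands
#>   band seg_lo seg_hi n_segments count     wn_lo     wn_hi
#> 1    1     14     14          1     3  471.7100  476.1229
#> 2    2     51     52          2     8  675.8077  685.7368
#> 3    3     55     55          1     2  697.8723  702.2853
#> 4    4    149    149          1     4 1216.3909 1220.8038
#> 5    5    191    191          1     3 1448.0693 1452.4823
#> 6    6    214    214          1     4 1574.9409 1579.3538

vars <- expand_chromosome(unlist(Map(seq, bands$seg_lo, bands$seg_hi)), idx)
cv   <- loocv(clean, variables = vars)
compute_metrics(cv)
#> confusion: TP=52 FN=3 TN=33 FP=3
#> sensitivity 94.5%  specificity 91.7%  accuracy 93.4%

roc_curve(cv$score, cv$label)
#> <roc_result> 92 thresholds, AUC 0.987
```

The consensus bands land on (or on the flank of) the generator's planted
diagnostic lines — 481, 683, 1219, 1445 and 1585 cm⁻¹ here — and the
six-band LDA separates the held-out spectra with ~93% accuracy and AUC 0.99
at the generator's default class overlap. `run_pipeline()` chains all five
stages and writes CSV/JSON artifacts plus a reproducibility manifest;
`inst/cli/sersga.R` exposes the same stages as shell subcommands
(`simulate`, `preprocess`, `select`, `classify`, `evaluate`, `run`).

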