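# qparscreen

Screening bioactive components out of herbal-medicine fingerprints by
quantitative pattern–activity relationship (QPAR) modelling.

Given a chromatographic feature table (samples × peak areas), a
bioactivity fraction per sample and, optionally, a UV spectrum per
feature, the package asks: *which features does the activity follow?*
It is written for analytical chemists and chemometricians working on
mixture bioactivity — the motivating system is the osteoclast
growth-inhibition activity of *Herba epimedii* extracts, assayed as an
inhibition rate `I = (At − Ab)/(Ac − Ab)` on RAW264.7 cells.

## The models

Single constituents follow a full-range Hill curve
`E(c) = 1/(1 + (EC50/c)^p)`. Mixtures combine through the joint-action
family:

* **Concentration addition (CA)** — similarly acting constituents; toxic
  units `S = Σ c_i/EC50_i` share one sigmoid, `E = S^p/(1+S^p)`.
* **Response addition (RA)** — dissimilarly acting constituents;
  `E = 1 − Π(1 − E_i)`.
* **Olmstead cassette model** — CA inside cassettes of similar mode of
  action (inferred from UV-spectrum clustering), RA across cassettes.
  It reduces exactly to CA with one cassette and to RA with singleton
  cassettes.

Feature relevance is scored by the **Good2bad value**: over many Monte
Carlo (sample, feature) subsets, each fitted as a sub-model, a feature's
selection frequency in the small-error tail (SEM) is divided by its
frequency in the big-error tail (BEM); activity-relevant features
accumulate in well-predicting sub-models. A NIPALS PLS1 regression is
included as the linear baseline, and mixture-design utilities construct
the uniform-design standard mixtures (U7(7^6) levels, EC-proportional
ratios, 2× dilution series) and pairwise 1:1 sample blends.

## Worked example

```r
library(qparscreen)

# Hill algebra on a reference standard (EC5 = 13.77, EC50 = 77.06 ug/mL)
hp <- fit_two_point(13.77, 0.05, 77.06, 0.50)
hp
#> Hill parameters: EC50 = 77.06, slope p = 1.71
c(EC10 = ec_x(hp, 0.10), EC20 = ec_x(hp, 0.20))
#> EC10 = 21.32, EC20 = 34.25 ug/mL

# a synthetic fingerprint world with known actives (F1-F3)
truth <- generate_qpar_dataset(generator_config(n_features = 40, seed = 1))
truth
#> Synthetic QPAR dataset: 12 base samples -> 66 blends, 40 features (3 active), 3 cassettes
#>   activity: mean 0.314, sd 0.121, range [0.092, 0.657]

res <- run_screen(truth$table, truth$activity, spectra = truth$spectra,
                  model = "olmstead",
                  config = mcs_config(iterations = 300, seed = 1))
res
#> QPAR screen (olmstead model): top candidates F3, F12, F18
head(res$ranking[order(res$ranking$rank), ], 5)
#>  feature_id    rt f_sem f_bem score rank
#>          F3 0.987 0.400     0     7    1
#>         F12 3.179 0.133     0     3    2
#>         F18 4.641 0.133     0     3    3
#>          F2 0.744 0.133     0     3    4
#>         F31 7.808 0.133     0     3    5
```

`f_sem`/`f_bem` are tail selection frequencies, `score` the
pseudocounted Good2bad ratio: F3 sat in 40% of the best-predicting
sub-models and none of the worst, so it tops the ranking; a true active
(F3) leads here while the other two sit amid look-alike noise features —
see the methods vignette for what recovery rates this world does and
does not support. The cassette labels came from silhouette-guided
k-means on the spectra (`res$k_diagnostics`), and rerunning with the
same seed reproduces every number exactly.

A thin CLI over the same functions lives at `inst/exec/qpar.R`
(`generate`, `cluster`, `screen`, `design` subcommands).

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package, the
concentrations eliciting 10%/20%/30% effects for three reference
standards by fitting Hill parameters to each standard's printed
(EC5, EC50) pair via the closed-form two-point fit and inverting the
Hill equation, and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

* `R/` — Hill algebra, joint-action predictors (Rcpp kernel in `src/`),
  estimation and PLS baseline, spectrum clustering, Good2bad Monte
  Carlo, mixture design, synthetic data, I/O and pipeline.
* `inst/extdata/standards_ec50.csv` — EC5–EC50 ladder of the six
  reference flavonoid standards (µg/mL).
* `tests/testthat/` — unit, property and acceptance suites.
* `vignettes/qpar-methods.Rmd` — models, parameter choices, generator
  calibration, known limitations.
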