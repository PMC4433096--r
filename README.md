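# mockbias

Quantify and correct taxonomic bias in 16S rRNA amplicon pipelines with
mock-community mixture experiments.

An amplicon pipeline distorts community composition at every stage: DNA
extraction lyses taxa unevenly, PCR amplifies templates preferentially,
sequencing and classification add residual error, and 16S gene copy number
inflates read counts multiplicatively. `mockbias` implements the full
mixture-experiment protocol for measuring those distortions on a fixed
taxon panel and inverting them, aimed at microbiome researchers who run
mock-community controls (the shipped panel is seven vaginally relevant
species).

The package covers the protocol end to end:

* **D-optimal mixture designs** on the simplex (proportions sum to one).
  A Scheffé special cubic model in *p* components,

  $$E(y) = \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j +
  \sum_{i<j<k} \beta_{ijk} x_i x_j x_k,$$

  needs `p + C(p,2) + C(p,3)` runs (63 for 7 taxa); support points are
  chosen by Fedorov point exchange, plus interior lack-of-fit points and
  replicate runs for pure-error estimation.
* **Forward simulation** of the three companion experiments — mixing
  cells, extracted DNA, or PCR product — from explicit per-taxon stage
  efficiencies and pairwise interaction coefficients, with multinomial
  read sampling and lognormal technical jitter.
* **Bias decomposition**: copy-number/genome-size count adjustment, the
  per-taxon bias `x̂_i − x_i`, its attribution to extraction
  (cells − DNA), PCR (DNA − PCR) and sequencing/classification
  (PCR − prescribed), replicate technical variation, and bootstrap
  Mahalanobis significance tests.
* **Scheffé mixture-effect models** per taxon, with Bonferroni screening
  of blending terms into synergistic (positive) and antagonistic
  (negative) relationships, and blending-surface contours.
* **Inverse correction**: per-taxon random forests (500 trees, 2 splitting
  variables) of the scaling factor (observed/actual proportion) on the
  observed proportion vector, applied to predict true composition of new
  samples, with sample-level cross-validation.

## Worked example

```r
library(mockbias)

taxa   <- read_taxa(system.file("extdata", "vaginal_taxa.csv", package = "mockbias"))
design <- build_design(taxa, seed = 1)
design
#> Mixture design: 80 runs, 65 unique treatments, 7 components
#>   roles: lack_of_fit=2, replicate=15, support=63

truth  <- make_truth(7, "default", seed = 1)          # known bias parameters
counts <- simulate_experiment(design, truth, taxa, "cells")
props  <- adjust_counts(counts, taxa)                 # divide by copy number, normalize

fits <- fit_scheffe_models(props, design)
fits
#> Scheffe mixture models for 7 taxa
#>   A. vaginae           R-squared 0.9998
#>   G. vaginalis         R-squared 0.9998
#>   L. crispatus         R-squared 0.9997
#>   ...

head(screen_blends(fits[["L. crispatus"]]), 3)
#>                        term degree estimate  p.value p.adjusted    direction
#> 1     L. crispatus:L. iners      2   -1.588 3.33e-20   1.87e-18 antagonistic
#> 2 G. vaginalis:L. crispatus      2   -0.866 3.09e-17   1.73e-15 antagonistic
#> 3     L. crispatus:P. bivia      2   -0.846 1.32e-15   7.39e-14 antagonistic
```

The blending screen reads: when *L. crispatus* co-occurs with *L. iners*,
its observed proportion falls about `β_ij x_i x_j` short of linear
blending — an antagonistic pair; adjusted p-values are Bonferroni over the
56 blending terms of that taxon's model. Each R² near 1 means the special
cubic surface captures essentially all design-driven variation at depth
16,000.

Replicate technical variation and the inverse correction:

```r
technical_variation(props, design)[1:2, ]
#>          taxon n_deviations     mae
#> 1   A. vaginae           10 0.00721
#> 2 G. vaginalis           12 0.00714

models    <- fit_inverse(scaling_factors(props, design), seed = 1)
profiles  <- random_profiles(50, taxa, seed = 2)      # "clinical" samples
clin      <- simulate_clinical(truth, taxa, profiles, seed = 3)
corrected <- correct_sample(clin$counts, taxa, models)
observed  <- adjust_counts(clin$counts, taxa, "cells")
round(c(corrected   = mean(abs(corrected - clin$true_profiles)),
        uncorrected = mean(abs(observed  - clin$true_profiles))), 4)
#>   corrected uncorrected
#>      0.0128      0.0846
```

Replicate median absolute error sits well below 5% per taxon, and the
inverse models cut the mean absolute compositional error of held-out
samples from 8.5% to 1.3%.

`run_pipeline(default_config())` chains all of the above and can write
every artifact (design CSV, count TSVs, bias tables, significance JSON) to
disk; `inst/scripts/mockbias.R` exposes `design`, `simulate` and `run`
subcommands for shell use.

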