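# omiflim

Label-free **optical metabolic imaging (OMI)** analysis for fluorescence
lifetime microscopy of immune cells, in R. The package is written for
researchers who measure NAD(P)H and FAD autofluorescence by
time-correlated single photon counting (TCSPC) FLIM — for example to
read out the metabolic state of macrophages at wounds in live zebrafish
larvae — and need the whole computational chain from photon-count decay
cubes to cohort-level statistics to be scripted, tested, and
reproducible.

## What it computes

Per pixel, the photon arrival-time histogram is fitted (with the
instrument response function convolved into the model) to the
two-component decay

```
I(t) = α₁·exp(−t/τ₁) + α₂·exp(−t/τ₂) + C,     α₁ + α₂ = 1
```

where τ₁/τ₂ are the short/long lifetimes of the free and protein-bound
coenzyme pools (reversed for FAD) and C is constant background. From the
fits and channel intensities come the standard endpoints:

- **optical redox ratio** ORR = I_NAD(P)H / (I_NAD(P)H + I_FAD) ∈ [0, 1];
- **mean lifetime** τm = α₁τ₁ + α₂τ₂ per channel;
- **OMI index** = ORRᵢ/⟨ORR⟩ + τmᴺᵢ/⟨τmᴺ⟩ − τmᶠᵢ/⟨τmᶠ⟩, the
  mean-centred composite with coefficients (1, 1, −1).

Cells are segmented from an mCherry macrophage-marker image
(rescale-by-max, threshold 0.15, 8-connected components) and scored
TNFα+/− from a GFP reporter; endpoints are averaged over each cell's
valid pixels. Cohort inference fits general linear models — one data
point per macrophage, experiment day as a fixed block, optional
interactions and log transform — with **cluster-robust (CR1) standard
errors clustered by larva** and t(G−1) inference, reporting estimated
means with 95% CI and pairwise contrasts (fold changes under log), with
no multiplicity adjustment.

A synthetic TCSPC generator (scenes of disk-shaped cells in two
activation groups, Poisson photon statistics, cells nested in larvae
nested in days) provides ground truth for every stage, so the pipeline
is fully testable without microscope data.

## Worked example

Simulate a small cohort (2 days × 3 larvae × 8 cells, 64×64 fields),
run the full chain, and model the TNFα effect on the redox ratio:

```r
library(omiflim)

cfg <- default_config(seed = 7)
cfg$simulate$shape <- c(64L, 64L)
cfg$fit$binning   <- 2L
cfg$stats$outcome <- c("orr", "nadph_tm")

res <- run_all(cfg, quiet = TRUE)

dplyr::select(head(res$cells, 4), cell_id, larva_id, tnfa_status,
              n_valid_pixels, orr, nadph_tm, omi)
#> # A tibble: 4 × 7
#>   cell_id larva_id tnfa_status n_valid_pixels   orr nadph_tm   omi
#>     <int> <chr>    <chr>                <int> <dbl>    <dbl> <dbl>
#> 1       1 D1_L1    positive                33 0.493    1.09  1.32
#> 2       2 D1_L1    positive                49 0.518    1.09  1.36
#> 3       3 D1_L1    positive                41 0.378    0.706 0.661
#> 4       4 D1_L1    positive                34 0.435    0.695 0.643

res$stats$orr
#> <omi_glm> orr ~ tnfa_status + day_id, 47 cells / 6 larvae / 2 days
#> Estimated means (95% CI):
#>      group estimate       se conf_low conf_high df
#> 1 negative   0.5121 0.013786   0.4767    0.5475  5
#> 2 positive   0.4524 0.005277   0.4388    0.4660  5
#> Contrasts:
#>               contrast estimate      se conf_low conf_high statistic p_value df
#> 1 positive vs negative -0.05971 0.01583  -0.1004  -0.01902    -3.772 0.01299  5
```

Each row of `res$cells` is one macrophage with its per-cell endpoint
means. The model output reads: TNFα+ (M1-like) cells have an estimated
redox ratio 0.060 lower than TNFα− cells (95% CI −0.100 to −0.019,
p = 0.013 with larva-clustered uncertainty on 5 degrees of freedom) —
recovering the oxidised shift injected by the generator. `tidy()`,
`glance()`, `autoplot()` and `plot_cohort_endpoint()` give broom-style
tables and ggplot displays; `run_all(cfg, out_dir = "out")` additionally
writes every artifact (TIFF cubes and maps, CSV tables, JSON sidecars)
plus a checksummed manifest.

A command-line front end with verbs `simulate`, `fit`, `segment`,
`endpoints`, `stats`, `run-all` is installed at
`system.file("cli", "omiflim", package = "omiflim")`.

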