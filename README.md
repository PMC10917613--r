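# saponinbias

Saponin-based host DNA depletion is a popular wet-lab step before shotgun
metagenomic sequencing of host-dominated specimens (saliva, sputum, skin,
biopsies, swabs): the detergent lyses eukaryotic cells so a DNase can digest
the released host DNA before microbial DNA extraction. It works — but it is
not selective. Saponin also lyses bacteria, and Gram-negative bacteria (thin
wall, outer membrane) far more readily than Gram-positive ones, so the
taxonomic profile that comes out of the sequencer can be severely distorted
toward Gram-positives even at low detergent concentrations.

`saponinbias` gives microbiome researchers the quantitative toolkit for
assessing that distortion:

- **Read-filtering accounting** — recompute "% filtered host" from the three
  per-sample read totals (produced, high-quality, retained after host-read
  alignment filtering), render publication-style filtering tables, and
  report host reduction between treated/untreated pairs.
- **Taxonomic variation index (TVI)** — the L1 divergence between two
  relative-abundance profiles on the percent scale,
  `TVI = Σ_t |p_t(a) − p_t(b)|`, ranging from 0 (identical) to 200
  (disjoint taxa); equivalently `200 × Bray-Curtis`. Includes per-taxon
  deltas and lost/gained-taxon reports.
- **Subsampling comparability checks** — rarefy a count table to a fixed
  depth (hypergeometric, without replacement) and measure the TVI between
  full-depth and subsampled profiles, to verify a shallow depth (e.g. 200
  reads) still supports profile comparison.
- **Gram-stratified dose-response** — aggregate profiles by Gram class
  across a saponin concentration series and quantify the Gram-negative
  decline (Spearman rank correlation, least-squares slope).
- **Compositional survival-rate contrasts** — under an exponential-survival
  lysis model (`survival = exp(−k_class · c)` at concentration `c`, %
  wt/vol), fit `log(p_t(c)/p_ref(c)) = α_t + β_t c` by OLS; `β_t` estimates
  `k_ref − k_t`. Only rate *contrasts* are identifiable from relative
  abundances — never absolute rates.
- **A synthetic differential-lysis simulator** — host + multi-taxon
  community with known Gram labels, class-specific exponential survival,
  and multinomial shallow sequencing — the fully-controlled test bed for
  every statistic above.

Everything is tidyverse-native: functions take tibbles first and return
tibbles, fitted objects have `tidy()` / `glance()` / `autoplot()` methods.

## Worked example

Recompute a filtering table from its count columns (the bundled example
tables ship only counts; the percentage is always recomputed):

```r
library(saponinbias)
filtering_table(example_filtering_table("sputum_titration"))
#>   sample_id      reads_produced high_quality_reads retained_after_host_filter
#> 1 Sputum-0.0125% 51,453         48,877             31,094
#> 2 Sputum-0.05%   34,712         33,795             31,860
#> ...                                        pct_host_filtered: 36.38%, 5.73%, ...
```

Compare a treated profile against its untreated counterpart:

```r
untreated <- tibble::tibble(
  taxon = c("Prevotella histicola", "Veillonella atypica",
            "Streptococcus salivarius", "Schalia sp."),
  abundance = c(40, 30, 20, 10))
treated <- tibble::tibble(
  taxon = c("Prevotella histicola", "Streptococcus salivarius", "Schalia sp."),
  abundance = c(10, 60, 30))
ann <- tibble::tibble(
  taxon = untreated$taxon,
  gram = c("gram_negative", "gram_negative", "gram_positive", "gram_positive"))

evaluate_pair(untreated, treated, annotation = ann)
#> Depletion-bias evaluation report
#> Profile comparison (treated vs untreated)
#>   TVI: 120 (range 0-200)
#>   taxa in union: 4 | lost: 1 | gained: 0
#>   top lost: Veillonella atypica
#>   Gram-negative shift: -60.00 percentage points
```

The TVI of 120 says the two profiles differ by 120 percent-points of total
abundance movement; the Gram-negative share dropped 60 points, and one
Gram-negative taxon was lost outright.

Run the whole simulated experiment — community construction, differential
lysis across a saponin titration, shallow sequencing, and every downstream
statistic:

```r
e <- end_to_end(default_scenario(), seed = 1)
dplyr::select(e$summary, concentration, gram_negative_pct,
              pct_host_filtered, tvi)
#>   concentration gram_negative_pct pct_host_filtered   tvi
#> 1        0                   82.1             52.9   0
#> 2        0.0125              81.8             52.6   1.20
#> 3        0.05                81.4             51.3   1.81
#> 4        0.1                 80.8             49.4   2.80
#> 5        0.5                 75.5             36.1  13.1
#> 6        1.5                 59.5             11.8  45.1
#> 7        2                   50.1              5.91 63.8
#> 8        2.5                 40.8              2.82 82.6
#>
#> Gram-negative slope: -16.262 pct points per % wt/vol; rho = -1.000
#> Estimated k_neg - k_pos: 0.753 per % wt/vol
#> Sampling-noise TVI floor at this depth: 1.178
```

Host reads fall from 52.9% to 2.8% of the library as the saponin
concentration rises — the depletion works — while the Gram-negative share
of the *microbial* profile collapses from 82% to 41% and the TVI against
the untreated profile climbs to 83: the bias the package is built to
expose. The fitted class-rate contrast (0.753) recovers the simulator's
ground truth (`k_neg − k_pos = 0.75`), and the sampling-noise TVI floor
(1.18) shows how much divergence re-sequencing alone would produce.

## Documentation

The methods vignette (`vignettes/depletion-bias-methods.Rmd`) describes the
divergence statistics, the exponential-survival lysis model, the
compositional identifiability argument, the simulator's assumptions, and
the package's numerical conventions in detail.
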