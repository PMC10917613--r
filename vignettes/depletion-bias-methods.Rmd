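---
title: "Quantifying host-DNA-depletion bias: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying host-DNA-depletion bias: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saponinbias)
library(dplyr)
```

## The problem

Clinical and environmental specimens are often dominated by host DNA —
saliva and biopsies can be ~90% human reads — so protocols deplete host DNA
before sequencing, typically by lysing host cells with a saponin detergent
and digesting the released DNA with DNase. The depletion is real, but so is
its side effect: saponin also lyses bacteria, and it lyses Gram-negative
cells (thin peptidoglycan wall under an outer membrane) much faster than
Gram-positive cells (thick wall). A depleted library can therefore show a
microbial community that never existed: Gram-negative taxa shrunken or
absent, Gram-positives inflated by compositional closure.

`saponinbias` treats the depletion protocol as a measurement instrument
with a bias to be characterised. Its inputs are the artifacts any
read-classification pipeline already produces — per-sample read-accounting
totals and taxon tables — plus a Gram annotation; its outputs are
divergence statistics, Gram-stratified dose-response summaries, and
survival-rate contrasts, all validated against a synthetic community whose
ground truth is known exactly.

## Data contracts

All user-facing data are plain tibbles:

* **profile** — `taxon`, `abundance` (percent). A *normalized* profile sums
  to 100 within 1e-6. Taxon identity is the exact name string: no fuzzy
  matching, no rank parsing — silent merges are worse than a failed join.
* **count table** — `taxon`, `count` (non-negative integers). Rows named
  `"Homo sapiens"` (configurable) and `"unclassified"` are reserved: they
  ride along in the table but are routed out of the microbial denominator
  by `as_profile()`.
* **accounting** — `sample_id`, `reads_produced`, `high_quality_reads`,
  `retained_after_host_filter`, with
  `retained ≤ high-quality ≤ produced` enforced.
* **Gram annotation** — `taxon`, `gram ∈ {gram_negative, gram_positive,
  unknown}`. Lookups of unannotated taxa return `unknown`, never an error,
  and unknown mass is reported as its own bucket — prorating it across the
  two known classes would fabricate data.

File dialects (percent vs count) are declared by the caller and never
sniffed: a column of small percentages is indistinguishable from a column
of counts.

Whether unclassified reads belong in the relative-abundance denominator is
a genuine convention choice; the package excludes them by default (profiles
are "percent of classified microbial reads") and exposes
`exclude_unclassified` for the other convention.

## Read-filtering accounting

The host-filtered percentage is
`100 × (high_quality − retained) / high_quality`, rounded **half-up** at
two decimals. Half-up (not banker's) rounding is deliberate: it reproduces
every cell of the published filtering tables bundled with the package
bit-exactly from their count columns, which is what `filtering_table()` is
for. Full float precision is kept internally; rounding happens only at
report time.

`host_reduction()` reports a treated/untreated pair both as an absolute
percentage-point drop and as a reduction relative to the untreated
percentage. Both are reported because summaries in the literature mix the
two framings; the relative form is undefined (NA) when the untreated
percentage is zero.

## The taxonomic variation index

For normalized profiles $a$ and $b$ the TVI is

$$\mathrm{TVI}(a,b) \;=\; \sum_{t \in T_a \cup T_b} \lvert p_t(a) - p_t(b)\rvert,$$

with $p_t = 0$ for a taxon absent from a profile. The absence convention is
forced by the stated range: only if absent taxa contribute their full
abundance on the other side can two disjoint profiles reach the upper
bound of 200. TVI is symmetric, zero exactly on identical profiles,
satisfies the triangle inequality, and equals
$2 \times 100 \times$ Bray–Curtis dissimilarity on the percent vectors —
the test suite cross-checks this against `vegan::vegdist()` on a thousand
random profile pairs.

`compare_profiles()` adds the per-taxon signed deltas and the lost/gained
taxa. The default presence threshold is 0 (any positive abundance counts as
present); published "lost taxa in the 0.5–25.7% range" style statements are
descriptive, not a filter, so the threshold is a parameter rather than a
constant. Lost/gained lists are sorted by descending abundance with
lexicographic tie-break, so reports are deterministic.

## Subsampling comparability

Shallow libraries (a few hundred retained reads) raise the question whether
depth, not treatment, explains a divergence. `subsample_counts()` rarefies
a count table to an exact depth **without replacement** — a multivariate
hypergeometric draw, realised as sequential conditional `rhyper()` draws so
no read-expansion is needed — because a "subset of N reads" selects among
reads that exist. `comparability_check()` repeats the draw, converts each
replicate to a microbial profile, and reports the distribution of TVIs
against the full-depth profile. No pass/fail verdict is attached: the
analyst must judge the noise floor against the effect sizes of interest,
and `end_to_end()` reports the analogous two-independent-draws TVI floor
for the same reason.

## The differential-lysis model

The simulator is the package's ground-truth generator and encodes the
minimal model consistent with a monotone dose–response:

* a community of $n$ bacterial taxa with log-normal absolute DNA copy
  numbers and independent Gram labels, plus a host compartment set as a
  fixed multiple of total bacterial copies;
* **exponential survival in concentration**: at saponin concentration $c$
  (% wt/vol) a compartment of class $g$ retains
  $\exp(-k_g c)$ of its copies. One parameter per class is the smallest
  model that is monotone, continuous, and nests "no effect" ($k=0$); no
  published functional form exists to prefer over it. DNase digestion of
  host DNA is folded into $k_{\mathrm{host}}$, since only the net host
  fraction is observable downstream;
* **multinomial sequencing**: `depth` reads drawn with replacement with
  probabilities proportional to surviving copies. Sequencing *generates*
  reads from an effectively unbounded molecule pool, which is why this step
  is multinomial while the comparability check is hypergeometric — the
  distinction is intentional. An optional misclassification rate reroutes
  bacterial reads to `unclassified`.

Per-taxon rate jitter around the class rate is deliberately off by default
so that class-level recovery has an exact target.

### Default scenario

The defaults are fixed once, to emulate a sputum-like titration
experiment:

| parameter | value | why |
|---|---|---|
| `n_taxa` | 10 | species-level richness of a dominant-taxa sputum profile |
| `gram_neg_fraction` | 0.5 | even prior over classes |
| `host_to_bacteria_ratio` | 0.53/0.47 | ≈53% host reads untreated, matching the untreated sputum filtering row |
| `abundance_spread` | 1.0 (sdlog) | order-of-magnitude abundance range typical of dominant taxa |
| `k_host, k_neg, k_pos` | 2.0, 0.8, 0.05 per % wt/vol | host ≫ Gram-negative > Gram-positive ≈ 0 |
| concentrations | 0, 0.0125, 0.05, 0.1, 0.5, 1.5, 2, 2.5 | the published titration grid plus the standard 2.5% protocol dose |
| `depth` | 1e5 (1e6 in recovery runs) | shallow shotgun scale; 1e6 makes binomial noise negligible for parameter recovery |

With these rates, the expected host share declines strictly with $c$ and
the expected Gram-negative microbial share declines strictly with $c$. At
shallow depth the *empirical* host percentage inherits the strict decline
(the signal dominates binomial noise at every step except the nearly flat
0.0125→0.05 one, where an occasional inversion at the 0.1-point scale is
possible); the empirical Gram-negative share declines in expectation and
monotonically in rank for typical seeds.

## Survival-rate contrasts and identifiability

Relative abundances are compositions: multiplying all copies by a constant
changes nothing observable, so absolute survival rates $k_t$ are not
identifiable from profiles. Ratios survive closure:

$$\log\frac{p_t(c)}{p_{\mathrm{ref}}(c)}
  = \log\frac{a_t}{a_{\mathrm{ref}}} + (k_{\mathrm{ref}} - k_t)\,c,$$

so `survival_contrast()` fits this line per taxon by OLS and returns
$\beta_t = k_{\mathrm{ref}} - k_t$. Any taxon with a zero at any
concentration is dropped (with a warning) rather than pseudocounted:
imputation would bias exactly the taxa the method is about. The estimates
are invariant to per-profile rescaling, which the tests verify directly.
`gram_rate_contrast()` summarises reference-free: median $\beta$ among
Gram-positive taxa minus median among Gram-negative taxa estimates
$k_{\mathrm{neg}} - k_{\mathrm{pos}}$.

Concentration enters every fit on the linear % wt/vol scale — the
untreated arm at $c=0$ makes a log scale impossible, and under the
exponential model it is log-abundance that is linear in $c$. The
dose-response monotonicity statistic is the Spearman rank correlation,
reported descriptively (no p-value) because a titration grid has few
points; with a constant Gram-negative share it is undefined and returned
as NA rather than 0.

## Numerical conventions and degenerate inputs

* Normalization tolerance 1e-6 on the sum; write/read round-trips preserve
  abundances to 1e-9 (values are written with 17 significant digits).
* Unnormalized input to TVI or `compare_profiles()` is an error, not an
  implicit rescale — silent renormalization hides upstream filtering
  mistakes.
* Empty denominators (all reads excluded, all mass dropped) raise typed
  errors (`saponinbias_empty_profile_error`, ...); an empty profile in
  `gram_fractions()` returns zeros with a warning since "no microbial
  reads" is a data outcome, not a usage error.
* All stochastic functions take an optional `seed` and restore the
  caller's RNG state; identical config + seed gives byte-identical
  scenario output.
* A replicate of the comparability check whose subsample contains no
  microbial reads yields NA with a warning — at depth 200 on a
  host-dominated table this is a real possibility, not a bug.

## What the tests do and do not show

The validation strategy is dual-route: every statistic is checked against
an independent implementation or oracle — hand arithmetic for the small
examples, `vegan`'s Bray–Curtis for TVI, a label-expansion `sample()`
oracle for the hypergeometric subsampler, binomial standard errors for the
sequencer, and closed-form constructions plus simulator recovery (10 seeds
at depth 1e6 for the contrast; 200 runs for the null slope; 1000
replicates for the subsampling oracle — sizes chosen so Monte-Carlo error
is well under the tested tolerances) for the estimators.

Passing these tests shows the statistics are computed correctly and that
the estimators recover the generative model they assume. It does not show
that real depletion follows exponential survival in concentration, that
lysis susceptibility is binary in Gram class (it varies by species and
growth phase), or that classifier error is ignorable; the simulator has no
taxon-level rate variation by default, no GC/extraction bias, and no read
misclassification beyond a uniform relabeling rate. Conclusions about a
real protocol should rest on the package's descriptive statistics applied
to that protocol's own treated/untreated pairs.

## Limitations

* Gram annotation is explicit input; the package never infers Gram status
  from taxonomy, so unannotated taxa stay `unknown`.
* Lost-taxon analysis is threshold-based presence/absence; it cannot
  distinguish "lysed away" from "fell below detection at this depth" —
  use the comparability check to bound the latter.
* `survival_contrast()` needs taxa present along the whole series; in
  heavily depleted series this can leave few eligible taxa, and the
  Gram-class contrast then rests on small medians.
* TVI weights all abundance movement equally; it is blind to phylogenetic
  relatedness (no UniFrac-style distances here by design).
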