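# msatabc

Approximate Bayesian Computation (ABC) for demographic inference from
multilocus microsatellite genotypes, built around the question of how the
southern-European grey wolf populations (Italian Peninsula, Iberian
Peninsula, Dinaric regions) acquired their standing genetic variation:
through a deep, late-Pleistocene isolation with bottlenecks, or through
recent anthropogenic collapse.

The package provides, as composable tidyverse-style functions:

* **Scenario models and priors** — four competing histories for three
  populations splitting from a common ancestor (simultaneously or
  sequentially, with or without bottlenecks), uniform priors with
  ordering constraints (`db < t1 < t2`), and executable epoch plans.
* **A structured-coalescent simulator** (Rcpp) with piecewise-constant
  population sizes, the generalized stepwise mutation model
  (Poisson(μb) mutations per branch, geometric step sizes
  P(k) = (1−p)p^(k−1)) and a single-nucleotide-indel overlay that takes
  alleles off the repeat ladder.
* **DIYABC-style summary statistics** — per population: mean number of
  alleles, unbiased genetic diversity n_c/(n_c−1)(1−Σp²), allele-size
  variance; per pair: pooled allele number and diversity, Weir–Cockerham
  θ (ratio of summed variance components), shared-allele distance DAS —
  plus the descriptive A_o/A_e/H_o/H_e/F report and mtDNA statistics
  (indel-aware haplotype collapsing, haplotype diversity
  H = n/(n−1)(1−Σp²), nucleotide diversity
  π = n/(n−1)·Σ 2p_i p_j d_ij / L).
* **The ABC engine** — reference tables, median/MAD-standardized
  rejection, scenario choice by direct composition and weighted
  multinomial logistic regression at the observed point, logit-bounded
  local-linear (Beaumont) parameter adjustment, posterior predictive
  model checking with Bonferroni correction, PCA pre-evaluation, and
  conversions to years (3 years/generation) and bottleneck severity
  ratios R = N_b/N.
* **Synthetic data generators** — pseudo-observed microsatellite datasets
  with stored truth (for recovery and coverage experiments) and mtDNA
  fixtures with exact haplotype structure, so the whole pipeline is
  testable without any external data.

Genepop and FASTA input/output are included; results come back as tibbles
with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

A pseudo-observed dataset at the published posterior medians (39 loci;
samples 39/20/40), against a reference table of 1,000 simulations per
scenario (a fast demonstration; the validation suite uses 10,000):

```r
library(msatabc)
set.seed(1)

po  <- make_pseudo_observed(scenario = 2, n_loci = 39,
                            sample_sizes = c(39, 20, 40))
obs <- summary_vector(po$data)
tab <- build_reference_table(1:4, n_per_scenario = 1000, n_loci = 20,
                             sample_sizes = c(39, 20, 40))

model_choice(tab, obs, fraction = 0.01) |> tidy()
#> # A tibble: 4 × 4
#>   scenario n_retained prob_direct prob_logistic
#>      <int>      <int>       <dbl>         <dbl>
#> 1        1         13       0.325      9.34e- 1
#> 2        2         10       0.25       6.62e- 2
#> 3        3          8       0.2        3.67e-30
#> 4        4          9       0.225      3.19e- 7

post <- estimate_posteriors(tab, obs, scenario = 2, fraction = 0.05)
tidy(post)[tidy(post)$parameter %in% c("t1", "db"), c(1:4, 5)]
#> # A tibble: 2 × 5
#>   parameter median  q050  q950 median_years
#>   <chr>      <dbl> <dbl> <dbl>        <dbl>
#> 1 t1         5923. 3563. 8957.       17768.
#> 2 db         3861. 1757. 8117.       11582.
```

The parameter posteriors behave well: the true divergence and bottleneck
times (6,830 and 5,010 generations, i.e. 20,490 and 15,030 years at
3 years/generation) fall inside the 90% intervals. The scenario choice,
however, lands on the no-bottleneck alternative here — a deliberate
illustration of the method's resolution limits at demonstration scale:
the true history is a *mild* bottleneck (severity ratios 1.9–4.4), the
sequential-bottleneck scenario nests the true one, and at 1,000
simulations per scenario the four prior-predictive clouds overlap
heavily. The methods vignette quantifies this (even at 10,000
simulations per scenario the true scenario is modal in only about half
to two thirds of replicates) and explains which settings sharpen it.
`autoplot(post)` draws the posterior densities;
`model_check(post, obs, ...)` simulates from the fitted posterior and
flags summary statistics the model cannot reproduce;
`autoplot(pca_preevaluation(tab, obs))` shows the observed point inside
the simulated statistic cloud. `run_full_analysis(config, out_dir)` (or
`inst/scripts/run-abc.R` from a shell) chains all of the above and writes
CSV/JSON artifacts stamped with the seed and a config hash.

The mtDNA side works from alignments:

```r
fr  <- make_mtdna_fixture(c(34, 5), region_lengths = c(CR = 498),
                          n_variants = 1)
hap <- collapse_haplotypes(concatenate_regions(fr))
haplotype_diversity(hap)   # 0.2294...  -> 0.229
nucleotide_diversity(hap)  # 0.0004607  -> 0.00046
```

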