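# regevo

Comparative evolution of tissue regulomes from histone-mark ChIP-seq
peaks.

Regulatory regions can be read out of three histone modifications:
H3K4me3 together with H3K27ac marks **active promoters (AP)**, H3K27ac
with H3K4me1 marks **active enhancers (AE)**, and H3K4me1 alone marks
**primed enhancers (PE)**. Given per-replicate peak calls for several
species and tissues, pairwise genome-alignment maps, and repeat
annotation, `regevo`:

* builds reproducible consensus peaks (reciprocal ≥ 50% overlap across
  biological replicates) and calls AP/AE/PE regulomes per species and
  tissue, with exclusion rules that keep the classes base-disjoint;
* classifies tissue specificity and intra-species dynamic signatures
  (promoter ↔ enhancer switching between tissues of one species) and
  associates enhancers to their nearest promoter and promoters to their
  nearest gene TSS (≤ 1 Mb);
* projects regions across species and partitions each regulome as
  *P<sub>A</sub> = P<sub>N</sub> + P<sub>L</sub> + P<sub>M</sub>*
  (unaligned + aligned-without-regulation + maintained), computes the
  maintenance fraction
  ½·(P<sub>M,i→j</sub>/(P<sub>M,i→j</sub>+P<sub>L,i→j</sub>) +
  P<sub>M,j→i</sub>/(P<sub>M,j→i</sub>+P<sub>L,j→i</sub>))·100 per
  signature class, anchors the divergence-zero point with replicate-pair
  reproducibility, and fits per-category linear rates with
  divergence × category interaction tests;
* decomposes maintained 1-to-1 aligned regions by partner signature and
  estimates a row-stochastic 3×3 ancestral→derived transition matrix over
  {AP, AE, PE} from species triads by outgroup parsimony, with df = 2
  chi-square tests against the background outgroup distribution;
* computes transposable-element relative enrichment (the percentage-point
  difference in repeat-subgroup shares between two region sets, e.g.
  tissue-specific vs tissue-shared), LINE age/length comparisons by
  one-sided Wilcoxon tests, and a shuffled-region null for LINE overlap;
* ships a forward simulator of regulome evolution on a phylogeny
  (region loss linear in divergence time, per-MY signature switching,
  replicate jitter/dropout/noise, alignability loss, biased L1/L2
  placement) with recorded ground truth, so the whole pipeline is
  testable without any external download.

Everything is tidyverse-shaped: functions take data frames and return
tibbles, fitted objects have `tidy()`/`glance()`/`autoplot()` methods,
and `run_pipeline()` chains the stages with a hashed artifact manifest.

## Worked example

Simulate a three-species triad (ingroups split 25 MY ago, outgroup at
82 MY) and run the full pipeline:

```r
library(regevo)
sim <- make_fixture("triad", seed = 42)
res <- run_pipeline(pipeline_config(sim, out_dir = "demo_out"), quiet = TRUE)

dplyr::filter(tidy(res$results$rate_fit), grepl("^AP", category))
#> # A tibble: 2 × 6
#>   category           intercept  slope slope_se r_squared n_points
#>   <chr>                  <dbl>  <dbl>    <dbl>     <dbl>    <int>
#> 1 AP_tissue_shared        98.1 -0.233   0.0171     0.995        3
#> 2 AP_tissue_specific      96.1 -0.433   0.0127     0.999        3
```

The fitted promoter loss rates — 0.23 %/MY for tissue-shared and
0.43 %/MY for tissue-specific promoters — recover the simulator's
configured slopes (0.25 and 0.45 %/MY): tissue-specific regions decay
almost twice as fast. The pairwise summaries behind the fit:

```r
ps <- res$results$pair_summary
ps[ps$signature == "AP" & ps$specificity == "tissue_specific",
   c("species_i", "species_j", "divergence_mya", "P_M_i", "P_L_i", "P_N_i",
     "maintenance_fraction_pct")]
#>   species_i species_j divergence_mya P_M_i P_L_i P_N_i maintenance_fraction_pct
#> 1  ingroupA  ingroupB             25   200    33    16                 85.24211
#> 2  ingroupA  outgroup             82   128    87    34                 60.99015
#> 3  ingroupB  outgroup             82   126    89    38                 60.15339
```

At 25 MY about 85% of alignable tissue-specific promoters are still
regulatory in the other species; by 82 MY only about 61% are. The
outgroup-parsimony transition model from the same run:

```r
res$results$transition_model
#> Ancestral -> derived signature transition probabilities
#>       AP    AE    PE
#> AP 0.839 0.077 0.084
#> AE 0.137 0.712 0.151
#> PE 0.073 0.136 0.791
#> Parsimony-resolvable counts per ancestral state: AP=155, AE=139, PE=110
```

Rows sum to one; promoters are the most stable state, and ancestral
enhancers turn into promoters (0.137) more often than the reverse
(0.077). `autoplot()` on the rate fit or the transition model draws the
corresponding figures, and `res$manifest` lists every TSV written to
`demo_out/` with its MD5.

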