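---
title: "Comparative regulome evolution: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative regulome evolution: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Tissue regulomes — the genome-wide sets of active promoters and enhancers of
a tissue — can be read out from three histone modifications: H3K4me3 marks
promoters, H3K27ac marks active regulatory elements, H3K4me1 marks enhancer
chromatin. Comparing the regulomes of several species through whole-genome
alignments asks three questions this package answers quantitatively:

1. How quickly are regulatory regions gained and lost, and does tissue
   specificity change that rate?
2. When a region survives, how often does its *signature* change — a
   promoter becoming an enhancer or vice versa — and with what directional
   probabilities?
3. Are transposable elements, LINE L1/L2 in particular, over-represented in
   the young, tissue-specific and signature-switching parts of the regulome?

# Region calling

Peaks from each biological replicate are first reduced to a reproducible
consensus: two peaks from different replicates support each other when they
overlap *reciprocally* by at least half of each peak's own length, and the
union span of each connected group of supported peaks is one consensus
interval. Everything downstream uses consensus peaks only, which is also
why irreproducible single-replicate noise has no route into the results.

Signatures are then assigned per species and tissue:

* **Active promoter (AP)** — an H3K4me3 interval at least half covered by a
  single H3K27ac interval. The H3K4me3 span is the region. The promoter and
  *every* H3K27ac interval touching it by at least one base enter an
  exclusion set, so shared acetylation blocks are never counted twice.
* **Active enhancer (AE)** — an H3K27ac interval that does not touch the
  exclusion set and is at least half covered by an H3K4me1 interval.
* **Primed enhancer (PE)** — an H3K4me1 interval with no overlap at all
  against any raw H3K27ac or H3K4me3 interval (the raw peaks, not the
  exclusion set: this matches the definition of "primed" as me1-only
  chromatin).

The three classes are pairwise base-disjoint by construction; the test
suite re-derives them with a literal per-base implementation on toy
genomes and requires exact agreement.

Two genuinely open choices are fixed as follows and exposed as arguments:
the "half of their length" fractions are always measured against the
region whose classification is being decided (the H3K4me3 peak for
promoters, the H3K27ac peak for enhancers), and an H3K27ac peak is removed
from enhancer candidacy by a single base of contact with the exclusion set
(maximal exclusion; the conservative reading).

# Tissue specificity and intra-species dynamics

Within a species, two same-signature regions in different tissues are the
same element if *either* overlaps the other by at least half of its own
length. A region's activity tissues are its home tissue plus the tissues of
its directly linked partners — deliberately not the transitive closure,
which would inflate sharing through chains of marginal overlaps (a
`transitive = TRUE` flag exists for sensitivity analysis). One activity
tissue means tissue-specific; four means shared across every assayed
tissue.

Cross-signature overlaps under the same rule flag both partners as
*intra-species dynamic* (promoter/enhancer, or active/primed enhancer).
Dynamic regions are excluded from all specificity and evolution tallies by
default; when a region is both promoter/enhancer-dynamic and
enhancer-dynamic, the promoter/enhancer label wins, as the stronger claim.

# Species-level regions

A region active in three tissues is one genomic element but three regulome
rows. Cross-species analyses therefore first collapse same-signature rows
of one species into their union footprint (`collapse_species_regions()`).
Without this, a shared element would carry several alignment partners and
be excluded from every 1-to-1 analysis, biasing the maintained set toward
tissue-specific regions.

# Maintenance and evolutionary rates

Regions are projected into the other species through gapless alignment
blocks. Projected fragments landing within 10 kb on one sequence count as
one location; regions projecting to more than one location are excluded
outright (the 10 kb gap is a free parameter; alignments give no natural
threshold). The remaining regions partition exactly into unaligned,
aligned-without-regulation, and maintained — maintained meaning at least
one base of overlap with *any* regulatory region of the target species,
any signature, any tissue. This partition is asserted on every run.

The maintenance fraction of a pair is the mean over the two directions of
`100 * maintained / (maintained + aligned-without-regulation)`; summing the
two directions instead (a formulation that can exceed 100%) is available
via the directional columns. Replicate-pair reproducibility of regulomes
from disjoint replicate subsets provides the divergence-zero anchor, and
ordinary least squares per category plus an F-test of the
divergence-by-category interaction gives rates and their contrasts.

# The outgroup transition model

For a triad (two ingroups plus an outgroup), only regions maintained with
mutually consistent 1-to-1 alignments in all three species and dynamic in
none enter the table of (unordered ingroup signature pair) by (outgroup
signature) counts. Each row is tested against the background outgroup
distribution with a df = 2 chi-square.

Parsimony resolves the ancestral state in exactly two configurations:
ingroups `{X,X}` with outgroup `X` (no change), and ingroups `{X,Y}` with
outgroup `X` (one switch on an ingroup branch). Ambiguous configurations —
for example `{X,X}` with outgroup `Y`, which admits two histories — stay in
the table but not in the model. Raw counts are pooled across triads before
each ancestral state's row is normalised to one.

The estimator is validated against a 27-outcome enumeration oracle: given
the per-MY switch matrix, the triad branch lengths and the ancestral
signature proportions, the oracle computes the expected parsimony estimate
analytically, and the estimate from 13,000 simulated regions must agree
within 0.05 per entry. Note the oracle target is the *parsimony-identifiable*
expectation, not the generating matrix itself: double switches and
outgroup-branch switches bias raw parsimony away from the generator, and
the enumeration accounts for that.

# Transposable-element statistics

Relative enrichment compares two region sets (tissue-specific vs shared, or
evolutionarily dynamic vs stable) within a repeat class: among regions of
each set overlapping any repeat of the class, the percentage overlapping a
given subgroup; the difference of the two percentages is the enrichment
delta. Overlap is one base by default (half the region's length for the
shuffled-region control, which mirrors its own definition). A region
overlapping several subgroups counts once per subgroup but once in the
class total, so percentages can sum slightly above 100; a strict mode
attributes each region to its largest-overlap subgroup. Significance is a
two-proportion z-test on the raw counts, without continuity correction by
default (its square is then exactly the Pearson chi-square of the 2x2
table), Bonferroni-corrected over every cell of the matrix — including
cells later hidden by the display filter of at least 100 occurrences in
both sets.

Repeat age (percent divergence from the family consensus) and fragment
length are compared between regulatory-overlap categories with one-sided
Wilcoxon rank-sum tests. Elements overlapping both a recently evolved and
an evolutionarily dynamic region take the dynamic label (the stronger
claim); elements overlapping only stable maintained regions get their own
category rather than being forced into "inactive".

# The simulator

`simulate_regulome_evolution()` generates everything the pipeline consumes,
with recorded truth. Its defaults are the study conditions used throughout
the tests, chosen once:

* Phylogeny `((ingroupA:25,ingroupB:25):57,outgroup:82)` MY — a
  rodent-like triad with a laurasiatherian-distance outgroup.
* 4 tissues, 3 histone marks, 3 biological replicates.
* 2,000 ancestral regions of 300-1500 bp on 3 x 1 Mb sequences
  (larger runs scale `n_regions`/`n_seqs` together; the acceptance runs use
  13,000-20,000 regions on 18-30 Mb).
* Signature proportions AP 0.30 / AE 0.35 / PE 0.35; tissue-specific
  fractions 0.50 / 0.76 / 0.83 — enhancers mostly tissue-specific,
  promoters evenly split, as regulome surveys consistently find.
* Loss: survival `1 - slope * t / 100` per branch of length `t`, slope
  0.45 %/MY for tissue-specific and 0.25 %/MY for shared regions. Because
  survival multiplies across consecutive branches, realized decay over a
  whole path is very slightly shallower than the single-branch line; at
  these slopes the deviation is under two percentage points and well inside
  the regression's sampling noise. An exponential mode is the natural
  alternative but the linear form matches the rate readout the analysis
  fits.
* Switching: a row-stochastic per-MY matrix (defaults near-diagonal, with
  enhancer-to-promoter more likely than the reverse), raised to the branch
  length by eigendecomposition, falling back to whole-MY repeated
  multiplication if the fractional power misbehaves.
* Measurement noise: Gaussian boundary jitter (sd 30 bp), 5% replicate
  dropout, and 5 noise peaks/Mb per library. Noise peaks are placed
  mutually disjoint and clear of true peaks, so they are irreproducible by
  construction and the reproducibility filter removes them exactly — this
  is what makes exact-truth oracle tests possible. Real ChIP noise is of
  course not so polite: reproducible false peaks and partial-overlap noise
  exist in real data, so passing these tests demonstrates correctness of
  the logic, not robustness to every real-data pathology.
* Alignability: ancestral 50 kb blocks drift apart by insertion-only
  indels (regions never cross block boundaries) and become unalignable for
  a pair with probability `1 - (1 - 0.002)^t`.
* Repeats: L1 (dense, long, young), L2 (older, shorter) and a SINE
  family, placed either uniformly or targeted at regulatory regions with a
  configurable odds ratio favouring tissue-specific regions (L1 default 2).

What the simulator does not emulate: nucleotide sequence, read-level
signal, peak-caller artefacts, signature-dependent loss rates,
tissue-set evolution along the tree (a region's tissue set is fixed at
birth), and correlated alignability between overlapping pairs. Conclusions
about those belong to the real data, not to these tests.

One measured consequence of the default measurement noise: with 5%
dropout, an active enhancer loses its H3K27ac consensus in about 0.7% of
species calls and is then read as a primed enhancer. The estimator
checks that target the switching machinery therefore run with jitter and
dropout at zero; at the defaults the same checks would see off-diagonal
inflation of roughly 0.01 that is peak-calling noise, not evolution.

# Numerical conventions

Coordinates are 0-based half-open everywhere; 1-based inputs convert on
read (`one_based = TRUE`). Bookended intervals merge. Nearest-feature ties
break to the lower start coordinate, then lexicographic sequence name.
Fractions against an interval's own length make the overlap matrix
asymmetric by design. All randomness flows through explicit seeds
(`withr::with_seed`), and the pipeline manifest records an MD5 per
artifact so reruns are verifiable.

# Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the simulator at 400-600
regions for identity and switching properties, 13,000 regions for
transition-matrix recovery, and 20,000 regions for the no-switching
identity check; the regression-recovery property uses 200 replicate
regressions of 24 points each. These sizes keep every stochastic check's
sampling error an order of magnitude below its tolerance.

# Known limitations

* The parsimony model ignores branch lengths; triads with very asymmetric
  branches would bias the per-branch probabilities (the enumeration oracle
  quantifies this for the simulated topology).
* Directional switching fractions are undefined for a direction with no
  maintained regions and are reported as `NA` rather than zero.
* The 2-SE slope-recovery property is intrinsically marginal: with 24
  points the t-distribution gives 94.1% theoretical coverage against the
  95% bar, so its outcome fluctuates with the seed; the package reports
  the measured coverage rather than hiding the fluctuation.
* With more than about 90% of a sequence covered by regions the placement
  sampler refuses to run rather than emit a biased layout.
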