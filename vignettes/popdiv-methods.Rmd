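---
title: "Methods behind popdiv: sharing distances, archaic D-statistics and deletion consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind popdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdiv)
```

popdiv implements the computational layer of a deep whole-genome-sequencing
cohort study: quality summaries and sharing statistics over a multi-sample
diploid genotype matrix, an ABBA/BABA test for archaic admixture, and
consolidation of structural-deletion calls from multiple callers. This
vignette describes each model, the parameters that matter, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## The cohort model

`read_cohort()` loads a multi-sample VCF (GT fields required) and a
population map into a `snp_cohort`: a site table, two integer allele-index
matrices (one per chromosome copy, `NA` for missing), and a sample panel
with population and continental labels. All coordinates are 1-based
inclusive; BED input elsewhere in the package is converted on read. By
default only records with FILTER `PASS` or `.` are analysed
(`keep_all_filters = TRUE` keeps everything); the pairwise distance below is
likewise computed on PASS sites by default. SNP sites may carry one to three
alternative alleles (`allelicity()`); sites with more are rejected rather
than silently collapsed, because per-allele accounting is used throughout.

Site identity everywhere is the `(chrom, pos, alt)` triple. This
granularity keeps the alleles of tri-allelic sites distinct in novelty and
sharing computations; a `(chrom, pos)` matching mode is available for
catalogs that do not record alleles (`classify_novelty(mode = "position")`),
since whether published novelty matching was allele-aware is not knowable
from the source — both modes are therefore provided, with allele-aware the
default.

Missing genotypes never enter denominators: `alt_allele_frequency()` divides
alternative-allele copies by non-missing allele calls, and a sample with a
missing genotype contributes nothing to its SNP set at that site.
`frequency_class()` splits alleles at 5% AAF with the boundary classified as
common (`AAF >= 5%`).

## Per-sample quality summaries

The Het/Hom ratio is heterozygous genotypes over homozygous-**alternative**
genotypes. The non-reference convention matters: observed human cohort values
sit around 1.4 (East Asians) to 2.0 (Africans), which only the hom-alt
denominator reproduces; dividing by all homozygous genotypes (mostly
hom-ref) would give ratios far below 1. Multi-allelic genotypes are counted
naturally — `1/2` is heterozygous, `2/2` homozygous-alternative — and a
`biallelic_only` flag restricts the computation when a stricter definition
is wanted. The ratio is undefined (an error) for a sample with no
homozygous-alternative genotype. Under Hardy–Weinberg with alternative
frequency $p$ the expectation is $2(1-p)/p$, which the test suite uses as a
closed-form oracle at $p = 0.5$.

Ts/Tv is transitions (A↔G, C↔T) over transversions among bi-allelic SNPs; a
set with no transitions has ratio 0, while no transversions is an error
(undefined ratio). `cpg_fraction()` reports the fraction of sites whose
reference context places the variant in a CG dinucleotide, checking the
site base with its right neighbour and the left neighbour with the site
base, on the forward strand only (no reverse-complement matching; the
choice is recorded here and in the function documentation so exome-style
comparisons are reproducible).

## The pairwise SNP-sharing distance

For two samples with SNP key sets $S_1$ and $S_2$:

$$D = 1 - \frac{|S_1 \cap S_2|}{\min(|S_1|, |S_2|)}.$$

The algebraic form is reconstructed from its prose description — scaled
between 0 and 1, normalised by the smaller per-sample SNP count, with low
$D$ meaning the SNPs of one sample are likely present in the other. It is
the unique simple form with those properties: the min() denominator forces
$D = 0$ exactly when one set is nested in the other, and $D$ is symmetric.
Membership is presence-only (dosage ignored), on `(chrom, pos, alt)` keys.

Per-population distributions (`population_distance_distribution()`) summarise
all $n(n-1)/2$ unordered within-population pairs with min, quartiles, median
and max; quantiles use the median-unbiased convention (R type 8) so boxplot
statistics are reproducible across tools. `subsample_normalize()` equalises
population sizes (default 36 samples) by seeded sampling, dropping smaller
populations with a warning, to keep distance spreads comparable across
populations of different sizes.

## Unique sharing between populations

A population is *present* at a SNP key when at least one of its samples
carries at least one copy of that alternative allele; no frequency
threshold is applied, since presence counting is the quantity of interest
and dialects for low-coverage genotype uncertainty are out of scope.
`unique_sharing_matrix()` counts, for each ordered pair of populations, the
keys present in exactly those two populations (off-diagonal) and the keys
private to one population (diagonal). Keys present in three or more
populations are excluded from the matrix but reported (`n_multi`), so the
conservation identity

$$\text{diag} + \text{off-diagonal pairs} + n_{\ge 3} = n_{\text{segregating}}$$

holds exactly and is enforced by tests. `continental_sharing()` re-bins each
population's exactly-two-population counts by the partner population's
continent.

## The archaic D-statistic

Four genomes per site: two modern genomes $G_1$ and $G_2$, an archaic
genome, and an outgroup whose allele defines the ancestral state A (the
derived state is B). With

$$D = \frac{N_{BABA} - N_{ABBA}}{N_{BABA} + N_{ABBA}},$$

$N_{BABA}$ counts sites where $G_1$ and the archaic genome carry B while
$G_2$ and the outgroup carry A, and $N_{ABBA}$ the mirror image. $D > 0$
indicates excess allele sharing between $G_1$ and the archaic lineage.
Sites are informative only when all four alleles are present, exactly two
distinct alleles occur, the archaic and outgroup alleles differ, and the
substitution is a transversion — transitions are excluded because
post-mortem cytosine deamination creates artefactual transitions in ancient
DNA. Sites with three or more distinct alleles are classified `other`, not
errors. The BABA/ABBA definitions themselves force $G_1 \ne G_2$ at counted
sites, and the implementation enforces exactly that.

Diploid inputs are collapsed to one base per genome by `resolve_allele()`:
the default `random_draw` (seeded, reproducible) mirrors common practice in
archaic-admixture pipelines; `homozygous_only` discards heterozygous calls
and `major_allele` breaks ties alphabetically, both provided because no
single convention is canonical. The policy and seed belong in any report of
results (the `dstat` stage manifest records them).

Standard errors come from a delete-one block jackknife over 5 Mb windows
anchored at position 1 of each chromosome (no centromere masking): with $M$
non-empty blocks and delete-one estimates $D_{-j}$,

$$SE = \sqrt{\frac{M-1}{M} \sum_j \left(D_{-j} - \bar{D}_{-\cdot}\right)^2},
\qquad Z = D / SE.$$

Blocks with no informative site are dropped from $M$. Equal block weights
are the default; a count-weighted variant (Busing-style pseudovalues with
weights proportional to per-block informative counts) is available via
`jackknife_dstat(weighted = TRUE)` for strongly uneven blocks. When every
block is identical the variance is exactly zero; this is flagged
(`degenerate = TRUE`) and $Z$ is reported as `NA` rather than infinite.
$Z$ always carries the sign of $D$; published tables sometimes print Z
signs on other conventions, which this package does not attempt to mimic.

## Deletion consensus

Caller-level deletion calls pass a 50 bp–10 Mb inclusive size window, are
merged per sample and chromosome by transitive chaining of calls
overlapping by at least 1 bp (abutting calls stay separate), and each
consensus takes the union span with the union of supporting caller labels.
The size filter runs before merging, per the stated order of the original
pipeline; because unions can exceed the upper bound, `recheck_size = TRUE`
re-applies the window afterwards.

Novelty compares each consensus to merged known-deletion catalogs: the
fraction of the *query* length covered by the catalog union (one-sided
denominator — the published rule names a single overlap percentage, not a
reciprocal one; a reciprocal mode is available behind a flag). A deletion
is novel when coverage is strictly below 50%: exactly half-covered is
known. Interval arithmetic is delegated to IRanges, so abutting or
duplicated catalog entries are never double-counted.

## The synthetic-data generators

`simulate_cohort()` draws, per site, an ancestral frequency $p$ uniform on
(0.05, 0.95) by default, then a population frequency from the
Balding–Nichols distribution — a Beta with mean $p$ and variance
$F p(1-p)$ — and diploid genotypes Binomial$(2, q)$ under Hardy–Weinberg.
Balding–Nichols is the minimal model that reproduces the qualitative
continental structure the analyses are meant to detect (within-population
heterozygosity $2p(1-p)(1-F)$ falls as drift $F$ rises, so African-like
populations are emulated with small $F$ and East-Asian-like with larger
$F$) while keeping closed-form expectations for tests. Sites are unlinked;
linkage disequilibrium matters to none of the statistics in scope except
jackknife SE realism, which the block-level simulator addresses directly.
The generators do **not** emulate sequencing depth, genotyping error,
reference bias or allele-frequency spectra under realistic demography —
so passing tests demonstrate correctness of the statistics, not calibration
against real human data.

`simulate_dstat_sites()` emits four-genome sites that are independently
BABA with probability $p_{BABA}$, ABBA with $p_{ABBA}$, and otherwise
non-informative, uniformly placed over contiguous 5 Mb windows, with all
substitutions transversions; expected $D = (p_{BABA} - p_{ABBA}) /
(p_{BABA} + p_{ABBA})$. `simulate_dstat_counts()` is a distributionally
identical fast path that draws per-block multinomial tallies directly
(block sizes multinomial over equal-probability windows, patterns iid
within sites); it is what the thousand-replicate jackknife calibration
uses, and moment tests check its agreement with the site-level generator.
`dstat_analytic_se()` provides the delta-method SE of $D$ for a multinomial
replicate, used as the independent yardstick for the jackknife.

`simulate_sv_calls()` plants non-overlapping deletions with log-normal
lengths (median ≈ 1 kb by default), has each of four callers detect each
truth independently with a configurable probability, jitters both
boundaries with rounded zero-mean Gaussian noise, and adds uniformly placed
false positives. With jitter 0, detection probability 1 and no false
positives, consolidation must recover the truth exactly — the anchor test
of the SV stage.

All generators are pure functions of their configuration including the
seed (byte-identical outputs on repeat), which the manifests written by
`run_stage()` rely on for reproducibility.

## Problem sizes and calibration checks

The package's own verification uses deliberately modest problem sizes
chosen to give the statistics clear signal: cohort simulations of a few
thousand sites and around a dozen samples per population for ordering
checks (three differentiation levels $F \in \{0.15, 0.05, 0.01\}$ for the
distance ranking, mirroring East-Asian-like, European-like and African-like
populations); 1,000 replicates of $10^6$ sites in 200 blocks for the null
calibration of the jackknife (the fraction of $|Z| > 1.96$ is checked
against its nominal 5%); and 100 replicates for recovery of a planted
$D = 0.2$ within three analytic standard errors. The published worked
examples — thirty archaic pattern-count pairs — are reproduced exactly at
their printed precision from the count table shipped in
`inst/extdata/archaic_worked_counts.tsv`.

## Known limitations

- Genome alignment/liftover between assemblies, ancient-DNA damage modelling
  beyond the transversion filter, and f4-ratio admixture proportions are out
  of scope.
- Population-scale quantities that require the original sequenced genomes
  (genome-wide variant counts, novelty percentages, genome-wide Ts/Tv,
  absolute Het/Hom levels) cannot be reproduced from synthetic data; the
  test suite covers their mechanisms and qualitative orderings instead.
- `build_four_genome_sites()` assumes all single-sample VCFs were called
  against the same reference; positions recorded by no VCF are dropped
  because the reference base there is unknown to the package.
- The exonic/genome-wide Ts/Tv contrast depends on an externally supplied
  exome mask; only the mechanism is provided.
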