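# popdiv

Cohort-level population genetics from multi-sample VCFs: who shares which
SNPs, how diverse each population is, how much archaic (Neanderthal /
Denisovan-style) ancestry a genome carries relative to another, and which
structural deletions are real and novel.

popdiv is aimed at analysts of deep whole-genome-sequencing cohorts — the
setting where a few dozen genomes per population are sequenced at high
coverage and the questions are comparative: between-population sharing,
within-population diversity, admixture with archaic hominins, and
multi-caller structural-variant consolidation.

## What it computes

**Per-sample QC** — heterozygous-to-homozygous-alternative genotype ratio
(Het/Hom), transition/transversion ratio (Ts/Tv) over bi-allelic SNPs,
CpG-context fraction against a reference FASTA, alternative-allele
frequencies with a low (<5%) / common (≥5%) split, and novelty against
known-variant catalogs.

**Intra-population diversity** — a pairwise SNP-sharing distance between
samples,

    D = 1 − |S₁ ∩ S₂| / min(|S₁|, |S₂|),

where S₁ and S₂ are the sets of (chrom, pos, alt) SNP keys each sample
carries. D is 0 when one sample's SNPs are nested in the other's and
approaches 1 for disjoint SNP content; per-population boxplot summaries
over all sample pairs quantify diversity, with seeded subsampling to
equalise population sizes.

**Inter-population sharing** — for every segregating SNP allele, the set of
populations carrying it; matrices of alleles shared by exactly two
populations and private alleles, plus continental aggregation.

**Archaic admixture** — the ABBA/BABA D-statistic over four genomes
(G₁, G₂, archaic, outgroup), restricted to bi-allelic transversions,

    D = (N_BABA − N_ABBA) / (N_BABA + N_ABBA),

with standard error and Z score from a delete-one block jackknife over
5 Mb windows. D > 0 means G₁ shares more derived alleles with the archaic
genome than G₂ does.

**Deletion consensus** — multi-caller deletion calls filtered to
50 bp–10 Mb, merged by transitive union of overlapping intervals with
caller evidence tracked, and classified novel when strictly less than 50%
of their length is covered by catalogued deletions.

**Synthetic data** — seeded Balding–Nichols cohort VCFs with per-population
differentiation, four-genome site tables with a planted BABA/ABBA excess,
and multi-caller deletion call sets with boundary jitter, detection
probabilities and false positives. Every analysis input can be generated,
which is how the test suite validates the pipeline end to end.

## Worked example

```r
library(popdiv)

# three populations emulating East-Asian-like, European-like and
# African-like drift levels (F = 0.15, 0.05, 0.01)
d <- tempfile(); dir.create(d)
sim <- simulate_cohort(n_populations = 3, samples_per_pop = 12,
                       n_sites = 4000, fst = c(0.15, 0.05, 0.01),
                       seed = 1, dir = d,
                       pop_labels = c("EAS", "EUR", "AFR"),
                       continent_labels = c("ASN", "EUR", "AFR"))
cohort <- read_cohort(sim$vcf, sim$popmap)
#> snp_cohort: 4000 sites x 36 samples, 3 population(s)

population_het_hom(sample_metrics(cohort))
#>   population n_samples     mean       min        q1    median        q3       max
#> 1        EAS        12 0.873445 0.8196834 0.8515958 0.8816118 0.8879761 0.9240876
#> 2        EUR        12 1.064485 0.9992453 1.0415527 1.0678193 1.0923924 1.1075949
#> 3        AFR        12 1.139154 1.0684615 1.1196943 1.1417201 1.1700372 1.1900958

population_distance_summaries(sample_snp_sets(cohort), cohort$panel)
#>   population n_samples n_pairs       min        q1    median        q3       max
#> 1        EAS        12      66 0.1724138 0.1809404 0.1857010 0.1896454 0.1974498
#> 2        EUR        12      66 0.1882173 0.1988613 0.2025656 0.2072599 0.2108457
#> 3        AFR        12      66 0.1944961 0.2045630 0.2088364 0.2104874 0.2166481
```

Both statistics rank the populations by their simulated drift: the
least-drifted (African-like) population keeps the most heterozygosity
(highest Het/Hom mean, 1.14) and the highest pairwise distances (median
D = 0.209), the most-drifted (East-Asian-like) the least — the qualitative
ordering seen in real human cohorts.

```r
# D-statistic from published pattern counts (an African comparison genome):
dstatistic(73774, 69606, percent = TRUE)
#> [1] 2.906961

# and over a simulated site table with a planted excess (expected D = 20%):
sites <- simulate_dstat_sites(n_sites = 2e5, n_blocks = 100,
                              p_baba = 0.003, p_abba = 0.002, seed = 1)
dstat_analysis(sites)
#>   n_baba n_abba dstat_pct   se_pct       z m_blocks
#> 1    624    392  22.83465 3.316246 6.88569      100
```

The positive percent D (2.91%) reproduces the published value for that
count pair; the simulated analysis recovers the planted 20% excess within
one jackknife standard error and flags it as highly significant.

A stage-oriented interface (`run_stage()`, with a thin Rscript wrapper in
`inst/cli/popdiv.R`) drives the same analyses from file inputs and writes
TSV outputs plus a JSON manifest of parameters and seeds per stage.

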