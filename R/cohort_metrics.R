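# Per-sample and per-population descriptive statistics: Het/Hom ratio,
# Ts/Tv ratio, CpG-context fraction, per-sample variant counts.
#
# Genotype classes (diploid, allele indices a1/a2):
#   missing : either allele missing
#   hom_ref : 0/0
#   het     : a1 != a2 (includes multi-allelic genotypes such as 1/2)
#   hom_alt : a1 == a2 > 0
# The Het/Hom denominator is homozygous-ALTERNATIVE genotypes only; the
# hom-ref convention would give ratios far below the 1.4-2.0 range typical
# of human cohorts.

#' Classify diploid genotypes
#'
#' @param a1,a2 integer allele indices (0 = reference), `NA` = missing.
#' @return character vector in `missing`, `hom_ref`, `het`, `hom_alt`.
#' @export
genotype_class <- function(a1, a2) {
  out <- rep("missing", length(a1))
  ok <- !is.na(a1) & !is.na(a2)
  out[ok & a1 == 0L & a2 == 0L] <- "hom_ref"
  out[ok & a1 != a2] <- "het"
  out[ok & a1 == a2 & a1 > 0L] <- "hom_alt"
  out
}

#' Heterozygous-to-homozygous genotype ratio
#'
#' Count of heterozygous genotypes divided by count of
#' homozygous-alternative genotypes. Undefined (error) when no
#' homozygous-alternative genotype exists.
#'
#' @param n_het,n_hom_alt non-negative counts.
#' @return the ratio.
#' @export
het_hom_ratio <- function(n_het, n_hom_alt) {
  stopifnot(n_het >= 0, n_hom_alt >= 0)
  if (n_hom_alt == 0)
    stop("Het/Hom undefined: no homozygous-alternative genotypes")
  n_het / n_hom_alt
}

#' Per-sample genotype metrics
#'
#' For each sample: heterozygous, homozygous-alternative, homozygous-reference
#' and missing genotype counts over the (by default autosomal SNP) sites,
#' the Het/Hom ratio and the SNP-set size (number of `chrom:pos:alt` keys
#' at which the sample carries at least one alternative allele).
#'
#' @param cohort a `snp_cohort`.
#' @param snps_only restrict to SNP sites (default).
#' @param biallelic_only restrict additionally to bi-allelic SNPs.
#' @return data.frame with columns `sample`, `population`, `n_het`,
#'   `n_hom_alt`, `n_hom_ref`, `n_missing`, `het_hom`, `n_snps`.
#' @export
sample_metrics <- function(cohort, snps_only = TRUE, biallelic_only = FALSE) {
  keep <- if (snps_only) site_is_snp(cohort$sites) else
    rep(TRUE, nrow(cohort$sites))
  if (biallelic_only)
    keep <- keep & !grepl(",", cohort$sites$alt, fixed = TRUE)
  a1 <- cohort$a1[keep, , drop = FALSE]
  a2 <- cohort$a2[keep, , drop = FALSE]
  sets <- sample_snp_sets(cohort, snps_only = snps_only)
  res <- lapply(seq_len(nrow(cohort$panel)), function(j) {
    cls <- genotype_class(a1[, j], a2[, j])
    n_het <- sum(cls == "het"); n_hom_alt <- sum(cls == "hom_alt")
    data.frame(sample = cohort$panel$sample[j],
               population = cohort$panel$population[j],
               n_het = n_het, n_hom_alt = n_hom_alt,
               n_hom_ref = sum(cls == "hom_ref"),
               n_missing = sum(cls == "missing"),
               het_hom = if (n_hom_alt > 0) n_het / n_hom_alt else NA_real_,
               n_snps = length(sets[[j]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Population-level Het/Hom summary
#'
#' Arithmetic mean of the per-sample Het/Hom ratios within each population,
#' plus min/quartiles/max for boxplot display. Quartiles use the
#' median-unbiased convention (`type = 8`).
#'
#' @param metrics data.frame from [sample_metrics()].
#' @return data.frame with one row per population: `population`, `n_samples`,
#'   `mean`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
population_het_hom <- function(metrics) {
  pops <- unique(metrics$population)
  res <- lapply(pops, function(p) {
    x <- metrics$het_hom[metrics$population == p]
    x <- x[!is.na(x)]
    if (length(x) == 0) stop("population '", p, "' has no Het/Hom values")
    q <- quantile(x, c(0, .25, .5, .75, 1), type = 8, names = FALSE)
    data.frame(population = p, n_samples = length(x), mean = mean(x),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Transition/transversion summary for bi-allelic SNPs
#'
#' @param ref,alt character vectors of reference/alternative bases of
#'   bi-allelic SNP sites.
#' @return list with `n_transitions`, `n_transversions`, `ratio`. The ratio
#'   is 0 when there are no transitions; an error is raised when there are
#'   no transversions (ratio undefined).
#' @export
ts_tv_ratio <- function(ref, alt) {
  tv <- is_transversion(ref, alt)
  n_tv <- sum(tv); n_ts <- sum(!tv)
  if (n_tv == 0) stop("Ts/Tv undefined: no transversions observed")
  list(n_transitions = n_ts, n_transversions = n_tv, ratio = n_ts / n_tv)
}

#' Ts/Tv over the bi-allelic SNPs of a cohort
#'
#' @param cohort a `snp_cohort`.
#' @return list as in [ts_tv_ratio()].
#' @export
cohort_ts_tv <- function(cohort) {
  keep <- site_is_snp(cohort$sites) &
    !grepl(",", cohort$sites$alt, fixed = TRUE)
  ts_tv_ratio(cohort$sites$ref[keep], cohort$sites$alt[keep])
}

#' Fraction of variant sites in CpG context
#'
#' A site is in CpG context when its reference base together with the next
#' reference base forms `CG`, or the previous base with the site base forms
#' `CG` (forward strand only, no complementing).
#'
#' @param sites data.frame with columns `chrom`, `pos`.
#' @param fasta_path reference FASTA (names up to first whitespace must
#'   match `chrom` labels).
#' @return list with `n_cpg`, `n_sites`, `fraction`.
#' @export
cpg_fraction <- function(sites, fasta_path) {
  ref <- Biostrings::readDNAStringSet(fasta_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  flags <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]; p <- sites$pos[i]
    if (!ch %in% names(ref)) stop("contig '", ch, "' not in reference")
    len <- Biostrings::width(ref[ch])
    if (p < 1 || p > len)
      stop("site position ", p, " beyond contig '", ch, "' length ", len)
    sq <- ref[[ch]]
    b <- as.character(Biostrings::subseq(sq, p, p))
    nxt <- if (p < len) as.character(Biostrings::subseq(sq, p + 1, p + 1)) else ""
    prv <- if (p > 1) as.character(Biostrings::subseq(sq, p - 1, p - 1)) else ""
    flags[i] <- (b == "C" && nxt == "G") || (prv == "C" && b == "G")
  }
  list(n_cpg = sum(flags), n_sites = length(flags),
       fraction = if (length(flags)) mean(flags) else NA_real_)
}
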