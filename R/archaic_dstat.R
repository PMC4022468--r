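# ABBA/BABA D-statistic between two modern genomes (G1, G2), an archaic
# genome and an outgroup, restricted to bi-allelic transversion
# substitutions, with a delete-one 5 Mb block jackknife for SE and Z.
#
# The outgroup allele defines ancestral state A; the derived state is B.
#   N_BABA : sites where G1 and the archaic genome carry B while G2 and the
#            outgroup carry A
#   N_ABBA : sites where G2 and the archaic genome carry B while G1 and the
#            outgroup carry A
#   D = (N_BABA - N_ABBA) / (N_BABA + N_ABBA), reported x100 as a percent.
# An excess of BABA over ABBA (D > 0) indicates gene flow between G1 and
# the archaic lineage relative to G2. Transitions (A<->G, C<->T) are
# excluded because post-mortem cytosine deamination inflates them in
# ancient DNA.

#' Resolve a diploid genotype to a single allele
#'
#' Archaic-admixture pattern counting needs one base per genome per site;
#' this collapses a diploid call under one of three policies:
#' `random_draw` picks one of the two alleles uniformly (seeded),
#' `homozygous_only` returns missing unless both alleles agree, and
#' `major_allele` breaks heterozygous ties deterministically to the
#' alphabetically first base.
#'
#' @param allele1,allele2 character vectors of single bases (`NA` = missing).
#' @param policy one of `"random_draw"`, `"homozygous_only"`, `"major_allele"`.
#' @param seed integer seed used by `random_draw` (ignored otherwise).
#' @return character vector of resolved bases, `NA` where missing/unresolved.
#' @export
resolve_allele <- function(allele1, allele2,
                           policy = c("random_draw", "homozygous_only",
                                      "major_allele"),
                           seed = 1L) {
  policy <- match.arg(policy)
  miss <- is.na(allele1) | is.na(allele2)
  out <- switch(policy,
    random_draw = withr::with_seed(seed, {
      pick <- runif(length(allele1)) < 0.5
      ifelse(pick, allele1, allele2)
    }),
    homozygous_only = ifelse(allele1 == allele2, allele1, NA_character_),
    major_allele = pmin(allele1, allele2))
  out[miss] <- NA_character_
  out
}

#' Classify four-genome sites into BABA / ABBA / other
#'
#' A site is informative only when all four alleles are present, exactly two
#' distinct alleles occur among them, the archaic and outgroup alleles
#' differ, and the substitution between the two observed alleles is a
#' transversion. `BABA` iff G1 matches the archaic allele and G2 the
#' outgroup; `ABBA` iff G2 matches the archaic allele and G1 the outgroup;
#' everything else (including >2 distinct alleles or transitions) is
#' `other`.
#'
#' @param g1,g2,archaic,outgroup character vectors of single bases
#'   (`NA` = missing).
#' @return character vector in `BABA`, `ABBA`, `other`.
#' @export
classify_pattern <- function(g1, g2, archaic, outgroup) {
  n <- length(g1)
  stopifnot(length(g2) == n, length(archaic) == n, length(outgroup) == n)
  out <- rep("other", n)
  ok <- !(is.na(g1) | is.na(g2) | is.na(archaic) | is.na(outgroup))
  if (!any(ok)) return(out)
  two <- ok
  two[ok] <- vapply(which(ok), function(i)
    length(unique(c(g1[i], g2[i], archaic[i], outgroup[i]))) == 2L,
    logical(1))
  informative <- two & archaic != outgroup
  informative[informative] <-
    is_transversion(archaic[informative], outgroup[informative])
  out[informative & g1 == archaic & g2 == outgroup] <- "BABA"
  out[informative & g2 == archaic & g1 == outgroup] <- "ABBA"
  out
}

#' The D-statistic point estimate
#'
#' @param n_baba,n_abba pattern counts (their sum must be positive).
#' @param percent return the value multiplied by 100.
#' @return signed fraction in \[-1, 1\] (or percent).
#' @examples
#' dstatistic(73774, 69606, percent = TRUE)
#' @export
dstatistic <- function(n_baba, n_abba, percent = FALSE) {
  stopifnot(n_baba >= 0, n_abba >= 0)
  if (n_baba + n_abba == 0)
    stop("D-statistic undefined: no BABA or ABBA sites")
  d <- (n_baba - n_abba) / (n_baba + n_abba)
  if (percent) 100 * d else d
}

#' Partition classified sites into fixed genomic blocks
#'
#' Blocks tile each chromosome from position 1 in non-overlapping windows
#' of `block_size` (default 5 Mb); each site falls in exactly one block.
#' Blocks without any BABA/ABBA site are dropped.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `pattern`
#'   (`BABA`/`ABBA`/`other`), sorted by (chrom, pos).
#' @param block_size block width in bases.
#' @return data.frame with one row per non-empty block: `block_id`, `chrom`,
#'   `start`, `end`, `n_baba`, `n_abba`.
#' @export
block_partition <- function(sites, block_size = 5e6) {
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("sites must be sorted by (chrom, pos)")
  idx <- (sites$pos - 1) %/% block_size
  key <- paste(sites$chrom, idx, sep = "@")
  baba <- tapply(sites$pattern == "BABA", key, sum)
  abba <- tapply(sites$pattern == "ABBA", key, sum)
  parts <- strsplit(names(baba), "@", fixed = TRUE)
  out <- data.frame(
    block_id = names(baba),
    chrom = vapply(parts, `[`, "", 1L),
    start = as.numeric(vapply(parts, `[`, "", 2L)) * block_size + 1,
    n_baba = as.integer(baba), n_abba = as.integer(abba),
    stringsAsFactors = FALSE)
  out$end <- out$start + block_size - 1
  out <- out[out$n_baba + out$n_abba > 0, , drop = FALSE]
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out[, c("block_id", "chrom", "start", "end", "n_baba", "n_abba")]
}

#' Block-jackknife mean, SE and Z of the D-statistic
#'
#' Point estimate from the summed counts; delete-one-block pseudo-estimates
#' give the standard error
#' `SE = sqrt((M-1)/M * sum((D_-j - mean(D_-j))^2))` (equal-weight
#' delete-one), and `Z = D/SE`. A count-weighted variant (block-size
#' weighted pseudovalues, Busing-style) is available with
#' `weighted = TRUE`. Blocks with zero informative sites must already have
#' been dropped ([block_partition()] does this).
#'
#' @param blocks data.frame with columns `n_baba`, `n_abba` (one row per
#'   block; at least 2 blocks).
#' @param weighted use the count-weighted jackknife.
#' @return list with `n_baba`, `n_abba`, `dstat` (fraction), `se`, `z`,
#'   `m_blocks` and `degenerate` (TRUE when the jackknife variance is 0, in
#'   which case `z` is `NA`).
#' @export
jackknife_dstat <- function(blocks, weighted = FALSE) {
  M <- nrow(blocks)
  if (M < 2) stop("block jackknife requires at least 2 non-empty blocks")
  B <- sum(blocks$n_baba); A <- sum(blocks$n_abba)
  d <- dstatistic(B, A)
  leave_b <- B - blocks$n_baba
  leave_a <- A - blocks$n_abba
  tot <- leave_b + leave_a
  if (any(tot == 0))
    stop("a delete-one estimate is undefined: one block holds every site")
  d_minus <- (leave_b - leave_a) / tot
  if (!weighted) {
    se <- sqrt((M - 1) / M * sum((d_minus - mean(d_minus))^2))
  } else {
    # block-weighted delete-one jackknife (weights = informative counts)
    m_j <- blocks$n_baba + blocks$n_abba
    n <- B + A
    h <- n / m_j
    theta_jack <- M * d - sum((1 - m_j / n) * d_minus)
    pseudo <- h * d - (h - 1) * d_minus
    se <- sqrt(sum((pseudo - theta_jack)^2 / (h - 1)) / M)
  }
  degenerate <- se == 0
  list(n_baba = B, n_abba = A, dstat = d, se = se,
       z = if (degenerate) NA_real_ else d / se,
       m_blocks = M, degenerate = degenerate)
}

#' Full D-statistic analysis of a four-genome site table
#'
#' Classifies every site, partitions the informative ones into fixed blocks
#' and runs the block jackknife.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `g1`, `g2`,
#'   `archaic`, `outgroup` (single bases, `NA` = missing), sorted by
#'   (chrom, pos).
#' @param block_size jackknife block width in bases (default 5 Mb).
#' @param weighted use the count-weighted jackknife.
#' @return one-row data.frame: `n_baba`, `n_abba`, `dstat_pct`, `se_pct`,
#'   `z`, `m_blocks`.
#' @export
dstat_analysis <- function(sites, block_size = 5e6, weighted = FALSE) {
  sites$pattern <- classify_pattern(sites$g1, sites$g2,
                                    sites$archaic, sites$outgroup)
  blocks <- block_partition(sites, block_size = block_size)
  jk <- jackknife_dstat(blocks, weighted = weighted)
  data.frame(n_baba = jk$n_baba, n_abba = jk$n_abba,
             dstat_pct = 100 * jk$dstat, se_pct = 100 * jk$se,
             z = jk$z, m_blocks = jk$m_blocks)
}

# read one single-sample VCF into a per-position diploid base table
read_allele_track <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (ncol(gt) != 1) stop("allele-track VCF must be single-sample: ", vcf_path)
  al <- parse_gt_matrix(gt)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  base_of <- function(idx) {
    out <- rep(NA_character_, length(idx))
    for (k in seq_along(idx)) {
      if (is.na(idx[k])) next
      out[k] <- if (idx[k] == 0L) fix$REF[k] else alts[[k]][idx[k]]
    }
    out
  }
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             b1 = base_of(al$a1[, 1]), b2 = base_of(al$a2[, 1]),
             stringsAsFactors = FALSE)
}

#' Join per-genome allele tracks into a four-genome site table
#'
#' Each modern/archaic genome is a single-sample VCF against one shared
#' reference; the outgroup is a TSV of (`chrom`, `pos`, `base`). Sites are
#' the outgroup positions; a genome whose VCF lacks a position is taken as
#' homozygous for the reference allele recorded at that position by any VCF
#' that has it (positions recorded by no VCF are dropped, since the
#' reference base there is unknown). Diploid calls are collapsed with
#' [resolve_allele()].
#'
#' @param g1_vcf,g2_vcf,archaic_vcf single-sample VCF paths.
#' @param outgroup_tsv TSV with header columns `chrom`, `pos`, `base`.
#' @param policy,seed passed to [resolve_allele()].
#' @return data.frame with columns `chrom`, `pos`, `g1`, `g2`, `archaic`,
#'   `outgroup`, sorted by (chrom, pos).
#' @export
build_four_genome_sites <- function(g1_vcf, g2_vcf, archaic_vcf, outgroup_tsv,
                                    policy = "random_draw", seed = 1L) {
  tracks <- list(g1 = read_allele_track(g1_vcf),
                 g2 = read_allele_track(g2_vcf),
                 archaic = read_allele_track(archaic_vcf))
  og <- read.delim(outgroup_tsv, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "base") %in% names(og)))
  key <- function(ch, p) paste(ch, p, sep = ":")
  refmap <- unique(do.call(rbind, lapply(tracks, function(t)
    t[, c("chrom", "pos", "ref")])))
  if (anyDuplicated(key(refmap$chrom, refmap$pos)))
    stop("inconsistent REF alleles between allele-track VCFs")
  out <- og[key(og$chrom, og$pos) %in% key(refmap$chrom, refmap$pos), ,
            drop = FALSE]
  ref_of <- setNames(refmap$ref, key(refmap$chrom, refmap$pos))
  k <- key(out$chrom, out$pos)
  for (nm in names(tracks)) {
    t <- tracks[[nm]]
    tk <- key(t$chrom, t$pos)
    i <- match(k, tk)
    b1 <- ifelse(is.na(i), ref_of[k], t$b1[i])
    b2 <- ifelse(is.na(i), ref_of[k], t$b2[i])
    out[[nm]] <- resolve_allele(b1, b2, policy = policy,
                                seed = seed + match(nm, names(tracks)))
  }
  out$outgroup <- out$base
  out <- out[order(out$chrom, out$pos),
             c("chrom", "pos", "g1", "g2", "archaic", "outgroup")]
  rownames(out) <- NULL
  out
}
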