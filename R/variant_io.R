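# Reading multi-sample VCFs and population maps into the internal
# site/genotype model, plus per-site classifiers (allelicity, AAF,
# frequency class, novelty, transition/transversion).
#
# Internal model: a `snp_cohort` is a list with
#   sites : data.frame(chrom, pos, id, ref, alt, filter_pass) -- alt is a
#           comma-separated string of 1..3 alternative alleles
#   a1,a2 : integer matrices (sites x samples) of allele indices, NA = missing;
#           either both alleles are called or the genotype is missing
#   panel : data.frame(sample, population, continent)
# Coordinates are 1-based inclusive (VCF convention) throughout.

MISSING_GT <- c(".", "./.", ".|.", "./0", "0/.", ".|0", "0|.")

#' Read a population map
#'
#' Three-column TSV (`sample`, `population`, `continent`) with a header.
#' Every sample must map to exactly one population and every population to
#' exactly one continent.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sample`, `population`, `continent`.
#' @export
read_popmap <- function(path) {
  pm <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("sample", "population", "continent")
  if (!all(need %in% names(pm)))
    stop("population map must have columns: ", paste(need, collapse = ", "))
  pm <- pm[, need]
  if (anyDuplicated(pm$sample))
    stop("duplicated sample in population map: ",
         pm$sample[duplicated(pm$sample)][1])
  cpp <- unique(pm[, c("population", "continent")])
  if (anyDuplicated(cpp$population))
    stop("population mapped to more than one continent: ",
         cpp$population[duplicated(cpp$population)][1])
  pm
}

# parse a character matrix of GT strings into two integer allele matrices
parse_gt_matrix <- function(gt) {
  flat <- as.vector(gt)
  flat[is.na(flat)] <- "."
  flat <- sub(":.*$", "", flat)
  miss <- flat %in% MISSING_GT
  ok <- grepl("^[0-9]+[/|][0-9]+$", flat)
  bad <- which(!ok & !miss)
  if (length(bad)) {
    i <- (bad[1] - 1L) %% nrow(gt) + 1L
    j <- (bad[1] - 1L) %/% nrow(gt) + 1L
    stop(sprintf("malformed GT '%s' at site row %d, sample column %d",
                 flat[bad[1]], i, j))
  }
  a1 <- suppressWarnings(as.integer(sub("[/|].*$", "", flat)))
  a2 <- suppressWarnings(as.integer(sub("^.*[/|]", "", flat)))
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  dim(a1) <- dim(gt); dim(a2) <- dim(gt)
  dimnames(a1) <- dimnames(gt); dimnames(a2) <- dimnames(gt)
  list(a1 = a1, a2 = a2)
}

#' Read a multi-sample VCF and population map into a cohort object
#'
#' Parses diploid GT fields, orders sites by (chrom, pos) and keeps samples
#' in VCF header order. By default only records with FILTER `PASS` or `.`
#' are retained. Missing genotypes (`./.`) are preserved as missing.
#'
#' @param vcf_path path to a VCF 4.x file with GT fields.
#' @param popmap_path path to the population map TSV (see [read_popmap()]);
#'   every VCF sample must appear in the map.
#' @param keep_all_filters keep records regardless of FILTER status.
#' @return an object of class `snp_cohort` (see package overview).
#' @export
read_cohort <- function(vcf_path, popmap_path, keep_all_filters = FALSE) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(v@gt)[-1]
  pm <- read_popmap(popmap_path)
  absent <- setdiff(samples, pm$sample)
  if (length(absent))
    stop("sample(s) in VCF absent from population map: ",
         paste(absent, collapse = ", "))
  panel <- pm[match(samples, pm$sample), ]
  rownames(panel) <- NULL

  filt <- fix$FILTER
  filter_pass <- is.na(filt) | filt %in% c("PASS", ".")
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      id = ifelse(is.na(fix$ID), ".", fix$ID),
                      ref = fix$REF, alt = fix$ALT,
                      filter_pass = filter_pass,
                      stringsAsFactors = FALSE)
  keep <- if (keep_all_filters) rep(TRUE, nrow(sites)) else sites$filter_pass
  sites <- sites[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  rownames(sites) <- NULL

  al <- parse_gt_matrix(gt)
  n_alt <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  is_snp <- site_is_snp(sites)
  if (any(is_snp & n_alt > 3))
    stop("SNP site with more than 3 alternative alleles at row ",
         which(is_snp & n_alt > 3)[1])
  amax <- pmax(al$a1, al$a2, na.rm = FALSE)
  over <- which(apply(amax > n_alt, 1, any, na.rm = TRUE))
  if (length(over))
    stop("genotype allele index exceeds ALT count at site row ", over[1])

  a1 <- al$a1; a2 <- al$a2
  dimnames(a1) <- dimnames(a2) <- list(NULL, samples)
  structure(list(sites = sites, a1 = a1, a2 = a2, panel = panel),
            class = "snp_cohort")
}

#' @export
print.snp_cohort <- function(x, ...) {
  cat(sprintf("snp_cohort: %d sites x %d samples, %d population(s)\n",
              nrow(x$sites), nrow(x$panel),
              length(unique(x$panel$population))))
  invisible(x)
}

# split comma-separated ALT strings into a list of allele vectors
alt_list <- function(sites) strsplit(sites$alt, ",", fixed = TRUE)

site_is_snp <- function(sites) {
  nchar(sites$ref) == 1L &
    vapply(alt_list(sites), function(a) all(nchar(a) == 1L), logical(1))
}

#' Classify a SNP site by its number of alternative alleles
#'
#' @param alts character vector of alternative alleles at one site, or a
#'   comma-separated string.
#' @return `"biallelic"`, `"triallelic"` or `"quadallelic"`.
#' @examples
#' allelicity(c("G"))
#' allelicity("G,T")
#' @export
allelicity <- function(alts) {
  if (length(alts) == 1L && grepl(",", alts))
    alts <- strsplit(alts, ",", fixed = TRUE)[[1]]
  if (!all(nchar(alts) == 1L)) stop("allelicity is defined for SNP alleles")
  n <- length(alts)
  if (n < 1L || n > 3L)
    stop("site with ", n, " alternative alleles is not representable ",
         "(1-3 supported)")
  c("biallelic", "triallelic", "quadallelic")[n]
}

#' Alternative allele frequency at one site
#'
#' Counts of each alternative allele divided by the number of non-missing
#' allele calls. Genotypes with any missing allele are excluded from the
#' denominator.
#'
#' @param a1,a2 integer vectors of per-sample allele indices (0 = reference),
#'   `NA` = missing.
#' @param n_alt number of alternative alleles at the site.
#' @return numeric vector of length `n_alt` with AAF per alternative allele.
#' @export
alt_allele_frequency <- function(a1, a2, n_alt = max(c(a1, a2), 1L, na.rm = TRUE)) {
  miss <- is.na(a1) | is.na(a2)
  a1 <- a1[!miss]; a2 <- a2[!miss]
  denom <- 2L * length(a1)
  if (denom == 0L) stop("all genotypes missing: AAF undefined")
  vapply(seq_len(n_alt),
         function(k) (sum(a1 == k) + sum(a2 == k)) / denom, numeric(1))
}

#' Per-site AAF table for a cohort
#'
#' One row per (site, alternative allele); `key` is `chrom:pos:alt`.
#'
#' @param cohort a `snp_cohort`.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `key`, `aaf`,
#'   `class` (`low`/`common` at the default 5% threshold).
#' @param threshold AAF boundary passed to [frequency_class()].
#' @export
site_aaf <- function(cohort, threshold = 0.05) {
  alts <- alt_list(cohort$sites)
  out <- vector("list", nrow(cohort$sites))
  for (i in seq_along(out)) {
    f <- alt_allele_frequency(cohort$a1[i, ], cohort$a2[i, ],
                              n_alt = length(alts[[i]]))
    out[[i]] <- data.frame(chrom = cohort$sites$chrom[i],
                           pos = cohort$sites$pos[i],
                           ref = cohort$sites$ref[i],
                           alt = alts[[i]], aaf = f,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$key <- paste(res$chrom, res$pos, res$alt, sep = ":")
  res$class <- frequency_class(res$aaf, threshold = threshold)
  res[, c("chrom", "pos", "ref", "alt", "key", "aaf", "class")]
}

#' Low-frequency vs common classification of an allele frequency
#'
#' `low` iff `aaf < threshold`; the boundary itself is `common`
#' (AAF >= 5% is common at the default).
#'
#' @param aaf numeric vector of allele frequencies in \[0, 1\].
#' @param threshold boundary (default 0.05).
#' @return character vector of `"low"`/`"common"`.
#' @export
frequency_class <- function(aaf, threshold = 0.05) {
  stopifnot(all(aaf >= 0 & aaf <= 1))
  ifelse(aaf < threshold, "low", "common")
}

#' Site keys of a cohort
#'
#' `chrom:pos:alt` keys, one per (site, alternative allele).
#'
#' @param cohort a `snp_cohort`.
#' @param snps_only restrict to SNP sites.
#' @return character vector of keys.
#' @export
site_keys <- function(cohort, snps_only = TRUE) {
  keep <- if (snps_only) site_is_snp(cohort$sites) else
    rep(TRUE, nrow(cohort$sites))
  s <- cohort$sites[keep, , drop = FALSE]
  alts <- alt_list(s)
  unlist(Map(function(ch, p, a) paste(ch, p, a, sep = ":"),
             rep(s$chrom, lengths(alts)), rep(s$pos, lengths(alts)),
             unlist(alts)), use.names = FALSE)
}

#' Per-sample SNP sets
#'
#' For each sample, the set of `chrom:pos:alt` keys at which it carries at
#' least one copy of that alternative allele. Presence only; dosage is
#' ignored. Missing genotypes contribute nothing.
#'
#' @param cohort a `snp_cohort`.
#' @param snps_only restrict to SNP sites (default).
#' @return named list of character vectors, one per sample.
#' @export
sample_snp_sets <- function(cohort, snps_only = TRUE) {
  keep <- if (snps_only) site_is_snp(cohort$sites) else
    rep(TRUE, nrow(cohort$sites))
  s <- cohort$sites[keep, , drop = FALSE]
  a1 <- cohort$a1[keep, , drop = FALSE]
  a2 <- cohort$a2[keep, , drop = FALSE]
  alts <- alt_list(s)
  samples <- cohort$panel$sample
  res <- vector("list", length(samples))
  names(res) <- samples
  for (j in seq_along(samples)) {
    keys <- character(0)
    for (k in seq_len(max(lengths(alts)))) {
      hit <- which((a1[, j] %in% k) | (a2[, j] %in% k))
      hit <- hit[lengths(alts)[hit] >= k]
      if (length(hit))
        keys <- c(keys, paste(s$chrom[hit], s$pos[hit],
                              vapply(alts[hit], `[`, "", k), sep = ":"))
    }
    res[[j]] <- sort(unique(keys))
  }
  res
}

#' Read a known-variant catalog
#'
#' Accepts a VCF (keys built from CHROM/POS/ALT, multi-allelic records
#' expanded) or a TSV with columns `chrom`, `pos` and optionally `alt`.
#'
#' @param path catalog file path.
#' @param mode `"allele"` for (chrom,pos,alt) keys or `"position"` for
#'   (chrom,pos) keys.
#' @return character vector of keys.
#' @export
read_catalog <- function(path, mode = c("allele", "position")) {
  mode <- match.arg(mode)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    if (mode == "position")
      return(unique(paste(fix$CHROM, fix$POS, sep = ":")))
    return(unique(unlist(Map(function(ch, p, a) paste(ch, p, a, sep = ":"),
                             rep(fix$CHROM, lengths(alts)),
                             rep(fix$POS, lengths(alts)), unlist(alts)),
                          use.names = FALSE)))
  }
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(tab)))
    stop("catalog TSV must have columns chrom, pos (and optionally alt)")
  if (mode == "allele") {
    if (!"alt" %in% names(tab))
      stop("allele-mode catalog TSV requires an alt column")
    unique(paste(tab$chrom, tab$pos, tab$alt, sep = ":"))
  } else {
    unique(paste(tab$chrom, tab$pos, sep = ":"))
  }
}

#' Classify site keys as known or novel against catalogs
#'
#' A site is `novel` iff it is absent from the union of all catalogs.
#'
#' @param keys character vector of `chrom:pos:alt` site keys.
#' @param catalogs list of character vectors of catalog keys (allele- or
#'   position-mode, see `mode`).
#' @param mode `"allele"` matches on (chrom,pos,alt); `"position"` matches
#'   on (chrom,pos) only.
#' @return character vector of `"known"`/`"novel"`, one per key.
#' @export
classify_novelty <- function(keys, catalogs, mode = c("allele", "position")) {
  mode <- match.arg(mode)
  universe <- unique(unlist(catalogs, use.names = FALSE))
  q <- if (mode == "position") sub("^([^:]+:[^:]+).*$", "\\1", keys) else keys
  ifelse(q %in% universe, "known", "novel")
}

#' Is a substitution a transversion?
#'
#' Transitions are A<->G and C<->T; every other base change is a
#' transversion. Symmetric in its arguments.
#'
#' @param ref_base,alt_base single bases in `A`, `C`, `G`, `T` (vectorized).
#' @return logical vector.
#' @export
is_transversion <- function(ref_base, alt_base) {
  bases <- c("A", "C", "G", "T")
  if (!all(ref_base %in% bases) || !all(alt_base %in% bases))
    stop("non-ACGT base in transversion test")
  purine <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  unname(purine[ref_base] != purine[alt_base])
}

#' Write the cohort site table to TSV
#'
#' @param cohort a `snp_cohort`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(cohort, path) {
  gt <- matrix(paste(cohort$a1, cohort$a2, sep = "/"),
               nrow = nrow(cohort$sites))
  gt[is.na(cohort$a1) | is.na(cohort$a2)] <- "./."
  colnames(gt) <- cohort$panel$sample
  out <- cbind(cohort$sites, as.data.frame(gt, stringsAsFactors = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site table written by [write_site_table()]
#'
#' @param path TSV path.
#' @param popmap_path population map TSV for the panel.
#' @return a `snp_cohort`.
#' @export
read_site_table <- function(path, popmap_path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  fixed_cols <- c("chrom", "pos", "id", "ref", "alt", "filter_pass")
  samples <- setdiff(names(tab), fixed_cols)
  sites <- data.frame(chrom = tab$chrom, pos = as.integer(tab$pos),
                      id = tab$id, ref = tab$ref, alt = tab$alt,
                      filter_pass = as.logical(tab$filter_pass),
                      stringsAsFactors = FALSE)
  gt <- as.matrix(tab[, samples, drop = FALSE])
  pm <- read_popmap(popmap_path)
  absent <- setdiff(samples, pm$sample)
  if (length(absent))
    stop("sample(s) in site table absent from population map: ",
         paste(absent, collapse = ", "))
  panel <- pm[match(samples, pm$sample), ]
  rownames(panel) <- NULL
  al <- parse_gt_matrix(gt)
  a1 <- al$a1; a2 <- al$a2
  dimnames(a1) <- dimnames(a2) <- list(NULL, samples)
  structure(list(sites = sites, a1 = a1, a2 = a2, panel = panel),
            class = "snp_cohort")
}
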