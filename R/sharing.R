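# Inter-population unique sharing: for every segregating SNP allele, the set
# of populations carrying it; counts of SNPs shared by exactly two
# populations, private SNPs, and continental aggregation of the
# exactly-two-population sharing.

#' Population presence profiles of segregating SNP alleles
#'
#' A population is "present" at a `chrom:pos:alt` key iff at least one of
#' its samples carries at least one copy of that alternative allele (no
#' frequency threshold). Monomorphic-reference keys (carried by no sample)
#' are excluded.
#'
#' @param cohort a `snp_cohort`.
#' @param snps_only restrict to SNP sites (default).
#' @return data.frame with columns `key`, `populations` (comma-separated,
#'   sorted), `n_populations`.
#' @export
presence_profiles <- function(cohort, snps_only = TRUE) {
  sets <- sample_snp_sets(cohort, snps_only = snps_only)
  pop_of <- setNames(cohort$panel$population, cohort$panel$sample)
  key_pop <- unique(data.frame(
    key = unlist(sets, use.names = FALSE),
    population = rep(pop_of[names(sets)], lengths(sets)),
    stringsAsFactors = FALSE))
  if (nrow(key_pop) == 0)
    return(data.frame(key = character(0), populations = character(0),
                      n_populations = integer(0), stringsAsFactors = FALSE))
  sp <- split(key_pop$population, key_pop$key)
  pops <- vapply(sp, function(p) paste(sort(unique(p)), collapse = ","), "")
  data.frame(key = names(sp), populations = unname(pops),
             n_populations = unname(vapply(sp, function(p)
               length(unique(p)), integer(1))),
             stringsAsFactors = FALSE)
}

#' Unique-sharing matrix between populations
#'
#' Square symmetric count matrix over the panel's populations: off-diagonal
#' entry (i, j) is the number of SNP alleles present in exactly the two
#' populations i and j; diagonal entry (i, i) is the number private to i.
#' Alleles present in three or more populations are counted in neither but
#' reported in the `n_multi` attribute.
#'
#' @param profiles data.frame from [presence_profiles()].
#' @param panel cohort panel data.frame (fixes population order).
#' @return integer matrix with attributes `n_multi` (number of keys present
#'   in >= 3 populations) and `n_segregating` (total profiled keys).
#' @export
unique_sharing_matrix <- function(profiles, panel) {
  pops <- unique(panel$population)
  m <- matrix(0L, length(pops), length(pops), dimnames = list(pops, pops))
  singles <- profiles$populations[profiles$n_populations == 1L]
  t1 <- table(factor(singles, levels = pops))
  diag(m) <- as.integer(t1)
  duos <- profiles$populations[profiles$n_populations == 2L]
  if (length(duos)) {
    t2 <- table(duos)
    for (nm in names(t2)) {
      pq <- strsplit(nm, ",", fixed = TRUE)[[1]]
      m[pq[1], pq[2]] <- m[pq[1], pq[2]] + as.integer(t2[[nm]])
      m[pq[2], pq[1]] <- m[pq[2], pq[1]] + as.integer(t2[[nm]])
    }
  }
  attr(m, "n_multi") <- sum(profiles$n_populations >= 3L)
  attr(m, "n_segregating") <- nrow(profiles)
  m
}

#' Continental aggregation of exactly-two-population sharing
#'
#' For each reference population, its exactly-two-population shared SNP
#' counts binned by the partner population's continent.
#'
#' @param profiles data.frame from [presence_profiles()].
#' @param panel cohort panel data.frame with a `continent` column.
#' @return integer matrix, populations x continents.
#' @export
continental_sharing <- function(profiles, panel) {
  pops <- unique(panel$population)
  conts <- unique(panel$continent)
  cont_of <- setNames(panel$continent[match(pops, panel$population)], pops)
  m <- matrix(0L, length(pops), length(conts), dimnames = list(pops, conts))
  duos <- profiles$populations[profiles$n_populations == 2L]
  if (length(duos)) {
    t2 <- table(duos)
    for (nm in names(t2)) {
      pq <- strsplit(nm, ",", fixed = TRUE)[[1]]
      n <- as.integer(t2[[nm]])
      m[pq[1], cont_of[[pq[2]]]] <- m[pq[1], cont_of[[pq[2]]]] + n
      m[pq[2], cont_of[[pq[1]]]] <- m[pq[2], cont_of[[pq[1]]]] + n
    }
  }
  m
}
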