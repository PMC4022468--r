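# Intra-population diversity: the pairwise SNP-sharing distance
#
#   D = 1 - |S1 intersect S2| / min(|S1|, |S2|)
#
# between the SNP sets of two samples, scaled to [0, 1]. A low D means the
# SNPs of the smaller set are largely contained in the other sample, i.e.
# high sharing; D = 0 exactly when one set is nested in the other. This
# min-normalised form follows the statistic's prose definition: the
# denominator is the smaller of the two per-sample SNP counts.

#' Pairwise SNP-sharing distance between two samples
#'
#' @param s1,s2 character vectors of `chrom:pos:alt` site keys (the per-sample
#'   SNP sets, see [sample_snp_sets()]); both must be non-empty.
#' @return list with `n_a`, `n_b`, `n_shared` and the distance `d`.
#' @examples
#' pairwise_d(c("1:5:A", "1:9:T"), c("1:5:A", "1:9:T", "2:3:G"))$d  # nested: 0
#' @export
pairwise_d <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  if (length(s1) == 0 || length(s2) == 0)
    stop("pairwise distance undefined for an empty SNP set")
  n_shared <- sum(s1 %in% s2)
  list(n_a = length(s1), n_b = length(s2), n_shared = n_shared,
       d = 1 - n_shared / min(length(s1), length(s2)))
}

#' All pairwise distances within (or across) populations
#'
#' @param snp_sets named list of per-sample SNP key sets.
#' @param panel cohort panel data.frame (`sample`, `population`, `continent`);
#'   optional -- without it all sample pairs are computed and the population
#'   columns are `NA`.
#' @param within_only keep only pairs from the same population.
#' @return data.frame with one row per unordered pair: `sample_a`, `sample_b`,
#'   `population_a`, `population_b`, `n_a`, `n_b`, `n_shared`, `d`.
#' @export
pairwise_distances <- function(snp_sets, panel = NULL, within_only = FALSE) {
  samples <- names(snp_sets)
  if (length(samples) < 2) stop("need at least two samples")
  pop <- if (is.null(panel)) setNames(rep(NA_character_, length(samples)), samples)
         else setNames(panel$population, panel$sample)
  idx <- combn(length(samples), 2)
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    if (within_only && !identical(pop[[samples[i]]], pop[[samples[j]]]))
      return(NULL)
    pd <- pairwise_d(snp_sets[[i]], snp_sets[[j]])
    data.frame(sample_a = samples[i], sample_b = samples[j],
               population_a = pop[[samples[i]]],
               population_b = pop[[samples[j]]],
               n_a = pd$n_a, n_b = pd$n_b, n_shared = pd$n_shared, d = pd$d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distribution of the pairwise distance within one population
#'
#' Five-number summary (min, quartiles, max; median-unbiased quantiles,
#' `type = 8`) over all unordered within-population pairs, as displayed in
#' per-population boxplots, plus the per-pair table.
#'
#' @param snp_sets named list of per-sample SNP key sets.
#' @param panel cohort panel data.frame.
#' @param population population label (must have >= 2 samples).
#' @return list with `summary` (one-row data.frame: `population`, `n_samples`,
#'   `n_pairs`, `min`, `q1`, `median`, `q3`, `max`) and `pairs` (per-pair
#'   data.frame from [pairwise_distances()]).
#' @export
population_distance_distribution <- function(snp_sets, panel, population) {
  samples <- panel$sample[panel$population == population]
  if (length(samples) < 2)
    stop("population '", population, "' has fewer than 2 samples")
  pairs <- pairwise_distances(snp_sets[samples],
                              panel[panel$sample %in% samples, ])
  stopifnot(nrow(pairs) == length(samples) * (length(samples) - 1) / 2)
  q <- quantile(pairs$d, c(0, .25, .5, .75, 1), type = 8, names = FALSE)
  list(summary = data.frame(population = population,
                            n_samples = length(samples),
                            n_pairs = nrow(pairs),
                            min = q[1], q1 = q[2], median = q[3],
                            q3 = q[4], max = q[5],
                            stringsAsFactors = FALSE),
       pairs = pairs)
}

#' Distance summaries for every population in a panel
#'
#' @param snp_sets named list of per-sample SNP key sets.
#' @param panel cohort panel data.frame.
#' @return data.frame with one summary row per population with >= 2 samples.
#' @export
population_distance_summaries <- function(snp_sets, panel) {
  pops <- unique(panel$population)
  pops <- pops[vapply(pops, function(p) sum(panel$population == p) >= 2,
                      logical(1))]
  do.call(rbind, lapply(pops, function(p)
    population_distance_distribution(snp_sets, panel, p)$summary))
}

#' Equalise population sizes by random subsampling
#'
#' Reduces every population to exactly `n` samples by seeded random
#' selection; populations with fewer than `n` samples are dropped with a
#' warning. Deterministic given `seed`.
#'
#' @param panel cohort panel data.frame.
#' @param n target samples per population (default 36).
#' @param seed integer RNG seed.
#' @return reduced panel data.frame.
#' @export
subsample_normalize <- function(panel, n = 36, seed = 1L) {
  if (n < 2) stop("subsample size must be at least 2")
  counts <- table(panel$population)
  drop <- names(counts)[counts < n]
  if (length(drop))
    warning("dropping population(s) with fewer than ", n, " samples: ",
            paste(drop, collapse = ", "))
  keep_pops <- setdiff(names(counts), drop)
  withr::with_seed(seed, {
    kept <- unlist(lapply(keep_pops, function(p) {
      s <- panel$sample[panel$population == p]
      if (length(s) == n) s else sample(s, n)
    }))
  })
  out <- panel[panel$sample %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}
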