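# Seeded generators for every input the pipeline consumes:
#   - multi-population diploid genotype VCFs under the Balding-Nichols
#     model (population allele frequency ~ Beta with mean p and variance
#     F*p*(1-p); genotypes Binomial(2, q) under Hardy-Weinberg),
#   - four-genome site tables with tunable BABA/ABBA excess,
#   - multi-caller deletion call sets with boundary jitter, per-caller
#     detection probability and false positives, plus ground truth.
# All generators are pure functions of their arguments (seed included).

# Balding-Nichols population frequency draw; F ~ 0 degenerates to q = p
rbalding_nichols <- function(n, p, F) {
  if (any(F < 0) || any(F >= 1)) stop("differentiation F must be in [0, 1)")
  q <- ifelse(rep(F, length.out = n) < 1e-12, p,
              rbeta(n, p * (1 - F) / F, (1 - p) * (1 - F) / F))
  pmin(pmax(q, 0), 1)
}

# minimal VCF 4.2 writer for bi-allelic SNP genotype matrices
write_vcf <- function(path, chrom, pos, ref, alt, gt, samples,
                      contig_len = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popdiv-simulator",
           sprintf("##contig=<ID=%s%s>", unique(chrom),
                   if (is.null(contig_len)) "" else
                     paste0(",length=", contig_len)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a multi-population genotype cohort (Balding-Nichols)
#'
#' Per site, an ancestral allele frequency `p` is drawn uniformly from
#' `ancestral_freq_range`; each population's frequency comes from the
#' Balding-Nichols distribution (Beta with mean `p`, variance
#' `F * p * (1-p)`; its own `F` per population), and diploid genotypes are
#' `Binomial(2, q)` under Hardy-Weinberg. Reference/alternative bases are
#' drawn uniformly over distinct base pairs. Deterministic (byte-identical
#' files) given `seed`.
#'
#' @param n_populations number of populations.
#' @param samples_per_pop samples per population (scalar or vector).
#' @param n_sites number of bi-allelic SNP sites.
#' @param fst per-population differentiation parameter in \[0, 1) (scalar
#'   or vector of length `n_populations`).
#' @param ancestral_freq_range interval within (0, 1) for the ancestral
#'   frequency draw.
#' @param seed integer RNG seed.
#' @param dir output directory; when non-NULL a VCF (`cohort.vcf`) and a
#'   population map (`popmap.tsv`) are written there.
#' @param chrom chromosome label used for every site.
#' @param pop_labels,continent_labels labels for the generated populations.
#' @return list with `vcf`, `popmap` (paths or NA), `panel`, `sites`
#'   (data.frame incl. the per-population truth frequencies) and `gt`
#'   (genotype string matrix).
#' @export
simulate_cohort <- function(n_populations = 3, samples_per_pop = 12,
                            n_sites = 1000, fst = 0.05,
                            ancestral_freq_range = c(0.05, 0.95),
                            seed = 1L, dir = NULL, chrom = "1",
                            pop_labels = paste0("POP", seq_len(n_populations)),
                            continent_labels = pop_labels) {
  stopifnot(length(ancestral_freq_range) == 2,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2])
  if (any(fst < 0) || any(fst >= 1)) stop("differentiation F must be in [0, 1)")
  fst <- rep(fst, length.out = n_populations)
  spp <- rep(samples_per_pop, length.out = n_populations)
  samples <- unlist(lapply(seq_len(n_populations), function(i)
    sprintf("%s_S%02d", pop_labels[i], seq_len(spp[i]))))
  panel <- data.frame(
    sample = samples,
    population = rep(pop_labels, spp),
    continent = rep(rep(continent_labels, length.out = n_populations), spp),
    stringsAsFactors = FALSE)

  withr::with_seed(seed, {
    p_anc <- runif(n_sites, ancestral_freq_range[1], ancestral_freq_range[2])
    q <- vapply(seq_len(n_populations), function(i)
      rbalding_nichols(n_sites, p_anc, fst[i]), numeric(n_sites))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    gt <- matrix("", n_sites, nrow(panel))
    for (i in seq_len(n_populations)) {
      cols <- which(panel$population == pop_labels[i])
      for (j in cols) {
        dose <- rbinom(n_sites, 2, q[, i])
        gt[, j] <- c("0/0", "0/1", "1/1")[dose + 1L]
      }
    }
  })
  pos <- seq_len(n_sites) * 100L
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
                      p_ancestral = p_anc, stringsAsFactors = FALSE)
  for (i in seq_len(n_populations)) sites[[paste0("q_", pop_labels[i])]] <- q[, i]

  vcf_path <- popmap_path <- NA_character_
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    vcf_path <- file.path(dir, "cohort.vcf")
    popmap_path <- file.path(dir, "popmap.tsv")
    write_vcf(vcf_path, sites$chrom, sites$pos, sites$ref, sites$alt,
              gt, panel$sample, contig_len = max(pos) + 100L)
    write.table(panel, popmap_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(vcf = vcf_path, popmap = popmap_path, panel = panel, sites = sites,
       gt = gt)
}

#' Simulate a four-genome site table with tunable BABA/ABBA excess
#'
#' Each site is independently a BABA pattern with probability `p_baba`, an
#' ABBA pattern with `p_abba`, and otherwise non-informative (all four
#' genomes share the outgroup allele except the archaic genome). Sites are
#' placed uniformly over `n_blocks` contiguous windows of `block_size` on
#' one chromosome; all emitted substitutions are transversions. The
#' expected D-statistic is `(p_baba - p_abba) / (p_baba + p_abba)`.
#'
#' @param n_sites number of sites.
#' @param n_blocks number of contiguous windows spanned.
#' @param p_baba,p_abba pattern probabilities (`p_baba + p_abba < 1`).
#' @param seed integer RNG seed.
#' @param block_size window width in bases (default 5 Mb).
#' @param chrom chromosome label.
#' @return data.frame with columns `chrom`, `pos`, `g1`, `g2`, `archaic`,
#'   `outgroup`, sorted by position.
#' @export
simulate_dstat_sites <- function(n_sites, n_blocks, p_baba, p_abba,
                                 seed = 1L, block_size = 5e6, chrom = "1") {
  stopifnot(p_baba >= 0, p_abba >= 0)
  if (p_baba + p_abba >= 1)
    stop("p_baba + p_abba must be below 1")
  tv_pairs <- rbind(c("A", "C"), c("A", "T"), c("C", "A"), c("C", "G"),
                    c("G", "C"), c("G", "T"), c("T", "A"), c("T", "G"))
  withr::with_seed(seed, {
    pos <- sort(sample.int(n_blocks * block_size, n_sites))
    u <- runif(n_sites)
    pat <- ifelse(u < p_baba, "BABA",
                  ifelse(u < p_baba + p_abba, "ABBA", "other"))
    pair <- tv_pairs[sample.int(nrow(tv_pairs), n_sites, replace = TRUE), ,
                     drop = FALSE]
  })
  a <- pair[, 1]; b <- pair[, 2]  # a = outgroup/ancestral, b = derived
  g1 <- ifelse(pat == "BABA", b, a)
  g2 <- ifelse(pat == "ABBA", b, a)
  archaic <- b  # archaic always carries the derived allele
  # non-informative sites: G1 = G2 = outgroup = a, archaic = b -> "other"
  data.frame(chrom = chrom, pos = pos, g1 = g1, g2 = g2,
             archaic = archaic, outgroup = a, stringsAsFactors = FALSE)
}

#' Simulate per-block BABA/ABBA tallies directly
#'
#' Fast path distributionally identical to classifying and block-partitioning
#' [simulate_dstat_sites()] output: site counts per block are multinomial
#' over equal-probability blocks and patterns are iid within sites. Used for
#' large replicate studies of the jackknife.
#'
#' @inheritParams simulate_dstat_sites
#' @return data.frame with one row per non-empty block: `block_id`,
#'   `n_baba`, `n_abba`.
#' @export
simulate_dstat_counts <- function(n_sites, n_blocks, p_baba, p_abba,
                                  seed = 1L) {
  stopifnot(p_baba >= 0, p_abba >= 0)
  if (p_baba + p_abba >= 1) stop("p_baba + p_abba must be below 1")
  withr::with_seed(seed, {
    m <- as.integer(rmultinom(1, n_sites, rep(1 / n_blocks, n_blocks)))
    baba <- rbinom(n_blocks, m, p_baba)
    abba <- rbinom(n_blocks, m - baba, p_abba / (1 - p_baba))
  })
  out <- data.frame(block_id = seq_len(n_blocks), n_baba = baba,
                    n_abba = abba)
  out[out$n_baba + out$n_abba > 0, , drop = FALSE]
}

#' Analytic (delta-method) SE of the simulated D-statistic
#'
#' For counts `X ~ multinomial(n, (p_baba, p_abba, rest))` and
#' `D = (X_baba - X_abba) / (X_baba + X_abba)`, the first-order variance of
#' D around its expectation.
#'
#' @inheritParams simulate_dstat_sites
#' @return standard error of D for one replicate of `n_sites` sites.
#' @export
dstat_analytic_se <- function(n_sites, p_baba, p_abba) {
  s <- p_baba + p_abba
  eb <- n_sites * p_baba; ea <- n_sites * p_abba; es <- n_sites * s
  db <- 2 * ea / es^2   # dD/dX_baba at expectation
  da <- -2 * eb / es^2  # dD/dX_abba
  vb <- n_sites * p_baba * (1 - p_baba)
  va <- n_sites * p_abba * (1 - p_abba)
  cab <- -n_sites * p_baba * p_abba
  sqrt(db^2 * vb + da^2 * va + 2 * db * da * cab)
}

#' Simulate multi-caller deletion call sets with ground truth
#'
#' True deletions are placed without overlap on one chromosome with
#' log-normal lengths; each caller reports each truth independently with
#' its detection probability, with both boundaries jittered by rounded
#' zero-mean Gaussian draws; false positives are placed uniformly.
#'
#' @param n_true_deletions number of planted deletions.
#' @param genome_length chromosome length in bases.
#' @param length_meanlog,length_sdlog log-normal length parameters
#'   (defaults give a median around 1 kb).
#' @param boundary_jitter_sd per-boundary jitter SD in bases (0 = exact).
#' @param detection_prob per-caller detection probability (scalar or one
#'   per caller).
#' @param n_false_positives expected false positives per caller.
#' @param callers caller labels.
#' @param seed integer RNG seed.
#' @param min_len,max_len length window for planted truths.
#' @return list with `truth` (data.frame `chrom`, `start`, `end`) and
#'   `calls` (data.frame `chrom`, `start`, `end`, `caller`, `sample`,
#'   `is_false_positive`, `truth_id`).
#' @export
simulate_sv_calls <- function(n_true_deletions = 50, genome_length = 1e7,
                              length_meanlog = log(1000), length_sdlog = 0.8,
                              boundary_jitter_sd = 0, detection_prob = 0.9,
                              n_false_positives = 0,
                              callers = c("breakdancer", "variationhunter",
                                          "pindel", "delly"),
                              seed = 1L, min_len = 50, max_len = 1e7,
                              chrom = "1", sample_id = "S1") {
  stopifnot(boundary_jitter_sd >= 0,
            all(detection_prob >= 0 & detection_prob <= 1))
  detection_prob <- rep(detection_prob, length.out = length(callers))
  withr::with_seed(seed, {
    lens <- pmin(pmax(round(rlnorm(n_true_deletions, length_meanlog,
                                   length_sdlog)), min_len), max_len)
    # non-overlapping placement: partition the slack uniformly between gaps
    slack <- genome_length - sum(lens) - n_true_deletions  # >= 1 bp gaps
    if (slack < 0)
      stop("genome too small to place ", n_true_deletions,
           " non-overlapping deletions")
    gaps <- if (n_true_deletions > 0) {
      cuts <- sort(sample.int(slack + 1, n_true_deletions, replace = TRUE)) - 1
      diff(c(0, cuts)) + 1  # >= 1 bp between consecutive deletions
    } else integer(0)
    starts <- cumsum(gaps) + c(0, cumsum(lens[-n_true_deletions]))
    truth <- data.frame(chrom = chrom, start = starts + 1,
                        end = starts + lens, stringsAsFactors = FALSE)
    calls <- list()
    for (ci in seq_along(callers)) {
      det <- runif(n_true_deletions) < detection_prob[ci]
      if (any(det)) {
        js <- round(rnorm(sum(det), 0, boundary_jitter_sd))
        je <- round(rnorm(sum(det), 0, boundary_jitter_sd))
        st <- pmax(truth$start[det] + js, 1)
        en <- pmin(truth$end[det] + je, genome_length)
        en <- pmax(en, st)
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = chrom, start = st, end = en, caller = callers[ci],
          sample = sample_id, is_false_positive = FALSE,
          truth_id = which(det), stringsAsFactors = FALSE)
      }
      n_fp <- if (n_false_positives > 0)
        rbinom(1, 10 * n_false_positives, 0.1) else 0L
      if (n_fp > 0) {
        fl <- pmin(pmax(round(rlnorm(n_fp, length_meanlog, length_sdlog)),
                        min_len), max_len)
        fs <- vapply(fl, function(l)
          sample.int(genome_length - l + 1, 1), integer(1))
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = chrom, start = fs, end = fs + fl - 1,
          caller = callers[ci], sample = sample_id,
          is_false_positive = TRUE, truth_id = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  })
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               caller = character(0), sample = character(0),
               is_false_positive = logical(0), truth_id = integer(0))
  rownames(calls) <- NULL
  list(truth = truth, calls = calls)
}
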