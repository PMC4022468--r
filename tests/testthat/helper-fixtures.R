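# Fixtures are built in code at test time; nothing binary is stored.

# write a VCF from explicit components; gt is a character matrix of GT strings
write_test_vcf <- function(chrom, pos, ref, alt, gt, samples,
                           filter = rep("PASS", length(pos)),
                           path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", unique(chrom)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(chrom, pos, ".", ref, alt, ".", filter, ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  path
}

write_test_popmap <- function(samples, populations,
                              continents = populations,
                              path = tempfile(fileext = ".tsv")) {
  write.table(data.frame(sample = samples, population = populations,
                         continent = continents),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# 3-sample, 5-site toy cohort: one missing genotype, one tri-allelic site
toy_cohort_paths <- function() {
  gt <- rbind(c("0/1", "0/0", "1/1"),
              c("0/0", "./.", "0/1"),
              c("1/1", "0/1", "0/0"),
              c("0/1", "1/2", "2/2"),   # tri-allelic
              c("0/0", "0/1", "0/0"))
  vcf <- write_test_vcf(chrom = rep("1", 5),
                        pos = c(100, 200, 300, 400, 500),
                        ref = c("A", "C", "G", "T", "A"),
                        alt = c("G", "T", "A", "C,G", "T"),
                        gt = gt, samples = c("S1", "S2", "S3"))
  popmap <- write_test_popmap(c("S1", "S2", "S3"), c("P1", "P1", "P2"),
                              c("ASN", "ASN", "EUR"))
  list(vcf = vcf, popmap = popmap)
}

# simulate a cohort to files and read it back
simulated_cohort <- function(...) {
  d <- tempfile(); dir.create(d)
  sim <- simulate_cohort(..., dir = d)
  read_cohort(sim$vcf, sim$popmap)
}

# brute-force oracle for the pairwise distance: naive membership loop
oracle_pairwise_d <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  shared <- 0L
  for (x in s1) if (any(x == s2)) shared <- shared + 1L
  1 - shared / min(length(s1), length(s2))
}

# brute-force transitive interval components (adjacency by >= 1 bp overlap)
oracle_merge <- function(start, end) {
  n <- length(start)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && start[i] <= end[j] && start[j] <= end[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc)
    data.frame(start = min(start[comp == cc]), end = max(end[comp == cc]))))
  out[order(out$start), , drop = FALSE]
}

# brute-force coverage oracle on small coordinates
oracle_overlap_fraction <- function(q_start, q_end, c_start, c_end) {
  covered <- unique(unlist(Map(seq, c_start, c_end)))
  mean(seq(q_start, q_end) %in% covered)
}
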