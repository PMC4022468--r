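# Consolidation of structural-deletion calls from multiple callers:
# size-window filter (50 bp - 10 Mb), transitive union merging of
# overlapping calls into consensus deletions, and novelty classification by
# coverage overlap against known-deletion catalogs (< 50% overlap = novel).
#
# Intervals are 1-based inclusive internally; BED input (0-based half-open)
# is converted on read. Interval arithmetic is delegated to IRanges.

#' Read deletion calls from BED or TSV
#'
#' BED input (no header, 0-based half-open) is converted to 1-based
#' inclusive coordinates; a TSV with header columns `chrom`, `start`, `end`
#' (1-based inclusive) and optionally `caller`, `sample` is taken as-is.
#'
#' @param path file path.
#' @param caller caller label applied to every call (overrides any column).
#' @param sample_id sample label applied to every call.
#' @param format `"auto"` (header sniffing), `"bed"` or `"tsv"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `caller`,
#'   `sample`.
#' @export
read_deletion_calls <- function(path, caller = NA_character_,
                                sample_id = NA_character_,
                                format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^chrom\t", first)) "tsv" else "bed"
  }
  if (format == "bed") {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(chrom = as.character(tab[[1]]),
                      start = as.integer(tab[[2]]) + 1L,  # 0-based -> 1-based
                      end = as.integer(tab[[3]]),
                      caller = caller, sample = sample_id,
                      stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "end") %in% names(tab)))
    out <- data.frame(chrom = as.character(tab$chrom),
                      start = as.integer(tab$start),
                      end = as.integer(tab$end),
                      caller = if ("caller" %in% names(tab) && is.na(caller))
                        tab$caller else caller,
                      sample = if ("sample" %in% names(tab) && is.na(sample_id))
                        tab$sample else sample_id,
                      stringsAsFactors = FALSE)
  }
  if (any(out$start > out$end)) stop("invalid interval: start > end")
  out
}

#' Filter deletion calls by length
#'
#' Length is `end - start + 1`; bounds are inclusive (default window
#' 50 bp to 10 Mb).
#'
#' @param calls data.frame with columns `start`, `end`.
#' @param min_len,max_len inclusive length bounds.
#' @return filtered data.frame.
#' @export
size_filter <- function(calls, min_len = 50, max_len = 1e7) {
  len <- calls$end - calls$start + 1
  out <- calls[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge caller-level deletion calls into consensus deletions
#'
#' Within each sample and chromosome, calls overlapping by at least 1 bp
#' are chained transitively into one consensus whose span is the union
#' (minimum start, maximum end); abutting but non-overlapping calls are
#' kept separate. Supporting callers are the union of the labels of the
#' merged calls.
#'
#' @param calls data.frame with columns `chrom`, `start`, `end`, `caller`
#'   and optionally `sample` (missing/NA treated as a single sample).
#' @return data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `length`, `callers` (comma-separated sorted labels), `n_callers`,
#'   `n_calls`.
#' @export
merge_union <- function(calls) {
  if (!"sample" %in% names(calls)) calls$sample <- NA_character_
  grp <- split(calls, list(calls$sample, calls$chrom), drop = TRUE,
               sep = "\r")
  res <- lapply(grp, function(g) {
    ir <- IRanges::IRanges(start = g$start, end = g$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)  # overlap >= 1 bp only
    hits <- IRanges::findOverlaps(ir, red)
    comp <- factor(S4Vectors::subjectHits(hits), levels = seq_along(red))
    by_comp <- split(g$caller[S4Vectors::queryHits(hits)], comp)
    data.frame(sample = g$sample[1], chrom = g$chrom[1],
               start = IRanges::start(red), end = IRanges::end(red),
               length = IRanges::width(red),
               callers = unname(vapply(by_comp, function(cl)
                 paste(sort(unique(cl)), collapse = ","), "")),
               n_callers = unname(vapply(by_comp, function(cl)
                 length(unique(cl)), integer(1))),
               n_calls = unname(lengths(by_comp)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$sample, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of a query interval covered by a catalog
#'
#' Coverage of the query by the union of catalog intervals, divided by the
#' query length -- overlapping or abutting catalog entries are never double
#' counted.
#'
#' @param query one-row list/data.frame with `chrom`, `start`, `end`.
#' @param catalog data.frame of catalog intervals (`chrom`, `start`, `end`).
#' @return fraction in \[0, 1\].
#' @export
overlap_fraction <- function(query, catalog) {
  cat_c <- catalog[catalog$chrom == query$chrom, , drop = FALSE]
  if (nrow(cat_c) == 0) return(0)
  q <- IRanges::IRanges(start = query$start, end = query$end)
  u <- IRanges::reduce(IRanges::IRanges(start = cat_c$start, end = cat_c$end))
  covered <- sum(IRanges::width(IRanges::intersect(u, q)))
  covered / IRanges::width(q)
}

#' Classify consensus deletions as known or novel
#'
#' Novel iff strictly less than `threshold` (default 50%) of the deletion's
#' length is covered by catalogued deletions; exactly 50% overlap is known.
#' The default denominator is the query length (one-sided); with
#' `reciprocal = TRUE` both the query and (each overlapping) catalog
#' interval must reach the threshold for a `known` call.
#'
#' @param consensus data.frame of deletions (`chrom`, `start`, `end`).
#' @param catalogs list of catalog data.frames, merged into one interval set.
#' @param threshold overlap fraction boundary (default 0.5).
#' @param reciprocal require the overlap fraction on both sides.
#' @return the `consensus` data.frame with added columns `overlap_frac` and
#'   `novelty` (`"known"`/`"novel"`).
#' @export
classify_sv_novelty <- function(consensus, catalogs, threshold = 0.5,
                                reciprocal = FALSE) {
  catalog <- do.call(rbind, lapply(catalogs, function(x)
    x[, c("chrom", "start", "end")]))
  frac <- numeric(nrow(consensus))
  known <- logical(nrow(consensus))
  for (i in seq_len(nrow(consensus))) {
    q <- consensus[i, ]
    frac[i] <- overlap_fraction(q, catalog)
    if (!reciprocal) {
      known[i] <- frac[i] >= threshold
    } else {
      cat_c <- catalog[catalog$chrom == q$chrom, , drop = FALSE]
      rec <- FALSE
      if (nrow(cat_c) && frac[i] >= threshold) {
        qr <- IRanges::IRanges(q$start, q$end)
        cr <- IRanges::IRanges(cat_c$start, cat_c$end)
        ov <- IRanges::pintersect(IRanges::findOverlapPairs(cr, qr))
        idx <- S4Vectors::queryHits(IRanges::findOverlaps(cr, qr))
        if (length(idx))
          rec <- any(IRanges::width(ov) / IRanges::width(cr[idx]) >= threshold)
      }
      known[i] <- rec
    }
  }
  consensus$overlap_frac <- frac
  consensus$novelty <- ifelse(known, "known", "novel")
  consensus
}

#' Consolidate caller-level deletion calls end to end
#'
#' Applies the size window, merges overlapping calls per sample and
#' chromosome into consensus deletions, optionally re-applies the size
#' window to the merged spans (unions can exceed the upper bound), and
#' classifies novelty when catalogs are supplied.
#'
#' @param calls data.frame of caller-level calls (see [merge_union()]).
#' @param min_len,max_len size window (inclusive; defaults 50 bp, 10 Mb).
#' @param catalogs optional list of catalog data.frames.
#' @param threshold novelty overlap boundary.
#' @param recheck_size re-apply the size window after merging.
#' @param reciprocal passed to [classify_sv_novelty()].
#' @return consensus data.frame.
#' @export
consolidate_deletions <- function(calls, min_len = 50, max_len = 1e7,
                                  catalogs = NULL, threshold = 0.5,
                                  recheck_size = FALSE, reciprocal = FALSE) {
  filtered <- size_filter(calls, min_len = min_len, max_len = max_len)
  if (nrow(filtered) == 0)
    stop("no calls remain after the size filter")
  consensus <- merge_union(filtered)
  if (recheck_size) consensus <- size_filter(consensus, min_len, max_len)
  if (!is.null(catalogs))
    consensus <- classify_sv_novelty(consensus, catalogs,
                                     threshold = threshold,
                                     reciprocal = reciprocal)
  consensus
}

#' Write consensus deletions as BED
#'
#' Converts back to 0-based half-open coordinates.
#'
#' @param consensus consensus data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_bed <- function(consensus, path) {
  bed <- data.frame(consensus$chrom, consensus$start - 1L, consensus$end,
                    consensus$callers)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
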