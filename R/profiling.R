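## Short-read depth profiling over a reference panel, off-target insertion
## scanning against decoy chromosomes, read-set summary statistics, and
## in-silico PCR genotyping.

#' Per-base depth profiles over a reference panel
#'
#' Each read is assigned to its best-scoring panel reference (no
#' multi-mapping split; ties broken by lowest reference label then leftmost
#' position) and depth is incremented over the aligned target span, so the
#' summed depth over all profiles equals the total aligned bases.
#'
#' @param reads `read_set` of (short) reads.
#' @param panel `read_set` of references.
#' @param seed_k Seed k-mer length for the mapper.
#' @param min_anchors Minimum chained seeds for a mapping.
#' @return List with `profiles` (named list of integer depth vectors, one
#'   per reference) and `summary` (data.frame: reference, n_reads,
#'   aligned_bases, mean_depth, median_depth).
#' @export
depth_profile <- function(reads, panel, seed_k = 15L, min_anchors = 3L) {
  profiles <- lapply(setNames(nchar(panel$seq), panel$id),
                     function(n) integer(n))
  counts <- setNames(integer(nrow(panel)), panel$id)
  bases <- setNames(numeric(nrow(panel)), panel$id)
  if (nrow(reads) > 0) {
    hits <- .cpp_map_reads(reads$seq, panel$seq, as.integer(seed_k),
                           as.integer(min_anchors), 100L, 48L,
                           1L, -1L, -2L, -1L, TRUE)
    if (nrow(hits) > 0) {
      hits$label <- panel$id[hits$target]
      ord <- order(hits$query, -hits$score, hits$label, hits$tstart)
      hits <- hits[ord, , drop = FALSE]
      hits <- hits[!duplicated(hits$query), , drop = FALSE]
      for (lab in panel$id) {
        h <- hits[hits$label == lab, , drop = FALSE]
        counts[lab] <- nrow(h)
        if (nrow(h) == 0) next
        n <- length(profiles[[lab]])
        delta <- integer(n + 1L)
        starts <- pmax(1L, h$tstart + 1L)
        ends <- pmin(n, h$tend)
        for (i in seq_len(nrow(h))) {
          delta[starts[i]] <- delta[starts[i]] + 1L
          delta[ends[i] + 1L] <- delta[ends[i] + 1L] - 1L
        }
        profiles[[lab]] <- cumsum(delta[seq_len(n)])
        bases[lab] <- sum(ends - starts + 1L)
      }
    }
  }
  summary <- data.frame(
    reference = panel$id,
    n_reads = as.integer(counts[panel$id]),
    aligned_bases = as.numeric(bases[panel$id]),
    mean_depth = vapply(profiles[panel$id], mean, 0),
    median_depth = vapply(profiles[panel$id], median, 0),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(profiles = profiles, summary = summary)
}

#' Export depth profiles in `samtools depth` layout
#' @param depth Result of [depth_profile()].
#' @param path Output TSV path (columns: reference, 1-based position, depth).
#' @return Invisibly, `path`.
#' @export
write_depth_tsv <- function(depth, path) {
  df <- do.call(rbind, lapply(names(depth$profiles), function(lab) {
    d <- depth$profiles[[lab]]
    data.frame(ref = lab, pos = seq_along(d), depth = d)
  }))
  write_tsv(df, path)
}

#' Scan for off-target donor integration
#'
#' Counts reads whose best alignment is to a decoy contig and which contain
#' any donor/template 25-mer (on either strand). On a clean simulation the
#' count is zero by construction of the decoys.
#'
#' @param reads `read_set` of reads.
#' @param ref Composite reference including decoy contigs.
#' @param lib A `segment_library` (source of donor 25-mers).
#' @param seed_k,min_anchors Mapper thresholds.
#' @return List with `n_flagged` and `flagged` (read ids).
#' @export
off_target_scan <- function(reads, ref, lib, seed_k = 15L, min_anchors = 4L) {
  if (nrow(reads) == 0) return(list(n_flagged = 0L, flagged = character(0)))
  decoy_labels <- ref$id[grepl("^decoy", ref$id)]
  if (length(decoy_labels) == 0) {
    stop("composite reference contains no decoy contigs", call. = FALSE)
  }
  hits <- .cpp_map_reads(reads$seq, ref$seq, as.integer(seed_k),
                         as.integer(min_anchors), 100L, 48L,
                         1L, -1L, -2L, -1L, TRUE)
  if (nrow(hits) == 0) return(list(n_flagged = 0L, flagged = character(0)))
  hits$label <- ref$id[hits$target]
  ord <- order(hits$query, -hits$score, hits$label, hits$tstart)
  best <- hits[ord, , drop = FALSE]
  best <- best[!duplicated(best$query), , drop = FALSE]
  cand <- best$query[best$label %in% decoy_labels]
  if (length(cand) == 0) return(list(n_flagged = 0L, flagged = character(0)))
  donor <- unique(c(canonical_kmers(segment_seq(lib, "TEMPLATE"), 25L),
                    canonical_kmers(segment_seq(lib, "PUC"), 25L)))
  flagged <- character(0)
  for (qi in cand) {
    rk <- canonical_kmers(reads$seq[qi], 25L)
    if (any(rk %in% donor)) flagged <- c(flagged, reads$id[qi])
  }
  list(n_flagged = length(flagged), flagged = flagged)
}

#' Read-set summary statistics
#'
#' @param reads `read_set`, or a numeric vector of read lengths.
#' @param genome_size Optional genome size for fold-coverage.
#' @return List: `n_reads`, `total_bases`, `mean_len` (2 decimals),
#'   `max_len`, `coverage` (if `genome_size` given).
#' @export
readset_stats <- function(reads, genome_size = NULL) {
  lens <- if (is.numeric(reads)) reads else nchar(reads$seq)
  n <- length(lens)
  total <- sum(as.numeric(lens))
  out <- list(n_reads = n, total_bases = total,
              mean_len = if (n > 0) round(total / n, 2) else NA_real_,
              max_len = if (n > 0) max(lens) else NA_integer_)
  if (!is.null(genome_size)) out$coverage <- total / genome_size
  out
}

#' Read-set summary from pre-computed totals
#'
#' The same summary as [readset_stats()] when only the read count and total
#' base count are known (e.g. from a sequencing provider report).
#'
#' @param n_reads Number of reads.
#' @param total_bases Summed read length (bp).
#' @param max_len Optional largest read length.
#' @param genome_size Optional genome size for fold-coverage.
#' @return List: `n_reads`, `total_bases`, `mean_len` (2 decimals),
#'   `max_len`, and `coverage` when `genome_size` is given.
#' @export
readset_summary <- function(n_reads, total_bases, max_len = NA_real_,
                            genome_size = NULL) {
  out <- list(n_reads = n_reads, total_bases = total_bases,
              mean_len = round(total_bases / n_reads, 2), max_len = max_len)
  if (!is.null(genome_size)) out$coverage <- total_bases / genome_size
  out
}

#' Report a percentage from a count and a total
#'
#' Plain reporting arithmetic for tables of rates (e.g. development or
#' knock-in rates): `100 * count / total`, rounded to `digits`.
#'
#' @param count,total Non-negative numbers, `total > 0`.
#' @param digits Decimal places (default 0).
#' @return Percentage as a number.
#' @export
percent_rate <- function(count, total, digits = 0) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  round(100 * count / total, digits)
}

#' In-silico PCR amplicon prediction
#'
#' Finds exact (0-mismatch, full-length) matches of the forward primer and
#' the reverse complement of the reverse primer on both strands and reports
#' product lengths up to `max_product`.
#'
#' @param allele Template sequence (string).
#' @param forward,reverse Primer sequences (>= 15 nt).
#' @param max_product Maximum reported product length (bp).
#' @return Sorted integer vector of product lengths (possibly empty).
#' @export
insilico_pcr <- function(allele, forward, reverse, max_product = 20000L) {
  if (nchar(forward) < 15 || nchar(reverse) < 15) {
    stop("primers must be at least 15 nt", call. = FALSE)
  }
  find_all <- function(pattern, subject) {
    m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  products <- integer(0)
  # orientation 1: forward primer on +, reverse primer on -
  f <- find_all(forward, allele)
  r <- find_all(revcomp(reverse), allele)
  for (fs in f) {
    for (rs in r) {
      len <- rs + nchar(reverse) - fs
      if (len >= nchar(forward) && len <= max_product) {
        products <- c(products, len)
      }
    }
  }
  # orientation 2: reverse primer on +, forward primer on -
  f2 <- find_all(revcomp(forward), allele)
  r2 <- find_all(reverse, allele)
  for (rs in r2) {
    for (fs in f2) {
      len <- fs + nchar(forward) - rs
      if (len >= nchar(reverse) && len <= max_product) {
        products <- c(products, len)
      }
    }
  }
  sort(unique(products))
}
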