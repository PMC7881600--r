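#' @useDynLib kiresolve, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom runif rlnorm rnorm setNames
#' @importFrom utils head tail write.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

assert_dna <- function(seq, what = "seq") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains non-DNA characters (allowed: A,C,G,T,N)", what),
         call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet `{A,C,G,T,N}`; `N` maps to
#' `N`. An involution: `revcomp(revcomp(x)) == x`.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements (names preserved).
#' @examples
#' revcomp("AAACN")  # "NGTTT"
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0) return(character(0))
  stopifnot(is.character(seq))
  assert_dna(seq)
  .cpp_revcomp(seq)
}

#' Enumerate overlapping k-mers
#'
#' Returns the `len(seq) - k + 1` overlapping k-mers of a sequence in order
#' (an empty vector when the sequence is shorter than `k`). A 50 nt sequence
#' yields exactly 26 k-mers at `k = 25`.
#'
#' @param seq A single DNA string.
#' @param k K-mer length (positive integer).
#' @return Character vector of k-mers.
#' @export
kmers <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1)
  substring(seq, starts, starts + k - 1)
}

canonical_kmers <- function(seq, k) {
  fw <- kmers(seq, k)
  if (length(fw) == 0) return(character(0))
  rv <- revcomp(fw)
  pmin(fw, rv)
}

#' Local alignment of two sequences
#'
#' Reports non-overlapping local alignment hits on both strands, highest score
#' first. Short inputs (query at most 2 kb) are aligned by exhaustive affine
#' Smith-Waterman; longer inputs go through a seed (exact 15-mer) ->
#' diagonal-chain -> banded-extension path. Scoring defaults: match +1,
#' mismatch -1, gap open -2, gap extend -1; `N` matches nothing. Coordinates
#' are 0-based half-open; minus-strand hits report the target span on the
#' forward strand.
#'
#' @param query,target Single DNA strings (non-empty).
#' @param min_score Minimum alignment score for a reported hit.
#' @param scoring Named list with `match`, `mismatch`, `gap_open`, `gap_ext`.
#' @param seed_k Seed k-mer length for the long-input path.
#' @param min_anchors Minimum chained seeds for a candidate hit.
#' @return A data.frame with columns `qstart`, `qend`, `tstart`, `tend`,
#'   `strand`, `identity`, `score`.
#' @export
align_local <- function(query, target, min_score = 30,
                        scoring = default_scoring(),
                        seed_k = 15, min_anchors = 4) {
  stopifnot(is.character(query), is.character(target),
            length(query) == 1, length(target) == 1)
  if (nchar(query) == 0 || nchar(target) == 0) {
    stop("align_local requires non-empty sequences", call. = FALSE)
  }
  assert_dna(query, "query"); assert_dna(target, "target")
  if (nchar(query) <= 2000 && nchar(target) <= 50000) {
    hp <- .cpp_sw_hits(query, target, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_ext, min_score, 25L)
    hm <- .cpp_sw_hits(revcomp(query), target, scoring$match,
                       scoring$mismatch, scoring$gap_open, scoring$gap_ext,
                       min_score, 25L)
    hp$strand <- rep("+", nrow(hp))
    hm$strand <- rep("-", nrow(hm))
    hits <- rbind(hp, hm)
    if (nrow(hits) > 0) {
      minus <- hits$strand == "-"
      if (any(minus)) {
        n <- nchar(query)
        qs <- hits$qstart[minus]; qe <- hits$qend[minus]
        hits$qstart[minus] <- n - qe
        hits$qend[minus] <- n - qs
      }
    }
  } else {
    hits <- .cpp_map_reads(query, target, as.integer(seed_k),
                           as.integer(min_anchors), 100L, 48L,
                           scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_ext, TRUE)
    hits$query <- NULL; hits$target <- NULL; hits$n_anchors <- NULL
  }
  if (nrow(hits) == 0) {
    return(data.frame(qstart = integer(0), qend = integer(0),
                      tstart = integer(0), tend = integer(0),
                      strand = character(0), identity = numeric(0),
                      score = numeric(0)))
  }
  hits$identity <- hits$matches / pmax(1L, hits$aln_cols)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  hits <- hits[order(-hits$score, hits$tstart, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("qstart", "qend", "tstart", "tend", "strand", "identity", "score")]
}

#' Default alignment scoring parameters
#' @return Named list: match +1, mismatch -1, gap open -2, gap extend -1.
#' @export
default_scoring <- function() {
  list(match = 1L, mismatch = -1L, gap_open = -2L, gap_ext = -1L)
}

banded_align <- function(q, t, band = NULL, scoring = default_scoring(),
                         traceback = FALSE) {
  if (is.null(band)) {
    band <- max(48L, as.integer(0.05 * max(nchar(q), nchar(t))))
  }
  .cpp_banded_align(q, t, as.integer(band), scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_ext, traceback)
}

## ---------------------------------------------------------------------------
## Read sets and FASTA/FASTQ I/O
## ---------------------------------------------------------------------------

#' Construct a read set
#'
#' A read set is a plain data.frame with columns `id`, `seq` and optionally
#' `qual` (Sanger Phred+33 strings of the same length as `seq`). Identifiers
#' must be non-empty.
#'
#' @param id Character vector of identifiers.
#' @param seq Character vector of DNA sequences.
#' @param qual Optional character vector of quality strings.
#' @return A `read_set` data.frame.
#' @export
read_set <- function(id, seq, qual = NULL) {
  stopifnot(length(id) == length(seq))
  if (any(!nzchar(id))) stop("read ids must be non-empty", call. = FALSE)
  assert_dna(seq)
  if (!is.null(qual)) {
    stopifnot(length(qual) == length(seq))
    if (any(nchar(qual) != nchar(seq))) {
      stop("quality strings must match sequence lengths", call. = FALSE)
    }
  }
  out <- data.frame(id = as.character(id), seq = as.character(seq),
                    stringsAsFactors = FALSE)
  if (!is.null(qual)) out$qual <- as.character(qual)
  class(out) <- c("read_set", "data.frame")
  out
}

#' Read a FASTA file into a read set
#' @param path Path to a (multi-line) FASTA file.
#' @return A `read_set` data.frame.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  read_set(ids, unname(seqs))
}

#' Write a read set to FASTA
#' @param reads A `read_set`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(reads, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(paste0(">", reads$id[i]), con)
    s <- reads$seq[i]
    n <- nchar(s)
    if (n == 0) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' Strict 4-line-per-record Sanger FASTQ. Malformed records raise an error
#' that names the offending line number.
#'
#' @param path Path to a FASTQ file.
#' @return A `read_set` with a `qual` column.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(read_set(character(0), character(0), character(0)))
  if (length(lines) %% 4 != 0) {
    stop(sprintf("truncated FASTQ record starting at line %d",
                 4 * (length(lines) %/% 4) + 1), call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0) {
    stop(sprintf("expected '@' header at line %d", idx[bad[1]]), call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0) {
    stop(sprintf("expected '+' separator at line %d", idx[bad[1]] + 2L),
         call. = FALSE)
  }
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad) > 0) {
    stop(sprintf("quality length does not match sequence length at line %d",
                 idx[bad[1]] + 3L), call. = FALSE)
  }
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad) > 0) {
    stop(sprintf("non-DNA characters in sequence at line %d", idx[bad[1]] + 1L),
         call. = FALSE)
  }
  read_set(sub("^@", "", sub("\\s.*$", "", hdr)), seqs, qual)
}

#' Write a read set to FASTQ
#' @param reads A `read_set`; if it has no `qual` column, constant Q30 is used.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- strrep("?", nchar(reads$seq))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual)), con)
  invisible(path)
}

#' Export intervals as BED6
#'
#' @param df Data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (0-based half-open).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  stopifnot(all(cols %in% names(df)))
  write.table(df[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
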