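## Confirmation of allele sub-structure sequences: supporting long reads are
## grouped per substructure (cluster block string), trimmed of genomic flank
## sequence beyond a small margin, multiply aligned by a center-star
## procedure, and collapsed to a majority-rule consensus.

kmer_profile <- function(seq, k = 15L) unique(kmers(seq, k))

#' Center-star multiple sequence alignment
#'
#' The center sequence is the read with the highest summed pairwise
#' similarity to the others (estimated from shared 15-mers; ties broken by
#' length then input order). Every other sequence is globally aligned to the
#' center with a banded affine aligner and the pairwise alignments are merged
#' under the "once a gap, always a gap" rule. Deterministic.
#'
#' @param seqs Character vector of sequences (>= 1).
#' @param band Alignment band (default scales with length).
#' @return List with `matrix` (character matrix, one row per sequence,
#'   `"-"` for gaps) and `center` (row index of the center sequence).
#' @export
msa <- function(seqs, band = NULL) {
  n <- length(seqs)
  if (n == 0) stop("msa requires at least one sequence", call. = FALSE)
  if (n == 1) {
    m <- matrix(strsplit(seqs[1], "")[[1]], nrow = 1)
    rownames(m) <- names(seqs)[1]
    return(list(matrix = m, center = 1L))
  }
  profs <- lapply(seqs, kmer_profile)
  sim <- vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n)[-i], function(j) {
      length(intersect(profs[[i]], profs[[j]])) /
        max(1L, min(length(profs[[i]]), length(profs[[j]])))
    }, 0))
  }, 0)
  center <- order(-sim, -nchar(seqs), seq_len(n))[1]
  cseq <- seqs[center]
  L <- nchar(cseq)
  others <- setdiff(seq_len(n), center)
  ins_counts <- matrix(0L, nrow = length(others), ncol = L + 1L)
  aligned <- vector("list", length(others))    # per center position, '-' for del
  ins_chars <- vector("list", length(others))  # list of insertion strings per gap slot
  for (oi in seq_along(others)) {
    i <- others[oi]
    # anchor the read on the center first: reads of one substructure start at
    # staggered offsets, so the alignable core must be located before banding
    qs <- 0L; qe <- nchar(seqs[i]); ts <- 0L; te <- L
    band_i <- band
    ch <- .cpp_map_reads(seqs[i], cseq, 15L, 4L, 100L, 48L,
                         1L, -1L, -2L, -1L, FALSE)
    ch <- ch[ch$strand == "+", , drop = FALSE]
    if (nrow(ch) > 0) {
      b <- ch[order(-ch$n_anchors, ch$tstart), ][1, ]
      qs <- b$qstart; qe <- b$qend; ts <- b$tstart; te <- b$tend
      band_i <- max(64L, abs((qe - qs) - (te - ts)) +
                      as.integer(0.02 * (qe - qs)) + 48L)
    } else if (is.null(band_i)) {
      band_i <- max(200L, as.integer(0.05 * max(nchar(seqs[i]), L)))
    }
    al <- banded_align(substr(seqs[i], qs + 1L, qe),
                       substr(cseq, ts + 1L, te),
                       band = band_i, traceback = TRUE)
    qa <- strsplit(al$q_aln, "")[[1]]
    ta <- strsplit(al$t_aln, "")[[1]]
    ach <- rep("-", L)
    ich <- vector("list", L + 1L)
    p <- ts
    for (col in seq_along(ta)) {
      if (ta[col] != "-") {
        p <- p + 1L
        ach[p] <- qa[col]
      } else {
        ich[[p + 1L]] <- c(ich[[p + 1L]], qa[col])
      }
    }
    aligned[[oi]] <- ach
    ins_chars[[oi]] <- ich
    ins_counts[oi, ] <- vapply(ich, length, 0L)
  }
  master <- if (length(others) > 0) apply(ins_counts, 2, max) else
    integer(L + 1L)
  ncol_out <- L + sum(master)
  rows <- matrix("-", nrow = n, ncol = ncol_out)
  # column layout: [ins before pos1][pos1][ins after pos1][pos2]...
  col_of_pos <- integer(L)
  cc <- 0L
  for (p in 0:L) {
    cc <- cc + master[p + 1L]
    if (p < L) col_of_pos[p + 1L] <- cc + 1L
    if (p < L) cc <- cc + 1L
  }
  cchars <- strsplit(cseq, "")[[1]]
  rows[center, col_of_pos] <- cchars
  for (oi in seq_along(others)) {
    i <- others[oi]
    rows[i, col_of_pos] <- aligned[[oi]]
    ich <- ins_chars[[oi]]
    for (p in 0:L) {
      chars <- ich[[p + 1L]]
      if (length(chars) == 0) next
      slot_end <- if (p < L) col_of_pos[p + 1L] - 1L else ncol_out
      start <- slot_end - master[p + 1L] + 1L
      rows[i, start + seq_along(chars) - 1L] <- chars
    }
  }
  rownames(rows) <- names(seqs)
  list(matrix = rows, center = center)
}

#' Majority-rule consensus of an alignment
#'
#' Per column, the residue with frequency above `plurality` among non-gap
#' entries is emitted; ties are broken by the fixed base order A < C < G < T.
#' Columns where gaps form a strict majority emit nothing.
#'
#' @param alignment Result of [msa()] (or a character matrix).
#' @param plurality Required frequency among non-gap entries.
#' @return List with `seq` (consensus string), `depth` (non-gap count per
#'   emitted column) and `agreement` (overall fraction of non-gap entries
#'   matching the consensus residue).
#' @export
consensus_call <- function(alignment, plurality = 0.5) {
  m <- if (is.list(alignment)) alignment$matrix else alignment
  if (is.null(dim(m)) || nrow(m) == 0 || ncol(m) == 0) {
    stop("consensus requires a non-empty alignment", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  out <- character(ncol(m))
  depth <- integer(ncol(m))
  agree <- integer(ncol(m))
  keep <- logical(ncol(m))
  nr <- nrow(m)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gaps <- sum(col == "-")
    if (gaps > nr - gaps) next     # gap-majority column
    cnt <- c(sum(col == "A"), sum(col == "C"), sum(col == "G"),
             sum(col == "T"))
    if (all(cnt == 0)) next
    top <- max(cnt)
    cand <- bases[cnt == top]
    nongap <- nr - gaps
    res <- if (top / nongap > plurality) bases[which.max(cnt)] else cand[1]
    out[j] <- res
    depth[j] <- nongap
    agree[j] <- cnt[match(res, bases)]
    keep[j] <- TRUE
  }
  d <- depth[keep]
  list(seq = paste(out[keep], collapse = ""), depth = d,
       agreement = if (sum(d) > 0) sum(agree[keep]) / sum(d) else NA_real_)
}

#' Group supporting reads per substructure and trim genomic flanks
#'
#' Each reported structure's supporting clusters define its substructures; a
#' substructure group holds the cluster's reads, oriented to the canonical
#' block-string orientation and trimmed so at most `flank_margin` bp of
#' genomic flank remain beyond the insertion boundary (for the cut-spanning
#' wild-type/NHEJ string, a window of `flank_margin` each side of the cut).
#'
#' @param reads `read_set` of the candidate reads.
#' @param structures List of `structure_call`s from [call_structures()].
#' @param clustering Result of [cluster_blockstrings()].
#' @param blocks_by_read Named list of per-read block data.frames.
#' @param cut Cas9 cut position on `chr17`.
#' @param flank_margin Genomic flank kept beyond the insertion boundary (bp).
#' @param min_reads Minimum group size to keep.
#' @return List of groups: `structure`, `cluster` (block string), `seqs`
#'   (named, oriented, trimmed), `trims`.
#' @export
group_and_trim <- function(reads, structures, clustering, blocks_by_read,
                           cut, flank_margin = 200L, min_reads = 1L) {
  groups <- list()
  for (st in structures) {
    strings <- unique(clustering$reads$string[
      match(st$support, clustering$reads$read_id)])
    for (s in sort(strings)) {
      ids <- clustering$reads$read_id[clustering$reads$string == s &
                                        clustering$reads$read_id %in% st$support]
      if (length(ids) < min_reads) next
      seqs <- character(0); trims <- list()
      for (id in ids) {
        seq <- reads$seq[match(id, reads$id)]
        blk <- blocks_by_read[[id]]
        flipped <- clustering$reads$flipped[match(id, clustering$reads$read_id)]
        L <- nchar(seq)
        if (flipped) {
          seq <- revcomp(seq)
          qs <- L - blk$qend; qe <- L - blk$qstart
          blk$qstart <- qs; blk$qend <- qe
          blk <- blk[rev(seq_len(nrow(blk))), , drop = FALSE]
        }
        from <- 1L; to <- L
        toks <- strsplit(s, " ", fixed = TRUE)[[1]]
        if (length(toks) == 1 && startsWith(toks[1], "chr17F")) {
          cutpos <- cut - blk$tstart[1] + blk$qstart[1]
          from <- max(1L, cutpos - flank_margin)
          to <- min(L, cutpos + flank_margin)
        } else {
          if (blk$target[1] == "chr17") {
            from <- max(1L, blk$qend[1] - flank_margin + 1L)
          }
          nlast <- nrow(blk)
          if (blk$target[nlast] == "chr17") {
            to <- min(L, blk$qstart[nlast] + flank_margin)
          }
        }
        seqs <- c(seqs, setNames(substr(seq, from, to), id))
        trims[[length(trims) + 1L]] <- data.frame(
          read_id = id, from = from, to = to, flipped = flipped)
      }
      groups[[length(groups) + 1L]] <- list(
        structure = st$name, cluster = s, seqs = seqs,
        trims = do.call(rbind, trims))
    }
  }
  groups
}

#' Consensus confirmation of substructures
#'
#' Runs [msa()] + [consensus_call()] on each substructure group (capped at
#' `max_reads` longest reads for tractability).
#'
#' @param groups Result of [group_and_trim()].
#' @param max_reads Group size cap.
#' @param min_reads Minimum reads required to attempt a consensus.
#' @return The groups, each augmented with `consensus`, `agreement` and
#'   `n_used`.
#' @export
confirm_substructures <- function(groups, max_reads = 20L, min_reads = 2L) {
  cache <- new.env(parent = emptyenv())
  lapply(groups, function(g) {
    seqs <- g$seqs
    if (length(seqs) < min_reads) {
      g$consensus <- NA_character_
      g$agreement <- NA_real_
      g$n_used <- length(seqs)
      return(g)
    }
    if (length(seqs) > max_reads) {
      seqs <- seqs[order(-nchar(seqs), names(seqs))[seq_len(max_reads)]]
    }
    key <- paste(c(g$cluster, sort(names(seqs))), collapse = "\r")
    hit <- cache[[key]]
    if (is.null(hit)) {
      band <- max(200L, as.integer(0.03 * max(nchar(seqs))))
      hit <- consensus_call(msa(seqs, band = band))
      cache[[key]] <- hit
    }
    g$consensus <- hit$seq
    g$agreement <- hit$agreement
    g$n_used <- length(seqs)
    g
  })
}
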