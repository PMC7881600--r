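## Junction discovery from short reads: the terminal 50 nt of each edge of
## the plasmid backbone and the complete template are turned into overlapping
## 25-mers; short reads containing any of these k-mers (or their reverse
## complements) are selected, error-trimmed by k-mer abundance within the
## selected set, assembled by greedy maximal-overlap extension, and the
## contigs are annotated by local alignment against the references to call
## junctions and classify their inserted sequence.

#' Build the edge k-mer index
#'
#' Both ends of each linear reference contribute one edge of `edge_len` nt;
#' each edge yields `edge_len - k + 1` k-mers (26 for a 50 nt edge at
#' k = 25). The index holds the forward k-mers and their reverse
#' complements.
#'
#' @param refs Named character vector of reference sequences (default use:
#'   plasmid backbone and complete template).
#' @param edge_len Edge length (nt), `edge_len >= k`.
#' @param k K-mer length.
#' @return List with `edges` (data.frame: edge name, sequence), `kmer_table`
#'   (edge, kmer), and `all_kmers` (forward union reverse complement).
#' @export
build_edge_index <- function(refs, edge_len = 50L, k = 25L) {
  if (edge_len < k) stop("edge_len must be >= k", call. = FALSE)
  edges <- list()
  for (nm in names(refs)) {
    s <- refs[[nm]]
    edges[[paste0(nm, "_start")]] <- substr(s, 1L, edge_len)
    edges[[paste0(nm, "_end")]] <- substr(s, nchar(s) - edge_len + 1L,
                                          nchar(s))
  }
  tab <- do.call(rbind, lapply(names(edges), function(e) {
    data.frame(edge = e, kmer = kmers(edges[[e]], k), stringsAsFactors = FALSE)
  }))
  list(edges = data.frame(edge = names(edges),
                          seq = unlist(edges, use.names = FALSE),
                          stringsAsFactors = FALSE),
       kmer_table = tab,
       all_kmers = unique(c(tab$kmer, revcomp(tab$kmer))),
       k = as.integer(k))
}

#' Select short reads containing edge k-mers
#'
#' Exact containment of any edge k-mer or its reverse complement.
#'
#' @param reads `read_set` of short reads.
#' @param index Result of [build_edge_index()].
#' @return List with `reads` (selected subset) and `per_edge` (selected-read
#'   counts per edge).
#' @export
select_reads <- function(reads, index) {
  per_edge <- setNames(integer(nrow(index$edges)), index$edges$edge)
  if (nrow(reads) == 0) {
    return(list(reads = reads, per_edge = per_edge))
  }
  subj <- Biostrings::DNAStringSet(reads$seq)
  pd <- Biostrings::PDict(index$all_kmers)
  cnt <- Biostrings::vcountPDict(pd, subj)   # patterns x reads
  sel <- colSums(cnt) > 0
  # per-edge counts (a read may count for several edges)
  kmap <- rbind(data.frame(edge = index$kmer_table$edge,
                           kmer = index$kmer_table$kmer),
                data.frame(edge = index$kmer_table$edge,
                           kmer = revcomp(index$kmer_table$kmer)))
  rowedge <- kmap$edge[match(index$all_kmers, kmap$kmer)]
  for (e in unique(rowedge)) {
    per_edge[e] <- sum(colSums(cnt[rowedge == e, , drop = FALSE]) > 0)
  }
  out <- reads[sel, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  list(reads = out, per_edge = per_edge)
}

#' Abundance-based error trimming of selected reads
#'
#' K-mer abundances are counted within the selected set (canonical, i.e.
#' strand-insensitive). Each read is truncated at the first position all of
#' whose covering k-mers have abundance below `cutoff`; reads shorter than
#' `k` after trimming are dropped. `cutoff = 1` is the identity.
#'
#' @param reads `read_set` of selected reads.
#' @param cutoff Abundance cutoff.
#' @param k K-mer length.
#' @return Trimmed `read_set`.
#' @export
error_trim <- function(reads, cutoff = 3L, k = 25L) {
  if (cutoff < 1) stop("cutoff must be >= 1", call. = FALSE)
  if (nrow(reads) == 0) return(reads)
  if (cutoff == 1) return(reads)
  kml <- lapply(reads$seq, canonical_kmers, k = k)
  counts <- table(unlist(kml))
  keep_id <- character(0); keep_seq <- character(0); keep_q <- character(0)
  has_q <- !is.null(reads$qual)
  for (i in seq_len(nrow(reads))) {
    km <- kml[[i]]
    n <- nchar(reads$seq[i])
    if (length(km) == 0) next
    strong <- as.integer(counts[km]) >= cutoff
    m <- length(km)
    # base j is covered by kmers starting in [j-k+1, j] (1-based, clamped)
    covered <- integer(n + 1L)
    for (j in which(strong)) {
      covered[j] <- covered[j] + 1L
      covered[min(n, j + k - 1L) + 1L] <- covered[min(n, j + k - 1L) + 1L] - 1L
    }
    ok <- cumsum(covered[seq_len(n)]) > 0L
    first_weak <- which(!ok)[1]
    end <- if (is.na(first_weak)) n else first_weak - 1L
    if (end < k) next
    keep_id <- c(keep_id, reads$id[i])
    keep_seq <- c(keep_seq, substr(reads$seq[i], 1L, end))
    if (has_q) keep_q <- c(keep_q, substr(reads$qual[i], 1L, end))
  }
  read_set(keep_id, keep_seq, if (has_q) keep_q else NULL)
}

## greedy assembly -----------------------------------------------------------

#' Greedy maximal-overlap assembly of selected reads
#'
#' SSAKE-style contig extension: the seed is the unassembled read with the
#' highest total k-mer abundance (ties: longest, then lexicographically
#' smallest sequence); the contig is extended 3' then 5' by the unused read
#' (either strand) with the maximal exact overlap of at least `min_overlap`
#' (ties: higher abundance, then lexicographic); each read is usable once.
#' Deterministic and invariant to input read order.
#'
#' @param reads `read_set` (or character vector) of trimmed reads.
#' @param min_overlap Minimum exact overlap (>= 11).
#' @param k K-mer length for abundance scoring.
#' @return `read_set` of contigs (`contig1`, `contig2`, ...), longest first.
#' @export
assemble_greedy <- function(reads, min_overlap = 16L, k = 25L) {
  if (min_overlap < 11) stop("min_overlap must be >= 11", call. = FALSE)
  seqs <- if (is.character(reads)) reads else reads$seq
  seqs <- seqs[nchar(seqs) >= min_overlap]
  if (length(seqs) == 0) return(read_set(character(0), character(0)))
  counts <- table(unlist(lapply(seqs, canonical_kmers, k = k)))
  # deduplicate by canonical orientation; multiplicity feeds abundance
  canon <- pmin(seqs, revcomp(seqs))
  mult <- table(canon)
  useqs <- sort(unique(canon))
  abund <- vapply(useqs, function(s) {
    km <- canonical_kmers(s, k)
    (if (length(km) > 0) sum(as.numeric(counts[km]), na.rm = TRUE) else
       nchar(s)) * as.integer(mult[s])
  }, 0)
  n <- length(useqs)
  used <- rep(FALSE, n)
  fwd <- useqs
  rev_ <- revcomp(useqs)
  # hash: prefix of length min_overlap -> candidate (index, strand)
  pre <- new.env(parent = emptyenv())
  addpre <- function(key, val) {
    cur <- pre[[key]]
    pre[[key]] <- if (is.null(cur)) list(val) else c(cur, list(val))
  }
  for (i in seq_len(n)) {
    addpre(substr(fwd[i], 1L, min_overlap), c(i, 1L))
    addpre(substr(rev_[i], 1L, min_overlap), c(i, 2L))
  }
  get_seq <- function(i, strand) if (strand == 1L) fwd[i] else rev_[i]
  extend3 <- function(contig) {
    repeat {
      L <- nchar(contig)
      omax <- min(L, max(nchar(useqs)))
      found <- FALSE
      for (o in seq(omax, min_overlap)) {
        key <- substr(contig, L - o + 1L, L - o + min_overlap)
        cands <- pre[[key]]
        if (is.null(cands)) next
        best_i <- 0L; best_strand <- 1L; best_ab <- -1; best_seq <- ""
        for (cv in cands) {
          i <- cv[1]; strand <- cv[2]
          if (used[i]) next
          s <- get_seq(i, strand)
          if (nchar(s) < o) next
          if (substr(s, 1L, o) != substr(contig, L - o + 1L, L)) next
          if (nchar(s) == o) { used[i] <<- TRUE; next }  # contained
          if (abund[i] > best_ab ||
              (abund[i] == best_ab && s < best_seq)) {
            best_i <- i; best_strand <- strand; best_ab <- abund[i]
            best_seq <- s
          }
        }
        if (best_i > 0L) {
          used[best_i] <<- TRUE
          contig <- paste0(contig, substr(best_seq, o + 1L, nchar(best_seq)))
          found <- TRUE
          break
        }
      }
      if (!found) return(contig)
    }
  }
  contigs <- character(0)
  repeat {
    free <- which(!used)
    if (length(free) == 0) break
    seed <- free[order(-abund[free], -nchar(useqs[free]), useqs[free])[1]]
    used[seed] <- TRUE
    contig <- fwd[seed]
    contig <- extend3(contig)
    contig <- revcomp(extend3(revcomp(contig)))
    contigs <- c(contigs, contig)
  }
  ord <- order(-nchar(contigs), contigs)
  contigs <- contigs[ord]
  read_set(sprintf("contig%d", seq_along(contigs)), contigs)
}

## contig annotation ---------------------------------------------------------

canonical_junction_key <- function(lref, lor, rref, ror, insert_len) {
  a <- sprintf("%s:%s|%s:%s", lref, lor, rref, ror)
  flip <- function(o) if (o == "+") "-" else "+"
  b <- sprintf("%s:%s|%s:%s", rref, flip(ror), lref, flip(lor))
  sprintf("%s#%d", min(a, b), insert_len)
}

#' Annotate contigs and call junctions
#'
#' Each contig is locally aligned against the references (plasmid backbone,
#' complete template, wild-type locus); maximal non-overlapping hits of at
#' least `min_side` bp tile the contig and each adjacent pair of hits to
#' different references/orientations (or non-collinear coordinates) is
#' called as a junction. The intervening unaligned insert is annotated as a
#' homology-repair boundary (empty insert, genomic on one side), a partial
#' gRNA-site footprint, a plasmid backbone fragment, or unknown.
#'
#' Hits shorter than `min_anchor` never anchor the tiling (a short backbone
#' fragment at a junction aligns to the backbone too, but is debris captured
#' by the insert annotation, not a block).
#'
#' @param contigs `read_set` of contigs.
#' @param refs Named character vector of reference sequences; must contain
#'   `template`, `puc`, `chr17`.
#' @param grna_site gRNA target site sequence (protospacer + PAM).
#' @param min_side Minimum annotatable block per side (bp).
#' @param min_anchor Minimum length of a tiling anchor hit (bp).
#' @param min_identity Minimum identity of a contributing hit.
#' @return Data.frame of junction calls: contig, block pair (reference and
#'   orientation each side), contig coordinates, insert length and sequence,
#'   annotation, and a strand-canonical junction key.
#' @export
annotate_contigs <- function(contigs, refs, grna_site, min_side = 30L,
                             min_anchor = 60L, min_identity = 0.9) {
  calls <- list()
  for (ci in seq_len(nrow(contigs))) {
    cseq <- contigs$seq[ci]
    if (nchar(cseq) < 2L * min_side) next
    hits <- list()
    for (nm in names(refs)) {
      h <- align_local(cseq, refs[[nm]], min_score = min_side - 5L)
      if (nrow(h) == 0) next
      h$ref <- nm
      hits[[length(hits) + 1L]] <- h
    }
    if (length(hits) == 0) next
    hits <- do.call(rbind, hits)
    hits <- hits[(hits$qend - hits$qstart) >= max(min_side, min_anchor) &
                   hits$identity >= min_identity, , drop = FALSE]
    if (nrow(hits) < 2) next
    # greedy non-overlapping tiling of the contig by score
    hits <- hits[order(-hits$score, hits$ref, hits$tstart), , drop = FALSE]
    kept <- list()
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      overlap <- FALSE
      for (kp in kept) {
        # tolerate small hit overlaps: junctions inside a shared gRNA-site
        # footprint let both sides absorb a few common bases
        ov <- min(h$qend, kp$qend) - max(h$qstart, kp$qstart)
        if (ov > 25) { overlap <- TRUE; break }
      }
      if (!overlap) kept[[length(kept) + 1L]] <- h
    }
    kept <- do.call(rbind, kept)
    kept <- kept[order(kept$qstart), , drop = FALSE]
    if (nrow(kept) < 2) next
    for (i in seq_len(nrow(kept) - 1L)) {
      l <- kept[i, ]; r <- kept[i + 1L, ]
      gap_read <- r$qstart - l$qend
      same_block <- FALSE
      if (l$ref == r$ref && l$strand == r$strand) {
        gap_ref <- if (l$strand == "+") r$tstart - l$tend else l$tstart - r$tend
        if (abs(gap_ref - gap_read) <= 30) same_block <- TRUE
      }
      if (same_block) next
      ins_len <- max(0L, gap_read)
      ins_seq <- if (ins_len > 0) substr(cseq, l$qend + 1L, r$qstart) else ""
      genomic <- l$ref == "chr17" || r$ref == "chr17"
      ann <- if (ins_len == 0) {
        if (genomic) "HR_boundary" else "blunt"
      } else if (grepl(ins_seq, grna_site, fixed = TRUE) ||
                 grepl(revcomp(ins_seq), grna_site, fixed = TRUE)) {
        sprintf("partial_gRNA_footprint(%d)", ins_len)
      } else if (grepl(ins_seq, refs[["puc"]], fixed = TRUE) ||
                 grepl(revcomp(ins_seq), refs[["puc"]], fixed = TRUE)) {
        sprintf("backbone_fragment(%d)", ins_len)
      } else "unknown"
      calls[[length(calls) + 1L]] <- data.frame(
        contig = contigs$id[ci],
        left_ref = l$ref, left_orient = l$strand, left_end = l$qend,
        right_ref = r$ref, right_orient = r$strand, right_start = r$qstart,
        insert_len = ins_len, insert_seq = ins_seq, annotation = ann,
        key = canonical_junction_key(l$ref, l$strand, r$ref, r$strand,
                                     ins_len),
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0) {
    return(data.frame(contig = character(0), left_ref = character(0),
                      left_orient = character(0), left_end = integer(0),
                      right_ref = character(0), right_orient = character(0),
                      right_start = integer(0), insert_len = integer(0),
                      insert_seq = character(0), annotation = character(0),
                      key = character(0)))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Strand-canonical junction keys for a truth junction table
#' @param junctions Truth junction data.frame from [build_allele()].
#' @return Character vector of canonical keys.
#' @export
truth_junction_keys <- function(junctions) {
  vapply(seq_len(nrow(junctions)), function(i) {
    canonical_junction_key(junctions$left_ref[i], junctions$left_orient[i],
                           junctions$right_ref[i], junctions$right_orient[i],
                           junctions$insert_len[i])
  }, "")
}
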