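## Allele-structure inference from candidate long reads: tile reads into
## overlapping subreads, align them to a composite reference (genomic locus,
## plasmid backbone, complete template, optional decoys), merge collinear
## subread hits into per-read block strings, cluster identical canonical
## strings, and chain cluster strings into complete allele structures
## anchored at the genomic flanks.

#' Build the composite reference
#'
#' Contains the wild-type locus contig (`chr17`, both flanks around the
#' break point), the plasmid backbone (`puc`), the complete template
#' (`template`) and any decoy contigs.
#'
#' @param lib A `segment_library`.
#' @param decoys Optional decoy `read_set` from [make_decoy_genome()].
#' @return A `read_set` with an attribute `cut_site` (0-based position of the
#'   Cas9 cut on `chr17`).
#' @export
composite_reference <- function(lib, decoys = NULL) {
  wt <- build_allele(lib, builtin_blueprints(lib)$wildtype)
  ids <- c("chr17", "puc", "template")
  seqs <- c(wt$seq, segment_seq(lib, "PUC"), build_complete_template(lib)$seq)
  if (!is.null(decoys) && nrow(decoys) > 0) {
    ids <- c(ids, decoys$id)
    seqs <- c(seqs, decoys$seq)
  }
  if (anyDuplicated(ids)) stop("reference labels must be unique", call. = FALSE)
  ref <- read_set(ids, seqs)
  attr(ref, "cut_site") <- wt$cut_site
  ref
}

#' Tile a read into overlapping subreads
#'
#' 1 kb windows advancing by 0.5 kb (so consecutive subreads overlap by
#' 0.5 kb); the final subread is extended/shortened to end at the read end
#' and is never shorter than `window - step`. Reads shorter than `window`
#' yield a single whole-read subread.
#'
#' @param len Read length in bp (or a string, in which case its length is
#'   used).
#' @param window Subread window (bp).
#' @param step Tiling step (bp); must satisfy `window > step > 0`.
#' @return Data.frame with 0-based half-open `start`, `end`.
#' @export
tile_read <- function(len, window = 1000L, step = 500L) {
  if (is.character(len)) len <- nchar(len)
  if (!(window > step && step > 0)) {
    stop("window must exceed step and step must be positive", call. = FALSE)
  }
  if (len == 0) return(data.frame(start = integer(0), end = integer(0)))
  if (len < window) return(data.frame(start = 0L, end = as.integer(len)))
  count <- max(1L, as.integer(ceiling((len - window) / step)) + 1L)
  start <- (seq_len(count) - 1L) * as.integer(step)
  end <- pmin(start + as.integer(window), as.integer(len))
  end[count] <- as.integer(len)
  data.frame(start = start, end = end)
}

#' Map subreads to the composite reference
#'
#' Each subread receives its best hit (or none below the thresholds); ties
#' are broken deterministically (lowest reference label lexicographically,
#' then leftmost target position).
#'
#' @param subreads `read_set` of subreads.
#' @param ref Composite reference from [composite_reference()].
#' @param seed_k Seed k-mer length.
#' @param min_anchors Minimum chained seeds per candidate hit.
#' @param min_identity,min_len Hit acceptance thresholds.
#' @return Data.frame of best hits keyed by `subread` (index into
#'   `subreads`).
#' @export
map_subreads <- function(subreads, ref, seed_k = 15L, min_anchors = 5L,
                         min_identity = 0.66, min_len = 120L) {
  hits <- .cpp_map_reads(subreads$seq, ref$seq, as.integer(seed_k),
                         as.integer(min_anchors), 100L, 48L,
                         1L, -1L, -2L, -1L, TRUE)
  if (nrow(hits) == 0) return(hits)
  hits <- hits[hits$identity >= min_identity &
                 (hits$qend - hits$qstart) >= min_len, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  hits$target_label <- ref$id[hits$target]
  ord <- order(hits$query, -hits$score, hits$target_label, hits$tstart,
               hits$strand)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$query), , drop = FALSE]
  names(hits)[names(hits) == "query"] <- "subread"
  rownames(hits) <- NULL
  hits
}

#' Derive a read's block string from its subread hits
#'
#' Merges consecutive subread hits to the same reference and orientation
#' with collinear coordinates (read-gap vs ref-gap within `merge_tol`) into
#' blocks; orientation flips, label changes and collinearity breaks (e.g.
#' the wrap from the end of one tandem template copy to the start of the
#' next) open new blocks. Blocks supported by less than `min_block_len` bp
#' of read are dropped; block read spans are made non-overlapping.
#'
#' @param hits Data.frame of this read's subread hits with read-coordinate
#'   columns `rstart`, `rend` (subread hit endpoints shifted to read
#'   coordinates), plus `target_label`, `strand`, `tstart`, `tend`.
#' @param read_id Identifier stored in the result.
#' @param min_block_len Minimum block support (bp of read).
#' @param merge_tol Collinearity tolerance (bp).
#' @return Data.frame: one row per block, ordered along the read.
#' @export
block_string <- function(hits, read_id = "read", min_block_len = 300L,
                         merge_tol = 200L) {
  empty <- data.frame(read_id = character(0), target = character(0),
                      strand = character(0), qstart = integer(0),
                      qend = integer(0), tstart = integer(0),
                      tend = integer(0), n_subreads = integer(0))
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  hits <- hits[order(hits$rstart, hits$rend), , drop = FALSE]
  blocks <- list()
  cur <- NULL
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (!is.null(cur) && h$target_label == cur$target &&
        h$strand == cur$strand) {
      gap_read <- h$rstart - cur$qend
      gap_ref <- if (h$strand == "+") h$tstart - cur$tend
                 else cur$tstart - h$tend
      if (abs(gap_ref - gap_read) <= merge_tol) {
        cur$qend <- max(cur$qend, h$rend)
        cur$qstart <- min(cur$qstart, h$rstart)
        cur$tstart <- min(cur$tstart, h$tstart)
        cur$tend <- max(cur$tend, h$tend)
        cur$n_subreads <- cur$n_subreads + 1L
        next
      }
    }
    if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
    cur <- data.frame(read_id = read_id, target = h$target_label,
                      strand = h$strand, qstart = h$rstart, qend = h$rend,
                      tstart = h$tstart, tend = h$tend, n_subreads = 1L,
                      stringsAsFactors = FALSE)
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
  out <- do.call(rbind, blocks)
  out <- out[(out$qend - out$qstart) >= min_block_len, , drop = FALSE]
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {     # enforce non-overlapping read spans
      if (out$qstart[i] < out$qend[i - 1]) {
        mid <- (out$qstart[i] + out$qend[i - 1]) %/% 2L
        out$qend[i - 1] <- mid
        out$qstart[i] <- mid
      }
    }
  }
  rownames(out) <- NULL
  out
}

## token helpers -------------------------------------------------------------

classify_chr17 <- function(tstart, tend, cut, tol = 60L) {
  if (tstart < cut - tol && tend > cut + tol) return("chr17F")
  if (tend <= cut + tol) return("chr17L")
  if (tstart >= cut - tol) return("chr17R")
  "chr17F"
}

block_tokens <- function(blocks, cut) {
  if (nrow(blocks) == 0) return(character(0))
  labs <- blocks$target
  is17 <- labs == "chr17"
  if (any(is17)) {
    labs[is17] <- mapply(classify_chr17, blocks$tstart[is17],
                         blocks$tend[is17], MoreArgs = list(cut = cut))
  }
  paste0(labs, ":", blocks$strand)
}

flip_tokens <- function(tokens) {
  if (length(tokens) == 0) return(tokens)
  lab <- sub(":[+-]$", "", tokens)
  str <- sub("^.*:", "", tokens)
  rev(paste0(lab, ":", ifelse(str == "+", "-", "+")))
}

token_compatible <- function(read_tok, struct_tok) {
  if (read_tok == struct_tok) return(TRUE)
  # a partial flank observation is compatible with a cut-spanning flank
  rl <- sub(":[+-]$", "", read_tok); rs <- sub("^.*:", "", read_tok)
  sl <- sub(":[+-]$", "", struct_tok); ss <- sub("^.*:", "", struct_tok)
  rs == ss && sl == "chr17F" && rl %in% c("chr17L", "chr17R")
}

# offsets (1-based) at which `sub` matches a contiguous window of `full`
sublist_offsets <- function(sub, full) {
  n <- length(sub); m <- length(full)
  if (n == 0 || n > m) return(integer(0))
  offs <- integer(0)
  for (o in seq_len(m - n + 1L)) {
    ok <- TRUE
    for (i in seq_len(n)) {
      if (!token_compatible(sub[i], full[o + i - 1L])) { ok <- FALSE; break }
    }
    if (ok) offs <- c(offs, o)
  }
  offs
}

#' Cluster per-read block strings
#'
#' Reads with identical canonical block-label/orientation strings form one
#' cluster; canonicalisation maps a string and its reverse complement
#' (reversed order, flipped orientations) to one representative. Partial
#' strings stay in their own cluster but are annotated as compatible with
#' longer clusters' strings.
#'
#' @param blocks_by_read Named list of block data.frames (one per read) from
#'   [block_string()].
#' @param cut Cas9 cut position on the `chr17` reference.
#' @return List with `reads` (per-read canonical string and orientation) and
#'   `clusters` (one row per distinct canonical string with size and
#'   compatible longer clusters).
#' @export
cluster_blockstrings <- function(blocks_by_read, cut) {
  per_read <- lapply(names(blocks_by_read), function(id) {
    toks <- block_tokens(blocks_by_read[[id]], cut)
    if (length(toks) == 0) return(NULL)
    fwd <- paste(toks, collapse = " ")
    flp <- paste(flip_tokens(toks), collapse = " ")
    if (flp < fwd) {
      list(read_id = id, tokens = flip_tokens(toks), flipped = TRUE)
    } else {
      list(read_id = id, tokens = toks, flipped = FALSE)
    }
  })
  per_read <- Filter(Negate(is.null), per_read)
  if (length(per_read) == 0) {
    return(list(reads = data.frame(read_id = character(0),
                                   string = character(0),
                                   flipped = logical(0)),
                clusters = data.frame(cluster = integer(0),
                                      string = character(0),
                                      n_reads = integer(0),
                                      compatible_with = character(0))))
  }
  reads <- data.frame(
    read_id = vapply(per_read, `[[`, "", "read_id"),
    string = vapply(per_read, function(x) paste(x$tokens, collapse = " "), ""),
    flipped = vapply(per_read, `[[`, TRUE, "flipped"),
    stringsAsFactors = FALSE)
  strings <- sort(unique(reads$string))
  sizes <- vapply(strings, function(s) sum(reads$string == s), 0L)
  toks <- strsplit(strings, " ", fixed = TRUE)
  compat <- vapply(seq_along(strings), function(i) {
    longer <- which(lengths(toks) > length(toks[[i]]))
    hit <- longer[vapply(longer, function(j) {
      length(sublist_offsets(toks[[i]], toks[[j]])) > 0 ||
        length(sublist_offsets(flip_tokens(toks[[i]]), toks[[j]])) > 0
    }, TRUE)]
    paste(hit, collapse = ",")
  }, "")
  list(reads = reads,
       clusters = data.frame(cluster = seq_along(strings), string = strings,
                             n_reads = unname(sizes),
                             compatible_with = compat,
                             stringsAsFactors = FALSE))
}

## chaining ------------------------------------------------------------------

chain_structures <- function(cluster_tokens, max_blocks = 60L,
                             max_states = 20000L, min_overlap = 3L) {
  # orientations available for chaining
  orients <- list()
  for (tk in cluster_tokens) {
    orients[[length(orients) + 1L]] <- tk
    orients[[length(orients) + 1L]] <- flip_tokens(tk)
  }
  orients <- unique(orients)
  completes <- list()
  seen <- new.env(parent = emptyenv())
  states <- 0L
  is_complete <- function(chain) {
    length(chain) >= 1 &&
      (chain[1] == "chr17F:+" ||
         (chain[1] == "chr17L:+" && chain[length(chain)] == "chr17R:+"))
  }
  extend <- function(chain) {
    states <<- states + 1L
    if (states > max_states || length(chain) > max_blocks) return(invisible())
    key <- paste(chain, collapse = " ")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    if (is_complete(chain)) {
      completes[[length(completes) + 1L]] <<- chain
      return(invisible())
    }
    nexts <- character(0)
    for (s in orients) {
      if (length(s) < min_overlap + 1L) next
      omax <- min(length(chain), length(s) - 1L)
      if (omax < min_overlap) next
      for (o in seq(omax, min_overlap)) {
        if (identical(s[seq_len(o)],
                      chain[seq(length(chain) - o + 1L, length(chain))])) {
          nexts <- c(nexts, s[o + 1L])
          break
        }
      }
    }
    for (nx in unique(nexts)) extend(c(chain, nx))
    invisible()
  }
  starts <- Filter(function(s) s[1] %in% c("chr17L:+", "chr17F:+"), orients)
  for (s in starts) extend(s)
  unique(completes)
}

#' Call allele structures from block-string clusters
#'
#' Chains cluster block strings into maximal allele structures anchored at
#' the genomic flanks (each extension requires a suffix/prefix overlap of at
#' least `min_overlap` blocks, so a structure can only be assembled when at
#' least one read distinguishes it from every alternative continuation). A
#' structure is reported when supported by at least `min_reads` compatible
#' reads drawn from at least `min_clusters` distinct clusters; structures
#' short enough to be spanned by single reads may instead be validated by
#' `min_reads` full-span reads. Structures without any uniquely-supporting
#' read are flagged `ambiguous`.
#'
#' @param clustering Result of [cluster_blockstrings()].
#' @param blocks_by_read Named list of per-read block data.frames (for block
#'   length and junction-gap estimation).
#' @param cut Cas9 cut position on `chr17`.
#' @param min_reads,min_clusters Support rule thresholds.
#' @param min_overlap Chaining overlap (blocks).
#' @return List of `structure_call` lists sorted by decreasing insertion
#'   length: `blockstring`, `tokens`, `n_template_copies`,
#'   `n_backbone_copies`, `insertion_length_bp`, `insertion_kb_floor`,
#'   `n_support`, `n_clusters`, `support`, `ambiguous`.
#' @export
call_structures <- function(clustering, blocks_by_read, cut,
                            min_reads = 2L, min_clusters = 2L,
                            min_overlap = 3L) {
  if (min_reads < 1 || min_clusters < 1) {
    stop("support thresholds must be >= 1", call. = FALSE)
  }
  cl <- clustering$clusters
  if (nrow(cl) == 0) return(list())
  cluster_tokens <- strsplit(cl$string, " ", fixed = TRUE)
  chains <- chain_structures(cluster_tokens, min_overlap = min_overlap)
  if (length(chains) == 0) return(list())
  read_tokens <- strsplit(clustering$reads$string, " ", fixed = TRUE)
  names(read_tokens) <- clustering$reads$read_id
  calls <- list()
  for (chain in chains) {
    # supporting reads: canonical string compatible with the chain
    offsets <- lapply(read_tokens, function(tk) {
      o <- sublist_offsets(tk, chain)
      if (length(o) == 0) {
        o <- sublist_offsets(flip_tokens(tk), chain)
        if (length(o) > 0) attr(o, "flip") <- TRUE
      }
      o
    })
    supp <- names(offsets)[lengths(offsets) > 0]
    if (length(supp) == 0) next
    strings <- clustering$reads$string[match(supp, clustering$reads$read_id)]
    full <- supp[vapply(supp, function(id)
      length(read_tokens[[id]]) == length(chain), TRUE)]
    n_support <- length(supp)
    n_clusters <- length(unique(strings))
    ok <- n_support >= min_reads &&
      (n_clusters >= min_clusters || length(full) >= min_reads)
    if (!ok) next
    labs <- sub(":[+-]$", "", chain)
    genomic <- grepl("^chr17", labs)
    # estimate per-position block lengths and junction gaps from reads with a
    # unique placement on the chain
    len_obs <- vector("list", length(chain))
    gap_obs <- vector("list", max(0L, length(chain) - 1L))
    for (id in supp) {
      o <- offsets[[id]]
      if (length(o) != 1) next
      blk <- blocks_by_read[[id]]
      flipped_canon <- clustering$reads$flipped[
        match(id, clustering$reads$read_id)]
      flipped_match <- isTRUE(attr(o, "flip"))
      if (xor(flipped_canon, flipped_match)) {
        blk <- blk[rev(seq_len(nrow(blk))), , drop = FALSE]
        # read-coordinate order reversed; spans/gaps are orientation-free
        qs <- blk$qstart; qe <- blk$qend
        blk$qstart <- -qe; blk$qend <- -qs
      }
      n <- nrow(blk)
      for (i in seq_len(n)) {
        pos <- o + i - 1L
        if (i > 1 && i < n) {   # interior blocks reflect true block extent
          len_obs[[pos]] <- c(len_obs[[pos]], blk$tend[i] - blk$tstart[i])
        }
        if (i < n) {
          gap_obs[[pos]] <- c(gap_obs[[pos]],
                              max(0L, blk$qstart[i + 1L] - blk$qend[i]))
        }
      }
    }
    len_est <- numeric(length(chain))
    for (p in seq_along(chain)) {
      if (genomic[p]) next
      len_est[p] <- if (length(len_obs[[p]]) > 0) {
        median(len_obs[[p]])
      } else {
        # fall back to the widest span observed anywhere for this position
        spans <- unlist(lapply(supp, function(id) {
          o <- offsets[[id]]
          if (length(o) != 1) return(numeric(0))
          blk <- blocks_by_read[[id]]
          i <- p - o + 1L
          if (i >= 1 && i <= nrow(blk)) blk$tend[i] - blk$tstart[i] else numeric(0)
        }))
        if (length(spans) > 0) max(spans) else 0
      }
    }
    gap_est <- vapply(gap_obs, function(g)
      if (length(g) > 0) median(g) else 0, 0)
    ins_len <- sum(len_est) + sum(gap_est)
    calls[[length(calls) + 1L]] <- list(
      tokens = chain,
      blockstring = paste(chain, collapse = " "),
      n_template_copies = sum(labs == "template"),
      n_backbone_copies = sum(labs == "puc"),
      insertion_length_bp = round(ins_len),
      insertion_kb_floor = floor(round(ins_len) / 1000),
      block_lengths = round(len_est), junction_gaps = round(gap_est),
      n_support = n_support, n_clusters = n_clusters,
      support = supp, n_fullspan = length(full))
  }
  if (length(calls) == 0) return(list())
  # ambiguity: no read supports only this structure
  supp_sets <- lapply(calls, `[[`, "support")
  for (i in seq_along(calls)) {
    others <- unique(unlist(supp_sets[-i]))
    calls[[i]]$ambiguous <- length(setdiff(supp_sets[[i]], others)) == 0
  }
  ord <- order(-vapply(calls, `[[`, 0, "insertion_length_bp"),
               vapply(calls, `[[`, "", "blockstring"))
  calls <- calls[ord]
  for (i in seq_along(calls)) {
    calls[[i]]$name <- sprintf("structure%d", i)
    class(calls[[i]]) <- "structure_call"
  }
  calls
}

#' Call the small indel at the Cas9 cut site
#'
#' For a structure without template copies, reconstructs the locus sequence
#' from its cut-spanning supporting reads (majority consensus when several
#' are available), aligns it to the wild-type locus, and reports the net
#' signed indel length within `window` bp of the cut together with the
#' inserted sequence.
#'
#' @param structure A `structure_call` with `n_template_copies == 0`.
#' @param reads `read_set` containing the supporting reads.
#' @param blocks_by_read Named list of per-read block data.frames.
#' @param wildtype Wild-type locus sequence (string).
#' @param cut 0-based cut position on the wild-type locus.
#' @param window Half-width of the window around the cut (bp).
#' @param max_reads Consensus group size cap.
#' @return List with `indel` (signed bp; insertions positive) and
#'   `insert_seq`.
#' @export
call_cutsite_indel <- function(structure, reads, blocks_by_read, wildtype,
                               cut, window = 50L, max_reads = 20L) {
  if (structure$n_template_copies != 0) {
    stop("cut-site indel calling requires a template-free structure",
         call. = FALSE)
  }
  ids <- structure$support
  spanning <- character(0)
  orient <- character(0)
  for (id in ids) {
    blk <- blocks_by_read[[id]]
    if (is.null(blk) || nrow(blk) != 1 || blk$target != "chr17") next
    if (blk$tstart < cut - window && blk$tend > cut + window) {
      spanning <- c(spanning, id)
      orient <- c(orient, blk$strand)
    }
  }
  if (length(spanning) == 0) return(list(indel = NA_integer_, insert_seq = ""))
  if (length(spanning) > max_reads) {
    lens <- nchar(reads$seq[match(spanning, reads$id)])
    keep <- order(-lens, spanning)[seq_len(max_reads)]
    orient <- orient[keep]; spanning <- spanning[keep]
  }
  seqs <- reads$seq[match(spanning, reads$id)]
  seqs[orient == "-"] <- revcomp(seqs[orient == "-"])
  query <- if (length(seqs) >= 2) {
    consensus_call(msa(seqs))$seq
  } else {
    seqs[1]
  }
  band <- max(150L, abs(nchar(query) - nchar(wildtype)) + 60L)
  al <- banded_align(query, wildtype, band = band, traceback = TRUE)
  qa <- strsplit(al$q_aln, "")[[1]]
  ta <- strsplit(al$t_aln, "")[[1]]
  tpos <- cumsum(ta != "-")       # wildtype position after each column
  inwin <- tpos > cut - window & tpos <= cut + window
  ins_cols <- inwin & ta == "-"
  del_cols <- inwin & qa == "-"
  list(indel = sum(ins_cols) - sum(del_cols),
       insert_seq = paste(qa[ins_cols], collapse = ""))
}

#' Expected block tokens of a built allele (truth oracle helper)
#'
#' Converts a [build_allele()] truth object into the token string the
#' structure caller should recover (adjacent genomic blocks merge into a
#' cut-spanning flank token).
#'
#' @param allele Result of [build_allele()].
#' @return Character vector of tokens.
#' @export
truth_tokens <- function(allele) {
  b <- allele$blocks[allele$blocks$role != "insert", , drop = FALSE]
  toks <- character(0)
  i <- 1
  while (i <= nrow(b)) {
    if (b$ref[i] == "chr17") {
      if (i < nrow(b) && b$ref[i + 1] == "chr17") {
        toks <- c(toks, "chr17F:+"); i <- i + 2; next
      }
      side <- if (b$seg[i] == "CHR17_L") "chr17L" else "chr17R"
      toks <- c(toks, paste0(side, ":+")); i <- i + 1; next
    }
    toks <- c(toks, paste0(b$ref[i], ":", b$orient[i]))
    i <- i + 1
  }
  toks
}
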