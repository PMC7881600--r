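## Bait construction and candidate long-read recruitment: the first stage of
## the resolution chain. A read is recruited when it aligns to any of four
## baits (wild-type locus around the break point, plasmid backbone, complete
## template, NHEJ-insertion allele) with at least `min_hit_len` aligned bases
## at `min_identity` on either strand.

#' Build the recruitment bait set
#'
#' Four baits: the wild-type locus (1 kb before and after the break point,
#' 2000 bp with defaults), the plasmid backbone, the complete template
#' (including the homology arms), and the NHEJ-insertion allele detected by
#' Sanger sequencing (wild type + 26 bp).
#'
#' @param lib A `segment_library`.
#' @param blueprints Named list of blueprints (defaults to
#'   [builtin_blueprints()]); must contain `wildtype` and `alleleA`.
#' @return A `read_set` with records `wildtype_locus`, `puc_backbone`,
#'   `complete_template`, `nhej_allele`.
#' @export
build_baits <- function(lib, blueprints = NULL) {
  if (is.null(blueprints)) blueprints <- builtin_blueprints(lib)
  for (nm in c("wildtype", "alleleA")) {
    if (!nm %in% names(blueprints)) {
      stop(sprintf("blueprint '%s' required for baits", nm), call. = FALSE)
    }
  }
  wt <- build_allele(lib, blueprints$wildtype)
  a <- build_allele(lib, blueprints$alleleA)
  read_set(c("wildtype_locus", "puc_backbone", "complete_template",
             "nhej_allele"),
           c(wt$seq, segment_seq(lib, "PUC"),
             build_complete_template(lib)$seq, a$seq))
}

#' Recruit candidate reads against the bait set
#'
#' @param reads A `read_set` of long reads (may be empty).
#' @param baits A bait `read_set` from [build_baits()].
#' @param min_hit_len Minimum aligned length of a recruiting hit (bp).
#' @param min_identity Minimum alignment identity of a recruiting hit.
#' @param seed_k Seed k-mer length for the mapper.
#' @return List with `reads` (the recruited subset, original order) and
#'   `report` (one row per read x bait with the best hit: aligned span,
#'   identity, strand, and whether it recruits).
#' @export
recruit_reads <- function(reads, baits, min_hit_len = 500,
                          min_identity = 0.8, seed_k = 15L) {
  if (min_hit_len <= 0 || min_identity <= 0) {
    stop("recruitment thresholds must be positive", call. = FALSE)
  }
  empty_report <- data.frame(read_id = character(0), bait = character(0),
                             strand = character(0), hit_len = integer(0),
                             identity = numeric(0), score = numeric(0),
                             recruited = logical(0))
  if (is.null(reads) || nrow(reads) == 0) {
    return(list(reads = read_set(character(0), character(0)),
                report = empty_report))
  }
  hits <- .cpp_map_reads(reads$seq, baits$seq, as.integer(seed_k), 4L, 100L,
                         48L, 1L, -1L, -2L, -1L, TRUE)
  if (nrow(hits) == 0) {
    return(list(reads = reads[0, , drop = FALSE], report = empty_report))
  }
  hits$hit_len <- hits$qend - hits$qstart
  hits$read_id <- reads$id[hits$query]
  hits$bait <- baits$id[hits$target]
  hits$recruiting <- hits$hit_len >= min_hit_len & hits$identity >= min_identity
  # best hit per read x bait (highest score, then longest)
  ord <- order(hits$read_id, hits$bait, -hits$score, -hits$hit_len)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(paste(hits$read_id, hits$bait)), , drop = FALSE]
  # recruiting flag must consider all hits, not only the best-scoring one
  rec_by_pair <- tapply(hits$recruiting, paste(hits$read_id, hits$bait), any)
  best$recruited <- as.logical(rec_by_pair[paste(best$read_id, best$bait)])
  report <- data.frame(read_id = best$read_id, bait = best$bait,
                       strand = best$strand, hit_len = best$hit_len,
                       identity = best$identity, score = best$score,
                       recruited = best$recruited, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  keep_ids <- unique(report$read_id[report$recruited])
  out <- reads[reads$id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  list(reads = out, report = report)
}
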