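## End-to-end orchestration: simulate a dataset from a run configuration,
## resolve allele structures from reads, and write report bundles. Every
## stage is deterministic given the configuration seed.

#' Default run configuration
#'
#' All stage thresholds in one serialisable list; a run is fully reproducible
#' from the configuration alone.
#'
#' @param seed Integer master seed (sub-seeds are derived from it).
#' @param ... Named overrides of any configuration entry.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    length_overrides = NULL,
    genotype = default_genotype(),
    coverage_long = 50,
    coverage_short = 100,
    long_model = long_read_model(),
    short_model = short_read_model(),
    decoy_n = 2L, decoy_len = 20000L,
    recruit_min_hit_len = 500L, recruit_min_identity = 0.8,
    tile_window = 1000L, tile_step = 500L,
    min_block_len = 300L, merge_tol = 200L,
    min_reads = 2L, min_clusters = 2L, chain_overlap = 3L,
    edge_len = 50L, edge_k = 25L, trim_cutoff = 3L, asm_min_overlap = 16L,
    flank_margin = 200L, consensus_max_reads = 20L, consensus_min_reads = 2L
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Simulate a complete synthetic dataset
#'
#' Builds the segment library, decoy contigs, ground-truth alleles and both
#' read sets from the configuration. Identical configurations produce
#' byte-identical outputs.
#'
#' @param config A [default_config()] list.
#' @param outdir Optional directory; when given, references, reads and truth
#'   tables are written there along with a manifest.
#' @return List: `lib`, `blueprints`, `alleles`, `decoys`, `long`, `short`,
#'   `manifest`.
#' @export
run_simulate <- function(config = default_config(), outdir = NULL) {
  if (config$coverage_long <= 0 || config$coverage_short <= 0) {
    stop("coverage must be positive", call. = FALSE)
  }
  lib <- make_library(config$seed, config$length_overrides)
  blueprints <- builtin_blueprints(lib)
  alleles <- lapply(config$genotype$name,
                    function(nm) build_allele(lib, blueprints[[nm]]))
  names(alleles) <- config$genotype$name
  decoys <- make_decoy_genome(lib, config$decoy_n, config$decoy_len,
                              seed = config$seed + 7L)
  long <- simulate_long(lib, config$genotype, config$long_model,
                        config$coverage_long, seed = config$seed + 1L,
                        blueprints = blueprints)
  short <- simulate_short(lib, config$genotype, config$short_model,
                          config$coverage_short, seed = config$seed + 2L,
                          blueprints = blueprints)
  manifest <- list(
    seed = config$seed,
    alleles = data.frame(
      name = config$genotype$name,
      abundance = config$genotype$abundance,
      length = vapply(alleles, function(a) nchar(a$seq), 0),
      insertion_length = vapply(alleles, `[[`, 0, "insertion_length")),
    n_long_reads = nrow(long$reads),
    long_bases = sum(nchar(long$reads$seq)),
    n_short_pairs = nrow(short$truth),
    files = character(0))
  out <- list(lib = lib, blueprints = blueprints, alleles = alleles,
              decoys = decoys, long = long, short = short,
              manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      refs = write_fasta(read_set(
        c("template", "puc", "wildtype_locus"),
        c(build_complete_template(lib)$seq, segment_seq(lib, "PUC"),
          build_allele(lib, blueprints$wildtype)$seq)),
        file.path(outdir, "references.fasta")),
      decoys = write_fasta(decoys, file.path(outdir, "decoys.fasta")),
      long = write_fastq(long$reads, file.path(outdir, "long_reads.fastq")),
      r1 = write_fastq(short$r1, file.path(outdir, "short_R1.fastq")),
      r2 = write_fastq(short$r2, file.path(outdir, "short_R2.fastq")),
      long_truth = write_tsv(long$truth, file.path(outdir, "long_truth.tsv")),
      short_truth = write_tsv(short$truth, file.path(outdir, "short_truth.tsv")))
    for (nm in names(alleles)) {
      files[paste0("allele_", nm)] <- write_fasta(
        read_set(nm, alleles[[nm]]$seq),
        file.path(outdir, paste0(nm, ".fasta")))
      files[paste0("bed_", nm)] <- allele_truth_bed(
        alleles[[nm]], file.path(outdir, paste0(nm, "_blocks.bed")))
    }
    out$manifest$files <- unname(files)
    jsonlite::write_json(out$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Resolve allele structures from a simulated (or loaded) dataset
#'
#' Runs the full chain: recruit candidate long reads, tile and map subreads,
#' build and cluster block strings, chain structures, call the cut-site
#' indel for template-free structures, discover junctions from short reads,
#' confirm substructure consensi, profile depth and scan for off-target
#' integration. Returns a JSON-serialisable summary bundle.
#'
#' @param sim Result of [run_simulate()] (or a compatible list with `lib`,
#'   `decoys`, `long`, `short`).
#' @param config A [default_config()] list.
#' @return A `resolve_bundle` list; see the summary element names.
#' @export
run_resolve <- function(sim, config = default_config()) {
  lib <- sim$lib
  long_reads <- sim$long$reads
  if (is.null(long_reads) || nrow(long_reads) == 0) {
    warning("empty long-read set: nothing to resolve")
    return(structure(list(summary = list(n_reads_in = 0L, structures = list()),
                          empty = TRUE), class = "resolve_bundle"))
  }
  baits <- build_baits(lib)
  rec <- recruit_reads(long_reads, baits, config$recruit_min_hit_len,
                       config$recruit_min_identity)
  message(sprintf("recruit: %d / %d reads", nrow(rec$reads), nrow(long_reads)))
  ref <- composite_reference(lib, sim$decoys)
  cut <- attr(ref, "cut_site")
  res <- resolve_structures(rec$reads, ref, cut, config)
  structures <- res$structures
  wt_seq <- build_allele(lib, builtin_blueprints(lib)$wildtype)$seq
  for (i in seq_along(structures)) {
    if (structures[[i]]$n_template_copies == 0) {
      ind <- call_cutsite_indel(structures[[i]], rec$reads,
                                res$blocks_by_read, wt_seq, cut)
      structures[[i]]$cutsite_indel <- ind$indel
      structures[[i]]$cutsite_insert_seq <- ind$insert_seq
    } else {
      structures[[i]]$cutsite_indel <- NA_integer_
      structures[[i]]$cutsite_insert_seq <- ""
    }
  }
  message(sprintf("structures: %d reported", length(structures)))
  # junction discovery from short reads
  refs2 <- c(puc = segment_seq(lib, "PUC"),
             template = build_complete_template(lib)$seq)
  idx <- build_edge_index(refs2, config$edge_len, config$edge_k)
  short_all <- read_set(c(sim$short$r1$id, sim$short$r2$id),
                        c(sim$short$r1$seq, sim$short$r2$seq))
  sel <- select_reads(short_all, idx)
  trimmed <- error_trim(sel$reads, config$trim_cutoff, config$edge_k)
  contigs <- assemble_greedy(trimmed, config$asm_min_overlap, config$edge_k)
  jrefs <- c(refs2, chr17 = wt_seq)
  junctions <- annotate_contigs(contigs, jrefs, lib$grna_site)
  message(sprintf("junctions: %d selected reads, %d contigs, %d calls",
                  nrow(sel$reads), nrow(contigs), nrow(junctions)))
  # consensus confirmation
  groups <- group_and_trim(rec$reads, structures, res$clustering,
                           res$blocks_by_read, cut, config$flank_margin)
  groups <- confirm_substructures(groups, config$consensus_max_reads,
                                  config$consensus_min_reads)
  # profiling
  panel <- read_set(c("complete_template", "nhej_allele", "puc_backbone"),
                    c(build_complete_template(lib)$seq,
                      build_allele(lib, builtin_blueprints(lib)$alleleA)$seq,
                      segment_seq(lib, "PUC")))
  depth <- depth_profile(short_all, panel)
  offt <- off_target_scan(long_reads, ref, lib)
  struct_df <- if (length(structures) > 0) {
    do.call(rbind, lapply(structures, function(s) data.frame(
      name = s$name, blockstring = s$blockstring,
      n_template_copies = s$n_template_copies,
      n_backbone_copies = s$n_backbone_copies,
      insertion_length_bp = s$insertion_length_bp,
      insertion_kb_floor = s$insertion_kb_floor,
      cutsite_indel = s$cutsite_indel,
      n_support = s$n_support, n_clusters = s$n_clusters,
      ambiguous = s$ambiguous, stringsAsFactors = FALSE)))
  } else {
    data.frame()
  }
  summary <- list(
    n_reads_in = nrow(long_reads),
    n_recruited = nrow(rec$reads),
    n_read_clusters = nrow(res$clustering$clusters),
    structures = struct_df,
    junctions = junctions,
    per_edge_selected = as.list(sel$per_edge),
    n_contigs = nrow(contigs),
    substructures = data.frame(
      structure = vapply(groups, `[[`, "", "structure"),
      cluster = vapply(groups, `[[`, "", "cluster"),
      n_reads = vapply(groups, function(g) length(g$seqs), 0L),
      n_used = vapply(groups, `[[`, 0L, "n_used"),
      consensus_len = vapply(groups, function(g)
        if (is.na(g$consensus)) 0L else nchar(g$consensus), 0L),
      consensus_agreement = vapply(groups, function(g)
        round(g$agreement, 5), 0)),
    depth = depth$summary,
    off_target = offt$n_flagged)
  structure(list(summary = summary, structures = structures,
                 recruit_report = rec$report, clustering = res$clustering,
                 blocks_by_read = res$blocks_by_read, groups = groups,
                 contigs = contigs, depth = depth, empty = FALSE),
            class = "resolve_bundle")
}

#' Core structure-resolution step (tile, map, block strings, cluster, chain)
#'
#' @param reads Recruited `read_set`.
#' @param ref Composite reference from [composite_reference()].
#' @param cut Cas9 cut position on `chr17`.
#' @param config A [default_config()] list.
#' @return List: `structures`, `clustering`, `blocks_by_read`, `subread_hits`.
#' @export
resolve_structures <- function(reads, ref, cut, config = default_config()) {
  if (nrow(reads) == 0) {
    return(list(structures = list(),
                clustering = cluster_blockstrings(list(), cut),
                blocks_by_read = list(), subread_hits = NULL))
  }
  sub_id <- character(0); sub_seq <- character(0)
  sub_read <- character(0); sub_start <- integer(0)
  for (i in seq_len(nrow(reads))) {
    tiles <- tile_read(nchar(reads$seq[i]), config$tile_window,
                       config$tile_step)
    if (nrow(tiles) == 0) next
    sub_id <- c(sub_id, sprintf("%s_t%03d", reads$id[i], seq_len(nrow(tiles))))
    sub_seq <- c(sub_seq, substring(reads$seq[i], tiles$start + 1L, tiles$end))
    sub_read <- c(sub_read, rep(reads$id[i], nrow(tiles)))
    sub_start <- c(sub_start, tiles$start)
  }
  subreads <- read_set(sub_id, sub_seq)
  hits <- map_subreads(subreads, ref)
  blocks_by_read <- list()
  if (nrow(hits) > 0) {
    hits$read_id <- sub_read[hits$subread]
    hits$rstart <- sub_start[hits$subread] + hits$qstart
    hits$rend <- sub_start[hits$subread] + hits$qend
    for (id in unique(hits$read_id)) {
      b <- block_string(hits[hits$read_id == id, , drop = FALSE], id,
                        config$min_block_len, config$merge_tol)
      if (nrow(b) > 0) blocks_by_read[[id]] <- b
    }
  }
  clustering <- cluster_blockstrings(blocks_by_read, cut)
  structures <- call_structures(clustering, blocks_by_read, cut,
                                config$min_reads, config$min_clusters,
                                config$chain_overlap)
  list(structures = structures, clustering = clustering,
       blocks_by_read = blocks_by_read, subread_hits = hits)
}

#' Write a human-readable report bundle
#'
#' Idempotent: re-running on the same bundle produces byte-identical files.
#'
#' @param bundle A `resolve_bundle` from [run_resolve()].
#' @param outdir Output directory.
#' @return Invisibly, the written file paths.
#' @export
run_report <- function(bundle, outdir) {
  if (is.null(bundle) || !inherits(bundle, "resolve_bundle")) {
    stop("run_report requires a resolve_bundle", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  s <- bundle$summary
  files <- character(0)
  files["summary"] <- file.path(outdir, "summary.json")
  jsonlite::write_json(s, files["summary"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!bundle$empty) {
    files["structures"] <- write_tsv(s$structures,
                                     file.path(outdir, "structures.tsv"))
    files["junctions"] <- write_tsv(s$junctions,
                                    file.path(outdir, "junctions.tsv"))
    files["clusters"] <- write_tsv(bundle$clustering$clusters,
                                   file.path(outdir, "clusters.tsv"))
    files["depth"] <- write_depth_tsv(bundle$depth,
                                      file.path(outdir, "depth.tsv"))
    files["contigs"] <- write_fasta(bundle$contigs,
                                    file.path(outdir, "contigs.fasta"))
    # inferred junction positions on each reconstructed allele (insertion
    # coordinates: genomic flanks contribute no length)
    jb <- list()
    for (st in bundle$structures) {
      if (length(st$tokens) < 2) next
      for (k in seq_len(length(st$tokens) - 1L)) {
        pos <- sum(st$block_lengths[seq_len(k)]) +
          sum(st$junction_gaps[seq_len(k)]) - st$junction_gaps[k]
        jb[[length(jb) + 1L]] <- data.frame(
          chrom = st$name, start = max(0L, pos),
          end = max(0L, pos) + max(1L, st$junction_gaps[k]),
          name = paste(st$tokens[k], st$tokens[k + 1L], sep = "|"),
          score = st$n_support, strand = "+")
      }
    }
    if (length(jb) > 0) {
      files["junction_bed"] <- write_bed(do.call(rbind, jb),
                                         file.path(outdir, "junctions.bed"))
    }
    md <- c("# Allele resolution summary", "",
            sprintf("- reads in: %d; recruited: %d", s$n_reads_in,
                    s$n_recruited),
            sprintf("- block-string clusters: %d", s$n_read_clusters),
            sprintf("- structures reported: %d", nrow(s$structures)),
            if (nrow(s$structures) > 0)
              sprintf("  - %s: %d template copies, %d backbone, ~%d kb (%d bp), support %d",
                      s$structures$name, s$structures$n_template_copies,
                      s$structures$n_backbone_copies,
                      s$structures$insertion_kb_floor,
                      s$structures$insertion_length_bp,
                      s$structures$n_support),
            sprintf("- junction calls: %d; contigs: %d",
                    nrow(s$junctions), s$n_contigs),
            sprintf("- off-target flagged reads: %d", s$off_target))
    files["md"] <- file.path(outdir, "summary.md")
    writeLines(md, files["md"])
  }
  invisible(files)
}
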