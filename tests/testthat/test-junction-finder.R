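edge_refs <- function() {
  lib <- fix_lib()
  c(puc = segment_seq(lib, "PUC"),
    template = build_complete_template(lib)$seq)
}

test_that("edge index yields 26 k-mers per 50 nt edge", {
  idx <- build_edge_index(edge_refs())
  expect_equal(nrow(idx$edges), 4)            # 2 references x 2 edges
  expect_equal(nrow(idx$kmer_table), 4 * 26)  # before dedup
  expect_true(all(table(idx$kmer_table$edge) == 26))
  idx1 <- build_edge_index(edge_refs(), edge_len = 25, k = 25)
  expect_true(all(table(idx1$kmer_table$edge) == 1))
  expect_error(build_edge_index(edge_refs(), edge_len = 20, k = 25), ">=")
})

test_that("select_reads equals the brute-force containment oracle", {
  idx <- build_edge_index(edge_refs())
  lib <- fix_lib()
  tmpl <- build_complete_template(lib)$seq
  withr::with_seed(51, {
    rnd <- vapply(1:30, function(i)
      paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""),
      "")
  })
  reads <- read_set(
    sprintf("s%02d", 1:33),
    c(substr(tmpl, 1, 50),                      # equals an edge 50-mer
      unname(revcomp(substr(tmpl, 1, 50))),     # its reverse complement
      substr(tmpl, 2000, 2149),                 # template interior: no edge
      rnd))
  sel <- select_reads(reads, idx)
  oracle <- vapply(reads$seq, function(r)
    any(vapply(idx$all_kmers, grepl, TRUE, x = r, fixed = TRUE)), TRUE)
  expect_setequal(sel$reads$id, reads$id[oracle])
  expect_true("s01" %in% sel$reads$id)
  expect_true("s02" %in% sel$reads$id)
  expect_false("s03" %in% sel$reads$id)
})

test_that("selection fishes every junction-adjacent edge of the simulation", {
  sim <- fix_sim()
  idx <- build_edge_index(edge_refs())
  short_all <- read_set(c(sim$short$r1$id, sim$short$r2$id),
                        c(sim$short$r1$seq, sim$short$r2$seq))
  sel <- select_reads(short_all, idx)
  expect_true(all(sel$per_edge > 0))
  # decoy-only reads select nothing
  decoys <- make_decoy_genome(fix_lib(), 1, 10000, seed = 52L)
  withr::with_seed(53, starts <- sample.int(9800, 50))
  dreads <- read_set(sprintf("d%02d", 1:50),
                     substring(decoys$seq[1], starts, starts + 149))
  expect_equal(nrow(select_reads(dreads, idx)$reads), 0)
})

test_that("error trimming truncates at the first weak-abundance base", {
  lib <- fix_lib()
  base <- substr(build_complete_template(lib)$seq, 101, 250)  # 150 bp
  clean <- read_set(sprintf("c%02d", 1:30), rep(base, 30))
  # cutoff 1 is the identity
  expect_identical(error_trim(clean, cutoff = 1)$seq, clean$seq)
  # at high coverage nothing is trimmed
  expect_identical(error_trim(clean, cutoff = 3)$seq, clean$seq)
  # one read with a substitution at position 75: every 25-mer covering the
  # error is unique, so the read is cut right at the error
  mut <- base
  substr(mut, 75, 75) <- setdiff(c("A", "C", "G", "T"),
                                 substr(base, 75, 75))[1]
  tr <- error_trim(read_set(c(clean$id, "mut"), c(clean$seq, mut)),
                   cutoff = 3)
  expect_equal(nchar(tr$seq[tr$id == "mut"]), 74)
  expect_identical(tr$seq[tr$id == "mut"], substr(base, 1, 74))
  # a singleton read (all its k-mers unique) is dropped entirely
  lone <- read_set("x", withr::with_seed(55, paste(
    sample(c("A", "C", "G", "T"), 160, replace = TRUE), collapse = "")))
  expect_equal(nrow(error_trim(rbind(clean, lone), cutoff = 3)), 30)
  expect_error(error_trim(clean, cutoff = 0), ">= 1")
})

test_that("greedy assembly reconstructs a tiled region into one contig", {
  lib <- fix_lib()
  region <- substr(build_complete_template(lib)$seq, 1001, 1600)  # 600 bp
  starts <- seq(1, 451, by = 50)
  reads <- read_set(sprintf("t%02d", seq_along(starts)),
                    substring(region, starts, starts + 149))
  ctg <- assemble_greedy(reads)
  expect_equal(nrow(ctg), 1)
  expect_true(grepl(region, ctg$seq[1], fixed = TRUE) ||
                grepl(unname(revcomp(region)), ctg$seq[1], fixed = TRUE))
  # order invariance (including reverse-complemented input reads)
  perm <- withr::with_seed(54, sample(nrow(reads)))
  reads2 <- reads[perm, ]
  reads2$seq[c(2, 5)] <- unname(revcomp(reads2$seq[c(2, 5)]))
  ctg2 <- assemble_greedy(reads2)
  canon <- function(x) pmin(x, unname(revcomp(x)))
  expect_identical(canon(ctg$seq), canon(ctg2$seq))
  # overlap below the minimum stays unassembled
  a <- substr(region, 1, 60); b <- substr(region, 51, 120)  # overlap 10 < 16
  expect_equal(nrow(assemble_greedy(read_set(c("a", "b"), c(a, b)),
                                    min_overlap = 16)), 2)
  # the same pair assembles once the overlap clears the threshold
  b2 <- substr(region, 41, 120)                             # overlap 20
  expect_equal(nrow(assemble_greedy(read_set(c("a", "b"), c(a, b2)),
                                    min_overlap = 16)), 1)
  # empty input
  expect_equal(nrow(assemble_greedy(read_set(character(0), character(0)))), 0)
  expect_error(assemble_greedy(reads, min_overlap = 10), ">= 11")
})

test_that("contig annotation recovers constructed junctions exactly", {
  lib <- fix_lib()
  tmpl <- build_complete_template(lib)$seq
  puc <- segment_seq(lib, "PUC")
  wt <- build_allele(lib, fix_blueprints()$wildtype)$seq
  refs <- c(puc = puc, template = tmpl, chr17 = wt)
  site20 <- substr(lib$grna_site, 1, 20)
  contigs <- read_set(
    c("j_footprint", "j_backbone56", "j_hr", "interior"),
    c(paste0(substr(tmpl, 5000, 5144), site20, substr(puc, 1, 140)),
      paste0(substr(puc, 2560, 2700), substr(puc, 1001, 1056),
             substr(tmpl, 1, 140)),
      paste0(substr(wt, 861, 1000), substr(tmpl, 23, 160)),
      substr(tmpl, 3000, 3400)))
  jc <- annotate_contigs(contigs, refs, lib$grna_site)
  fp <- jc[jc$contig == "j_footprint", ]
  expect_equal(fp$insert_len, 20)
  expect_equal(fp$annotation, "partial_gRNA_footprint(20)")
  expect_setequal(c(fp$left_ref, fp$right_ref), c("template", "puc"))
  bb <- jc[jc$contig == "j_backbone56", ]
  expect_equal(bb$insert_len, 56)
  expect_equal(bb$annotation, "backbone_fragment(56)")
  hr <- jc[jc$contig == "j_hr", ]
  expect_equal(hr$insert_len, 0)
  expect_equal(hr$annotation, "HR_boundary")
  # a contig wholly within the template calls no junction
  expect_false("interior" %in% jc$contig)
})
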