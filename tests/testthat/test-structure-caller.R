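test_that("tile_read follows the window/step geometry", {
  t3000 <- tile_read(3000)
  expect_equal(t3000$start, c(0, 500, 1000, 1500, 2000))
  expect_equal(t3000$end, c(1000, 1500, 2000, 2500, 3000))
  # consecutive subreads overlap by exactly 500 bp
  expect_true(all(t3000$end[-nrow(t3000)] - t3000$start[-1] == 500))
  t800 <- tile_read(800)
  expect_equal(nrow(t800), 1)
  expect_equal(t800$end, 800)
  # last subread is >= window - step for assorted lengths
  for (len in c(1000, 1001, 1499, 1500, 2999, 3200, 12345)) {
    tt <- tile_read(len)
    expect_gte(tt$end[nrow(tt)] - tt$start[nrow(tt)], 500)
    expect_equal(tt$end[nrow(tt)], len)
    expect_equal(nrow(tt), max(1, ceiling((len - 1000) / 500) + 1))
  }
  expect_equal(nrow(tile_read(0)), 0)
  expect_error(tile_read(1000, window = 500, step = 600), "exceed")
})

test_that("map_subreads assigns subreads to the correct reference", {
  lib <- fix_lib()
  ref <- composite_reference(lib, make_decoy_genome(lib, 1, 10000, seed = 31L))
  tmpl <- build_complete_template(lib)$seq
  subs <- read_set(
    c("in_template", "in_decoy", "junction"),
    c(substr(tmpl, 2001, 3000),
      substr(ref$seq[ref$id == "decoy1"], 501, 1500),
      # 700 bp of template end + 300 bp of backbone start
      paste0(substr(tmpl, 4445, 5144),
             substr(segment_seq(lib, "PUC"), 1, 300))))
  hits <- map_subreads(subs, ref)
  h1 <- hits[hits$subread == 1, ]
  expect_equal(h1$target_label, "template")
  expect_equal(h1$identity, 1)
  expect_equal(hits$target_label[hits$subread == 2], "decoy1")
  # junction subread: best hit covers the majority (template) side
  h3 <- hits[hits$subread == 3, ]
  expect_equal(h3$target_label, "template")
  expect_gte(h3$qend - h3$qstart, 500)
})

test_that("block_string merges collinear hits and splits at flips and wraps", {
  mk <- function(rstart, rend, label, strand, tstart, tend) {
    data.frame(rstart = rstart, rend = rend, target_label = label,
               strand = strand, tstart = tstart, tend = tend)
  }
  # collinear template hits merge; a wrap to the next copy opens a block
  hits <- rbind(mk(0, 1000, "template", "+", 3000, 4000),
                mk(500, 1500, "template", "+", 3500, 4500),
                mk(1000, 2000, "template", "+", 4000, 5000),
                mk(1700, 2600, "template", "+", 50, 950),   # next copy
                mk(2500, 3400, "template", "-", 4000, 4900)) # inversion
  b <- block_string(hits, "r1")
  expect_equal(nrow(b), 3)
  expect_equal(b$strand, c("+", "+", "-"))
  expect_equal(b$tstart[1], 3000)
  expect_equal(b$tend[1], 5000)
  # read spans are non-overlapping and increasing
  expect_true(all(diff(b$qstart) > 0))
  expect_true(all(b$qstart[-1] >= b$qend[-nrow(b)]))
  # short blocks are dropped
  hits2 <- rbind(mk(0, 1000, "template", "+", 0, 1000),
                 mk(1000, 1200, "puc", "+", 0, 200))
  expect_equal(nrow(block_string(hits2, "r2")), 1)
  expect_equal(nrow(block_string(hits2[0, ], "r3")), 0)
})

test_that("clustering canonicalises reverse-complement twins into one cluster", {
  blkA <- data.frame(read_id = "a", target = c("chr17", "template"),
                     strand = c("+", "+"), qstart = c(0, 700),
                     qend = c(700, 4000), tstart = c(300, 22),
                     tend = c(1000, 3300), n_subreads = c(2, 7))
  # the same walk observed from the opposite strand
  blkB <- data.frame(read_id = "b", target = c("template", "chr17"),
                     strand = c("-", "-"), qstart = c(0, 3300),
                     qend = c(3300, 4000), tstart = c(22, 300),
                     tend = c(3300, 1000), n_subreads = c(7, 2))
  cl <- cluster_blockstrings(list(a = blkA, b = blkB), cut = 1000)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n_reads, 2)
  expect_setequal(cl$reads$flipped, c(TRUE, FALSE))
})

test_that("error-free full-span reads recover every blueprint exactly", {
  sim <- fix_fullspan()   # every read spans its whole allele, zero errors
  lib <- fix_lib()
  ref <- composite_reference(lib)
  cut <- attr(ref, "cut_site")
  cfg <- default_config(seed = 1)
  res <- resolve_structures(sim$reads, ref, cut, cfg)
  expect_length(res$structures, 3)
  got <- lapply(res$structures, `[[`, "tokens")
  truthB <- truth_tokens(fix_allele("alleleB"))
  truthC <- truth_tokens(fix_allele("alleleC"))
  truthA <- truth_tokens(fix_allele("alleleA"))
  expect_true(any(vapply(got, identical, TRUE, truthB)))
  expect_true(any(vapply(got, identical, TRUE, truthC)))
  expect_true(any(vapply(got, identical, TRUE, truthA)))
  copies <- vapply(res$structures, `[[`, 0L, "n_template_copies")
  expect_setequal(copies, c(7L, 3L, 0L))
})

test_that("a structure with a single supporting read is not reported", {
  sim <- fix_fullspan()
  keep <- c(which(sim$truth$allele == "alleleB")[1],
            which(sim$truth$allele == "alleleA"))
  reads <- sim$reads[keep, ]
  class(reads) <- c("read_set", "data.frame")
  ref <- composite_reference(fix_lib())
  res <- resolve_structures(reads, ref, attr(ref, "cut_site"),
                            default_config(seed = 1))
  copies <- vapply(res$structures, `[[`, 0L, "n_template_copies")
  expect_false(7L %in% copies)   # one read of the concatemer is not enough
  expect_true(0L %in% copies)    # the multi-read NHEJ structure remains
})

test_that("wild-type-only simulation yields one structure with no insertion", {
  lib <- fix_lib()
  gt <- data.frame(name = "wildtype", abundance = 1)
  sim <- simulate_long(lib, gt, long_read_model(), coverage_per_allele = 20,
                       seed = 41L, blueprints = fix_blueprints())
  ref <- composite_reference(lib)
  cut <- attr(ref, "cut_site")
  res <- resolve_structures(sim$reads, ref, cut, default_config(seed = 1))
  expect_length(res$structures, 1)
  st <- res$structures[[1]]
  expect_equal(st$n_template_copies, 0)
  expect_equal(st$insertion_length_bp, 0)
  wt <- build_allele(lib, fix_blueprints()$wildtype)$seq
  ind <- call_cutsite_indel(st, sim$reads, res$blocks_by_read, wt, cut)
  expect_equal(ind$indel, 0)
})

test_that("cut-site indel calling recovers insertions and deletions", {
  lib <- fix_lib()
  # synthetic 9 bp deletion allele: right flank loses its first 9 bases
  del_bp <- fix_blueprints()$wildtype
  del_bp$name <- "del9"
  del_bp$blocks$start[2] <- 10L
  del_bp$blocks$end[2] <- 1000L
  blueprints <- c(fix_blueprints(), list(del9 = del_bp))
  gt <- data.frame(name = "del9", abundance = 1)
  sim <- simulate_long(lib, gt, long_read_model(), coverage_per_allele = 20,
                       seed = 42L, blueprints = blueprints)
  ref <- composite_reference(lib)
  cut <- attr(ref, "cut_site")
  res <- resolve_structures(sim$reads, ref, cut, default_config(seed = 1))
  expect_length(res$structures, 1)
  wt <- build_allele(lib, fix_blueprints()$wildtype)$seq
  ind <- call_cutsite_indel(res$structures[[1]], sim$reads,
                            res$blocks_by_read, wt, cut)
  expect_equal(ind$indel, -9)
  expect_error(call_cutsite_indel(list(n_template_copies = 3), sim$reads,
                                  res$blocks_by_read, wt, cut),
               "template-free")
})

test_that("reported structures persist as coverage increases", {
  lib <- fix_lib()
  gt <- data.frame(name = "alleleB", abundance = 1)
  ref <- composite_reference(lib)
  cut <- attr(ref, "cut_site")
  support <- integer(0)
  for (cov in c(12, 25)) {
    sim <- simulate_long(lib, gt, long_read_model(), coverage_per_allele = cov,
                         seed = 43L, blueprints = fix_blueprints())
    res <- resolve_structures(sim$reads, ref, cut, default_config(seed = 1))
    copies <- vapply(res$structures, `[[`, 0L, "n_template_copies")
    expect_true(7L %in% copies)
    support <- c(support,
                 res$structures[[which(copies == 7L)[1]]]$n_support)
  }
  expect_gte(support[2], support[1])
})
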