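test_that("long-read simulation is deterministic and hits target coverage", {
  sim <- fix_sim()
  sim2 <- simulate_long(fix_lib(), default_genotype(), long_read_model(),
                        coverage_per_allele = 50, seed = 2L,
                        blueprints = fix_blueprints())
  sim2b <- simulate_long(fix_lib(), default_genotype(), long_read_model(),
                         coverage_per_allele = 50, seed = 2L,
                         blueprints = fix_blueprints())
  expect_identical(sim2$reads, sim2b$reads)   # byte-identical per seed
  expect_identical(sim2$truth, sim2b$truth)
  # per-allele base budgets: ~50X for abundance-1 alleles, ~5X for the minor
  truth <- sim$long$truth
  for (nm in c("alleleA", "alleleB", "alleleC")) {
    alen <- nchar(fix_allele(nm)$seq)
    ab <- default_genotype()$abundance[default_genotype()$name == nm]
    bases <- sum(truth$end[truth$allele == nm] - truth$start[truth$allele == nm])
    expect_gte(bases, 0.85 * 50 * ab * alen)
    expect_lte(bases, 1.15 * 50 * ab * alen + 60000)
  }
  expect_error(simulate_long(fix_lib(), default_genotype()[0, ]), "allele")
  expect_error(simulate_long(fix_lib(), default_genotype(),
                             coverage_per_allele = 0), "positive")
})

test_that("error-free reads are exact oriented substrings of their origin allele", {
  model <- long_read_model(sub = 0, ins = 0, del = 0)
  sim <- simulate_long(fix_lib(), data.frame(name = "alleleB", abundance = 1),
                       model, coverage_per_allele = 3, seed = 9L,
                       blueprints = fix_blueprints())
  aB <- fix_allele("alleleB")$seq
  for (i in seq_len(nrow(sim$reads))) {
    tr <- sim$truth[i, ]
    frag <- substr(aB, tr$start + 1, tr$end)
    if (tr$strand == "-") frag <- unname(revcomp(frag))
    expect_identical(sim$reads$seq[i], frag)
  }
})

test_that("a read longer than the allele returns the whole allele", {
  model <- long_read_model(mean_len = 1e6, max_len = 2e6, sub = 0, ins = 0,
                           del = 0)
  sim <- simulate_long(fix_lib(), data.frame(name = "alleleA", abundance = 1),
                       model, coverage_per_allele = 1, seed = 4L,
                       blueprints = fix_blueprints())
  aA <- fix_allele("alleleA")$seq
  obs <- sim$reads$seq[1]
  if (sim$truth$strand[1] == "-") obs <- unname(revcomp(obs))
  expect_identical(obs, aA)
})

test_that("read counts per allele follow abundance x length proportions", {
  # short fixed-length reads so length truncation cannot distort proportions
  model <- long_read_model(mean_len = 60, sigma = 0.01, min_len = 50,
                           max_len = 70, sub = 0, ins = 0, del = 0)
  gt <- data.frame(name = c("alleleA", "alleleB", "alleleC"),
                   abundance = c(1, 1, 0.1))
  sim <- simulate_long(fix_lib(), gt, model, coverage_per_allele = 15,
                       seed = 5L, blueprints = fix_blueprints())
  counts <- table(factor(sim$truth$allele, levels = gt$name))
  expect_gte(sum(counts), 1e4)
  lens <- vapply(gt$name, function(nm) nchar(fix_allele(nm)$seq), 0)
  p <- gt$abundance * lens / sum(gt$abundance * lens)
  gof <- suppressWarnings(chisq.test(as.vector(counts), p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("short-read pairs are FR-oriented exact substrings at error rate 0", {
  model <- short_read_model(sub = 0)
  sim <- simulate_short(fix_lib(), data.frame(name = "alleleA", abundance = 1),
                        model, coverage = 10, seed = 6L,
                        blueprints = fix_blueprints())
  aA <- fix_allele("alleleA")$seq
  both <- paste0(aA, "#", revcomp(aA))
  for (i in seq_len(min(50, nrow(sim$r1)))) {
    expect_true(grepl(sim$r1$seq[i], both, fixed = TRUE))
    expect_true(grepl(sim$r2$seq[i], both, fixed = TRUE))
    # mates reconstruct the fragment ends
    tr <- sim$truth[i, ]
    frag <- substr(aA, tr$start + 1, tr$end)
    if (tr$strand == "-") frag <- unname(revcomp(frag))
    expect_identical(sim$r1$seq[i], substr(frag, 1, 150))
    expect_identical(unname(revcomp(sim$r2$seq[i])),
                     substr(frag, nchar(frag) - 149, nchar(frag)))
    expect_equal(tr$mate_gap, tr$insert - 300)
  }
  expect_warning(short_read_model(insert_mean = 200), "overlap")
})

test_that("decoy chromosomes share no 25-mer with donor segments", {
  lib <- fix_lib()
  decoys <- make_decoy_genome(lib, 2, 10000, seed = 13L)
  decoys2 <- make_decoy_genome(lib, 2, 10000, seed = 13L)
  expect_identical(decoys, decoys2)
  expect_equal(nchar(decoys$seq), c(10000, 10000))
  donor <- unique(c(canonical_kmers(segment_seq(lib, "TEMPLATE"), 25),
                    canonical_kmers(segment_seq(lib, "PUC"), 25)))
  for (i in 1:2) {
    expect_length(intersect(canonical_kmers(decoys$seq[i], 25), donor), 0)
  }
  expect_error(make_decoy_genome(lib, 1, -5), "positive")
})
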