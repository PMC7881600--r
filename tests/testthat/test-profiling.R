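test_that("depth profiles count aligned bases conservatively", {
  lib <- fix_lib()
  tmpl <- build_complete_template(lib)$seq
  panel <- read_set(c("template", "puc"),
                    c(tmpl, segment_seq(lib, "PUC")))
  one <- read_set("r1", substr(tmpl, 1001, 1150))
  d <- depth_profile(one, panel)
  expect_equal(sum(d$profiles$template == 1), 150)
  expect_equal(sum(d$profiles$template), 150)
  expect_equal(sum(d$profiles$puc), 0)
  # conservation: sum of depth equals sum of aligned bases
  sim <- fix_sim()
  sub <- read_set(sim$short$r1$id[1:400], sim$short$r1$seq[1:400])
  d2 <- depth_profile(sub, panel)
  expect_equal(sum(vapply(d2$profiles, sum, 0)),
               sum(d2$summary$aligned_bases))
  # no reads -> all-zero profile
  d0 <- depth_profile(read_set(character(0), character(0)), panel)
  expect_true(all(vapply(d0$profiles, sum, 0) == 0))
})

test_that("multi-copy enrichment shows as deeper template coverage", {
  bundle <- fix_bundle()
  d <- bundle$depth$summary
  tmpl_depth <- d$mean_depth[d$reference == "complete_template"]
  nhej_depth <- d$mean_depth[d$reference == "nhej_allele"]
  expect_gt(tmpl_depth, nhej_depth)  # direction only
})

test_that("off-target scan is clean on simulations and fires on a plant", {
  lib <- fix_lib()
  sim <- fix_sim()
  ref <- composite_reference(lib, sim$decoys)
  clean <- off_target_scan(sim$long$reads, ref, lib)
  expect_equal(clean$n_flagged, 0)
  # plant a template copy inside a decoy and sample reads across it
  tmpl <- build_complete_template(lib)$seq
  host <- sim$decoys$seq[1]
  planted <- paste0(substr(host, 1, 8000), tmpl,
                    substr(host, 8001, nchar(host)))
  pref <- read_set(c("chr17", "puc", "template", "decoy1"),
                   c(ref$seq[ref$id == "chr17"], ref$seq[ref$id == "puc"],
                     ref$seq[ref$id == "template"], planted))
  attr(pref, "cut_site") <- attr(ref, "cut_site")
  reads <- read_set(c("p1", "p2", "p3"),
                    c(substr(planted, 5000, 11000),
                      substr(planted, 7000, 14000),
                      substr(planted, 1, 4000)))
  hit <- off_target_scan(reads, pref, lib)
  expect_gt(hit$n_flagged, 0)
  expect_false("p3" %in% hit$flagged)  # decoy-only read is not flagged
  # empty read set
  e <- off_target_scan(read_set(character(0), character(0)), ref, lib)
  expect_equal(e$n_flagged, 0)
})

test_that("read-set statistics follow the printed arithmetic", {
  expect_equal(readset_stats(c(100))$mean_len, 100)
  s <- readset_stats(c(100, 200), genome_size = 100)
  expect_equal(s$mean_len, 150)
  expect_equal(s$max_len, 200)
  expect_equal(s$coverage, 3)
  rs <- read_set(c("a", "b"), c("ACGT", "ACGTACGT"))
  expect_equal(readset_stats(rs)$total_bases, 12)
  # mean * n == total (to rounding)
  expect_equal(readset_stats(c(101, 102, 104))$mean_len * 3, 307,
               tolerance = 0.02)
  expect_equal(readset_summary(4, 600)$mean_len, 150)
})

test_that("percentage reporting is exact", {
  expect_equal(percent_rate(22, 200), 11)
  expect_equal(percent_rate(9, 22, 0), 41)
  expect_error(percent_rate(1, 0), "positive")
})

test_that("in-silico PCR reports products shifted by insertions", {
  lib <- fix_lib()
  wt <- build_allele(lib, fix_blueprints()$wildtype)$seq
  # primers flanking the Cas9 cut at position 1000
  fwd <- substr(wt, 801, 820)
  rev <- unname(revcomp(substr(wt, 1281, 1300)))
  expect_equal(insilico_pcr(wt, fwd, rev), 500)
  aA <- fix_allele("alleleA")$seq
  expect_equal(insilico_pcr(aA, fwd, rev), 526)   # + 26 bp insertion
  # insertion of length d between the primer sites shifts the product by d
  for (d in c(1, 9, 150)) {
    ins <- paste0(substr(wt, 1, 1000),
                  strrep("A", d), substr(wt, 1001, 2000))
    expect_equal(insilico_pcr(ins, fwd, rev), 500 + d)
  }
  # swapped primer orientation is detected on the opposite strand
  expect_equal(insilico_pcr(unname(revcomp(wt)), fwd, rev), 500)
  # absent primers; product cap
  expect_length(insilico_pcr(wt, strrep("A", 20), rev), 0)
  expect_length(insilico_pcr(wt, fwd, rev, max_product = 100), 0)
  expect_error(insilico_pcr(wt, "ACGT", rev), "15")
})
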