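test_that("segment library is deterministic with the documented lengths", {
  lib1 <- make_library(1); lib2 <- make_library(1)
  expect_identical(lib1$segments, lib2$segments)
  lens <- nchar(lib1$segments)
  expect_equal(unname(lens[c("CHR17_L", "CHR17_R", "LHA", "SRY", "GFP",
                             "RHA", "PUC", "NHEJ_INSERT")]),
               c(1000, 1000, 1000, 1800, 1300, 1000, 2700, 26))
  expect_equal(nchar(lib1$grna_site), 22)  # 19 nt protospacer + PAM
  lib3 <- make_library(2)
  expect_false(identical(lib1$segments[["SRY"]], lib3$segments[["SRY"]]))
  expect_error(make_library(1, c(SRY = -5)), "positive")
})

test_that("different segments share no canonical 25-mer", {
  lib <- fix_lib()
  sets <- lapply(names(lib$segments), function(s)
    unique(canonical_kmers(lib$segments[[s]], 25L)))
  names(sets) <- names(lib$segments)
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (j <= i) next
      expect_length(intersect(sets[[i]], sets[[j]]), 0)
    }
  }
})

test_that("the wild-type locus carries the gRNA site across the cut", {
  lib <- fix_lib()
  wt <- build_allele(lib, fix_blueprints()$wildtype)
  expect_equal(nchar(wt$seq), 2000)
  expect_equal(wt$cut_site, 1000)
  site_start <- wt$cut_site - lib$cut_in_site + 1
  expect_identical(substr(wt$seq, site_start, site_start + 21), lib$grna_site)
})

test_that("complete template has the expected composition and length", {
  lib <- fix_lib()
  tm <- build_complete_template(lib)
  expect_equal(nchar(tm$seq), 5144)  # 22 + 1000 + 1800 + 1300 + 1000 + 22
  # exactly two protospacer copies, LHA exactly once on the + strand
  proto <- substr(lib$grna_site, 1, 19)
  expect_length(gregexpr(proto, tm$seq, fixed = TRUE)[[1]], 2)
  expect_length(gregexpr(lib$segments[["LHA"]], tm$seq, fixed = TRUE)[[1]], 1)
  expect_equal(gregexpr(lib$segments[["LHA"]],
                        revcomp(tm$seq), fixed = TRUE)[[1]][1], -1L)
  lib_broken <- fix_lib()
  lib_broken$segments <- lib_broken$segments[
    names(lib_broken$segments) != "GFP"]
  expect_error(build_complete_template(lib_broken), "GFP")
})

test_that("built-in blueprints reproduce the three-allele architecture", {
  bps <- fix_blueprints()
  expect_setequal(names(bps),
                  c("wildtype", "alleleA", "alleleB", "alleleC",
                    "donor_plasmid"))
  expect_equal(template_copies(bps$alleleB), 7)
  expect_equal(template_copies(bps$alleleC), 3)
  expect_equal(template_copies(bps$alleleB) - template_copies(bps$alleleC), 4)
  expect_true(bps$donor_plasmid$circular)
  # the deletion unit (copies 3-6 of B): two reverse then two forward
  tb <- bps$alleleB$blocks
  mid <- tb$orient[tb$seg == "TEMPLATE"][3:6]
  expect_identical(mid, c("-", "-", "+", "+"))
})

test_that("built alleles conserve length and carry the expected junctions", {
  wt <- fix_allele("wildtype"); aA <- fix_allele("alleleA")
  aB <- fix_allele("alleleB"); aC <- fix_allele("alleleC")
  expect_equal(nchar(wt$seq), 2000)
  expect_equal(nchar(aA$seq), 2026)        # 2000 + 26 bp NHEJ insertion
  expect_equal(aA$insertion_length, 26)
  expect_gte(aB$insertion_length, 38000)
  expect_lte(aB$insertion_length, 38999)
  expect_equal(floor(aC$insertion_length / 1000), 18)
  # conservation: emitted length equals the sum of emitted block lengths
  for (al in list(wt, aA, aB, aC)) {
    expect_equal(nchar(al$seq), sum(al$blocks$end - al$blocks$start))
  }
  # the two backbone-fragment junctions measure 56 and 9 bp
  frag <- aB$junctions$insert_len[grepl("backbone", aB$junctions$annotation)]
  expect_setequal(frag, c(56, 9))
  # outer boundaries are HR-repaired: no footprint, wild-type flank intact
  expect_identical(aB$junctions$annotation[1], "HR_boundary")
  expect_identical(aB$junctions$annotation[nrow(aB$junctions)], "HR_boundary")
  lib <- fix_lib()
  expect_identical(substr(aB$seq, 1, 1000), lib$segments[["CHR17_L"]])
  expect_identical(substr(aB$seq, nchar(aB$seq) - 999, nchar(aB$seq)),
                   lib$segments[["CHR17_R"]])
  # no gRNA-site footprint at the outer boundaries
  site20 <- substr(lib$grna_site, 1, 20)
  expect_false(grepl(site20, substr(aB$seq, 900, 1100), fixed = TRUE))
  expect_error(build_allele(lib, local({
    bp <- fix_blueprints()$alleleB
    bp$blocks$start[2] <- 99999; bp$blocks$end[2] <- 100100
    bp
  })), "truncation")
})

test_that("the 18 kb allele is an exact contiguous-deletion derivative of the 38 kb allele", {
  aB <- fix_allele("alleleB"); aC <- fix_allele("alleleC")
  nB <- nchar(aB$seq); nC <- nchar(aC$seq)
  # common prefix P and suffix S with B = P + D + S, C = P + S
  pre <- 0L
  while (substr(aB$seq, pre + 1, pre + 1) == substr(aC$seq, pre + 1, pre + 1))
    pre <- pre + 1L
  suf <- 0L
  while (substr(aB$seq, nB - suf, nB - suf) == substr(aC$seq, nC - suf, nC - suf))
    suf <- suf + 1L
  expect_gte(pre + suf, nC)  # every base of C is explained by prefix + suffix
  expect_equal(nB - nC, 4 * 5144 + 4 * 20)  # four copies + their footprints
})

test_that("allele truth BED export is well-formed", {
  aB <- fix_allele("alleleB")
  path <- tempfile(fileext = ".bed")
  allele_truth_bed(aB, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(nrow(bed), nrow(aB$blocks))
  expect_true(all(bed$V2 < bed$V3))
  unlink(path)
})
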