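test_that("revcomp complements, maps N to N, and is an involution", {
  expect_identical(unname(revcomp("ACGT")), "ACGT")
  expect_identical(unname(revcomp("AAACN")), "NGTTT")
  expect_identical(revcomp(character(0)), character(0))
  expect_error(revcomp("ACGU"), "non-DNA")
  withr::with_seed(5, {
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T", "N"), sample(0:80, 1),
                        replace = TRUE), collapse = "")
      expect_identical(unname(revcomp(revcomp(s))), s)
    }
  })
})

test_that("kmers enumerates overlapping windows in order", {
  expect_length(kmers(strrep("A", 50), 25), 26L)
  expect_identical(kmers("ACGT", 4), "ACGT")
  expect_identical(kmers("ACGTA", 2), c("AC", "CG", "GT", "TA"))
  expect_identical(kmers("ACG", 5), character(0))
  expect_error(kmers("ACGT", 0), "positive")
  # |kmers(s, k)| == max(0, len - k + 1)
  withr::with_seed(6, {
    for (i in 1:20) {
      n <- sample(0:60, 1); k <- sample(1:30, 1)
      s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
      expect_length(kmers(s, k), max(0L, n - k + 1L))
    }
  })
})

test_that("align_local finds exact substrings with identity 1 on both strands", {
  withr::with_seed(2, {
    t <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  })
  q <- substr(t, 501, 1000)
  h <- align_local(q, t)
  expect_equal(h$identity[1], 1)
  expect_equal(c(h$tstart[1], h$tend[1]), c(500, 1000))
  expect_equal(c(h$qstart[1], h$qend[1]), c(0, 500))
  expect_equal(h$strand[1], "+")
  hr <- align_local(unname(revcomp(q)), t)
  expect_equal(hr$strand[1], "-")
  expect_equal(c(hr$tstart[1], hr$tend[1]), c(500, 1000))
  expect_error(align_local("", t), "non-empty")
})

test_that("align_local identity matches the known true alignment under 5% substitutions", {
  withr::with_seed(3, {
    t <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
    qs <- strsplit(substr(t, 301, 1300), "")[[1]]
    pos <- which(runif(1000) < 0.05)
    for (p in pos) qs[p] <- sample(setdiff(c("A", "C", "G", "T"), qs[p]), 1)
  })
  truth_identity <- (1000 - length(pos)) / 1000  # matching columns, no indels
  h <- align_local(paste(qs, collapse = ""), t)
  expect_gte(h$identity[1], 0.93)
  expect_lte(h$identity[1], 0.97)
  expect_equal(h$identity[1], truth_identity, tolerance = 0.01)
})

test_that("self-alignment yields a full-length identity-1 hit", {
  withr::with_seed(4, {
    s <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
               collapse = "")
  })
  h <- align_local(s, s)
  expect_equal(h$identity[1], 1)
  expect_equal(c(h$qstart[1], h$qend[1]), c(0, 800))
  expect_equal(c(h$tstart[1], h$tend[1]), c(0, 800))
})

test_that("FASTA and FASTQ round-trips are lossless", {
  withr::with_seed(7, {
    n <- 100
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), sample(30:200, 1), replace = TRUE),
            collapse = ""), "")
    qual <- vapply(nchar(seqs), function(L)
      rawToChar(as.raw(sample(33:73, L, replace = TRUE))), "")
  })
  rs <- read_set(sprintf("read%03d", seq_len(n)), seqs, qual)
  fa <- tempfile(fileext = ".fasta"); fq <- tempfile(fileext = ".fastq")
  write_fasta(rs, fa, width = 60)
  back <- read_fasta(fa)
  expect_identical(back$id, rs$id)
  expect_identical(back$seq, rs$seq)
  write_fastq(rs, fq)
  backq <- read_fastq(fq)
  expect_identical(backq$seq, rs$seq)
  expect_identical(backq$qual, rs$qual)
  unlink(c(fa, fq))
})

test_that("malformed FASTQ raises a parse error naming the line", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIII"), fq)  # qual too short
  expect_error(read_fastq(fq), "line 4")
  writeLines(c("r1", "ACGT", "+", "IIII"), fq)
  expect_error(read_fastq(fq), "line 1")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), fq)
  expect_error(read_fastq(fq), "line 5")
  unlink(fq)
})
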