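## Synthetic-data generator: seeded long-read and paired-end short-read
## simulation from a multi-allele genotype, plus decoy chromosomes for
## off-target scans. Every downstream stage is testable from these outputs
## without any external data.

#' Long-read error/length model
#'
#' Lengths are log-normal with the given mean and sigma (clamped to
#' `[min_len, max_len]` and to the allele length). The default error profile
#' is HiFi-like (sub/ins/del = 0.01/0.005/0.005); `preset = "clr"` switches
#' to a CLR-like 0.05/0.05/0.03. Base qualities are written as constant Q20.
#'
#' @param mean_len Mean read length (bp).
#' @param sigma Log-normal sigma.
#' @param min_len,max_len Read length clamp.
#' @param sub,ins,del Per-base error rates (each in \[0, 0.2\]).
#' @param preset `"hifi"` or `"clr"`; explicit rates override the preset.
#' @return A `long_read_model` list.
#' @export
long_read_model <- function(mean_len = 15000, sigma = 0.6, min_len = 500,
                            max_len = 60000, sub = NULL, ins = NULL,
                            del = NULL, preset = c("hifi", "clr")) {
  preset <- match.arg(preset)
  rates <- if (preset == "hifi") c(0.01, 0.005, 0.005) else c(0.05, 0.05, 0.03)
  if (!is.null(sub)) rates[1] <- sub
  if (!is.null(ins)) rates[2] <- ins
  if (!is.null(del)) rates[3] <- del
  if (any(rates < 0 | rates > 0.2)) {
    stop("error rates must lie in [0, 0.2]", call. = FALSE)
  }
  if (mean_len <= 0 || min_len <= 0 || max_len < min_len) {
    stop("invalid length parameters", call. = FALSE)
  }
  list(mean_len = mean_len, sigma = sigma, min_len = min_len,
       max_len = max_len, sub = rates[1], ins = rates[2], del = rates[3])
}

#' Short-read model
#'
#' 150 bp FR paired-end reads with normal insert sizes; substitution errors
#' only. Base qualities are written as constant Q30. A warning is issued when
#' the mean insert is shorter than two read lengths (overlapping pairs).
#'
#' @param read_len Read length (bp).
#' @param insert_mean,insert_sd Fragment (insert) size distribution.
#' @param sub Per-base substitution rate.
#' @return A `short_read_model` list.
#' @export
short_read_model <- function(read_len = 150, insert_mean = 350,
                             insert_sd = 50, sub = 0.001) {
  if (insert_mean < 2 * read_len) {
    warning("insert_mean < 2 * read_len: mates will overlap")
  }
  if (sub < 0 || sub > 0.2) stop("error rate must lie in [0, 0.2]", call. = FALSE)
  list(read_len = as.integer(read_len), insert_mean = insert_mean,
       insert_sd = insert_sd, sub = sub)
}

#' Default genotype of the modelled animal
#'
#' One NHEJ-insertion allele and one multi-copy concatemer allele at equal
#' abundance, plus the deletion derivative at one tenth the abundance of the
#' concatemer allele.
#'
#' @return Data.frame with columns `name` and `abundance`.
#' @export
default_genotype <- function() {
  data.frame(name = c("alleleA", "alleleB", "alleleC"),
             abundance = c(1, 1, 0.1), stringsAsFactors = FALSE)
}

mutate_seq <- function(seq, sub, ins, del) {
  if (sub == 0 && ins == 0 && del == 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  bases <- c("A", "C", "G", "T")
  s <- which(runif(n) < sub)
  if (length(s) > 0) {
    repl <- sample(bases, length(s), replace = TRUE)
    same <- repl == x[s]
    while (any(same)) {   # substitute with a different base
      repl[same] <- sample(bases, sum(same), replace = TRUE)
      same <- repl == x[s]
    }
    x[s] <- repl
  }
  keep <- runif(n) >= del
  x <- x[keep]
  n <- length(x)
  if (n == 0) return("")
  ia <- which(runif(n) < ins)
  if (length(ia) > 0) {
    extra <- sample(bases, length(ia), replace = TRUE)
    # inserted base goes directly after its anchor position
    pieces <- as.list(x)
    for (j in seq_along(ia)) pieces[[ia[j]]] <- c(pieces[[ia[j]]], extra[j])
    return(paste(unlist(pieces), collapse = ""))
  }
  paste(x, collapse = "")
}

qual_string <- function(n, q) strrep(rawToChar(as.raw(q + 33L)), n)

#' Simulate long reads from a genotype
#'
#' Reads are drawn allele by allele until each allele reaches
#' `coverage_per_allele * abundance` fold coverage (so the default genotype
#' yields ~50X for the two major alleles and ~5X for the minor derivative).
#' Read starts are uniform; reads longer than the allele return the whole
#' allele (circular blueprints are sampled from the doubled sequence).
#' Deterministic given `seed`.
#'
#' @param lib A `segment_library`.
#' @param genotype Data.frame with `name`, `abundance` (positive).
#' @param model A [long_read_model()].
#' @param coverage_per_allele Fold coverage for an abundance-1 allele.
#' @param seed Integer seed.
#' @param blueprints Named list of blueprints (defaults to
#'   [builtin_blueprints()]).
#' @return List with `reads` (a `read_set` with `qual`) and `truth`
#'   (data.frame: `read_id`, `allele`, `start`, `end`, `strand`; 0-based
#'   half-open coordinates on the allele).
#' @export
simulate_long <- function(lib, genotype, model = long_read_model(),
                          coverage_per_allele = 50, seed = 1L,
                          blueprints = NULL) {
  if (is.null(genotype) || nrow(genotype) == 0) {
    stop("genotype must list at least one allele", call. = FALSE)
  }
  if (any(genotype$abundance <= 0)) {
    stop("abundances must be positive", call. = FALSE)
  }
  if (coverage_per_allele <= 0) stop("coverage must be positive", call. = FALSE)
  if (is.null(blueprints)) blueprints <- builtin_blueprints(lib)
  alleles <- lapply(genotype$name, function(nm) {
    if (!nm %in% names(blueprints)) {
      stop(sprintf("no blueprint named '%s'", nm), call. = FALSE)
    }
    build_allele(lib, blueprints[[nm]])
  })
  names(alleles) <- genotype$name
  mu <- log(model$mean_len) - model$sigma^2 / 2
  withr::with_seed(as.integer(seed), {
    ids <- list(); seqs <- list()
    t_allele <- list(); t_start <- list(); t_end <- list(); t_strand <- list()
    ctr <- 0L
    for (ai in seq_len(nrow(genotype))) {
      al <- alleles[[ai]]
      alen <- nchar(al$seq)
      target <- coverage_per_allele * genotype$abundance[ai] * alen
      src <- if (al$circular) paste0(al$seq, al$seq) else al$seq
      got <- 0
      while (got < target) {
        ctr <- ctr + 1L
        len <- round(rlnorm(1, mu, model$sigma))
        len <- max(model$min_len, min(model$max_len, len))
        if (!al$circular && len >= alen) {
          start <- 0L; end <- alen
        } else {
          len <- min(len, alen)
          start <- sample.int(alen - len + 1L, 1L) - 1L
          end <- start + len
        }
        frag <- substr(src, start + 1L, end)
        strand <- if (runif(1) < 0.5) "+" else "-"
        if (strand == "-") frag <- revcomp(frag)
        obs <- mutate_seq(frag, model$sub, model$ins, model$del)
        if (nchar(obs) == 0) next
        k <- length(ids) + 1L
        ids[[k]] <- sprintf("lr%05d_%s", ctr, al$id)
        seqs[[k]] <- obs
        t_allele[[k]] <- al$id; t_start[[k]] <- start
        t_end[[k]] <- end; t_strand[[k]] <- strand
        got <- got + (end - start)
      }
    }
    seqs <- unlist(seqs)
    reads <- read_set(unlist(ids), seqs, qual_string(nchar(seqs), 20L))
    list(reads = reads,
         truth = data.frame(read_id = unlist(ids),
                            allele = unlist(t_allele),
                            start = unlist(t_start), end = unlist(t_end),
                            strand = unlist(t_strand),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate paired-end short reads from a genotype
#'
#' FR-oriented pairs with normal insert sizes; per-allele coverage follows
#' `coverage * abundance` as in [simulate_long()]. With error rate 0 every
#' read is an exact substring of an allele or its reverse complement.
#'
#' @inheritParams simulate_long
#' @param coverage Fold coverage for an abundance-1 allele.
#' @return List with `r1`, `r2` (read_sets) and `truth` (pair table with
#'   fragment coordinates, strand and insert size).
#' @export
simulate_short <- function(lib, genotype, model = short_read_model(),
                           coverage = 100, seed = 1L, blueprints = NULL) {
  if (is.null(genotype) || nrow(genotype) == 0) {
    stop("genotype must list at least one allele", call. = FALSE)
  }
  if (any(genotype$abundance <= 0)) {
    stop("abundances must be positive", call. = FALSE)
  }
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  if (is.null(blueprints)) blueprints <- builtin_blueprints(lib)
  alleles <- lapply(genotype$name, function(nm) build_allele(lib, blueprints[[nm]]))
  rl <- model$read_len
  withr::with_seed(as.integer(seed), {
    pid <- list(); s1 <- list(); s2 <- list()
    t_allele <- list(); t_start <- list(); t_ins <- list(); t_strand <- list()
    ctr <- 0L
    for (ai in seq_len(nrow(genotype))) {
      al <- alleles[[ai]]
      alen <- nchar(al$seq)
      src <- if (al$circular) paste0(al$seq, al$seq) else al$seq
      target <- coverage * genotype$abundance[ai] * alen
      got <- 0
      while (got < target) {
        ctr <- ctr + 1L
        ins <- round(rnorm(1, model$insert_mean, model$insert_sd))
        ins <- max(rl, min(ins, alen))
        start <- sample.int(alen - ins + 1L, 1L) - 1L
        frag <- substr(src, start + 1L, start + ins)
        strand <- if (runif(1) < 0.5) "+" else "-"
        if (strand == "-") frag <- revcomp(frag)
        r1 <- substr(frag, 1L, rl)
        r2 <- revcomp(substr(frag, max(1L, ins - rl + 1L), ins))
        if (model$sub > 0) {
          r1 <- mutate_seq(r1, model$sub, 0, 0)
          r2 <- mutate_seq(r2, model$sub, 0, 0)
        }
        k <- length(pid) + 1L
        pid[[k]] <- sprintf("sr%06d_%s", ctr, al$id)
        s1[[k]] <- r1; s2[[k]] <- r2
        t_allele[[k]] <- al$id; t_start[[k]] <- start
        t_ins[[k]] <- ins; t_strand[[k]] <- strand
        got <- got + 2L * rl
      }
    }
    pid <- unlist(pid); s1 <- unlist(s1); s2 <- unlist(s2)
    ins <- unlist(t_ins); start <- unlist(t_start)
    list(r1 = read_set(paste0(pid, "/1"), s1, qual_string(nchar(s1), 30L)),
         r2 = read_set(paste0(pid, "/2"), s2, qual_string(nchar(s2), 30L)),
         truth = data.frame(pair_id = pid, allele = unlist(t_allele),
                            start = start, end = start + ins,
                            strand = unlist(t_strand), insert = ins,
                            mate_gap = ins - 2L * rl,
                            stringsAsFactors = FALSE))
  })
}

#' Generate decoy chromosomes sharing no 25-mer with the donor
#'
#' Random background contigs for recruitment specificity and off-target
#' scans: by rejection, no canonical 25-mer is shared with any library
#' segment or the complete template.
#'
#' @param lib A `segment_library`.
#' @param n_chrom Number of decoy contigs.
#' @param lengths Integer vector of contig lengths (recycled).
#' @param seed Integer seed.
#' @return A `read_set` of decoy contigs named `decoy1`, `decoy2`, ...
#' @export
make_decoy_genome <- function(lib, n_chrom = 2L, lengths = 20000L, seed = 99L) {
  if (any(lengths <= 0)) stop("decoy lengths must be positive", call. = FALSE)
  lengths <- rep_len(as.integer(lengths), n_chrom)
  donor <- unique(unlist(lapply(c(names(lib$segments), "TEMPLATE"),
                                function(s) canonical_kmers(segment_seq(lib, s), 25L))))
  withr::with_seed(as.integer(seed), {
    seqs <- character(n_chrom)
    for (i in seq_len(n_chrom)) {
      for (round in 1:50) {
        cand <- random_dna(lengths[i])
        if (length(intersect(canonical_kmers(cand, 25L), donor)) == 0) break
      }
      seqs[i] <- cand
    }
    read_set(paste0("decoy", seq_len(n_chrom)), seqs)
  })
}
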