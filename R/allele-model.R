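## Segment library, allele blueprints and ground-truth allele construction.
##
## The model locus is a safe-harbor site on chromosome 17 cut by Cas9 at a
## gRNA target site. The donor is a plasmid carrying a "complete template"
## (gRNA site + left homology arm + SRY + GFP + right homology arm + gRNA
## site, 5144 bp with defaults) in a 2.7 kb backbone. Three edited alleles are
## modelled: a 26 bp NHEJ insertion allele, a ~38 kb concatemer of seven
## template copies plus one backbone copy, and an 18 kb derivative of the
## latter missing the middle four (inverted-repeat) template copies.

GRNA_PROTOSPACER <- "TAGCCATAAGACTACCTAT"  # 19 nt, as printed
GRNA_PAM <- "TGG"

#' Default segment lengths
#' @return Named integer vector of default segment lengths (bp).
#' @export
segment_defaults <- function() {
  c(CHR17_L = 1000L, CHR17_R = 1000L, LHA = 1000L, SRY = 1800L,
    GFP = 1300L, RHA = 1000L, PUC = 2700L,
    GRNA_SITE = nchar(GRNA_PROTOSPACER) + nchar(GRNA_PAM), NHEJ_INSERT = 26L)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a deterministic segment library
#'
#' Generates the named component sequences (genomic flanks, homology arms,
#' SRY, GFP, plasmid backbone, gRNA target site, NHEJ insert) from a seed.
#' Different segments share no 25-mer (on either strand), by rejection. The
#' wild-type locus carries the gRNA target site across the Cas9 cut:
#' `CHR17_L` ends with the first 16 nt of the protospacer and `CHR17_R`
#' starts with the remaining 3 nt plus the PAM (the cut lies 3 bp 5' of the
#' PAM). The site is only 22 nt, so the 25-mer disjointness invariant holds.
#'
#' @param seed Integer seed; the library is regenerable bit-exactly.
#' @param length_overrides Optional named vector overriding default lengths.
#' @param protospacer gRNA protospacer sequence (19 nt as printed; length is
#'   a free parameter).
#' @param pam PAM trinucleotide.
#' @return A `segment_library` list with elements `segments` (named character
#'   vector), `seed`, `lengths`, `grna_site`, `cut_in_site`.
#' @export
make_library <- function(seed = 1L, length_overrides = NULL,
                         protospacer = GRNA_PROTOSPACER, pam = GRNA_PAM) {
  lens <- segment_defaults()
  grna_site <- paste0(toupper(protospacer), toupper(pam))
  assert_dna(grna_site, "gRNA site")
  lens["GRNA_SITE"] <- nchar(grna_site)
  if (!is.null(length_overrides)) {
    if (any(length_overrides <= 0)) {
      stop("segment length overrides must be positive", call. = FALSE)
    }
    lens[names(length_overrides)] <- as.integer(length_overrides)
  }
  cut_in_site <- nchar(protospacer) - 3L  # cut 3 bp 5' of the PAM
  random_labels <- c("CHR17_L", "CHR17_R", "LHA", "SRY", "GFP", "RHA",
                     "PUC", "NHEJ_INSERT")
  segs <- withr::with_seed(seed, {
    out <- setNames(vector("character", length(random_labels)), random_labels)
    for (lab in random_labels) out[lab] <- random_dna(lens[lab])
    # embed the gRNA site across the wild-type cut
    left_part <- substr(grna_site, 1L, cut_in_site)
    right_part <- substr(grna_site, cut_in_site + 1L, nchar(grna_site))
    out["CHR17_L"] <- paste0(
      substr(out["CHR17_L"], 1L, lens["CHR17_L"] - nchar(left_part)), left_part)
    out["CHR17_R"] <- paste0(
      right_part,
      substr(out["CHR17_R"], nchar(right_part) + 1L, lens["CHR17_R"]))
    # rejection: no canonical 25-mer shared between different labels
    for (round in 1:50) {
      sets <- lapply(out, canonical_kmers, k = 25L)
      clash <- character(0)
      labs <- names(out)
      for (i in seq_along(labs)) {
        for (j in seq_along(labs)) {
          if (j <= i) next
          if (length(intersect(sets[[i]], sets[[j]])) > 0) {
            clash <- c(clash, labs[j])
          }
        }
      }
      if (length(clash) == 0) break
      for (lab in unique(clash)) out[lab] <- random_dna(lens[lab])
    }
    out
  })
  segs["GRNA_SITE"] <- grna_site
  lib <- list(segments = segs, seed = as.integer(seed), lengths = lens,
              grna_site = grna_site, cut_in_site = cut_in_site)
  class(lib) <- "segment_library"
  lib
}

#' Fetch a segment (or the composite template) sequence
#' @param lib A `segment_library`.
#' @param seg Segment label, or `"TEMPLATE"` for the complete template.
#' @return DNA string.
#' @export
segment_seq <- function(lib, seg) {
  if (seg == "TEMPLATE") return(build_complete_template(lib)$seq)
  if (!seg %in% names(lib$segments)) {
    stop(sprintf("segment '%s' missing from library", seg), call. = FALSE)
  }
  unname(lib$segments[[seg]])
}

#' Build the complete donor template
#'
#' gRNA site + LHA + SRY + GFP + RHA + gRNA site; 5144 bp with defaults
#' (22 + 1000 + 1800 + 1300 + 1000 + 22).
#'
#' @param lib A `segment_library`.
#' @return List with `id` and `seq`.
#' @export
build_complete_template <- function(lib) {
  needed <- c("GRNA_SITE", "LHA", "SRY", "GFP", "RHA")
  missing <- setdiff(needed, names(lib$segments))
  if (length(missing) > 0) {
    stop(sprintf("library lacks segments: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  s <- lib$segments
  list(id = "template",
       seq = paste0(s[["GRNA_SITE"]], s[["LHA"]], s[["SRY"]], s[["GFP"]],
                    s[["RHA"]], s[["GRNA_SITE"]]))
}

blueprint_block <- function(seg, orient = "+", start = NA_integer_,
                            end = NA_integer_, role = "block") {
  data.frame(seg = seg, orient = orient, start = start, end = end,
             role = role, stringsAsFactors = FALSE)
}

#' Built-in allele blueprints
#'
#' Returns the blueprints for the wild-type locus, the 26 bp NHEJ-insertion
#' allele (A), the seven-copy template + backbone concatemer allele (B), its
#' three-copy deletion derivative (C, missing the middle four copies: two in
#' reverse then two in forward orientation), and the circular donor plasmid.
#'
#' Allele B block order: CHR17_L, T(+, gRNA-trimmed), 20 bp gRNA footprint,
#' PUC, 56 bp backbone fragment, T(+), 9 bp backbone fragment,
#' T(-), 20 bp, T(-), 20 bp, T(+), 20 bp, T(+), 20 bp, T(-, gRNA-trimmed),
#' CHR17_R. The outer boundaries are homology-repaired (no gRNA footprint);
#' the bracketed middle four copies T(-) T(-) T(+) T(+) are the deletion unit
#' that converts B into C, so C is an exact contiguous-deletion derivative.
#'
#' @param lib A `segment_library`.
#' @param footprint_len Length of the partial gRNA-site remnant at internal
#'   junctions (default 20).
#' @param puc_fragments Lengths of the two plasmid-backbone junction
#'   fragments (default 56 and 9).
#' @return Named list of `allele_blueprint` objects.
#' @export
builtin_blueprints <- function(lib, footprint_len = 20L,
                               puc_fragments = c(56L, 9L)) {
  tlen <- sum(lib$lengths[c("LHA", "SRY", "GFP", "RHA")]) +
    2L * nchar(lib$grna_site)
  gsite_len <- nchar(lib$grna_site)
  ttrim <- c(gsite_len + 1L, tlen)         # template minus its 5' gRNA site
  footp <- blueprint_block("GRNA_SITE", "+", 1L, footprint_len, "insert")
  frag56 <- blueprint_block("PUC", "+", 1001L, 1000L + puc_fragments[1],
                            "insert")
  frag9 <- blueprint_block("PUC", "+", 2001L, 2000L + puc_fragments[2],
                           "insert")
  flankL <- blueprint_block("CHR17_L", "+", role = "flank")
  flankR <- blueprint_block("CHR17_R", "+", role = "flank")
  Tp <- blueprint_block("TEMPLATE", "+")
  Tm <- blueprint_block("TEMPLATE", "-")
  Tp_trim <- blueprint_block("TEMPLATE", "+", ttrim[1], ttrim[2])
  Tm_trim <- blueprint_block("TEMPLATE", "-", ttrim[1], ttrim[2])

  bp <- function(name, blocks, circular = FALSE) {
    out <- list(name = name, blocks = do.call(rbind, blocks),
                cut_site = lib$lengths[["CHR17_L"]], circular = circular)
    class(out) <- "allele_blueprint"
    out
  }
  list(
    wildtype = bp("wildtype", list(flankL, flankR)),
    alleleA = bp("alleleA", list(
      flankL, blueprint_block("NHEJ_INSERT", "+", role = "insert"), flankR)),
    alleleB = bp("alleleB", list(
      flankL, Tp_trim, footp, blueprint_block("PUC", "+"), frag56, Tp, frag9,
      Tm, footp, Tm, footp, Tp, footp, Tp, footp, Tm_trim, flankR)),
    alleleC = bp("alleleC", list(
      flankL, Tp_trim, footp, blueprint_block("PUC", "+"), frag56, Tp, frag9,
      Tm_trim, flankR)),
    donor_plasmid = bp("donor_plasmid",
                       list(blueprint_block("TEMPLATE", "+"),
                            blueprint_block("PUC", "+")), circular = TRUE)
  )
}

block_emit <- function(lib, seg, orient, start, end) {
  s <- segment_seq(lib, seg)
  if (!is.na(start)) {
    if (start < 1 || end > nchar(s) || start > end) {
      stop(sprintf("truncation [%d,%d] outside segment %s (len %d)",
                   start, end, seg, nchar(s)), call. = FALSE)
    }
    s <- substr(s, start, end)
  }
  if (orient == "-") s <- revcomp(s)
  s
}

ref_label_of <- function(seg) {
  switch(seg,
         CHR17_L = "chr17", CHR17_R = "chr17",
         TEMPLATE = "template", PUC = "puc", seg)
}

#' Construct a ground-truth allele from a blueprint
#'
#' Emits the concatenation of the blueprint's oriented, optionally truncated
#' blocks, together with a truth table of emitted block coordinates and a
#' truth table of the junctions between consecutive major blocks (runs of
#' short `insert` blocks between them become the junction's inserted
#' sequence, annotated as homology-repair boundary, partial gRNA-site
#' footprint, backbone fragment, or NHEJ insert).
#'
#' @param lib A `segment_library`.
#' @param bp An `allele_blueprint`.
#' @return List with `id`, `seq`, `blocks` (emitted, 0-based half-open
#'   allele coordinates), `junctions`, `insertion_length` (bp between the
#'   outer genomic flanks) and `cut_site`.
#' @export
build_allele <- function(lib, bp) {
  blocks <- bp$blocks
  pieces <- character(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    pieces[i] <- block_emit(lib, blocks$seg[i], blocks$orient[i],
                            blocks$start[i], blocks$end[i])
  }
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  starts <- ends - lens
  emitted <- data.frame(seg = blocks$seg, orient = blocks$orient,
                        role = blocks$role, start = starts, end = ends,
                        ref = vapply(blocks$seg, ref_label_of, ""),
                        stringsAsFactors = FALSE)
  major <- which(blocks$role != "insert")
  jn <- list()
  if (length(major) >= 2) {
    for (k in seq_len(length(major) - 1L)) {
      i <- major[k]; j <- major[k + 1L]
      ins_idx <- setdiff(seq(i + 1L, j - 1L), integer(0))
      ins_idx <- ins_idx[ins_idx < j & ins_idx > i]
      ins_seq <- if (length(ins_idx) > 0) paste(pieces[ins_idx], collapse = "") else ""
      ins_segs <- if (length(ins_idx) > 0) blocks$seg[ins_idx] else character(0)
      ann <- if (nchar(ins_seq) == 0) {
        if (emitted$ref[i] == "chr17" || emitted$ref[j] == "chr17")
          "HR_boundary" else "blunt"
      } else if (all(ins_segs == "GRNA_SITE")) {
        sprintf("partial_gRNA_footprint(%d)", nchar(ins_seq))
      } else if (all(ins_segs == "PUC")) {
        sprintf("backbone_fragment(%d)", nchar(ins_seq))
      } else if (all(ins_segs == "NHEJ_INSERT")) {
        sprintf("nhej_insert(%d)", nchar(ins_seq))
      } else "unknown"
      jn[[k]] <- data.frame(
        left_ref = emitted$ref[i], left_orient = blocks$orient[i],
        right_ref = emitted$ref[j], right_orient = blocks$orient[j],
        pos = ends[i], insert_len = nchar(ins_seq), insert_seq = ins_seq,
        annotation = ann, stringsAsFactors = FALSE)
    }
  }
  junctions <- if (length(jn) > 0) do.call(rbind, jn) else
    data.frame(left_ref = character(0), left_orient = character(0),
               right_ref = character(0), right_orient = character(0),
               pos = integer(0), insert_len = integer(0),
               insert_seq = character(0), annotation = character(0))
  total <- sum(lens)
  flank_len <- sum(lens[blocks$role == "flank"])
  structure(list(id = bp$name, seq = paste(pieces, collapse = ""),
                 blocks = emitted, junctions = junctions,
                 insertion_length = total - flank_len,
                 cut_site = bp$cut_site, circular = isTRUE(bp$circular)),
            class = "allele")
}

#' Export an allele's truth block boundaries as BED6
#' @param allele Result of [build_allele()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
allele_truth_bed <- function(allele, path) {
  b <- allele$blocks
  write_bed(data.frame(chrom = allele$id, start = b$start, end = b$end,
                       name = paste0(b$seg, ifelse(is.na(b$start), "", "")),
                       score = 0L, strand = b$orient), path)
}

#' Template copy count of a blueprint
#' @param bp An `allele_blueprint`.
#' @return Number of template blocks (truncated copies count).
#' @export
template_copies <- function(bp) sum(bp$blocks$seg == "TEMPLATE")
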