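---
title: "Resolving complex knock-in alleles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving complex knock-in alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `kiresolve`, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
design choices made where the design was genuinely open. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## The locus model

The modelled system is a Cas9 edit at an autosomal safe-harbor locus. The
donor is a plasmid carrying a *complete template* — gRNA target site, 1 kb
left homology arm, 1.8 kb *SRY*, 1.3 kb GFP, 1 kb right homology arm, gRNA
target site; 5144 bp with the default lengths — inside a 2.7 kb pUC
backbone. Because the donor's own target sites are cleavable, repair can
concatenate released template fragments. Three edited alleles are built in:

* **alleleA** — the wild-type locus with a 26 bp insertion at the cut
  (NHEJ repair); 2026 bp end to end.
* **alleleB** — left flank · T(+) · pUC(+) · T(+) · [T(−) · T(−) · T(+) ·
  T(+)] · T(−) · right flank: seven template copies plus one backbone copy,
  38,829 bp of insertion (floors to 38 kb).
* **alleleC** — alleleB minus the bracketed middle four copies (two reverse
  then two forward — an inverted repeat, the plausible cause of the
  deletion): three copies plus the backbone, 18,173 bp (18 kb). C is an
  exact contiguous-deletion derivative of B, so every C junction sequence
  also occurs in B.

Junction footprints encode the repair pathway: the two outer boundaries are
homology-repaired and carry no gRNA-site remnant (the first and last
template copies are emitted with their boundary-side gRNA site trimmed);
internal blunt-ligation junctions carry a 20 bp partial gRNA-site remnant,
except two junctions that instead carry backbone fragments of 56 bp
(backbone→template side of the pUC copy) and 9 bp (the junction that
survives the B→C deletion). The fragments are drawn from the backbone
interior so that annotation can separate them from the adjacent full
backbone copy. The published architecture figure is schematic; the exact
copy order and fragment placement are configurable
(`builtin_blueprints()`), and the constraints the defaults satisfy are: 7
copies + 1 backbone at ~38 kb, middle-four inverted-repeat deletion to 3 + 1
at 18 kb, identical B/C ends, footprint-free outer boundaries, and 56/9 bp
backbone fragments at two internal junctions.

The wild-type locus embeds the gRNA site across the cut (left flank ends
with the first 16 protospacer bases; the right flank starts with the
remaining 3 plus the PAM; the cut sits 3 bp 5′ of the PAM). The printed
protospacer is 19 nt — one base short of a canonical SpCas9 spacer — and is
used exactly as printed, with the length exposed as a parameter. All other
segments are seeded random sequence, pairwise sharing no 25-mer (by
rejection), so k-mer-level reasoning about baits, decoys and junction
selection is exact. Sequence content is synthetic: results about *sequence
composition* (GC structure, repeats, mappability) do not transfer to the
real locus, but results about *architecture recovery* do, because they
depend only on segment lengths, copy arrangement and read geometry.

## The synthetic reads

`simulate_long()` draws read lengths from a log-normal with mean 15 kb
(sigma 0.6, clamped to [0.5 kb, 60 kb]) — matching the reported average —
and samples each allele to a per-allele base budget of
`coverage × abundance × length`, so the default genotype
(A:B:C = 1:1:0.1 at 50X) yields ~50X for the two major alleles and ~5X for
the derivative, the coverages of the motivating case. Budgeted sampling rather
than one global multinomial keeps per-allele coverage stable at these small
read counts; per-read allele proportions still follow abundance × length,
which the test suite checks by a chi-square goodness of fit at n ≥ 10⁴.
The default error profile is HiFi-like (sub/ins/del = 1%/0.5%/0.5%); a
CLR-like preset (5%/5%/3%) is available since the instrument mode is not
pinned down. Qualities are constant (Q20/Q30) because no stage weights by
quality. `simulate_short()` produces 150 bp FR pairs with N(350, 50) insert
sizes. Not modelled: chimeric reads, adapters, PCR duplicates, coverage
biases. Reads never extend past the allele ends (the 1 kb genomic flanks
are the outer limits), which slightly shortens reads from the 2 kb NHEJ
allele relative to a whole-genome library; this is why per-allele budgets,
not read counts, define coverage.

## Alignment kernels

Alignment uses match +1, mismatch −1, gap open −2, gap extend −1, with `N`
matching nothing. Inputs up to 2 kb are aligned by exhaustive affine
Smith–Waterman (multiple hits by target masking and rescanning); longer
inputs go through exact 15-mer seeding, diagonal clustering (diagonal gap
≤ 100 bp splits chains), greedy monotone chaining, and banded affine
verification over the chain extent (band = diagonal spread + 48). All
coordinates are 0-based half-open; minus-strand hits report the target span
on the forward strand. These kernels live in `src/` because the subread
mapping step aligns thousands of 1 kb fragments.

## Structure calling

Reads are tiled into 1 kb subreads stepping 0.5 kb; the last subread is
extended to the read end and never falls below 0.5 kb. Consecutive subread
hits to the same reference and orientation merge when the read-gap and
ref-gap agree within 200 bp; the coordinate wrap between tandem template
copies breaks collinearity, so each copy becomes its own block and copy
number is simply the number of template blocks. Blocks with under 300 bp of
read support are dropped — with the 1 kb/0.5 kb tiling geometry, shorter
blocks are alignment noise.

Block strings are canonicalised against their reverse complement and
clustered by exact identity. Cluster strings are then chained into
candidate structures anchored at the genomic flanks, with every extension
requiring a suffix/prefix overlap of **three** blocks. Three is the
smallest overlap that prevents the deletion derivative from being
hallucinated out of major-allele reads alone: every two-block adjacency of
alleleC also occurs in alleleB, so only reads carrying
backbone→template→template→right-flank (or a whole-allele span) genuinely
distinguish C, and the chain can only fork where such a read exists. The
flip side is a detection floor: at ~5X the derivative yields such a read in
the large majority of simulations, but a run without one leaves C
unreported — the honest information-theoretic limit of ~15 kb reads on this
allele (in the motivating case, only five long reads unambiguously
supported the derivative).

The support rule — "at least two reads from more than one cluster" — is
read conjunctively (≥ 2 compatible reads AND ≥ 2 distinct clusters), the
stricter of its two parses; both thresholds are configurable. One amendment
was necessary: a structure short enough that single reads span it entirely
(the wild-type or NHEJ locus) produces exactly one cluster by construction,
so the cluster requirement is alternatively satisfied by ≥ 2 whole-span
reads. Multi-cluster agreement substitutes for direct observation precisely
when no read can span the allele; when reads do span it, they are the
stronger evidence. A reported structure with no uniquely-supporting read is
flagged `ambiguous`.

Insertion length is estimated as the sum of per-position block lengths
(median reference span over reads where the block is internal) plus median
inter-block read gaps; junction gaps carry subread-boundary noise of a few
tens of bp, which is immaterial at the kb granularity reported
(`insertion_kb_floor`), while exact junction inserts come from the
short-read stage. The cut-site indel of a template-free structure is called
from a majority consensus of its cut-spanning reads aligned to the wild
type, counting net inserted minus deleted bases within ±50 bp of the cut —
at 1% read error and ≥ 10 reads this is exact. Two cut-spanning alleles
whose difference is confined to the cut (e.g. a wild-type/NHEJ
heterozygote) collapse into one block-string structure; separating them
would need indel-aware sub-clustering, which is out of scope — the
three-allele genotype has no wild-type homologue, so the situation does not
arise there.

## Junction discovery

Edge 25-mers (26 per 50 nt edge, forward and reverse complement) select
junction-spanning short reads exactly as a containment test. Error trimming
recounts 25-mer abundances *within the selected set* (strand-insensitive)
and truncates each read at the first base all of whose covering k-mers fall
below abundance 3; this mirrors trimming only the fished reads rather than
genome-wide counting. Assembly is greedy maximal-overlap extension with
minimum overlap 16 (the wrapped assembler's classic default): seeds are
chosen by total k-mer abundance (ties: longest, then lexicographically
smallest sequence), reads are usable once in either orientation, and all
tie-breaks are total orders, making the output invariant to input order —
a property the suite tests. At branch points (junctions sharing a flank)
the greedy contig commits to one branch and leftover reads seed the other,
so each true junction ends up in some contig; near coverage boundaries a
contig tail can chimerically switch branches, which surfaces as a handful
of `unknown` annotations alongside the true calls and is the reason the
original workflow kept a manual-examination step.

Contigs are annotated by local alignment against backbone, template and
wild-type locus. Tiling anchors must be ≥ 60 bp — deliberately larger than
the largest junction fragment (56 bp), so that a backbone fragment *at* a
junction is captured as the junction's insert rather than as a spurious
block — and anchor overlaps up to 25 bp are tolerated because the gRNA-site
bases shared between the genomic cut region and the template edge let both
sides absorb a few common bases. Inserts are classified by exact substring
match against the gRNA site first (footprints are ≤ 22 bp), then the
backbone, else `unknown`.

## Consensus

Substructure groups (one per supporting cluster of a reported structure)
are oriented to the canonical strand and trimmed to 200 bp of genomic flank
— enough anchor to align, little enough that wild-type sequence does not
dominate. The multiple alignment is center-star: the center is the read
with the highest summed pairwise similarity, estimated from shared 15-mers
rather than by all-pairs alignment (n² full alignments of 15 kb reads would
dominate the runtime, and the center choice affects only gap placement,
never the majority call); each read is first anchored on the center by seed
chains — reads of one substructure start at staggered offsets, so the
alignable core must be located before banding — then banded-aligned, and
the pairwise alignments merge under "once a gap, always a gap". Groups are
capped at the 20 longest reads. The consensus emits, per column, the
residue with plurality > 0.5 among non-gap entries, ties resolved A < C <
G < T, and emits nothing where gaps hold a strict majority (this pins down
one of several gap conventions found among consensus tools). Consensus
accuracy is checked in the covered interior of each group; the staggered
group ends are covered by few reads and retain their residual error.

## Profiling

Depth profiles assign each short read to its best-scoring panel reference —
no multi-mapping split, so summed depth equals summed aligned bases
(conservation is a tested invariant). The observed template-vs-NHEJ depth
ratio mixes copy number, shared homology arms and allele dosage, so only
the direction (template deeper) is asserted anywhere. The off-target scan
counts reads that best-align to a decoy contig *and* contain a donor
25-mer; decoys are built to share no 25-mer with the donor, so a clean
simulation yields zero and a planted template copy is detected. In-silico
PCR uses exact full-length primer matches (diagnostic-PCR semantics) and
reports products on both strands up to a length cap.

## Problem sizes and determinism

The default study-scale run — ~200 long reads (2.3 Mb), ~15,000 short-read
pairs, full chain — was chosen so that simulation and resolution complete
in about two to three minutes on one CPU; unit and property tests run on
much smaller constructed cases. Every source of randomness flows from one
master seed through fixed offsets; inference itself is
deterministic (all ties broken by total orders), so identical
configuration and seed give byte-identical outputs, which both the suite
and the acceptance script rely on.

## Known limitations

* Allele structures distinguishable only by features smaller than the
  block resolution (~300 bp) or confined to the cut site collapse into one
  structure.
* Derivative alleles at very low coverage are only reported when a
  distinguishing long read exists; there is no rescue from short reads.
* The greedy assembler can emit chimeric contig tails at coverage
  boundaries; junction calls should be read as a set (true junctions are
  recovered; a few `unknown` extras may accompany them).
* The synthetic locus is random sequence: repeat- or GC-driven artifacts
  of real data are not represented, and recruitment/selectivity results
  should be read as upper bounds on specificity.
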