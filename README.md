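# kiresolve

Resolving the structure of complex CRISPR knock-in alleles from long- and
short-read sequencing.

## The problem

Cas9-mediated knock-ins that use donors with homology arms flanked by gRNA
target sites (HMEJ-style designs) do not always integrate as the single
intended copy. Cleavage of the donor's own target sites releases template
fragments that can concatenate by blunt-end ligation, producing multi-copy
tandem/inverted arrays that may also capture the plasmid backbone. At a
bovine safe-harbor locus (H11, chromosome 17) such an event produced, in one
animal, a 26 bp NHEJ insertion allele on one homologue and a ~38 kb complex
allele on the other — seven copies of the 5.1 kb *SRY*-GFP donor cassette in
mixed orientations plus one copy of the 2.7 kb pUC backbone — together with
a minor 18 kb derivative missing the middle four (inverted-repeat) cassette
copies, present at about one tenth the coverage.

Standard variant callers do not reconstruct such alleles. `kiresolve`
implements the resolution chain as a reusable, tested pipeline:

1. **Recruitment** — candidate long reads are fished with a four-record bait
   set: the wild-type locus (1 kb either side of the break point), the
   plasmid backbone, the complete template, and the small-insertion allele.
2. **Block strings** — each candidate read is fragmented into 1 kb subreads
   with 0.5 kb overlap, subreads are aligned to a composite reference
   (locus, backbone, template, decoys), and collinear hits are merged into a
   per-read ordered list of (reference, orientation) blocks. Copy number
   falls out of the wraps on the collapsed template reference.
3. **Clustering and chaining** — reads with identical canonical block
   strings form clusters; cluster strings are chained (suffix/prefix overlap
   of ≥ 3 blocks) into complete allele structures anchored at the genomic
   flanks. A structure is reported when supported by ≥ 2 reads from ≥ 2
   clusters (or ≥ 2 whole-allele-spanning reads). Template-free structures
   get a cut-site indel call from a read consensus aligned to the wild type.
4. **Junctions** — the terminal 50 nt of each donor/backbone edge become 26
   overlapping 25-mers; short reads containing any of them (or their
   reverse complement) are selected, error-trimmed by within-set k-mer
   abundance, assembled by greedy maximal-overlap extension (SSAKE-style),
   and contigs are annotated by local alignment to call each junction's
   block pair and classify its insert (HR boundary, partial gRNA-site
   footprint, backbone fragment).
5. **Confirmation and profiling** — center-star multiple alignment and
   majority-rule consensus per substructure; per-base short-read depth over
   the reference panel; an off-target scan for donor k-mers on background
   contigs; in-silico PCR genotyping.

A seeded synthetic-data generator (`make_library()`, `builtin_blueprints()`,
`simulate_long()`, `simulate_short()`) reproduces the study conditions — the
three-allele genotype, PacBio-like ~15 kb reads at ~50X per allele (the
derivative at one tenth abundance), and 150 bp paired-end short reads — so
the whole chain runs and is tested without any external data.

## Worked example

The numbered scripts under `analysis/` run the full study on the default
seeded simulation (`Rscript analysis/01_simulate.R`, then `02` … `05`).
Output of the structure-calling step (`analysis/03_structures.R`):

```
        name n_template_copies n_backbone_copies insertion_kb_floor
1 structure1                 7                 1                 38
2 structure2                 3                 1                 18
3 structure3                 0                 0                  0
  cutsite_indel n_support
1            NA       152
2            NA        43
3            26        50
```

Read: the major allele is reconstructed with 7 template copies plus 1
backbone copy and a 38 kb insertion; the minor allele (simulated at one
tenth coverage) with 3 copies plus 1 backbone at 18 kb (their copy-number
difference of 4 is the inverted-repeat deletion unit); the third structure
carries no template and a +26 bp insertion at the Cas9 cut — the NHEJ
allele. No wild-type structure is reported. Junction discovery from the
short reads (`analysis/04_junctions.R`) recovers every truth junction:

```
backbone_fragment(56)  backbone_fragment(9)  HR_boundary  partial_gRNA_footprint(20)
                    2                     2            3                          10
```

i.e. the 56 bp and 9 bp backbone fragments at two internal junctions, the
footprint-free homology-repaired outer boundaries, and 20 bp partial
gRNA-site footprints at the remaining junctions. Depth profiling shows the
multi-copy enrichment of template-aligned reads relative to the NHEJ allele
(mean depth 728 vs 191 here), the off-target scan flags 0 reads, and
in-silico PCR with a wild-type 500 bp design amplifies 526 bp from the NHEJ
allele (shifted by the 26 bp insertion) and nothing from the concatemer
alleles.

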