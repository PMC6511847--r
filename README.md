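# rippmine

Family-independent mining of RiPP precursor peptides near tailoring enzymes.

## The problem

Ribosomally synthesized and post-translationally modified peptides (RiPPs)
are made from short, gene-encoded precursor peptides, but their biosynthetic
gene clusters are hard to predict: there is no biosynthetic feature shared
by all RiPP classes, and the precursor genes themselves are so short that
standard genome annotation usually misses them. What RiPP clusters *do*
reliably contain is a tailoring enzyme (RTE) — for example the YcaO/TfuA
pair implicated in backbone thioamidation. `rippmine` turns that around: it
takes genomic regions anchored on a user-designated RTE and hunts the
neighborhood for plausible precursor-peptide ORFs regardless of RiPP class.

It is aimed at natural-product genome miners who have candidate RTE loci
(as GenBank records) and want a ranked, networked set of candidate
precursor peptides to inspect.

## The method

Per region, with all defaults adjustable in a flat `local.conf`-style file:

1. **Window** — a sub-region of `flankLen` nt (default 17 500) on each side
   of the RTE is extracted.
2. **Short-ORF enumeration** — every start-to-stop span (ATG/GTG/TTG,
   translation table 11) of at least 60 nt in all six frames is a
   candidate; every in-frame upstream start sharing a stop is kept as a
   distinct candidate.
3. **Coding scoring** — a self-trained model scores each candidate:
   in-frame hexamer log-odds (annotated CDS vs whole-region background),
   ribosome-binding-site 6-mer/spacer weights learned from the region's own
   genes, and a start-codon term, summed and affinely calibrated so that
   gene-like ORFs typically exceed the default retrieval threshold of 7.5.
4. **Filters and reward** — candidates overlapping annotated genes by more
   than `maxOverlapNt` (20) are dropped, peptides must be 20–120 aa
   (`minPPlen`/`maxPPlen`), and candidates on the RTE's strand gain
   `sameStrandReward` (5). Annotated genes encoding peptides ≤ 120 aa enter
   the same pool.
5. **Retrieval** — within `maxDistFromTE` (8 000 nt) of the RTE, the top
   `fastaOutputLimit` (3) scorers are always retrieved, plus anything at or
   above `prodigalScoreThresh` (7.5). Results are tabulated in `out.txt`
   and written to `out.faa`, and the region is re-emitted as a GenBank file
   with candidates colour-ramped from pale red to bright pink (RTE in
   green).
6. **Distant rescue** — every non-retrieved candidate in the file is
   scanned against position-specific precursor-domain profiles; hits are
   tabulated in `distant.txt`/`distant.faa` regardless of distance or
   score.
7. **Networking** — all retrieved plus distant peptides are aligned
   all-vs-all (Smith–Waterman, BLOSUM62, gap open 11 / extend 1). An edge
   requires E ≤ 10 (Karlin–Altschul, λ = 0.267, K = 0.041), ≥ 40% identity
   over alignment columns, the hit covering ≥ 35% of the shorter peptide,
   and ≥ 15 aligned columns. Connected components, ranked by size, are the
   candidate peptide families (`network.sif`, `networks.tsv`,
   `node_attributes.tsv` for graph viewers). A greedy 99%-identity
   dereplicator is included for redundant input sets.

A small mass module covers the downstream arithmetic for thioamidated
products: monoisotopic masses of peptides with N-acetyl (+42.010565),
backbone thioamide (+15.977156, S for O) and desaturation (−2.015650)
modifications, protonated m/z, H₂S neutral-loss (33.987721 Da) screening of
fragment lists, and tolerance-based comparative feature matching
(100 mDa / 0.1 min / 10⁵ intensity defaults).

Seeded synthetic fixtures (`make_synthetic_region`, `make_peptide_family`)
generate GC-rich contigs with annotated genes, one marked RTE and planted
unannotated precursors — with truth tables — so the whole workflow is
testable offline.

## Worked example

```r
library(rippmine)

planted <- data.frame(length_aa = c(40L, 60L), dist_nt = c(3000L, 9500L),
                      strand = c(1L, 1L), has_domain = c(FALSE, TRUE))
fx <- make_synthetic_region(region_spec(seed = 42, planted = planted))
res <- run_ripper(run_manifest(list(fx$region), output_dir = "demo-out",
                               profiles = list(toy_domain_profile())))
res$report
#>       accession candidates retrieved distant
#> 1 SYNREG0000042        684         3       3
res$out[, c("peptide", "distance_nt", "same_strand", "score")]
#>                                          peptide distance_nt same_strand   score
#> 1 MSEEDLMFRWCSDFYVDWRHGYWRWKLNQMHSNLVILFTHWDSHVT        2976        TRUE  7.5728
#> 2       MFRWCSDFYVDWRHGYWRWKLNQMHSNLVILFTHWDSHVT        2994        TRUE 12.0950
#> 3                           MTLRRWDEWNHGISANVVGR        6413        TRUE  4.1073
```

The planted 40-aa precursor 3 kb from the RTE is retrieved (rows 1–2 are
its two in-frame start variants; the nested start scores higher and both
exceed or approach the 7.5 threshold after the +5 same-strand reward). The
planted distant precursor at 9.5 kb is outside the 8 kb window but carries
the domain motif, so its start variants land in `res$distant` with the
profile name in the `domains` column. Scores are unitless coding-likelihood
values; `distance_nt` is the gap to the RTE in nucleotides.

Mass arithmetic, e.g. the [M+H]⁺ of an N-acetylated APR tripeptide with a
thioamide on the Pro–Arg bond:

```r
mz_protonated(modified_peptide("APR", n_acetyl = TRUE, thioamide = 2))
#> [1] 401.1966
```

A thin CLI wraps the same functions: see `inst/scripts/ripper-mine`
(`run`, `network`, `synth`, `mass` subcommands).

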