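---
title: "Mining RiPP precursor peptides near tailoring enzymes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining RiPP precursor peptides near tailoring enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rippmine)
```

# The mining model

RiPP precursor genes are short (here 20–120 aa), frequently unannotated,
and share no universal sequence feature across RiPP classes. What they do
share is context: they sit near a tailoring-enzyme (RTE) gene, they tend to
lie on the same strand as it, and they look like genes — biased codon
usage, a ribosome binding site, a proper start codon. `rippmine` encodes
exactly those signals and nothing class-specific, which is what makes the
search family-independent.

The workflow is a composition of small, separately testable stages:
windowing around the RTE, six-frame short-ORF enumeration, self-trained
coding scoring, annotation-overlap and size filters, a same-strand reward,
distance-bounded top-N retrieval, profile-based rescue of distant
domain-bearing peptides, and similarity networking of everything
retrieved.

# The coding-potential score

The score must rank unannotated short ORFs against annotated short genes
on one scale, with a threshold that separates "gene-like" from
"background". A full bacterial gene-finder model is not needed for that
contract; the score used here has three additive parts, each trained on
the analysis region itself:

* **Hexamer log-odds.** In-frame hexamers (step 3, i.e. di-codons) are
  counted over annotated CDS of ≥ 300 nt on their coding strands;
  background counts come from all hexamer offsets of both strands of the
  whole region. The per-hexamer score is
  `log(freq_coding / freq_background)` with add-one smoothing over all
  4096 hexamers; a candidate's coding component is the sum over its
  in-frame hexamers (stop codon excluded), i.e. the mean log-odds scaled
  by length. Hexamers containing N contribute 0.
* **RBS weights.** Each (6-mer, spacer) pair observed in the 21 nt
  upstream of training-gene starts, with spacers of 3–15 nt, is weighted
  by `log(observed / expected-from-background)`; only positive weights are
  kept. A candidate receives the best match in its own upstream window.
* **Start bonus.** Log-odds of the candidate's start codon (ATG/GTG/TTG)
  against a uniform prior, from the training genes' start codons.

With fewer than three usable training genes the model is flagged untrained
and all learned terms are zero — candidates are then ranked by start/RBS
evidence only, and the condition is recorded in their notes.

The total is `0.55 × (coding + rbs + start)`. That affine calibration is a
fixed constant committed in the code, not fitted per run: it was chosen
once against the seeded synthetic fixture suite so that planted authentic
genes typically score above the default retrieval threshold of 7.5 while
random intergenic ORFs score well below it (fixture medians sit around −6;
planted precursors around 7–12 before the strand reward). The numeric
scale of the thresholds (7.5 default, 15 strict) therefore has meaning
only relative to this calibration, which is why it is frozen.

Enumeration keeps *every* in-frame upstream start sharing a stop as a
distinct candidate rather than committing to one start site; retrieval
later picks by score. This trades a little redundancy in the output tables
for never missing the correct start. The enumerator's hard length cap is
twice `maxPPlen`, purely to bound work — the retrieval filter re-applies
the real 20–120 aa window.

# Retrieval parameters

| key | default | meaning |
|---|---|---|
| `flankLen` | 17 500 nt | window half-width around the RTE |
| `maxOverlapNt` | 20 nt | tolerated overlap with annotated genes (strand-blind interval intersection) |
| `minPPlen`/`maxPPlen` | 20/120 aa | precursor size window |
| `sameStrandReward` | 5 | score added on the RTE's strand |
| `maxDistFromTE` | 8 000 nt | retrieval distance (half-open interval gap; abutment = 0) |
| `fastaOutputLimit` | 3 | top scorers always retrieved |
| `prodigalScoreThresh` | 7.5 | additional retrieval threshold |

Ties in the top-N slice are broken by smaller distance, then smaller start
coordinate — an arbitrary but deterministic order chosen so reruns are
byte-identical. Annotated genes encoding ≤ `maxPPlen` peptides join the
candidate pool (one pool, ranked together), bypass the overlap filter
(they *are* the annotation) and the minimum length, and receive the strand
reward like any other candidate. The dedup key for retrieval includes
coordinates, so identical peptide sequences at different loci are all
kept.

# Domain rescue

Peptides outside the distance window are rescued if they carry a
recognizable precursor-peptide domain. The scanner is an ungapped
position-specific score matrix slid over the peptide, with a per-profile
reporting threshold in the spirit of a family gathering cutoff. Full
profile-HMM alignment is deliberately out of scope: for short, compact
precursor domains an ungapped scan preserves the rescue contract while
keeping the profile format a versioned plain-text table. `X` residues
score 0 at any column and flanking `X` runs are trimmed, so `X` padding
cannot change a result; a peptide shorter than a profile can never hit it.

# Networking

Edges require a local alignment (BLOSUM62, gap open 11 / extend 1) passing
all of: E ≤ 10, identity ≥ 40% over alignment columns (gap columns
included — the usual pairwise-BLAST convention; the identity denominator
was a genuinely open choice and this is the one documented here), coverage
≥ 35% of the shorter peptide, and ≥ 15 aligned columns. The E-value uses
the closed Karlin–Altschul form with fixed gapped constants (λ = 0.267,
K = 0.041). With E ≤ 10 the topology is dominated by the
identity/coverage/length thresholds, so the approximation is low-risk.
Each unordered pair is aligned once (the score is symmetric under this
scheme). Components are ranked by size, ties by smallest member id;
singletons are reported separately. Dereplication (default 99% global
identity, greedy by length) is available for redundant inputs.

# Mass arithmetic

Modifications are pure mass deltas on standard monoisotopic residue
masses: N-acetyl +42.010565 Da, thioamide +15.977156 Da (S replacing the
carbonyl O of a named backbone bond), desaturation −2.015650 Da. The
thioamide is modeled only as the O→S substitution — the YcaO/TfuA
enzymology is not modeled — and the desaturation is position-agnostic,
since its mass effect does not depend on the site. All tolerance
comparisons (H₂S-loss pairing at 0.01 Da, feature matching at 100 mDa /
0.1 min / 10⁵ intensity) are inclusive at the bound. For replicate
matching, a feature is unique to a group only if present post-threshold in
*all* of that group's replicates and matched in none of any other group's
— the strictest consensus rule, chosen because it cannot promote noise
features.

# What the synthetic fixtures emulate — and what they do not

`make_synthetic_region` builds a 25 kb (configurable), 65% GC contig with
10 annotated CDS of 150–400 codons sharing a GC-biased codon-usage table
and an AGGAGG RBS at 5–9 nt spacing, one gene marked as the RTE, and
planted unannotated precursors (20–120 aa, same codon usage and RBS) at
requested distances and strands. Intergenic background is random sequence
at the GC target, repaired so that no frame on either strand runs more
than 50 codons without a stop — suppressing long accidental ORFs where
compatible with the GC target. Planted "domain-bearing" precursors carry a
fixed 15-aa core motif with a matching toy profile
(`toy_domain_profile()`), a synthetic stand-in for a curated
precursor-domain model.

`make_peptide_family` grows families from random 80-aa ancestors by
per-site substitution. The ancestor length matters: families must cohere
at substitution rate 0.15 (pairwise identity ≈ 72%, far above the 40%
edge threshold) while unrelated peptides stay unconnected. Chance local
alignments between unrelated random peptides occasionally reach 40%
identity over ≥ 15 columns, so the discriminating threshold is coverage of
the shorter sequence; at 80 aa a chance hit would need ≥ 28 aligned
residues, which in practice does not occur, whereas at much shorter
lengths the 35% bar is within reach of background alignments.

These fixtures establish that the machinery finds what its model says it
should find. They do not emulate real genomes' repeat structure, skewed
intergenic composition, operonic gene spacing, pseudogenes, or annotation
errors — so passing fixture tests demonstrates correctness of the method,
not field sensitivity/specificity on real Actinobacteria, which depend on
the genome and the curated domain profiles supplied.

Problem sizes used by the test suite (chosen as comfortable desk-scale
checks): oracle equivalence on 500 random sequences up to 1 kb, 200
random alignment pairs up to 12 aa (exhaustive DP), 1 000 randomized
retrieval sets, and planted-precursor recovery over 50 seeded regions.

# Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally; GenBank's 1-based
  inclusive form exists only at the file boundary. Distance between
  intervals is the gap between nearest ends; overlap or abutment is 0.
* Compound (`join`/`order`) feature locations are rejected with a clear
  error; bacterial single-span inputs are the target.
* The RTE is designated by an explicit identifier argument (which errors
  if it matches no CDS), else a `/ripper_rte` qualifier, else the CDS
  nearest the record midpoint; the mode used is logged on the region.
* Features only partly inside an extracted window are truncated and lose
  their stored translation.
* Score text in the output tables is fixed at four decimals so identical
  runs are byte-identical.
* The strand reward is guarded by a flag: applying it twice is a no-op.
* An all-negative alignment (no positive substitution pair) has raw score
  0, an empty hit, and can never form an edge.

# Known limitations

* The coding model is intentionally simpler than a production gene
  finder: no GC-frame-plot start refinement, no dicodon interpolation, no
  metagenomic fallback models. Its scores are comparable only within the
  calibration shipped here.
* The domain scanner is ungapped; profiles with indel-tolerant cores
  would need the external-HMM route.
* One E-value constant set is shipped (BLOSUM62, 11/1 gaps); other
  matrices would need their own λ/K.
* GenBank I/O is single-record and single-span; EMBL and multi-record
  files are out of scope.
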