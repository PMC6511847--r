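Package: rippmine
Title: Family-Independent Mining of RiPP Precursor Peptides Near Tailoring Enzymes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds candidate ribosomally synthesized and post-translationally
    modified peptide (RiPP) precursor open reading frames in genomic
    neighborhoods anchored on a user-designated RiPP tailoring enzyme (RTE).
    Short ORFs (down to 60 nt) are enumerated in all six frames, scored for
    coding potential with a self-trained hexamer/ribosome-binding-site model,
    filtered against the existing annotation, rewarded for sharing the RTE's
    strand, and retrieved by a top-N-plus-score-threshold rule within a
    distance window. Distant peptides carrying known precursor-peptide
    domains are rescued by a profile scan. Retrieved peptides are grouped
    into similarity networks (Smith-Waterman, BLOSUM62, identity/coverage/
    length/E-value thresholds) and exported for graph viewers. A small mass
    module performs monoisotopic mass arithmetic for modified peptides
    (N-acetylation, backbone thioamidation, desaturation), H2S neutral-loss
    screening of fragment lists, and tolerance-based comparative feature
    matching. Seeded synthetic genomic regions and peptide families make the
    whole workflow testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
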