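# Seeded synthetic genomic regions and peptide families. The generator
# emulates the workflow's input material: a GC-rich (60-75%) actinobacterial
# contig of 25-35 kb carrying ~10 annotated CDS that share a codon-usage
# table and a Shine-Dalgarno motif, one gene marked as the RiPP tailoring
# enzyme, and 0-3 planted unannotated precursor ORFs (20-120 aa) built from
# the same codon usage and RBS at controlled distances/strands from the RTE.
# Truth tables make every pipeline stage testable without downloads.

# Fixed 15-aa core motif carried by "domain-bearing" planted precursors,
# with its companion toy profile for the rescue step. Synthetic stand-in
# for a characterized precursor-peptide domain.
DOMAIN_CORE_PEPTIDE <- "CWGEDHLTPLKCWGC"

#' Toy precursor-domain profile matching the planted core motif
#'
#' A position-specific profile scoring +3 for the consensus residue and -1
#' otherwise, thresholded so that the planted motif always hits and random
#' peptides essentially never do (threshold 30 allows up to three
#' mismatches of the 15 positions).
#'
#' @param name Profile name.
#' @return A [domain_profile()].
#' @export
toy_domain_profile <- function(name = "precursor_core_synthetic") {
  res <- strsplit(DOMAIN_CORE_PEPTIDE, "", fixed = TRUE)[[1]]
  mat <- matrix(-1, nrow = 20L, ncol = length(res), dimnames = list(AA20, NULL))
  mat[cbind(match(res, AA20), seq_along(res))] <- 3
  domain_profile(name, mat, threshold = 30)
}

#' Specification for one synthetic region
#'
#' @param seed Integer seed; fixes every random choice.
#' @param length_nt Contig length (default 25000).
#' @param gc_fraction Target GC content (default 0.65).
#' @param n_genes Number of annotated CDS (default 10).
#' @param rbs_motif Shine-Dalgarno motif written upstream of every gene and
#'   planted precursor (default `"AGGAGG"`).
#' @param rte_index Which gene (1-based, in left-to-right order) is the RTE;
#'   default the middle one.
#' @param planted Data frame describing planted precursors, columns
#'   `length_aa` (20-120), `dist_nt` (requested distance from the RTE),
#'   `strand` (+1 same as RTE, -1 opposite), `has_domain` (logical).
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(seed, length_nt = 25000L, gc_fraction = 0.65,
                        n_genes = 10L, rbs_motif = "AGGAGG",
                        rte_index = NULL,
                        planted = data.frame(length_aa = integer(),
                                             dist_nt = integer(),
                                             strand = integer(),
                                             has_domain = logical())) {
  if (is.null(rte_index)) rte_index <- as.integer(ceiling(n_genes / 2))
  stopifnot(gc_fraction > 0, gc_fraction < 1, n_genes >= 1L,
            rte_index >= 1L, rte_index <= n_genes)
  if (nrow(planted)) {
    stopifnot(all(planted$length_aa >= 20L), all(planted$length_aa <= 120L),
              all(planted$dist_nt >= 0L),
              all(planted$dist_nt < length_nt),
              all(planted$strand %in% c(1L, -1L)))
  }
  structure(list(seed = as.integer(seed), length_nt = as.integer(length_nt),
                 gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
                 rbs_motif = rbs_motif, rte_index = as.integer(rte_index),
                 planted = planted), class = "region_spec")
}

# Codon-usage table biased toward the GC target: each codon weighted by the
# product of per-base probabilities, normalized within each amino acid.
gc_codon_usage <- function(gc_fraction) {
  tab <- codon_table()
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  codons <- names(tab)
  w <- vapply(codons, function(cd) {
    prod(p[strsplit(cd, "")[[1]]])
  }, numeric(1))
  split(stats::setNames(w, codons), unname(tab))
}

# Encode an amino-acid sequence with weighted codon sampling (no stop).
encode_peptide <- function(pep, usage) {
  res <- strsplit(pep, "", fixed = TRUE)[[1]]
  cods <- vapply(res, function(a) {
    u <- usage[[a]]
    sample(names(u), 1L, prob = u)
  }, character(1))
  paste(cods, collapse = "")
}

random_peptide <- function(len, first = "M") {
  # mildly GC-codon-compatible amino-acid palette; no stops by construction
  paste0(first, paste(sample(AA20, len - 1L, replace = TRUE), collapse = ""))
}

random_dna <- function(n, gc_fraction) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                        gc_fraction / 2, (1 - gc_fraction) / 2)),
        collapse = "")
}

# Background intergenic sequence: random at the GC target, then repaired so
# no reading frame on either strand runs more than max_run codons without a
# stop (long accidental ORFs are suppressed where compatible with GC).
stop_rich_dna <- function(n, gc_fraction, max_run = 50L) {
  s <- strsplit(random_dna(n, gc_fraction), "", fixed = TRUE)[[1]]
  if (n < 6L) return(paste(s, collapse = ""))
  for (pass in 1:3) {
    seqstr <- paste(s, collapse = "")
    rc <- revcomp(seqstr)
    changed <- FALSE
    for (strand in 1:2) {
      cur <- if (strand == 1L) seqstr else rc
      for (frame in 0:2) {
        cods <- codons_of(cur, frame + 1L)
        if (length(cods) < 2L) next
        is_stop <- cods %in% STOP_CODONS
        run <- 0L
        for (k in seq_along(cods)) {
          if (is_stop[k]) { run <- 0L; next }
          run <- run + 1L
          if (run > max_run) {
            # overwrite this codon with TGA (GC-friendliest stop)
            p0 <- frame + (k - 1L) * 3L  # 0-based within cur
            if (strand == 1L) {
              s[(p0 + 1L):(p0 + 3L)] <- c("T", "G", "A")
            } else {
              q0 <- n - (p0 + 3L)        # map back to forward strand
              s[(q0 + 1L):(q0 + 3L)] <- c("T", "C", "A")  # revcomp of TGA
            }
            run <- 0L; changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  paste(s, collapse = "")
}

#' Generate a seeded synthetic genomic region with planted precursors
#'
#' Deterministic for a fixed spec (same seed twice gives byte-identical
#' output). Annotated genes and planted precursors share the codon-usage
#' table and RBS motif; the intergenic background is stop-codon-rich random
#' sequence at the GC target. Planted precursors are NOT annotated as
#' features; the truth table lists their coordinates, strands, peptides and
#' realized distances from the RTE.
#'
#' @param spec A [region_spec()].
#' @param dir Optional directory; when given, `<accession>.gbk` and
#'   `<accession>_truth.tsv` are written there.
#' @return List with `region` (a [genomic_region()]), `truth` (data frame),
#'   and (if written) `genbank_path`, `truth_path`.
#' @export
make_synthetic_region <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "region_spec"))
  with_seed(spec$seed, {
    usage <- gc_codon_usage(spec$gc_fraction)
    acc <- sprintf("SYNREG%07d", spec$seed %% 10000000L)

    # gene lengths in codons (excl. stop); all well above the precursor
    # window so annotated genes do not crowd the peptide pool
    gene_aa <- sample(150:400, spec$n_genes, replace = TRUE)
    gene_nt <- (gene_aa + 1L) * 3L
    # gaps sized so everything fits with room for planted precursors
    spare <- spec$length_nt - sum(gene_nt)
    if (spare < 400L * (spec$n_genes + 1L)) {
      stop("region too short for ", spec$n_genes, " genes")
    }
    gap_w <- runif(spec$n_genes + 1L, 0.8, 1.2)
    gap_nt <- floor(gap_w / sum(gap_w) * spare)
    gap_nt[1] <- gap_nt[1] + (spare - sum(gap_nt))

    # lay out [gap1][gene1][gap2][gene2]...[gapN+1]
    gene_start <- integer(spec$n_genes)
    pos <- 0L
    for (i in seq_len(spec$n_genes)) {
      pos <- pos + gap_nt[i]
      gene_start[i] <- pos
      pos <- pos + gene_nt[i]
    }
    gene_end <- gene_start + gene_nt
    gene_strand <- sample(c(1L, -1L), spec$n_genes, replace = TRUE,
                          prob = c(0.7, 0.3))
    gene_strand[spec$rte_index] <- 1L  # planted strands are defined
                                       # relative to the RTE; fix it forward
    gene_pep <- vapply(gene_aa, function(k) random_peptide(k), character(1))

    seq_chars <- strsplit(stop_rich_dna(spec$length_nt, spec$gc_fraction),
                          "", fixed = TRUE)[[1]]

    write_gene <- function(seq_chars, start, strand, pep, rbs_motif) {
      cds <- paste0(encode_peptide(pep, usage), "TGA")
      nt <- nchar(cds)
      if (strand < 0) cds <- revcomp(cds)
      seq_chars[(start + 1L):(start + nt)] <- strsplit(cds, "", fixed = TRUE)[[1]]
      # RBS on the coding strand, spacer 5-9 nt upstream of the start
      spacer <- sample(5:9, 1L)
      mlen <- nchar(rbs_motif)
      if (strand > 0) {
        a <- start - spacer - mlen
        if (a >= 0L) {
          seq_chars[(a + 1L):(a + mlen)] <- strsplit(rbs_motif, "", fixed = TRUE)[[1]]
        }
      } else {
        a <- start + nt + spacer
        if (a + mlen <= length(seq_chars)) {
          seq_chars[(a + 1L):(a + mlen)] <-
            strsplit(revcomp(rbs_motif), "", fixed = TRUE)[[1]]
        }
      }
      seq_chars
    }

    for (i in seq_len(spec$n_genes)) {
      seq_chars <- write_gene(seq_chars, gene_start[i], gene_strand[i],
                              gene_pep[i], spec$rbs_motif)
    }

    rte_s <- gene_start[spec$rte_index]; rte_e <- gene_end[spec$rte_index]
    rte_strand <- gene_strand[spec$rte_index]

    # plant precursors into intergenic space at the requested distances
    truth <- data.frame(start = integer(), end = integer(), strand = integer(),
                        peptide = character(), length_aa = integer(),
                        dist_requested = integer(), dist_nt = integer(),
                        has_domain = logical(), stringsAsFactors = FALSE)
    occupied <- cbind(gene_start, gene_end)
    margin <- 30L  # keep clear of gene RBS regions and gap edges
    for (k in seq_len(nrow(spec$planted))) {
      p <- spec$planted[k, ]
      pep_body <- random_peptide(p$length_aa)
      if (p$has_domain) {
        ins <- 3L  # after the leader start
        substr(pep_body, ins + 1L, ins + nchar(DOMAIN_CORE_PEPTIDE)) <-
          DOMAIN_CORE_PEPTIDE
      }
      nt_len <- (p$length_aa + 1L) * 3L
      strand <- p$strand * rte_strand
      # candidate placements: scan intergenic gaps for slots matching dist
      best <- NULL; best_err <- Inf
      pos0 <- 0L
      gaps <- list()
      for (i in seq_len(spec$n_genes)) {
        gaps[[i]] <- c(pos0, gene_start[i])
        pos0 <- gene_end[i]
      }
      gaps[[spec$n_genes + 1L]] <- c(pos0, spec$length_nt)
      for (g in gaps) {
        a <- g[1] + margin; b <- g[2] - margin
        if (b - a < nt_len + margin) next
        for (st in seq.int(a, b - nt_len, by = 17L)) {
          d <- interval_gap_nt(st, st + nt_len, rte_s, rte_e)
          err <- abs(d - p$dist_nt)
          clash <- any(interval_overlap_nt(st - margin, st + nt_len + margin,
                                           occupied[, 1], occupied[, 2]) > 0L)
          if (!clash && err < best_err) { best <- st; best_err <- err }
        }
      }
      if (is.null(best)) stop("no intergenic slot for planted precursor ", k)
      seq_chars <- write_gene(seq_chars, best, strand, pep_body, spec$rbs_motif)
      occupied <- rbind(occupied, c(best, best + nt_len))
      truth <- rbind(truth, data.frame(
        start = best, end = best + nt_len, strand = strand,
        peptide = pep_body, length_aa = p$length_aa,
        dist_requested = p$dist_nt,
        dist_nt = interval_gap_nt(best, best + nt_len, rte_s, rte_e),
        has_domain = p$has_domain, stringsAsFactors = FALSE))
    }

    sequence <- paste(seq_chars, collapse = "")
    features <- data.frame(
      feature_id = sprintf("SYN_%04d", seq_len(spec$n_genes)),
      start = gene_start, end = gene_end, strand = gene_strand, kind = "CDS",
      product = ifelse(seq_len(spec$n_genes) == spec$rte_index,
                       "TfuA-like RiPP tailoring protein",
                       "hypothetical protein"),
      translation = gene_pep, annotated = TRUE, stringsAsFactors = FALSE)

    region <- genomic_region(acc, sequence, features,
                             rte_feature_id = sprintf("SYN_%04d", spec$rte_index),
                             organism = sprintf("Synthetica fixturensis seed%d",
                                                spec$seed))
    out <- list(region = region, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      gb <- file.path(dir, paste0(acc, ".gbk"))
      write_annotated_genbank(region, empty_candidates(), gb)
      tt <- file.path(dir, paste0(acc, "_truth.tsv"))
      utils::write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
      out$genbank_path <- gb
      out$truth_path <- tt
    }
    out
  })
}

#' Generate seeded peptide families for networking fixtures
#'
#' Each family grows from a random ancestor by independent per-site
#' substitutions at the given rate; at rates up to 0.25 members typically
#' stay at or above 40% pairwise identity, while unrelated families share
#' far less with high probability.
#'
#' @param seed Integer seed.
#' @param family_sizes Integer vector; one family per element.
#' @param substitution_rate Per-site substitution probability per member.
#' @param length_aa Ancestor length (default 80; long enough that chance
#'   local alignments between unrelated peptides essentially never reach
#'   the coverage threshold).
#' @param n_singletons Additional unrelated singleton peptides.
#' @return Data frame with columns `id`, `family` (`NA` for singletons),
#'   `sequence`.
#' @export
make_peptide_family <- function(seed, family_sizes, substitution_rate = 0.15,
                                length_aa = 80L, n_singletons = 0L) {
  with_seed(seed, {
    out <- list()
    for (f in seq_along(family_sizes)) {
      anc <- strsplit(random_peptide(length_aa), "", fixed = TRUE)[[1]]
      for (m in seq_len(family_sizes[f])) {
        res <- anc
        mut <- which(stats::runif(length(res)) < substitution_rate)
        if (length(mut)) {
          res[mut] <- sample(AA20, length(mut), replace = TRUE)
        }
        out[[length(out) + 1L]] <- data.frame(
          id = sprintf("fam%02d_m%02d", f, m), family = f,
          sequence = paste(res, collapse = ""), stringsAsFactors = FALSE)
      }
    }
    for (s in seq_len(n_singletons)) {
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("single_%02d", s), family = NA_integer_,
        sequence = random_peptide(length_aa), stringsAsFactors = FALSE)
    }
    if (!length(out)) {
      return(data.frame(id = character(), family = integer(),
                        sequence = character(), stringsAsFactors = FALSE))
    }
    do.call(rbind, out)
  })
}

#' Compare retrieved peptides against a reference set
#'
#' Exact sequence equality after stripping trailing stop marks (`*`). Used
#' for output-vs-reference validation of retrieval runs.
#'
#' @param retrieved Character vector of retrieved peptide sequences.
#' @param reference Character vector of reference peptide sequences.
#' @return List with `matched`, `total_reference`, `fraction`.
#' @export
compare_to_reference <- function(retrieved, reference) {
  strip <- function(x) sub("\\*+$", "", x)
  retrieved <- unique(strip(retrieved))
  reference <- unique(strip(reference))
  matched <- sum(reference %in% retrieved)
  list(matched = matched, total_reference = length(reference),
       fraction = if (length(reference)) matched / length(reference) else NA_real_)
}
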