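# Retrieval rules: overlap and size filters, same-strand reward, distance
# from the tailoring enzyme, top-N-plus-threshold selection, domain rescue
# of distant peptides, and the tab-separated output tables.

#' Workflow configuration
#'
#' All tunable retrieval parameters, with the defaults used throughout:
#' 17.5 kb flanks, +5 same-strand reward, a 20-120 aa peptide window, an
#' 8 kb retrieval distance, the top 3 peptides plus any scoring at least
#' 7.5, and a 20 nt annotation-overlap allowance.
#'
#' @param flank_len Flank length (nt) each side of the RTE for windowing.
#' @param same_strand_reward Score added to candidates on the RTE's strand.
#' @param min_pp_len,max_pp_len Precursor peptide size window (aa).
#' @param max_dist_from_te Retrieval distance from the RTE (nt).
#' @param fasta_output_limit Number of top-scoring peptides always retrieved.
#' @param prodigal_score_thresh Score above which further in-window peptides
#'   are retrieved.
#' @param max_overlap_nt Maximum tolerated overlap with annotated genes.
#' @return Object of class `ripper_config`.
#' @export
ripper_config <- function(flank_len = 17500L, same_strand_reward = 5,
                          min_pp_len = 20L, max_pp_len = 120L,
                          max_dist_from_te = 8000L, fasta_output_limit = 3L,
                          prodigal_score_thresh = 7.5, max_overlap_nt = 20L) {
  stopifnot(min_pp_len < max_pp_len, flank_len >= 0, max_dist_from_te >= 0,
            fasta_output_limit >= 0, max_overlap_nt >= 0)
  structure(list(flank_len = as.integer(flank_len),
                 same_strand_reward = same_strand_reward,
                 min_pp_len = as.integer(min_pp_len),
                 max_pp_len = as.integer(max_pp_len),
                 max_dist_from_te = as.integer(max_dist_from_te),
                 fasta_output_limit = as.integer(fasta_output_limit),
                 prodigal_score_thresh = prodigal_score_thresh,
                 max_overlap_nt = as.integer(max_overlap_nt)),
            class = "ripper_config")
}

#' Read a flat key = value configuration file
#'
#' Keys use the workflow's conventional names (flankLen, sameStrandReward,
#' minPPlen, maxPPlen, maxDistFromTE, fastaOutputLimit, prodigalScoreThresh,
#' maxOverlapNt); unknown keys are ignored with a warning, missing keys keep
#' their defaults.
#'
#' @param path Configuration file; `#` starts a comment.
#' @return A [ripper_config()].
#' @export
read_local_conf <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  map <- c(flankLen = "flank_len", sameStrandReward = "same_strand_reward",
           minPPlen = "min_pp_len", maxPPlen = "max_pp_len",
           maxDistFromTE = "max_dist_from_te",
           fastaOutputLimit = "fasta_output_limit",
           prodigalScoreThresh = "prodigal_score_thresh",
           maxOverlapNt = "max_overlap_nt")
  args <- list()
  for (i in seq_along(keys)) {
    if (keys[i] %in% names(map)) {
      args[[map[[keys[i]]]]] <- as.numeric(vals[i])
    } else if (nzchar(keys[i])) {
      warning("ignoring unknown configuration key: ", keys[i])
    }
  }
  do.call(ripper_config, args)
}

#' Filter candidates by annotation overlap and peptide size
#'
#' Keeps unannotated candidates whose overlap with every annotated feature
#' is at most `cfg$max_overlap_nt` (strand-blind interval intersection) and
#' whose peptide length lies within the precursor size window. Annotated
#' candidates (wrapped annotated short genes) bypass both conditions except
#' the maximum-length bound applied at wrapping time.
#'
#' @param candidates Scored candidate data frame.
#' @param features Annotated feature data frame of the same region.
#' @param cfg A [ripper_config()].
#' @return The surviving candidates.
#' @export
filter_candidates <- function(candidates, features, cfg = ripper_config()) {
  if (!nrow(candidates)) return(candidates)
  ann <- features[features$annotated, , drop = FALSE]
  keep <- rep(TRUE, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    if (isTRUE(candidates$annotated[i])) next
    plen <- nchar(candidates$peptide[i])
    if (plen < cfg$min_pp_len || plen > cfg$max_pp_len) { keep[i] <- FALSE; next }
    if (nrow(ann)) {
      ov <- interval_overlap_nt(candidates$start[i], candidates$end[i],
                                ann$start, ann$end)
      if (max(ov) > cfg$max_overlap_nt) keep[i] <- FALSE
    }
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reward candidates on the tailoring enzyme's strand
#'
#' Adds `reward` to the total score of every candidate sharing the RTE's
#' strand. Guarded by the `strand_rewarded` flag so a repeated call is a
#' no-op.
#'
#' @param candidates Scored candidate data frame.
#' @param rte One-row feature data frame for the RTE.
#' @param reward Score increment (default 5).
#' @return Candidates with adjusted `total_score`.
#' @export
apply_strand_reward <- function(candidates, rte, reward = 5) {
  if (!nrow(candidates)) return(candidates)
  todo <- !candidates$strand_rewarded & candidates$strand == rte$strand
  candidates$total_score[todo] <- candidates$total_score[todo] + reward
  candidates$strand_rewarded[candidates$strand == rte$strand] <- TRUE
  candidates
}

#' Distance between a candidate and the tailoring enzyme
#'
#' Zero when the two half-open intervals overlap or abut; otherwise the gap
#' between the nearest interval ends.
#'
#' @param start,end Candidate interval (0-based half-open); vectorized.
#' @param rte One-row feature data frame for the RTE.
#' @return Integer distances in nt.
#' @export
distance_from_te <- function(start, end, rte) {
  interval_gap_nt(start, end, rte$start, rte$end)
}

#' Wrap annotated short genes as scored candidates
#'
#' Annotated CDS encoding peptides of at most `cfg$max_pp_len` residues are
#' retrieved and scored alongside unannotated candidates; they are exempt
#' from the overlap filter and the minimum-length bound. Stored
#' translations are used verbatim; otherwise the CDS is translated.
#'
#' @param region A [genomic_region()].
#' @param cfg A [ripper_config()].
#' @param model A `coding_model` (possibly untrained).
#' @return Candidate data frame with `annotated = TRUE`.
#' @export
collect_annotated_short_genes <- function(region, cfg, model) {
  f <- region$features
  f <- f[f$kind == "CDS" & f$annotated, , drop = FALSE]
  if (!is.na(region$rte_feature_id)) {
    f <- f[f$feature_id != region$rte_feature_id, , drop = FALSE]
  }
  out <- empty_candidates()
  for (i in seq_len(nrow(f))) {
    pep <- f$translation[i]
    if (is.na(pep)) {
      pep <- tryCatch(
        translate_cds(coding_seq(region, f$start[i], f$end[i], f$strand[i])),
        error = function(e) NA_character_)
      if (is.na(pep)) next
    }
    if (nchar(pep) > cfg$max_pp_len) next
    out <- rbind(out, data.frame(
      start = f$start[i], end = f$end[i], strand = f$strand[i], peptide = pep,
      rbs_score = 0, coding_score = 0, start_bonus = 0, total_score = 0,
      annotated = TRUE, strand_rewarded = FALSE,
      notes = paste0("annotated gene ", f$feature_id[i]),
      stringsAsFactors = FALSE))
  }
  score_candidates(out, model, region)
}

#' Select retrieved peptides within the distance window
#'
#' Among candidates within `max_dist_from_te` of the RTE: the
#' `fasta_output_limit` highest-scoring items are always retrieved (ties
#' broken by smaller distance, then smaller start coordinate), plus every
#' further item with score at least `prodigal_score_thresh`. The result is
#' deduplicated by (source accession, start, end, strand).
#'
#' @param candidates Scored, strand-rewarded candidate data frame carrying a
#'   `distance_nt` column.
#' @param cfg A [ripper_config()].
#' @return The retrieved subset, ordered by the selection sort.
#' @export
select_peptides <- function(candidates, cfg = ripper_config()) {
  if (!nrow(candidates)) return(candidates)
  win <- candidates[candidates$distance_nt <= cfg$max_dist_from_te, , drop = FALSE]
  if (!nrow(win)) return(win[0, , drop = FALSE])
  key <- paste(win$start, win$end, win$strand)
  win <- win[!duplicated(key), , drop = FALSE]
  ord <- order(-win$total_score, win$distance_nt, win$start)
  win <- win[ord, , drop = FALSE]
  n_top <- min(cfg$fasta_output_limit, nrow(win))
  take <- seq_len(n_top)
  if (nrow(win) > n_top) {
    extra <- which(win$total_score >= cfg$prodigal_score_thresh)
    take <- sort(union(take, extra))
  }
  out <- win[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rescue distant domain-bearing peptides
#'
#' Every candidate not retrieved by [select_peptides()] (no distance or
#' score condition) is scanned against the precursor-domain profiles; those
#' with at least one hit form the distant table. Candidates without hits are
#' dropped.
#'
#' @param all_candidates All filtered candidates of the region (with
#'   `distance_nt`).
#' @param retrieved The output of [select_peptides()].
#' @param profiles Profile list from [load_profiles()] (may be empty).
#' @return Data frame of distant candidates with a `domains` column
#'   (semicolon-joined hit names).
#' @export
rescue_distant <- function(all_candidates, retrieved, profiles) {
  if (!nrow(all_candidates) || !length(profiles)) {
    return(all_candidates[0, , drop = FALSE])
  }
  key_all <- paste(all_candidates$start, all_candidates$end, all_candidates$strand)
  key_ret <- paste(retrieved$start, retrieved$end, retrieved$strand)
  rest <- all_candidates[!(key_all %in% key_ret), , drop = FALSE]
  if (!nrow(rest)) return(rest)
  doms <- vapply(rest$peptide, function(p) {
    hits <- scan_peptide(p, profiles)
    paste(hits$profile_name, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  out <- rest[nzchar(doms), , drop = FALSE]
  out$domains <- doms[nzchar(doms)]
  rownames(out) <- NULL
  out
}

# Shape candidates into the tabulated retrieved-peptide form.
as_retrieved <- function(candidates, region, bucket, profiles = list()) {
  rte <- rte_feature(region)
  n <- nrow(candidates)
  doms <- candidates$domains %||% rep("", n)
  if (n && length(profiles) && is.null(candidates$domains)) {
    doms <- vapply(candidates$peptide, function(p) {
      hits <- scan_peptide(p, profiles)
      paste(hits$profile_name, collapse = ";")
    }, character(1), USE.NAMES = FALSE)
  }
  data.frame(
    te_accession = rep(if (nrow(rte)) rte$feature_id else NA_character_, n),
    source_accession = rep(region$accession, n),
    strain = rep(region$organism, n),
    peptide = candidates$peptide,
    distance_nt = candidates$distance_nt %||% rep(NA_integer_, n),
    same_strand = candidates$strand == (if (nrow(rte)) rte$strand else NA_integer_),
    score = candidates$total_score,
    annotated = candidates$annotated,
    start = candidates$start, end = candidates$end, strand = candidates$strand,
    domains = doms, bucket = rep(bucket, n),
    stringsAsFactors = FALSE
  )
}

PEPTIDE_COLUMNS <- c("te_accession", "source_accession", "strain", "peptide",
                     "distance_nt", "same_strand", "score", "annotated",
                     "start", "end", "strand", "domains")

#' Write (or append) the tab-separated peptide tables
#'
#' One header row, stable column order (`te_accession`, `source_accession`,
#' `strain`, `peptide`, `distance_nt`, `same_strand`, `score`, `annotated`,
#' `start`, `end`, `strand`, `domains`). When several regions are analyzed
#' in one run their rows are collated into a single file.
#'
#' @param peptides Retrieved-peptide data frame.
#' @param path Output file.
#' @param append Append data rows to an existing file (header written only
#'   when the file is new).
#' @return `path`, invisibly.
#' @export
tabulate_peptides <- function(peptides, path, append = FALSE) {
  new_file <- !append || !file.exists(path)
  con <- file(path, if (new_file) "w" else "a")
  on.exit(close(con))
  if (new_file) writeLines(paste(PEPTIDE_COLUMNS, collapse = "\t"), con)
  for (i in seq_len(nrow(peptides))) {
    row <- c(peptides$te_accession[i], peptides$source_accession[i],
             peptides$strain[i], peptides$peptide[i],
             as.character(peptides$distance_nt[i]),
             as.character(peptides$same_strand[i]),
             fmt_num(peptides$score[i]),
             as.character(peptides$annotated[i]),
             as.character(peptides$start[i]), as.character(peptides$end[i]),
             as.character(peptides$strand[i]), peptides$domains[i])
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a peptide table written by [tabulate_peptides()]
#'
#' @param path The out.txt / distant.txt file.
#' @return Data frame with the standard peptide columns.
#' @export
read_peptide_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = c(
                             te_accession = "character",
                             source_accession = "character",
                             strain = "character", peptide = "character",
                             distance_nt = "integer", same_strand = "logical",
                             score = "numeric", annotated = "logical",
                             start = "integer", end = "integer",
                             strand = "integer", domains = "character"))
  tab$domains[is.na(tab$domains)] <- ""
  tab
}
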