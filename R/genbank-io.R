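# Single-record GenBank flat-file I/O, RTE designation, and neighborhood
# windowing. Internal coordinates are 0-based half-open; conversion to
# GenBank's 1-based inclusive form happens only at the file boundary.

#' Construct a genomic region
#'
#' A nucleotide sequence with its annotated gene features and one designated
#' RiPP tailoring enzyme (RTE) feature anchoring the precursor search.
#'
#' @param accession Record accession.
#' @param sequence Nucleotide string over A/C/G/T/N.
#' @param features Data frame with columns `feature_id`, `start`, `end`
#'   (0-based half-open), `strand` (+1/-1), `kind` (`"CDS"` or other),
#'   `product`, `translation`, `annotated`.
#' @param rte_feature_id `feature_id` of the designated RTE; must name
#'   exactly one CDS feature (may be `NA` for regions without an anchor).
#' @param organism Source organism / strain text.
#' @param log Character vector of processing notes.
#' @return Object of class `genomic_region`.
#' @export
genomic_region <- function(accession, sequence, features = empty_features(),
                           rte_feature_id = NA_character_,
                           organism = "unknown organism", log = character()) {
  sequence <- toupper(sequence)
  stopifnot(grepl("^[ACGTN]*$", sequence))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features)) {
    stopifnot(all(features$start >= 0L), all(features$start < features$end),
              all(features$end <= nchar(sequence)))
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  if (!is.na(rte_feature_id)) {
    hit <- features$feature_id == rte_feature_id & features$kind == "CDS"
    if (sum(hit) != 1L) {
      stop("RTE not found: '", rte_feature_id, "' does not name exactly one CDS in ",
           accession)
    }
  }
  structure(list(accession = accession, organism = organism,
                 sequence = sequence, features = features,
                 rte_feature_id = rte_feature_id, log = log),
            class = "genomic_region")
}

empty_features <- function() {
  data.frame(feature_id = character(), start = integer(), end = integer(),
             strand = integer(), kind = character(), product = character(),
             translation = character(), annotated = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> %s (%s): %d nt, %d features, RTE = %s\n",
              x$accession, x$organism, nchar(x$sequence), nrow(x$features),
              x$rte_feature_id))
  invisible(x)
}

rte_feature <- function(region) {
  f <- region$features
  f[f$feature_id == region$rte_feature_id & f$kind == "CDS", , drop = FALSE]
}

# ---- parsing ---------------------------------------------------------------

parse_location <- function(loc) {
  loc <- gsub("[<>]", "", loc)
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order", loc)) {
    stop("compound (join/order) locations are not supported: ", loc)
  }
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
  if (length(m) != 3L) stop("unparseable feature location: ", loc)
  a <- as.integer(m[2]); b <- as.integer(m[3])
  list(start = a - 1L, end = b, strand = strand)  # to 0-based half-open
}

parse_qualifiers <- function(lines) {
  # qualifier lines start at column 22 with /key="value" (value may span lines)
  txt <- sub("^ {21}", "", lines)
  quals <- list()
  cur_key <- NULL; cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_key)) {
      v <- paste(cur_val, collapse = "")
      v <- sub("^\"", "", sub("\"$", "", v))
      quals[[cur_key]] <<- v
    }
  }
  for (ln in txt) {
    m <- regmatches(ln, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", ln))[[1]]
    if (length(m)) {
      flush()
      cur_key <- m[2]
      cur_val <- if (nchar(m[4])) m[4] else "true"
    } else if (!is.null(cur_key)) {
      cur_val <- c(cur_val, ln)
    }
  }
  flush()
  quals
}

#' Read a single-record GenBank flat file
#'
#' Coordinates are converted from GenBank 1-based inclusive to internal
#' 0-based half-open; `/translation` qualifiers are preserved verbatim. The
#' RTE is designated by, in order of preference: a `/ripper_rte` qualifier
#' in the file, an explicit `rte_id` argument matched against
#' `/protein_id`/`/locus_tag`, or (if `rte_fallback_midpoint`) the CDS
#' nearest the record midpoint. The designation mode is recorded in the
#' region log.
#'
#' @param path GenBank file path.
#' @param rte_id Optional protein_id or locus_tag naming the RTE.
#' @param rte_fallback_midpoint Use the CDS nearest the record midpoint when
#'   nothing else designates an RTE (default TRUE).
#' @return A [genomic_region()].
#' @export
read_genbank <- function(path, rte_id = NULL, rte_fallback_midpoint = TRUE) {
  lines <- readLines(path)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("not a GenBank file (no LOCUS line): ", path)
  accession <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i[1]])), "\\s+")[[1]][1]
  acc_i <- grep("^ACCESSION", lines)
  if (length(acc_i)) {
    a <- strsplit(trimws(sub("^ACCESSION", "", lines[acc_i[1]])), "\\s+")[[1]][1]
    if (!is.na(a) && nzchar(a)) accession <- a
  }
  organism <- "unknown organism"
  org_i <- grep("^ {0,2}ORGANISM", lines)
  if (length(org_i)) organism <- trimws(sub("^ {0,2}ORGANISM", "", lines[org_i[1]]))
  src_i <- grep("^SOURCE", lines)
  if (!length(org_i) && length(src_i)) {
    organism <- trimws(sub("^SOURCE", "", lines[src_i[1]]))
  }

  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) stop("parse error: no ORIGIN section in ", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_i <- grep("^FEATURES", lines)
  features <- empty_features()
  rte_from_qualifier <- NA_character_
  rte_from_arg <- NA_character_
  if (length(feat_i)) {
    fl <- lines[(feat_i[1] + 1L):(origin_i[1] - 1L)]
    # feature headers have a key at column 6; qualifiers/continuations at 22
    hdr <- grepl("^ {5}\\S", fl)
    idx <- which(hdr)
    n_auto <- 0L
    for (k in seq_along(idx)) {
      i0 <- idx[k]
      i1 <- if (k < length(idx)) idx[k + 1L] - 1L else length(fl)
      key <- strsplit(trimws(fl[i0]), "\\s+")[[1]][1]
      if (key == "source") next
      loc_txt <- trimws(sub("^ {5}\\S+\\s*", "", fl[i0]))
      qlines <- if (i1 > i0) fl[(i0 + 1L):i1] else character()
      # location may continue before first qualifier line
      while (length(qlines) && !grepl("^ {21}/", qlines[1])) {
        loc_txt <- paste0(loc_txt, trimws(qlines[1]))
        qlines <- qlines[-1]
      }
      loc <- parse_location(loc_txt)
      quals <- parse_qualifiers(qlines)
      n_auto <- n_auto + 1L
      fid <- quals$locus_tag %||% quals$protein_id %||% sprintf("feat_%04d", n_auto)
      tr <- quals$translation %||% NA_character_
      features <- rbind(features, data.frame(
        feature_id = fid, start = loc$start, end = loc$end,
        strand = loc$strand, kind = if (key == "CDS") "CDS" else key,
        product = quals$product %||% "", translation = tr,
        annotated = TRUE, stringsAsFactors = FALSE))
      if (!is.null(quals$ripper_rte) && key == "CDS") rte_from_qualifier <- fid
      if (!is.null(rte_id) && key == "CDS" &&
          (identical(quals$protein_id, rte_id) || identical(quals$locus_tag, rte_id))) {
        rte_from_arg <- fid
      }
    }
  }

  log <- character()
  rte <- NA_character_
  cds <- features[features$kind == "CDS", , drop = FALSE]
  if (!is.null(rte_id) && is.na(rte_from_arg)) {
    stop("RTE not found: no CDS matches '", rte_id, "' in record ", accession)
  }
  if (!is.na(rte_from_arg)) {
    rte <- rte_from_arg
    log <- c(log, "RTE designated by supplied identifier")
  } else if (!is.na(rte_from_qualifier)) {
    rte <- rte_from_qualifier
    log <- c(log, "RTE designated by qualifier")
  } else if (rte_fallback_midpoint && nrow(cds)) {
    mid <- nchar(sequence) / 2
    d <- abs((cds$start + cds$end) / 2 - mid)
    rte <- cds$feature_id[which.min(d)]
    log <- c(log, "RTE designated by midpoint fallback")
  }
  genomic_region(accession, sequence, features, rte_feature_id = rte,
                 organism = organism, log = log)
}

# ---- windowing -------------------------------------------------------------

#' Extract the RTE-centered analysis window
#'
#' Returns the sub-region spanning `flank_len` nt on each side of the RTE
#' feature, clipped silently at contig ends (clipping is recorded in the
#' region log). Features intersecting the window are retained with shifted
#' coordinates; features only partly inside are truncated (their translation
#' is dropped).
#'
#' @param region A [genomic_region()] with a designated RTE.
#' @param flank_len Flank length in nt on each side of the RTE (default
#'   17500; 12500 reproduces a 25 kb window for a typical RTE).
#' @return A [genomic_region()] covering the window.
#' @export
extract_window <- function(region, flank_len = 17500L) {
  rte <- rte_feature(region)
  if (!nrow(rte)) stop("region has no designated RTE")
  L <- nchar(region$sequence)
  w0 <- max(0L, rte$start - as.integer(flank_len))
  w1 <- min(L, rte$end + as.integer(flank_len))
  log <- region$log
  if (w0 == 0L && rte$start - flank_len < 0L) {
    log <- c(log, sprintf("left flank clipped to %d nt", rte$start))
  }
  if (w1 == L && rte$end + flank_len > L) {
    log <- c(log, sprintf("right flank clipped to %d nt", L - rte$end))
  }
  f <- region$features
  keep <- f$end > w0 & f$start < w1
  f <- f[keep, , drop = FALSE]
  if (nrow(f)) {
    trunc <- f$start < w0 | f$end > w1
    f$start <- pmax(f$start, w0) - w0
    f$end <- pmin(f$end, w1) - w0
    if (any(trunc)) {
      f$translation[trunc] <- NA_character_
      f$product[trunc] <- paste0(f$product[trunc], " (truncated by window)")
    }
  }
  genomic_region(region$accession, substring(region$sequence, w0 + 1L, w1),
                 f, rte_feature_id = region$rte_feature_id,
                 organism = region$organism, log = log)
}

# ---- writing ---------------------------------------------------------------

gb_location <- function(start, end, strand) {
  loc <- sprintf("%d..%d", start + 1L, end)   # back to 1-based inclusive
  if (strand < 0) loc <- sprintf("complement(%s)", loc) else loc
}

wrap_qualifier <- function(key, value, quote = TRUE, width = 58L) {
  v <- if (quote) paste0("\"", value, "\"") else value
  first <- paste0("                     /", key, "=")
  out <- character()
  line <- paste0(first, substring(v, 1L, width))
  rest <- substring(v, width + 1L)
  out <- c(out, line)
  while (nchar(rest)) {
    out <- c(out, paste0("                     ", substring(rest, 1L, width + 10L)))
    rest <- substring(rest, width + 11L)
  }
  out
}

score_colour_ramp <- function(scores) {
  # linear ramp from pale red (low) to bright pink (high), Artemis
  # /colour "R G B" convention
  if (!length(scores)) return(character())
  lo <- min(scores); hi <- max(scores)
  t <- if (hi > lo) (scores - lo) / (hi - lo) else rep(1, length(scores))
  g <- round(200 * (1 - t))
  b <- round(200 + 55 * t)
  sprintf("255 %d %d", g, b)
}

#' Write a GenBank record with scored candidates annotated
#'
#' Original features are preserved; each candidate is added as a CDS with an
#' Artemis-style `/colour` qualifier interpolated linearly from pale red
#' (lowest score in the file, `255 200 200`) to bright pink (highest,
#' `255 0 255`); the RTE gets green (`0 255 0`). Scoring criteria are
#' written as a `/note` per candidate.
#'
#' @param region A [genomic_region()].
#' @param candidates Scored candidate data frame (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_genbank <- function(region, candidates, path) {
  L <- nchar(region$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT %s",
                     region$accession, L, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s candidate precursor annotation.", region$accession), con)
  writeLines(sprintf("ACCESSION   %s", region$accession), con)
  writeLines(sprintf("SOURCE      %s", region$organism), con)
  writeLines(sprintf("  ORGANISM  %s", region$organism), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  writeLines(wrap_qualifier("organism", region$organism), con)

  f <- region$features
  for (i in seq_len(nrow(f))) {
    key <- if (f$kind[i] == "CDS") "CDS" else f$kind[i]
    writeLines(sprintf("     %-15s %s", key,
                       gb_location(f$start[i], f$end[i], f$strand[i])), con)
    writeLines(wrap_qualifier("locus_tag", f$feature_id[i]), con)
    if (nzchar(f$product[i])) writeLines(wrap_qualifier("product", f$product[i]), con)
    if (!is.na(region$rte_feature_id) && f$feature_id[i] == region$rte_feature_id &&
        f$kind[i] == "CDS") {
      writeLines(wrap_qualifier_flag("ripper_rte"), con)
      writeLines(wrap_qualifier("colour", "0 255 0", quote = FALSE), con)
    }
    if (!is.na(f$translation[i])) {
      writeLines(wrap_qualifier("translation", f$translation[i]), con)
    }
  }

  if (nrow(candidates)) {
    cols <- score_colour_ramp(candidates$total_score)
    for (i in seq_len(nrow(candidates))) {
      writeLines(sprintf("     CDS             %s",
                         gb_location(candidates$start[i], candidates$end[i],
                                     candidates$strand[i])), con)
      writeLines(wrap_qualifier("locus_tag",
                                sprintf("cand_%05d_%05d_%s", candidates$start[i],
                                        candidates$end[i],
                                        if (candidates$strand[i] > 0) "f" else "r")), con)
      writeLines(wrap_qualifier("product", "putative RiPP precursor peptide"), con)
      writeLines(wrap_qualifier("colour", cols[i], quote = FALSE), con)
      note <- sprintf(paste0("total score %.4f (coding %.4f, RBS %.4f, start ",
                             "%.4f%s); %s"),
                      candidates$total_score[i], candidates$coding_score[i],
                      candidates$rbs_score[i], candidates$start_bonus[i],
                      if (isTRUE(candidates$strand_rewarded[i])) ", strand reward applied" else "",
                      if (isTRUE(candidates$annotated[i])) "annotated gene" else "unannotated ORF")
      writeLines(wrap_qualifier("note", note), con)
      writeLines(wrap_qualifier("translation", candidates$peptide[i]), con)
    }
  }

  writeLines("ORIGIN", con)
  pos <- seq.int(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substring(region$sequence, p, min(L, p + 59L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

# wrap_qualifier with NULL value: bare flag qualifier
wrap_qualifier_flag <- function(key) paste0("                     /", key)

#' Write retrieved peptides to FASTA
#'
#' One record per peptide; the header encodes the RTE accession, source
#' accession, coordinates, strand, and score, pipe-separated. No
#' deduplication is applied at this layer.
#'
#' @param peptides Retrieved-peptide data frame (see [tabulate_peptides()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peptides, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(peptides))) {
    hdr <- sprintf(">%s|%s|%d-%d|%s|%s", peptides$te_accession[i],
                   peptides$source_accession[i], peptides$start[i],
                   peptides$end[i],
                   if (peptides$strand[i] > 0) "+" else "-",
                   fmt_num(peptides$score[i]))
    writeLines(hdr, con)
    s <- peptides$peptide[i]
    writeLines(substring(s, seq(1, nchar(s), 60),
                         pmin(nchar(s), seq(60, nchar(s) + 59, 60))), con)
  }
  invisible(path)
}

#' Read a FASTA file of peptides
#'
#' @param path FASTA path.
#' @return Data frame with columns `id` (full header) and `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1), collapse = "")
  # headers with no sequence lines
  out <- data.frame(id = ids, sequence = "", stringsAsFactors = FALSE)
  out$sequence[as.integer(names(seqs))] <- unname(seqs)
  out
}
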