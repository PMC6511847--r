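# Lightweight position-specific profile scanner used to rescue distant
# precursor peptides. Profiles are ungapped per-position score tables over
# the 20 aa alphabet with a per-profile reporting threshold (in the spirit
# of a family gathering cutoff), stored in a versioned plain-text format.

PROFILE_HEADER <- "RIPPMINE-PROFILES 1 ACDEFGHIKLMNPQRSTVWY"

#' Construct a domain profile
#'
#' @param name Profile name (unique within a set).
#' @param mat Numeric matrix, 20 rows named with the amino-acid alphabet
#'   `ACDEFGHIKLMNPQRSTVWY`, one column per profile position.
#' @param threshold Reporting threshold; a window is a hit iff its score is
#'   at least this value.
#' @return Object of class `domain_profile`.
#' @export
domain_profile <- function(name, mat, threshold) {
  stopifnot(is.matrix(mat), nrow(mat) == 20L)
  if (is.null(rownames(mat))) rownames(mat) <- AA20
  stopifnot(identical(rownames(mat), AA20))
  structure(list(name = name, mat = mat, threshold = threshold,
                 min_len = ncol(mat)), class = "domain_profile")
}

#' Write domain profiles to the plain-text profile format
#'
#' Format: a versioned header line naming the alphabet; per profile a
#' `PROFILE name threshold length` line followed by `length` lines of 20
#' scores (alphabet order).
#'
#' @param profiles List of [domain_profile()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(PROFILE_HEADER, con)
  for (p in profiles) {
    writeLines(sprintf("PROFILE %s %.6g %d", p$name, p$threshold, p$min_len), con)
    for (j in seq_len(p$min_len)) {
      writeLines(paste(sprintf("%.6g", p$mat[, j]), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Load domain profiles from the plain-text profile format
#'
#' Malformed lines raise an error naming the line number; duplicate profile
#' names are rejected.
#'
#' @param path Profile file path.
#' @return List of [domain_profile()] objects (possibly empty).
#' @export
load_profiles <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(list())
  if (!startsWith(lines[1], "RIPPMINE-PROFILES")) {
    stop("line 1: missing profile-file header")
  }
  profiles <- list()
  i <- 2L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    p <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(p) != 4L || p[1] != "PROFILE") {
      stop("line ", i, ": expected 'PROFILE name threshold length'")
    }
    name <- p[2]; threshold <- as.numeric(p[3]); len <- as.integer(p[4])
    if (is.na(threshold) || is.na(len) || len < 1L) {
      stop("line ", i, ": bad threshold or length")
    }
    if (name %in% vapply(profiles, `[[`, character(1), "name")) {
      stop("line ", i, ": duplicate profile name '", name, "'")
    }
    mat <- matrix(0, nrow = 20L, ncol = len, dimnames = list(AA20, NULL))
    for (j in seq_len(len)) {
      ln <- i + j
      if (ln > length(lines)) stop("line ", ln, ": truncated profile '", name, "'")
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]), "\\s+")[[1]]))
      if (length(v) != 20L || anyNA(v)) {
        stop("line ", ln, ": expected 20 numeric scores")
      }
      mat[, j] <- v
    }
    profiles[[length(profiles) + 1L]] <- domain_profile(name, mat, threshold)
    i <- i + len + 1L
  }
  profiles
}

#' Scan a peptide against domain profiles
#'
#' For each profile the best-scoring full-length ungapped window over the
#' peptide is found; a hit is reported iff that score reaches the profile's
#' threshold. Residue `X` contributes 0 at any position, and flanking `X`
#' runs are ignored, so padding a peptide with `X` never changes the
#' result. Peptides shorter than a profile yield no hit from it.
#'
#' @param peptide Amino-acid string (X allowed).
#' @param profiles List of [domain_profile()] objects.
#' @return Data frame of hits: `profile_name`, `score`, `start`, `end`
#'   (0-based half-open aa offsets in the original peptide).
#' @export
scan_peptide <- function(peptide, profiles) {
  empty <- data.frame(profile_name = character(), score = numeric(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!length(profiles)) return(empty)
  # trim flanking X so X padding is a no-op
  core_m <- regexpr("[^X]+(.*[^X])?", peptide)
  if (core_m < 0) return(empty)
  off <- as.integer(core_m) - 1L
  core <- regmatches(peptide, core_m)
  res <- strsplit(core, "", fixed = TRUE)[[1]]
  idx <- match(res, AA20)  # NA for X or unknown -> contributes 0
  n <- length(res)
  hits <- empty
  for (p in profiles) {
    L <- p$min_len
    if (n < L) next
    best <- -Inf; best_o <- NA_integer_
    for (o in 0:(n - L)) {
      ii <- idx[(o + 1L):(o + L)]
      ok <- !is.na(ii)
      s <- if (any(ok)) sum(p$mat[cbind(ii[ok], which(ok))]) else 0
      if (s > best) { best <- s; best_o <- o }
    }
    if (best >= p$threshold) {
      hits <- rbind(hits, data.frame(
        profile_name = p$name, score = best,
        start = off + best_o, end = off + best_o + L,
        stringsAsFactors = FALSE))
    }
  }
  hits
}
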