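# Monoisotopic mass arithmetic for modified short peptides, plus the two MS
# screening utilities used to hunt thioamidated products: H2S neutral-loss
# pairing in fragment lists, and tolerance-based comparative feature matching
# between sample groups.

# Standard monoisotopic residue masses (Da), from standard atomic masses.
RESIDUE_MASS <- c(
  A = 71.037114, C = 103.009185, D = 115.026943, E = 129.042593,
  F = 147.068414, G = 57.021464, H = 137.058912, I = 113.084064,
  K = 128.094963, L = 113.084064, M = 131.040485, N = 114.042927,
  P = 97.052764, Q = 128.058578, R = 156.101111, S = 87.032028,
  T = 101.047678, V = 99.068414, W = 186.079313, Y = 163.063329
)

MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276
MASS_ACETYL <- 42.010565     # +C2H2O on the N terminus
MASS_THIOAMIDE <- 15.977156  # S replaces O on a backbone amide
MASS_DEHYDRO <- 2.015650     # loss of H2 for one desaturation
MASS_H2S <- 33.987721        # neutral loss diagnostic for thioamides

#' Construct a modified peptide
#'
#' A peptide sequence plus the set of modifications handled by the mass
#' module: N-terminal acetylation, backbone thioamidation (sulfur replacing
#' the carbonyl oxygen of a specified inter-residue bond), and desaturations
#' (each a loss of H2; position-agnostic for mass purposes).
#'
#' @param sequence One-letter amino-acid string over the 20 standard residues.
#' @param n_acetyl Logical; is the N terminus acetylated?
#' @param thioamide Integer vector of inter-residue bond indices carrying a
#'   thioamide; bond `i` is the amide after residue `i`, so valid indices are
#'   `1 .. nchar(sequence) - 1`.
#' @param dehydro Number of desaturations (each -H2).
#' @return An object of class `modified_peptide`.
#' @examples
#' modified_peptide("APR", n_acetyl = TRUE, thioamide = 2)
#' @export
modified_peptide <- function(sequence, n_acetyl = FALSE, thioamide = integer(),
                             dehydro = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(res, names(RESIDUE_MASS))
  if (length(bad)) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  thioamide <- as.integer(thioamide)
  if (length(thioamide) && (any(thioamide < 1L) || any(thioamide > length(res) - 1L))) {
    stop("thioamide bond indices must lie in [1, ", length(res) - 1L, "]")
  }
  if (anyDuplicated(thioamide)) stop("duplicated thioamide bond index")
  stopifnot(dehydro >= 0)
  structure(
    list(sequence = sequence, n_acetyl = isTRUE(n_acetyl),
         thioamide = sort(thioamide), dehydro = as.integer(dehydro)),
    class = "modified_peptide"
  )
}

#' @export
print.modified_peptide <- function(x, ...) {
  mods <- c(
    if (x$n_acetyl) "N-acetyl",
    if (length(x$thioamide)) paste0("thioamide@", paste(x$thioamide, collapse = ",")),
    if (x$dehydro > 0) paste0(x$dehydro, "x dehydro")
  )
  cat(sprintf("<modified_peptide> %s [%s] M = %.6f Da, [M+H]+ = %.6f\n",
              x$sequence, if (length(mods)) paste(mods, collapse = "; ") else "unmodified",
              monoisotopic_mass(x), mz_protonated(x)))
  invisible(x)
}

#' Monoisotopic mass of a modified peptide
#'
#' Sum of residue monoisotopic masses plus water, plus +42.010565 for an
#' N-acetyl group, +15.977156 per backbone thioamide (S for O), and
#' -2.015650 per desaturation.
#'
#' @param p A [modified_peptide()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass(modified_peptide("G")) # 75.032029
#' @export
monoisotopic_mass <- function(p) {
  stopifnot(inherits(p, "modified_peptide"))
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  sum(RESIDUE_MASS[res]) + MASS_WATER +
    (if (p$n_acetyl) MASS_ACETYL else 0) +
    length(p$thioamide) * MASS_THIOAMIDE -
    p$dehydro * MASS_DEHYDRO
}

#' m/z of the protonated ion
#'
#' @param p A [modified_peptide()].
#' @param charge Positive integer charge state.
#' @return `(M + charge * 1.007276) / charge`.
#' @examples
#' # thioamidated N-acetyl-APR, the ion observed for thiovarsolin B
#' mz_protonated(modified_peptide("APR", n_acetyl = TRUE, thioamide = 2))
#' @export
mz_protonated <- function(p, charge = 1L) {
  stopifnot(charge >= 1L)
  (monoisotopic_mass(p) + charge * MASS_PROTON) / charge
}

#' Screen fragment lists for H2S neutral losses
#'
#' A mass difference of 33.987721 Da (H2S) between two fragments, or between
#' the precursor and a fragment, is a fragmentation signature of backbone
#' thioamides. Every pair within a spectrum whose difference lies within
#' `tol` Da of the H2S mass is reported.
#'
#' @param fragments Data frame with columns `spectrum_id` and `mz`, one row
#'   per fragment ion.
#' @param precursors Optional data frame with columns `spectrum_id` and `mz`
#'   giving each spectrum's precursor ion.
#' @param tol Inclusive tolerance in Da on the mass difference.
#' @return Data frame with columns `spectrum_id`, `mz_high`, `mz_low`,
#'   `delta`, `kind` (`"fragment-fragment"` or `"precursor-fragment"`).
#' @export
h2s_loss_screen <- function(fragments, precursors = NULL, tol = 0.01) {
  stopifnot(all(c("spectrum_id", "mz") %in% names(fragments)))
  out <- list()
  pair_hits <- function(id, hi_mz, lo_mz, kind) {
    if (!length(hi_mz) || !length(lo_mz)) return(NULL)
    g <- expand.grid(hi = hi_mz, lo = lo_mz)
    g$delta <- g$hi - g$lo
    g <- g[abs(g$delta - MASS_H2S) <= tol, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    data.frame(spectrum_id = id, mz_high = g$hi, mz_low = g$lo,
               delta = g$delta, kind = kind, stringsAsFactors = FALSE)
  }
  for (id in unique(fragments$spectrum_id)) {
    fz <- sort(fragments$mz[fragments$spectrum_id == id])
    out[[length(out) + 1L]] <- pair_hits(id, fz, fz, "fragment-fragment")
    if (!is.null(precursors)) {
      pz <- precursors$mz[precursors$spectrum_id == id]
      out[[length(out) + 1L]] <- pair_hits(id, pz, fz, "precursor-fragment")
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(spectrum_id = character(), mz_high = numeric(),
                      mz_low = numeric(), delta = numeric(), kind = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Features unique to one sample group
#'
#' Comparative-metabolomics style differential screening: features below the
#' intensity threshold are discarded; features are matched across tables when
#' both the m/z and retention-time differences are within tolerance; a
#' feature is unique to a group when it is present (post-threshold) in every
#' replicate of that group and matched in no replicate of any other group.
#'
#' @param sample_groups Named list; each element is a list of replicate
#'   feature tables (data frames with columns `mz`, `rt`, `intensity`).
#' @param mz_tol Inclusive m/z tolerance in Da (default 0.1, i.e. 100 mDa).
#' @param rt_tol Inclusive retention-time tolerance in minutes.
#' @param intensity_min Intensity threshold below which features are ignored.
#' @return Data frame of unique features with columns `group`, `mz`, `rt`,
#'   `intensity` (intensity from the group's first replicate).
#' @export
differential_features <- function(sample_groups, mz_tol = 0.1, rt_tol = 0.1,
                                  intensity_min = 1e5) {
  stopifnot(is.list(sample_groups), !is.null(names(sample_groups)),
            all(nzchar(names(sample_groups))))
  thresh <- function(tab) tab[tab$intensity >= intensity_min, , drop = FALSE]
  matched_in <- function(mz, rt, tab) {
    any(abs(tab$mz - mz) <= mz_tol & abs(tab$rt - rt) <= rt_tol)
  }
  groups <- lapply(sample_groups, function(reps) lapply(reps, thresh))
  out <- list()
  for (g in names(groups)) {
    reps <- groups[[g]]
    if (!length(reps)) stop("group '", g, "' has no replicate tables")
    anchors <- reps[[1]]
    others <- unlist(groups[setdiff(names(groups), g)], recursive = FALSE)
    for (i in seq_len(nrow(anchors))) {
      mz <- anchors$mz[i]; rt <- anchors$rt[i]
      in_all_reps <- all(vapply(reps, function(tab) matched_in(mz, rt, tab), logical(1)))
      in_any_other <- any(vapply(others, function(tab) matched_in(mz, rt, tab), logical(1)))
      if (in_all_reps && !in_any_other) {
        out[[length(out) + 1L]] <- data.frame(
          group = g, mz = mz, rt = rt, intensity = anchors$intensity[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(group = character(), mz = numeric(), rt = numeric(),
                      intensity = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read a feature table (mz, rt, intensity) from CSV or TSV
#'
#' @param path File with columns `mz`, `rt`, `intensity`; delimiter inferred
#'   from the extension (`.csv` comma, otherwise tab).
#' @return Data frame with the three numeric columns.
#' @export
read_feature_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("mz", "rt", "intensity")
  if (!all(need %in% names(tab))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  }
  tab[need]
}
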