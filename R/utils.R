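# Internal helpers shared across modules.

# Run code under a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Reverse complement of an unambiguous/N DNA string (kept base-R: called in
# tight loops where DNAString round trips dominate runtime).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' @importFrom utils head tail
NULL

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Interval helpers on 0-based half-open coordinates.
interval_overlap_nt <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

interval_gap_nt <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

fmt_num <- function(x, digits = 4) {
  # Stable text form for tabular output; guarantees byte-identical reruns.
  sprintf(paste0("%.", digits, "f"), x)
}
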