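# Short-ORF enumeration and coding-potential scoring.
#
# The scorer is a deliberately simple self-trained model with the same
# contract as a bacterial gene finder's score: in-frame hexamer log-odds
# (coding vs whole-region background), ribosome-binding-site k-mer/spacer
# weights learned from the region's own annotated genes, and a start-codon
# term. Higher means more gene-like; the retrieval threshold compares
# against these totals after a fixed affine calibration committed below.

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

# Translation-table-11 codon lookup built from the standard genetic code;
# bacterial alternative starts are handled separately at position 1.
.codon_env <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(.codon_env$tab)) {
    gc <- Biostrings::GENETIC_CODE
    tab <- as.character(gc)
    names(tab) <- names(gc)
    tab[tab == "*"] <- "*"
    .codon_env$tab <- tab
  }
  .codon_env$tab
}

all_hexamers <- function() {
  if (is.null(.codon_env$hex)) {
    b <- c("A", "C", "G", "T")
    g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
    # expand.grid varies the first factor fastest; paste in reverse for
    # lexicographic order (cosmetic only - lookups are by name).
    .codon_env$hex <- sort(do.call(paste0, g))
  }
  .codon_env$hex
}

# Split a sequence into consecutive codons starting at 1-based offset.
codons_of <- function(seq, offset = 1L) {
  n <- nchar(seq)
  starts <- seq.int(offset, n - 2L, by = 3L)
  if (!length(starts) || starts[1] > n - 2L) return(character())
  substring(seq, starts, starts + 2L)
}

#' Translate a CDS nucleotide sequence (translation table 11)
#'
#' Bacterial alternative starts (GTG, TTG) render as M at position 1; the
#' trailing stop codon, if present, is removed. An internal stop is an
#' error.
#'
#' @param nt Nucleotide string; length divisible by 3. If `strand` is `-1`
#'   the reverse complement is translated.
#' @param strand `+1` or `-1`.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGTAA")    # "M"
#' translate_cds("GTGGCTTAA") # "MA"
#' @export
translate_cds <- function(nt, strand = 1L) {
  nt <- toupper(nt)
  if (nchar(nt) %% 3 != 0) stop("CDS length not divisible by 3")
  if (strand < 0) nt <- revcomp(nt)
  cods <- codons_of(nt)
  aa <- unname(codon_table()[cods])
  aa[is.na(aa)] <- "X"  # codons containing N
  n <- length(aa)
  if (n > 1L && aa[n] == "*") aa <- aa[-n]
  internal <- which(aa == "*")
  if (length(internal)) {
    stop("internal stop codon at codon offset ", internal[1])
  }
  if (length(aa) && cods[1] %in% START_CODONS) aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Enumerate short ORFs in all six frames
#'
#' Every span from a start codon (ATG/GTG/TTG) to the next in-frame stop, in
#' all six reading frames, is a candidate, provided it is at least `min_nt`
#' nucleotides (stop included) and encodes at most `2 * max_aa` residues (a
#' work bound; retrieval applies the real size window). Each upstream start
#' sharing a stop yields a distinct candidate. Reverse-strand candidates are
#' reported in forward-axis 0-based half-open coordinates.
#'
#' @param region A [genomic_region()].
#' @param min_nt Minimum ORF length in nucleotides, stop codon included
#'   (default 60).
#' @param max_aa Nominal maximum peptide length; the enumerator's hard cap
#'   is twice this value.
#' @return Data frame of candidates: `start`, `end`, `strand`, `peptide`,
#'   score columns (zeroed), `annotated = FALSE`.
#' @export
enumerate_orfs <- function(region, min_nt = 60L, max_aa = 120L) {
  seq_fwd <- region$sequence
  L <- nchar(seq_fwd)
  if (L == 0L) stop("region sequence is empty")
  hard_cap_aa <- 2L * max_aa
  tab <- codon_table()
  rows <- vector("list", 64)
  nr <- 0L

  for (str in c(1L, -1L)) {
    sq <- if (str == 1L) seq_fwd else revcomp(seq_fwd)
    for (frame in 0:2) {
      cods <- codons_of(sq, frame + 1L)
      nc <- length(cods)
      if (nc < 2L) next
      aa <- unname(tab[cods])
      aa[is.na(aa)] <- "X"
      prot <- paste(aa, collapse = "")
      stop_i <- which(aa == "*")
      start_i <- which(cods %in% START_CODONS)
      if (!length(stop_i) || !length(start_i)) next
      prev_stop <- c(0L, stop_i[-length(stop_i)])
      for (k in seq_along(stop_i)) {
        s <- stop_i[k]
        cand_starts <- start_i[start_i > prev_stop[k] & start_i < s]
        if (!length(cand_starts)) next
        for (st in cand_starts) {
          ncod <- s - st + 1L           # codons incl. stop
          if (ncod * 3L < min_nt) next
          pep_len <- ncod - 1L
          if (pep_len > hard_cap_aa) next
          pep <- substring(prot, st, s - 1L)
          substr(pep, 1L, 1L) <- "M"
          # 1-based codon index -> nt coords within frame sequence
          a <- frame + (st - 1L) * 3L       # 0-based start in sq
          b <- frame + s * 3L               # 0-based half-open end in sq
          if (str == 1L) {
            start0 <- a; end0 <- b
          } else {
            start0 <- L - b; end0 <- L - a
          }
          nr <- nr + 1L
          if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
          rows[[nr]] <- list(start = start0, end = end0, strand = str,
                             peptide = pep)
        }
      }
    }
  }
  if (nr == 0L) return(empty_candidates())
  rows <- rows[seq_len(nr)]
  out <- data.frame(
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = vapply(rows, `[[`, integer(1), "strand"),
    peptide = vapply(rows, `[[`, character(1), "peptide"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start, out$end, -out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$rbs_score <- 0
  out$coding_score <- 0
  out$start_bonus <- 0
  out$total_score <- 0
  out$annotated <- FALSE
  out$strand_rewarded <- FALSE
  out$notes <- ""
  out
}

empty_candidates <- function() {
  data.frame(start = integer(), end = integer(), strand = integer(),
             peptide = character(), rbs_score = numeric(),
             coding_score = numeric(), start_bonus = numeric(),
             total_score = numeric(), annotated = logical(),
             strand_rewarded = logical(), notes = character(),
             stringsAsFactors = FALSE)
}

# Coding-strand nucleotide sequence of a feature/candidate interval.
coding_seq <- function(region, start, end, strand) {
  s <- substring(region$sequence, start + 1L, end)
  if (strand < 0) s <- revcomp(s)
  s
}

# Upstream window (length win nt, coding strand, adjacent to the start
# codon) of an interval; shorter near contig edges.
upstream_window <- function(region, start, end, strand, win = 21L) {
  L <- nchar(region$sequence)
  if (strand >= 0) {
    a <- max(0L, start - win)
    if (a >= start) return("")
    substring(region$sequence, a + 1L, start)
  } else {
    b <- min(L, end + win)
    if (end >= b) return("")
    revcomp(substring(region$sequence, end + 1L, b))
  }
}

# Fixed affine calibration of the summed log-odds terms onto the threshold
# scale used by retrieval (7.5 default / 15 strict). Committed constants;
# no per-run fitting.
SCORE_CAL_A <- 0.55
SCORE_CAL_B <- 0.0

#' Train the region's coding model
#'
#' Accumulates in-frame hexamer counts over annotated CDS of at least
#' `min_training_nt` (coding strand), against background hexamer counts from
#' the whole region (both strands, all offsets), with add-one smoothing over
#' all 4096 hexamers. RBS weights are learned from the 21 nt upstream of
#' training-gene starts (6-mer x spacer 3-15 nt) against the background
#' 6-mer frequency; start-codon weights from the training genes' start
#' codons. Fewer than 3 usable training genes yields an untrained zero
#' model.
#'
#' @param region A [genomic_region()].
#' @param min_training_nt Minimum annotated CDS length used for training.
#' @return Object of class `coding_model`.
#' @export
train_coding_model <- function(region, min_training_nt = 300L) {
  feats <- region$features
  cds <- feats[feats$kind == "CDS" & (feats$end - feats$start) >= min_training_nt, ,
               drop = FALSE]
  hex <- all_hexamers()

  # background: all hexamer offsets, both strands
  bg_counts <- integer(length(hex)); names(bg_counts) <- hex
  for (sq in c(region$sequence, revcomp(region$sequence))) {
    n <- nchar(sq)
    if (n < 6L) next
    hx <- substring(sq, 1:(n - 5L), 6:n)
    hx <- hx[!grepl("N", hx, fixed = TRUE)]
    tb <- table(hx)
    bg_counts[names(tb)] <- bg_counts[names(tb)] + as.integer(tb)
  }

  cod_counts <- integer(length(hex)); names(cod_counts) <- hex
  n_train <- 0L
  rbs_obs <- list()
  start_obs <- character()
  for (i in seq_len(nrow(cds))) {
    sq <- coding_seq(region, cds$start[i], cds$end[i], cds$strand[i])
    n <- nchar(sq)
    if (n < 6L) next
    pos <- seq.int(1L, n - 5L, by = 3L)
    hx <- substring(sq, pos, pos + 5L)
    hx <- hx[!grepl("N", hx, fixed = TRUE)]
    tb <- table(hx)
    cod_counts[names(tb)] <- cod_counts[names(tb)] + as.integer(tb)
    n_train <- n_train + 1L
    rbs_obs[[length(rbs_obs) + 1L]] <-
      upstream_window(region, cds$start[i], cds$end[i], cds$strand[i])
    start_obs <- c(start_obs, substring(sq, 1L, 3L))
  }

  if (n_train < 3L) {
    lo <- numeric(length(hex)); names(lo) <- hex
    return(structure(list(
      hexamer_logodds = lo, rbs_weights = numeric(0),
      start_weights = c(ATG = 0, GTG = 0, TTG = 0),
      bg_freq = NULL, trained = FALSE, training_cds_count = n_train
    ), class = "coding_model"))
  }

  bg_total <- sum(bg_counts)
  cod_total <- sum(cod_counts)
  lo <- log((cod_counts + 1) / (cod_total + length(hex))) -
        log((bg_counts + 1) / (bg_total + length(hex)))
  names(lo) <- hex

  bg_freq <- (bg_counts + 1) / (bg_total + length(hex))

  # RBS: observed (6-mer, spacer) pairs vs background expectation
  obs <- list()
  for (w in rbs_obs) {
    nw <- nchar(w)
    if (nw < 6L) next
    for (i in seq_len(nw - 5L)) {
      spacer <- nw - (i + 5L)
      if (spacer < 3L || spacer > 15L) next
      km <- substring(w, i, i + 5L)
      if (grepl("N", km, fixed = TRUE)) next
      key <- paste0(km, ":", spacer)
      obs[[key]] <- (obs[[key]] %||% 0L) + 1L
    }
  }
  rbs_w <- numeric(0)
  if (length(obs)) {
    keys <- names(obs)
    kms <- substring(keys, 1L, 6L)
    cnt <- unlist(obs, use.names = FALSE)
    expect <- n_train * bg_freq[kms]
    w <- log((cnt + 0.1) / (expect + 0.1))
    keep <- w > 0
    rbs_w <- w[keep]; names(rbs_w) <- keys[keep]
  }

  sc <- table(factor(start_obs, levels = START_CODONS))
  start_w <- log((as.numeric(sc) + 1) / (sum(sc) + 3)) - log(1 / 3)
  names(start_w) <- START_CODONS

  structure(list(
    hexamer_logodds = lo, rbs_weights = rbs_w, start_weights = start_w,
    bg_freq = bg_freq, trained = TRUE, training_cds_count = n_train
  ), class = "coding_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.coding_model <- function(x, ...) {
  cat(sprintf("<coding_model> trained=%s, %d training CDS, %d RBS weights\n",
              x$trained, x$training_cds_count, length(x$rbs_weights)))
  invisible(x)
}

# Raw (uncalibrated) score components of one interval.
score_components <- function(region, start, end, strand, model) {
  sq <- coding_seq(region, start, end, strand)
  n <- nchar(sq)
  coding <- 0
  if (n >= 9L) {
    # in-frame hexamers fully inside the coding part (stop codon excluded)
    pos <- seq.int(1L, n - 8L, by = 3L)
    if (length(pos)) {
      hx <- substring(sq, pos, pos + 5L)
      v <- model$hexamer_logodds[hx]
      v[is.na(v)] <- 0  # hexamers containing N
      coding <- sum(v)
    }
  }
  rbs <- 0
  if (length(model$rbs_weights)) {
    w <- upstream_window(region, start, end, strand)
    nw <- nchar(w)
    if (nw >= 6L) {
      i <- seq_len(nw - 5L)
      spacer <- nw - (i + 5L)
      ok <- spacer >= 3L & spacer <= 15L
      if (any(ok)) {
        keys <- paste0(substring(w, i[ok], i[ok] + 5L), ":", spacer[ok])
        v <- model$rbs_weights[keys]
        v[is.na(v)] <- 0
        rbs <- max(0, v)
      }
    }
  }
  sc <- substring(sq, 1L, 3L)
  start_bonus <- if (sc %in% names(model$start_weights)) {
    unname(model$start_weights[sc])
  } else 0
  list(coding = coding, rbs = rbs, start_bonus = start_bonus)
}

#' Score candidate ORFs with a coding model
#'
#' The coding component is the summed in-frame hexamer log-odds over the
#' candidate (mean log-odds scaled by length); the RBS component is the best
#' (6-mer, spacer) weight in the 21 nt upstream window; the start bonus comes
#' from the start-codon weights. The total is a fixed affine rescale of the
#' component sum, putting authentic genes typically above the default
#' retrieval threshold of 7.5 and random intergenic ORFs typically below it.
#'
#' @param candidates Candidate data frame from [enumerate_orfs()] (or
#'   annotated short genes wrapped by [collect_annotated_short_genes()]).
#' @param model A `coding_model` from [train_coding_model()].
#' @param region The [genomic_region()] the candidates refer to.
#' @return The candidate data frame with score columns filled.
#' @export
score_candidates <- function(candidates, model, region) {
  stopifnot(inherits(model, "coding_model"))
  n <- nrow(candidates)
  if (n == 0L) return(candidates)
  for (i in seq_len(n)) {
    comp <- score_components(region, candidates$start[i], candidates$end[i],
                             candidates$strand[i], model)
    candidates$coding_score[i] <- comp$coding
    candidates$rbs_score[i] <- comp$rbs
    candidates$start_bonus[i] <- comp$start_bonus
    candidates$total_score[i] <-
      SCORE_CAL_A * (comp$coding + comp$rbs + comp$start_bonus) + SCORE_CAL_B
    if (!model$trained) {
      candidates$notes[i] <- paste0(candidates$notes[i],
                                    "[untrained model: coding term zero]")
    }
  }
  candidates
}

#' Dump / load a coding model as a plain-text table
#'
#' A line-oriented text serialization (hexamer log-odds, RBS weights, start
#' weights) used for test fixtures and reproducibility.
#'
#' @param model A `coding_model`.
#' @param path Output (or input) file path.
#' @return `write_coding_model` returns `path` invisibly;
#'   `read_coding_model` returns a `coding_model`.
#' @export
write_coding_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CODING-MODEL 1 trained=%d count=%d",
                     as.integer(model$trained), model$training_cds_count), con)
  nz <- model$hexamer_logodds[model$hexamer_logodds != 0]
  writeLines(sprintf("H %s %.10g", names(nz), nz), con)
  if (length(model$rbs_weights)) {
    writeLines(sprintf("R %s %.10g", names(model$rbs_weights), model$rbs_weights), con)
  }
  writeLines(sprintf("S %s %.10g", names(model$start_weights), model$start_weights), con)
  invisible(path)
}

#' @rdname write_coding_model
#' @export
read_coding_model <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (hdr[1] != "CODING-MODEL") stop("not a coding-model file: ", path)
  trained <- sub("trained=", "", hdr[3]) == "1"
  count <- as.integer(sub("count=", "", hdr[4]))
  hex <- all_hexamers()
  lo <- numeric(length(hex)); names(lo) <- hex
  rbs <- numeric(0)
  start_w <- c(ATG = 0, GTG = 0, TTG = 0)
  for (ln in lines[-1]) {
    p <- strsplit(ln, " ", fixed = TRUE)[[1]]
    v <- as.numeric(p[3])
    switch(p[1],
      H = { lo[p[2]] <- v },
      R = { rbs[p[2]] <- v },
      S = { start_w[p[2]] <- v },
      stop("malformed model line: ", ln))
  }
  structure(list(hexamer_logodds = lo, rbs_weights = rbs,
                 start_weights = start_w, bg_freq = NULL,
                 trained = trained, training_cds_count = count),
            class = "coding_model")
}
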