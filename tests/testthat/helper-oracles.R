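# Independent oracles used to validate the implementation. These are
# written from first principles (direct loops, exhaustive enumeration) and
# share no code with the package paths they check.

# Codon -> aa lookup taken straight from the standard genetic code.
.oracle_code <- as.character(Biostrings::GENETIC_CODE)
names(.oracle_code) <- names(Biostrings::GENETIC_CODE)

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

oracle_translate <- function(nt) {
  out <- character()
  for (i in seq(1, nchar(nt) - 2, by = 3)) {
    out <- c(out, .oracle_code[[substr(nt, i, i + 2)]])
  }
  paste(out, collapse = "")
}

# Exhaustive six-frame ORF scan: for every position and strand, every
# start codon followed in-frame by a stop with no intervening stop.
oracle_orfs <- function(seq, min_nt = 60L, hard_cap_aa = 240L) {
  L <- nchar(seq)
  rows <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else oracle_revcomp(seq)
    for (a in seq_len(L)) {            # 1-based start of a candidate codon
      if (a + 2 > L) next
      if (!(substr(s, a, a + 2) %in% c("ATG", "GTG", "TTG"))) next
      j <- a
      pep <- character()
      repeat {
        if (j + 2 > L) { pep <- NULL; break }
        cod <- substr(s, j, j + 2)
        aa <- .oracle_code[[cod]]
        if (identical(aa, "*")) break
        pep <- c(pep, aa)
        j <- j + 3
      }
      if (is.null(pep)) next           # ran off the contig without a stop
      nt_len <- (j + 3) - a            # start..stop inclusive
      if (nt_len < min_nt) next
      if (length(pep) > hard_cap_aa) next
      pep[1] <- "M"
      if (strand == 1L) {
        start0 <- a - 1L; end0 <- j + 2L
      } else {
        start0 <- L - (j + 2L); end0 <- L - a + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = start0, end = end0, strand = strand,
        peptide = paste(pep, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(), strand = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, -out$strand), , drop = FALSE]
}

# Smith-Waterman with affine gaps (gap of length L costs open + L * ext),
# plain Gotoh DP over the given substitution matrix; score floored at 0.
oracle_sw <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)   # gap in b (vertical)
  Iy <- matrix(-Inf, n + 1, m + 1)   # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]))
      Ix[i, j] <- max(M[i - 1, j] - (open + ext), Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - (open + ext), Iy[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Reachability by boolean-matrix transitive closure.
oracle_components <- function(ids, edges) {
  n <- length(ids)
  R <- diag(TRUE, n)
  dimnames(R) <- list(ids, ids)
  for (k in seq_len(nrow(edges))) {
    R[edges$query_id[k], edges$subject_id[k]] <- TRUE
    R[edges$subject_id[k], edges$query_id[k]] <- TRUE
  }
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R > 0)) break
    R <- R2
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[which(R[i, ])] <- cid
    }
  }
  split(ids, comp)
}

# Literal restatement of the retrieval rule: sort by (score desc, distance
# asc, start asc) after dedup, slice the top N, union everything at or
# above the threshold.
oracle_select <- function(tab, limit, thresh, maxdist) {
  tab <- tab[tab$distance_nt <= maxdist, , drop = FALSE]
  tab <- tab[!duplicated(paste(tab$start, tab$end, tab$strand)), , drop = FALSE]
  tab <- tab[order(-tab$total_score, tab$distance_nt, tab$start), , drop = FALSE]
  idx <- seq_len(min(limit, nrow(tab)))
  idx <- sort(union(idx, which(tab$total_score >= thresh)))
  tab[idx, , drop = FALSE]
}

# Small hand-built region: explicit sequence assembled from parts.
toy_region <- function(genes, length_nt = 3000L, seed = 7L,
                       rte_id = genes$feature_id[1]) {
  # genes: data.frame(feature_id, start, strand, peptide)
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), length_nt, replace = TRUE,
                  prob = c(.2, .3, .3, .2))
  feats <- list()
  for (i in seq_len(nrow(genes))) {
    nt <- character()
    for (aa in strsplit(genes$peptide[i], "")[[1]]) {
      cands <- names(.oracle_code)[.oracle_code == aa]
      nt <- c(nt, sample(cands, 1))
    }
    nt[1] <- "ATG"
    cds <- paste(c(nt, "TGA"), collapse = "")
    if (genes$strand[i] < 0) cds <- oracle_revcomp(cds)
    st <- genes$start[i]
    chars[(st + 1):(st + nchar(cds))] <- strsplit(cds, "")[[1]]
    feats[[i]] <- data.frame(
      feature_id = genes$feature_id[i], start = st, end = st + nchar(cds),
      strand = genes$strand[i], kind = "CDS", product = "toy protein",
      translation = genes$peptide[i], annotated = TRUE,
      stringsAsFactors = FALSE)
  }
  genomic_region("TOY0001", paste(chars, collapse = ""),
                 do.call(rbind, feats), rte_feature_id = rte_id,
                 organism = "Toyus testus")
}

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_pep_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
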