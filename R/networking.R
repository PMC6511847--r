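# Peptide similarity networking: all-vs-all Smith-Waterman local alignment
# (BLOSUM62, affine gaps), Karlin-Altschul E-values, thresholded edges,
# connected components ranked by size, graph-viewer export, and
# 99%-identity dereplication.

#' Networking configuration
#'
#' Edge thresholds follow the similarity-network settings used for
#' precursor-peptide family detection: E-value at most 10, at least 40%
#' identity over alignment columns, the hit covering at least 35% of the
#' shorter sequence, and a minimum hit length of 15 aligned columns.
#' Alignment uses BLOSUM62 with gap open 11 / extend 1; the E-value uses
#' fixed gapped Karlin-Altschul constants for that matrix.
#'
#' @param evalue_max,identity_min_pct,coverage_min_pct,hitlen_min Edge
#'   thresholds.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param lambda,k_param Karlin-Altschul constants.
#' @param matrix Substitution matrix name (only `"BLOSUM62"` is shipped).
#' @return Object of class `network_config`.
#' @export
network_config <- function(evalue_max = 10, identity_min_pct = 40,
                           coverage_min_pct = 35, hitlen_min = 15L,
                           gap_open = 11, gap_extend = 1,
                           lambda = 0.267, k_param = 0.041,
                           matrix = "BLOSUM62") {
  stopifnot(evalue_max >= 0, identity_min_pct >= 0, coverage_min_pct >= 0,
            hitlen_min >= 0, matrix == "BLOSUM62")
  structure(list(evalue_max = evalue_max, identity_min_pct = identity_min_pct,
                 coverage_min_pct = coverage_min_pct,
                 hitlen_min = as.integer(hitlen_min), gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, k_param = k_param,
                 matrix = matrix), class = "network_config")
}

.net_env <- new.env(parent = emptyenv())

# BLOSUM62 with the X row/column zeroed (X scores 0 against everything).
scoring_matrix <- function() {
  if (is.null(.net_env$mat)) {
    mat <- get_blosum62()
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
    .net_env$mat <- mat
  }
  .net_env$mat
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

clean_peptide <- function(x) {
  x <- toupper(gsub("\\*+$", "", x))
  gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", x)
}

#' Optimal local alignment of two peptides
#'
#' Smith-Waterman under BLOSUM62 with affine gaps (a gap of length L costs
#' `gap_open + L * gap_extend`). Identity is computed over alignment
#' columns (gap columns included); coverage is the aligned span of the
#' shorter sequence over its length. Non-standard residues are scored as X
#' (0 against everything).
#'
#' @param a,b Peptide strings (non-empty).
#' @param cfg A [network_config()].
#' @param n_db Total database residues for the E-value (defaults to
#'   `nchar(b)`).
#' @return One-row data frame: `raw_score`, `bit_score`, `evalue`,
#'   `identity_pct`, `hit_len`, `coverage_shorter_pct`.
#' @export
local_align <- function(a, b, cfg = network_config(), n_db = nchar(b)) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  a <- clean_peptide(a); b <- clean_peptide(b)
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = scoring_matrix(),
    gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend)
  raw <- max(0, Biostrings::score(al))
  if (raw <= 0) {
    return(data.frame(raw_score = 0, bit_score = bit_score(0, cfg),
                      evalue = estimate_evalue(0, nchar(a), n_db, cfg),
                      identity_pct = 0, hit_len = 0L,
                      coverage_shorter_pct = 0))
  }
  cols <- Biostrings::nchar(al)           # alignment columns incl. gaps
  ident <- Biostrings::nmatch(al) / cols * 100
  pat <- Biostrings::pattern(al); sub <- Biostrings::subject(al)
  span_a <- Biostrings::end(pat) - Biostrings::start(pat) + 1L
  span_b <- Biostrings::end(sub) - Biostrings::start(sub) + 1L
  if (nchar(a) <= nchar(b)) {
    cov <- span_a / nchar(a) * 100
  } else {
    cov <- span_b / nchar(b) * 100
  }
  data.frame(raw_score = raw, bit_score = bit_score(raw, cfg),
             evalue = estimate_evalue(raw, nchar(a), n_db, cfg),
             identity_pct = ident, hit_len = as.integer(cols),
             coverage_shorter_pct = cov)
}

bit_score <- function(raw, cfg = network_config()) {
  (cfg$lambda * raw - log(cfg$k_param)) / log(2)
}

#' Karlin-Altschul E-value estimate
#'
#' `bit = (lambda * raw - ln K) / ln 2`; `E = m * n * 2^(-bit)`. Strictly
#' decreasing in the raw score and linear in the search-space sizes.
#'
#' @param raw_score Raw alignment score (matrix units), non-negative.
#' @param m Query length (residues).
#' @param n Total database residues.
#' @param cfg A [network_config()].
#' @return The expected number of chance hits at this score.
#' @export
estimate_evalue <- function(raw_score, m, n, cfg = network_config()) {
  stopifnot(all(raw_score >= 0))
  m * n * 2^(-bit_score(raw_score, cfg))
}

#' Build peptide similarity networks
#'
#' Aligns every unordered pair once (scores are symmetric under this
#' scheme); an undirected edge is drawn iff the hit passes all four
#' thresholds. Connected components are ranked by size (descending), ties
#' broken by the lexicographically smallest member id; singletons are
#' reported separately.
#'
#' @param peptides Data frame with columns `id` (unique) and `sequence`, or
#'   a named character vector.
#' @param cfg A [network_config()].
#' @return List with `networks` (data frame `rank`, `size`, `members`
#'   semicolon-joined), `membership` (named vector id -> rank, NA for
#'   singletons), `singletons` (character), `edges` (data frame of passing
#'   hits), `hits` (all computed pairwise hits).
#' @export
build_network <- function(peptides, cfg = network_config()) {
  if (is.character(peptides)) {
    peptides <- data.frame(id = names(peptides), sequence = unname(peptides),
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(peptides)),
            !anyDuplicated(peptides$id))
  ids <- peptides$id
  seqs <- clean_peptide(peptides$sequence)
  n <- length(ids)
  n_db <- sum(nchar(seqs))
  hits <- list()
  for (i in seq_len(max(0, n - 1))) {
    js <- (i + 1L):n
    for (j in js) {
      h <- local_align(seqs[i], seqs[j], cfg, n_db = n_db)
      h$query_id <- ids[i]; h$subject_id <- ids[j]
      hits[[length(hits) + 1L]] <- h
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(raw_score = numeric(), bit_score = numeric(), evalue = numeric(),
               identity_pct = numeric(), hit_len = integer(),
               coverage_shorter_pct = numeric(), query_id = character(),
               subject_id = character(), stringsAsFactors = FALSE)
  pass <- hits$evalue <= cfg$evalue_max &
    hits$identity_pct >= cfg$identity_min_pct &
    hits$coverage_shorter_pct >= cfg$coverage_min_pct &
    hits$hit_len >= cfg$hitlen_min
  edges <- hits[pass, , drop = FALSE]
  rownames(edges) <- NULL

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$query_id, ids),
                                    match(edges$subject_id, ids)))
  }
  comp <- igraph::components(g)
  members <- split(ids, comp$membership)
  sizes <- vapply(members, length, integer(1))
  multi <- members[sizes >= 2L]
  singletons <- sort(unlist(members[sizes == 1L], use.names = FALSE))
  if (length(multi)) {
    first_id <- vapply(multi, function(m) sort(m)[1], character(1))
    ord <- order(-vapply(multi, length, integer(1)), first_id)
    multi <- multi[ord]
    networks <- data.frame(
      rank = seq_along(multi),
      size = vapply(multi, length, integer(1)),
      members = vapply(multi, function(m) paste(sort(m), collapse = ";"),
                       character(1)),
      stringsAsFactors = FALSE)
  } else {
    networks <- data.frame(rank = integer(), size = integer(),
                           members = character(), stringsAsFactors = FALSE)
  }
  membership <- rep(NA_integer_, n); names(membership) <- ids
  for (k in seq_len(nrow(networks))) {
    membership[strsplit(networks$members[k], ";", fixed = TRUE)[[1]]] <- k
  }
  list(networks = networks, membership = membership, singletons = singletons,
       edges = edges, hits = hits)
}

#' Export a network for graph viewers
#'
#' Writes a SIF file (`id1 sim id2`, one line per edge), an edge table with
#' all hit metrics, and a node-attribute TSV keyed by node id.
#'
#' @param net Result of [build_network()].
#' @param node_attributes Data frame keyed by an `id` column (e.g. the
#'   retrieved-peptide table with ids added); may be `NULL`.
#' @param sif_path,edges_path,attrs_path Output paths (NULL to skip one).
#' @return Invisibly, the list of written paths.
#' @export
export_network <- function(net, node_attributes = NULL, sif_path = NULL,
                           edges_path = NULL, attrs_path = NULL) {
  written <- list()
  if (!is.null(sif_path)) {
    lines <- sprintf("%s\tsim\t%s", net$edges$query_id, net$edges$subject_id)
    writeLines(lines, sif_path)
    written$sif <- sif_path
  }
  if (!is.null(edges_path)) {
    utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written$edges <- edges_path
  }
  if (!is.null(attrs_path) && !is.null(node_attributes)) {
    stopifnot("id" %in% names(node_attributes))
    attrs <- node_attributes
    attrs$network_rank <- net$membership[attrs$id]
    utils::write.table(attrs, attrs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written$attrs <- attrs_path
  }
  invisible(written)
}

#' Read a SIF file back as an edge list
#'
#' @param path SIF file written by [export_network()].
#' @return Data frame with columns `query_id`, `subject_id`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(query_id = vapply(parts, `[`, character(1), 1),
             subject_id = vapply(parts, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}

#' Collapse near-identical sequences to representatives
#'
#' Greedy dereplication: sequences are processed by length (descending,
#' ties by id); a sequence joins an existing representative if its global
#' alignment identity (matches over alignment columns) is at least the
#' threshold, otherwise it becomes a new representative.
#'
#' @param sequences Named character vector (names are ids).
#' @param identity_threshold_pct Identity threshold, default 99.
#' @return List with `representatives` (named character vector) and
#'   `membership` (named vector id -> representative id).
#' @export
dereplicate <- function(sequences, identity_threshold_pct = 99) {
  stopifnot(!is.null(names(sequences)), !anyDuplicated(names(sequences)))
  ids <- names(sequences)[order(-nchar(sequences), names(sequences))]
  reps <- character()
  membership <- stats::setNames(character(length(sequences)), names(sequences))
  for (id in ids) {
    s <- clean_peptide(sequences[[id]])
    assigned <- NA_character_
    for (r in reps) {
      rs <- clean_peptide(sequences[[r]])
      if (s == rs) { assigned <- r; break }
      al <- Biostrings::pairwiseAlignment(
        s, rs, type = "global", substitutionMatrix = scoring_matrix(),
        gapOpening = 11, gapExtension = 1)
      ident <- Biostrings::nmatch(al) / Biostrings::nchar(al) * 100
      if (ident >= identity_threshold_pct) { assigned <- r; break }
    }
    if (is.na(assigned)) {
      reps <- c(reps, id)
      membership[id] <- id
    } else {
      membership[id] <- assigned
    }
  }
  list(representatives = sequences[reps], membership = membership)
}
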