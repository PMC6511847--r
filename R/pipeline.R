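# End-to-end orchestration: per-region windowing, model training, ORF
# enumeration, scoring, filtering, strand reward, selection and domain
# rescue; across regions, collated tables and FASTA plus one similarity
# network over all retrieved and distant peptides.

#' Build a run manifest
#'
#' @param inputs Data frame with columns `path` (GenBank file) and
#'   optionally `rte_id` (protein_id/locus_tag of the RTE; `NA` lets the
#'   file's own qualifier or the midpoint fallback designate it). For
#'   in-memory runs, a list of [genomic_region()] objects is also accepted.
#' @param config A [ripper_config()].
#' @param net_config A [network_config()].
#' @param output_dir Output directory (created if needed).
#' @param profiles Precursor-domain profiles: a path to a profile file, a
#'   list of [domain_profile()] objects, or `NULL` to skip the rescue scan.
#' @return Object of class `run_manifest`.
#' @export
run_manifest <- function(inputs, config = ripper_config(),
                         net_config = network_config(), output_dir = tempdir(),
                         profiles = NULL) {
  if (is.character(profiles)) profiles <- load_profiles(profiles)
  if (is.null(profiles)) profiles <- list()
  if (is.data.frame(inputs)) {
    stopifnot(nrow(inputs) >= 1L, "path" %in% names(inputs))
  } else {
    stopifnot(is.list(inputs), length(inputs) >= 1L)
  }
  structure(list(inputs = inputs, config = config, net_config = net_config,
                 output_dir = output_dir, profiles = profiles),
            class = "run_manifest")
}

# Run all per-region stages; returns the retrieved and distant tables.
process_region <- function(region, cfg, profiles) {
  window <- extract_window(region, cfg$flank_len)
  rte <- rte_feature(window)
  model <- train_coding_model(window)
  cands <- enumerate_orfs(window, max_aa = cfg$max_pp_len)
  cands <- score_candidates(cands, model, window)
  cands <- filter_candidates(cands, window$features, cfg)
  ann <- collect_annotated_short_genes(window, cfg, model)
  pool <- rbind(cands, ann)
  pool <- apply_strand_reward(pool, rte, cfg$same_strand_reward)
  pool$distance_nt <- distance_from_te(pool$start, pool$end, rte)
  retrieved <- select_peptides(pool, cfg)
  distant <- rescue_distant(pool, retrieved, profiles)
  list(window = window, pool = pool,
       retrieved = as_retrieved(retrieved, window, "retrieved", profiles),
       distant = as_retrieved(distant, window, "distant"),
       retrieved_cands = retrieved)
}

#' Run the full precursor-retrieval workflow
#'
#' Per region: window around the RTE, train the coding model, enumerate and
#' score short ORFs, filter against the annotation, add annotated short
#' genes, apply the strand reward, select in-window peptides, rescue
#' distant domain-bearing ones, and write the color-annotated GenBank.
#' Across regions: collated `out.txt`/`distant.txt` (sorted by source
#' accession then distance), `out.faa`/`distant.faa`, and one similarity
#' network over all retrieved plus distant peptides (`network.sif`,
#' `edges.tsv`, `networks.tsv`, `node_attributes.tsv`). A failing region is
#' logged and skipped; the run fails only if every region fails.
#'
#' @param manifest A [run_manifest()].
#' @return Invisibly, a list with `out`, `distant` (data frames), `network`
#'   (from [build_network()]), `report` (per-region counts), `errors`.
#' @export
run_ripper <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  cfg <- manifest$config
  dir.create(manifest$output_dir, recursive = TRUE, showWarnings = FALSE)
  all_out <- list(); all_distant <- list()
  report <- list(); errors <- character()

  regions <- manifest$inputs
  n_inputs <- if (is.data.frame(regions)) nrow(regions) else length(regions)
  for (i in seq_len(n_inputs)) {
    res <- tryCatch({
      region <- if (is.data.frame(regions)) {
        rid <- if ("rte_id" %in% names(regions) && !is.na(regions$rte_id[i])) {
          regions$rte_id[i]
        } else NULL
        read_genbank(regions$path[i], rte_id = rid)
      } else {
        regions[[i]]
      }
      pr <- process_region(region, cfg, manifest$profiles)
      gb_path <- file.path(manifest$output_dir,
                           paste0(pr$window$accession, "_annotated.gbk"))
      write_annotated_genbank(pr$window, pr$retrieved_cands, gb_path)
      pr
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("input %d failed: %s", i, conditionMessage(res)))
      next
    }
    all_out[[length(all_out) + 1L]] <- res$retrieved
    all_distant[[length(all_distant) + 1L]] <- res$distant
    report[[length(report) + 1L]] <- data.frame(
      accession = res$window$accession,
      candidates = nrow(res$pool),
      retrieved = nrow(res$retrieved),
      distant = nrow(res$distant), stringsAsFactors = FALSE)
  }
  if (!length(report)) {
    stop("all regions failed:\n", paste(errors, collapse = "\n"))
  }

  bind_or_empty <- function(lst) {
    if (length(lst)) do.call(rbind, lst) else
      as_retrieved(empty_candidates(),
                   genomic_region("EMPTY", "A"), "retrieved")[0, ]
  }
  out <- bind_or_empty(all_out)
  distant <- bind_or_empty(all_distant)
  sort_tab <- function(tab) {
    tab <- tab[order(tab$source_accession, tab$distance_nt, tab$start), ,
               drop = FALSE]
    rownames(tab) <- NULL
    tab
  }
  out <- sort_tab(out); distant <- sort_tab(distant)

  tabulate_peptides(out, file.path(manifest$output_dir, "out.txt"))
  tabulate_peptides(distant, file.path(manifest$output_dir, "distant.txt"))
  write_fasta(out, file.path(manifest$output_dir, "out.faa"))
  write_fasta(distant, file.path(manifest$output_dir, "distant.faa"))

  both <- rbind(out, distant)
  net <- NULL
  if (nrow(both)) {
    ids <- sprintf("%s|%d-%d|%s", both$source_accession, both$start, both$end,
                   ifelse(both$strand > 0, "+", "-"))
    nodes <- data.frame(id = ids, sequence = both$peptide,
                        stringsAsFactors = FALSE)
    nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
    net <- build_network(nodes, manifest$net_config)
    attrs <- cbind(data.frame(id = ids, stringsAsFactors = FALSE), both)
    attrs <- attrs[!duplicated(attrs$id), , drop = FALSE]
    export_network(net, attrs,
                   sif_path = file.path(manifest$output_dir, "network.sif"),
                   edges_path = file.path(manifest$output_dir, "edges.tsv"),
                   attrs_path = file.path(manifest$output_dir,
                                          "node_attributes.tsv"))
    utils::write.table(net$networks,
                       file.path(manifest$output_dir, "networks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- do.call(rbind, report)
  invisible(list(out = out, distant = distant, network = net,
                 report = report, errors = errors))
}
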