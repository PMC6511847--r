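# Filters, strand reward, distance rule, top-N selection, rescue, tables.

mk_cand <- function(start, end, strand = 1L, peptide = strrep("A", 30),
                    score = 0, annotated = FALSE) {
  n <- length(start)
  data.frame(start = as.integer(start), end = as.integer(end),
             strand = rep_len(as.integer(strand), n),
             peptide = rep_len(peptide, n),
             rbs_score = rep_len(0, n), coding_score = rep_len(0, n),
             start_bonus = rep_len(0, n), total_score = rep_len(score, n),
             annotated = rep_len(annotated, n),
             strand_rewarded = rep_len(FALSE, n), notes = rep_len("", n),
             stringsAsFactors = FALSE)
}

mk_feat <- function(start, end, strand = 1L, id = "g") {
  data.frame(feature_id = id, start = as.integer(start), end = as.integer(end),
             strand = as.integer(strand), kind = "CDS", product = "",
             translation = NA_character_, annotated = TRUE,
             stringsAsFactors = FALSE)
}

test_that("the 20 nt overlap allowance is a hard boundary", {
  cfg <- ripper_config()
  feat <- mk_feat(1000, 1300)
  pep30 <- paste0("M", strrep("A", 29))

  inside <- mk_cand(1100, 1190, peptide = pep30)
  expect_equal(nrow(filter_candidates(inside, feat, cfg)), 0)

  # ending exactly 20 nt into the gene: retained; 21 nt: removed
  at20 <- mk_cand(930, 1020, peptide = pep30)
  expect_equal(nrow(filter_candidates(at20, feat, cfg)), 1)
  at21 <- mk_cand(931, 1021, peptide = pep30)
  expect_equal(nrow(filter_candidates(at21, feat, cfg)), 0)

  # size window: 20-120 aa inclusive for unannotated candidates
  too_short <- mk_cand(1, 61, peptide = paste0("M", strrep("A", 18)))
  in_window <- mk_cand(1, 64, peptide = paste0("M", strrep("A", 19)))
  too_long <- mk_cand(1, 367, peptide = paste0("M", strrep("A", 120)))
  at_max <- mk_cand(1, 364, peptide = paste0("M", strrep("A", 119)))
  got <- filter_candidates(rbind(too_short, in_window, too_long, at_max),
                           mk_feat(5000, 5300), cfg)
  expect_equal(nrow(got), 2)
  expect_setequal(nchar(got$peptide), c(20, 120))

  # annotated wrappers bypass both filters
  ann <- mk_cand(1100, 1150, peptide = "MSHORT", annotated = TRUE)
  expect_equal(nrow(filter_candidates(ann, feat, cfg)), 1)
})

test_that("randomized overlap filtering equals the pairwise interval oracle", {
  set.seed(42)
  cfg <- ripper_config()
  for (rep in 1:50) {
    n_feat <- sample(1:6, 1)
    feats <- do.call(rbind, lapply(seq_len(n_feat), function(i) {
      s <- sample(0:5000, 1); mk_feat(s, s + sample(100:900, 1), id = paste0("g", i))
    }))
    n_cand <- sample(1:15, 1)
    cands <- do.call(rbind, lapply(seq_len(n_cand), function(i) {
      s <- sample(0:5800, 1)
      len_aa <- sample(15:130, 1)
      mk_cand(s, s + (len_aa + 1) * 3,
              peptide = paste0("M", strrep("A", len_aa - 1)))
    }))
    got <- filter_candidates(cands, feats, cfg)
    keep <- logical(n_cand)
    for (i in seq_len(n_cand)) {
      plen <- nchar(cands$peptide[i])
      ovs <- vapply(seq_len(n_feat), function(j) {
        max(0, min(cands$end[i], feats$end[j]) - max(cands$start[i], feats$start[j]))
      }, numeric(1))
      keep[i] <- plen >= 20 && plen <= 120 && all(ovs <= 20)
    }
    expect_equal(got$start, cands$start[keep])
    expect_equal(got$end, cands$end[keep])
  }
})

test_that("the same-strand reward is applied exactly once", {
  rte <- mk_feat(5000, 6000, strand = 1L)
  cands <- rbind(mk_cand(100, 190, strand = 1L, score = 10),
                 mk_cand(300, 390, strand = -1L, score = 10))
  zero <- apply_strand_reward(cands, rte, reward = 0)
  expect_equal(zero$total_score, c(10, 10))

  once <- apply_strand_reward(cands, rte, reward = 5)
  expect_equal(once$total_score, c(15, 10))
  twice <- apply_strand_reward(once, rte, reward = 5)
  expect_equal(twice$total_score, c(15, 10))
})

test_that("distance to the tailoring enzyme uses nearest half-open ends", {
  rte <- mk_feat(1100, 2000)
  expect_equal(distance_from_te(1500L, 1600L, rte), 0L)   # inside
  expect_equal(distance_from_te(900L, 1000L, rte), 100L)  # gap of 100
  expect_equal(distance_from_te(900L, 1100L, rte), 0L)    # abutting
  expect_equal(distance_from_te(2300L, 2400L, rte), 300L) # right side
})

test_that("annotated short genes are wrapped below the maximum length only", {
  pep80 <- paste0("M", random_pep_str(79))
  pep130 <- paste0("M", random_pep_str(129))
  genes <- data.frame(feature_id = c("rte", "short", "long"),
                      start = c(200, 800, 1400), strand = 1L,
                      peptide = c(paste0("M", random_pep_str(150)), pep80, pep130),
                      stringsAsFactors = FALSE)
  reg <- toy_region(genes, length_nt = 4000, rte_id = "rte")
  model <- train_coding_model(reg)
  got <- collect_annotated_short_genes(reg, ripper_config(), model)
  expect_equal(nrow(got), 1)
  expect_equal(got$peptide, pep80)
  expect_true(got$annotated)
})

test_that("top-N plus threshold selection follows the documented rule", {
  tab <- function(scores, dists = seq_along(scores)) {
    d <- mk_cand(10 * seq_along(scores), 10 * seq_along(scores) + 63,
                 score = scores)
    d$distance_nt <- as.integer(dists)
    d
  }
  cfg <- ripper_config(fasta_output_limit = 3, prodigal_score_thresh = 15)

  got <- select_peptides(tab(c(20, 16, 10, 9, 3)), cfg)
  expect_equal(sort(got$total_score, decreasing = TRUE), c(20, 16, 10))

  got <- select_peptides(tab(c(20, 18, 16, 15, 9)), cfg)
  expect_equal(sort(got$total_score, decreasing = TRUE), c(20, 18, 16, 15))

  none <- tab(numeric(0))
  expect_equal(nrow(select_peptides(none, cfg)), 0)

  # everything beyond the distance window is invisible to selection
  far <- tab(c(20, 16, 10), dists = c(100, 9000, 100))
  got <- select_peptides(far, cfg)
  expect_setequal(got$total_score, c(20, 10))
})

test_that("selection equals the brute-force rule on randomized candidate sets", {
  set.seed(7)
  for (rep in 1:300) {
    n <- sample(0:12, 1)
    cfg <- ripper_config(
      fasta_output_limit = sample(0:4, 1),
      prodigal_score_thresh = runif(1, -5, 25),
      max_dist_from_te = sample(c(500L, 2000L, 8000L), 1))
    tab <- mk_cand(sample(1:2000, max(n, 1)),
                   sample(2001:4000, max(n, 1)),
                   score = round(runif(max(n, 1), -10, 30), 1))[seq_len(n), ]
    if (n) tab$distance_nt <- sample(0:10000, n, replace = TRUE)
    else tab$distance_nt <- integer(0)
    got <- select_peptides(tab, cfg)
    want <- oracle_select(tab, cfg$fasta_output_limit,
                          cfg$prodigal_score_thresh, cfg$max_dist_from_te)
    expect_equal(got$start, want$start)
    expect_equal(got$total_score, want$total_score)
  }
})

test_that("raising the score threshold never grows the retrieved set", {
  set.seed(13)
  tab <- mk_cand(sample(1:2000, 12), sample(2001:4000, 12),
                 score = runif(12, -5, 25))
  tab$distance_nt <- sample(0:10000, 12, replace = TRUE)
  prev <- Inf
  for (th in c(-10, 0, 7.5, 15, 50)) {
    got <- select_peptides(tab, ripper_config(prodigal_score_thresh = th))
    expect_lte(nrow(got), prev)
    prev <- nrow(got)
  }
})

test_that("distant rescue keeps only non-retrieved, domain-bearing peptides", {
  profiles <- list(toy_domain_profile())
  dom_pep <- paste0("MKL", rippmine:::DOMAIN_CORE_PEPTIDE, random_pep_str(20))
  plain_pep <- paste0("M", random_pep_str(35))

  all_c <- rbind(mk_cand(100, 200, score = 20, peptide = plain_pep),
                 mk_cand(9000, 9100, score = 3, peptide = dom_pep),
                 mk_cand(12000, 12100, score = 2, peptide = plain_pep))
  all_c$distance_nt <- c(100L, 8800L, 11800L)
  retrieved <- select_peptides(all_c, ripper_config())

  distant <- rescue_distant(all_c, retrieved, profiles)
  expect_equal(nrow(distant), 1)
  expect_equal(distant$start, 9000)
  expect_equal(distant$domains, "precursor_core_synthetic")

  # bucket exclusivity: a retrieved domain-bearing peptide is not "distant"
  all_c2 <- rbind(mk_cand(100, 200, score = 20, peptide = dom_pep))
  all_c2$distance_nt <- 100L
  r2 <- select_peptides(all_c2, ripper_config())
  expect_equal(nrow(rescue_distant(all_c2, r2, profiles)), 0)

  # no profiles, no rescue
  expect_equal(nrow(rescue_distant(all_c, retrieved, list())), 0)
})

test_that("peptide tables collate across regions and round-trip", {
  fx1 <- make_synthetic_region(region_spec(seed = 61))
  fx2 <- make_synthetic_region(region_spec(seed = 62))
  path <- tempfile(fileext = ".txt")

  empty <- rippmine:::as_retrieved(rippmine:::empty_candidates(),
                                   fx1$region, "retrieved")
  tabulate_peptides(empty, path)
  expect_equal(length(readLines(path)), 1)  # header only

  rows <- function(fx, n) {
    cand <- mk_cand(seq(100, by = 400, length.out = n),
                    seq(190, by = 400, length.out = n),
                    score = seq(10, 10 + n - 1),
                    peptide = vapply(seq_len(n), function(i)
                      paste0("M", random_pep_str(25)), character(1)))
    cand$distance_nt <- seq(500L, by = 100L, length.out = n)
    rippmine:::as_retrieved(cand, fx$region, "retrieved")
  }
  t1 <- rows(fx1, 3); t2 <- rows(fx2, 3)
  tabulate_peptides(t1, path)
  tabulate_peptides(t2, path, append = TRUE)
  back <- read_peptide_table(path)
  expect_equal(nrow(back), 6)
  expect_equal(unique(back$source_accession),
               c(fx1$region$accession, fx2$region$accession))
  expect_equal(back$peptide, c(t1$peptide, t2$peptide))
  expect_equal(back$distance_nt, c(t1$distance_nt, t2$distance_nt))
  expect_equal(back$score, round(c(t1$score, t2$score), 4))
})

test_that("configuration files override defaults key by key", {
  conf <- tempfile(fileext = ".conf")
  writeLines(c("# comment", "flankLen = 12500", "prodigalScoreThresh = 15",
               "fastaOutputLimit=5"), conf)
  cfg <- read_local_conf(conf)
  expect_equal(cfg$flank_len, 12500L)
  expect_equal(cfg$prodigal_score_thresh, 15)
  expect_equal(cfg$fasta_output_limit, 5L)
  expect_equal(cfg$same_strand_reward, 5)     # untouched default
  expect_equal(cfg$max_dist_from_te, 8000L)
  writeLines("bogusKey = 1", conf)
  expect_warning(read_local_conf(conf), "unknown configuration key")
})
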