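# Six-frame short-ORF enumeration and the self-trained coding model.

test_that("table-11 translation renders alternative starts and strips the stop", {
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_equal(translate_cds("GTGGCTTAA"), "MA")
  expect_equal(translate_cds("TTGGCT"), "MA")      # no stop present
  expect_error(translate_cds("ATGTAAGCTTAA"), "internal stop")
  expect_error(translate_cds("ATGCA"), "divisible by 3")
  # reverse strand
  expect_equal(translate_cds(oracle_revcomp("ATGGCTTAA"), strand = -1), "MA")
  # random stop-free frames agree with a character-by-character codon lookup
  set.seed(5)
  n_done <- 0
  while (n_done < 20) {
    nt <- random_dna_str(99)
    aa <- oracle_translate(nt)
    if (grepl("\\*", aa)) next
    expect_equal(translate_cds(nt), aa)
    n_done <- n_done + 1
  }
})

test_that("enumeration honors the 60 nt minimum and emits one candidate per start", {
  # no start codons at all
  r <- genomic_region("P1", strrep("A", 300))
  expect_equal(nrow(enumerate_orfs(r)), 0)

  # exactly 63 nt: ATG + 19 codons + stop -> single 20-aa forward candidate
  body <- strrep("GCT", 19)
  r <- genomic_region("P2", paste0(strrep("C", 30), "ATG", body, "TAA",
                                   strrep("C", 30)))
  orfs <- enumerate_orfs(r)
  fwd <- orfs[orfs$strand == 1, ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$start, 30)
  expect_equal(fwd$end, 30 + 63)
  expect_equal(fwd$peptide, paste0("M", strrep("A", 19)))

  # one codon shorter falls under the minimum
  r60 <- genomic_region("P3", paste0("ATG", strrep("GCT", 18), "TAA"))
  expect_equal(nrow(enumerate_orfs(r60)[enumerate_orfs(r60)$strand == 1, ]), 1)
  r57 <- genomic_region("P4", paste0("ATG", strrep("GCT", 17), "TAA"))
  expect_equal(sum(enumerate_orfs(r57)$strand == 1), 0)

  # two in-frame starts sharing one stop give two candidates
  r2 <- genomic_region("P5", paste0("ATG", strrep("GCT", 10), "GTG",
                                    strrep("GCT", 19), "TGA"))
  fwd2 <- enumerate_orfs(r2)
  fwd2 <- fwd2[fwd2$strand == 1, ]
  expect_equal(nrow(fwd2), 2)
  expect_equal(sort(nchar(fwd2$peptide)), c(20, 31))
})

test_that("enumeration equals the exhaustive six-frame oracle on random sequences", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(c(150, 240, 400), 1)
    seqs <- random_dna_str(n, gc = runif(1, 0.35, 0.7))
    got <- enumerate_orfs(genomic_region("R", seqs))
    want <- oracle_orfs(seqs)
    expect_equal(got[c("start", "end", "strand", "peptide")],
                 want, ignore_attr = TRUE)
  }
})

test_that("training hexamer counts match a brute-force counter on a toy region", {
  genes <- data.frame(
    feature_id = c("g1", "g2", "g3"),
    start = c(100, 800, 1600), strand = c(1, -1, 1),
    peptide = c(random_pep_str(120), random_pep_str(150), random_pep_str(110)),
    stringsAsFactors = FALSE)
  genes$peptide <- paste0("M", substr(genes$peptide, 2, nchar(genes$peptide)))
  reg <- toy_region(genes)
  model <- train_coding_model(reg)
  expect_true(model$trained)
  expect_equal(model$training_cds_count, 3)

  # brute-force in-frame hexamer count over the same spans (coding strand,
  # step 3, stop codon span included)
  counts <- integer(0)
  for (i in 1:3) {
    f <- reg$features[reg$features$feature_id == genes$feature_id[i], ]
    s <- substr(reg$sequence, f$start + 1, f$end)
    if (f$strand < 0) s <- oracle_revcomp(s)
    for (p in seq(1, nchar(s) - 5, by = 3)) {
      h <- substr(s, p, p + 5)
      counts[h] <- (if (is.na(counts[h])) 0L else counts[h]) + 1L
    }
  }
  # recover counts from the smoothed log-odds by inverting the formula
  bg <- model$bg_freq
  tot_cod <- sum(counts)
  for (h in names(counts)) {
    implied <- exp(model$hexamer_logodds[[h]]) * bg[[h]] * (tot_cod + 4096) - 1
    expect_equal(implied, counts[[h]], tolerance = 1e-6)
  }
})

test_that("regions with too few training genes give a flagged zero model", {
  r <- genomic_region("NOCDS", random_dna_str(2000))
  model <- train_coding_model(r)
  expect_false(model$trained)
  expect_true(all(model$hexamer_logodds == 0))
  orfs <- enumerate_orfs(r)
  scored <- score_candidates(orfs, model, r)
  if (nrow(scored)) {
    expect_true(all(scored$coding_score == 0))
    expect_true(all(grepl("untrained", scored$notes)))
  }
})

test_that("a hand-filled model scores a small ORF to the hand-summed value", {
  # region: 9-codon ORF (incl stop) with known upstream window
  up <- "CCCCCCAGGAGGCCCCCCCCC"  # motif AGGAGG at spacer 9
  orf <- paste0("ATG", "GCTGCTGCTGCTGCTGCTGCT", "TAA")
  reg <- genomic_region("H1", paste0(up, orf, strrep("C", 30)))
  model <- structure(list(
    hexamer_logodds = stats::setNames(numeric(4096), rippmine:::all_hexamers()),
    rbs_weights = c("AGGAGG:9" = 2.5),
    start_weights = c(ATG = 0.7, GTG = -0.1, TTG = -0.3),
    bg_freq = NULL, trained = TRUE, training_cds_count = 3
  ), class = "coding_model")
  model$hexamer_logodds[c("ATGGCT", "GCTGCT")] <- c(1.25, 0.5)
  cand <- enumerate_orfs(reg, min_nt = 27)
  cand <- cand[cand$strand == 1 & cand$start == 21, ]
  got <- score_candidates(cand, model, reg)
  # in-frame hexamers of the coding part: ATGGCT + 6x GCTGCT
  coding <- 1.25 + 6 * 0.5
  expect_equal(got$coding_score, coding)
  expect_equal(got$rbs_score, 2.5)
  expect_equal(got$start_bonus, 0.7)
  expect_equal(got$total_score, 0.55 * (coding + 2.5 + 0.7), tolerance = 1e-9)
})

test_that("an ORF with background hexamer composition has zero coding component", {
  reg <- genomic_region("B1", paste0("ATG", strrep("GCA", 30), "TAA"))
  model <- structure(list(
    hexamer_logodds = stats::setNames(numeric(4096), rippmine:::all_hexamers()),
    rbs_weights = numeric(0), start_weights = c(ATG = 0, GTG = 0, TTG = 0),
    bg_freq = NULL, trained = TRUE, training_cds_count = 3
  ), class = "coding_model")
  got <- score_candidates(enumerate_orfs(reg), model, reg)
  expect_true(all(got$coding_score == 0))
})

test_that("scores are invariant under reverse-complementing the region", {
  planted <- data.frame(length_aa = 40L, dist_nt = 3000L, strand = 1L,
                        has_domain = FALSE)
  fx <- make_synthetic_region(region_spec(seed = 77, planted = planted))
  reg <- fx$region
  L <- nchar(reg$sequence)
  f2 <- reg$features
  tmp <- L - f2$end
  f2$end <- L - f2$start
  f2$start <- tmp
  f2$strand <- -f2$strand
  reg2 <- genomic_region(reg$accession, oracle_revcomp(reg$sequence), f2,
                         rte_feature_id = reg$rte_feature_id,
                         organism = reg$organism)
  m1 <- train_coding_model(reg)
  m2 <- train_coding_model(reg2)
  c1 <- score_candidates(enumerate_orfs(reg), m1, reg)
  c2 <- score_candidates(enumerate_orfs(reg2), m2, reg2)
  # mirror c2 onto c1 coordinates
  c2m <- c2
  tmp <- L - c2$end
  c2m$end <- L - c2$start; c2m$start <- tmp; c2m$strand <- -c2$strand
  key1 <- paste(c1$start, c1$end, c1$strand)
  key2 <- paste(c2m$start, c2m$end, c2m$strand)
  expect_setequal(key1, key2)
  o <- match(key1, key2)
  expect_equal(c1$total_score, c2m$total_score[o], tolerance = 1e-9)
})

test_that("planted precursors outscore random intergenic candidates", {
  # shuffle-control flavor: across seeded fixtures the planted gene's score
  # exceeds the median score of surviving intergenic candidates
  wins <- 0L
  n_seeds <- 12L
  for (s in seq_len(n_seeds)) {
    planted <- data.frame(length_aa = 50L, dist_nt = 3000L, strand = 1L,
                          has_domain = FALSE)
    fx <- make_synthetic_region(region_spec(seed = 9000 + s, planted = planted))
    reg <- fx$region
    model <- train_coding_model(reg)
    cands <- score_candidates(enumerate_orfs(reg), model, reg)
    cands <- filter_candidates(cands, reg$features, ripper_config())
    hit <- cands[cands$start == fx$truth$start & cands$end == fx$truth$end &
                   cands$strand == fx$truth$strand, ]
    expect_equal(nrow(hit), 1)
    others <- cands$total_score[cands$start != fx$truth$start]
    if (hit$total_score > stats::median(others)) wins <- wins + 1L
  }
  expect_gte(wins / n_seeds, 0.9)
})

test_that("a trained model round-trips through its plain-text dump", {
  genes <- data.frame(feature_id = c("g1", "g2", "g3"),
                      start = c(100, 800, 1600), strand = c(1, 1, -1),
                      peptide = paste0("M", c(random_pep_str(119),
                                              random_pep_str(139),
                                              random_pep_str(109))),
                      stringsAsFactors = FALSE)
  reg <- toy_region(genes, seed = 3)
  model <- train_coding_model(reg)
  path <- tempfile()
  write_coding_model(model, path)
  back <- read_coding_model(path)
  expect_equal(back$hexamer_logodds, model$hexamer_logodds, tolerance = 1e-8)
  expect_equal(sort(names(back$rbs_weights)), sort(names(model$rbs_weights)))
  expect_equal(back$start_weights, model$start_weights, tolerance = 1e-8)
  expect_equal(back$trained, model$trained)
})
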