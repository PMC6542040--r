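small_db <- function() {
  data.frame(
    accession = c("P1", "P2", "P3"),
    symbol = c("Alpha", "Beta", "Gamma"),
    source = c("MEROPS", "SignalP", "MEROPS,SignalP"),
    description = "",
    sequence = c("MKWVTFISLLLLFSSAYSRGVFRRDTHKSEIAHRFKDLGE",
                 "LPFKNLDEQLAHQNMVKTESSARNPLE",
                 "QDALSGSSDLLELLLQEDSRGGKKWQ"),
    stringsAsFactors = FALSE)
}

test_that("index prefix arrays are exact substring-mass oracles", {
  db <- small_db()
  idx <- build_index(db)
  expect_length(idx$prefixes, 3L)
  for (k in 1:3) {
    p <- idx$prefixes[[k]]
    expect_equal(p[1L], 0)
    expect_length(p, nchar(db$sequence[k]) + 1L)
    expect_true(all(diff(p) > 0))
  }
  set.seed(3)
  for (rep in 1:200) {
    pi <- sample(1:3, 1L)
    L <- nchar(db$sequence[pi])
    i <- sample(L, 1L); j <- i + sample.int(L - i + 1L, 1L) - 1L
    expect_equal(substring_mass(idx, pi, i, j),
                 residue_mass_sum(substr(db$sequence[pi], i, j)),
                 tolerance = 1e-9)
  }
  expect_error(build_index(db[0, ]), "empty")
  dup <- rbind(db, db[1, ])
  expect_error(build_index(dup), "duplicate")
})

test_that("candidate generation equals exhaustive substring enumeration", {
  db <- small_db()
  idx <- build_index(db)
  # known peptide: found at its own MH+
  mh <- peptide_mh("LPFKNL")
  cand <- candidate_peptides(mh, idx)
  expect_true("LPFKNL" %in% cand$sequence)
  expect_lte(max(abs(cand$ppm)), 6)
  # far precursor: empty
  expect_equal(nrow(candidate_peptides(150.0, idx)), 0L)
  expect_error(candidate_peptides(-1, idx), "positive")

  # oracle equivalence over a grid of precursors
  set.seed(17)
  probes <- c(vapply(1:15, function(i) {
    pi <- sample(1:3, 1L)
    L <- nchar(db$sequence[pi])
    i0 <- sample(L - 6L, 1L); j0 <- min(L, i0 + sample(5:20, 1L))
    peptide_mh(substr(db$sequence[pi], i0, j0)) * (1 + runif(1, -4, 4) / 1e6)
  }, 0), runif(10, 600, 3000))
  for (mh in probes) {
    got <- candidate_peptides(mh, idx)
    want <- oracle_candidates(mh, db)
    expect_setequal(got$sequence, unique(want$sequence))
  }
})

test_that("PSM scoring rewards the true ladder and ignores unmatched candidates", {
  sp <- synthesize_spectra("LPFKNL", frag_sampling = 1,
                           precursor_ppm_jitter = 0, product_ppm_jitter = 0,
                           noise_peaks = 0, seed = 1)[[1L]]
  res <- score_psm(sp, "LPFKNL")
  expect_equal(res$n_b, 5L)
  expect_equal(res$n_y, 5L)
  expect_gt(res$score, 0)
  expect_lt(res$max_product_ppm, 1e-6)

  # candidate sharing no fragments scores zero
  res0 <- score_psm(sp, "WWWWHHHH")
  expect_equal(res0$score, 0)
  expect_equal(res0$n_b + res0$n_y, 0L)
})

test_that("true sequences outscore shuffled decoy sequences", {
  set.seed(23)
  wins <- 0L
  n_trials <- 200L
  peps <- vapply(seq_len(n_trials), function(i) random_peptide(sample(8:25, 1L)), "")
  spectra <- synthesize_spectra(peps, seed = 24)
  for (i in seq_len(n_trials)) {
    true_score <- score_psm(spectra[[i]], peps[i])$score
    shuf <- paste(sample(strsplit(peps[i], "")[[1L]]), collapse = "")
    if (shuf == peps[i]) { wins <- wins + 1L; next }
    if (true_score > score_psm(spectra[[i]], shuf)$score) wins <- wins + 1L
  }
  expect_gte(wins / n_trials, 0.95)
})

test_that("decoy database preserves length, composition and total mass", {
  db <- build_toy_substrate_db()
  dec <- decoy_db(db, seed = 7)
  expect_equal(nchar(dec$sequence), nchar(db$sequence))
  for (k in seq_len(nrow(db))) {
    expect_equal(sort(strsplit(dec$sequence[k], "")[[1L]]),
                 sort(strsplit(db$sequence[k], "")[[1L]]))
    expect_equal(residue_mass_sum(dec$sequence[k]),
                 residue_mass_sum(db$sequence[k]), tolerance = 1e-9)
  }
  expect_true(all(startsWith(dec$accession, "DECOY_")))
  # deterministic
  expect_identical(decoy_db(db, seed = 7), dec)
})

test_that("target best scores dominate decoy best scores on true spectra", {
  db <- small_db()
  idx <- build_index(db)
  set.seed(29)
  seqs <- vapply(1:100, function(i) {
    pi <- sample(1:3, 1L)
    L <- nchar(db$sequence[pi])
    i0 <- sample(L - 8L, 1L)
    substr(db$sequence[pi], i0, min(L, i0 + sample(7:15, 1L)))
  }, "")
  spectra <- synthesize_spectra(seqs, seed = 30)
  res <- decoy_search(spectra, idx)
  expect_gt(nrow(res$target), 0L)
  mw <- wilcox.test(res$target$score, res$decoy$score, alternative = "greater")
  expect_lt(mw$p.value, 0.01)
})

test_that("FDR thresholding follows the decoy/target tail ratio", {
  t_tab <- data.table::data.table(title = sprintf("t%d", 1:4),
                                  score = c(10, 8, 6, 4))
  # all decoys above all targets -> nothing accepted
  d_hi <- data.table::data.table(score = c(20, 19, 18, 17, 16))
  none <- fdr_threshold(t_tab, d_hi, 0.10)
  expect_false(any(none$accepted))
  # zero decoys above the top target -> top target accepted at q = 0
  d_lo <- data.table::data.table(score = c(5, 3))
  some <- fdr_threshold(t_tab, d_lo, 0.10)
  expect_equal(some$q_value[1L], 0)
  expect_true(some$accepted[1L])
  # q values are monotone nonincreasing in score
  expect_true(all(diff(some$q_value) >= 0))
  # empty input passes through
  empty <- fdr_threshold(t_tab[0], d_lo, 0.10)
  expect_equal(nrow(empty), 0L)
})

test_that("accepted matches respect the 6/12 ppm containment limits", {
  db <- small_db()
  idx <- build_index(db)
  set.seed(31)
  seqs <- c("LPFKNLDEQ", "MKWVTFISLL", "QDALSGSSDLLE")
  spectra <- synthesize_spectra(seqs, seed = 32)
  res <- decoy_search(spectra, idx)
  out <- fdr_threshold(res$target, res$decoy, 0.10)
  acc <- out[out$accepted]
  expect_gt(nrow(acc), 0L)
  expect_lte(max(abs(acc$precursor_ppm)), 6)
  expect_lte(max(acc$max_product_ppm, na.rm = TRUE), 12)
})

test_that("annotation reports provenance and round-trips coordinates", {
  db <- build_toy_substrate_db()
  idx <- build_index(db)
  tsp <- "QQRGRSCDVTSNTCLGPSLQTRTCSLGKCDTRLRQNGGWSHWSPWSSCSVTCGVGNVTR"
  expect_equal(nchar(tsp), 59L)
  sp <- synthesize_spectra(tsp, frag_sampling = 0.9, seed = 33)[[1L]]
  best <- peptidome:::.best_match(sp, idx, 6, 12, c(6, 80))
  expect_equal(best$sequence, tsp)
  ann <- annotate_match(best, idx)
  expect_equal(ann$symbol, "Thbs2")
  expect_equal(ann$source, "MEROPS")
  expect_equal(substr(db$sequence[best$protein], ann$start, ann$end), tsp)
  expect_equal(ann$peptide_mass, 6737.0870, tolerance = 1e-3 / 6737)

  # printed theoretical mass for a known row
  expect_equal(residue_mass_sum("PPASVVVGPVVVPR"), 1353.8132,
               tolerance = 5e-4 / 1353)
})
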