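test_that("gap-containing columns are excluded from the match states", {
  rows <- c(r1 = "ACDEFGHIKL", r2 = "AC-EFGHIKL", r3 = "ACDEFGHIK-")
  hmm <- build_profile(seed_alignment(rows))
  expect_identical(hmm$n_match, 8L) # columns 3 and 10 carry gaps
  expect_identical(hmm$retained_columns, c(1:2, 4:9))

  gapless <- c(r1 = "ACDEFG", r2 = "AWDEFG")
  expect_identical(build_profile(seed_alignment(gapless))$n_match, 6L)

  allgap <- c(r1 = "A-", r2 = "-C")
  expect_error(build_profile(seed_alignment(allgap)), "no match states")

  # fractional-occupancy option retains minority-gap columns
  hmm2 <- build_profile(seed_alignment(rows), max_gap_frac = 0.5)
  expect_identical(hmm2$n_match, 10L)
})

test_that("match emissions equal pseudocount-smoothed observed frequencies", {
  rows <- c(r1 = "AC", r2 = "AC", r3 = "WC")
  w <- 2
  hmm <- build_profile(seed_alignment(rows), pseudocount_weight = w)
  bg <- aa_background()
  expect_equal(unname(hmm$match_probs[1, "A"]), unname((2 + w * bg[["A"]]) / (3 + w)))
  expect_equal(unname(hmm$match_probs[1, "W"]), (1 + w * bg[["W"]]) / (3 + w))
  expect_equal(unname(hmm$match_probs[1, "C"]), (0 + w * bg[["C"]]) / (3 + w))
  expect_equal(unname(hmm$match_probs[2, "C"]), (3 + w * bg[["C"]]) / (3 + w))
  # rows re-normalise exactly
  expect_equal(unname(rowSums(hmm$match_probs)), c(1, 1), tolerance = 1e-12)
})

test_that("emission and transition rows normalise after exponentiation", {
  hmm <- random_hmm(6, n_rows = 5, seed = 3)
  expect_equal(unname(rowSums(hmm$match_probs)), rep(1, 6), tolerance = 1e-12)
  tr <- hmm$transitions
  expect_equal(unname(2^tr$mm + 2^tr$mi + 2^tr$md), rep(1, 5),
               tolerance = 1e-12)
  expect_equal(unname(2^tr$im + 2^tr$ii), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(2^tr$dm + 2^tr$dd), rep(1, 5), tolerance = 1e-12)
})

test_that("Viterbi equals exhaustive path enumeration on small models", {
  set.seed(11)
  for (K in 1:4) {
    hmm <- random_hmm(K, n_rows = 3, seed = 100 + K)
    for (rep in 1:8) {
      L <- sample(1:6, 1)
      s <- random_proteins(1, L)
      got <- viterbi_score(hmm, s)$score_bits
      want <- oracle_viterbi_score(hmm, s)
      expect_equal(got, want, tolerance = 1e-9, info = paste(K, s))
    }
  }
})

test_that("scoring the consensus of a conserved seed is strictly positive", {
  rows <- setNames(rep("ACDEFGHIKLMNPQ", 4), paste0("r", 1:4))
  hmm <- build_profile(seed_alignment(rows))
  hit <- viterbi_score(hmm, hmm$consensus)
  expect_gt(hit$score_bits, 0)
  expect_equal(hit$envelope, c(0L, nchar(hmm$consensus)))
})

test_that("background flanks never decrease the local score", {
  set.seed(21)
  hmm <- random_hmm(8, n_rows = 4, seed = 9)
  core <- hmm$consensus
  base <- viterbi_score(hmm, core)$score_bits
  for (rep in 1:5) {
    flank_l <- random_proteins(1, 50)
    flank_r <- random_proteins(1, 50)
    expect_gte(viterbi_score(hmm, paste0(flank_l, core, flank_r))$score_bits,
               base - 1e-9)
  }
})

test_that("unknown residues score as background and cannot create hits", {
  hmm <- random_hmm(5, n_rows = 4, seed = 13)
  s <- hmm$consensus
  sx <- paste0(substr(s, 1, 2), "X", substr(s, 4, 5))
  expect_lt(viterbi_score(hmm, sx)$score_bits,
            viterbi_score(hmm, s)$score_bits)
  expect_equal(viterbi_score(hmm, "XXXXX")$score_bits, 0, tolerance = 1e-9)
  expect_error(viterbi_score(hmm, ""), "empty")
})

test_that("column information content matches direct relative entropy", {
  hmm <- random_hmm(4, n_rows = 5, seed = 17)
  info <- column_information(hmm)
  bg <- aa_background()
  for (k in 1:4) {
    p <- hmm$match_probs[k, ]
    expect_equal(info$bits[[k]], sum(p * log2(p / bg)), tolerance = 1e-12)
  }
  # a column emitting the background has zero information
  p_bg <- matrix(bg, 1, 20, dimnames = list(NULL, names(bg)))
  hmm0 <- hmm; hmm0$match_probs <- p_bg
  hmm0$match_logodds <- log2(sweep(p_bg, 2, bg, "/"))
  expect_equal(column_information(hmm0)$bits[[1]], 0, tolerance = 1e-12)
  # a degenerate single-residue column approaches log2(20) at uniform bg
  p1 <- matrix(c(1, rep(0, 19)), 1, 20, dimnames = list(NULL, names(bg)))
  hmmu <- hmm
  hmmu$background <- setNames(rep(1 / 20, 20), names(bg))
  expect_equal(sum(p1 * log2(pmax(p1, 1e-300) / (1 / 20)), na.rm = TRUE),
               log2(20), tolerance = 1e-9)
})

test_that("threshold calibration separates seed from null and is reproducible", {
  sim <- simulate_proteomes(benchmark_tree_5sp(), benchmark_params(),
                            n_families = 4, seed = 31, decoy_factor = 0)
  seed_aln <- truth_seed_alignment(sim, max_rows = 20)
  hmm <- build_profile(seed_aln)
  cal1 <- calibrate_threshold(hmm, seed_aln, null_samples = 300, seed_rng = 5)
  cal2 <- calibrate_threshold(hmm, seed_aln, null_samples = 300, seed_rng = 5)
  expect_identical(cal1$threshold_bits, cal2$threshold_bits)
  expect_gt(cal1$min_seed_score, cal1$null_quantile)
  expect_gt(cal1$threshold_bits, cal1$null_quantile)
  expect_lt(cal1$threshold_bits, cal1$min_seed_score)
})

test_that("scan results shrink monotonically in the threshold and vanish at +Inf", {
  sim <- simulate_proteomes(benchmark_tree_5sp(), benchmark_params(),
                            n_families = 3, seed = 37, decoy_factor = 1)
  seed_aln <- truth_seed_alignment(sim, max_rows = 12)
  hmm <- build_profile(seed_aln)
  h1 <- scan_proteomes(hmm, sim$proteomes, threshold = 50)
  h2 <- scan_proteomes(hmm, sim$proteomes, threshold = 150)
  h3 <- scan_proteomes(hmm, sim$proteomes, threshold = Inf)
  expect_true(all(h2$protein_id %in% h1$protein_id))
  expect_gte(nrow(h1), nrow(h2))
  expect_identical(nrow(h3), 0L)
  expect_error(scan_proteomes(hmm, sim$proteomes), "threshold")
})
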