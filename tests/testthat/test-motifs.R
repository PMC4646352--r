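test_that("the diagnostic family patterns compile to the expected element sets", {
  a <- compile_pattern("GxxFxP")
  expect_identical(a$length, 6L)
  expect_identical(a$elements[[1]], "G")
  expect_length(a$elements[[2]], 20)
  expect_length(a$elements[[3]], 20)
  expect_identical(a$elements[[4]], "F")
  expect_identical(a$elements[[6]], "P")

  lp <- compile_pattern("LP[QX]L[ED]SP")
  expect_identical(lp$length, 7L)
  expect_length(lp$elements[[3]], 20) # X-in-bracket is a wildcard
  expect_setequal(lp$elements[[5]], c("E", "D"))

  wq <- compile_pattern("W[RA]ALD[KR][FL][VL]ASQL")
  expect_identical(wq$length, 12L)
  expect_setequal(wq$elements[[2]], c("R", "A"))
  expect_setequal(wq$elements[[6]], c("K", "R"))

  expect_identical(compile_pattern("WxMHEY")$length, 6L)
})

test_that("malformed patterns are rejected with positional errors", {
  expect_error(compile_pattern("["), "unbalanced")
  expect_error(compile_pattern("A]B"), "unbalanced")
  expect_error(compile_pattern("A[]"), "empty bracket")
  expect_error(compile_pattern("AB1"), "illegal residue")
  expect_error(compile_pattern("A[BZ]"), "illegal residue")
  expect_error(compile_pattern(""), "empty pattern")
})

test_that("motif scanning matches and rejects the constructed examples", {
  lp <- compile_pattern("LP[QX]L[ED]SP", name = "LP-box")
  hit <- scan_motif(lp, "MMMLPQLESPWW")
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start, 3L)
  expect_identical(hit$match, "LPQLESP")
  # wildcard position accepts any residue; [ED] position does not
  expect_identical(nrow(scan_motif(lp, "MMMLPWLDSPWW")), 1L)
  expect_identical(nrow(scan_motif(lp, "MMMLPQLKSPWW")), 0L)

  am <- compile_pattern("GxxFxP")
  expect_identical(nrow(scan_motif(am, "GKRFHP")), 1L)
  expect_identical(nrow(scan_motif(am, "GKRYHP")), 0L)

  wq <- compile_pattern("W[RA]ALD[KR][FL][VL]ASQL")
  expect_identical(nrow(scan_motif(wq, "AAWRALDKFVASQLAA")), 1L)
  expect_identical(nrow(scan_motif(wq, "AAWWALDKFVASQLAA")), 0L)

  dm <- compile_pattern("WxMHEY")
  expect_identical(nrow(scan_motif(dm, "AAWKMHEYAA")), 1L)
  expect_identical(nrow(scan_motif(dm, "AAWKMHEWAA")), 0L)
})

test_that("exhaustive scanning equals the brute-force checker and leftmost rule holds", {
  set.seed(61)
  pat <- compile_pattern("G[AV]x[ILV]")
  for (rep in 1:40) {
    s <- random_proteins(1, 60)
    all_hits <- scan_motif(pat, s, mode = "exhaustive")
    expect_identical(all_hits$start, oracle_motif_positions(pat, s))
    one <- scan_motif(pat, s)
    if (nrow(all_hits) > 0) {
      expect_identical(one$start, all_hits$start[1])
    } else {
      expect_identical(nrow(one), 0L)
    }
  }
})

test_that("hydropathy windows match the direct-summation oracle", {
  set.seed(67)
  for (rep in 1:20) {
    s <- random_proteins(1, sample(19:80, 1))
    means <- oracle_window_means(s, 19)
    tm <- predict_tm(s)
    above <- which(means > 1.6)
    expect_identical(tm$has_tmm, length(above) > 0)
    if (nrow(tm$segments) > 0) {
      # segments cover exactly the above-cutoff windows
      covered <- unlist(lapply(seq_len(nrow(tm$segments)), function(i)
        seq(tm$segments$start[i] + 1, tm$segments$end[i] - 19 + 1)))
      expect_setequal(covered, above)
      # merged segments never overlap
      if (nrow(tm$segments) > 1) {
        expect_true(all(tm$segments$start[-1] >=
                          tm$segments$end[-nrow(tm$segments)]))
      }
    }
  }
})

test_that("hydropathy extremes behave as constructed", {
  allI <- strrep("I", 19)
  tm <- predict_tm(allI)
  expect_true(tm$has_tmm)
  expect_identical(nrow(tm$segments), 1L)
  expect_equal(tm$segments$mean_hydropathy, 4.5)
  expect_identical(tm$segments$start, 0L)
  expect_identical(tm$segments$end, 19L)

  expect_false(predict_tm(strrep("D", 19))$has_tmm)
  expect_false(predict_tm("ILVF")$has_tmm) # shorter than the window
})

test_that("TM truth flags agree with the predictor on simulator output", {
  tree <- benchmark_tree_5sp()
  for (p_tm in c(0, 1)) {
    params <- benchmark_params(dup_rate = 0, loss_rate = 0,
                               tm_insertion_prob = p_tm)
    set.seed(71 + p_tm)
    n_match <- 0; n_tot <- 0
    for (f in 1:10) {
      h <- evolve_family(tree, params)
      em <- emit_sequences(h, params)
      for (i in seq_along(em$sequences)) {
        pred <- predict_tm(em$sequences[[i]])$has_tmm
        n_match <- n_match + (pred == em$truth$has_tm[i])
        n_tot <- n_tot + 1
      }
    }
    expect_gte(n_match / n_tot, 0.99)
  }
})

test_that("motif files round-trip and annotation flags are consistent", {
  tf <- tempfile()
  writeLines(c("# comment", "LP-box\tLP[QX]L[ED]SP", "A-motif\tGxxFxP"), tf)
  pats <- read_motifs(tf)
  expect_named(pats, c("LP-box", "A-motif"))
  p <- proteome(c(x1 = paste0("MMMLPQLESP", strrep("I", 21), "GKRFHP"),
                  x2 = strrep("D", 40)), "X")
  ann <- annotate_proteins(p, motifs = pats)
  expect_true(ann$`LP-box`[ann$protein_id == "x1"])
  expect_true(ann$`A-motif`[ann$protein_id == "x1"])
  expect_true(ann$has_tmm[ann$protein_id == "x1"])
  expect_false(any(unlist(ann[ann$protein_id == "x2",
                              c("LP-box", "A-motif", "has_tmm")])))
})
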