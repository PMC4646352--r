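make_proteome_pair <- function(n = 4, len = 260, seed = 1) {
  set.seed(seed)
  seqs <- random_proteins(n, len)
  names(seqs) <- paste0("A_g", seq_len(n))
  a <- proteome(seqs, "A")
  copies <- seqs
  names(copies) <- paste0("B_g", seq_len(n))
  b <- proteome(copies, "B")
  list(a = a, b = b)
}

test_that("a proteome against an identical copy pairs every gene with its twin", {
  pp <- make_proteome_pair(n = 4, seed = 5)
  hits <- all_vs_all(pp$a, pp$b)
  # every protein has a passing self-counterpart
  expect_length(attr(hits, "ruled_out"), 0)
  rbh <- reciprocal_best_hits(hits, "A", "B")
  expect_identical(nrow(rbh), 4L)
  expect_identical(sub("A_", "", rbh$gene_a), sub("B_", "", rbh$gene_b))
})

test_that("unrelated random proteomes yield an essentially empty hit table", {
  set.seed(9)
  a <- proteome(setNames(random_proteins(40, 100), paste0("A_", 1:40)), "A")
  b <- proteome(setNames(random_proteins(40, 100), paste0("B_", 1:40)), "B")
  hits <- all_vs_all(a, b) # 1600 random pairs
  expect_identical(nrow(hits), 0L)
  expect_length(attr(hits, "ruled_out"), 80)
})

test_that("best-hit resolution reproduces the worked 3-gene example", {
  hits <- data.frame(
    query = c("A1", "A1", "B1", "B2"),
    subject = c("B1", "B2", "A1", "A1"),
    query_species = c("A", "A", "B", "B"),
    subject_species = c("B", "B", "A", "A"),
    raw_score = 0L, bit_score = c(300, 250, 300, 260),
    identity = c(0.9, 0.8, 0.9, 0.85), qcov = 1, scov = 1,
    qstart = 0L, qend = 1L, sstart = 0L, send = 1L,
    stringsAsFactors = FALSE)
  rbh <- reciprocal_best_hits(hits, "A", "B")
  expect_identical(nrow(rbh), 1L)
  expect_identical(rbh$gene_a, "A1")
  expect_identical(rbh$gene_b, "B1")
  expect_error(reciprocal_best_hits(hits[1:2, ], "A", "B"), "direction")
})

test_that("RBH output is a symmetric partial matching on simulated data", {
  sim <- simulate_proteomes(benchmark_tree_5sp(), benchmark_params(),
                            n_families = 8, seed = 43, decoy_factor = 0)
  a <- sim$proteomes$A; b <- sim$proteomes$B
  expect_true(length(a) >= 2 && length(b) >= 2)
  hits <- all_vs_all(a, b)
  rbh <- reciprocal_best_hits(hits, "A", "B")
  expect_identical(anyDuplicated(rbh$gene_a), 0L)
  expect_identical(anyDuplicated(rbh$gene_b), 0L)
  # swapping the species yields the same unordered pairs
  rbh_rev <- reciprocal_best_hits(hits, "B", "A")
  expect_setequal(paste(rbh$gene_a, rbh$gene_b),
                  paste(rbh_rev$gene_b, rbh_rev$gene_a))
})

test_that("OG assembly builds presence rows and reports pivot-specific genes", {
  rbh_b <- data.frame(gene_a = c("P_g1", "P_g2"), gene_b = c("B_g1", "B_g2"),
                      bits_ab = c(300, 280), bits_ba = c(300, 275),
                      stringsAsFactors = FALSE)
  rbh_c <- data.frame(gene_a = "P_g1", gene_b = "C_g9",
                      bits_ab = 260, bits_ba = 255, stringsAsFactors = FALSE)
  og <- build_ogs(list(B = rbh_b, C = rbh_c), pivot_id = "P",
                  pivot_genes = c("P_g1", "P_g2", "P_g3"),
                  lineages = list(clade = c("B", "C")))
  expect_identical(length(og$anchors), 2L)
  expect_identical(colnames(og$presence), c("P", "B", "C"))
  expect_identical(unname(og$presence["OG_P_g1", ]), c(1L, 1L, 1L))
  expect_identical(unname(og$presence["OG_P_g2", ]), c(1L, 1L, 0L))
  expect_identical(og$pivot_specific, "P_g3")
  expect_identical(og$core$clade, "OG_P_g1")
  # presence row sums match the member counts in the OG table
  for (ogid in rownames(og$presence)) {
    expect_identical(sum(og$presence[ogid, ]),
                     sum(og$ogs$og_id == ogid))
  }
})

test_that("paralog attachment is exclusive and follows the best within-species hit", {
  og <- build_ogs(list(B = data.frame(gene_a = "P_g1", gene_b = "B_g1",
                                      bits_ab = 300, bits_ba = 300)),
                  pivot_id = "P", pivot_genes = "P_g1")
  within <- list(B = data.frame(
    query = c("B_g2", "B_g2"), subject = c("B_g1", "B_g3"),
    query_species = "B", subject_species = "B",
    raw_score = 0L, bit_score = c(280, 500), identity = c(0.8, 0.95),
    qcov = 1, scov = 1, qstart = 0L, qend = 1L, sstart = 0L, send = 1L,
    stringsAsFactors = FALSE))
  # best hit of B_g2 is B_g3 (not an OG member): no attachment happens there,
  # but attachment considers only hits onto members, so B_g2 -> B_g1
  out <- attach_paralogs(og, within)
  para <- out$ogs[out$ogs$role == "paralog", ]
  expect_identical(para$member_id, "B_g2")
  expect_identical(para$og_id, "OG_P_g1")
  expect_identical(out$presence["OG_P_g1", "B"], 2L)
  # no within hits: unchanged
  out2 <- attach_paralogs(og, list())
  expect_identical(out2$ogs, og$ogs)
})

test_that("a retained WGD copy is attached as exactly one paralog", {
  tree <- species_tree("((A:0.5,B:0.5):0.5,C:1);",
                       wgd = data.frame(child = "A", frac = 0.5,
                                        retention = 1))
  params <- simulation_params(dup_rate = 0, loss_rate = 0,
                              base_subs_rate = 0.2, tm_insertion_prob = 0)
  set.seed(47)
  h <- evolve_family(tree, params)
  em <- emit_sequences(h, params)
  ids <- names(em$sequences)
  sp <- setNames(em$truth$species, em$truth$id)
  prot <- lapply(c("A", "B", "C"), function(s)
    proteome(em$sequences[sp[ids] == s], s))
  names(prot) <- c("A", "B", "C")
  expect_identical(length(prot$A), 2L) # WGD doubled species A
  hits_ab <- all_vs_all(prot$A, prot$B)
  rbh <- reciprocal_best_hits(hits_ab, "B", "A")
  og <- build_ogs(list(A = rbh), pivot_id = "B",
                  pivot_genes = names(prot$B))
  within_a <- all_vs_all(prot$A, prot$A)
  out <- attach_paralogs(og, list(A = within_a))
  para <- out$ogs[out$ogs$role == "paralog", ]
  expect_identical(nrow(para), 1L)
  expect_identical(unname(sp[para$member_id]), "A")
})

test_that("Venn regions match brute-force set arithmetic and sum to the union", {
  set.seed(53)
  for (rep in 1:100) {
    n <- sample(2:4, 1)
    universe <- paste0("x", 1:15)
    sets <- lapply(seq_len(n), function(i)
      sample(universe, sample(0:12, 1)))
    names(sets) <- paste0("S", seq_len(n))
    got <- venn_regions(sets)
    want <- oracle_venn(sets)
    expect_identical(unname(got), want)
    expect_identical(sum(got), length(unique(unlist(sets))))
  }
})

test_that("disjoint OG collections give zero BOGs and an empty core region", {
  bogs <- intersect_bogs(list(p1 = c("O_1", "O_2"), p2 = c("O_3")))
  expect_length(bogs$bogs, 0)
  expect_identical(unname(bogs$venn_counts["p1&p2"]), 0L)
  expect_identical(bogs$union_size, 3L)
  expect_identical(sum(bogs$venn_counts), bogs$union_size)
})

test_that("raising the bit threshold never increases the OG count", {
  sim <- simulate_proteomes(benchmark_tree_5sp(), benchmark_params(),
                            n_families = 6, seed = 59, decoy_factor = 0)
  a <- sim$proteomes$A; e <- sim$proteomes$E
  expect_true(length(a) >= 2 && length(e) >= 2)
  n_og <- function(bits) {
    hits <- all_vs_all(a, e, min_bits = bits)
    if (nrow(hits) == 0) return(0L)
    rbh <- reciprocal_best_hits(hits, "A", "E")
    length(build_ogs(list(E = rbh), "A")$anchors)
  }
  counts <- vapply(c(100, 200, 300, 400), n_og, integer(1))
  expect_true(all(diff(counts) <= 0))
})
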