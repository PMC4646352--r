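test_that("neutral limit yields one gene per species and the species-tree shape", {
  params <- simulation_params(dup_rate = 0, loss_rate = 0)
  shapes <- c("((A:1,B:1):1,(C:1,D:1):1);",
              "((((A:1,B:1):1,C:2):1,D:3):1,E:4);",
              "(A:2,(B:1,C:1):1);")
  for (nwk in shapes) {
    tree <- species_tree(nwk)
    h <- evolve_family(tree, params)
    counts <- extant_counts(h)
    expect_true(all(counts == 1L), info = nwk)
    # with no duplications every internal gene-tree node is a speciation
    expect_setequal(setdiff(unique(h$nodes$type), c("root", "leaf")),
                    "speciation")
    expect_identical(nrow(h$leaves), length(tree$phy$tip.label))
  }
})

test_that("a fully retained root WGD doubles every proteome", {
  tree <- species_tree("((A:1,B:1):1,C:2);",
                       wgd = data.frame(child = "root", frac = 0.5,
                                        retention = 1.0))
  params <- simulation_params(dup_rate = 0, loss_rate = 0)
  h <- evolve_family(tree, params)
  expect_true(all(extant_counts(h) == 2L))
  expect_identical(sum(h$nodes$type == "wgd"), 1L)

  # retention 0: the new copy is never created, recorded as unretained
  tree0 <- species_tree("((A:1,B:1):1,C:2);",
                        wgd = data.frame(child = "root", frac = 0.5,
                                         retention = 0))
  h0 <- evolve_family(tree0, params)
  expect_true(all(extant_counts(h0) == 1L))
  expect_identical(h0$losses$cause, "wgd_not_retained")
})

test_that("WGD placement and structural validation are enforced", {
  expect_error(species_tree("(A:1,B:1,C:1);"), "binary")
  expect_error(species_tree("((A:1,B:1):1,C:2);",
                            wgd = data.frame(child = "A", frac = 1.2,
                                             retention = 1)),
               "strictly within")
  expect_error(species_tree("((A:1,B:1):1,C:2);",
                            wgd = data.frame(child = "Z", frac = 0.5,
                                             retention = 1)),
               "name tree nodes")
  expect_error(species_tree("((A:1,A:1):1,C:2);"), "unique")
})

test_that("surviving leaves equal the family genes in emitted proteomes", {
  tree <- benchmark_tree_5sp()
  sim <- simulate_proteomes(tree, benchmark_params(), n_families = 5,
                            seed = 19, decoy_factor = 2)
  leaf_total <- sum(vapply(sim$histories, function(h) nrow(h$leaves), 0L))
  fam_truth <- sim$truth[sim$truth$family != "decoy", ]
  expect_identical(nrow(fam_truth), leaf_total)
  in_proteomes <- sum(vapply(names(sim$proteomes), function(sp)
    sum(names(sim$proteomes[[sp]]) %in% fam_truth$id), 0L))
  expect_identical(in_proteomes, leaf_total)
  # decoys are 3x.. here 2x the family size per species (ceiling)
  for (sp in names(sim$proteomes)) {
    nfam <- sum(fam_truth$species == sp)
    ndec <- sum(startsWith(names(sim$proteomes[[sp]]), paste0(sp, "_decoy")))
    expect_identical(ndec, as.integer(ceiling(2 * nfam)))
  }
})

test_that("identical seeds give byte-identical FASTA output", {
  tree <- benchmark_tree_5sp()
  d1 <- tempfile(); d2 <- tempfile()
  for (d in c(d1, d2)) {
    sim <- simulate_proteomes(tree, benchmark_params(), n_families = 3,
                              seed = 77)
    write_proteomes(sim$proteomes, d)
  }
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("zero substitution rate emits the ancestral sequence everywhere", {
  tree <- species_tree("((A:1,B:1):1,C:2);")
  params <- simulation_params(dup_rate = 0, loss_rate = 0,
                              base_subs_rate = 0, tm_insertion_prob = 0)
  set.seed(4)
  h <- evolve_family(tree, params)
  em <- emit_sequences(h, params)
  expect_true(all(em$sequences == em$ancestor))
})

test_that("domain columns stay more conserved than tail columns", {
  tree <- benchmark_tree_5sp()
  params <- benchmark_params(dup_rate = 0, loss_rate = 0,
                             tm_insertion_prob = 0)
  set.seed(23)
  dom_ids <- c(); tail_ids <- c()
  for (f in 1:60) {
    h <- evolve_family(tree, params)
    em <- emit_sequences(h, params)
    m <- do.call(rbind, strsplit(em$sequences, ""))
    dom <- m[, 1:params$domain_length, drop = FALSE]
    tail_m <- m[, (params$domain_length + 1):ncol(m), drop = FALSE]
    pid <- function(x) {
      tot <- 0; idn <- 0
      for (i in 1:(nrow(x) - 1)) for (j in (i + 1):nrow(x)) {
        idn <- idn + sum(x[i, ] == x[j, ]); tot <- tot + ncol(x)
      }
      idn / tot
    }
    dom_ids <- c(dom_ids, pid(dom)); tail_ids <- c(tail_ids, pid(tail_m))
  }
  expect_gt(mean(dom_ids), mean(tail_ids))
  expect_gt(mean(dom_ids) - mean(tail_ids), 0.1)
})

test_that("forced TM insertion creates hydrophobic windows the predictor finds", {
  tree <- species_tree("((A:1,B:1):1,C:2);")
  params <- simulation_params(dup_rate = 0, loss_rate = 0,
                              tm_insertion_prob = 1)
  set.seed(29)
  h <- evolve_family(tree, params)
  em <- emit_sequences(h, params)
  expect_true(all(em$truth$has_tm))
  for (i in seq_along(em$sequences)) {
    seg <- substr(em$sequences[[i]], em$truth$tm_start[i] + 1,
                  em$truth$tm_end[i])
    kd <- oracle_window_means(seg, 19)
    expect_true(any(kd > 1.6))
    expect_true(predict_tm(em$sequences[[i]])$has_tmm)
  }
})

test_that("ortholog/paralog classification matches the ancestor-set oracle", {
  tree <- benchmark_tree_5sp()
  params <- simulation_params(dup_rate = 0.5, loss_rate = 0.3)
  set.seed(31)
  h <- NULL
  for (try in 1:50) { # find a history rich in events
    cand <- evolve_family(tree, params)
    if (nrow(cand$leaves) >= 8 && nrow(cand$losses) >= 2) { h <- cand; break }
  }
  expect_false(is.null(h))
  truth <- true_orthologs(h)
  for (r in seq_len(nrow(truth$pairs))) {
    expect_identical(truth$pairs$relation[r],
                     oracle_classify_pair(h, truth$pairs$gene_a[r],
                                          truth$pairs$gene_b[r]))
  }
})

test_that("ortholog and paralog pairs partition all surviving cross pairs", {
  tree <- benchmark_tree_5sp()
  set.seed(41)
  h <- evolve_family(tree, simulation_params(dup_rate = 0.4, loss_rate = 0.2))
  truth <- true_orthologs(h)
  n <- nrow(h$leaves)
  expect_identical(nrow(truth$pairs), n * (n - 1L) %/% 2L)
  expect_identical(nrow(truth$ortholog_pairs) + nrow(truth$paralog_pairs),
                   nrow(truth$pairs))
  key <- function(d) paste(d$gene_a, d$gene_b)
  expect_length(intersect(key(truth$ortholog_pairs),
                          key(truth$paralog_pairs)), 0)
  # same-species pairs are never orthologs
  sp <- setNames(h$leaves$species, h$leaves$id)
  o <- truth$ortholog_pairs
  if (nrow(o)) expect_true(all(sp[o$gene_a] != sp[o$gene_b]))
})

test_that("no-duplication histories have only cross-species ortholog pairs", {
  tree <- species_tree("((A:1,B:1):1,C:2);")
  h <- evolve_family(tree, simulation_params(dup_rate = 0, loss_rate = 0))
  truth <- true_orthologs(h)
  expect_identical(nrow(truth$paralog_pairs), 0L)
  expect_identical(nrow(truth$ortholog_pairs), 3L)

  # root WGD at full retention: exactly one ortholog per species pair per copy
  treew <- species_tree("(A:1,B:1);",
                        wgd = data.frame(child = "root", frac = 0.5,
                                         retention = 1))
  hw <- evolve_family(treew, simulation_params(dup_rate = 0, loss_rate = 0))
  tw <- true_orthologs(hw)
  sp <- setNames(hw$leaves$species, hw$leaves$id)
  for (g in hw$leaves$id[hw$leaves$species == "A"]) {
    o <- tw$ortholog_pairs
    partners <- c(o$gene_b[o$gene_a == g], o$gene_a[o$gene_b == g])
    expect_length(partners, 1) # the same-subtree copy only
    p <- tw$paralog_pairs
    cross_par <- sum(p$gene_a == g & sp[p$gene_b] == "B") +
      sum(p$gene_b == g & sp[p$gene_a] == "B")
    expect_identical(cross_par, 1L) # the cross-subtree WGD relation
  }
})
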