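# Fixed simulation scenarios used to validate the pipeline stages against
# ground truth. The scenario settings (tree shapes, rates, family counts)
# are the package's standard study conditions; the seed is the only free
# input.

#' Five-species benchmark tree
#'
#' Asymmetric rooted tree of five species normalised to unit root-to-tip
#' depth (deepest species pair 2 time units apart), used by the
#' ortholog-recovery and detection benchmarks. With unit depth the per-time
#' event rates read directly as expected events per root-to-tip lineage.
#'
#' @return A [species_tree()].
#' @export
benchmark_tree_5sp <- function() {
  species_tree("((((A:0.25,B:0.25):0.25,C:0.5):0.25,D:0.75):0.25,E:1);")
}

#' Standard benchmark parameters
#'
#' dup 0.1 / loss 0.05 per gene per time unit, base substitution rate 0.25
#' per site per time unit: on the unit-depth [benchmark_tree_5sp()] the
#' deepest species pair diverges by 2 x 0.25 = 0.5 substitutions per site
#' overall, and the conserved domain by 0.3 of that.
#'
#' @param ... Overrides passed to [simulation_params()].
#' @return A [simulation_params()].
#' @export
benchmark_params <- function(...) {
  args <- list(dup_rate = 0.1, loss_rate = 0.05, base_subs_rate = 0.25)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_params, args)
}

#' Ortholog-recovery benchmark: RBH against simulated truth
#'
#' Simulates `n_families` independent families on the five-species tree,
#' pools the family proteins per species, computes all-vs-all filtered hits
#' and reciprocal best hits for every species pair, and scores the predicted
#' ortholog pairs against the simulator's truth.
#'
#' @param seed Integer seed.
#' @param n_families Families simulated (default 20).
#' @param min_bits,min_coverage Hit filter thresholds.
#' @return List: `precision`, `recall`, `n_predicted`, `n_true`, `pairs`.
#' @export
rbh_benchmark <- function(seed = 1L, n_families = 20, min_bits = 200,
                          min_coverage = 0.5) {
  tree <- benchmark_tree_5sp()
  sim <- simulate_proteomes(tree, benchmark_params(), n_families = n_families,
                            seed = seed, decoy_factor = 0)
  species <- tree$phy$tip.label
  scheme <- scoring_scheme()
  predicted <- character(0)
  for (i in seq_len(length(species) - 1)) {
    for (j in seq.int(i + 1, length(species))) {
      a <- sim$proteomes[[species[i]]]; b <- sim$proteomes[[species[j]]]
      if (length(a) == 0 || length(b) == 0) next
      hits <- all_vs_all(a, b, scheme, min_bits, min_coverage)
      if (nrow(hits) == 0) next
      rbh <- reciprocal_best_hits(hits, species[i], species[j])
      if (nrow(rbh))
        predicted <- c(predicted, paste(pmin(rbh$gene_a, rbh$gene_b),
                                        pmax(rbh$gene_a, rbh$gene_b),
                                        sep = "|"))
    }
  }
  truth_pairs <- unlist(lapply(sim$truths, function(tr) {
    o <- tr$ortholog_pairs
    paste(o$gene_a, o$gene_b, sep = "|")
  }))
  tp <- sum(predicted %in% truth_pairs)
  list(precision = if (length(predicted)) tp / length(predicted) else NA_real_,
       recall = if (length(truth_pairs)) tp / length(truth_pairs) else NA_real_,
       n_predicted = length(predicted), n_true = length(truth_pairs),
       pairs = predicted)
}

#' Detection benchmark: calibrated profile-HMM scan with decoys
#'
#' Simulates families plus 3x background decoys, builds a profile from the
#' true domain regions, calibrates the acceptance threshold, scans all
#' proteomes, and scores detection of family membership.
#'
#' @param seed Integer seed.
#' @param n_families Families simulated (default 12).
#' @param null_samples Null sequences for calibration.
#' @param n_fpr_decoys Extra decoy-only sequences for the false-positive-rate
#'   estimate (default 1000).
#' @return List: `precision`, `recall`, `threshold_bits`,
#'   `false_positive_rate`, `n_family`, `n_decoys`.
#' @export
detection_benchmark <- function(seed = 1L, n_families = 12,
                                null_samples = 1000, n_fpr_decoys = 1000) {
  tree <- benchmark_tree_5sp()
  sim <- simulate_proteomes(tree, benchmark_params(), n_families = n_families,
                            seed = seed, decoy_factor = 3)
  seed_aln <- truth_seed_alignment(sim, max_rows = 50)
  hmm <- build_profile(seed_aln)
  cal <- calibrate_threshold(hmm, seed_aln, null_samples = null_samples,
                             seed_rng = seed + 1L)
  hmm <- set_threshold(hmm, cal)
  hits <- scan_proteomes(hmm, sim$proteomes)
  fam_ids <- sim$truth$id[sim$truth$family != "decoy"]
  tp <- sum(hits$protein_id %in% fam_ids)
  precision <- if (nrow(hits)) tp / nrow(hits) else NA_real_
  recall <- tp / length(fam_ids)
  set.seed(seed + 2L)
  extra <- random_proteins(n_fpr_decoys, sample(100:500, n_fpr_decoys,
                                                replace = TRUE))
  names(extra) <- sprintf("null%04d", seq_len(n_fpr_decoys))
  fp_hits <- scan_proteomes(hmm, proteome(extra, "null"))
  list(precision = precision, recall = recall,
       threshold_bits = cal$threshold_bits,
       false_positive_rate = nrow(fp_hits) / n_fpr_decoys,
       n_family = length(fam_ids),
       n_decoys = sum(sim$truth$family == "decoy"))
}

#' Constructed basal-orthologous-group scenario
#'
#' Four genomes: an outgroup `O`, an early-branching species `S`, and two
#' pivots `R` and `V`. Exactly five basal families predate the outgroup
#' split and survive in all four genomes; additional families are restricted
#' to subsets (`O`+`S`, `O`+`R`, `O`+`V`, and one `R`+`V` family absent from
#' the outgroup). Outgroup-anchored OG collections against `S`, `R` and `V`
#' are computed by all-vs-all + RBH and intersected; the expected result is
#' exactly five BOGs.
#'
#' @param seed Integer seed.
#' @param min_bits,min_coverage Hit filter thresholds.
#' @return List: `bogs` ([intersect_bogs()] result), `expected_bogs` (the
#'   five basal outgroup gene ids), `collections`, `proteomes`.
#' @export
bog_scenario <- function(seed = 1L, min_bits = 200, min_coverage = 0.5) {
  set.seed(seed)
  par0 <- benchmark_params(dup_rate = 0, loss_rate = 0, base_subs_rate = 0.05)
  full <- species_tree("(((R:1,V:1):1,S:2):1,O:3);")
  sub <- list(OS = species_tree("(S:2.5,O:2.5);"),
              OR = species_tree("(R:2.5,O:2.5);"),
              OV = species_tree("(V:2.5,O:2.5);"),
              RV = species_tree("(R:1,V:1);"))
  fams <- c(sprintf("B%02d", 1:5), "SO1", "SO2", "RO1", "VO1", "RV1")
  trees <- c(rep(list(full), 5),
             list(sub$OS, sub$OS, sub$OR, sub$OV, sub$RV))
  seqs_by_sp <- list(O = character(), S = character(),
                     R = character(), V = character())
  expected <- character(0)
  for (k in seq_along(fams)) {
    h <- evolve_family(trees[[k]], par0, gene_prefix = fams[k])
    em <- emit_sequences(h, par0)
    for (i in seq_len(nrow(em$truth))) {
      sp <- em$truth$species[i]
      seqs_by_sp[[sp]][em$truth$id[i]] <- em$sequences[[em$truth$id[i]]]
    }
    if (k <= 5) expected <- c(expected, em$truth$id[em$truth$species == "O"])
  }
  proteomes <- lapply(names(seqs_by_sp), function(sp)
    proteome(seqs_by_sp[[sp]], sp))
  names(proteomes) <- names(seqs_by_sp)
  scheme <- scoring_scheme()
  collections <- list()
  for (sp in c("S", "R", "V")) {
    hits <- all_vs_all(proteomes$O, proteomes[[sp]], scheme, min_bits,
                       min_coverage)
    rbh <- reciprocal_best_hits(hits, "O", sp)
    og <- build_ogs(setNames(list(rbh), sp), pivot_id = "O",
                    pivot_genes = names(proteomes$O))
    collections[[paste0("O_vs_", sp)]] <- og
  }
  bogs <- intersect_bogs(collections)
  list(bogs = bogs, expected_bogs = sort(expected),
       collections = collections, proteomes = proteomes)
}

#' Neighbor-joining consistency sweep on additive matrices
#'
#' Generates random rooted trees (4-8 taxa, branch lengths uniform on
#' \[0.1, 1\]), computes their exact additive (cophenetic) distance
#' matrices, rebuilds each tree with [neighbor_joining()], and counts exact
#' unrooted-topology recoveries.
#'
#' @param n_trees Number of random trees (default 100).
#' @param seed Integer seed.
#' @return List: `recovered`, `n_trees`, `fraction`.
#' @export
nj_recovery <- function(n_trees = 100, seed = 1L) {
  set.seed(seed)
  recovered <- 0L
  for (r in seq_len(n_trees)) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(D)
    if (ape::dist.topo(ape::unroot(tr), est) == 0) recovered <- recovered + 1L
  }
  list(recovered = recovered, n_trees = n_trees,
       fraction = recovered / n_trees)
}

#' Birth-death expectation check
#'
#' Replicated Gillespie simulations of a family on a two-species tree with
#' root-to-tip time `T`; the mean extant copy number per species should match
#' the linear birth-death expectation `exp((dup - loss) * T)`.
#'
#' @param seed Integer seed.
#' @param reps Number of replicates (default 2000).
#' @param dup_rate,loss_rate Birth and death rates.
#' @param total_time Root-to-tip time `T`.
#' @return List: `mean`, `se`, `expected`, `z` (standard errors from the
#'   expectation), `reps`.
#' @export
bd_expectation <- function(seed = 1L, reps = 2000, dup_rate = 0.2,
                           loss_rate = 0.1, total_time = 5) {
  tree <- species_tree(sprintf("(A:%g,B:%g);", total_time, total_time))
  params <- simulation_params(dup_rate = dup_rate, loss_rate = loss_rate,
                              base_subs_rate = 0)
  set.seed(seed)
  counts <- integer(reps)
  for (r in seq_len(reps)) {
    h <- evolve_family(tree, params)
    counts[r] <- extant_counts(h)[["A"]]
  }
  m <- mean(counts)
  se <- stats::sd(counts) / sqrt(reps)
  expected <- exp((dup_rate - loss_rate) * total_time)
  list(mean = m, se = se, expected = expected,
       z = (m - expected) / se, reps = reps)
}
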