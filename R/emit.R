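# Apply a Poisson number of substitutions per site along one gene-tree edge.
# Replacement residues are drawn from the stationary distribution excluding
# the current residue.
mutate_seq <- function(codes, site_rates, dt, bg) {
  if (dt <= 0) return(codes)
  k <- rpois(length(codes), site_rates * dt)
  for (i in which(k > 0)) {
    cur <- codes[i]
    for (j in seq_len(k[i])) {
      p <- bg; p[cur] <- 0
      cur <- sample.int(20L, 1L, prob = p)
    }
    codes[i] <- cur
  }
  codes
}

#' Emit protein sequences for a simulated family history
#'
#' The ancestral protein is drawn from the stationary soluble-protein
#' distribution ([aa_soluble_background()]):
#' `domain_length` slowly evolving domain columns followed by
#' `tail_length` fast-evolving tail columns. Substitution counts per site are
#' Poisson with rate `base_subs_rate * class multiplier * branch length`.
#' Each surviving gene is independently flagged with probability
#' `tm_insertion_prob` to carry one contiguous hydrophobic segment
#' (`tm_length >= 19` residues sampled uniformly from I, L, V, F, A, M)
#' inserted at a random position in its tail.
#'
#' @param history A [evolve_family()] result.
#' @param params A [simulation_params()] (defaults to the history's own).
#' @param root_codes Optional integer codes (1-20) of the family's root
#'   sequence; by default a fresh root is drawn from the stationary
#'   distribution. Supplying it lets several families share ancestry (an
#'   ancient radiation).
#' @return List of class `family_emission`: `sequences` (named character
#'   vector, one per surviving gene), `truth` (data.frame: id, species,
#'   family, length, domain_start/domain_end \[0-based half-open\], has_tm,
#'   tm_start/tm_end), `ancestor` (root sequence).
#' @export
emit_sequences <- function(history, params = history$params,
                           root_codes = NULL) {
  stopifnot(inherits(history, "family_history"),
            inherits(params, "simulation_params"))
  bg <- unname(aa_soluble_background())
  Ld <- params$domain_length; Lt <- params$tail_length
  L <- Ld + Lt
  site_rates <- params$base_subs_rate *
    c(rep(params$domain_rate_multiplier, Ld),
      rep(params$tail_rate_multiplier, Lt))
  if (is.null(root_codes))
    root_codes <- sample.int(20L, L, replace = TRUE, prob = bg)
  stopifnot(length(root_codes) == L)

  nodes <- history$nodes
  children <- split(nodes$id, nodes$parent)
  leaf_codes <- vector("list", nrow(nodes))

  # iterative preorder walk over the gene tree
  stack <- list(list(id = nodes$id[nodes$parent == 0L][1], codes = root_codes))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$id
    if (nodes$type[nd] == "leaf") leaf_codes[[nd]] <- top$codes
    ch <- children[[as.character(nd)]]
    for (c in ch) {
      dt <- nodes$time[c] - nodes$time[nd]
      stack[[length(stack) + 1L]] <- list(id = c,
                                          codes = mutate_seq(top$codes, site_rates, dt, bg))
    }
  }

  lv <- history$leaves
  n <- nrow(lv)
  seqs <- character(n); has_tm <- logical(n)
  tm_start <- rep(NA_integer_, n); tm_end <- rep(NA_integer_, n)
  lens <- integer(n)
  tm_alpha <- c("I", "L", "V", "F", "A", "M")
  for (i in seq_len(n)) {
    codes <- leaf_codes[[lv$node_id[i]]]
    chars <- AA20[codes]
    if (runif(1) < params$tm_insertion_prob && Lt > 0) {
      seg <- sample(tm_alpha, params$tm_length, replace = TRUE)
      pos <- sample.int(Lt + 1L, 1L) + Ld - 1L # insertion point in the tail
      chars <- append(chars, seg, after = pos)
      has_tm[i] <- TRUE
      tm_start[i] <- pos; tm_end[i] <- pos + params$tm_length
    }
    seqs[i] <- paste(chars, collapse = "")
    lens[i] <- length(chars)
  }
  names(seqs) <- lv$id
  truth <- data.frame(id = lv$id, species = lv$species,
                      family = history$gene_prefix, length = lens,
                      domain_start = 0L, domain_end = Ld,
                      has_tm = has_tm, tm_start = tm_start, tm_end = tm_end,
                      stringsAsFactors = FALSE)
  structure(list(sequences = seqs, truth = truth,
                 ancestor = paste(AA20[root_codes], collapse = "")),
            class = "family_emission")
}

#' Construct a proteome object
#'
#' A proteome is a named character vector of protein sequences tagged with
#' its species label.
#'
#' @param seqs Named character vector of sequences.
#' @param species Species label.
#' @return Object of class `proteome`.
#' @export
proteome <- function(seqs, species) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  structure(seqs, species = species, class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("proteome %s: %d proteins\n", attr(x, "species"), length(x)))
  invisible(x)
}

#' Simulate proteomes for a radiated set of gene families
#'
#' Evolves `n_families` families on the same species tree and emits their
#' sequences. The family root sequences descend from one common ancestral
#' domain-bearing gene: each family's root is the ancestor evolved along a
#' pre-root branch of `radiation_time` time units (an ancient radiation), so
#' all family members share the conserved domain while distinct families are
#' ancient paralogs of one another. Each proteome is padded with decoy
#' (non-family) proteins: independent background-random sequences with
#' lengths uniform on `decoy_length`, `decoy_factor` times the species'
#' family-gene count (so detection specificity is testable).
#'
#' @param tree A [species_tree()].
#' @param params A [simulation_params()].
#' @param n_families Number of families (ancient paralog lineages).
#' @param seed Integer seed; the whole output is deterministic given it.
#' @param decoy_factor Decoys per family gene (default 3).
#' @param decoy_length Length range of decoy proteins.
#' @param radiation_time Pre-root branch length separating each family's
#'   root from the common ancestor (default 5; 0 makes families unrelated
#'   only in their birth-death histories, identical in sequence at the
#'   root).
#' @return List of class `simulated_proteomes`: `proteomes` (named list of
#'   [proteome()]s), `truth` (per-gene table incl. decoys with
#'   `family = "decoy"`), `histories` (per-family [evolve_family()] results),
#'   `truths` (per-family [true_orthologs()], surviving families only).
#' @export
simulate_proteomes <- function(tree, params, n_families = 6, seed = 1L,
                               decoy_factor = 3, decoy_length = c(100L, 500L),
                               radiation_time = 5) {
  set.seed(seed)
  species <- tree$phy$tip.label
  bg <- unname(aa_soluble_background())
  L <- params$domain_length + params$tail_length
  site_rates <- params$base_subs_rate *
    c(rep(params$domain_rate_multiplier, params$domain_length),
      rep(params$tail_rate_multiplier, params$tail_length))
  ancestor <- sample.int(20L, L, replace = TRUE, prob = bg)
  histories <- list(); emissions <- list()
  for (f in seq_len(n_families)) {
    prefix <- sprintf("F%02d", f)
    h <- evolve_family(tree, params, gene_prefix = prefix)
    histories[[prefix]] <- h
    if (nrow(h$leaves) > 0) {
      root_f <- mutate_seq(ancestor, site_rates, radiation_time, bg)
      emissions[[prefix]] <- emit_sequences(h, params, root_codes = root_f)
    }
  }
  truth <- do.call(rbind, lapply(emissions, `[[`, "truth"))
  all_seqs <- unlist(unname(lapply(emissions, `[[`, "sequences")))

  proteomes <- list()
  decoy_truth <- list()
  for (sp in species) {
    fam_ids <- truth$id[truth$species == sp]
    fam <- all_seqs[fam_ids]
    n_dec <- ceiling(decoy_factor * length(fam_ids))
    dec <- character(0)
    if (n_dec > 0) {
      lens <- sample.int(decoy_length[2] - decoy_length[1] + 1L, n_dec,
                         replace = TRUE) + decoy_length[1] - 1L
      dec <- random_proteins(n_dec, lens)
      names(dec) <- sprintf("%s_decoy%03d", sp, seq_len(n_dec))
      decoy_truth[[sp]] <- data.frame(
        id = names(dec), species = sp, family = "decoy",
        length = nchar(dec), domain_start = NA_integer_,
        domain_end = NA_integer_, has_tm = FALSE,
        tm_start = NA_integer_, tm_end = NA_integer_,
        stringsAsFactors = FALSE)
    }
    proteomes[[sp]] <- proteome(c(fam, dec), sp)
  }
  truth <- rbind(truth, do.call(rbind, decoy_truth))
  rownames(truth) <- NULL
  truths <- lapply(histories[names(emissions)], true_orthologs)
  structure(list(proteomes = proteomes, truth = truth,
                 histories = histories, truths = truths,
                 tree = tree, params = params, seed = seed),
            class = "simulated_proteomes")
}

#' Extract a gapless seed alignment of true domain regions
#'
#' Uses the simulator's truth coordinates to cut the (slowly evolving) domain
#' region out of family sequences; because the simulator introduces no indels
#' in the domain, the cut regions align column-for-column and form a valid
#' gapless seed alignment for [build_profile()].
#'
#' @param sim A [simulate_proteomes()] result.
#' @param species Species whose family sequences seed the alignment (default:
#'   all).
#' @param max_rows Optional cap on the number of rows; rows are kept
#'   round-robin across families so every family stays represented.
#' @return A [seed_alignment()].
#' @export
truth_seed_alignment <- function(sim, species = NULL, max_rows = NULL) {
  tr <- sim$truth[sim$truth$family != "decoy", , drop = FALSE]
  if (!is.null(species)) tr <- tr[tr$species %in% species, , drop = FALSE]
  if (nrow(tr) < 2) stop("not enough family sequences for a seed alignment")
  if (!is.null(max_rows) && nrow(tr) > max_rows) {
    by_fam <- split(seq_len(nrow(tr)), tr$family)
    # round-robin: first member of each family, then second of each, ...
    pos <- unlist(lapply(seq_len(max(lengths(by_fam))), function(k)
      vapply(by_fam, function(ix) if (length(ix) >= k) ix[k] else NA_integer_,
             integer(1))))
    pos <- pos[!is.na(pos)]
    tr <- tr[pos[seq_len(max_rows)], , drop = FALSE]
  }
  rows <- vapply(seq_len(nrow(tr)), function(i) {
    sp <- tr$species[i]
    s <- sim$proteomes[[sp]][[tr$id[i]]]
    substr(s, tr$domain_start[i] + 1L, tr$domain_end[i])
  }, character(1))
  names(rows) <- tr$id
  seed_alignment(rows)
}

#' Write proteomes as FASTA (one file per species)
#'
#' @param proteomes Named list of [proteome()]s.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths.
#' @export
write_proteomes <- function(proteomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(proteomes), function(sp) {
    p <- file.path(dir, paste0(sp, ".fasta"))
    ss <- Biostrings::AAStringSet(unclass(proteomes[[sp]]))
    Biostrings::writeXStringSet(ss, p)
    p
  }, character(1))
  paths
}

#' Read proteomes from FASTA files
#'
#' @param paths Named character vector of FASTA paths; names are the species
#'   labels (defaults to file base names).
#' @return Named list of [proteome()]s.
#' @export
read_proteomes <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.fa(sta)?$", "", basename(paths))
  out <- lapply(names(paths), function(sp) {
    ss <- Biostrings::readAAStringSet(paths[[sp]])
    proteome(setNames(as.character(ss), names(ss)), sp)
  })
  setNames(out, names(paths))
}
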