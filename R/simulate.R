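#' Species tree with whole-genome-duplication events
#'
#' Wraps a rooted binary `ape::phylo` tree (or Newick string) together with
#' the WGD events placed on its edges. Each WGD is located on the edge above
#' a named node at a fractional position along that edge and carries a
#' retention probability for the duplicated gene copies. The reserved name
#' `"root"` places a WGD on the stem above the root (affecting the whole
#' family before the first speciation).
#'
#' @param phy `ape::phylo` object or a Newick string. Must be rooted and
#'   binary with positive branch lengths and unique tip labels.
#' @param wgd Optional data.frame with columns `child` (tip/node label or
#'   `"root"`), `frac` (position in (0,1) along the edge from its parent),
#'   `retention` (probability in \[0,1\]).
#' @return Object of class `species_tree`.
#' @export
species_tree <- function(phy, wgd = NULL) {
  if (is.character(phy)) phy <- ape::read.tree(text = phy)
  if (!inherits(phy, "phylo")) stop("phy must be a phylo object or Newick string")
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    stop("species tree must be rooted and binary")
  if (is.null(phy$edge.length) || any(phy$edge.length <= 0))
    stop("species tree must have positive branch lengths")
  if (anyDuplicated(phy$tip.label)) stop("leaf labels must be unique")
  if (is.null(phy$node.label) || !any(nzchar(phy$node.label)))
    phy$node.label <- paste0("N", seq_len(phy$Nnode))
  if (!is.null(wgd)) {
    wgd <- as.data.frame(wgd)
    stopifnot(all(c("child", "frac", "retention") %in% names(wgd)))
    labs <- c(phy$tip.label, phy$node.label, "root")
    if (!all(wgd$child %in% labs))
      stop("wgd 'child' labels must name tree nodes (or 'root')")
    if (any(wgd$frac <= 0 | wgd$frac >= 1))
      stop("wgd positions must lie strictly within their edge")
    stopifnot(all(wgd$retention >= 0 & wgd$retention <= 1))
  }
  structure(list(phy = phy, wgd = wgd), class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("species tree: %d tips (%s), %d WGD event(s)\n",
              length(x$phy$tip.label), paste(x$phy$tip.label, collapse = ", "),
              if (is.null(x$wgd)) 0L else nrow(x$wgd)))
  invisible(x)
}

#' Simulation parameters for gene-family evolution
#'
#' @param dup_rate,loss_rate Duplications / losses per gene per time unit.
#' @param domain_length,tail_length Number of slowly evolving domain columns
#'   and fast-evolving tail columns in the ancestral protein.
#' @param domain_rate_multiplier,tail_rate_multiplier Relative substitution
#'   rates of the two column classes (defaults 0.3 and 1.5).
#' @param base_subs_rate Substitutions per site per time unit before the
#'   class multiplier.
#' @param tm_insertion_prob Per-gene probability that an emitted family
#'   protein carries a hydrophobic transmembrane segment in its tail.
#' @param tm_length Length of the inserted segment (>= 19 residues).
#' @return Object of class `simulation_params`.
#' @export
simulation_params <- function(dup_rate = 0.1, loss_rate = 0.05,
                              domain_length = 150L, tail_length = 100L,
                              domain_rate_multiplier = 0.3,
                              tail_rate_multiplier = 1.5,
                              base_subs_rate = 0.06,
                              tm_insertion_prob = 0.2, tm_length = 21L) {
  stopifnot(dup_rate >= 0, loss_rate >= 0, base_subs_rate >= 0,
            domain_rate_multiplier > 0, tail_rate_multiplier > 0,
            tm_insertion_prob >= 0, tm_insertion_prob <= 1,
            domain_length >= 1, tail_length >= 0, tm_length >= 19)
  structure(list(dup_rate = dup_rate, loss_rate = loss_rate,
                 domain_length = as.integer(domain_length),
                 tail_length = as.integer(tail_length),
                 domain_rate_multiplier = domain_rate_multiplier,
                 tail_rate_multiplier = tail_rate_multiplier,
                 base_subs_rate = base_subs_rate,
                 tm_insertion_prob = tm_insertion_prob,
                 tm_length = as.integer(tm_length)),
            class = "simulation_params")
}

#' Evolve one gene family along a species tree
#'
#' A Gillespie walk per species-tree edge: each live gene lineage draws
#' exponential waiting times for duplication (rate `dup_rate`) and loss
#' (rate `loss_rate`); at a WGD event every live gene duplicates and each new
#' copy survives with the event's retention probability; at speciations every
#' live gene branches into both daughter edges. Gene identifiers encode the
#' species and the lineage path (`-1`/`-2` for duplication daughters,
#' `-w1`/`-w2` for WGD copies), so truth tables are self-describing.
#'
#' @param tree A [species_tree()].
#' @param params A [simulation_params()].
#' @param gene_prefix Prefix for gene identifiers (e.g. a family label).
#' @return Object of class `family_history`: `nodes` (event table: id,
#'   parent, type, time), `leaves` (id, node_id, species, lineage), `losses`,
#'   plus the tree and params. A family extinct in all species has zero
#'   leaves and is reported as an empty history.
#' @export
evolve_family <- function(tree, params, gene_prefix = "g") {
  stopifnot(inherits(tree, "species_tree"), inherits(params, "simulation_params"))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  node_label <- c(phy$tip.label, phy$node.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  edge_len <- numeric(ntip + phy$Nnode)
  edge_len[phy$edge[, 2]] <- phy$edge.length
  node_time <- numeric(ntip + phy$Nnode)
  ord <- rev(ape::postorder(phy)) # parent-before-child edge order
  for (e in ord) {
    node_time[phy$edge[e, 2]] <- node_time[phy$edge[e, 1]] + phy$edge.length[e]
  }

  wgd_on <- function(v) {
    if (is.null(tree$wgd)) return(NULL)
    w <- tree$wgd[tree$wgd$child == node_label[v], , drop = FALSE]
    if (nrow(w) == 0) return(NULL)
    w[order(w$frac), , drop = FALSE]
  }

  ids <- 0L
  np <- integer(0); ntype <- character(0); ntime <- numeric(0)
  new_node <- function(parent, type, time) {
    ids <<- ids + 1L
    np[ids] <<- parent; ntype[ids] <<- type; ntime[ids] <<- time
    ids
  }
  leaves <- list(); losses <- list()
  dup <- params$dup_rate; lor <- params$loss_rate; rate <- dup + lor

  at_node <- function(v, gparent, lineage) {
    if (v <= ntip) {
      nd <- new_node(gparent, "leaf", node_time[v])
      leaves[[length(leaves) + 1L]] <<- list(
        id = paste0(node_label[v], "_", gene_prefix, lineage),
        node_id = nd, species = node_label[v], lineage = lineage)
    } else {
      nd <- new_node(gparent, "speciation", node_time[v])
      for (u in kids[[as.character(v)]]) walk(u, nd, lineage, 0)
    }
  }

  # one gene lineage traversing the edge above v, entering at offset s
  walk <- function(v, gparent, lineage, s) {
    el <- edge_len[v]
    t0 <- node_time[v] - el
    wg <- wgd_on(v)
    wpos <- if (is.null(wg)) numeric(0) else wg$frac * el
    wret <- if (is.null(wg)) numeric(0) else wg$retention
    keepw <- wpos > s
    wpos <- wpos[keepw]; wret <- wret[keepw]
    t <- s
    repeat {
      nb <- if (length(wpos)) wpos[1] else el
      wait <- if (rate > 0) rexp(1, rate) else Inf
      if (t + wait < nb) {
        t <- t + wait
        if (runif(1) < dup / rate) {
          nd <- new_node(gparent, "duplication", t0 + t)
          walk(v, nd, paste0(lineage, "-1"), t)
          walk(v, nd, paste0(lineage, "-2"), t)
        } else {
          losses[[length(losses) + 1L]] <<- list(
            lineage = lineage, branch = node_label[v], time = t0 + t,
            cause = "loss")
        }
        return(invisible())
      }
      t <- nb
      if (length(wpos)) { # WGD boundary
        ret <- wret[1]
        wpos <- wpos[-1]; wret <- wret[-1]
        nd <- new_node(gparent, "wgd", t0 + t)
        if (runif(1) < ret) {
          walk(v, nd, paste0(lineage, "-w2"), t)
        } else {
          losses[[length(losses) + 1L]] <<- list(
            lineage = paste0(lineage, "-w2"), branch = node_label[v],
            time = t0 + t, cause = "wgd_not_retained")
        }
        gparent <- nd
        lineage <- paste0(lineage, "-w1")
      } else {
        at_node(v, gparent, lineage)
        return(invisible())
      }
    }
  }

  groot <- new_node(0L, "root", 0)
  gparent <- groot; lineage <- ""
  if (!is.null(tree$wgd)) {
    sw <- tree$wgd[tree$wgd$child == "root", , drop = FALSE]
    if (nrow(sw) > 0) {
      pend <- list(list(gparent = groot, lineage = ""))
      for (i in seq_len(nrow(sw))) {
        nxt <- list()
        for (g in pend) {
          nd <- new_node(g$gparent, "wgd", 0)
          nxt[[length(nxt) + 1L]] <- list(gparent = nd,
                                          lineage = paste0(g$lineage, "-w1"))
          if (runif(1) < sw$retention[i]) {
            nxt[[length(nxt) + 1L]] <- list(gparent = nd,
                                            lineage = paste0(g$lineage, "-w2"))
          } else {
            losses[[length(losses) + 1L]] <- list(
              lineage = paste0(g$lineage, "-w2"), branch = "root", time = 0,
              cause = "wgd_not_retained")
          }
        }
        pend <- nxt
      }
      for (g in pend) at_node(root, g$gparent, g$lineage)
    } else {
      at_node(root, gparent, lineage)
    }
  } else {
    at_node(root, gparent, lineage)
  }

  leaves_df <- if (length(leaves))
    data.frame(id = vapply(leaves, `[[`, "", "id"),
               node_id = vapply(leaves, `[[`, 0L, "node_id"),
               species = vapply(leaves, `[[`, "", "species"),
               lineage = vapply(leaves, `[[`, "", "lineage"),
               stringsAsFactors = FALSE)
  else data.frame(id = character(), node_id = integer(),
                  species = character(), lineage = character())
  losses_df <- if (length(losses))
    data.frame(lineage = vapply(losses, `[[`, "", "lineage"),
               branch = vapply(losses, `[[`, "", "branch"),
               time = vapply(losses, `[[`, 0, "time"),
               cause = vapply(losses, `[[`, "", "cause"),
               stringsAsFactors = FALSE)
  else data.frame(lineage = character(), branch = character(),
                  time = numeric(), cause = character())

  structure(list(
    nodes = data.frame(id = seq_len(ids), parent = np, type = ntype,
                       time = ntime, stringsAsFactors = FALSE),
    leaves = leaves_df, losses = losses_df,
    tree = tree, params = params, gene_prefix = gene_prefix),
    class = "family_history")
}

#' @export
print.family_history <- function(x, ...) {
  cat(sprintf("family history: %d surviving genes in %d species, %d losses\n",
              nrow(x$leaves), length(unique(x$leaves$species)),
              nrow(x$losses)))
  invisible(x)
}

#' Number of surviving genes per species
#'
#' @param history A [evolve_family()] result.
#' @param species Optional species labels to report (defaults to the tree's
#'   tips, reporting 0 where the family is extinct).
#' @return Named integer vector.
#' @export
extant_counts <- function(history, species = NULL) {
  if (is.null(species)) species <- history$tree$phy$tip.label
  tab <- table(factor(history$leaves$species, levels = species))
  setNames(as.integer(tab), species)
}

# Root-to-leaf node-id paths for every surviving gene.
leaf_paths <- function(history) {
  parent <- history$nodes$parent
  lapply(history$leaves$node_id, function(nd) {
    path <- integer(0)
    while (nd != 0L) { path <- c(nd, path); nd <- parent[nd] }
    path
  })
}

#' Ground-truth ortholog/paralog classification of a family history
#'
#' Classifies every unordered pair of surviving genes by the label of their
#' gene-tree most recent common ancestor: speciation nodes yield ortholog
#' pairs, duplication and WGD nodes yield paralog pairs. Deterministic.
#'
#' @param history A [evolve_family()] result with at least one surviving gene.
#' @return Object of class `truth_orthology`: data.frame `pairs` with
#'   `gene_a`, `gene_b` (gene_a < gene_b), `relation`
#'   (`ortholog`/`paralog`), `mrca_label`, plus `ortholog_pairs` and
#'   `paralog_pairs` accessor copies.
#' @export
true_orthologs <- function(history) {
  stopifnot(inherits(history, "family_history"))
  n <- nrow(history$leaves)
  if (n < 1) stop("history has no surviving genes")
  paths <- leaf_paths(history)
  types <- history$nodes$type
  ids <- history$leaves$id
  out <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(max(n - 1, 0))) {
    pi <- paths[[i]]
    for (j in seq.int(i + 1L, n)) {
      pj <- paths[[j]]
      m <- min(length(pi), length(pj))
      common <- which(pi[seq_len(m)] != pj[seq_len(m)])
      mrca <- if (length(common)) pi[common[1] - 1L] else pi[m]
      lab <- types[mrca]
      k <- k + 1L
      a <- ids[i]; b <- ids[j]
      if (a > b) { tmp <- a; a <- b; b <- tmp }
      out[[k]] <- list(gene_a = a, gene_b = b,
                       relation = if (lab == "speciation") "ortholog" else "paralog",
                       mrca_label = lab)
    }
  }
  pairs <- if (k > 0)
    data.frame(gene_a = vapply(out, `[[`, "", "gene_a"),
               gene_b = vapply(out, `[[`, "", "gene_b"),
               relation = vapply(out, `[[`, "", "relation"),
               mrca_label = vapply(out, `[[`, "", "mrca_label"),
               stringsAsFactors = FALSE)
  else data.frame(gene_a = character(), gene_b = character(),
                  relation = character(), mrca_label = character())
  structure(list(pairs = pairs,
                 ortholog_pairs = pairs[pairs$relation == "ortholog", , drop = FALSE],
                 paralog_pairs = pairs[pairs$relation == "paralog", , drop = FALSE]),
            class = "truth_orthology")
}

#' Write a truth-orthology table as TSV
#'
#' Columns: `gene_a`, `gene_b`, `relation`, `mrca_label`.
#'
#' @param truth A [true_orthologs()] result.
#' @param path Output file path.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
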