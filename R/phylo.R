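#' Kimura protein distances from a multiple alignment
#'
#' For each sequence pair, columns with a gap in either member are excluded;
#' `p` is the mismatch fraction over the remaining columns and the distance
#' is `d = -ln(1 - p - 0.2 p^2)`. Values of `p` beyond the formula's domain
#' (or distances above the cap) are capped at `d_max` with a warning, keeping
#' saturated pairs finite.
#'
#' @param aln Named character vector of equal-length aligned sequences, a
#'   character matrix (rows = sequences), or a [seed_alignment()].
#' @param d_max Distance cap for saturated pairs (default 10).
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
kimura_distance <- function(aln, d_max = 10) {
  m <- if (inherits(aln, "seed_alignment")) aln$rows
  else if (is.matrix(aln)) aln
  else seed_alignment(aln)$rows
  n <- nrow(m)
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("s", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  capped <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok))
        stop("no comparable columns between ", labs[i], " and ", labs[j])
      p <- mean(m[i, ok] != m[j, ok])
      arg <- 1 - p - 0.2 * p^2
      d <- if (arg <= 0) Inf else -log(arg)
      if (!is.finite(d) || d > d_max) { d <- d_max; capped <- TRUE }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (capped)
    warning("saturated pair(s): distance capped at ", d_max)
  D
}

# distance between two protein sequences from their local alignment
pairwise_kimura <- function(a, b, scheme = scoring_scheme(), d_max = 10) {
  aln <- local_align(a, b, scheme)
  if (aln$n_columns == 0) return(Inf)
  p <- 1 - aln$identity_fraction
  arg <- 1 - p - 0.2 * p^2
  d <- if (arg <= 0) Inf else -log(arg)
  if (d > d_max) d_max else d
}

#' Neighbor joining
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in the
#' Q-minimisation are broken deterministically by the smallest (sorted) label
#' pair, a cluster being labelled by its lexicographically smallest member.
#' Negative branch lengths are floored at 0 with the deficit shifted to the
#' sibling edge.
#'
#' @param D Symmetric distance matrix with >= 3 labelled rows.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  labs <- rownames(D)
  if (is.null(labs)) labs <- colnames(D)
  if (is.null(labs)) stop("distance matrix must be labelled")
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 labels")
  stopifnot(isTRUE(all.equal(D, t(D), check.attributes = FALSE)),
            all(diag(D) == 0))
  frag <- labs              # newick fragment per active cluster
  key <- labs               # smallest member label, for tie-breaking
  eps <- 1e-12
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (n > 3) {
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= eps * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- apply(cand, 1, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(pair_keys)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi), frag[j], fmt(vj))
    newkey <- min(key[i], key[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    rownames(D) <- colnames(D) <- NULL
    n <- n - 1
  }
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(va), frag[2], fmt(vb),
                 frag[3], fmt(vc))
  ape::read.tree(text = txt)
}

#' Nonparametric bootstrap support for a neighbor-joining tree
#'
#' Columns of the alignment are resampled with replacement per replicate, a
#' tree is built per replicate ([kimura_distance()] + [neighbor_joining()]),
#' and the support of each internal split of the original tree is the
#' percentage of replicate trees containing it. Deterministic given the seed.
#'
#' @param aln Alignment accepted by [kimura_distance()] (>= 3 rows).
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Integer RNG seed.
#' @param d_max Distance cap, as in [kimura_distance()].
#' @return The original NJ tree (`ape::phylo`) with `node.label` set to the
#'   bootstrap support percentages in \[0, 100\] (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = 1L, d_max = 10) {
  m <- if (inherits(aln, "seed_alignment")) aln$rows
  else if (is.matrix(aln)) aln
  else seed_alignment(aln)$rows
  if (nrow(m) < 3) stop("bootstrap needs >= 3 aligned sequences")
  tree <- neighbor_joining(suppressWarnings(kimura_distance(m, d_max)))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[r]] <- neighbor_joining(
      suppressWarnings(kimura_distance(m[, cols, drop = FALSE], d_max)))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps, 1)
  tree$node.label <- as.character(support)
  attr(tree, "bootstrap") <- support
  tree
}

#' Assign sequences to groups by nearest labelled anchor
#'
#' Each member is aligned to every anchor with [local_align()]; anchors whose
#' alignment fails the bit-score/coverage filter are ignored. The member is
#' assigned the group of its nearest anchor by the Kimura distance of the
#' aligned region (ties broken by the smallest anchor label); members with no
#' filter-passing anchor alignment are `"unplaced"`.
#'
#' @param members Named character vector of sequences to place.
#' @param anchors Named character vector of reference sequences.
#' @param anchor_groups Named character vector mapping anchor id -> group
#'   label.
#' @param scheme A [scoring_scheme()].
#' @param min_bits,min_coverage Filter thresholds for an anchor alignment to
#'   count (defaults 200 bits, 0.5 coverage).
#' @param d_max Distance cap.
#' @return Data.frame: `id`, `group`, `anchor`, `distance`.
#' @export
assign_groups <- function(members, anchors, anchor_groups,
                          scheme = scoring_scheme(), min_bits = 200,
                          min_coverage = 0.5, d_max = 10) {
  stopifnot(!is.null(names(members)), !is.null(names(anchors)),
            all(names(anchors) %in% names(anchor_groups)))
  anchor_ids <- sort(names(anchors))
  rows <- lapply(names(members), function(id) {
    best_d <- Inf; best_a <- NA_character_
    for (a in anchor_ids) {
      aln <- local_align(members[[id]], anchors[[a]], scheme)
      if (!hit_filter(aln, min_bits, min_coverage)) next
      p <- 1 - aln$identity_fraction
      arg <- 1 - p - 0.2 * p^2
      d <- if (arg <= 0) d_max else min(-log(arg), d_max)
      if (d < best_d - 1e-12) { best_d <- d; best_a <- a }
    }
    if (is.na(best_a))
      data.frame(id = id, group = "unplaced", anchor = NA_character_,
                 distance = NA_real_, stringsAsFactors = FALSE)
    else
      data.frame(id = id, group = unname(anchor_groups[best_a]),
                 anchor = best_a, distance = best_d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param D Labelled symmetric matrix.
#' @param path Output path.
#' @export
write_phylip <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(c(sprintf("%-10s", rownames(D)[i]),
                       sprintf("%.6f", D[i, ])), collapse = " "), con)
  }
  invisible(path)
}
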