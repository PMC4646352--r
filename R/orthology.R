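empty_hits <- function() {
  data.frame(query = character(), subject = character(),
             query_species = character(), subject_species = character(),
             raw_score = integer(), bit_score = numeric(),
             identity = numeric(), qcov = numeric(), scov = numeric(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), stringsAsFactors = FALSE)
}

#' All-vs-all filtered similarity search between two proteomes
#'
#' Aligns every cross pair with [local_align()] and keeps only records
#' passing [hit_filter()]. Both directions of each passing pair are emitted
#' (bit score is symmetric; coverages swap). When `a` and `b` are the same
#' proteome (paralog search), self-pairs are skipped.
#'
#' @param a,b [proteome()] objects.
#' @param scheme A [scoring_scheme()].
#' @param min_bits,min_coverage Filter thresholds (see [hit_filter()]).
#' @return A hit table data.frame (query, subject, species, scores,
#'   identity, coverages, 0-based half-open spans) with attribute
#'   `ruled_out`: ids of proteins with no surviving hit.
#' @export
all_vs_all <- function(a, b, scheme = scoring_scheme(), min_bits = 200,
                       min_coverage = 0.5) {
  sp_a <- attr(a, "species"); sp_b <- attr(b, "species")
  stopifnot(length(a) > 0, length(b) > 0)
  same <- identical(sp_a, sp_b) && identical(names(a), names(b))
  rows <- list(); k <- 0L
  for (i in seq_along(a)) {
    jj <- if (same) seq_len(i - 1L) else seq_along(b)
    for (j in jj) {
      r <- local_align(a[[i]], b[[j]], scheme,
                       query_id = names(a)[i], subject_id = names(b)[j])
      if (hit_filter(r, min_bits, min_coverage)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          query = names(a)[i], subject = names(b)[j],
          query_species = sp_a, subject_species = sp_b,
          raw_score = r$raw_score, bit_score = r$bit_score,
          identity = r$identity_fraction,
          qcov = r$coverage_query, scov = r$coverage_subject,
          qstart = r$aligned_span_query[1], qend = r$aligned_span_query[2],
          sstart = r$aligned_span_subject[1], send = r$aligned_span_subject[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  fwd <- if (k > 0) do.call(rbind, rows) else empty_hits()
  rev <- fwd
  if (nrow(fwd) > 0) {
    rev[, c("query", "subject")] <- fwd[, c("subject", "query")]
    rev[, c("query_species", "subject_species")] <-
      fwd[, c("subject_species", "query_species")]
    rev[, c("qcov", "scov")] <- fwd[, c("scov", "qcov")]
    rev[, c("qstart", "qend", "sstart", "send")] <-
      fwd[, c("sstart", "send", "qstart", "qend")]
  }
  out <- rbind(fwd, rev)
  rownames(out) <- NULL
  hit_ids <- unique(c(out$query, out$subject))
  ruled_out <- setdiff(c(names(a), if (!same) names(b)), hit_ids)
  attr(out, "ruled_out") <- ruled_out
  out
}

# deterministic best hit per query: max bits, ties by identity, then
# lexicographically smallest subject id
best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$query, -hits$bit_score, -hits$identity, hits$subject)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$query), , drop = FALSE]
}

#' Reciprocal best hits between two species
#'
#' The best hit per query is the maximal bit score (ties broken by higher
#' identity, then smallest subject id); a pair is kept iff mutual.
#'
#' @param table A hit table from [all_vs_all()] containing both directions.
#' @param species_a,species_b Species labels present in the table.
#' @return Data.frame of ortholog pairs: `gene_a` (species_a), `gene_b`,
#'   `bits_ab`, `bits_ba`.
#' @export
reciprocal_best_hits <- function(table, species_a, species_b) {
  ab <- table[table$query_species == species_a &
                table$subject_species == species_b, , drop = FALSE]
  ba <- table[table$query_species == species_b &
                table$subject_species == species_a, , drop = FALSE]
  if ((nrow(ab) == 0) != (nrow(ba) == 0))
    stop("hit table is missing one direction for ",
         species_a, " vs ", species_b)
  if (nrow(ab) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      bits_ab = numeric(), bits_ba = numeric(),
                      stringsAsFactors = FALSE))
  fa <- best_hits(ab); fb <- best_hits(ba)
  back <- setNames(fb$subject, fb$query) # best hit of each b-gene
  keep <- !is.na(back[fa$subject]) & back[fa$subject] == fa$query
  fa <- fa[keep, , drop = FALSE]
  bits_ba <- fb$bit_score[match(fa$subject, fb$query)]
  out <- data.frame(gene_a = fa$query, gene_b = fa$subject,
                    bits_ab = fa$bit_score, bits_ba = bits_ba,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_a), , drop = FALSE]
}

#' Assemble pivot-anchored orthologous groups
#'
#' One orthologous group (OG) per pivot gene with at least one reciprocal
#' best hit partner. Pivot genes with no partner anywhere are reported as
#' pivot-specific.
#'
#' @param pairs_by_species Named list (species label -> RBH table of pivot vs
#'   that species, as from [reciprocal_best_hits()] with the pivot as
#'   species_a).
#' @param pivot_id Pivot species label.
#' @param pivot_genes Optional character vector of all pivot gene ids (used
#'   to report pivot-specific genes).
#' @param lineages Optional named list (lineage -> species labels) used to
#'   flag OGs present in every species of a lineage as that lineage's core.
#' @return Object of class `og_set`: `ogs` (data.frame og_id, anchor,
#'   species, member_id, role, bits), `presence` (OG x species 0/1 member
#'   counts matrix), `pivot_specific`, `core` (named list per lineage),
#'   `pivot`, `species`.
#' @export
build_ogs <- function(pairs_by_species, pivot_id, pivot_genes = NULL,
                      lineages = NULL) {
  species <- names(pairs_by_species)
  stopifnot(length(species) > 0)
  anchors <- sort(unique(unlist(lapply(pairs_by_species,
                                       function(p) p$gene_a))))
  rows <- list()
  for (a in anchors) {
    og <- paste0("OG_", a)
    rows[[length(rows) + 1L]] <- data.frame(
      og_id = og, anchor = a, species = pivot_id, member_id = a,
      role = "anchor", bits = NA_real_, stringsAsFactors = FALSE)
    for (sp in species) {
      p <- pairs_by_species[[sp]]
      hit <- p[p$gene_a == a, , drop = FALSE]
      if (nrow(hit) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          og_id = og, anchor = a, species = sp, member_id = hit$gene_b[1],
          role = "ortholog", bits = hit$bits_ab[1], stringsAsFactors = FALSE)
      }
    }
  }
  ogs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(og_id = character(), anchor = character(),
               species = character(), member_id = character(),
               role = character(), bits = numeric(), stringsAsFactors = FALSE)
  og_ids <- paste0("OG_", anchors)
  all_species <- c(pivot_id, species)
  presence <- matrix(0L, length(og_ids), length(all_species),
                     dimnames = list(og_ids, all_species))
  for (r in seq_len(nrow(ogs)))
    presence[ogs$og_id[r], ogs$species[r]] <-
      presence[ogs$og_id[r], ogs$species[r]] + 1L
  core <- NULL
  if (!is.null(lineages)) {
    core <- lapply(lineages, function(sps) {
      sps <- intersect(sps, species)
      if (!length(sps)) return(character(0))
      rownames(presence)[rowSums(presence[, sps, drop = FALSE] > 0) ==
                           length(sps)]
    })
  }
  pivot_specific <- if (is.null(pivot_genes)) character(0)
  else setdiff(pivot_genes, anchors)
  structure(list(ogs = ogs, presence = presence, anchors = anchors,
                 pivot_specific = pivot_specific, core = core,
                 pivot = pivot_id, species = all_species),
            class = "og_set")
}

#' @export
print.og_set <- function(x, ...) {
  cat(sprintf("OG set anchored on %s: %d OGs over %d species (%d pivot-specific)\n",
              x$pivot, length(x$anchors), length(x$species),
              length(x$pivot_specific)))
  invisible(x)
}

#' Attach within-species paralogs to orthologous groups
#'
#' For every species, genes that are not OG members but whose best
#' filter-passing within-species hit lands on an OG member (or on the pivot's
#' anchor genes for the pivot species) are attached as paralogs of that
#' member's group. Each gene attaches to at most one OG (highest bit score,
#' ties broken by identity then smallest subject id).
#'
#' @param og An [build_ogs()] result.
#' @param within_species_hits Named list (species -> within-species hit table
#'   from `all_vs_all(p, p, ...)`).
#' @return The `og_set` with paralog rows (`role = "paralog"`) appended and
#'   the presence matrix updated.
#' @export
attach_paralogs <- function(og, within_species_hits) {
  member_og <- setNames(og$ogs$og_id, og$ogs$member_id) # anchors included
  rows <- list()
  for (sp in names(within_species_hits)) {
    hits <- within_species_hits[[sp]]
    if (is.null(hits) || nrow(hits) == 0) next
    target_og <- member_og[names(member_og) %in%
                             og$ogs$member_id[og$ogs$species == sp]]
    onto <- hits[hits$subject %in% names(target_og) &
                   !(hits$query %in% names(target_og)), , drop = FALSE]
    if (nrow(onto) == 0) next
    bh <- best_hits(onto)
    for (r in seq_len(nrow(bh))) {
      ogid <- unname(target_og[bh$subject[r]])
      rows[[length(rows) + 1L]] <- data.frame(
        og_id = ogid, anchor = sub("^OG_", "", ogid), species = sp,
        member_id = bh$query[r], role = "paralog", bits = bh$bit_score[r],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    para <- do.call(rbind, rows)
    og$ogs <- rbind(og$ogs, para)
    for (r in seq_len(nrow(para)))
      og$presence[para$og_id[r], para$species[r]] <-
        og$presence[para$og_id[r], para$species[r]] + 1L
  }
  og
}

#' Venn region counts for a list of sets
#'
#' @param sets Named list of character vectors.
#' @return Named integer vector over the `2^n - 1` non-empty region
#'   memberships; names join the member set names with `&`.
#' @export
venn_regions <- function(sets) {
  n <- length(sets)
  stopifnot(n >= 1, !is.null(names(sets)))
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, names(sets)))
  masks <- seq_len(2^n - 1)
  counts <- integer(length(masks))
  names(counts) <- vapply(masks, function(m) {
    paste(names(sets)[bitwAnd(m, 2^(seq_len(n) - 1)) > 0], collapse = "&")
  }, character(1))
  if (length(universe) > 0) {
    code <- as.integer(memb %*% 2^(seq_len(n) - 1))
    tab <- table(code)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  counts
}

#' Basal orthologous groups by n-way intersection
#'
#' Intersects two or more OG collections that share the outgroup's gene
#' identifiers as keys (e.g. outgroup-vs-pivot comparisons). The basal
#' orthologous groups (BOGs) are the outgroup genes whose OGs appear in
#' every compared collection; all `2^n - 1` Venn region counts are computed
#' and sum to the size of the union.
#'
#' @param og_sets Named list of either `og_set` objects (anchored on the
#'   outgroup) or character vectors of outgroup gene ids.
#' @return Object of class `bog_set`: `bogs` (sorted outgroup gene ids),
#'   `venn_counts`, `union_size`, `sets`.
#' @export
intersect_bogs <- function(og_sets) {
  stopifnot(length(og_sets) >= 2, !is.null(names(og_sets)))
  sets <- lapply(og_sets, function(x) {
    if (inherits(x, "og_set")) x$anchors else as.character(x)
  })
  bogs <- sort(Reduce(intersect, sets))
  venn <- venn_regions(sets)
  structure(list(bogs = bogs, venn_counts = venn,
                 union_size = length(unique(unlist(sets))), sets = sets),
            class = "bog_set")
}

#' @export
print.bog_set <- function(x, ...) {
  cat(sprintf("BOG set: %d basal orthologous groups (union %d)\n",
              length(x$bogs), x$union_size))
  invisible(x)
}

#' Write a hit table in BLAST outfmt-6-like TSV
#'
#' Columns: qseqid, sseqid, pident, length, qstart, qend, sstart, send,
#' bitscore, qcovs, scovs. Coordinates are converted to 1-based inclusive in
#' this format for ecosystem compatibility (internally the package uses
#' 0-based half-open intervals).
#'
#' @param hits Hit table from [all_vs_all()].
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(qseqid = hits$query, sseqid = hits$subject,
                    pident = round(100 * hits$identity, 2),
                    length = hits$qend - hits$qstart,
                    qstart = hits$qstart + 1L, qend = hits$qend,
                    sstart = hits$sstart + 1L, send = hits$send,
                    bitscore = round(hits$bit_score, 1),
                    qcovs = round(hits$qcov, 3), scovs = round(hits$scov, 3),
                    stringsAsFactors = FALSE)
  cat("# qseqid\tsseqid\tpident\tlength\tqstart\tqend\tsstart\tsend\tbitscore\tqcovs\tscovs (1-based inclusive)\n",
      file = path)
  suppressWarnings(write.table(out, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE,
                               append = TRUE))
  invisible(path)
}
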