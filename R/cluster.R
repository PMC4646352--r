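#' Greedy redundancy clustering at an identity cutoff
#'
#' Incremental clustering in the style of CD-HIT: sequences are sorted by
#' length (longest first, ties by identifier) and each sequence joins the
#' first existing cluster whose representative it matches at
#' `identity >= identity_cutoff`, otherwise it founds a new cluster.
#' Identity is counted as identical aligned residues divided by the shorter
#' sequence's length, computed from the package's local alignment.
#'
#' @param seqs Named character vector of protein sequences (>= 1).
#' @param identity_cutoff Identity threshold in (0, 1], default 0.7.
#' @param scheme A [scoring_scheme()] for the underlying alignments.
#' @return Object of class `redundancy_clustering`: list with `clusters`
#'   (named list, representative id -> member ids including the
#'   representative), `representative` (named vector member -> rep),
#'   `identity_cutoff`.
#' @export
cluster_redundant <- function(seqs, identity_cutoff = 0.7,
                              scheme = scoring_scheme()) {
  stopifnot(length(seqs) >= 1, identity_cutoff > 0, identity_cutoff <= 1)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  members <- list()
  assignment <- character(length(seqs)); names(assignment) <- names(seqs)
  for (id in names(seqs)) {
    placed <- FALSE
    for (rep_id in reps) {
      aln <- local_align(seqs[[id]], seqs[[rep_id]], scheme)
      ident <- aln$n_identical / min(nchar(seqs[[id]]), nchar(seqs[[rep_id]]))
      if (ident >= identity_cutoff) {
        members[[rep_id]] <- c(members[[rep_id]], id)
        assignment[id] <- rep_id
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[id]] <- id
      assignment[id] <- id
    }
  }
  structure(list(clusters = members, representative = assignment,
                 identity_cutoff = identity_cutoff),
            class = "redundancy_clustering")
}

#' @export
print.redundancy_clustering <- function(x, ...) {
  cat(sprintf("redundancy clustering: %d sequences -> %d clusters (cutoff %.2f)\n",
              length(x$representative), length(x$clusters), x$identity_cutoff))
  invisible(x)
}
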