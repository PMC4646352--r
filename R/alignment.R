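#' Scoring scheme for local protein alignment
#'
#' Bundles the substitution matrix, affine gap penalties, and the
#' Karlin-Altschul parameters used to convert raw alignment scores into bit
#' scores. Defaults are the standard gapped BLOSUM62 / 11 / 1 constants
#' (lambda = 0.267, K = 0.041). Opening a gap costs
#' `gap_open + gap_extend` for its first position and `gap_extend` for each
#' additional position, the BLAST accounting dialect.
#'
#' @param matrix 20x20 integer substitution matrix over the standard
#'   amino-acid alphabet (default BLOSUM62).
#' @param gap_open Positive integer gap-opening penalty.
#' @param gap_extend Positive integer gap-extension penalty
#'   (`gap_extend <= gap_open`).
#' @param lambda,K Karlin-Altschul statistics for the matrix/gap combination.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) matrix <- blosum62_matrix()
  matrix <- as.matrix(matrix)
  stopifnot(nrow(matrix) == 20, ncol(matrix) == 20)
  if (!isTRUE(all.equal(matrix, t(matrix), check.attributes = FALSE)))
    stop("substitution matrix must be symmetric")
  storage.mode(matrix) <- "integer"
  dimnames(matrix) <- list(AA20, AA20)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  stopifnot(gap_open > 0, gap_extend > 0, gap_extend <= gap_open,
            lambda > 0, K > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps (Gotoh three-matrix recurrence). One
#' optimal alignment is reported with deterministic traceback tie-breaking:
#' diagonal first, then gap-in-subject, then gap-in-query.
#'
#' @param a,b Non-empty protein sequences (single strings over the 20-letter
#'   alphabet).
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Optional sequence identifiers carried into the
#'   result.
#' @return An `alignment_result` list: `raw_score`, `bit_score`,
#'   `identity_fraction` (identical pairs / aligned columns), per-sequence
#'   coverages, 0-based half-open aligned spans, and the identical/column
#'   counts.
#' @export
local_align <- function(a, b, scheme = scoring_scheme(),
                        query_id = NA_character_, subject_id = NA_character_) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  qi <- aa_encode(a); si <- aa_encode(b)
  r <- sw_align_cpp(qi, si, scheme$matrix, scheme$gap_open, scheme$gap_extend)
  len_q <- nchar(a); len_s <- nchar(b)
  span_q <- c(r$qstart, r$qend); span_s <- c(r$sstart, r$send)
  structure(list(
    query_id = query_id, subject_id = subject_id,
    raw_score = r$score,
    bit_score = bit_score(r$score, scheme),
    aligned_span_query = span_q, aligned_span_subject = span_s,
    n_identical = r$n_identical, n_columns = r$n_columns,
    identity_fraction = if (r$n_columns > 0) r$n_identical / r$n_columns else 0,
    coverage_query = (span_q[2] - span_q[1]) / len_q,
    coverage_subject = (span_s[2] - span_s[1]) / len_s,
    query_length = len_q, subject_length = len_s),
    class = "alignment_result")
}

#' Convert a raw local-alignment score to bits
#'
#' Karlin-Altschul normalisation: `bits = (lambda * raw - ln K) / ln 2`.
#'
#' @param raw Non-negative raw score.
#' @param scheme A [scoring_scheme()] providing lambda and K.
#' @return Bit score (numeric).
#' @export
bit_score <- function(raw, scheme = scoring_scheme()) {
  stopifnot(all(raw >= 0))
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

#' Significance filter on an alignment result
#'
#' A hit passes when its bit score exceeds `min_bits` and the alignment covers
#' at least `min_coverage` of *both* sequences' lengths (set
#' `both_lengths = FALSE` for a query-only coverage reading).
#'
#' @param result An [local_align()] result.
#' @param min_bits Bit-score cutoff (exclusive), default 200.
#' @param min_coverage Minimum coverage (inclusive), default 0.5.
#' @param both_lengths Require coverage on both sequences (default) or on the
#'   query alone.
#' @return Logical scalar.
#' @export
hit_filter <- function(result, min_bits = 200, min_coverage = 0.5,
                       both_lengths = TRUE) {
  cov_ok <- if (both_lengths)
    result$coverage_query >= min_coverage &&
      result$coverage_subject >= min_coverage
  else result$coverage_query >= min_coverage
  result$bit_score > min_bits && cov_ok
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("local alignment %s vs %s: raw %d, %.1f bits, id %.3f, cov %.2f/%.2f\n",
              x$query_id, x$subject_id, x$raw_score, x$bit_score,
              x$identity_fraction, x$coverage_query, x$coverage_subject))
  invisible(x)
}
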