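#' Read or construct a seed alignment
#'
#' A seed alignment is a character matrix (rows = sequences, columns =
#' alignment columns) over the 20 amino acids plus `-` for gaps.
#'
#' @param x Either a path to an aligned FASTA file or a character vector of
#'   equal-length aligned sequences (optionally named).
#' @return Object of class `seed_alignment`: list with `rows` (character
#'   matrix), `row_ids`, `column_count`.
#' @export
seed_alignment <- function(x) {
  if (length(x) == 1 && file.exists(x)) {
    ss <- Biostrings::readAAStringSet(x)
    x <- setNames(as.character(ss), names(ss))
  }
  if (length(x) < 2) stop("a seed alignment needs at least 2 rows")
  widths <- nchar(x)
  if (length(unique(widths)) != 1) stop("aligned rows must have equal length")
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seed", seq_along(x))
  m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
  rownames(m) <- ids
  bad <- setdiff(unique(as.vector(m)), c(AA20, "-", "."))
  if (length(bad))
    stop("illegal alignment symbol(s): ", paste(bad, collapse = ", "))
  m[m == "."] <- "-"
  structure(list(rows = m, row_ids = ids, column_count = ncol(m)),
            class = "seed_alignment")
}

#' Build a profile HMM from a seed alignment
#'
#' Columns containing any gap are excluded from the match-state set (the
#' strict reading of the gap-column rule; `max_gap_frac` relaxes this to a
#' fractional-occupancy rule). The retained columns become match states in
#' order. Match emissions are pseudocount-smoothed observed frequencies,
#' `(count + w * background) / (n_obs + w)`, reported as log2-odds against the
#' background; insert states emit at background. Transitions are estimated
#' from retained-column adjacency with Laplace (+1) smoothing.
#'
#' @param seed A [seed_alignment()].
#' @param pseudocount_weight Positive total pseudocount weight `w`.
#' @param max_gap_frac Maximum gap fraction a column may have and still become
#'   a match state; the default `0` is the strict any-gap exclusion rule.
#' @return Object of class `profile_hmm`.
#' @export
build_profile <- function(seed, pseudocount_weight = 1, max_gap_frac = 0) {
  stopifnot(inherits(seed, "seed_alignment"), pseudocount_weight > 0,
            max_gap_frac >= 0, max_gap_frac < 1)
  m <- seed$rows
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= max_gap_frac)
  if (length(keep) == 0)
    stop("every alignment column contains gaps; no match states can be built")
  K <- length(keep)
  bg <- aa_background()
  w <- pseudocount_weight

  probs <- matrix(0, K, 20, dimnames = list(NULL, AA20))
  for (k in seq_len(K)) {
    col <- m[, keep[k]]
    col <- col[col != "-"]
    cnt <- table(factor(col, levels = AA20))
    probs[k, ] <- (as.numeric(cnt) + w * bg) / (length(col) + w)
  }
  logodds <- log2(sweep(probs, 2, bg, "/"))

  # transition counts across the K-1 inter-column gaps
  trans <- list(mm = NULL, mi = NULL, md = NULL, im = NULL, ii = NULL,
                dm = NULL, dd = NULL)
  if (K > 1) {
    cmm <- cmi <- cmd <- cim <- cii <- cdm <- cdd <- rep(1, K - 1) # Laplace
    for (r in seq_len(nrow(m))) {
      row <- m[r, ]
      present <- row[keep] != "-"
      for (k in seq_len(K - 1)) {
        between <- row[seq.int(keep[k] + 1L, length.out = keep[k + 1] - keep[k] - 1L)]
        nins <- sum(between != "-")
        from_m <- present[k]; to_m <- present[k + 1]
        if (from_m && nins == 0 && to_m) cmm[k] <- cmm[k] + 1
        if (from_m && nins == 0 && !to_m) cmd[k] <- cmd[k] + 1
        if (from_m && nins > 0) cmi[k] <- cmi[k] + 1
        if (nins > 1) cii[k] <- cii[k] + (nins - 1)
        if (nins > 0 && to_m) cim[k] <- cim[k] + 1
        # inserts between a delete and the next column are rare; fold the
        # delete-side bookkeeping into the pure delete transitions
        if (!from_m && to_m) cdm[k] <- cdm[k] + 1
        if (!from_m && !to_m) cdd[k] <- cdd[k] + 1
      }
    }
    msum <- cmm + cmi + cmd; isum <- cim + cii; dsum <- cdm + cdd
    trans <- list(mm = log2(cmm / msum), mi = log2(cmi / msum),
                  md = log2(cmd / msum), im = log2(cim / isum),
                  ii = log2(cii / isum), dm = log2(cdm / dsum),
                  dd = log2(cdd / dsum))
  } else {
    trans <- lapply(trans, function(z) numeric(0))
  }

  consensus <- AA20[apply(probs, 1, which.max)]
  structure(list(
    n_match = K, match_probs = probs, match_logodds = logodds,
    transitions = trans, background = bg, retained_columns = keep,
    consensus = paste(consensus, collapse = ""),
    pseudocount_weight = w, score_threshold_bits = NULL),
    class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile HMM: %d match states, consensus %s\n", x$n_match,
              x$consensus))
  if (!is.null(x$score_threshold_bits))
    cat(sprintf("  calibrated threshold: %.2f bits\n", x$score_threshold_bits))
  invisible(x)
}

#' Score a protein sequence against a profile HMM
#'
#' Local Viterbi: the best-scoring state path may enter and leave the model at
#' any match state, and unaligned flanking residues are unscored (background).
#' Scores are in bits (log2-odds against the background null). Unknown
#' residues (X, B, Z, U, ...) emit at background, contributing 0 bits.
#'
#' @param hmm A [build_profile()] model.
#' @param seq Non-empty protein sequence (single string).
#' @param protein_id Optional identifier carried into the hit.
#' @return A `domain_hit` list: `protein_id`, `score_bits`, `envelope`
#'   (0-based half-open residue interval consumed by match/insert states),
#'   and a state-path summary (match/insert/delete counts, model columns
#'   spanned).
#' @export
viterbi_score <- function(hmm, seq, protein_id = NA_character_) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (!nzchar(seq)) stop("cannot score an empty sequence")
  code <- aa_encode(seq, strict = FALSE)
  emis <- cbind(hmm$match_logodds, 0) # unknown-residue column
  tr <- hmm$transitions
  r <- viterbi_cpp(code, emis, tr$mm, tr$mi, tr$md, tr$im, tr$ii, tr$dm, tr$dd)
  structure(list(
    protein_id = protein_id, score_bits = r$score_bits,
    envelope = c(r$env_start, r$env_end),
    path_summary = c(match = r$n_match, insert = r$n_insert,
                     delete = r$n_delete),
    model_span = c(r$first_match_state, r$last_match_state)),
    class = "domain_hit")
}

#' Per-column information content of a profile HMM
#'
#' Relative entropy of each match state against the background,
#' `sum_a p(a) log2(p(a)/bg(a))`, plus the per-residue letter heights
#' `p(a) * content` used for logo rendering.
#'
#' @param hmm A [build_profile()] model.
#' @return List with `bits` (numeric, one per match state) and `heights`
#'   (matrix, match states x residues).
#' @export
column_information <- function(hmm) {
  stopifnot(inherits(hmm, "profile_hmm"))
  bits <- rowSums(hmm$match_probs * hmm$match_logodds)
  heights <- sweep(hmm$match_probs, 1, bits, "*")
  list(bits = bits, heights = heights)
}

#' Calibrate the acceptance threshold of a profile HMM
#'
#' Scores the (ungapped) seed rows with the model and compares them with an
#' empirical null of background-random sequences of matched lengths. The
#' threshold is the midpoint between the minimum seed score and the 99.9th
#' percentile of the null scores. When the distributions overlap (minimum
#' seed score at or below the null percentile) the calibration failure is
#' surfaced with a warning and the threshold is set to the null percentile.
#'
#' @param hmm A [build_profile()] model.
#' @param seed The [seed_alignment()] the model was built from.
#' @param null_samples Number of background-random null sequences.
#' @param seed_rng Integer seed for the null draw (determinism).
#' @return List of class `hmm_calibration`: `threshold_bits`,
#'   `min_seed_score`, `null_quantile`, `seed_scores`, `null_scores`.
#' @export
calibrate_threshold <- function(hmm, seed, null_samples = 1000,
                                seed_rng = 1L) {
  stopifnot(inherits(hmm, "profile_hmm"), inherits(seed, "seed_alignment"))
  rows <- apply(seed$rows, 1, function(r) paste(r[r != "-"], collapse = ""))
  rows <- rows[nzchar(rows)]
  seed_scores <- vapply(rows, function(s) viterbi_score(hmm, s)$score_bits,
                        numeric(1))
  lens <- nchar(rows)
  withr_seed <- function(expr) { # local RNG scope
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed_rng); expr
  }
  nulls <- withr_seed(random_proteins(
    null_samples, lens[sample.int(length(lens), null_samples, replace = TRUE)]))
  null_scores <- vapply(nulls, function(s) viterbi_score(hmm, s)$score_bits,
                        numeric(1), USE.NAMES = FALSE)
  q <- unname(quantile(null_scores, 0.999, type = 7))
  lo <- min(seed_scores)
  if (lo <= q) {
    warning("calibration failure: seed scores overlap the null distribution; ",
            "threshold set to the null 99.9th percentile")
    thr <- q
  } else {
    thr <- (lo + q) / 2
  }
  structure(list(threshold_bits = thr, min_seed_score = lo, null_quantile = q,
                 seed_scores = seed_scores, null_scores = null_scores),
            class = "hmm_calibration")
}

#' Apply a calibrated threshold to a model
#'
#' @param hmm A [build_profile()] model.
#' @param calibration A [calibrate_threshold()] result, or a numeric bit
#'   threshold.
#' @return The model with `score_threshold_bits` set.
#' @export
set_threshold <- function(hmm, calibration) {
  hmm$score_threshold_bits <- if (is.numeric(calibration)) calibration
  else calibration$threshold_bits
  hmm
}

#' Scan proteomes for family members
#'
#' Every protein scoring at or above the model threshold is returned with its
#' single best-scoring envelope.
#'
#' @param hmm A [build_profile()] model with `score_threshold_bits` set (see
#'   [set_threshold()]), or pass `threshold` explicitly.
#' @param proteomes A single proteome (named character vector of sequences
#'   with a `species` attribute, see [proteome()]) or a list of them.
#' @param threshold Bit-score cutoff; defaults to the model's calibrated one.
#' @return A data.frame of hits: `protein_id`, `species`, `score_bits`,
#'   `env_start`, `env_end` (0-based half-open), plus a `counts` attribute
#'   with per-species hit counts.
#' @export
scan_proteomes <- function(hmm, proteomes, threshold = NULL) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (is.null(threshold)) threshold <- hmm$score_threshold_bits
  if (is.null(threshold))
    stop("no score threshold: calibrate the model or pass `threshold`")
  if (!is.list(proteomes)) proteomes <- list(proteomes)
  out <- lapply(proteomes, function(p) {
    sp <- attr(p, "species")
    if (is.null(sp)) sp <- NA_character_
    hits <- lapply(names(p), function(id) {
      h <- viterbi_score(hmm, p[[id]], protein_id = id)
      if (is.finite(h$score_bits) && h$score_bits >= threshold)
        data.frame(protein_id = id, species = sp,
                   score_bits = h$score_bits,
                   env_start = h$envelope[1], env_end = h$envelope[2],
                   stringsAsFactors = FALSE)
      else NULL
    })
    do.call(rbind, hits)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(protein_id = character(), species = character(),
                      score_bits = numeric(), env_start = integer(),
                      env_end = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "counts") <- table(res$species)
  res
}
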