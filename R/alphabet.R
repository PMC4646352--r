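#' @useDynLib orthofam, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rexp rpois runif rbinom quantile setNames
#' @importFrom utils write.table read.table head
NULL

# The 20-letter amino-acid alphabet in the conventional BLOSUM ordering.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# BLOSUM62 background (Robinson-Robinson style) amino-acid frequencies,
# renormalised to sum to one. Used as the stationary distribution of the
# sequence simulator, the null model of the profile HMM, and the insert-state
# emission distribution.
BLOSUM62_BG <- local({
  p <- c(A = 0.0742, R = 0.0520, N = 0.0449, D = 0.0536, C = 0.0247,
         Q = 0.0341, E = 0.0543, G = 0.0741, H = 0.0262, I = 0.0679,
         L = 0.0989, K = 0.0582, M = 0.0247, F = 0.0475, P = 0.0390,
         S = 0.0572, T = 0.0511, W = 0.0130, Y = 0.0321, V = 0.0730)
  p / sum(p)
})

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
              L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Background amino-acid frequencies
#'
#' The BLOSUM62 background distribution used throughout the package as the
#' null amino-acid model (decoys, profile-HMM background, alignment
#' statistics).
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_background <- function() BLOSUM62_BG

# Soluble-protein composition: BLOSUM62 background with the strongly
# hydrophobic residues downweighted (x0.45) and renormalised. Used as the
# simulator's stationary distribution so that non-membrane family proteins
# rarely contain spurious transmembrane-like windows, as is true of real
# soluble transcription factors; membrane character enters only through the
# explicit TM-segment insertion.
SOLUBLE_BG <- local({
  p <- BLOSUM62_BG
  hydro <- c("I", "L", "V", "F", "M", "A", "C", "W")
  p[hydro] <- p[hydro] * 0.45
  p / sum(p)
})

#' Soluble-protein stationary amino-acid frequencies
#'
#' Polar-biased composition used by the sequence simulator for family
#' proteins (see the package vignette for rationale).
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_soluble_background <- function() SOLUBLE_BG

# Map residues to 0-based integer codes for the C++ kernels.
# strict = TRUE errors on anything outside the 20-letter alphabet;
# strict = FALSE maps unknowns (X, B, Z, U, ...) to code 20 ("background").
aa_encode <- function(seq, strict = TRUE) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, AA20)
  if (anyNA(idx)) {
    if (strict) {
      bad <- chars[which(is.na(idx))[1]]
      stop("non-amino-acid symbol '", bad, "' in sequence", call. = FALSE)
    }
    idx[is.na(idx)] <- 21L
  }
  as.integer(idx - 1L)
}

#' Sample random protein sequences from the background distribution
#'
#' @param n Number of sequences.
#' @param length Either a single length or a vector (recycled) of lengths.
#' @param freq Amino-acid frequencies (defaults to [aa_background()]).
#' @return Character vector of sequences.
#' @export
random_proteins <- function(n, length, freq = aa_background()) {
  length <- rep_len(length, n)
  vapply(seq_len(n), function(i) {
    paste(sample(AA20, length[i], replace = TRUE, prob = freq), collapse = "")
  }, character(1))
}

# BLOSUM62 restricted to the 20-letter alphabet, cached per session.
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      m <- env$BLOSUM62[AA20, AA20]
      storage.mode(m) <- "integer"
      cache <<- m
    }
    cache
  }
})
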