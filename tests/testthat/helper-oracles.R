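# Independent oracles used to validate the package's optimised
# implementations. These deliberately use different algorithms/code paths.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Plain memoized-recursion Gotoh local alignment score (no vectorisation).
oracle_sw_score <- function(a, b, sub, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  open <- gap_open + gap_extend
  M <- X <- Y <- array(NA_real_, c(n + 1, m + 1))
  getM <- function(i, j) {
    if (i < 1 || j < 1) return(-Inf)
    if (!is.na(M[i + 1, j + 1])) return(M[i + 1, j + 1])
    prev <- max(0, getM(i - 1, j - 1), getX(i - 1, j - 1), getY(i - 1, j - 1))
    v <- sub[av[i], bv[j]] + prev
    M[i + 1, j + 1] <<- v
    v
  }
  getX <- function(i, j) { # gap in subject: consumes a[i]
    if (i < 1 || j < 0) return(-Inf)
    if (j == 0) return(-Inf)
    if (!is.na(X[i + 1, j + 1])) return(X[i + 1, j + 1])
    v <- max(max(0, getM(i - 1, j), getX(i - 1, j), getY(i - 1, j)) - open,
             getX(i - 1, j) - gap_extend)
    X[i + 1, j + 1] <<- v
    v
  }
  getY <- function(i, j) { # gap in query: consumes b[j]
    if (j < 1 || i < 0) return(-Inf)
    if (i == 0) return(-Inf)
    if (!is.na(Y[i + 1, j + 1])) return(Y[i + 1, j + 1])
    v <- max(max(0, getM(i, j - 1), getX(i, j - 1), getY(i, j - 1)) - open,
             getY(i, j - 1) - gap_extend)
    Y[i + 1, j + 1] <<- v
    v
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    best <- max(best, getM(i, j), getX(i, j), getY(i, j))
  }
  best
}

# Exhaustive enumeration of all legal local state paths through a profile
# HMM (entry/exit at match states), returning the best bit score.
oracle_viterbi_score <- function(hmm, seq) {
  x <- match(strsplit(seq, "")[[1]], AA)
  L <- length(x); K <- hmm$n_match
  e <- hmm$match_logodds
  tr <- hmm$transitions
  best <- -Inf
  extend <- function(state, i, k, score) {
    if (state == "M") best <<- max(best, score) # exit allowed here
    if (state == "M") {
      if (k < K && i < L)
        extend("M", i + 1, k + 1, score + tr$mm[k] + e[k + 1, x[i + 1]])
      if (k < K && i < L)
        extend("I", i + 1, k, score + tr$mi[k])
      if (k + 1 <= K)
        extend("D", i, k + 1, score + tr$md[k])
    } else if (state == "I") {
      if (i < L) extend("I", i + 1, k, score + tr$ii[k])
      if (i < L && k < K)
        extend("M", i + 1, k + 1, score + tr$im[k] + e[k + 1, x[i + 1]])
    } else { # D
      if (k < K && i < L)
        extend("M", i + 1, k + 1, score + tr$dm[k] + e[k + 1, x[i + 1]])
      if (k + 1 <= K)
        extend("D", i, k + 1, score + tr$dd[k])
    }
  }
  for (i0 in seq_len(L)) for (k0 in seq_len(K)) {
    extend("M", i0, k0, e[k0, x[i0]])
  }
  best
}

# Quadratic brute-force motif finder over all windows.
oracle_motif_positions <- function(pattern, seq) {
  chars <- strsplit(seq, "")[[1]]
  k <- pattern$length
  pos <- integer(0)
  if (length(chars) >= k) {
    for (s in seq_len(length(chars) - k + 1)) {
      win <- chars[s:(s + k - 1)]
      if (all(vapply(seq_len(k), function(e)
        win[e] %in% pattern$elements[[e]], logical(1))))
        pos <- c(pos, s - 1L)
    }
  }
  pos
}

# Sliding-window means by direct summation (oracle for the cumulative-sum
# implementation).
oracle_window_means <- function(seq, window) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  h <- unname(kd[strsplit(seq, "")[[1]]])
  n <- length(h)
  if (n < window) return(numeric(0))
  vapply(seq_len(n - window + 1), function(s) sum(h[s:(s + window - 1)]) / window,
         numeric(1))
}

# Brute-force Venn region counts by per-element membership enumeration.
oracle_venn <- function(sets) {
  u <- unique(unlist(sets))
  out <- integer(2^length(sets) - 1)
  for (el in u) {
    mask <- sum(2^(which(vapply(sets, function(s) el %in% s, logical(1))) - 1))
    out[mask] <- out[mask] + 1L
  }
  out
}

# MRCA classification via explicit ancestor-set intersection (different
# algorithm from the package's common-prefix walk).
oracle_classify_pair <- function(history, id_a, id_b) {
  nodes <- history$nodes
  anc <- function(id) {
    nd <- history$leaves$node_id[history$leaves$id == id]
    out <- integer(0)
    while (nd != 0L) { out <- c(out, nd); nd <- nodes$parent[nd] }
    out
  }
  common <- intersect(anc(id_a), anc(id_b))
  mrca <- common[which.max(nodes$time[common])]
  if (nodes$type[mrca] == "speciation") "ortholog" else "paralog"
}

# Small random profile HMM built from a random gapless alignment.
random_hmm <- function(n_match, n_rows = 4, seed = 1) {
  set.seed(seed)
  rows <- vapply(seq_len(n_rows), function(i)
    paste(sample(AA, n_match, replace = TRUE), collapse = ""), character(1))
  names(rows) <- paste0("r", seq_len(n_rows))
  build_profile(seed_alignment(rows))
}
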