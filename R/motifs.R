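#' Compile a motif pattern string
#'
#' Patterns are ordered residue sets: a literal amino acid is a singleton, a
#' bracket `[...]` is the set of listed residues, and `x`/`X` (inside or
#' outside brackets) denotes any residue. Example diagnostic motifs of the
#' family are the LP-box `LP[QX]L[ED]SP`, the WQ-box
#' `W[RA]ALD[KR][FL][VL]ASQL`, `GxxFxP`, and `WxMHEY`.
#'
#' @param spec Pattern string.
#' @param name Optional motif name carried into matches.
#' @return Object of class `motif_pattern`: `name`, `elements` (list of
#'   residue character vectors), `length`.
#' @export
compile_pattern <- function(spec, name = spec) {
  chars <- strsplit(spec, "", fixed = TRUE)[[1]]
  if (length(chars) == 0) stop("empty pattern")
  elements <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (length(close) == 0)
        stop("unbalanced bracket at position ", i, " in pattern '", spec, "'")
      close <- close[1]
      inner <- chars[seq.int(i + 1L, length.out = close - i - 1L)]
      if (length(inner) == 0)
        stop("empty bracket at position ", i, " in pattern '", spec, "'")
      if (any(inner %in% c("x", "X"))) {
        elements[[length(elements) + 1L]] <- AA20 # wildcard absorbs the class
      } else {
        inner <- toupper(inner)
        bad <- setdiff(inner, AA20)
        if (length(bad))
          stop("illegal residue '", bad[1], "' at position ", i,
               " in pattern '", spec, "'")
        elements[[length(elements) + 1L]] <- unique(inner)
      }
      i <- close + 1L
    } else if (ch == "]") {
      stop("unbalanced bracket at position ", i, " in pattern '", spec, "'")
    } else if (ch %in% c("x", "X")) {
      elements[[length(elements) + 1L]] <- AA20
      i <- i + 1L
    } else {
      up <- toupper(ch)
      if (!up %in% AA20)
        stop("illegal residue '", ch, "' at position ", i,
             " in pattern '", spec, "'")
      elements[[length(elements) + 1L]] <- up
      i <- i + 1L
    }
  }
  structure(list(name = name, elements = elements,
                 length = length(elements)), class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("motif %s: %d elements\n", x$name, x$length))
  invisible(x)
}

#' Scan a sequence for a motif
#'
#' In `one_per_sequence` mode (the default, mirroring single-occurrence motif
#' scanning) the leftmost satisfying window is returned; `exhaustive` mode
#' returns all windows.
#'
#' @param pattern A [compile_pattern()] result.
#' @param seq Protein sequence.
#' @param mode `"one_per_sequence"` or `"exhaustive"`.
#' @param protein_id Optional identifier carried into matches.
#' @return Data.frame of matches (`protein_id`, `name`, `start`, `end`
#'   0-based half-open, `match`); zero rows when absent.
#' @export
scan_motif <- function(pattern, seq, mode = c("one_per_sequence", "exhaustive"),
                       protein_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(inherits(pattern, "motif_pattern"))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(chars); k <- pattern$length
  hits <- list()
  if (L >= k) {
    for (s in seq_len(L - k + 1L)) {
      ok <- TRUE
      for (e in seq_len(k)) {
        if (!chars[s + e - 1L] %in% pattern$elements[[e]]) { ok <- FALSE; break }
      }
      if (ok) {
        hits[[length(hits) + 1L]] <- data.frame(
          protein_id = protein_id, name = pattern$name,
          start = s - 1L, end = s - 1L + k,
          match = paste(chars[seq.int(s, length.out = k)], collapse = ""),
          stringsAsFactors = FALSE)
        if (mode == "one_per_sequence") break
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(protein_id = character(), name = character(),
               start = integer(), end = integer(), match = character(),
               stringsAsFactors = FALSE)
}

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' Kyte-Doolittle hydropathy averaged over sliding windows; windows whose
#' mean exceeds `cutoff` are merged when overlapping. This is the classic
#' hydropathy heuristic standing in for an external transmembrane-topology
#' predictor; window 19 and cutoff 1.6 are its conventional parameters.
#'
#' @param seq Protein sequence.
#' @param window Window length (default 19).
#' @param cutoff Mean-hydropathy cutoff (default 1.6).
#' @param protein_id Optional identifier.
#' @return List of class `tm_prediction`: `segments` (data.frame
#'   `protein_id`, `start`, `end` 0-based half-open, `mean_hydropathy`),
#'   `has_tmm`. Sequences shorter than the window yield no segments.
#' @export
predict_tm <- function(seq, window = 19L, cutoff = 1.6,
                       protein_id = NA_character_) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  h <- unname(KD_SCALE[chars])
  h[is.na(h)] <- 0 # unknown residues are hydropathy-neutral
  L <- length(h)
  segs <- data.frame(protein_id = character(), start = integer(),
                     end = integer(), mean_hydropathy = numeric(),
                     stringsAsFactors = FALSE)
  if (L >= window) {
    cs <- c(0, cumsum(h))
    means <- (cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]) / window
    above <- which(means > cutoff)
    if (length(above)) {
      # merge overlapping/adjacent windows into maximal runs
      breaks <- c(0, which(diff(above) >= window), length(above))
      runs <- lapply(seq_len(length(breaks) - 1), function(i) {
        idx <- above[(breaks[i] + 1):breaks[i + 1]]
        s <- idx[1]; e <- idx[length(idx)] + window - 1L
        data.frame(protein_id = protein_id, start = s - 1L, end = e,
                   mean_hydropathy = mean(h[s:e]), stringsAsFactors = FALSE)
      })
      segs <- do.call(rbind, runs)
    }
  }
  structure(list(segments = segs, has_tmm = nrow(segs) > 0,
                 protein_id = protein_id), class = "tm_prediction")
}

#' Default diagnostic motif patterns of the family
#'
#' The signature motifs of the basal groups: the LP-box and WQ-box of the
#' first basal group and the conserved A-/D-subdomain residues.
#'
#' @return Named list of [compile_pattern()] objects.
#' @export
default_motifs <- function() {
  specs <- c("LP-box" = "LP[QX]L[ED]SP",
             "WQ-box" = "W[RA]ALD[KR][FL][VL]ASQL",
             "A-motif" = "GxxFxP",
             "D-motif" = "WxMHEY")
  lapply(setNames(names(specs), names(specs)),
         function(n) compile_pattern(specs[[n]], name = n))
}

#' Load motif patterns from a plain-text file
#'
#' One `name<TAB>pattern` per line; `#` lines are comments.
#'
#' @param path File path.
#' @return Named list of [compile_pattern()] objects.
#' @export
read_motifs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(parts, function(p) compile_pattern(p[2], name = p[1]))
  setNames(out, vapply(parts, `[[`, "", 1))
}

#' Annotate proteins with motifs and transmembrane segments
#'
#' @param proteomes Named list of [proteome()]s (or a single one).
#' @param motifs Named list of patterns (default [default_motifs()]).
#' @param ids Optional character vector restricting annotation to these
#'   protein ids.
#' @param window,cutoff Parameters of [predict_tm()].
#' @return Data.frame: `protein_id`, `species`, `has_tmm`, `n_tm_segments`,
#'   one logical column per motif, and motif/TM interval columns in list
#'   form via attributes `motif_hits` and `tm_segments`.
#' @export
annotate_proteins <- function(proteomes, motifs = default_motifs(),
                              ids = NULL, window = 19L, cutoff = 1.6) {
  if (!is.list(proteomes) || inherits(proteomes, "proteome"))
    proteomes <- list(proteomes)
  rows <- list(); motif_hits <- list(); tm_segs <- list()
  for (p in proteomes) {
    sp <- attr(p, "species")
    use <- if (is.null(ids)) names(p) else intersect(names(p), ids)
    for (id in use) {
      s <- p[[id]]
      tm <- predict_tm(s, window, cutoff, protein_id = id)
      mm <- lapply(motifs, function(pat)
        scan_motif(pat, s, protein_id = id))
      found <- vapply(mm, function(m) nrow(m) > 0, logical(1))
      row <- data.frame(protein_id = id, species = sp, has_tmm = tm$has_tmm,
                        n_tm_segments = nrow(tm$segments),
                        stringsAsFactors = FALSE)
      for (nm in names(found)) row[[nm]] <- found[[nm]]
      rows[[length(rows) + 1L]] <- row
      motif_hits[[id]] <- do.call(rbind, mm)
      tm_segs[[id]] <- tm$segments
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "motif_hits") <- motif_hits
  attr(out, "tm_segments") <- tm_segs
  out
}
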