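PIPELINE_STAGES <- c("simulate", "detect", "align", "orthologs", "bogs",
                     "annotate", "group", "report")

log_msg <- function(...) message(sprintf("[orthofam %s] ", format(Sys.time(), "%H:%M:%S")), ...)

stage_seed <- function(seed, stage) {
  idx <- match(stage, PIPELINE_STAGES)
  as.integer((as.numeric(seed) * 101 + idx * 1009) %% 2147483647)
}

#' Default pipeline configuration (standard simulated scenario)
#'
#' Six species on a rooted tree with an outgroup `F` and two lineages
#' (`A`,`B`,`C` anchored on pivot `A`; `D`,`E` anchored on pivot `D`), six
#' independent gene families, and the standard benchmark rates.
#'
#' @param seed Master seed.
#' @param outdir Artifact directory.
#' @return A named configuration list (see [run_pipeline()]).
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("orthofam_run_")) {
  list(
    seed = as.integer(seed), outdir = outdir,
    simulation = list(
      tree = "((((A:0.25,B:0.25):0.25,C:0.5):0.25,(D:0.5,E:0.5):0.25):0.25,F:1);",
      n_families = 6, dup_rate = 0.1, loss_rate = 0.05,
      base_subs_rate = 0.25, tm_insertion_prob = 0.2, decoy_factor = 3),
    proteomes = NULL, seed_alignment = NULL, anchors = NULL,
    outgroup = "F",
    pivots = list(clade1 = "A", clade2 = "D"),
    lineages = list(clade1 = c("A", "B", "C"), clade2 = c("D", "E")),
    thresholds = list(min_bits = 200, min_coverage = 0.5,
                      identity_cutoff = 0.7),
    hmm = list(pseudocount = 1, null_samples = 500, seed_max_rows = 60))
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_run_config()].
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$outgroup) == 1,
            length(cfg$pivots) >= 1)
  th <- cfg$thresholds
  stopifnot(th$min_bits > 0, th$min_coverage > 0, th$min_coverage <= 1,
            th$identity_cutoff > 0, th$identity_cutoff <= 1)
  if (!is.null(cfg$proteomes)) {
    missing <- cfg$proteomes[!file.exists(unlist(cfg$proteomes))]
    if (length(missing))
      stop("config names missing proteome file(s): ",
           paste(unlist(missing), collapse = ", "))
    if (is.null(cfg$seed_alignment))
      stop("a seed alignment is required when proteomes are supplied")
    sp <- names(cfg$proteomes)
    need <- c(cfg$outgroup, unlist(cfg$pivots))
    if (!all(need %in% sp))
      stop("outgroup and pivots must name supplied proteomes")
  }
  invisible(cfg)
}

art <- function(cfg, ...) file.path(cfg$outdir, ...)

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             quote = "", comment.char = "#")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pipeline_proteomes <- function(cfg) {
  if (!is.null(cfg$proteomes)) {
    read_proteomes(unlist(cfg$proteomes))
  } else {
    paths <- list.files(art(cfg, "proteomes"), pattern = "\\.fasta$",
                        full.names = TRUE)
    read_proteomes(setNames(paths, sub("\\.fasta$", "", basename(paths))))
  }
}

stage_simulate <- function(cfg) {
  if (!is.null(cfg$proteomes)) {
    log_msg("simulate: user proteomes supplied, nothing to simulate")
    return(invisible(NULL))
  }
  s <- cfg$simulation
  tree <- species_tree(s$tree)
  params <- simulation_params(
    dup_rate = s$dup_rate, loss_rate = s$loss_rate,
    base_subs_rate = s$base_subs_rate,
    tm_insertion_prob = s$tm_insertion_prob)
  sim <- simulate_proteomes(tree, params, n_families = s$n_families,
                            seed = stage_seed(cfg$seed, "simulate"),
                            decoy_factor = s$decoy_factor)
  write_proteomes(sim$proteomes, art(cfg, "proteomes"))
  dir.create(art(cfg, "truth"), showWarnings = FALSE, recursive = TRUE)
  write_tsv(sim$truth, art(cfg, "truth", "genes.tsv"))
  all_pairs <- do.call(rbind, lapply(sim$truths, `[[`, "pairs"))
  write_tsv(all_pairs, art(cfg, "truth", "orthologs.tsv"))
  seed_aln <- truth_seed_alignment(sim, max_rows = cfg$hmm$seed_max_rows)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(apply(seed_aln$rows, 1, paste, collapse = "")),
    art(cfg, "truth", "seed_alignment.fasta"))
  # anchors: one labelled exemplar per family, preferentially from a pivot
  pref <- c(unlist(cfg$pivots), cfg$outgroup, tree$phy$tip.label)
  fam <- sim$truth[sim$truth$family != "decoy", , drop = FALSE]
  anchors <- do.call(rbind, lapply(split(fam, fam$family), function(g) {
    g <- g[order(match(g$species, pref)), , drop = FALSE]
    data.frame(id = g$id[1], group = g$family[1], species = g$species[1],
               stringsAsFactors = FALSE)
  }))
  write_tsv(anchors, art(cfg, "truth", "anchors.tsv"))
  invisible(sim)
}

stage_detect <- function(cfg) {
  proteomes <- pipeline_proteomes(cfg)
  seed_path <- if (!is.null(cfg$seed_alignment)) cfg$seed_alignment
  else art(cfg, "truth", "seed_alignment.fasta")
  seed_aln <- seed_alignment(seed_path)
  hmm <- build_profile(seed_aln, pseudocount_weight = cfg$hmm$pseudocount)
  cal <- calibrate_threshold(hmm, seed_aln,
                             null_samples = cfg$hmm$null_samples,
                             seed_rng = stage_seed(cfg$seed, "detect"))
  hmm <- set_threshold(hmm, cal)
  hits <- scan_proteomes(hmm, proteomes)
  dir.create(art(cfg, "detect"), showWarnings = FALSE, recursive = TRUE)
  write_tsv(hits, art(cfg, "detect", "hits.tsv"))
  jsonlite::write_json(
    list(threshold_bits = cal$threshold_bits,
         min_seed_score = cal$min_seed_score,
         null_quantile = cal$null_quantile, n_match = hmm$n_match),
    art(cfg, "detect", "threshold.json"), auto_unbox = TRUE, digits = 10)
  info <- column_information(hmm)
  write_tsv(data.frame(column = seq_along(info$bits), bits = info$bits),
            art(cfg, "detect", "logo_heights.tsv"))
  # redundancy clustering of the detected set
  detected <- unlist(unname(lapply(proteomes, function(p)
    unclass(p)[intersect(names(p), hits$protein_id)])))
  if (length(detected)) {
    cl <- cluster_redundant(detected, cfg$thresholds$identity_cutoff)
    write_tsv(data.frame(member = names(cl$representative),
                         representative = unname(cl$representative)),
              art(cfg, "detect", "clusters.tsv"))
  } else {
    write_tsv(data.frame(member = character(), representative = character()),
              art(cfg, "detect", "clusters.tsv"))
  }
  invisible(hits)
}

detected_proteomes <- function(cfg) {
  proteomes <- pipeline_proteomes(cfg)
  hits <- read_tsv(art(cfg, "detect", "hits.tsv"))
  out <- lapply(proteomes, function(p) {
    keep <- intersect(names(p), hits$protein_id)
    proteome(unclass(p)[keep], attr(p, "species"))
  })
  out[vapply(out, length, 0L) > 0]
}

pipeline_pairs <- function(cfg, species) {
  pairs <- list()
  add <- function(a, b) {
    if (a %in% species && b %in% species && a != b)
      pairs[[length(pairs) + 1L]] <<- c(a, b)
  }
  for (pv in unlist(cfg$pivots)) add(cfg$outgroup, pv)
  for (ln in names(cfg$lineages)) {
    pv <- cfg$pivots[[ln]]
    for (sp in setdiff(cfg$lineages[[ln]], pv)) add(pv, sp)
  }
  pvs <- unlist(cfg$pivots)
  if (length(pvs) >= 2) {
    for (i in seq_len(length(pvs) - 1))
      for (j in seq.int(i + 1, length(pvs))) add(pvs[i], pvs[j])
  }
  unique(pairs)
}

stage_align <- function(cfg) {
  dp <- detected_proteomes(cfg)
  th <- cfg$thresholds
  scheme <- scoring_scheme()
  dir.create(art(cfg, "align"), showWarnings = FALSE, recursive = TRUE)
  for (pr in pipeline_pairs(cfg, names(dp))) {
    hits <- all_vs_all(dp[[pr[1]]], dp[[pr[2]]], scheme, th$min_bits,
                       th$min_coverage)
    write_tsv(hits, art(cfg, "align", sprintf("hits_%s__%s.tsv", pr[1], pr[2])))
    write_hit_table(hits, art(cfg, "align",
                              sprintf("blast6_%s__%s.tsv", pr[1], pr[2])))
  }
  # within-species tables for paralog attachment
  for (sp in names(dp)) {
    if (length(dp[[sp]]) < 2) next
    hits <- all_vs_all(dp[[sp]], dp[[sp]], scheme, th$min_bits,
                       th$min_coverage)
    write_tsv(hits, art(cfg, "align", sprintf("within_%s.tsv", sp)))
  }
  invisible(NULL)
}

read_pair_hits <- function(cfg, a, b) {
  p1 <- art(cfg, "align", sprintf("hits_%s__%s.tsv", a, b))
  p2 <- art(cfg, "align", sprintf("hits_%s__%s.tsv", b, a))
  if (file.exists(p1)) read_tsv(p1) else if (file.exists(p2)) read_tsv(p2)
  else NULL
}

stage_orthologs <- function(cfg) {
  dp <- detected_proteomes(cfg)
  dir.create(art(cfg, "orthologs"), showWarnings = FALSE, recursive = TRUE)
  within <- list()
  for (sp in names(dp)) {
    p <- art(cfg, "align", sprintf("within_%s.tsv", sp))
    if (file.exists(p)) within[[sp]] <- read_tsv(p)
  }
  for (ln in names(cfg$lineages)) {
    pv <- cfg$pivots[[ln]]
    if (!pv %in% names(dp)) next
    rbh_list <- list()
    for (sp in setdiff(cfg$lineages[[ln]], pv)) {
      hits <- read_pair_hits(cfg, pv, sp)
      if (is.null(hits) || nrow(hits) == 0) next
      rbh <- reciprocal_best_hits(hits, pv, sp)
      write_tsv(rbh, art(cfg, "orthologs", sprintf("rbh_%s__%s.tsv", pv, sp)))
      if (nrow(rbh)) rbh_list[[sp]] <- rbh
    }
    if (!length(rbh_list)) next
    og <- build_ogs(rbh_list, pivot_id = pv, pivot_genes = names(dp[[pv]]),
                    lineages = cfg$lineages[ln])
    og <- attach_paralogs(og, within)
    write_tsv(og$ogs, art(cfg, "orthologs", sprintf("ogs_%s.tsv", pv)))
    pres <- data.frame(og_id = rownames(og$presence), og$presence,
                       check.names = FALSE)
    write_tsv(pres, art(cfg, "orthologs", sprintf("presence_%s.tsv", pv)))
    writeLines(og$pivot_specific,
               art(cfg, "orthologs", sprintf("specific_%s.txt", pv)))
    core <- og$core[[ln]]
    writeLines(if (is.null(core)) character(0) else core,
               art(cfg, "orthologs", sprintf("core_%s.txt", pv)))
  }
  # outgroup-anchored collections (one per pivot) for the BOG stage
  for (pv in unlist(cfg$pivots)) {
    hits <- read_pair_hits(cfg, cfg$outgroup, pv)
    if (is.null(hits) || nrow(hits) == 0) {
      writeLines(character(0),
                 art(cfg, "orthologs", sprintf("outgroup_og_%s.txt", pv)))
      next
    }
    rbh <- reciprocal_best_hits(hits, cfg$outgroup, pv)
    write_tsv(rbh, art(cfg, "orthologs",
                       sprintf("rbh_%s__%s.tsv", cfg$outgroup, pv)))
    writeLines(sort(unique(rbh$gene_a)),
               art(cfg, "orthologs", sprintf("outgroup_og_%s.txt", pv)))
  }
  # pivot-vs-pivot OG count
  pvs <- unlist(cfg$pivots)
  if (length(pvs) >= 2) {
    hits <- read_pair_hits(cfg, pvs[1], pvs[2])
    n <- if (!is.null(hits) && nrow(hits) > 0)
      nrow(reciprocal_best_hits(hits, pvs[1], pvs[2])) else 0L
    writeLines(as.character(n), art(cfg, "orthologs", "pivot_pair_ogs.txt"))
  }
  invisible(NULL)
}

stage_bogs <- function(cfg) {
  sets <- list()
  for (pv in unlist(cfg$pivots)) {
    p <- art(cfg, "orthologs", sprintf("outgroup_og_%s.txt", pv))
    sets[[paste0(cfg$outgroup, "_vs_", pv)]] <-
      if (file.exists(p)) readLines(p) else character(0)
  }
  dir.create(art(cfg, "bogs"), showWarnings = FALSE, recursive = TRUE)
  if (length(sets) >= 2 && any(lengths(sets) > 0)) {
    bogs <- intersect_bogs(sets)
    out <- list(bogs = bogs$bogs, venn = as.list(bogs$venn_counts),
                union_size = bogs$union_size)
  } else {
    out <- list(bogs = character(0), venn = list(), union_size = 0L)
  }
  jsonlite::write_json(out, art(cfg, "bogs", "bogs.json"), auto_unbox = TRUE,
                       digits = 10)
  invisible(out)
}

stage_annotate <- function(cfg) {
  proteomes <- pipeline_proteomes(cfg)
  hits <- read_tsv(art(cfg, "detect", "hits.tsv"))
  ann <- annotate_proteins(proteomes, ids = hits$protein_id)
  dir.create(art(cfg, "annotate"), showWarnings = FALSE, recursive = TRUE)
  if (is.null(ann))
    ann <- data.frame(protein_id = character(), species = character(),
                      has_tmm = logical(), n_tm_segments = integer())
  write_tsv(ann, art(cfg, "annotate", "annotations.tsv"))
  invisible(ann)
}

stage_group <- function(cfg) {
  dp <- detected_proteomes(cfg)
  all_seqs <- unlist(unname(lapply(dp, unclass)))
  dir.create(art(cfg, "group"), showWarnings = FALSE, recursive = TRUE)
  anchors_path <- if (!is.null(cfg$anchors)) cfg$anchors
  else art(cfg, "truth", "anchors.tsv")
  if (!file.exists(anchors_path) || length(all_seqs) == 0) {
    write_tsv(data.frame(id = character(), group = character(),
                         anchor = character(), distance = numeric()),
              art(cfg, "group", "assignments.tsv"))
    return(invisible(NULL))
  }
  anc <- read_tsv(anchors_path)
  anc <- anc[anc$id %in% names(all_seqs), , drop = FALSE]
  if (nrow(anc) == 0) {
    write_tsv(data.frame(id = character(), group = character(),
                         anchor = character(), distance = numeric()),
              art(cfg, "group", "assignments.tsv"))
    return(invisible(NULL))
  }
  clusters <- read_tsv(art(cfg, "detect", "clusters.tsv"))
  reps <- unique(clusters$representative)
  members <- all_seqs[intersect(reps, names(all_seqs))]
  asg <- assign_groups(members, all_seqs[anc$id],
                       setNames(anc$group, anc$id),
                       min_bits = cfg$thresholds$min_bits,
                       min_coverage = cfg$thresholds$min_coverage)
  write_tsv(asg, art(cfg, "group", "assignments.tsv"))
  invisible(asg)
}

stage_report <- function(cfg) {
  hits <- read_tsv(art(cfg, "detect", "hits.tsv"))
  species <- sort(unique(hits$species))
  family_counts <- as.list(table(factor(hits$species, levels = species)))
  ann_path <- art(cfg, "annotate", "annotations.tsv")
  ann <- if (file.exists(ann_path)) read_tsv(ann_path) else NULL
  tmm_counts <- lapply(species, function(sp) {
    if (is.null(ann) || nrow(ann) == 0) 0L
    else sum(ann$has_tmm[ann$species == sp])
  })
  names(tmm_counts) <- species
  clusters <- read_tsv(art(cfg, "detect", "clusters.tsv"))
  og_counts <- list()
  for (ln in names(cfg$lineages)) {
    pv <- cfg$pivots[[ln]]
    p <- art(cfg, "orthologs", sprintf("presence_%s.tsv", pv))
    if (file.exists(p)) {
      pres <- read_tsv(p)
      og_counts[[paste0("lineage_", ln)]] <- nrow(pres)
      core_p <- art(cfg, "orthologs", sprintf("core_%s.txt", pv))
      og_counts[[paste0("core_", ln)]] <-
        if (file.exists(core_p)) length(readLines(core_p)) else 0L
    } else {
      og_counts[[paste0("lineage_", ln)]] <- 0L
      og_counts[[paste0("core_", ln)]] <- 0L
    }
  }
  for (pv in unlist(cfg$pivots)) {
    p <- art(cfg, "orthologs", sprintf("outgroup_og_%s.txt", pv))
    og_counts[[paste0("outgroup_vs_", pv)]] <-
      if (file.exists(p)) length(readLines(p)) else 0L
  }
  ppath <- art(cfg, "orthologs", "pivot_pair_ogs.txt")
  og_counts$pivot_vs_pivot <-
    if (file.exists(ppath)) as.integer(readLines(ppath)) else 0L
  specific <- list()
  for (ln in names(cfg$lineages)) {
    pv <- cfg$pivots[[ln]]
    p <- art(cfg, "orthologs", sprintf("specific_%s.txt", pv))
    specific[[pv]] <- if (file.exists(p)) length(readLines(p)) else 0L
  }
  bogs <- jsonlite::read_json(art(cfg, "bogs", "bogs.json"),
                              simplifyVector = TRUE)
  gpath <- art(cfg, "group", "assignments.tsv")
  groups <- if (file.exists(gpath)) read_tsv(gpath) else NULL
  group_counts <- if (is.null(groups) || nrow(groups) == 0) list()
  else as.list(table(groups$group))

  report <- list(
    species = species,
    family_counts = family_counts,
    tmm_counts = tmm_counts,
    total_detected = nrow(hits),
    nonredundant_count = length(unique(clusters$representative)),
    og_counts = og_counts,
    species_specific = specific,
    bogs = if (length(bogs$bogs)) bogs$bogs else character(0),
    bog_count = length(bogs$bogs),
    venn = bogs$venn, venn_union = bogs$union_size,
    group_counts = group_counts,
    seed = cfg$seed)
  rendered <- render_report(report)
  writeLines(rendered$json, art(cfg, "report.json"))
  writeLines(rendered$text, art(cfg, "report.txt"))
  invisible(report)
}

#' Render a pipeline summary report
#'
#' Checks the internal aggregation identities (Venn region counts sum to the
#' union size; transmembrane counts never exceed family counts) and renders
#' the report as canonical JSON and a human-readable text block.
#'
#' @param report Report list as assembled by the report stage.
#' @return List with `json` and `text` strings.
#' @export
render_report <- function(report) {
  if (length(report$venn)) {
    stopifnot(sum(unlist(report$venn)) == report$venn_union)
  }
  for (sp in report$species) {
    stopifnot(report$tmm_counts[[sp]] <= report$family_counts[[sp]])
  }
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE)
  lines <- c(
    "orthofam pipeline summary",
    "=========================",
    sprintf("species analysed : %s", paste(report$species, collapse = ", ")),
    sprintf("family members detected : %d", report$total_detected),
    sprintf("non-redundant after clustering : %d", report$nonredundant_count),
    "per-species counts (family / with TMM):",
    vapply(report$species, function(sp)
      sprintf("  %-6s %4d / %d", sp, report$family_counts[[sp]],
              report$tmm_counts[[sp]]), character(1)),
    "orthologous groups:",
    vapply(names(report$og_counts), function(k)
      sprintf("  %-22s %d", k, report$og_counts[[k]]), character(1)),
    sprintf("basal orthologous groups : %d (%s)", report$bog_count,
            paste(report$bogs, collapse = ", ")),
    sprintf("group memberships : %s",
            if (length(report$group_counts))
              paste(sprintf("%s=%d", names(report$group_counts),
                            unlist(report$group_counts)), collapse = ", ")
            else "none"))
  list(json = as.character(json), text = lines)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, detect (+ redundancy clustering), align, orthologs,
#' bogs, annotate, group and report in order, persisting each stage's
#' artifacts under `config$outdir`. Fully deterministic given
#' `config$seed`: every stage draws from its own seed derived from the
#' master seed and the stage name, so stages can be rerun independently.
#'
#' @param config Configuration list from [default_run_config()] or
#'   [read_run_config()].
#' @param stages Stages to run (default: all, in order).
#' @return The summary report list (invisible for partial runs).
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = PIPELINE_STAGES) {
  validate_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  writeLines(yaml::as.yaml(config[setdiff(names(config), "outdir")]),
             file.path(config$outdir, "config.yaml"))
  report <- NULL
  for (st in stages) {
    t0 <- Sys.time()
    log_msg("stage ", st, " started")
    fn <- switch(st, simulate = stage_simulate, detect = stage_detect,
                 align = stage_align, orthologs = stage_orthologs,
                 bogs = stage_bogs, annotate = stage_annotate,
                 group = stage_group, report = stage_report)
    res <- tryCatch(fn(config), error = function(e)
      stop("pipeline stage '", st, "' failed: ", conditionMessage(e),
           call. = FALSE))
    if (st == "report") report <- res
    log_msg(sprintf("stage %s finished in %.1fs", st,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  invisible(report)
}
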