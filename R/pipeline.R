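#' Default pipeline configuration
#'
#' Every threshold of the analysis is a named key with its published
#' default: candidate floor `p_min = 30`, per-predictor positivity
#' `positivity_threshold = 50`, vote `n_positive_min = 3` (of 6), bin
#' edges 75/50/30, alignment-column trimming rule 0.5, plus alignment
#' parameters and the full synthetic-data configuration.
#'
#' @param seed master seed.
#' @param ... overrides for any key, including nested `sim` entries.
#' @return named list.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    p_min = 30, positivity_threshold = 50, n_positive_min = 3,
    bin_strong = 75, bin_moderate = 50, bin_weak = 30,
    trim_max_missing = 0.5,
    k = 21, min_intron = 30, flank = 300,
    summary_base = "nucleus", n_mtdna = 66,
    sim = unclass(sim_config(seed = seed))
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "sim") cfg$sim[names(dots$sim)] <- dots$sim
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' Read / write a pipeline configuration (JSON)
#'
#' The run configuration is a single JSON file mirroring
#' [default_config()]; unknown keys are an error so typos do not silently
#' fall back to defaults.
#'
#' @param path JSON file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config(seed = if (!is.null(raw$seed)) raw$seed else 1)
  bad <- setdiff(names(raw), names(base))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in setdiff(names(raw), "sim")) base[[nm]] <- raw[[nm]]
  if (!is.null(raw$sim)) {
    bad <- setdiff(names(raw$sim), names(base$sim))
    if (length(bad)) stop("unknown sim key(s): ", paste(bad, collapse = ", "))
    base$sim[names(raw$sim)] <- raw$sim
  }
  base
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline: simulate, score, reconcile, context, summarize
#'
#' One reproducible run: generates (or loads) the inputs, applies the
#' consensus targeting assessment and curation overrides, reconciles gene
#' models against transcripts, detects co-assembled pairs, and writes the
#' candidate table, summary and a run manifest with input/output checksums.
#' Identical config and inputs give identical output checksums. Any stage
#' failure aborts with the stage name.
#'
#' @param config list from [default_config()] / [read_config()].
#' @param out_dir output directory.
#' @param inputs optional named list of pre-existing input files
#'   (`genome`, `gff3`, `transcripts`, `scores`, `flags`); when `NULL`
#'   the synthetic generator supplies them.
#' @param quiet suppress progress messages.
#' @return list with `assessments`, `reconciliation`, `pairs`,
#'   `candidates`, `summary`, `manifest` (all also written under
#'   `out_dir`).
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         inputs = NULL, quiet = FALSE) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[mitocensus] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  truth_tx_map <- NULL
  if (is.null(inputs)) {
    say("simulate: n_genes = ", config$sim$n_genes,
        ", seed = ", config$sim$seed)
    sim <- stage("simulate", {
      simulate_dataset(do.call(sim_config, config$sim),
                       out_dir = file.path(out_dir, "inputs"))
    })
    genome <- sim$genome; models <- sim$models
    transcripts <- sim$transcripts
    scores <- sim$scores; flags <- sim$flags
    input_files <- list.files(file.path(out_dir, "inputs"),
                              full.names = TRUE)
  } else {
    say("loading inputs")
    genome <- stage("load", read_fasta(inputs$genome))
    models <- stage("load", read_gff3(inputs$gff3))
    transcripts <- stage("load", read_fasta(inputs$transcripts))
    scores <- stage("load", read_scores(inputs$scores))
    flags <- stage("load", if (!is.null(inputs$flags))
      read_tsv(inputs$flags) else NULL)
    input_files <- unlist(inputs)
  }

  say("score: ", nrow(scores), " proteins")
  assessments <- stage("score",
    assess_targeting(scores, flags,
                     positivity_threshold = config$positivity_threshold))
  write_tsv(assessments, file.path(out_dir, "assessments.tsv"))

  say("reconcile: ", length(models), " gene models, ",
      length(transcripts), " transcripts")
  rec <- stage("reconcile", {
    reconcile_genes(genome, models, transcripts,
                    rescore = NULL, k = config$k,
                    min_intron = config$min_intron, flank = config$flank)
  })
  write_gff3(rec$models, file.path(out_dir, "models.corrected.gff3"))
  write_tsv(rec$report, file.path(out_dir, "reconciliation.tsv"))
  if (!is.null(rec$introns)) {
    write_tsv(rec$introns, file.path(out_dir, "introns.tsv"))
  }
  if (!is.null(rec$mismatches)) {
    write_tsv(rec$mismatches, file.path(out_dir, "mismatches.tsv"))
  }

  say("context: co-assembled pairs")
  pairs <- stage("context", detect_coassembled_pairs(rec$models, rec$tx_map))
  write_tsv(pairs, file.path(out_dir, "pairs.tsv"))

  say("summarize")
  candidates <- stage("summarize", {
    build_candidate_table(rec, assessments, flags, genome)
  })
  write_candidate_table(candidates, file.path(out_dir, "candidates.tsv"))
  keep <- candidates[candidates$is_candidate, ]
  summ <- stage("summarize",
    summarize_candidates(keep, pairs, base = config$summary_base,
                         n_mtdna = config$n_mtdna))
  write_summary(summ, file.path(out_dir, "summary.tsv"),
                file.path(out_dir, "summary.md"))

  manifest <- run_manifest(config, input_files, out_dir, t0)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done in ", round(as.numeric(Sys.time() - t0, units = "secs"), 1), " s")
  invisible(list(assessments = assessments, reconciliation = rec,
                 pairs = pairs, candidates = candidates, summary = summ,
                 manifest = manifest))
}

build_candidate_table <- function(rec, assessments, flags, genome) {
  gids <- names(rec$models)
  pid <- paste0(gids, ".p")
  i <- match(pid, assessments$protein_id)
  rep_i <- match(gids, rec$report$gene_id)
  cat_i <- if (!is.null(flags) && "category" %in% names(flags)) {
    flags$category[match(pid, flags$protein_id)]
  } else NA_character_
  intr_sizes <- vapply(gids, function(g) {
    if (is.null(rec$introns)) return(NA_character_)
    s <- rec$introns$size[rec$introns$gene_id == g]
    if (!length(s)) NA_character_ else paste(s, collapse = ",")
  }, character(1))
  n_intr <- rec$report$n_introns[rep_i]
  n_intr[is.na(n_intr)] <- 0L
  data.frame(
    protein_id = pid, gene_id = gids,
    category = cat_i,
    category_label = ifelse(cat_i %in% names(CATEGORY_LABELS),
                            CATEGORY_LABELS[cat_i], NA_character_),
    P = round_half_up(assessments$P[i], 1),
    bin = as.character(assessments$bin[i]),
    n_positive = assessments$n_positive[i],
    is_candidate = assessments$is_candidate[i],
    override = as.character(assessments$override[i]),
    n_introns = n_intr,
    intron_sizes = intr_sizes,
    start_provenance = rec$report$start_provenance[rep_i],
    stop_source = rec$report$stop_source[rep_i],
    identity = rec$report$identity[rep_i],
    protein_seq = vapply(rec$models, function(m)
      if (is.null(m$protein)) NA_character_ else m$protein, character(1)),
    cds_seq = vapply(rec$models, function(m)
      spliced_cds(m, genome), character(1)),
    row.names = NULL
  )
}

run_manifest <- function(config, input_files, out_dir, t0) {
  cfg_file <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_file))
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  outputs <- setdiff(list.files(out_dir, full.names = TRUE, recursive = TRUE),
                     file.path(out_dir, "manifest.json"))
  list(
    tool = "mitocensus",
    version = as.character(utils::packageVersion("mitocensus")),
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(tools::md5sum(sort(unlist(input_files)))),
    outputs = as.list(tools::md5sum(sort(outputs)))
  )
}
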