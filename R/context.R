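#' Detect co-assembled adjacent gene pairs
#'
#' Genes packed closely enough that the untranslated, overlapping portions
#' of their transcripts assemble into a single RNA-Seq contig are detected
#' from the transcript-to-gene map: any transcript contig mapping to two
#' genes that are adjacent on the same genomic contig yields a pair. The
#' intergenic spacer is measured between the coding regions (CDS end of
#' the upstream gene to CDS start of the downstream gene), not between
#' transcript spans, which may overlap while the CDS spacer is positive.
#' Orientation is `same` iff the two strands are equal. Overlapping CDSs
#' give `spacer_nt = 0` with `overlap = TRUE`.
#'
#' @param models named list of [gene_model()] objects.
#' @param tx_map data.frame with `transcript_id`, `gene_id` (from
#'   [map_transcripts()] or the simulator's truth).
#' @return data.frame with one row per pair: `gene_id_a`, `gene_id_b`
#'   (a upstream), `transcript_id`, `spacer_nt`, `orientation`, `overlap`,
#'   `coassembled`.
#' @export
detect_coassembled_pairs <- function(models, tx_map) {
  cds_lo <- vapply(models, function(m) m$exons[1, 1], integer(1))
  cds_hi <- vapply(models, function(m) m$exons[nrow(m$exons), 2], integer(1))
  contig <- vapply(models, `[[`, character(1), "contig_id")
  strand <- vapply(models, `[[`, character(1), "strand")
  ids <- vapply(models, `[[`, character(1), "gene_id")

  rows <- list()
  for (tid in unique(tx_map$transcript_id)) {
    g <- tx_map$gene_id[tx_map$transcript_id == tid]
    if (length(g) < 2) next
    i <- match(g, ids)
    if (length(unique(contig[i])) != 1) next
    o <- i[order(cds_lo[i])]
    for (j in seq_len(length(o) - 1L)) {      # consecutive pairs along contig
      a <- o[j]; b <- o[j + 1L]
      spacer <- cds_lo[b] - cds_hi[a]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id_a = ids[a], gene_id_b = ids[b], transcript_id = tid,
        spacer_nt = max(0L, spacer),
        orientation = if (strand[a] == strand[b]) "same" else "opposite",
        overlap = spacer < 0,
        coassembled = TRUE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id_a = character(0), gene_id_b = character(0),
                      transcript_id = character(0), spacer_nt = integer(0),
                      orientation = character(0), overlap = logical(0),
                      coassembled = logical(0)))
  }
  do.call(rbind, rows)
}

#' Summarize a candidate set
#'
#' Produces the inventory-style summary: candidate count, functional
#' category composition (counts and percentages), the targeting-strength
#' distribution (strong / moderate / weak / no MTS predicted), intron
#' statistics with per-category enrichment, and intergenic-spacer
#' statistics for co-assembled pairs. Category percentages are computed
#' over the nucleus-encoded candidates by default; `base = "total"`
#' divides by candidates plus the mtDNA-encoded proteins (`n_mtdna`)
#' instead. Percentages are reported to one decimal, half-up. The summary
#' is a pure, order-invariant function of its inputs.
#'
#' @param records data.frame of candidate records; must carry `category`,
#'   `bin`, and `n_introns` (optionally `intron_sizes`, comma-separated).
#' @param pairs optional data.frame from [detect_coassembled_pairs()].
#' @param base percentage denominator: `"nucleus"` (candidate records) or
#'   `"total"` (records + `n_mtdna`).
#' @param n_mtdna number of mtDNA-encoded proteins for the `"total"` base.
#' @return object of class `mito_summary` (a list of data.frames/lists).
#' @export
summarize_candidates <- function(records, pairs = NULL,
                                 base = c("nucleus", "total"), n_mtdna = 66) {
  base <- match.arg(base)
  n <- nrow(records)
  denom <- if (base == "nucleus") n else n + n_mtdna

  cat_vec <- as.character(records$category)
  if (any(is.na(cat_vec) | !nzchar(cat_vec))) {
    warning(sum(is.na(cat_vec) | !nzchar(cat_vec)),
            " record(s) missing a category; counted as 'unassigned'")
    cat_vec[is.na(cat_vec) | !nzchar(cat_vec)] <- "unassigned"
  }
  cat_levels <- c(names(CATEGORY_LABELS),
                  setdiff(unique(cat_vec), names(CATEGORY_LABELS)))
  cat_counts <- table(factor(cat_vec, levels = cat_levels))
  categories <- data.frame(
    category = names(cat_counts),
    label = unname(ifelse(names(cat_counts) %in% names(CATEGORY_LABELS),
                          CATEGORY_LABELS[names(cat_counts)],
                          names(cat_counts))),
    n = as.integer(cat_counts),
    pct = round_half_up(100 * as.integer(cat_counts) / denom, 1)
  )

  bin <- as.character(records$bin)
  targeting <- data.frame(
    class = c("strong", "moderate", "weak", "no_mts"),
    n = c(sum(bin == "strong"), sum(bin == "moderate"),
          sum(bin == "weak"), sum(bin == "not_predicted")),
    stringsAsFactors = FALSE
  )
  targeting$pct <- round_half_up(100 * targeting$n / n, 1)

  n_intr_per <- as.integer(records$n_introns)
  n_intr_per[is.na(n_intr_per)] <- 0L
  with_intr <- n_intr_per > 0L
  sizes <- numeric(0)
  if ("intron_sizes" %in% names(records)) {
    sizes <- as.numeric(unlist(strsplit(
      records$intron_sizes[with_intr & !is.na(records$intron_sizes)], ",")))
  }
  introns <- list(
    n_genes_with_introns = sum(with_intr),
    fraction_intron_genes = if (n) sum(with_intr) / n else NA_real_,
    n_introns = sum(n_intr_per),
    fraction_single_intron = if (any(with_intr))
      sum(n_intr_per == 1L) / sum(with_intr) else NA_real_,
    mean_size = if (length(sizes)) mean(sizes) else NA_real_,
    min_size = if (length(sizes)) min(sizes) else NA_real_,
    max_size = if (length(sizes)) max(sizes) else NA_real_
  )

  enrich <- do.call(rbind, lapply(split(with_intr, factor(cat_vec, cat_levels)),
                                  function(v) {
    data.frame(n_genes = length(v), n_with_introns = sum(v),
               pct = if (length(v)) round_half_up(100 * sum(v) / length(v), 1)
                     else NA_real_)
  }))
  enrich <- cbind(category = rownames(enrich), enrich)
  rownames(enrich) <- NULL

  spacers <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    spacers <- list(
      n_pairs = nrow(pairs),
      mean = mean(pairs$spacer_nt), min = min(pairs$spacer_nt),
      max = max(pairs$spacer_nt),
      n_opposite = sum(pairs$orientation == "opposite"),
      n_same = sum(pairs$orientation == "same")
    )
  }

  structure(list(
    n_candidates = n, base = base, denominator = denom, n_mtdna = n_mtdna,
    categories = categories, targeting = targeting, introns = introns,
    intron_enrichment = enrich, spacers = spacers
  ), class = "mito_summary")
}

#' @export
print.mito_summary <- function(x, ...) {
  cat(sprintf("Candidate mitochondrial proteome summary\n"))
  cat(sprintf("  nucleus-encoded candidates: %d (percentage base: %s, n = %d)\n",
              x$n_candidates, x$base, x$denominator))
  cat("  functional categories:\n")
  for (i in seq_len(nrow(x$categories))) {
    if (x$categories$n[i] == 0) next
    cat(sprintf("    %-2s %-45s %5d  %5.1f%%\n", x$categories$category[i],
                substr(x$categories$label[i], 1, 45), x$categories$n[i],
                x$categories$pct[i]))
  }
  cat("  targeting strength:\n")
  for (i in seq_len(nrow(x$targeting))) {
    cat(sprintf("    %-9s %5d  %5.1f%%\n", x$targeting$class[i],
                x$targeting$n[i], x$targeting$pct[i]))
  }
  with(x$introns, cat(sprintf(
    paste0("  introns: %d gene(s) with introns (%.1f%%), %d introns, ",
           "%.0f%% single-intron,\n    mean size %.1f nt (range %g-%g)\n"),
    n_genes_with_introns, 100 * fraction_intron_genes, n_introns,
    100 * fraction_single_intron, mean_size, min_size, max_size)))
  if (!is.null(x$spacers)) {
    with(x$spacers, cat(sprintf(
      paste0("  co-assembled pairs: %d, spacer mean %.1f nt (range %g-%g), ",
             "orientation %d opposite : %d same\n"),
      n_pairs, mean, min, max, n_opposite, n_same)))
  }
  invisible(x)
}

#' Write a summary to TSV (machine-readable) and Markdown (human-readable)
#'
#' @param x a [summarize_candidates()] result.
#' @param tsv_path,md_path output paths (`NULL` to skip one).
#' @export
write_summary <- function(x, tsv_path = NULL, md_path = NULL) {
  rows <- rbind(
    data.frame(section = "overview", key = "n_candidates",
               value = x$n_candidates),
    data.frame(section = "overview", key = "percentage_base",
               value = x$denominator),
    data.frame(section = "category_n", key = x$categories$category,
               value = x$categories$n),
    data.frame(section = "category_pct", key = x$categories$category,
               value = x$categories$pct),
    data.frame(section = "targeting_n", key = x$targeting$class,
               value = x$targeting$n),
    data.frame(section = "targeting_pct", key = x$targeting$class,
               value = x$targeting$pct),
    data.frame(section = "introns", key = names(x$introns),
               value = unlist(x$introns))
  )
  if (!is.null(x$spacers)) {
    rows <- rbind(rows, data.frame(section = "spacers",
                                   key = names(x$spacers),
                                   value = unlist(x$spacers)))
  }
  rownames(rows) <- NULL
  if (!is.null(tsv_path)) write_tsv(rows, tsv_path)
  if (!is.null(md_path)) {
    con <- file(md_path, "w")
    sink(con); print(x); sink()
    close(con)
  }
  invisible(rows)
}

#' Remove alignment columns dominated by missing characters
#'
#' Drops every column whose fraction of missing characters (gaps or
#' unknowns) is strictly greater than `max_missing` (default: more than
#' 50%). Row order is preserved and the operation is idempotent. A column
#' at exactly the threshold is retained.
#'
#' @param alignment character vector of equal-length gapped sequences
#'   (names preserved), or a character matrix (rows = sequences).
#' @param max_missing maximum tolerated missing fraction.
#' @param missing_chars characters counted as missing.
#' @return object of the same shape with offending columns removed.
#' @export
trim_alignment_columns <- function(alignment, max_missing = 0.5,
                                   missing_chars = c("-", ".", "?", "X", "x")) {
  was_matrix <- is.matrix(alignment)
  if (!was_matrix) {
    if (length(unique(nchar(alignment))) > 1) {
      stop("ragged alignment: sequences differ in length")
    }
    if (length(alignment) == 0 || nchar(alignment[1]) == 0) return(alignment)
    m <- do.call(rbind, strsplit(alignment, ""))
  } else {
    m <- alignment
  }
  miss <- matrix(m %in% missing_chars, nrow = nrow(m))
  keep <- colMeans(miss) <= max_missing
  m2 <- m[, keep, drop = FALSE]
  if (was_matrix) return(m2)
  setNames(apply(m2, 1, paste, collapse = ""), names(alignment))
}
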