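# coding axis: position along the gene's coding strand, 0 = first base of
# the contig's coding-strand rendering (for "-" genes the contig is read
# reverse-complemented)
axis_point <- function(p, strand, L) if (strand == "+") p else L - 1L - p
axis_interval <- function(a, b, strand, L) {
  if (strand == "+") c(a, b) else c(L - b, L - a)
}

coding_contig <- function(genome, contig_id, strand, cache = NULL) {
  if (!is.null(cache)) {
    key <- paste0(contig_id, strand)
    if (!is.null(cache[[key]])) return(cache[[key]])
  }
  seq <- genome[[contig_id]]
  if (strand == "-") seq <- revcomp(seq)
  if (!is.null(cache)) cache[[key]] <- seq
  seq
}

#' Assign the protein N-terminus, extending upstream where evidence allows
#'
#' When the reading frame remains open upstream of the annotated
#' initiation codon and the transcript evidence does not extend 5' far
#' enough to cover the putative extension, the start is moved to the
#' nearest upstream in-frame ATG whose extended protein is scored
#' MTS-positive by `rescore`; otherwise the annotated start is kept. When
#' the transcript's aligned span does not reach the in-frame upstream stop
#' codon, the stop is inferred from genomic sequence and that provenance is
#' recorded.
#'
#' The extension can never cross an in-frame stop (the scan halts there),
#' never shortens the protein, preserves frame, and always yields a protein
#' beginning with Met. If upstream in-frame ATGs exist but the transcript
#' covers them (contradictory evidence about the start), the
#' transcript-supported annotated start is kept and flagged.
#'
#' @param model a [gene_model()].
#' @param aln the gene's [align_transcript()] result.
#' @param genome named character vector of contigs.
#' @param rescore callback `function(protein) -> TRUE/FALSE` (MTS-positive
#'   under the consensus assessment); the pipeline is predictor-agnostic
#'   and takes the scorer as a function.
#' @param max_scan maximum upstream distance scanned, nt.
#' @return list with `model` (possibly extended), and `provenance`:
#'   `start_provenance` ("annotated" or "upstream_extension"),
#'   `extension_nt`, `stop_source` ("transcript", "genome", "none_found"),
#'   `note`.
#' @export
assign_start <- function(model, aln, genome, rescore, max_scan = 3000) {
  contig <- genome[[model$contig_id]]
  L <- nchar(contig)
  cseq <- coding_contig(genome, model$contig_id, model$strand)
  n <- nrow(model$exons)
  s0 <- if (model$strand == "+") model$exons[1, 1] else L - model$exons[n, 2]

  # scan upstream in-frame codons to the first stop
  atg <- integer(0)
  s_stop <- NA_integer_
  i <- 1L
  while (s0 - 3L * i >= 0L && 3L * i <= max_scan) {
    p <- s0 - 3L * i
    codon <- substring(cseq, p + 1L, p + 3L)
    if (codon %in% STOP_CODONS) { s_stop <- p; break }
    if (codon == "ATG") atg <- c(atg, p)
    i <- i + 1L
  }

  # 5'-most transcript-covered coding-axis position
  ax <- t(mapply(function(a, b) axis_interval(a, b, model$strand, L),
                 aln$blocks$contig_start, aln$blocks$contig_end))
  cov5 <- min(ax[, 1])

  stop_source <- if (is.na(s_stop)) "none_found"
                 else if (s_stop >= cov5) "transcript" else "genome"

  prov <- list(start_provenance = "annotated", extension_nt = 0L,
               stop_source = stop_source, note = NA_character_)
  if (!length(atg)) {
    return(list(model = model, provenance = prov))
  }
  eligible <- atg[atg < cov5]  # uncovered by transcript evidence
  if (!length(eligible)) {
    prov$note <- "upstream_atg_covered_by_transcript"
    return(list(model = model, provenance = prov))
  }
  cds <- spliced_cds(model, genome)
  for (p in sort(eligible, decreasing = TRUE)) {  # nearest first
    ext <- substring(cseq, p + 1L, s0)
    new_protein <- translate_cds(paste0(ext, cds))
    if (isTRUE(rescore(new_protein))) {
      delta <- as.integer(unname(s0 - p))
      exons <- model$exons
      if (model$strand == "+") exons[1, 1] <- exons[1, 1] - delta
      else exons[n, 2] <- exons[n, 2] + delta
      new <- gene_model(model$gene_id, model$contig_id, model$strand, exons,
                        tx_start = min(model$tx_start, exons[1, 1]),
                        tx_end = max(model$tx_end, exons[nrow(exons), 2]),
                        protein = new_protein)
      prov$start_provenance <- "upstream_extension"
      prov$extension_nt <- delta
      return(list(model = new, provenance = prov))
    }
  }
  list(model = model, provenance = prov)
}

#' Classify transcript-vs-genome mismatches
#'
#' Single-nucleotide differences between the assembled transcript and the
#' genome (SNPs in a non-clonal or near-homozygous diploid sample) are
#' labeled `silent_third_position`, `silent_other`, `nonsynonymous`
#' (standard genetic code) or `UTR` when outside the CDS. A mismatch
#' falling inside a called intron is an internal error: introns are never
#' part of alignment blocks.
#'
#' @param aln a [align_transcript()] result.
#' @param model the gene's [gene_model()].
#' @param genome named character vector of contigs.
#' @return data.frame with one row per mismatch: `contig_pos`, `t_base`,
#'   `g_base`, `codon_index`, `codon_pos` (NA outside CDS), `ref_codon`,
#'   `alt_codon`, `label`.
#' @export
classify_mismatches <- function(aln, model, genome) {
  mm <- aln$mismatches
  w <- aln$window
  out <- data.frame(
    contig_pos = integer(0), t_base = character(0), g_base = character(0),
    codon_index = integer(0), codon_pos = integer(0),
    ref_codon = character(0), alt_codon = character(0), label = character(0)
  )
  if (!nrow(mm)) return(out)
  cp <- if (w$strand == "+") w$start + mm$w_pos else w$end - 1L - mm$w_pos

  if (nrow(aln$introns) &&
      any(vapply(cp, function(p) any(p >= aln$introns$contig_start &
                                     p < aln$introns$contig_end), logical(1)))) {
    stop("internal error: mismatch inside a called intron")
  }

  exons <- model$exons
  lens <- exons[, 2] - exons[, 1]
  before <- cumsum(c(0L, lens))[seq_len(nrow(exons))]
  total <- sum(lens)
  cds <- spliced_cds(model, genome)

  res <- lapply(seq_along(cp), function(j) {
    p <- cp[j]
    ex <- which(exons[, 1] <= p & p < exons[, 2])
    if (!length(ex)) {
      return(data.frame(contig_pos = p, t_base = mm$t_base[j],
                        g_base = mm$g_base[j], codon_index = NA_integer_,
                        codon_pos = NA_integer_, ref_codon = NA_character_,
                        alt_codon = NA_character_, label = "UTR"))
    }
    off_plus <- before[ex] + (p - exons[ex, 1])
    cds_pos <- if (model$strand == "+") off_plus else total - 1L - off_plus
    ci <- cds_pos %/% 3L
    within <- cds_pos %% 3L + 1L
    ref <- substring(cds, ci * 3L + 1L, ci * 3L + 3L)
    alt <- ref
    substring(alt, within, within) <- mm$t_base[j]
    label <- if (identical(codon_aa(ref), codon_aa(alt))) {
      if (within == 3L) "silent_third_position" else "silent_other"
    } else "nonsynonymous"
    data.frame(contig_pos = p, t_base = mm$t_base[j], g_base = mm$g_base[j],
               codon_index = ci, codon_pos = within, ref_codon = ref,
               alt_codon = alt, label = label)
  })
  do.call(rbind, res)
}

#' Map assembled transcripts to gene models
#'
#' Short probes (k-mers) sampled along each transcript are matched against
#' the contigs (both strands, via `Biostrings::matchPDict`). Probe hits on
#' a contig are clustered into the transcript's implied genomic span
#' (tolerating intron-sized gaps between probes), and the transcript is
#' assigned to every gene whose CDS interval overlaps that span. Because
#' UTRs never reach into a neighbouring CDS, an ordinary transcript maps
#' to exactly its own gene, while a co-assembled contig spanning two genes
#' maps to both.
#'
#' @param models named list of [gene_model()] objects.
#' @param transcripts named character vector of transcript sequences.
#' @param genome named character vector of contigs.
#' @param k probe length.
#' @param probe_spacing approximate distance between probes along the
#'   transcript.
#' @param max_gap largest genomic gap between probe hits still considered
#'   one locus (introns are far below this).
#' @return data.frame with columns `transcript_id`, `gene_id`.
#' @export
map_transcripts <- function(models, transcripts, genome, k = 21,
                            probe_spacing = 250, max_gap = 10000) {
  probe_seq <- character(0); probe_tx <- character(0)
  for (tid in names(transcripts)) {
    s <- transcripts[[tid]]
    n <- nchar(s) - k + 1L
    if (n < 1L) next
    n_probes <- max(4L, min(24L, ceiling(nchar(s) / probe_spacing)))
    at <- unique(pmax(1L, pmin(n, as.integer(round(
      seq(1L, n, length.out = n_probes))))))
    probe_seq <- c(probe_seq, substring(s, at, at + k - 1L))
    probe_tx <- c(probe_tx, rep(tid, length(at)))
  }
  both <- c(probe_seq, revcomp(probe_seq))
  both_tx <- c(probe_tx, probe_tx)
  keep <- !grepl("[^ACGT]", both)
  dict <- Biostrings::PDict(Biostrings::DNAStringSet(both[keep]))
  both_tx <- both_tx[keep]

  gene_df <- data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    contig_id = vapply(models, `[[`, character(1), "contig_id"),
    lo = vapply(models, function(m) m$exons[1, 1], numeric(1)),
    hi = vapply(models, function(m) m$exons[nrow(m$exons), 2], numeric(1))
  )

  hits <- list()
  for (ctg in unique(gene_df$contig_id)) {
    subj <- Biostrings::DNAString(genome[[ctg]])
    mi <- Biostrings::matchPDict(dict, subj)
    starts <- BiocGenerics::start(mi)
    cnt <- S4Vectors::elementNROWS(starts)
    if (!sum(cnt)) next
    pos <- unlist(starts, use.names = FALSE) - 1L
    tx_of_hit <- rep(both_tx, cnt)
    gctg <- gene_df[gene_df$contig_id == ctg, ]
    for (tid in unique(tx_of_hit)) {
      p <- sort(pos[tx_of_hit == tid])
      # keep the largest cluster of hits (guards against stray repeats)
      brk <- c(0L, which(diff(p) > max_gap), length(p))
      sizes <- diff(brk)
      best <- which.max(sizes)
      p <- p[(brk[best] + 1L):brk[best + 1L]]
      span_lo <- p[1]; span_hi <- p[length(p)] + k
      ov <- gctg$lo < span_hi & gctg$hi > span_lo
      if (any(ov)) {
        hits[[length(hits) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gctg$gene_id[ov])
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(transcript_id = character(0), gene_id = character(0)))
  }
  unique(do.call(rbind, hits))
}

#' Reconcile gene models against transcript evidence
#'
#' The batch driver: maps transcripts to genes, aligns each gene's
#' transcript to its genomic window, calls and canonicalizes introns,
#' classifies mismatches, optionally reassigns the N-terminus (when a
#' `rescore` callback is supplied), and emits corrected gene models plus a
#' per-gene report. The corrected CDS structure is the annotated CDS span
#' with the transcript-called introns removed; genes whose transcript does
#' not fully cover the CDS are reported, not silently corrected.
#'
#' @param genome named character vector of contigs.
#' @param models named list of [gene_model()] objects.
#' @param transcripts named character vector of transcript sequences.
#' @param rescore optional callback `function(protein) -> logical` used by
#'   [assign_start()]; `NULL` disables start reassignment.
#' @param k,min_intron,flank alignment parameters.
#' @return list with `models` (corrected), `report` (one row per gene),
#'   `introns` (one row per called intron), `mismatches`, `tx_map`.
#' @export
reconcile_genes <- function(genome, models, transcripts, rescore = NULL,
                            k = 21, min_intron = 30, flank = 300) {
  tx_map <- map_transcripts(models, transcripts, genome, k = k)
  rep_rows <- list(); intr_rows <- list(); mm_rows <- list()
  out_models <- models

  for (gid in names(models)) {
    model <- models[[gid]]
    tids <- tx_map$transcript_id[tx_map$gene_id == gid]
    if (!length(tids)) {
      rep_rows[[gid]] <- data.frame(
        gene_id = gid, transcript_id = NA_character_, status = "no_transcript",
        n_introns = NA_integer_, all_canonical = NA, identity = NA_real_,
        n_mismatch = NA_integer_, n_silent_third = NA_integer_,
        n_nonsynonymous = NA_integer_, start_provenance = NA_character_,
        extension_nt = NA_integer_, stop_source = NA_character_,
        model_changed = NA)
      next
    }
    tid <- tids[1]  # one transcript contig per gene assumed
    win <- genomic_window(genome, model, flank = flank)
    aln <- tryCatch(
      align_transcript(transcripts[[tid]], win, k = k,
                       min_intron = min_intron,
                       transcript_id = tid, gene_id = gid),
      error = function(e) e)
    if (inherits(aln, "error")) {
      rep_rows[[gid]] <- data.frame(
        gene_id = gid, transcript_id = tid,
        status = paste0("alignment_failed: ", conditionMessage(aln)),
        n_introns = NA_integer_, all_canonical = NA, identity = NA_real_,
        n_mismatch = NA_integer_, n_silent_third = NA_integer_,
        n_nonsynonymous = NA_integer_, start_provenance = NA_character_,
        extension_nt = NA_integer_, stop_source = NA_character_,
        model_changed = NA)
      next
    }

    covered <- covers_cds_after_introns(aln, model)
    intr <- call_introns(aln)
    corrected <- correct_model(model, intr)
    mm <- classify_mismatches(aln, corrected, genome)

    prov <- list(start_provenance = "annotated", extension_nt = 0L,
                 stop_source = NA_character_)
    if (!is.null(rescore)) {
      res <- assign_start(corrected, aln, genome, rescore)
      corrected <- res$model
      prov <- res$provenance
    }
    corrected$protein <- translate_cds(spliced_cds(corrected, genome))
    out_models[[gid]] <- corrected

    if (nrow(intr)) {
      intr_rows[[gid]] <- cbind(gene_id = gid, intr)
    }
    if (nrow(mm)) {
      mm_rows[[gid]] <- cbind(gene_id = gid, mm)
    }
    rep_rows[[gid]] <- data.frame(
      gene_id = gid, transcript_id = tid,
      status = if (covered) "ok" else "cds_not_covered",
      n_introns = nrow(intr),
      all_canonical = if (nrow(intr)) all(intr$canonical) else TRUE,
      identity = aln$identity,
      n_mismatch = nrow(mm),
      n_silent_third = sum(mm$label == "silent_third_position"),
      n_nonsynonymous = sum(mm$label == "nonsynonymous"),
      start_provenance = prov$start_provenance,
      extension_nt = prov$extension_nt,
      stop_source = prov$stop_source,
      model_changed = !identical(corrected$exons, model$exons))
  }

  list(
    models = out_models,
    report = do.call(rbind, c(rep_rows, list(make.row.names = FALSE))),
    introns = if (length(intr_rows))
      do.call(rbind, c(intr_rows, list(make.row.names = FALSE))) else NULL,
    mismatches = if (length(mm_rows))
      do.call(rbind, c(mm_rows, list(make.row.names = FALSE))) else NULL,
    tx_map = tx_map
  )
}

# CDS coverage check on the *exon union* of the original annotation: the
# aligned blocks must jointly span the CDS interval minus called introns.
covers_cds_after_introns <- function(aln, model) {
  cds_lo <- model$exons[1, 1]
  cds_hi <- model$exons[nrow(model$exons), 2]
  blocks <- aln$blocks
  cov <- blocks$contig_start <= cds_lo & blocks$contig_end >= cds_lo
  # walk coverage across [cds_lo, cds_hi) allowing jumps across called introns
  pos <- cds_lo
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 1000L) return(FALSE)
    b <- which(blocks$contig_start <= pos & blocks$contig_end > pos)
    if (!length(b)) return(FALSE)
    pos <- max(blocks$contig_end[b])
    if (pos >= cds_hi) return(TRUE)
    nxt <- which(aln$introns$contig_start == pos)
    if (length(nxt)) pos <- aln$introns$contig_end[nxt[1]] else return(FALSE)
  }
}

# rebuild CDS exon structure from the annotated CDS span minus the called
# introns that fall strictly inside it
correct_model <- function(model, introns) {
  cds_lo <- model$exons[1, 1]
  cds_hi <- model$exons[nrow(model$exons), 2]
  if (!nrow(introns)) {
    keep <- model$exons
    if (nrow(keep) == 1) return(model)
    exons <- cbind(start = cds_lo, end = cds_hi)
  } else {
    ii <- introns[introns$contig_start > cds_lo & introns$contig_end < cds_hi, ]
    ii <- ii[order(ii$contig_start), ]
    exons <- cbind(start = c(cds_lo, ii$contig_end),
                   end = c(ii$contig_start, cds_hi))
  }
  gene_model(model$gene_id, model$contig_id, model$strand, exons,
             tx_start = min(model$tx_start, cds_lo),
             tx_end = max(model$tx_end, cds_hi),
             protein = model$protein)
}
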