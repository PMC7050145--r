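# Memoized synthetic worlds shared across test files (built on first use
# within a test session).
.world_cache <- new.env(parent = emptyenv())

small_world <- function() {
  if (is.null(.world_cache$small)) {
    cfg <- sim_config(seed = 7, n_genes = 80, genes_per_contig = 40,
                      n_coassembled_pairs = 6)
    sim <- simulate_dataset(cfg)
    rec <- reconcile_genes(sim$genome, sim$models, sim$transcripts)
    .world_cache$small <- list(cfg = cfg, sim = sim, rec = rec)
  }
  .world_cache$small
}

# Acceptance-scale stated world: n_genes = 2000 over a ~2 Mb genome, 47
# co-assembled pairs, default laws; error-free transcripts (snp_rate = 0)
# as the structure-recovery criterion specifies. Built once; the elapsed
# wall time of the full pipeline pass is kept for the runtime criterion.
acc_world <- function() {
  if (is.null(.world_cache$acc)) {
    t0 <- Sys.time()
    cfg <- sim_config(seed = 1, snp_rate = 0)
    dir <- file.path(tempdir(), "mitocensus-acc")
    sim <- simulate_dataset(cfg, out_dir = dir)
    assessments <- assess_targeting(sim$scores, sim$flags)
    rec <- reconcile_genes(sim$genome, sim$models, sim$transcripts)
    pairs <- detect_coassembled_pairs(rec$models, rec$tx_map)
    elapsed <- as.numeric(Sys.time() - t0, units = "secs")
    .world_cache$acc <- list(cfg = cfg, dir = dir, sim = sim,
                             assessments = assessments, rec = rec,
                             pairs = pairs, elapsed = elapsed)
  }
  .world_cache$acc
}

# hand-built locus for start assignment: upstream of the annotated ATG the
# frame is open through two in-frame ATGs, then hits a TAA stop
start_locus <- function(strand = "+", utr5 = 4) {
  up_frame <- paste0("TAA", "ATGGCC", "ATGACC")   # stop, atg@-12, atg@-6
  lead <- "CCACCTTGCACCTTGCACCTTG"                # pad, keeps frame intact
  cds <- paste0("ATGCTTGAAGTTCAAATCCTTGACTTCGGACATAAGCTGTGGCGTATC",
                "TCCTATAACTAA")
  down <- "CGATCGGATCCAATTGGCCTAG"
  plus <- paste0(lead, up_frame, cds, down)
  contig <- if (strand == "+") plus else mitocensus:::revcomp(plus)
  L <- nchar(contig)
  s0 <- nchar(lead) + nchar(up_frame)             # coding-axis CDS start
  cds_lo <- if (strand == "+") s0 else L - s0 - nchar(cds)
  cds_hi <- cds_lo + nchar(cds)
  model <- gene_model("gs", "ctgS", strand, cbind(cds_lo, cds_hi),
                      tx_start = max(0, cds_lo - utr5),
                      tx_end = min(L, cds_hi + utr5),
                      protein = mitocensus:::translate_cds(cds))
  transcript <- paste0(
    substring(plus, s0 - utr5 + 1, s0), cds,
    substring(plus, s0 + nchar(cds) + 1, s0 + nchar(cds) + 6))
  list(genome = c(ctgS = contig), model = model,
       transcript = transcript, cds = cds, s0 = s0)
}

aln_for <- function(loc, flank = 25) {
  align_transcript(loc$transcript,
                   genomic_window(loc$genome, loc$model, flank = flank))
}

# hand-built single-gene locus with one planted intron; everything about it
# is written out longhand so it is independent of the generator
toy_locus <- function(strand = "+", intron = "GTAAGTTTTTTTTTTTTTTTTTTTTTTTTTTCTAG",
                      utr5 = 12, utr3 = 10) {
  # 20 codons; starts ATG, ends TAA; junction after 27 CDS bases (base 27 = C)
  cds <- paste0("ATGGCTGAAGTTCAAATCCTAGACTTC",
                "GGACATAAGCTGTGGCGTATCTCCTATAACTAA")
  stopifnot(nchar(cds) == 60, substring(cds, 27, 27) == "C")
  exon1 <- substring(cds, 1, 27)
  exon2 <- substring(cds, 28, 60)
  up <- "ACCACCACCACCTTGATCGATC"    # 22 nt upstream pad / UTR source
  down <- "CGATCGGATCCAATTGGCCTTA"   # 22 nt downstream pad
  body <- paste0(exon1, intron, exon2)
  plus_gene <- paste0(up, body, down)
  contig <- if (strand == "+") plus_gene else mitocensus:::revcomp(plus_gene)
  L <- nchar(contig)
  cds_lo <- if (strand == "+") nchar(up) else L - nchar(up) - nchar(body)
  cds_hi <- cds_lo + nchar(body)
  i_lo <- if (strand == "+") cds_lo + 27 else cds_lo + nchar(exon2)
  i_hi <- i_lo + nchar(intron)
  exons <- rbind(c(cds_lo, i_lo), c(i_hi, cds_hi))
  tx_lo <- max(0, cds_lo - if (strand == "+") utr5 else utr3)
  tx_hi <- min(L, cds_hi + if (strand == "+") utr3 else utr5)
  model <- gene_model("toy", "ctgT", strand, exons,
                      tx_start = tx_lo, tx_end = tx_hi,
                      protein = mitocensus:::translate_cds(cds))
  transcript <- paste0(substring(if (strand == "+") plus_gene else plus_gene,
                                 nchar(up) - utr5 + 1, nchar(up)),
                       cds,
                       substring(plus_gene, nchar(up) + nchar(body) + 1,
                                 nchar(up) + nchar(body) + utr3))
  list(genome = c(ctgT = contig), model = model, transcript = transcript,
       cds = cds, intron = c(start = i_lo, end = i_hi),
       intron_size = nchar(intron))
}
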