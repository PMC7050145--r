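#' Configuration for the synthetic-data generator
#'
#' Defaults are the stated world the pipeline is verified against: a
#' compact, intron-poor nuclear genome in which ~12% of genes carry
#' (mostly single) GT..AG introns with truncated-log-normal sizes averaging
#' 151 nt on [55, 756]; intergenic spacers on [44, 691] averaging 217 nt;
#' co-assembled adjacent gene pairs transcribed in opposite orientation
#' 38:9; and predictor scores concentrated high for MTS-bearing
#' mitochondrial proteins, low for everything else including the
#' mitochondrial no-MTS class (carriers, membrane proteins).
#'
#' @param seed integer master seed; every entity derives its own stream
#'   from `(seed, entity id)`, so adding genes never perturbs existing ones.
#' @param n_genes number of genes.
#' @param genes_per_contig contig packing.
#' @param p_intron_gene probability a gene carries introns.
#' @param p_single_intron probability an intron-bearing gene has exactly
#'   one intron (otherwise two).
#' @param intron_meanlog,intron_sdlog,intron_range truncated log-normal
#'   intron-size law; the default meanlog is fitted so the truncated mean
#'   is 151 nt.
#' @param spacer_range,spacer_shape1,spacer_shape2 intergenic-spacer law:
#'   shifted Beta scaled to the range (defaults give mean 217 nt).
#' @param p_opposite probability a co-assembled pair is divergently /
#'   convergently transcribed (default 38/47).
#' @param n_coassembled_pairs planted co-assembled pairs (intronless genes;
#'   requires `2 * n_coassembled_pairs <= n_genes`).
#' @param p_true_mitochondrial,p_no_mts_given_mito,p_rna_contaminant
#'   localization-class mix: MTS-bearing mitochondrial, mitochondrial
#'   lacking an MTS (16%, as observed for carriers/membrane proteins),
#'   RNA-binding contaminants with spuriously high scores.
#' @param beta_high,beta_low Beta parameters (x100 scale) for predictor
#'   scores of MTS-bearing (and contaminant) vs other proteins.
#' @param snp_rate per-gene probability of one planted transcript SNP.
#' @param p_snp_silent fraction of planted SNPs that are silent
#'   third-position changes (the rest nonsynonymous).
#' @param cds_codons,utr_range,pad CDS length range (codons), UTR length
#'   range (nt), terminal contig pad (nt).
#' @param max_contig_length optional cap; exceeding it is a sizing error.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_genes = 2000, genes_per_contig = 100,
                       p_intron_gene = 0.12, p_single_intron = 0.82,
                       intron_meanlog = 4.8999, intron_sdlog = 0.45,
                       intron_range = c(55, 756),
                       spacer_range = c(44, 691),
                       spacer_shape1 = 2, spacer_shape2 = 5.4798,
                       p_opposite = 38 / 47, n_coassembled_pairs = 47,
                       p_true_mitochondrial = 0.30,
                       p_no_mts_given_mito = 0.16,
                       p_rna_contaminant = 0.036,
                       beta_high = c(8, 2), beta_low = c(2, 8),
                       snp_rate = 0.01, p_snp_silent = 0.8,
                       cds_codons = c(100, 500), utr_range = c(20, 80),
                       pad = 200, max_contig_length = NULL) {
  cfg <- as.list(environment())
  probs <- c(p_intron_gene, p_single_intron, p_opposite,
             p_true_mitochondrial, p_no_mts_given_mito, p_rna_contaminant,
             snp_rate, p_snp_silent)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (2 * n_coassembled_pairs > n_genes) {
    stop("n_coassembled_pairs too large: need 2 * pairs <= n_genes")
  }
  structure(cfg, class = "sim_config")
}

NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

rtrunc_lnorm <- function(n, meanlog, sdlog, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n * 3 + 10, meanlog, sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  as.integer(round(out[seq_len(n)]))
}

# All per-gene randomness for gene i happens inside one derived stream.
make_gene_spec <- function(i, cfg, in_pair) {
  with_entity_seed(cfg$seed, i, {
    cls_p <- c(
      mitochondrial_mts = cfg$p_true_mitochondrial * (1 - cfg$p_no_mts_given_mito),
      mitochondrial_no_mts = cfg$p_true_mitochondrial * cfg$p_no_mts_given_mito,
      rna_binding_contaminant = cfg$p_rna_contaminant)
    cls_p <- c(cls_p, non_mitochondrial = 1 - sum(cls_p))
    class <- sample(names(cls_p), 1, prob = cls_p)

    n_codons <- sample(seq(cfg$cds_codons[1], cfg$cds_codons[2]), 1)
    cds <- paste0("ATG",
                  paste(sample(NONSTOP_CODONS, n_codons - 2, TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1))
    cds_len <- 3L * n_codons

    n_introns <- 0L
    if (!in_pair && runif(1) < cfg$p_intron_gene) {
      n_introns <- if (runif(1) < cfg$p_single_intron) 1L else 2L
    }
    intron_pos <- integer(0); intron_size <- integer(0); intron_seq <- character(0)
    if (n_introns > 0) {
      # junction after `pos` CDS bases; the exonic base 5' of the donor must
      # not be G, so the planted junction is the leftmost GT..AG placement
      cand <- which(strsplit(cds, "")[[1]] != "G")
      cand <- cand[cand >= 30 & cand <= cds_len - 30]
      pos <- integer(0)
      for (jj in seq_len(n_introns)) {
        ok <- cand[vapply(cand, function(p) all(abs(p - pos) >= 60), logical(1))]
        if (!length(ok)) break
        pos <- c(pos, ok[sample.int(length(ok), 1)])
      }
      pos <- sort(pos)
      n_introns <- length(pos)
      intron_pos <- pos
      intron_size <- rtrunc_lnorm(n_introns, cfg$intron_meanlog,
                                  cfg$intron_sdlog, cfg$intron_range)
      intron_seq <- vapply(intron_size, function(s)
        paste0("GT", random_dna(s - 4L), "AG"), character(1))
    }

    snp <- NULL
    if (!in_pair && runif(1) < cfg$snp_rate) {
      snp <- plant_snp(cds, n_codons, intron_pos,
                       silent = runif(1) < cfg$p_snp_silent)
    }

    high <- class %in% c("mitochondrial_mts", "rna_binding_contaminant")
    bp <- if (high) cfg$beta_high else cfg$beta_low
    scores <- round(100 * rbeta(length(ALL_PREDICTORS), bp[1], bp[2]), 2)
    names(scores) <- ALL_PREDICTORS

    flags <- list(
      known_exclusive_mitochondrial =
        class == "mitochondrial_mts" && runif(1) < 0.2,
      known_no_mts_class = class == "mitochondrial_no_mts",
      known_other_compartment =
        class == "non_mitochondrial" && runif(1) < 0.05,
      rna_binding_suspect = class == "rna_binding_contaminant"
    )
    category <- if (startsWith(class, "mito")) {
      sample(names(CATEGORY_LABELS), 1,
             prob = c(4, 17, 8, 15.5, 5, 8, 17, 5, 3, 27.5))
    } else NA_character_

    list(i = i, class = class, cds = cds, cds_len = cds_len,
         n_introns = n_introns, intron_pos = intron_pos,
         intron_size = intron_size, intron_seq = intron_seq,
         snp = snp, scores = scores, flags = flags, category = category)
  })
}

# pick a silent third-position (or nonsynonymous first-position) change,
# >= 30 nt away from intron junctions and CDS ends; NULL if no site found
plant_snp <- function(cds, n_codons, intron_pos, silent) {
  for (try in 1:25) {
    ci <- sample(10:(n_codons - 10), 1)
    p3 <- 3L * ci            # 1-based position of the codon's third base
    if (length(intron_pos) && any(abs(p3 - intron_pos) < 30)) next
    codon <- substring(cds, p3 - 2L, p3)
    if (silent) {
      for (b in sample(setdiff(c("A", "C", "G", "T"), substring(codon, 3, 3)))) {
        alt <- codon
        substring(alt, 3, 3) <- b
        if (identical(codon_aa(alt), codon_aa(codon))) {
          return(list(cds_pos = p3 - 1L, base = b,  # 0-based spliced-CDS pos
                      label = "silent_third_position"))
        }
      }
    } else {
      for (b in sample(setdiff(c("A", "C", "G", "T"), substring(codon, 1, 1)))) {
        alt <- codon
        substring(alt, 1, 1) <- b
        if (!alt %in% STOP_CODONS && !identical(codon_aa(alt), codon_aa(codon))) {
          return(list(cds_pos = p3 - 3L, base = b, label = "nonsynonymous"))
        }
      }
    }
  }
  NULL
}

#' Generate a synthetic genome with gene models and a truth ledger
#'
#' Genes are packed onto contigs with spacers drawn from the spacer law;
#' introns are inserted with GT..AG termini at their planted sizes; every
#' CDS translates cleanly under the standard genetic code. The first
#' `n_coassembled_pairs` adjacent (odd, even) gene index pairs are
#' designated co-assembled: their facing UTRs are sized to overlap across
#' the spacer and their second gene's strand is drawn opposite with
#' probability `p_opposite`. The ledger describes exactly the emitted
#' sequences and is what every test assertion resolves against.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character), `models` (named list of
#'   [gene_model()]), `proteins` (named character), and `ledger` (list of
#'   data.frames: `genes`, `introns`, `pairs`, `snps`).
#' @export
generate_genome <- function(config) {
  cfg <- config
  n <- cfg$n_genes
  n_pairs <- cfg$n_coassembled_pairs
  pair_of <- integer(n)                      # 0 = none, else pair index
  if (n_pairs > 0) {
    pair_of[seq_len(2 * n_pairs)] <- rep(seq_len(n_pairs), each = 2)
  }

  specs <- lapply(seq_len(n), function(i)
    make_gene_spec(i, cfg, in_pair = pair_of[i] > 0))

  # strands: sequential so a pair's second gene is set relative to the first
  strand <- character(n)
  for (i in seq_len(n)) {
    strand[i] <- with_entity_seed(cfg$seed, 3e6 + i, {
      second <- pair_of[i] > 0 && i %% 2 == 0
      if (second) {
        if (runif(1) < cfg$p_opposite) setdiff(c("+", "-"), strand[i - 1])
        else strand[i - 1]
      } else sample(c("+", "-"), 1)
    })
  }

  spacer_after <- vapply(seq_len(n), function(i) with_entity_seed(
    cfg$seed, 1e6 + i,
    as.integer(round(cfg$spacer_range[1] +
      diff(cfg$spacer_range) * rbeta(1, cfg$spacer_shape1, cfg$spacer_shape2)))
  ), integer(1))

  contig_of <- (seq_len(n) - 1L) %/% cfg$genes_per_contig + 1L
  genome <- character(0)
  gene_rows <- list(); intron_rows <- list(); pair_rows <- list()
  snp_rows <- list(); models <- list(); proteins <- character(0)

  for (ctg in unique(contig_of)) {
    idx <- which(contig_of == ctg)
    cid <- sprintf("ctg%03d", ctg)
    parts <- list(with_entity_seed(cfg$seed, 2e6 + ctg, random_dna(cfg$pad)))
    pos <- as.integer(cfg$pad)
    coords <- data.frame(i = idx, cds_lo = NA_integer_, cds_hi = NA_integer_)

    for (k in seq_along(idx)) {
      i <- idx[k]
      sp <- specs[[i]]
      body <- splice_in_introns(sp$cds, sp$intron_pos, sp$intron_seq)
      if (strand[i] == "-") body <- revcomp(body)
      coords$cds_lo[k] <- pos
      pos <- pos + nchar(body)
      coords$cds_hi[k] <- pos
      parts[[length(parts) + 1L]] <- body
      gap <- if (k < length(idx)) spacer_after[i] else as.integer(cfg$pad)
      parts[[length(parts) + 1L]] <-
        with_entity_seed(cfg$seed, 5e6 + i, random_dna(gap))
      pos <- pos + gap
    }
    seq <- paste(unlist(parts), collapse = "")
    if (!is.null(cfg$max_contig_length) && nchar(seq) > cfg$max_contig_length) {
      stop("sizing error: contig ", cid, " length ", nchar(seq),
           " exceeds max_contig_length")
    }
    genome[cid] <- seq

    # UTR lengths in contig orientation (left/right of the CDS block)
    for (k in seq_along(idx)) {
      i <- idx[k]
      sp <- specs[[i]]
      avail_l <- if (k == 1) cfg$pad else spacer_after[idx[k - 1]]
      avail_r <- if (k == length(idx)) cfg$pad else spacer_after[i]
      u <- with_entity_seed(cfg$seed, 4e6 + i, {
        c(sample(cfg$utr_range[1]:cfg$utr_range[2], 1),
          sample(cfg$utr_range[1]:cfg$utr_range[2], 1))
      })
      u_l <- min(u[1], avail_l); u_r <- min(u[2], avail_r)
      p <- pair_of[i]
      if (p > 0) {  # facing UTRs overlap across the pair spacer
        if (i %% 2 == 1) {
          s <- spacer_after[i]
          u_r <- min(avail_r, s %/% 2L + 30L)
        } else {
          s <- spacer_after[i - 1]
          u_l <- min(avail_l, s - s %/% 2L + 30L)
        }
      }
      lo <- coords$cds_lo[k]; hi <- coords$cds_hi[k]
      tx_lo <- lo - u_l; tx_hi <- hi + u_r

      # intron contig intervals
      if (sp$n_introns > 0) {
        off <- cumsum(c(0L, sp$intron_size))[seq_len(sp$n_introns)]
        s_cod <- sp$intron_pos + off
        e_cod <- s_cod + sp$intron_size
        blen <- hi - lo
        if (strand[i] == "+") {
          istart <- lo + s_cod; iend <- lo + e_cod
        } else {
          istart <- lo + blen - e_cod; iend <- lo + blen - s_cod
        }
        o <- order(istart)
        intron_rows[[length(intron_rows) + 1L]] <- data.frame(
          gene_id = gene_name(i), contig_id = cid,
          start = as.integer(istart[o]), end = as.integer(iend[o]),
          size = as.integer((iend - istart)[o]), coding_order = o)
      }

      exons <- exon_intervals(lo, hi,
        if (sp$n_introns > 0) intron_rows[[length(intron_rows)]] else NULL)
      prot <- translate_cds(sp$cds)
      models[[gene_name(i)]] <- gene_model(
        gene_name(i), cid, strand[i], exons,
        tx_start = tx_lo, tx_end = tx_hi, protein = prot)
      proteins[gene_name(i)] <- prot

      if (!is.null(sp$snp)) {
        snp_rows[[length(snp_rows) + 1L]] <- data.frame(
          gene_id = gene_name(i), cds_pos = sp$snp$cds_pos,
          base = sp$snp$base, label = sp$snp$label)
      }
      gene_rows[[length(gene_rows) + 1L]] <- cbind(
        data.frame(
          gene_id = gene_name(i), contig_id = cid, strand = strand[i],
          class = sp$class, category = sp$category,
          cds_start = as.integer(lo), cds_end = as.integer(hi),
          tx_start = as.integer(tx_lo), tx_end = as.integer(tx_hi),
          cds_len = sp$cds_len, n_introns = sp$n_introns,
          pair = pair_of[i],
          utr5 = if (strand[i] == "+") u_l else u_r,
          utr3 = if (strand[i] == "+") u_r else u_l),
        as.data.frame(as.list(sp$scores)),
        as.data.frame(sp$flags))
    }
  }

  genes <- do.call(rbind, gene_rows)
  if (n_pairs > 0) {
    for (p in seq_len(n_pairs)) {
      a <- 2L * p - 1L; b <- 2L * p
      pair_rows[[p]] <- data.frame(
        pair = p, gene_id_a = gene_name(a), gene_id_b = gene_name(b),
        spacer_nt = spacer_after[a],
        orientation = if (strand[a] == strand[b]) "same" else "opposite",
        transcript_id = sprintf("txpair_%04d", p))
    }
  }

  list(
    genome = genome, models = models, proteins = proteins,
    ledger = list(
      genes = genes,
      introns = if (length(intron_rows)) do.call(rbind, intron_rows) else
        data.frame(gene_id = character(0), contig_id = character(0),
                   start = integer(0), end = integer(0), size = integer(0),
                   coding_order = integer(0)),
      pairs = if (length(pair_rows)) do.call(rbind, pair_rows) else
        data.frame(pair = integer(0), gene_id_a = character(0),
                   gene_id_b = character(0), spacer_nt = integer(0),
                   orientation = character(0), transcript_id = character(0)),
      snps = if (length(snp_rows)) do.call(rbind, snp_rows) else
        data.frame(gene_id = character(0), cds_pos = integer(0),
                   base = character(0), label = character(0)),
      config = cfg
    )
  )
}

gene_name <- function(i) sprintf("g%05d", i)

splice_in_introns <- function(cds, pos, seqs) {
  if (!length(pos)) return(cds)
  out <- character(0)
  prev <- 0L
  for (j in seq_along(pos)) {
    out <- c(out, substring(cds, prev + 1L, pos[j]), seqs[j])
    prev <- pos[j]
  }
  paste(c(out, substring(cds, prev + 1L, nchar(cds))), collapse = "")
}

exon_intervals <- function(lo, hi, introns) {
  if (is.null(introns) || !nrow(introns)) {
    return(cbind(start = lo, end = hi))
  }
  cbind(start = c(lo, introns$end), end = c(introns$start, hi))
}

#' Generate transcript contigs from a synthetic genome
#'
#' Spliced mRNAs with UTRs read off the genome; for each designated
#' co-assembled pair a single merged contig spanning both genes'
#' transcribed regions is emitted instead of two transcripts (the
#' overlapping UTRs would co-assemble); planted SNPs are applied to the
#' transcript sequence.
#'
#' @param sim a [generate_genome()] result.
#' @return list with `transcripts` (named character) and `tx_map` (truth
#'   data.frame transcript_id / gene_id).
#' @export
generate_transcripts <- function(sim) {
  genes <- sim$ledger$genes
  introns <- sim$ledger$introns
  snps <- sim$ledger$snps
  tx <- character(0)
  map_rows <- list()

  paired <- genes$pair > 0
  for (r in which(!paired)) {
    g <- genes[r, ]
    seq <- spliced_region(sim$genome[[g$contig_id]], g$tx_start, g$tx_end,
                          introns[introns$gene_id == g$gene_id, ])
    if (g$strand == "-") seq <- revcomp(seq)
    srow <- snps[snps$gene_id == g$gene_id, ]
    if (nrow(srow)) {
      at <- g$utr5 + srow$cds_pos[1] + 1L
      substring(seq, at, at) <- srow$base[1]
    }
    tid <- paste0("tx_", g$gene_id)
    tx[tid] <- seq
    map_rows[[length(map_rows) + 1L]] <-
      data.frame(transcript_id = tid, gene_id = g$gene_id)
  }

  pairs <- sim$ledger$pairs
  for (p in seq_len(nrow(pairs))) {
    ga <- genes[genes$gene_id == pairs$gene_id_a[p], ]
    gb <- genes[genes$gene_id == pairs$gene_id_b[p], ]
    lo <- min(ga$tx_start, gb$tx_start)
    hi <- max(ga$tx_end, gb$tx_end)
    tid <- pairs$transcript_id[p]
    tx[tid] <- substring(sim$genome[[ga$contig_id]], lo + 1L, hi)
    map_rows[[length(map_rows) + 1L]] <- data.frame(
      transcript_id = tid, gene_id = c(ga$gene_id, gb$gene_id))
  }

  list(transcripts = tx, tx_map = do.call(rbind, map_rows))
}

spliced_region <- function(contig, lo, hi, introns) {
  seq <- substring(contig, lo + 1L, hi)
  if (!nrow(introns)) return(seq)
  ii <- introns[order(introns$start, decreasing = TRUE), ]
  for (j in seq_len(nrow(ii))) {
    seq <- paste0(substring(seq, 1L, ii$start[j] - lo),
                  substring(seq, ii$end[j] - lo + 1L, nchar(seq)))
  }
  seq
}

#' Simulate external predictor score and annotation-flag tables
#'
#' Stands in for the six external targeting predictors: MTS-bearing
#' mitochondrial proteins (and RNA-binding contaminants, whose amino-acid
#' composition spuriously looks mitochondrial) draw scores from the
#' high-concentration law, everything else — including mitochondrial
#' proteins of the no-MTS class — from the low law. Positivity calls are
#' score >= 50.
#'
#' @param sim a [generate_genome()] result.
#' @return list with `scores` and `flags` data.frames (protein ids are
#'   `<gene_id>.p`).
#' @export
simulate_predictors <- function(sim) {
  genes <- sim$ledger$genes
  scores <- cbind(data.frame(protein_id = paste0(genes$gene_id, ".p")),
                  genes[, ALL_PREDICTORS])
  rownames(scores) <- NULL
  flags <- data.frame(
    protein_id = paste0(genes$gene_id, ".p"),
    category = genes$category,
    known_exclusive_mitochondrial = genes$known_exclusive_mitochondrial,
    known_no_mts_class = genes$known_no_mts_class,
    known_other_compartment = genes$known_other_compartment,
    rna_binding_suspect = genes$rna_binding_suspect
  )
  list(scores = scores, flags = flags)
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_genome()], [generate_transcripts()] and
#' [simulate_predictors()]; optionally writes genome.fa, models.gff3,
#' transcripts.fa, proteins.fa, scores.tsv, flags.tsv and the truth ledger
#' TSVs to `out_dir`. Identical seed and config give byte-identical
#' outputs.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list: `genome`, `models`, `proteins`, `transcripts`, `tx_map`,
#'   `scores`, `flags`, `ledger`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  sim <- generate_genome(config)
  txs <- generate_transcripts(sim)
  pred <- simulate_predictors(sim)
  out <- c(sim, txs, pred)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(out$genome, file.path(out_dir, "genome.fa"))
    write_fasta(out$transcripts, file.path(out_dir, "transcripts.fa"))
    write_fasta(out$proteins, file.path(out_dir, "proteins.fa"))
    write_gff3(out$models, file.path(out_dir, "models.gff3"))
    write_tsv(out$scores, file.path(out_dir, "scores.tsv"))
    write_tsv(out$flags, file.path(out_dir, "flags.tsv"))
    write_tsv(out$ledger$genes, file.path(out_dir, "truth_genes.tsv"))
    write_tsv(out$ledger$introns, file.path(out_dir, "truth_introns.tsv"))
    write_tsv(out$ledger$pairs, file.path(out_dir, "truth_pairs.tsv"))
    write_tsv(out$ledger$snps, file.path(out_dir, "truth_snps.tsv"))
    write_tsv(out$tx_map, file.path(out_dir, "truth_tx_map.tsv"))
  }
  out
}
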