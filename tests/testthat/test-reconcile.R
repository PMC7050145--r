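test_that("upstream extension fires iff the extension rescored MTS-positive", {
  for (strand in c("+", "-")) {
    loc <- start_locus(strand)
    genome <- loc$genome
    aln <- aln_for(loc)
    old_prot <- loc$model$protein

    res_yes <- assign_start(loc$model, aln, genome, rescore = function(p) TRUE)
    expect_equal(res_yes$provenance$start_provenance, "upstream_extension")
    expect_equal(res_yes$provenance$extension_nt, 6L)   # nearest ATG first
    new_prot <- res_yes$model$protein
    expect_gt(nchar(new_prot), nchar(old_prot))
    expect_equal(substring(new_prot, 1, 1), "M")
    expect_equal(substring(new_prot, nchar(new_prot) - nchar(old_prot) + 1),
                 old_prot)  # never shortens, frame preserved

    res_no <- assign_start(loc$model, aln, genome, rescore = function(p) FALSE)
    expect_equal(res_no$provenance$start_provenance, "annotated")
    expect_identical(res_no$model$exons, loc$model$exons)
  }
})

test_that("the extension can pick a farther ATG when the nearest fails", {
  loc <- start_locus("+")
  seen <- character(0)
  res <- assign_start(loc$model, aln_for(loc), loc$genome,
                      rescore = function(p) {
                        seen <<- c(seen, p)
                        nchar(p) > nchar(loc$model$protein) + 2
                      })
  expect_length(seen, 2)                     # tried nearest, then farther
  expect_equal(res$provenance$extension_nt, 12L)
  expect_equal(substring(res$model$protein, 1, 1), "M")
})

test_that("an immediate upstream stop leaves the start unchanged", {
  loc <- start_locus("+")
  # annotate the start at the -12 ATG: only TAA remains upstream in frame
  m2 <- gene_model("gs", "ctgS", "+",
                   cbind(loc$model$exons[1, 1] - 12L, loc$model$exons[1, 2]),
                   tx_start = loc$model$tx_start - 12L,
                   tx_end = loc$model$tx_end)
  m2$protein <- mitocensus:::translate_cds(spliced_cds(m2, loc$genome))
  tx2 <- paste0(substring(loc$genome[[1]], m2$exons[1, 1] - 5, m2$exons[1, 1]),
                spliced_cds(m2, loc$genome))
  aln <- align_transcript(tx2, genomic_window(loc$genome, m2, flank = 25))
  res <- assign_start(m2, aln, loc$genome, rescore = function(p) TRUE)
  expect_equal(res$provenance$start_provenance, "annotated")
  expect_identical(res$model$exons, m2$exons)
})

test_that("transcript-covered upstream ATGs are not used for extension", {
  loc <- start_locus("+", utr5 = 20)   # transcript covers both upstream ATGs
  res <- assign_start(loc$model, aln_for(loc), loc$genome,
                      rescore = function(p) TRUE)
  expect_equal(res$provenance$start_provenance, "annotated")
  expect_equal(res$provenance$note, "upstream_atg_covered_by_transcript")
})

test_that("upstream stop provenance distinguishes transcript from genome", {
  loc_short <- start_locus("+", utr5 = 4)    # stop far upstream, uncovered
  res <- assign_start(loc_short$model, aln_for(loc_short), loc_short$genome,
                      rescore = function(p) FALSE)
  expect_equal(res$provenance$stop_source, "genome")

  loc_long <- start_locus("+", utr5 = 20)    # UTR reaches past the stop
  res2 <- assign_start(loc_long$model, aln_for(loc_long), loc_long$genome,
                       rescore = function(p) FALSE)
  expect_equal(res2$provenance$stop_source, "transcript")
})

test_that("mismatches classify by codon position and translation", {
  toy <- toy_locus()
  # codon 2 of the CDS is GCT (Ala); transcript pos of its 3rd base is
  # utr5 (12) + 6
  tx <- toy$transcript
  substring(tx, 18, 18) <- "C"   # GCT -> GCC, still Ala
  substring(tx, 16, 16) <- "A"   # GCT -> ACT at codon pos 1: Ala -> Thr
  substring(tx, 5, 5) <- chartr("ACGT", "TACG", substring(tx, 5, 5))  # 5' UTR
  aln <- align_transcript(tx, genomic_window(toy$genome, toy$model, flank = 10))
  mm <- classify_mismatches(aln, toy$model, toy$genome)
  expect_equal(nrow(mm), 3L)
  expect_setequal(mm$label, c("silent_third_position", "nonsynonymous", "UTR"))
  third <- mm[mm$label == "silent_third_position", ]
  expect_equal(third$codon_pos, 3L)
  expect_equal(third$ref_codon, "GCT")
  expect_equal(third$alt_codon, "GCC")
  ns <- mm[mm$label == "nonsynonymous", ]
  expect_equal(ns$codon_pos, 1L)
  expect_equal(ns$alt_codon, "ACT")
})

test_that("transcripts map to their own gene; merged contigs map to both", {
  w <- small_world()
  truth <- w$sim$tx_map
  got <- map_transcripts(w$sim$models, w$sim$transcripts, w$sim$genome)
  key <- function(d) sort(paste(d$transcript_id, d$gene_id))
  expect_identical(key(got), key(truth))
})

test_that("reconciliation recovers every planted structure exactly", {
  w <- small_world()
  rec <- w$rec
  expect_true(all(rec$report$status == "ok"))
  truth <- w$sim$ledger$introns
  called <- rec$introns
  n_called <- if (is.null(called)) 0L else nrow(called)
  expect_equal(n_called, nrow(truth))
  if (n_called) {
    key <- function(d, a, b) sort(paste(d$gene_id, d[[a]], d[[b]]))
    expect_identical(key(called, "contig_start", "contig_end"),
                     key(truth, "start", "end"))
    expect_true(all(called$canonical))
    expect_true(all(called$donor == "GT" & called$acceptor == "AG"))
  }
  # corrected models still translate cleanly
  ok <- vapply(rec$models, function(m)
    isTRUE(validate_gene_model(m, w$sim$genome)$translation_ok), logical(1))
  expect_true(all(ok))
  # planted SNPs are found and labeled as planted
  snps <- w$sim$ledger$snps
  if (nrow(snps)) {
    mm <- rec$mismatches
    expect_equal(sort(mm$gene_id), sort(snps$gene_id))
    expect_identical(
      mm$label[order(mm$gene_id)],
      snps$label[order(snps$gene_id)])
  }
  # genes without planted SNPs align at identity 1
  clean <- setdiff(rec$report$gene_id, w$sim$ledger$snps$gene_id)
  expect_true(all(rec$report$identity[rec$report$gene_id %in% clean] == 1))
})
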