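test_that("a transcript identical to the genomic CDS gives one block", {
  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  model <- gene_model("g", "c1", "+", cbind(100L, 300L))
  genome <- c(c1 = seq)
  win <- genomic_window(genome, model, flank = 100)
  tx <- substring(seq, 101, 300)
  aln <- align_transcript(tx, win)
  expect_equal(nrow(aln$blocks), 1L)
  expect_equal(nrow(aln$introns), 0L)
  expect_equal(aln$identity, 1.0)
  expect_equal(aln$blocks$contig_start, 100L)
  expect_equal(aln$blocks$contig_end, 300L)
})

test_that("a planted GT..AG intron is recovered at its exact coordinates", {
  for (strand in c("+", "-")) {
    toy <- toy_locus(strand = strand)
    win <- genomic_window(toy$genome, toy$model, flank = 10)
    aln <- align_transcript(toy$transcript, win)
    intr <- call_introns(aln)
    expect_equal(nrow(intr), 1L)
    expect_equal(intr$contig_start, unname(toy$intron["start"]))
    expect_equal(intr$contig_end, unname(toy$intron["end"]))
    expect_equal(intr$size, toy$intron_size)
    expect_equal(intr$donor, "GT")
    expect_equal(intr$acceptor, "AG")
    expect_true(intr$canonical)
    expect_equal(aln$identity, 1.0)
    expect_true(covers_cds(aln, toy$model))
    # splicing identity: removing the intron reproduces the aligned span
    b <- aln$blocks[order(aln$blocks$contig_start), ]
    spliced <- vapply(seq_len(nrow(b)), function(i)
      substring(toy$genome[["ctgT"]], b$contig_start[i] + 1,
                b$contig_end[i]), character(1))
    joined <- paste(spliced, collapse = "")
    if (strand == "-") joined <- mitocensus:::revcomp(joined)
    expect_true(grepl(toy$cds, joined, fixed = TRUE))
  }
})

test_that("introns at the observed size extremes are recovered exactly", {
  # sizes at the envelope ends and mean: 55, 151, 756
  set.seed(23)
  sizes <- c(55L, 151L, 756L)
  cds <- paste0("ATG", paste(sample(mitocensus:::NONSTOP_CODONS, 148, TRUE),
                             collapse = ""), "TAA")
  # junction sites whose preceding exonic base is not G (keeps the planted
  # placement canonical), roughly 120 nt apart
  non_g <- which(strsplit(cds, "")[[1]] != "G")
  pos <- as.integer(c(min(non_g[non_g >= 90]), min(non_g[non_g >= 210]),
                      min(non_g[non_g >= 330])))
  intr_seq <- vapply(sizes, function(s)
    paste0("GT", mitocensus:::random_dna(s - 4L), "AG"), character(1))
  body <- mitocensus:::splice_in_introns(cds, pos, intr_seq)
  pad <- mitocensus:::random_dna(80)
  genome <- c(cX = paste0(pad, body, pad))
  off <- cumsum(c(0L, sizes))[1:3]
  exons <- cbind(start = 80L + c(0L, pos + off[1:3] + sizes),
                 end = 80L + c(pos + off, nchar(body)))
  model <- gene_model("g3", "cX", "+", exons)
  aln <- align_transcript(cds, genomic_window(genome, model, flank = 50))
  intr <- call_introns(aln)
  expect_equal(intr$size, sizes)
  expect_true(all(intr$canonical))
  expect_equal(intr$contig_start, 80L + pos + off)
})

test_that("junction placement matches the exhaustive oracle", {
  set.seed(31)
  n_checked <- 0
  for (rep in 1:60) {
    exL <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    exR <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    L <- sample(30:80, 1)
    intron <- paste0("GT", mitocensus:::random_dna(L - 4L), "AG")
    g <- paste0(exL, intron, exR)
    t <- paste0(exL, exR)
    expected <- oracle_single_junction(g, t, L)
    model <- gene_model("g", "c", "+",
                        cbind(c(0L, 60L + L), c(60L, nchar(g))))
    aln <- align_transcript(t, genomic_window(c(c = g), model, flank = 0))
    intr <- call_introns(aln)
    expect_equal(nrow(intr), 1L)
    expect_equal(c(intr$contig_start, intr$contig_end), expected)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 60)
})

test_that("non-GT..AG introns are returned flagged, never dropped", {
  toy <- toy_locus(intron = paste0("GC", strrep("T", 30), "AG"))
  aln <- align_transcript(toy$transcript,
                          genomic_window(toy$genome, toy$model, flank = 10))
  intr <- call_introns(aln)
  expect_equal(nrow(intr), 1L)
  expect_false(intr$canonical)
  expect_equal(intr$size, 34L)
})

test_that("sub-minimum genomic gaps are alignment gaps, not introns", {
  toy <- toy_locus(intron = paste0("GT", strrep("C", 16), "AG"))  # 20 nt
  aln <- align_transcript(toy$transcript,
                          genomic_window(toy$genome, toy$model, flank = 10))
  expect_equal(nrow(aln$introns), 0L)
  expect_equal(nrow(aln$gaps), 1L)
  expect_equal(aln$gaps$size, 20L)
})

test_that("isolated substitutions stay inside one block as mismatches", {
  set.seed(13)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  model <- gene_model("g", "c1", "+", cbind(100L, 300L))
  genome <- c(c1 = seq)
  tx <- substring(seq, 101, 300)
  substring(tx, 100, 100) <- chartr("ACGT", "CAAC", substring(tx, 100, 100))
  aln <- align_transcript(tx, genomic_window(genome, model, flank = 100))
  expect_equal(nrow(aln$blocks), 1L)
  expect_equal(nrow(aln$mismatches), 1L)
  expect_equal(nrow(aln$introns), 0L)
  expect_equal(aln$identity, 1 - 1 / 200)
  mmpos <- aln$mismatches$w_pos + aln$window$start
  expect_equal(mmpos, 199L)  # 0-based contig position of the substitution
})

test_that("wrong-contig transcripts and short inputs are refused", {
  toy <- toy_locus()
  win <- genomic_window(toy$genome, toy$model, flank = 10)
  set.seed(5)
  stranger <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  expect_error(align_transcript(stranger, win), "unalignable")
  expect_error(align_transcript("ACGTACGTA", win), "60 nt")
})

test_that("non-colinear evidence is reported as rearranged", {
  set.seed(8)
  seg1 <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  seg2 <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  genome <- c(c1 = paste0(seg1, seg2))
  model <- gene_model("g", "c1", "+", cbind(0L, 160L))
  win <- genomic_window(genome, model, flank = 0)
  scrambled <- paste0(seg2, seg1)
  expect_error(align_transcript(scrambled, win), "rearranged")
})

test_that("minus-strand orientation is auto-detected", {
  toy <- toy_locus(strand = "-")
  win <- genomic_window(toy$genome, toy$model, flank = 10)
  aln <- align_transcript(toy$transcript, win)
  # transcript is coding-strand, gene on minus: alignment still succeeds
  expect_equal(aln$identity, 1.0)
  expect_equal(call_introns(aln)$donor, "GT")
  # and the antisense rendering of the same transcript aligns too
  aln2 <- align_transcript(mitocensus:::revcomp(toy$transcript), win)
  expect_equal(call_introns(aln2)$contig_start, call_introns(aln)$contig_start)
})
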