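#' Extract a coding-strand genomic window around a gene
#'
#' All splice-signal work is done on the coding strand: for minus-strand
#' genes the window sequence is reverse-complemented, and window positions
#' are mapped back to contig coordinates on output.
#'
#' @param genome named character vector of contigs.
#' @param model a [gene_model()]; the window spans its transcribed region
#'   plus `flank` on each side, clipped to the contig.
#' @param flank flank size in nt.
#' @return a `genomic_window` list: contig_id, start, end (0-based
#'   half-open contig coords), strand, seq (coding strand).
#' @export
genomic_window <- function(genome, model, flank = 300) {
  contig <- genome[[model$contig_id]]
  if (is.null(contig)) stop("contig ", model$contig_id, " absent from genome")
  lo <- max(0L, model$tx_start - as.integer(flank))
  hi <- min(nchar(contig), model$tx_end + as.integer(flank))
  seq <- substring(contig, lo + 1L, hi)
  if (model$strand == "-") seq <- revcomp(seq)
  structure(list(contig_id = model$contig_id, start = lo, end = hi,
                 strand = model$strand, seq = seq),
            class = "genomic_window")
}

# window coding-space interval [a, b) -> contig 0-based half-open interval
window_to_contig <- function(window, a, b) {
  if (window$strand == "+") {
    cbind(start = window$start + a, end = window$start + b)
  } else {
    cbind(start = window$end - b, end = window$end - a)
  }
}

#' Align an assembled transcript to a genomic window
#'
#' Splice-aware alignment by exact-anchor chaining: k-mers unique in both
#' the transcript and the window are matched and chained colinearly;
#' genomic gaps of at least `min_intron` nt between chained anchor runs
#' become candidate introns (placed canonically by [call_introns()]),
#' smaller gaps are reported as alignment gaps (indel evidence, not
#' splicing). Isolated substitutions inside a chained run are recorded as
#' mismatches. This is deliberately not a general-purpose spliced aligner:
#' it expects near-identical transcript evidence, as from the same strain's
#' RNA-Seq assembly.
#'
#' Both transcript orientations are tried; the one yielding anchors wins.
#'
#' @param transcript transcript sequence (character scalar, >= 60 nt).
#' @param window a [genomic_window()].
#' @param k anchor k-mer size.
#' @param min_intron smallest genomic gap treated as an intron.
#' @param transcript_id,gene_id identifiers carried into the result.
#' @return a `transcript_alignment`: blocks (coding-space and contig
#'   coordinates), introns (see [call_introns()]), gaps, mismatches,
#'   identity over the aligned span.
#' @export
align_transcript <- function(transcript, window, k = 21, min_intron = 30,
                             transcript_id = NA_character_,
                             gene_id = NA_character_) {
  if (nchar(transcript) < 60) stop("transcript shorter than 60 nt")
  G <- window$seq

  fw <- chain_anchors(transcript, G, k)
  # a transcript in the right orientation yields many anchors, the wrong
  # one essentially none, so the second pass is skipped when unambiguous
  rc <- if (is.null(fw) || nrow(fw) < 10) chain_anchors(revcomp(transcript), G, k)
        else NULL
  if (is.null(fw) && is.null(rc)) stop("unalignable: no unique anchors")
  use_rc <- is.null(fw) || (!is.null(rc) && nrow(rc) > nrow(fw))
  T <- if (use_rc) revcomp(transcript) else transcript
  anchors <- if (use_rc) rc else fw

  d <- anchors[, "g"] - anchors[, "t"]
  if (is.unsorted(d) || is.unsorted(anchors[, "g"], strictly = TRUE)) {
    stop("rearranged evidence: anchors are not colinear")
  }

  Tc <- strsplit(T, "")[[1]]
  Gc <- strsplit(G, "")[[1]]

  # maximal runs of equal diagonal = provisional blocks
  runs <- rle(d)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  blocks <- data.frame(
    diag = runs$values,
    t_lo = anchors[starts, "t"],                 # covered t range [t_lo, t_hi)
    t_hi = anchors[ends, "t"] + k
  )

  # junctions between consecutive blocks: feasible placement range
  junctions <- NULL
  if (nrow(blocks) > 1) {
    junctions <- vector("list", nrow(blocks) - 1L)
    for (i in seq_len(nrow(blocks) - 1L)) {
      dA <- blocks$diag[i]; dB <- blocks$diag[i + 1L]
      covA <- blocks$t_hi[i]; covB <- blocks$t_lo[i + 1L]
      hi <- covA
      while (hi < covB && Tc[hi + 1L] == Gc[hi + dA + 1L]) hi <- hi + 1L
      lo <- covB
      while (lo > covA && Tc[lo] == Gc[lo + dB]) lo <- lo - 1L
      if (lo > hi) {  # mismatch inside the uncovered junction region
        lo <- hi
      }
      junctions[[i]] <- list(lo = lo, hi = hi, dA = dA, dB = dB,
                             gap = dB - dA)
    }
  }

  # extend terminal blocks, tolerating isolated substitutions (SNPs near
  # the transcript ends); a run of >3 consecutive mismatches ends the block
  # at the last matching base
  t <- blocks$t_lo[1]; g <- t + blocks$diag[1]
  run <- 0L; new_lo <- t
  while (t > 0L && g > 0L && run <= 3L) {
    if (Tc[t] == Gc[g]) { run <- 0L; new_lo <- t - 1L } else run <- run + 1L
    t <- t - 1L; g <- g - 1L
  }
  blocks$t_lo[1] <- new_lo
  nb <- nrow(blocks)
  nT <- length(Tc); nG <- length(Gc)
  t <- blocks$t_hi[nb]; g <- t + blocks$diag[nb]
  run <- 0L; new_hi <- t
  while (t < nT && g < nG && run <= 3L) {
    if (Tc[t + 1L] == Gc[g + 1L]) { run <- 0L; new_hi <- t + 1L } else run <- run + 1L
    t <- t + 1L; g <- g + 1L
  }
  blocks$t_hi[nb] <- new_hi

  aln <- structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    contig_id = window$contig_id, strand = window$strand,
    transcript_strand = if (use_rc) "-" else "+",
    window = window, k = k, min_intron = min_intron,
    T = T, blocks = blocks, junctions = junctions
  ), class = "transcript_alignment")
  finalize_alignment(aln)
}

# Unique-kmer anchors between transcript and window; NULL if none.
# Returns a matrix with 0-based columns t, g sorted by t.
chain_anchors <- function(T, G, k) {
  kt <- kmer_starts(T, k)
  kg <- kmer_starts(G, k)
  if (!length(kt) || !length(kg)) return(NULL)
  ut <- which(!(duplicated(kt) | duplicated(kt, fromLast = TRUE)))
  ug <- which(!(duplicated(kg) | duplicated(kg, fromLast = TRUE)))
  m <- match(kt[ut], kg[ug])
  keep <- !is.na(m)
  if (!any(keep)) return(NULL)
  cbind(t = ut[keep] - 1L, g = ug[m[keep]] - 1L)
}

# Resolve junction placements (leftmost GT..AG), cut blocks there, collect
# introns / gaps / mismatches and identity.
finalize_alignment <- function(aln) {
  blocks <- aln$blocks
  Tc <- strsplit(aln$T, "")[[1]]
  Gc <- strsplit(aln$window$seq, "")[[1]]
  introns <- list(); gaps <- list()
  cut <- integer(0)

  if (!is.null(aln$junctions)) {
    for (i in seq_along(aln$junctions)) {
      j <- aln$junctions[[i]]
      cand <- j$lo:j$hi
      gs <- cand + j$dA          # 0-based intron start in window space
      ge <- cand + j$dB          # half-open end
      donor <- paste0(Gc[gs + 1L], Gc[gs + 2L])
      acceptor <- paste0(Gc[ge - 1L], Gc[ge])
      canon <- donor == "GT" & acceptor == "AG"
      pick <- if (any(canon)) which(canon)[1] else 1L
      tstar <- cand[pick]
      cut <- c(cut, tstar)
      rec <- data.frame(
        w_start = gs[pick], w_end = ge[pick], size = j$gap,
        donor = donor[pick], acceptor = acceptor[pick],
        canonical = canon[pick], t_pos = tstar
      )
      if (j$gap >= aln$min_intron) {
        introns[[length(introns) + 1L]] <- rec
      } else {
        gaps[[length(gaps) + 1L]] <- rec
      }
    }
  }

  # final block boundaries in transcript space: [t_lo1, cut1), [cut1, cut2)...
  t_lo <- c(blocks$t_lo[1], cut)
  t_hi <- c(cut, blocks$t_hi[nrow(blocks)])
  out_blocks <- data.frame(
    t_start = t_lo, t_end = t_hi,
    g_start = t_lo + blocks$diag, g_end = t_hi + blocks$diag
  )

  # mismatches: compare each block span base by base
  mm <- list()
  for (b in seq_len(nrow(out_blocks))) {
    ts <- out_blocks$t_start[b]; te <- out_blocks$t_end[b]
    if (te <= ts) next
    dd <- out_blocks$g_start[b] - ts
    idx <- which(Tc[(ts + 1L):te] != Gc[(ts + dd + 1L):(te + dd)])
    if (length(idx)) {
      tp <- ts + idx - 1L
      mm[[length(mm) + 1L]] <- data.frame(
        t_pos = tp, w_pos = tp + dd,
        t_base = Tc[tp + 1L], g_base = Gc[tp + dd + 1L]
      )
    }
  }
  mismatches <- if (length(mm)) do.call(rbind, mm) else
    data.frame(t_pos = integer(0), w_pos = integer(0),
               t_base = character(0), g_base = character(0))
  intr <- if (length(introns)) do.call(rbind, introns) else
    data.frame(w_start = integer(0), w_end = integer(0), size = integer(0),
               donor = character(0), acceptor = character(0),
               canonical = logical(0), t_pos = integer(0))
  gapdf <- if (length(gaps)) do.call(rbind, gaps) else intr[0, ]

  # contig coordinates
  add_contig <- function(df, a = "w_start", b = "w_end") {
    if (nrow(df)) {
      cc <- window_to_contig(aln$window, df[[a]], df[[b]])
      df$contig_start <- cc[, "start"]; df$contig_end <- cc[, "end"]
    } else {
      df$contig_start <- integer(0); df$contig_end <- integer(0)
    }
    df
  }
  intr <- add_contig(intr)
  gapdf <- add_contig(gapdf)
  bc <- window_to_contig(aln$window, out_blocks$g_start, out_blocks$g_end)
  out_blocks$contig_start <- bc[, "start"]; out_blocks$contig_end <- bc[, "end"]

  aligned_len <- sum(out_blocks$t_end - out_blocks$t_start)
  aln$blocks <- out_blocks
  aln$introns <- intr
  aln$gaps <- gapdf
  aln$mismatches <- mismatches
  aln$identity <- if (aligned_len) 1 - nrow(mismatches) / aligned_len else NA_real_
  aln$aligned_len <- aligned_len
  aln$junctions <- NULL
  aln
}

#' @export
print.transcript_alignment <- function(x, ...) {
  cat(sprintf(
    "<transcript_alignment> %s -> %s (%s)  %d block(s), %d intron(s), identity %.4f\n",
    x$transcript_id, x$contig_id, x$strand, nrow(x$blocks), nrow(x$introns),
    x$identity))
  invisible(x)
}

#' Introns called from a transcript alignment
#'
#' Each genomic gap of at least the alignment's minimum intron size is
#' reported as an intron with donor/acceptor dinucleotides read from the
#' coding strand. When a junction can slide without changing the spliced
#' product, the leftmost placement consistent with GT..AG termini is the
#' canonical form (leftmost among several GT..AG placements; leftmost
#' overall if none is GT..AG). Non-GT..AG introns are returned with
#' `canonical = FALSE`, never dropped.
#'
#' @param aln a [align_transcript()] result.
#' @return data.frame with coding-space (`w_start`, `w_end`) and contig
#'   (`contig_start`, `contig_end`) 0-based half-open coordinates, `size`,
#'   `donor`, `acceptor`, `canonical`.
#' @export
call_introns <- function(aln) {
  stopifnot(inherits(aln, "transcript_alignment"))
  aln$introns
}

#' Check that an alignment covers a model's CDS
#'
#' @param aln a `transcript_alignment`.
#' @param model the [gene_model()] it was aligned against.
#' @return TRUE/FALSE.
#' @export
covers_cds <- function(aln, model) {
  need <- model$exons
  got <- aln$blocks[, c("contig_start", "contig_end")]
  for (i in seq_len(nrow(need))) {
    ok <- any(got$contig_start <= need[i, 1] & got$contig_end >= need[i, 2])
    if (!ok) return(FALSE)
  }
  TRUE
}
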