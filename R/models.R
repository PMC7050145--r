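#' Construct a gene model
#'
#' A gene model records the coding structure of one gene on a contig:
#' ordered coding-exon intervals (0-based, half-open, ascending on the
#' contig), strand, the transcribed span (UTRs included) and optionally the
#' protein translation. Internally all coordinates are 0-based half-open;
#' GFF3 I/O converts to/from 1-based inclusive.
#'
#' @param gene_id,contig_id identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with columns `start`, `end` (0-based
#'   half-open CDS segments, ascending, non-overlapping).
#' @param tx_start,tx_end transcribed span (0-based half-open); defaults to
#'   the CDS span.
#' @param protein optional amino-acid sequence.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig_id, strand, exons,
                       tx_start = NULL, tx_end = NULL, protein = NULL) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2)
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) > 1) {
    o <- order(exons[, 1])
    exons <- exons[o, , drop = FALSE]
    if (any(exons[-1, 1] < exons[-nrow(exons), 2])) {
      stop("gene ", gene_id, ": exons overlap or are unsorted")
    }
  }
  if (any(exons[, 2] <= exons[, 1])) stop("gene ", gene_id, ": empty exon")
  structure(list(
    gene_id = gene_id, contig_id = contig_id, strand = strand,
    exons = exons,
    tx_start = as.integer(if (is.null(tx_start)) exons[1, 1] else tx_start),
    tx_end = as.integer(if (is.null(tx_end)) exons[nrow(exons), 2] else tx_end),
    protein = protein
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d CDS segment(s)\n",
              x$gene_id, x$contig_id, x$tx_start, x$tx_end, x$strand,
              nrow(x$exons)))
  invisible(x)
}

cds_length <- function(model) sum(model$exons[, 2] - model$exons[, 1])

#' Spliced coding sequence of a gene model
#'
#' Concatenates the CDS segments in contig order and reverse-complements
#' for minus-strand genes, yielding the coding-strand CDS.
#'
#' @param model a [gene_model()].
#' @param genome named character vector of contig sequences.
#' @return coding sequence (character scalar).
#' @export
spliced_cds <- function(model, genome) {
  seq <- genome[[model$contig_id]]
  parts <- substring(seq, model$exons[, 1] + 1L, model$exons[, 2])
  cds <- paste(parts, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  cds
}

#' Validate a gene model against the genome
#'
#' Checks that the spliced CDS length is divisible by 3 and, when the model
#' carries a protein, that the standard-genetic-code translation matches.
#'
#' @inheritParams spliced_cds
#' @return invisibly, a list with `cds_ok` (divisible by 3) and
#'   `translation_ok` (NA when no protein is attached). A CDS whose length
#'   is not a multiple of 3 only warns, so damaged annotations can still be
#'   inspected.
#' @export
validate_gene_model <- function(model, genome) {
  cds <- spliced_cds(model, genome)
  cds_ok <- nchar(cds) %% 3 == 0
  if (!cds_ok) {
    warning("gene ", model$gene_id, ": CDS length ", nchar(cds),
            " not divisible by 3")
  }
  translation_ok <- NA
  if (!is.null(model$protein) && cds_ok) {
    translation_ok <- identical(translate_cds(cds), model$protein)
  }
  invisible(list(cds_ok = cds_ok, translation_ok = translation_ok))
}

#' Introns implied by a gene model
#'
#' @param model a [gene_model()].
#' @return data.frame of 0-based half-open intron intervals (contig
#'   coordinates) with sizes; zero rows for single-exon genes.
#' @export
model_introns <- function(model) {
  n <- nrow(model$exons)
  if (n < 2) {
    return(data.frame(start = integer(0), end = integer(0), size = integer(0)))
  }
  start <- model$exons[-n, 2]
  end <- model$exons[-1, 1]
  data.frame(start = start, end = end, size = end - start)
}
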