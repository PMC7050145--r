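#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences. Duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  setNames(as.character(set), ids)
}

#' Write a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (anyDuplicated(names(seqs))) stop("duplicate sequence id(s)")
  set <- Biostrings::BStringSet(unlist(as.list(seqs)))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features (via rtracklayer) into a list of
#' [gene_model()] objects; GFF3's 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention. One mRNA per
#' gene is assumed. A child feature outside its gene span is a validation
#' error.
#'
#' @param path GFF3 file.
#' @return named list of `gene_model` objects (by gene id).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$ID <- as.character(df$ID)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))

  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type == "mRNA", ]
  cdss <- df[df$type == "CDS", ]
  exons <- df[df$type == "exon", ]

  models <- vector("list", nrow(genes))
  names(models) <- genes$ID
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    mr <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == g$ID, ]
    mid <- if (nrow(mr)) mr$ID[1] else g$ID
    cd <- cdss[!is.na(cdss$Parent) & cdss$Parent == mid, ]
    ex <- exons[!is.na(exons$Parent) & exons$Parent == mid, ]
    if (nrow(cd) == 0) stop("gene ", g$ID, ": no CDS features")
    if (any(cd$start < g$start | cd$end > g$end)) {
      stop("gene ", g$ID, ": CDS outside gene span")
    }
    tx_lo <- if (nrow(ex)) min(ex$start) else min(cd$start)
    tx_hi <- if (nrow(ex)) max(ex$end) else max(cd$end)
    if (tx_lo < g$start || tx_hi > g$end) {
      stop("gene ", g$ID, ": exon outside gene span")
    }
    if (sum(cd$end - cd$start + 1L) %% 3L != 0L) {
      warning("gene ", g$ID, ": CDS length not divisible by 3")
    }
    models[[i]] <- gene_model(
      gene_id = g$ID, contig_id = as.character(g$seqnames),
      strand = as.character(g$strand),
      exons = cbind(start = cd$start - 1L, end = cd$end),
      tx_start = tx_lo - 1L, tx_end = tx_hi
    )
  }
  models
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS features, converting internal 0-based half-open
#' coordinates to GFF3's 1-based inclusive.
#'
#' @param models list of [gene_model()] objects.
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @export
write_gff3 <- function(models, path, source = "mitocensus") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    gid <- m$gene_id
    mid <- paste0(gid, ".mRNA")
    line <- function(type, s, e, attrs, phase = ".") {
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              m$contig_id, source, type, s + 1L, e, m$strand, phase, attrs)
    }
    out <- c(
      line("gene", m$tx_start, m$tx_end, paste0("ID=", gid)),
      line("mRNA", m$tx_start, m$tx_end,
           paste0("ID=", mid, ";Parent=", gid))
    )
    # exon features: transcribed span minus introns (introns lie within CDS)
    intr <- model_introns(m)
    ex_lo <- c(m$tx_start, intr$end)
    ex_hi <- c(intr$start, m$tx_end)
    out <- c(out,
      sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              m$contig_id, source, ex_lo + 1L, ex_hi, m$strand, mid))
    # CDS phase: offset of the first complete codon within each segment
    n <- nrow(m$exons)
    lens <- m$exons[, 2] - m$exons[, 1]
    coding_order <- if (m$strand == "+") seq_len(n) else rev(seq_len(n))
    before <- cumsum(c(0L, lens[coding_order]))[seq_len(n)]
    phase <- integer(n)
    phase[coding_order] <- (3L - before %% 3L) %% 3L
    out <- c(out,
      sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
              m$contig_id, source, m$exons[, 1] + 1L, m$exons[, 2],
              m$strand, phase, mid))
    writeLines(out, con)
  }
  invisible(path)
}

#' Read/write tab-separated tables
#'
#' Canonical interchange is UTF-8 TSV with `.` for missing values.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = ".",
                                  header = TRUE))
}

#' @rdname read_tsv
#' @param x data.frame to write.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' Read a predictor score table
#'
#' TSV with header `protein_id, targetp, mitoprot, predotar, psort2,
#' predsl, mitofates` plus optional `<predictor>_call` columns. Scores are
#' on a 0-100 scale; a malformed probability cell is a row-level error.
#'
#' @param path TSV file.
#' @return data.frame of scores.
#' @export
read_scores <- function(path) {
  raw <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = ".",
                                         header = TRUE, colClasses = "character"))
  if (!"protein_id" %in% names(raw)) stop("score table lacks protein_id column")
  for (p in intersect(ALL_PREDICTORS, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[p]]))
    bad <- which(!is.na(raw[[p]]) & is.na(v))
    if (length(bad)) {
      stop("malformed probability cell in column '", p, "', line ",
           bad[1] + 1L, " of ", path)
    }
    raw[[p]] <- v
  }
  for (cc in grep("_call$", names(raw), value = TRUE)) {
    raw[[cc]] <- as.logical(raw[[cc]])
  }
  raw
}

#' Read / write the candidate table
#'
#' A Table-S1-like TSV: one row per candidate with identifiers, functional
#' category (A-J), sequences, the targeting assessment and intron/curation
#' annotations. Round-trips losslessly.
#'
#' @param path TSV file.
#' @return data.frame of candidate records.
#' @export
read_candidate_table <- function(path) {
  x <- read_tsv(path)
  req <- c("protein_id", "gene_id", "category")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("candidate table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !is.na(x$category) & !(x$category %in% names(CATEGORY_LABELS))
  if (any(bad)) {
    stop("unknown category code(s): ",
         paste(unique(x$category[bad]), collapse = ", "))
  }
  if (!"category_label" %in% names(x)) {
    x$category_label <- unname(CATEGORY_LABELS[x$category])
  }
  x
}

#' @rdname read_candidate_table
#' @param x data.frame of candidate records.
#' @export
write_candidate_table <- function(x, path) {
  write_tsv(x, path)
}

#' Convert a spreadsheet supplementary table to candidate TSV
#'
#' Ingests an XLSX workbook (one sheet per functional category, tolerant of
#' minor header variation) into the canonical TSV schema. Reading XLSX
#' requires the system `python` with openpyxl, which this helper shells out
#' to; XLSX is supported read-only.
#'
#' @param xlsx_path input workbook.
#' @param out_tsv output TSV path.
#' @param python python executable.
#' @return the output path, invisibly.
#' @export
xlsx_to_candidate_tsv <- function(xlsx_path, out_tsv,
                                  python = Sys.which("python")) {
  if (!nzchar(python)) stop("no python interpreter found for XLSX ingest")
  script <- system.file("python", "xlsx2tsv.py", package = "mitocensus")
  status <- system2(python, c(script, shQuote(xlsx_path), shQuote(out_tsv)),
                    stdout = "", stderr = "")
  if (status != 0) stop("XLSX conversion failed (exit ", status, ")")
  invisible(out_tsv)
}
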