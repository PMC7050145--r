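#' @import methods
#' @importFrom stats rbeta rbinom runif setNames
#' @importFrom utils head tail
NULL

PRIMARY_PREDICTORS <- c("targetp", "mitoprot", "predotar", "psort2")
ALL_PREDICTORS <- c(PRIMARY_PREDICTORS, "predsl", "mitofates")

CATEGORY_LABELS <- c(
  A = "Pyruvate metabolism, TCA cycle",
  B = "Energy metabolism",
  C = "DNA and RNA metabolism",
  D = "Translation, ribosome",
  E = "Membrane structure and function",
  F = "Protein and metabolite trafficking",
  G = "General metabolism",
  H = "Protein folding, processing, and degradation",
  I = "Reactive oxygen species (ROS) metabolism, regulation",
  J = "Unknown function"
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Round half up
#'
#' Base R `round()` rounds half to even; reports here use conventional
#' half-up rounding (0.05 -> 0.1 at one decimal).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# standard genetic code (NCBI table 1), from Biostrings
GENETIC_CODE_1 <- Biostrings::GENETIC_CODE

#' Reverse complement of a DNA string
#'
#' Plain-character implementation: the pipeline reverse-complements many
#' short strings per gene and XStringSet construction overhead dominates
#' at that call rate.
#'
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @keywords internal
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtNn", "TGCAtgcaNn", x))
}

#' Translate a coding sequence (standard genetic code)
#'
#' @param cds character scalar, length divisible by 3. Trailing stop codon,
#'   if present, is dropped from the protein.
#' @return amino-acid string.
#' @keywords internal
translate_cds <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3 == 0)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- paste(GENETIC_CODE_1[codons], collapse = "")
  sub("\\*$", "", aa)
}

codon_aa <- function(codon) {
  unname(GENETIC_CODE_1[codon])
}

# Deterministic per-entity seed stream: generating entity i is unaffected by
# how many other entities exist. Kept below 2^31.
derive_seed <- function(seed, id) {
  (as.numeric(seed) * 48271 + as.numeric(id) * 16807) %% 2147483647
}

with_entity_seed <- function(seed, id, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(derive_seed(seed, id))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substring k-mers, 0-based start positions in attribute
kmer_starts <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) return(character(0))
  substring(s, seq_len(n), seq_len(n) + k - 1L)
}
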