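# Independent oracles, kept deliberately naive.

# brute-force consensus mean over the four primary predictors
oracle_p <- function(scores) {
  prim <- c("targetp", "mitoprot", "predotar", "psort2")
  vals <- vapply(prim, function(p) {
    if (is.null(scores[[p]]) || is.na(scores[[p]])) NA_real_ else scores[[p]]
  }, numeric(1))
  if (any(is.na(vals))) return(NA_real_)
  s <- 0
  for (v in vals) s <- s + v
  s / 4
}

# enumerate every junction placement of a single intron of length L in a
# genomic string g that splices to transcript t; return the canonical one
# (leftmost GT..AG, else leftmost) as c(start, end), 0-based half-open
oracle_single_junction <- function(g, t, L) {
  feas <- list()
  for (s in 0:(nchar(g) - L)) {
    spliced <- paste0(substring(g, 1, s), substring(g, s + L + 1, nchar(g)))
    if (identical(spliced, t)) feas[[length(feas) + 1L]] <- c(s, s + L)
  }
  if (!length(feas)) return(NULL)
  canon <- vapply(feas, function(iv) {
    substring(g, iv[1] + 1, iv[1] + 2) == "GT" &&
      substring(g, iv[2] - 1, iv[2]) == "AG"
  }, logical(1))
  if (any(canon)) feas[[which(canon)[1]]] else feas[[1]]
}

# naive column trimmer: loop over columns, count missing
oracle_trim <- function(rows, missing_chars = c("-", ".", "?", "X", "x")) {
  m <- do.call(rbind, strsplit(rows, ""))
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    keep[j] <- mean(m[, j] %in% missing_chars) <= 0.5
  }
  apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
}
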