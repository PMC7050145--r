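#' Consensus mitochondrial-targeting probability (P)
#'
#' The consensus metric P is the arithmetic mean, on a 0-100 scale, of the
#' four primary predictors' mitochondrial probabilities (TargetP, MitoProt,
#' Predotar, PSORT II). The tertiary predictors (PredSL, MitoFates) count
#' toward the positivity vote but never enter P. If any of the four primary
#' scores is missing, P is undefined (`NA`).
#'
#' All scores must already be normalized to the 0-100 scale at ingest;
#' `consensus_p()` refuses values outside [0, 100] rather than guessing a
#' scale.
#'
#' @param scores either a named numeric vector/list for one protein (names
#'   among `targetp, mitoprot, predotar, psort2, predsl, mitofates`) or a
#'   data.frame with those columns plus `protein_id`.
#' @return numeric vector of P values (NA where undefined), one per protein.
#' @examples
#' consensus_p(c(targetp = 90, mitoprot = 80, predotar = 85, psort2 = 81))
#' @export
consensus_p <- function(scores) {
  m <- scores_matrix(scores)
  validate_scores(m)
  unname(rowMeans(m[, PRIMARY_PREDICTORS, drop = FALSE]))
}

# normalize the two accepted input shapes into a numeric matrix with one
# row per protein and one column per predictor (NA = absent)
scores_matrix <- function(scores) {
  if (is.data.frame(scores)) {
    m <- matrix(NA_real_, nrow(scores), length(ALL_PREDICTORS),
                dimnames = list(scores[["protein_id"]], ALL_PREDICTORS))
    for (p in intersect(ALL_PREDICTORS, names(scores))) {
      m[, p] <- as.numeric(scores[[p]])
    }
    m
  } else {
    scores <- unlist(scores)
    bad <- setdiff(names(scores), ALL_PREDICTORS)
    if (length(bad)) {
      stop("unknown predictor(s) in score map: ", paste(bad, collapse = ", "))
    }
    m <- matrix(NA_real_, 1L, length(ALL_PREDICTORS),
                dimnames = list(NULL, ALL_PREDICTORS))
    m[1L, names(scores)] <- as.numeric(scores)
    m
  }
}

validate_scores <- function(m) {
  for (p in colnames(m)) {
    v <- m[, p]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      stop("score out of [0, 100] for predictor '", p, "'")
    }
  }
  invisible(m)
}

#' Assign a targeting-strength bin
#'
#' Bins reflect relative targeting strength: `strong` (P >= 75), `moderate`
#' (50 <= P < 75), `weak` (30 <= P < 50), otherwise `not_predicted`. The
#' moderate and weak bins correspond to "probable" and "possible"
#' candidates. There is no upper cap on `strong`: the published 75-95 range
#' records an observed maximum, not a rule. Undefined P maps to
#' `not_predicted`.
#'
#' @param P numeric vector of consensus probabilities on 0-100 (NA allowed).
#' @return factor with ordered levels `not_predicted < weak < moderate < strong`.
#' @export
assign_bin <- function(P) {
  if (any(!is.na(P) & (P < 0 | P > 100))) stop("P out of range [0, 100]")
  bin <- rep("not_predicted", length(P))
  bin[!is.na(P) & P >= 30] <- "weak"
  bin[!is.na(P) & P >= 50] <- "moderate"
  bin[!is.na(P) & P >= 75] <- "strong"
  factor(bin, levels = c("not_predicted", "weak", "moderate", "strong"),
         ordered = TRUE)
}

OVERRIDE_LEVELS <- c("none", "functions_elsewhere_exclusion",
                     "rna_binding_false_positive_exclusion",
                     "exclusive_mito_inclusion", "no_mts_class_inclusion")

#' Apply the candidate decision rule with curation overrides
#'
#' The baseline rule accepts a protein as a mitochondrial candidate when
#' P >= 30 AND at least three of the six predictors call it mitochondrial.
#' Curation flags override the baseline, in fixed precedence (exclusions
#' beat inclusions):
#'
#' 1. `known_other_compartment` -> excluded (`functions_elsewhere_exclusion`);
#' 2. `rna_binding_suspect` -> excluded (`rna_binding_false_positive_exclusion`);
#' 3. `known_exclusive_mitochondrial` -> included regardless of P
#'    (`exclusive_mito_inclusion`);
#' 4. `known_no_mts_class` -> included (carriers, membrane proteins known to
#'    lack an N-terminal MTS; `no_mts_class_inclusion`);
#' 5. otherwise the baseline rule applies (`override = "none"`).
#'
#' Per-predictor positivity defaults to score >= `positivity_threshold`; a
#' `<predictor>_call` logical column in `scores`, when present, takes
#' precedence (ingest may map external class labels directly).
#'
#' @param scores data.frame of predictor scores (see [consensus_p()]); may
#'   carry optional `<predictor>_call` logical columns.
#' @param flags optional data.frame of annotation flags with columns
#'   `protein_id`, `known_exclusive_mitochondrial`, `known_no_mts_class`,
#'   `known_other_compartment`, `rna_binding_suspect` (missing columns are
#'   treated as all-FALSE).
#' @param positivity_threshold score at or above which a predictor is
#'   counted as calling "mitochondrial" (default 50).
#' @return data.frame with columns `protein_id`, `P`, `bin`, `n_positive`,
#'   `is_candidate`, `override`.
#' @export
assess_targeting <- function(scores, flags = NULL, positivity_threshold = 50) {
  stopifnot(is.data.frame(scores), "protein_id" %in% names(scores))
  m <- scores_matrix(scores)
  validate_scores(m)
  P <- unname(rowMeans(m[, PRIMARY_PREDICTORS, drop = FALSE]))
  pos <- positivity_matrix(scores, m, positivity_threshold)
  n_positive <- rowSums(pos, na.rm = TRUE)
  baseline <- !is.na(P) & P >= 30 & n_positive >= 3

  fl <- resolve_flags(scores[["protein_id"]], flags)
  if (any(fl$known_exclusive_mitochondrial & fl$known_other_compartment)) {
    stop("known_exclusive_mitochondrial and known_other_compartment are ",
         "mutually exclusive")
  }
  override <- rep("none", nrow(scores))
  override[fl$known_no_mts_class] <- "no_mts_class_inclusion"
  override[fl$known_exclusive_mitochondrial] <- "exclusive_mito_inclusion"
  override[fl$rna_binding_suspect] <- "rna_binding_false_positive_exclusion"
  override[fl$known_other_compartment] <- "functions_elsewhere_exclusion"

  is_candidate <- baseline
  is_candidate[override %in% c("exclusive_mito_inclusion",
                               "no_mts_class_inclusion")] <- TRUE
  is_candidate[override %in% c("functions_elsewhere_exclusion",
                               "rna_binding_false_positive_exclusion")] <- FALSE

  data.frame(
    protein_id = scores[["protein_id"]],
    P = P,
    bin = assign_bin(P),
    n_positive = as.integer(n_positive),
    is_candidate = is_candidate,
    override = factor(override, levels = OVERRIDE_LEVELS),
    stringsAsFactors = FALSE
  )
}

positivity_matrix <- function(scores, m, threshold) {
  pos <- !is.na(m) & m >= threshold
  for (p in ALL_PREDICTORS) {
    call_col <- paste0(p, "_call")
    if (call_col %in% names(scores)) {
      v <- as.logical(scores[[call_col]])
      pos[!is.na(v), p] <- v[!is.na(v)]
    }
  }
  pos
}

resolve_flags <- function(protein_id, flags) {
  cols <- c("known_exclusive_mitochondrial", "known_no_mts_class",
            "known_other_compartment", "rna_binding_suspect")
  out <- as.data.frame(setNames(
    rep(list(rep(FALSE, length(protein_id))), length(cols)), cols))
  if (is.null(flags)) return(out)
  stopifnot(is.data.frame(flags), "protein_id" %in% names(flags))
  i <- match(protein_id, flags[["protein_id"]])
  for (col in intersect(cols, names(flags))) {
    v <- as.logical(flags[[col]])[i]
    out[[col]] <- !is.na(v) & v
  }
  out
}

#' Screen RNA-binding false positives among TargetP-positive proteins
#'
#' Proteins with spuriously predicted mitochondrial targeting (typically
#' RNA-binding: cytosolic ribosomal proteins, histones, spliceosomal
#' proteins) are excluded during curation; in the source survey they made up
#' 10-15% of all proteins retrieved by the TargetP screen. This reports the
#' excluded set and that fraction for a batch.
#'
#' @param assessments output of [assess_targeting()].
#' @param scores the matching predictor score table (for TargetP positivity).
#' @param positivity_threshold threshold used for the TargetP call when no
#'   `targetp_call` column is present.
#' @return list with `excluded` (protein ids excluded as RNA-binding false
#'   positives), `n_targetp_positive`, and `fraction` (excluded /
#'   TargetP-positive; NA for an empty or TargetP-negative batch).
#' @export
screen_false_positives <- function(assessments, scores,
                                   positivity_threshold = 50) {
  if (nrow(assessments) == 0) {
    return(list(excluded = character(0), n_targetp_positive = 0L,
                fraction = NA_real_))
  }
  m <- scores_matrix(scores)
  pos <- positivity_matrix(scores, m, positivity_threshold)
  tp_pos <- scores[["protein_id"]][pos[, "targetp"]]
  excl <- assessments$protein_id[
    assessments$override == "rna_binding_false_positive_exclusion"]
  excl <- intersect(excl, tp_pos)
  list(
    excluded = excl,
    n_targetp_positive = length(tp_pos),
    fraction = if (length(tp_pos)) length(excl) / length(tp_pos) else NA_real_
  )
}
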