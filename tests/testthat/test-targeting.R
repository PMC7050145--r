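test_that("consensus_p averages the four primary predictors only", {
  expect_equal(consensus_p(c(targetp = 100, mitoprot = 100, predotar = 100,
                             psort2 = 100, predsl = 0, mitofates = 0)), 100)
  expect_equal(consensus_p(c(targetp = 0, mitoprot = 0, predotar = 0,
                             psort2 = 0)), 0)
  expect_equal(consensus_p(c(targetp = 90, mitoprot = 80, predotar = 85,
                             psort2 = 81)), 84)
  # tertiary predictors never enter P
  expect_equal(
    consensus_p(c(targetp = 40, mitoprot = 40, predotar = 40, psort2 = 40,
                  predsl = 100, mitofates = 100)), 40)
})

test_that("consensus_p is undefined when a primary predictor is missing", {
  expect_true(is.na(consensus_p(c(targetp = 90, mitoprot = 80,
                                  predotar = 85))))
  df <- data.frame(protein_id = c("a", "b"), targetp = c(50, 60),
                   mitoprot = c(50, NA), predotar = c(50, 60),
                   psort2 = c(50, 60))
  expect_equal(consensus_p(df), c(50, NA))
})

test_that("consensus_p validates its input", {
  expect_error(consensus_p(c(targetp = 101, mitoprot = 0, predotar = 0,
                             psort2 = 0)), "targetp")
  expect_error(consensus_p(c(targetp = 50, mitoprot = -1, predotar = 0,
                             psort2 = 0)), "mitoprot")
  expect_error(consensus_p(c(bogus = 50)), "bogus")
})

test_that("consensus_p equals the brute-force oracle on random score maps", {
  set.seed(42)
  for (i in 1:200) {
    sc <- as.list(setNames(runif(6, 0, 100),
                           c("targetp", "mitoprot", "predotar", "psort2",
                             "predsl", "mitofates")))
    expect_lt(abs(consensus_p(sc) - oracle_p(sc)), 1e-9)
    # permutation invariance over predictor order
    perm <- sample(names(sc))
    expect_identical(consensus_p(sc[perm]), consensus_p(sc))
  }
})

test_that("assign_bin implements the published bin edges", {
  expect_equal(as.character(assign_bin(75)), "strong")
  expect_equal(as.character(assign_bin(50)), "moderate")
  expect_equal(as.character(assign_bin(74.999)), "moderate")
  expect_equal(as.character(assign_bin(30)), "weak")
  expect_equal(as.character(assign_bin(49.999)), "weak")
  expect_equal(as.character(assign_bin(29.99)), "not_predicted")
  expect_equal(as.character(assign_bin(100)), "strong")  # no upper cap
  expect_equal(as.character(assign_bin(NA)), "not_predicted")
  expect_error(assign_bin(101), "range")
  expect_error(assign_bin(-0.5), "range")
})

test_that("assign_bin is monotone non-decreasing in P", {
  p <- sort(c(runif(500, 0, 100), 30, 50, 75))
  bins <- assign_bin(p)
  expect_true(all(diff(as.integer(bins)) >= 0))
})

make_scores <- function(..., id = "p1") {
  data.frame(protein_id = id, ..., stringsAsFactors = FALSE)
}

test_that("the baseline candidate rule needs P >= 30 and 3 of 6 positives", {
  # P = 40 with exactly three positives
  s <- make_scores(targetp = 70, mitoprot = 60, predotar = 15, psort2 = 15,
                   predsl = 55, mitofates = 10)
  a <- assess_targeting(s)
  expect_equal(a$P, 40)
  expect_equal(a$n_positive, 3L)
  expect_true(a$is_candidate)
  expect_equal(as.character(a$bin), "weak")
  expect_equal(as.character(a$override), "none")

  # same P, only two positives
  s2 <- make_scores(targetp = 70, mitoprot = 60, predotar = 15, psort2 = 15,
                    predsl = 10, mitofates = 10)
  a2 <- assess_targeting(s2)
  expect_equal(a2$P, 40)
  expect_false(a2$is_candidate)

  # P below the floor, many positives (calls overriding scores)
  s3 <- make_scores(targetp = 20, mitoprot = 20, predotar = 20, psort2 = 20,
                    targetp_call = TRUE, mitoprot_call = TRUE,
                    predotar_call = TRUE)
  a3 <- assess_targeting(s3)
  expect_equal(a3$n_positive, 3L)
  expect_false(a3$is_candidate)
})

test_that("explicit call columns override the score threshold", {
  s <- make_scores(targetp = 90, mitoprot = 90, predotar = 90, psort2 = 90,
                   targetp_call = FALSE)
  a <- assess_targeting(s)
  expect_equal(a$n_positive, 3L)
  s2 <- make_scores(targetp = 10, mitoprot = 10, predotar = 10, psort2 = 10,
                    targetp_call = TRUE)
  expect_equal(assess_targeting(s2)$n_positive, 1L)
  # threshold itself is configurable
  s3 <- make_scores(targetp = 45, mitoprot = 45, predotar = 45, psort2 = 45)
  expect_equal(assess_targeting(s3, positivity_threshold = 40)$n_positive, 4L)
})

test_that("curation overrides follow the fixed precedence", {
  s <- make_scores(targetp = 10, mitoprot = 10, predotar = 10, psort2 = 10)
  fl <- data.frame(protein_id = "p1", known_exclusive_mitochondrial = TRUE)
  a <- assess_targeting(s, fl)
  expect_true(a$is_candidate)
  expect_equal(as.character(a$override), "exclusive_mito_inclusion")

  fl2 <- data.frame(protein_id = "p1", known_no_mts_class = TRUE)
  a2 <- assess_targeting(s, fl2)
  expect_true(a2$is_candidate)
  expect_equal(as.character(a2$override), "no_mts_class_inclusion")

  # a robustly predicted protein functioning elsewhere is still excluded
  s3 <- make_scores(targetp = 90, mitoprot = 90, predotar = 90, psort2 = 90,
                    predsl = 90, mitofates = 90)
  fl3 <- data.frame(protein_id = "p1", known_other_compartment = TRUE)
  a3 <- assess_targeting(s3, fl3)
  expect_false(a3$is_candidate)
  expect_equal(as.character(a3$override), "functions_elsewhere_exclusion")

  # exclusions beat inclusions; exclusive-mito beats no-MTS-class
  fl4 <- data.frame(protein_id = "p1", known_no_mts_class = TRUE,
                    rna_binding_suspect = TRUE)
  expect_equal(as.character(assess_targeting(s3, fl4)$override),
               "rna_binding_false_positive_exclusion")
  fl5 <- data.frame(protein_id = "p1", known_exclusive_mitochondrial = TRUE,
                    known_no_mts_class = TRUE)
  expect_equal(as.character(assess_targeting(s3, fl5)$override),
               "exclusive_mito_inclusion")
  fl6 <- data.frame(protein_id = "p1", known_exclusive_mitochondrial = TRUE,
                    known_other_compartment = TRUE)
  expect_error(assess_targeting(s3, fl6), "mutually exclusive")
})

test_that("a missing primary predictor blocks candidacy except by inclusion", {
  s <- make_scores(targetp = 90, mitoprot = 90, predotar = 90,
                   psort2 = NA, predsl = 90, mitofates = 90)
  a <- assess_targeting(s)
  expect_true(is.na(a$P))
  expect_equal(as.character(a$bin), "not_predicted")
  expect_false(a$is_candidate)
  fl <- data.frame(protein_id = "p1", known_exclusive_mitochondrial = TRUE)
  expect_true(assess_targeting(s, fl)$is_candidate)
})

test_that("increasing one predictor never flips a baseline candidate off", {
  set.seed(99)
  for (i in 1:100) {
    sc <- setNames(as.list(runif(6, 0, 100)), mitocensus:::ALL_PREDICTORS)
    df <- do.call(make_scores, sc)
    before <- assess_targeting(df)
    p <- sample(mitocensus:::ALL_PREDICTORS, 1)
    df2 <- df
    df2[[p]] <- min(100, df[[p]] + runif(1, 0, 100 - df[[p]]))
    after <- assess_targeting(df2)
    if (before$is_candidate) expect_true(after$is_candidate)
  }
})

test_that("screen_false_positives reports the excluded fraction", {
  n <- 20
  scores <- data.frame(
    protein_id = sprintf("p%02d", 1:n),
    targetp = 90, mitoprot = 90, predotar = 90, psort2 = 90)
  flags <- data.frame(protein_id = sprintf("p%02d", 1:3),
                      rna_binding_suspect = TRUE)
  a <- assess_targeting(scores, flags)
  r <- screen_false_positives(a, scores)
  expect_equal(r$n_targetp_positive, 20L)
  expect_equal(sort(r$excluded), sprintf("p%02d", 1:3))
  expect_equal(r$fraction, 0.15)

  r0 <- screen_false_positives(assess_targeting(scores), scores)
  expect_length(r0$excluded, 0)
  expect_equal(r0$fraction, 0)

  empty <- scores[0, ]
  re <- screen_false_positives(assess_targeting(empty), empty)
  expect_true(is.na(re$fraction))
})
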