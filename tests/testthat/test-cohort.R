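test_that("proband categorization follows positive > inconclusive > negative", {
  expect_identical(categorize_proband(c("P_LP", "VUS")), "positive")
  expect_identical(categorize_proband(character(0)), "negative")
  expect_identical(categorize_proband(c("B_LB", "B_LB")), "negative")
  # Novel variants (class NA) are inconclusive irrespective of VarSome tier.
  expect_identical(categorize_proband("NA"), "inconclusive")
  expect_identical(categorize_proband("VUS"), "inconclusive")
  # Conflicts, even those favoring pathogenicity, never make a positive.
  expect_identical(categorize_proband("CON_VUS_LP"), "inconclusive")
  expect_identical(categorize_proband("CON_VUS_BLB"), "inconclusive")
  expect_identical(categorize_proband(c("B_LB", "VUS")), "inconclusive")
  expect_error(categorize_proband("pathogenic"), "unknown")
})

test_that("categorization is a partition and is monotone in the evidence", {
  classes <- c("P_LP", "VUS", "B_LB", "CON_VUS_LP", "CON_VUS_BLB", "NA")
  withr::with_seed(202L, {
    for (rep in seq_len(200)) {
      verdict_list <- sample(classes, sample(0:6, 1), replace = TRUE)
      cat0 <- categorize_proband(verdict_list)
      # Exactly one category.
      expect_true(cat0 %in% c("positive", "inconclusive", "negative"))
      # Adding a P/LP verdict always yields positive.
      expect_identical(categorize_proband(c(verdict_list, "P_LP")), "positive")
      # Removing variants never moves negative -> positive.
      if (length(verdict_list)) {
        sub <- verdict_list[sample(seq_along(verdict_list),
                                   sample(0:length(verdict_list), 1))]
        if (cat0 == "negative") {
          expect_identical(categorize_proband(sub), "negative")
        }
        # And a subset can never be positive unless it retains a P_LP.
        if (!"P_LP" %in% sub) {
          expect_false(categorize_proband(sub) == "positive")
        }
      }
    }
  })
})

test_that("summarize_cohort computes distinctness, recurrence and yield", {
  # One proband, no variants.
  empty <- summarize_cohort(
    make_verdicts(character(0), character(0), character(0), character(0)),
    probands = "S1"
  )
  expect_identical(empty$n_distinct_variants, 0L)
  expect_identical(empty$category_counts[["negative"]], 1L)
  expect_identical(empty$yield_percentages[["negative"]], 100)

  # Two probands sharing one variant key: one distinct variant, recurrent.
  shared <- summarize_cohort(
    make_verdicts(c("S1", "S2"), c("MYH7", "MYH7"),
                  c("c.715G>A", "c.715G>A"), c("VUS", "VUS")),
    probands = c("S1", "S2", "S3")
  )
  expect_identical(shared$n_distinct_variants, 1L)
  expect_identical(nrow(shared$recurrent_variants), 1L)
  expect_identical(shared$recurrent_variants$n_probands, 2L)
  expect_identical(shared$category_counts[["inconclusive"]], 2L)
  expect_identical(shared$category_counts[["negative"]], 1L)
  # Yield formula: 100 * count / n, one decimal.
  expect_identical(shared$yield_percentages[["inconclusive"]], round(200 / 3, 1))

  expect_error(
    summarize_cohort(make_verdicts("S1", "MYH7", "c.1A>G", "VUS"),
                     probands = c("S1", "S1")),
    "duplicate"
  )
})

test_that("identical groups compare with p = 1 on all covariates", {
  verdicts <- make_verdicts(c("S1", "S2"), c("MYH7", "MYH7"),
                            c("c.715G>A", "c.716G>A"), c("P_LP", "P_LP"))
  results <- proband_results(verdicts, c("S1", "S2", "S3", "S4"))
  covariates <- data.frame(
    proband_id = c("S1", "S2", "S3", "S4"),
    age = c(40, 60, 40, 60),
    sex = c("m", "f", "m", "f"),
    stringsAsFactors = FALSE
  )
  cmp <- compare_groups(results, covariates)
  expect_identical(nrow(cmp), 2L)
  expect_true(all(abs(cmp$p_value - 1) < 1e-12))
})

test_that("degenerate covariates are flagged, not fatal", {
  verdicts <- make_verdicts(c("S1", "S2", "S3"), rep("MYH7", 3),
                            sprintf("c.%dG>A", 1:3), rep("P_LP", 3))
  results <- proband_results(verdicts, sprintf("S%d", 1:6))
  covariates <- data.frame(
    proband_id = sprintf("S%d", 1:6),
    age = c(34, 34, 34, 53, 53, 53),
    stringsAsFactors = FALSE
  )
  cmp <- compare_groups(results, covariates)
  expect_true(is.na(cmp$p_value))
  expect_match(cmp$note, "zero variance")

  # A group of one: not computable, no crash.
  one <- proband_results(
    make_verdicts("S1", "MYH7", "c.1G>A", "P_LP"), sprintf("S%d", 1:4)
  )
  cmp <- compare_groups(one, covariates[1:4, , drop = FALSE])
  expect_true(is.na(cmp$p_value))
  expect_match(cmp$note, "smaller than 2")
})

test_that("group age contrast at study moments is detected in most simulated cohorts", {
  # G+ n = 6 ~ Normal(34, 10.3); G- n = 39 ~ Normal(53, 14.7). The Welch
  # comparison should reject at 0.05 in the clear majority of cohorts.
  verdicts <- make_verdicts(sprintf("S%02d", 1:6), rep("MYH7", 6),
                            sprintf("c.%dG>A", 1:6), rep("P_LP", 6))
  results <- proband_results(verdicts, sprintf("S%02d", 1:45))
  hits <- withr::with_seed(303L, {
    vapply(seq_len(1000), function(i) {
      covariates <- data.frame(
        proband_id = sprintf("S%02d", 1:45),
        age = c(stats::rnorm(6, 34, 10.3), stats::rnorm(39, 53, 14.7)),
        stringsAsFactors = FALSE
      )
      compare_groups(results, covariates)$p_value < 0.05
    }, logical(1))
  })
  expect_gt(mean(hits), 0.6)
})
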