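test_that("sim_config validates its inputs", {
  expect_error(sim_config(recurrence_rate = 1.2), "rates")
  expect_error(sim_config(class_mixture = c(P_LP = 1)), "named over")
  expect_error(
    sim_config(class_mixture = c(P_LP = 0.5, VUS = 0.1, CON_VUS_LP = 0.1,
                                 CON_VUS_BLB = 0.1, B_LB = 0.1,
                                 NA_reported = 0.1, novel = 0.5)),
    "sum to 1"
  )
  expect_error(sim_config(n_probands = 0), "positive")
  expect_error(sim_config(mean_variants_per_proband = -1), "positive")
})

test_that("identical seeds produce byte-identical cohorts", {
  cfg <- sim_config(seed = 42L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- generate_cohort(cfg, d1)
  s2 <- generate_cohort(cfg, d2)
  for (f in c("vcf", "annotations", "panel")) {
    expect_identical(readLines(s1$paths[[f]]), readLines(s2$paths[[f]]),
                     info = f)
  }
  # And a different seed differs.
  s3 <- generate_cohort(sim_config(seed = 43L), withr::local_tempdir())
  expect_false(identical(readLines(s1$paths$vcf), readLines(s3$paths$vcf)))
})

test_that("generation does not disturb the caller's RNG stream", {
  withr::with_seed(7L, {
    before <- stats::runif(1)
  })
  withr::with_seed(7L, {
    generate_cohort(sim_config(seed = 42L), withr::local_tempdir())
    after <- stats::runif(1)
  })
  expect_identical(before, after)
})

test_that("a pure P/LP mixture with no decoys makes every carrier positive", {
  cfg <- sim_config(
    class_mixture = c(P_LP = 1, VUS = 0, CON_VUS_LP = 0, CON_VUS_BLB = 0,
                      B_LB = 0, NA_reported = 0, novel = 0),
    decoy_common_rate = 0, decoy_offpanel_rate = 0, decoy_nonpass_rate = 0,
    decoy_noncoding_rate = 0, seed = 5L
  )
  sim <- generate_cohort(cfg, withr::local_tempdir())
  carriers <- unique(sim$calls$proband_id)
  truth <- sim$truth_probands
  expect_true(all(truth$category[truth$proband_id %in% carriers] == "positive"))
  expect_true(all(truth$category[!truth$proband_id %in% carriers] == "negative"))
})

test_that("per-proband counts match the truncated-Poisson mean (Monte Carlo)", {
  mean_target <- 2.1
  max_k <- 11L
  # Brute-force oracle: conditional mean by direct summation over 0..max.
  p <- stats::dpois(0:max_k, mean_target)
  oracle_mean <- sum((0:max_k) * p) / sum(p)

  draws <- withr::with_seed(909L, {
    hcmtriage:::rtruncpois(20000L, mean_target, max_k)
  })
  expect_true(all(draws >= 0 & draws <= max_k))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - oracle_mean), 3 * se)
})

test_that("realized class mixture matches the configured mixture", {
  cfg <- sim_config(seed = 1L)
  classes <- unlist(lapply(1:25, function(s) {
    sim <- generate_cohort(sim_config(seed = s), withr::local_tempdir())
    tv <- sim$truth_variants
    tv <- tv[tv$fate == "retained", ]
    # Distinct variants only (recurrent copies share the class of the first).
    tv$class[!duplicated(paste(tv$gene, tv$hgvs_c))]
  }))
  observed <- table(factor(classes, levels = names(cfg$class_mixture)))
  gof <- stats::chisq.test(observed, p = cfg$class_mixture)
  expect_gt(gof$p.value, 0.01)
})

test_that("the pipeline recovers ground-truth fates and categories exactly", {
  # Full file round trip (VCF + TSVs) for a few seeds; the acceptance suite
  # extends the same check across many more seeds in memory.
  for (seed in c(101L, 102L, 103L)) {
    sim <- generate_cohort(sim_config(seed = seed), withr::local_tempdir())
    res <- run_triage(sim$paths$vcf, sim$paths$annotations, sim$paths$panel,
                      probands = sim$probands)
    key <- function(d) paste(d$proband_id, d$gene, d$hgvs_c)
    truth <- sim$truth_variants

    retained_truth <- truth[truth$fate == "retained", ]
    expect_setequal(key(res$retained), key(retained_truth))

    excluded_truth <- truth[truth$fate == "excluded", ]
    ex <- attr(res$retained, "exclusions")
    m <- match(key(excluded_truth), key(ex))
    expect_false(anyNA(m), info = seed)
    expect_identical(ex$reason[m], excluded_truth$reason, info = seed)

    m2 <- match(sim$truth_probands$proband_id, res$results$proband_id)
    expect_identical(res$results$category[m2], sim$truth_probands$category,
                     info = seed)
  }
})

test_that("every decoy kind is emitted and excluded for its own reason", {
  sim <- generate_cohort(sim_config(seed = 77L), withr::local_tempdir())
  reasons <- sim$truth_variants$reason[sim$truth_variants$fate == "excluded"]
  expect_setequal(
    unique(reasons),
    c("off_panel", "non_pass", "non_coding", "af_above_threshold")
  )
})
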