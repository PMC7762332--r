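base_call <- function(gene = "MYBPC3", hgvs_c = "c.772G>A",
                      hgvs_p = "p.Glu258Lys", filter_status = "PASS") {
  data.frame(
    proband_id = "S1", chrom = "11", pos = 1000L, ref = "G", alt = "A",
    filter_status = filter_status, genotype = "het", depth = 100L,
    gene = gene, hgvs_c = hgvs_c, hgvs_p = hgvs_p, stringsAsFactors = FALSE
  )
}

base_annotation <- function(gene = "MYBPC3", hgvs_c = "c.772G>A",
                            hgvs_p = "p.Glu258Lys",
                            af_gnomad = NA_real_, af_1000g = NA_real_,
                            dbsnp_id = "", clinvar_id = "",
                            assertions = character(0),
                            varsome_class = NA_character_) {
  ann <- data.frame(
    gene = gene, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
    dbsnp_id = dbsnp_id, clinvar_id = clinvar_id,
    af_gnomad = af_gnomad, af_1000g = af_1000g,
    sift = NA_character_, provean = NA_character_, polyphen = NA_character_,
    mutation_taster = NA_character_, varsome_class = varsome_class,
    stringsAsFactors = FALSE
  )
  ann$clinvar_assertions <- list(assertions)
  ann$key <- paste(ann$gene, ann$hgvs_c, sep = "|")
  ann
}

default_config <- filter_config(panel = c("MYBPC3", "MYH7", "TTN"))

test_that("each filter predicate excludes with its own logged reason", {
  cases <- list(
    list(call = base_call(gene = "DSP"),
         ann = base_annotation(gene = "DSP"),
         reason = "off_panel"),
    list(call = base_call(filter_status = "q30"),
         ann = base_annotation(),
         reason = "non_pass"),
    list(call = base_call(hgvs_c = "c.100+8G>A", hgvs_p = ""),
         ann = base_annotation(hgvs_c = "c.100+8G>A", hgvs_p = ""),
         reason = "non_coding"),
    list(call = base_call(),
         ann = base_annotation(af_gnomad = 0.002),
         reason = "af_above_threshold")
  )
  for (case in cases) {
    kept <- apply_filters(case$call, case$ann, default_config)
    expect_identical(nrow(kept), 0L, info = case$reason)
    expect_identical(attr(kept, "exclusions")$reason, case$reason)
  }
})

test_that("threshold is strict and absent AF sources impose no constraint", {
  # 0.002 in any single source is enough to exclude.
  kept <- apply_filters(base_call(), base_annotation(af_1000g = 0.002),
                        default_config)
  expect_identical(nrow(kept), 0L)
  # Exactly at the threshold is excluded (strict <).
  kept <- apply_filters(base_call(), base_annotation(af_gnomad = 0.001),
                        default_config)
  expect_identical(nrow(kept), 0L)
  # Just below passes.
  kept <- apply_filters(base_call(), base_annotation(af_gnomad = 0.000999),
                        default_config)
  expect_identical(nrow(kept), 1L)
  # Absent from both sources: vacuously rare.
  kept <- apply_filters(base_call(), base_annotation(), default_config)
  expect_identical(nrow(kept), 1L)
})

test_that("unannotated calls survive on VCF-borne HGVS and are flagged", {
  call <- base_call(gene = "MYH7", hgvs_c = "c.715G>A", hgvs_p = "p.Asp239Asn")
  empty_ann <- base_annotation()[0, ]
  kept <- apply_filters(call, empty_ann, default_config)
  expect_identical(nrow(kept), 1L)
  expect_false(kept$annotated)
  expect_identical(kept$consequence, "missense")
  # With no HGVS at all the consequence cannot be established: coding filter.
  call$hgvs_c <- NA_character_
  call$hgvs_p <- NA_character_
  kept <- apply_filters(call, empty_ann, default_config)
  expect_identical(nrow(kept), 0L)
  expect_identical(attr(kept, "exclusions")$reason, "non_coding")
})

test_that("filter cascade agrees with the brute-force comprehension oracle", {
  for (seed in c(11L, 12L, 13L)) {
    inputs <- random_filter_inputs(400L, seed)
    kept <- apply_filters(inputs$calls, inputs$annotations, inputs$config)
    want <- oracle_keep(inputs$calls, inputs$annotations, inputs$config)
    got <- rep(FALSE, nrow(inputs$calls))
    got_keys <- paste(kept$proband_id, kept$pos)
    all_keys <- paste(inputs$calls$proband_id, inputs$calls$pos)
    expect_identical(all_keys %in% got_keys, want, info = seed)
    # Partition: every call is retained or excluded, never both or neither.
    ex <- attr(kept, "exclusions")
    expect_identical(nrow(kept) + nrow(ex), nrow(inputs$calls))
    expect_true(all(ex$reason %in% c("off_panel", "non_pass", "non_coding",
                                     "af_above_threshold")))
  }
})

test_that("filtering is idempotent and monotone in the AF threshold", {
  inputs <- random_filter_inputs(300L, 99L)
  kept1 <- apply_filters(inputs$calls, inputs$annotations, inputs$config)
  kept2 <- apply_filters(kept1, inputs$annotations, inputs$config)
  expect_identical(nrow(kept2), nrow(kept1))
  expect_identical(kept2[names(inputs$calls)], kept1[names(inputs$calls)])

  thresholds <- c(0.0001, 0.0005, 0.001, 0.005, 0.05)
  retained_sets <- lapply(thresholds, function(th) {
    cfg <- filter_config(panel = inputs$config$panel, af_threshold = th)
    k <- apply_filters(inputs$calls, inputs$annotations, cfg)
    paste(k$proband_id, k$pos)
  })
  for (i in seq_len(length(thresholds) - 1)) {
    expect_true(all(retained_sets[[i]] %in% retained_sets[[i + 1]]),
                info = thresholds[i])
  }
})

test_that("ClinVar aggregation matches set-logic oracle on every assertion subset", {
  levels <- c("B", "LB", "VUS", "LP", "P")
  # All 32 subsets, including the benign+pathogenic mixtures that warn.
  for (bits in 0:31) {
    set <- levels[as.logical(bitwAnd(bits, 2^(0:4)))]
    want <- oracle_clinvar_class(set)
    spans <- any(set %in% c("P", "LP")) && any(set %in% c("B", "LB"))
    if (spans) {
      expect_warning(got <- derive_clinvar_class(set), "CON_VUS_LP")
    } else {
      got <- derive_clinvar_class(set)
    }
    expect_identical(got, want, info = paste(set, collapse = ","))
  }
})

test_that("ClinVar aggregation reproduces the documented examples", {
  expect_identical(derive_clinvar_class(c("VUS", "LP")), "CON_VUS_LP")
  expect_identical(derive_clinvar_class(c("B", "LB", "VUS")), "CON_VUS_BLB")
  expect_identical(derive_clinvar_class(character(0)), "NA")
  expect_identical(derive_clinvar_class("P"), "P_LP")
  expect_identical(derive_clinvar_class(c("LP", "P")), "P_LP")
  expect_identical(derive_clinvar_class(c("B", "VUS")), "CON_VUS_BLB")
  expect_error(derive_clinvar_class("pathogenic"), "unknown")
})

test_that("novelty requires the absence of both identifiers", {
  expect_true(determine_novelty("", ""))
  expect_false(determine_novelty("rs397516264", "43100"))
  expect_false(determine_novelty("rs767039057", ""))
  expect_false(determine_novelty("", "520341"))
  expect_true(determine_novelty(NA_character_, NA_character_))
})

test_that("in-silico consensus counts the right predictors per consequence", {
  expect_identical(insilico_consensus("D", "D", "PrD", "DC", "missense"), 4L)
  expect_identical(insilico_consensus("T", "N", "B", "Pol", "missense"), 0L)
  expect_identical(insilico_consensus("D", "N", "PoD", "Pol", "missense"), 2L)
  # PoD counts as a deleterious PolyPhen call.
  expect_identical(insilico_consensus("T", "N", "PoD", "Pol", "missense"), 1L)
  # Non-missense: MutationTaster alone, SIFT/Provean/PolyPhen ignored.
  expect_identical(insilico_consensus(NA, NA, NA, "DC", "synonymous"), 1L)
  expect_identical(insilico_consensus("D", "D", "PrD", "Pol", "stop_gained"), 0L)
  # NA contributes no vote.
  expect_identical(insilico_consensus(NA, "D", NA, "DC", "missense"), 2L)
})

test_that("five-tier assignment follows provenance rules", {
  got <- assign_five_tier(novel = FALSE, clinvar_class = "P_LP",
                          assertions = "P", varsome_class = NA)
  expect_identical(got[c("five_tier", "five_tier_source")],
                   list(five_tier = "P", five_tier_source = "clinvar"))
  # Mixed LP/P asserts the most severe.
  got <- assign_five_tier(FALSE, "P_LP", c("LP", "P"), NA)
  expect_identical(got$five_tier, "P")
  got <- assign_five_tier(FALSE, "P_LP", "LP", NA)
  expect_identical(got$five_tier, "LP")
  got <- assign_five_tier(FALSE, "B_LB", "B", NA)
  expect_identical(got$five_tier, "B")
  got <- assign_five_tier(FALSE, "B_LB", c("B", "LB"), NA)
  expect_identical(got$five_tier, "LB")
  # CON collapses to tier VUS, subtype kept on the verdict, source clinvar.
  got <- assign_five_tier(FALSE, "CON_VUS_LP", c("VUS", "LP"), NA)
  expect_identical(got[c("five_tier", "five_tier_source")],
                   list(five_tier = "VUS", five_tier_source = "clinvar"))
  # Reported but unclassified: VUS via the in-silico rule.
  got <- assign_five_tier(FALSE, "NA", character(0), NA)
  expect_identical(got[c("five_tier", "five_tier_source")],
                   list(five_tier = "VUS", five_tier_source = "insilico_rule"))
  # Novel with a VarSome class takes it.
  got <- assign_five_tier(TRUE, "NA", character(0), "LP")
  expect_identical(got[c("five_tier", "five_tier_source")],
                   list(five_tier = "LP", five_tier_source = "varsome"))
})

test_that("novel variants without VarSome fall back to the bounded in-silico rule", {
  # All available predictors benign -> LB.
  got <- assign_five_tier(TRUE, "NA", character(0), NA,
                          sift = "T", provean = "N", polyphen = "B",
                          mutation_taster = "Pol", consequence = "missense")
  expect_identical(got$five_tier, "LB")
  expect_false(got$suspicious)
  # All deleterious -> still VUS (computational evidence is capped), flagged.
  got <- assign_five_tier(TRUE, "NA", character(0), NA,
                          sift = "D", provean = "D", polyphen = "PrD",
                          mutation_taster = "DC", consequence = "missense")
  expect_identical(got$five_tier, "VUS")
  expect_true(got$suspicious)
  # Mixed evidence -> VUS, not flagged.
  got <- assign_five_tier(TRUE, "NA", character(0), NA,
                          sift = "D", provean = "N", polyphen = "B",
                          mutation_taster = "DC", consequence = "missense")
  expect_identical(got$five_tier, "VUS")
  expect_false(got$suspicious)
  # No predictor available at all -> VUS, never LB.
  got <- assign_five_tier(TRUE, "NA", character(0), NA,
                          consequence = "splice_site")
  expect_identical(got$five_tier, "VUS")
  expect_false(got$suspicious)
  # Non-missense: only MutationTaster counts; DC on 1 available -> suspicious.
  got <- assign_five_tier(TRUE, "NA", character(0), NA,
                          sift = "T", provean = "N", polyphen = "B",
                          mutation_taster = "DC", consequence = "synonymous")
  expect_identical(got$five_tier, "VUS")
  expect_true(got$suspicious)
})

test_that("triage_variants derives coherent verdict columns", {
  calls <- rbind(
    base_call(),                                    # reported P
    base_call(gene = "MYH7", hgvs_c = "c.9G>A", hgvs_p = "p.Trp3Ter")  # novel
  )
  calls$proband_id <- c("S1", "S2")
  ann <- rbind(
    base_annotation(dbsnp_id = "rs397516074", clinvar_id = "42792",
                    assertions = "P"),
    base_annotation(gene = "MYH7", hgvs_c = "c.9G>A", hgvs_p = "p.Trp3Ter",
                    varsome_class = "P")
  )
  cfg <- filter_config(panel = c("MYBPC3", "MYH7"))
  verdicts <- triage_variants(apply_filters(calls, ann, cfg))
  expect_identical(verdicts$novel, c(FALSE, TRUE))
  expect_identical(verdicts$clinvar_class, c("P_LP", "NA"))
  expect_identical(verdicts$five_tier, c("P", "P"))
  expect_identical(verdicts$five_tier_source, c("clinvar", "varsome"))
  # Novelty always implies ClinVar class NA on the verdict table.
  expect_true(all(!verdicts$novel | verdicts$clinvar_class == "NA"))
})
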