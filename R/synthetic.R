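#' @name synthetic
#' @title Synthetic panel cohorts with ground truth
#' @description
#' Generates fully synthetic gene-panel cohorts with the statistical
#' structure of a 45-proband HCM screening study: per-proband variant counts
#' from a truncated Poisson (mean ~2.1, maximum 11), genes drawn with
#' weights favouring MYBPC3/TTN/MYH7, HGVS descriptor pairs built from
#' per-consequence templates, annotation bundles realising a configurable
#' mixture of ClinVar classes (including conflicting-interpretation
#' subtypes), ~45% novel variants, ~5% recurrent variants, and decoy calls
#' that each violate exactly one filter predicate. Every run records its
#' ground truth (intended filter fate per call, intended category per
#' proband), making the generator an end-to-end oracle for the pipeline.
NULL

CLASS_MIXTURE_LEVELS <- c(
  "P_LP", "VUS", "CON_VUS_LP", "CON_VUS_BLB", "B_LB", "NA_reported", "novel"
)

#' Simulation configuration
#'
#' Defaults encode the reference study's conditions: 45 probands, a mean of
#' 2.1 rare variants per proband truncated at 11, class mixture equal to the
#' reference cohort's distinct-variant distribution
#' (6/14/2/6/11/13/43 over P_LP, VUS, CON_VUS_LP, CON_VUS_BLB, B_LB,
#' reported-without-ClinVar-class, novel), and a 5% recurrence rate.
#'
#' @param n_probands Number of probands.
#' @param mean_variants_per_proband Mean of the (untruncated) Poisson for
#'   per-proband retained-variant counts.
#' @param max_variants_per_proband Truncation bound: counts are drawn from
#'   the Poisson conditioned on \code{0..max}.
#' @param class_mixture Named probability vector over
#'   \code{P_LP, VUS, CON_VUS_LP, CON_VUS_BLB, B_LB, NA_reported, novel};
#'   must sum to 1.
#' @param recurrence_rate Fraction of variant observations that are second
#'   copies of an already-generated variant (carried by a distinct proband).
#' @param decoy_common_rate,decoy_offpanel_rate,decoy_nonpass_rate,decoy_noncoding_rate
#'   Decoy calls added per true variant: above-threshold allele frequency,
#'   off-panel gene, non-PASS call, deep-intronic (not splice-classifiable)
#'   consequence.
#' @param seed Integer seed; one seed, one byte-identical cohort.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_probands = 45L,
                       mean_variants_per_proband = 2.1,
                       max_variants_per_proband = 11L,
                       class_mixture = c(
                         P_LP = 6 / 95, VUS = 14 / 95, CON_VUS_LP = 2 / 95,
                         CON_VUS_BLB = 6 / 95, B_LB = 11 / 95,
                         NA_reported = 13 / 95, novel = 43 / 95
                       ),
                       recurrence_rate = 0.05,
                       decoy_common_rate = 0.10,
                       decoy_offpanel_rate = 0.05,
                       decoy_nonpass_rate = 0.05,
                       decoy_noncoding_rate = 0.05,
                       seed = 1L) {
  if (!setequal(names(class_mixture), CLASS_MIXTURE_LEVELS)) {
    stop("class_mixture must be named over: ",
         paste(CLASS_MIXTURE_LEVELS, collapse = ", "))
  }
  class_mixture <- class_mixture[CLASS_MIXTURE_LEVELS]
  rates <- c(recurrence_rate, decoy_common_rate, decoy_offpanel_rate,
             decoy_nonpass_rate, decoy_noncoding_rate)
  if (any(class_mixture < 0) || abs(sum(class_mixture) - 1) > 1e-8) {
    stop("class_mixture probabilities must be non-negative and sum to 1")
  }
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (n_probands < 1L) stop("n_probands must be positive")
  if (mean_variants_per_proband <= 0) stop("mean_variants_per_proband must be positive")
  if (max_variants_per_proband < 1L) stop("max_variants_per_proband must be >= 1")
  structure(
    list(
      n_probands = as.integer(n_probands),
      mean_variants_per_proband = mean_variants_per_proband,
      max_variants_per_proband = as.integer(max_variants_per_proband),
      class_mixture = class_mixture,
      recurrence_rate = recurrence_rate,
      decoy_common_rate = decoy_common_rate,
      decoy_offpanel_rate = decoy_offpanel_rate,
      decoy_nonpass_rate = decoy_nonpass_rate,
      decoy_noncoding_rate = decoy_noncoding_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Exact truncated-Poisson sampler: Poisson(mean) conditioned on 0..max.
rtruncpois <- function(n, mean, max) {
  probs <- stats::dpois(0:max, mean)
  sample(0:max, n, replace = TRUE, prob = probs)
}

# Closed-form mean of the truncated Poisson (the brute-force oracle used in
# tests is an independent summation).
truncpois_mean <- function(mean, max) {
  p <- stats::dpois(0:max, mean)
  sum((0:max) * p) / sum(p)
}

#' Generate a synthetic cohort
#'
#' Writes a multi-sample VCF, an annotation TSV and a panel TSV to
#' \code{dir}, and returns them together with the generation ground truth.
#' Identical config (including seed) produces byte-identical files; the
#' caller's RNG state is untouched.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return A list: \code{paths} (vcf, annotations, panel), \code{calls}
#'   (the written calls), \code{truth_variants} (per generated call: key,
#'   intended class, intended fate \code{retained}/\code{excluded} and
#'   exclusion reason), \code{truth_probands} (per proband: intended
#'   category), \code{config}.
#' @export
generate_cohort <- function(config, dir = tempfile("simcohort")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- withr::with_seed(config$seed, generate_cohort_impl(config))

  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    panel = file.path(dir, "panel.tsv")
  )
  write_vcf(out$calls, paths$vcf, samples = out$probands)
  write_annotation_table(out$annotations, paths$annotations)
  utils::write.table(out$panel, paths$panel, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(
    paths = paths,
    probands = out$probands,
    calls = out$calls,
    annotations = out$annotations,
    panel = out$panel,
    truth_variants = out$truth_variants,
    truth_probands = out$truth_probands,
    config = config
  )
}

generate_cohort_impl <- function(config) {
  fixture <- load_hcm_fixture()
  panel <- fixture$panel
  # Gene weights follow the reference cohort's per-gene variant counts, with
  # a small pseudo-count so unhit panel genes remain drawable.
  gene_counts <- table(factor(fixture$variants$gene, levels = panel$gene))
  gene_weights <- as.numeric(gene_counts) + 0.5

  probands <- sprintf("S%03d", seq_len(config$n_probands))
  k <- rtruncpois(config$n_probands, config$mean_variants_per_proband,
                  config$max_variants_per_proband)
  n_obs <- sum(k)

  # Distinct variants vs recurrent second copies.
  n_recurrent <- min(floor(config$recurrence_rate * n_obs), max(n_obs - 1, 0))
  n_distinct <- n_obs - n_recurrent

  classes <- if (n_distinct) {
    sample(CLASS_MIXTURE_LEVELS, n_distinct, replace = TRUE,
           prob = config$class_mixture)
  } else {
    character(0)
  }
  variants <- synth_variants(classes, panel, gene_weights, offset = 0L)

  # Decoys: each violates exactly one predicate.
  n_dec <- function(rate) round(rate * n_distinct)
  decoys <- rbind(
    synth_decoys("af_above_threshold", n_dec(config$decoy_common_rate),
                 panel, gene_weights, offset = n_distinct),
    synth_decoys("off_panel", n_dec(config$decoy_offpanel_rate),
                 panel, gene_weights, offset = n_distinct + 1000L),
    synth_decoys("non_pass", n_dec(config$decoy_nonpass_rate),
                 panel, gene_weights, offset = n_distinct + 2000L),
    synth_decoys("non_coding", n_dec(config$decoy_noncoding_rate),
                 panel, gene_weights, offset = n_distinct + 3000L)
  )

  # Assign true observations to probands: one slot per retained variant,
  # recurrent copies forced onto a different proband than their first copy.
  slots <- rep(probands, k)
  slots <- sample(slots)
  obs_variant <- integer(n_obs)
  if (n_distinct) obs_variant[seq_len(n_distinct)] <- seq_len(n_distinct)
  if (n_recurrent) {
    obs_variant[n_distinct + seq_len(n_recurrent)] <-
      sample(seq_len(n_distinct), n_recurrent,
             replace = n_recurrent > n_distinct)
  }
  # A proband must not carry the same variant twice: where a recurrent copy
  # landed on its first copy's proband, swap slots with an observation whose
  # proband is conflict-free for both variants.
  conflicted <- function(i) {
    any(obs_variant[-i][slots[-i] == slots[i]] == obs_variant[i])
  }
  if (n_obs > 1) {
    for (i in seq_len(n_obs)) {
      if (!conflicted(i)) next
      for (j in seq_len(n_obs)[-i]) {
        if (slots[j] == slots[i]) next
        proposal <- slots
        proposal[c(i, j)] <- slots[c(j, i)]
        ok_i <- !any(obs_variant[-i][proposal[-i] == proposal[i]] == obs_variant[i])
        ok_j <- !any(obs_variant[-j][proposal[-j] == proposal[j]] == obs_variant[j])
        if (ok_i && ok_j) {
          slots <- proposal
          break
        }
      }
    }
  }

  calls_true <- if (n_obs) data.frame(
    proband_id = slots,
    chrom = variants$chrom[obs_variant],
    pos = variants$pos[obs_variant],
    ref = variants$ref[obs_variant],
    alt = variants$alt[obs_variant],
    filter_status = "PASS",
    genotype = "het",
    depth = pmax(25L, stats::rpois(n_obs, 202L)),
    gene = variants$gene[obs_variant],
    hgvs_c = variants$hgvs_c[obs_variant],
    hgvs_p = variants$hgvs_p[obs_variant],
    stringsAsFactors = FALSE
  ) else empty_calls()

  calls_decoy <- if (nrow(decoys)) data.frame(
    proband_id = sample(probands, nrow(decoys), replace = TRUE),
    chrom = decoys$chrom,
    pos = decoys$pos,
    ref = decoys$ref,
    alt = decoys$alt,
    filter_status = ifelse(decoys$reason == "non_pass", "q30", "PASS"),
    genotype = "het",
    depth = pmax(25L, stats::rpois(nrow(decoys), 202L)),
    gene = decoys$gene,
    hgvs_c = decoys$hgvs_c,
    hgvs_p = decoys$hgvs_p,
    stringsAsFactors = FALSE
  ) else NULL

  calls <- rbind(calls_true, calls_decoy)

  annotations <- build_annotations(variants, decoys)

  truth_variants <- data.frame(
    proband_id = calls$proband_id,
    gene = calls$gene,
    hgvs_c = calls$hgvs_c,
    class = c(variants$class[obs_variant], decoys$class),
    fate = c(rep("retained", n_obs),
             rep("excluded", nrow(decoys))),
    reason = c(rep(NA_character_, n_obs), decoys$reason),
    stringsAsFactors = FALSE
  )

  # Intended category per proband from intended classes of retained variants.
  cls_map <- c(P_LP = "P_LP", VUS = "VUS", CON_VUS_LP = "CON_VUS_LP",
               CON_VUS_BLB = "CON_VUS_BLB", B_LB = "B_LB",
               NA_reported = "NA", novel = "NA")
  retained_cls <- split(cls_map[variants$class[obs_variant]], slots)
  truth_probands <- data.frame(
    proband_id = probands,
    category = vapply(probands, function(p) {
      categorize_proband(retained_cls[[p]] %||% character(0))
    }, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )

  list(
    probands = probands, calls = calls, annotations = annotations,
    panel = panel, truth_variants = truth_variants,
    truth_probands = truth_probands
  )
}

# --- synthetic variant construction ---------------------------------------

# Consequence mixture of generated variants (reference cohort proportions).
SYNTH_CONSEQUENCE_PROBS <- c(
  missense = 65, stop_gained = 3, inframe_indel = 3, frameshift = 1,
  splice_site = 1, synonymous = 22
) / 95

AA3_NO_TER <- setdiff(AA3, "Ter")

synth_variants <- function(classes, panel, gene_weights, offset) {
  n <- length(classes)
  if (!n) {
    return(data.frame(
      gene = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), hgvs_c = character(0),
      hgvs_p = character(0), consequence = character(0), class = character(0),
      stringsAsFactors = FALSE
    ))
  }
  gene_idx <- sample(seq_len(nrow(panel)), n, replace = TRUE, prob = gene_weights)
  consequence <- sample(names(SYNTH_CONSEQUENCE_PROBS), n, replace = TRUE,
                        prob = SYNTH_CONSEQUENCE_PROBS)
  hgvs <- synth_hgvs(consequence, codon = offset + seq_len(n) + 10L)
  data.frame(
    gene = panel$gene[gene_idx],
    chrom = panel$chromosome[gene_idx],
    pos = gene_idx * 1000000L + offset + seq_len(n),
    ref = hgvs$ref, alt = hgvs$alt,
    hgvs_c = hgvs$hgvs_c, hgvs_p = hgvs$hgvs_p,
    consequence = consequence,
    class = classes,
    stringsAsFactors = FALSE
  )
}

# HGVS c./p. template pairs per consequence; codon indexes keep keys unique.
synth_hgvs <- function(consequence, codon) {
  n <- length(consequence)
  ref <- character(n); alt <- character(n)
  hgvs_c <- character(n); hgvs_p <- character(n)
  aa1 <- sample(AA3_NO_TER, n, replace = TRUE)
  aa2 <- sample(AA3_NO_TER, n, replace = TRUE)
  for (i in seq_len(n)) {
    cpos <- codon[i] * 3L - 2L
    switch(consequence[i],
      missense = {
        ref[i] <- "G"; alt[i] <- "A"
        hgvs_c[i] <- sprintf("c.%dG>A", cpos)
        aa_to <- if (aa2[i] == aa1[i]) "His" else aa2[i]
        if (aa_to == aa1[i]) aa_to <- "Arg"
        hgvs_p[i] <- sprintf("p.%s%d%s", aa1[i], codon[i], aa_to)
      },
      synonymous = {
        ref[i] <- "C"; alt[i] <- "T"
        hgvs_c[i] <- sprintf("c.%dC>T", cpos + 2L)
        hgvs_p[i] <- sprintf("p.%s%d=", aa1[i], codon[i])
      },
      stop_gained = {
        ref[i] <- "G"; alt[i] <- "T"
        hgvs_c[i] <- sprintf("c.%dG>T", cpos)
        hgvs_p[i] <- sprintf("p.%s%dTer", aa1[i], codon[i])
      },
      inframe_indel = {
        ref[i] <- "TGCA"; alt[i] <- "T"
        hgvs_c[i] <- sprintf("c.%d_%ddelGCA", cpos, cpos + 2L)
        hgvs_p[i] <- sprintf("p.%s%ddel", aa1[i], codon[i])
      },
      frameshift = {
        ref[i] <- "T"; alt[i] <- "TGC"
        hgvs_c[i] <- sprintf("c.%d_%dinsGC", cpos, cpos + 1L)
        hgvs_p[i] <- sprintf("p.%s%d%sfsTer%d", aa1[i], codon[i], aa2[i],
                             5L + (codon[i] %% 20L))
      },
      splice_site = {
        ref[i] <- "G"; alt[i] <- "T"
        hgvs_c[i] <- sprintf("c.%d+1G>T", cpos + 2L)
        hgvs_p[i] <- ""
      },
      stop("unknown consequence template: ", consequence[i])
    )
  }
  list(ref = ref, alt = alt, hgvs_c = hgvs_c, hgvs_p = hgvs_p)
}

OFFPANEL_GENES <- c("DSP", "PKP2", "LMNA", "SCN5A")

synth_decoys <- function(reason, n, panel, gene_weights, offset) {
  empty <- data.frame(
    gene = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), hgvs_c = character(0),
    hgvs_p = character(0), consequence = character(0), class = character(0),
    reason = character(0), stringsAsFactors = FALSE
  )
  if (n < 1L) return(empty)
  if (reason == "off_panel") {
    gene <- sample(OFFPANEL_GENES, n, replace = TRUE)
    chrom <- rep("0", n)
    gpos <- 90000000L + offset + seq_len(n)
  } else {
    gene_idx <- sample(seq_len(nrow(panel)), n, replace = TRUE, prob = gene_weights)
    gene <- panel$gene[gene_idx]
    chrom <- panel$chromosome[gene_idx]
    gpos <- gene_idx * 1000000L + offset + seq_len(n)
  }
  if (reason == "non_coding") {
    # Deep intronic: offset beyond the canonical +/-2 dinucleotide, no
    # protein descriptor -> not splice-classifiable -> fails the coding filter.
    cpos <- (offset + seq_len(n)) * 3L
    hgvs_c <- sprintf("c.%d+%dG>A", cpos, 10L + (seq_len(n) %% 30L))
    hgvs_p <- rep("", n)
    consequence <- rep(NA_character_, n)
    ref <- rep("G", n); alt <- rep("A", n)
  } else {
    hgvs <- synth_hgvs(rep("missense", n), codon = offset + seq_len(n) + 10L)
    hgvs_c <- hgvs$hgvs_c; hgvs_p <- hgvs$hgvs_p
    consequence <- rep("missense", n)
    ref <- hgvs$ref; alt <- hgvs$alt
  }
  data.frame(
    gene = gene, chrom = chrom, pos = gpos, ref = ref, alt = alt,
    hgvs_c = hgvs_c, hgvs_p = hgvs_p, consequence = consequence,
    class = rep("decoy", n), reason = rep(reason, n),
    stringsAsFactors = FALSE
  )
}

# Annotation bundles realising each intended class (plus decoy bundles).
build_annotations <- function(variants, decoys) {
  all <- rbind(
    variants[c("gene", "hgvs_c", "hgvs_p", "class")],
    decoys[c("gene", "hgvs_c", "hgvs_p", "class")]
  )
  n <- nrow(all)
  reason <- c(rep(NA_character_, nrow(variants)), decoys$reason)
  consequence <- c(variants$consequence, decoys$consequence)

  assertion_sets <- list(
    P_LP = list("P", "LP", c("LP", "P")),
    VUS = list("VUS"),
    CON_VUS_LP = list(c("VUS", "LP"), c("VUS", "P")),
    CON_VUS_BLB = list(c("VUS", "LB"), c("VUS", "B"), c("B", "LB", "VUS")),
    B_LB = list("B", "LB", c("B", "LB"))
  )

  dbsnp <- character(n); clinvar_id <- character(n)
  assertions <- rep(list(character(0)), n)
  af_gnomad <- rep(NA_real_, n); af_1000g <- rep(NA_real_, n)
  sift <- rep(NA_character_, n); provean <- rep(NA_character_, n)
  polyphen <- rep(NA_character_, n); mt <- rep(NA_character_, n)
  varsome <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    cls <- all$class[i]
    reported <- cls %in% c(names(assertion_sets), "NA_reported") ||
      (cls == "decoy" && stats::runif(1) < 0.7)
    if (reported) {
      dbsnp[i] <- sprintf("rs%d", 100000000L + i)
      af_gnomad[i] <- stats::runif(1, 0, 0.0009)
      if (stats::runif(1) < 0.5) af_1000g[i] <- stats::runif(1, 0, 0.0009)
    }
    if (cls %in% names(assertion_sets)) {
      pool <- assertion_sets[[cls]]
      assertions[[i]] <- pool[[sample.int(length(pool), 1L)]]
      clinvar_id[i] <- sprintf("%d", 400000L + i)
    }
    if (cls == "novel") {
      # Mostly VarSome-classified; some NA to exercise the in-silico fallback.
      varsome[i] <- sample(c("P", "LP", "VUS", "LB", NA_character_), 1L,
                           prob = c(0.1, 0.2, 0.35, 0.25, 0.1))
    }
    if (identical(consequence[i], "missense")) {
      deleterious <- stats::runif(1) < 0.4
      sift[i] <- if (deleterious) "D" else "T"
      provean[i] <- if (deleterious) "D" else "N"
      polyphen[i] <- sample(if (deleterious) c("PrD", "PoD") else "B", 1L)
      mt[i] <- if (deleterious) "DC" else "Pol"
    } else if (!is.na(consequence[i])) {
      mt[i] <- sample(c("DC", "Pol"), 1L,
                      prob = if (consequence[i] == "synonymous") c(0.3, 0.7)
                             else c(0.9, 0.1))
    }
    if (!is.na(reason[i]) && reason[i] == "af_above_threshold") {
      dbsnp[i] <- sprintf("rs%d", 100000000L + i)
      af_gnomad[i] <- stats::runif(1, 0.002, 0.05)
    }
  }

  ann <- data.frame(
    gene = all$gene, hgvs_c = all$hgvs_c, hgvs_p = all$hgvs_p,
    dbsnp_id = dbsnp, clinvar_id = clinvar_id,
    af_gnomad = af_gnomad, af_1000g = af_1000g,
    sift = sift, provean = provean, polyphen = polyphen,
    mutation_taster = mt, varsome_class = varsome,
    stringsAsFactors = FALSE
  )
  ann$clinvar_assertions <- assertions
  ann$key <- paste(ann$gene, ann$hgvs_c, sep = "|")
  stopifnot(!anyDuplicated(ann$key))
  ann
}
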