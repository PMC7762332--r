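#' @name triage
#' @title Candidate-variant selection and verdict derivation
#' @description
#' The candidate-selection cascade retains a call when all four predicates
#' hold: (1) the gene is on the analysis panel; (2) the caller marked the
#' call PASS; (3) the consequence is protein-coding in the broad sense
#' (missense, synonymous, stop gain/loss, frameshift, in-frame indel or
#' canonical splice site); (4) the allele frequency is below the rarity
#' threshold (default 0.1%, chosen from an HCM prevalence of roughly 1/1000
#' chromosomes) in every population source where the variant has been
#' observed — absence from a source imposes no constraint, so undatabased
#' (novel) variants are retained. The threshold is a strict inequality.
#' Retained variants then receive a verdict: novelty, ClinVar-derived class
#' with conflicting-interpretation subtypes, in-silico consensus votes, and
#' a five-tier (B/LB/VUS/LP/P) label with provenance.
NULL

CLINVAR_CLASS_LEVELS <- c("P_LP", "VUS", "B_LB", "CON_VUS_LP", "CON_VUS_BLB", "NA")
FIVE_TIER_SOURCES <- c("clinvar", "varsome", "insilico_rule")
EXCLUSION_REASONS <- c("off_panel", "non_pass", "non_coding", "af_above_threshold")

# Consequences that count as protein-coding for the cascade.
CODING_CONSEQUENCES <- c(
  "missense", "synonymous", "stop_gained", "stop_lost",
  "frameshift", "inframe_indel", "splice_site"
)

#' Filter configuration
#'
#' @param panel Character vector of panel gene symbols (non-empty).
#' @param af_threshold Rarity threshold as a fraction, strict upper bound on
#'   every observed population allele frequency. Default 0.001 (0.1%).
#' @param require_pass Keep only caller-PASS calls. Default TRUE.
#' @param coding_only Keep only protein-coding consequences (including
#'   synonymous and canonical splice sites). Default TRUE.
#' @return A list of class \code{filter_config}.
#' @export
filter_config <- function(panel, af_threshold = 0.001, require_pass = TRUE,
                          coding_only = TRUE) {
  if (!length(panel)) stop("panel must be non-empty")
  if (!is.numeric(af_threshold) || af_threshold <= 0 || af_threshold >= 1) {
    stop("af_threshold must lie strictly between 0 and 1")
  }
  structure(
    list(
      panel = unique(as.character(panel)),
      af_threshold = af_threshold,
      require_pass = isTRUE(require_pass),
      coding_only = isTRUE(coding_only)
    ),
    class = "filter_config"
  )
}

#' Apply the candidate-selection filter cascade
#'
#' Joins calls to their annotation bundles on (gene, HGVS c.) and retains
#' exactly the calls passing all four predicates (panel, PASS, coding
#' consequence, rarity). Filtering is total: nothing errors out, and every
#' exclusion is logged with the first failed criterion, in cascade order
#' \code{off_panel}, \code{non_pass}, \code{non_coding},
#' \code{af_above_threshold}.
#'
#' @param calls Data frame of raw calls (see [read_vcf()]).
#' @param annotations Annotation data frame (see [read_annotation_table()]).
#' @param config A [filter_config()].
#' @return The retained calls, annotated: all call columns plus
#'   \code{annotated} (logical: had an annotation row), \code{consequence},
#'   and the annotation evidence columns. The dropped calls, with a
#'   \code{reason} column, are attached as \code{attr(, "exclusions")}.
#'
#' @details Calls with no annotation row are not dropped by the join: their
#'   consequence is classified from the HGVS descriptors carried in the VCF
#'   INFO column, and only when no consequence can be established do they
#'   fail the coding filter. Variants absent from every AF source pass the
#'   rarity predicate vacuously (unobserved = rare).
#' @export
apply_filters <- function(calls, annotations, config) {
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(calls)
  idx <- match(paste(calls$gene, calls$hgvs_c, sep = "|"), annotations$key)
  annotated <- !is.na(idx)

  # Effective HGVS pair: annotation row wins, VCF INFO is the fallback.
  eff_c <- ifelse(annotated, annotations$hgvs_c[idx], calls$hgvs_c)
  eff_p <- ifelse(annotated, annotations$hgvs_p[idx], calls$hgvs_p)

  consequence <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.na(eff_c[i]) || !nzchar(eff_c[i])) next
    consequence[i] <- tryCatch(
      classify_consequence(eff_c[i], if (is.na(eff_p[i])) "" else eff_p[i]),
      error = function(e) NA_character_
    )
  }

  on_panel <- !is.na(calls$gene) & calls$gene %in% config$panel
  pass_ok <- if (config$require_pass) calls$filter_status == "PASS" else rep(TRUE, n)
  coding_ok <- if (config$coding_only) {
    !is.na(consequence) & consequence %in% CODING_CONSEQUENCES
  } else {
    rep(TRUE, n)
  }
  af_g <- ifelse(annotated, annotations$af_gnomad[idx], NA_real_)
  af_k <- ifelse(annotated, annotations$af_1000g[idx], NA_real_)
  rare_ok <- (is.na(af_g) | af_g < config$af_threshold) &
    (is.na(af_k) | af_k < config$af_threshold)

  keep <- on_panel & pass_ok & coding_ok & rare_ok
  reason <- rep(NA_character_, n)
  reason[!rare_ok] <- "af_above_threshold"
  reason[!coding_ok] <- "non_coding"
  reason[!pass_ok] <- "non_pass"
  reason[!on_panel] <- "off_panel"

  retained <- calls[keep, , drop = FALSE]
  retained$annotated <- annotated[keep]
  retained$hgvs_c <- eff_c[keep]
  retained$hgvs_p <- ifelse(is.na(eff_p[keep]), "", eff_p[keep])
  retained$consequence <- consequence[keep]
  # Evidence columns from the annotation bundle (NA / empty when unannotated).
  ann_cols <- c("dbsnp_id", "clinvar_id", "af_gnomad", "af_1000g",
                "sift", "provean", "polyphen", "mutation_taster", "varsome_class")
  for (col in ann_cols) {
    vals <- annotations[[col]][idx[keep]]
    if (col %in% c("dbsnp_id", "clinvar_id")) vals[is.na(vals)] <- ""
    retained[[col]] <- vals
  }
  retained$clinvar_assertions <- lapply(idx[keep], function(j) {
    if (is.na(j)) character(0) else annotations$clinvar_assertions[[j]]
  })
  rownames(retained) <- NULL

  exclusions <- calls[!keep, , drop = FALSE]
  exclusions$reason <- reason[!keep]
  rownames(exclusions) <- NULL
  attr(retained, "exclusions") <- exclusions
  retained
}

#' Aggregate ClinVar assertions into a derived class
#'
#' Collapses the set of ClinVar-submitted interpretations of one variant
#' into a single derived class, keeping conflicting interpretations (CON)
#' as explicit subtypes:
#' no assertions -> \code{"NA"}; a subset of \{P, LP\} -> \code{"P_LP"};
#' a subset of \{B, LB\} -> \code{"B_LB"}; \{VUS\} alone -> \code{"VUS"};
#' VUS together with LP or P (no benign assertion) -> \code{"CON_VUS_LP"};
#' VUS together with B or LB (no pathogenic assertion) ->
#' \code{"CON_VUS_BLB"}. A mixture spanning both benign and pathogenic
#' assertions is assigned \code{"CON_VUS_LP"} — conservative toward clinical
#' follow-up — with a warning.
#'
#' @param assertions Character vector (a set) drawn from
#'   \code{B, LB, VUS, LP, P}; may be empty.
#' @return One of \code{c("P_LP","VUS","B_LB","CON_VUS_LP","CON_VUS_BLB","NA")}.
#' @examples
#' derive_clinvar_class(c("VUS", "LP"))      # CON_VUS_LP
#' derive_clinvar_class(c("B", "LB", "VUS")) # CON_VUS_BLB
#' derive_clinvar_class(character(0))        # "NA"
#' @export
derive_clinvar_class <- function(assertions) {
  assertions <- unique(assertions[!is.na(assertions) & nzchar(assertions)])
  bad <- setdiff(assertions, CLINVAR_ASSERTION_LEVELS)
  if (length(bad)) stop("unknown ClinVar assertion: ", paste(bad, collapse = ", "))
  if (!length(assertions)) return("NA")
  has_path <- any(assertions %in% c("LP", "P"))
  has_ben <- any(assertions %in% c("B", "LB"))
  has_vus <- "VUS" %in% assertions
  if (has_path && !has_ben && !has_vus) return("P_LP")
  if (has_ben && !has_path && !has_vus) return("B_LB")
  if (has_vus && !has_path && !has_ben) return("VUS")
  if (has_vus && has_path && !has_ben) return("CON_VUS_LP")
  if (has_vus && has_ben && !has_path) return("CON_VUS_BLB")
  # Benign and pathogenic assertions on the same variant: treat the conflict
  # as favoring pathogenicity.
  warning("ClinVar assertions span benign and pathogenic; classed CON_VUS_LP")
  "CON_VUS_LP"
}

#' Is a variant novel?
#'
#' A variant is novel when it has never been reported: operationally, no
#' dbSNP identifier and no ClinVar record. Any identifier defeats novelty.
#'
#' @param dbsnp_id dbSNP rs identifier, \code{""}/\code{NA} when absent.
#' @param clinvar_id ClinVar accession, \code{""}/\code{NA} when absent.
#' @return Logical (vectorised over its arguments).
#' @export
determine_novelty <- function(dbsnp_id, clinvar_id) {
  no_dbsnp <- is.na(dbsnp_id) | !nzchar(dbsnp_id)
  no_clinvar <- is.na(clinvar_id) | !nzchar(clinvar_id)
  no_dbsnp & no_clinvar
}

#' Count deleterious in-silico predictor votes
#'
#' For missense variants all four predictors vote: SIFT (\code{D}), Provean
#' (\code{D}), PolyPhen-2 (\code{PrD} or \code{PoD}) and MutationTaster
#' (\code{DC}). For every other consequence (stop gain/loss, splice,
#' frameshift, in-frame indel, synonymous) only MutationTaster is consulted,
#' so the vote count is 0 or 1. An \code{NA} call contributes no vote.
#'
#' @param sift,provean,polyphen,mutation_taster Predictor calls (single
#'   values; \code{NA} allowed).
#' @param consequence The variant's consequence category.
#' @return Integer vote count in 0..4.
#' @export
insilico_consensus <- function(sift, provean, polyphen, mutation_taster,
                               consequence) {
  mt_vote <- isTRUE(mutation_taster == "DC")
  if (!identical(consequence, "missense")) {
    return(as.integer(mt_vote))
  }
  as.integer(isTRUE(sift == "D")) +
    as.integer(isTRUE(provean == "D")) +
    as.integer(isTRUE(polyphen %in% c("PrD", "PoD"))) +
    as.integer(mt_vote)
}

#' Assign the five-tier label and its provenance
#'
#' Previously reported variants take their ClinVar-derived tier: the most
#' severe pathogenic assertion for \code{P_LP} (P over LP), \code{B} only
#' when benign assertions are exclusively B, \code{VUS} for VUS; a CON class
#' collapses to tier VUS (the subtype is kept separately on the verdict);
#' a reported variant with no ClinVar classification defaults to VUS with
#' source \code{insilico_rule}. Novel variants take the VarSome class
#' (source \code{varsome}); when no VarSome class is available the
#' documented in-silico fallback applies: all available predictors benign
#' -> LB; at least three quarters of the available predictors deleterious
#' -> VUS flagged suspicious; otherwise VUS. Computational evidence alone is
#' never allowed to reach LP.
#'
#' @param novel Logical: is the variant novel?
#' @param clinvar_class Derived class from [derive_clinvar_class()].
#' @param assertions ClinVar assertion set (character vector).
#' @param varsome_class VarSome five-tier class or \code{NA}.
#' @param sift,provean,polyphen,mutation_taster Predictor calls.
#' @param consequence Consequence category (drives which predictors count).
#' @return A list with \code{five_tier}, \code{five_tier_source} and
#'   \code{suspicious} (logical: predictor-only evidence pointed strongly at
#'   pathogenicity).
#' @export
assign_five_tier <- function(novel, clinvar_class, assertions, varsome_class,
                             sift = NA, provean = NA, polyphen = NA,
                             mutation_taster = NA, consequence = "missense") {
  if (!novel) {
    tier <- switch(clinvar_class,
      P_LP = if ("P" %in% assertions) "P" else "LP",
      B_LB = if (all(assertions == "B")) "B" else "LB",
      VUS = "VUS",
      CON_VUS_LP = ,
      CON_VUS_BLB = "VUS",
      "NA" = NA_character_,
      stop("unknown clinvar_class: ", clinvar_class)
    )
    if (!is.na(tier)) {
      return(list(five_tier = tier, five_tier_source = "clinvar", suspicious = FALSE))
    }
    return(list(five_tier = "VUS", five_tier_source = "insilico_rule", suspicious = FALSE))
  }
  if (!is.na(varsome_class)) {
    return(list(five_tier = varsome_class, five_tier_source = "varsome",
                suspicious = FALSE))
  }
  calls <- if (identical(consequence, "missense")) {
    c(sift, provean, polyphen, mutation_taster)
  } else {
    mutation_taster
  }
  available <- sum(!is.na(calls))
  votes <- insilico_consensus(sift, provean, polyphen, mutation_taster, consequence)
  benign_calls <- sum(
    isTRUE(sift == "T"), isTRUE(provean == "N"), isTRUE(polyphen == "B"),
    isTRUE(mutation_taster == "Pol")
  )
  if (available > 0L && benign_calls == available) {
    return(list(five_tier = "LB", five_tier_source = "insilico_rule",
                suspicious = FALSE))
  }
  suspicious <- available > 0L && votes >= ceiling(0.75 * available)
  list(five_tier = "VUS", five_tier_source = "insilico_rule",
       suspicious = suspicious)
}

#' Derive verdicts for a table of retained variants
#'
#' Runs novelty, ClinVar aggregation, in-silico consensus and five-tier
#' assignment over the output of [apply_filters()].
#'
#' @param retained Annotated retained calls from [apply_filters()].
#' @return The input with verdict columns added: \code{novel},
#'   \code{clinvar_class}, \code{insilico_votes}, \code{five_tier},
#'   \code{five_tier_source}, \code{suspicious}.
#' @export
triage_variants <- function(retained) {
  n <- nrow(retained)
  retained$novel <- determine_novelty(retained$dbsnp_id, retained$clinvar_id)
  retained$clinvar_class <- vapply(
    retained$clinvar_assertions, derive_clinvar_class, character(1)
  )
  # Novelty implies no ClinVar record, hence class NA, by construction of
  # determine_novelty(); assert rather than assume.
  stopifnot(all(!retained$novel | retained$clinvar_class == "NA"))

  votes <- integer(n)
  tier <- character(n)
  src <- character(n)
  susp <- logical(n)
  for (i in seq_len(n)) {
    votes[i] <- insilico_consensus(
      retained$sift[i], retained$provean[i], retained$polyphen[i],
      retained$mutation_taster[i], retained$consequence[i]
    )
    res <- assign_five_tier(
      novel = retained$novel[i],
      clinvar_class = retained$clinvar_class[i],
      assertions = retained$clinvar_assertions[[i]],
      varsome_class = retained$varsome_class[i],
      sift = retained$sift[i], provean = retained$provean[i],
      polyphen = retained$polyphen[i],
      mutation_taster = retained$mutation_taster[i],
      consequence = retained$consequence[i]
    )
    tier[i] <- res$five_tier
    src[i] <- res$five_tier_source
    susp[i] <- res$suspicious
  }
  retained$insilico_votes <- votes
  retained$five_tier <- tier
  retained$five_tier_source <- src
  retained$suspicious <- susp
  retained
}
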