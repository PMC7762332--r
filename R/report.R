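#' @name report
#' @title Triage reports
#' @description
#' The machine-readable report is a JSON document holding the full cohort
#' summary; re-reading it reproduces the summary object exactly. A
#' human-oriented tab-separated per-variant table (one row per distinct
#' variant, mirroring the layout of clinical variant tables: identifiers,
#' evidence, derived class, five-tier label, number of carriers) can be
#' written alongside.
NULL

#' Write a triage report
#'
#' @param summary A \code{cohort_summary} from [summarize_cohort()].
#' @param path Output path for the JSON report.
#' @param verdicts Optional verdict table from [triage_variants()]; when
#'   given, a per-variant TSV is written next to the JSON (same path with a
#'   \code{.tsv} extension) or at \code{variants_path}.
#' @param variants_path Optional explicit path for the TSV table.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(summary, path, verdicts = NULL, variants_path = NULL) {
  stopifnot(inherits(summary, "cohort_summary"))
  validate_cohort_summary(summary)
  jsonlite::write_json(
    summary_to_list(summary), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(verdicts)) {
    if (is.null(variants_path)) variants_path <- sub("\\.json$", ".tsv", path)
    utils::write.table(
      variant_table(verdicts), variants_path,
      sep = "\t", quote = FALSE, row.names = FALSE, na = ""
    )
  }
  invisible(path)
}

#' Read a triage report back into a cohort summary
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return A \code{cohort_summary} equal to the one written.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  named_int <- function(lst) {
    stats::setNames(vapply(lst, as.integer, integer(1)), names(lst))
  }
  named_num <- function(lst) {
    stats::setNames(vapply(lst, as.numeric, numeric(1)), names(lst))
  }
  rec <- x$recurrent_variants
  recurrent_variants <- data.frame(
    gene = vapply(rec, function(r) r$gene, character(1)),
    hgvs_c = vapply(rec, function(r) r$hgvs_c, character(1)),
    n_probands = vapply(rec, function(r) as.integer(r$n_probands), integer(1)),
    stringsAsFactors = FALSE
  )
  summary <- list(
    n_probands = as.integer(x$n_probands),
    n_distinct_variants = as.integer(x$n_distinct_variants),
    n_genes_hit = as.integer(x$n_genes_hit),
    per_gene_counts = named_int(x$per_gene_counts),
    consequence_counts = named_int(x$consequence_counts),
    clinvar_class_counts = named_int(x$clinvar_class_counts),
    n_novel = as.integer(x$n_novel),
    n_reported = as.integer(x$n_reported),
    recurrent_variants = recurrent_variants,
    category_counts = named_int(x$category_counts),
    yield_percentages = named_num(x$yield_percentages),
    n_multi_variant_probands = as.integer(x$n_multi_variant_probands),
    max_variants_per_proband = as.integer(x$max_variants_per_proband)
  )
  class(summary) <- "cohort_summary"
  validate_cohort_summary(summary)
  summary
}

summary_to_list <- function(s) {
  as_map <- function(v) as.list(v)  # named vector -> JSON object
  list(
    n_probands = s$n_probands,
    n_distinct_variants = s$n_distinct_variants,
    n_genes_hit = s$n_genes_hit,
    per_gene_counts = as_map(s$per_gene_counts),
    consequence_counts = as_map(s$consequence_counts),
    clinvar_class_counts = as_map(s$clinvar_class_counts),
    n_novel = s$n_novel,
    n_reported = s$n_reported,
    recurrent_variants = lapply(seq_len(nrow(s$recurrent_variants)), function(i) {
      as.list(s$recurrent_variants[i, , drop = FALSE])
    }),
    category_counts = as_map(s$category_counts),
    yield_percentages = as_map(s$yield_percentages),
    n_multi_variant_probands = s$n_multi_variant_probands,
    max_variants_per_proband = s$max_variants_per_proband
  )
}

# One row per distinct variant, evidence and verdict side by side.
variant_table <- function(verdicts) {
  key <- paste(verdicts$gene, verdicts$hgvs_c, sep = "|")
  occ <- tapply(verdicts$proband_id, key, function(x) length(unique(x)))
  distinct <- verdicts[!duplicated(key), , drop = FALSE]
  data.frame(
    gene = distinct$gene,
    hgvs_c = distinct$hgvs_c,
    hgvs_p = distinct$hgvs_p,
    consequence = distinct$consequence,
    novel = distinct$novel,
    dbsnp_id = distinct$dbsnp_id,
    clinvar_id = distinct$clinvar_id,
    clinvar_assertions = vapply(distinct$clinvar_assertions, paste,
                                character(1), collapse = ","),
    clinvar_class = distinct$clinvar_class,
    sift = distinct$sift,
    provean = distinct$provean,
    polyphen = distinct$polyphen,
    mutation_taster = distinct$mutation_taster,
    insilico_votes = distinct$insilico_votes,
    varsome_class = distinct$varsome_class,
    five_tier = distinct$five_tier,
    five_tier_source = distinct$five_tier_source,
    n_probands = as.integer(occ[key[!duplicated(key)]]),
    stringsAsFactors = FALSE
  )
}
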