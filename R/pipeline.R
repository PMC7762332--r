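#' Run the full triage pipeline on files
#'
#' Convenience wrapper chaining the whole analysis: read the cohort VCF, the
#' annotation table and the gene panel; apply the candidate-selection filter
#' cascade; derive per-variant verdicts; categorize probands; summarize the
#' cohort; optionally write the JSON report and per-variant TSV.
#'
#' @param vcf Path to the cohort VCF (see [read_vcf()]).
#' @param annotations Path to the annotation TSV (see
#'   [read_annotation_table()]).
#' @param panel Path to the gene panel TSV (see [read_panel()]).
#' @param probands All proband ids in the cohort. Defaults to the VCF sample
#'   set with at least one call; pass the full roster explicitly so that
#'   variant-free probands are counted (they are negatives, and the
#'   diagnostic-yield denominator).
#' @param af_threshold,require_pass,coding_only See [filter_config()].
#' @param out_dir If non-NULL, report files are written here
#'   (\code{report.json}, \code{report.tsv}).
#' @return A list: \code{calls}, \code{retained} (with exclusions attached as
#'   an attribute), \code{verdicts}, \code{results}, \code{summary}.
#' @export
run_triage <- function(vcf, annotations, panel, probands = NULL,
                       af_threshold = 0.001, require_pass = TRUE,
                       coding_only = TRUE, out_dir = NULL) {
  calls <- read_vcf(vcf)
  ann <- read_annotation_table(annotations)
  panel_tab <- read_panel(panel)
  if (is.null(probands)) probands <- sort(unique(calls$proband_id))

  config <- filter_config(
    panel = panel_tab$gene, af_threshold = af_threshold,
    require_pass = require_pass, coding_only = coding_only
  )
  retained <- apply_filters(calls, ann, config)
  verdicts <- triage_variants(retained)
  results <- proband_results(verdicts, probands)
  summary <- summarize_cohort(verdicts, probands)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(summary, file.path(out_dir, "report.json"),
                 verdicts = verdicts,
                 variants_path = file.path(out_dir, "report.tsv"))
  }
  list(calls = calls, retained = retained, verdicts = verdicts,
       results = results, summary = summary)
}
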