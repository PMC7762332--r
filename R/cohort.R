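#' @name cohort
#' @title Proband categorization and cohort summaries
#' @description
#' Verdicts aggregate to a per-proband genetic-testing category and then to
#' cohort-level accounting. A proband is \emph{positive} when any carried
#' variant has ClinVar-derived class P/LP; \emph{negative} when it carries no
#' rare variant at all or only B/LB variants; \emph{inconclusive} otherwise
#' (VUS, conflicting interpretations, reported variants without a ClinVar
#' classification, and all novel variants irrespective of their VarSome
#' class). A conflicting class that includes LP (CON_VUS_LP) does not make a
#' proband positive: the conflict is surfaced as favoring pathogenicity but
#' the case remains inconclusive.
NULL

PROBAND_CATEGORIES <- c("positive", "inconclusive", "negative")

#' Categorize one proband from its verdicts
#'
#' @param clinvar_classes Character vector of ClinVar-derived classes of the
#'   proband's retained variants (possibly empty).
#' @return One of \code{"positive"}, \code{"inconclusive"}, \code{"negative"}.
#'   Precedence: positive > inconclusive > negative.
#' @examples
#' categorize_proband(c("P_LP", "VUS"))  # positive
#' categorize_proband(character(0))      # negative
#' categorize_proband(c("B_LB", "B_LB")) # negative
#' categorize_proband("CON_VUS_LP")      # inconclusive
#' @export
categorize_proband <- function(clinvar_classes) {
  bad <- setdiff(clinvar_classes, CLINVAR_CLASS_LEVELS)
  if (length(bad)) stop("unknown ClinVar-derived class: ", paste(bad, collapse = ", "))
  if (any(clinvar_classes == "P_LP")) return("positive")
  if (length(clinvar_classes) == 0L || all(clinvar_classes == "B_LB")) {
    return("negative")
  }
  "inconclusive"
}

#' Per-proband results
#'
#' @param verdicts Verdict table from [triage_variants()] (needs
#'   \code{proband_id} and \code{clinvar_class}).
#' @param probands Character vector of all proband ids in the cohort,
#'   including variant-free probands; must be unique.
#' @return Data frame with one row per proband: \code{proband_id},
#'   \code{n_variants}, \code{category}.
#' @export
proband_results <- function(verdicts, probands) {
  probands <- as.character(probands)
  if (anyDuplicated(probands)) stop("duplicate proband ids")
  extra <- setdiff(verdicts$proband_id, probands)
  if (length(extra)) {
    stop("verdicts carry probands absent from the roster: ",
         paste(extra, collapse = ", "))
  }
  split_classes <- split(verdicts$clinvar_class, verdicts$proband_id)
  data.frame(
    proband_id = probands,
    n_variants = vapply(probands, function(p) {
      length(split_classes[[p]])
    }, integer(1), USE.NAMES = FALSE),
    category = vapply(probands, function(p) {
      categorize_proband(split_classes[[p]] %||% character(0))
    }, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a cohort
#'
#' Aggregates verdicts and proband categories into the cohort accounting:
#' distinct variants (keyed by gene and HGVS c.), per-gene counts,
#' consequence breakdown, ClinVar class distribution over previously
#' reported variants, novelty split, recurrence, per-proband category
#' counts and diagnostic-yield percentages (one decimal).
#'
#' @param verdicts Verdict table from [triage_variants()].
#' @param probands Character vector of all proband ids (unique).
#' @return A list of class \code{cohort_summary}; see
#'   [write_report()] for its serialised form.
#' @export
summarize_cohort <- function(verdicts, probands) {
  results <- proband_results(verdicts, probands)
  key <- paste(verdicts$gene, verdicts$hgvs_c, sep = "|")

  # Occurrence = number of distinct probands carrying the keyed variant.
  occ <- integer(0)
  if (nrow(verdicts)) {
    occ_tab <- tapply(verdicts$proband_id, key, function(x) length(unique(x)))
    occ <- as.integer(occ_tab)
    names(occ) <- names(occ_tab)
  }

  first <- !duplicated(key)
  distinct <- verdicts[first, , drop = FALSE]
  dkey <- key[first]

  per_gene <- table_to_named_int(distinct$gene)
  consequence_counts <- count_with_levels(distinct$consequence, CONSEQUENCE_LEVELS)
  reported <- distinct[!distinct$novel, , drop = FALSE]
  clinvar_class_counts <- count_with_levels(reported$clinvar_class, CLINVAR_CLASS_LEVELS)
  category_counts <- count_with_levels(results$category, PROBAND_CATEGORIES)
  n_probands <- length(probands)

  rec <- dkey[occ[dkey] >= 2L]
  recurrent_variants <- data.frame(
    gene = distinct$gene[dkey %in% rec],
    hgvs_c = distinct$hgvs_c[dkey %in% rec],
    n_probands = as.integer(occ[dkey[dkey %in% rec]]),
    stringsAsFactors = FALSE
  )
  recurrent_variants <- recurrent_variants[order(recurrent_variants$gene,
                                                 recurrent_variants$hgvs_c), ,
                                           drop = FALSE]
  rownames(recurrent_variants) <- NULL

  summary <- list(
    n_probands = n_probands,
    n_distinct_variants = nrow(distinct),
    n_genes_hit = length(per_gene),
    per_gene_counts = per_gene,
    consequence_counts = consequence_counts,
    clinvar_class_counts = clinvar_class_counts,
    n_novel = sum(distinct$novel),
    n_reported = sum(!distinct$novel),
    recurrent_variants = recurrent_variants,
    category_counts = category_counts,
    yield_percentages = round(100 * category_counts / max(n_probands, 1L), 1),
    n_multi_variant_probands = sum(results$n_variants >= 2L),
    max_variants_per_proband = if (nrow(results)) max(results$n_variants) else 0L
  )
  class(summary) <- "cohort_summary"
  validate_cohort_summary(summary)
  summary
}

table_to_named_int <- function(x) {
  if (!length(x)) return(stats::setNames(integer(0), character(0)))
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

count_with_levels <- function(x, levels) {
  tab <- table(factor(x, levels = levels))
  stats::setNames(as.integer(tab), levels)
}

validate_cohort_summary <- function(s) {
  stopifnot(
    sum(s$category_counts) == s$n_probands,
    sum(s$per_gene_counts) == s$n_distinct_variants,
    sum(s$consequence_counts) == s$n_distinct_variants,
    s$n_novel + s$n_reported == s$n_distinct_variants,
    sum(s$clinvar_class_counts) == s$n_reported,
    s$n_probands == 0 || abs(sum(s$yield_percentages) - 100) <= 0.2
  )
  invisible(s)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n_probands, "probands:",
      x$n_distinct_variants, "distinct rare variants in",
      x$n_genes_hit, "genes\n")
  cat("  novel:", x$n_novel, "| previously reported:", x$n_reported, "\n")
  cat("  consequences:",
      paste(names(x$consequence_counts), x$consequence_counts,
            sep = "=", collapse = ", "), "\n")
  cat("  ClinVar classes (reported variants):",
      paste(names(x$clinvar_class_counts), x$clinvar_class_counts,
            sep = "=", collapse = ", "), "\n")
  cat("  recurrent variants (>=2 probands):", nrow(x$recurrent_variants), "\n")
  cat("  categories:",
      paste(names(x$category_counts), x$category_counts,
            sep = "=", collapse = ", "), "\n")
  cat("  diagnostic yield:",
      paste0(names(x$yield_percentages), "=", x$yield_percentages, "%",
             collapse = ", "), "\n")
  invisible(x)
}

#' Compare positive and non-positive probands on clinical covariates
#'
#' Splits the cohort into G+ (positive category) and G- (everyone else) and
#' compares each covariate across groups: continuous covariates by group
#' mean and SD with a Welch two-sample unequal-variance t-test; categorical
#' covariates by counts and percentages with Fisher's exact test.
#'
#' @param results Per-proband results from [proband_results()].
#' @param covariates Data frame keyed by \code{proband_id}, one column per
#'   covariate; numeric columns are treated as continuous, everything else
#'   as categorical.
#' @return Data frame with one row per covariate: \code{variable},
#'   \code{type}, \code{g_pos}, \code{g_neg} (formatted summaries),
#'   \code{p_value} and \code{note}. Degenerate inputs (a group smaller than
#'   two, constant values) yield \code{NA} p-values with an explanatory
#'   note instead of an error; constant but identical groups report p = 1.
#' @export
compare_groups <- function(results, covariates) {
  if (!"proband_id" %in% names(covariates)) {
    stop("covariates must carry a proband_id column")
  }
  idx <- match(covariates$proband_id, results$proband_id)
  if (anyNA(idx)) stop("covariates list unknown proband ids")
  is_pos <- results$category[idx] == "positive"

  vars <- setdiff(names(covariates), "proband_id")
  rows <- lapply(vars, function(v) {
    x <- covariates[[v]]
    if (is.numeric(x)) {
      compare_continuous(v, x[is_pos], x[!is_pos])
    } else {
      compare_categorical(v, x[is_pos], x[!is_pos])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

compare_continuous <- function(name, a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  fmt <- function(x) {
    if (!length(x)) return("-")
    sprintf("%.2f ± %.2f (n=%d)", mean(x), stats::sd(x), length(x))
  }
  p <- NA_real_
  note <- ""
  if (length(a) < 2L || length(b) < 2L) {
    note <- "group smaller than 2; test not computable"
  } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      p <- 1
      note <- "both groups constant and equal"
    } else {
      note <- "degenerate zero variance; groups differ"
    }
  } else {
    p <- stats::t.test(a, b, var.equal = FALSE)$p.value
  }
  data.frame(
    variable = name, type = "continuous", g_pos = fmt(a), g_neg = fmt(b),
    p_value = p, note = note, stringsAsFactors = FALSE
  )
}

compare_categorical <- function(name, a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  levels_all <- sort(unique(c(a, b)))
  fmt <- function(x) {
    if (!length(x)) return("-")
    tab <- table(factor(x, levels = levels_all))
    paste(sprintf("%s: %d (%.1f%%)", names(tab), as.integer(tab),
                  100 * as.integer(tab) / length(x)), collapse = "; ")
  }
  p <- NA_real_
  note <- ""
  if (!length(a) || !length(b)) {
    note <- "empty group; test not computable"
  } else if (length(levels_all) < 2L) {
    p <- 1
    note <- "single level in both groups"
  } else {
    tab <- rbind(table(factor(a, levels = levels_all)),
                 table(factor(b, levels = levels_all)))
    p <- stats::fisher.test(tab)$p.value
  }
  data.frame(
    variable = name, type = "categorical", g_pos = fmt(a), g_neg = fmt(b),
    p_value = p, note = note, stringsAsFactors = FALSE
  )
}
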