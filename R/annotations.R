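#' @name annotations
#' @title Annotation and panel tables
#' @description
#' External evidence for each variant (population allele frequencies, ClinVar
#' assertions, in-silico predictor calls, identifiers) arrives as a
#' tab-separated table with one row per variant, keyed by the pair
#' (gene symbol, HGVS c.). The gene panel is a second TSV listing the genes
#' under analysis with their chromosome and a core-sarcomeric flag.
NULL

CLINVAR_ASSERTION_LEVELS <- c("B", "LB", "VUS", "LP", "P")
SIFT_LEVELS <- c("D", "T")
PROVEAN_LEVELS <- c("D", "N")
POLYPHEN_LEVELS <- c("PrD", "PoD", "B")
MT_LEVELS <- c("DC", "Pol")
FIVE_TIER_LEVELS <- c("B", "LB", "VUS", "LP", "P")

# Column layout of the annotation TSV. AF columns are fractions in [0, 1];
# an empty cell means "not observed in that source".
ANNOTATION_COLUMNS <- c(
  "gene", "hgvs_c", "hgvs_p", "dbsnp_id", "clinvar_id", "clinvar_assertions",
  "af_gnomad", "af_1000g", "sift", "provean", "polyphen", "mutation_taster",
  "varsome_class"
)

#' Read a variant annotation table
#'
#' Reads a tab-separated annotation table (one row per variant) into a data
#' frame keyed by \code{(gene, hgvs_c)}. Required columns: \code{gene},
#' \code{hgvs_c}, \code{hgvs_p}, \code{dbsnp_id}, \code{clinvar_id},
#' \code{clinvar_assertions} (comma-separated subset of
#' \code{B,LB,VUS,LP,P}; empty when the variant has no ClinVar record),
#' \code{af_gnomad} and \code{af_1000g} (allele-frequency fractions, empty =
#' not observed in that source), the four in-silico predictor calls
#' \code{sift} (\code{D}/\code{T}), \code{provean} (\code{D}/\code{N}),
#' \code{polyphen} (\code{PrD}/\code{PoD}/\code{B}),
#' \code{mutation_taster} (\code{DC}/\code{Pol}) — \code{NA} allowed for all
#' four — and \code{varsome_class} (\code{B}/\code{LB}/\code{VUS}/\code{LP}/
#' \code{P} or \code{NA}).
#'
#' @param path Path to the TSV file (header row required).
#' @return A data frame with one row per variant and a \code{key} column
#'   (\code{gene|hgvs_c}); \code{clinvar_assertions} is a list column of
#'   character vectors. Attributes are plain; row order follows the file.
#'
#' @details Duplicate \code{(gene, hgvs_c)} keys, allele frequencies outside
#'   [0, 1], unknown enum strings, and rows whose ClinVar assertion set is
#'   inconsistent with the ClinVar id (one empty, the other not) are errors.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  tab <- utils::read.delim(
    path,
    colClasses = "character", na.strings = NULL,
    check.names = FALSE, quote = "", comment.char = ""
  )
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("annotation table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  tab <- tab[ANNOTATION_COLUMNS]
  if (nrow(tab) == 0L) {
    tab$key <- character(0)
    tab$clinvar_assertions <- list()
    tab$af_gnomad <- numeric(0)
    tab$af_1000g <- numeric(0)
    return(tab)
  }
  if (any(!nzchar(tab$gene)) || any(!nzchar(tab$hgvs_c))) {
    stop("annotation table: gene and hgvs_c must be non-empty")
  }
  key <- paste(tab$gene, tab$hgvs_c, sep = "|")
  if (anyDuplicated(key)) {
    stop(
      "duplicate annotation keys: ",
      paste(unique(key[duplicated(key)]), collapse = ", ")
    )
  }

  parse_af <- function(x, label) {
    out <- rep(NA_real_, length(x))
    have <- nzchar(x) & x != "NA"
    out[have] <- suppressWarnings(as.numeric(x[have]))
    if (any(have & is.na(out))) stop(label, ": non-numeric allele frequency")
    bad <- !is.na(out) & (out < 0 | out > 1)
    if (any(bad)) {
      stop(label, ": allele frequency outside [0,1] for key ",
           paste(key[bad], collapse = ", "))
    }
    out
  }
  check_enum <- function(x, levels, label) {
    x[!nzchar(x)] <- "NA"
    bad <- !(x %in% c(levels, "NA"))
    if (any(bad)) {
      stop(label, ": unknown value(s) ", paste(unique(x[bad]), collapse = ", "),
           " (allowed: ", paste(levels, collapse = ", "), " or NA)")
    }
    ifelse(x == "NA", NA_character_, x)
  }

  assertions <- lapply(tab$clinvar_assertions, function(x) {
    if (!nzchar(x)) return(character(0))
    vals <- strsplit(x, ",", fixed = TRUE)[[1]]
    vals <- trimws(vals)
    bad <- setdiff(vals, CLINVAR_ASSERTION_LEVELS)
    if (length(bad)) {
      stop("unknown ClinVar assertion value(s): ", paste(bad, collapse = ", "))
    }
    unique(vals)
  })
  inconsistent <- nzchar(tab$clinvar_id) != (lengths(assertions) > 0L)
  if (any(inconsistent)) {
    stop(
      "ClinVar assertions must be present exactly when a ClinVar id is: ",
      paste(key[inconsistent], collapse = ", ")
    )
  }

  tab$key <- key
  tab$clinvar_assertions <- assertions
  tab$af_gnomad <- parse_af(tab$af_gnomad, "af_gnomad")
  tab$af_1000g <- parse_af(tab$af_1000g, "af_1000g")
  tab$sift <- check_enum(tab$sift, SIFT_LEVELS, "sift")
  tab$provean <- check_enum(tab$provean, PROVEAN_LEVELS, "provean")
  tab$polyphen <- check_enum(tab$polyphen, POLYPHEN_LEVELS, "polyphen")
  tab$mutation_taster <- check_enum(tab$mutation_taster, MT_LEVELS, "mutation_taster")
  tab$varsome_class <- check_enum(tab$varsome_class, FIVE_TIER_LEVELS, "varsome_class")
  tab
}

#' Write a variant annotation table
#'
#' Inverse of [read_annotation_table()]: serialises the annotation data frame
#' back to the documented TSV layout.
#'
#' @param annotations Data frame as returned by [read_annotation_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(annotations, path) {
  out <- annotations[intersect(ANNOTATION_COLUMNS, names(annotations))]
  out$clinvar_assertions <- vapply(
    annotations$clinvar_assertions, paste, character(1), collapse = ","
  )
  for (col in c("af_gnomad", "af_1000g")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", format(out[[col]], scientific = FALSE, trim = TRUE))
  }
  for (col in c("sift", "provean", "polyphen", "mutation_taster", "varsome_class")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a gene panel definition
#'
#' @param path TSV with columns \code{gene}, \code{chromosome}, \code{core}
#'   (logical: core sarcomeric gene).
#' @return Data frame with those three columns; duplicate genes are an error.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character", quote = "")
  needed <- c("gene", "chromosome", "core")
  if (!all(needed %in% names(tab))) {
    stop("panel file must have columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(tab$gene)) stop("panel file lists duplicate genes")
  tab$core <- as.logical(tab$core)
  tab[needed]
}
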