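#' @name vcf_io
#' @title Cohort VCF input and output
#' @description
#' Raw calls enter the pipeline from a multi-sample VCF 4.x file as produced
#' by a germline small-variant caller (GRCh37 coordinates, 1-based; the
#' pipeline never converts to 0-based — genomic positions are carried for
#' provenance only). Gene symbol and HGVS descriptors travel in the INFO
#' column under the keys \code{GENE}, \code{HGVSC} and \code{HGVSP}, the
#' usual shape of an annotated panel VCF; the annotation join happens on
#' (gene, HGVS c.), never on coordinates.
NULL

GENOTYPE_LEVELS <- c("het", "hom", "hemi")

RAWCALL_COLUMNS <- c(
  "proband_id", "chrom", "pos", "ref", "alt", "filter_status",
  "genotype", "depth", "gene", "hgvs_c", "hgvs_p"
)

#' Read cohort calls from a VCF file
#'
#' Produces one raw call per sample-ALT pair with a called non-reference
#' genotype. Multi-allelic sites are decomposed into one call per ALT allele;
#' a sample contributes a call for every distinct ALT allele present in its
#' genotype (\code{het} when the allele appears once in a diploid genotype,
#' \code{hom} when twice, \code{hemi} when the genotype has a single allele).
#' Record order follows the file; within a record, ALT alleles in column
#' order, then samples in header order.
#'
#' @param path Path to a VCF 4.x file.
#' @return A data frame of raw calls with columns \code{proband_id},
#'   \code{chrom}, \code{pos} (integer, 1-based), \code{ref}, \code{alt},
#'   \code{filter_status}, \code{genotype} (het/hom/hemi), \code{depth}
#'   (sample DP, \code{NA} when absent), and the INFO-borne annotation hooks
#'   \code{gene}, \code{hgvs_c}, \code{hgvs_p} (\code{NA} when the file
#'   carries none).
#'
#' @details A malformed file raises a parse error naming the offending line.
#'   Records without a GT entry in FORMAT are skipped with a warning. A
#'   header-only file yields a zero-row data frame.
#' @export
read_vcf <- function(path) {
  lines <- validate_vcf_lines(path)
  n_data <- sum(!startsWith(lines, "#"))
  if (n_data == 0L) {
    return(empty_calls())
  }

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  samples <- colnames(gt)[-1L]
  info <- parse_info(fix[, "INFO"])

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    fmt <- strsplit(gt[i, "FORMAT"], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    dp_idx <- match("DP", fmt)
    if (is.na(gt_idx)) {
      warning("record at ", fix[i, "CHROM"], ":", fix[i, "POS"],
              " has no GT field; skipped")
      next
    }
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    rows <- list()
    for (a in seq_along(alts)) {
      for (s in samples) {
        parts <- strsplit(gt[i, s], ":", fixed = TRUE)[[1]]
        g <- decode_genotype(parts[gt_idx], a)
        if (is.null(g)) next
        depth <- NA_integer_
        if (!is.na(dp_idx) && length(parts) >= dp_idx && parts[dp_idx] != ".") {
          depth <- as.integer(parts[dp_idx])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          proband_id = s,
          chrom = fix[i, "CHROM"],
          pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"],
          alt = alts[a],
          filter_status = ifelse(is.na(fix[i, "FILTER"]), ".", fix[i, "FILTER"]),
          genotype = g,
          depth = depth,
          gene = info$gene[i],
          hgvs_c = info$hgvs_c[i],
          hgvs_p = info$hgvs_p[i],
          stringsAsFactors = FALSE
        )
      }
    }
    out[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_calls())
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  calls
}

empty_calls <- function() {
  data.frame(
    proband_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), filter_status = character(0),
    genotype = character(0), depth = integer(0), gene = character(0),
    hgvs_c = character(0), hgvs_p = character(0), stringsAsFactors = FALSE
  )
}

# Map one sample genotype string to het/hom/hemi with respect to ALT index
# `a` (1-based); NULL when the sample does not carry that allele or the
# genotype is missing.
decode_genotype <- function(gt_string, a) {
  if (is.na(gt_string) || gt_string %in% c(".", "./.", ".|.")) return(NULL)
  alleles <- strsplit(gt_string, "[/|]")[[1]]
  if (any(alleles == ".")) return(NULL)
  alleles <- suppressWarnings(as.integer(alleles))
  if (anyNA(alleles)) return(NULL)
  n <- sum(alleles == a)
  if (n == 0L) return(NULL)
  if (length(alleles) == 1L) return("hemi")
  if (n >= 2L) "hom" else "het"
}

# INFO is split manually (';' then first '='): HGVS protein strings can end
# in '=', which regex-based INFO extraction mishandles.
parse_info <- function(info_strings) {
  pick <- function(pairs, key) {
    hit <- pairs[[key]]
    if (is.null(hit)) NA_character_ else hit
  }
  parsed <- lapply(info_strings, function(s) {
    if (is.na(s) || s == ".") return(list())
    fields <- strsplit(s, ";", fixed = TRUE)[[1]]
    keys <- sub("=.*$", "", fields)
    vals <- ifelse(grepl("=", fields), sub("^[^=]*=", "", fields), "")
    stats::setNames(as.list(vals), keys)
  })
  list(
    gene = vapply(parsed, pick, character(1), key = "GENE"),
    hgvs_c = vapply(parsed, pick, character(1), key = "HGVSC"),
    hgvs_p = vapply(parsed, pick, character(1), key = "HGVSP")
  )
}

validate_vcf_lines <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("malformed VCF (line 1): missing ##fileformat header in ", path)
  }
  header_at <- which(startsWith(lines, "#CHROM"))
  if (!length(header_at)) {
    stop("malformed VCF: no #CHROM header line in ", path)
  }
  header_at <- header_at[1]
  n_fields <- length(strsplit(lines[header_at], "\t", fixed = TRUE)[[1]])
  data_at <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in data_at) {
    n <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (n != n_fields) {
      stop("malformed VCF (line ", i, "): ", n, " fields, expected ", n_fields)
    }
  }
  lines
}

#' Write calls to a multi-sample VCF 4.2 file
#'
#' Inverse of [read_vcf()] for pipeline-shaped call tables; used by the
#' synthetic cohort generator. One VCF record is written per distinct
#' (chrom, pos, ref, alt); every carrier of that variant gets its genotype
#' in the corresponding sample column (GT:DP), all other samples are 0/0.
#'
#' @param calls Data frame of raw calls (see [read_vcf()] for columns).
#' @param path Output path.
#' @param samples Sample column order; defaults to the sorted carriers.
#'   Samples with no calls are legitimate (variant-free probands).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(calls, path, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$proband_id))
  stopifnot(all(calls$proband_id %in% samples))
  if (nrow(calls)) {
    stopifnot(
      all(calls$pos >= 1L),
      all(nzchar(calls$ref)), all(nzchar(calls$alt)),
      all(calls$ref != calls$alt),
      all(calls$genotype %in% GENOTYPE_LEVELS)
    )
  }

  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"HGNC gene symbol\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"HGVS coding descriptor\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"HGVS protein descriptor\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )

  if (nrow(calls) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }

  vkey <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
  first <- !duplicated(vkey)
  variants <- calls[first, , drop = FALSE]
  consistent <- tapply(calls$filter_status, vkey, function(x) length(unique(x)) == 1L)
  if (!all(consistent)) {
    stop("write_vcf: conflicting filter_status among carriers of one variant")
  }

  gt_code <- c(het = "0/1", hom = "1/1", hemi = "1")
  lines <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    k <- vkey[first][i]
    carriers <- calls[vkey == k, , drop = FALSE]
    info_parts <- character(0)
    if (!is.na(v$gene) && nzchar(v$gene)) info_parts <- c(info_parts, paste0("GENE=", v$gene))
    if (!is.na(v$hgvs_c) && nzchar(v$hgvs_c)) info_parts <- c(info_parts, paste0("HGVSC=", v$hgvs_c))
    if (!is.na(v$hgvs_p) && nzchar(v$hgvs_p)) info_parts <- c(info_parts, paste0("HGVSP=", v$hgvs_p))
    info <- if (length(info_parts)) paste(info_parts, collapse = ";") else "."
    cells <- stats::setNames(rep("0/0:.", length(samples)), samples)
    for (j in seq_len(nrow(carriers))) {
      dp <- carriers$depth[j]
      cells[carriers$proband_id[j]] <- paste0(
        gt_code[[carriers$genotype[j]]], ":", ifelse(is.na(dp), ".", dp)
      )
    }
    lines[i] <- paste(
      c(v$chrom, v$pos, ".", v$ref, v$alt, ".", v$filter_status, info,
        "GT:DP", cells),
      collapse = "\t"
    )
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
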