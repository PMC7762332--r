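#' @name hgvs
#' @title HGVS protein-descriptor parsing and consequence classification
#' @description
#' Variants flow through the pipeline identified by their HGVS coding
#' (\code{c.}) and protein (\code{p.}) descriptors, as emitted by clinical
#' annotation software. These functions parse the protein descriptor into a
#' structured change and map each \code{c.}/\code{p.} pair onto a single
#' molecular-consequence category. HGVS strings are trusted inputs: no
#' transcript model is consulted and nothing is re-derived from genomic
#' coordinates.
NULL

# Recognised molecular-consequence categories (the coding filter's allow-list).
CONSEQUENCE_LEVELS <- c(
  "missense", "synonymous", "stop_gained", "stop_lost",
  "frameshift", "inframe_indel", "splice_site", "other_coding"
)

# Protein-change kinds produced by parse_hgvs_p().
PROTEIN_KINDS <- c(
  "substitution", "identity", "deletion", "duplication", "insertion",
  "delins", "frameshift", "extension", "none"
)

AA3 <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val",
  "Ter"
)

.aa <- "(Ala|Arg|Asn|Asp|Cys|Gln|Glu|Gly|His|Ile|Leu|Lys|Met|Phe|Pro|Ser|Thr|Trp|Tyr|Val|Ter)"

#' Parse an HGVS protein descriptor
#'
#' Accepts the protein-level HGVS strings used in clinical variant tables
#' (three-letter amino-acid codes, e.g. \code{"p.Ser283Asn"},
#' \code{"p.Ile137="}, \code{"p.Ala417GlnfsTer29"},
#' \code{"p.Gly653_Arg654del"}) and returns a structured description of the
#' protein change. One-letter amino-acid codes are rejected, not converted.
#'
#' @param hgvs_p A single string: either empty (\code{""} or \code{NA}, no
#'   protein-level prediction, e.g. an intronic variant) or a descriptor
#'   beginning with \code{"p."}. Enclosing parentheses (predicted changes,
#'   \code{"p.(...)"}) are tolerated and stripped.
#'
#' @return A list with elements \code{kind} (one of substitution, identity,
#'   deletion, duplication, insertion, delins, frameshift, extension, none),
#'   \code{start_residue} (three-letter code), \code{start_pos},
#'   \code{end_pos} (equal to \code{start_pos} for point events) and
#'   \code{new_residue} (three-letter code, \code{"Ter"} allowed; \code{""}
#'   where not applicable).
#'
#' @details Any string containing an \code{fs} token is a frameshift
#'   regardless of other tokens, so \code{"p.Ala417GlnfsTer29"} parses as a
#'   frameshift starting at Ala417, not a stop gain. Unparseable strings
#'   raise an error carrying the offending string; nothing is silently
#'   misclassified.
#'
#' @examples
#' parse_hgvs_p("p.Glu293Ter")$kind        # substitution (to a stop)
#' parse_hgvs_p("p.Ile137=")$kind          # identity
#' parse_hgvs_p("p.Gly653_Arg654del")$kind # deletion
#' parse_hgvs_p("")$kind                   # none
#' @export
parse_hgvs_p <- function(hgvs_p) {
  if (length(hgvs_p) != 1L) stop("parse_hgvs_p() expects a single string")
  if (is.na(hgvs_p) || !nzchar(hgvs_p)) {
    return(protein_change("none"))
  }
  if (!startsWith(hgvs_p, "p.")) {
    stop("not an HGVS protein descriptor (must begin with 'p.'): ", sQuote(hgvs_p))
  }
  body <- sub("^p\\.", "", hgvs_p)
  # predicted-consequence parentheses: p.(Arg97Gln)
  body <- sub("^\\((.*)\\)$", "\\1", body)

  fail <- function() {
    stop("unparseable HGVS protein descriptor: ", sQuote(hgvs_p))
  }
  grab <- function(pattern) {
    m <- regmatches(body, regexec(pattern, body))[[1]]
    if (length(m)) m else NULL
  }

  # Frameshift takes absolute precedence over any embedded Ter token.
  if (grepl("fs", body, fixed = TRUE)) {
    m <- grab(paste0("^", .aa, "([0-9]+)(", .aa, ")?fs(Ter([0-9]+|\\?))?$"))
    if (is.null(m)) fail()
    pos <- as.integer(m[3])
    return(protein_change("frameshift", m[2], pos, pos, m[4]))
  }
  # Identity: p.Ile137=
  m <- grab(paste0("^", .aa, "([0-9]+)=$"))
  if (!is.null(m)) {
    pos <- as.integer(m[3])
    return(protein_change("identity", m[2], pos, pos))
  }
  # Stop-loss extension: p.Ter110GlnextTer17
  m <- grab(paste0("^Ter([0-9]+)", .aa, "ext(Ter([0-9]+|\\?))?$"))
  if (!is.null(m)) {
    pos <- as.integer(m[2])
    return(protein_change("extension", "Ter", pos, pos, m[3]))
  }
  # Single-residue substitution: p.Ser283Asn, p.Glu293Ter
  m <- grab(paste0("^", .aa, "([0-9]+)", .aa, "$"))
  if (!is.null(m)) {
    pos <- as.integer(m[3])
    return(protein_change("substitution", m[2], pos, pos, m[4]))
  }
  # Range or point deletion / duplication / delins / insertion.
  m <- grab(paste0("^", .aa, "([0-9]+)(_", .aa, "([0-9]+))?delins([A-Za-z]+)$"))
  if (!is.null(m)) {
    return(range_change("delins", m, hgvs_p, new = m[7]))
  }
  m <- grab(paste0("^", .aa, "([0-9]+)(_", .aa, "([0-9]+))?(del|dup)$"))
  if (!is.null(m)) {
    kind <- if (m[7] == "del") "deletion" else "duplication"
    return(range_change(kind, m, hgvs_p))
  }
  m <- grab(paste0("^", .aa, "([0-9]+)_", .aa, "([0-9]+)ins([A-Za-z]+)$"))
  if (!is.null(m)) {
    start <- as.integer(m[3]); end <- as.integer(m[5])
    if (end < start) fail()
    return(protein_change("insertion", m[2], start, end, m[6]))
  }
  fail()
}

# Constructor with the ProteinChange invariants enforced.
protein_change <- function(kind, start_residue = "", start_pos = NA_integer_,
                           end_pos = NA_integer_, new_residue = "") {
  if (is.na(new_residue) || is.null(new_residue)) new_residue <- ""
  if (!is.na(start_pos)) {
    stopifnot(start_pos >= 1L, end_pos >= start_pos)
  }
  list(
    kind = kind,
    start_residue = start_residue,
    start_pos = start_pos,
    end_pos = end_pos,
    new_residue = new_residue
  )
}

range_change <- function(kind, m, hgvs_p, new = "") {
  start <- as.integer(m[3])
  end <- if (nzchar(m[4])) as.integer(m[6]) else start
  if (end < start) {
    stop("unparseable HGVS protein descriptor: ", sQuote(hgvs_p))
  }
  protein_change(kind, m[2], start, end, new)
}

#' Classify the molecular consequence of a variant
#'
#' Maps an HGVS \code{c.}/\code{p.} pair onto exactly one consequence
#' category, using a fixed precedence so that every variant receives a single
#' deterministic label:
#' \enumerate{
#'   \item frameshift, if the protein descriptor contains an \code{fs} token;
#'   \item splice_site, if no protein descriptor exists and the coding
#'     position carries a canonical intronic offset of +/-1 or +/-2
#'     (the splice donor/acceptor dinucleotide, e.g. \code{c.22816+1G>T});
#'   \item stop_gained, if the substituted residue is \code{Ter};
#'   \item stop_lost, for an extension replacing a \code{Ter};
#'   \item synonymous, for a protein identity (\code{"="});
#'   \item inframe_indel, for deletions, duplications, insertions and
#'     delins without a frameshift;
#'   \item missense, for a one-residue substitution.
#' }
#' Frameshift outranks stop gain, so \code{fsTer} descriptors are
#' frameshifts. Deeper intronic offsets (beyond +/-2) are not
#' splice-classifiable: with no protein descriptor they raise an error, which
#' the filter cascade treats as "not protein-coding".
#'
#' @param hgvs_c HGVS coding descriptor (non-empty, e.g. \code{"c.877G>T"}).
#' @param hgvs_p HGVS protein descriptor, possibly empty.
#' @return A single string, one of
#'   \code{c("missense","synonymous","stop_gained","stop_lost","frameshift",
#'   "inframe_indel","splice_site","other_coding")}.
#' @examples
#' classify_consequence("c.877G>T", "p.Glu293Ter")    # stop_gained
#' classify_consequence("c.22816+1G>T", "")           # splice_site
#' classify_consequence("c.848G>A", "p.Ser283Asn")    # missense
#' @export
classify_consequence <- function(hgvs_c, hgvs_p) {
  if (length(hgvs_c) != 1L || is.na(hgvs_c) || !nzchar(hgvs_c)) {
    stop("hgvs_c must be a non-empty string")
  }
  if (length(hgvs_p) != 1L) stop("hgvs_p must be a single string")
  if (is.na(hgvs_p)) hgvs_p <- ""

  if (nzchar(hgvs_p) && grepl("fs", hgvs_p, fixed = TRUE)) {
    parse_hgvs_p(hgvs_p)  # still validated; errors propagate
    return("frameshift")
  }

  change <- parse_hgvs_p(hgvs_p)
  if (change$kind == "none") {
    if (is_canonical_splice(hgvs_c)) {
      return("splice_site")
    }
    stop(
      "cannot classify consequence: no protein descriptor and ",
      sQuote(hgvs_c), " is not a canonical splice-site position"
    )
  }

  switch(change$kind,
    substitution = if (change$new_residue == "Ter") "stop_gained" else "missense",
    extension = "stop_lost",
    identity = "synonymous",
    deletion = ,
    duplication = ,
    insertion = ,
    delins = "inframe_indel",
    frameshift = "frameshift",
    stop("unclassifiable protein change kind: ", change$kind)
  )
}

# TRUE when the c. descriptor touches the canonical splice dinucleotide:
# an intronic offset of exactly +/-1 or +/-2 next to an exon boundary.
is_canonical_splice <- function(hgvs_c) {
  m <- regmatches(
    hgvs_c,
    regexec("^c\\.[0-9]+(_[0-9]+)?([+-])([0-9]+)", hgvs_c)
  )[[1]]
  if (!length(m)) return(FALSE)
  as.integer(m[4]) <= 2L
}
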