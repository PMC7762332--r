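# Independent oracles and random-input builders shared across test files.

# Brute-force set-comprehension oracle for the filter cascade: evaluates the
# four predicates directly, one call at a time, with no shared cascade code.
oracle_keep <- function(calls, annotations, config) {
  vapply(seq_len(nrow(calls)), function(i) {
    gene <- calls$gene[i]
    in_panel <- !is.na(gene) && gene %in% config$panel
    pass <- !config$require_pass || calls$filter_status[i] == "PASS"

    j <- match(paste(gene, calls$hgvs_c[i], sep = "|"), annotations$key)
    hc <- if (!is.na(j)) annotations$hgvs_c[j] else calls$hgvs_c[i]
    hp <- if (!is.na(j)) annotations$hgvs_p[j] else calls$hgvs_p[i]
    if (is.na(hp)) hp <- ""
    cons <- if (is.na(hc) || !nzchar(hc)) NA_character_ else {
      tryCatch(classify_consequence(hc, hp), error = function(e) NA_character_)
    }
    coding <- !config$coding_only ||
      (!is.na(cons) && cons %in% c("missense", "synonymous", "stop_gained",
                                   "stop_lost", "frameshift", "inframe_indel",
                                   "splice_site"))

    rare <- TRUE
    if (!is.na(j)) {
      for (af in c(annotations$af_gnomad[j], annotations$af_1000g[j])) {
        if (!is.na(af) && af >= config$af_threshold) rare <- FALSE
      }
    }
    in_panel && pass && coding && rare
  }, logical(1))
}

# Random calls + annotations exercising every predicate (and their overlaps):
# on/off-panel genes, PASS and non-PASS, coding / splice / deep-intronic /
# unannotated HGVS, below- and above-threshold AFs in either source.
random_filter_inputs <- function(n, seed) {
  withr::with_seed(seed, {
    panel_genes <- c("MYBPC3", "MYH7", "TTN", "TNNT2", "DES")
    genes <- sample(c(panel_genes, "DSP", "PKP2"), n, replace = TRUE)
    kind <- sample(c("missense", "synonymous", "stop", "splice", "intronic"),
                   n, replace = TRUE)
    hgvs_c <- character(n)
    hgvs_p <- character(n)
    for (i in seq_len(n)) {
      base <- 3L * i
      switch(kind[i],
        missense = {
          hgvs_c[i] <- sprintf("c.%dG>A", base)
          hgvs_p[i] <- sprintf("p.Gly%dAsp", i)
        },
        synonymous = {
          hgvs_c[i] <- sprintf("c.%dC>T", base)
          hgvs_p[i] <- sprintf("p.Leu%d=", i)
        },
        stop = {
          hgvs_c[i] <- sprintf("c.%dG>T", base)
          hgvs_p[i] <- sprintf("p.Glu%dTer", i)
        },
        splice = {
          hgvs_c[i] <- sprintf("c.%d+%dG>T", base, sample(1:2, 1))
          hgvs_p[i] <- ""
        },
        intronic = {
          hgvs_c[i] <- sprintf("c.%d+%dG>T", base, sample(5:40, 1))
          hgvs_p[i] <- ""
        }
      )
    }
    annotated <- stats::runif(n) < 0.8
    draw_af <- function() {
      u <- stats::runif(1)
      if (u < 0.4) NA_real_
      else if (u < 0.8) stats::runif(1, 0, 0.00099)
      else stats::runif(1, 0.001, 0.05)
    }
    ann <- data.frame(
      gene = genes[annotated], hgvs_c = hgvs_c[annotated],
      hgvs_p = hgvs_p[annotated],
      dbsnp_id = "", clinvar_id = "",
      af_gnomad = vapply(which(annotated), function(i) draw_af(), numeric(1)),
      af_1000g = vapply(which(annotated), function(i) draw_af(), numeric(1)),
      sift = NA_character_, provean = NA_character_, polyphen = NA_character_,
      mutation_taster = NA_character_, varsome_class = NA_character_,
      stringsAsFactors = FALSE
    )
    ann$clinvar_assertions <- rep(list(character(0)), nrow(ann))
    ann$key <- paste(ann$gene, ann$hgvs_c, sep = "|")
    ann <- ann[!duplicated(ann$key), , drop = FALSE]

    calls <- data.frame(
      proband_id = sprintf("S%03d", sample(1:20, n, replace = TRUE)),
      chrom = "1", pos = seq_len(n), ref = "G", alt = "A",
      filter_status = sample(c("PASS", "q30"), n, replace = TRUE,
                             prob = c(0.8, 0.2)),
      genotype = "het", depth = 100L,
      gene = genes, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
      stringsAsFactors = FALSE
    )
    list(calls = calls, annotations = ann,
         config = filter_config(panel = panel_genes))
  })
}

# Brute-force decomposition oracle: expected (alt, genotype) pairs for one
# sample genotype string over a multi-allelic site, by direct allele counting.
oracle_decompose <- function(gt_string, alts) {
  if (gt_string %in% c(".", "./.", ".|.")) return(NULL)
  alleles <- as.integer(strsplit(gt_string, "[/|]")[[1]])
  out <- NULL
  for (a in seq_along(alts)) {
    cnt <- sum(alleles == a)
    if (cnt == 0) next
    g <- if (length(alleles) == 1) "hemi" else if (cnt >= 2) "hom" else "het"
    out <- rbind(out, data.frame(alt = alts[a], genotype = g,
                                 stringsAsFactors = FALSE))
  }
  out
}

# Independent ClinVar aggregation oracle: plain set logic over one assertion
# subset, written out case by case.
oracle_clinvar_class <- function(set) {
  if (length(set) == 0) return("NA")
  p <- any(set %in% c("P", "LP")); b <- any(set %in% c("B", "LB"))
  v <- "VUS" %in% set
  if (!v && !b) return("P_LP")
  if (!v && !p) return("B_LB")
  if (v && !p && !b) return("VUS")
  if (v && p && !b) return("CON_VUS_LP")
  if (v && b && !p) return("CON_VUS_BLB")
  "CON_VUS_LP"
}

# Minimal verdict-table builder for cohort-level tests.
make_verdicts <- function(proband_id, gene, hgvs_c, clinvar_class,
                          novel = FALSE, consequence = "missense") {
  n <- length(proband_id)
  novel <- rep_len(novel, n)
  df <- data.frame(
    proband_id = proband_id, gene = gene, hgvs_c = hgvs_c,
    hgvs_p = rep_len("p.Gly1Asp", n), consequence = rep_len(consequence, n),
    novel = novel, clinvar_class = clinvar_class,
    dbsnp_id = ifelse(novel, "", "rs1"),
    clinvar_id = rep_len("", n),
    sift = rep_len(NA_character_, n), provean = rep_len(NA_character_, n),
    polyphen = rep_len(NA_character_, n),
    mutation_taster = rep_len(NA_character_, n),
    insilico_votes = rep_len(0L, n),
    varsome_class = rep_len(NA_character_, n),
    five_tier = rep_len("VUS", n),
    five_tier_source = rep_len("insilico_rule", n),
    suspicious = rep_len(FALSE, n), stringsAsFactors = FALSE
  )
  df$clinvar_assertions <- rep(list(character(0)), n)
  df
}
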