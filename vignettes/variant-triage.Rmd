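---
title: "Rare-variant triage for HCM gene panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant triage for HCM gene panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcmtriage)
```

## The problem

Targeted gene-panel sequencing of hypertrophic cardiomyopathy (HCM) probands
produces thousands of raw calls per sample, of which only a handful are
plausibly disease-relevant. The clinical question is threefold: which calls
are candidate variants at all; what does the available evidence say about
each candidate; and what does the per-variant evidence imply for each proband
(a definite genetic etiology, an inconclusive result, or a negative test).
`hcmtriage` implements that analysis stage — everything downstream of the
variant caller and upstream of clinical sign-out — as small, separately
testable functions plus one end-to-end pipeline, together with a packaged
45-proband reference cohort and a synthetic cohort generator used as an
oracle in the test suite.

## The filter cascade

A call is a candidate when all four predicates hold, evaluated in this
order (the order only affects which reason is logged for an excluded call):

1. **Panel membership.** The gene is one of the 47 HCM-associated genes on
   the analysis panel (8 core sarcomeric genes plus emerging and phenocopy
   genes). Off-panel calls are excluded as `off_panel`.
2. **Call quality.** The caller marked the call `PASS`. Toggleable via
   `require_pass` for callers whose filter column is unreliable.
3. **Protein-coding consequence.** The HGVS descriptors classify into one of
   missense, synonymous, stop gained, stop lost, frameshift, in-frame indel,
   or canonical splice site. Synonymous variants deliberately pass — they
   are part of the reportable spectrum here. Anything unclassifiable (deep
   intronic positions, UTR-only descriptors, missing HGVS) fails as
   `non_coding`.
4. **Rarity.** In every population source where the variant has been
   observed (gnomAD total population including controls, and the 1000
   Genomes frequencies), the allele frequency is strictly below
   `af_threshold`. The default of 0.001 (0.1%) follows from the disease
   prevalence of roughly 1 in 500 individuals, i.e. 1 per 1000 chromosomes:
   a causal allele cannot plausibly be more common than the disease.

Two rarity conventions deserve emphasis because they shape the results. The
bound is a **strict** inequality: a variant at exactly 0.1% is excluded.
And **absence is rarity**: a variant with no record in any frequency source
imposes no constraint and is retained — this is what lets never-reported
(novel) variants through, and it is the behaviour a clinical analyst expects
when a database simply has no entry. The cascade is total (never errors),
idempotent, and monotone in the threshold; the test suite checks all three
properties against a brute-force predicate-comprehension oracle on
randomized cohorts.

Unannotated calls are not dropped at the join: their consequence is
classified from the HGVS descriptors carried in the VCF INFO column, they
are flagged `annotated = FALSE`, and the cascade — not the I/O layer —
decides their fate.

## Consequence classification from HGVS

`classify_consequence()` maps an HGVS c./p. pair to exactly one category
using a fixed precedence: frameshift (any `fs` token) first; then canonical
splice site when no protein descriptor exists and the coding position
carries an intronic offset of ±1/±2; then stop gained (substitution to
`Ter`); stop lost (extension of a `Ter`); synonymous (`=`); in-frame indel
(del/dup/ins/delins); missense last. Two tie-breaks are deliberate:

* **Frameshift outranks stop gain**, so `p.Ala417GlnfsTer29` is a
  frameshift, matching how clinical variant tables label such entries.
* **Splice is claimed only for the canonical ±1/±2 dinucleotide.** Deeper
  intronic offsets are not guessed at; without a protein descriptor they
  raise an error, which the cascade maps to `non_coding`. This keeps the
  coding filter honest rather than silently admitting intronic variants.

The parser accepts three-letter amino-acid codes only (as printed in
clinical reports); one-letter input is rejected, never converted, and an
unparseable descriptor raises an error carrying the offending string — the
classifier never silently misassigns. A consequence of being strictly
HGVS-faithful is that a descriptor like `p.Glu904Ter` is always a stop gain,
even where an upstream tally may have counted such a variant under
missense; when the package's counts are compared against externally
published aggregates, that is the one place a one-variant disagreement can
legitimately appear.

## Evidence aggregation

**ClinVar.** The set of submitted interpretations collapses to a derived
class: `P_LP`, `B_LB`, `VUS`, `NA` (no record), or a conflict subtype —
`CON_VUS_LP` (VUS together with LP/P) or `CON_VUS_BLB` (VUS together with
B/LB). A mixture spanning both benign and pathogenic assertions (not seen in
the reference cohort) is classed `CON_VUS_LP` with a warning: conservative
toward clinical follow-up. The aggregation is a total function and is tested
against an independent set-logic oracle on all 32 assertion subsets.

**Novelty.** A variant is novel exactly when it has neither a dbSNP
identifier nor a ClinVar record. Any identifier defeats novelty. This is an
operational proxy for "never published or databased"; proprietary databases
that cannot be redistributed play no part in it.

**In-silico consensus.** Four predictors vote on missense variants (SIFT
`D`, Provean `D`, PolyPhen-2 `PrD`/`PoD`, MutationTaster `DC`); for every
other consequence only MutationTaster is consulted, so votes are 0–4 for
missense and 0–1 otherwise. `NA` calls contribute nothing. The predictors
themselves are annotation inputs — nothing is re-scored.

**Five-tier label.** Reported variants take their ClinVar tier (most severe
pathogenic assertion for `P_LP`; conflicts collapse to tier VUS while the
subtype is kept on the verdict; no classification defaults to VUS). Novel
variants take the VarSome class when one exists. When it does not, a bounded
fallback applies: all available predictors benign → LB; at least three
quarters deleterious → VUS flagged *suspicious*; otherwise VUS. The cap is
deliberate — under ACMG/AMP reasoning, computational evidence alone is
supporting-strength and can never reach LP, so the rule never outputs
anything above VUS.

## Proband categorization and yield

A proband is **positive** if any retained variant has ClinVar-derived class
`P_LP`; **negative** if it carries nothing or only `B_LB` variants;
**inconclusive** otherwise. Three consequences of that rule matter:

* `CON_VUS_LP` does *not* make a proband positive. The conflict is surfaced
  as favoring pathogenicity, but a conflicted variant is not a definite
  etiology.
* Novel variants are inconclusive irrespective of their VarSome tier — a
  never-reported variant cannot anchor a definite diagnosis without
  segregation or functional data.
* A proband carrying only B/LB variants is negative by rule, even though in
  the reference cohort the negative probands happen to carry nothing at all.

Diagnostic yield is reported per category as `100 × count / n_probands`,
rounded to one decimal.

## The packaged reference cohort

`load_hcm_fixture()` returns the reference cohort: a 47-gene panel, 43 novel
variants (with predictor calls and VarSome classes) and 52 previously
reported variants (with dbSNP/ClinVar identifiers and assertion sets), 95
distinct variants in all, 5 of them observed in two probands each (100
observations). Allele frequencies are not part of the record; all fixture
variants are below threshold by construction, which the cascade handles via
the absence-is-rarity rule.

The per-proband assignment of those observations is **reconstructed, not
transcribed** — the published record identifies variants, carriers counts
and cohort aggregates, but not which proband carries what.
`reconstruct_assignment()` builds one deterministic assignment satisfying
every published aggregate: 37 of 45 probands carry at least one variant;
probands 1–6 each carry exactly one P/LP variant and no other proband
carries any; probands 38–45 carry nothing; 27 probands carry two or more
variants with a maximum of 11 in one proband; the two copies of each
recurrent variant sit on distinct probands; every non-positive carrier has
at least one variant that is neither P/LP nor B/LB, making it inconclusive.
Any assignment satisfying those constraints is equally valid; the packaged
one is simply reproducible. Accordingly, the 31/45 inconclusive split, the
27 multi-variant carriers and the 11-variant maximum are *fixture
consistency checks*, not quantities recoverable from the published
per-variant data alone, and the test suite labels them as such. Genomic
coordinates for fixture calls are synthetic provenance stubs: the analysis
joins on (gene, HGVS c.) and never on position.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of the study so that
the whole pipeline can be tested against known ground truth:

* **Per-proband variant counts** are drawn from a Poisson with mean 2.1
  conditioned on 0..11 — sampled exactly from the renormalised probabilities,
  not by rejection, so the conditional mean has a closed-form oracle used in
  the tests.
* **Class mixture** defaults to the reference cohort's distinct-variant
  distribution (6 P/LP : 14 VUS : 2 CON VUS+LP : 6 CON VUS+B/LB : 11 B/LB :
  13 reported-unclassified : 43 novel, over 95).
* **Genes** are drawn with weights proportional to the reference cohort's
  per-gene variant counts (plus a 0.5 pseudo-count so unhit panel genes stay
  drawable), concentrating variants in MYBPC3, TTN and MYH7 as observed.
* **HGVS pairs** are built from per-consequence templates (substitution,
  `=`, `Ter`, `fsTer`, del, dup, +1 splice), so the classifier is exercised
  on generated data without a transcript model.
* **Recurrence**: 5% of observations are second copies of an existing
  variant, always placed on a different proband.
* **Decoys** exercise every exclusion reason: above-threshold allele
  frequency, off-panel gene, non-PASS call, deep-intronic position. Each
  decoy violates exactly one predicate, so the logged reason is
  unambiguous. The decoy rates (0.10/0.05/0.05/0.05 per true variant) are
  the package's own choice of modest contamination — no empirical decoy
  rates exist for this design, and the rates only need to guarantee that
  every branch of the cascade fires.
* **Determinism**: one integer seed drives the run via an isolated RNG
  scope (`withr::with_seed`); the same config yields byte-identical output
  files and the caller's RNG stream is untouched.

What the generator does **not** emulate: sequence context (REF/ALT strings
are plausible but arbitrary), transcript-consistent HGVS/coordinate
relationships, population-genetic allele-frequency spectra, relatedness, or
caller error modes. Passing the round-trip tests therefore demonstrates that
the rule engine is exact on well-formed inputs, not that the pipeline is
robust to malformed real-world annotation — the I/O layer's validation
errors are tested separately.

## Numerical and degenerate-input choices

* The AF threshold comparison is strict (`<`), applied per source, with
  absent sources unconstrained.
* Percentages are rounded to one decimal; category counts always sum to the
  number of probands (checked as a class invariant on every summary).
* Group comparison (`compare_groups()`) uses Welch's unequal-variance
  t-test for continuous covariates and Fisher's exact test for categorical
  ones. The choice is the package's own: the underlying study design
  compares a 6-proband positive group against the rest, where equal-variance
  assumptions and asymptotic count tests are both indefensible. Degenerate
  inputs (a group smaller than two, zero variance on both sides) yield an
  `NA` p-value with an explanatory note rather than an error; two constant,
  equal groups report p = 1.
* JSON reports round-trip bit-exactly: `read_report(write_report(s)) == s`
  with `identical()`.

## Test problem sizes

The suite runs the filter oracle on 1200 randomized calls, the
categorization invariants on 500 randomized verdict lists, the
truncated-Poisson mean check on 20,000 draws, and the generator
ground-truth round trip on 100 seeded cohorts (plus 3 seeds through the
full file-based path). These sizes were chosen so the whole suite completes
in a few minutes on one core while keeping each Monte-Carlo check's
sampling error an order of magnitude below its tolerance.

## Known limitations

* No full ACMG/AMP 28-criterion engine: only the operational subset above.
  In particular, PVS1-style reasoning (null variant in an LOF-intolerant
  gene) is not applied to novel truncating variants — they stay VUS unless
  VarSome says otherwise.
* Novelty cannot see databases that are not provided as inputs; variants
  known only to proprietary archives will be flagged novel.
* HGVS descriptors are trusted, not re-derived; a wrong descriptor upstream
  yields a wrong (but loudly deterministic) consequence.
* The X-linked panel genes (LAMP2, GLA, FHL1) support hemizygous calls in
  the VCF layer, but the reference cohort contains heterozygous calls only.
* Multi-allelic decomposition policy (one call per ALT with per-allele
  genotype) is the package's choice; upstream tools differ and no published
  convention exists for this design.
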