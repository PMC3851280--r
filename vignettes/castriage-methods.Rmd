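---
title: "Triage of clinical exomes for childhood apraxia of speech: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of clinical exomes for childhood apraxia of speech: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castriage)
```

## The problem

Childhood apraxia of speech (CAS) is a rare, persistent pediatric motor
speech disorder. It is genetically heterogeneous: beyond the classical
FOXP2 findings, variants in FOXP1, CNTNAP2, ATP13A4, KIAA0319, SETX and
others have been implicated in CAS or in overlapping phenotypes (specific
language impairment, dyslexia, AOA2). A whole-exome experiment on such a
cohort produces roughly 10^5 annotated variant calls per sample; the
interpretation ("tertiary") stage must reduce these to a handful of
clinically reportable candidates, reproducibly and with an audit trail.

`castriage` models that stage as a pure rule engine over an annotated
variant table. Annotation itself (consequence calling, predictor scores,
database frequencies) is an *input*: the package never runs SIFT or
touches reads.

## The variant model

One row per called variant per sample, with 1-based inclusive coordinates,
a consequence from a fixed taxonomy, allele frequencies from four
population sources (dbSNP 137, ESP6500/EVS, 1000 Genomes, in-house panel),
five in-silico predictor calls, zygosity, percent read support and depth.
Two representation rules matter:

* **Absent is not zero.** A frequency missing from a database is `NA`.
  Filters must branch on absence explicitly; the parser never coerces
  "Not found" to 0. Absence from *all* sources defines a *novel* variant.
* **Percentages as printed.** Read support is kept on the 0--100 scale used
  in clinical reports, avoiding silent rescaling errors.

The canonical dialect is a 23-column TSV; a VCF adapter maps single-sample
VCF 4.x files with annotation INFO keys onto the same model, splitting
multi-allelic records. The TSV schema carries `splice_distance` explicitly
because near-splice variants cannot be impact-classified without it.

## Triage rules and their parameters

| Rule | Parameter | Default | Rationale |
|------|-----------|---------|-----------|
| frequency | `frequency_threshold` | 0.003 (proportion) | rare-disorder bound: candidate alleles should be rare in controls; *strictly greater* in the **maximum** over queried databases fails |
| impact | `near_splice_window` | 10 bases | near-splice changes beyond the window are unlikely to alter splicing |
| consensus | `consensus_rule` | majority (≥ 3 of 5) | the predictors disagree often; unanimity is tracked separately for the strongest clinical call |
| read support | `min_read_support_pct` | 10 (%) | calls on fewer than 10% of reads are likely sequencing/mapping errors; the boundary passes |
| zygosity | — | never filtered | a single defective allele can suffice for a speech-language phenotype; homozygotes may simply be more severe |
| neutral | `known_neutral` flag | — | previously confirmed neutral polymorphisms are excluded outright |

The reference analysis prints its rarity bound both as "0.3%" and as
"&lt;0.03" in its summary table; this package treats the prose value 0.003
as authoritative and leaves the alternative reading available through
`triage_config()`.

A variant is prioritized iff it has adequate read support, is not a known
neutral, carries impact class 1--3, and passes the frequency rule **or** is
rescued. Rescue has three routes: gene tier (`TIER_CAS` or `TIER_OVERLAP`
in the gene-knowledge table), exact prior-variant evidence (e.g. KIAA0319
p.Ala311Thr, known from dyslexia/SLI families), or the cross-sample pass —
genes carrying a prioritized variant in any sample of a run become genes of
interest for every other sample. Every variant, kept or excluded, carries
full provenance (`freq_pass`, `max_af`, triggering database, consensus,
impact class, rescue route), and the test suite cross-checks that
provenance against an independent scalar re-implementation of each rule.

## Report categories

The reference report does not publish a decision table; the rules here are
reverse-engineered from its six per-gene narratives and kept deliberately
small:

* **LIKELY_PATHOGENIC** — novel (absent from all four sources, no dbSNP
  id), nonsynonymous with *unanimous* (5/5) damaging calls, in a `TIER_CAS`
  gene. Both reference likely-pathogenic calls (CNTNAP2 p.Arg171Cys, FOXP1
  p.Ile107Thr) fit this pattern.
* **VUS** — any other prioritized variant in a `TIER_CAS` or `TIER_OVERLAP`
  gene: either the functional evidence is uncertain (near-splice, non-
  unanimous consensus) or the variant failed the frequency rule and was
  rescued (the ATP13A4 g.1938A>T case: strong functional evidence, but an
  allele frequency of 0.056--0.089 caps the category at VUS).
* **VUS_IN_GUS** — majority-damaging variant in a `TIER_GUS` gene.
* **NOT_REPORTABLE** — everything else, notably prioritized variants in
  genes with no catalogued association.

Two design choices deserve note. First, SETX is tiered `TIER_GUS` in the
default knowledge table: the reference's summary table prints its finding
as "VUS in GUS" even though its running text calls the gene
overlapping-phenotype; the printed category is treated as authoritative and
the discrepancy is surfaced in the cohort-report notes. Second, two-gene
("two-hit") candidate counting uses only LIKELY_PATHOGENIC and VUS
findings: with GUS findings included, four fixture participants (1, 4, 9,
10) would have two-gene findings, whereas the reference counts three
(1, 4, 10) — participant 9's second finding is a VUS in a GUS, which is
exactly the distinction the exclusion encodes.

## Phenotype rates and costs

`missing_adjusted_rate()` removes `ND` (no data) entries from the
denominator and rounds half away from zero, reproducing the published
rates (5/9 = 56% familial aggregation, 8/9 = 89% gross motor, 7/7 = 100%
oral nonverbal). Blank cells in the printed grid encode NEGATIVE; only
`ND` is missing. The published 78% rate for "either or both" language
comprehension/expression impairment does not recompute unambiguously from
the printed grid under any single either/both rule (either-or gives 8/9 =
89%; comprehension alone gives 7/9 = 78%), so it is deliberately not a
golden value here. `cost_per_diagnosis()` truncates to whole dollars,
which is what reproduces the published \$8,333 (5000/0.60) and \$16,666
(5000/0.30) exactly.

## The synthetic generator: what it emulates, what it does not

`generate_sample()` produces an exome-scale annotated table (default
116,836 variants, the reference per-sample average) in which the generator
and the rule engine are two independent encodings of the same contract:

* **Planted reportable variants** are constructed to satisfy their
  intended category's rules (e.g. a LIKELY_PATHOGENIC plant is novel,
  nonsynonymous, 5/5 damaging, in a `TIER_CAS` gene).
* **Planted prioritizable background** realizes per-class count targets
  drawn uniformly inside the reference summary's printed per-sample ranges
  (19--27 rare premature stops, 13--22 frameshift insertions, 78--101
  near-splice, class-2 total 53--66, possibly-deleterious total 238--249,
  PolyPhen/SIFT damaging-NS rows 120--152 / 111--153), in a `PGENE` pool
  with no phenotype association — prioritized but not reportable.
* **Background** variants each fail at least one named rule — common
  allele frequency (55%), trivial impact, sub-10% read support (2%), or
  confirmed-neutral flag (0.5%) — with the failing rules recorded in the
  truth table. Background lives in a disjoint `BGENE` pool so the
  cross-sample rescue pass can never promote it. Boundary-equal values
  (frequency exactly at the threshold, read support exactly 10%) are
  planted on the passing side of each rule.

Allele frequencies use a two-component mixture (absent vs. log-uniform):
the reference gives no distribution, and only threshold behavior matters
for the rules, so the mixture is chosen to exercise both sides of every
boundary. The generator does **not** simulate reads, capture coverage,
linkage, or realistic site-frequency spectra; a green synthetic test
establishes that the pipeline implements its stated rules exactly
(recall = precision = 1 against planted truth *by construction*), not that
the rules are well calibrated for real exomes. Real per-sample averages
(116,836 calls, 401 prioritized) are properties of the original cohort and
are not reproduction targets.

Determinism: a sample is a pure function of its spec (the RNG is seeded
from `spec$seed`); cohort seeds derive per-sample seeds below 2^31.

## Numerical and degenerate-input choices

* Frequency comparison is strict (`> threshold` fails), read support is
  `>=` (printed "fewer than 10%" excludes); both boundaries therefore pass.
* Consensus ties (2 damaging / 2 neutral / 1 unknown) are `discordant`,
  which never satisfies a damaging requirement.
* `near_splice` without a splice distance is an error, not a silent skip.
* Empty variant tables flow through the whole pipeline and produce valid
  empty reports; an all-`ND` phenotype column is an error naming the
  column (the rate is undefined, not 0).
* Rounding: rates half-away-from-zero to integer percent; costs floored to
  whole dollars; prioritized fraction to two decimals.

## Known limitations

* The gene-knowledge table is static input; there is no literature mining,
  segregation analysis, or pathway analysis.
* Structural variants are out of scope (as in the reference analysis).
* The report-category rules are a faithful but minimal reconstruction of a
  narrative process; real clinical review weighs evidence the model does
  not see. They are configurable via the knowledge table for that reason.
* The packaged fixture transcribes 12 printed variant records; cohort-level
  summaries derived from it (80% reportable, 2 likely pathogenic, 3
  two-gene participants) are exact reproductions, but per-class count
  summaries at exome scale are only checkable against synthetic data.
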