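# castriage

Rule-based tertiary analysis of whole-exome sequencing (WES) data for rare
pediatric motor speech disorders, centred on childhood apraxia of speech
(CAS).

After read mapping and variant calling, a clinical exome yields on the order
of 10^5 annotated variant calls per sample; only a handful are plausible
candidates for a rare disorder. `castriage` implements the interpretation
stage as a transparent, testable rule engine:

1. **Frequency deprioritization** — drop variants whose allele frequency
   exceeds a rarity bound (default 0.3%) in any of four population sources
   (dbSNP 137, ESP6500/EVS, 1000 Genomes, an in-house panel). Absence from
   all sources means the variant is novel and passes.
2. **Impact classes** — class 1: known functional; class 2 (likely
   deleterious): premature stop, start loss, canonical splice, stop
   read-through, frameshift indels; class 3 (possibly deleterious):
   near-splice (≤ 10 bases), in-frame indels, and nonsynonymous changes
   called damaging by a ≥ 3-of-5 consensus of PROVEAN, SIFT, Mutation
   Assessor, Condel and PolyPhen-2.
3. **Read support** — drop calls supported by fewer than 10% of reads
   (likely sequencing/mapping errors).
4. **Zygosity** — annotated and reported, never filtered.
5. **Known-gene rescue** — variants failing the frequency rule are kept when
   their gene is tiered as CAS-associated or overlapping-phenotype in a
   gene-knowledge table, when the exact variant has prior phenotype
   association, or when the gene was flagged in another sample of the run.
6. **Neutral exclusion** — drop variants previously confirmed to be neutral
   polymorphisms.

Surviving variants receive ACMG-style clinical report categories:
**likely pathogenic** (novel, unanimously damaging nonsynonymous change in a
causally associated gene), **VUS** (variant of uncertain significance in an
associated or overlapping-phenotype gene), or **VUS in GUS** (predicted
damaging in a gene of uncertain significance). Cohort summaries cover
shared variants, two-gene ("two-hit") candidates, missing-data-adjusted
phenotype rates and cost-per-diagnosis arithmetic. A seeded synthetic
annotated-exome generator plants ground truth so the whole pipeline is
verifiable end to end without any external data.

## Worked example

```r
library(castriage)

fx  <- load_cohort_fixture()          # packaged 10-participant reference cohort
pri <- prioritize_cohort(fx$variants) # six-rule triage with provenance
rep <- build_cohort_report(assign_report_category(pri), fx$participants)
print(rep)
```

```
CAS cohort clinical report
  participants: 10; with reportable finding: 8 (80%)
  likely-pathogenic participants: 2; two-gene participants: 3
  findings: 12 in 6 genes on 5 chromosomes
  shared variants:
    ATP13A4 g.1938A>T: participants 1, 2, 4
    KIAA0319 c.931G>A: participants 1, 9, 10
    CNTNAP2 c.3714-7insTTG: participants 4, 10
  note: SETX findings are categorized VUS_IN_GUS (as printed in the
  reference report) although its phenotype (AOA2) overlaps CAS.
```

8 of 10 participants carry reportable findings; the two likely-pathogenic
calls are the novel CNTNAP2 p.Arg171Cys and FOXP1 p.Ile107Thr variants
(participants 6 and 8); three participants have findings in two genes,
consistent with a two-hit mechanism.

```r
sapply(phenotype_rates(load_phenotype_fixture()), `[[`, "percent")
#>       familial      cognitive          onset  comprehension     expression
#>             56             30            100             78             78
#>    gross_motor oral_nonverbal
#>             89            100

cost_per_diagnosis(5000, 0.60)   # $8,333  per WES diagnosis at a 60% rate
cost_per_diagnosis(2250, 0.04)   # $56,250 per single-gene diagnosis at 4%
prioritized_fraction(401, 116836) # 0.34 — percent of calls surviving triage
```

Synthetic data with planted truth:

```r
sp  <- synthetic_spec(n_variants = 120000, seed = 42,
                      planted_reportable = data.frame(
                        gene = "CNTNAP2", category = "LIKELY_PATHOGENIC"))
smp <- generate_sample(sp)
pri <- prioritize_sample(smp$variants, keep_all = TRUE)
identical(pri$prioritized, smp$truth$should_prioritize)  # TRUE
```

## Command line

```sh
Rscript inst/cli/castriage triage --variants cohort.tsv --out results/
Rscript inst/cli/castriage simulate --out sim/ --seed 7
Rscript inst/cli/castriage phenotype --table phenotypes.tsv --out rates.json
```

## Layout

- `R/` — variant model and dialects (`variant-model.R`, `io.R`,
  `fixtures.R`), triage rules (`prioritization.R`), clinical categories and
  cohort report (`interpretation.R`), rates and costs (`phenotype.R`),
  synthetic generator (`simulate.R`), CLI (`cli.R`).
- `inst/extdata/` — transcribed reference-cohort, phenotype and
  gene-knowledge tables.
- `vignettes/castriage-methods.Rmd` — model, assumptions, design choices.
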