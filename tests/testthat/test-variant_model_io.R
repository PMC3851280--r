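# Variant model, TSV/VCF dialects, gene knowledge, packaged fixtures.

test_that("TSV parsing maps printed table rows onto the variant model", {
  fx <- load_cohort_fixture()
  v <- fx$variants[sample_id == "1" & gene == "ATP13A4"]
  expect_equal(nrow(v), 1L)
  expect_equal(v$af_evs, 0.0886)
  expect_equal(v$af_tgp, 0.05576)
  expect_identical(v$dbsnp_id, "rs35424709")
  expect_identical(v$zygosity, "heterozygous")
  expect_equal(v$reads_pct, 60.47)
  expect_equal(v$depth, 43L)
  expect_identical(v$protein_change, "p.Glu646Asp")

  # "Not found" frequency cells are ABSENT (NA), never 0
  novel <- fx$variants[gene == "FOXP1"]
  expect_true(all(is.na(novel[, .(af_dbsnp, af_evs, af_tgp, af_inhouse)])))
  expect_true(is.na(novel$dbsnp_id))
})

test_that("empty file with a valid header parses to an empty table", {
  path <- tempfile(fileext = ".tsv")
  write_variant_tsv(empty_variant_table(), path)
  v <- read_variant_tsv(path)
  expect_equal(nrow(v), 0L)
  expect_identical(names(v), variant_columns())
})

test_that("schema violations are reported by name and line", {
  path <- tempfile(fileext = ".tsv")
  v <- make_variant()
  tab <- data.table::copy(v)[, gene := NULL]
  data.table::fwrite(tab, path, sep = "\t")
  expect_error(read_variant_tsv(path), "gene")

  tab <- data.table::copy(v)
  tab[, af_evs := "zero point five"]
  data.table::fwrite(tab, path, sep = "\t", na = "NA")
  expect_error(read_variant_tsv(path), "af_evs.*line 2")

  tab <- data.table::copy(v)
  tab[, consequence := "missense"]
  data.table::fwrite(tab, path, sep = "\t", na = "NA")
  expect_error(read_variant_tsv(path), "nonsynonymous")  # lists accepted
})

test_that("write/parse round-trips a variant table field-for-field", {
  set.seed(11)
  vt <- generate_sample(synthetic_spec(n_variants = 400, seed = 11))$variants
  path <- tempfile(fileext = ".tsv")
  write_variant_tsv(vt, path)
  back <- read_variant_tsv(path)
  expect_equal(back, vt)
})

test_that("variant table invariants are enforced", {
  expect_error(make_variant(reads_pct = 101), "reads_pct")
  expect_error(make_variant(depth = 0L), "depth")
  expect_error(make_variant(af_tgp = 1.2), "af_tgp")
  expect_error(make_variant(start = 10L, end = 5L), "start > end")
  expect_error(make_variant(zygosity = "triploid"), "zygosity")
})

test_that("gene knowledge: defaults, lookups, duplicate and tier errors", {
  kt <- default_gene_knowledge()
  expect_identical(gene_tier(kt, "CNTNAP2"), "TIER_CAS")
  expect_identical(gene_tier(kt, "KIAA0319"), "TIER_OVERLAP")
  expect_match(kt[kt$gene == "CNTNAP2", ]$phenotype_note,
               "Intellectual delay, ASD, CAS")
  expect_match(kt[kt$gene == "KIAA0319", ]$phenotype_note,
               "Developmental dyslexia, SLI")
  # unlisted genes default to TIER_NONE; empty table maps everything there
  expect_identical(gene_tier(kt, "NOT_A_GENE"), "TIER_NONE")
  empty <- as_gene_knowledge(data.frame(gene = character(),
                                        tier = character()))
  expect_identical(gene_tier(empty, c("FOXP1", "SETX")),
                   c("TIER_NONE", "TIER_NONE"))

  expect_error(as_gene_knowledge(data.frame(
    gene = c("A", "A"), tier = "TIER_CAS")), "duplicate")
  expect_error(as_gene_knowledge(data.frame(
    gene = "A", tier = "TIER_MAYBE")), "tier")
})

test_that("gene knowledge round-trips through YAML", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "- gene: KIAA0319",
    "  tier: TIER_OVERLAP",
    "  phenotype_note: Developmental dyslexia, SLI",
    "  prior_variants:",
    "    - p.Ala311Thr",
    "    - c.931G>A",
    "- gene: CNTNAP1",
    "  tier: TIER_GUS"), path)
  kt <- read_gene_knowledge(path)
  expect_identical(gene_tier(kt, "KIAA0319"), "TIER_OVERLAP")
  expect_identical(kt$prior_variants[1L], "p.Ala311Thr,c.931G>A")
})

test_that("packaged cohort fixture matches the printed tables", {
  fx <- load_cohort_fixture()
  expect_equal(nrow(fx$variants), 12L)  # 12 printed records
  expect_setequal(unique(fx$variants$gene),
                  c("ATP13A4", "KIAA0319", "CNTNAP2", "CNTNAP1", "FOXP1",
                    "SETX"))
  expect_length(unique(fx$variants$gene), 6L)
  expect_setequal(unique(fx$variants$chrom),
                  c("Chr3", "Chr6", "Chr7", "Chr9", "Chr17"))
  expect_setequal(setdiff(fx$participants, fx$variants$sample_id),
                  c("3", "5"))
  # golden spot-checks against printed cells
  setx <- fx$variants[gene == "SETX"]
  expect_equal(setx$af_evs, 0.0009)
  expect_equal(setx$af_tgp, 0.0096)
  expect_equal(setx$depth, 191L)
  p6 <- fx$variants[sample_id == "6"]
  expect_equal(p6$reads_pct, 38.46)
  expect_identical(p6$nucleotide_desc, "c.511C>T")
  ins <- fx$variants[nucleotide_desc == "c.3714-7insTTG"]
  expect_equal(nrow(ins), 2L)
  expect_identical(unique(ins$consequence), "near_splice")
  expect_equal(unique(ins$splice_distance), 7L)
  expect_equal(unique(ins$start), 148106475L)
  expect_equal(unique(ins$end), 148106477L)
})

test_that("VCF dialect maps onto the same model, splitting multi-allelics", {
  skip_if_not_installed("VariantAnnotation")
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=NUCDESC,Number=A,Type=String,Description=\"HGVS\">",
    "##INFO=<ID=PROT,Number=A,Type=String,Description=\"Protein\">",
    "##INFO=<ID=READSPCT,Number=A,Type=Float,Description=\"Read support\">",
    "##INFO=<ID=AF_EVS,Number=A,Type=Float,Description=\"EVS AF\">",
    "##INFO=<ID=AF_TGP,Number=A,Type=Float,Description=\"TGP AF\">",
    "##INFO=<ID=PROVEAN,Number=A,Type=String,Description=\"call\">",
    "##INFO=<ID=SIFT,Number=A,Type=String,Description=\"call\">",
    "##INFO=<ID=MA,Number=A,Type=String,Description=\"call\">",
    "##INFO=<ID=CONDEL,Number=A,Type=String,Description=\"call\">",
    "##INFO=<ID=PP2,Number=A,Type=String,Description=\"call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1",
    paste0("Chr7\t146372040\t.\tC\tT\t50\tPASS\t",
           "GENE=CNTNAP2;CSQ=nonsynonymous;NUCDESC=c.511C>T;",
           "PROT=p.Arg171Cys;READSPCT=38.46;PROVEAN=damaging;",
           "SIFT=damaging;MA=damaging;CONDEL=damaging;PP2=damaging",
           "\tGT:DP\t0/1:52"),
    paste0("Chr3\t193171979\trs35424709\tA\tT,G\t50\tPASS\t",
           "GENE=ATP13A4,ATP13A4;CSQ=nonsynonymous,nonsynonymous;",
           "NUCDESC=g.1938A>T,g.1938A>G;PROT=p.Glu646Asp,p.Glu646Gly;",
           "READSPCT=60.47,10.0;AF_EVS=0.0886,.;AF_TGP=0.05576,.;",
           "PROVEAN=neutral,neutral;SIFT=neutral,neutral;",
           "MA=damaging,neutral;CONDEL=damaging,neutral;",
           "PP2=damaging,neutral\tGT:DP\t0/1:43")), path)
  v <- suppressWarnings(read_variant_vcf(path))
  expect_equal(nrow(v), 3L)  # multi-allelic record split per ALT
  expect_identical(unique(v$sample_id), "P1")
  cn <- v[gene == "CNTNAP2"]
  expect_identical(cn$nucleotide_desc, "c.511C>T")
  expect_equal(cn$reads_pct, 38.46)
  expect_equal(cn$depth, 52L)
  expect_identical(cn$zygosity, "heterozygous")
  atp <- v[nucleotide_desc == "g.1938A>T"]
  expect_equal(atp$af_evs, 0.0886)
  expect_identical(atp$dbsnp_id, "rs35424709")
  expect_identical(atp$mutation_assessor, "damaging")
  # triage result agrees across dialects for the shared record
  expect_identical(
    classify_impact(cn), classify_impact(make_variant(
      gene = "CNTNAP2", provean = "damaging", sift = "damaging",
      mutation_assessor = "damaging", condel = "damaging",
      polyphen2 = "damaging")))
})
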