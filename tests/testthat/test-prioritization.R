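# The six triage rules, impact classes, provenance and class summaries.

test_that("frequency rule: max across databases, strictly-greater fails", {
  # printed KIAA0319 frequencies: deprioritized at the 0.3% bound
  v <- make_variant(af_evs = 0.427, af_tgp = 0.234, dbsnp_id = "rs4504469")
  fp <- frequency_pass(v, threshold = 0.003)
  expect_false(fp$pass)
  expect_equal(fp$max_af, 0.427)
  expect_identical(fp$max_af_db, "EVS6500")

  # absent everywhere -> novel -> passes
  fp <- frequency_pass(make_variant())
  expect_true(fp$pass)
  expect_true(is.na(fp$max_af))

  # one database over the bound suffices (printed SETX frequencies)
  fp <- frequency_pass(make_variant(af_evs = 0.0009, af_tgp = 0.0096),
                       threshold = 0.003)
  expect_false(fp$pass)
  expect_identical(fp$max_af_db, "TGP")

  # boundary-equal passes; restricting databases changes the verdict
  expect_true(frequency_pass(make_variant(af_evs = 0.003))$pass)
  expect_false(frequency_pass(make_variant(af_evs = 0.0031))$pass)
  expect_true(frequency_pass(make_variant(af_tgp = 0.0096),
                             databases = c("dbSNP137", "EVS6500"))$pass)
  expect_error(frequency_pass(make_variant(), databases = "gnomAD"),
               "unknown database")
})

test_that("read-support rule: fewer than min_pct fails, boundary passes", {
  v <- make_variants(make_variant(reads_pct = 38.46),
                     make_variant(reads_pct = 10),
                     make_variant(reads_pct = 9.99))
  expect_identical(read_support_pass(v), c(TRUE, TRUE, FALSE))
  expect_identical(read_support_pass(v, min_pct = 40), c(FALSE, FALSE, FALSE))
})

test_that("predictor consensus: majority of five, unanimity tracked", {
  cases <- list(
    list(calls = rep("damaging", 5), consensus = "damaging",
         unanimous = TRUE),
    # 3-of-5 majority despite two neutral calls
    list(calls = c("neutral", "neutral", "damaging", "damaging",
                   "damaging"), consensus = "damaging", unanimous = FALSE),
    # the 2-damaging / 3-neutral split resolves neutral
    list(calls = c("neutral", "neutral", "damaging", "damaging",
                   "neutral"), consensus = "neutral", unanimous = FALSE),
    list(calls = rep("unknown", 5), consensus = "unknown",
         unanimous = FALSE),
    list(calls = c("damaging", "damaging", "neutral", "neutral",
                   "unknown"), consensus = "discordant", unanimous = FALSE))
  for (cs in cases) {
    got <- predictor_consensus(with_predictors(make_variant(), cs$calls))
    expect_identical(got$consensus, cs$consensus)
    expect_identical(got$unanimous_damaging, cs$unanimous)
  }
})

test_that("impact classes follow the consequence taxonomy", {
  expect_identical(classify_impact(make_variant(
    consequence = "premature_stop")), "CLASS2_LIKELY_DELETERIOUS")
  for (csq in c("start_loss", "canonical_splice", "stop_readthrough",
                "frameshift_insertion", "frameshift_deletion")) {
    expect_identical(classify_impact(make_variant(consequence = csq)),
                     "CLASS2_LIKELY_DELETERIOUS")
  }
  expect_identical(classify_impact(make_variant(
    consequence = "known_functional")), "CLASS1_KNOWN_FUNCTIONAL")
  dam <- with_predictors(make_variant(), rep("damaging", 5))
  expect_identical(classify_impact(dam), "CLASS3_POSSIBLY_DELETERIOUS")
  neu <- with_predictors(make_variant(), rep("neutral", 5))
  expect_identical(classify_impact(neu), "UNPRIORITIZED")
  expect_identical(classify_impact(make_variant(consequence = "other")),
                   "UNPRIORITIZED")
  # near-splice: inside the 10-base window only; distance is mandatory
  expect_identical(classify_impact(make_variant(
    consequence = "near_splice", splice_distance = 7L)),
    "CLASS3_POSSIBLY_DELETERIOUS")
  expect_identical(classify_impact(make_variant(
    consequence = "near_splice", splice_distance = 11L)), "UNPRIORITIZED")
  expect_error(classify_impact(make_variant(consequence = "near_splice")),
               "splice_distance")
})

test_that("prioritize_sample: rescue, neutral exclusion, read support", {
  kt <- default_gene_knowledge()
  # frequency-failed KIAA0319 record rescued via tier + prior evidence
  kia <- with_predictors(make_variant(
    gene = "KIAA0319", af_evs = 0.427, af_tgp = 0.234,
    dbsnp_id = "rs4504469", protein_change = "p.Ala311Thr"),
    rep("damaging", 5))
  out <- prioritize_sample(kia, kt)
  expect_equal(nrow(out), 1L)
  expect_false(out$freq_pass)
  expect_true(out$rescued_by_gene)
  expect_true(out$prior_variant_evidence)

  # known neutral polymorphism is excluded even in a strongly associated gene
  neutral <- with_predictors(make_variant(gene = "CNTNAP2",
                                          known_neutral = TRUE),
                             rep("damaging", 5))
  expect_equal(nrow(prioritize_sample(neutral, kt)), 0L)

  # low read support dominates every rescue route
  low <- with_predictors(make_variant(gene = "CNTNAP2", reads_pct = 5),
                         rep("damaging", 5))
  expect_equal(nrow(prioritize_sample(low, kt)), 0L)

  # zygosity never filters
  hom <- with_predictors(make_variant(gene = "CNTNAP2",
                                      zygosity = "homozygous"),
                         rep("damaging", 5))
  expect_equal(nrow(prioritize_sample(hom, kt)), 1L)

  expect_error(prioritize_sample(make_variants(
    make_variant(sample_id = "A"), make_variant(sample_id = "B"))),
    "single sample")
})

test_that("cross-sample pass rescues genes of interest from other samples", {
  kt <- as_gene_knowledge(data.frame(gene = "NOVELGENE",
                                     tier = "TIER_NONE"))
  # sample A: novel damaging variant in NOVELGENE -> prioritized
  a <- with_predictors(make_variant(sample_id = "A", gene = "NOVELGENE"),
                       rep("damaging", 5))
  # sample B: same gene but frequency-failed -> only kept by the second pass
  b <- with_predictors(make_variant(sample_id = "B", gene = "NOVELGENE",
                                    af_evs = 0.01, dbsnp_id = "rs1"),
                       rep("damaging", 5))
  both <- make_variants(a, b)
  with_pass <- prioritize_cohort(both, kt)
  expect_setequal(with_pass$sample_id, c("A", "B"))
  without <- prioritize_cohort(both, kt, cross_sample_rescue = FALSE)
  expect_identical(without$sample_id, "A")
})

test_that("provenance matches an independent rule-by-rule re-check", {
  set.seed(202)
  cfg <- triage_config()
  kt <- default_gene_knowledge()
  smp <- generate_sample(synthetic_spec(n_variants = 600, seed = 202,
    planted_reportable = data.frame(
      gene = c("FOXP1", "KIAA0319"),
      category = c("LIKELY_PATHOGENIC", "VUS"))))
  got <- prioritize_sample(smp$variants, kt, cfg, keep_all = TRUE)
  ref <- brute_force_rules(smp$variants, kt, cfg)
  expect_identical(got$freq_pass, ref$freq_ok)
  expect_identical(got$read_support_pass, ref$rs_ok)
  expect_identical(substr(got$impact_class, 1, 6),
                   substr(ref$impact, 1, 6))
  expect_identical(got$prioritized, ref$prioritized)
  # every excluded variant fails at least one independently-verified rule
  excl <- !got$prioritized
  expect_true(all((!ref$freq_ok[excl] & !ref$rescued[excl]) |
                    !ref$rs_ok[excl] |
                    smp$variants$known_neutral[excl] |
                    ref$impact[excl] == "UNPRIORITIZED"))
})

test_that("monotonicity: thresholds move the prioritized set one way", {
  set.seed(77)
  smp <- generate_sample(synthetic_spec(n_variants = 3000, seed = 77))
  thresholds <- sort(runif(5, 0.0001, 0.4))
  sizes <- vapply(thresholds, function(th) {
    nrow(prioritize_sample(smp$variants,
                           config = triage_config(frequency_threshold = th)))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))  # raising the AF bound never shrinks

  supports <- sort(runif(5, 0, 100))
  sizes <- vapply(supports, function(ms) {
    nrow(prioritize_sample(smp$variants,
                           config = triage_config(min_read_support_pct = ms)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))  # raising min support never grows
})

test_that("prioritization is invariant to input row order", {
  set.seed(31)
  smp <- generate_sample(synthetic_spec(n_variants = 1500, seed = 31))
  a <- prioritize_sample(smp$variants)
  perm <- sample.int(nrow(smp$variants))
  b <- prioritize_sample(smp$variants[perm])
  key <- c("chrom", "start", "gene", "nucleotide_desc")
  data.table::setorderv(a, key)
  data.table::setorderv(b, key)
  expect_equal(a, b)
})

test_that("summarize_classes counts genes and variants per subcategory", {
  kt <- default_gene_knowledge()
  # 20 rare premature stops in 17 genes (3 genes carry 2 variants)
  genes <- c(sprintf("G%02d", 1:17), "G01", "G02", "G03")
  rows <- lapply(genes, function(g) make_variant(
    gene = g, consequence = "premature_stop",
    nucleotide_desc = paste0("c.", which(genes == g)[1], "C>T")))
  vt <- data.table::rbindlist(rows)
  pri <- prioritize_sample(vt, kt)
  sc <- summarize_classes(pri)
  row <- sc[sc$subcategory == "rare_premature_stop", ]
  expect_equal(row$gene_count, 17L)
  expect_equal(row$variant_count, 20L)
  expect_equal(sc[sc$subcategory == "highly_likely_deleterious_rare",
                  ]$variant_count, 20L)

  # singleton frameshift insertion
  one <- prioritize_sample(make_variant(consequence = "frameshift_insertion"),
                           kt)
  sc1 <- summarize_classes(one)
  expect_equal(sc1[sc1$subcategory == "rare_frameshift_insertion",
                   ]$variant_count, 1L)
  expect_equal(sc1[sc1$subcategory == "rare_frameshift_insertion",
                   ]$gene_count, 1L)

  # empty input -> all-zero counts; gene count never exceeds variant count
  sc0 <- summarize_classes(prioritize_sample(empty_variant_table(), kt))
  expect_true(all(sc0$variant_count == 0L))
  expect_true(all(sc0$gene_count == 0L))
  expect_true(all(sc$gene_count <= sc$variant_count))
})
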