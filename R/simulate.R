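# Synthetic annotated-exome generator with planted ground truth.
#
# The generator and the triage rules are two independent encodings of the
# same contract: every generated variant either satisfies all prioritization
# rules by construction (planted) or is engineered to fail at least one
# named rule (background), so the prioritized set on a synthetic sample can
# be compared against planted truth exactly.

#' Specification for one synthetic annotated exome
#'
#' Defaults emulate the reference analysis' per-sample shape: about 116,836
#' high-quality called variants, of which a few hundred survive triage, with
#' per-class counts drawn uniformly within the reference summary's printed
#' per-sample ranges (e.g. 19-27 rare premature stops, 78-101 intronic
#' near-splice, possibly-deleterious total 238-249).
#'
#' @param n_variants Total variants in the sample (default 116836).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @param class_counts Optional named list of exact per-class counts
#'   (`premature_stop`, `readthrough`, `start_codon`, `splice`,
#'   `frameshift_insertion`, `frameshift_deletion`, `inframe_insertion`,
#'   `inframe_deletion`, `near_splice`, `ns_damaging`, `polyphen_damaging`,
#'   `sift_damaging`); drawn within the reference ranges when `NULL`.
#' @param planted_reportable Optional data.frame with columns `gene` and
#'   `category` (`LIKELY_PATHOGENIC`, `VUS`, `VUS_IN_GUS`): clinically
#'   reportable variants planted so they satisfy their intended category's
#'   rules by construction.
#' @param low_support_fraction Fraction of background variants given read
#'   support below 10% (sequencing-error contaminant; default 0.02).
#' @param known_neutral_fraction Fraction of background variants flagged as
#'   confirmed neutral polymorphisms (default 0.005).
#' @param common_fraction Fraction of background variants given an allele
#'   frequency above the rarity threshold (default 0.55).
#' @param frequency_threshold Rarity bound used when generating allele
#'   frequencies (default 0.003, matching [triage_config()]).
#' @return A list of class `synthetic_spec`.
#' @export
#' @examples
#' sp <- synthetic_spec(n_variants = 5000, seed = 7)
#' smp <- generate_sample(sp)
#' nrow(smp$variants)
synthetic_spec <- function(n_variants = 116836L, seed = 1L,
                           class_counts = NULL, planted_reportable = NULL,
                           low_support_fraction = 0.02,
                           known_neutral_fraction = 0.005,
                           common_fraction = 0.55,
                           frequency_threshold = 0.003) {
  stopifnot(n_variants >= 1L, low_support_fraction >= 0,
            low_support_fraction < 1, known_neutral_fraction >= 0,
            common_fraction >= 0, common_fraction < 1,
            frequency_threshold > 0, frequency_threshold < 1)
  if (!is.null(planted_reportable)) {
    planted_reportable <- as.data.table(planted_reportable)
    stopifnot(all(c("gene", "category") %in% names(planted_reportable)))
    bad <- setdiff(planted_reportable$category,
                   c("LIKELY_PATHOGENIC", "VUS", "VUS_IN_GUS"))
    if (length(bad) > 0L) {
      stop("unknown planted category: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(n_variants = as.integer(n_variants), seed = as.integer(seed),
                 class_counts = class_counts,
                 planted_reportable = planted_reportable,
                 low_support_fraction = low_support_fraction,
                 known_neutral_fraction = known_neutral_fraction,
                 common_fraction = common_fraction,
                 frequency_threshold = frequency_threshold),
            class = "synthetic_spec")
}

# reference per-sample variant-count ranges for the planted classes
CLASS_RANGES <- list(
  premature_stop = c(19L, 27L), readthrough = c(0L, 1L),
  start_codon = c(0L, 1L), splice = c(3L, 8L),
  frameshift_insertion = c(13L, 22L), frameshift_deletion = c(6L, 17L),
  class2_total = c(53L, 66L),
  inframe_insertion = c(0L, 6L), inframe_deletion = c(0L, 6L),
  near_splice = c(78L, 101L), possibly_total = c(238L, 249L),
  polyphen_damaging = c(120L, 152L), sift_damaging = c(111L, 153L)
)

runifint <- function(n, lo, hi) lo + sample.int(hi - lo + 1L, n,
                                                replace = TRUE) - 1L

# draw class targets inside the printed ranges, net of the contributions the
# planted reportable variants will make to the same summary rows
draw_class_targets <- function(k_class3_rare, k_near_splice, k_pp, k_sift) {
  repeat {  # class-2 subcounts conditioned on their printed total range
    ps <- runifint(1, 19L, 27L); rt <- runifint(1, 0L, 1L)
    sc <- runifint(1, 0L, 1L); sp <- runifint(1, 3L, 8L)
    fi <- runifint(1, 13L, 22L); fd <- runifint(1, 6L, 17L)
    if ((ps + rt + sc + sp + fi + fd) >= 53L &&
        (ps + rt + sc + sp + fi + fd) <= 66L) break
  }
  ii <- runifint(1, 0L, 6L); id <- runifint(1, 0L, 6L)
  nsp_row <- runifint(1, 78L, 101L)
  nsp <- nsp_row - k_near_splice          # background near-splice count
  possibly <- runifint(1, 238L, 249L)
  ns_dam <- possibly - ii - id - nsp_row - (k_class3_rare - k_near_splice)
  pp_row <- runifint(1, 120L, min(152L, ns_dam + k_pp))
  sift_row <- runifint(1, 111L, min(153L, ns_dam + k_sift))
  list(premature_stop = ps, readthrough = rt, start_codon = sc, splice = sp,
       frameshift_insertion = fi, frameshift_deletion = fd,
       inframe_insertion = ii, inframe_deletion = id, near_splice = nsp,
       ns_damaging = ns_dam,
       polyphen_damaging = max(0L, pp_row - k_pp),
       sift_damaging = max(0L, sift_row - k_sift))
}

# allele-frequency helpers -------------------------------------------------

# rare profile: each database independently absent or present with a
# log-uniform frequency at or below the threshold (boundary-equal passes)
rare_af_matrix <- function(n, threshold) {
  m <- matrix(NA_real_, n, 4L)
  for (j in 1:4) {
    present <- runif(n) < 0.4
    m[present, j] <- signif(10^runif(sum(present), -5,
                                     log10(threshold)), 4)
  }
  m
}

# common profile: guaranteed above the threshold in at least one database
common_af_matrix <- function(n, threshold) {
  m <- rare_af_matrix(n, threshold)
  m[, 2L] <- signif(10^runif(n, log10(threshold) + 0.01, log10(0.5)), 4)
  m
}

synthetic_block <- function(n, sample_id, gene_pool, consequence,
                            af = c("rare", "common", "novel"),
                            predictors = "unknown",
                            reads = c("good", "low"),
                            known_neutral = FALSE, threshold = 0.003,
                            splice_distance = NA_integer_) {
  af <- match.arg(af)
  reads <- match.arg(reads)
  if (n == 0L) return(NULL)
  afm <- switch(af,
                rare = rare_af_matrix(n, threshold),
                common = common_af_matrix(n, threshold),
                novel = matrix(NA_real_, n, 4L))
  dbid <- rep(NA_character_, n)
  if (af == "rare") {
    has_id <- runif(n) < 0.3
    dbid[has_id] <- sprintf("rs%08d", sample.int(9e7, sum(has_id)))
  } else if (af == "common") {
    has_id <- runif(n) < 0.9
    dbid[has_id] <- sprintf("rs%08d", sample.int(9e7, sum(has_id)))
  }
  pm <- matrix("unknown", n, 5L,
               dimnames = list(NULL, PREDICTORS))
  if (identical(predictors, "damaging3")) {
    pm[, c("provean", "mutation_assessor", "condel")] <- "damaging"
    pm[, c("sift", "polyphen2")] <- "neutral"
  } else if (identical(predictors, "damaging5")) {
    pm[] <- "damaging"
  } else if (identical(predictors, "neutral")) {
    pm[, sample(5L, 3L)] <- "neutral"
    extra <- runif(n)
    pm[extra < 0.3, ] <- "neutral"
  } else if (identical(predictors, "mixed")) {
    # roughly half damaging-consensus, half neutral-consensus
    dam <- runif(n) < 0.5
    pm[dam, c("provean", "mutation_assessor", "condel")] <- "damaging"
    pm[dam, c("sift", "polyphen2")] <- "neutral"
    pm[!dam, c("provean", "sift", "polyphen2")] <- "neutral"
    pm[!dam, c("mutation_assessor", "condel")] <- "damaging"
  } else if (identical(predictors, "discordant")) {
    pm[, c("provean", "sift")] <- "damaging"
    pm[, c("mutation_assessor", "condel")] <- "neutral"
  }
  reads_pct <- if (reads == "good") round(runif(n, 12, 98), 2)
               else round(runif(n, 0, 9.99), 2)
  zyg <- sample(ZYGOSITIES, n, replace = TRUE, prob = c(0.88, 0.10, 0.02))
  start <- sample.int(240000000L, n, replace = TRUE)
  data.table(
    sample_id = sample_id,
    chrom = sample(c(paste0("Chr", 1:22), "ChrX"), n, replace = TRUE),
    start = start, end = start,
    gene = sample(gene_pool, n, replace = TRUE),
    consequence = if (length(consequence) == 1L) consequence
                  else sample(consequence, n, replace = TRUE),
    nucleotide_desc = sprintf("c.%dA>G", sample.int(9000L, n,
                                                    replace = TRUE)),
    protein_change = NA_character_,
    zygosity = zyg, reads_pct = reads_pct,
    depth = rpois(n, 80) + 1L,
    af_dbsnp = afm[, 1L], af_evs = afm[, 2L], af_tgp = afm[, 3L],
    af_inhouse = afm[, 4L], dbsnp_id = dbid,
    provean = pm[, "provean"], sift = pm[, "sift"],
    mutation_assessor = pm[, "mutation_assessor"],
    condel = pm[, "condel"], polyphen2 = pm[, "polyphen2"],
    known_neutral = known_neutral,
    splice_distance = splice_distance)
}

# one planted reportable variant satisfying its intended category's rules
reportable_variant <- function(sample_id, gene, category, knowledge,
                               threshold) {
  tier <- gene_tier(knowledge, gene)
  start <- sample.int(240000000L, 1L)
  base <- data.table(
    sample_id = sample_id, chrom = sample(paste0("Chr", 1:22), 1L),
    start = start, end = start, gene = gene,
    consequence = "nonsynonymous",
    nucleotide_desc = sprintf("c.%dG>A", sample.int(9000L, 1L)),
    protein_change = sprintf("p.Ala%dThr", sample.int(1500L, 1L)),
    zygosity = "heterozygous",
    reads_pct = round(runif(1, 30, 95), 2), depth = rpois(1, 60) + 10L,
    af_dbsnp = NA_real_, af_evs = NA_real_, af_tgp = NA_real_,
    af_inhouse = NA_real_, dbsnp_id = NA_character_,
    provean = "damaging", sift = "damaging",
    mutation_assessor = "damaging", condel = "damaging",
    polyphen2 = "damaging", known_neutral = FALSE,
    splice_distance = NA_integer_)
  if (category == "LIKELY_PATHOGENIC") {
    if (tier != "TIER_CAS") {
      stop("a LIKELY_PATHOGENIC variant needs a TIER_CAS gene, but ", gene,
           " is ", tier, call. = FALSE)
    }
    return(base)  # novel, nonsynonymous, unanimous damaging, TIER_CAS
  }
  if (category == "VUS") {
    if (tier == "TIER_CAS") {
      # uncertain functional impact: novel near-splice insertion
      base[, `:=`(consequence = "near_splice",
                  nucleotide_desc = sprintf("c.%d-%dinsTTG",
                                            sample.int(9000L, 1L),
                                            runifint(1, 3L, 7L)),
                  protein_change = NA_character_,
                  provean = "unknown", sift = "unknown",
                  mutation_assessor = "unknown", condel = "unknown",
                  polyphen2 = "unknown",
                  splice_distance = runifint(1, 3L, 10L))]
      return(base)
    }
    if (tier == "TIER_OVERLAP") {
      # frequency-failed, rescued by the gene's phenotype association
      base[, `:=`(af_evs = signif(10^runif(1, log10(threshold) + 0.3,
                                           log10(0.45)), 3),
                  af_tgp = signif(10^runif(1, log10(threshold) + 0.1,
                                           log10(0.3)), 3),
                  dbsnp_id = sprintf("rs%07d", sample.int(9e6, 1L)))]
      return(base)
    }
    stop("a VUS needs a TIER_CAS or TIER_OVERLAP gene, but ", gene, " is ",
         tier, call. = FALSE)
  }
  # VUS_IN_GUS: novel, damaging by majority but not unanimously, TIER_GUS
  if (tier != "TIER_GUS") {
    stop("a VUS_IN_GUS variant needs a TIER_GUS gene, but ", gene, " is ",
         tier, call. = FALSE)
  }
  base[, `:=`(sift = "neutral", polyphen2 = "neutral")]
  base
}

#' Generate one synthetic annotated exome with planted truth
#'
#' Deterministic for a fixed spec (the RNG is seeded from `spec$seed`).
#' The sample contains (a) the planted reportable variants, constructed to
#' satisfy their intended report category's rules; (b) planted
#' prioritizable background variants realizing the per-class count targets
#' (rare, adequately supported, impactful, in a synthetic `PGENE` pool with
#' no phenotype association, hence prioritized but not reportable); and (c)
#' background variants each engineered to fail at least one named triage
#' rule (common frequency, trivial impact, low read support or confirmed
#' neutral), in a disjoint `BGENE` pool so cross-sample rescue can never
#' promote them.
#'
#' @param spec A [synthetic_spec()].
#' @param knowledge Gene-knowledge table used for planted reportable
#'   variants (default [default_gene_knowledge()]).
#' @param sample_id Sample identifier (default `"S1"`).
#' @return A list of class `synthetic_sample`: `variants` (variant table),
#'   `truth` (`data.table` with `variant_id`, `should_prioritize`,
#'   `intended_category`, `failed_rules`, row-aligned with `variants`),
#'   `class_targets` (the realized per-class counts) and `spec`.
#' @export
generate_sample <- function(spec, knowledge = default_gene_knowledge(),
                            sample_id = "S1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  thr <- spec$frequency_threshold
  # planted reportable variants first: their contributions offset the
  # class-count targets
  rep_dt <- NULL
  rep_truth <- NULL
  if (!is.null(spec$planted_reportable) &&
      nrow(spec$planted_reportable) > 0L) {
    rep_dt <- rbindlist(lapply(seq_len(nrow(spec$planted_reportable)),
      function(i) {
        reportable_variant(sample_id, spec$planted_reportable$gene[i],
                           spec$planted_reportable$category[i], knowledge,
                           thr)
      }))
    rep_truth <- data.table(
      should_prioritize = TRUE,
      intended_category = spec$planted_reportable$category,
      failed_rules = "")
  }
  k_rare_class3 <- if (is.null(rep_dt)) 0L else
    sum(is.na(rep_dt$af_evs))                 # rare (novel) class-3 records
  k_near_splice <- if (is.null(rep_dt)) 0L else
    sum(rep_dt$consequence == "near_splice")
  k_pp <- if (is.null(rep_dt)) 0L else
    sum(rep_dt$consequence == "nonsynonymous" &
          rep_dt$polyphen2 == "damaging" & is.na(rep_dt$af_evs))
  k_sift <- if (is.null(rep_dt)) 0L else
    sum(rep_dt$consequence == "nonsynonymous" &
          rep_dt$sift == "damaging" & is.na(rep_dt$af_evs))
  targets <- spec$class_counts
  if (is.null(targets)) {
    targets <- draw_class_targets(k_rare_class3, k_near_splice, k_pp,
                                  k_sift)
  }
  pg <- sprintf("PGENE%05d", 1:20000)  # prioritized-pool gene labels
  bg <- sprintf("BGENE%05d", 1:20000)  # background-pool gene labels
  blocks <- list()
  for (csq in c("premature_stop", "readthrough", "start_codon", "splice",
                "frameshift_insertion", "frameshift_deletion",
                "inframe_insertion", "inframe_deletion")) {
    consequence <- switch(csq, readthrough = "stop_readthrough",
                          start_codon = "start_loss",
                          splice = "canonical_splice", csq)
    blocks[[csq]] <- synthetic_block(targets[[csq]], sample_id, pg,
                                     consequence, af = "rare",
                                     threshold = thr)
  }
  if (targets$near_splice > 0L) {
    ns <- synthetic_block(targets$near_splice, sample_id, pg, "near_splice",
                          af = "rare", threshold = thr)
    ns[, splice_distance := runifint(.N, 3L, 10L)]
    blocks$near_splice <- ns
  }
  if (targets$ns_damaging > 0L) {
    nd <- synthetic_block(targets$ns_damaging, sample_id, pg,
                          "nonsynonymous", af = "rare",
                          predictors = "damaging3", threshold = thr)
    # PROVEAN/MutationAssessor/Condel damaging for all (3-of-5 consensus);
    # PolyPhen-2 and SIFT damaging on subsets hitting the summary-row targets
    pp_idx <- sample.int(nrow(nd), min(targets$polyphen_damaging, nrow(nd)))
    sift_idx <- sample.int(nrow(nd), min(targets$sift_damaging, nrow(nd)))
    nd[pp_idx, polyphen2 := "damaging"]
    nd[sift_idx, sift := "damaging"]
    # exercise rule boundaries: frequency exactly at the threshold and read
    # support exactly at 10% both pass
    if (nrow(nd) >= 2L) {
      nd[1L, `:=`(af_evs = thr, af_dbsnp = NA_real_, af_tgp = NA_real_,
                  af_inhouse = NA_real_)]
      nd[2L, reads_pct := 10]
    }
    blocks$ns_damaging <- nd
  }
  planted <- rbindlist(blocks, use.names = TRUE)
  n_planted <- nrow(planted) + (if (is.null(rep_dt)) 0L else nrow(rep_dt))
  n_bg <- spec$n_variants - n_planted
  if (n_bg < 0L) {
    stop("infeasible spec: planted counts (", n_planted,
         ") exceed n_variants (", spec$n_variants, ")", call. = FALSE)
  }
  planted_truth <- data.table(should_prioritize = TRUE,
                              intended_category = "NOT_REPORTABLE",
                              failed_rules = "")[rep(1L, nrow(planted))]
  # background: every variant fails >= 1 rule by construction
  n_low <- round(spec$low_support_fraction * n_bg)
  n_kn <- round(spec$known_neutral_fraction * n_bg)
  n_common <- round(spec$common_fraction * n_bg)
  n_rest <- n_bg - n_low - n_kn - n_common
  n_rare_other <- round(0.8 * n_rest)
  n_rare_ns <- n_rest - n_rare_other
  b_low <- synthetic_block(n_low, sample_id, bg, "premature_stop",
                           af = "rare", reads = "low", threshold = thr)
  b_kn <- synthetic_block(n_kn, sample_id, bg, "nonsynonymous",
                          af = "rare", predictors = "damaging5",
                          known_neutral = TRUE, threshold = thr)
  n_common_ns <- round(0.35 * n_common)
  b_common_other <- synthetic_block(n_common - n_common_ns, sample_id, bg,
                                    c("other", "premature_stop",
                                      "canonical_splice"),
                                    af = "common", threshold = thr)
  b_common_ns <- synthetic_block(n_common_ns, sample_id, bg,
                                 "nonsynonymous", af = "common",
                                 predictors = "mixed", threshold = thr)
  b_rare_other <- synthetic_block(n_rare_other, sample_id, bg, "other",
                                  af = "rare", threshold = thr)
  n_disc <- round(0.25 * n_rare_ns)
  b_rare_ns <- synthetic_block(n_rare_ns - n_disc, sample_id, bg,
                               "nonsynonymous", af = "rare",
                               predictors = "neutral", threshold = thr)
  b_disc <- synthetic_block(n_disc, sample_id, bg, "nonsynonymous",
                            af = "rare", predictors = "discordant",
                            threshold = thr)
  failed_common_other <- {
    x <- b_common_other
    if (is.null(x)) character() else
      ifelse(x$consequence %in% CLASS2_CONSEQUENCES, "frequency",
             "frequency,impact")
  }
  failed_common_ns <- {
    x <- b_common_ns
    if (is.null(x)) character() else {
      cons <- predictor_consensus(x)$consensus
      ifelse(cons == "damaging", "frequency", "frequency,impact")
    }
  }
  bg_dt <- rbindlist(list(b_low, b_kn, b_common_other, b_common_ns,
                          b_rare_other, b_rare_ns, b_disc),
                     use.names = TRUE)
  bg_truth <- data.table(
    should_prioritize = FALSE,
    intended_category = "NOT_REPORTABLE",
    failed_rules = c(rep("read_support", n_low),
                     rep("neutral", n_kn),
                     failed_common_other, failed_common_ns,
                     rep("impact", n_rare_other),
                     rep("impact", n_rare_ns)))
  variants <- rbindlist(c(list(rep_dt, planted, bg_dt)), use.names = TRUE)
  truth <- rbindlist(list(rep_truth, planted_truth, bg_truth),
                     use.names = TRUE)
  # shuffle so planted structure is not positional
  perm <- sample.int(nrow(variants))
  variants <- variants[perm]
  truth <- truth[perm]
  truth[, variant_id := sprintf("%s_v%06d", sample_id, seq_len(.N))]
  data.table::setcolorder(truth, "variant_id")
  structure(list(variants = as_variant_table(variants), truth = truth,
                 class_targets = targets, spec = spec,
                 sample_id = sample_id),
            class = "synthetic_sample")
}

#' Generate a synthetic cohort
#'
#' Generates `n_samples` synthetic exomes from a common spec template.
#' `round(reportable_fraction * n_samples)` samples carry one or two planted
#' clinically reportable variants (categories drawn roughly in the
#' proportions of the reference cohort: mostly VUS, some likely pathogenic
#' and VUS-in-GUS); the remaining samples carry none. Per-sample seeds are
#' derived deterministically from `seed`.
#'
#' @param n_samples Number of samples (>= 1).
#' @param spec_template A [synthetic_spec()] used for every sample (its
#'   `seed` and `planted_reportable` fields are overridden per sample).
#' @param reportable_fraction Fraction of samples with planted reportable
#'   findings, in \eqn{[0,1]} (default 0.8, mirroring 8 of 10).
#' @param seed Cohort-level seed.
#' @param knowledge Gene-knowledge table for planted variants.
#' @return List of `synthetic_sample` objects, sample ids `"1"`,
#'   `"2"`, ...
#' @export
generate_cohort <- function(n_samples, spec_template = synthetic_spec(),
                            reportable_fraction = 0.8, seed = 1L,
                            knowledge = default_gene_knowledge()) {
  stopifnot(n_samples >= 1L, reportable_fraction >= 0,
            reportable_fraction <= 1)
  set.seed(seed)
  n_rep <- round(reportable_fraction * n_samples)
  rep_samples <- sort(sample.int(n_samples, n_rep))
  cas_genes <- knowledge$gene[knowledge$tier == "TIER_CAS"]
  overlap_genes <- knowledge$gene[knowledge$tier == "TIER_OVERLAP"]
  gus_genes <- knowledge$gene[knowledge$tier == "TIER_GUS"]
  plans <- vector("list", n_samples)
  for (i in rep_samples) {
    k <- 1L + rbinom(1L, 1L, 0.3)
    cats <- sample(c("LIKELY_PATHOGENIC", "VUS", "VUS_IN_GUS"), k,
                   replace = TRUE, prob = c(0.2, 0.6, 0.2))
    genes <- vapply(cats, function(cat) {
      pool <- switch(cat, LIKELY_PATHOGENIC = cas_genes,
                     VUS = c(cas_genes, overlap_genes), gus_genes)
      sample(pool, 1L)
    }, character(1L))
    # distinct genes within a sample keep two-gene counting unambiguous
    while (anyDuplicated(genes)) {
      j <- which(duplicated(genes))[1L]
      pool <- switch(cats[j], LIKELY_PATHOGENIC = cas_genes,
                     VUS = c(cas_genes, overlap_genes), gus_genes)
      if (all(pool %in% genes)) { genes <- genes[-j]; cats <- cats[-j] }
      else genes[j] <- sample(setdiff(pool, genes), 1L)
    }
    plans[[i]] <- data.table(gene = genes, category = cats)
  }
  seeds <- (abs(seed) %% 100000L) * 10007L + seq_len(n_samples)
  lapply(seq_len(n_samples), function(i) {
    sp <- spec_template
    sp$seed <- seeds[i]
    sp$planted_reportable <- plans[[i]]
    generate_sample(sp, knowledge = knowledge,
                    sample_id = as.character(i))
  })
}

#' Write a synthetic sample to disk
#'
#' Emits the canonical variant TSV (`<sample_id>_variants.tsv`) and the
#' ground-truth TSV (`<sample_id>_truth.tsv`) into `dir`.
#'
#' @param sample A `synthetic_sample`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the two paths, invisibly.
#' @export
write_synthetic_sample <- function(sample, dir) {
  stopifnot(inherits(sample, "synthetic_sample"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vpath <- file.path(dir, paste0(sample$sample_id, "_variants.tsv"))
  tpath <- file.path(dir, paste0(sample$sample_id, "_truth.tsv"))
  write_variant_tsv(sample$variants, vpath)
  fwrite(sample$truth, tpath, sep = "\t", quote = FALSE, na = "NA")
  invisible(c(vpath, tpath))
}
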