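# Rule-based variant prioritization: the six triage assumptions and the
# impact-class taxonomy, with per-variant filter provenance.

#' Triage configuration
#'
#' Bundles the tunable thresholds of the prioritization rules.
#'
#' @param frequency_threshold Allele-frequency bound as a proportion; a
#'   variant whose maximum frequency across the queried databases is
#'   *strictly greater* is deprioritized. Default 0.003 (0.3%), the rare-
#'   disorder bound used in the reference analysis. (Its summary table
#'   prints the bound as "<0.03"; that reading is available here as a
#'   configuration choice but is not the default.)
#' @param min_read_support_pct Minimum percentage of reads supporting the
#'   alternate call; variants supported by *fewer than* this percentage are
#'   deprioritized as likely sequencing/mapping errors. Default 10.
#' @param near_splice_window Maximum distance (bases) from a splice site for
#'   a `near_splice` variant to count as possibly deleterious. Default 10.
#' @param databases Allele-frequency databases to query; subset of
#'   `names(af_databases())`.
#' @param consensus_rule Predictor consensus rule; only `"majority"`
#'   (at least 3 of the 5 tools) is implemented.
#' @return A list of class `triage_config`.
#' @export
#' @examples
#' triage_config(frequency_threshold = 0.03)
triage_config <- function(frequency_threshold = 0.003,
                          min_read_support_pct = 10,
                          near_splice_window = 10L,
                          databases = names(af_databases()),
                          consensus_rule = "majority") {
  stopifnot(is.numeric(frequency_threshold), length(frequency_threshold) == 1,
            frequency_threshold > 0, frequency_threshold < 1,
            is.numeric(min_read_support_pct), min_read_support_pct >= 0,
            min_read_support_pct <= 100, near_splice_window >= 0)
  consensus_rule <- match.arg(consensus_rule, "majority")
  unknown <- setdiff(databases, names(af_databases()))
  if (length(unknown) > 0L) {
    stop("unknown database name(s): ", paste(unknown, collapse = ", "),
         "; known: ", paste(names(af_databases()), collapse = ", "),
         call. = FALSE)
  }
  structure(list(frequency_threshold = frequency_threshold,
                 min_read_support_pct = min_read_support_pct,
                 near_splice_window = as.integer(near_splice_window),
                 databases = databases,
                 consensus_rule = consensus_rule),
            class = "triage_config")
}

#' Allele-frequency deprioritization rule
#'
#' A variant fails the frequency rule when its maximum observed allele
#' frequency across the queried databases strictly exceeds the threshold.
#' Frequencies absent from every queried database pass: such variants are
#' novel, exactly the profile expected for a rare disorder.
#'
#' @param variants A variant table.
#' @param threshold Frequency bound as a proportion (default 0.003).
#' @param databases Databases to query (default: all four).
#' @return A `data.table` with one row per variant: `pass` (logical),
#'   `max_af` (maximum observed frequency, `NA` if absent everywhere) and
#'   `max_af_db` (database contributing the maximum).
#' @export
#' @examples
#' fx <- load_cohort_fixture()
#' frequency_pass(fx$variants)$pass
frequency_pass <- function(variants, threshold = 0.003,
                           databases = names(af_databases())) {
  variants <- as_variant_table(variants)
  stopifnot(threshold > 0, threshold < 1)
  unknown <- setdiff(databases, names(af_databases()))
  if (length(unknown) > 0L) {
    stop("unknown database name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cols <- unname(af_databases()[databases])
  if (nrow(variants) == 0L) {
    return(data.table(pass = logical(), max_af = numeric(),
                      max_af_db = character()))
  }
  m <- as.matrix(variants[, cols, with = FALSE])
  all_absent <- rowSums(!is.na(m)) == 0L
  max_af <- suppressWarnings(apply(m, 1L, max, na.rm = TRUE))
  max_af[all_absent] <- NA_real_
  which_db <- rep(NA_character_, nrow(m))
  present <- which(!all_absent)
  if (length(present) > 0L) {
    which_db[present] <- databases[max.col(
      replace(m, is.na(m), -Inf)[present, , drop = FALSE],
      ties.method = "first")]
  }
  data.table(pass = all_absent | max_af <= threshold,
             max_af = max_af, max_af_db = which_db)
}

#' Read-support rule
#'
#' Variants supported by fewer than `min_pct` percent of the reads covering
#' the position are deprioritized as probable sequencing or mapping errors.
#' The boundary passes: exactly `min_pct` percent support is kept.
#'
#' @param variants A variant table.
#' @param min_pct Minimum supporting-read percentage (default 10).
#' @return Logical vector, `TRUE` where support is adequate.
#' @export
read_support_pass <- function(variants, min_pct = 10) {
  variants <- as_variant_table(variants)
  stopifnot(min_pct >= 0, min_pct <= 100)
  variants$reads_pct >= min_pct
}

#' In-silico predictor consensus
#'
#' Combines the calls of the five predictors (PROVEAN, SIFT, Mutation
#' Assessor, Condel, PolyPhen-2) by majority: `damaging` or `neutral` when at
#' least 3 of 5 so agree, `unknown` when all five calls are unknown, and
#' `discordant` otherwise. Unanimity (all five known calls damaging) is
#' reported separately because the strongest clinical category requires it.
#'
#' @param variants A variant table.
#' @return A `data.table` with columns `consensus` (one of `damaging`,
#'   `neutral`, `discordant`, `unknown`) and `unanimous_damaging` (logical,
#'   all five predictors called damaging).
#' @export
#' @examples
#' fx <- load_cohort_fixture()
#' predictor_consensus(fx$variants)
predictor_consensus <- function(variants) {
  variants <- as_variant_table(variants)
  m <- as.matrix(variants[, PREDICTORS, with = FALSE])
  n_dam <- rowSums(m == "damaging")
  n_neu <- rowSums(m == "neutral")
  n_unk <- rowSums(m == "unknown")
  consensus <- rep("discordant", nrow(variants))
  consensus[n_dam >= 3L] <- "damaging"
  consensus[n_neu >= 3L] <- "neutral"
  consensus[n_unk == length(PREDICTORS)] <- "unknown"
  data.table(consensus = consensus,
             unanimous_damaging = n_dam == length(PREDICTORS))
}

#' Impact classification
#'
#' Assigns each variant to one of the triage impact classes:
#' \describe{
#'   \item{CLASS1_KNOWN_FUNCTIONAL}{already shown to affect the feature.}
#'   \item{CLASS2_LIKELY_DELETERIOUS}{premature stop, start-codon loss,
#'     canonical splice, stop read-through, frameshift insertion/deletion.}
#'   \item{CLASS3_POSSIBLY_DELETERIOUS}{near-splice within the window,
#'     in-frame insertion/deletion, or a nonsynonymous change with a
#'     damaging predictor consensus.}
#'   \item{UNPRIORITIZED}{everything else (insufficient or negative
#'     evidence of impact).}
#' }
#'
#' @param variants A variant table.
#' @param consensus Optional consensus table from [predictor_consensus()]
#'   (computed if omitted).
#' @param near_splice_window Near-splice window in bases (default 10).
#' @return Character vector of impact classes.
#' @export
classify_impact <- function(variants, consensus = NULL,
                            near_splice_window = 10L) {
  variants <- as_variant_table(variants)
  if (is.null(consensus)) consensus <- predictor_consensus(variants)
  cons <- if (is.data.frame(consensus)) consensus$consensus else consensus
  stopifnot(length(cons) == nrow(variants))
  csq <- variants$consequence
  ns_missing <- csq == "near_splice" & is.na(variants$splice_distance)
  if (any(ns_missing)) {
    stop("near_splice variant without splice_distance (row ",
         which(ns_missing)[1L], ")", call. = FALSE)
  }
  out <- rep("UNPRIORITIZED", nrow(variants))
  out[csq == "known_functional"] <- "CLASS1_KNOWN_FUNCTIONAL"
  out[csq %in% CLASS2_CONSEQUENCES] <- "CLASS2_LIKELY_DELETERIOUS"
  class3 <- (csq == "near_splice" &
               variants$splice_distance <= near_splice_window) |
    csq %in% c("inframe_insertion", "inframe_deletion") |
    (csq == "nonsynonymous" & cons == "damaging")
  out[class3] <- "CLASS3_POSSIBLY_DELETERIOUS"
  out
}

#' Prioritize the variants of one sample
#'
#' Applies the triage rules to a single sample's annotated variants and
#' returns the prioritized subset with full filter provenance. A variant is
#' prioritized iff it has adequate read support, is not a known neutral
#' polymorphism, carries a non-trivial impact class, and either passes the
#' frequency rule or is rescued: its gene is tiered `TIER_CAS`/`TIER_OVERLAP`
#' in the knowledge table, the exact variant has catalogued prior phenotype
#' association, or the gene is on `extra_rescue_genes` (the cross-sample
#' genes-of-interest list). Zygosity is annotated but never filtered.
#'
#' @param variants Variant table; all rows must share one `sample_id`.
#' @param knowledge A `gene_knowledge` table (default:
#'   [default_gene_knowledge()]).
#' @param config A [triage_config()].
#' @param extra_rescue_genes Character vector of additional genes of
#'   interest whose variants are rescued from the frequency rule.
#' @param keep_all If `TRUE`, return every input variant with a
#'   `prioritized` flag instead of only the prioritized subset.
#' @return A `data.table`: the variant columns plus provenance columns
#'   `freq_pass`, `max_af`, `max_af_db`, `read_support_pass`,
#'   `neutral_excluded`, `consensus`, `unanimous_damaging`, `impact_class`,
#'   `rescued_by_gene`, `rescue_tier`, `prior_variant_evidence`,
#'   `prioritized`.
#' @export
#' @examples
#' fx <- load_cohort_fixture()
#' p1 <- prioritize_sample(fx$variants[fx$variants$sample_id == "1", ])
#' p1[, c("gene", "impact_class", "rescued_by_gene")]
prioritize_sample <- function(variants, knowledge = default_gene_knowledge(),
                              config = triage_config(),
                              extra_rescue_genes = character(),
                              keep_all = FALSE) {
  variants <- as_variant_table(variants)
  stopifnot(inherits(config, "triage_config"))
  if (length(unique(variants$sample_id)) > 1L) {
    stop("prioritize_sample() expects a single sample; found sample_ids: ",
         paste(unique(variants$sample_id), collapse = ", "), call. = FALSE)
  }
  prov <- variant_provenance(variants, knowledge, config, extra_rescue_genes)
  out <- cbind(variants, prov)
  if (!keep_all) out <- out[prioritized == TRUE]
  out[]
}

# provenance for every variant (vectorized core shared by sample/cohort)
variant_provenance <- function(variants, knowledge, config,
                               extra_rescue_genes = character()) {
  fp <- frequency_pass(variants, config$frequency_threshold,
                       config$databases)
  rs <- read_support_pass(variants, config$min_read_support_pct)
  cons <- predictor_consensus(variants)
  impact <- classify_impact(variants, cons, config$near_splice_window)
  tiers <- gene_tier(knowledge, variants$gene)
  prior <- prior_variant_match(knowledge, variants$gene,
                               variants$protein_change,
                               variants$nucleotide_desc)
  rescued <- tiers %in% c("TIER_CAS", "TIER_OVERLAP") | prior |
    variants$gene %in% extra_rescue_genes
  prioritized <- rs & !variants$known_neutral &
    impact != "UNPRIORITIZED" & (fp$pass | rescued)
  data.table(
    freq_pass = fp$pass, max_af = fp$max_af, max_af_db = fp$max_af_db,
    read_support_pass = rs, neutral_excluded = variants$known_neutral,
    consensus = cons$consensus,
    unanimous_damaging = cons$unanimous_damaging,
    impact_class = impact, rescued_by_gene = rescued, rescue_tier = tiers,
    prior_variant_evidence = prior, prioritized = prioritized)
}

#' Prioritize a multi-sample cohort
#'
#' Runs [prioritize_sample()] per sample, then performs the cross-sample
#' genes-of-interest pass: genes carrying a prioritized variant in any
#' sample are added to the rescue list and every sample is re-triaged, so a
#' frequency-failed variant is kept when the same gene was flagged in
#' another participant.
#'
#' @inheritParams prioritize_sample
#' @param cross_sample_rescue Enable the second pass (default `TRUE`).
#' @return As [prioritize_sample()], rows for all samples.
#' @export
prioritize_cohort <- function(variants, knowledge = default_gene_knowledge(),
                              config = triage_config(),
                              cross_sample_rescue = TRUE,
                              keep_all = FALSE) {
  variants <- as_variant_table(variants)
  prov <- variant_provenance(variants, knowledge, config)
  if (cross_sample_rescue) {
    genes_of_interest <- unique(variants$gene[prov$prioritized])
    prov <- variant_provenance(variants, knowledge, config,
                               extra_rescue_genes = genes_of_interest)
  }
  out <- cbind(variants, prov)
  if (!keep_all) out <- out[prioritized == TRUE]
  out[]
}

# Table-3-shaped subcategory definitions. Each entry: label + predicate on a
# prioritized/provenance table.
CLASS_SUMMARY_ROWS <- c(
  "highly_likely_deleterious_rare", "rare_premature_stop",
  "rare_readthrough", "rare_start_codon", "rare_splice",
  "rare_frameshift_insertion", "rare_frameshift_deletion",
  "possibly_deleterious_rare", "damaging_polyphen_ns", "damaging_sift_ns",
  "inframe_insertion", "inframe_deletion", "intronic_near_splice",
  "clinically_associated_rare"
)

#' Class-count summary of a prioritized set
#'
#' Summarizes a prioritized variant set into the classification subcategories
#' of the reference analysis (rare premature stop, rare frameshift insertion,
#' damaging-PolyPhen nonsynonymous change, intronic near-splice, ...),
#' reporting distinct-gene and variant counts per subcategory. "Rare" means
#' the variant passed the frequency rule.
#'
#' @param prioritized Output of [prioritize_sample()] /
#'   [prioritize_cohort()] (provenance columns required).
#' @return A `data.table` with columns `subcategory`, `gene_count`,
#'   `variant_count`.
#' @export
summarize_classes <- function(prioritized) {
  need <- c("freq_pass", "impact_class", "consequence", "gene",
            "polyphen2", "sift", "rescue_tier")
  missing <- setdiff(need, names(prioritized))
  if (length(missing) > 0L) {
    stop("summarize_classes() needs provenance columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- as.data.table(prioritized)
  rare <- p$freq_pass
  preds <- list(
    highly_likely_deleterious_rare =
      rare & p$impact_class == "CLASS2_LIKELY_DELETERIOUS",
    rare_premature_stop = rare & p$consequence == "premature_stop",
    rare_readthrough = rare & p$consequence == "stop_readthrough",
    rare_start_codon = rare & p$consequence == "start_loss",
    rare_splice = rare & p$consequence == "canonical_splice",
    rare_frameshift_insertion =
      rare & p$consequence == "frameshift_insertion",
    rare_frameshift_deletion = rare & p$consequence == "frameshift_deletion",
    possibly_deleterious_rare =
      rare & p$impact_class == "CLASS3_POSSIBLY_DELETERIOUS",
    damaging_polyphen_ns =
      rare & p$consequence == "nonsynonymous" & p$polyphen2 == "damaging",
    damaging_sift_ns =
      rare & p$consequence == "nonsynonymous" & p$sift == "damaging",
    inframe_insertion = rare & p$consequence == "inframe_insertion",
    inframe_deletion = rare & p$consequence == "inframe_deletion",
    intronic_near_splice = rare & p$consequence == "near_splice",
    clinically_associated_rare = rare & p$rescue_tier != "TIER_NONE"
  )
  rbindlist(lapply(names(preds), function(nm) {
    sel <- preds[[nm]]
    data.table(subcategory = nm,
               gene_count = length(unique(p$gene[sel])),
               variant_count = sum(sel))
  }))
}
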