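# Clinical interpretation: ACMG-style report categories for prioritized
# variants and cohort-level summaries.

#' Assign clinical report categories to prioritized variants
#'
#' Categories, in decreasing strength:
#' \describe{
#'   \item{LIKELY_PATHOGENIC}{novel variant (absent from all four frequency
#'     databases and without a dbSNP identifier), nonsynonymous with
#'     unanimous (5/5) damaging predictor agreement, in a gene causally
#'     associated with the phenotype (`TIER_CAS`).}
#'   \item{VUS}{variant in a `TIER_CAS` or `TIER_OVERLAP` gene that does not
#'     meet the likely-pathogenic bar — either its functional impact is
#'     uncertain (near-splice, non-unanimous or non-damaging consensus) or it
#'     failed the frequency rule and was admitted by gene/prior-variant
#'     rescue.}
#'   \item{VUS_IN_GUS}{predicted-damaging (majority) variant in a gene of
#'     uncertain significance (`TIER_GUS`).}
#'   \item{NOT_REPORTABLE}{anything else (in particular, prioritized
#'     variants in unlisted genes).}
#' }
#' Assignment is a pure function of the variant, its filter provenance and
#' its gene-knowledge entry.
#'
#' @param prioritized Output rows of [prioritize_sample()] /
#'   [prioritize_cohort()] (provenance columns required).
#' @param knowledge A `gene_knowledge` table.
#' @return `prioritized` with added columns `report_category` and
#'   `category_reason`.
#' @export
#' @examples
#' fx <- load_cohort_fixture()
#' pri <- prioritize_cohort(fx$variants)
#' assign_report_category(pri)[, c("sample_id", "gene", "report_category")]
assign_report_category <- function(prioritized,
                                   knowledge = default_gene_knowledge()) {
  need <- c("freq_pass", "consensus", "unanimous_damaging", "consequence")
  missing <- setdiff(need, names(prioritized))
  if (length(missing) > 0L) {
    stop("assign_report_category() needs provenance columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- as.data.table(prioritized)
  tiers <- gene_tier(knowledge, p$gene)
  af_cols <- unname(af_databases())
  novel <- rowSums(!is.na(as.matrix(p[, af_cols, with = FALSE]))) == 0L &
    is.na(p$dbsnp_id)
  lp <- novel & p$consequence == "nonsynonymous" & p$unanimous_damaging &
    tiers == "TIER_CAS"
  vus <- !lp & tiers %in% c("TIER_CAS", "TIER_OVERLAP")
  gus <- !lp & !vus & tiers == "TIER_GUS" & p$consensus == "damaging"
  category <- rep("NOT_REPORTABLE", nrow(p))
  category[gus] <- "VUS_IN_GUS"
  category[vus] <- "VUS"
  category[lp] <- "LIKELY_PATHOGENIC"
  reason <- rep("gene not associated or insufficient evidence", nrow(p))
  reason[gus] <- "predicted damaging in a gene of uncertain significance"
  reason[vus & !p$freq_pass] <-
    "frequency-failed, rescued by gene/prior-variant evidence"
  reason[vus & p$freq_pass] <-
    "associated gene, uncertain or non-unanimous functional evidence"
  reason[lp] <- "novel, unanimous damaging, causally associated gene"
  p[, report_category := category]
  p[, category_reason := reason]
  p[]
}

#' Build a cohort-level clinical report
#'
#' Aggregates categorized findings over a cohort: per-participant findings,
#' counts of participants with at least one reportable finding, with a
#' likely-pathogenic finding, and with reportable findings in two or more
#' genes; shared-variant groups (identical gene + nucleotide change in two
#' or more participants); distinct genes and chromosomes carrying
#' reportable findings.
#'
#' @param categorized Output of [assign_report_category()].
#' @param participants Character vector of all cohort participant ids
#'   (including those without findings); must be unique.
#' @return A list of class `cas_cohort_report` with elements `findings`,
#'   `participants`, `counts`, `shared_groups`, `no_finding_participants`
#'   and `notes`.
#' @export
build_cohort_report <- function(categorized, participants) {
  participants <- as.character(participants)
  if (anyDuplicated(participants)) {
    stop("participant id(s) appear more than once: ",
         paste(unique(participants[duplicated(participants)]),
               collapse = ", "), call. = FALSE)
  }
  p <- as.data.table(categorized)
  if (nrow(p) > 0 && !"report_category" %in% names(p)) {
    stop("categorized findings need a 'report_category' column", call. = FALSE)
  }
  if (nrow(p) > 0) {
    unknown <- setdiff(unique(p$sample_id), participants)
    if (length(unknown) > 0L) {
      stop("findings for participant(s) not in the cohort: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  reportable <- if (nrow(p) > 0) p[report_category != "NOT_REPORTABLE"]
                else p
  with_finding <- unique(reportable$sample_id)
  lp_participants <- unique(
    reportable$sample_id[reportable$report_category == "LIKELY_PATHOGENIC"])
  # two-gene ("two-hit") counting excludes GUS-category findings: a finding
  # in a gene of uncertain significance does not count towards a two-gene
  # mechanism in established genes.
  non_gus <- reportable[reportable$report_category %in%
                          c("LIKELY_PATHOGENIC", "VUS"), ]
  genes_per_participant <- if (nrow(non_gus) > 0) {
    non_gus[, .(n_genes = length(unique(gene))), by = sample_id]
  } else data.table(sample_id = character(), n_genes = integer())
  two_gene <- genes_per_participant[n_genes >= 2L]
  shared <- if (nrow(reportable) > 0) {
    g <- reportable[, .(participants = list(sort_ids(unique(sample_id))),
                        n_participants = length(unique(sample_id)),
                        category = report_category[1L]),
                    by = .(gene, nucleotide_desc)]
    g[g$n_participants >= 2L]
  } else {
    data.table(gene = character(), nucleotide_desc = character(),
               participants = list(), n_participants = integer(),
               category = character())
  }
  counts <- list(
    cohort_size = length(participants),
    participants_with_reportable = length(with_finding),
    participants_likely_pathogenic = length(lp_participants),
    participants_with_two_gene_findings = nrow(two_gene),
    distinct_genes = length(unique(reportable$gene)),
    distinct_chromosomes = length(unique(reportable$chrom)),
    reportable_findings = nrow(reportable))
  notes <- character()
  if (nrow(reportable) > 0 &&
      any(reportable$gene == "SETX" &
            reportable$report_category == "VUS_IN_GUS")) {
    notes <- c(notes, paste(
      "SETX findings are categorized VUS_IN_GUS (as printed in the",
      "reference report) although its phenotype (AOA2) overlaps CAS."))
  }
  structure(list(
    findings = reportable,
    participants = participants,
    counts = counts,
    shared_groups = shared,
    no_finding_participants = setdiff(participants, with_finding),
    notes = notes), class = "cas_cohort_report")
}

# numeric-aware id sort ("2" before "10" when all ids are numerals)
sort_ids <- function(ids) {
  if (all(grepl("^[0-9]+$", ids))) ids[order(as.integer(ids))]
  else sort(ids)
}

#' @export
print.cas_cohort_report <- function(x, ...) {
  c_ <- x$counts
  cat("CAS cohort clinical report\n")
  cat(sprintf("  participants: %d; with reportable finding: %d (%.0f%%)\n",
              c_$cohort_size, c_$participants_with_reportable,
              100 * c_$participants_with_reportable / c_$cohort_size))
  cat(sprintf("  likely-pathogenic participants: %d; two-gene participants: %d\n",
              c_$participants_likely_pathogenic,
              c_$participants_with_two_gene_findings))
  cat(sprintf("  findings: %d in %d genes on %d chromosomes\n",
              c_$reportable_findings, c_$distinct_genes,
              c_$distinct_chromosomes))
  if (nrow(x$shared_groups) > 0) {
    cat("  shared variants:\n")
    for (i in seq_len(nrow(x$shared_groups))) {
      cat(sprintf("    %s %s: participants %s\n",
                  x$shared_groups$gene[i], x$shared_groups$nucleotide_desc[i],
                  paste(x$shared_groups$participants[[i]], collapse = ", ")))
    }
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Participants with reportable findings in two or more genes
#'
#' Lists cohort participants whose reportable findings (likely pathogenic or
#' VUS; GUS-category findings excluded) span at least two distinct genes —
#' candidates for a two-hit causal mechanism.
#'
#' @param report A `cas_cohort_report` from [build_cohort_report()].
#' @return A `data.table` with columns `participant` and `genes`
#'   (comma-separated, alphabetical), sorted by participant id.
#' @export
two_hit_candidates <- function(report) {
  stopifnot(inherits(report, "cas_cohort_report"))
  f <- report$findings
  f <- f[f$report_category %in% c("LIKELY_PATHOGENIC", "VUS"), ]
  if (nrow(f) == 0L) {
    return(data.table(participant = character(), genes = character()))
  }
  out <- f[, .(n_genes = length(unique(gene)),
               genes = paste(sort(unique(gene)), collapse = ",")),
           by = .(participant = sample_id)]
  out <- out[n_genes >= 2L, .(participant, genes)]
  setorderv(out, "participant")
  # numeric-aware ordering when ids are numerals
  if (all(grepl("^[0-9]+$", out$participant))) {
    setorderv(out[, .tmp := as.integer(participant)], ".tmp")
    out[, .tmp := NULL]
  }
  out[]
}

#' Serialize a cohort report to JSON
#'
#' @param report A `cas_cohort_report`.
#' @param path Output path; created/overwritten.
#' @return `path`, invisibly.
#' @export
write_cohort_report_json <- function(report, path) {
  stopifnot(inherits(report, "cas_cohort_report"))
  findings <- as.data.frame(report$findings)
  payload <- list(
    counts = report$counts,
    per_participant = lapply(
      setNames(report$participants, report$participants),
      function(pid) {
        f <- findings[findings$sample_id == pid,
                      c("gene", "chrom", "nucleotide_desc", "protein_change",
                        "zygosity", "report_category", "category_reason"),
                      drop = FALSE]
        unname(split(f, seq_len(nrow(f))))
      }),
    shared_variants = if (nrow(report$shared_groups) > 0) {
      lapply(seq_len(nrow(report$shared_groups)), function(i) {
        list(gene = report$shared_groups$gene[i],
             nucleotide_desc = report$shared_groups$nucleotide_desc[i],
             participants = report$shared_groups$participants[[i]])
      })
    } else list(),
    two_hit_candidates = as.data.frame(two_hit_candidates(report)),
    notes = report$notes)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
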