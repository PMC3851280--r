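# Domain model: annotated exome variants, gene knowledge tiers, enumerations.

#' Enumerations used by the variant model
#'
#' Accepted values for the enumerated fields of an annotated variant table:
#' consequence types, zygosity states, in-silico predictor names and calls,
#' allele-frequency database names, gene association tiers and clinical
#' report categories.
#'
#' @details
#' Consequence types follow the impact taxonomy used for clinical exome
#' triage: `known_functional` (class 1, already shown to affect the feature),
#' the five truncating/splice/start types plus frameshifts (class 2, likely
#' deleterious), and the "possibly deleterious" types (`near_splice`,
#' `inframe_insertion`, `inframe_deletion`, `nonsynonymous`) that are class 3
#' only under additional evidence. `other` is never prioritized on impact.
#'
#' @name castriage-enums
#' @keywords internal
NULL

CONSEQUENCES <- c(
  "known_functional", "premature_stop", "start_loss", "canonical_splice",
  "stop_readthrough", "frameshift_insertion", "frameshift_deletion",
  "near_splice", "inframe_insertion", "inframe_deletion", "nonsynonymous",
  "other"
)

# class-2 ("highly likely deleterious") consequence types
CLASS2_CONSEQUENCES <- c(
  "premature_stop", "start_loss", "canonical_splice", "stop_readthrough",
  "frameshift_insertion", "frameshift_deletion"
)

ZYGOSITIES <- c("heterozygous", "homozygous", "hemizygous")

PREDICTORS <- c("provean", "sift", "mutation_assessor", "condel", "polyphen2")
PREDICTOR_CALLS <- c("damaging", "neutral", "unknown")

#' Allele-frequency databases and their table columns
#'
#' The four population allele-frequency sources consulted by the frequency
#' rule, mapped to the columns of the canonical variant table:
#' dbSNP build 137 (`af_dbsnp`), the NHLBI ESP6500 set from the Exome Variant
#' Server (`af_evs`), the 1000 Genomes Project (`af_tgp`) and an in-house
#' panel of 128 exomes/genomes (`af_inhouse`).
#'
#' @return Named character vector mapping database name to column name.
#' @export
#' @examples
#' af_databases()
af_databases <- function() {
  c(dbSNP137 = "af_dbsnp", EVS6500 = "af_evs", TGP = "af_tgp",
    in_house_128 = "af_inhouse")
}

GENE_TIERS <- c("TIER_CAS", "TIER_OVERLAP", "TIER_GUS", "TIER_NONE")

REPORT_CATEGORIES <- c("LIKELY_PATHOGENIC", "VUS", "VUS_IN_GUS",
                       "NOT_REPORTABLE")

IMPACT_CLASSES <- c("CLASS1_KNOWN_FUNCTIONAL", "CLASS2_LIKELY_DELETERIOUS",
                    "CLASS3_POSSIBLY_DELETERIOUS", "UNPRIORITIZED")

# Canonical column order of the variant-table TSV dialect. `splice_distance`
# extends the minimal schema: `near_splice` rows cannot be impact-classified
# without it, so the writer always emits it and the reader tolerates its
# absence (NA).
VARIANT_COLUMNS <- c(
  "sample_id", "chrom", "start", "end", "gene", "consequence",
  "nucleotide_desc", "protein_change", "zygosity", "reads_pct", "depth",
  "af_dbsnp", "af_evs", "af_tgp", "af_inhouse", "dbsnp_id",
  "provean", "sift", "mutation_assessor", "condel", "polyphen2",
  "known_neutral", "splice_distance"
)

#' Construct / validate an annotated variant table
#'
#' An annotated variant table is a `data.table` with one row per called
#' variant per sample and a fixed column schema (see [variant_columns()]).
#' Coordinates are 1-based inclusive. Allele frequencies are proportions in
#' \eqn{[0,1]}; an absent frequency (not catalogued in that database) is `NA`,
#' never 0. `reads_pct` is the percentage (0-100 scale, as printed in source
#' reports) of reads supporting the alternate call.
#'
#' @param x A data.frame with at least the canonical columns minus
#'   `splice_distance` (filled with `NA` if missing).
#' @return A validated `data.table` with columns in canonical order.
#' @export
#' @examples
#' v <- empty_variant_table()
#' nrow(v)
as_variant_table <- function(x) {
  x <- as.data.table(x)
  required <- setdiff(VARIANT_COLUMNS, "splice_distance")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("variant table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"splice_distance" %in% names(x)) x[, splice_distance := NA_integer_]
  x <- x[, VARIANT_COLUMNS, with = FALSE]
  coerce <- function(col, fun) x[, (col) := fun(x[[col]])]
  coerce("sample_id", as.character); coerce("chrom", as.character)
  coerce("start", as.integer);       coerce("end", as.integer)
  coerce("gene", as.character);      coerce("consequence", as.character)
  coerce("nucleotide_desc", as.character)
  coerce("protein_change", as.character)
  coerce("zygosity", as.character)
  coerce("reads_pct", as.numeric);   coerce("depth", as.integer)
  for (col in unname(af_databases())) coerce(col, as.numeric)
  coerce("dbsnp_id", as.character)
  for (col in PREDICTORS) coerce(col, as.character)
  coerce("known_neutral", as.logical)
  coerce("splice_distance", as.integer)
  validate_variant_table(x)
  x[]
}

validate_variant_table <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  bad <- setdiff(unique(x$consequence), CONSEQUENCES)
  if (length(bad) > 0L) {
    stop("unknown consequence value(s): ", paste(bad, collapse = ", "),
         "; accepted values are: ", paste(CONSEQUENCES, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(x$zygosity), ZYGOSITIES)
  if (length(bad) > 0L) {
    stop("unknown zygosity value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (p in PREDICTORS) {
    bad <- setdiff(unique(x[[p]]), PREDICTOR_CALLS)
    if (length(bad) > 0L) {
      stop("unknown predictor call in column '", p, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  with_pos <- !is.na(x$start) & !is.na(x$end)
  if (any(x$start[with_pos] > x$end[with_pos])) {
    stop("variant with start > end", call. = FALSE)
  }
  if (any(x$reads_pct < 0 | x$reads_pct > 100, na.rm = TRUE)) {
    stop("reads_pct outside [0, 100]", call. = FALSE)
  }
  if (any(x$depth < 1L, na.rm = TRUE)) stop("depth < 1", call. = FALSE)
  for (col in unname(af_databases())) {
    if (any(x[[col]] < 0 | x[[col]] > 1, na.rm = TRUE)) {
      stop("allele frequency in '", col, "' outside [0, 1]", call. = FALSE)
    }
  }
  if (any(is.na(x$known_neutral))) {
    stop("known_neutral must be TRUE or FALSE, not NA", call. = FALSE)
  }
  invisible(x)
}

#' @rdname as_variant_table
#' @export
empty_variant_table <- function() {
  as_variant_table(data.table(
    sample_id = character(), chrom = character(), start = integer(),
    end = integer(), gene = character(), consequence = character(),
    nucleotide_desc = character(), protein_change = character(),
    zygosity = character(), reads_pct = numeric(), depth = integer(),
    af_dbsnp = numeric(), af_evs = numeric(), af_tgp = numeric(),
    af_inhouse = numeric(), dbsnp_id = character(), provean = character(),
    sift = character(), mutation_assessor = character(), condel = character(),
    polyphen2 = character(), known_neutral = logical(),
    splice_distance = integer()))
}

#' @rdname as_variant_table
#' @export
variant_columns <- function() VARIANT_COLUMNS

#' Construct / validate a gene-knowledge table
#'
#' The gene-knowledge table drives known-gene rescue during prioritization and
#' report-category assignment. Each gene carries an association tier:
#' `TIER_CAS` (causally associated with childhood apraxia of speech or the
#' same phenotype), `TIER_OVERLAP` (associated with an overlapping phenotype
#' such as specific language impairment or dyslexia), `TIER_GUS` (gene of
#' uncertain significance) or `TIER_NONE`. `prior_variants` lists variant
#' descriptions (protein or nucleotide) with prior phenotype association,
#' comma-separated; a match rescues a frequency-failed variant.
#'
#' Genes absent from the table query to `TIER_NONE`.
#'
#' @param x data.frame with columns `gene`, `tier` and optionally
#'   `phenotype_note`, `prior_variants`.
#' @return A validated `data.table` of class `gene_knowledge`.
#' @export
#' @examples
#' kt <- as_gene_knowledge(data.frame(gene = "CNTNAP2", tier = "TIER_CAS"))
#' gene_tier(kt, c("CNTNAP2", "UNLISTED"))
as_gene_knowledge <- function(x) {
  x <- as.data.table(x)
  if (!all(c("gene", "tier") %in% names(x))) {
    stop("gene knowledge table needs columns 'gene' and 'tier'",
         call. = FALSE)
  }
  if (!"phenotype_note" %in% names(x)) x[, phenotype_note := NA_character_]
  if (!"prior_variants" %in% names(x)) x[, prior_variants := NA_character_]
  x <- x[, c("gene", "tier", "phenotype_note", "prior_variants"),
         with = FALSE]
  x[, gene := as.character(gene)]
  x[, tier := as.character(tier)]
  x[, phenotype_note := as.character(phenotype_note)]
  x[, prior_variants := as.character(prior_variants)]
  if (anyDuplicated(x$gene)) {
    stop("duplicate gene(s) in knowledge table: ",
         paste(unique(x$gene[duplicated(x$gene)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(x$tier), GENE_TIERS)
  if (length(bad) > 0L) {
    stop("unknown tier token(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(GENE_TIERS, collapse = ", "), call. = FALSE)
  }
  data.table::setattr(x, "class", c("gene_knowledge", class(x)))
  x[]
}

#' @rdname as_gene_knowledge
#' @param knowledge A `gene_knowledge` table.
#' @param genes Character vector of gene symbols to look up.
#' @return `gene_tier()`: character vector of tiers (default `TIER_NONE`).
#' @export
gene_tier <- function(knowledge, genes) {
  idx <- match(genes, knowledge$gene)
  tiers <- knowledge$tier[idx]
  tiers[is.na(idx)] <- "TIER_NONE"
  tiers
}

# prior-variant rescue: does variant description (protein or nucleotide)
# match a catalogued prior variant for its gene?
prior_variant_match <- function(knowledge, genes, protein_change,
                                nucleotide_desc) {
  idx <- match(genes, knowledge$gene)
  prior <- knowledge$prior_variants[idx]
  out <- logical(length(genes))
  has <- !is.na(prior) & nzchar(prior)
  if (!any(has)) return(out)
  for (i in which(has)) {
    toks <- trimws(strsplit(prior[i], ",", fixed = TRUE)[[1L]])
    out[i] <- (!is.na(protein_change[i]) && protein_change[i] %in% toks) ||
      (!is.na(nucleotide_desc[i]) && nucleotide_desc[i] %in% toks)
  }
  out
}
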