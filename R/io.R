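# Readers/writers for the variant-table TSV dialect, the optional VCF
# dialect, and gene-knowledge tables.

# tokens accepted as "absent" in frequency / identifier columns
ABSENT_TOKENS <- c("", "NA", "Not found", "not found", "NOT FOUND", ".",
                   "ABSENT")

parse_numeric_column <- function(values, column, lines) {
  out <- rep(NA_real_, length(values))
  present <- !(values %in% ABSENT_TOKENS) & !is.na(values)
  suppressWarnings(parsed <- as.numeric(values[present]))
  if (anyNA(parsed)) {
    bad <- which(present)[is.na(parsed)][1L]
    stop("cannot parse value '", values[bad], "' in column '", column,
         "' at line ", lines[bad], call. = FALSE)
  }
  out[present] <- parsed
  out
}

#' Read and write the canonical variant-table TSV
#'
#' The canonical dialect is a UTF-8, tab-separated table with a header row
#' of the columns in [variant_columns()]. Absent allele frequencies may be
#' written as empty, `NA` or `Not found` and are read back as `NA` (absent),
#' never silently as 0. `write_variant_tsv()` followed by
#' `read_variant_tsv()` round-trips a table field-for-field.
#'
#' @param path Path to a TSV file.
#' @return `read_variant_tsv()`: a validated variant table
#'   (see [as_variant_table()]).
#' @export
read_variant_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               na.strings = NULL, quote = "")
  required <- setdiff(VARIANT_COLUMNS, "splice_distance")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("variant table ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1
  out <- data.table(
    sample_id = raw$sample_id, chrom = raw$chrom,
    start = as.integer(parse_numeric_column(gsub(",", "", raw$start,
                                                 fixed = TRUE),
                                            "start", lines)),
    end = as.integer(parse_numeric_column(gsub(",", "", raw$end,
                                               fixed = TRUE),
                                          "end", lines)),
    gene = raw$gene, consequence = raw$consequence,
    nucleotide_desc = blank_to_na(raw$nucleotide_desc),
    protein_change = blank_to_na(raw$protein_change),
    zygosity = tolower(raw$zygosity),
    reads_pct = parse_numeric_column(raw$reads_pct, "reads_pct", lines),
    depth = as.integer(parse_numeric_column(raw$depth, "depth", lines)),
    af_dbsnp = parse_numeric_column(raw$af_dbsnp, "af_dbsnp", lines),
    af_evs = parse_numeric_column(raw$af_evs, "af_evs", lines),
    af_tgp = parse_numeric_column(raw$af_tgp, "af_tgp", lines),
    af_inhouse = parse_numeric_column(raw$af_inhouse, "af_inhouse", lines),
    dbsnp_id = blank_to_na(raw$dbsnp_id),
    provean = norm_call(raw$provean), sift = norm_call(raw$sift),
    mutation_assessor = norm_call(raw$mutation_assessor),
    condel = norm_call(raw$condel), polyphen2 = norm_call(raw$polyphen2),
    known_neutral = parse_logical_column(raw$known_neutral, lines),
    splice_distance = if ("splice_distance" %in% names(raw)) {
      as.integer(parse_numeric_column(raw$splice_distance,
                                      "splice_distance", lines))
    } else NA_integer_
  )
  as_variant_table(out)
}

blank_to_na <- function(x) {
  x[x %in% ABSENT_TOKENS] <- NA_character_
  x
}

norm_call <- function(x) {
  x <- tolower(x)
  x[x %in% c("", "na", ".", "not found")] <- "unknown"
  x
}

parse_logical_column <- function(values, lines) {
  v <- toupper(values)
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[v %in% c("FALSE", "F", "0", "NO", "")] <- FALSE
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop("cannot parse value '", values[bad],
         "' in column 'known_neutral' at line ", lines[bad], call. = FALSE)
  }
  out
}

#' @rdname read_variant_tsv
#' @param variants A variant table ([as_variant_table()]).
#' @return `write_variant_tsv()`: `path`, invisibly.
#' @export
write_variant_tsv <- function(variants, path) {
  variants <- as_variant_table(variants)
  fwrite(variants, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a gene-knowledge table from TSV or YAML
#'
#' TSV files need columns `gene` and `tier` (optionally `phenotype_note`,
#' `prior_variants` as a comma-separated list). YAML files hold a list of
#' entries with the same keys (`prior_variants` as a sequence). Duplicate
#' genes and unknown tier tokens are errors.
#'
#' @param path Path to a `.tsv`/`.txt` or `.yml`/`.yaml` file.
#' @return A `gene_knowledge` table (see [as_gene_knowledge()]).
#' @export
read_gene_knowledge <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML gene-knowledge tables requires the 'yaml' package",
           call. = FALSE)
    }
    entries <- yaml::read_yaml(path)
    dt <- rbindlist(lapply(entries, function(e) {
      data.table(
        gene = as.character(e$gene), tier = as.character(e$tier),
        phenotype_note = if (is.null(e$phenotype_note)) NA_character_
                         else as.character(e$phenotype_note),
        prior_variants = if (is.null(e$prior_variants)) NA_character_
                         else paste(e$prior_variants, collapse = ","))
    }))
    return(as_gene_knowledge(dt))
  }
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               na.strings = c("", "NA"), quote = "")
  as_gene_knowledge(raw)
}

#' Default gene-knowledge table for the CAS cohort
#'
#' The packaged association tiers for the six genes with clinically
#' reportable findings in the reference cohort, plus FOXP2. FOXP1, FOXP2,
#' CNTNAP2 and ATP13A4 are tiered `TIER_CAS` (causally associated with
#' childhood apraxia of speech or the same phenotype); KIAA0319 is
#' `TIER_OVERLAP` (dyslexia/SLI); CNTNAP1 and SETX are `TIER_GUS`. SETX's
#' phenotype (AOA2) overlaps CAS, but its findings are reported in the
#' "VUS in GUS" category, so its tier is GUS here; the overlap is kept in
#' the phenotype note. Prior-variant evidence (e.g. KIAA0319 p.Ala311Thr,
#' SETX p.Lys992Arg) enables rescue of frequency-failed variants.
#'
#' @return A `gene_knowledge` table.
#' @export
#' @examples
#' default_gene_knowledge()
default_gene_knowledge <- function() {
  path <- system.file("extdata", "gene_knowledge_default.tsv",
                      package = "castriage", mustWork = TRUE)
  read_gene_knowledge(path)
}

#' Read annotated variants from the VCF dialect
#'
#' A thin adapter over `VariantAnnotation::readVcf()` mapping a single-sample
#' VCF 4.x file with annotation INFO keys onto the same variant model as the
#' TSV dialect. Multi-allelic records are split (one variant per ALT) before
#' mapping. Expected INFO keys (Number=A for per-ALT values): `GENE`, `CSQ`
#' (a consequence token from the canonical enumeration), `NUCDESC`, `PROT`,
#' `READSPCT`, `AF_DBSNP`, `AF_EVS`, `AF_TGP`, `AF_INHOUSE`, `KNOWN_NEUTRAL`,
#' `SPLICEDIST` and the predictor keys `PROVEAN`, `SIFT`, `MA`, `CONDEL`,
#' `PP2`. `sample_id` is taken from the VCF sample name, zygosity from the
#' genotype, depth from `DP`, the dbSNP identifier from the ID field.
#'
#' @param path Path to a VCF file.
#' @return A validated variant table.
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("the VCF dialect requires the 'VariantAnnotation' package",
         call. = FALSE)
  }
  raw_vcf <- VariantAnnotation::readVcf(path)
  # carry the VCF ID column through expand(), which drops row names
  raw_ids <- names(SummarizedExperiment::rowRanges(raw_vcf))
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(raw_vcf))
  ids <- if (is.null(raw_ids)) character(0) else rep(raw_ids, n_alt)
  vcf <- VariantAnnotation::expand(raw_vcf)  # one row per ALT
  n <- nrow(vcf)
  if (length(ids) != n) ids <- rep(NA_character_, n)
  smp <- colnames(vcf)
  if (length(smp) != 1L) {
    stop("the VCF dialect expects exactly one sample, found ",
         length(smp), call. = FALSE)
  }
  info <- VariantAnnotation::info(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT[, 1L]
  zyg <- ifelse(gt %in% c("1/1", "1|1"), "homozygous",
         ifelse(gt %in% c("1", "1/.", "./1"), "hemizygous", "heterozygous"))
  dp <- if ("DP" %in% names(VariantAnnotation::geno(vcf))) {
    as.integer(VariantAnnotation::geno(vcf)$DP[, 1L])
  } else if ("DP" %in% names(info)) as.integer(info$DP) else rep(1L, n)
  ids <- ifelse(grepl("^rs", ids), ids, NA_character_)
  ichr <- function(key, default = NA_character_) {
    if (key %in% names(info)) {
      v <- as.character(info[[key]]); v[v %in% ABSENT_TOKENS] <- NA; v
    } else rep(default, n)
  }
  inum <- function(key) {
    if (key %in% names(info)) suppressWarnings(as.numeric(info[[key]]))
    else rep(NA_real_, n)
  }
  dt <- data.table(
    sample_id = rep(smp, n),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    start = BiocGenerics::start(rr), end = BiocGenerics::end(rr),
    gene = ichr("GENE"), consequence = ichr("CSQ", "other"),
    nucleotide_desc = ichr("NUCDESC"), protein_change = ichr("PROT"),
    zygosity = zyg, reads_pct = inum("READSPCT"), depth = dp,
    af_dbsnp = inum("AF_DBSNP"), af_evs = inum("AF_EVS"),
    af_tgp = inum("AF_TGP"), af_inhouse = inum("AF_INHOUSE"),
    dbsnp_id = ids,
    provean = norm_call(ichr("PROVEAN", "unknown")),
    sift = norm_call(ichr("SIFT", "unknown")),
    mutation_assessor = norm_call(ichr("MA", "unknown")),
    condel = norm_call(ichr("CONDEL", "unknown")),
    polyphen2 = norm_call(ichr("PP2", "unknown")),
    known_neutral = {
      v <- ichr("KNOWN_NEUTRAL", "FALSE"); toupper(v) %in% c("TRUE", "1")
    },
    splice_distance = as.integer(inum("SPLICEDIST")))
  as_variant_table(dt)
}
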