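# Packaged in-paper fixtures: the reference CAS cohort (Tables of most
# highly prioritized variants) and its phenotype grid.

#' Load the packaged reference-cohort fixture
#'
#' The fixture transcribes the reference study's per-participant summary of
#' most highly prioritized whole-exome variants: 12 variant records across 8
#' of 10 participants, in 6 genes (ATP13A4, KIAA0319, CNTNAP2, CNTNAP1,
#' FOXP1, SETX) on 5 chromosomes; participants 3 and 5 have no reportable
#' findings. Expected clinical report categories, as printed in the source
#' report, are carried alongside for golden testing.
#'
#' @return A list with elements `variants` (variant table), `cohort_size`
#'   (10), `participants` (character ids "1".."10"), `no_finding_participants`
#'   (`c("3","5")`) and `expected_categories` (data.table keyed by
#'   sample/gene/nucleotide description).
#' @export
#' @examples
#' fx <- load_cohort_fixture()
#' nrow(fx$variants)
load_cohort_fixture <- function() {
  vpath <- system.file("extdata", "cas_cohort_tables45.tsv",
                       package = "castriage", mustWork = TRUE)
  epath <- system.file("extdata", "cas_cohort_expected_categories.tsv",
                       package = "castriage", mustWork = TRUE)
  variants <- read_variant_tsv(vpath)
  expected <- fread(epath, sep = "\t", colClasses = "character", quote = "")
  list(
    variants = variants,
    cohort_size = 10L,
    participants = as.character(1:10),
    no_finding_participants = c("3", "5"),
    expected_categories = expected
  )
}

#' Load or read a participant phenotype table
#'
#' The packaged fixture mirrors the reference study's phenotype grid for 10
#' participants: per-participant gender, developmental age group (A: 3-6 yr,
#' B: 7-9 yr, C: 10-19 yr) and years of apraxia treatment, plus seven coded
#' trait columns (`familial`, `cognitive`, `onset`, `comprehension`,
#' `expression`, `gross_motor`, `oral_nonverbal`), each `POSITIVE`,
#' `NEGATIVE` or `ND` (no data). Blank cells in the printed grid encode
#' `NEGATIVE`; only `ND` marks missing data.
#'
#' @param path Path to a phenotype TSV with the columns above.
#' @return A `data.table`, one row per participant.
#' @export
#' @examples
#' pt <- load_phenotype_fixture()
#' table(pt$familial)
load_phenotype_fixture <- function() {
  path <- system.file("extdata", "cas_phenotype_table1.tsv",
                      package = "castriage", mustWork = TRUE)
  read_phenotype_tsv(path)
}

#' @rdname load_phenotype_fixture
#' @export
read_phenotype_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- fread(path, sep = "\t", colClasses = "character", quote = "")
  trait_cols <- setdiff(names(x), c("participant", "gender", "age_group",
                                    "years_treatment"))
  if (length(trait_cols) == 0L) {
    stop("phenotype table has no trait columns", call. = FALSE)
  }
  for (col in trait_cols) {
    v <- x[[col]]
    v[v == ""] <- "NEGATIVE"  # blank cells encode negative
    bad <- setdiff(unique(v), c("POSITIVE", "NEGATIVE", "ND"))
    if (length(bad) > 0L) {
      stop("unknown phenotype code(s) in column '", col, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    data.table::set(x, j = col, value = v)
  }
  if (anyDuplicated(x$participant)) {
    stop("duplicate participant id in phenotype table", call. = FALSE)
  }
  x[]
}
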