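# Phenotype-rate and cost-effectiveness arithmetic.

#' Missing-data-adjusted phenotype rate
#'
#' Rate of positive codes in a trait column with `ND` (no data) entries
#' removed from the denominator: `numerator / (n - n_ND)`, reported as an
#' integer percent rounded half away from zero (55.56 -> 56, 88.89 -> 89).
#'
#' @param column Character vector of codes, each `POSITIVE`, `NEGATIVE`
#'   or `ND`.
#' @return A list of class `rate_result`: `numerator`, `denominator`,
#'   `percent`.
#' @export
#' @examples
#' pt <- load_phenotype_fixture()
#' missing_adjusted_rate(pt$familial)  # 5/9 = 56%
missing_adjusted_rate <- function(column) {
  if (length(column) == 0L) stop("empty phenotype column", call. = FALSE)
  bad <- setdiff(unique(column), c("POSITIVE", "NEGATIVE", "ND"))
  if (length(bad) > 0L) {
    stop("unknown phenotype code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  denom <- sum(column != "ND")
  if (denom == 0L) {
    stop("rate undefined: column is all ND (no data)", call. = FALSE)
  }
  num <- sum(column == "POSITIVE")
  structure(list(numerator = num, denominator = denom,
                 percent = round_half_away(100 * num / denom)),
            class = "rate_result")
}

# round to nearest integer, halves away from zero (base round() is
# round-half-even, which would turn 55.5 into 56 but 88.5 into 88)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("%d/%d = %d%%\n", x$numerator, x$denominator, x$percent))
  invisible(x)
}

#' All missing-adjusted rates of a phenotype table
#'
#' @param phenotype A phenotype table ([read_phenotype_tsv()]).
#' @param traits Trait columns to summarize (default: all coded columns).
#' @return Named list of `rate_result`s.
#' @export
#' @examples
#' phenotype_rates(load_phenotype_fixture())
phenotype_rates <- function(phenotype,
                            traits = setdiff(names(phenotype),
                                             c("participant", "gender",
                                               "age_group",
                                               "years_treatment"))) {
  out <- lapply(setNames(traits, traits), function(tr) {
    tryCatch(missing_adjusted_rate(phenotype[[tr]]),
             error = function(e) {
               stop("column '", tr, "': ", conditionMessage(e),
                    call. = FALSE)
             })
  })
  out
}

#' Cost per diagnosis
#'
#' Cost of one diagnostic test divided by the expected diagnosis rate,
#' truncated to whole dollars (floor): a $5,000 exome at a 60% diagnosis
#' rate costs $8,333 per diagnosis; a $2,250 single-gene test at 4% costs
#' $56,250.
#'
#' @param test_cost Cost of the test in dollars (> 0).
#' @param diagnosis_rate Expected diagnosis rate as a fraction in (0, 1].
#' @return Integer dollars per diagnosis.
#' @export
#' @examples
#' cost_per_diagnosis(5000, 0.60)
cost_per_diagnosis <- function(test_cost, diagnosis_rate) {
  stopifnot(is.numeric(test_cost), length(test_cost) == 1L, test_cost > 0,
            is.numeric(diagnosis_rate), length(diagnosis_rate) == 1L)
  if (diagnosis_rate <= 0 || diagnosis_rate > 1) {
    stop("diagnosis_rate must be in (0, 1]", call. = FALSE)
  }
  as.integer(floor(test_cost / diagnosis_rate))
}

#' Prioritized fraction of called variants
#'
#' Percentage of called variants remaining under consideration after
#' prioritization, rounded to two decimals: 401 of 116,836 -> 0.34.
#'
#' @param mean_prioritized Mean prioritized variant count per sample (> 0).
#' @param mean_called Mean called variant count per sample (> 0).
#' @return Percent, rounded to 2 decimal places.
#' @export
#' @examples
#' prioritized_fraction(401, 116836)
prioritized_fraction <- function(mean_prioritized, mean_called) {
  stopifnot(is.numeric(mean_prioritized), is.numeric(mean_called),
            length(mean_prioritized) == 1L, length(mean_called) == 1L)
  if (mean_called <= 0) stop("mean_called must be > 0", call. = FALSE)
  if (mean_prioritized <= 0) {
    stop("mean_prioritized must be > 0", call. = FALSE)
  }
  if (mean_prioritized > mean_called) {
    stop("mean_prioritized cannot exceed mean_called", call. = FALSE)
  }
  round(100 * mean_prioritized / mean_called, 2)
}
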