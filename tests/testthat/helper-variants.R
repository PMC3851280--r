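# Builders for small in-code fixtures.

# one-row variant table with overridable fields
make_variant <- function(...) {
  defaults <- list(
    sample_id = "S1", chrom = "Chr1", start = 1000L, end = 1000L,
    gene = "GENEX", consequence = "nonsynonymous",
    nucleotide_desc = "c.100A>G", protein_change = "p.Lys34Arg",
    zygosity = "heterozygous", reads_pct = 50, depth = 40L,
    af_dbsnp = NA_real_, af_evs = NA_real_, af_tgp = NA_real_,
    af_inhouse = NA_real_, dbsnp_id = NA_character_,
    provean = "unknown", sift = "unknown", mutation_assessor = "unknown",
    condel = "unknown", polyphen2 = "unknown", known_neutral = FALSE,
    splice_distance = NA_integer_)
  args <- utils::modifyList(defaults, list(...))
  as_variant_table(as.data.frame(args, stringsAsFactors = FALSE))
}

# n-row variant table from per-field vectors
make_variants <- function(...) {
  rows <- list(...)
  data.table::rbindlist(rows)
}

# set all five predictor calls at once
with_predictors <- function(v, calls) {
  stopifnot(length(calls) == 5L)
  preds <- c("provean", "sift", "mutation_assessor", "condel", "polyphen2")
  for (i in seq_along(preds)) data.table::set(v, j = preds[i],
                                              value = calls[i])
  v
}

# brute-force re-application of each rule independently, row by row;
# deliberately scalar and naive -- the oracle for provenance completeness
brute_force_rules <- function(variants, knowledge, config) {
  af_cols <- c(dbSNP137 = "af_dbsnp", EVS6500 = "af_evs", TGP = "af_tgp",
               in_house_128 = "af_inhouse")[config$databases]
  out <- lapply(seq_len(nrow(variants)), function(i) {
    v <- as.data.frame(variants[i, ])
    afs <- unlist(v[unname(af_cols)])
    freq_ok <- if (all(is.na(afs))) TRUE else
      max(afs, na.rm = TRUE) <= config$frequency_threshold
    rs_ok <- v$reads_pct >= config$min_read_support_pct
    calls <- unlist(v[c("provean", "sift", "mutation_assessor", "condel",
                        "polyphen2")])
    cons <- if (sum(calls == "damaging") >= 3) "damaging"
            else if (sum(calls == "neutral") >= 3) "neutral"
            else if (all(calls == "unknown")) "unknown" else "discordant"
    class2 <- c("premature_stop", "start_loss", "canonical_splice",
                "stop_readthrough", "frameshift_insertion",
                "frameshift_deletion")
    impact <- if (v$consequence == "known_functional") "CLASS1"
      else if (v$consequence %in% class2) "CLASS2"
      else if ((v$consequence == "near_splice" &&
                  !is.na(v$splice_distance) &&
                  v$splice_distance <= config$near_splice_window) ||
               v$consequence %in% c("inframe_insertion",
                                    "inframe_deletion") ||
               (v$consequence == "nonsynonymous" && cons == "damaging"))
        "CLASS3"
      else "UNPRIORITIZED"
    idx <- match(v$gene, knowledge$gene)
    tier <- if (is.na(idx)) "TIER_NONE" else knowledge$tier[idx]
    prior <- if (!is.na(idx) && !is.na(knowledge$prior_variants[idx])) {
      toks <- trimws(strsplit(knowledge$prior_variants[idx], ",")[[1]])
      (!is.na(v$protein_change) && v$protein_change %in% toks) ||
        (!is.na(v$nucleotide_desc) && v$nucleotide_desc %in% toks)
    } else FALSE
    rescued <- tier %in% c("TIER_CAS", "TIER_OVERLAP") || prior
    list(freq_ok = freq_ok, rs_ok = rs_ok, impact = impact,
         rescued = rescued,
         prioritized = rs_ok && !v$known_neutral &&
           impact != "UNPRIORITIZED" && (freq_ok || rescued))
  })
  data.table::rbindlist(out)
}
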