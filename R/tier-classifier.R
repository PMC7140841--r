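#' Classifier thresholds
#'
#' Variants with a reference-population minor allele frequency above
#' `max_maf` are excluded as common. Protein-truncating variants require a
#' CADD phred score of at least `min_cadd` (an absent CADD, typical for
#' indels, passes the condition). Missense variants qualify on scores when
#' both CADD >= `min_cadd` and REVEL >= `min_revel`. All score comparisons
#' are inclusive; the rarity exclusion is strict (`maf > max_maf`).
#'
#' @param max_maf maximum minor allele frequency for a rare variant.
#' @param min_cadd minimum CADD phred score.
#' @param min_revel minimum REVEL score for score-qualified missense.
#' @return list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(max_maf = 0.01, min_cadd = 20,
                                  min_revel = 0.75) {
  stopifnot(max_maf > 0, max_maf <= 0.5, min_revel >= 0, min_revel <= 1,
            is.finite(min_cadd))
  structure(list(max_maf = max_maf, min_cadd = min_cadd,
                 min_revel = min_revel),
            class = "classifier_thresholds")
}

.truncating_classes <- c("stopgain", "frameshift_insertion",
                         "frameshift_deletion", "splicing")

#' Pre-classification exclusion filter
#'
#' Flags variants that never reach the tier rules: genes off the analysis
#' panel, intergenic variants, and common variants (MAF strictly above the
#' threshold). An absent MAF never triggers the rarity exclusion — a variant
#' unobserved in the reference population is rare, not common.
#'
#' @param variants a [variant_table].
#' @param panel a [read_gene_panel()] result (character vector of symbols).
#' @param thresholds a [classifier_thresholds] object.
#' @return character vector of exclusion reasons (`"OFF_PANEL"`,
#'   `"INTERGENIC"`, `"COMMON"`) with `NA` where no exclusion applies.
#' @export
prefilter_variants <- function(variants, panel,
                               thresholds = classifier_thresholds()) {
  validate_variant_table(variants)
  reason <- rep(NA_character_, nrow(variants))
  common <- !is.na(variants$maf) & variants$maf > thresholds$max_maf
  reason[common] <- "COMMON"
  reason[variants$region_class == "intergenic"] <- "INTERGENIC"
  reason[!(variants$gene %in% toupper(panel))] <- "OFF_PANEL"
  reason
}

#' Assign damaging-variant tiers
#'
#' Applies the exclusion prefilter and then the tier decision procedure, in
#' order:
#'
#' 1. ClinVar benign precedence: a variant asserted benign or likely benign
#'    with no coexisting pathogenic/likely-pathogenic assertion is
#'    `NEUTRAL`/`CLINVAR_BENIGN`, regardless of scores.
#' 2. Protein-truncating variants (stopgain, frameshift indels, splice-site
#'    altering) with CADD >= `min_cadd` (absent CADD passes) are `TIER1` when
#'    ClinVar asserts pathogenic/likely pathogenic (`TRUNCATING_PLP`) or,
#'    failing that, when the truncation disrupts an annotated protein domain
#'    (`TRUNCATING_DOMAIN`).
#' 3. Missense variants are `TIER2` when ClinVar asserts pathogenic/likely
#'    pathogenic (`MISSENSE_PLP`) or when CADD >= `min_cadd` and REVEL >=
#'    `min_revel` (`MISSENSE_SCORES`).
#' 4. Anything else is `NEUTRAL`/`NO_RULE_MET`.
#'
#' Mixed ClinVar assertion sets such as `"5,4,3"` count as
#' pathogenic/likely pathogenic whenever any code is 4 or 5; benign
#' precedence applies only when no such code coexists. An absent
#' `disrupts_domain` flag is treated as `FALSE`.
#'
#' @param variants a [variant_table].
#' @param panel optional gene panel; when `NULL`, no panel restriction is
#'   applied.
#' @param thresholds a [classifier_thresholds] object.
#' @return data frame with columns `variant_key`, `gene`, `tier`
#'   (`TIER1`/`TIER2`/`NEUTRAL`/`EXCLUDED`) and `reason`, one row per input
#'   variant, in input order; classification is total and deterministic.
#' @export
classify_variants <- function(variants, panel = NULL,
                              thresholds = classifier_thresholds()) {
  validate_variant_table(variants)
  n <- nrow(variants)
  tier <- rep("NEUTRAL", n)
  reason <- rep("NO_RULE_MET", n)
  if (n == 0L)
    return(data.frame(variant_key = character(0), gene = character(0),
                      tier = character(0), reason = character(0),
                      stringsAsFactors = FALSE))

  has_plp <- clinvar_has_plp(variants$clinvar)
  benign <- clinvar_benign_only(variants$clinvar)
  trunc <- variants$func_class %in% .truncating_classes
  cadd_ok <- is.na(variants$cadd_phred) |
    variants$cadd_phred >= thresholds$min_cadd
  domain <- !is.na(variants$disrupts_domain) & variants$disrupts_domain
  missense <- variants$func_class == "missense"
  scores_ok <- !is.na(variants$cadd_phred) &
    variants$cadd_phred >= thresholds$min_cadd &
    !is.na(variants$revel) & variants$revel >= thresholds$min_revel

  set <- function(idx, t, r) {
    tier[idx] <<- t
    reason[idx] <<- r
  }
  set(benign, "NEUTRAL", "CLINVAR_BENIGN")
  live <- !benign
  set(live & trunc & cadd_ok & has_plp, "TIER1", "TRUNCATING_PLP")
  set(live & trunc & cadd_ok & !has_plp & domain, "TIER1", "TRUNCATING_DOMAIN")
  set(live & missense & has_plp, "TIER2", "MISSENSE_PLP")
  set(live & missense & !has_plp & scores_ok, "TIER2", "MISSENSE_SCORES")

  if (!is.null(panel)) {
    excl <- prefilter_variants(variants, panel, thresholds)
    tier[!is.na(excl)] <- "EXCLUDED"
    reason[!is.na(excl)] <- excl[!is.na(excl)]
  }
  data.frame(variant_key = variants$variant_key, gene = variants$gene,
             tier = tier, reason = reason, stringsAsFactors = FALSE)
}

#' Classify the distinct variants of one or more cohorts
#'
#' Convenience wrapper collecting the distinct variants seen across cohort
#' genotype sets and control allele-count tables and classifying them under
#' one set of thresholds, so case and comparison cohorts are always tiered
#' by identical rules.
#'
#' @param ... [cohort_genotypes], [control_gene_counts] or [variant_table]
#'   objects.
#' @param panel gene panel.
#' @param thresholds a [classifier_thresholds] object.
#' @return assignment data frame as in [classify_variants()], one row per
#'   distinct `variant_key` (first occurrence wins).
#' @export
classify_cohorts <- function(..., panel = NULL,
                             thresholds = classifier_thresholds()) {
  pieces <- lapply(list(...), function(x) {
    if (inherits(x, "cohort_genotypes")) cohort_variants(x)
    else if (inherits(x, "control_gene_counts")) x$rows[, .variant_cols]
    else x[, .variant_cols]
  })
  all <- do.call(rbind, pieces)
  all <- all[!duplicated(all$variant_key), , drop = FALSE]
  rownames(all) <- NULL
  classify_variants(all, panel = panel, thresholds = thresholds)
}
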