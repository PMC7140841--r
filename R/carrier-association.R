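#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value by the minimum-likelihood
#' convention: with both margins fixed, the p-value is the sum of the point
#' probabilities of every table whose probability does not exceed that of
#' the observed table, with a relative tolerance of `1e-7` for ties. This is
#' the standard two-sided convention for Fisher's test.
#'
#' @param a,b,c,d non-negative integer cell counts: `a` case carriers, `b`
#'   case non-carriers, `c` comparison carriers, `d` comparison
#'   non-carriers.
#' @return the p-value, a number in `(0, 1]`.
#' @export
#' @examples
#' fisher_two_sided(1, 121, 0, 6192)   # 0.019 at 3 d.p.
fisher_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0))
    stop_("all four cell counts must be non-negative")
  if (any(cells != round(cells))) stop_("cell counts must be integers")
  r1 <- a + b
  r2 <- c + d
  if (r1 < 1 || r2 < 1) stop_("each row margin must be at least 1")
  k <- a + c
  if (k == 0 || k == r1 + r2) return(1)
  support <- max(0, k - r2):min(k, r1)
  probs <- stats::dhyper(support, r1, r2, k)
  p0 <- probs[support == a]
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}

#' Expected carriers at a given carrier rate
#'
#' The expected number of carriers among `n` individuals when the carrier
#' rate is `rate` — used, e.g., to ask how many BRCA2 carriers a cohort of
#' 122 would be expected to yield at a 0.93% population carrier rate (1.1).
#'
#' @param rate carrier rate in `[0, 1]`.
#' @param n cohort size.
#' @return `rate * n`.
#' @export
expected_carriers <- function(rate, n) {
  stopifnot(rate >= 0, rate <= 1, n > 0)
  rate * n
}

.check_tier <- function(tier) {
  if (!tier %in% c("TIER1", "TIER2"))
    stop_("tier must be TIER1 or TIER2 (not a burden category: %s)", tier)
  tier
}

#' Count carriers in a genotyped case cohort
#'
#' Counts distinct individuals carrying at least one variant of the given
#' tier (optionally restricted to one gene); an individual with several
#' qualifying variants counts once.
#'
#' @param cohort a [cohort_genotypes] object (after QC filtering).
#' @param assignments classification as from [classify_variants()], covering
#'   every variant in the cohort.
#' @param tier `"TIER1"` or `"TIER2"`.
#' @param gene optional gene symbol; `NULL` counts across all genes.
#' @return one-row data frame: `gene` (symbol or `"ALL"`), `tier`,
#'   `n_carriers`, `n_total`, `rate`.
#' @export
case_carriers <- function(cohort, assignments, tier, gene = NULL) {
  .check_tier(tier)
  calls <- cohort$calls
  missing_keys <- setdiff(calls$variant_key, assignments$variant_key)
  if (length(missing_keys))
    stop_("assignments do not cover cohort variant(s): %s", missing_keys[1L])
  qual <- assignments$variant_key[assignments$tier == tier &
                                    (is.null(gene) |
                                       assignments$gene == toupper(gene %||% ""))]
  carriers <- unique(calls$sample_id[calls$variant_key %in% qual])
  n_total <- nrow(cohort$samples)
  if (n_total < 1L) stop_("cohort has no samples")
  data.frame(gene = toupper(gene %||% "ALL"), tier = tier,
             n_carriers = length(carriers), n_total = n_total,
             rate = length(carriers) / n_total, stringsAsFactors = FALSE)
}

#' Estimate carriers from control allele counts
#'
#' For allele-count population summaries the per-gene carrier count is the
#' sum of alternate allele counts over the gene's qualifying variants, under
#' the assumption that each individual carries at most one deleterious
#' mutation in the explored gene (capped at the denominator). The `"ALL"`
#' count sums the per-gene counts; an individual mutated in two different
#' genes would then be counted twice, a slight overestimation of the
#' cohort-wide carrier rate that is accepted by design (and conservative
#' for case-enrichment tests).
#'
#' The denominator is the cohort-level covered-persons value: the explicit
#' `covered_persons` field of the container if set, otherwise the unique
#' per-row value. When per-variant denominators differ within a gene, the
#' minimum across the gene's qualifying variants is used (conservative);
#' for `"ALL"`, differing per-row denominators without an explicit
#' cohort-level value are an error.
#'
#' @param controls a [control_gene_counts] object.
#' @param assignments classification covering every counted variant.
#' @param tier `"TIER1"` or `"TIER2"`.
#' @param gene optional gene symbol; `NULL` gives the `"ALL"` summation.
#' @return one-row data frame as in [case_carriers()].
#' @export
control_carriers <- function(controls, assignments, tier, gene = NULL) {
  .check_tier(tier)
  rows <- controls$rows
  missing_keys <- setdiff(rows$variant_key, assignments$variant_key)
  if (length(missing_keys))
    stop_("assignments do not cover control variant(s): %s", missing_keys[1L])
  asg <- assignments[match(rows$variant_key, assignments$variant_key), ]
  qual <- asg$tier == tier
  cohort_n <- controls$covered_persons
  if (is.null(cohort_n)) {
    u <- unique(rows$covered_persons)
    if (length(u) == 1L) cohort_n <- u
  }
  if (is.null(gene)) {
    if (is.null(cohort_n))
      stop_("inconsistent covered_persons across rows; supply an explicit cohort-level covered_persons for the ALL summation")
    per_gene <- tapply(rows$allele_count[qual], rows$gene[qual], sum)
    denom_g <- tapply(rows$covered_persons[qual], rows$gene[qual], min)
    n_carriers <- sum(pmin(as.integer(per_gene), as.integer(denom_g)))
    n_carriers <- min(n_carriers, cohort_n)
    gene_lab <- "ALL"
    n_total <- cohort_n
  } else {
    gene_lab <- toupper(gene)
    sel <- qual & rows$gene == gene_lab
    n_total <- if (any(sel)) min(rows$covered_persons[sel]) else
      (cohort_n %||% stop_("no qualifying rows for gene %s and no cohort-level covered_persons", gene_lab))
    n_carriers <- min(sum(rows$allele_count[sel]), n_total)
  }
  data.frame(gene = gene_lab, tier = tier, n_carriers = n_carriers,
             n_total = n_total, rate = n_carriers / n_total,
             stringsAsFactors = FALSE)
}

carriers_for <- function(cohort, assignments, tier, gene = NULL) {
  if (inherits(cohort, "cohort_genotypes"))
    case_carriers(cohort, assignments, tier, gene)
  else if (inherits(cohort, "control_gene_counts"))
    control_carriers(cohort, assignments, tier, gene)
  else stop_("unsupported cohort object of class %s", class(cohort)[1L])
}

#' Render p-values as in published carrier tables
#'
#' Three decimal places, with values below 0.0005 rendered `"<0.001"`.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_p_value <- function(p) {
  ifelse(p < 5e-4, "<0.001", sprintf("%.3f", p))
}

#' Build a gene-level carrier association table
#'
#' For every gene with at least one qualifying (Tier 1 or Tier 2) variant in
#' any cohort, and for the `"ALL"` aggregate, per tier and per comparison
#' cohort: the 2x2 carrier table and the two-sided Fisher p-value. Cases are
#' counted as distinct carrier individuals; allele-count comparison cohorts
#' are estimated as in [control_carriers()].
#'
#' @param case_cohort a [cohort_genotypes] object (after QC).
#' @param comparisons named list of comparison cohorts, each either a
#'   [cohort_genotypes] or a [control_gene_counts] object.
#' @param assignments classification of all variants involved, produced with
#'   identical thresholds for every cohort (see [classify_cohorts()]).
#' @return data frame with one row per gene x tier x comparison: `gene`,
#'   `tier`, `comparison`, the 2x2 cells `a`,`b`,`c`,`d` (`a` = case
#'   carriers, `c` = comparison carriers), unrounded `p_value`, carrier
#'   rates as percentages rounded to 2 d.p. (`rate_case_pct`,
#'   `rate_comp_pct`) and `p_display` (3 d.p., `<0.001` floor).
#' @export
build_association_table <- function(case_cohort, comparisons, assignments) {
  stopifnot(inherits(case_cohort, "cohort_genotypes"), is.list(comparisons))
  if (is.null(names(comparisons)) || any(!nzchar(names(comparisons))))
    stop_("comparisons must be a named list")
  for (cmp in comparisons) {
    if (inherits(cmp, "cohort_genotypes")) {
      shared <- intersect(case_cohort$samples$sample_id,
                          cmp$samples$sample_id)
      if (length(shared))
        stop_("case and comparison cohorts share sample id(s): %s", shared[1L])
    }
  }
  damaging <- assignments[assignments$tier %in% c("TIER1", "TIER2"), ,
                          drop = FALSE]
  genes <- sort(unique(damaging$gene))
  out <- list()
  for (tier in c("TIER1", "TIER2")) {
    for (g in c(as.list(genes), list(NULL))) {
      cc <- case_carriers(case_cohort, assignments, tier, g)
      for (nm in names(comparisons)) {
        kk <- carriers_for(comparisons[[nm]], assignments, tier, g)
        a <- cc$n_carriers; b <- cc$n_total - cc$n_carriers
        cJ <- kk$n_carriers; d <- kk$n_total - kk$n_carriers
        p <- fisher_two_sided(a, b, cJ, d)
        out[[length(out) + 1L]] <- data.frame(
          gene = cc$gene, tier = tier, comparison = nm,
          a = a, b = b, c = cJ, d = d, p_value = p,
          rate_case_pct = round(100 * cc$rate, 2),
          rate_comp_pct = round(100 * kk$rate, 2),
          p_display = format_p_value(p), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
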