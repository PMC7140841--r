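#' Per-gene carrier rates of the lethal case cohort
#'
#' Default per-gene Tier 1 and Tier 2 carrier probabilities used by the
#' simulator: the carrier counts observed among 122 lethal prostate cancer
#' cases (Tier 1: ATM 4, CHEK2 5, FANCM 2, NTHL1 2, ERCC3 1, RAD18 1;
#' Tier 2 across 14 genes), expressed as per-individual probabilities.
#'
#' @return data frame with columns `gene`, `tier1`, `tier2`.
#' @export
lethal_case_rates <- function() {
  n <- 122
  df <- data.frame(
    gene  = c("ATM", "CHEK2", "FANCM", "NTHL1", "ERCC3", "RAD18", "MUTYH",
              "HLTF", "POLL", "MRE11A", "RECQL", "FAN1", "NEIL1", "POLG",
              "TP53", "BRCA1", "RECQL5"),
    tier1 = c(4, 5, 2, 2, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0) / n,
    tier2 = c(2, 1, 0, 0, 1, 0, 0, 1, 1, 1, 1, 1, 1, 5, 2, 1, 1) / n,
    stringsAsFactors = FALSE)
  df
}

#' Simulation configuration
#'
#' Defines a synthetic study: cohort sizes, per-gene Tier 1/Tier 2 carrier
#' probabilities, the size of the generated variant catalog, and the noise
#' models for annotation scores and call-level QC fields. Defaults emulate
#' the study conditions: 122 analyzable cases, 6192 population controls,
#' the observed per-gene lethal-case carrier rates, and a fraction of
#' low-coverage samples matching the 10-of-192 exclusion of the source
#' cohorts.
#'
#' Carrier genotype calls are drawn from QC-passing distributions (allele
#' fraction Beta(20, 20) truncated at the 0.3 filter, depth Poisson with
#' mean `depth_mean` truncated at 12, readPosRankSum standard normal
#' truncated above -1.7 and missing for indels), so the configured carrier
#' probabilities are the post-QC truth the pipeline should recover. QC
#' failures are injected separately into non-carrier noise calls at rate
#' `qc_fail_fraction`, one randomly chosen failing field each, to exercise
#' the filters.
#'
#' @param seed integer seed; every draw of the generator flows from it.
#' @param n_cases number of analyzable case individuals.
#' @param n_controls control denominator (covered persons).
#' @param per_gene_tier_rates data frame `gene`/`tier1`/`tier2`; per-gene
#'   probabilities must sum to at most 1.
#' @param variant_catalog_size_per_gene catalog variants generated per gene
#'   and tier.
#' @param score_noise list: `cadd_range` and `revel_range` (uniform ranges
#'   straddling the 20 / 0.75 thresholds, used for noise variants) and
#'   `maf_log10_range` (log10-uniform MAF range for noise variants).
#' @param qc_noise list: `depth_mean` (Poisson mean), `af_shape` (Beta
#'   shape for the allele fraction), `rprs_missing_indel` (probability that
#'   readPosRankSum is missing on an indel call).
#' @param frac_low_coverage_samples fraction of sequenced samples expected
#'   to fail the 30%-of-bases-at-20x exclusion; the generator adds this many
#'   extra samples on top of `n_cases`.
#' @param noise_calls_per_sample Poisson mean of non-qualifying noise calls
#'   per retained sample.
#' @param qc_fail_fraction fraction of noise calls given one failing QC
#'   field.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_cases = 122L,
                              n_controls = 6192L,
                              per_gene_tier_rates = lethal_case_rates(),
                              variant_catalog_size_per_gene = 3L,
                              score_noise = list(cadd_range = c(5, 45),
                                                 revel_range = c(0, 1),
                                                 maf_log10_range = c(-6, log10(0.05))),
                              qc_noise = list(depth_mean = 60,
                                              af_shape = 20,
                                              rprs_missing_indel = 0.9),
                              frac_low_coverage_samples = 10 / 192,
                              noise_calls_per_sample = 2,
                              qc_fail_fraction = 0.15) {
  r <- per_gene_tier_rates
  stopifnot(is.data.frame(r), all(c("gene", "tier1", "tier2") %in% names(r)),
            n_cases >= 1, n_controls >= 1,
            variant_catalog_size_per_gene >= 1,
            frac_low_coverage_samples >= 0, frac_low_coverage_samples < 1,
            qc_fail_fraction >= 0, qc_fail_fraction <= 1)
  if (any(r$tier1 < 0 | r$tier2 < 0 | r$tier1 > 1 | r$tier2 > 1))
    stop_("carrier probabilities must lie in [0,1]")
  if (any(r$tier1 + r$tier2 > 1))
    stop_("infeasible config: tier1 + tier2 carrier probability exceeds 1 for gene %s",
          r$gene[which(r$tier1 + r$tier2 > 1)[1L]])
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 per_gene_tier_rates = transform(r, gene = toupper(gene)),
                 variant_catalog_size_per_gene =
                   as.integer(variant_catalog_size_per_gene),
                 score_noise = score_noise, qc_noise = qc_noise,
                 frac_low_coverage_samples = frac_low_coverage_samples,
                 noise_calls_per_sample = noise_calls_per_sample,
                 qc_fail_fraction = qc_fail_fraction),
            class = "simulation_config")
}

runif_range <- function(n, range) stats::runif(n, range[1L], range[2L])

# Catalog rows whose annotations guarantee the intended tier under default
# thresholds, by construction from the classifier's decision rules (rather
# than sampling until acceptance): Tier 1 alternates the ClinVar-P/LP and
# domain-disruption routes over truncating classes; Tier 2 alternates the
# ClinVar-P/LP and CADD/REVEL score routes over missense variants.
catalog_for_gene <- function(cfg, gene, tier, gene_idx) {
  k <- cfg$variant_catalog_size_per_gene
  pos0 <- gene_idx * 100000L + (if (tier == "TIER1") 0L else 50000L)
  bases <- c("A", "C", "G", "T")
  if (tier == "TIER1") {
    func <- sample(c("stopgain", "frameshift_insertion", "frameshift_deletion",
                     "splicing"), k, replace = TRUE)
    is_indel <- func %in% c("frameshift_insertion", "frameshift_deletion")
    plp_route <- seq_len(k) %% 2L == 1L
    clinvar <- ifelse(plp_route, sample(c("5", "4", "5,4", "5,3"), k,
                                        replace = TRUE), NA_character_)
    domain <- !plp_route
    cadd <- ifelse(is_indel, NA_real_, stats::runif(k, 25, 45))
    revel <- rep(NA_real_, k)
    ref <- ifelse(is_indel, paste0(sample(bases, k, TRUE),
                                   sample(bases, k, TRUE)),
                  sample(bases, k, TRUE))
    alt <- ifelse(func == "frameshift_deletion", NA_character_,
                  sample(bases, k, TRUE))
    ref[func == "frameshift_insertion"] <- NA_character_
    prot <- sprintf("%s%d%s", sample(LETTERS, k, TRUE), sample(50:999, k),
                    ifelse(func == "stopgain", "X", "fs"))
  } else {
    func <- rep("missense", k)
    plp_route <- seq_len(k) %% 2L == 1L
    clinvar <- ifelse(plp_route, sample(c("5", "4", "5,4", "4,3", "5,3"), k,
                                        replace = TRUE), NA_character_)
    domain <- rep(NA, k)
    cadd <- stats::runif(k, 20, 40)
    revel <- ifelse(plp_route, stats::runif(k, 0.3, 1),
                    stats::runif(k, 0.75, 0.99))
    ref <- sample(bases, k, TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    prot <- sprintf("%s%d%s", sample(LETTERS, k, TRUE), sample(50:999, k),
                    sample(LETTERS, k, TRUE))
  }
  data.frame(
    variant_key = sprintf("chr%d:%d:%s:%s", gene_idx %% 22L + 1L,
                          pos0 + seq_len(k), ifelse(is.na(ref), "-", ref),
                          ifelse(is.na(alt), "-", alt)),
    rsid = NA_character_, gene = gene, func_class = func,
    protein_change = prot, ref = ref, alt = alt, clinvar = clinvar,
    cadd_phred = cadd, revel = revel,
    maf = 10^stats::runif(k, -6, log10(0.005)),
    disrupts_domain = domain,
    region_class = "exonic_or_splicing",
    intended_tier = tier, stringsAsFactors = FALSE)
}

# Non-qualifying variants: common, ClinVar-benign, sub-threshold missense,
# off-panel and intergenic records that the prefilter or the neutral rule
# must remove.
noise_catalog <- function(cfg) {
  genes <- cfg$per_gene_tier_rates$gene
  kinds <- c("common", "benign", "subthreshold", "off_panel", "intergenic")
  k <- length(kinds) * max(4L, length(genes))
  kind <- rep(kinds, length.out = k)
  gene <- rep(genes, length.out = k)
  gene[kind == "off_panel"] <- sample(c("TTN", "OR2T4", "MUC16", "USH2A"),
                                      sum(kind == "off_panel"), TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, k, TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  maf <- 10^runif_range(k, cfg$score_noise$maf_log10_range)
  maf[kind == "common"] <- stats::runif(sum(kind == "common"), 0.0101, 0.05)
  maf[kind != "common"] <- pmin(maf[kind != "common"], 0.009)
  cadd <- runif_range(k, cfg$score_noise$cadd_range)
  revel <- runif_range(k, cfg$score_noise$revel_range)
  # sub-threshold missense stays neutral whichever score straddles the cut
  sub <- kind == "subthreshold"
  low_cadd <- sub & seq_len(k) %% 2L == 0L
  cadd[low_cadd] <- stats::runif(sum(low_cadd), 1, 19.9)
  revel[sub & !low_cadd] <- stats::runif(sum(sub & !low_cadd), 0, 0.74)
  cadd[sub & !low_cadd] <- stats::runif(sum(sub & !low_cadd), 20, 40)
  clinvar <- rep(NA_character_, k)
  clinvar[kind == "benign"] <- sample(c("1", "2", "2,3", "2,1"),
                                      sum(kind == "benign"), TRUE)
  cadd[kind == "benign"] <- stats::runif(sum(kind == "benign"), 20, 40)
  revel[kind == "benign"] <- stats::runif(sum(kind == "benign"), 0.75, 0.99)
  data.frame(
    variant_key = sprintf("chr%d:%d:%s:%s", seq_len(k) %% 22L + 1L,
                          9000000L + seq_len(k), ref, alt),
    rsid = NA_character_, gene = gene, func_class = "missense",
    protein_change = sprintf("%s%d%s", sample(LETTERS, k, TRUE),
                             sample(50:999, k), sample(LETTERS, k, TRUE)),
    ref = ref, alt = alt, clinvar = clinvar, cadd_phred = cadd,
    revel = revel, maf = maf, disrupts_domain = NA,
    region_class = ifelse(kind == "intergenic", "intergenic",
                          "exonic_or_splicing"),
    intended_tier = "NONE", stringsAsFactors = FALSE)
}

#' Generate the synthetic variant catalog
#'
#' Builds, deterministically from the configuration seed, a catalog of
#' variants whose annotations guarantee their intended tier under default
#' thresholds, plus non-qualifying noise variants (common, ClinVar-benign,
#' sub-threshold, off-panel, intergenic). The same catalog underlies
#' [simulate_case_cohort()] and [simulate_control_counts()] for a given
#' configuration, so case and control cohorts share variants.
#'
#' @param cfg a [simulation_config].
#' @return a [variant_table] with an extra `intended_tier` column
#'   (`"TIER1"`, `"TIER2"` or `"NONE"`).
#' @export
simulate_variant_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, build_catalog(cfg))
}

build_catalog <- function(cfg) {
  r <- cfg$per_gene_tier_rates
  pieces <- list()
  for (i in seq_len(nrow(r))) {
    pieces[[length(pieces) + 1L]] <- catalog_for_gene(cfg, r$gene[i], "TIER1", i)
    pieces[[length(pieces) + 1L]] <- catalog_for_gene(cfg, r$gene[i], "TIER2", i)
  }
  pieces[[length(pieces) + 1L]] <- noise_catalog(cfg)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

carrier_call_qc <- function(n, cfg, is_indel) {
  shape <- cfg$qc_noise$af_shape
  af <- stats::qbeta(stats::runif(n, stats::pbeta(0.3, shape, shape), 1),
                     shape, shape)
  dp <- stats::qpois(stats::runif(n, stats::ppois(11, cfg$qc_noise$depth_mean), 1),
                     cfg$qc_noise$depth_mean)
  rprs <- stats::qnorm(stats::runif(n, stats::pnorm(-1.7), 1))
  rprs[is_indel & stats::runif(n) < cfg$qc_noise$rprs_missing_indel] <- NA
  data.frame(allele_fraction = af, depth = as.integer(dp),
             read_pos_rank_sum = rprs, filter_status = "PASS",
             stringsAsFactors = FALSE)
}

failing_call_qc <- function(n, cfg) {
  qc <- carrier_call_qc(n, cfg, is_indel = rep(FALSE, n))
  rule <- sample(c("af", "depth", "rprs", "vqsr"), n, replace = TRUE)
  qc$allele_fraction[rule == "af"] <- stats::runif(sum(rule == "af"), 0, 0.29)
  qc$depth[rule == "depth"] <- sample(0:11, sum(rule == "depth"), TRUE)
  qc$read_pos_rank_sum[rule == "rprs"] <-
    stats::runif(sum(rule == "rprs"), -6, -1.7)
  qc$filter_status[rule == "vqsr"] <- "FAIL"
  qc
}

#' Simulate a genotyped case cohort
#'
#' Per analyzable individual and gene, carrier status is drawn Bernoulli at
#' the configured Tier 1 / Tier 2 probabilities (at most one qualifying
#' variant per gene per individual); carriers receive a variant drawn from
#' the gene's catalog of the intended tier with QC-passing call fields.
#' Noise calls on non-qualifying variants — a configured fraction of which
#' fail one QC filter each — are added per sample, and
#' `frac_low_coverage_samples` extra samples are generated below the
#' coverage-exclusion threshold (with a token call each) so the sample
#' filter has work to do. Fully deterministic given the configuration seed.
#'
#' @param cfg a [simulation_config].
#' @param cohort_label label for the generated cohort.
#' @return a [cohort_genotypes] object; the catalog used (including
#'   `intended_tier`) is attached as the `"catalog"` attribute and the
#'   per-gene true carrier draws as the `"truth"` attribute.
#' @export
simulate_case_cohort <- function(cfg, cohort_label = "synthetic_cases") {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    catalog <- build_catalog(cfg)
    r <- cfg$per_gene_tier_rates
    n <- cfg$n_cases
    f <- cfg$frac_low_coverage_samples
    n_low <- round(n * f / (1 - f))
    ids <- sprintf("S%04d", seq_len(n + n_low))
    low <- ids[seq_len(n_low) + n]
    samples <- data.frame(
      sample_id = ids,
      frac_bases_ge_20x = c(stats::runif(n, 0.80, 0.99),
                            stats::runif(n_low, 0.05, 0.295)),
      stringsAsFactors = FALSE)
    calls <- list()
    truth <- list()
    for (i in seq_len(nrow(r))) {
      u <- stats::runif(n)
      tier <- ifelse(u < r$tier1[i], "TIER1",
                     ifelse(u < r$tier1[i] + r$tier2[i], "TIER2", NA))
      truth[[i]] <- data.frame(gene = r$gene[i],
                               tier1_carriers = sum(tier == "TIER1", na.rm = TRUE),
                               tier2_carriers = sum(tier == "TIER2", na.rm = TRUE),
                               stringsAsFactors = FALSE)
      for (tt in c("TIER1", "TIER2")) {
        who <- which(!is.na(tier) & tier == tt)
        if (!length(who)) next
        pool <- catalog[catalog$gene == r$gene[i] &
                          catalog$intended_tier == tt, , drop = FALSE]
        pick <- pool[sample(nrow(pool), length(who), replace = TRUE), ,
                     drop = FALSE]
        qc <- carrier_call_qc(length(who), cfg,
                              grepl("frameshift", pick$func_class))
        calls[[length(calls) + 1L]] <-
          cbind(data.frame(sample_id = ids[who], stringsAsFactors = FALSE),
                pick[, .variant_cols], qc)
      }
    }
    # noise calls on retained samples
    noise_pool <- catalog[catalog$intended_tier == "NONE", , drop = FALSE]
    n_noise <- stats::rpois(n, cfg$noise_calls_per_sample)
    who <- rep(ids[seq_len(n)], n_noise)
    if (length(who)) {
      pick <- noise_pool[sample(nrow(noise_pool), length(who), TRUE), ,
                         drop = FALSE]
      fail <- stats::runif(length(who)) < cfg$qc_fail_fraction
      qc <- carrier_call_qc(length(who), cfg, rep(FALSE, length(who)))
      if (any(fail)) qc[fail, ] <- failing_call_qc(sum(fail), cfg)
      calls[[length(calls) + 1L]] <-
        cbind(data.frame(sample_id = who, stringsAsFactors = FALSE),
              pick[, .variant_cols], qc)
    }
    if (n_low > 0L) {
      pick <- noise_pool[sample(nrow(noise_pool), n_low, TRUE), , drop = FALSE]
      calls[[length(calls) + 1L]] <-
        cbind(data.frame(sample_id = low, stringsAsFactors = FALSE),
              pick[, .variant_cols],
              carrier_call_qc(n_low, cfg, rep(FALSE, n_low)))
    }
    calls <- do.call(rbind, calls)
    calls <- calls[!duplicated(calls[, c("sample_id", "variant_key")]), ,
                   drop = FALSE]
    rownames(calls) <- NULL
    out <- cohort_genotypes(cohort_label, samples, calls)
    attr(out, "catalog") <- catalog
    attr(out, "truth") <- do.call(rbind, truth)
    out
  })
}

#' Simulate a control allele-count table
#'
#' Per gene and tier, the number of carrier alleles is drawn
#' Binomial(`n_controls`, rate) — one allele per carrier, matching the
#' at-most-one-mutation-per-gene assumption used when estimating carrier
#' rates from allele counts — and split multinomially across the gene's
#' catalog variants of that tier. Benign/common noise variants receive
#' small background counts. The covered-persons denominator is
#' `n_controls` for every row.
#'
#' @param cfg a [simulation_config]; carrier rates are taken from
#'   `cfg$per_gene_tier_rates` (pass a config with control-specific rates to
#'   emulate a different population).
#' @param population_label label for the generated population.
#' @return a [control_gene_counts] object with the catalog attached as the
#'   `"catalog"` attribute.
#' @export
simulate_control_counts <- function(cfg, population_label = "synthetic_controls") {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    catalog <- build_catalog(cfg)
    r <- cfg$per_gene_tier_rates
    rows <- list()
    for (i in seq_len(nrow(r))) {
      for (tt in c("TIER1", "TIER2")) {
        rate <- if (tt == "TIER1") r$tier1[i] else r$tier2[i]
        pool <- catalog[catalog$gene == r$gene[i] &
                          catalog$intended_tier == tt, , drop = FALSE]
        total <- stats::rbinom(1L, cfg$n_controls, rate)
        split <- as.integer(stats::rmultinom(1L, total,
                                             rep(1, nrow(pool))))
        rows[[length(rows) + 1L]] <-
          cbind(pool[, .variant_cols],
                data.frame(allele_count = split,
                           covered_persons = cfg$n_controls))
      }
    }
    noise_pool <- catalog[catalog$intended_tier == "NONE", , drop = FALSE]
    rows[[length(rows) + 1L]] <-
      cbind(noise_pool[, .variant_cols],
            data.frame(allele_count = stats::rbinom(nrow(noise_pool),
                                                    cfg$n_controls, 0.001),
                       covered_persons = cfg$n_controls))
    rows <- do.call(rbind, rows)
    rownames(rows) <- NULL
    out <- control_gene_counts(population_label, rows,
                               covered_persons = cfg$n_controls)
    attr(out, "catalog") <- catalog
    out
  })
}
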