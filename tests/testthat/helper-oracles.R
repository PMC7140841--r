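# Independent oracles and small-object builders shared across tests.

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins, compute each table's probability directly from binomial
# coefficients, and sum those no more likely than the observed table.
oracle_fisher <- function(a, b, c, d, tol = 1e-7) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  av <- max(0, k - r2):min(k, r1)
  p <- exp(lchoose(r1, av) + lchoose(r2, k - av) - lchoose(r1 + r2, k))
  p0 <- p[av == a]
  min(1, sum(p[p <= p0 * (1 + tol)]))
}

# Row-by-row QC retention predicate, written independently of filter_calls.
oracle_keep_call <- function(af, depth, rprs, status, thr = qc_thresholds()) {
  status == "PASS" && af >= thr$min_allele_fraction &&
    depth >= thr$min_depth &&
    (is.na(rprs) || rprs > thr$max_read_pos_rank_sum)
}

# A valid variant table from per-field vectors, with sensible defaults.
make_variants <- function(gene, func_class, clinvar = NA_character_,
                          cadd = NA_real_, revel = NA_real_, maf = NA_real_,
                          domain = NA, region = "exonic_or_splicing",
                          key = NULL) {
  n <- length(gene)
  is_snv <- func_class %in% c("missense", "stopgain", "splicing")
  data.frame(
    variant_key = key %||% sprintf("chr1:%d:A:G", seq_len(n) + 1000L),
    rsid = rep_len(NA_character_, n), gene = toupper(gene),
    func_class = func_class, protein_change = sprintf("P%d", seq_len(n)),
    ref = ifelse(is_snv, "A", NA_character_),
    alt = ifelse(is_snv, "G", NA_character_),
    clinvar = rep_len(as.character(clinvar), n),
    cadd_phred = rep_len(cadd, n), revel = rep_len(revel, n),
    maf = rep_len(maf, n), disrupts_domain = rep_len(domain, n),
    region_class = rep_len(region, n), stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A cohort with one passing call per (sample, variant) pair.
make_cohort <- function(sample_ids, variant_rows, call_pairs,
                        frac_cov = 0.95, label = "cases") {
  samples <- data.frame(sample_id = sample_ids,
                        frac_bases_ge_20x = rep_len(frac_cov,
                                                    length(sample_ids)),
                        stringsAsFactors = FALSE)
  calls <- cbind(
    data.frame(sample_id = call_pairs$sample_id, stringsAsFactors = FALSE),
    variant_rows[match(call_pairs$variant_key, variant_rows$variant_key), ],
    data.frame(allele_fraction = 0.5, depth = 50L,
               read_pos_rank_sum = NA_real_, filter_status = "PASS",
               stringsAsFactors = FALSE))
  rownames(calls) <- NULL
  cohort_genotypes(label, samples, calls)
}

# Control counts with one qualifying variant per gene at a given tier.
make_controls <- function(genes, counts, covered, tier = "TIER1",
                          label = "controls") {
  func <- if (tier == "TIER1") "stopgain" else "missense"
  rows <- cbind(
    make_variants(genes, rep(func, length(genes)), clinvar = "5",
                  cadd = 35, revel = if (tier == "TIER2") 0.9 else NA_real_,
                  maf = 1e-4,
                  key = sprintf("chr2:%d:C:T", seq_along(genes) + 5000L)),
    data.frame(allele_count = counts,
               covered_persons = rep_len(covered, length(genes))))
  control_gene_counts(label, rows, covered_persons = covered)
}

random_qc_cohort <- function(n_samples = 20, n_calls = 60) {
  vt <- make_variants(sample(c("ATM", "CHEK2", "TP53"), n_calls, TRUE),
                      sample(c("missense", "stopgain"), n_calls, TRUE),
                      key = sprintf("chr3:%d:A:G", seq_len(n_calls)))
  samples <- data.frame(sample_id = sprintf("P%03d", seq_len(n_samples)),
                        frac_bases_ge_20x = runif(n_samples, 0, 1))
  calls <- cbind(
    data.frame(sample_id = sample(samples$sample_id, n_calls, TRUE)),
    vt,
    data.frame(allele_fraction = runif(n_calls),
               depth = rpois(n_calls, 15),
               read_pos_rank_sum = ifelse(runif(n_calls) < 0.3, NA,
                                          rnorm(n_calls, 0, 2)),
               filter_status = sample(c("PASS", "FAIL"), n_calls, TRUE,
                                      prob = c(0.9, 0.1))))
  calls <- calls[!duplicated(calls[, c("sample_id", "variant_key")]), ]
  rownames(calls) <- NULL
  cohort_genotypes("random", samples, calls)
}
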