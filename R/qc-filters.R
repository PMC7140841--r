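#' Quality-control thresholds
#'
#' Defaults follow standard germline exome practice: samples with less than
#' 30% of target bases covered by at least 20 reads are excluded; calls with
#' an allele fraction below 0.3 or site depth below 12 are removed; calls
#' with a readPosRankSum of -1.7 or lower are removed (strongly negative
#' values indicate the variant is seen only near read ends, an alignment
#' artifact signature). Upstream variant-quality recalibration is consumed
#' as the `filter_status` PASS/FAIL flag.
#'
#' @param min_frac_bases_20x minimum fraction of bases at >= 20x per sample.
#' @param min_allele_fraction minimum variant allele fraction per call.
#' @param min_depth minimum read depth per call.
#' @param max_read_pos_rank_sum calls with `read_pos_rank_sum <=` this value
#'   are discarded; an absent value is non-disqualifying (the annotation is
#'   routinely missing for indel and homozygous calls).
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_frac_bases_20x = 0.30,
                          min_allele_fraction = 0.3,
                          min_depth = 12L,
                          max_read_pos_rank_sum = -1.7) {
  stopifnot(is.finite(min_frac_bases_20x), min_frac_bases_20x >= 0,
            min_frac_bases_20x <= 1, is.finite(min_allele_fraction),
            is.finite(min_depth), is.finite(max_read_pos_rank_sum))
  structure(list(min_frac_bases_20x = min_frac_bases_20x,
                 min_allele_fraction = min_allele_fraction,
                 min_depth = as.integer(min_depth),
                 max_read_pos_rank_sum = max_read_pos_rank_sum),
            class = "qc_thresholds")
}

#' Exclude samples with insufficient sequencing coverage
#'
#' Removes every sample whose fraction of target bases at >= 20x is strictly
#' below the threshold, together with all of its calls.
#'
#' @param cohort a [cohort_genotypes] object.
#' @param thresholds a [qc_thresholds] object.
#' @param verbose emit a per-stage count message.
#' @return list with elements `cohort` (retained [cohort_genotypes]) and
#'   `excluded_samples` (character vector of removed sample ids).
#' @export
filter_samples <- function(cohort, thresholds = qc_thresholds(),
                           verbose = FALSE) {
  keep <- cohort$samples$frac_bases_ge_20x >= thresholds$min_frac_bases_20x
  excluded <- cohort$samples$sample_id[!keep]
  samples <- cohort$samples[keep, , drop = FALSE]
  calls <- cohort$calls[cohort$calls$sample_id %in% samples$sample_id, ,
                        drop = FALSE]
  rownames(samples) <- rownames(calls) <- NULL
  if (verbose)
    message(sprintf("filter_samples: excluded %d of %d samples (< %.0f%% bases at >=20x)",
                    length(excluded), length(keep),
                    100 * thresholds$min_frac_bases_20x))
  list(cohort = cohort_genotypes(cohort$cohort_label, samples, calls),
       excluded_samples = excluded)
}

#' Filter variant calls on call-level quality
#'
#' A call is retained iff `filter_status == "PASS"`, `allele_fraction >=`
#' the minimum, `depth >=` the minimum, and `read_pos_rank_sum` is either
#' absent or strictly greater than the cutoff. The three value filters are a
#' single conjunction, so the result is order-independent and idempotent.
#'
#' @inheritParams filter_samples
#' @return the filtered [cohort_genotypes]; the per-rule removal counts are
#'   attached as the `"filter_log"` attribute.
#' @export
filter_calls <- function(cohort, thresholds = qc_thresholds(),
                         verbose = FALSE) {
  calls <- cohort$calls
  fail_vqsr <- calls$filter_status != "PASS"
  fail_af <- calls$allele_fraction < thresholds$min_allele_fraction
  fail_dp <- calls$depth < thresholds$min_depth
  fail_rprs <- !is.na(calls$read_pos_rank_sum) &
    calls$read_pos_rank_sum <= thresholds$max_read_pos_rank_sum
  keep <- !(fail_vqsr | fail_af | fail_dp | fail_rprs)
  log <- c(vqsr_fail = sum(fail_vqsr), low_allele_fraction = sum(fail_af),
           low_depth = sum(fail_dp), read_pos_rank_sum = sum(fail_rprs),
           removed = sum(!keep), retained = sum(keep))
  if (verbose)
    message(sprintf("filter_calls: removed %d of %d calls (VQSR %d, AF %d, depth %d, readPosRankSum %d)",
                    log[["removed"]], nrow(calls), log[["vqsr_fail"]],
                    log[["low_allele_fraction"]], log[["low_depth"]],
                    log[["read_pos_rank_sum"]]))
  kept <- calls[keep, , drop = FALSE]
  rownames(kept) <- NULL
  out <- cohort_genotypes(cohort$cohort_label, cohort$samples, kept)
  attr(out, "filter_log") <- log
  out
}
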