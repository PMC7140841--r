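#' Packaged study fixtures
#'
#' The package ships, as plain-text fixtures, the desk-scale data of the
#' lethal prostate cancer study it reproduces: the 31 potentially damaging
#' variants identified among 122 lethal cases with their annotations and
#' published tier labels; the published gene-level carrier counts for the
#' lethal (n = 122) and unselected (n = 60) case cohorts and the Finnish
#' (n = 3307) and Swedish (n = 6192) population controls; and a default
#' DNA-repair gene panel.
#'
#' @name fixtures
NULL

fixture_path <- function(file) {
  system.file("extdata", file, package = "repaircarrier", mustWork = TRUE)
}

#' @describeIn fixtures the 31 lethal-case variants as a [variant_table]
#'   with an extra `printed_tier` column (the published tier label, for
#'   regression checks). Domain-disruption flags are set for the truncating
#'   variants that lack a ClinVar pathogenic/likely-pathogenic assertion.
#' @export
lethal_case_variants <- function() {
  path <- fixture_path("lethal_case_variants.tsv")
  vt <- read_variant_table(path, dialect = "tsv")
  raw <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  vt$printed_tier <- paste0("TIER", raw$tier)
  vt
}

#' @describeIn fixtures published per-gene carrier counts by tier and
#'   cohort, with the printed p-value strings; cohort denominators are
#'   attached as the `"denominators"` attribute.
#' @export
published_carrier_counts <- function() {
  path <- fixture_path("published_carrier_counts.tsv")
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = c(gene = "character",
                                         tier = "character",
                                         p_unselected = "character",
                                         p_finnish = "character",
                                         p_swedish = "character"))
  header <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  denom <- list()
  for (h in grep("n_", header, value = TRUE)) {
    kv <- strsplit(sub("^#\\s*", "", h), "=")[[1L]]
    denom[[trimws(kv[1L])]] <- as.integer(kv[2L])
  }
  attr(df, "denominators") <- denom
  df
}

#' @describeIn fixtures the default DNA-repair gene panel: the 17 genes in
#'   which damaging case variants were found, extended with canonical
#'   repair genes screened by such panels. For faithful reuse on real data,
#'   supply the full analysis panel instead.
#' @export
default_repair_panel <- function() {
  read_gene_panel(fixture_path("dna_repair_panel.txt"))
}
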