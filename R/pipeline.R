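#' Run the full prioritization and association pipeline
#'
#' Executes, in order: sample coverage exclusion, call-level QC filtering,
#' tier classification of the distinct variants (cases and, when supplied,
#' controls, under one set of thresholds), carrier association versus every
#' comparison cohort, and report writing. Outputs are `assignments.tsv`,
#' `association.tsv` (when any comparison is configured) and a
#' `run_summary.json` with the per-stage record counts and the thresholds
#' used. Re-running on the same inputs produces byte-identical reports.
#'
#' @param config a list, or path to a YAML file, with entries:
#'   * `paths`: `case_calls`, `case_samples`, `panel`, optionally one or
#'     more `controls` (control allele-count TSVs, named), and `out_dir`.
#'   * `cohort_label` (default `"cases"`).
#'   * `qc`: overrides for [qc_thresholds()] arguments.
#'   * `classifier`: overrides for [classifier_thresholds()] arguments.
#' @return invisibly, a list with the retained cohort, assignments,
#'   association table (or `NULL`) and the run summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  paths <- config$paths %||% stop_("config lacks a 'paths' block")
  for (nm in c("case_calls", "case_samples", "panel", "out_dir"))
    if (is.null(paths[[nm]])) stop_("config paths lack '%s'", nm)
  for (nm in c("case_calls", "case_samples", "panel"))
    if (!file.exists(paths[[nm]]))
      stop_("missing input: %s (%s)", nm, paths[[nm]])
  dir.create(paths$out_dir, showWarnings = FALSE, recursive = TRUE)

  qc_thr <- do.call(qc_thresholds, config$qc %||% list())
  cls_thr <- do.call(classifier_thresholds, config$classifier %||% list())
  cohort <- read_cohort_genotypes(paths$case_calls, paths$case_samples,
                                  config$cohort_label %||% "cases")
  panel <- read_gene_panel(paths$panel)

  n_samples_in <- nrow(cohort$samples)
  n_calls_in <- nrow(cohort$calls)
  fs <- filter_samples(cohort, qc_thr)
  calls_after_samples <- nrow(fs$cohort$calls)
  filtered <- filter_calls(fs$cohort, qc_thr)
  flog <- attr(filtered, "filter_log")

  controls <- list()
  ctrl_paths <- paths$controls %||% list()
  if (is.character(ctrl_paths))
    ctrl_paths <- as.list(stats::setNames(ctrl_paths,
                                          names(ctrl_paths) %||%
                                            basename(ctrl_paths)))
  for (nm in names(ctrl_paths)) {
    if (!file.exists(ctrl_paths[[nm]]))
      stop_("missing input: controls '%s' (%s)", nm, ctrl_paths[[nm]])
    controls[[nm]] <- read_control_counts(ctrl_paths[[nm]],
                                          population_label = nm)
  }

  assignments <- do.call(classify_cohorts,
                         c(list(filtered), unname(controls),
                           list(panel = panel, thresholds = cls_thr)))
  write_assignments(assignments, file.path(paths$out_dir, "assignments.tsv"))

  association <- NULL
  if (length(controls)) {
    association <- build_association_table(filtered, controls, assignments)
    write_association_report(association,
                             file.path(paths$out_dir, "association.tsv"))
  }

  summary <- list(
    cohort_label = filtered$cohort_label,
    thresholds = list(qc = unclass(qc_thr), classifier = unclass(cls_thr)),
    samples = list(input = n_samples_in,
                   excluded = length(fs$excluded_samples),
                   retained = nrow(filtered$samples)),
    calls = list(input = n_calls_in,
                 removed_with_samples = n_calls_in - calls_after_samples,
                 removed_by_call_filters = unname(flog[["removed"]]),
                 removed_per_rule = as.list(flog[c("vqsr_fail",
                                                   "low_allele_fraction",
                                                   "low_depth",
                                                   "read_pos_rank_sum")]),
                 retained = nrow(filtered$calls)),
    variants = as.list(table(assignments$tier)),
    outputs = list(assignments = "assignments.tsv",
                   association = if (length(controls)) "association.tsv"))
  jsonlite::write_json(summary,
                       file.path(paths$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = filtered, excluded_samples = fs$excluded_samples,
                 assignments = assignments, association = association,
                 summary = summary))
}
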