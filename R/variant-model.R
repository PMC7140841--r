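#' @name variant_table
#' @title Annotated variant tables
#'
#' @description
#' Variants are carried as plain data frames with one row per variant and a
#' fixed set of columns:
#'
#' * `variant_key` — `chrom:pos:ref:alt` (1-based VCF convention) when
#'   coordinates are available, otherwise a stable surrogate such as
#'   `gene:protein_change`; the genome build travels as the `"genome"`
#'   attribute (default `"hg19"`).
#' * `rsid`, `gene`, `protein_change`, `ref`, `alt` — character, `NA` allowed
#'   except `gene`.
#' * `func_class` — one of `"stopgain"`, `"frameshift_insertion"`,
#'   `"frameshift_deletion"`, `"splicing"`, `"missense"`, `"other"`.
#' * `clinvar` — comma-separated clinical-significance codes as asserted by
#'   submitters (`5` pathogenic, `4` likely pathogenic, `3` uncertain,
#'   `2` likely benign, `1` benign), e.g. `"5,4,3"`; `NA` when unreported.
#' * `cadd_phred` — non-negative scaled deleteriousness score, `NA` allowed
#'   (typically absent for indels).
#' * `revel` — missense ensemble pathogenicity score in `[0,1]`, `NA` allowed.
#' * `maf` — reference-population minor allele frequency in `[0,0.5]`,
#'   `NA` allowed.
#' * `disrupts_domain` — logical; `TRUE` when a truncation occurs before or
#'   within an annotated protein domain. This is an input annotation; `NA`
#'   is treated as `FALSE` by the classifier.
#' * `region_class` — `"exonic_or_splicing"`, `"intergenic"` or
#'   `"other_noncoding"`.
#'
#' `validate_variant_table()` checks the column contract and value ranges and
#' returns its input invisibly.
NULL

.func_class_levels <- c("stopgain", "frameshift_insertion",
                        "frameshift_deletion", "splicing", "missense", "other")
.region_levels <- c("exonic_or_splicing", "intergenic", "other_noncoding")
.variant_cols <- c("variant_key", "rsid", "gene", "func_class",
                   "protein_change", "ref", "alt", "clinvar", "cadd_phred",
                   "revel", "maf", "disrupts_domain", "region_class")

# Tokens accepted on input (ANNOVAR-style and free-text) -> canonical class.
.func_aliases <- c(
  "stopgain"            = "stopgain",
  "stopgain snv"        = "stopgain",
  "frameshift ins"      = "frameshift_insertion",
  "frameshift insertion" = "frameshift_insertion",
  "frameshift_insertion" = "frameshift_insertion",
  "frameshift del"      = "frameshift_deletion",
  "frameshift deletion" = "frameshift_deletion",
  "frameshift_deletion" = "frameshift_deletion",
  "splicing"            = "splicing",
  "splice"              = "splicing",
  "missense"            = "missense",
  "nonsynonymous snv"   = "missense",
  "other"               = "other")

canonical_func_class <- function(x) {
  key <- tolower(trimws(x))
  out <- unname(.func_aliases[key])
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop_("unknown variant class token '%s'; accepted tokens: %s",
          x[bad[1L]], paste(sort(unique(names(.func_aliases))), collapse = ", "))
  }
  out
}

parse_clinvar_codes <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(gsub("\\s", "", x), ",")[[1L]])
}

clinvar_has_plp <- function(clinvar) {
  vapply(clinvar, function(s) any(parse_clinvar_codes(s) %in% c(4L, 5L)),
         logical(1), USE.NAMES = FALSE)
}

clinvar_benign_only <- function(clinvar) {
  vapply(clinvar, function(s) {
    codes <- parse_clinvar_codes(s)
    any(codes %in% c(1L, 2L)) && !any(codes %in% c(4L, 5L))
  }, logical(1), USE.NAMES = FALSE)
}

#' @rdname variant_table
#' @param variants data frame to validate.
#' @export
validate_variant_table <- function(variants) {
  stopifnot(is.data.frame(variants))
  missing_cols <- setdiff(.variant_cols, names(variants))
  if (length(missing_cols))
    stop_("variant table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (nrow(variants) == 0L) return(invisible(variants))
  if (anyNA(variants$gene) || any(!nzchar(variants$gene)))
    stop_("variant table has rows without a gene symbol")
  bad <- setdiff(unique(variants$func_class), .func_class_levels)
  if (length(bad))
    stop_("invalid func_class value(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(variants$region_class), .region_levels)
  if (length(bad))
    stop_("invalid region_class value(s): %s", paste(bad, collapse = ", "))
  chk_range <- function(v, lo, hi, nm) {
    out <- !is.na(v) & (v < lo | v > hi)
    if (any(out)) stop_("%s out of [%g,%g] in row %d", nm, lo, hi, which(out)[1L])
  }
  chk_range(variants$revel, 0, 1, "revel")
  chk_range(variants$maf, 0, 0.5, "maf")
  chk_range(variants$cadd_phred, 0, Inf, "cadd_phred")
  for (i in seq_len(nrow(variants))) {
    codes <- parse_clinvar_codes(variants$clinvar[i])
    if (length(codes) && !all(codes %in% 1:5))
      stop_("clinvar codes outside 1..5 in row %d ('%s')", i,
            variants$clinvar[i])
  }
  mis <- variants$func_class == "missense" &
    !is.na(variants$ref) & !is.na(variants$alt)
  if (any(mis & (nchar(variants$ref) != 1L | nchar(variants$alt) != 1L)))
    stop_("missense variants must be single-nucleotide substitutions (row %d)",
          which(mis & (nchar(variants$ref) != 1L | nchar(variants$alt) != 1L))[1L])
  if (anyDuplicated(variants$variant_key))
    stop_("duplicate variant_key '%s'",
          variants$variant_key[duplicated(variants$variant_key)][1L])
  invisible(variants)
}

# Assemble the canonical column set from parsed character/numeric vectors,
# deriving variant_key when coordinates are absent.
build_variant_table <- function(df, genome = "hg19") {
  n <- nrow(df)
  get_chr <- function(nm) {
    v <- df[[nm]] %||% rep(NA_character_, n)
    v <- trimws(as.character(v))
    v[v %in% c("-", ".", "")] <- NA_character_
    v
  }
  gene <- toupper(get_chr("gene"))
  ref <- get_chr("ref"); alt <- get_chr("alt")
  protein_change <- get_chr("protein_change")
  chrom <- get_chr("chrom"); pos <- get_chr("pos")
  key <- get_chr("variant_key")
  derived <- ifelse(!is.na(chrom) & !is.na(pos),
                    paste(chrom, pos, ifelse(is.na(ref), "-", ref),
                          ifelse(is.na(alt), "-", alt), sep = ":"),
                    ifelse(!is.na(protein_change), paste(gene, protein_change, sep = ":"),
                           paste(gene, get_chr("rsid"), seq_len(n), sep = ":")))
  key[is.na(key)] <- derived[is.na(key)]
  dd <- df[["disrupts_domain"]] %||% rep(NA, n)
  if (!is.logical(dd)) {
    dd <- tolower(trimws(as.character(dd)))
    dd <- ifelse(dd %in% c("true", "t", "1", "yes"), TRUE,
                 ifelse(dd %in% c("false", "f", "0", "no"), FALSE, NA))
  }
  region <- get_chr("region_class")
  region[is.na(region)] <- "exonic_or_splicing"
  clinvar <- get_chr("clinvar")
  out <- data.frame(
    variant_key = key,
    rsid = get_chr("rsid"),
    gene = gene,
    func_class = canonical_func_class(df[["type"]] %||% df[["func_class"]]),
    protein_change = protein_change,
    ref = ref,
    alt = alt,
    clinvar = clinvar,
    cadd_phred = parse_numeric(df[["cadd"]] %||% df[["cadd_phred"]] %||%
                                 rep(NA_character_, n)),
    revel = parse_numeric(df[["revel"]] %||% rep(NA_character_, n)),
    maf = parse_numeric(df[["maf"]] %||% rep(NA_character_, n)),
    disrupts_domain = dd,
    region_class = tolower(region),
    stringsAsFactors = FALSE)
  attr(out, "genome") <- genome
  validate_variant_table(out)
  out
}

#' Read an annotated variant table
#'
#' @param path path to a tab-delimited table or a VCF 4.x file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param mapping for the VCF dialect, a named list mapping canonical fields
#'   to INFO keys; see [default_vcf_mapping()]. May also be a path to a YAML
#'   file with a `mapping:` block.
#' @param genome genome build label carried as metadata.
#'
#' The TSV dialect requires (case-insensitively) at least the columns
#' `gene`, `type`, `clinvar`, `cadd`, `revel`, `maf`; `rsid`, `ref`, `alt`,
#' `protein_change`, `chrom`, `pos`, `disrupts_domain` and `region_class` are
#' honored when present and `"-"`/`"."` denote missing values. Minor allele
#' frequencies in typeset scientific notation (`"2.5 × 10−5"`) are accepted.
#'
#' @return a [variant_table] data frame.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               mapping = default_vcf_mapping(),
                               genome = "hg19") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_("variant table not found: %s", path)
  if (dialect == "vcf") return(read_variant_vcf(path, mapping, genome))

  lines <- readLines(path, warn = FALSE)
  header_at <- which(!grepl("^\\s*(#|$)", lines))[1L]
  if (is.na(header_at)) stop_("no header line found in %s", path)
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  names(df) <- tolower(names(df))
  need <- c("gene", "type", "clinvar", "cadd", "revel", "maf")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_("%s: header lacks required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(build_variant_table(df[0, , drop = FALSE], genome))

  # Report parse failures with the 1-based file line of the offending row.
  line_of <- function(i) header_at + i
  for (col in c("cadd", "revel", "maf")) {
    raw <- trimws(df[[col]])
    parsed <- parse_numeric(raw)
    bad <- which(is.na(parsed) & !(raw %in% c("-", ".", "", "NA")))
    if (length(bad))
      stop_("%s: line %d, column '%s': cannot parse '%s' as a number",
            path, line_of(bad[1L]), col, raw[bad[1L]])
  }
  tryCatch(build_variant_table(df, genome), error = function(e) {
    stop_("%s: %s", path, conditionMessage(e))
  })
}

#' Default VCF INFO-field mapping
#'
#' Annotation pipelines differ in how they name INFO keys; the reader is
#' therefore configured with a mapping from canonical fields to keys. The
#' default matches the TSV column vocabulary.
#'
#' @return named list of INFO keys.
#' @export
default_vcf_mapping <- function() {
  list(gene = "GENE", func_class = "FUNC_CLASS", clinvar = "CLNSIG",
       cadd = "CADD_PHRED", revel = "REVEL", maf = "MAF",
       protein_change = "PROTEIN_CHANGE", disrupts_domain = "DOMAIN_DISRUPT",
       region_class = "REGION_CLASS")
}

#' Read reader configuration from YAML
#'
#' Reads a YAML file with optional keys `mapping` (INFO-field mapping, see
#' [default_vcf_mapping()]), `missing_tokens` and `genome`; absent keys fall
#' back to package defaults.
#'
#' @param path YAML file.
#' @return list with elements `mapping`, `missing_tokens`, `genome`.
#' @export
read_reader_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(mapping = utils::modifyList(default_vcf_mapping(),
                                   cfg$mapping %||% list()),
       missing_tokens = cfg$missing_tokens %||% c("-", ".", "", "NA"),
       genome = cfg$genome %||% "hg19")
}

read_variant_vcf <- function(path, mapping, genome) {
  if (is.character(mapping) && length(mapping) == 1L)
    mapping <- read_reader_config(mapping)$mapping
  mapping <- utils::modifyList(default_vcf_mapping(), as.list(mapping))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(build_variant_table(
      data.frame(gene = character(0), type = character(0)), genome))
  info_of <- function(key) {
    if (is.null(key)) return(rep(NA_character_, nrow(fix)))
    as.character(vcfR::extract.info(vcf, element = key))
  }
  df <- data.frame(
    chrom = fix$CHROM, pos = fix$POS, ref = fix$REF, alt = fix$ALT,
    rsid = fix$ID,
    gene = info_of(mapping$gene),
    type = info_of(mapping$func_class),
    clinvar = info_of(mapping$clinvar),
    cadd = info_of(mapping$cadd),
    revel = info_of(mapping$revel),
    maf = info_of(mapping$maf),
    protein_change = info_of(mapping$protein_change),
    disrupts_domain = info_of(mapping$disrupts_domain),
    region_class = info_of(mapping$region_class),
    stringsAsFactors = FALSE)
  build_variant_table(df, genome)
}

#' Read a gene panel
#'
#' One gene symbol per line; blank lines and `#` comments are ignored;
#' symbols are case-normalized (upper case) and deduplicated.
#'
#' @param path plain-text panel file.
#' @return character vector of class `gene_panel`.
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) stop_("gene panel not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  genes <- toupper(trimws(lines))
  genes <- unique(genes[nzchar(genes)])
  if (length(genes) == 0L) stop_("gene panel %s contains no gene symbols", path)
  structure(genes, class = c("gene_panel", "character"))
}

#' Cohort genotype container
#'
#' Bundles per-sample coverage QC with per-sample variant calls for one
#' cohort.
#'
#' @param cohort_label cohort name, e.g. `"lethal"`.
#' @param samples data frame with columns `sample_id` and
#'   `frac_bases_ge_20x` (fraction of target bases covered by >= 20 reads).
#' @param calls data frame with columns `sample_id`, the [variant_table]
#'   columns, and the call-level QC fields `allele_fraction` (`[0,1]`),
#'   `depth` (reads covering the site), `read_pos_rank_sum` (`NA` allowed)
#'   and `filter_status` (`"PASS"`/`"FAIL"`, the upstream variant-quality
#'   recalibration outcome, consumed not computed).
#' @return object of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(cohort_label, samples, calls) {
  stopifnot(is.data.frame(samples), is.data.frame(calls))
  need_s <- c("sample_id", "frac_bases_ge_20x")
  if (length(setdiff(need_s, names(samples))))
    stop_("samples must have columns %s", paste(need_s, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop_("duplicate sample_id in samples")
  if (any(samples$frac_bases_ge_20x < 0 | samples$frac_bases_ge_20x > 1))
    stop_("frac_bases_ge_20x must lie in [0,1]")
  need_c <- c("sample_id", .variant_cols, "allele_fraction", "depth",
              "read_pos_rank_sum", "filter_status")
  missing_cols <- setdiff(need_c, names(calls))
  if (length(missing_cols))
    stop_("calls lack column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(calls)) {
    if (!all(calls$sample_id %in% samples$sample_id))
      stop_("calls reference sample_id absent from samples: %s",
            setdiff(calls$sample_id, samples$sample_id)[1L])
    if (anyDuplicated(calls[, c("sample_id", "variant_key")]))
      stop_("duplicate (sample_id, variant_key) call")
    if (any(calls$allele_fraction < 0 | calls$allele_fraction > 1))
      stop_("allele_fraction must lie in [0,1]")
    if (any(calls$depth < 0)) stop_("depth must be non-negative")
    if (!all(calls$filter_status %in% c("PASS", "FAIL")))
      stop_("filter_status must be PASS or FAIL")
  }
  structure(list(cohort_label = cohort_label,
                 samples = samples[, need_s],
                 calls = calls[, need_c]),
            class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat(sprintf("<cohort_genotypes '%s': %d samples, %d calls, %d variants>\n",
              x$cohort_label, nrow(x$samples), nrow(x$calls),
              length(unique(x$calls$variant_key))))
  invisible(x)
}

#' Extract the distinct variants of a cohort
#'
#' @param cohort a [cohort_genotypes] object.
#' @return a [variant_table] with one row per distinct `variant_key`.
#' @export
cohort_variants <- function(cohort) {
  v <- cohort$calls[!duplicated(cohort$calls$variant_key), .variant_cols,
                    drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Control allele-count container
#'
#' Population summaries in the style of exome-aggregation releases: per
#' variant, the alternate allele count and the number of individuals with
#' adequate sequence coverage at that site.
#'
#' @param population_label population name, e.g. `"swedish"`.
#' @param rows data frame with the [variant_table] columns plus
#'   `allele_count` (non-negative integer) and `covered_persons`
#'   (positive integer denominator).
#' @param covered_persons optional explicit cohort-level denominator,
#'   overriding the per-row values for cohort-wide rates.
#' @return object of class `control_gene_counts`.
#' @export
control_gene_counts <- function(population_label, rows,
                                covered_persons = NULL) {
  stopifnot(is.data.frame(rows))
  need <- c(.variant_cols, "allele_count", "covered_persons")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols))
    stop_("control rows lack column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(rows)) {
    if (any(rows$allele_count < 0)) stop_("allele_count must be non-negative")
    if (any(rows$covered_persons < 1)) stop_("covered_persons must be positive")
    if (any(rows$allele_count > 2 * rows$covered_persons))
      stop_("allele_count exceeds 2 x covered_persons in row %d",
            which(rows$allele_count > 2 * rows$covered_persons)[1L])
  }
  structure(list(population_label = population_label, rows = rows,
                 covered_persons = covered_persons),
            class = "control_gene_counts")
}

#' @export
print.control_gene_counts <- function(x, ...) {
  cat(sprintf("<control_gene_counts '%s': %d variant rows, %d genes>\n",
              x$population_label, nrow(x$rows), length(unique(x$rows$gene))))
  invisible(x)
}

.write_tsv <- function(df, path, comments = character(0)) {
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    stop_("cannot write to %s", path))
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "-")
}

#' Write and re-read tier assignments
#'
#' `write_assignments()` writes one row per variant with its annotations,
#' assigned tier and machine-readable reason; `read_assignments()` restores
#' the same logical records.
#'
#' @param assignments data frame as returned by [classify_variants()].
#' @param path output TSV path.
#' @export
write_assignments <- function(assignments, path) {
  .write_tsv(assignments, path)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) stop_("assignments file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character",
                          na.strings = "-", check.names = FALSE)
  for (col in c("cadd_phred", "revel", "maf"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  if ("disrupts_domain" %in% names(df))
    df$disrupts_domain <- as.logical(df$disrupts_domain)
  df
}

#' Write an association report
#'
#' One row per gene x tier x comparison with the 2x2 carrier table, carrier
#' rates as percentages (2 decimal places) and the two-sided Fisher p-value
#' rendered to 3 decimal places with a `<0.001` floor.
#'
#' @param results data frame as returned by [build_association_table()].
#' @param path output TSV path.
#' @export
write_association_report <- function(results, path) {
  .write_tsv(results, path)
  invisible(path)
}

#' Read and write cohort genotype tables
#'
#' A cohort is stored as two TSVs: a calls table (`sample_id`, variant
#' annotation columns, call QC columns) and a samples table (`sample_id`,
#' `frac_bases_ge_20x`).
#'
#' @param cohort a [cohort_genotypes] object.
#' @param calls_path,samples_path TSV paths.
#' @param cohort_label label for the cohort on read.
#' @export
write_cohort_genotypes <- function(cohort, calls_path, samples_path) {
  .write_tsv(cohort$calls, calls_path,
             comments = sprintf("cohort=%s", cohort$cohort_label))
  .write_tsv(cohort$samples, samples_path,
             comments = sprintf("cohort=%s", cohort$cohort_label))
  invisible(c(calls_path, samples_path))
}

#' @rdname write_cohort_genotypes
#' @export
read_cohort_genotypes <- function(calls_path, samples_path,
                                  cohort_label = "cases") {
  for (p in c(calls_path, samples_path))
    if (!file.exists(p)) stop_("cohort file not found: %s", p)
  calls <- utils::read.delim(calls_path, comment.char = "#",
                             colClasses = "character", na.strings = "-",
                             check.names = FALSE)
  samples <- utils::read.delim(samples_path, comment.char = "#",
                               check.names = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  for (col in c("cadd_phred", "revel", "maf", "allele_fraction",
                "read_pos_rank_sum"))
    calls[[col]] <- as.numeric(calls[[col]])
  calls$depth <- as.integer(calls$depth)
  calls$disrupts_domain <- as.logical(calls$disrupts_domain)
  cohort_genotypes(cohort_label, samples, calls)
}

#' Read and write control allele-count tables
#'
#' @param controls a [control_gene_counts] object.
#' @param path TSV path.
#' @param population_label label for the population on read.
#' @export
write_control_counts <- function(controls, path) {
  cm <- sprintf("population=%s", controls$population_label)
  if (!is.null(controls$covered_persons))
    cm <- c(cm, sprintf("covered_persons=%d", controls$covered_persons))
  .write_tsv(controls$rows, path, comments = cm)
  invisible(path)
}

#' @rdname write_control_counts
#' @export
read_control_counts <- function(path, population_label = NULL) {
  if (!file.exists(path)) stop_("control counts file not found: %s", path)
  header <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  lab <- sub("^#\\s*population=", "", grep("population=", header, value = TRUE))
  cp <- sub("^#\\s*covered_persons=", "",
            grep("covered_persons=", header, value = TRUE))
  rows <- utils::read.delim(path, comment.char = "#",
                            colClasses = "character", na.strings = "-",
                            check.names = FALSE)
  for (col in c("cadd_phred", "revel", "maf"))
    rows[[col]] <- as.numeric(rows[[col]])
  rows$allele_count <- as.integer(rows$allele_count)
  rows$covered_persons <- as.integer(rows$covered_persons)
  rows$disrupts_domain <- as.logical(rows$disrupts_domain)
  control_gene_counts(population_label %||%
                        (if (length(lab)) lab[1L] else "controls"),
                      rows,
                      covered_persons = if (length(cp)) as.integer(cp[1L]))
}
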