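`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse numbers that may use typeset scientific notation
#'
#' Annotation tables copied from publications often print minor allele
#' frequencies as, e.g., `"2.5 × 10−5"` (multiplication sign,
#' Unicode minus, optional superscript carets) rather than `"2.5e-5"`. This
#' normalizes both forms; the missing-value tokens `"-"`, `"."` and `""` map
#' to `NA`.
#'
#' @param x character vector.
#' @param missing_tokens strings treated as absent values.
#' @return numeric vector with `NA` for missing entries.
#' @export
#' @examples
#' parse_numeric(c("2.5 × 10−5", "1e-3", "-", "0.25"))
parse_numeric <- function(x, missing_tokens = c("-", ".", "", "NA")) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  live <- !is.na(x) & !(x %in% missing_tokens)
  if (!any(live)) return(out)
  y <- x[live]
  y <- gsub("^", "", y, fixed = TRUE)
  y <- gsub("−", "-", y)            # Unicode minus
  y <- gsub("×", "x", y)            # multiplication sign
  y <- gsub("([0-9.]+)\\s*[xX]\\s*10\\s*(-?[0-9]+)", "\\1e\\2", y)
  out[live] <- suppressWarnings(as.numeric(y))
  out
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
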