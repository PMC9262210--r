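#' Read and write cohort tables
#'
#' Cohorts are exchanged as tab-separated tables with a header row and
#' `NA` for missing values.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `read_cohort()` returns a data frame; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE)
}

#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics table with columns
#' `id`, `chr`, `pos` (1-based), `effect_allele`, `beta`, `p`.
#'
#' @param path File path.
#' @return Data frame of summary statistics, validated (unique ids,
#'   p in (0, 1], non-negative positions).
#' @export
read_summary_stats <- function(path) {
  ss <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("id", "chr", "pos", "effect_allele", "beta", "p")
  missing_cols <- setdiff(need, names(ss))
  if (length(missing_cols)) {
    stop("summary stats missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ss$id)) stop("variant ids must be unique", call. = FALSE)
  if (any(ss$p <= 0 | ss$p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  if (any(ss$pos < 0)) stop("positions must be non-negative", call. = FALSE)
  ss
}

#' Read a scenario or cohort configuration from YAML
#'
#' Builds a [cohort_config()] from a structured YAML file.  Recognised
#' keys mirror the `cohort_config()` arguments; trait entries are maps
#' of [effect_params()] arguments, e.g.
#' \preformatted{
#' n_individuals: 50000
#' traits:
#'   ea: {k_i: 0.23, k_s: 0.0125}
#' sibship_size_distribution: {0: 0.132, 1: 0.4, 2: 0.468}
#' seed: 1
#' }
#'
#' @param path YAML file path.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$traits)) {
    args$traits <- lapply(raw$traits, function(tr) do.call(effect_params, tr))
  }
  if (!is.null(raw$sibship_size_distribution)) {
    d <- unlist(raw$sibship_size_distribution)
    args$sibship_size_distribution <- stats::setNames(as.numeric(d), names(d))
  }
  if (!is.null(raw$sibling_ige_cap)) {
    args$sibling_ige_cap <- unlist(raw$sibling_ige_cap)
  }
  if (!is.null(raw$birth_year_range)) {
    args$birth_year_range <- as.integer(unlist(raw$birth_year_range))
  }
  do.call(cohort_config, args)
}

## Canonical YAML text of a config, used for the manifest hash.
config_yaml <- function(config) {
  ser <- rapply(unclass(config), function(x) x, how = "replace")
  yaml::as.yaml(ser)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(config_yaml(config), tf)
  unname(tools::md5sum(tf))
}
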