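#' Run the full singleton/non-singleton replication pipeline
#'
#' Executes, on a synthetic cohort, every analysis of the study design in
#' order: stratum assignment; per-trait singleton and non-singleton PGS
#' associations and their delta-method difference (% attenuation,
#' non-singleton reference); firstborn and non-firstborn associations,
#' their difference, and the firstborn-vs-singleton difference;
#' per-sibship-size associations with the 6+-vs-rest comparison; linear,
#' quadratic and 6+-excluded linear sibling-count interaction models; the
#' times-two scaling of the excluded linear interaction term to a
#' per-sibling IGE; and group-level difference tables.  All stage outputs
#' are pure functions of `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Run-level integer seed, expanded deterministically into
#'   per-stage seeds; overrides `config$seed`.
#' @param sibship_trait Trait used for the sibship-size and interaction
#'   analyses (default: the first configured trait).
#' @param out_dir Optional directory; when given, every intermediate
#'   table is written as TSV plus a JSON run manifest.  On a stage
#'   failure the error names the stage and tables computed so far are
#'   still persisted.
#' @param verbose Log row counts per stage.
#' @return An object of class `replication_report`: a list with elements
#'   `cohort_counts`, `associations`, `differences`, `firstborn`,
#'   `sibship`, `interactions`, `ige`, `group_diffs`, `results` (the
#'   flattened [results_table()]), and `provenance`.
#' @examples
#' cfg <- cohort_config(n_individuals = 5000,
#'                      traits = list(ea = effect_params(0.23, k_s = 0.05)))
#' rep <- run_replication(cfg, seed = 1)
#' rep$ige
#' @export
run_replication <- function(config, seed = NULL, sibship_trait = NULL,
                            out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  traits <- names(config$traits)
  sibship_trait <- sibship_trait %||% traits[1]
  if (!sibship_trait %in% traits) stop("unknown sibship_trait", call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_msg <- function(...) if (verbose) message(sprintf(...))
  persist <- function(obj, name) {
    if (!is.null(out_dir) && !is.null(obj)) {
      utils::write.table(obj, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate_cohort", simulate_cohort(config, seed = derive_seed(seed, 1L)))
  log_msg("simulated %d individuals", nrow(cohort))
  strata <- stage("assign_strata", assign_strata(cohort))
  log_msg("after adoption exclusion: %d rows (removed %d adopted)",
          nrow(strata), nrow(cohort) - nrow(strata))
  persist(strata, "cohort")
  counts <- list(
    simulated = nrow(cohort),
    adopted_removed = nrow(cohort) - nrow(strata),
    analysed = nrow(strata),
    singleton = sum(strata$singleton, na.rm = TRUE),
    non_singleton = sum(!strata$singleton, na.rm = TRUE),
    singleton_missing = sum(is.na(strata$singleton)),
    firstborn = sum(stratum_rows(strata, "firstborn")),
    non_firstborn = sum(stratum_rows(strata, "non_firstborn"))
  )
  log_msg("strata: %d singleton / %d non-singleton / %d missing",
          counts$singleton, counts$non_singleton, counts$singleton_missing)

  associations <- list(); differences <- list(); firstborn <- list()
  for (tr in traits) {
    a <- stage("fit_association", list(
      singleton = fit_association(strata, tr, "singleton"),
      non_singleton = fit_association(strata, tr, "non_singleton")
    ))
    associations[[tr]] <- a
    differences[[tr]] <- stage("estimate_difference",
      estimate_difference(a$non_singleton, a$singleton, reference = "a"))
    fb <- stage("firstborn_analyses", {
      f1 <- fit_association(strata, tr, "firstborn")
      f2 <- fit_association(strata, tr, "non_firstborn")
      list(firstborn = f1, non_firstborn = f2,
           non_firstborn_vs_firstborn = estimate_difference(f2, f1, reference = "a"),
           firstborn_vs_singleton = estimate_difference(
             f1, a$singleton, reference = "a"))
    })
    firstborn[[tr]] <- fb
  }

  sibship <- stage("associations_by_sibship",
                   associations_by_sibship(strata, sibship_trait))
  interactions <- stage("fit_sibling_interaction", list(
    linear = fit_sibling_interaction(strata, sibship_trait, "linear", "none"),
    quadratic = fit_sibling_interaction(strata, sibship_trait, "quadratic", "none"),
    linear_6plus_removed = fit_sibling_interaction(strata, sibship_trait,
                                                   "linear", "6+_removed")
  ))
  ige <- stage("scale_sibling_ige",
               scale_sibling_ige(interactions$linear_6plus_removed))

  gd_vars_unadj <- intersect(c("sex", "birth_year"), names(strata))
  gd_vars_adj <- intersect(c(traits, paste0("pgs_", traits)), names(strata))
  group_diffs <- stage("group_differences", list(
    unadjusted = group_differences(strata, gd_vars_unadj,
                                   "singleton-vs-nonsingleton", "none"),
    adjusted = group_differences(strata, gd_vars_adj,
                                 "singleton-vs-nonsingleton", "sex+age"),
    vs_firstborn = group_differences(strata, gd_vars_adj,
                                     "singleton-vs-firstborn", "sex+age")
  ))

  results <- results_table(
    association = associations, attenuation = differences,
    firstborn = firstborn, sibship = sibship$estimates,
    sibship_top_vs_rest = sibship$top_vs_rest,
    interaction = interactions, sibling_ige = ige
  )
  persist(results, "results")
  persist(group_diffs$unadjusted, "group_differences_unadjusted")
  persist(group_diffs$adjusted, "group_differences_adjusted")

  provenance <- list(
    package = "sibige",
    version = as.character(utils::packageVersion("sibige")),
    seed = seed,
    config_hash = config_hash(config),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(provenance, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(cohort_counts = counts, associations = associations,
                 differences = differences, firstborn = firstborn,
                 sibship = sibship, interactions = interactions, ige = ige,
                 group_diffs = group_diffs, results = results,
                 provenance = provenance),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat("Singleton/non-singleton replication report\n")
  cat(sprintf("  cohort: %d analysed (%d singleton, %d non-singleton, %d missing)\n",
              x$cohort_counts$analysed, x$cohort_counts$singleton,
              x$cohort_counts$non_singleton, x$cohort_counts$singleton_missing))
  for (tr in names(x$differences)) {
    d <- x$differences[[tr]]
    cat(sprintf("  %s attenuation: %.1f%% (95%% CI %.1f%%, %.1f%%), p = %.3g\n",
                tr, d$attenuation_pct, d$attenuation_ci95[1],
                d$attenuation_ci95[2], d$p))
  }
  print(x$ige)
  invisible(x)
}
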