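#' Configuration for a synthetic biobank-style cohort
#'
#' Describes a cohort of nominally unrelated index individuals whose
#' phenotypes were generated inside simulated nuclear families: per trait
#' a standardized PGS and a phenotype built from direct, parental and
#' sibling genetic effects, plus self-reported sibling counts (with
#' partial missingness), birth order (available in a subset), an adoption
#' flag, and the standard association covariates (sex, birth year, 10
#' principal components).
#'
#' The default sibship-size distribution reproduces the gross margins of
#' a large UK cohort: about 13.2% singletons and about 4.9% of
#' individuals with 6 or more siblings; the interior masses decay
#' geometrically, which is a realism choice rather than a fitted
#' quantity.
#'
#' @param n_individuals Number of index individuals.
#' @param traits Named list of [effect_params()], one per trait (e.g.
#'   `list(ea = effect_params(...), height = ...)`).
#' @param sibship_size_distribution Named probability vector over sibling
#'   counts (`"0"`, `"1"`, ...); must sum to 1.
#' @param older_sib_only_ige If `TRUE`, only older siblings exert the
#'   `k_s` IGE on the index individual (firstborns then receive none);
#'   if `FALSE` all siblings contribute.
#' @param sibling_ige_cap Optional named numeric, per trait: the maximum
#'   number of siblings whose IGEs accumulate (default `Inf`).  A finite
#'   cap makes the sibship-size/slope relationship flatten in large
#'   families.
#' @param adoption_rate Proportion flagged as adopted (excluded by
#'   [assign_strata()]).
#' @param sibling_question_missingness Probability that one of the two
#'   sibling-count questions (brothers/sisters) is unanswered.
#' @param birth_order_coverage Proportion of the cohort with birth-order
#'   (older-sibling count) data.
#' @param sex_female_prop Proportion female; `sex` is coded 1 = female.
#' @param birth_year_range Integer range of birth years (uniform).
#' @param n_pcs,pc_sd Number and SD of principal-component covariates
#'   (independent normals by default).
#' @param sex_effect,birth_year_effect Additive covariate effects on every
#'   phenotype (birth-year effect per year, centred).
#' @param pc_confounding Optional list `list(strength_pgs = a,
#'   strength_y = b)`: a shared family ancestry component (PC1) is mixed
#'   into all family members' PGS with loading `a` (PGS re-standardized)
#'   and added to the phenotype with slope `b`, creating a
#'   stratification-type confounder.  Default no confounding.
#' @param mating `"model1"` (random mating) or `"model2"` (assortative).
#' @param seed Default seed used by [simulate_cohort()] when no seed is
#'   passed there.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 10000L,
                          traits = list(ea = effect_params(k_i = 0.23, k_s = 0.0125,
                                                           sigma_eps = 1)),
                          sibship_size_distribution = default_sibship_distribution(),
                          older_sib_only_ige = FALSE,
                          sibling_ige_cap = NULL,
                          adoption_rate = 0.016,
                          sibling_question_missingness = 0.02,
                          birth_order_coverage = 0.29,
                          sex_female_prop = 0.54,
                          birth_year_range = c(1937L, 1970L),
                          n_pcs = 10L,
                          pc_sd = 1,
                          sex_effect = 0.2,
                          birth_year_effect = 0.01,
                          pc_confounding = NULL,
                          mating = c("model1", "model2"),
                          seed = NULL) {
  mating <- match.arg(mating)
  if (length(traits) == 0 || is.null(names(traits)) || any(names(traits) == "")) {
    stop("traits must be a named list of effect_params", call. = FALSE)
  }
  for (tr in traits) stopifnot(inherits(tr, "effect_params"))
  p <- sibship_size_distribution
  if (length(p) == 0) stop("sibship size distribution is empty", call. = FALSE)
  if (is.null(names(p)) || anyNA(suppressWarnings(as.integer(names(p))))) {
    stop("sibship_size_distribution must be named by sibling counts", call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("sibship_size_distribution must be non-negative and sum to 1", call. = FALSE)
  }
  props <- c(adoption = adoption_rate, missing = sibling_question_missingness,
             bo = birth_order_coverage, female = sex_female_prop)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  structure(list(
    n_individuals = as.integer(n_individuals),
    traits = traits,
    sibship_size_distribution = p,
    older_sib_only_ige = isTRUE(older_sib_only_ige),
    sibling_ige_cap = sibling_ige_cap,
    adoption_rate = adoption_rate,
    sibling_question_missingness = sibling_question_missingness,
    birth_order_coverage = birth_order_coverage,
    sex_female_prop = sex_female_prop,
    birth_year_range = as.integer(birth_year_range),
    n_pcs = as.integer(n_pcs),
    pc_sd = pc_sd,
    sex_effect = sex_effect,
    birth_year_effect = birth_year_effect,
    pc_confounding = pc_confounding,
    mating = mating,
    seed = seed
  ), class = "cohort_config")
}

#' @rdname cohort_config
#' @details `default_sibship_distribution()` returns the default
#'   categorical distribution over 0..8 siblings (13.2% singletons, 4.9%
#'   with 6 or more).
#' @export
default_sibship_distribution <- function() {
  c("0" = 0.132, "1" = 0.301, "2" = 0.250, "3" = 0.150, "4" = 0.079,
    "5" = 0.039, "6" = 0.025, "7" = 0.014, "8" = 0.010)
}

#' Simulate a synthetic cohort of index individuals
#'
#' For each index individual a sibship size is drawn, the full family's
#' PGS are simulated via the within-family correlation structure, the
#' phenotype of the index individual is generated from the trait's
#' [effect_params()] (sibling IGEs summing over all siblings, or over
#' older siblings only when configured), and all relatives' PGS are then
#' discarded, mirroring a sample of unrelateds.  Covariates (sex, birth
#' year, PCs) are generated independently of the PGS unless PC
#' confounding is configured.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; overrides `config$seed`.
#' @return A data frame (one row per individual) with columns `id`,
#'   `pgs_<trait>` and `<trait>` per trait, `sex`, `birth_year`,
#'   `pc1..pcK`, `n_brothers`, `n_sisters`, `n_older_sibs` (each possibly
#'   `NA`), `n_siblings_true`, and `adopted`.  Pass through
#'   [assign_strata()] before analysis.
#' @examples
#' cfg <- cohort_config(n_individuals = 2000, seed = 1)
#' coh <- assign_strata(simulate_cohort(cfg))
#' table(coh$sibship_category)
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  with_seed(seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_individuals
  p <- config$sibship_size_distribution
  sizes <- as.integer(names(p))
  n_sibs <- sample(sizes, n, replace = TRUE, prob = p)
  ## birth position uniform among the n_sibs + 1 sibship slots
  position <- floor(stats::runif(n) * (n_sibs + 1)) + 1L
  n_older <- position - 1L

  sex <- stats::rbinom(n, 1L, config$sex_female_prop)
  by_range <- config$birth_year_range
  birth_year <- sample(seq(by_range[1], by_range[2]), n, replace = TRUE)
  pcs <- matrix(stats::rnorm(n * config$n_pcs, sd = config$pc_sd), nrow = n)
  colnames(pcs) <- paste0("pc", seq_len(config$n_pcs))

  conf <- config$pc_confounding
  a <- if (is.null(conf)) 0 else conf$strength_pgs %||% 0
  b <- if (is.null(conf)) 0 else conf$strength_y %||% 0

  struct_fn <- if (config$mating == "model1") model1_structure else model2_structure
  out <- data.frame(id = seq_len(n))
  by_centered <- birth_year - mean(birth_year)
  cov_part <- config$sex_effect * sex + config$birth_year_effect * by_centered +
    b * pcs[, 1]

  for (trait in names(config$traits)) {
    ep <- config$traits[[trait]]
    cap <- Inf
    if (!is.null(config$sibling_ige_cap) && trait %in% names(config$sibling_ige_cap)) {
      cap <- config$sibling_ige_cap[[trait]]
    }
    pgs_index <- numeric(n)
    sib_contrib <- numeric(n)
    parent_contrib <- numeric(n)
    for (s in sort(unique(n_sibs))) {
      idx <- which(n_sibs == s)
      G <- rmvn_chol(length(idx), struct_fn(s + 1L)$corr)
      if (a != 0) {
        ## shared family ancestry component loads on every member's PGS
        G <- sqrt(1 - a^2) * G + a * pcs[idx, 1]
      }
      pgs_index[idx] <- G[, "O1"]
      parent_contrib[idx] <- ep$k_m * G[, "M"] + ep$k_p * G[, "P"]
      if (s >= 1L) {
        sib_cols <- G[, paste0("O", 1L + seq_len(s)), drop = FALSE]
        ## siblings are exchangeable: the first n_contrib columns stand for
        ## the contributing (e.g. older) siblings
        n_contrib <- if (config$older_sib_only_ige) n_older[idx] else s
        n_contrib <- as.integer(pmin(n_contrib, s, cap))
        cum <- matrix(0, length(idx), s + 1L)
        for (j in seq_len(s)) cum[, j + 1L] <- cum[, j] + sib_cols[, j]
        sib_contrib[idx] <- ep$k_s * cum[cbind(seq_along(idx), n_contrib + 1L)]
      }
    }
    y <- ep$k_i * pgs_index + parent_contrib + sib_contrib +
      ep$c_conf * pgs_index + cov_part +
      stats::rnorm(n, sd = ep$sigma_eps)
    out[[paste0("pgs_", trait)]] <- pgs_index
    out[[trait]] <- y
  }

  out$sex <- sex
  out$birth_year <- birth_year
  out <- cbind(out, as.data.frame(pcs))

  n_brothers <- stats::rbinom(n, n_sibs, 0.5)
  n_sisters <- n_sibs - n_brothers
  miss <- stats::runif(n) < config$sibling_question_missingness
  which_q <- stats::runif(n) < 0.5
  n_brothers[miss & which_q] <- NA_integer_
  n_sisters[miss & !which_q] <- NA_integer_
  out$n_brothers <- n_brothers
  out$n_sisters <- n_sisters
  older <- n_older
  older[stats::runif(n) >= config$birth_order_coverage] <- NA_integer_
  out$n_older_sibs <- older
  out$n_siblings_true <- n_sibs
  out$adopted <- stats::rbinom(n, 1L, config$adoption_rate) == 1L
  attr(out, "cohort_config") <- config
  out
}

#' Attach stratum labels to a cohort
#'
#' Applies the study's stratum definitions: singletons report both zero
#' full brothers and zero full sisters; non-singletons report one or more
#' of either; an individual reporting zero to one question while leaving
#' the other unanswered has singleton status set to missing.  Firstborns
#' report zero older siblings.  Sibship-size categories are 0..5 and
#' `"6+"`.  Adopted individuals are removed.
#'
#' @param cohort A data frame with columns `n_brothers`, `n_sisters`,
#'   `n_older_sibs` and `adopted` (as from [simulate_cohort()]).
#' @return The cohort with adopted rows removed and derived columns
#'   `n_siblings` (NA unless both questions answered), `singleton`,
#'   `firstborn` (logical, possibly NA) and `sibship_category` (factor
#'   `"0"`..`"5"`, `"6+"`).
#' @export
assign_strata <- function(cohort) {
  required <- c("n_brothers", "n_sisters", "n_older_sibs", "adopted")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  counts <- c(cohort$n_brothers, cohort$n_sisters, cohort$n_older_sibs)
  if (any(counts < 0, na.rm = TRUE)) {
    stop("negative sibling counts are invalid", call. = FALSE)
  }
  cohort <- cohort[!cohort$adopted, , drop = FALSE]
  nb <- cohort$n_brothers
  ns <- cohort$n_sisters
  singleton <- ifelse(!is.na(nb) & !is.na(ns), nb == 0 & ns == 0, NA)
  ## a reported sibling determines non-singleton status even if the other
  ## question is unanswered; zero + unanswered stays missing
  singleton[(!is.na(nb) & nb > 0) | (!is.na(ns) & ns > 0)] <- FALSE
  n_siblings <- ifelse(!is.na(nb) & !is.na(ns), nb + ns, NA_integer_)
  cohort$n_siblings <- as.integer(n_siblings)
  cohort$singleton <- singleton
  cohort$firstborn <- ifelse(is.na(cohort$n_older_sibs), NA,
                             cohort$n_older_sibs == 0)
  cat_lab <- ifelse(is.na(n_siblings), NA_character_,
                    ifelse(n_siblings >= 6, "6+", as.character(n_siblings)))
  cohort$sibship_category <- factor(cat_lab, levels = c(as.character(0:5), "6+"))
  cohort
}
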