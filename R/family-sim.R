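#' Simulate family-structured polygenic scores
#'
#' Draws standardized PGS for `n_families` nuclear families as exact
#' multivariate normals with the correlation matrix given by a
#' [mating_structure()] (Cholesky factorisation of the correlation
#' matrix applied to iid standard normals).
#'
#' @param n_families Number of families to draw (at least 1).
#' @param structure A [mating_structure()].
#' @param kind One of `"trio"` (one offspring), `"quad"` (sibling pair) or
#'   `"sibship"`; with `"sibship"` the offspring count is taken from
#'   `structure`.  The member count implied by `kind` must match
#'   `structure`.
#' @param seed Optional integer seed; the draw is deterministic given it.
#'
#' @return An object of class `family_pgs`: a list with `pgs` (an
#'   `n_families` x members matrix, columns `M`, `P`, `O1..On`), `kind`,
#'   `n_families` and the generating `structure`.
#'
#' @examples
#' fam <- sample_family_pgs(1000, model1_structure(2), kind = "quad", seed = 1)
#' round(cor(fam$pgs), 2)
#' @export
sample_family_pgs <- function(n_families, structure,
                              kind = c("trio", "quad", "sibship"),
                              seed = NULL) {
  kind <- match.arg(kind)
  n_families <- as.integer(n_families)
  if (n_families < 1L) stop("n_families must be at least 1", call. = FALSE)
  if (!inherits(structure, "mating_structure")) {
    structure <- as_mating_structure(structure)
  }
  validate_mating_structure(structure)
  n_off <- n_offspring_of(structure)
  expected_off <- switch(kind, trio = 1L, quad = 2L, sibship = n_off)
  if (n_off != expected_off) {
    stop("structure has ", n_off, " offspring but kind '", kind,
         "' requires ", expected_off, call. = FALSE)
  }
  pgs <- with_seed(seed, rmvn_chol(n_families, structure$corr))
  structure(list(pgs = pgs, kind = kind, n_families = n_families,
                 structure = structure),
            class = "family_pgs")
}

#' @export
print.family_pgs <- function(x, ...) {
  cat("Family PGS draw: ", x$n_families, " families (", x$kind, ", ",
      ncol(x$pgs), " members)\n", sep = "")
  invisible(x)
}

#' Simulate index-individual phenotypes from family PGS
#'
#' Generates the phenotype of the index offspring (`O1`) as
#' \deqn{Y = k_I G_{O1} + k_M G_M + k_P G_P + k_S \sum_{j \ge 2} G_{Oj}
#'           + C G_{O1} + \epsilon,\quad \epsilon \sim N(0, \sigma_\epsilon^2).}
#' Sibling IGEs sum over all siblings present in the family.
#'
#' @param pgs A [sample_family_pgs()] result.
#' @param effects An [effect_params()] set.  `k_s` must be zero when the
#'   families contain no siblings (trios).
#' @param seed Optional integer seed for the error draw.
#'
#' @return An object of class `phenotype_vector`: list with `y` (numeric,
#'   one value per family), and `generator_params`.
#' @examples
#' fam <- sample_family_pgs(500, model1_structure(1), "trio", seed = 1)
#' ph <- simulate_phenotypes(fam, effect_params(k_i = 0.5), seed = 2)
#' @export
simulate_phenotypes <- function(pgs, effects, seed = NULL) {
  stopifnot(inherits(pgs, "family_pgs"), inherits(effects, "effect_params"))
  G <- pgs$pgs
  n_off <- ncol(G) - 2L
  if (effects$k_s != 0 && n_off < 2L) {
    stop("k_s is nonzero but the families contain no siblings (trio input)",
         call. = FALSE)
  }
  sib_sum <- if (n_off >= 2L) {
    rowSums(G[, paste0("O", 2:n_off), drop = FALSE])
  } else 0
  eps <- with_seed(seed, stats::rnorm(nrow(G), sd = effects$sigma_eps))
  y <- effects$k_i * G[, "O1"] + effects$k_m * G[, "M"] +
    effects$k_p * G[, "P"] + effects$k_s * sib_sum +
    effects$c_conf * G[, "O1"] + eps
  structure(list(y = y, generator_params = effects, kind = pgs$kind),
            class = "phenotype_vector")
}

#' Analytic expectation of the stratified PGS slope
#'
#' Under random mating (all parent-offspring and sibling PGS correlations
#' 0.5) the expected OLS slope of phenotype on the index individual's own
#' standardized PGS is
#' \deqn{\beta_{NS} = k_I + 0.5 k_M + 0.5 k_P + N \cdot 0.5 k_S + C}
#' for non-singletons with \eqn{N} siblings, and
#' \deqn{\beta_S = k_I + 0.5 k_M + 0.5 k_P + C}
#' for singletons (no sibling term possible).
#'
#' @param effects An [effect_params()] set.
#' @param stratum `"singleton"` or `"non_singleton"`.
#' @param n_sibs Number of siblings; must be 0 exactly when
#'   `stratum = "singleton"`.
#' @return Expected slope (trait units per SD PGS).
#' @examples
#' expected_slope(effect_params(0.5, 0.1, 0.1, 0.2), "non_singleton", 1)  # 0.7
#' @export
expected_slope <- function(effects, stratum = c("singleton", "non_singleton"),
                           n_sibs = 0L) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(effects, "effect_params"))
  if (n_sibs < 0) stop("n_sibs must be non-negative", call. = FALSE)
  if ((n_sibs == 0L) != (stratum == "singleton")) {
    stop("n_sibs must be 0 exactly when stratum is 'singleton'", call. = FALSE)
  }
  effects$k_i + 0.5 * effects$k_m + 0.5 * effects$k_p +
    n_sibs * 0.5 * effects$k_s + effects$c_conf
}

#' Expected bias decomposition of the singleton difference estimator
#'
#' Decomposes the expected unscaled difference
#' \eqn{\beta_{NS} - \beta_S} (non-singletons with one sibling vs
#' singletons) into its additive sources: the sibling IGE signal
#' (\eqn{0.5 k_S}) plus the bias terms that arise when the strata differ
#' in direct effects (\eqn{k_{NS,I} - k_{S,I}}), maternal or paternal
#' IGEs (half of each difference), or confounding
#' (\eqn{C_{NS} - C_S}).
#'
#' @param effects_ns Non-singleton stratum [effect_params()].
#' @param effects_s Singleton stratum [effect_params()].
#' @return A named list `sibling_term`, `direct_term`, `maternal_term`,
#'   `paternal_term`, `confounder_term`, plus `total` (their sum).  The
#'   components sum exactly to
#'   `expected_slope(effects_ns, "non_singleton", 1) -
#'    expected_slope(effects_s, "singleton", 0)`.
#' @examples
#' ep <- effect_params(0.5, 0.1, 0.1, k_s = 0.2)
#' expected_bias(ep, ep)$sibling_term  # 0.1
#' @export
expected_bias <- function(effects_ns, effects_s) {
  stopifnot(inherits(effects_ns, "effect_params"),
            inherits(effects_s, "effect_params"))
  out <- list(
    sibling_term    = 0.5 * effects_ns$k_s,
    direct_term     = effects_ns$k_i - effects_s$k_i,
    maternal_term   = 0.5 * (effects_ns$k_m - effects_s$k_m),
    paternal_term   = 0.5 * (effects_ns$k_p - effects_s$k_p),
    confounder_term = effects_ns$c_conf - effects_s$c_conf
  )
  out$total <- sum(unlist(out))
  out
}

#' Export simulated families as a data frame
#'
#' Combines a family PGS draw and the corresponding phenotype vector into
#' one table (one row per family) for writing as tab-separated output.
#'
#' @param pgs A [sample_family_pgs()] result.
#' @param phenotypes Optional matching [simulate_phenotypes()] result.
#' @return A data frame with one column per family member PGS and,
#'   when supplied, a `y` phenotype column.
#' @export
family_table <- function(pgs, phenotypes = NULL) {
  stopifnot(inherits(pgs, "family_pgs"))
  out <- as.data.frame(pgs$pgs)
  names(out) <- paste0("pgs_", names(out))
  if (!is.null(phenotypes)) {
    stopifnot(inherits(phenotypes, "phenotype_vector"),
              length(phenotypes$y) == nrow(out))
    out$y <- phenotypes$y
  }
  out
}
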