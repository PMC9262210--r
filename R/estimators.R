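#' Default association covariates
#'
#' Sex, birth year and the first `n_pcs` principal components — the
#' covariate set used by all stratified PGS associations.
#' @param n_pcs Number of principal components.
#' @return Character vector of column names.
#' @export
default_covariates <- function(n_pcs = 10L) {
  c("sex", "birth_year", paste0("pc", seq_len(n_pcs)))
}

stratum_rows <- function(cohort, stratum) {
  switch(stratum,
    all = rep(TRUE, nrow(cohort)),
    singleton = !is.na(cohort$singleton) & cohort$singleton,
    non_singleton = !is.na(cohort$singleton) & !cohort$singleton,
    ## firstborns are non-singletons with no older siblings; singletons are
    ## kept out of both birth-order strata
    firstborn = !is.na(cohort$firstborn) & cohort$firstborn &
      !is.na(cohort$singleton) & !cohort$singleton,
    non_firstborn = !is.na(cohort$firstborn) & !cohort$firstborn,
    {
      if (!"sibship_category" %in% names(cohort)) {
        stop("unknown stratum '", stratum, "'", call. = FALSE)
      }
      if (!stratum %in% levels(cohort$sibship_category)) {
        stop("unknown stratum '", stratum, "'", call. = FALSE)
      }
      !is.na(cohort$sibship_category) & cohort$sibship_category == stratum
    }
  )
}

#' Covariate-adjusted stratified PGS association
#'
#' Ordinary least squares of a phenotype on its standardized PGS plus
#' covariates, within one stratum of the cohort, with classical
#' (homoskedastic) standard errors and complete-case handling of missing
#' values.  Strata: `"all"`, `"singleton"`, `"non_singleton"`,
#' `"firstborn"`, `"non_firstborn"` (birth-order strata exclude
#' singletons and require birth-order data), or a sibship-size category
#' label (`"0"`..`"5"`, `"6+"`).
#'
#' @param cohort A stratified cohort from [assign_strata()] (column
#'   `pgs_<trait>` and `<trait>` must exist).
#' @param trait Trait name, e.g. `"ea"`.
#' @param stratum Stratum label (see Details).
#' @param covariates Character vector of covariate column names; may be
#'   empty.
#' @return An object of class `assoc_estimate`: `beta`, `se`, `p`, `n`,
#'   `stratum`, `trait`, `covariates`.
#' @examples
#' cfg <- cohort_config(n_individuals = 5000, seed = 3)
#' coh <- assign_strata(simulate_cohort(cfg))
#' fit_association(coh, "ea", "singleton")
#' @export
fit_association <- function(cohort, trait, stratum = "all",
                            covariates = default_covariates()) {
  pgs_col <- paste0("pgs_", trait)
  need <- c(pgs_col, trait, covariates)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rows <- stratum_rows(cohort, stratum)
  dat <- cohort[rows, need, drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) == 0) stop("stratum '", stratum, "' is empty", call. = FALSE)
  names(dat)[1] <- "PGS"
  fml <- stats::reformulate(c("PGS", covariates), response = trait)
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design: column(s) ", paste(bad, collapse = ", "),
         " dropped", call. = FALSE)
  }
  est <- coef_se(fit, "PGS")
  structure(list(beta = unname(est["beta"]), se = unname(est["se"]),
                 p = unname(est["p"]), n = nrow(dat),
                 stratum = stratum, trait = trait, covariates = covariates),
            class = "assoc_estimate")
}

#' @export
print.assoc_estimate <- function(x, ...) {
  cat(sprintf("PGS association [%s, %s]: beta = %.4f (se %.4f), n = %d, p = %.3g\n",
              x$trait, x$stratum, x$beta, x$se, x$n, x$p))
  invisible(x)
}

#' Delta-method difference of two independent association estimates
#'
#' Difference of two stratified OLS slopes estimated in non-overlapping
#' samples, assuming zero covariance between them:
#' `se = sqrt(se_a^2 + se_b^2)`, Wald normal p, 95% CI as
#' `delta +/- 1.96 se`.  The difference is also rescaled as percent
#' attenuation relative to the reference estimate: the difference and
#' both CI bounds are divided by the fixed reference point estimate
#' (denominator uncertainty is ignored, which is anti-conservative).
#' With `a` the non-singleton and `b` the singleton estimate and
#' reference `"a"`, attenuation is positive when the non-singleton slope
#' is larger.
#'
#' @param a,b [fit_association()] results for the same trait in disjoint
#'   strata.
#' @param reference `"a"` or `"b"`: the denominator of the attenuation
#'   ratio.
#' @return An object of class `difference_estimate`: `delta`, `se`, `z`,
#'   `p`, `ci95`, `attenuation_pct`, `attenuation_ci95`, plus the input
#'   labels.
#' @export
estimate_difference <- function(a, b, reference = c("a", "b")) {
  reference <- match.arg(reference)
  stopifnot(inherits(a, "assoc_estimate") || is.list(a),
            inherits(b, "assoc_estimate") || is.list(b))
  if (!is.null(a$trait) && !is.null(b$trait) && !identical(a$trait, b$trait)) {
    stop("estimates are for different traits", call. = FALSE)
  }
  if (!is.null(a$stratum) && identical(a$stratum, b$stratum)) {
    stop("strata must be disjoint", call. = FALSE)
  }
  delta <- a$beta - b$beta
  se <- sqrt(a$se^2 + b$se^2)
  z <- if (se > 0) delta / se else 0
  p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(delta == 0)
  ci <- delta + c(-1, 1) * 1.96 * se
  beta_ref <- if (reference == "a") a$beta else b$beta
  if (beta_ref == 0) {
    warning("reference estimate is zero; attenuation undefined")
    att <- NA_real_; att_ci <- c(NA_real_, NA_real_)
  } else {
    att <- 100 * delta / beta_ref
    att_ci <- sort(100 * ci / beta_ref)
  }
  structure(list(delta = delta, se = se, z = z, p = p, ci95 = ci,
                 attenuation_pct = att, attenuation_ci95 = att_ci,
                 reference = reference,
                 stratum_a = a$stratum %||% NA, stratum_b = b$stratum %||% NA,
                 trait = a$trait %||% NA),
            class = "difference_estimate")
}

#' @export
print.difference_estimate <- function(x, ...) {
  cat(sprintf("Difference (%s - %s): %.4f (se %.4f), 95%% CI (%.4f, %.4f), p = %.3g\n",
              x$stratum_a, x$stratum_b, x$delta, x$se, x$ci95[1], x$ci95[2], x$p))
  if (!is.na(x$attenuation_pct)) {
    cat(sprintf("  attenuation: %.1f%% (95%% CI %.1f%%, %.1f%%)\n",
                x$attenuation_pct, x$attenuation_ci95[1], x$attenuation_ci95[2]))
  }
  invisible(x)
}

#' Sibling-count by PGS interaction model
#'
#' Fits `trait ~ PGS + N + N:PGS + covariates` by OLS, where `N` is the
#' self-reported number of siblings; the coefficient on `N:PGS` is the
#' change in PGS association per additional sibling.  The quadratic model
#' adds `N^2` and `N^2:PGS`.  With `exclusion = "6+_removed"`,
#' individuals reporting 6 or more siblings are dropped before fitting
#' (the outlier rule: that group is about 5% of the sample and shows
#' attenuated associations).
#'
#' @param cohort A stratified cohort ([assign_strata()]); rows with
#'   missing `n_siblings` are dropped.
#' @param trait Trait name.
#' @param model `"linear"` or `"quadratic"`.
#' @param exclusion `"none"` or `"6+_removed"`.
#' @param covariates Covariate columns (default sex, birth year, PCs).
#' @return An object of class `interaction_estimate` with `beta_pgs`,
#'   `beta_n`, `beta_nxpgs` (and `beta_n2`, `beta_n2xpgs` for the
#'   quadratic model), matching `se_*` and `p_*` fields, and `n`.
#' @export
fit_sibling_interaction <- function(cohort, trait,
                                    model = c("linear", "quadratic"),
                                    exclusion = c("none", "6+_removed"),
                                    covariates = default_covariates()) {
  model <- match.arg(model)
  exclusion <- match.arg(exclusion)
  pgs_col <- paste0("pgs_", trait)
  need <- c(pgs_col, trait, "n_siblings", covariates)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- cohort[!is.na(cohort$n_siblings), need, drop = FALSE]
  if (exclusion == "6+_removed") dat <- dat[dat$n_siblings < 6, , drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) == 0) stop("no usable rows for the interaction model", call. = FALSE)
  names(dat)[1] <- "PGS"
  dat$N <- dat$n_siblings
  if (model == "quadratic" && max(dat$N) <= 1) {
    stop("quadratic model is degenerate: no variation in N beyond 0/1", call. = FALSE)
  }
  terms <- c("PGS", "N", "N:PGS")
  if (model == "quadratic") {
    dat$N2 <- dat$N^2
    terms <- c(terms, "N2", "N2:PGS")
  }
  fml <- stats::reformulate(c(terms, covariates), response = trait)
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design: column(s) ", paste(bad, collapse = ", "),
         " dropped", call. = FALSE)
  }
  grab <- function(term) coef_se(fit, term)
  pgs <- grab("PGS"); nn <- grab("N"); nx <- grab("PGS:N")
  out <- list(beta_pgs = unname(pgs["beta"]), se_pgs = unname(pgs["se"]),
              p_pgs = unname(pgs["p"]),
              beta_n = unname(nn["beta"]), se_n = unname(nn["se"]),
              p_n = unname(nn["p"]),
              beta_nxpgs = unname(nx["beta"]), se_nxpgs = unname(nx["se"]),
              p_nxpgs = unname(nx["p"]),
              model = model, exclusion = exclusion, trait = trait,
              n = nrow(dat))
  if (model == "quadratic") {
    n2 <- grab("N2"); n2x <- grab("PGS:N2")
    out$beta_n2 <- unname(n2["beta"]); out$se_n2 <- unname(n2["se"])
    out$p_n2 <- unname(n2["p"])
    out$beta_n2xpgs <- unname(n2x["beta"]); out$se_n2xpgs <- unname(n2x["se"])
    out$p_n2xpgs <- unname(n2x["p"])
  }
  structure(out, class = "interaction_estimate")
}

#' @export
print.interaction_estimate <- function(x, ...) {
  cat(sprintf("Sibling-count interaction [%s, %s model%s], n = %d\n",
              x$trait, x$model,
              if (x$exclusion == "6+_removed") ", 6+ removed" else "", x$n))
  cat(sprintf("  N x PGS: %.4f (se %.4f), p = %.3g\n",
              x$beta_nxpgs, x$se_nxpgs, x$p_nxpgs))
  if (x$model == "quadratic") {
    cat(sprintf("  N^2 x PGS: %.4f (se %.4f), p = %.3g\n",
                x$beta_n2xpgs, x$se_n2xpgs, x$p_n2xpgs))
  }
  invisible(x)
}

#' Scale a coefficient to a per-sibling indirect genetic effect
#'
#' Because a sibling shares half an index individual's PGS variance, a
#' sibling IGE `k_S` contributes only `0.5 k_S` per sibling to the
#' index-PGS slope; both the singleton/non-singleton difference (one
#' sibling) and the per-sibling interaction coefficient therefore
#' estimate `0.5 k_S`.  This operation doubles a coefficient, its SE and
#' its CI bounds to recover `k_S`, the effect of a 1 SD increase in one
#' sibling's PGS on the index individual's phenotype.
#'
#' @param x A coefficient (numeric), an `interaction_estimate` (its
#'   `N:PGS` term is used) or a `difference_estimate` (its `delta`).
#' @param se Standard error (numeric method only).
#' @param ci Optional length-2 CI; defaults to `x +/- 1.96 se`.
#' @param ... Unused.
#' @return An object of class `ige_estimate`: `k_s_hat` (exactly twice
#'   the input point estimate), `se`, `ci95`, `p`.
#' @examples
#' scale_sibling_ige(0.012, se = 0.003)
#' @export
scale_sibling_ige <- function(x, ...) UseMethod("scale_sibling_ige")

#' @rdname scale_sibling_ige
#' @export
scale_sibling_ige.numeric <- function(x, se, ci = NULL, ...) {
  stopifnot(length(x) == 1, is.finite(se))
  if (is.null(ci)) ci <- x + c(-1, 1) * 1.96 * se
  p <- if (se > 0) 2 * stats::pnorm(-abs(x / se)) else as.numeric(x == 0)
  structure(list(k_s_hat = 2 * x, se = 2 * se, ci95 = 2 * ci, p = p,
                 source = "coefficient"),
            class = "ige_estimate")
}

#' @rdname scale_sibling_ige
#' @export
scale_sibling_ige.interaction_estimate <- function(x, ...) {
  out <- scale_sibling_ige(x$beta_nxpgs, se = x$se_nxpgs)
  out$source <- "sibling-count interaction"
  out
}

#' @rdname scale_sibling_ige
#' @export
scale_sibling_ige.difference_estimate <- function(x, ...) {
  out <- scale_sibling_ige(x$delta, se = x$se, ci = x$ci95)
  out$source <- "stratum difference"
  out
}

#' @export
print.ige_estimate <- function(x, ...) {
  cat(sprintf("Sibling IGE estimate (%s): %.4f (se %.4f), 95%% CI (%.4f, %.4f)\n",
              x$source, x$k_s_hat, x$se, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' PGS associations stratified by number of siblings
#'
#' Fits one covariate-adjusted association per sibling-count category
#' (0, 1, ..., `top_category - 1`, and `top_category`+ pooled), and the
#' delta-method difference between the pooled below-top remainder
#' (reference) and the top category.
#'
#' @inheritParams fit_association
#' @param top_category Sibling count at and above which individuals are
#'   pooled (default 6).
#' @return A list with `estimates` (list of `assoc_estimate` or `NULL`
#'   for empty categories, named by category), `counts`, and
#'   `top_vs_rest` (a [estimate_difference()] of pooled remainder minus
#'   top category, reference = remainder).
#' @export
associations_by_sibship <- function(cohort, trait, top_category = 6L,
                                    covariates = default_covariates()) {
  if (!"n_siblings" %in% names(cohort)) {
    stop("cohort must carry n_siblings (run assign_strata first)", call. = FALSE)
  }
  dat <- cohort[!is.na(cohort$n_siblings), , drop = FALSE]
  labs <- c(as.character(seq_len(top_category) - 1L), paste0(top_category, "+"))
  cat_of <- ifelse(dat$n_siblings >= top_category, paste0(top_category, "+"),
                   as.character(dat$n_siblings))
  estimates <- stats::setNames(vector("list", length(labs)), labs)
  counts <- stats::setNames(integer(length(labs)), labs)
  for (lab in labs) {
    sub <- dat[cat_of == lab, , drop = FALSE]
    counts[lab] <- nrow(sub)
    if (nrow(sub) > 0) {
      est <- fit_association(cbind(sub), trait, stratum = "all",
                             covariates = covariates)
      est$stratum <- paste0("siblings_", lab)
      estimates[[lab]] <- est
    }
  }
  rest <- dat[dat$n_siblings < top_category, , drop = FALSE]
  top <- dat[dat$n_siblings >= top_category, , drop = FALSE]
  top_vs_rest <- NULL
  if (nrow(rest) > 0 && nrow(top) > 0) {
    est_rest <- fit_association(rest, trait, "all", covariates)
    est_rest$stratum <- paste0("siblings_<", top_category)
    est_top <- fit_association(top, trait, "all", covariates)
    est_top$stratum <- paste0("siblings_", top_category, "+")
    top_vs_rest <- estimate_difference(est_rest, est_top, reference = "a")
  }
  list(estimates = estimates, counts = counts, top_vs_rest = top_vs_rest)
}

#' Two-estimate heterogeneity test
#'
#' Normal z-test for the difference of two independent estimates:
#' `z = (a - b) / sqrt(se_a^2 + se_b^2)`, two-sided p.  Used e.g. to
#' compare a sibling IGE estimate against an external family-based
#' estimate.
#'
#' @param a,b Point estimates.
#' @param se_a,se_b Their standard errors (not both zero).
#' @return List with `z` and `p`.
#' @examples
#' heterogeneity_z(0.025, 0.0059, 0.025, 0.02)
#' @export
heterogeneity_z <- function(a, se_a, b, se_b) {
  if (se_a == 0 && se_b == 0) {
    stop("both standard errors are zero; no sampling distribution", call. = FALSE)
  }
  z <- (a - b) / sqrt(se_a^2 + se_b^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Group-level differences between strata
#'
#' Compares covariates and phenotypes between two strata.  Unadjusted
#' variables use the difference-of-two-means delta method with
#' `se = sqrt(v1/n1 + v2/n2)` where `v` is the maximum-likelihood
#' (population) variance, so a binary share reduces exactly to the
#' two-proportion closed form `sqrt(p(1-p)/n + ...)`.  Adjusted
#' variables are fit by OLS on a group indicator with sex and age
#' (`age = 2008 - birth_year`, the approximate assessment midpoint) as
#' covariates.  The difference is group 1 minus group 2 in the
#' comparison's naming order (e.g. singleton minus non-singleton).
#'
#' @param cohort A stratified cohort ([assign_strata()]).
#' @param variables Character vector of column names to compare.
#' @param comparison `"singleton-vs-nonsingleton"` or
#'   `"singleton-vs-firstborn"`.
#' @param adjustment `"none"` (delta method) or `"sex+age"` (OLS).
#' @return A data frame `{variable, difference, se, ci_low, ci_high, p,
#'   n1, n2, method}`.
#' @export
group_differences <- function(cohort, variables,
                              comparison = c("singleton-vs-nonsingleton",
                                             "singleton-vs-firstborn"),
                              adjustment = c("none", "sex+age")) {
  comparison <- match.arg(comparison)
  adjustment <- match.arg(adjustment)
  unknown <- setdiff(variables, names(cohort))
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  g1 <- stratum_rows(cohort, "singleton")
  g2 <- if (comparison == "singleton-vs-nonsingleton") {
    stratum_rows(cohort, "non_singleton")
  } else {
    stratum_rows(cohort, "firstborn")
  }
  rows <- lapply(variables, function(v) {
    x1 <- cohort[[v]][g1]; x2 <- cohort[[v]][g2]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (adjustment == "none") {
      d <- mean(x1) - mean(x2)
      v1 <- mean((x1 - mean(x1))^2); v2 <- mean((x2 - mean(x2))^2)
      se <- sqrt(v1 / length(x1) + v2 / length(x2))
      p <- if (se > 0) 2 * stats::pnorm(-abs(d / se)) else as.numeric(d == 0)
      method <- "delta"
    } else {
      dat <- data.frame(
        y = c(x1, x2),
        group1 = rep(c(1, 0), c(length(x1), length(x2))),
        sex = c(cohort$sex[g1][!is.na(cohort[[v]][g1])],
                cohort$sex[g2][!is.na(cohort[[v]][g2])]),
        age = 2008 - c(cohort$birth_year[g1][!is.na(cohort[[v]][g1])],
                       cohort$birth_year[g2][!is.na(cohort[[v]][g2])])
      )
      fit <- stats::lm(y ~ group1 + sex + age, data = dat)
      est <- coef_se(fit, "group1")
      d <- unname(est["beta"]); se <- unname(est["se"]); p <- unname(est["p"])
      method <- "ols sex+age"
    }
    data.frame(variable = v, difference = d, se = se,
               ci_low = d - 1.96 * se, ci_high = d + 1.96 * se, p = p,
               n1 = length(x1), n2 = length(x2), method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "comparison") <- comparison
  out
}

#' Flatten estimates to a results table
#'
#' Converts association, difference, interaction and IGE estimates into
#' uniform rows `{analysis, trait, stratum, n, estimate, se, ci_low,
#' ci_high, p}` for tab-separated output.
#'
#' @param ... Estimate objects (or lists of them), optionally named; the
#'   name becomes the `analysis` label.
#' @return A data frame.
#' @export
results_table <- function(...) {
  items <- list(...)
  labs <- names(items) %||% rep("", length(items))
  rows <- list()
  add <- function(analysis, trait, stratum, n, est, se, lo, hi, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      analysis = analysis, trait = trait %||% NA_character_,
      stratum = stratum %||% NA_character_, n = n %||% NA_integer_,
      estimate = est, se = se, ci_low = lo, ci_high = hi, p = p,
      stringsAsFactors = FALSE)
  }
  walk <- function(x, label) {
    if (inherits(x, "assoc_estimate")) {
      add(label, x$trait, x$stratum, x$n, x$beta, x$se,
          x$beta - 1.96 * x$se, x$beta + 1.96 * x$se, x$p)
    } else if (inherits(x, "difference_estimate")) {
      add(label, x$trait, paste0(x$stratum_a, "-", x$stratum_b), NA,
          x$delta, x$se, x$ci95[1], x$ci95[2], x$p)
    } else if (inherits(x, "interaction_estimate")) {
      add(paste0(label, ":NxPGS"), x$trait, x$exclusion, x$n,
          x$beta_nxpgs, x$se_nxpgs,
          x$beta_nxpgs - 1.96 * x$se_nxpgs, x$beta_nxpgs + 1.96 * x$se_nxpgs,
          x$p_nxpgs)
      if (x$model == "quadratic") {
        add(paste0(label, ":N2xPGS"), x$trait, x$exclusion, x$n,
            x$beta_n2xpgs, x$se_n2xpgs,
            x$beta_n2xpgs - 1.96 * x$se_n2xpgs,
            x$beta_n2xpgs + 1.96 * x$se_n2xpgs, x$p_n2xpgs)
      }
    } else if (inherits(x, "ige_estimate")) {
      add(label, NA, x$source, NA, x$k_s_hat, x$se, x$ci95[1], x$ci95[2], x$p)
    } else if (is.list(x)) {
      for (i in seq_along(x)) {
        if (!is.null(x[[i]])) {
          sub <- names(x)[i] %||% as.character(i)
          walk(x[[i]], if (nzchar(label)) paste0(label, ":", sub) else sub)
        }
      }
    }
  }
  for (i in seq_along(items)) walk(items[[i]], labs[i])
  do.call(rbind, rows)
}
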