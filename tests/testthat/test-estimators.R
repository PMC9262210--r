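test_that("association fit is exact on a noise-free construction", {
  coh <- data.frame(pgs_tr = rnorm(200))
  coh$tr <- 2 * coh$pgs_tr
  # lm warns about the essentially perfect fit on this noise-free input
  est <- suppressWarnings(fit_association(coh, "tr", "all",
                                          covariates = character(0)))
  expect_equal(est$beta, 2, tolerance = 1e-10)
  expect_lt(est$se, 1e-8)
  expect_equal(est$n, 200)
})

test_that("association fit rejects empty strata and collinear designs", {
  coh <- make_test_cohort(n = 2000, seed = 31)
  only_ns <- coh[!is.na(coh$singleton) & !coh$singleton, ]
  expect_error(fit_association(only_ns, "ea", "singleton"), "empty")
  coh$dup <- coh$sex  # exact copy -> collinear
  expect_error(fit_association(coh, "ea", "all",
                               covariates = c("sex", "dup")),
               "collinear")
  expect_error(fit_association(coh, "ea", "bogus"), "unknown stratum")
})

test_that("singleton-stratum slope matches the printed expectation, with and without confounding", {
  n <- 100000
  for (cc in c(0, 0.1)) {
    fam <- sample_family_pgs(n, model1_structure(1), "trio",
                             seed = 400 + round(100 * cc))
    ep <- effect_params(0.5, 0.1, 0.1, 0, c_conf = cc)
    ph <- simulate_phenotypes(fam, ep, seed = 500 + round(100 * cc))
    coh <- data.frame(pgs_tr = fam$pgs[, "O1"], tr = ph$y)
    est <- fit_association(coh, "tr", "all", covariates = character(0))
    expect_lt(abs(est$beta - (0.6 + cc)), 5 * est$se,
              label = sprintf("C = %g", cc))
  }
})

test_that("difference estimator follows the delta-method closed form exactly", {
  a <- structure(list(beta = 0.26, se = 0.010, n = 1000,
                      stratum = "non_singleton", trait = "ea"),
                 class = "assoc_estimate")
  b <- structure(list(beta = 0.23, se = 0.010, n = 1000,
                      stratum = "singleton", trait = "ea"),
                 class = "assoc_estimate")
  d <- estimate_difference(a, b, reference = "a")
  expect_equal(d$delta, 0.03)
  expect_equal(d$se, sqrt(2) * 0.010, tolerance = 1e-12)
  expect_equal(d$ci95, 0.03 + c(-1, 1) * 1.96 * sqrt(2e-4), tolerance = 1e-10)
  expect_equal(d$ci95, c(0.0022814, 0.0577186), tolerance = 1e-6)
  # attenuation is the same affine transform of the difference CI
  expect_equal(d$attenuation_pct, 100 * 0.03 / 0.26, tolerance = 1e-12)
  expect_equal(d$attenuation_ci95, 100 * d$ci95 / 0.26, tolerance = 1e-12)
  expect_equal(d$attenuation_pct, 11.538, tolerance = 1e-3)
  expect_equal(d$attenuation_ci95, c(0.8775, 22.1995), tolerance = 1e-3)
})

test_that("difference estimator degenerate cases behave", {
  a <- structure(list(beta = 0.2, se = 0.01, stratum = "s1", trait = "ea"),
                 class = "assoc_estimate")
  b <- a; b$stratum <- "s2"
  d <- estimate_difference(a, b)
  expect_equal(d$delta, 0)
  expect_equal(d$p, 1)
  expect_equal(d$attenuation_pct, 0)
  # zero reference: attenuation flagged undefined
  a0 <- a; a0$beta <- 0
  expect_warning(d0 <- estimate_difference(a0, b, reference = "a"),
                 "attenuation undefined")
  expect_true(is.na(d0$attenuation_pct))
  # same stratum rejected; different trait rejected
  expect_error(estimate_difference(a, a), "disjoint")
  b2 <- b; b2$trait <- "height"
  expect_error(estimate_difference(a, b2), "different traits")
})

test_that("heterogeneity z-test matches its closed form", {
  h0 <- heterogeneity_z(0.025, 0.0059, 0.025, 0.02)
  expect_equal(h0$z, 0)
  expect_equal(h0$p, 1)
  h1 <- heterogeneity_z(1, 1, 0, 1)
  expect_equal(h1$z, 1 / sqrt(2), tolerance = 1e-10)
  expect_equal(h1$p, 0.4795, tolerance = 1e-4)
  expect_error(heterogeneity_z(1, 0, 0, 0), "zero")
})

test_that("IGE scaling is an exact doubling of point, SE and CI", {
  est <- scale_sibling_ige(0.012, se = 0.003)
  expect_equal(est$k_s_hat, 0.024)
  expect_equal(est$se, 0.006)
  est2 <- scale_sibling_ige(0.012, se = 0.003, ci = c(0.006, 0.018))
  expect_equal(est2$ci95, c(0.012, 0.036))
  expect_equal(scale_sibling_ige(0, se = 0.001)$k_s_hat, 0)
  # method dispatch off the interaction fit uses the N x PGS term
  fake <- structure(list(beta_nxpgs = 0.01, se_nxpgs = 0.002),
                    class = "interaction_estimate")
  expect_equal(scale_sibling_ige(fake)$k_s_hat, 0.02)
})

test_that("sibling-count interaction recovers the generating increment", {
  k_s <- 0.2
  coh <- make_test_cohort(n = 150000, k_s = k_s, seed = 37)
  li <- fit_sibling_interaction(coh, "ea", "linear", "none")
  expect_lt(abs(li$beta_nxpgs - 0.5 * k_s), 5 * li$se_nxpgs)
  ige <- scale_sibling_ige(li)
  expect_lt(abs(ige$k_s_hat - k_s), 5 * ige$se)
  # null calibration
  coh0 <- make_test_cohort(n = 60000, k_s = 0, seed = 38)
  li0 <- fit_sibling_interaction(coh0, "ea", "linear", "none")
  expect_lt(abs(li0$beta_nxpgs), 5 * li0$se_nxpgs)
})

test_that("an attenuated-large-family generator flips the diagnostics", {
  cfg <- cohort_config(
    n_individuals = 150000,
    traits = list(ea = effect_params(0.23, 0.05, 0.05, k_s = 0.2)),
    sibling_ige_cap = c(ea = 5),
    seed = 39)
  coh <- assign_strata(simulate_cohort(cfg))
  full <- fit_sibling_interaction(coh, "ea", "linear", "none")
  excl <- fit_sibling_interaction(coh, "ea", "linear", "6+_removed")
  expect_lt(full$beta_nxpgs, excl$beta_nxpgs)
  quad <- fit_sibling_interaction(coh, "ea", "quadratic", "none")
  expect_lt(quad$beta_n2xpgs, 0)
})

test_that("quadratic model is rejected when N has no curvature support", {
  coh <- make_test_cohort(n = 3000, seed = 40)
  coh$n_siblings <- pmin(coh$n_siblings, 1L)
  expect_error(fit_sibling_interaction(coh, "ea", "quadratic"), "degenerate")
})

test_that("per-sibship associations increase linearly and handle edge categories", {
  k_s <- 0.2
  coh <- make_test_cohort(n = 120000, k_s = k_s, seed = 41)
  by_sib <- associations_by_sibship(coh, "ea")
  betas <- sapply(by_sib$estimates[as.character(0:5)], function(e) e$beta)
  inc <- coef(lm(betas ~ I(0:5)))[2]
  expect_lt(abs(unname(inc) - 0.5 * k_s), 0.02)
  expect_false(is.null(by_sib$top_vs_rest))

  # cohort of only singletons: single category populated, no difference
  sing <- coh[!is.na(coh$singleton) & coh$singleton, ]
  bs <- associations_by_sibship(sing, "ea")
  expect_false(is.null(bs$estimates[["0"]]))
  expect_true(all(sapply(bs$estimates[-1], is.null)))
  expect_true(is.null(bs$top_vs_rest))
  expect_equal(unname(bs$counts["0"]), nrow(sing))
})

test_that("group differences: nulls, constructed shifts and the binary closed form", {
  coh <- make_test_cohort(n = 20000, k_s = 0, seed = 43)
  gd <- group_differences(coh, c("sex", "birth_year"),
                          "singleton-vs-nonsingleton", "none")
  expect_true(all(abs(gd$difference) < 5 * gd$se))
  # binary variable SE equals the two-proportion closed form
  g1 <- coh$sex[!is.na(coh$singleton) & coh$singleton]
  g2 <- coh$sex[!is.na(coh$singleton) & !coh$singleton]
  p1 <- mean(g1); p2 <- mean(g2)
  se_closed <- sqrt(p1 * (1 - p1) / length(g1) + p2 * (1 - p2) / length(g2))
  expect_equal(gd$se[gd$variable == "sex"], se_closed, tolerance = 1e-12)
  # constructed +1 shift recovered exactly by the adjusted model
  coh$height <- rnorm(nrow(coh)) + 0.3 * coh$sex +
    ifelse(!is.na(coh$singleton) & coh$singleton, 1, 0)
  gda <- group_differences(coh, "height", "singleton-vs-nonsingleton", "sex+age")
  expect_lt(abs(gda$difference - 1), 5 * gda$se)
  expect_error(group_differences(coh, "nope", "singleton-vs-nonsingleton"),
               "unknown variable")
})

test_that("results_table flattens heterogeneous estimates into uniform rows", {
  coh <- make_test_cohort(n = 5000, seed = 44)
  a <- fit_association(coh, "ea", "singleton")
  b <- fit_association(coh, "ea", "non_singleton")
  d <- estimate_difference(b, a, "a")
  tab <- results_table(assoc = list(sing = a, nonsing = b), diff = d)
  expect_identical(names(tab),
                   c("analysis", "trait", "stratum", "n", "estimate", "se",
                     "ci_low", "ci_high", "p"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$estimate[3], d$delta)
})
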