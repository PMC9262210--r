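test_that("mating structure presets encode the stated correlations and invariants", {
  m1 <- model1_structure(2)
  expect_identical(m1$member_labels, c("M", "P", "O1", "O2"))
  expect_equal(m1$corr["M", "P"], 0)
  expect_equal(m1$corr["M", "O1"], 0.5)
  expect_equal(m1$corr["O1", "O2"], 0.5)
  expect_equal(diag(m1$corr), setNames(rep(1, 4), m1$member_labels))
  expect_true(isSymmetric(m1$corr))

  m2 <- model2_structure(2)
  expect_equal(m2$corr["M", "P"], 0.2)
  expect_equal(m2$corr["P", "O2"], 0.6)
  expect_equal(m2$corr["O1", "O2"], 0.6)
})

test_that("invalid structures are rejected with diagnostics", {
  # spousal correlation 1 with parent-offspring 0 is not PSD-consistent here:
  # build a non-PSD matrix directly
  R <- diag(3); dimnames(R) <- list(c("M","P","O1"), c("M","P","O1"))
  R["M","P"] <- R["P","M"] <- 0.9
  R["M","O1"] <- R["O1","M"] <- 0.9
  R["P","O1"] <- R["O1","P"] <- -0.9
  expect_error(as_mating_structure(R), "positive semidefinite.*eigenvalue")
  expect_error(as_mating_structure(matrix(1, 2, 2)), "row and column names")
  expect_error(mating_structure(0, 0.5, n_offspring = 0), "at least 1")
  # member-count mismatch between structure and kind
  expect_error(sample_family_pgs(10, model1_structure(1), "quad"),
               "requires 2")
})

test_that("sampled family PGS match the requested correlation structure", {
  n <- 100000
  fam <- sample_family_pgs(n, model1_structure(1), "trio", seed = 101)
  rc <- cor(fam$pgs)
  expect_lt(abs(rc["M", "P"]), 0.01)
  expect_lt(abs(rc["M", "O1"] - 0.5), 0.01)
  expect_lt(abs(rc["P", "O1"] - 0.5), 0.01)
  expect_true(all(abs(apply(fam$pgs, 2, mean)) < 3 / sqrt(n)))
  expect_true(all(abs(apply(fam$pgs, 2, sd) - 1) < 3 / sqrt(n)))

  quad <- sample_family_pgs(n, model2_structure(2), "quad", seed = 102)
  rq <- cor(quad$pgs)
  expect_lt(abs(rq["O1", "O2"] - 0.6), 0.01)
  expect_lt(abs(rq["M", "O1"] - 0.6), 0.01)
  expect_lt(abs(rq["M", "P"] - 0.2), 0.01)
})

test_that("sampling is deterministic given a seed and shape-valid at tiny n", {
  f1 <- sample_family_pgs(50, model1_structure(2), "quad", seed = 7)
  f2 <- sample_family_pgs(50, model1_structure(2), "quad", seed = 7)
  expect_identical(f1$pgs, f2$pgs)
  ident <- as_mating_structure(
    {R <- diag(3); dimnames(R) <- list(c("M","P","O1"), c("M","P","O1")); R})
  tiny <- sample_family_pgs(5, ident, "trio", seed = 1)
  expect_equal(dim(tiny$pgs), c(5L, 3L))
  expect_true(all(is.finite(cor(tiny$pgs))))
})

test_that("phenotype generation follows the additive family model", {
  fam <- sample_family_pgs(50000, model1_structure(1), "trio", seed = 11)
  # pure noise: slope ~ 0
  ph0 <- simulate_phenotypes(fam, effect_params(sigma_eps = 1), seed = 12)
  expect_lt(abs(slope_se(fam$pgs[, "O1"], ph0$y)["beta"]), 0.02)
  # noise-free direct effect: exact
  ph2 <- simulate_phenotypes(fam, effect_params(k_i = 2, sigma_eps = 0), seed = 13)
  expect_equal(ph2$y, 2 * fam$pgs[, "O1"])
  # sibling effect with trio input is rejected
  expect_error(simulate_phenotypes(fam, effect_params(k_s = 0.2)), "trio")
})

test_that("large-n slopes match the analytic expectation, including confounding", {
  n <- 100000
  params <- list(
    list(ep = effect_params(0.5, 0.1, 0.1, 0.2), kind = "quad", sibs = 1),
    list(ep = effect_params(0.3, 0.2, 0.05, 0, c_conf = 0.1), kind = "trio", sibs = 0),
    list(ep = effect_params(0.5, 0.1, 0.1, 0.2, c_conf = -0.15), kind = "quad", sibs = 1)
  )
  for (i in seq_along(params)) {
    p <- params[[i]]
    struct <- model1_structure(if (p$kind == "trio") 1 else 2)
    fam <- sample_family_pgs(n, struct, p$kind, seed = 200 + i)
    ph <- simulate_phenotypes(fam, p$ep, seed = 300 + i)
    fit <- slope_se(fam$pgs[, "O1"], ph$y)
    expected <- expected_slope(p$ep,
                               if (p$sibs == 0) "singleton" else "non_singleton",
                               p$sibs)
    expect_lt(abs(fit["beta"] - expected), 5 * fit["se"],
              label = sprintf("parameter set %d slope error", i))
  }
})

test_that("quad slope reflects the 0.7 printed expectation example", {
  fam <- sample_family_pgs(100000, model1_structure(2), "quad", seed = 21)
  ph <- simulate_phenotypes(fam, effect_params(0.5, 0.1, 0.1, 0.2), seed = 22)
  fit <- slope_se(fam$pgs[, "O1"], ph$y)
  expect_lt(abs(fit["beta"] - 0.7), 5 * fit["se"])
})

test_that("expected_slope implements the stratified linear expectation", {
  expect_equal(expected_slope(effect_params(0.5, 0.1, 0.1, 0.2), "non_singleton", 1), 0.7)
  expect_equal(expected_slope(effect_params(), "singleton", 0), 0)
  expect_equal(expected_slope(effect_params(k_s = 0.2), "non_singleton", 3), 0.3)
  expect_equal(expected_slope(effect_params(0.5, c_conf = 0.1), "singleton", 0), 0.6)
  expect_error(expected_slope(effect_params(), "singleton", 1), "n_sibs")
  expect_error(expected_slope(effect_params(), "non_singleton", -1), "non-negative")
})

test_that("bias decomposition matches the printed formulas and sums exactly", {
  ep <- effect_params(0.5, 0.1, 0.1, k_s = 0.2)
  b <- expected_bias(ep, ep)
  expect_equal(b$sibling_term, 0.1)
  expect_equal(b$direct_term, 0)
  expect_equal(b$maternal_term, 0)

  ns <- effect_params(0.55, 0.1, 0.1, 0)
  s <- effect_params(0.5, 0.1, 0.1, 0)
  expect_equal(expected_bias(ns, s)$direct_term, 0.05)

  ns2 <- effect_params(0.5, 0.3, 0.1, 0)
  s2 <- effect_params(0.5, 0.1, 0.1, 0)
  expect_equal(expected_bias(ns2, s2)$maternal_term, 0.1)

  # components sum to the difference of expectations, machine precision,
  # over random parameter sets
  set.seed(99)
  for (i in 1:20) {
    ns_i <- effect_params(rnorm(1), rnorm(1), rnorm(1), rnorm(1), rnorm(1))
    s_i <- effect_params(rnorm(1), rnorm(1), rnorm(1), 0, rnorm(1))
    d <- expected_bias(ns_i, s_i)
    expect_equal(d$total,
                 expected_slope(ns_i, "non_singleton", 1) -
                   expected_slope(s_i, "singleton", 0),
                 tolerance = 1e-12)
  }
})

test_that("assortative mating inflates the stratum difference beyond 0.5 k_s", {
  n <- 100000
  ep <- effect_params(0.5, 0.1, 0.1, k_s = 0.2)
  ep_trio <- effect_params(0.5, 0.1, 0.1, 0)
  quad <- sample_family_pgs(n, model2_structure(2), "quad", seed = 31)
  trio <- sample_family_pgs(n, model2_structure(1), "trio", seed = 32)
  b_ns <- slope_se(quad$pgs[, "O1"],
                   simulate_phenotypes(quad, ep, seed = 33)$y)["beta"]
  b_s <- slope_se(trio$pgs[, "O1"],
                  simulate_phenotypes(trio, ep_trio, seed = 34)$y)["beta"]
  expect_gt(b_ns - b_s, 0.5 * ep$k_s)
})
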