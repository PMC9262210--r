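# Shared fixtures and independent oracles used across test files.

## Closed-form simple-regression slope and its classical SE; used as a
## second route alongside fit_association / lm.
slope_se <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  beta <- sum(xc * yc) / sum(xc^2)
  rss <- sum((yc - beta * xc)^2)
  c(beta = beta, se = sqrt(rss / ((n - 2) * sum(xc^2))))
}

## Independent brute-force greedy clumping oracle: explicit enumeration of
## the rule (repeatedly take the smallest-p survivor, discard correlated
## neighbours in the window), written against plain data structures.
clump_oracle <- function(stats, dosage, p_threshold, r2_threshold, window_kb) {
  df <- stats[stats$p < p_threshold, , drop = FALSE]
  selected <- character(0)
  while (nrow(df) > 0) {
    ord <- order(df$p, df$chr, df$pos, df$id)
    df <- df[ord, , drop = FALSE]
    pick <- df[1, ]
    selected <- c(selected, pick$id)
    keep <- logical(nrow(df))
    for (k in seq_len(nrow(df))) {
      if (df$id[k] == pick$id) next
      same_chr <- df$chr[k] == pick$chr
      close <- abs(df$pos[k] - pick$pos) <= window_kb * 1000
      if (same_chr && close) {
        r <- suppressWarnings(cor(dosage[, pick$id], dosage[, df$id[k]]))
        if (is.na(r)) r <- 0
        if (r^2 >= r2_threshold) next
      }
      keep[k] <- TRUE
    }
    df <- df[keep, , drop = FALSE]
  }
  selected
}

## Random small clumping instance with variants scattered over 2
## chromosomes so window and chromosome boundaries are both exercised.
random_clump_instance <- function(m, n = 80) {
  g <- simulate_ld_genotypes(n, m, block_size = sample(2:5, 1),
                             rho = runif(1, 0, 0.95),
                             maf_range = c(0.1, 0.5),
                             spacing_bp = sample(c(1e4, 5e6, 2e7), 1))
  ss <- g$variants
  ss$chr <- rep(1:2, length.out = m)[sample.int(m)]
  g$variants$chr <- ss$chr
  ss$beta <- rnorm(m)
  ss$p <- 10^runif(m, -9, 0)
  list(stats = ss, genotypes = g)
}

## Small cohort reused by estimator tests.
make_test_cohort <- function(n = 20000, k_s = 0.1, seed = 42, ...) {
  cfg <- cohort_config(
    n_individuals = n,
    traits = list(ea = effect_params(k_i = 0.23, k_m = 0.05, k_p = 0.05,
                                     k_s = k_s)),
    seed = seed, ...)
  assign_strata(simulate_cohort(cfg))
}
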