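#' Clumping configuration
#'
#' Thresholds for greedy LD clumping of GWAS summary statistics: keep the
#' smallest-p variant passing the p-value threshold, remove correlated
#' neighbours within a physical window, repeat.
#'
#' @param p_threshold Association p-value threshold (default `1e-5`).
#' @param r2_threshold Squared-correlation threshold above which a
#'   neighbour is removed (default `0.001`).
#' @param window_kb Physical window, in kilobases, on either side of the
#'   index variant (default `10000`).
#' @return An object of class `clump_config`.
#' @export
clump_config <- function(p_threshold = 1e-5, r2_threshold = 0.001,
                         window_kb = 10000) {
  if (p_threshold <= 0 || r2_threshold <= 0 || window_kb <= 0) {
    stop("clumping thresholds must be positive", call. = FALSE)
  }
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb),
            class = "clump_config")
}

#' Simulate genotype dosages with block LD structure
#'
#' Generates biallelic dosages (0/1/2) for `n` individuals at
#' `m_variants` variants arranged in LD blocks: within a block the two
#' latent haplotype liabilities follow an AR(1) correlation `rho` between
#' adjacent variants, and blocks are mutually independent.  Each
#' haplotype carries the effect allele when its liability exceeds the
#' allele-frequency quantile, so dosages are in Hardy-Weinberg
#' proportions at the stated frequency.
#'
#' @param n Number of individuals.
#' @param m_variants Number of variants.
#' @param block_size Variants per LD block (last block may be shorter).
#' @param rho AR(1) latent correlation between adjacent variants within a
#'   block; `0 <= rho < 1`.
#' @param maf_range Range of minor-allele frequencies, a sub-interval of
#'   `(0, 0.5]`, sampled uniformly per variant.
#' @param seed Optional integer seed.
#' @param chromosome Chromosome assigned to all variants.
#' @param spacing_bp Physical distance between adjacent variants (1-based
#'   positions `1, 1 + spacing_bp, ...`).
#'
#' @return An object of class `genotype_matrix`: list with `dosage`
#'   (`n` x `m` matrix, values 0..2, columns named by variant id),
#'   `variants` (data frame `id`, `chr`, `pos`, `effect_allele`, `maf`)
#'   and block metadata.
#' @examples
#' g <- simulate_ld_genotypes(100, 20, block_size = 5, rho = 0.8, seed = 1)
#' dim(g$dosage)
#' @export
simulate_ld_genotypes <- function(n, m_variants, block_size = 10L, rho = 0,
                                  maf_range = c(0.05, 0.5), seed = NULL,
                                  chromosome = 1L, spacing_bp = 100000L) {
  if (rho < 0 || rho >= 1) stop("rho must satisfy 0 <= rho < 1", call. = FALSE)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  n <- as.integer(n); m <- as.integer(m_variants)
  stopifnot(n >= 1L, m >= 1L)
  with_seed(seed, {
    maf <- stats::runif(m, maf_range[1], maf_range[2])
    thresh <- stats::qnorm(1 - maf)
    blocks <- split(seq_len(m), (seq_len(m) - 1L) %/% block_size)
    hap_pair <- function() {
      Z <- matrix(0, n, m)
      for (bl in blocks) {
        Zb <- matrix(stats::rnorm(n * length(bl)), n)
        if (rho > 0 && length(bl) > 1L) {
          for (j in 2:length(bl)) {
            Zb[, j] <- rho * Zb[, j - 1] + sqrt(1 - rho^2) * Zb[, j]
          }
        }
        Z[, bl] <- Zb
      }
      Z
    }
    H1 <- sweep(hap_pair(), 2, thresh, ">")
    H2 <- sweep(hap_pair(), 2, thresh, ">")
    dosage <- H1 + H2
    ids <- sprintf("rs%05d", seq_len(m))
    colnames(dosage) <- ids
    variants <- data.frame(
      id = ids, chr = chromosome,
      pos = 1L + (seq_len(m) - 1L) * as.integer(spacing_bp),
      effect_allele = "A", maf = maf,
      stringsAsFactors = FALSE
    )
    structure(list(dosage = dosage, variants = variants,
                   block_size = as.integer(block_size), rho = rho),
              class = "genotype_matrix")
  })
}

#' Marginal single-variant association scan
#'
#' Per-variant simple linear regression (with intercept) of a phenotype
#' on each dosage column, returning summary statistics suitable for
#' clumping and scoring.  Monomorphic variants are reported with beta 0
#' and p 1, with a warning.
#'
#' @param genotypes A [simulate_ld_genotypes()] result (or any object
#'   with `dosage` and `variants` components).
#' @param phenotype Numeric vector, one value per individual.
#' @return A data frame of summary statistics: `id`, `chr`, `pos`,
#'   `effect_allele`, `beta`, `se`, `p`.
#' @export
marginal_gwas <- function(genotypes, phenotype) {
  G <- genotypes$dosage
  y <- as.numeric(phenotype)
  if (length(y) != nrow(G)) stop("phenotype length must match individuals", call. = FALSE)
  n <- length(y)
  gm <- colMeans(G)
  Sxx <- colSums(G^2) - n * gm^2
  yc <- y - mean(y)
  Sxy <- as.numeric(crossprod(G, yc))
  Syy <- sum(yc^2)
  zero_var <- Sxx <= .Machine$double.eps * n
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance variant(s) reported with beta 0, p 1")
  }
  beta <- ifelse(zero_var, 0, Sxy / Sxx)
  if (n > 2) {
    rss <- pmax(Syy - beta * Sxy, 0)
    se <- ifelse(zero_var, NA_real_, sqrt(rss / ((n - 2) * Sxx)))
    tval <- ifelse(zero_var | se == 0, 0, beta / se)
    p <- ifelse(zero_var, 1, 2 * stats::pt(-abs(tval), df = n - 2))
    p[!zero_var & se == 0 & beta != 0] <- 0  # perfect fit
  } else {
    se <- rep(NA_real_, length(beta))
    p <- rep(1, length(beta))
  }
  out <- genotypes$variants[, c("id", "chr", "pos", "effect_allele")]
  out$beta <- beta
  out$se <- se
  out$p <- p
  out
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly selects the remaining variant with the smallest p-value
#' below `p_threshold` and removes all unselected variants on the same
#' chromosome within `window_kb` kilobases whose dosage r-squared with
#' the selected variant is at least `r2_threshold`.  Ties on p are broken
#' by chromosome, then position, then id, for determinism.
#'
#' @param stats Summary statistics data frame with columns `id`, `chr`,
#'   `pos`, `beta`, `p` (as from [marginal_gwas()] or read from a
#'   tab-separated file).
#' @param ld_source A [simulate_ld_genotypes()] result providing the
#'   dosages from which r-squared is computed; its variant ids must
#'   cover all of `stats`' ids.
#' @param config A [clump_config()].
#' @return Character vector of selected variant ids, in selection order.
#' @examples
#' g <- simulate_ld_genotypes(500, 10, block_size = 5, rho = 0.9, seed = 1)
#' ss <- marginal_gwas(g, g$dosage[, 1] + rnorm(500, sd = 0.5))
#' ld_clump(ss, g, clump_config())
#' @export
ld_clump <- function(stats, ld_source, config = clump_config()) {
  stopifnot(inherits(config, "clump_config"))
  need <- c("id", "chr", "pos", "p")
  if (!all(need %in% names(stats))) {
    stop("stats must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(stats$id)) stop("variant ids must be unique", call. = FALSE)
  missing_ids <- setdiff(stats$id, colnames(ld_source$dosage))
  if (length(missing_ids)) {
    stop("variant not present in LD source: ", missing_ids[1], call. = FALSE)
  }
  if (any(stats$p <= 0 | stats$p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)

  cand <- stats[stats$p < config$p_threshold, , drop = FALSE]
  ## deterministic processing order: p, then chr, pos, id
  cand <- cand[order(cand$p, cand$chr, cand$pos, cand$id), , drop = FALSE]
  alive <- rep(TRUE, nrow(cand))
  selected <- character(0)
  G <- ld_source$dosage
  window_bp <- config$window_kb * 1000
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    selected <- c(selected, cand$id[i])
    alive[i] <- FALSE
    near <- which(alive & cand$chr == cand$chr[i] &
                    abs(cand$pos - cand$pos[i]) <= window_bp)
    if (length(near)) {
      g0 <- G[, cand$id[i]]
      r2 <- suppressWarnings(stats::cor(g0, G[, cand$id[near], drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      alive[near[r2 >= config$r2_threshold]] <- FALSE
    }
  }
  selected
}

#' Score polygenic scores from variant weights
#'
#' Computes the weighted allele-dosage sum \eqn{\sum_j \beta_j d_{ij}}
#' per individual.  Weight substitution is supported by construction:
#' the same variant set can be scored with alternative beta vectors
#' (e.g. weights re-estimated within sibships).
#'
#' @param genotypes A [simulate_ld_genotypes()] result.
#' @param weights Named numeric vector, variant id to beta.  Every id
#'   must be present in the genotypes.
#' @param standardize If `TRUE` (default), the score is standardized to
#'   sample mean 0 and SD 1.
#' @return Numeric vector of per-individual scores.
#' @export
score_pgs <- function(genotypes, weights, standardize = TRUE) {
  if (is.null(names(weights))) stop("weights must be named by variant id", call. = FALSE)
  missing_ids <- setdiff(names(weights), colnames(genotypes$dosage))
  if (length(missing_ids)) {
    stop("variants absent from genotypes: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  score <- as.numeric(genotypes$dosage[, names(weights), drop = FALSE] %*% weights)
  if (standardize) {
    s <- stats::sd(score)
    if (nrow(genotypes$dosage) < 2 || s == 0) {
      stop("cannot standardize a constant score", call. = FALSE)
    }
    score <- (score - mean(score)) / s
  }
  score
}
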