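#' Direct and indirect genetic effect parameters
#'
#' Bundles the coefficients of the generative phenotype model
#' \deqn{Y = k_I G_I + k_M G_M + k_P G_P + k_S \sum_{sibs} G_{sib} + C G_I + \epsilon,}
#' where \eqn{G} are standardized PGS: `k_i` is the direct effect of the
#' index individual's own PGS, `k_m` and `k_p` are the maternal and
#' paternal indirect genetic effects (IGEs), `k_s` is the per-sibling IGE
#' (summed over siblings), and `c_conf` is a confounding term that shifts
#' the PGS slope additively (population stratification or assortative
#' mating acting through the index PGS).  `sigma_eps` is the SD of the
#' Normal error.
#'
#' Effects are on the phenotype scale per SD of PGS.  A `stratum` label
#' allows stratum-specific parameter sets (e.g. singleton vs
#' non-singleton) for bias analyses.
#'
#' @param k_i Direct effect of the index individual's PGS.
#' @param k_m,k_p Maternal and paternal IGEs.
#' @param k_s Per-sibling IGE.
#' @param c_conf Confounding slope shift applied to the index PGS.
#' @param sigma_eps Error SD, strictly positive (or zero for exact
#'   noise-free checks).
#' @param stratum Optional stratum label for stratum-specific copies.
#'
#' @return An object of class `effect_params`.
#' @examples
#' effect_params(k_i = 0.5, k_m = 0.1, k_p = 0.1, k_s = 0.2)
#' @export
effect_params <- function(k_i = 0, k_m = 0, k_p = 0, k_s = 0,
                          c_conf = 0, sigma_eps = 1, stratum = NULL) {
  vals <- c(k_i = k_i, k_m = k_m, k_p = k_p, k_s = k_s,
            c_conf = c_conf, sigma_eps = sigma_eps)
  if (!all(is.finite(vals))) stop("all effect parameters must be finite", call. = FALSE)
  if (sigma_eps < 0) stop("sigma_eps must be non-negative", call. = FALSE)
  structure(list(k_i = k_i, k_m = k_m, k_p = k_p, k_s = k_s,
                 c_conf = c_conf, sigma_eps = sigma_eps,
                 stratum = stratum),
            class = "effect_params")
}

#' @export
print.effect_params <- function(x, ...) {
  cat("Effect parameters",
      if (!is.null(x$stratum)) paste0(" [stratum: ", x$stratum, "]"), ":\n",
      sep = "")
  cat(sprintf("  k_i = %g, k_m = %g, k_p = %g, k_s = %g, c_conf = %g, sigma_eps = %g\n",
              x$k_i, x$k_m, x$k_p, x$k_s, x$c_conf, x$sigma_eps))
  invisible(x)
}
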