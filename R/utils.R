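# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Set the RNG state for one operation call.  A NULL seed leaves the global
## stream untouched; an integer seed makes the call deterministic.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Expand a run-level seed into a deterministic per-call seed stream.
## Kept below 2^31 - 1 so the result is always a valid R integer.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483647)
}

## Exact multivariate standard-normal draw with correlation matrix R,
## via the Cholesky factor: rows of Z %*% chol(R) have correlation R.
rmvn_chol <- function(n, R) {
  L <- chol(R)
  Z <- matrix(stats::rnorm(n * ncol(R)), nrow = n)
  X <- Z %*% L
  colnames(X) <- colnames(R)
  X
}

## Classical simple/multiple OLS wrapper returning beta and SE for one term.
coef_se <- function(fit, term) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) {
    stop("term '", term, "' not estimable (dropped from the fit)", call. = FALSE)
  }
  c(beta = sm[term, 1], se = sm[term, 2], p = sm[term, 4])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
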