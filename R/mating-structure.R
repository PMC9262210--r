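#' Within-family PGS correlation structure
#'
#' A `mating_structure` describes the correlation matrix of standardized
#' polygenic scores among the members of a nuclear family: mother (`M`),
#' father (`P`) and offspring (`O1`, ..., `On`).  The three free parameters
#' are the spousal (mother-father) correlation, the parent-offspring
#' correlation (constant across all parent-offspring pairs) and the
#' sibling-sibling correlation (constant across all sibling pairs).
#'
#' Under random mating the expected values are spousal 0 and
#' parent-offspring and sibling correlations 0.5; phenotype-correlated mate
#' choice (assortative mating) raises all three.
#'
#' @param spousal Correlation between maternal and paternal PGS.
#' @param parent_offspring Correlation between each parent's and each
#'   offspring's PGS.
#' @param sibling Correlation between the PGS of each pair of siblings.
#'   Ignored when `n_offspring == 1`.
#' @param n_offspring Number of offspring columns (`O1..On`), at least 1.
#'
#' @return An object of class `mating_structure` with elements
#'   `member_labels` (character vector `M`, `P`, `O1..On`) and `corr`
#'   (the correlation matrix, unit diagonal, symmetric, positive
#'   semidefinite).
#'
#' @examples
#' model1_structure(n_offspring = 2)  # random mating, sibling pair
#' mating_structure(0.2, 0.6, 0.6)    # assortative mating trio
#' @seealso [model1_structure()], [model2_structure()], [sample_family_pgs()]
#' @export
mating_structure <- function(spousal, parent_offspring, sibling = parent_offspring,
                             n_offspring = 1L) {
  n_offspring <- as.integer(n_offspring)
  if (n_offspring < 1L) stop("n_offspring must be at least 1", call. = FALSE)
  labels <- c("M", "P", paste0("O", seq_len(n_offspring)))
  k <- length(labels)
  R <- diag(k)
  dimnames(R) <- list(labels, labels)
  R["M", "P"] <- R["P", "M"] <- spousal
  off <- labels[-(1:2)]
  for (o in off) {
    R["M", o] <- R[o, "M"] <- parent_offspring
    R["P", o] <- R[o, "P"] <- parent_offspring
  }
  if (n_offspring > 1L) {
    for (i in seq_along(off)) {
      for (j in seq_along(off)) {
        if (i != j) R[off[i], off[j]] <- sibling
      }
    }
  }
  validate_mating_structure(
    structure(list(member_labels = labels, corr = R), class = "mating_structure")
  )
}

#' @rdname mating_structure
#' @param corr For [as_mating_structure()], a full correlation matrix with
#'   row/column names `M`, `P`, `O1..On`.
#' @export
as_mating_structure <- function(corr) {
  labels <- colnames(corr)
  if (is.null(labels) || !identical(labels, rownames(corr))) {
    stop("corr must have matching row and column names", call. = FALSE)
  }
  expected <- c("M", "P", paste0("O", seq_len(length(labels) - 2L)))
  if (length(labels) < 3L || !identical(labels, expected)) {
    stop("member labels must be M, P, O1..On", call. = FALSE)
  }
  validate_mating_structure(
    structure(list(member_labels = labels, corr = corr), class = "mating_structure")
  )
}

validate_mating_structure <- function(x) {
  R <- x$corr
  if (any(abs(diag(R) - 1) > 1e-12)) stop("correlation matrix must have unit diagonal", call. = FALSE)
  if (any(abs(R - t(R)) > 1e-12)) stop("correlation matrix must be symmetric", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("correlation matrix is not positive semidefinite (smallest eigenvalue ",
         fmt_num(min(ev)), ")", call. = FALSE)
  }
  off <- x$member_labels[-(1:2)]
  if (length(off) > 1L) {
    ss <- R[off, off][upper.tri(diag(length(off)))]
    if (diff(range(ss)) > 1e-12) stop("sibling-sibling correlations must be constant", call. = FALSE)
  }
  po <- c(R["M", off], R["P", off])
  if (diff(range(po)) > 1e-12) stop("parent-offspring correlations must be constant", call. = FALSE)
  x
}

#' @rdname mating_structure
#' @details `model1_structure()` is the random-mating preset (spousal 0,
#'   parent-offspring and sibling 0.5); `model2_structure()` is the
#'   assortative-mating preset (spousal 0.2, parent-offspring and sibling
#'   0.6).
#' @export
model1_structure <- function(n_offspring = 1L) {
  mating_structure(0, 0.5, 0.5, n_offspring = n_offspring)
}

#' @rdname mating_structure
#' @export
model2_structure <- function(n_offspring = 1L) {
  mating_structure(0.2, 0.6, 0.6, n_offspring = n_offspring)
}

#' @export
print.mating_structure <- function(x, ...) {
  cat("Within-family PGS correlation structure (",
      length(x$member_labels) - 2L, " offspring)\n", sep = "")
  print(round(x$corr, 3))
  invisible(x)
}

n_offspring_of <- function(structure) length(structure$member_labels) - 2L
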