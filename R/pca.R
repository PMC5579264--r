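## Dimensionality reduction and dissimilarity matrices: correlation-matrix
## PCA with eigenvalue > 1 retention, Euclidean phrase distances on the
## retained standardized scores, individual averaging, and normalization.

#' Principal components with Kaiser (eigenvalue > 1) retention
#'
#' Variables are z-scored and the correlation matrix eigendecomposed;
#' components with eigenvalue > 1 are retained. Loadings follow the factor
#' convention (eigenvector times the square root of its eigenvalue) with a
#' deterministic sign: the largest-magnitude loading of each component is
#' positive. Scores are the standardized (unit-variance, regression-type)
#' component scores, which makes downstream Euclidean distances scale-free.
#' An optional varimax rotation of the retained loadings is available;
#' rotated scores are recomputed from the rotated loadings.
#'
#' @param x numeric matrix or data.frame of observations x variables (no
#'   missing values, at least 2 variables, more observations than
#'   variables). Metadata columns must be removed first (see
#'   [feature_values()]).
#' @param rotate `"none"` (default) or `"varimax"`.
#' @return a `pca_kaiser` object: `n_retained`, `loadings` (variables x
#'   retained components), `scores` (observations x retained components,
#'   unit variance), `eigenvalues` (all), `var_explained` (all components,
#'   percent; sums to 100), `cum_var_retained` (percent of variance carried
#'   by the retained components).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' x <- cbind(x, x[, 1] + rnorm(100, sd = 0.2))
#' pca_kaiser(x)
#' @export
pca_kaiser <- function(x, rotate = c("none", "varimax")) {
  rotate <- match.arg(rotate)
  x <- as.matrix(x)
  if (!is.numeric(x)) stopf("`x` must be numeric")
  if (anyNA(x)) stopf("`x` contains missing values")
  if (ncol(x) < 2L) stopf("at least 2 variables are required")
  if (nrow(x) <= ncol(x))
    stopf("more observations (%d) than variables (%d) are required",
          nrow(x), ncol(x))
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stopf("constant variable(s) with zero variance: %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)
  eg <- eigen(stats::cor(x), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  keep <- which(ev > 1)
  if (!length(keep))
    stopf("no component has eigenvalue > 1; nothing to retain")
  vec <- eg$vectors[, keep, drop = FALSE]
  ## deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  loadings <- sweep(vec, 2, sqrt(ev[keep]), `*`)
  scores <- sweep(z %*% vec, 2, sqrt(ev[keep]), `/`)
  if (rotate == "varimax" && length(keep) > 1L) {
    rot <- stats::varimax(loadings)
    loadings <- unclass(rot$loadings)
    ## regression-type scores for the rotated solution
    scores <- z %*% loadings %*% solve(crossprod(loadings))
    scores <- sweep(scores, 2, apply(scores, 2, stats::sd), `/`)
  }
  dimnames(loadings) <- list(colnames(x), sprintf("PC%d", seq_along(keep)))
  dimnames(scores) <- list(rownames(x), sprintf("PC%d", seq_along(keep)))
  structure(list(
    n_retained = length(keep), loadings = loadings, scores = scores,
    eigenvalues = eg$values,
    var_explained = 100 * eg$values / sum(eg$values),
    cum_var_retained = 100 * sum(ev[keep]) / sum(eg$values),
    rotation = rotate),
    class = "pca_kaiser")
}

#' @export
print.pca_kaiser <- function(x, ...) {
  cat(sprintf(
    "PCA (correlation matrix, Kaiser retention%s): %d of %d components retained, %.1f%% of variance\n",
    if (x$rotation != "none") paste0(", ", x$rotation) else "",
    x$n_retained, length(x$eigenvalues), x$cum_var_retained))
  invisible(x)
}

#' Euclidean distance matrix between phrases
#'
#' @param scores a [pca_kaiser()] object or a numeric matrix of component
#'   scores with row labels.
#' @return labeled symmetric matrix of pairwise Euclidean distances, zero
#'   diagonal.
#' @export
phrase_distance <- function(scores) {
  if (inherits(scores, "pca_kaiser")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (!nrow(scores)) stopf("`scores` is empty")
  if (is.null(rownames(scores)))
    stopf("`scores` must carry row labels (phrase ids)")
  m <- as.matrix(stats::dist(scores))
  diag(m) <- 0
  m
}

#' Average a phrase-level distance matrix to the individual level
#'
#' Entry (i, j) for two distinct individuals is the mean of the phrase
#' distances over all cross pairs (one phrase from each); the diagonal is
#' set to 0 and excluded from all downstream statistics.
#'
#' @param d labeled symmetric phrase-distance matrix.
#' @param phrase_to_individual named character vector mapping every phrase
#'   label of `d` to an individual id.
#' @return labeled symmetric matrix over individuals (in first-appearance
#'   order of the mapping).
#' @export
individual_mean_distance <- function(d, phrase_to_individual) {
  check_square_matrix(d)
  unmapped <- setdiff(rownames(d), names(phrase_to_individual))
  if (length(unmapped))
    stopf("phrases not mapped to individuals: %s",
          paste(utils::head(unmapped, 5), collapse = ", "))
  ind <- phrase_to_individual[rownames(d)]
  ids <- unique(unname(ind))
  out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  idx <- split(seq_len(nrow(d)), factor(ind, levels = ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j) {
      v <- mean(d[idx[[i]], idx[[j]], drop = FALSE])
      out[i, j] <- out[j, i] <- v
    }
  }
  out
}
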