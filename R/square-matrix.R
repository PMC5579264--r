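## Labeled symmetric matrices are passed around as plain numeric matrices with
## identical row/column names; these helpers centralize validation and the
## min-max normalization every matrix goes through before a permutation test.

check_square_matrix <- function(m, name = deparse(substitute(m)),
                                tol = 1e-12) {
  if (!is.matrix(m) || !is.numeric(m))
    stopf("`%s` must be a numeric matrix", name)
  if (nrow(m) != ncol(m)) stopf("`%s` must be square", name)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("`%s` must carry row and column labels", name)
  if (!identical(rownames(m), colnames(m)))
    stopf("row and column labels of `%s` differ", name)
  if (anyNA(m)) stopf("`%s` contains missing values", name)
  if (max(abs(m - t(m))) > tol)
    stopf("`%s` is not symmetric (tolerance %g)", name, tol)
  invisible(m)
}

off_diag <- function(m) m[row(m) != col(m)]

#' Min-max normalize the off-diagonal of a symmetric matrix to [0, 1]
#'
#' Rescales all off-diagonal entries linearly so the smallest becomes 0 and
#' the largest 1, the convention applied to every dissimilarity or
#' relatedness matrix before it enters a permutation test. The diagonal is
#' set to 0 and is excluded from all downstream statistics.
#'
#' @param m labeled symmetric numeric matrix with at least two distinct
#'   off-diagonal values.
#' @return a matrix of the same shape and labels with off-diagonal values in
#'   `[0, 1]` (minimum exactly 0, maximum exactly 1) and zero diagonal.
#' @examples
#' m <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' normalize01(m)
#' @export
normalize01 <- function(m) {
  check_square_matrix(m)
  v <- off_diag(m)
  lo <- min(v); hi <- max(v)
  if (hi - lo <= 0)
    stopf("cannot normalize: all off-diagonal values are equal (%g)", lo)
  out <- (m - lo) / (hi - lo)
  diag(out) <- 0
  ## exact symmetry can drift by one ulp through the affine map
  out <- (out + t(out)) / 2
  out
}

#' Restrict a labeled square matrix to a subset of its labels
#'
#' Used to align matrices on a common individual set (and order) before a
#' permutation test, e.g. for per-sex analyses.
#'
#' @param m labeled symmetric numeric matrix.
#' @param ids labels to keep, in the requested order.
#' @return the submatrix over `ids`.
#' @export
restrict_matrix <- function(m, ids) {
  check_square_matrix(m)
  missing <- setdiff(ids, rownames(m))
  if (length(missing))
    stopf("labels absent from matrix: %s", paste(missing, collapse = ", "))
  m[ids, ids, drop = FALSE]
}

## Write/read a labeled square matrix as CSV with labels in the first column.
write_square_matrix <- function(m, path) {
  check_square_matrix(m)
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_square_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_square_matrix(m)
  m
}
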