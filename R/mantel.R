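## Matrix permutation tests. The standard Mantel test correlates the
## off-diagonal entries of two labeled symmetric matrices and builds its
## null by simultaneous row/column permutation of one matrix; the
## kin-category variant correlates acoustic similarity with a binary
## parent-offspring design and permutes offspring identities only.

new_mantel_result <- function(n, r, p, n_perm, tail, perm_r = NULL,
                              method = "mantel") {
  structure(list(n = n, r = r, p = p, n_permutations = n_perm, tail = tail,
                 perm_r = perm_r, method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s: n = %d, r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$method, x$n, x$r, x$p, x$tail, x$n_permutations))
  invisible(x)
}

tail_p <- function(obs, perm, tail) {
  eps <- 1e-12
  exceed <- switch(tail,
    greater = sum(perm >= obs - eps),
    less = sum(perm <= obs + eps),
    two.sided = sum(abs(perm) >= abs(obs) - eps))
  (exceed + 1) / (length(perm) + 1)
}

#' Mantel matrix permutation test
#'
#' Pearson correlation between the upper-triangle entries of two labeled
#' symmetric matrices, with significance from simultaneous row/column
#' permutations of the first matrix. The p-value uses the plus-one rule
#' `(exceedances + 1) / (n_perm + 1)`, so it can never be 0; the default
#' tail is one-sided (`"greater"`).
#'
#' When an explicit permutation matrix is supplied (one permutation per
#' row, typically the complete set from [all_permutations()]), it is
#' treated as the exhaustive null and the p-value is the exact proportion
#' of those permutations reaching the observed correlation.
#'
#' @param a,b labeled symmetric numeric matrices with identical labels in
#'   identical order; n >= 4; non-constant off-diagonals.
#' @param n_perm number of random permutations (default 9999).
#' @param tail `"greater"`, `"less"` or `"two.sided"`.
#' @param seed optional integer seed; results are reproducible.
#' @param permutations optional integer matrix of explicit permutations.
#' @return a `mantel_result` with fields `n`, `r`, `p`, `n_permutations`,
#'   `tail` and the permutation correlations `perm_r`.
#' @examples
#' m1 <- as.matrix(dist(matrix(rnorm(10), 5)))
#' m2 <- as.matrix(dist(matrix(rnorm(10), 5)))
#' mantel_test(m1, m2, n_perm = 99, seed = 1)
#' @export
mantel_test <- function(a, b, n_perm = 9999,
                        tail = c("greater", "less", "two.sided"),
                        seed = NULL, permutations = NULL) {
  tail <- match.arg(tail)
  check_square_matrix(a, "a"); check_square_matrix(b, "b")
  if (!identical(rownames(a), rownames(b)))
    stopf("matrix labels differ between `a` and `b`")
  n <- nrow(a)
  if (n < 4L) stopf("matrix order must be >= 4 (got %d)", n)
  ut <- upper.tri(a)
  va <- a[ut]; vb <- b[ut]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stopf("off-diagonal values are constant; correlation undefined")
  r <- stats::cor(va, vb)
  if (!is.null(permutations)) {
    if (ncol(permutations) != n) stopf("permutations must have %d columns", n)
    perm_r <- apply(permutations, 1, function(p) {
      ap <- a[p, p]
      stats::cor(ap[ut], vb)
    })
    eps <- 1e-12
    exceed <- switch(tail,
      greater = sum(perm_r >= r - eps),
      less = sum(perm_r <= r + eps),
      two.sided = sum(abs(perm_r) >= abs(r) - eps))
    p <- exceed / nrow(permutations)
    return(new_mantel_result(n, r, p, nrow(permutations), tail, perm_r))
  }
  n_perm <- check_count(n_perm, "n_perm")
  perm_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      pp <- sample.int(n)
      ap <- a[pp, pp]
      stats::cor(ap[ut], vb)
    }, numeric(1))
  })
  new_mantel_result(n, r, tail_p(r, perm_r, tail), n_perm, tail, perm_r)
}

#' Exact Mantel test by full enumeration
#'
#' Enumerates all `n!` simultaneous row/column permutations and reports the
#' exact proportion reaching the observed correlation. Intended as a small-n
#' oracle; the correlation is computed by an explicit double loop,
#' independent of [mantel_test()]'s vectorized path.
#'
#' @inheritParams mantel_test
#' @param max_n refuse matrices larger than this (default 7).
#' @return a `mantel_result` with `n_permutations = n!`.
#' @export
mantel_exact <- function(a, b, max_n = 7,
                         tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  check_square_matrix(a, "a"); check_square_matrix(b, "b")
  if (!identical(rownames(a), rownames(b)))
    stopf("matrix labels differ between `a` and `b`")
  n <- nrow(a)
  if (n > max_n) stopf("n = %d exceeds max_n = %d for exact enumeration",
                       n, max_n)
  loop_cor <- function(m1, m2) {
    x <- numeric(0); y <- numeric(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      x <- c(x, m1[i, j]); y <- c(y, m2[i, j])
    }
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  r <- loop_cor(a, b)
  perms <- all_permutations(n)
  perm_r <- numeric(nrow(perms))
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ]
    perm_r[k] <- loop_cor(a[p, p], b)
  }
  eps <- 1e-12
  exceed <- switch(tail,
    greater = sum(perm_r >= r - eps),
    less = sum(perm_r <= r + eps),
    two.sided = sum(abs(perm_r) >= abs(r) - eps))
  new_mantel_result(n, r, exceed / nrow(perms), nrow(perms), tail, perm_r,
                    method = "exact mantel")
}

#' Build a parent-offspring kin-category design
#'
#' Collects the reproductive individuals of the parental role (fathers or
#' mothers) and the offspring of the offspring role (sons or daughters)
#' from a pedigree, and encodes the binary design matrix whose entry is 1
#' for a true parent-offspring dyad and 0 for a parent paired with another
#' pair's offspring of the same role. Within-role dyads are excluded by
#' construction (the design is a parents x offspring rectangle).
#'
#' @param ped a pedigree table.
#' @param parent_role `"father"` or `"mother"`.
#' @param offspring_role `"son"` or `"daughter"`.
#' @param individuals optional character vector restricting the design to
#'   individuals that actually carry acoustic data.
#' @return a `kin_category_design`: `parents`, `offspring`, binary matrix
#'   `pairs` (parents x offspring) and the roles.
#' @export
kin_category_design <- function(ped, parent_role = c("father", "mother"),
                                offspring_role = c("son", "daughter"),
                                individuals = NULL) {
  parent_role <- match.arg(parent_role)
  offspring_role <- match.arg(offspring_role)
  validate_pedigree(ped)
  psex <- if (parent_role == "father") "M" else "F"
  osex <- if (offspring_role == "son") "M" else "F"
  keep <- if (is.null(individuals)) ped$id else intersect(ped$id, individuals)
  parents <- ped$id[ped$role == "reproductive" & ped$sex == psex &
                      ped$id %in% keep]
  off <- ped[ped$role == "offspring" & ped$sex == osex &
               ped$id %in% keep, , drop = FALSE]
  parcol <- if (parent_role == "father") off$father else off$mother
  ok <- parcol %in% parents
  off <- off[ok, , drop = FALSE]; parcol <- parcol[ok]
  pairs <- matrix(0L, length(parents), nrow(off),
                  dimnames = list(parents, off$id))
  for (k in seq_len(nrow(off))) pairs[parcol[k], off$id[k]] <- 1L
  structure(list(parents = parents, offspring = off$id, pairs = pairs,
                 parent_role = parent_role, offspring_role = offspring_role),
            class = "kin_category_design")
}

#' Kin-category Mantel test
#'
#' Tests whether offspring phrases are acoustically more similar to their
#' own parent's than to other parents' phrases. Acoustic dissimilarity is
#' converted to similarity (`1 - ` min-max-normalized dissimilarity),
#' restricted to the design's parent x offspring dyads, and correlated with
#' the binary true-pair matrix. The null permutes offspring identities
#' among the offspring while holding the parents fixed; the test is
#' one-tailed for greater similarity of true pairs.
#'
#' @param acoustic labeled symmetric acoustic dissimilarity matrix covering
#'   all design individuals.
#' @param design a [kin_category_design()] with at least 2 parents and 2
#'   offspring.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed.
#' @return a `mantel_result`; `n` is the number of offspring (the
#'   permutation units).
#' @export
kin_category_mantel <- function(acoustic, design, n_perm = 9999,
                                seed = NULL) {
  if (!inherits(design, "kin_category_design"))
    stopf("`design` must come from kin_category_design()")
  check_square_matrix(acoustic, "acoustic")
  if (length(design$parents) < 2L || length(design$offspring) < 2L)
    stopf("design needs >= 2 parents and >= 2 offspring (got %d and %d)",
          length(design$parents), length(design$offspring))
  ids <- c(design$parents, design$offspring)
  missing <- setdiff(ids, rownames(acoustic))
  if (length(missing))
    stopf("design individuals absent from acoustic matrix: %s",
          paste(missing, collapse = ", "))
  sim <- 1 - normalize01(acoustic)
  sub <- sim[design$parents, design$offspring, drop = FALSE]
  bin <- design$pairs
  if (stats::sd(as.vector(sub)) == 0)
    stopf("acoustic similarities are constant over the design; correlation undefined")
  if (stats::sd(as.vector(bin)) == 0)
    stopf("design matrix is constant; no true/false contrast")
  r <- stats::cor(as.vector(sub), as.vector(bin))
  n_perm <- check_count(n_perm, "n_perm")
  n_off <- ncol(sub)
  perm_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      pp <- sample.int(n_off)
      stats::cor(as.vector(sub[, pp, drop = FALSE]), as.vector(bin))
    }, numeric(1))
  })
  new_mantel_result(n_off, r, tail_p(r, perm_r, "greater"), n_perm,
                    "greater", perm_r, method = "kin-category mantel")
}
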