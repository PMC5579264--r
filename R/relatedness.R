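## Pairwise relatedness estimation from co-dominant microsatellite genotypes.
##
## All estimators work from a genotype_table plus per-locus allele
## frequencies. Shared low-level kernels: Hardy-Weinberg genotype
## probabilities, the one-gene-IBD transition probability, and the
## allele-sharing similarity category of a genotype pair. The same kernels
## drive the dyadic likelihood, the Wang-style similarity-category moment
## system, and the test oracles.

## P(genotype {a,b}) under HWE given named frequency vector p.
hwe_prob <- function(a, b, p) {
  pa <- p[[a]]; pb <- p[[b]]
  if (a == b) pa * pa else 2 * pa * pb
}

## P(genotype y = {c,d} | y shares exactly one gene IBD with x = {a,b}):
## the IBD gene is one of x's alleles with probability 1/2 each; the other
## gene is an independent draw from the population.
ibd1_trans <- function(a, b, c, d, p) {
  t <- 0
  for (s in c(a, b)) {
    if (c == d) {
      if (s == c) t <- t + 0.5 * p[[c]]
    } else {
      if (s == c) t <- t + 0.5 * p[[d]]
      if (s == d) t <- t + 0.5 * p[[c]]
    }
  }
  t
}

same_genotype <- function(a, b, c, d) {
  (a == c && b == d) || (a == d && b == c)
}

## Allele-sharing similarity category of an unordered genotype pair:
## 1 = identical genotypes, 2 = homozygote vs heterozygote sharing its
## allele, 3 = sharing exactly one allele (both heterozygous), 4 = none.
pair_category <- function(a, b, c, d) {
  m <- sum(c(a, b) %in% c(c, d)) + sum(c(c, d) %in% c(a, b))
  if (m == 4L) 1L else if (m == 3L) 2L else if (m == 2L) 3L else 4L
}

## Likelihood components of a genotype pair at one locus: probability of
## observing (gx, gy) given the dyad shares 0, 1 or 2 genes IBD.
pair_lik_components <- function(a, b, c, d, p) {
  hx <- hwe_prob(a, b, p)
  c(L0 = hx * hwe_prob(c, d, p),
    L1 = hx * ibd1_trans(a, b, c, d, p),
    L2 = hx * as.numeric(same_genotype(a, b, c, d)))
}

## Exact expected probabilities of similarity categories 1..3 under 0/1/2
## genes IBD, by enumeration over all genotype pairs at the locus. Returns
## list(K0, K1, K2) of 3-vectors plus the locus weight used by the Wang-style
## moment estimator.
wang_locus_coeffs <- function(p) {
  al <- names(p)
  k <- length(al)
  K0 <- K1 <- K2 <- numeric(3)
  for (i in seq_len(k)) for (j in i:k) {
    gx <- c(al[i], al[j])
    hx <- hwe_prob(gx[1], gx[2], p)
    for (u in seq_len(k)) for (v in u:k) {
      gy <- c(al[u], al[v])
      s <- pair_category(gx[1], gx[2], gy[1], gy[2])
      if (s == 4L) next
      K0[s] <- K0[s] + hx * hwe_prob(gy[1], gy[2], p)
      K1[s] <- K1[s] + hx * ibd1_trans(gx[1], gx[2], gy[1], gy[2], p)
      if (same_genotype(gx[1], gx[2], gy[1], gy[2])) K2[s] <- K2[s] + hx
    }
  }
  a2 <- sum(p^2); a3 <- sum(p^3)
  list(K0 = K0, K1 = K1, K2 = K2, weight = 1 / (2 * a2 - a3))
}

## ---- per-dyad estimators -------------------------------------------------
## gx, gy: 2 x L character matrices of allele names (NA = untyped locus).

dyad_qg <- function(gx, gy, freqs) {
  num <- den <- num2 <- den2 <- 0
  used <- FALSE
  for (l in seq_along(freqs)) {
    if (anyNA(gx[, l]) || anyNA(gy[, l])) next
    p <- freqs[[l]]
    a <- gx[1, l]; b <- gx[2, l]; c <- gy[1, l]; d <- gy[2, l]
    sh <- 0.5 * ((a == c) + (a == d) + (b == c) + (b == d))
    num <- num + sh - p[[a]] - p[[b]]
    den <- den + 1 + (a == b) - p[[a]] - p[[b]]
    num2 <- num2 + sh - p[[c]] - p[[d]]
    den2 <- den2 + 1 + (c == d) - p[[c]] - p[[d]]
    used <- TRUE
  }
  if (!used) return(NA_real_)
  (num / den + num2 / den2) / 2
}

dyad_li <- function(gx, gy, freqs) {
  num <- den <- 0
  used <- FALSE
  for (l in seq_along(freqs)) {
    if (anyNA(gx[, l]) || anyNA(gy[, l])) next
    p <- freqs[[l]]
    m <- sum(gx[, l] %in% gy[, l]) + sum(gy[, l] %in% gx[, l])
    S <- m / 4
    S0 <- sum(p^2 * (2 - p))
    num <- num + (S - S0)
    den <- den + (1 - S0)
    used <- TRUE
  }
  if (!used) return(NA_real_)
  num / den
}

lr_directional <- function(gx, gy, freqs) {
  wr <- w <- 0
  used <- FALSE
  for (l in seq_along(freqs)) {
    if (anyNA(gx[, l]) || anyNA(gy[, l])) next
    p <- freqs[[l]]
    a <- gx[1, l]; b <- gx[2, l]; c <- gy[1, l]; d <- gy[2, l]
    pa <- p[[a]]; pb <- p[[b]]
    den <- (1 + (a == b)) * (pa + pb) - 4 * pa * pb
    if (den <= 1e-12) next  # reference genotype carries no information here
    num <- pa * ((b == c) + (b == d)) + pb * ((a == c) + (a == d)) -
      4 * pa * pb
    wl <- den / (2 * pa * pb)
    wr <- wr + wl * (num / den)
    w <- w + wl
    used <- TRUE
  }
  if (!used || w <= 0) return(NA_real_)
  wr / w
}

dyad_lr <- function(gx, gy, freqs) {
  r1 <- lr_directional(gx, gy, freqs)
  r2 <- lr_directional(gy, gx, freqs)
  if (is.na(r1) && is.na(r2)) return(NA_real_)
  mean(c(r1, r2), na.rm = TRUE)
}

dyad_wang <- function(gx, gy, freqs, coeffs) {
  M <- matrix(0, 2, 2); v <- numeric(2)
  used <- FALSE
  for (l in seq_along(freqs)) {
    if (anyNA(gx[, l]) || anyNA(gy[, l])) next
    cf <- coeffs[[l]]
    s <- pair_category(gx[1, l], gx[2, l], gy[1, l], gy[2, l])
    obs <- as.numeric(seq_len(3) == s)
    A <- cbind(cf$K1 - cf$K0, cf$K2 - cf$K0)
    y <- obs - cf$K0
    M <- M + cf$weight * crossprod(A)
    v <- v + cf$weight * crossprod(A, y)
    used <- TRUE
  }
  if (!used) return(NA_real_)
  theta <- tryCatch(solve(M, v), error = function(e) NULL)
  if (is.null(theta)) return(NA_real_)
  theta[2] + theta[1] / 2  # r = Delta + phi/2
}

## (k0, k1, k2) simplex grid; rows ordered by increasing r so flat-likelihood
## ties resolve to the least-related point.
ibd_grid <- function(resolution) {
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      resolution <= 0 || resolution > 1)
    stopf("`grid_resolution` must be in (0, 1]")
  v <- seq(0, 1, by = resolution)
  if (v[length(v)] < 1 - 1e-9) v <- c(v, 1)
  g <- expand.grid(k1 = v, k2 = v)
  g <- g[g$k1 + g$k2 <= 1 + 1e-9, ]
  g$k0 <- pmax(0, 1 - g$k1 - g$k2)
  g$r <- g$k2 + g$k1 / 2
  g <- g[order(g$r, g$k2), ]
  as.matrix(g[, c("k0", "k1", "k2", "r")])
}

dyad_ml <- function(gx, gy, freqs, grid) {
  K <- NULL
  for (l in seq_along(freqs)) {
    if (anyNA(gx[, l]) || anyNA(gy[, l])) next
    K <- cbind(K, pair_lik_components(gx[1, l], gx[2, l],
                                      gy[1, l], gy[2, l], freqs[[l]]))
  }
  if (is.null(K)) return(NA_real_)
  lik <- grid[, c("k0", "k1", "k2")] %*% K
  ll <- rowSums(log(lik))
  grid[which.max(ll), "r"]
}

## ---- genotype-table plumbing --------------------------------------------

## Convert one individual's row into a 2 x L character matrix of allele
## names; validates that every observed allele is covered by `freqs`.
genotype_chars <- function(g, i, freqs) {
  x <- rbind(as.character(g$a1[i, ]), as.character(g$a2[i, ]))
  x[x == "NA"] <- NA_character_
  for (l in seq_len(ncol(x))) {
    obs <- x[, l][!is.na(x[, l])]
    bad <- setdiff(obs, names(freqs[[l]]))
    if (length(bad))
      stopf("allele(s) %s at locus '%s' are absent from the supplied frequencies",
            paste(bad, collapse = ", "), names(freqs)[l])
  }
  x
}

check_freqs <- function(freqs, g) {
  if (is.null(names(freqs)) ||
      !identical(unname(names(freqs)), unname(colnames(g$a1))))
    stopf("`freqs` must be a named list matching the table's loci")
  invisible(freqs)
}

relatedness_from_pairs <- function(g, freqs, pair_fun, estimator) {
  check_freqs(freqs, g)
  ids <- genotype_individuals(g)
  n <- length(ids)
  chars <- lapply(seq_len(n), function(i) genotype_chars(g, i, freqs))
  r <- matrix(0, n, n, dimnames = list(ids, ids))
  flagged <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    val <- pair_fun(chars[[i]], chars[[j]])
    if (is.na(val)) flagged <- c(flagged, paste(ids[i], ids[j], sep = ":"))
    r[i, j] <- r[j, i] <- val
  }
  structure(list(r = r, estimator = estimator, freqs = freqs,
                 no_shared_loci = flagged),
            class = "relatedness_matrix")
}

#' Moment estimators of pairwise relatedness
#'
#' Computes a multilocus moment estimate of relatedness for every dyad in a
#' genotype table. Four estimators are registered:
#' `"queller_goodnight"` (ratio of locus-summed numerators/denominators,
#' averaged over the two reference directions), `"li"` (allele-sharing
#' similarity index corrected by its unrelated expectation), `"lynch_ritland"`
#' (reference-genotype regression estimator with the published locus weights,
#' direction-averaged) and `"wang"` (similarity-category moment system with
#' exact enumeration-based coefficients, solved by weighted least squares
#' across loci). A slot for a fifth moment estimator can be added by
#' registering a pair function of the same signature.
#'
#' Raw estimates may fall outside `[-1, 1]`; they are preserved in the
#' result's `r` field and clamped only by [as.matrix.relatedness_matrix()].
#'
#' @param g a `genotype_table`.
#' @param freqs per-locus allele frequencies (default: gene counts from `g`
#'   via [allele_frequencies()]). Must cover every observed allele.
#' @param estimator one of `"queller_goodnight"`, `"li"`, `"lynch_ritland"`,
#'   `"wang"`.
#' @return a `relatedness_matrix`: raw symmetric estimate matrix, estimator
#'   name, frequencies used, and the dyads flagged for having no shared
#'   typed locus (estimate `NA`).
#' @examples
#' ped <- simulate_pedigree(3, seed = 1)
#' g <- simulate_genotypes(ped, seed = 2)
#' rm <- moment_estimators(g, estimator = "queller_goodnight")
#' round(as.matrix(rm), 2)
#' @export
moment_estimators <- function(g, freqs = allele_frequencies(g),
                              estimator = c("queller_goodnight", "li",
                                            "lynch_ritland", "wang")) {
  if (!inherits(g, "genotype_table")) stopf("`g` must be a genotype_table")
  estimator <- match.arg(estimator)
  pair_fun <- switch(estimator,
    queller_goodnight = function(x, y) dyad_qg(x, y, freqs),
    li = function(x, y) dyad_li(x, y, freqs),
    lynch_ritland = function(x, y) dyad_lr(x, y, freqs),
    wang = {
      coeffs <- lapply(freqs, wang_locus_coeffs)
      function(x, y) dyad_wang(x, y, freqs, coeffs)
    })
  relatedness_from_pairs(g, freqs, pair_fun, estimator)
}

#' Dyadic maximum-likelihood relatedness
#'
#' For each dyad, maximizes the product over loci of the genotype-pair
#' likelihood over the IBD coefficients (k0, k1, k2) on the simplex, by grid
#' search at the requested resolution; the estimate is r = k2 + k1/2. The
#' grid is scanned in order of increasing r, so flat likelihoods resolve to
#' the least-related maximizer. Estimates lie in [0, 1] by construction.
#'
#' @inheritParams moment_estimators
#' @param grid_resolution spacing of the simplex grid (default 0.01).
#' @return a `relatedness_matrix` (see [moment_estimators()]).
#' @examples
#' ped <- simulate_pedigree(2, seed = 1)
#' g <- simulate_genotypes(ped, seed = 2)
#' rm <- dyadic_ml(g, grid_resolution = 0.05)
#' @export
dyadic_ml <- function(g, freqs = allele_frequencies(g),
                      grid_resolution = 0.01) {
  if (!inherits(g, "genotype_table")) stopf("`g` must be a genotype_table")
  grid <- ibd_grid(grid_resolution)
  relatedness_from_pairs(g, freqs,
                         function(x, y) dyad_ml(x, y, freqs, grid),
                         "dyadml")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  n <- nrow(x$r)
  vals <- x$r[upper.tri(x$r)]
  cat(sprintf("Relatedness matrix (%s): %d individuals, %d dyads\n",
              x$estimator, n, length(vals)))
  cat(sprintf("  r range: [%.3f, %.3f], mean %.3f\n",
              min(vals, na.rm = TRUE), max(vals, na.rm = TRUE),
              mean(vals, na.rm = TRUE)))
  if (length(x$no_shared_loci))
    cat("  dyads with no shared typed locus:",
        paste(x$no_shared_loci, collapse = ", "), "\n")
  invisible(x)
}

#' Export a relatedness matrix, clamped to [-1, 1]
#'
#' @param x a `relatedness_matrix`.
#' @param ... unused.
#' @return plain labeled symmetric matrix with values clamped to `[-1, 1]`.
#' @export
as.matrix.relatedness_matrix <- function(x, ...) {
  pmin(pmax(x$r, -1), 1)
}

#' Convert relatedness to a genetic distance matrix
#'
#' Genetic distance is `1 - normalized relatedness`: the clamped estimates
#' are min-max rescaled to `[0, 1]` and inverted so that the genetic and the
#' acoustic matrices point in the same (dissimilarity) direction.
#'
#' @param x a `relatedness_matrix`.
#' @return labeled symmetric distance matrix with off-diagonal values in
#'   `[0, 1]` and zero diagonal.
#' @export
relatedness_to_distance <- function(x) {
  m <- as.matrix(x)
  if (anyNA(m))
    stopf("relatedness matrix contains NA dyads; cannot build a distance matrix")
  d <- 1 - normalize01(m)
  diag(d) <- 0
  d
}
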