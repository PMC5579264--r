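## Permuted discriminant function analysis with a test factor (e.g.
## individual) and a control factor (e.g. song). Phrases are grouped into
## blocks (test x control cells); balanced training selections sample
## control levels, not phrases, so the non-independence of phrases within a
## song never inflates the classification rate; the permutation null
## relabels whole blocks.

## Fisher discriminant via whitening: nearest-centroid classification in
## the whitened space is identical to classification in the discriminant
## subspace, because directions orthogonal to the centroid span add the
## same distance to every centroid.
lda_fit <- function(x, y) {
  y <- droplevels(factor(y))
  classes <- levels(y)
  k <- length(classes)
  n <- nrow(x); p <- ncol(x)
  mns <- rowsum(x, y) / as.vector(table(y))
  xc <- x - mns[as.integer(y), , drop = FALSE]
  denom <- max(n - k, 1L)
  W <- crossprod(xc) / denom
  ridge <- 0
  R <- NULL
  lambda <- 1e-8 * mean(diag(W))
  if (lambda <= 0) lambda <- 1e-8
  repeat {
    R <- tryCatch(chol(W + diag(ridge, p)), error = function(e) NULL)
    if (!is.null(R)) break
    ridge <- if (ridge == 0) lambda else ridge * 10
    if (ridge > 1e6 * max(lambda, 1)) stopf("within-class scatter irreparably singular")
  }
  Rinv <- backsolve(R, diag(p))
  centroids <- mns %*% Rinv
  ## discriminant axes: eigenvectors of the between-scatter of whitened
  ## centroids (weighted by class size)
  cw <- as.vector(table(y)) / n
  gm <- colSums(centroids * cw)
  cc <- sweep(centroids, 2, gm)
  B <- crossprod(cc * sqrt(cw))
  eb <- eigen(B, symmetric = TRUE)
  keep <- which(eb$values > max(eb$values[1], 1e-12) * 1e-8)
  axes <- Rinv %*% eb$vectors[, keep, drop = FALSE]
  structure(list(classes = classes, whiten = Rinv, centroids = centroids,
                 axes = axes, ridge = ridge),
            class = "songkin_lda")
}

lda_classify <- function(model, x) {
  z <- x %*% model$whiten
  C <- model$centroids
  d2 <- outer(rowSums(z^2), rep(1, nrow(C))) - 2 * z %*% t(C) +
    outer(rep(1, nrow(z)), rowSums(C^2))
  model$classes[max.col(-d2, ties.method = "first")]
}

#' Train a linear discriminant classifier
#'
#' Fisher discriminant analysis: within-class scatter is pooled, the space
#' whitened, and cases are classified to the nearest class centroid in the
#' whitened (equivalently, discriminant) space with uniform priors. A
#' singular within-class scatter is ridge-regularized with an escalating
#' constant recorded in the result. With at least as many variables as
#' cases, variables are truncated to the leading principal components with
#' a warning.
#'
#' @param x numeric matrix of cases x variables.
#' @param labels class label per case; >= 2 classes with >= 2 cases each.
#' @return a `songkin_lda` model with `classes`, discriminant `axes`
#'   (at most `classes - 1`), whitening matrix and centroids.
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20))
#' m <- lda_train(x, rep(c("a", "b"), each = 20))
#' mean(predict(m, x) == rep(c("a", "b"), each = 20))
#' @export
lda_train <- function(x, labels) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) stopf("`x` must be numeric without NAs")
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2L) stopf("at least 2 classes are required")
  if (any(table(y) < 2L)) stopf("every class needs at least 2 cases")
  trunc_map <- NULL; trunc_d <- NULL
  if (nrow(x) <= ncol(x)) {
    d <- min(nrow(x) - nlevels(y), ncol(x) - 1L)
    if (d < 1L) stopf("too few cases for any discriminant variable")
    warnf("more variables (%d) than cases (%d): truncating to %d leading components",
          ncol(x), nrow(x), d)
    trunc_map <- stats::prcomp(x, center = TRUE)
    trunc_d <- d
    x <- trunc_map$x[, seq_len(d), drop = FALSE]
  }
  m <- lda_fit(x, y)
  m$trunc_map <- trunc_map
  m$trunc_d <- trunc_d
  m
}

#' @export
predict.songkin_lda <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$trunc_map))
    x <- stats::predict(object$trunc_map, x)[, seq_len(object$trunc_d),
                                             drop = FALSE]
  lda_classify(object, x)
}

## ---- pDFA ----------------------------------------------------------------

## Average training/testing correct-classification rates over `n_sel`
## balanced random selections for one block labeling.
pdfa_rates <- function(x, block_of, block_idx, block_labels, quota, n_sel,
                       collect_confusion = FALSE) {
  lv <- levels(block_labels)
  tr <- te <- numeric(n_sel)
  conf <- NULL
  if (collect_confusion)
    conf <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  for (s in seq_len(n_sel)) {
    train_blocks <- unlist(lapply(lv, function(l) {
      bs <- which(block_labels == l)
      sample_vec(bs, quota)
    }))
    tr_idx <- unlist(block_idx[train_blocks])
    te_idx <- setdiff(seq_len(nrow(x)), tr_idx)
    lab <- as.character(block_labels)[block_of]
    fit <- lda_fit(x[tr_idx, , drop = FALSE], lab[tr_idx])
    pr_tr <- lda_classify(fit, x[tr_idx, , drop = FALSE])
    pr_te <- lda_classify(fit, x[te_idx, , drop = FALSE])
    tr[s] <- 100 * mean(pr_tr == lab[tr_idx])
    te[s] <- 100 * mean(pr_te == lab[te_idx])
    if (collect_confusion) {
      tt <- table(factor(lab[te_idx], levels = lv),
                  factor(pr_te, levels = lv))
      conf <- conf + as.matrix(tt)
    }
  }
  list(training = mean(tr), testing = mean(te), confusion = conf)
}

#' Permuted discriminant function analysis
#'
#' Tests whether phrases can be assigned to the levels of a test factor
#' (individual, group) better than chance while respecting a control factor
#' (song, individual) whose levels make phrases non-independent.
#'
#' Observed statistic: for each of `n_selections` random balanced
#' selections, every test level contributes `quota` of its control levels
#' to training; a discriminant classifier trained on those phrases is
#' scored on the training phrases (training rate) and on the held-out
#' phrases (testing rate), and rates are averaged over selections. Null
#' distribution: test-level labels are permuted over blocks (test x control
#' cells; every phrase inherits its block's permuted label) and the
#' averaged rates recomputed with fresh selections. P-values use the
#' plus-one rule, separately for training and testing.
#'
#' @param x numeric matrix of phrases x variables (e.g. component scores).
#' @param test factor (or vector) with the test-factor level per phrase.
#' @param control factor with the control-factor level per phrase. Every
#'   test level must span at least 2 control levels.
#' @param n_selections random balanced training selections (default 100).
#' @param n_permutations permutations for the null (default 1000).
#' @param quota control levels per test level entering training; default
#'   `max(1, min(control levels per test level) - 1)`, which always leaves
#'   held-out data.
#' @param seed optional integer seed; the result is fully reproducible.
#' @return a `pdfa_result`: training/testing rates (%), permutation
#'   p-values, chance rate `100 / n test levels`, the testing-phase
#'   confusion matrix accumulated over the observed selections, and the
#'   configuration used.
#' @examples
#' ped <- simulate_pedigree(2, c(1, 1), seed = 1)
#' ps <- simulate_phrases(ped, seed = 2)
#' f <- temporal_features(subset_phrases(ps, type = "DP2"))
#' pdfa(feature_values(f), f$individual_id, f$song_id,
#'      n_selections = 3, n_permutations = 19, seed = 3)
#' @export
pdfa <- function(x, test, control, n_selections = 100,
                 n_permutations = 1000, quota = NULL, seed = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) stopf("`x` must be numeric without NAs")
  test <- droplevels(factor(test)); control <- droplevels(factor(control))
  if (length(test) != nrow(x) || length(control) != nrow(x))
    stopf("`test` and `control` must have one entry per row of `x`")
  n_selections <- check_count(n_selections, "n_selections")
  n_permutations <- check_count(n_permutations, "n_permutations")
  ## control levels spanned by each test level
  span <- tapply(control, test, function(cc) length(unique(cc)))
  bad <- names(span)[span < 2L]
  if (length(bad))
    stopf("test level(s) with a single control level (no held-out data possible): %s",
          paste(bad, collapse = ", "))
  if (nlevels(test) < 2L) stopf("at least 2 test levels are required")
  block_f <- droplevels(interaction(test, control, drop = TRUE))
  block_of <- as.integer(block_f)
  block_idx <- split(seq_len(nrow(x)), block_of)
  block_labels <- factor(
    vapply(block_idx, function(i) as.character(test[i[1]]), ""),
    levels = levels(test))
  min_blocks <- min(table(block_labels))
  if (is.null(quota)) quota <- max(1L, min_blocks - 1L)
  quota <- check_count(quota, "quota")
  if (quota > min_blocks - 1L)
    stopf("quota %d leaves no held-out control level for the smallest test level (%d blocks)",
          quota, min_blocks)

  with_seed(seed, {
    obs <- pdfa_rates(x, block_of, block_idx, block_labels, quota,
                      n_selections, collect_confusion = TRUE)
    null_tr <- null_te <- numeric(n_permutations)
    nb <- length(block_idx)
    for (j in seq_len(n_permutations)) {
      perm_labels <- block_labels[sample.int(nb)]
      r <- pdfa_rates(x, block_of, block_idx, perm_labels, quota,
                      n_selections)
      null_tr[j] <- r$training; null_te[j] <- r$testing
    }
    eps <- 1e-9
    structure(list(
      training_rate = obs$training,
      training_p = (sum(null_tr >= obs$training - eps) + 1) /
        (n_permutations + 1),
      testing_rate = obs$testing,
      testing_p = (sum(null_te >= obs$testing - eps) + 1) /
        (n_permutations + 1),
      chance_rate = 100 / nlevels(test),
      confusion = obs$confusion,
      n_test_levels = nlevels(test),
      n_phrases = nrow(x),
      config = list(n_selections = n_selections,
                    n_permutations = n_permutations, quota = quota)),
      class = "pdfa_result")
  })
}

#' @export
print.pdfa_result <- function(x, ...) {
  cat(sprintf(
    "pDFA: %d phrases, %d test levels (chance %.1f%%)\n  training %.2f%% (p = %.4g)   testing %.2f%% (p = %.4g)\n",
    x$n_phrases, x$n_test_levels, x$chance_rate,
    x$training_rate, x$training_p, x$testing_rate, x$testing_p))
  invisible(x)
}

#' Run a pDFA separately for each sex
#'
#' @inheritParams pdfa
#' @param sex vector of `"M"`/`"F"` per phrase. A sex with fewer than 2
#'   test levels is skipped with a warning.
#' @param ... passed on to [pdfa()].
#' @return named list of `pdfa_result` (possibly of length 1).
#' @export
pdfa_by_sex <- function(x, test, control, sex, ...) {
  x <- as.matrix(x)
  out <- list()
  for (s in c("M", "F")) {
    i <- which(sex == s)
    lv <- unique(as.character(test[i]))
    if (length(lv) < 2L) {
      warnf("sex '%s' has fewer than 2 test levels; skipped", s)
      next
    }
    out[[s]] <- pdfa(x[i, , drop = FALSE], test[i], control[i], ...)
  }
  out
}

#' Group-membership pDFA
#'
#' Convenience wrapper using group as the test factor and individual
#' identity as the control factor: can phrases be assigned to the social
#' group once individual identity is controlled for?
#'
#' @inheritParams pdfa
#' @param group group id per phrase.
#' @param individual individual id per phrase.
#' @param ... passed on to [pdfa()].
#' @return a `pdfa_result`.
#' @export
pdfa_group <- function(x, group, individual, ...) {
  pdfa(x, test = group, control = individual, ...)
}
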