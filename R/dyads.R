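## Simulation of dyads of known relatedness and the estimator-comparison
## harness that selects a relatedness estimator for the main analysis.

dyad_categories <- function() {
  c(parent_offspring = 0.5, full_sibling = 0.5,
    half_sibling = 0.25, unrelated = 0)
}

## n independent HWE individuals as allele matrices (sizes).
hwe_draw <- function(loci, n, ids) {
  lnames <- vapply(loci, `[[`, "", "name")
  a1 <- matrix(NA_integer_, n, length(loci), dimnames = list(ids, lnames))
  a2 <- a1
  for (j in seq_along(loci)) {
    al <- loci[[j]]$alleles; fr <- loci[[j]]$freqs
    a1[, j] <- sample_vec(al, n, replace = TRUE, prob = fr)
    a2[, j] <- sample_vec(al, n, replace = TRUE, prob = fr)
  }
  list(a1 = a1, a2 = a2)
}

## One Mendelian child per row from parent allele matrices.
mendel_child <- function(pa, pm) {
  n <- nrow(pa$a1); L <- ncol(pa$a1)
  pick <- function(m1, m2) {
    sel <- matrix(stats::runif(n * L) < 0.5, n, L)
    out <- m1
    out[sel] <- m2[sel]
    out
  }
  list(a1 = pick(pa$a1, pa$a2), a2 = pick(pm$a1, pm$a2))
}

#' Simulate genotype dyads of a known relatedness category
#'
#' Dyads are built by explicit Mendelian construction — parents are drawn
#' from the locus allele frequencies under Hardy-Weinberg and offspring
#' inherit one allele from each parent — rather than by sampling IBD
#' coefficients directly. Categories: `parent_offspring` (true r = 0.5,
#' the dyad is a founder parent and its child by an independent mate),
#' `full_sibling` (0.5), `half_sibling` (0.25, one shared parent) and
#' `unrelated` (0).
#'
#' @param loci list of [locus_spec()] supplying allele frequencies.
#' @param category one of the four category names.
#' @param n number of dyads.
#' @param seed optional integer seed.
#' @return a `dyad_set`: allele matrices for the two members of each dyad
#'   (`x`, `y`, each with `a1`/`a2` of dimension `n x loci`), the category
#'   and its true relatedness.
#' @examples
#' ds <- simulate_dyads(default_locus_panel(), "full_sibling", 10, seed = 1)
#' ds$true_r
#' @export
simulate_dyads <- function(loci, category, n, seed = NULL) {
  cats <- dyad_categories()
  if (!is.character(category) || length(category) != 1L ||
      !category %in% names(cats))
    stopf("`category` must be one of: %s",
          paste(names(cats), collapse = ", "))
  n <- check_count(n, "n")
  ids <- sprintf("d%d", seq_len(n))
  with_seed(seed, {
    pair <- switch(category,
      unrelated = list(x = hwe_draw(loci, n, ids),
                       y = hwe_draw(loci, n, ids)),
      parent_offspring = {
        fa <- hwe_draw(loci, n, ids); mo <- hwe_draw(loci, n, ids)
        list(x = fa, y = mendel_child(fa, mo))
      },
      full_sibling = {
        fa <- hwe_draw(loci, n, ids); mo <- hwe_draw(loci, n, ids)
        list(x = mendel_child(fa, mo), y = mendel_child(fa, mo))
      },
      half_sibling = {
        fa <- hwe_draw(loci, n, ids)
        mo1 <- hwe_draw(loci, n, ids); mo2 <- hwe_draw(loci, n, ids)
        list(x = mendel_child(fa, mo1), y = mendel_child(fa, mo2))
      })
    structure(list(x = pair$x, y = pair$y, loci = loci,
                   category = category, true_r = unname(cats[category]),
                   n = n),
              class = "dyad_set")
  })
}

## Per-dyad estimates over a dyad_set for one registered estimator.
estimate_dyad_set <- function(ds, estimator, freqs = NULL,
                              grid_resolution = 0.01) {
  if (!inherits(ds, "dyad_set")) stopf("`ds` must be a dyad_set")
  if (is.null(freqs)) {
    freqs <- lapply(ds$loci, `[[`, "freqs")
    names(freqs) <- vapply(ds$loci, `[[`, "", "name")
  }
  char_row <- function(m, i) {
    x <- rbind(as.character(m$a1[i, ]), as.character(m$a2[i, ]))
    x[x == "NA"] <- NA_character_
    x
  }
  pair_fun <-
    if (is.function(estimator)) {
      function(x, y) estimator(x, y, freqs)
    } else switch(estimator,
      queller_goodnight = function(x, y) dyad_qg(x, y, freqs),
      li = function(x, y) dyad_li(x, y, freqs),
      lynch_ritland = function(x, y) dyad_lr(x, y, freqs),
      wang = {
        coeffs <- lapply(freqs, wang_locus_coeffs)
        function(x, y) dyad_wang(x, y, freqs, coeffs)
      },
      dyadml = {
        grid <- ibd_grid(grid_resolution)
        function(x, y) dyad_ml(x, y, freqs, grid)
      },
      stopf("unknown estimator '%s'", estimator))
  vapply(seq_len(ds$n),
         function(i) pair_fun(char_row(ds$x, i), char_row(ds$y, i)),
         numeric(1))
}

#' Compare relatedness estimators on simulated dyads of known relatedness
#'
#' Replicates the estimator-selection procedure used before a relatedness
#' analysis: simulate `n_per_category` dyads for each of the four known
#' categories with [simulate_dyads()], apply every registered estimator, and
#' rank the estimators by the Pearson correlation between their estimates
#' and the true relatedness pooled over all categories. An estimator whose
#' estimates are constant (correlation undefined) is flagged and ranked
#' last.
#'
#' @param loci list of [locus_spec()].
#' @param n_per_category dyads per category (default 100).
#' @param estimators character vector naming registered estimators; any of
#'   `"queller_goodnight"`, `"li"`, `"lynch_ritland"`, `"wang"`, `"dyadml"`.
#' @param extra_estimators optional named list of functions
#'   `f(gx, gy, freqs)` returning a single estimate for one dyad (each `gx`,
#'   `gy` a 2 x loci character matrix of allele names).
#' @param grid_resolution simplex grid spacing for `"dyadml"`.
#' @param seed optional integer seed; the full report is reproducible.
#' @return a `dyad_sim_report`: `summary` (estimator x category means and
#'   SDs), `ranking` (pooled correlation with truth, rank, degeneracy flag)
#'   and the per-dyad estimates.
#' @examples
#' rep <- compare_estimators(default_locus_panel(), n_per_category = 20,
#'                           estimators = c("queller_goodnight", "li"),
#'                           seed = 1)
#' rep$ranking
#' @export
compare_estimators <- function(loci, n_per_category = 100,
                               estimators = c("queller_goodnight", "li",
                                              "lynch_ritland", "wang",
                                              "dyadml"),
                               extra_estimators = NULL,
                               grid_resolution = 0.01, seed = NULL) {
  n_per_category <- check_count(n_per_category, "n_per_category")
  all_est <- c(as.list(estimators), extra_estimators)
  est_names <- c(estimators, names(extra_estimators))
  if (length(est_names) < 2L) stopf("at least two estimators are required")
  cats <- names(dyad_categories())
  sets <- lapply(seq_along(cats), function(k)
    simulate_dyads(loci, cats[k], n_per_category,
                   seed = derive_seed(seed, k)))
  names(sets) <- cats

  est_tab <- list(); summ <- list()
  for (e in seq_along(all_est)) {
    per_cat <- lapply(sets, estimate_dyad_set, estimator = all_est[[e]],
                      grid_resolution = grid_resolution)
    est_tab[[est_names[e]]] <- per_cat
    summ[[e]] <- data.frame(
      estimator = est_names[e], category = cats,
      true_r = unname(dyad_categories()[cats]),
      mean = vapply(per_cat, mean, 0, na.rm = TRUE),
      sd = vapply(per_cat, stats::sd, 0, na.rm = TRUE),
      row.names = NULL)
  }
  summary <- do.call(rbind, summ)

  truth <- rep(unname(dyad_categories()[cats]), each = n_per_category)
  ranking <- do.call(rbind, lapply(est_names, function(nm) {
    est <- unlist(est_tab[[nm]], use.names = FALSE)
    ok <- !is.na(est)
    degenerate <- sum(ok) < 3L || stats::sd(est[ok]) == 0
    r <- if (degenerate) NA_real_ else stats::cor(est[ok], truth[ok])
    data.frame(estimator = nm, correlation = r, degenerate = degenerate,
               row.names = NULL)
  }))
  ## undefined correlations rank last
  ord <- order(!is.na(ranking$correlation), ranking$correlation,
               decreasing = TRUE)
  ranking$rank <- NA_integer_
  ranking$rank[ord] <- seq_len(nrow(ranking))
  structure(list(summary = summary, ranking = ranking,
                 estimates = est_tab, n_per_category = n_per_category),
            class = "dyad_sim_report")
}

#' @export
print.dyad_sim_report <- function(x, ...) {
  cat(sprintf("Estimator comparison on %d simulated dyads per category\n",
              x$n_per_category))
  cat("\nMean estimate by category (true r in header):\n")
  wide <- stats::reshape(
    x$summary[, c("estimator", "category", "mean")],
    idvar = "estimator", timevar = "category", direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  cat("\nRanking by pooled correlation with true relatedness:\n")
  rk <- x$ranking[order(x$ranking$rank), ]
  print(rk, row.names = FALSE, digits = 3)
  if (any(rk$degenerate))
    cat("(degenerate estimators produce constant output; correlation undefined)\n")
  invisible(x)
}
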