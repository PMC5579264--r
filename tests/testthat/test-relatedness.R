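# Helper: a genotype_table built directly from explicit allele matrices.
manual_genotypes <- function(a1, a2, loci) {
  g <- simulate_genotypes(
    validate_pedigree(data.frame(
      id = rownames(a1), sex = "M", group = "g",
      father = NA_character_, mother = NA_character_,
      role = "reproductive")), loci, seed = 1)
  g$a1[] <- a1; g$a2[] <- a2
  g
}

two_allele_locus <- function(pA = 0.5) {
  list(locus_spec("L1", c(100L, 102L), c(pA, 1 - pA)))
}

test_that("allele frequencies are gene counts", {
  loci <- two_allele_locus()
  a1 <- matrix(c(100L, 100L), 2, 1, dimnames = list(c("x", "y"), "L1"))
  a2 <- matrix(c(100L, 102L), 2, 1, dimnames = list(c("x", "y"), "L1"))
  g <- manual_genotypes(a1, a2, loci)
  fr <- allele_frequencies(g)[["L1"]]
  expect_equal(unname(fr), c(0.75, 0.25))  # {AA, AB}

  # all homozygous
  g2 <- manual_genotypes(a1, a1, loci)
  expect_equal(unname(allele_frequencies(g2)[["L1"]]), 1)

  # hand count on 5 random individuals
  set.seed(7)
  loci3 <- list(locus_spec("L1", c(100L, 102L, 104L)))
  am <- matrix(sample(c(100L, 102L, 104L), 5, TRUE), 5, 1,
               dimnames = list(sprintf("i%d", 1:5), "L1"))
  bm <- matrix(sample(c(100L, 102L, 104L), 5, TRUE), 5, 1,
               dimnames = list(sprintf("i%d", 1:5), "L1"))
  g3 <- manual_genotypes(am, bm, loci3)
  fr3 <- allele_frequencies(g3)[["L1"]]
  hand <- table(c(am, bm)) / 10
  expect_equal(unname(fr3), unname(as.numeric(hand)))
})

test_that("Queller-Goodnight matches a hand-evaluated formula", {
  panel_freqs <- function(loci) {
    fr <- lapply(loci, `[[`, "freqs")
    names(fr) <- vapply(loci, `[[`, "", "name")
    fr
  }
  # identical heterozygotes AB at one locus, pA = pB = 0.25 (4 alleles):
  # per direction num = 1 - 0.5, den = 1 + 0 - 0.5 -> r = 1
  loci <- list(locus_spec("L1", c(100L, 102L, 104L, 106L)))
  a1 <- matrix(100L, 2, 1, dimnames = list(c("x", "y"), "L1"))
  a2 <- matrix(102L, 2, 1, dimnames = list(c("x", "y"), "L1"))
  g <- manual_genotypes(a1, a2, loci)
  rm <- moment_estimators(g, freqs = panel_freqs(loci),
                          estimator = "queller_goodnight")
  expect_equal(rm$r["x", "y"], 1)

  # AB vs AC with uniform 4-allele frequencies, by hand:
  # x-ref: num = 0.5*(1+0) - 0.5 = 0, den = 1 - 0.5 = 0.5 -> 0; same for y
  b2 <- matrix(c(102L, 104L), 2, 1, dimnames = list(c("x", "y"), "L1"))
  g2 <- manual_genotypes(a1, b2, loci)
  rm2 <- moment_estimators(g2, freqs = panel_freqs(loci),
                           estimator = "queller_goodnight")
  expect_equal(rm2$r["x", "y"], 0)

  # multilocus: identical heterozygotes at 6 panel loci -> r near 1
  panel <- default_locus_panel()
  a6 <- do.call(cbind, lapply(panel, function(l) rep(l$alleles[1], 2L)))
  b6 <- do.call(cbind, lapply(panel, function(l) rep(l$alleles[2], 2L)))
  dimnames(a6) <- dimnames(b6) <- list(c("x", "y"),
                                       vapply(panel, `[[`, "", "name"))
  g6 <- manual_genotypes(a6, b6, panel)
  rm6 <- moment_estimators(g6, freqs = panel_freqs(panel),
                           estimator = "queller_goodnight")
  expect_gt(rm6$r["x", "y"], 0.95)
})

test_that("similarity-category coefficients match the closed forms", {
  for (p in list(c(a = 0.5, b = 0.3, c = 0.2),
                 c(a = 0.25, b = 0.25, c = 0.25, d = 0.25))) {
    cf <- songkin:::wang_locus_coeffs(p)
    a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
    # no IBD: P(identical) = 2*a2^2 - a4, P(homo vs sharing het) = 4(a3-a4)
    expect_equal(cf$K0[1], 2 * a2^2 - a4, tolerance = 1e-12)
    expect_equal(cf$K0[2], 4 * (a3 - a4), tolerance = 1e-12)
    # one gene IBD: P(identical) = a2, P(homo vs sharing het) = 2(a2-a3)
    expect_equal(cf$K1[1], a2, tolerance = 1e-12)
    expect_equal(cf$K1[2], 2 * (a2 - a3), tolerance = 1e-12)
    # two genes IBD: genotypes always identical
    expect_equal(cf$K2, c(1, 0, 0), tolerance = 1e-12)
    # categories 1..3 + 4 partition the space under every IBD state
    expect_lte(cf$K0[3], 1); expect_lte(sum(cf$K1), 1)
  }
})

test_that("moment estimators are unbiased over Mendelian dyads", {
  loci <- default_locus_panel()
  for (cat in c("parent_offspring", "half_sibling", "unrelated")) {
    ds <- simulate_dyads(loci, cat, 300, seed = 1000 + nchar(cat))
    truth <- ds$true_r
    for (est in c("queller_goodnight", "li", "lynch_ritland", "wang")) {
      r <- songkin:::estimate_dyad_set(ds, est)
      se <- sd(r) / sqrt(length(r))
      expect_lt(abs(mean(r) - truth), 3 * se + 1e-9,
                label = sprintf("%s on %s (mean %.3f, 3se %.3f)",
                                est, cat, mean(r), 3 * se))
    }
  }
})

test_that("dyadic ML maximizes the genotype-pair likelihood on its grid", {
  loci <- default_locus_panel()
  freqs <- lapply(loci, `[[`, "freqs")
  names(freqs) <- vapply(loci, `[[`, "", "name")
  # degenerate grid (corners only): r restricted to {0, 0.5, 1}
  ds <- simulate_dyads(loci, "full_sibling", 20, seed = 5)
  r1 <- songkin:::estimate_dyad_set(ds, "dyadml", grid_resolution = 1)
  expect_true(all(r1 %in% c(0, 0.5, 1)))

  # parent-offspring-consistent genotypes over many loci: k1 -> 1, r -> 0.5
  many <- lapply(1:30, function(k) locus_spec(sprintf("L%d", k),
                                              seq(100L, 118L, 2L)))
  dsp <- simulate_dyads(many, "parent_offspring", 25, seed = 6)
  rp <- songkin:::estimate_dyad_set(dsp, "dyadml", grid_resolution = 0.01)
  expect_lt(abs(mean(rp) - 0.5), 0.035)

  # oracle: independent brute-force scan over the same grid on 10 dyads
  ds10 <- simulate_dyads(loci, "half_sibling", 10, seed = 7)
  rg <- songkin:::estimate_dyad_set(ds10, "dyadml", grid_resolution = 0.05)
  grid <- songkin:::ibd_grid(0.05)
  for (i in 1:10) {
    gx <- rbind(as.character(ds10$x$a1[i, ]), as.character(ds10$x$a2[i, ]))
    gy <- rbind(as.character(ds10$y$a1[i, ]), as.character(ds10$y$a2[i, ]))
    best_ll <- -Inf; best_r <- NA
    for (gi in seq_len(nrow(grid))) {
      ll <- 0
      for (l in seq_along(freqs)) {
        comp <- songkin:::pair_lik_components(gx[1, l], gx[2, l],
                                              gy[1, l], gy[2, l],
                                              freqs[[l]])
        ll <- ll + log(sum(grid[gi, c("k0", "k1", "k2")] * comp))
      }
      if (ll > best_ll + 1e-12) { best_ll <- ll; best_r <- grid[gi, "r"] }
    }
    expect_equal(rg[i], unname(best_r), tolerance = 1e-12)
  }
})

test_that("dyads with no shared typed locus are flagged as missing", {
  loci <- two_allele_locus()
  a1 <- matrix(c(100L, NA), 2, 1, dimnames = list(c("x", "y"), "L1"))
  a2 <- matrix(c(100L, NA), 2, 1, dimnames = list(c("x", "y"), "L1"))
  g <- manual_genotypes(a1, a2, loci)
  rm <- moment_estimators(g, estimator = "queller_goodnight")
  expect_true(is.na(rm$r["x", "y"]))
  expect_match(rm$no_shared_loci, "x:y")
  expect_error(relatedness_to_distance(rm), "NA")
})

test_that("simulated dyads respect Mendelian sharing patterns", {
  loci <- list(locus_spec("L1", seq(100L, 114L, 2L)))
  # parent-offspring: always share at least one allele
  po <- simulate_dyads(loci, "parent_offspring", 500, seed = 11)
  share <- mapply(function(a, b, c, d) length(intersect(c(a, b), c(c, d))),
                  po$x$a1[, 1], po$x$a2[, 1], po$y$a1[, 1], po$y$a2[, 1])
  expect_true(all(share >= 1))
  # determinism
  expect_identical(simulate_dyads(loci, "full_sibling", 10, seed = 3),
                   simulate_dyads(loci, "full_sibling", 10, seed = 3))
})

test_that("full siblings share 0/1/2 parental alleles with probability 1/4, 1/2, 1/4", {
  # one locus with many equifrequent alleles so parental alleles are
  # distinguishable; count shared-IBD configurations over 8,000 sib pairs
  loci <- list(locus_spec("L1", seq(100L, 198L, 2L)))
  fs <- simulate_dyads(loci, "full_sibling", 8000, seed = 13)
  nshared <- mapply(
    function(a, b, c, d) {
      x <- c(a, b); y <- c(c, d)
      sum(pmin(table(factor(x, unique(c(x, y)))),
               table(factor(y, unique(c(x, y))))))
    },
    fs$x$a1[, 1], fs$x$a2[, 1], fs$y$a1[, 1], fs$y$a2[, 1])
  pr <- as.vector(table(factor(nshared, levels = 0:2)) / length(nshared))
  # identity-by-state collisions (about 2% with 50 equifrequent alleles)
  # nudge mass from 0 toward 1 shared; bound deviations absolutely
  expect_lt(max(abs(pr - c(0.25, 0.5, 0.25))), 0.03)
})

test_that("the estimator comparison ranks by pooled correlation and flags degeneracy", {
  loci <- default_locus_panel()
  const0 <- function(gx, gy, freqs) 0
  rep1 <- compare_estimators(loci, n_per_category = 30,
                             estimators = c("queller_goodnight", "li"),
                             extra_estimators = list(constant = const0),
                             seed = 17)
  expect_identical(rep1,
                   compare_estimators(loci, n_per_category = 30,
                                      estimators = c("queller_goodnight",
                                                     "li"),
                                      extra_estimators = list(
                                        constant = const0),
                                      seed = 17))
  rk <- rep1$ranking
  expect_true(rk$degenerate[rk$estimator == "constant"])
  expect_true(is.na(rk$correlation[rk$estimator == "constant"]))
  expect_equal(rk$rank[rk$estimator == "constant"], nrow(rk))
  expect_true(all(rk$correlation[!rk$degenerate] > 0.5))
})

test_that("relatedness on the reference pedigree separates kin categories", {
  ped <- reference_pedigree()
  g <- simulate_genotypes(ped, seed = 19)
  rm <- dyadic_ml(g, grid_resolution = 0.02)
  m <- as.matrix(rm)
  founders <- ped$id[ped$role == "reproductive"]
  po <- mapply(function(o, f) m[o, f],
               ped$id[ped$role == "offspring"],
               ped$father[ped$role == "offspring"])
  unrel <- m[founders, founders][upper.tri(diag(length(founders)))]
  expect_gt(median(po), median(unrel))
  # distance conversion points the other way
  d <- relatedness_to_distance(rm)
  expect_lt(median(mapply(function(o, f) d[o, f],
                          ped$id[ped$role == "offspring"],
                          ped$father[ped$role == "offspring"])),
            median(d[founders, founders][upper.tri(
              diag(length(founders)))]))
})
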