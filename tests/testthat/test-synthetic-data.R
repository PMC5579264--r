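test_that("simulated pedigrees satisfy the structural invariants", {
  ped <- simulate_pedigree(7, c(0, 2), seed = 11)
  expect_s3_class(ped, "pedigree")
  expect_equal(sum(ped$role == "reproductive"), 14)
  off <- ped[ped$role == "offspring", ]
  expect_true(nrow(off) <= 14)
  # offspring always have both in-group parents, father male, mother female
  for (i in seq_len(nrow(off))) {
    fa <- ped[ped$id == off$father[i], ]
    mo <- ped[ped$id == off$mother[i], ]
    expect_equal(fa$sex, "M")
    expect_equal(mo$sex, "F")
    expect_equal(fa$group, off$group[i])
    expect_equal(mo$group, off$group[i])
  }
  # group sizes within 2..4 under the default offspring range
  expect_true(all(table(ped$group) >= 2 & table(ped$group) <= 4))

  # minimal pedigree: one group, no offspring -> two unrelated founders
  ped1 <- simulate_pedigree(1, c(0, 0), seed = 1)
  expect_equal(nrow(ped1), 2)
  expect_true(all(is.na(ped1$father)))

  # determinism
  expect_identical(simulate_pedigree(5, seed = 99),
                   simulate_pedigree(5, seed = 99))
  expect_error(simulate_pedigree(0), "n_groups")
  expect_error(simulate_pedigree(3, c(2, 1)), "offspring_range")
})

test_that("the reference pedigree matches the seven-group study structure", {
  ped <- reference_pedigree()
  expect_equal(length(unique(ped$group)), 7)
  off <- ped[ped$role == "offspring", ]
  expect_equal(nrow(off), 9)
  expect_equal(sum(off$sex == "M"), 5)
  expect_true(all(table(ped$group) >= 2 & table(ped$group) <= 4))
})

test_that("genotypes are Mendelian at every trio and locus", {
  ped <- reference_pedigree()
  g <- simulate_genotypes(ped, seed = 3)
  off <- which(!is.na(ped$father))
  for (i in off) {
    fi <- match(ped$father[i], ped$id)
    mi <- match(ped$mother[i], ped$id)
    for (j in seq_len(ncol(g$a1))) {
      expect_true(g$a1[i, j] %in% c(g$a1[fi, j], g$a2[fi, j]))
      expect_true(g$a2[i, j] %in% c(g$a1[mi, j], g$a2[mi, j]))
    }
  }
  # monomorphic locus: everyone homozygous
  mono <- list(locus_spec("M1", 100L))
  gm <- simulate_genotypes(ped, mono, seed = 4)
  expect_true(all(gm$a1 == 100L & gm$a2 == 100L))
  expect_identical(simulate_genotypes(ped, seed = 8),
                   simulate_genotypes(ped, seed = 8))
})

test_that("founder allele frequencies converge to the locus frequencies", {
  # 10,000 founders, frequency recovery within 0.02 by gene counting
  ped <- simulate_pedigree(5000, c(0, 0), seed = 21)
  loci <- list(locus_spec("L1", c(100L, 102L, 104L), c(0.5, 0.3, 0.2)))
  g <- simulate_genotypes(ped, loci, seed = 22)
  fr <- allele_frequencies(g)[["L1"]]
  expect_equal(unname(fr), c(0.5, 0.3, 0.2), tolerance = 0.02)
})

test_that("phrase heritability behaves correctly in the limiting cases", {
  # h = 0: father-son latent deviations uncorrelated over 150 pairs
  ped <- do.call(rbind, lapply(1:150, function(g) {
    data.frame(id = sprintf(c("F%d", "M%d", "S%d"), g),
               sex = c("M", "F", "M"), group = sprintf("G%d", g),
               father = c(NA, NA, sprintf("F%d", g)),
               mother = c(NA, NA, sprintf("M%d", g)),
               role = c("reproductive", "reproductive", "offspring"))
  }))
  ped <- validate_pedigree(ped)
  cfg0 <- song_effect_config(h_temporal = 0, transmission = "sex_path",
                             songs_per_group = 1, phrases_per_song = 4,
                             phrase_types = "DP2")
  ps0 <- simulate_phrases(ped, cfg0, seed = 31)
  dev <- attr(ps0, "latent")$DP2$dev
  fathers <- sprintf("F%d", 1:150); sons <- sprintf("S%d", 1:150)
  r0 <- cor(dev[fathers, "dur_unit1"], dev[sons, "dur_unit1"])
  expect_lt(abs(r0), 0.2)

  # h = 1, residual 0, sex path: son phrases identical to father phrases
  cfg1 <- song_effect_config(h_temporal = 1, h_frequency = 1,
                             residual_sd = zero_vec,
                             transmission = "sex_path",
                             songs_per_group = 1, phrases_per_song = 4,
                             phrase_types = "DP2")
  ped2 <- ped[ped$group %in% c("G1", "G2"), ]
  ped2 <- validate_pedigree(ped2)
  ps1 <- simulate_phrases(ped2, cfg1, seed = 32)
  f <- temporal_features(subset_phrases(ps1, type = "DP2"))
  fa <- f[f$individual_id == "F1", -(1:6)][1, ]
  so <- f[f$individual_id == "S1", -(1:6)][1, ]
  expect_equal(unlist(fa), unlist(so), tolerance = 1e-12)

  # h = 1, midparent: offspring latent mean equals the mid-parent mean
  cfg2 <- song_effect_config(h_temporal = 1, h_frequency = 1,
                             transmission = "midparent",
                             songs_per_group = 1, phrases_per_song = 4,
                             phrase_types = "DP2")
  ps2 <- simulate_phrases(ped2, cfg2, seed = 33)
  dev2 <- attr(ps2, "latent")$DP2$dev
  expect_equal(dev2["S1", ], (dev2["F1", ] + dev2["M1", ]) / 2,
               tolerance = 1e-12)
})

test_that("generator output round-trips losslessly through the CSV formats", {
  ped <- simulate_pedigree(3, seed = 41)
  g <- simulate_genotypes(ped, seed = 42)
  ps <- simulate_phrases(ped, small_song_config(phrase_types = "DP2"),
                         seed = 43)
  td <- withr::local_tempdir()
  write_pedigree_csv(ped, file.path(td, "ped.csv"))
  ped2 <- read_pedigree_csv(file.path(td, "ped.csv"))
  expect_equal(as.data.frame(ped2), as.data.frame(ped))

  write_genotype_csv(g, file.path(td, "gen.csv"))
  g2 <- read_genotype_csv(file.path(td, "gen.csv"), g$loci)
  expect_equal(g2$a1, g$a1)
  expect_equal(g2$a2, g$a2)

  write_phrase_csv(ps, file.path(td, "ph.csv"), file.path(td, "co.csv"))
  ps2 <- read_phrase_csv(file.path(td, "ph.csv"), file.path(td, "co.csv"))
  cols <- sort(names(ps$units))
  expect_equal(ps2$units[cols], ps$units[cols], tolerance = 1e-12)
  expect_equal(ps2$contours, ps$contours, tolerance = 1e-12)
})
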