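test_that("temporal parameters reproduce hand-computed boundary arithmetic", {
  tf <- temporal_features(toy_phrase_set())
  expect_equal(tf$dur_unit1, 0.5)
  expect_equal(tf$dur_unit2, 0.8)
  expect_equal(tf$dur_int1, 0.3)
  expect_equal(tf$ioi1, 0.8)
  expect_equal(tf$dur_total, 1.6)

  # adjacent units: zero interval
  u <- data.frame(phrase_id = "p", song_id = "s", individual_id = "i",
                  group_id = "g", sex = "F", phrase_type = "DP2",
                  unit_index = 1:2, unit_start_s = c(0, 1),
                  unit_end_s = c(1, 2))
  cont <- data.frame(phrase_id = "p", unit_index = rep(1:2, each = 2),
                     time_s = c(0, 1, 1, 2), f0_hz = c(700, 600, 590, 500))
  tf2 <- temporal_features(phrase_set(u, cont))
  expect_equal(tf2$dur_int1, 0)
})

test_that("the inter-onset identity ioi = dur + int holds exhaustively", {
  for (type in c("DP2", "DP3")) {
    ps <- random_phrase_set(500, type, seed = match(type, c("DP2", "DP3")))
    tf <- temporal_features(ps)
    K <- if (type == "DP2") 2L else 3L
    for (k in seq_len(K - 1L)) {
      expect_equal(tf[[sprintf("ioi%d", k)]],
                   tf[[sprintf("dur_unit%d", k)]] +
                     tf[[sprintf("dur_int%d", k)]],
                   tolerance = 1e-12)
    }
    expect_true(all(tf$dur_total >= tf$dur_unit1))
  }
})

test_that("features are invariant to shifting the phrase in time", {
  ps <- toy_phrase_set()
  shifted <- ps
  shifted$units$unit_start_s <- shifted$units$unit_start_s + 3.7
  shifted$units$unit_end_s <- shifted$units$unit_end_s + 3.7
  shifted$contours$time_s <- shifted$contours$time_s + 3.7
  expect_equal(temporal_features(shifted)[, -(1:6)],
               temporal_features(ps)[, -(1:6)], tolerance = 1e-12)
  expect_equal(frequency_features(shifted)[, -(1:6)],
               frequency_features(ps)[, -(1:6)], tolerance = 1e-12)
})

test_that("frequency parameters follow the contour landmarks and tie rules", {
  ff <- frequency_features(toy_phrase_set())
  # unit 1: rise 500 -> 700 then fall to 650
  expect_equal(ff$f0max_unit1, 700)
  expect_equal(ff$f0min_unit1, 500)
  expect_equal(ff$f0start_unit1, 500)
  expect_equal(ff$f0end_unit1, 650)
  expect_equal(ff$ptmax_unit1, 100 * 0.2 / 0.5)
  expect_equal(ff$ptmin_unit1, 0)
  # trapezoidal mean of the linear ramp 640 -> 580 over unit 2
  expect_equal(ff$f0mean_unit2, 610)
  expect_equal(ff$ptmax_unit2, 0)
  expect_equal(ff$ptmin_unit2, 100)

  # pure linear ramp: mean is the midpoint, extrema at the ends
  u <- data.frame(phrase_id = "p", song_id = "s", individual_id = "i",
                  group_id = "g", sex = "M", phrase_type = "DP2",
                  unit_index = 1:2, unit_start_s = c(0, 0.4),
                  unit_end_s = c(0.2, 0.8))
  cont <- rbind(
    data.frame(phrase_id = "p", unit_index = 1, time_s = c(0, 0.1, 0.2),
               f0_hz = c(500, 600, 700)),
    data.frame(phrase_id = "p", unit_index = 2, time_s = c(0.4, 0.8),
               f0_hz = c(400, 400)))
  ff2 <- frequency_features(phrase_set(u, cont))
  expect_equal(ff2$f0mean_unit1, 600)
  expect_equal(ff2$ptmax_unit1, 100)
  expect_equal(ff2$ptmin_unit1, 0)
  # constant contour: all f0 statistics equal; ties resolve to the earliest
  expect_equal(ff2$f0mean_unit2, 400)
  expect_equal(ff2$f0max_unit2, 400)
  expect_equal(ff2$f0min_unit2, 400)
  expect_equal(ff2$ptmax_unit2, 0)
  expect_equal(ff2$ptmin_unit2, 0)
})

test_that("Q50 is passed through, computed from spectra, or reported missing", {
  ps <- toy_phrase_set()
  ps$units$q50_hz <- c(710, 630)
  ff <- frequency_features(ps, q50 = "require")
  expect_equal(ff$q50_unit1, 710)
  expect_equal(ff$q50_unit2, 630)

  # flat two-bin spectrum over [0, 1000] -> median energy at 500 Hz
  expect_equal(q50_from_spectrum(c(250, 750), c(1, 1)), 500)

  ps2 <- toy_phrase_set()
  expect_error(frequency_features(ps2, q50 = "require"), "Q50 unavailable")
  expect_false("q50_unit1" %in% names(frequency_features(ps2, q50 = "auto")))
})

test_that("invalid phrases are rejected with the phrase named", {
  ps <- toy_phrase_set()
  bad <- ps$units
  bad$unit_start_s[2] <- 0.3  # overlaps unit 1 (ends at 0.5)
  expect_error(phrase_set(bad, ps$contours), "p1.*overlap")
  one <- ps$contours[-2, ]
  one <- one[!(one$unit_index == 1 & one$time_s > 0.1), ]
  expect_error(phrase_set(ps$units, one), "at least 2 f0 samples")
  neg <- ps$contours
  neg$f0_hz[1] <- -5
  expect_error(phrase_set(ps$units, neg), "positive")
  # mixed phrase types must be extracted separately
  ped <- simulate_pedigree(1, c(0, 0), seed = 1)
  psm <- simulate_phrases(ped, small_song_config(), seed = 2)
  expect_error(temporal_features(psm), "mixes types")
})

test_that("extracted features recover the generating parameter values", {
  ped <- simulate_pedigree(2, c(1, 1), seed = 51)
  # modest individual SDs keep every latent draw inside the physically
  # valid region (f0max above f0start/f0end and so on), where rendering is
  # exactly invertible
  cfg <- song_effect_config(residual_sd = zero_vec,
                            individual_sd = c(dur = 0.05, int = 0.03,
                                              f0 = 8, pt = 4, q50 = 8),
                            songs_per_group = 1, phrases_per_song = 4)
  ps <- simulate_phrases(ped, cfg, seed = 52)
  for (type in c("DP2", "DP3")) {
    mu <- attr(ps, "latent")[[type]]$mu
    sub <- subset_phrases(ps, type = type)
    tf <- temporal_features(sub)
    fq <- frequency_features(sub)
    for (ind in rownames(mu)) {
      i <- which(tf$individual_id == ind)[1]
      expect_equal(tf$dur_unit1[i], unname(mu[ind, "dur_unit1"]),
                   tolerance = 1e-12)
      expect_equal(tf$dur_int1[i], unname(mu[ind, "dur_int1"]),
                   tolerance = 1e-12)
      expect_equal(fq$f0start_unit1[i], unname(mu[ind, "f0start_unit1"]),
                   tolerance = 1e-12)
      expect_equal(fq$f0max_unit2[i], unname(mu[ind, "f0max_unit2"]),
                   tolerance = 1e-12)
      expect_equal(fq$ptmin_unit1[i], unname(mu[ind, "ptmin_unit1"]),
                   tolerance = 1e-9)
      expect_equal(fq$q50_unit1[i], unname(mu[ind, "q50_unit1"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("Praat PitchTier files parse in both text dialects", {
  td <- withr::local_tempdir()
  long <- c(
    'File type = "ooTextFile"', 'Object class = "PitchTier"', "",
    "xmin = 0", "xmax = 1.5", "points: size = 3",
    "points [1]:", "    number = 0.1", "    value = 512.5",
    "points [2]:", "    number = 0.6", "    value = 498",
    "points [3]:", "    number = 1.2", "    value = 455")
  writeLines(long, file.path(td, "long.PitchTier"))
  pl <- read_pitchtier(file.path(td, "long.PitchTier"))
  expect_equal(pl$time_s, c(0.1, 0.6, 1.2))
  expect_equal(pl$f0_hz, c(512.5, 498, 455))

  short <- c('File type = "ooTextFile"', 'Object class = "PitchTier"', "",
             "0", "1.5", "3", "0.1", "512.5", "0.6", "498", "1.2", "455")
  writeLines(short, file.path(td, "short.PitchTier"))
  psh <- read_pitchtier(file.path(td, "short.PitchTier"))
  expect_equal(psh, pl)

  writeLines("not a praat file", file.path(td, "bad.txt"))
  expect_error(read_pitchtier(file.path(td, "bad.txt")), "ooTextFile")
})
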