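test_that("the discriminant classifier separates and matches MASS::lda", {
  set.seed(101)
  x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 5), 30))
  y <- rep(c("a", "b"), each = 30)
  m <- lda_train(x, y)
  expect_equal(mean(predict(m, x) == y), 1)
  # rank bound: one discriminant axis for two classes
  expect_equal(ncol(m$axes), 1)

  skip_if_not_installed("MASS")
  set.seed(102)
  x3 <- rbind(matrix(rnorm(80, 0), 40), matrix(rnorm(80, 2), 40),
              matrix(rnorm(80, c(0, 4)), 40, byrow = TRUE))
  y3 <- rep(c("a", "b", "c"), each = 40)
  ours <- predict(lda_train(x3, y3), x3)
  ref <- as.character(predict(MASS::lda(x3, grouping = y3), x3)$class)
  expect_gt(mean(ours == ref), 0.98)
})

test_that("shuffled labels classify near chance", {
  set.seed(103)
  x <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 5), 50))
  acc <- replicate(30, {
    ys <- sample(rep(c("a", "b"), each = 50))
    mean(predict(lda_train(x, ys), x) == ys)
  })
  expect_lt(abs(mean(acc) - 0.5), 0.1)
})

test_that("pDFA is reproducible and invariant to phrase order within blocks", {
  ped <- simulate_pedigree(3, c(1, 2), seed = 111)
  ps <- simulate_phrases(ped, small_song_config(phrase_types = "DP2"),
                         seed = 112)
  f <- temporal_features(ps)
  x <- feature_values(f)
  r1 <- pdfa(x, f$individual_id, f$song_id, n_selections = 4,
             n_permutations = 29, seed = 113)
  r2 <- pdfa(x, f$individual_id, f$song_id, n_selections = 4,
             n_permutations = 29, seed = 113)
  expect_identical(r1, r2)
  expect_equal(r1$chance_rate, 100 / length(unique(f$individual_id)))

  # shuffle phrases globally (labels travel with their rows): same rates
  set.seed(114)
  perm <- sample(nrow(x))
  r3 <- pdfa(x[perm, ], f$individual_id[perm], f$song_id[perm],
             n_selections = 4, n_permutations = 29, seed = 113)
  expect_equal(r3$training_rate, r1$training_rate, tolerance = 1e-9)
  expect_equal(r3$testing_rate, r1$testing_rate, tolerance = 1e-9)
})

test_that("training accuracy exceeds testing accuracy under a real signature", {
  ped <- reference_pedigree()
  ps <- simulate_phrases(ped, small_song_config(phrase_types = "DP2"),
                         seed = 121)
  f <- temporal_features(ps)
  pc <- pca_kaiser(feature_values(f))
  res <- pdfa(pc$scores, f$individual_id, f$song_id, n_selections = 10,
              n_permutations = 49, seed = 122)
  expect_gt(res$training_rate, res$testing_rate)
  expect_gt(res$testing_rate, res$chance_rate)
  expect_lte(res$testing_p, 0.05)
  # confusion matrix covers every individual and sums to the tested phrases
  expect_equal(sort(rownames(res$confusion)),
               sort(unique(f$individual_id)))
})

test_that("the block permutation null matches hand enumeration on a toy design", {
  # 2 individuals x 2 songs, near-deterministic separation: of the 6
  # distinct label assignments to the 4 blocks, 2 preserve the partition,
  # so the testing p converges to 1/3
  set.seed(131)
  mkblock <- function(ind, song, mu) data.frame(
    ind = ind, song = song, v1 = rnorm(6, mu, 0.01), v2 = rnorm(6, 0, 0.01))
  d <- rbind(mkblock("A", "s1", 0), mkblock("A", "s2", 0),
             mkblock("B", "s3", 10), mkblock("B", "s4", 10))
  res <- pdfa(as.matrix(d[, c("v1", "v2")]), d$ind, d$song,
              n_selections = 2, n_permutations = 599, seed = 132)
  expect_equal(res$testing_rate, 100)
  expect_equal(res$testing_p, 1 / 3, tolerance = 0.07)
})

test_that("per-sex and per-group wrappers behave and validate", {
  ped <- reference_pedigree()
  ps <- simulate_phrases(ped, small_song_config(phrase_types = "DP2"),
                         seed = 141)
  f <- temporal_features(ps)
  pc <- pca_kaiser(feature_values(f))

  # sex-restricted run equals a full run on pre-filtered input
  males <- f$sex == "M"
  bs <- pdfa_by_sex(pc$scores, f$individual_id, f$song_id, f$sex,
                    n_selections = 3, n_permutations = 19, seed = 142)
  direct <- pdfa(pc$scores[males, ], f$individual_id[males],
                 f$song_id[males], n_selections = 3, n_permutations = 19,
                 seed = 142)
  expect_equal(bs[["M"]]$testing_rate, direct$testing_rate)
  expect_equal(bs[["M"]]$testing_p, direct$testing_p)

  # males-only input: one result plus a skip warning for the absent sex
  expect_warning(
    one <- pdfa_by_sex(pc$scores[males, ], f$individual_id[males],
                       f$song_id[males], f$sex[males],
                       n_selections = 2, n_permutations = 9, seed = 143),
    "skipped")
  expect_named(one, "M")

  # a group reduced to a single individual is rejected by name
  keep <- !(f$group_id == "G5" & f$individual_id == "G5_F")
  expect_error(
    pdfa_group(pc$scores[keep, ], f$group_id[keep], f$individual_id[keep],
               n_selections = 2, n_permutations = 9, seed = 144),
    "G5")
})
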