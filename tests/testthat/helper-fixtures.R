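# Fixtures are built in code; nothing is read from disk.

# The worked DP2 example used across feature tests: two units with a rising
# ramp and a falling ramp contour.
toy_phrase_set <- function() {
  u <- data.frame(
    phrase_id = "p1", song_id = "s1", individual_id = "i1",
    group_id = "g1", sex = "M", phrase_type = "DP2", unit_index = 1:2,
    unit_start_s = c(0, 0.8), unit_end_s = c(0.5, 1.6))
  cont <- rbind(
    data.frame(phrase_id = "p1", unit_index = 1,
               time_s = c(0, 0.1, 0.2, 0.5), f0_hz = c(500, 600, 700, 650)),
    data.frame(phrase_id = "p1", unit_index = 2,
               time_s = c(0.8, 1.2, 1.6), f0_hz = c(640, 610, 580)))
  phrase_set(u, cont)
}

# n random valid phrases of a given type with minimal 2-point contours,
# assembled in bulk for the temporal-identity property test.
random_phrase_set <- function(n, type = "DP2", seed = 1) {
  K <- if (type == "DP2") 2L else 3L
  set.seed(seed)
  dur <- matrix(runif(n * K, 0.1, 1.2), n, K)
  gap <- matrix(runif(n * (K - 1), 0, 0.6), n, K - 1L)
  starts <- t(apply(cbind(runif(n, 0, 2), dur[, -K, drop = FALSE] +
                            gap), 1, cumsum))
  ends <- starts + dur
  pid <- sprintf("rp%04d", seq_len(n))
  units <- data.frame(
    phrase_id = rep(pid, each = K), song_id = "s1",
    individual_id = "i1", group_id = "g1", sex = "M", phrase_type = type,
    unit_index = rep(seq_len(K), n),
    unit_start_s = as.vector(t(starts)), unit_end_s = as.vector(t(ends)))
  contours <- data.frame(
    phrase_id = rep(rep(pid, each = K), each = 2),
    unit_index = rep(rep(seq_len(K), n), each = 2),
    time_s = as.vector(rbind(as.vector(t(starts)), as.vector(t(ends)))),
    f0_hz = runif(2 * n * K, 300, 900))
  phrase_set(units, contours)
}

# Labeled random Euclidean distance matrix.
random_dist_matrix <- function(n, seed = 1, dim = 3) {
  set.seed(seed)
  m <- as.matrix(dist(matrix(rnorm(n * dim), n)))
  dimnames(m) <- list(sprintf("x%d", 1:n), sprintf("x%d", 1:n))
  m
}

# Small generator configuration used where effect structure, not sampling
# depth, is under test.
small_song_config <- function(...) {
  song_effect_config(songs_per_group = 3, phrases_per_song = 3, ...)
}

zero_vec <- c(dur = 0, int = 0, f0 = 0, pt = 0, q50 = 0)

# Run the acoustic side of the pipeline down to the normalized
# individual-level dissimilarity matrix for one phrase type and the
# temporal set.
individual_temporal_distance <- function(ps, type) {
  f <- temporal_features(subset_phrases(ps, type = type))
  pc <- pca_kaiser(feature_values(f))
  d <- phrase_distance(pc)
  normalize01(individual_mean_distance(
    d, stats::setNames(f$individual_id, f$phrase_id)))
}
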