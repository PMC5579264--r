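## Acoustic parameter extraction per phrase: the temporal set (unit
## durations, inter-unit intervals, inter-onset intervals, total duration)
## and the frequency set (per-unit f0 statistics from the pitch contour,
## plus Q50).

single_type <- function(ps) {
  types <- unique(ps$units$phrase_type)
  if (length(types) != 1L)
    stopf("phrase set mixes types (%s); extract features per type (see subset_phrases)",
          paste(types, collapse = ", "))
  types
}

#' Temporal parameters of descending phrases
#'
#' For a phrase with units k = 1..K: `dur_unit_k` = unit duration,
#' `dur_int_k` = silent interval between unit k and k+1, `ioi_k` =
#' inter-onset interval (onset of unit k to onset of unit k+1; always
#' `dur_unit_k + dur_int_k`), and `dur_total` = last offset minus first
#' onset. All values are in seconds and invariant to shifting the phrase in
#' time.
#'
#' @param ps a [phrase_set()] holding a single phrase type (DP2 or DP3).
#' @return data.frame, one row per phrase: metadata columns followed by the
#'   temporal features.
#' @examples
#' ps <- simulate_phrases(simulate_pedigree(1, c(1, 1), seed = 1), seed = 2)
#' head(temporal_features(subset_phrases(ps, type = "DP2")))
#' @export
temporal_features <- function(ps) {
  validate_phrase_set(ps)
  type <- single_type(ps)
  K <- if (type == "DP2") 2L else 3L
  meta <- phrase_meta(ps)
  ## units are sorted phrase-major with unit_index 1..K (validated), so the
  ## boundary columns reshape directly into phrase x unit matrices
  starts <- matrix(ps$units$unit_start_s, ncol = K, byrow = TRUE)
  ends <- matrix(ps$units$unit_end_s, ncol = K, byrow = TRUE)
  dur <- ends - starts
  out <- dur
  colnames(out) <- sprintf("dur_unit%d", seq_len(K))
  int <- starts[, -1, drop = FALSE] - ends[, -K, drop = FALSE]
  colnames(int) <- sprintf("dur_int%d", seq_len(K - 1L))
  ioi <- starts[, -1, drop = FALSE] - starts[, -K, drop = FALSE]
  colnames(ioi) <- sprintf("ioi%d", seq_len(K - 1L))
  res <- cbind(out, int, ioi, dur_total = ends[, K] - starts[, 1])
  cbind(meta, as.data.frame(res))
}

## Time-weighted (trapezoidal) mean of a sampled contour.
contour_mean <- function(t, f) {
  dt <- diff(t)
  sum((f[-1] + f[-length(f)]) / 2 * dt) / (t[length(t)] - t[1])
}

#' Q50 from a sampled energy spectrum
#'
#' Frequency at the upper limit of the second quartile of spectral energy:
#' the frequency below which half of the summed energy lies, interpolated
#' linearly inside the crossing bin (bin edges midway between sampled
#' frequencies).
#'
#' @param freq_hz sampled frequencies (Hz), at least two.
#' @param energy non-negative energy per bin.
#' @return Q50 in Hz.
#' @examples
#' q50_from_spectrum(c(250, 750), c(1, 1))  # flat spectrum over [0, 1000]
#' @export
q50_from_spectrum <- function(freq_hz, energy) {
  if (length(freq_hz) < 2L || any(energy < 0) || sum(energy) <= 0)
    stopf("spectrum must have >= 2 bins with non-negative energy")
  ord <- order(freq_hz)
  freq_hz <- freq_hz[ord]; energy <- energy[ord]
  cum <- cumsum(energy) / sum(energy)
  i <- which(cum >= 0.5)[1]
  ## energy of bin i is spread over [edge_{i-1}, edge_i]; bin edges midway
  ## between sampled frequencies, extended at the ends
  mids <- (freq_hz[-1] + freq_hz[-length(freq_hz)]) / 2
  lo_edges <- c(freq_hz[1] - (mids[1] - freq_hz[1]), mids)
  hi_edges <- c(mids, freq_hz[length(freq_hz)] +
                  (freq_hz[length(freq_hz)] - mids[length(mids)]))
  prev <- if (i == 1L) 0 else cum[i - 1L]
  frac <- (0.5 - prev) / (cum[i] - prev)
  lo_edges[i] + frac * (hi_edges[i] - lo_edges[i])
}

#' Frequency parameters of descending phrases
#'
#' Per unit: `f0mean` (time-weighted trapezoidal mean of the contour),
#' `f0max`/`f0min` (contour extrema), `f0start`/`f0end` (first/last
#' sample), `ptmax`/`ptmin` (percentage of the unit duration elapsed at the
#' pitch maximum/minimum; ties resolve to the earliest sample) and `q50`.
#' Q50 is passed through from the unit table when present, computed from
#' `spectra` when supplied, and otherwise raises an error if required.
#'
#' @param ps a [phrase_set()] holding a single phrase type.
#' @param q50 `"auto"` (include Q50 when available, silently omit
#'   otherwise), `"require"` (error if unavailable) or `"omit"`.
#' @param spectra optional data.frame `phrase_id`, `unit_index`, `freq_hz`,
#'   `energy` describing per-unit energy spectra for Q50 computation.
#' @return data.frame, one row per phrase: metadata then per-unit frequency
#'   features (`f0mean_unit1`, ...).
#' @export
frequency_features <- function(ps, q50 = c("auto", "require", "omit"),
                               spectra = NULL) {
  validate_phrase_set(ps)
  q50 <- match.arg(q50)
  type <- single_type(ps)
  K <- if (type == "DP2") 2L else 3L
  meta <- phrase_meta(ps)
  u <- ps$units; cont <- ps$contours
  has_q50_col <- "q50_hz" %in% names(u) && !anyNA(u$q50_hz)
  use_q50 <- q50 != "omit" && (has_q50_col || !is.null(spectra))
  if (q50 == "require" && !use_q50)
    stopf("Q50 unavailable: no `q50_hz` column and no `spectra` supplied")

  base <- c("f0mean", "f0max", "f0min", "f0start", "f0end", "ptmax", "ptmin")
  if (use_q50) base <- c(base, "q50")
  nb <- length(base)
  res <- matrix(NA_real_, nrow(meta), nb * K)
  colnames(res) <- as.vector(vapply(seq_len(K), function(k)
    sprintf("%s_unit%d", base, k), character(nb)))
  ## contour rows grouped per (phrase, unit); already time-sorted
  cidx <- split(seq_len(nrow(cont)),
                factor(paste(cont$phrase_id, cont$unit_index),
                       levels = unique(paste(cont$phrase_id,
                                             cont$unit_index))))
  ustart <- matrix(u$unit_start_s, ncol = K, byrow = TRUE)
  uend <- matrix(u$unit_end_s, ncol = K, byrow = TRUE)
  q50m <- if (has_q50_col) matrix(u$q50_hz, ncol = K, byrow = TRUE)
  for (i in seq_len(nrow(meta))) {
    pid <- meta$phrase_id[i]
    for (k in seq_len(K)) {
      rows <- cidx[[paste(pid, k)]]
      t <- cont$time_s[rows]; f <- cont$f0_hz[rows]
      dur <- uend[i, k] - ustart[i, k]
      imax <- which.max(f); imin <- which.min(f)
      v <- c(contour_mean(t, f), f[imax], f[imin], f[1], f[length(f)],
             100 * (t[imax] - ustart[i, k]) / dur,
             100 * (t[imin] - ustart[i, k]) / dur)
      if (use_q50) {
        q <- if (has_q50_col) q50m[i, k] else {
          sp <- spectra[spectra$phrase_id == pid &
                          spectra$unit_index == k, , drop = FALSE]
          if (!nrow(sp))
            stopf("Q50 unavailable for phrase '%s' unit %d", pid, k)
          q50_from_spectrum(sp$freq_hz, sp$energy)
        }
        v <- c(v, q)
      }
      res[i, seq.int((k - 1L) * nb + 1L, k * nb)] <- v
    }
  }
  cbind(meta, as.data.frame(res))
}

#' Strip metadata from a feature table
#'
#' @param features output of [temporal_features()] or
#'   [frequency_features()].
#' @return numeric matrix of feature values with phrase ids as row names.
#' @export
feature_values <- function(features) {
  meta_cols <- c("phrase_id", "song_id", "individual_id", "group_id",
                 "sex", "phrase_type")
  m <- as.matrix(features[, setdiff(names(features), meta_cols),
                          drop = FALSE])
  rownames(m) <- features$phrase_id
  m
}
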