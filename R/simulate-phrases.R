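## Synthetic descending-phrase generator. Each individual carries a latent
## per-parameter mean vector built from a species-level base value, a sex
## offset, an optionally heritable individual deviation and an optional
## group effect; every phrase realizes those means plus within-individual
## residual noise and is rendered as unit boundaries plus a piecewise-linear
## f0 contour whose extracted features recover the generating values
## (exactly when the residual SD is zero and the values are inside the
## physically valid region).

## Generative parameter table for a phrase type: parameter name, class
## (which SD/offset applies) and species-level base value. Frequency bases
## descend across units, as in descending phrases.
phrase_param_table <- function(type) {
  K <- if (type == "DP2") 2L else 3L
  rows <- list()
  for (k in seq_len(K))
    rows[[length(rows) + 1L]] <-
      data.frame(param = sprintf("dur_unit%d", k), class = "dur",
                 set = "temporal", base = c(0.9, 0.7, 0.5)[k])
  for (k in seq_len(K - 1L))
    rows[[length(rows) + 1L]] <-
      data.frame(param = sprintf("dur_int%d", k), class = "int",
                 set = "temporal", base = c(0.25, 0.2)[k])
  for (k in seq_len(K)) {
    drop <- 60 * (k - 1)
    f <- data.frame(
      param = sprintf(c("f0start_unit%d", "f0end_unit%d", "f0max_unit%d",
                        "f0min_unit%d", "ptmax_unit%d", "ptmin_unit%d",
                        "q50_unit%d"), k),
      class = c("f0", "f0", "f0", "f0", "pt", "pt", "q50"),
      set = "frequency",
      base = c(760 - drop, 660 - drop, 800 - drop, 630 - drop, 20, 85,
               750 - drop))
    rows[[length(rows) + 1L]] <- f
  }
  do.call(rbind, rows)
}

#' Configure the synthetic song-phrase generator
#'
#' All SDs and offsets are per parameter class: `dur` (unit durations, s),
#' `int` (inter-unit intervals, s), `f0` (contour landmarks, Hz), `pt`
#' (percent-of-duration positions of pitch extrema) and `q50` (spectral
#' median-energy frequency, Hz).
#'
#' @param individual_sd SD of the individual-specific latent deviation per
#'   class. Zero removes the individual signature entirely.
#' @param residual_sd within-individual (phrase-to-phrase) SD per class.
#' @param sex_offset additive offset applied to females per class.
#' @param group_sd SD of a group-level offset shared by group members
#'   (default 0: no group signal).
#' @param h_temporal,h_frequency heritability weight in `[0, 1]` applied to
#'   the parent latent deviation for the temporal (`dur`, `int`) and
#'   frequency (`f0`, `pt`, `q50`) parameter sets. An offspring's deviation
#'   is `h * parental deviation + sqrt(1 - h^2) * individual noise`.
#' @param transmission `"midparent"` (parental deviation = mean of both
#'   parents, both sexes) or `"sex_path"` (sons inherit from the father,
#'   daughters from the mother).
#' @param songs_per_group number of choral songs per group; all group
#'   members contribute phrases to every song.
#' @param phrases_per_song phrases per individual per song per phrase type.
#' @param phrase_types which phrase types to generate.
#' @param min_phrases minimum phrases each individual must contribute per
#'   type; the song/phrase counts must reach it.
#' @return a validated `song_effect_config` list.
#' @export
song_effect_config <- function(
    individual_sd = c(dur = 0.08, int = 0.04, f0 = 25, pt = 6, q50 = 25),
    residual_sd = c(dur = 0.04, int = 0.02, f0 = 12, pt = 4, q50 = 12),
    sex_offset = c(dur = 0.06, int = 0.02, f0 = 40, pt = 0, q50 = 40),
    group_sd = 0,
    h_temporal = 0, h_frequency = 0,
    transmission = c("midparent", "sex_path"),
    songs_per_group = 5, phrases_per_song = 9,
    phrase_types = c("DP2", "DP3"),
    min_phrases = 4) {
  classes <- c("dur", "int", "f0", "pt", "q50")
  fix <- function(x, name) {
    if (is.null(names(x)) && length(x) == 1L) x <- stats::setNames(rep(x, 5), classes)
    if (!all(classes %in% names(x)))
      stopf("`%s` must name all classes: %s", name,
            paste(classes, collapse = ", "))
    x <- x[classes]
    if (any(!is.finite(x))) stopf("`%s` must be finite", name)
    x
  }
  individual_sd <- fix(individual_sd, "individual_sd")
  residual_sd <- fix(residual_sd, "residual_sd")
  sex_offset <- fix(sex_offset, "sex_offset")
  if (any(individual_sd < 0) || any(residual_sd < 0) || group_sd < 0)
    stopf("all SDs must be >= 0")
  for (h in c(h_temporal, h_frequency))
    if (!is.numeric(h) || length(h) != 1L || h < 0 || h > 1)
      stopf("heritability weights must lie in [0, 1]")
  transmission <- match.arg(transmission)
  songs_per_group <- check_count(songs_per_group, "songs_per_group")
  phrases_per_song <- check_count(phrases_per_song, "phrases_per_song")
  min_phrases <- check_count(min_phrases, "min_phrases")
  if (!length(phrase_types) || !all(phrase_types %in% c("DP2", "DP3")))
    stopf("`phrase_types` must be a subset of c('DP2', 'DP3')")
  if (songs_per_group * phrases_per_song < min_phrases)
    stopf("songs_per_group * phrases_per_song (%d) is below min_phrases (%d)",
          songs_per_group * phrases_per_song, min_phrases)
  structure(list(individual_sd = individual_sd, residual_sd = residual_sd,
                 sex_offset = sex_offset, group_sd = group_sd,
                 h_temporal = h_temporal, h_frequency = h_frequency,
                 transmission = transmission,
                 songs_per_group = songs_per_group,
                 phrases_per_song = phrases_per_song,
                 phrase_types = unique(phrase_types),
                 min_phrases = min_phrases),
            class = "song_effect_config")
}

## Latent per-individual parameter means for one phrase type.
simulate_latent <- function(ped, cfg, type) {
  pt <- phrase_param_table(type)
  P <- nrow(pt); n <- nrow(ped)
  sd_i <- cfg$individual_sd[pt$class]
  h <- ifelse(pt$set == "temporal", cfg$h_temporal, cfg$h_frequency)
  dev <- matrix(NA_real_, n, P, dimnames = list(ped$id, pt$param))
  for (i in seq_len(n)) {
    z <- stats::rnorm(P) * sd_i
    if (is.na(ped$father[i])) {
      dev[i, ] <- z
    } else {
      fi <- match(ped$father[i], ped$id)
      mi <- match(ped$mother[i], ped$id)
      herit <- if (cfg$transmission == "midparent")
        (dev[fi, ] + dev[mi, ]) / 2
      else if (ped$sex[i] == "M") dev[fi, ] else dev[mi, ]
      dev[i, ] <- h * herit + sqrt(1 - h^2) * z
    }
  }
  groups <- unique(ped$group)
  geff <- matrix(stats::rnorm(length(groups) * P) * cfg$group_sd,
                 length(groups), P, dimnames = list(groups, pt$param))
  mu <- matrix(rep(pt$base, each = n), n, P,
               dimnames = list(ped$id, pt$param))
  mu <- mu + outer(ped$sex == "F", cfg$sex_offset[pt$class]) +
    dev + geff[ped$group, , drop = FALSE]
  list(mu = mu, dev = dev, group_effect = geff, params = pt)
}

## Render one phrase from realized parameter values: unit boundaries plus a
## piecewise-linear contour through the f0 landmarks, sampled densely so the
## polyline (and hence feature extraction) is exact at the landmarks.
## Returns plain column vectors; the caller assembles the big tables once.
render_phrase <- function(vals, type, pid, meta_row) {
  K <- if (type == "DP2") 2L else 3L
  dur <- pmax(vals[sprintf("dur_unit%d", seq_len(K))], 0.05)
  int <- if (K > 1L) pmax(vals[sprintf("dur_int%d", seq_len(K - 1L))], 0.01)
  starts <- cumsum(c(0, dur[-K] + int))
  ends <- starts + dur
  ct <- cf <- cu <- vector("list", K)
  for (k in seq_len(K)) {
    f0s <- vals[[sprintf("f0start_unit%d", k)]]
    f0e <- vals[[sprintf("f0end_unit%d", k)]]
    f0x <- max(vals[[sprintf("f0max_unit%d", k)]], max(f0s, f0e) + 1)
    f0n <- min(vals[[sprintf("f0min_unit%d", k)]], min(f0s, f0e) - 1)
    f0n <- max(f0n, 30)
    px <- min(max(vals[[sprintf("ptmax_unit%d", k)]], 1), 99)
    pn <- min(max(vals[[sprintf("ptmin_unit%d", k)]], 1), 99)
    if (abs(pn - px) < 2) pn <- if (px <= 96) px + 2 else px - 2
    ctrl_t <- c(0, px, pn, 100) / 100 * dur[k]
    ctrl_f <- c(f0s, f0x, f0n, f0e)
    ord <- order(ctrl_t)
    ctrl_t <- ctrl_t[ord]; ctrl_f <- ctrl_f[ord]
    tt <- sort(unique(c(ctrl_t, seq(0, dur[k], length.out = 15L))))
    ff <- stats::approx(ctrl_t, ctrl_f, xout = tt, ties = "ordered")$y
    ct[[k]] <- starts[k] + tt
    cf[[k]] <- pmax(ff, 1)
    cu[[k]] <- rep.int(k, length(tt))
  }
  list(unit_index = seq_len(K), unit_start_s = starts, unit_end_s = ends,
       q50_hz = unname(pmax(vals[sprintf("q50_unit%d", seq_len(K))], 50)),
       c_time = unlist(ct), c_f0 = unlist(cf), c_unit = unlist(cu))
}

#' Simulate a phrase dataset over a pedigree
#'
#' Generates, for every individual in the pedigree, descending phrases of
#' the configured types spread over choral songs shared by the group. The
#' latent structure (individual means, heritable component, sex and group
#' effects) is attached as attribute `"latent"` for inspection.
#'
#' @param ped a [simulate_pedigree()] table.
#' @param cfg a [song_effect_config()].
#' @param seed optional integer seed.
#' @return a [phrase_set()] with attributes `latent` (per type: `mu`, `dev`,
#'   `group_effect`, `params`) and `config`.
#' @examples
#' ped <- simulate_pedigree(2, seed = 1)
#' ps <- simulate_phrases(ped, seed = 2)
#' ps
#' @export
simulate_phrases <- function(ped, cfg = song_effect_config(), seed = NULL) {
  validate_pedigree(ped)
  if (!inherits(cfg, "song_effect_config"))
    stopf("`cfg` must come from song_effect_config()")
  with_seed(seed, {
    latent <- lapply(cfg$phrase_types, function(tp)
      simulate_latent(ped, cfg, tp))
    names(latent) <- cfg$phrase_types
    acc <- list()  # per-phrase rendered pieces plus metadata
    for (tp in cfg$phrase_types) {
      lt <- latent[[tp]]
      sd_r <- cfg$residual_sd[lt$params$class]
      for (g in unique(ped$group)) {
        members <- which(ped$group == g)
        for (s in seq_len(cfg$songs_per_group)) {
          sid <- sprintf("%s_S%d", g, s)
          for (i in members) {
            for (rp in seq_len(cfg$phrases_per_song)) {
              pid <- sprintf("%s_%s_%s_p%d", ped$id[i], sid, tp, rp)
              vals <- lt$mu[i, ] + stats::rnorm(nrow(lt$params)) * sd_r
              ph <- render_phrase(vals, tp, pid, NULL)
              ph$pid <- pid; ph$sid <- sid; ph$ind <- ped$id[i]
              ph$grp <- g; ph$sex <- ped$sex[i]; ph$type <- tp
              acc[[length(acc) + 1L]] <- ph
            }
          }
        }
      }
    }
    nun <- vapply(acc, function(p) length(p$unit_index), 0L)
    ncs <- vapply(acc, function(p) length(p$c_time), 0L)
    units <- data.frame(
      phrase_id = rep(vapply(acc, `[[`, "", "pid"), nun),
      song_id = rep(vapply(acc, `[[`, "", "sid"), nun),
      individual_id = rep(vapply(acc, `[[`, "", "ind"), nun),
      group_id = rep(vapply(acc, `[[`, "", "grp"), nun),
      sex = rep(vapply(acc, `[[`, "", "sex"), nun),
      phrase_type = rep(vapply(acc, `[[`, "", "type"), nun),
      unit_index = unlist(lapply(acc, `[[`, "unit_index")),
      unit_start_s = unlist(lapply(acc, `[[`, "unit_start_s")),
      unit_end_s = unlist(lapply(acc, `[[`, "unit_end_s")),
      q50_hz = unlist(lapply(acc, `[[`, "q50_hz")))
    contours <- data.frame(
      phrase_id = rep(vapply(acc, `[[`, "", "pid"), ncs),
      unit_index = unlist(lapply(acc, `[[`, "c_unit")),
      time_s = unlist(lapply(acc, `[[`, "c_time")),
      f0_hz = unlist(lapply(acc, `[[`, "c_f0")))
    ps <- phrase_set(units, contours)
    attr(ps, "latent") <- latent
    attr(ps, "config") <- cfg
    ps
  })
}
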