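## Container for descending-phrase data: a unit table (one row per unit,
## with phrase metadata and boundaries) plus an f0 contour table (one row
## per pitch sample). DP2 phrases have exactly two units, DP3 three.

phrase_units_cols <- c("phrase_id", "song_id", "individual_id", "group_id",
                       "sex", "phrase_type", "unit_index",
                       "unit_start_s", "unit_end_s")

#' Assemble and validate a phrase dataset
#'
#' @param units data.frame with columns `phrase_id`, `song_id`,
#'   `individual_id`, `group_id`, `sex`, `phrase_type` (`"DP2"`/`"DP3"`),
#'   `unit_index`, `unit_start_s`, `unit_end_s`, and optionally `q50_hz`
#'   (per-unit frequency at the upper limit of the second quartile of
#'   spectral energy).
#' @param contours data.frame with columns `phrase_id`, `unit_index`,
#'   `time_s`, `f0_hz` (fundamental-frequency samples; at least two per
#'   unit, all inside the unit's boundaries, all positive).
#' @return a `phrase_set` (list of the two validated tables).
#' @export
phrase_set <- function(units, contours) {
  miss <- setdiff(phrase_units_cols, names(units))
  if (length(miss))
    stopf("`units` is missing columns: %s", paste(miss, collapse = ", "))
  cmiss <- setdiff(c("phrase_id", "unit_index", "time_s", "f0_hz"),
                   names(contours))
  if (length(cmiss))
    stopf("`contours` is missing columns: %s", paste(cmiss, collapse = ", "))
  units <- units[order(units$phrase_id, units$unit_index), , drop = FALSE]
  rownames(units) <- NULL
  contours <- contours[order(contours$phrase_id, contours$unit_index,
                             contours$time_s), , drop = FALSE]
  rownames(contours) <- NULL
  ps <- structure(list(units = units, contours = contours),
                  class = "phrase_set")
  validate_phrase_set(ps)
  ps
}

## Vectorized invariant checks; error messages name the first offending
## phrase so malformed inputs are easy to locate.
validate_phrase_set <- function(ps) {
  units <- ps$units; contours <- ps$contours
  n <- nrow(units)
  if (!n) stopf("phrase set is empty")
  if (!all(units$phrase_type %in% c("DP2", "DP3")))
    stopf("phrase_type must be 'DP2' or 'DP3'")
  if (!all(units$sex %in% c("M", "F"))) stopf("sex must be 'M' or 'F'")
  if (any(contours$f0_hz <= 0)) stopf("all f0 samples must be positive")

  first <- !duplicated(units$phrase_id)
  pid <- units$phrase_id[first]
  expected <- ifelse(units$phrase_type[first] == "DP2", 2L, 3L)
  cnt <- as.vector(table(factor(units$phrase_id, levels = pid)))
  bad <- which(cnt != expected)
  if (length(bad))
    stopf("phrase '%s': %s must have %d units, found %d", pid[bad[1]],
          units$phrase_type[first][bad[1]], expected[bad[1]], cnt[bad[1]])
  ## units are sorted (constructor): unit_index must be 1..K per phrase
  expect_idx <- sequence(cnt)
  if (any(units$unit_index != expect_idx)) {
    i <- which(units$unit_index != expect_idx)[1]
    stopf("phrase '%s': unit_index must be 1..%d", units$phrase_id[i],
          cnt[match(units$phrase_id[i], pid)])
  }
  if (any(units$unit_end_s <= units$unit_start_s)) {
    i <- which(units$unit_end_s <= units$unit_start_s)[1]
    stopf("phrase '%s': unit end must exceed start", units$phrase_id[i])
  }
  same <- units$phrase_id[-1] == units$phrase_id[-n]
  olap <- same & (units$unit_start_s[-1] < units$unit_end_s[-n] - 1e-12)
  if (any(olap))
    stopf("phrase '%s': units overlap", units$phrase_id[which(olap)[1] + 1L])
  meta_u <- tapply(paste(units$individual_id, units$song_id, units$group_id,
                         units$sex, units$phrase_type),
                   units$phrase_id, function(x) length(unique(x)))
  if (any(meta_u != 1L))
    stopf("phrase '%s': inconsistent metadata", names(meta_u)[meta_u != 1][1])

  ukey <- paste(units$phrase_id, units$unit_index)
  ckey <- paste(contours$phrase_id, contours$unit_index)
  ccnt <- table(ckey)
  have <- ccnt[ukey]
  if (anyNA(have) || any(have < 2L)) {
    i <- which(is.na(have) | have < 2L)[1]
    stopf("phrase '%s' unit %d: at least 2 f0 samples are required",
          units$phrase_id[i], units$unit_index[i])
  }
  m <- match(ckey, ukey)
  if (anyNA(m)) {
    i <- which(is.na(m))[1]
    stopf("contour rows for unknown phrase/unit '%s'", ckey[i])
  }
  out <- contours$time_s < units$unit_start_s[m] - 1e-9 |
    contours$time_s > units$unit_end_s[m] + 1e-9
  if (any(out)) {
    i <- which(out)[1]
    stopf("phrase '%s' unit %d: f0 samples fall outside the unit",
          contours$phrase_id[i], contours$unit_index[i])
  }
  invisible(ps)
}

#' @export
print.phrase_set <- function(x, ...) {
  u <- x$units[x$units$unit_index == 1L, ]
  cat(sprintf("Phrase set: %d phrases (%s) from %d individuals in %d groups\n",
              nrow(u),
              paste(sprintf("%d %s", as.integer(table(u$phrase_type)),
                            names(table(u$phrase_type))), collapse = ", "),
              length(unique(u$individual_id)),
              length(unique(u$group_id))))
  invisible(x)
}

## One metadata row per phrase.
phrase_meta <- function(ps, type = NULL) {
  u <- ps$units[ps$units$unit_index == 1L,
                c("phrase_id", "song_id", "individual_id", "group_id",
                  "sex", "phrase_type")]
  if (!is.null(type)) u <- u[u$phrase_type == type, , drop = FALSE]
  rownames(u) <- NULL
  u
}

#' Subset a phrase set
#'
#' @param ps a [phrase_set()].
#' @param phrase_ids optional phrase ids to keep.
#' @param type optional phrase type (`"DP2"` or `"DP3"`) to keep.
#' @return the filtered `phrase_set`.
#' @export
subset_phrases <- function(ps, phrase_ids = NULL, type = NULL) {
  keep <- unique(ps$units$phrase_id)
  if (!is.null(type))
    keep <- intersect(keep,
                      ps$units$phrase_id[ps$units$phrase_type == type])
  if (!is.null(phrase_ids)) keep <- intersect(keep, phrase_ids)
  structure(list(
    units = ps$units[ps$units$phrase_id %in% keep, , drop = FALSE],
    contours = ps$contours[ps$contours$phrase_id %in% keep, , drop = FALSE]),
    class = "phrase_set")
}
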