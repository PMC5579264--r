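#' Simulate a multi-group family pedigree
#'
#' Builds a pedigree of `n_groups` social groups, each consisting of a
#' reproductive male, an unrelated reproductive female, and their common
#' offspring. This mirrors the social organization of family-living singing
#' primates such as the indri, where each group holds one breeding pair plus
#' 0-2 offspring (group sizes 2-4).
#'
#' @param n_groups number of social groups (>= 1).
#' @param offspring_range integer vector `c(min, max)` of offspring per
#'   group; each group draws its offspring count uniformly from this range.
#'   Default `c(0, 2)`.
#' @param seed optional integer seed; the same seed always yields the same
#'   pedigree.
#' @return a `data.frame` of class `pedigree` with columns `id`, `sex`
#'   (`"M"`/`"F"`), `group`, `father`, `mother` (`NA` for founders) and
#'   `role` (`"reproductive"` or `"offspring"`). Parents always precede
#'   their offspring.
#' @examples
#' ped <- simulate_pedigree(7, seed = 1)
#' table(ped$role)
#' @export
simulate_pedigree <- function(n_groups, offspring_range = c(0L, 2L),
                              seed = NULL) {
  n_groups <- check_count(n_groups, "n_groups")
  if (!is.numeric(offspring_range) || length(offspring_range) != 2L ||
      anyNA(offspring_range) || any(offspring_range != floor(offspring_range)))
    stopf("`offspring_range` must be two integers c(min, max)")
  offspring_range <- as.integer(offspring_range)
  if (offspring_range[1] < 0L || offspring_range[1] > offspring_range[2])
    stopf("`offspring_range` must satisfy 0 <= min <= max")

  with_seed(seed, {
    rows <- vector("list", n_groups)
    for (g in seq_len(n_groups)) {
      gid <- sprintf("G%d", g)
      male <- sprintf("%s_M", gid)
      female <- sprintf("%s_F", gid)
      n_off <- if (offspring_range[1] == offspring_range[2]) offspring_range[1]
               else sample(seq(offspring_range[1], offspring_range[2]), 1L)
      founders <- data.frame(
        id = c(male, female), sex = c("M", "F"), group = gid,
        father = NA_character_, mother = NA_character_,
        role = "reproductive", stringsAsFactors = FALSE)
      off <- NULL
      if (n_off > 0L) {
        osex <- sample(c("M", "F"), n_off, replace = TRUE)
        off <- data.frame(
          id = sprintf("%s_O%d", gid, seq_len(n_off)), sex = osex,
          group = gid, father = male, mother = female,
          role = "offspring", stringsAsFactors = FALSE)
      }
      rows[[g]] <- rbind(founders, off)
    }
    ped <- do.call(rbind, rows)
    rownames(ped) <- NULL
    class(ped) <- c("pedigree", "data.frame")
    validate_pedigree(ped)
    ped
  })
}

#' Reference seven-group study pedigree
#'
#' The fixed pedigree structure used throughout the package's examples and
#' calibration experiments: seven social groups, each a reproductive pair
#' plus 0-2 offspring (nine offspring in total, five males and four
#' females), mirroring the group composition of the wild study population
#' this package emulates.
#'
#' @return a `pedigree` (deterministic; no random component).
#' @examples
#' table(reference_pedigree()$sex, reference_pedigree()$role)
#' @export
reference_pedigree <- function() {
  counts <- c(2L, 1L, 2L, 1L, 0L, 2L, 1L)
  sexes <- list(c("F", "F"), "F", c("M", "F"), "M", character(0),
                c("M", "M"), "M")
  rows <- vector("list", 0)
  for (g in seq_along(counts)) {
    gid <- sprintf("G%d", g)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("%s_%s", gid, c("M", "F")), sex = c("M", "F"),
      group = gid, father = NA_character_, mother = NA_character_,
      role = "reproductive", stringsAsFactors = FALSE)
    if (counts[g] > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_O%d", gid, seq_len(counts[g])), sex = sexes[[g]],
        group = gid, father = sprintf("%s_M", gid),
        mother = sprintf("%s_F", gid), role = "offspring",
        stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate a pedigree table
#'
#' Checks the structural invariants every pedigree must satisfy: unique ids,
#' parents listed before their offspring, fathers male and mothers female,
#' and parent references that resolve within the table.
#'
#' @param ped a `data.frame` with columns `id`, `sex`, `group`, `father`,
#'   `mother`, `role`.
#' @return `ped`, invisibly, with class `pedigree`.
#' @export
validate_pedigree <- function(ped) {
  need <- c("id", "sex", "group", "father", "mother", "role")
  miss <- setdiff(need, names(ped))
  if (length(miss))
    stopf("pedigree is missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(ped$id)) stopf("pedigree ids are not unique")
  if (!all(ped$sex %in% c("M", "F")))
    stopf("pedigree sex must be 'M' or 'F'")
  is_founder <- is.na(ped$father) & is.na(ped$mother)
  if (any(is.na(ped$father) != is.na(ped$mother)))
    stopf("individuals must have either both parents or neither")
  pos <- seq_len(nrow(ped)); names(pos) <- ped$id
  for (i in which(!is_founder)) {
    for (p in c(ped$father[i], ped$mother[i])) {
      if (!p %in% ped$id)
        stopf("parent '%s' of '%s' is not in the pedigree", p, ped$id[i])
      if (pos[p] >= i)
        stopf("parent '%s' is listed after offspring '%s'", p, ped$id[i])
    }
    if (ped$sex[match(ped$father[i], ped$id)] != "M")
      stopf("father of '%s' is not male", ped$id[i])
    if (ped$sex[match(ped$mother[i], ped$id)] != "F")
      stopf("mother of '%s' is not female", ped$id[i])
  }
  if (!inherits(ped, "pedigree")) class(ped) <- c("pedigree", "data.frame")
  invisible(ped)
}
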