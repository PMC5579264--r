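## Plain-text interchange formats. All writers emit UTF-8 CSV with a header
## row and '.' decimal separator; missing alleles are coded 0 in genotype
## CSVs and empty parent fields mark founders in pedigree CSVs.

#' Write / read a pedigree CSV
#'
#' Columns: `individual_id,sex,group_id,father_id,mother_id` (empty parent
#' fields mark founders). Role is recovered on read from the parent fields.
#'
#' @param ped a pedigree table.
#' @param path file path.
#' @return `path` (writer) or a `pedigree` (reader).
#' @export
write_pedigree_csv <- function(ped, path) {
  validate_pedigree(ped)
  df <- data.frame(individual_id = ped$id, sex = ped$sex,
                   group_id = ped$group,
                   father_id = ifelse(is.na(ped$father), "", ped$father),
                   mother_id = ifelse(is.na(ped$mother), "", ped$mother))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  ped <- data.frame(
    id = df$individual_id, sex = df$sex, group = df$group_id,
    father = ifelse(nzchar(df$father_id), df$father_id, NA_character_),
    mother = ifelse(nzchar(df$mother_id), df$mother_id, NA_character_),
    stringsAsFactors = FALSE)
  ped$role <- ifelse(is.na(ped$father), "reproductive", "offspring")
  validate_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Write / read a genotype CSV
#'
#' Long format `individual_id,locus,allele1_bp,allele2_bp`; missing alleles
#' are coded 0. Reading requires the locus specifications so the table's
#' allele universe is known.
#'
#' @param g a `genotype_table`.
#' @param path file path.
#' @param loci list of [locus_spec()] (reader only).
#' @return `path` (writer) or a `genotype_table` (reader).
#' @export
write_genotype_csv <- function(g, path) {
  if (!inherits(g, "genotype_table")) stopf("`g` must be a genotype_table")
  ids <- rownames(g$a1); loci <- colnames(g$a1)
  df <- data.frame(
    individual_id = rep(ids, each = length(loci)),
    locus = rep(loci, length(ids)),
    allele1_bp = as.vector(t(ifelse(is.na(g$a1), 0L, g$a1))),
    allele2_bp = as.vector(t(ifelse(is.na(g$a2), 0L, g$a2))))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_genotype_csv
#' @export
read_genotype_csv <- function(path, loci) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  lnames <- unname(vapply(loci, `[[`, "", "name"))
  miss <- setdiff(unique(df$locus), lnames)
  if (length(miss))
    stopf("loci in file but not in `loci`: %s", paste(miss, collapse = ", "))
  ids <- unique(df$individual_id)
  a1 <- matrix(NA_integer_, length(ids), length(lnames),
               dimnames = list(ids, lnames))
  a2 <- a1
  ii <- match(df$individual_id, ids); jj <- match(df$locus, lnames)
  a1[cbind(ii, jj)] <- ifelse(df$allele1_bp == 0L, NA_integer_,
                              as.integer(df$allele1_bp))
  a2[cbind(ii, jj)] <- ifelse(df$allele2_bp == 0L, NA_integer_,
                              as.integer(df$allele2_bp))
  new_genotype_table(a1, a2, loci)
}

#' Write / read phrase and contour CSVs
#'
#' Phrase CSV columns: `phrase_id,song_id,individual_id,group_id,sex,`
#' `phrase_type,unit_index,unit_start_s,unit_end_s`; contour CSV columns:
#' `phrase_id,unit_index,time_s,f0_hz` plus an optional per-unit `q50_hz`
#' (constant within a unit). The round trip is lossless.
#'
#' @param ps a [phrase_set()].
#' @param phrases_path,contours_path file paths.
#' @return paths (writer) or a `phrase_set` (reader).
#' @export
write_phrase_csv <- function(ps, phrases_path, contours_path) {
  validate_phrase_set(ps)
  u <- ps$units[, phrase_units_cols]
  utils::write.csv(u, phrases_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  cont <- ps$contours[, c("phrase_id", "unit_index", "time_s", "f0_hz")]
  if ("q50_hz" %in% names(ps$units)) {
    key <- paste(ps$units$phrase_id, ps$units$unit_index)
    cont$q50_hz <- ps$units$q50_hz[match(
      paste(cont$phrase_id, cont$unit_index), key)]
  }
  utils::write.csv(cont, contours_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(c(phrases_path, contours_path))
}

#' @rdname write_phrase_csv
#' @export
read_phrase_csv <- function(phrases_path, contours_path) {
  u <- utils::read.csv(phrases_path, fileEncoding = "UTF-8",
                       colClasses = c(phrase_id = "character",
                                      song_id = "character",
                                      individual_id = "character",
                                      group_id = "character"))
  cont <- utils::read.csv(contours_path, fileEncoding = "UTF-8",
                          colClasses = c(phrase_id = "character"))
  if ("q50_hz" %in% names(cont)) {
    key <- paste(cont$phrase_id, cont$unit_index)
    ukey <- paste(u$phrase_id, u$unit_index)
    u$q50_hz <- cont$q50_hz[match(ukey, key)]
    cont$q50_hz <- NULL
  }
  phrase_set(u, cont)
}

#' Read a Praat PitchTier file
#'
#' Supports both the long ("ooTextFile" with `points [k]:` blocks) and the
#' short text dialect. Returns the pitch points as a contour table.
#'
#' @param path path to a PitchTier text file.
#' @return data.frame with columns `time_s`, `f0_hz`.
#' @export
read_pitchtier <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines) || !grepl("ooTextFile", lines[1]))
    stopf("'%s' is not a Praat text file (missing ooTextFile header)", path)
  if (!any(grepl("PitchTier", lines[1:2])))
    stopf("'%s' is not a PitchTier file", path)
  body <- lines[-(1:2)]
  body <- trimws(body[nzchar(trimws(body))])
  num <- function(x) suppressWarnings(as.numeric(sub(".*=", "", x)))
  if (any(grepl("^points", body))) {
    ## long dialect: number/value pairs inside points [k] blocks
    tvals <- num(grep("^number\\s*=", body, value = TRUE))
    fvals <- num(grep("^value\\s*=", body, value = TRUE))
  } else {
    ## short dialect: xmin, xmax, n, then alternating time/value lines
    vals <- suppressWarnings(as.numeric(body))
    if (anyNA(vals)) stopf("cannot parse short PitchTier '%s'", path)
    n <- as.integer(vals[3])
    pts <- vals[-(1:3)]
    if (length(pts) != 2 * n)
      stopf("short PitchTier '%s': expected %d points, found %d values",
            path, n, length(pts))
    tvals <- pts[seq(1, length(pts), by = 2)]
    fvals <- pts[seq(2, length(pts), by = 2)]
  }
  if (!length(tvals) || length(tvals) != length(fvals))
    stopf("could not extract pitch points from '%s'", path)
  data.frame(time_s = tvals, f0_hz = fvals)
}

#' Write a feature table to CSV
#'
#' @param features a feature table from [temporal_features()] or
#'   [frequency_features()].
#' @param path file path.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
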