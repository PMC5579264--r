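## End-to-end orchestration: from input files (or the synthetic generator)
## to the three report tables — Mantel tests of acoustic dissimilarity vs
## genetic distance (overall and per sex), kin-category Mantel tests, and
## pDFA classification of individuality and group membership.

#' Drop individuals contributing too few phrases
#'
#' Cohort filtering is applied per phrase type independently, so the DP2
#' and DP3 cohorts may differ. An individual is kept for a type when it
#' contributes at least `min_count` phrases of that type (inclusive).
#'
#' @param ps a [phrase_set()].
#' @param min_count minimum phrases per individual per type (default 4).
#' @return filtered `phrase_set`; dropped (individual, type) combinations
#'   are attached as attribute `"dropped"` and reported via `message()`.
#' @export
filter_individuals <- function(ps, min_count = 4) {
  min_count <- check_count(min_count, "min_count")
  meta <- phrase_meta(ps)
  counts <- stats::aggregate(phrase_id ~ individual_id + phrase_type,
                             data = meta, FUN = length)
  drop <- counts[counts$phrase_id < min_count, , drop = FALSE]
  if (nrow(drop)) {
    key <- paste(meta$individual_id, meta$phrase_type)
    bad <- paste(drop$individual_id, drop$phrase_type)
    keep_ids <- meta$phrase_id[!key %in% bad]
    message(sprintf("filter_individuals: dropping %s",
                    paste(sprintf("%s (%s, %d phrases)", drop$individual_id,
                                  drop$phrase_type, drop$phrase_id),
                          collapse = "; ")))
    ps <- subset_phrases(ps, phrase_ids = keep_ids)
  }
  if (!nrow(ps$units))
    stopf("no phrases left after filtering at min_count = %d", min_count)
  attr(ps, "dropped") <- drop[, c("individual_id", "phrase_type")]
  ps
}

#' Build a pipeline configuration
#'
#' @param simulate `NULL`, or a list describing the synthetic study:
#'   `n_groups` (default 7), `offspring_range` (default `c(0, 2)`),
#'   `loci` (default [default_locus_panel()]) and `song` (a
#'   [song_effect_config()]).
#' @param paths `NULL`, or a list of input files: `pedigree`, `genotypes`,
#'   `phrases`, `contours` (CSV dialects of the write_* functions), plus
#'   `loci` (a list of [locus_spec()]) for decoding genotypes.
#' @param min_phrases cohort filter threshold (default 4).
#' @param mantel_perm permutations for all Mantel tests (default 9999).
#' @param estimator relatedness estimator for the genetic matrix (default
#'   `"dyadml"`; any of the registered estimator names).
#' @param grid_resolution simplex grid for `"dyadml"` (default 0.01).
#' @param compare_estimators run the estimator-comparison harness and write
#'   its report (default `TRUE`).
#' @param n_per_category dyads per category in the comparison (default 100).
#' @param pdfa list with `n_selections` and `n_permutations` for all pDFA
#'   runs (defaults 100 and 1000).
#' @param out_dir output directory (created if needed).
#' @param seed global seed; every stochastic stage receives a seed derived
#'   deterministically from it.
#' @return a `run_config` list.
#' @export
run_config <- function(simulate = list(), paths = NULL, min_phrases = 4,
                       mantel_perm = 9999, estimator = "dyadml",
                       grid_resolution = 0.01, compare_estimators = TRUE,
                       n_per_category = 100,
                       pdfa = list(n_selections = 100, n_permutations = 1000),
                       out_dir = tempfile("songkin_run_"), seed = 1) {
  if (is.null(paths)) {
    simulate <- utils::modifyList(
      list(n_groups = 7, offspring_range = c(0, 2),
           loci = default_locus_panel(), song = song_effect_config()),
      simulate)
  } else {
    need <- c("pedigree", "genotypes", "phrases", "contours", "loci")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stopf("`paths` is missing entries: %s", paste(miss, collapse = ", "))
    simulate <- NULL
  }
  pdfa <- utils::modifyList(list(n_selections = 100, n_permutations = 1000),
                            pdfa)
  structure(list(simulate = simulate, paths = paths,
                 min_phrases = check_count(min_phrases, "min_phrases"),
                 mantel_perm = check_count(mantel_perm, "mantel_perm"),
                 estimator = estimator,
                 grid_resolution = grid_resolution,
                 compare_estimators = isTRUE(compare_estimators),
                 n_per_category = check_count(n_per_category,
                                              "n_per_category"),
                 pdfa = pdfa, out_dir = out_dir, seed = seed),
            class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes feature extraction, four PCAs (phrase type x parameter set),
#' phrase and individual dissimilarity matrices, relatedness estimation
#' (with optional estimator comparison), Mantel tests overall and per sex,
#' the four kin-category Mantel tests, and pDFAs for individuality
#' (overall and per sex) and group membership. All report tables are
#' written to `cfg$out_dir` together with a JSON run manifest; two runs
#' with the same configuration and seed produce byte-identical outputs.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with all intermediate objects and the report
#'   tables (`mantel`, `kin`, `pdfa`, `pca`).
#' @export
run_all <- function(cfg) {
  if (!inherits(cfg, "run_config")) stopf("`cfg` must come from run_config()")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  ## ---- inputs ----
  inputs <- run_stage("inputs", {
    if (is.null(cfg$paths)) {
      sim <- cfg$simulate
      ped <- simulate_pedigree(sim$n_groups, sim$offspring_range,
                               seed = derive_seed(cfg$seed, 1))
      g <- simulate_genotypes(ped, sim$loci, seed = derive_seed(cfg$seed, 2))
      ps <- simulate_phrases(ped, sim$song, seed = derive_seed(cfg$seed, 3))
      list(ped = ped, g = g, ps = ps, loci = sim$loci)
    } else {
      for (p in unlist(cfg$paths[c("pedigree", "genotypes", "phrases",
                                   "contours")]))
        if (!file.exists(p)) stopf("input file not found: %s", p)
      list(ped = read_pedigree_csv(cfg$paths$pedigree),
           g = read_genotype_csv(cfg$paths$genotypes, cfg$paths$loci),
           ps = read_phrase_csv(cfg$paths$phrases, cfg$paths$contours),
           loci = cfg$paths$loci)
    }
  })
  ped <- inputs$ped; g <- inputs$g
  note("inputs: %d individuals, %d phrases", nrow(ped),
       nrow(phrase_meta(inputs$ps)))

  ps <- run_stage("filter", suppressMessages(
    filter_individuals(inputs$ps, cfg$min_phrases)))

  ## ---- acoustics: features -> PCA -> distances, per type x set ----
  types <- intersect(c("DP2", "DP3"), unique(ps$units$phrase_type))
  acoustic <- list(); pca_rows <- list()
  for (tp in types) {
    sub <- subset_phrases(ps, type = tp)
    for (set in c("temporal", "frequency")) {
      key <- paste(tp, set, sep = "_")
      run_stage(paste0("acoustics:", key), {
        f <- if (set == "temporal") temporal_features(sub)
             else frequency_features(sub)
        pc <- pca_kaiser(feature_values(f))
        d <- phrase_distance(pc)
        map <- stats::setNames(f$individual_id, f$phrase_id)
        dm <- normalize01(individual_mean_distance(d, map))
        acoustic[[key]] <- list(features = f, pca = pc, dist = dm,
                                meta = phrase_meta(sub))
        pca_rows[[key]] <- data.frame(
          phrase_type = tp, set = set, n_phrases = nrow(f),
          n_variables = ncol(feature_values(f)),
          n_retained = pc$n_retained,
          cum_var_retained = pc$cum_var_retained)
        utils::write.csv(
          data.frame(variable = rownames(pc$loadings),
                     round(pc$loadings, 6)),
          file.path(cfg$out_dir, sprintf("loadings_%s.csv", key)),
          row.names = FALSE)
      })
    }
  }

  ## ---- relatedness ----
  rel <- run_stage("relatedness", {
    freqs <- allele_frequencies(g)
    rm <- if (cfg$estimator == "dyadml")
      dyadic_ml(g, freqs, cfg$grid_resolution)
    else moment_estimators(g, freqs, cfg$estimator)
    write_square_matrix(round(as.matrix(rm), 6),
                        file.path(cfg$out_dir, sprintf("relatedness_%s.csv",
                                                       cfg$estimator)))
    cmp <- NULL
    if (cfg$compare_estimators) {
      cmp <- compare_estimators(inputs$loci,
                                n_per_category = cfg$n_per_category,
                                grid_resolution = cfg$grid_resolution,
                                seed = derive_seed(cfg$seed, 4))
      utils::write.csv(cmp$summary,
                       file.path(cfg$out_dir, "estimator_comparison.csv"),
                       row.names = FALSE)
      utils::write.csv(cmp$ranking,
                       file.path(cfg$out_dir, "estimator_ranking.csv"),
                       row.names = FALSE)
    }
    list(matrix = rm, distance = relatedness_to_distance(rm),
         comparison = cmp)
  })

  ## ---- Mantel: overall and per sex ----
  mantel_rows <- list()
  kseed <- 100L
  for (key in names(acoustic)) {
    parts <- strsplit(key, "_")[[1]]
    dm <- acoustic[[key]]$dist
    common <- intersect(rownames(dm), rownames(rel$distance))
    for (subgroup in c("males", "females", "overall")) {
      ids <- switch(subgroup,
        males = common[ped$sex[match(common, ped$id)] == "M"],
        females = common[ped$sex[match(common, ped$id)] == "F"],
        overall = common)
      kseed <- kseed + 1L
      res <- if (length(ids) >= 4L)
        run_stage(paste0("mantel:", key, ":", subgroup),
                  mantel_test(restrict_matrix(dm, ids),
                              restrict_matrix(rel$distance, ids),
                              n_perm = cfg$mantel_perm,
                              seed = derive_seed(cfg$seed, kseed)))
      else NULL
      if (is.null(res))
        note("mantel %s %s skipped: fewer than 4 individuals", key, subgroup)
      mantel_rows[[length(mantel_rows) + 1L]] <- data.frame(
        phrase_type = parts[1], set = parts[2], subgroup = subgroup,
        n = if (is.null(res)) length(ids) else res$n,
        r = if (is.null(res)) NA_real_ else res$r,
        p = if (is.null(res)) NA_real_ else res$p)
    }
  }

  ## ---- kin-category Mantel ----
  kin_rows <- list()
  for (key in names(acoustic)) {
    parts <- strsplit(key, "_")[[1]]
    dm <- acoustic[[key]]$dist
    for (pr in c("father", "mother")) for (or in c("son", "daughter")) {
      kseed <- kseed + 1L
      res <- tryCatch({
        des <- kin_category_design(ped, pr, or, individuals = rownames(dm))
        kin_category_mantel(dm, des, n_perm = cfg$mantel_perm,
                            seed = derive_seed(cfg$seed, kseed))
      }, error = function(e) {
        note("kin mantel %s %s-%s skipped: %s", key, pr, or,
             conditionMessage(e))
        NULL
      })
      kin_rows[[length(kin_rows) + 1L]] <- data.frame(
        phrase_type = parts[1], set = parts[2], parent_role = pr,
        offspring_role = or,
        n = if (is.null(res)) NA_integer_ else res$n,
        r = if (is.null(res)) NA_real_ else res$r,
        p = if (is.null(res)) NA_real_ else res$p)
    }
  }

  ## ---- pDFA ----
  pdfa_rows <- list()
  for (key in names(acoustic)) {
    parts <- strsplit(key, "_")[[1]]
    sc <- acoustic[[key]]$pca$scores
    meta <- acoustic[[key]]$meta
    add_row <- function(analysis, res) {
      pdfa_rows[[length(pdfa_rows) + 1L]] <<- data.frame(
        phrase_type = parts[1], set = parts[2], analysis = analysis,
        training_rate = if (is.null(res)) NA_real_ else res$training_rate,
        training_p = if (is.null(res)) NA_real_ else res$training_p,
        testing_rate = if (is.null(res)) NA_real_ else res$testing_rate,
        testing_p = if (is.null(res)) NA_real_ else res$testing_p,
        chance_rate = if (is.null(res)) NA_real_ else res$chance_rate)
    }
    kseed <- kseed + 1L
    run_stage(paste0("pdfa:", key), {
      overall <- pdfa(sc, meta$individual_id, meta$song_id,
                      n_selections = cfg$pdfa$n_selections,
                      n_permutations = cfg$pdfa$n_permutations,
                      seed = derive_seed(cfg$seed, kseed))
      add_row("individuality_overall", overall)
      bysex <- suppressWarnings(
        pdfa_by_sex(sc, meta$individual_id, meta$song_id, meta$sex,
                    n_selections = cfg$pdfa$n_selections,
                    n_permutations = cfg$pdfa$n_permutations,
                    seed = derive_seed(cfg$seed, kseed + 1000L)))
      add_row("individuality_males", bysex[["M"]])
      add_row("individuality_females", bysex[["F"]])
      grp <- tryCatch(
        pdfa_group(sc, meta$group_id, meta$individual_id,
                   n_selections = cfg$pdfa$n_selections,
                   n_permutations = cfg$pdfa$n_permutations,
                   seed = derive_seed(cfg$seed, kseed + 2000L)),
        error = function(e) {
          note("group pdfa %s skipped: %s", key, conditionMessage(e))
          NULL
        })
      add_row("group_membership", grp)
    })
  }

  ## ---- reports ----
  tab_mantel <- do.call(rbind, mantel_rows)
  tab_kin <- do.call(rbind, kin_rows)
  tab_pdfa <- do.call(rbind, pdfa_rows)
  tab_pca <- do.call(rbind, pca_rows)
  utils::write.csv(tab_mantel, file.path(cfg$out_dir, "table1_mantel.csv"),
                   row.names = FALSE)
  utils::write.csv(tab_kin, file.path(cfg$out_dir, "table2_kin_mantel.csv"),
                   row.names = FALSE)
  utils::write.csv(tab_pdfa, file.path(cfg$out_dir, "table3_pdfa.csv"),
                   row.names = FALSE)
  utils::write.csv(tab_pca, file.path(cfg$out_dir, "pca_summary.csv"),
                   row.names = FALSE)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))

  manifest <- list(
    package = "songkin",
    version = as.character(utils::packageVersion("songkin")),
    seed = cfg$seed,
    config = list(
      simulated = is.null(cfg$paths), min_phrases = cfg$min_phrases,
      mantel_perm = cfg$mantel_perm, estimator = cfg$estimator,
      grid_resolution = cfg$grid_resolution,
      compare_estimators = cfg$compare_estimators,
      n_per_category = cfg$n_per_category, pdfa = cfg$pdfa))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(pedigree = ped, genotypes = g, phrases = ps,
                 acoustic = acoustic, relatedness = rel,
                 mantel = tab_mantel, kin = tab_kin, pdfa = tab_pdfa,
                 pca = tab_pca, out_dir = cfg$out_dir))
}
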