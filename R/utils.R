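## Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards so that seeded package
#' functions never perturb the surrounding session. A `NULL` seed leaves the
#' RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("`seed` must be a single non-missing number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic per-stage sub-seed, kept well inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  stage <- as.double(stage)
  as.integer((as.double(seed) * 7919 + stage * 104729) %% 2147483647) + 1L
}

## sample() without the length-1 surprise.
sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

## All n! permutations of 1..n as rows; only used for small n (oracles,
## exhaustive Mantel).
all_permutations <- function(n) {
  n <- check_count(n, "n")
  if (n > 9L) stopf("refusing to enumerate %d! permutations", n)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub)))
  }
  res <- do.call(rbind, out)
  dimnames(res) <- NULL
  res
}
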