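#' Describe a microsatellite locus
#'
#' @param name locus name.
#' @param alleles integer vector of allele fragment sizes (bp), at least two
#'   for a polymorphic locus (a single allele is accepted and describes a
#'   monomorphic locus).
#' @param freqs allele frequency vector aligned with `alleles`; defaults to
#'   uniform. Must be positive and sum to 1.
#' @return a `locus_spec` list with fields `name`, `alleles`, `freqs`.
#' @examples
#' locus_spec("L1", c(100, 102, 104))
#' @export
locus_spec <- function(name, alleles, freqs = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("`name` must be a non-empty string")
  if (!is.numeric(alleles) || length(alleles) < 1L || anyNA(alleles) ||
      any(alleles != floor(alleles)) || anyDuplicated(alleles))
    stopf("locus '%s': alleles must be distinct integer sizes", name)
  alleles <- as.integer(sort(alleles))
  if (is.null(freqs)) freqs <- rep(1 / length(alleles), length(alleles))
  if (length(freqs) != length(alleles) || anyNA(freqs) || any(freqs <= 0))
    stopf("locus '%s': frequencies must be positive, one per allele", name)
  if (abs(sum(freqs) - 1) > 1e-8)
    stopf("locus '%s': frequencies must sum to 1", name)
  freqs <- freqs / sum(freqs)
  names(freqs) <- as.character(alleles)
  structure(list(name = name, alleles = alleles, freqs = freqs),
            class = "locus_spec")
}

#' Default six-locus microsatellite panel
#'
#' A panel of six co-dominant dinucleotide-repeat loci modeled on the
#' markers developed for the indri (67HDZ series): allele sizes step by the
#' 2 bp repeat motif across each locus's published fragment-size range.
#' Observed allele frequencies for the wild population are not available, so
#' the panel defaults to uniform frequencies.
#'
#' @return named list of [locus_spec()] objects.
#' @examples
#' panel <- default_locus_panel()
#' sapply(panel, function(l) length(l$alleles))
#' @export
default_locus_panel <- function() {
  ranges <- list(
    `67HDZ25`  = c(218L, 253L),
    `67HDZ62`  = c(203L, 217L),
    `67HDZ18`  = c(164L, 190L),
    `67HDZ55`  = c(312L, 334L),
    `67HDZ180` = c(113L, 136L),
    `67HDZ39`  = c(148L, 162L))
  out <- lapply(names(ranges), function(nm) {
    r <- ranges[[nm]]
    locus_spec(nm, seq(r[1], r[2], by = 2L))
  })
  names(out) <- names(ranges)
  out
}

## Internal constructor: two ind x locus allele-size matrices.
new_genotype_table <- function(a1, a2, loci) {
  stopifnot(identical(dim(a1), dim(a2)))
  structure(list(a1 = a1, a2 = a2, loci = loci), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d individuals x %d loci (%s)\n",
              nrow(x$a1), ncol(x$a1),
              paste(colnames(x$a1), collapse = ", ")))
  invisible(x)
}

genotype_individuals <- function(g) rownames(g$a1)

#' Simulate Mendelian microsatellite genotypes down a pedigree
#'
#' Founders draw both alleles independently from each locus's allele
#' frequencies (Hardy-Weinberg); every offspring receives one allele chosen
#' uniformly from each parent at every locus. No mutation and no genotyping
#' error are modeled.
#'
#' @param ped a [simulate_pedigree()] table (or any valid pedigree).
#' @param loci list of [locus_spec()]; default [default_locus_panel()].
#' @param seed optional integer seed.
#' @return a `genotype_table` holding two allele-size matrices
#'   (individuals x loci) plus the locus specifications.
#' @examples
#' ped <- simulate_pedigree(2, seed = 1)
#' g <- simulate_genotypes(ped, seed = 2)
#' @export
simulate_genotypes <- function(ped, loci = default_locus_panel(),
                               seed = NULL) {
  validate_pedigree(ped)
  if (!length(loci)) stopf("`loci` must be a non-empty list of locus_spec")
  lapply(loci, function(l) {
    if (!inherits(l, "locus_spec")) stopf("`loci` entries must be locus_spec")
  })
  lnames <- unname(vapply(loci, `[[`, "", "name"))
  n <- nrow(ped)
  a1 <- matrix(NA_integer_, n, length(loci),
               dimnames = list(ped$id, lnames))
  a2 <- a1
  with_seed(seed, {
    for (j in seq_along(loci)) {
      al <- loci[[j]]$alleles
      fr <- loci[[j]]$freqs
      for (i in seq_len(n)) {
        if (is.na(ped$father[i])) {
          a1[i, j] <- sample_vec(al, 1L, prob = fr)
          a2[i, j] <- sample_vec(al, 1L, prob = fr)
        } else {
          fi <- match(ped$father[i], ped$id)
          mi <- match(ped$mother[i], ped$id)
          a1[i, j] <- sample_vec(c(a1[fi, j], a2[fi, j]), 1L)
          a2[i, j] <- sample_vec(c(a1[mi, j], a2[mi, j]), 1L)
        }
      }
    }
    new_genotype_table(a1, a2, loci)
  })
}

#' Gene-count allele frequencies from a genotype table
#'
#' @param g a `genotype_table`. Missing alleles (`NA`) are excluded from the
#'   counts; a locus with no typed individual is an error.
#' @return named list (one element per locus) of named frequency vectors
#'   summing to 1.
#' @examples
#' ped <- simulate_pedigree(3, seed = 1)
#' g <- simulate_genotypes(ped, seed = 2)
#' allele_frequencies(g)[[1]]
#' @export
allele_frequencies <- function(g) {
  if (!inherits(g, "genotype_table")) stopf("`g` must be a genotype_table")
  out <- vector("list", ncol(g$a1))
  names(out) <- colnames(g$a1)
  for (j in seq_len(ncol(g$a1))) {
    al <- c(g$a1[, j], g$a2[, j])
    al <- al[!is.na(al)]
    if (!length(al))
      stopf("locus '%s' has no typed individuals", colnames(g$a1)[j])
    tab <- table(al)
    out[[j]] <- as.numeric(tab) / sum(tab)
    names(out[[j]]) <- names(tab)
  }
  out
}

## Subset a genotype table by individual ids.
subset_genotypes <- function(g, ids) {
  missing <- setdiff(ids, rownames(g$a1))
  if (length(missing))
    stopf("individuals absent from genotype table: %s",
          paste(missing, collapse = ", "))
  new_genotype_table(g$a1[ids, , drop = FALSE], g$a2[ids, , drop = FALSE],
                     g$loci)
}
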