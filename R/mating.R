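# Random gamete pair formation and meiotic regrowth.

new_mating_result <- function(raw, pool_size) {
  res <- list(pairs = raw$pairs, unmated = raw$unmated, removed = raw$removed,
              pool_size = pool_size)
  structure(res, class = "mating_result")
}

#' @export
print.mating_result <- function(x, ...) {
  cat(sprintf("Mating result: %d pairs, %d unmated, %d removed (pool of %d)\n",
              nrow(x$pairs), x$unmated, x$removed, x$pool_size))
  invisible(x)
}

#' Random heterotypic pair formation
#'
#' Two distinct cells are repeatedly drawn uniformly at random from the
#' pool. A heterotypic draw (different mating-type alleles) forms a mated
#' pair and leaves the pool. The fate of a homotypic draw distinguishes the
#' two regimes:
#'
#' * **exhaustive** (`mate_exhaustive()`): both cells are returned to the
#'   pool and are repeatedly given a chance to mate; the process ends when
#'   the pool is empty, has a single cell, or is monotypic. With `m = 2`
#'   and type counts `N1 <= N2` this always yields exactly `N1` pairs.
#' * **speedy** (`mate_speedy()`): cells that first sample an incompatible
#'   partner are permanently removed from the gamete pool (counted in
#'   `removed`); the process ends when fewer than two cells remain.
#'
#' @param pop A [population()].
#' @param mode `"exhaustive"` or `"speedy"`.
#' @return An object of class `mating_result`: a list with `pairs` (integer
#'   matrix of cell-index pairs, one row per mated pair), `unmated` (count
#'   of cells left unpaired), `removed` (cells discarded by the speedy
#'   regime; 0 under exhaustive mating), and `pool_size`. Always satisfies
#'   `2 * nrow(pairs) + unmated + removed == pool_size`.
#' @examples
#' pop <- population(rep(c(1L, 2L), c(3, 7)), rep(1L, 10), rep(0, 10), m = 2)
#' set.seed(1)
#' mate_exhaustive(pop)  # exactly 3 pairs, 4 unmated
#' @export
mate_pool <- function(pop, mode = c("exhaustive", "speedy")) {
  stopifnot(inherits(pop, "population"))
  mode <- check_choice(mode[[1L]], "mating_mode", c("exhaustive", "speedy"))
  raw <- cpp_mate(pop$mating_type, pop$m, mode == "speedy")
  new_mating_result(raw, length(pop$mating_type))
}

#' @rdname mate_pool
#' @export
mate_exhaustive <- function(pop) mate_pool(pop, "exhaustive")

#' @rdname mate_pool
#' @export
mate_speedy <- function(pop) mate_pool(pop, "speedy")

#' Meiosis and regrowth to carrying capacity
#'
#' Produces exactly `N` haploid offspring by sampling mated pairs with
#' replacement. Each offspring independently selects a pair uniformly at
#' random, inherits its mating-type allele from one of the two parents with
#' probability 1/2, and independently inherits its switching genotype
#' (label and `ps`) from one of the two parents with probability 1/2 (free
#' recombination between the M and S loci). No switching and no `ps`
#' mutation occur at this step. When `cost` is supplied (the
#' once-per-sexual-generation cost timing), each candidate offspring
#' additionally survives with probability [survival_weight()] of its own
#' `ps`, making the regrowth a cost-weighted sample.
#'
#' @param result A `mating_result` from [mate_pool()] with at least one
#'   pair; an empty pair list is an error (a no-mating event, handled by
#'   [sexual_generation()]).
#' @param pop The [population()] that entered the mating pool.
#' @param N Carrying capacity of the next generation.
#' @param cost `NULL` for uniform regrowth, or a list with elements `c` and
#'   `k` to apply the survival cost once at this step.
#' @return A [population()] of exactly `N` cells.
#' @examples
#' pop <- population(c(1L, 2L), c(1L, 2L), c(0, 0.5), m = 2)
#' res <- mate_exhaustive(pop)
#' set.seed(1)
#' meiosis_regrow(res, pop, N = 4)
#' @export
meiosis_regrow <- function(result, pop, N, cost = NULL) {
  stopifnot(inherits(result, "mating_result"), inherits(pop, "population"))
  N <- check_count(N, "N", 2L)
  weighted <- !is.null(cost)
  cc <- if (weighted) check_prob(cost$c, "c") else 0
  kk <- if (weighted) check_nonneg(cost$k, "k") else 0
  out <- cpp_meiosis(result$pairs, pop$mating_type, pop$s_label, pop$ps,
                     N, weighted, cc, kk)
  population(out$mating_type, out$s_label, out$ps, pop$m)
}
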