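# Single-generation dynamics: clonal growth with switching and cost-weighted
# survival, then the sexual phase (pairing + meiotic regrowth).

#' Survival probability under costly switching
#'
#' Computes `f = 1 - c * ps^k`, the probability that a cell with switching
#' rate `ps` survives a cost-weighted down-sampling step. The exponent `k`
#' shapes the cost: accelerating for `k > 1`, decelerating for `k < 1`. At
#' `k = 0` the cost is fixed and independent of the rate: `f = 1` when
#' `ps = 0` and `f = 1 - c` for any `ps > 0`.
#'
#' @param ps Switching rate(s) in `[0, 1]` (vectorised).
#' @param c Cost coefficient in `[0, 1]`.
#' @param k Cost-shape exponent, `>= 0`.
#' @return Survival probabilities in `[0, 1]`, same length as `ps`.
#' @examples
#' survival_weight(0.5, c = 0.01, k = 2)  # 0.9975
#' survival_weight(c(0, 0.3), c = 0.2, k = 0)  # 1.0, 0.8
#' @export
survival_weight <- function(ps, c, k) {
  if (length(ps) == 0L || anyNA(ps) || min(ps) < 0 || max(ps) > 1)
    abort_validation("parameter 'ps' must lie in [0, 1]")
  c <- check_prob(c, "c")
  k <- check_nonneg(k, "k")
  if (k > 0) 1 - c * ps^k else ifelse(ps > 0, 1 - c, 1)
}

#' Mating type of the switching daughter
#'
#' At each clonal division one daughter inherits the parental mating type
#' faithfully; the other keeps it with probability `1 - ps` and otherwise
#' receives an allele drawn uniformly from the `m - 1` non-parental alleles
#' of the full allele set (so currently extinct alleles can reappear).
#'
#' @param parent_type Parental allele index (or vector of indices) in `1..m`.
#' @param ps Switching rate(s) in `[0, 1]`; recycled to the length of
#'   `parent_type`.
#' @param m Number of possible mating-type alleles.
#' @return Integer vector of daughter allele indices.
#' @examples
#' set.seed(1)
#' switch_daughter(rep(1L, 10), ps = 1, m = 2)  # all 2
#' @export
switch_daughter <- function(parent_type, ps, m) {
  m <- check_count(m, "m", 2L)
  parent_type <- as.integer(parent_type)
  if (anyNA(parent_type) || any(parent_type < 1L) || any(parent_type > m))
    abort_validation("parameter 'parent_type' must contain alleles in 1..%d", m)
  if (anyNA(ps) || any(ps < 0) || any(ps > 1))
    abort_validation("parameter 'ps' must lie in [0, 1]")
  ps <- rep_len(as.numeric(ps), length(parent_type))
  cpp_switch_daughter(parent_type, ps, m)
}

#' One clonal growth round
#'
#' Every cell divides, doubling the population from N to 2N. One daughter
#' inherits the parental mating type faithfully; the other is subject to
#' switching with the parent's `ps` (see [switch_daughter()]). Both
#' daughters inherit the parental switching genotype; with probability
#' `params$nu` each daughter independently mutates its `ps` by a
#' `Normal(0, params$xi)` increment clamped to `[0, 1]`. The pool is then
#' reduced back to N by sampling without replacement, weighted by
#' [survival_weight()] when `cost_timing = "per_growth_round"` and
#' `c > 0`, uniformly otherwise.
#'
#' @param pop A [population()] of `params$N` cells.
#' @param params A [lifecycle_params()] object.
#' @return A [population()] of exactly `params$N` cells.
#' @examples
#' set.seed(1)
#' p <- lifecycle_params(N = 10, m = 2)
#' pop <- initial_population(p, resident_ps = 0.5, mutant_ps = 0.5)
#' growth_round(pop, p)
#' @export
growth_round <- function(pop, params) {
  stopifnot(inherits(pop, "population"), inherits(params, "lifecycle_params"))
  if (length(pop$mating_type) != params$N)
    abort_validation("population size %d does not match N = %d",
                     length(pop$mating_type), params$N)
  weighted <- params$cost_timing == "per_growth_round" && params$c > 0
  out <- cpp_growth_round(pop$mating_type, pop$s_label, pop$ps,
                          params$m, params$c, params$k, weighted,
                          params$nu, params$xi)
  population(out$mating_type, out$s_label, out$ps, params$m)
}

#' One full sexual generation
#'
#' Applies `params$g` clonal growth rounds, then the configured mating
#' regime, then meiotic regrowth to carrying capacity. With
#' `cost_timing = "per_sexual_generation"` the growth rounds sample
#' uniformly and the survival cost is applied once, during the regrowth
#' after mating. If no heterotypic pairs form, the sexual step is skipped:
#' the post-growth population passes through unchanged and a `no_mating`
#' event is logged.
#'
#' @param pop A [population()] of `params$N` cells.
#' @param params A [lifecycle_params()] object.
#' @return A list with elements `population` (the next generation, exactly
#'   `params$N` cells) and `events` (a list with logical `no_mating` and an
#'   integer vector `extinct_types` of allele indices absent afterwards).
#' @examples
#' set.seed(1)
#' p <- lifecycle_params(N = 20, m = 2, g = 2)
#' pop <- initial_population(p, resident_ps = 0.1, mutant_ps = 0.1)
#' gen <- sexual_generation(pop, p)
#' gen$events
#' @export
sexual_generation <- function(pop, params) {
  stopifnot(inherits(pop, "population"), inherits(params, "lifecycle_params"))
  for (r in seq_len(params$g)) pop <- growth_round(pop, params)
  result <- mate_pool(pop, params$mating_mode)
  no_mating <- nrow(result$pairs) == 0L
  if (!no_mating) {
    cost <- if (params$cost_timing == "per_sexual_generation" && params$c > 0)
      list(c = params$c, k = params$k) else NULL
    pop <- meiosis_regrow(result, pop, params$N, cost = cost)
  }
  extinct <- which(type_counts(pop) == 0L)
  list(population = pop,
       events = list(no_mating = no_mating, extinct_types = extinct))
}
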