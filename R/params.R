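# Parameter bundle for the alternating clonal/sexual life cycle.

.param_defaults <- list(
  N = 100L,
  m = 2L,
  g = 10L,
  c = 0,
  k = 2,
  q0 = 0.05,
  nu = 0,
  xi = 0.01,
  mating_mode = "exhaustive",
  cost_timing = "per_growth_round",
  seed = 1L
)

.param_types <- c(
  N = "integer", m = "integer", g = "integer",
  c = "numeric", k = "numeric", q0 = "numeric", nu = "numeric", xi = "numeric",
  mating_mode = "character", cost_timing = "character", seed = "integer"
)

abort_validation <- function(...) {
  stop(structure(class = c("switchsim_validation_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}

check_count <- function(x, field, min) {
  if (length(x) != 1L || is.na(x) || x != trunc(x) || x < min)
    abort_validation("parameter '%s' must be a single integer >= %d (got %s)",
                     field, min, paste(format(x), collapse = ","))
  as.integer(x)
}

check_prob <- function(x, field) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
    abort_validation("parameter '%s' must be a single value in [0, 1] (got %s)",
                     field, paste(format(x), collapse = ","))
  as.numeric(x)
}

check_nonneg <- function(x, field) {
  if (length(x) != 1L || is.na(x) || x < 0)
    abort_validation("parameter '%s' must be a single value >= 0 (got %s)",
                     field, paste(format(x), collapse = ","))
  as.numeric(x)
}

check_choice <- function(x, field, choices) {
  if (length(x) != 1L || is.na(x) || !x %in% choices)
    abort_validation("parameter '%s' must be one of {%s} (got '%s')",
                     field, paste(choices, collapse = ", "), paste(x, collapse = ","))
  x
}

#' Life-cycle parameters
#'
#' Bundle of parameters describing a finite haploid population with
#' alternating clonal and sexual phases. Each cell carries a mating-type
#' locus with `m` possible alleles and a switching locus whose genotype sets
#' `ps`, the probability that the non-faithful daughter at a clonal division
#' changes mating type. The population undergoes `g` clonal growth rounds
#' (doubling to 2N, then down-sampling to `N`) before each sexual phase, in
#' which heterotypic pairs form at random, mate, and regrow the population
#' through meiosis.
#'
#' Switching can carry a survival cost `f = 1 - c * ps^k` (see
#' [survival_weight()]), applied either at every clonal growth round
#' (`cost_timing = "per_growth_round"`) or once per sexual generation during
#' the regrowth after mating (`"per_sexual_generation"`, an inbreeding-like
#' cost). The sexual phase can use `mating_mode = "exhaustive"` (homotypic
#' encounters are returned to the pool until no compatible gametes remain)
#' or `"speedy"` (cells that first meet an incompatible partner are removed).
#'
#' @param N Carrying capacity: number of haploid cells (integer >= 2).
#' @param m Number of possible mating-type alleles (integer >= 2).
#' @param g Clonal growth rounds per sexual cycle (integer >= 0).
#' @param c Cost coefficient in `[0, 1]`.
#' @param k Cost-shape exponent (>= 0). `k > 1` accelerating, `k < 1`
#'   decelerating, `k = 0` a fixed cost for any nonzero switching.
#' @param q0 Initial frequency of the mutant switching allele, in `[0, 1]`.
#' @param nu Per-daughter, per-division mutation probability of the
#'   switching rate (continuum-of-alleles model), in `[0, 1]`.
#' @param xi Standard deviation of the normal mutation increment applied to
#'   the switching rate.
#' @param mating_mode `"exhaustive"` or `"speedy"`.
#' @param cost_timing `"per_growth_round"` or `"per_sexual_generation"`.
#' @param seed Base integer RNG seed for experiments.
#'
#' @return An object of class `lifecycle_params` (a named list).
#' @examples
#' p <- lifecycle_params(N = 100, m = 2, g = 10)
#' p$N
#' @export
lifecycle_params <- function(N = 100, m = 2, g = 10, c = 0, k = 2,
                             q0 = 0.05, nu = 0, xi = 0.01,
                             mating_mode = c("exhaustive", "speedy"),
                             cost_timing = c("per_growth_round",
                                             "per_sexual_generation"),
                             seed = 1L) {
  if (length(mating_mode) > 1L) mating_mode <- mating_mode[[1L]]
  if (length(cost_timing) > 1L) cost_timing <- cost_timing[[1L]]
  p <- list(
    N = check_count(N, "N", 2L),
    m = check_count(m, "m", 2L),
    g = check_count(g, "g", 0L),
    c = check_prob(c, "c"),
    k = check_nonneg(k, "k"),
    q0 = check_prob(q0, "q0"),
    nu = check_prob(nu, "nu"),
    xi = check_nonneg(xi, "xi"),
    mating_mode = check_choice(mating_mode, "mating_mode",
                               c("exhaustive", "speedy")),
    cost_timing = check_choice(cost_timing, "cost_timing",
                               c("per_growth_round", "per_sexual_generation")),
    seed = check_count(seed, "seed", 0L)
  )
  structure(p, class = "lifecycle_params")
}

#' @export
print.lifecycle_params <- function(x, ...) {
  cat("Life-cycle parameters\n")
  cat(sprintf("  N = %d cells, m = %d mating types, g = %d growth rounds/cycle\n",
              x$N, x$m, x$g))
  cat(sprintf("  cost: c = %g, k = %g, timing = %s\n", x$c, x$k, x$cost_timing))
  cat(sprintf("  mutant q0 = %g; ps mutation: nu = %g, xi = %g\n",
              x$q0, x$nu, x$xi))
  cat(sprintf("  mating mode = %s, seed = %d\n", x$mating_mode, x$seed))
  invisible(x)
}

# Coerce a character config value to the declared type of a parameter field.
coerce_param <- function(value, field) {
  type <- .param_types[[field]]
  if (type == "character") return(value)
  num <- suppressWarnings(as.numeric(value))
  if (is.na(num))
    abort_validation("parameter '%s' must be numeric (got '%s')", field, value)
  num
}

#' Derive a reproducible per-replicate seed
#'
#' Maps a base seed and a replicate (stream) index to an integer seed below
#' 2^31, so that any replicate of an experiment can be reproduced in
#' isolation with `set.seed(replicate_seed(base, r))`. Grid harnesses give
#' every grid cell a disjoint block of stream indices.
#'
#' @param base Base seed (non-negative integer).
#' @param stream Stream index (non-negative integer; replicate number or a
#'   cell-offset replicate number).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @examples
#' replicate_seed(42, 1:3)
#' @export
replicate_seed <- function(base, stream) {
  m <- 2147483647
  as.integer(((as.numeric(base) %% m) * 48271 + as.numeric(stream) * 16807) %% m)
}
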