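# Replicate-level experiment harnesses.

update_params <- function(params, ...) {
  do.call(lifecycle_params, modifyList(unclass(params), list(...)))
}

#' Estimate the fixation probability of a mutant switching allele
#'
#' For each replicate, a population of residents (switching rate
#' `resident_ps`) receives `round(q0 * N)` mutant cells (label S2, rate
#' `mutant_ps`) and the full life cycle is iterated until the mutant label
#' fixes or is lost. Replicates still segregating after `max_generations`
#' sexual generations are censored: counted, warned about, and excluded
#' from the fixation fraction. Replicate `r` runs under
#' `set.seed(replicate_seed(params$seed, stream_offset + r))`, so any
#' replicate is reproducible in isolation.
#'
#' The difference between the estimate and the neutral expectation `q0`
#' measures the strength of selection on switching: under neutrality
#' (`c = 0` and `mutant_ps == resident_ps`) the fixation probability equals
#' the initial frequency.
#'
#' @param params A [lifecycle_params()] object; `params$q0` sets the
#'   initial mutant frequency.
#' @param resident_ps Switching rate of the resident S1 allele.
#' @param mutant_ps Switching rate of the invading S2 allele.
#' @param replicates Number of independent replicates (>= 1).
#' @param max_generations Cap on sexual generations per replicate; default
#'   `100 * params$N`.
#' @param stream_offset Offset added to replicate stream indices so that
#'   grid harnesses can give each cell a disjoint seed block.
#' @return An object of class `fixation_estimate`: replicate, fixation,
#'   loss and censoring counts, the estimated fixation probability
#'   `q_fix`, its standard error, and a 95% Wilson interval `ci95`.
#' @examples
#' p <- lifecycle_params(N = 30, g = 2, q0 = 0.1, seed = 1)
#' estimate_fixation(p, 0, 0, replicates = 50)
#' @export
estimate_fixation <- function(params, resident_ps = 0, mutant_ps = 0.5,
                              replicates = 1000,
                              max_generations = 100 * params$N,
                              stream_offset = 0) {
  stopifnot(inherits(params, "lifecycle_params"))
  replicates <- check_count(replicates, "replicates", 1L)
  max_generations <- check_count(max_generations, "max_generations", 1L)
  resident_ps <- check_prob(resident_ps, "resident_ps")
  mutant_ps <- check_prob(mutant_ps, "mutant_ps")
  if (params$q0 <= 0)
    abort_validation("parameter 'q0' must be positive for an invasion experiment")
  status <- integer(replicates)
  for (r in seq_len(replicates)) {
    set.seed(replicate_seed(params$seed, stream_offset + r))
    res <- cpp_run_fixation(params$N, params$m, params$g, params$c, params$k,
                            params$q0, params$nu, params$xi,
                            params$mating_mode == "speedy",
                            params$cost_timing == "per_sexual_generation",
                            resident_ps, mutant_ps, max_generations)
    status[r] <- res[[1L]]
  }
  fixations <- sum(status == 1L)
  losses <- sum(status == 0L)
  censored <- sum(status == 2L)
  if (censored > 0.01 * replicates)
    warning(sprintf("%d of %d replicates hit max_generations = %d without absorbing; consider raising the cap",
                    censored, replicates, max_generations))
  n_eff <- replicates - censored
  q_fix <- if (n_eff > 0) fixations / n_eff else NA_real_
  stderr <- if (n_eff > 0) sqrt(q_fix * (1 - q_fix) / n_eff) else NA_real_
  ci95 <- if (n_eff > 0) wilson_interval(fixations, n_eff) else c(NA_real_, NA_real_)
  structure(list(replicates = replicates, fixations = fixations,
                 losses = losses, censored = censored,
                 q_fix = q_fix, stderr = stderr, ci95 = ci95,
                 q0 = params$q0, resident_ps = resident_ps,
                 mutant_ps = mutant_ps),
            class = "fixation_estimate")
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("Fixation estimate: q_fix = %.4f (95%% CI %.4f-%.4f)\n",
              x$q_fix, x$ci95[[1L]], x$ci95[[2L]]))
  cat(sprintf("  %d fixations / %d losses / %d censored of %d replicates\n",
              x$fixations, x$losses, x$censored, x$replicates))
  cat(sprintf("  neutral expectation q0 = %g; mutant ps = %g vs resident %g\n",
              x$q0, x$mutant_ps, x$resident_ps))
  invisible(x)
}

#' Mating-type distortion during clonal growth
#'
#' Runs `rounds` clonal growth rounds (a vegetative bout) in a population
#' of identical switching genotype and records, after every round, the
#' ratio of the rarest to commonest extant mating-type allele and the
#' number of extant types, averaged over replicates. By default no sexual
#' phase occurs; with `include_sex = TRUE` a sexual phase is inserted after
#' every `params$g` rounds.
#'
#' @param params A [lifecycle_params()] object.
#' @param replicates Number of replicate populations.
#' @param rounds Number of clonal growth rounds to run (default `params$g`).
#' @param ps Common switching rate of every cell.
#' @param include_sex Insert a sexual phase every `params$g` rounds?
#' @param keep_replicates Also return the per-replicate ratio matrix
#'   (replicates x rounds + 1), as attribute `"ratio_replicates"`?
#' @return A data frame with columns `round` (0..rounds), `ratio` (mean
#'   rarest/commonest ratio) and `extant_types` (mean extant allele count).
#' @examples
#' p <- lifecycle_params(N = 60, m = 2, g = 10, seed = 1)
#' distortion_timeseries(p, replicates = 10, rounds = 5)
#' @export
distortion_timeseries <- function(params, replicates, rounds = params$g,
                                  ps = 0, include_sex = FALSE,
                                  keep_replicates = FALSE) {
  stopifnot(inherits(params, "lifecycle_params"))
  replicates <- check_count(replicates, "replicates", 1L)
  rounds <- check_count(rounds, "rounds", 1L)
  ps <- check_prob(ps, "ps")
  base <- update_params(params, q0 = 0)
  ratio <- matrix(NA_real_, replicates, rounds + 1L)
  extant <- matrix(NA_real_, replicates, rounds + 1L)
  for (r in seq_len(replicates)) {
    set.seed(replicate_seed(params$seed, r))
    pop <- initial_population(base, resident_ps = ps)
    counts <- type_counts(pop)
    ratio[r, 1L] <- rare_common_ratio(counts)
    extant[r, 1L] <- sum(counts > 0L)
    for (rd in seq_len(rounds)) {
      pop <- growth_round(pop, base)
      if (include_sex && rd %% params$g == 0L) {
        res <- mate_pool(pop, params$mating_mode)
        if (nrow(res$pairs) > 0L) {
          cost <- if (params$cost_timing == "per_sexual_generation" && params$c > 0)
            list(c = params$c, k = params$k) else NULL
          pop <- meiosis_regrow(res, pop, params$N, cost = cost)
        }
      }
      counts <- type_counts(pop)
      ratio[r, rd + 1L] <- rare_common_ratio(counts)
      extant[r, rd + 1L] <- sum(counts > 0L)
    }
  }
  out <- data.frame(round = 0:rounds,
                    ratio = colMeans(ratio),
                    extant_types = colMeans(extant))
  if (keep_replicates) attr(out, "ratio_replicates") <- ratio
  out
}

#' Extinction trajectory of the mutant switching allele
#'
#' For each initial frequency in `q0_values`, runs a single vegetative bout
#' of `rounds` clonal growth rounds (no sexual phase) and reports the
#' fraction of replicates in which the S2 label is absent by each round.
#' Curves are non-decreasing in the round index (extinction is absorbing)
#' and weakly higher for smaller `q0`.
#'
#' @param params A [lifecycle_params()] object.
#' @param q0_values Initial mutant frequencies, each in (0, 1).
#' @param replicates Replicates per initial frequency.
#' @param rounds Length of the vegetative bout (default `params$g`).
#' @param resident_ps,mutant_ps Switching rates of the two S alleles.
#' @return A data frame with columns `q0`, `round` and `extinct_fraction`.
#' @examples
#' p <- lifecycle_params(N = 40, g = 20, seed = 1)
#' extinction_trajectory(p, c(0.05, 0.2), replicates = 20)
#' @export
extinction_trajectory <- function(params, q0_values, replicates,
                                  rounds = params$g,
                                  resident_ps = 0, mutant_ps = 0.5) {
  stopifnot(inherits(params, "lifecycle_params"))
  replicates <- check_count(replicates, "replicates", 1L)
  rounds <- check_count(rounds, "rounds", 1L)
  if (length(q0_values) == 0L || any(q0_values <= 0) || any(q0_values >= 1))
    abort_validation("parameter 'q0_values' must lie in (0, 1)")
  out <- vector("list", length(q0_values))
  for (qi in seq_along(q0_values)) {
    base <- update_params(params, q0 = q0_values[[qi]])
    extinct_round <- rep(Inf, replicates)
    for (r in seq_len(replicates)) {
      set.seed(replicate_seed(params$seed, (qi - 1L) * replicates + r))
      pop <- initial_population(base, resident_ps, mutant_ps)
      for (rd in seq_len(rounds)) {
        pop <- growth_round(pop, base)
        freq <- s2_frequency(pop)
        if (freq == 0) { extinct_round[r] <- rd; break }
        if (freq == 1) break  # fixed: can never go extinct
      }
    }
    frac <- vapply(0:rounds, function(rd) mean(extinct_round <= rd), 0)
    out[[qi]] <- data.frame(q0 = q0_values[[qi]], round = 0:rounds,
                            extinct_fraction = frac)
  }
  do.call(rbind, out)
}

#' Cost-benefit invasion grid
#'
#' Runs [estimate_fixation()] for every combination of mutant switching
#' rate and cost coefficient, and reports the signed selection surface
#' `delta_q = q_fix - q0` relative to the neutral expectation. Positive
#' values mean switching is selectively favoured. Every grid cell uses a
#' disjoint block of replicate seed streams, so cells are independently
#' reproducible.
#'
#' @param params A [lifecycle_params()] object; `k` and `cost_timing` come
#'   from here.
#' @param ps_values Mutant switching rates (grid rows).
#' @param c_values Cost coefficients (grid columns).
#' @param replicates Replicates per grid cell.
#' @param resident_ps Switching rate of the resident allele.
#' @param max_generations Cap per replicate; default `100 * params$N`.
#' @return A data frame with one row per grid cell: `ps`, `c`, `q_fix`,
#'   `delta_q`, counts, and the 95% Wilson bounds.
#' @examples
#' p <- lifecycle_params(N = 30, g = 2, q0 = 0.1, seed = 1)
#' cost_grid(p, ps_values = c(0, 0.5), c_values = 0, replicates = 30)
#' @export
cost_grid <- function(params, ps_values, c_values, replicates = 200,
                      resident_ps = 0, max_generations = 100 * params$N) {
  stopifnot(inherits(params, "lifecycle_params"))
  if (length(ps_values) == 0L || length(c_values) == 0L)
    abort_validation("parameters 'ps_values' and 'c_values' must be non-empty")
  cells <- expand.grid(ps = ps_values, c = c_values, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- update_params(params, c = cells$c[[ci]])
    est <- estimate_fixation(cell, resident_ps = resident_ps,
                             mutant_ps = cells$ps[[ci]],
                             replicates = replicates,
                             max_generations = max_generations,
                             stream_offset = (ci - 1L) * replicates)
    rows[[ci]] <- data.frame(ps = cells$ps[[ci]], c = cells$c[[ci]],
                             q_fix = est$q_fix, delta_q = est$q_fix - est$q0,
                             fixations = est$fixations, losses = est$losses,
                             censored = est$censored,
                             ci_lower = est$ci95[[1L]],
                             ci_upper = est$ci95[[2L]])
  }
  do.call(rbind, rows)
}

#' Continuum-of-alleles evolution of the switching rate
#'
#' Evolves a population whose per-cell switching rate mutates at each
#' division with probability `params$nu` by a `Normal(0, params$xi)`
#' increment (clamped to `[0, 1]`). The population-mean rate is recorded
#' after every sexual generation; after `burn_in` generations, individual
#' `ps` values are sampled from the population every `sample_every`
#' generations, across replicate runs, until `sample_count` values have
#' been accumulated. The stationary shape of those samples reflects
#' mutation-selection balance between drift toward switching (rare-type
#' advantage at sex) and the survival cost during growth.
#'
#' A simple stationarity diagnostic compares the mean `ps` in the first and
#' second halves of the post-burn-in window; a difference above two pooled
#' standard errors flags (with a warning) that the burn-in may be too
#' short.
#'
#' @param params A [lifecycle_params()] object with `nu > 0`.
#' @param total_generations Sexual generations per run.
#' @param burn_in Generations discarded before sampling
#'   (< `total_generations`).
#' @param sample_count Target number of individual `ps` samples.
#' @param init_ps Initial switching rate of every cell.
#' @param sample_every Sampling stride (generations) after burn-in.
#' @param runs Number of replicate runs; default just enough to reach
#'   `sample_count`.
#' @return A list of class `continuum_run`: `mean_ps` (data frame with
#'   `run`, `generation`, `mean_ps`), `samples` (numeric vector),
#'   `stationary` (logical) and `diagnostic`.
#' @examples
#' p <- lifecycle_params(N = 40, g = 2, nu = 1e-3, xi = 0.05, seed = 1)
#' cr <- continuum_run(p, total_generations = 40, burn_in = 20,
#'                     sample_count = 200)
#' head(cr$mean_ps)
#' @export
continuum_run <- function(params, total_generations, burn_in = 5000,
                          sample_count = 100000, init_ps = 0.2,
                          sample_every = 10, runs = NULL) {
  stopifnot(inherits(params, "lifecycle_params"))
  total_generations <- check_count(total_generations, "total_generations", 2L)
  burn_in <- check_count(burn_in, "burn_in", 0L)
  sample_count <- check_count(sample_count, "sample_count", 1L)
  sample_every <- check_count(sample_every, "sample_every", 1L)
  init_ps <- check_prob(init_ps, "init_ps")
  if (params$nu <= 0)
    abort_validation("parameter 'nu' must be positive for a continuum-of-alleles run")
  if (burn_in >= total_generations)
    abort_validation("parameter 'burn_in' must be smaller than total_generations")
  per_run <- params$N * (((total_generations - burn_in - 1L) %/% sample_every) + 1L)
  if (is.null(runs)) runs <- max(1L, ceiling(sample_count / per_run))
  runs <- check_count(runs, "runs", 1L)
  samples <- numeric(0)
  series <- vector("list", runs)
  for (r in seq_len(runs)) {
    set.seed(replicate_seed(params$seed, r))
    need <- max(0L, sample_count - length(samples))
    res <- cpp_run_continuum(params$N, params$m, params$g, params$c, params$k,
                             params$nu, params$xi,
                             params$mating_mode == "speedy",
                             params$cost_timing == "per_sexual_generation",
                             init_ps, total_generations, burn_in,
                             sample_every, need)
    samples <- c(samples, res$samples)
    series[[r]] <- data.frame(run = r,
                              generation = seq_len(total_generations),
                              mean_ps = res$mean_ps)
  }
  mean_ps <- do.call(rbind, series)
  post <- mean_ps[mean_ps$generation > burn_in, ]
  mid <- burn_in + (total_generations - burn_in) / 2
  h1 <- post$mean_ps[post$generation <= mid]
  h2 <- post$mean_ps[post$generation > mid]
  se <- sqrt(sd(h1)^2 / length(h1) + sd(h2)^2 / length(h2))
  stationary <- is.finite(se) && abs(mean(h1) - mean(h2)) < 2 * se ||
    isTRUE(all.equal(mean(h1), mean(h2)))
  if (!stationary)
    warning("mean ps still drifting between the two halves of the post-burn-in window; consider a longer burn-in")
  structure(list(mean_ps = mean_ps, samples = samples, stationary = stationary,
                 diagnostic = list(first_half = mean(h1), second_half = mean(h2),
                                   pooled_se = se)),
            class = "continuum_run")
}

#' @export
print.continuum_run <- function(x, ...) {
  cat(sprintf("Continuum-of-alleles run: %d generations x %d run(s)\n",
              max(x$mean_ps$generation), max(x$mean_ps$run)))
  cat(sprintf("  %d ps samples; long-run mean ps = %.4f; stationary: %s\n",
              length(x$samples), mean(x$samples), x$stationary))
  invisible(x)
}

#' Proportion of cells that find a mate
#'
#' For each number of mating types in `m_values`, runs the vegetative phase
#' (`params$g` growth rounds) and one mating phase, and reports the mean
#' proportion of cells that end up in a mated pair,
#' `2 * pairs / pool size`. Under exhaustive mating this proportion
#' increases with the number of mating types, because a common type can
#' still mate with all the other types.
#'
#' @param params A [lifecycle_params()] object.
#' @param m_values Numbers of mating types to compare (each >= 2).
#' @param replicates Replicates per value of `m`.
#' @param ps Common switching rate of every cell.
#' @return A data frame with columns `m` and `mated_fraction`.
#' @examples
#' p <- lifecycle_params(N = 24, g = 2, seed = 1)
#' mated_fraction(p, m_values = c(2, 4), replicates = 10)
#' @export
mated_fraction <- function(params, m_values, replicates, ps = 0) {
  stopifnot(inherits(params, "lifecycle_params"))
  replicates <- check_count(replicates, "replicates", 1L)
  ps <- check_prob(ps, "ps")
  if (length(m_values) == 0L || any(m_values < 2))
    abort_validation("parameter 'm_values' must contain integers >= 2")
  frac <- numeric(length(m_values))
  for (mi in seq_along(m_values)) {
    base <- update_params(params, m = m_values[[mi]], q0 = 0)
    tot <- 0
    for (r in seq_len(replicates)) {
      set.seed(replicate_seed(params$seed, (mi - 1L) * replicates + r))
      pop <- initial_population(base, resident_ps = ps)
      for (rd in seq_len(base$g)) pop <- growth_round(pop, base)
      res <- mate_pool(pop, base$mating_mode)
      tot <- tot + 2 * nrow(res$pairs) / res$pool_size
    }
    frac[mi] <- tot / replicates
  }
  data.frame(m = as.integer(m_values), mated_fraction = frac)
}
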