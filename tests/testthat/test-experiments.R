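# Replicate harnesses: neutrality, trajectories, grids, continuum runs.

test_that("a neutral mutant fixes at its initial frequency", {
  # strongest end-to-end check of the life cycle: any (N, g, m) with c = 0
  # and equal switching rates must reproduce q_fix = q0
  p <- base_params(N = 50, m = 2, g = 4, q0 = 0.1, seed = 19)
  est <- estimate_fixation(p, resident_ps = 0.2, mutant_ps = 0.2,
                           replicates = 3000)
  expect_identical(est$fixations + est$losses + est$censored, est$replicates)
  se <- sqrt(0.1 * 0.9 / est$replicates)
  expect_lt(abs(est$q_fix - 0.1), 3 * se)
  expect_true(est$ci95[[1]] <= est$q_fix && est$q_fix <= est$ci95[[2]])
})

test_that("an already-fixed mutant reports q_fix = 1 with zero variance", {
  p <- base_params(N = 20, g = 1, q0 = 1)
  est <- estimate_fixation(p, 0, 0.5, replicates = 25)
  expect_identical(est$fixations, 25L)
  expect_equal(est$q_fix, 1)
  expect_equal(est$stderr, 0)
})

test_that("package fixation estimates agree with a plain-R reimplementation", {
  # same stochastic process, independently coded: compare estimates at
  # small N (not trajectories, since the RNG call sequences differ)
  N <- 12; m <- 2; g <- 2; q0 <- 0.25
  reps <- 400
  set.seed(101)
  oracle <- vapply(seq_len(reps), function(r)
    oracle_fixation_once(N, m, g, q0, 0, 0.5), 0L)
  expect_true(all(oracle != 2L))
  q_oracle <- mean(oracle)
  p <- base_params(N = N, m = m, g = g, q0 = q0, seed = 55)
  est <- estimate_fixation(p, 0, 0.5, replicates = reps)
  pooled_se <- sqrt(q_oracle * (1 - q_oracle) / reps +
                    est$q_fix * (1 - est$q_fix) / reps)
  expect_lt(abs(est$q_fix - q_oracle), 4 * pooled_se)
})

test_that("replicates that outlive the generation cap are censored with a warning", {
  # g = 0 keeps both S alleles segregating for many sexual generations, so
  # a cap of 1 censors most replicates
  p <- base_params(N = 50, g = 0, q0 = 0.5, seed = 23)
  expect_warning(
    est <- estimate_fixation(p, 0.1, 0.1, replicates = 40, max_generations = 1),
    "max_generations")
  expect_identical(est$fixations + est$losses + est$censored, 40L)
  expect_gt(est$censored, 0L)
})

test_that("distortion starts at parity and grows over clonal rounds", {
  p <- base_params(N = 100, m = 2, g = 40, seed = 3)
  ts <- distortion_timeseries(p, replicates = 60, rounds = 40, ps = 0)
  expect_equal(ts$ratio[[1]], 1)   # equal initial counts
  expect_equal(ts$extant_types[[1]], 2)
  expect_lt(ts$ratio[ts$round == 40], ts$ratio[ts$round == 5])
  # strong switching holds the ratio near parity
  ts_sw <- distortion_timeseries(p, replicates = 60, rounds = 40, ps = 1)
  expect_gt(ts_sw$ratio[ts_sw$round == 40], 0.8)
  expect_gt(ts_sw$ratio[ts_sw$round == 40], ts$ratio[ts$round == 40])
})

test_that("extinction curves are cumulative and ordered by initial frequency", {
  p <- base_params(N = 40, g = 60, seed = 13)
  tr <- extinction_trajectory(p, q0_values = c(0.05, 0.25), replicates = 150,
                              rounds = 60)
  for (q0 in c(0.05, 0.25)) {
    curve <- tr$extinct_fraction[tr$q0 == q0]
    expect_true(all(diff(curve) >= 0))   # extinction is absorbing
    expect_equal(curve[[1]], 0)
  }
  lo <- tr$extinct_fraction[tr$q0 == 0.05]
  hi <- tr$extinct_fraction[tr$q0 == 0.25]
  expect_gt(lo[[61]], hi[[61]])
  expect_true(all(lo - hi >= -0.05))
})

test_that("the cost grid reduces to the plain estimate at c = 0 and is flat for a null mutant", {
  p <- base_params(N = 30, g = 2, q0 = 0.1, seed = 77)
  grid <- cost_grid(p, ps_values = 0.5, c_values = 0, replicates = 120)
  est <- estimate_fixation(p, 0, 0.5, replicates = 120, stream_offset = 0)
  expect_identical(grid$fixations, est$fixations)  # same seeds, same path
  expect_equal(grid$q_fix, est$q_fix)
  expect_equal(grid$delta_q, est$q_fix - 0.1)

  # a mutant identical to the resident is neutral at any cost that also
  # burdens the resident equally (here: ps = 0 pays no rate cost at all)
  grid0 <- cost_grid(p, ps_values = 0, c_values = c(0, 0.2),
                     replicates = 400)
  for (dq in grid0$delta_q)
    expect_lt(abs(dq), 3 * sqrt(0.1 * 0.9 / 400))
})

test_that("fixation falls as costs rise", {
  p <- base_params(N = 40, g = 6, q0 = 0.1, seed = 31, k = 1)
  grid <- cost_grid(p, ps_values = 0.5, c_values = c(0, 0.25),
                    replicates = 500)
  q_free <- grid$q_fix[grid$c == 0]
  q_cost <- grid$q_fix[grid$c == 0.25]
  se <- sqrt(q_free * (1 - q_free) / 500 + q_cost * (1 - q_cost) / 500 + 1e-12)
  expect_gt(q_free - q_cost, 2 * se)
})

test_that("continuum runs require mutation and stay put without it", {
  p <- base_params(N = 40, g = 2, nu = 0)
  expect_error(continuum_run(p, 20, burn_in = 5, sample_count = 10), "'nu'")
  p2 <- base_params(N = 40, g = 2, nu = 1e-3, xi = 0.05, seed = 2)
  cr <- continuum_run(p2, total_generations = 30, burn_in = 10,
                      sample_count = 100, init_ps = 0.4)
  expect_true(all(cr$samples >= 0 & cr$samples <= 1))
  expect_identical(nrow(cr$mean_ps), 30L * max(cr$mean_ps$run))
  expect_gte(length(cr$samples), 100L)
  # determinism: same manifest, same numbers
  cr2 <- continuum_run(p2, total_generations = 30, burn_in = 10,
                       sample_count = 100, init_ps = 0.4)
  expect_identical(cr$mean_ps$mean_ps, cr2$mean_ps$mean_ps)
  expect_identical(cr$samples, cr2$samples)
})

test_that("everyone mates with two balanced types; more types mate more", {
  p <- base_params(N = 24, g = 0, seed = 6)
  mf <- mated_fraction(p, m_values = 2, replicates = 10)
  expect_equal(mf$mated_fraction, 1)   # equal counts, exhaustive, g = 0
  p2 <- base_params(N = 120, g = 15, seed = 6)
  mf2 <- suppressWarnings(
    mated_fraction(p2, m_values = c(2, 8), replicates = 120))
  expect_gt(mf2$mated_fraction[mf2$m == 8], mf2$mated_fraction[mf2$m == 2])
})
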