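# Clonal growth: survival cost, switching, and the 2N -> N reduction.

test_that("survival weight follows the closed form, including k = 0", {
  expect_equal(survival_weight(0.5, c = 0.01, k = 2), 0.9975)
  expect_equal(survival_weight(0, c = 0.9, k = 2), 1)
  expect_equal(survival_weight(0.3, c = 0.2, k = 0), 0.8)
  expect_equal(survival_weight(1, c = 1, k = 1), 0)
  expect_error(survival_weight(1.5, c = 0.1, k = 1), "'ps'")
  expect_error(survival_weight(0.5, c = 2, k = 1), "'c'")
})

test_that("survival weight is monotone in ps (k > 0) and in c", {
  ps <- seq(0, 1, by = 0.05)
  for (k in c(0.5, 1, 2, 3)) {
    f <- survival_weight(ps, c = 0.3, k = k)
    expect_true(all(diff(f) <= 1e-12), info = sprintf("k = %g", k))
    expect_true(all(f >= 0 & f <= 1))
  }
  for (p in c(0, 0.2, 1)) {
    f_by_c <- vapply(c(0, 0.3, 0.7, 1), function(cc)
      survival_weight(p, c = cc, k = 2), 0)
    expect_true(all(diff(f_by_c) <= 1e-12))
  }
})

test_that("daughter switching keeps or resamples the parental allele as specified", {
  set.seed(7)
  expect_true(all(switch_daughter(rep(1L, 200), ps = 0, m = 2) == 1L))
  expect_true(all(switch_daughter(rep(1L, 200), ps = 1, m = 2) == 2L))
  # ps = 0.5, m = 3: expect (parent 1/2, each other type 1/4)
  draws <- switch_daughter(rep(2L, 1e5), ps = 0.5, m = 3)
  obs <- tabulate(draws, 3)
  chisq <- sum((obs - 1e5 * c(0.25, 0.5, 0.25))^2 / (1e5 * c(0.25, 0.5, 0.25)))
  expect_lt(chisq, qchisq(0.999, df = 2))
})

test_that("a costless growth round is closed under identical genotypes", {
  p <- base_params(N = 4, g = 1)
  pop <- make_pop(c(4, 0), ps = 0)
  set.seed(1)
  out <- growth_round(pop, p)
  expect_identical(out$mating_type, rep(1L, 4))
  expect_identical(out$ps, rep(0, 4))
})

test_that("the 2N -> N reduction is hypergeometric sampling without replacement", {
  # N = 2 cells (M1, ps = 1): daughter pool is always {M1, M1, M2, M2};
  # the number of M2 cells kept is Hypergeometric(4, 2, 2): 1/6, 4/6, 1/6.
  p <- base_params(N = 2, m = 2)
  pop <- make_pop(c(2, 0), ps = 1)
  set.seed(99)
  reps <- 6000
  n2 <- integer(reps)
  for (r in seq_len(reps)) {
    out <- growth_round(pop, p)
    n2[r] <- sum(out$mating_type == 2L)
  }
  obs <- tabulate(n2 + 1L, 3L)
  expected <- reps * c(1, 4, 1) / 6
  chisq <- sum((obs - expected)^2 / expected)
  expect_lt(chisq, qchisq(0.999, df = 2))
})

test_that("without ps mutation no new switching rates ever appear", {
  p <- base_params(N = 30, nu = 0)
  pop <- population(rep_len(1:2, 30), rep(1L, 30),
                    rep_len(c(0.1, 0.37, 0.9), 30), m = 2)
  set.seed(3)
  for (i in 1:20) {
    pop <- growth_round(pop, p)
    expect_true(all(pop$ps %in% c(0.1, 0.37, 0.9)))
    expect_length(pop$ps, 30L)
  }
})

test_that("mutated switching rates stay inside [0, 1]", {
  p <- base_params(N = 40, nu = 1, xi = 0.8)
  pop <- make_pop(c(20, 20), ps = 0.5)
  set.seed(8)
  for (i in 1:10) {
    pop <- growth_round(pop, p)
    expect_true(all(pop$ps >= 0 & pop$ps <= 1))
  }
})

test_that("population size is conserved by growth and by a full sexual generation", {
  set.seed(21)
  for (i in 1:10) {
    N <- sample(c(10, 24, 61), 1)
    m <- sample(2:4, 1)
    p <- suppressWarnings(base_params(N = N, m = m, g = sample(0:3, 1)))
    pop <- suppressWarnings(initial_population(p, resident_ps = runif(1),
                                               mutant_ps = runif(1)))
    out <- sexual_generation(pop, p)
    expect_length(out$population$mating_type, N)
    expect_length(out$population$ps, N)
    g1 <- growth_round(pop, p)
    expect_length(g1$mating_type, N)
  }
})

test_that("a fully degenerate cost is reported as an error", {
  p <- base_params(N = 10, c = 1, k = 2)
  pop <- make_pop(c(5, 5), ps = 1)
  set.seed(1)
  expect_error(growth_round(pop, p), "degenerate cost")
})
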