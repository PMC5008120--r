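# Random heterotypic pair formation, both pool regimes.

test_that("two-type exhaustive mating always pairs the rarer type completely", {
  set.seed(5)
  for (case in 1:25) {
    n1 <- sample(0:40, 1)
    n2 <- sample(0:40, 1)
    if (n1 + n2 == 0) n1 <- 1
    res <- mate_exhaustive(make_pop(c(n1, n2)))
    expect_identical(nrow(res$pairs), min(n1, n2))
    expect_identical(res$removed, 0L)
    expect_identical(res$unmated, abs(n1 - n2))
  }
})

test_that("monotypic and tiny pools behave as the process dictates", {
  set.seed(2)
  res <- mate_exhaustive(make_pop(c(8, 0)))
  expect_identical(nrow(res$pairs), 0L)
  expect_identical(res$unmated, 8L)
  # three types, one cell each: any first draw is heterotypic
  for (i in 1:20) {
    res <- mate_exhaustive(make_pop(c(1, 1, 1)))
    expect_identical(nrow(res$pairs), 1L)
    expect_identical(res$unmated, 1L)
  }
  # speedy: (1,1) must pair; (2,0) must be wiped out
  expect_identical(nrow(mate_speedy(make_pop(c(1, 1)))$pairs), 1L)
  res <- mate_speedy(make_pop(c(2, 0)))
  expect_identical(nrow(res$pairs), 0L)
  expect_identical(res$removed, 2L)
})

test_that("every recorded pair is heterotypic and accounting balances", {
  set.seed(11)
  for (case in 1:30) {
    m <- sample(2:5, 1)
    counts <- rpois(m, 4)
    if (sum(counts) == 0) counts[1] <- 1
    pop <- make_pop(counts)
    for (speedy in c(FALSE, TRUE)) {
      res <- if (speedy) mate_speedy(pop) else mate_exhaustive(pop)
      if (nrow(res$pairs) > 0) {
        t1 <- pop$mating_type[res$pairs[, 1]]
        t2 <- pop$mating_type[res$pairs[, 2]]
        expect_true(all(t1 != t2))
      }
      expect_identical(2L * nrow(res$pairs) + res$unmated + res$removed,
                       sum(counts))
      if (!speedy) expect_identical(res$removed, 0L)
    }
  }
})

test_that("speedy mating on counts (2,2) forms two pairs with probability 2/3", {
  set.seed(4)
  tab <- switchsim:::cpp_mate_pair_count_sim(c(2L, 2L), TRUE, 20000L)
  p2 <- tab[[3]] / sum(tab)
  expect_identical(tab[[2]], 0L)  # one pair is impossible
  expect_lt(abs(p2 - 2 / 3), 3 * sqrt(2 / 9 / 20000) + 1e-9)
})

test_that("empirical pair counts match exact enumeration on small pools", {
  set.seed(14)
  cases <- list(c(2, 2), c(1, 3), c(2, 4), c(1, 1, 2), c(2, 2, 2))
  for (counts in cases) {
    for (speedy in c(FALSE, TRUE)) {
      tab <- switchsim:::cpp_mate_pair_count_sim(as.integer(counts), speedy, 2e4L)
      exact <- oracle_pair_dist(counts, speedy)
      expect_lt(tv_distance(as.numeric(tab), exact), 0.02)
    }
  }
})
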