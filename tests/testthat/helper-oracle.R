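# Independent oracles, kept deliberately separate from the package's engine:
# an exact enumeration of the sequential pair-formation process, and a plain
# interpreted re-implementation of the full life cycle for small populations.

# Exact distribution of the total number of pairs formed by the sequential
# drawing process, given per-type counts. Returns a vector p where p[i] is
# the probability of forming i - 1 pairs.
oracle_pair_dist <- function(counts, speedy) {
  memo <- new.env(parent = emptyenv())
  rec <- function(cnt) {
    cnt <- sort(cnt[cnt > 0])
    key <- paste(c(speedy, cnt), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    n <- sum(cnt)
    t <- length(cnt)
    if (n < 2 || (!speedy && t <= 1)) {
      res <- 1  # zero further pairs with probability 1
    } else {
      dist <- numeric(n %/% 2 + 1)
      if (speedy) {
        total <- choose(n, 2)
        for (i in seq_len(t)) {
          w_homo <- choose(cnt[i], 2) / total
          if (w_homo > 0) {               # both cells removed, no pair
            sub <- cnt; sub[i] <- sub[i] - 2L
            d <- rec(sub)
            dist[seq_along(d)] <- dist[seq_along(d)] + w_homo * d
          }
          if (i < t) for (j in (i + 1):t) {
            w <- cnt[i] * cnt[j] / total  # heterotypic pair
            sub <- cnt; sub[i] <- sub[i] - 1L; sub[j] <- sub[j] - 1L
            d <- rec(sub)
            dist[1 + seq_along(d)] <- dist[1 + seq_along(d)] + w * d
          }
        }
      } else {
        # homotypic draws change nothing, so condition on the next
        # heterotypic draw
        total_het <- 0
        for (i in seq_len(t - 1)) for (j in (i + 1):t)
          total_het <- total_het + cnt[i] * cnt[j]
        for (i in seq_len(t - 1)) for (j in (i + 1):t) {
          w <- cnt[i] * cnt[j] / total_het
          sub <- cnt; sub[i] <- sub[i] - 1L; sub[j] <- sub[j] - 1L
          d <- rec(sub)
          dist[1 + seq_along(d)] <- dist[1 + seq_along(d)] + w * d
        }
      }
      res <- dist[seq_len(max(which(dist > 0)))]
    }
    memo[[key]] <- res
    res
  }
  rec(as.integer(counts))
}

resample <- function(x, ...) x[sample.int(length(x), ...)]

# Plain-R replicate of the full life cycle (no costs, exhaustive mating),
# returning 1 on mutant fixation, 0 on loss, 2 if censored.
oracle_fixation_once <- function(N, m, g, q0, resident_ps, mutant_ps,
                                 max_generations = 10000) {
  mt <- rep_len(seq_len(m), N)
  sl <- rep(1L, N)
  ps <- rep(resident_ps, N)
  idx <- sample.int(N, round(q0 * N))
  sl[idx] <- 2L
  ps[idx] <- mutant_ps
  absorbed <- function(sl) {
    f <- mean(sl == 2L)
    if (f == 0) 0L else if (f == 1) 1L else -1L
  }
  for (gen in seq_len(max_generations)) {
    for (r in seq_len(g)) {
      d_mt <- c(mt, mt)
      for (i in seq_len(N))
        if (runif(1) < ps[i]) d_mt[N + i] <- resample(seq_len(m)[-mt[i]], 1)
      keep <- sample.int(2L * N, N)
      mt <- d_mt[keep]
      sl <- c(sl, sl)[keep]
      ps <- c(ps, ps)[keep]
      st <- absorbed(sl)
      if (st >= 0L) return(st)
    }
    pool <- seq_len(N)
    pa <- integer(0)
    pb <- integer(0)
    while (length(pool) >= 2 && length(unique(mt[pool])) > 1) {
      two <- resample(pool, 2)
      if (mt[two[[1]]] != mt[two[[2]]]) {
        pa <- c(pa, two[[1]])
        pb <- c(pb, two[[2]])
        pool <- setdiff(pool, two)
      }
    }
    if (length(pa) > 0) {
      pi <- sample.int(length(pa), N, replace = TRUE)
      mpar <- ifelse(runif(N) < 0.5, pa[pi], pb[pi])
      spar <- ifelse(runif(N) < 0.5, pa[pi], pb[pi])
      mt <- mt[mpar]
      new_sl <- sl[spar]
      new_ps <- ps[spar]
      sl <- new_sl
      ps <- new_ps
      st <- absorbed(sl)
      if (st >= 0L) return(st)
    }
  }
  2L
}

# Total-variation distance between an empirical pair-count table
# (index i = count of realizations with i - 1 pairs) and an exact
# distribution.
tv_distance <- function(tab, exact) {
  emp <- tab / sum(tab)
  len <- max(length(emp), length(exact))
  emp <- c(emp, rep(0, len - length(emp)))
  exact <- c(exact, rep(0, len - length(exact)))
  sum(abs(emp - exact)) / 2
}
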