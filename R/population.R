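# Population state: three parallel per-cell vectors plus the allele-set size.

#' Construct a population state
#'
#' A population is a set of `length(mating_type)` haploid cells, each with a
#' mating-type allele (integer in `1..m`), a switching-genotype label
#' (`1` = resident S1, `2` = mutant S2), and a switching rate `ps` in
#' `[0, 1]`.
#'
#' @param mating_type Integer vector of mating-type alleles in `1..m`.
#' @param s_label Integer vector of switching-genotype labels.
#' @param ps Numeric vector of per-cell switching rates in `[0, 1]`.
#' @param m Number of possible mating-type alleles.
#' @return An object of class `population`.
#' @examples
#' population(c(1L, 2L, 1L), c(1L, 1L, 2L), c(0, 0, 0.5), m = 2)
#' @export
population <- function(mating_type, s_label, ps, m) {
  m <- check_count(m, "m", 2L)
  mating_type <- as.integer(mating_type)
  s_label <- as.integer(s_label)
  ps <- as.numeric(ps)
  n <- length(mating_type)
  if (length(s_label) != n || length(ps) != n)
    abort_validation("population vectors must have identical length (got %d, %d, %d)",
                     n, length(s_label), length(ps))
  if (n > 0 && (anyNA(mating_type) || min(mating_type) < 1L || max(mating_type) > m))
    abort_validation("parameter 'mating_type' must contain alleles in 1..%d", m)
  if (n > 0 && (anyNA(ps) || min(ps) < 0 || max(ps) > 1))
    abort_validation("parameter 'ps' must lie in [0, 1]")
  structure(list(mating_type = mating_type, s_label = s_label, ps = ps, m = m),
            class = "population")
}

#' Initial population for an invasion experiment
#'
#' Cells receive mating types as evenly as divisibility allows (cell `i`
#' gets allele `i mod m`), and `round(q0 * N)` cells chosen uniformly at
#' random (without regard to mating type) carry the mutant switching allele
#' S2 with rate `mutant_ps`; the rest are residents (S1, `resident_ps`).
#'
#' @param params A [lifecycle_params()] object.
#' @param resident_ps Switching rate of the resident S1 allele.
#' @param mutant_ps Switching rate of the mutant S2 allele.
#' @return A [population()] of `params$N` cells.
#' @examples
#' set.seed(1)
#' pop <- initial_population(lifecycle_params(N = 20), 0, 0.5)
#' table(pop$mating_type)
#' @export
initial_population <- function(params, resident_ps = 0, mutant_ps = resident_ps) {
  stopifnot(inherits(params, "lifecycle_params"))
  resident_ps <- check_prob(resident_ps, "resident_ps")
  mutant_ps <- check_prob(mutant_ps, "mutant_ps")
  N <- params$N
  m <- params$m
  if (N %% m != 0L)
    warning(sprintf("N = %d is not divisible by m = %d; initial mating-type counts are only approximately equal", N, m))
  mt <- (seq_len(N) - 1L) %% m + 1L
  sl <- rep(1L, N)
  ps <- rep(resident_ps, N)
  nmut <- round(params$q0 * N)
  if (nmut > 0) {
    idx <- sample.int(N, nmut)
    sl[idx] <- 2L
    ps[idx] <- mutant_ps
  }
  population(mt, sl, ps, m)
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Population of %d cells, %d possible mating types\n",
              length(x$mating_type), x$m))
  cat("  type counts:",
      paste(sprintf("M%d=%d", seq_len(x$m), type_counts(x)), collapse = " "), "\n")
  cat(sprintf("  mutant (S2) frequency: %.4f; mean ps: %.4f\n",
              s2_frequency(x), mean(x$ps)))
  invisible(x)
}

#' Per-allele mating-type counts
#'
#' @param pop A [population()].
#' @return Integer vector of length `pop$m` with the count of each allele.
#' @examples
#' pop <- population(c(1L, 1L, 2L), c(1L, 1L, 1L), c(0, 0, 0), m = 3)
#' type_counts(pop)
#' @export
type_counts <- function(pop) {
  tabulate(pop$mating_type, nbins = pop$m)
}

#' Frequency of the mutant switching label
#'
#' @param pop A [population()].
#' @return Proportion of cells carrying the S2 label.
#' @examples
#' pop <- population(c(1L, 2L), c(1L, 2L), c(0, 0.5), m = 2)
#' s2_frequency(pop)
#' @export
s2_frequency <- function(pop) {
  if (length(pop$s_label) == 0L) return(NA_real_)
  mean(pop$s_label == 2L)
}
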