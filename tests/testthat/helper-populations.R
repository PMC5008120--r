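# Small populations built from type counts.

make_pop <- function(counts, ps = 0, s_label = 1L, m = length(counts)) {
  mt <- rep(seq_along(counts), counts)
  n <- length(mt)
  population(mt, rep_len(s_label, n), rep_len(ps, n), m = m)
}

base_params <- function(...) {
  do.call(lifecycle_params, modifyList(
    list(N = 60L, m = 2L, g = 5L, c = 0, k = 2, q0 = 0.1, seed = 42L),
    list(...)))
}
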