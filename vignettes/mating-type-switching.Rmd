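---
title: "Modelling the evolution of mating-type switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of mating-type switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(switchsim)
```

## The biological question

Many isogamous unicellular eukaryotes — yeasts, ciliates, some algae — carry
genetically encoded mating types and can only mate with a cell of a
*different* type. A number of these organisms stochastically *switch* the
mating type of one daughter cell during clonal division. `switchsim`
implements an individual-based model to ask when such switching is
selectively favoured, and what switching rates evolve.

The central idea: life cycles of these organisms alternate long clonal
(vegetative) phases with occasional sex. During clonal growth the mating-type
ratio drifts away from parity, so at the next sexual phase cells of the
commoner type fail to find partners and die unmated. An allele that makes its
carrier's daughters occasionally switch mating type keeps its own lineage
closer to parity, and therefore spreads — a generalisation of the "lonely
spore" intuition from budding yeast to drift during clonal growth.

## The model

A haploid population of fixed carrying capacity $N$ evolves in cycles:

1. **Clonal growth**, repeated $g$ times per cycle: each cell divides into
   two daughters. One daughter always inherits the parental mating-type
   allele; the other keeps it with probability $1 - p_s$ and otherwise
   receives one of the other $m - 1$ alleles, uniformly at random. The
   switching rate $p_s$ is set by the cell's genotype at an unlinked
   switching locus (wild-type allele S1, mutant S2). The $2N$ daughters are
   then reduced back to $N$ by sampling without replacement.
2. **Mating**: cells pair at random under the constraint that partners carry
   different mating-type alleles. Two regimes are implemented. Under
   *exhaustive* mating, incompatible encounters are returned to the pool and
   re-drawn until no compatible gametes remain; with $m = 2$ this pairs the
   whole rarer type. Under *speedy* mating, two cells that meet and find
   each other incompatible are permanently removed — a premium on finding a
   partner quickly that penalises common types.
3. **Meiosis and regrowth**: unmated cells are discarded; the next
   generation of $N$ haploids is produced by sampling mated pairs with
   replacement, each offspring inheriting its mating type from either parent
   with probability 1/2 and, independently, its switching genotype from
   either parent with probability 1/2 (free recombination). No switching
   occurs at meiosis.

Switching can carry a survival cost
$$f = 1 - c\,p_s^{\,k},$$
applied as weighted sampling in the $2N \to N$ reduction at every growth
round (the default), or once per sexual generation during the regrowth after
mating (an inbreeding-like cost). The exponent shapes the cost: accelerating
($k > 1$), decelerating ($k < 1$), or a fixed cost for any nonzero switching
($k = 0$, with the convention $f(0) = 1$ and $f(p_s > 0) = 1 - c$).

In the continuum-of-alleles mode, each daughter's $p_s$ additionally mutates
with probability $\nu$ per division by a $\mathcal{N}(0, \xi^2)$ increment,
clamped to $[0, 1]$.

## Parameters that matter

| Parameter | Meaning | Default |
|---|---|---|
| `N` | carrying capacity (cells) | 100 |
| `m` | number of mating-type alleles | 2 |
| `g` | clonal growth rounds per sexual cycle | 10 |
| `c` | cost coefficient, in $[0,1]$ | 0 |
| `k` | cost-shape exponent | 2 |
| `q0` | initial mutant frequency | 0.05 |
| `nu` | per-division $p_s$ mutation probability | 0 |
| `xi` | mutation increment SD | 0.01 |

`q0 = 0.05` is the canonical invasion frequency: under neutrality the
fixation probability of the mutant label equals `q0` exactly, so the
difference between the estimated $q_{fix}$ and `q0` measures selection on
switching. `nu` and `xi` defaults follow the continuum-of-alleles analyses
(mutation rate $10^{-4}$ per division when enabled, increments of SD 0.01);
`nu` defaults to 0 because invasion experiments track a fixed pair of
alleles.

## A worked invasion experiment

```{r fixation}
params <- lifecycle_params(N = 100, m = 2, g = 10, c = 0, q0 = 0.05,
                           seed = 11)
estimate_fixation(params, resident_ps = 0, mutant_ps = 0.5,
                  replicates = 2000)
```

A non-switching population is invaded by a large-effect switching allele
($p_s = 0.5$); its fixation probability roughly doubles the neutral
expectation of 0.05. Replicate `r` of every harness runs under
`set.seed(replicate_seed(seed, r))`, so any single replicate can be
reproduced in isolation, and grid harnesses give each cell a disjoint block
of streams.

## Design choices where the model description is open

Several micro-level details are not fixed by the verbal model description;
the package resolves them as follows and treats the choices as part of its
own specification:

* **Switching target set.** The switching daughter draws uniformly from the
  full allele set minus the parental allele, so a currently extinct mating
  type can reappear by switching. Rationale: the switching mechanism is
  genetic and encodes all alleles, not only the extant ones.
* **Cost-weighted reduction.** "Sampling with probability $f$" is
  implemented as weighted sampling without replacement (successive draws
  proportional to remaining weights, computed via exponential keys, which is
  distribution-identical). If fewer than $N$ cells have positive weight the
  reduction is impossible and a degenerate-cost error is raised.
* **Once-per-generation cost.** The regrowth after mating samples with
  replacement, so the cost is applied as per-offspring acceptance with
  probability $f(p_s)$ — exactly weighted sampling with replacement.
* **No heterotypic pairs.** If the pool is monotypic at the sexual phase, the
  sexual step is skipped, the population passes through unchanged, and a
  `no_mating` event is logged. This keeps the neutral martingale property
  intact and avoids undefined extinction semantics.
* **Boundary mutations.** Mutated switching rates are clamped to $[0, 1]$
  (not reflected or redrawn).
* **Censoring.** Invasion replicates are capped at `100 * N` sexual
  generations; censored replicates are counted and reported, never silently
  dropped.
* **Continuum initial state and burn-in.** Continuum runs start all cells at
  `init_ps = 0.2`, inside the stationary range observed across the
  parameter grids, which shortens burn-in from either direction. The
  default burn-in is 5,000 sexual generations with a two-half stationarity
  diagnostic (warn if the post-burn-in halves differ by more than two
  pooled standard errors).

## Numerical and performance notes

The engine is written in C++ (via Rcpp). Inner-loop randomness comes from a
local xoshiro256++ generator that is re-seeded from R's RNG stream at every
entry point, so `set.seed()` fully determines every result while draws stay
cheap enough for run-to-fixation experiments at $N = 5000$. Uniform indices
are generated by a single-multiply draw, whose $O(n/2^{32})$ truncation bias
is negligible against Monte Carlo error at these population sizes. Two
distribution-identical shortcuts keep large-$N$ invasion runs tractable:
uniform $2N \to N$ reduction uses sequential selection sampling with lazy
resolution of switching, and two-type exhaustive mating directly draws the
uniformly matched subset that the sequential pairing process induces. Both
shortcuts are validated in the test suite against exact enumeration of the
sequential processes and against an independently coded plain-R
implementation of the whole life cycle.

## What the simulations do and do not show

The model reproduces the headline qualitative behaviour: distortion of the
mating-type ratio grows with more clonal rounds, smaller populations, and
more mating types; a switching mutant invades a non-switching population at
about twice the neutral rate; costs restrict invasion, more severely when
charged every growth round than once per sexual generation; and under
exhaustive mating more mating types weaken selection for switching while
under speedy mating they strengthen it.

The continuum prediction that longer vegetative phases lower the evolved
switching rate holds at the headline mutation parameters ($\nu = 10^{-4}$,
$\xi = 0.01$): runs of 30,000 sexual generations at $c = 0.01$, $k = 2$,
$N = 500$ settle around a mean $p_s$ of roughly 0.13 for $g = 10$ versus
0.05 for $g = 50$. Two caveats are worth recording. First, the ordering is
a property of the selection–mutation balance point: when the mutation
supply is raised substantially (e.g. $\nu = 2 \times 10^{-3}$) to shorten
runs, the population-mean switching rate fluctuates over most of $[0, 0.3]$
and the ordering disappears or even reverses, so time-compressed runs are
not a substitute for long ones here. Second, the fixation probability of
the $p_s = 0.5$ mutant at $g = 10$ is close to twice the neutral
expectation across the whole range $N = 100$ to $N = 5000$, with no clear
monotone decline in $N$: the two-fold advantage in large populations is
reproduced, but at $m = 2$ the advantage in small populations is of
similar size rather than larger. Test problem sizes (replicate counts,
run lengths) are chosen so the full suite completes on a single CPU; they
are stated in each test.

The model deliberately omits spatial structure, diploid-phase selection,
mechanistic detail of the switching machinery, and evolution of the number
of mating types itself. Real populations violate several idealisations —
constant carrying capacity, synchronous division, panmictic gamete pools —
so passing tests demonstrate internal correctness of this model, not
quantitative predictions for any particular organism.
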