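// Core life-cycle engine for finite haploid populations with alternating
// clonal and sexual phases. Every exported entry point seeds a local fast
// generator from the R RNG stream, so set.seed() on the R side makes every
// routine reproducible.
//
// State layout: three parallel vectors per population.
//   mt : mating-type allele, integer in 1..m
//   sl : switching-genotype label (1 = resident S1, 2 = mutant S2)
//   ps : per-cell switching rate in [0, 1]
//
// The replicate drivers reuse scratch buffers across rounds; per-round
// allocation would otherwise dominate the run time at large N.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Pop {
  std::vector<int> mt, sl;
  std::vector<double> ps;
  int size() const { return (int) mt.size(); }
  void resize(int n) { mt.resize(n); sl.resize(n); ps.resize(n); }
};

// Scratch space shared by successive growth rounds.
struct Scratch {
  Pop d;                    // 2N daughter pool (fallback path)
  Pop out;                  // next N-cell population
  std::vector<int> pick;    // sampled daughter indices
  std::vector<double> key;  // exponential keys for weighted sampling
  std::vector<unsigned char> mflag;  // daughter carries a fresh ps mutation
  std::vector<double> mval;          // its mutated ps value
};

struct MateOut {
  std::vector<int> a, b;    // 0-based cell indices of each heterotypic pair
  int unmated = 0, removed = 0;
  std::vector<int> pool;    // scratch
  std::vector<int> counts;  // scratch
};

// ---------------------------------------------------------------------------
// Local RNG. R's unif_rand() goes through the RNG-kind dispatch on every
// call, which dominates the run time of the replicate drivers (tens of
// millions of draws per replicate). Each exported entry point therefore
// seeds a local xoshiro256++ generator from the R stream, so set.seed() on
// the R side still fully determines every result, while inner-loop draws
// cost a few nanoseconds.

static uint64_t rng_s[4];
static double norm_cache;
static bool norm_have;

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9e3779b97f4a7c15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline uint64_t rotl(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

static inline uint64_t rng_next() {
  const uint64_t result = rotl(rng_s[0] + rng_s[3], 23) + rng_s[0];
  const uint64_t t = rng_s[1] << 17;
  rng_s[2] ^= rng_s[0];
  rng_s[3] ^= rng_s[1];
  rng_s[1] ^= rng_s[2];
  rng_s[0] ^= rng_s[3];
  rng_s[2] ^= t;
  rng_s[3] = rotl(rng_s[3], 45);
  return result;
}

// seed the local generator from the R RNG stream (call once per entry point)
static void rng_seed_from_R() {
  uint64_t seed = ((uint64_t) (unif_rand() * 4294967296.0) << 32) ^
                  (uint64_t) (unif_rand() * 4294967296.0);
  for (int i = 0; i < 4; ++i) rng_s[i] = splitmix64(seed);
  if (!(rng_s[0] | rng_s[1] | rng_s[2] | rng_s[3])) rng_s[0] = 1;
  norm_have = false;
}

// uniform on (0, 1) with 53 random bits
static inline double rnd_unif() {
  return ((rng_next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double rnd_exp() {
  return -std::log(rnd_unif());
}

// standard normal via Box-Muller (second deviate cached)
static inline double rnd_norm() {
  if (norm_have) { norm_have = false; return norm_cache; }
  const double r = std::sqrt(2.0 * rnd_exp());
  const double a = 6.283185307179586476925286766559 * rnd_unif();
  norm_cache = r * std::sin(a);
  norm_have = true;
  return r * std::cos(a);
}

// Survival probability f = 1 - c * ps^k. The k = 0 convention is a fixed
// cost for any nonzero switching: f(0) = 1, f(ps > 0) = 1 - c.
static inline double surv_weight(double ps, double c, double k) {
  if (k == 2.0) return 1.0 - c * ps * ps;   // common cost shapes, pow-free
  if (k == 1.0) return 1.0 - c * ps;
  if (k > 0.0) return 1.0 - c * std::pow(ps, k);
  return (ps > 0.0) ? 1.0 - c : 1.0;
}

// Uniform integer on {0, ..., n-1} from a single rnd_unif() draw. The
// truncation bias is O(n / 2^32), negligible against Monte Carlo error at
// the population sizes used here, and one draw per index keeps the index
// generation from dominating the run time.
static inline int unif_int(int n) {
  int j = (int) (n * rnd_unif());
  return j >= n ? n - 1 : j;
}

// Daughter mating type: keep the parental allele with probability 1 - ps,
// otherwise rotate to one of the other m - 1 alleles uniformly. The target
// is drawn from the full allele set, so extinct alleles can reappear.
static inline int switch_type(int parent, double ps, int m) {
  if (ps > 0.0 && rnd_unif() < ps) {
    int t = parent + 1 + unif_int(m - 1);
    if (t > m) t -= m;
    return t;
  }
  return parent;
}

// One clonal growth round: every cell divides (N -> 2N); one daughter
// inherits the parental mating type faithfully, the other is subject to
// switching; both inherit the parental switching genotype. Each daughter
// then mutates its ps with probability nu (normal increment, sd xi, clamped
// to [0,1]). The pool is reduced back to N by sampling without replacement,
// weighted by survival when `weighted`.
static void growth_round_impl(Pop &pop, int m, double c, double k,
                              bool weighted, double nu, double xi,
                              Scratch &s) {
  const int n = pop.size();
  if (!(weighted && c > 0.0)) {
    // Uniform reduction: walk the parents in order, drawing for each how
    // many of its two (distinguishable) daughters survive from the
    // conditional law of a uniform N-subset of the 2N implicit daughters
    // (sequential selection sampling, one uniform per parent). Switching
    // and ps mutation are resolved lazily for survivors only, which is
    // distribution-identical because unselected daughters influence
    // nothing and uniform selection ignores genotype.
    s.out.resize(n);
    double R = n;            // survivor slots remaining
    double D = 2.0 * n;      // daughters remaining
    int w = 0;
    for (int par = 0; par < n && R > 0.0; ++par) {
      const double denom = D * (D - 1.0);
      const double p2 = R * (R - 1.0) / denom;       // both daughters kept
      const double p1 = R * (D - R) / denom;         // only one specific kept
      const double u = rnd_unif();
      const bool both = u < p2;
      const bool keep_f = both || u < p2 + p1;                   // faithful
      const bool keep_s = both ||
        (u >= p2 + p1 && u < p2 + 2.0 * p1);                     // switcher
      if (keep_f) {
        s.out.mt[w] = pop.mt[par];
        s.out.sl[w] = pop.sl[par];
        s.out.ps[w] = pop.ps[par];
        ++w; --R;
      }
      if (keep_s) {
        s.out.mt[w] = switch_type(pop.mt[par], pop.ps[par], m);
        s.out.sl[w] = pop.sl[par];
        s.out.ps[w] = pop.ps[par];
        ++w; --R;
      }
      D -= 2.0;
    }
    if (nu > 0.0) {
      // binomial thinning: draw how many survivors mutate, then where
      // (distinct cells; collisions are re-drawn)
      const int nmut = (int) R::rbinom((double) n, nu);
      std::vector<int> &hit = s.pick;
      hit.clear();
      for (int t = 0; t < nmut; ++t) {
        int i;
        do {
          i = unif_int(n);
        } while (std::find(hit.begin(), hit.end(), i) != hit.end());
        hit.push_back(i);
        double p = s.out.ps[i] + rnd_norm() * xi;
        s.out.ps[i] = p < 0.0 ? 0.0 : (p > 1.0 ? 1.0 : p);
      }
    }
    std::swap(pop, s.out);
    return;
  }
  // Cost-weighted reduction. Weights depend on ps only, so switching is
  // still resolved lazily for survivors; ps mutations are placed by
  // binomial thinning when rare, with a fully materialised fallback when
  // mutation is dense.
  const int nmut_w = nu > 0.0 ? (int) R::rbinom(2.0 * n, nu) : 0;
  if (nmut_w <= n / 2 + 1) {
    s.mflag.assign(2 * n, 0);
    s.mval.resize(2 * n);
    std::vector<int> &hit = s.pick;
    hit.clear();
    for (int t = 0; t < nmut_w; ++t) {
      int j;
      do { j = unif_int(2 * n); } while (s.mflag[j]);
      s.mflag[j] = 1;
      hit.push_back(j);
      double p = pop.ps[j >> 1] + rnd_norm() * xi;
      s.mval[j] = p < 0.0 ? 0.0 : (p > 1.0 ? 1.0 : p);
    }
    s.key.resize(2 * n);
    int npos = 0;
    for (int j = 0; j < 2 * n; ++j) {
      const double psv = s.mflag[j] ? s.mval[j] : pop.ps[j >> 1];
      const double w = surv_weight(psv, c, k);
      if (w > 0.0) { s.key[j] = rnd_exp() / w; ++npos; }
      else s.key[j] = R_PosInf;
    }
    if (npos < n)
      stop("degenerate cost: fewer than N cells have nonzero survival weight (c = %g, k = %g)",
           c, k);
    s.pick.resize(2 * n);
    for (int j = 0; j < 2 * n; ++j) s.pick[j] = j;
    std::nth_element(s.pick.begin(), s.pick.begin() + n, s.pick.end(),
                     [&](int a, int b) { return s.key[a] < s.key[b]; });
    std::sort(s.pick.begin(), s.pick.begin() + n);
    s.out.resize(n);
    for (int i = 0; i < n; ++i) {
      const int j = s.pick[i];
      const int par = j >> 1;
      s.out.sl[i] = pop.sl[par];
      s.out.ps[i] = s.mflag[j] ? s.mval[j] : pop.ps[par];
      s.out.mt[i] = (j & 1) ? switch_type(pop.mt[par], pop.ps[par], m)
                            : pop.mt[par];
    }
    std::swap(pop, s.out);
    return;
  }
  s.d.resize(2 * n);
  for (int i = 0; i < n; ++i) {
    s.d.mt[2 * i] = pop.mt[i];
    s.d.sl[2 * i] = pop.sl[i];
    s.d.ps[2 * i] = pop.ps[i];
    s.d.mt[2 * i + 1] = switch_type(pop.mt[i], pop.ps[i], m);
    s.d.sl[2 * i + 1] = pop.sl[i];
    s.d.ps[2 * i + 1] = pop.ps[i];
  }
  if (nu > 0.0) {
    for (int i = 0; i < 2 * n; ++i) {
      if (rnd_unif() < nu) {
        double p = s.d.ps[i] + rnd_norm() * xi;
        s.d.ps[i] = p < 0.0 ? 0.0 : (p > 1.0 ? 1.0 : p);
      }
    }
  }
  s.pick.resize(2 * n);
  for (int i = 0; i < 2 * n; ++i) s.pick[i] = i;
  if (weighted && c > 0.0) {
    // Exponential-key weighted sampling without replacement: keeping the n
    // smallest keys E_i / w_i is distribution-identical to successive draws
    // with probability proportional to the remaining weights.
    s.key.resize(2 * n);
    int npos = 0;
    for (int i = 0; i < 2 * n; ++i) {
      double w = surv_weight(s.d.ps[i], c, k);
      if (w > 0.0) { s.key[i] = rnd_exp() / w; ++npos; }
      else s.key[i] = R_PosInf;
    }
    if (npos < n)
      stop("degenerate cost: fewer than N cells have nonzero survival weight (c = %g, k = %g)",
           c, k);
    std::nth_element(s.pick.begin(), s.pick.begin() + n, s.pick.end(),
                     [&](int a, int b) { return s.key[a] < s.key[b]; });
    std::sort(s.pick.begin(), s.pick.begin() + n);  // platform-stable order
  } else {
    for (int i = 0; i < n; ++i) {               // partial Fisher-Yates
      int j = i + unif_int(2 * n - i);
      std::swap(s.pick[i], s.pick[j]);
    }
  }
  s.out.resize(n);
  for (int i = 0; i < n; ++i) {
    const int j = s.pick[i];
    s.out.mt[i] = s.d.mt[j];
    s.out.sl[i] = s.d.sl[j];
    s.out.ps[i] = s.d.ps[j];
  }
  std::swap(pop, s.out);
}

// Random pair formation. Repeatedly draw two distinct cells uniformly from
// the pool. Heterotypic draws pair and leave the pool. Homotypic draws are
// returned to the pool (exhaustive) or permanently discarded (speedy).
// Exhaustive mating stops when the pool is empty, a singleton, or monotypic.
// With two types and exhaustive mating the sequential process always pairs
// the whole rarer type with a uniformly chosen, uniformly matched subset of
// the commoner type (the process is exchangeable within types), so the
// result can be drawn directly.
static void mate_two_types_exhaustive(const std::vector<int> &mt,
                                      MateOut &out) {
  const int n = (int) mt.size();
  out.a.clear(); out.b.clear();
  out.removed = 0;
  std::vector<int> &one = out.pool;     // scratch reuse
  std::vector<int> &two = out.counts;
  one.clear(); two.clear();
  for (int i = 0; i < n; ++i) (mt[i] == 1 ? one : two).push_back(i);
  std::vector<int> &rare = one.size() <= two.size() ? one : two;
  std::vector<int> &common = one.size() <= two.size() ? two : one;
  const int P = (int) rare.size();
  for (int i = 0; i < P; ++i) {         // shuffle rare, subset-shuffle common
    int j = i + unif_int((int) rare.size() - i);
    std::swap(rare[i], rare[j]);
    int l = i + unif_int((int) common.size() - i);
    std::swap(common[i], common[l]);
  }
  for (int i = 0; i < P; ++i) {
    out.a.push_back(rare[i]);
    out.b.push_back(common[i]);
  }
  out.unmated = n - 2 * P;
}

static void mate_impl(const std::vector<int> &mt, int m, bool speedy,
                      MateOut &out) {
  if (!speedy && m == 2) {
    mate_two_types_exhaustive(mt, out);
    return;
  }
  const int n = (int) mt.size();
  out.a.clear(); out.b.clear();
  out.unmated = 0; out.removed = 0;
  out.pool.resize(n);
  out.counts.assign(m + 1, 0);
  for (int i = 0; i < n; ++i) { out.pool[i] = i; out.counts[mt[i]]++; }
  int npool = n;
  while (npool >= 2) {
    if (!speedy) {
      int cmax = 0;
      for (int t = 1; t <= m; ++t) cmax = std::max(cmax, out.counts[t]);
      if (cmax == npool) break;  // monotypic: no heterotypic pair can form
    }
    int i = unif_int(npool);
    int j = unif_int(npool - 1);
    if (j >= i) ++j;
    const int ci = out.pool[i], cj = out.pool[j];
    const bool hetero = mt[ci] != mt[cj];
    if (hetero || speedy) {
      if (hetero) { out.a.push_back(ci); out.b.push_back(cj); }
      else out.removed += 2;
      out.counts[mt[ci]]--; out.counts[mt[cj]]--;
      if (i < j) std::swap(i, j);      // drop the higher slot first
      out.pool[i] = out.pool[npool - 1]; --npool;
      out.pool[j] = out.pool[npool - 1]; --npool;
    }
  }
  out.unmated = npool;
}

// Meiosis and regrowth to carrying capacity N by sampling mated pairs with
// replacement. Each offspring picks a pair uniformly, then inherits the
// mating type from either parent with probability 1/2 and, independently,
// the switching genotype from either parent with probability 1/2 (free
// recombination). No switching and no ps mutation occur here. When
// `weighted`, each candidate offspring survives with probability f(ps)
// (accept-reject; exactly weighted sampling with replacement).
static void meiosis_impl(const MateOut &pairs, const Pop &par, int N,
                         bool weighted, double c, double k, Pop &out) {
  const int np = (int) pairs.a.size();
  if (np == 0)
    stop("no mated pairs: cannot regrow a population from an empty pair list");
  const bool wtd = weighted && c > 0.0;
  if (wtd) {
    double fmax = 0.0;
    for (int p = 0; p < np; ++p) {
      fmax = std::max(fmax, surv_weight(par.ps[pairs.a[p]], c, k));
      fmax = std::max(fmax, surv_weight(par.ps[pairs.b[p]], c, k));
    }
    if (fmax <= 0.0)
      stop("degenerate cost: every potential offspring has zero survival weight");
  }
  out.resize(N);
  for (int i = 0; i < N; ++i) {
    for (long attempt = 0; ; ++attempt) {
      if (attempt > 1000000L)
        stop("cost-weighted regrowth failed to accept an offspring");
      const int p = unif_int(np);
      // one uniform supplies both independent inheritance coins
      double u = rnd_unif();
      const bool mfirst = u < 0.5;
      u = 2.0 * u - (mfirst ? 0.0 : 1.0);
      const int mpar = mfirst ? pairs.a[p] : pairs.b[p];
      const int spar = (u < 0.5) ? pairs.a[p] : pairs.b[p];
      const double psv = par.ps[spar];
      if (wtd && rnd_unif() >= surv_weight(psv, c, k)) continue;
      out.mt[i] = par.mt[mpar];
      out.sl[i] = par.sl[spar];
      out.ps[i] = psv;
      break;
    }
  }
}

// 1 if the mutant label has fixed, 0 if lost, -1 if still segregating.
static int s2_status(const Pop &pop) {
  int cnt = 0;
  const int n = pop.size();
  for (int i = 0; i < n; ++i) if (pop.sl[i] == 2) ++cnt;
  return cnt == 0 ? 0 : (cnt == n ? 1 : -1);
}

static Pop make_pop(IntegerVector mt, IntegerVector sl, NumericVector ps) {
  Pop pop;
  pop.mt.assign(mt.begin(), mt.end());
  pop.sl.assign(sl.begin(), sl.end());
  pop.ps.assign(ps.begin(), ps.end());
  return pop;
}

static List pop_to_list(const Pop &pop) {
  return List::create(_["mating_type"] = wrap(pop.mt),
                      _["s_label"] = wrap(pop.sl),
                      _["ps"] = wrap(pop.ps));
}

// Fresh population: mating types as evenly as divisibility allows
// (cell i gets type i mod m), round(q0*N) random cells carry the mutant.
static Pop init_pop(int N, int m, double q0, double resident_ps,
                    double mutant_ps) {
  Pop pop;
  pop.resize(N);
  for (int i = 0; i < N; ++i) {
    pop.mt[i] = (i % m) + 1;
    pop.sl[i] = 1;
    pop.ps[i] = resident_ps;
  }
  const int nmut = (int) std::lround(q0 * N);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < nmut; ++i) {
    int j = i + unif_int(N - i);
    std::swap(idx[i], idx[j]);
    pop.sl[idx[i]] = 2;
    pop.ps[idx[i]] = mutant_ps;
  }
  return pop;
}

// [[Rcpp::export]]
List cpp_growth_round(IntegerVector mt, IntegerVector sl, NumericVector ps,
                      int m, double c, double k, bool weighted,
                      double nu, double xi) {
  rng_seed_from_R();
  Pop pop = make_pop(mt, sl, ps);
  Scratch s;
  growth_round_impl(pop, m, c, k, weighted, nu, xi, s);
  return pop_to_list(pop);
}

// [[Rcpp::export]]
IntegerVector cpp_switch_daughter(IntegerVector parent, NumericVector ps,
                                  int m) {
  rng_seed_from_R();
  const int n = parent.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = switch_type(parent[i], ps[i], m);
  return out;
}

// [[Rcpp::export]]
List cpp_mate(IntegerVector mt, int m, bool speedy) {
  rng_seed_from_R();
  std::vector<int> v(mt.begin(), mt.end());
  MateOut mo;
  if (!v.empty()) mate_impl(v, m, speedy, mo);
  const int np = (int) mo.a.size();
  IntegerMatrix pairs(np, 2);
  for (int p = 0; p < np; ++p) {
    pairs(p, 0) = mo.a[p] + 1;
    pairs(p, 1) = mo.b[p] + 1;
  }
  return List::create(_["pairs"] = pairs,
                      _["unmated"] = mo.unmated,
                      _["removed"] = mo.removed);
}

// [[Rcpp::export]]
List cpp_meiosis(IntegerMatrix pairs, IntegerVector mt, IntegerVector sl,
                 NumericVector ps, int N, bool weighted, double c, double k) {
  rng_seed_from_R();
  Pop par = make_pop(mt, sl, ps);
  MateOut mo;
  const int np = pairs.nrow();
  for (int p = 0; p < np; ++p) {
    mo.a.push_back(pairs(p, 0) - 1);
    mo.b.push_back(pairs(p, 1) - 1);
  }
  Pop out;
  meiosis_impl(mo, par, N, weighted, c, k, out);
  return pop_to_list(out);
}

// Run one replicate until the mutant label fixes (status 1) or is lost
// (status 0), or max_generations elapse (status 2, censored). Fixation is
// checked after every growth round and after every sexual step. If no
// heterotypic pairs form, the sexual step is skipped and the population
// passes through unchanged.
// [[Rcpp::export]]
IntegerVector cpp_run_fixation(int N, int m, int g, double c, double k,
                               double q0, double nu, double xi,
                               bool speedy, bool cost_at_sex,
                               double resident_ps, double mutant_ps,
                               int max_generations) {
  rng_seed_from_R();
  Pop pop = init_pop(N, m, q0, resident_ps, mutant_ps);
  int st = s2_status(pop);
  if (st >= 0) return IntegerVector::create(st, 0);
  const bool grow_weighted = !cost_at_sex && c > 0.0;
  const bool sex_weighted = cost_at_sex && c > 0.0;
  Scratch s;
  MateOut mo;
  Pop next;
  for (int gen = 1; gen <= max_generations; ++gen) {
    for (int r = 0; r < g; ++r) {
      growth_round_impl(pop, m, c, k, grow_weighted, nu, xi, s);
      st = s2_status(pop);
      if (st >= 0) return IntegerVector::create(st, gen);
    }
    mate_impl(pop.mt, m, speedy, mo);
    if (!mo.a.empty()) {
      meiosis_impl(mo, pop, N, sex_weighted, c, k, next);
      std::swap(pop, next);
      st = s2_status(pop);
      if (st >= 0) return IntegerVector::create(st, gen);
    }
  }
  return IntegerVector::create(2, max_generations);
}

// Continuum-of-alleles driver: a monomorphic-label population whose per-cell
// switching rate mutates during growth. Records the population mean ps after
// each sexual generation; after burn_in generations, appends the full
// population's ps values every sample_stride generations until max_samples
// values have been collected.
// [[Rcpp::export]]
List cpp_run_continuum(int N, int m, int g, double c, double k,
                       double nu, double xi, bool speedy, bool cost_at_sex,
                       double init_ps, int generations, int burn_in,
                       int sample_stride, int max_samples) {
  rng_seed_from_R();
  Pop pop = init_pop(N, m, 0.0, init_ps, init_ps);
  const bool grow_weighted = !cost_at_sex && c > 0.0;
  const bool sex_weighted = cost_at_sex && c > 0.0;
  NumericVector mean_ps(generations);
  std::vector<double> samples;
  Scratch s;
  MateOut mo;
  Pop next;
  for (int gen = 1; gen <= generations; ++gen) {
    for (int r = 0; r < g; ++r)
      growth_round_impl(pop, m, c, k, grow_weighted, nu, xi, s);
    mate_impl(pop.mt, m, speedy, mo);
    if (!mo.a.empty()) {
      meiosis_impl(mo, pop, N, sex_weighted, c, k, next);
      std::swap(pop, next);
    }
    double tot = 0.0;
    for (int i = 0; i < N; ++i) tot += pop.ps[i];
    mean_ps[gen - 1] = tot / N;
    if (gen > burn_in && (gen - burn_in - 1) % sample_stride == 0 &&
        (int) samples.size() < max_samples) {
      for (int i = 0; i < N && (int) samples.size() < max_samples; ++i)
        samples.push_back(pop.ps[i]);
    }
  }
  return List::create(_["mean_ps"] = mean_ps, _["samples"] = wrap(samples));
}

// Repeated simulation of the pair-formation process alone, for checking its
// distribution over final pair counts against exact enumeration. `counts`
// gives the number of cells per mating type; returns the tabulated number
// of pairs over reps draws (index p+1 = count of realizations with p pairs).
// [[Rcpp::export]]
IntegerVector cpp_mate_pair_count_sim(IntegerVector counts, bool speedy,
                                      int reps) {
  rng_seed_from_R();
  const int m = counts.size();
  int n = 0;
  for (int t = 0; t < m; ++t) n += counts[t];
  std::vector<int> mt;
  mt.reserve(n);
  for (int t = 0; t < m; ++t)
    for (int i = 0; i < counts[t]; ++i) mt.push_back(t + 1);
  IntegerVector tab(n / 2 + 1);
  MateOut mo;
  for (int r = 0; r < reps; ++r) {
    mate_impl(mt, m, speedy, mo);
    tab[(int) mo.a.size()]++;
  }
  return tab;
}
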