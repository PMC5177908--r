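// Founder-segment Wright-Fisher engine.
//
// Gametes are pairs (founder-state vector S, breakpoint vector B) with
// breakpoints in Morgans on (0, map_len); segment k covers [B[k-1], B[k]).
// All randomness comes from R's RNG (unif_rand / norm_rand / R::rpois), in
// a frozen draw order, so that pure-R re-implementations consuming the same
// stream reproduce trajectories bit-for-bit.
//
// Draw order, per generation:
//   for each deme d = 1..D:
//     [QTL selection only] per gamete n = 1..N: one N(0,1) polygenic then
//       one N(0,1) environmental deviate;
//     for each offspring slot n = 1..N:
//       one uniform per parent draw (two draws), then on even n one
//       uniform crossover draw r (crossover iff r < map_len);
//   then M migration events, two uniforms each.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<int> SVec;
typedef std::vector<double> BVec;

struct Pop {
  std::vector<SVec> states;
  std::vector<BVec> breaks;
};

static inline int unif_index(int n) {
  int i = (int)(unif_rand() * n);
  return i >= n ? n - 1 : i;
}

// first index with cumw[i] >= target (plain-double accumulation upstream)
static inline int weighted_index(const std::vector<double>& cumw,
                                 double target) {
  int i = (int)(std::lower_bound(cumw.begin(), cumw.end(), target) -
                cumw.begin());
  return i >= (int)cumw.size() ? (int)cumw.size() - 1 : i;
}

// founder state covering position pos (breakpoint belongs to its right)
static inline int founder_at(const SVec& s, const BVec& b, double pos) {
  size_t k = std::upper_bound(b.begin(), b.end(), pos) - b.begin();
  return s[k];
}

// child = p1 left of r + breakpoint r + p2 right of r
static void crossover(const SVec& s1, const BVec& b1,
                      const SVec& s2, const BVec& b2, double r,
                      SVec& cs, BVec& cb) {
  cs.clear(); cb.clear();
  size_t k1 = std::lower_bound(b1.begin(), b1.end(), r) - b1.begin();
  size_t k2 = std::upper_bound(b2.begin(), b2.end(), r) - b2.begin();
  cs.reserve(k1 + 1 + s2.size() - k2);
  cb.reserve(k1 + 1 + b2.size() - k2);
  cs.insert(cs.end(), s1.begin(), s1.begin() + k1 + 1);
  cb.insert(cb.end(), b1.begin(), b1.begin() + k1);
  cb.push_back(r);
  cs.insert(cs.end(), s2.begin() + k2, s2.end());
  cb.insert(cb.end(), b2.begin() + k2, b2.end());
}

// multi-crossover meiosis: alternate between gametes a/b at sorted
// crossover points, starting from `start` (0 = a, 1 = b)
static void meiosis_multi(const SVec& sa, const BVec& ba,
                          const SVec& sb, const BVec& bb,
                          const std::vector<double>& xpos, int start,
                          double map_len, SVec& cs, BVec& cb) {
  cs.clear(); cb.clear();
  const SVec* s[2] = { &sa, &sb };
  const BVec* b[2] = { &ba, &bb };
  int cur = start;
  double last = 0.0;
  for (size_t i = 0; i <= xpos.size(); ++i) {
    double hi = (i < xpos.size()) ? xpos[i] : map_len + 1.0;
    const SVec& ss = *s[cur];
    const BVec& bbk = *b[cur];
    size_t klo = std::upper_bound(bbk.begin(), bbk.end(), last) - bbk.begin();
    size_t khi = std::lower_bound(bbk.begin(), bbk.end(), hi) - bbk.begin();
    cs.insert(cs.end(), ss.begin() + klo, ss.begin() + khi + 1);
    cb.insert(cb.end(), bbk.begin() + klo, bbk.begin() + khi);
    if (i < xpos.size()) cb.push_back(xpos[i]);
    last = hi;
    cur = 1 - cur;
  }
}

static Pop pop_from_r(List states, List breaks) {
  Pop p;
  int n = states.size();
  p.states.resize(n); p.breaks.resize(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = states[i];
    NumericVector b = breaks[i];
    p.states[i].assign(s.begin(), s.end());
    p.breaks[i].assign(b.begin(), b.end());
  }
  return p;
}

static List pop_to_r(const Pop& p) {
  int n = p.states.size();
  List states(n), breaks(n);
  for (int i = 0; i < n; ++i) {
    states[i] = IntegerVector(p.states[i].begin(), p.states[i].end());
    breaks[i] = NumericVector(p.breaks[i].begin(), p.breaks[i].end());
  }
  return List::create(_["founder_states"] = states,
                      _["breakpoints"] = breaks);
}

static void do_migration(Pop& pop, int M) {
  int DN = pop.states.size();
  for (int k = 0; k < M; ++k) {
    int i = unif_index(DN);
    int j = unif_index(DN);
    pop.states[i] = pop.states[j];
    pop.breaks[i] = pop.breaks[j];
  }
}

// [[Rcpp::export]]
List cpp_wf_run(List init_states, List init_breaks, double map_len,
                int D, int N, int G, int M, List sel,
                bool poisson_crossover = false, bool log_traj = false) {
  RNGScope scope;
  Pop cur = pop_from_r(init_states, init_breaks);
  if ((int)cur.states.size() != D * N)
    stop("initial pool must hold D * N gametes");
  Pop nxt;
  nxt.states.resize(D * N);
  nxt.breaks.resize(D * N);

  bool qtl = sel.size() > 0;
  NumericVector qtl_pos;       // Morgans
  IntegerMatrix qtl_alleles;   // F x Q
  NumericVector effects;
  double va_poly = 0, ve = 0, vf = 1, optimum = 0, h2poly = 0;
  std::vector<double> polymean(D, 0.0);
  if (qtl) {
    qtl_pos = as<NumericVector>(sel["qtl_pos"]);
    qtl_alleles = as<IntegerMatrix>(sel["qtl_alleles"]);
    effects = as<NumericVector>(sel["effects"]);
    va_poly = as<double>(sel["va_poly"]);
    ve = as<double>(sel["ve"]);
    vf = as<double>(sel["variance_fitness"]);
    optimum = as<double>(sel["optimum"]);
    double pm0 = as<double>(sel["polygenic_mean"]);
    std::fill(polymean.begin(), polymean.end(), pm0);
    h2poly = va_poly / (va_poly + ve);
  }
  double sd_poly = std::sqrt(va_poly), sd_e = std::sqrt(ve);
  int Q = qtl ? qtl_pos.size() : 0;

  NumericMatrix log_pheno, log_poly, log_fit;
  if (log_traj) {
    log_pheno = NumericMatrix(G, D);
    log_poly = NumericMatrix(G, D);
    log_fit = NumericMatrix(G, D);
  }

  std::vector<double> pheno(N), w(N), cumw(N);

  for (int g = 0; g < G; ++g) {
    for (int d = 0; d < D; ++d) {
      int off = d * N;
      double sum_pheno = 0, sum_w = 0;
      if (qtl) {
        for (int n = 0; n < N; ++n) {
          double gsum = 0;
          const SVec& s = cur.states[off + n];
          const BVec& b = cur.breaks[off + n];
          for (int q = 0; q < Q; ++q) {
            int f = founder_at(s, b, qtl_pos[q]);
            gsum += effects[q] * qtl_alleles(f - 1, q);
          }
          double zp = norm_rand(), zen = norm_rand();
          pheno[n] = gsum + polymean[d] + zp * sd_poly + zen * sd_e;
          double dev = pheno[n] - optimum;
          w[n] = std::exp(-dev * dev / (2.0 * vf));
          sum_pheno += pheno[n];
          sum_w += w[n];
        }
        if (sum_w <= 0)
          stop("all fitness weights underflow to zero in deme %d: "
               "population too far from the optimum", d + 1);
        double acc = 0;
        for (int n = 0; n < N; ++n) { acc += w[n]; cumw[n] = acc; }
      }
      double parent_pheno_sum = 0;
      for (int n = 0; n < N; ++n) {
        int i1, i2;
        if (qtl) {
          i1 = weighted_index(cumw, unif_rand() * cumw[N - 1]);
          i2 = weighted_index(cumw, unif_rand() * cumw[N - 1]);
          parent_pheno_sum += pheno[i1] + pheno[i2];
        } else {
          i1 = unif_index(N);
          i2 = unif_index(N);
        }
        SVec& cs = nxt.states[off + n];
        BVec& cb = nxt.breaks[off + n];
        bool even = ((n + 1) % 2 == 0);  // slots are 1-based in the model
        if (!even) {
          cs = cur.states[off + i1];
          cb = cur.breaks[off + i1];
        } else if (!poisson_crossover) {
          double r = unif_rand();
          if (r < map_len) {
            crossover(cur.states[off + i1], cur.breaks[off + i1],
                      cur.states[off + i2], cur.breaks[off + i2], r, cs, cb);
          } else {
            cs = cur.states[off + i1];
            cb = cur.breaks[off + i1];
          }
        } else {
          int nco = (int)R::rpois(map_len);
          if (nco == 0) {
            cs = cur.states[off + i1];
            cb = cur.breaks[off + i1];
          } else {
            std::vector<double> xpos(nco);
            for (int k = 0; k < nco; ++k) xpos[k] = unif_rand() * map_len;
            std::sort(xpos.begin(), xpos.end());
            meiosis_multi(cur.states[off + i1], cur.breaks[off + i1],
                          cur.states[off + i2], cur.breaks[off + i2],
                          xpos, 0, map_len, cs, cb);
          }
        }
      }
      if (qtl) {
        double S = parent_pheno_sum / (2.0 * N) - sum_pheno / N;
        polymean[d] += h2poly * S;
        if (log_traj) {
          log_pheno(g, d) = sum_pheno / N;
          log_poly(g, d) = polymean[d];
          log_fit(g, d) = sum_w / N;
        }
      }
    }
    std::swap(cur.states, nxt.states);
    std::swap(cur.breaks, nxt.breaks);
    if (M > 0) do_migration(cur, M);
  }

  List out = pop_to_r(cur);
  out["generation"] = G;
  out["polygenic_mean"] = NumericVector(polymean.begin(), polymean.end());
  if (log_traj) {
    out["mean_phenotype"] = log_pheno;
    out["polygenic_mean_traj"] = log_poly;
    out["mean_fitness"] = log_fit;
  }
  return out;
}

// Diploid-mode engine with multiplicative per-locus fitness (fecundity
// selection): individuals are adjacent gamete pairs (2i-1, 2i); parents are
// drawn proportional to fitness (no selfing) and each transmits one gamete
// built by Poisson multi-crossover meiosis on the (sex-averaged) map.
//
// Draw order per offspring individual: one uniform per parent draw (second
// parent redrawn while equal to the first), then per transmitted gamete:
// one uniform (which parental gamete starts), one Poisson(map_len) draw,
// then that many uniform crossover positions.
// [[Rcpp::export]]
List cpp_wf_run_diploid(List init_states, List init_breaks, double map_len,
                        int D, int N, int G, int M,
                        NumericVector loci_pos, IntegerMatrix loci_alleles,
                        NumericVector s_coef, NumericVector h_coef,
                        IntegerVector favored) {
  RNGScope scope;
  if (N % 2 != 0) stop("diploid mode needs an even number of gametes N");
  Pop cur = pop_from_r(init_states, init_breaks);
  if ((int)cur.states.size() != D * N)
    stop("initial pool must hold D * N gametes");
  Pop nxt;
  nxt.states.resize(D * N);
  nxt.breaks.resize(D * N);
  int half = N / 2;
  int nloci = loci_pos.size();
  std::vector<double> fit(half), cumw(half);

  for (int g = 0; g < G; ++g) {
    for (int d = 0; d < D; ++d) {
      int off = d * N;
      double acc = 0;
      for (int i = 0; i < half; ++i) {
        double f = 1.0;
        for (int l = 0; l < nloci; ++l) {
          int a1 = loci_alleles(founder_at(cur.states[off + 2 * i],
                                           cur.breaks[off + 2 * i],
                                           loci_pos[l]) - 1, l);
          int a2 = loci_alleles(founder_at(cur.states[off + 2 * i + 1],
                                           cur.breaks[off + 2 * i + 1],
                                           loci_pos[l]) - 1, l);
          int cnt = (a1 == favored[l]) + (a2 == favored[l]);
          double wl = cnt == 0 ? 1.0
                    : cnt == 1 ? 1.0 + h_coef[l] * s_coef[l]
                               : 1.0 + s_coef[l];
          f *= wl;
        }
        fit[i] = f;
        acc += f;
        cumw[i] = acc;
      }
      if (acc <= 0) stop("all diploid fitnesses zero in deme %d", d + 1);
      for (int i = 0; i < half; ++i) {
        int pa = weighted_index(cumw, unif_rand() * cumw[half - 1]);
        int pb = weighted_index(cumw, unif_rand() * cumw[half - 1]);
        while (pb == pa && half > 1)  // selfing excluded
          pb = weighted_index(cumw, unif_rand() * cumw[half - 1]);
        int parents[2] = { pa, pb };
        for (int side = 0; side < 2; ++side) {
          int p = parents[side];
          int start = unif_rand() < 0.5 ? 0 : 1;
          int nco = (int)R::rpois(map_len);
          SVec& cs = nxt.states[off + 2 * i + side];
          BVec& cb = nxt.breaks[off + 2 * i + side];
          const SVec& sa = cur.states[off + 2 * p + start];
          const BVec& ba = cur.breaks[off + 2 * p + start];
          const SVec& sb = cur.states[off + 2 * p + (1 - start)];
          const BVec& bb = cur.breaks[off + 2 * p + (1 - start)];
          if (nco == 0) {
            cs = sa;
            cb = ba;
          } else {
            std::vector<double> xpos(nco);
            for (int k = 0; k < nco; ++k) xpos[k] = unif_rand() * map_len;
            std::sort(xpos.begin(), xpos.end());
            meiosis_multi(sa, ba, sb, bb, xpos, 0, map_len, cs, cb);
          }
        }
      }
    }
    std::swap(cur.states, nxt.states);
    std::swap(cur.breaks, nxt.breaks);
    if (M > 0) do_migration(cur, M);
  }
  List out = pop_to_r(cur);
  out["generation"] = G;
  return out;
}

// Exact allele-frequency projection: L x D matrix of per-deme means of the
// panel allele carried at each site.
// [[Rcpp::export]]
NumericMatrix cpp_project_freqs(List states, List breaks,
                                NumericVector site_pos,
                                IntegerMatrix founder_alleles,
                                int D, int N) {
  int L = site_pos.size();
  int F = founder_alleles.nrow();
  NumericMatrix out(L, D);
  std::vector<int> counts(L);
  for (int d = 0; d < D; ++d) {
    std::fill(counts.begin(), counts.end(), 0);
    for (int n = 0; n < N; ++n) {
      IntegerVector s = states[d * N + n];
      NumericVector b = breaks[d * N + n];
      int nb = b.size();
      int slo = 0;
      for (int k = 0; k <= nb; ++k) {
        // segment k covers [prev, b[k]); its sites are [slo, shi)
        int shi;
        if (k < nb) {
          shi = (int)(std::lower_bound(site_pos.begin() + slo,
                                       site_pos.end(), b[k]) -
                      site_pos.begin());
        } else {
          shi = L;
        }
        int f = s[k];
        if (f < 1 || f > F) stop("founder state out of range");
        for (int si = slo; si < shi; ++si)
          counts[si] += founder_alleles(f - 1, si);
        slo = shi;
      }
    }
    for (int si = 0; si < L; ++si)
      out(si, d) = (double)counts[si] / N;
  }
  return out;
}

// Mean number of breakpoints per gamete (segment-growth diagnostics).
// [[Rcpp::export]]
double cpp_mean_breakpoints(List breaks) {
  double tot = 0;
  int n = breaks.size();
  for (int i = 0; i < n; ++i) tot += Rf_length(breaks[i]);
  return n ? tot / n : 0.0;
}
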