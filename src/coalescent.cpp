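// Hudson-style ancestral recombination graph simulator for one or two
// populations, with a piecewise-constant bottleneck history and migration.
//
// Units follow the ms convention: time in units of 4*N_a generations,
// theta = 4*N_a*mu per locus, rho = 4*N_a*r per locus, migration rates
// 4*N_a*m per lineage.  Population 0 ("wild") has constant relative size 1;
// population 1 ("cultivated") has relative size np_rel on [0, tau1) and
// nb_rel on [tau1, tau2), and merges into population 0 at tau2.  Migration
// is active only while t < tau2.  Mutation follows the infinite-sites model
// on the unit interval.
//
// All randomness comes from R's RNG so set.seed() gives reproducible,
// platform-stable output.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <map>
#include <algorithm>
#include <array>
#include <cmath>

using namespace Rcpp;

namespace {

struct Seg {
  double l, r;   // half-open interval of ancestral material in [0,1)
  int node;      // ARG node carrying this material
  int ndesc;     // number of sampled leaves below 'node' on this interval
};
typedef std::vector<Seg> SegList;

struct Lineage {
  SegList segs;  // sorted, disjoint
  int pop;
  double span() const { return segs.back().r - segs.front().l; }
};

struct Edge {
  int parent, child;
  double l, r;
};

struct Mutation {
  double pos;
  std::vector<int> carriers;
};

// append a segment, merging with the previous one when contiguous and identical
inline void push_seg(SegList &out, const Seg &s) {
  if (s.r <= s.l) return;
  if (!out.empty()) {
    Seg &p = out.back();
    if (p.node == s.node && p.ndesc == s.ndesc && p.r >= s.l - 1e-15) {
      p.r = std::max(p.r, s.r);
      return;
    }
  }
  out.push_back(s);
}

struct Arg {
  std::vector<double> node_time;
  std::vector<Edge> edges;
  int ntot;
};

// coalesce lineages A and B at time t; returns merged lineage (possibly
// empty).  Left cursors al/bl track the unconsumed part of the current
// segment so the input lists are never copied.
Lineage coalesce(const Lineage &A, const Lineage &B, double t, Arg &arg) {
  Lineage out;
  out.pop = A.pop;
  out.segs.reserve(A.segs.size() + B.segs.size());
  int w = -1;
  size_t i = 0, j = 0;
  double al = A.segs.empty() ? 0 : A.segs[0].l;
  double bl = B.segs.empty() ? 0 : B.segs[0].l;
  while (i < A.segs.size() && j < B.segs.size()) {
    const Seg &x = A.segs[i];
    const Seg &y = B.segs[j];
    if (x.r <= bl) {
      push_seg(out.segs, Seg{al, x.r, x.node, x.ndesc});
      if (++i < A.segs.size()) al = A.segs[i].l;
      continue;
    }
    if (y.r <= al) {
      push_seg(out.segs, Seg{bl, y.r, y.node, y.ndesc});
      if (++j < B.segs.size()) bl = B.segs[j].l;
      continue;
    }
    double ol = std::max(al, bl), orr = std::min(x.r, y.r);
    if (al < ol) push_seg(out.segs, Seg{al, ol, x.node, x.ndesc});
    if (bl < ol) push_seg(out.segs, Seg{bl, ol, y.node, y.ndesc});
    if (w < 0) {
      w = (int)arg.node_time.size();
      arg.node_time.push_back(t);
    }
    arg.edges.push_back(Edge{w, x.node, ol, orr});
    arg.edges.push_back(Edge{w, y.node, ol, orr});
    int nd = x.ndesc + y.ndesc;
    if (nd < arg.ntot) push_seg(out.segs, Seg{ol, orr, w, nd});
    al = orr;
    bl = orr;
    if (al >= x.r) { if (++i < A.segs.size()) al = A.segs[i].l; }
    if (bl >= y.r) { if (++j < B.segs.size()) bl = B.segs[j].l; }
  }
  for (; i < A.segs.size(); ++i) {
    push_seg(out.segs, Seg{al, A.segs[i].r, A.segs[i].node, A.segs[i].ndesc});
    if (i + 1 < A.segs.size()) al = A.segs[i + 1].l;
  }
  for (; j < B.segs.size(); ++j) {
    push_seg(out.segs, Seg{bl, B.segs[j].r, B.segs[j].node, B.segs[j].ndesc});
    if (j + 1 < B.segs.size()) bl = B.segs[j + 1].l;
  }
  return out;
}

// Simulate the ARG and drop infinite-sites mutations.  Returns mutations
// sorted by position.
std::vector<Mutation> simulate_arg(int n1, int n2, double theta, double rho,
                                   double tau1, double tau2, double nb_rel,
                                   double np_rel, double mig_cw, double mig_wc) {
  if (nb_rel <= 0 || np_rel <= 0)
    stop("bottleneck and present population sizes must be positive");
  Arg arg;
  arg.ntot = n1 + n2;
  arg.node_time.assign(arg.ntot, 0.0);

  // lineages partitioned by population; removal is swap-and-pop
  std::vector<Lineage> pops[2];
  pops[0].reserve(4 * arg.ntot);
  pops[1].reserve(4 * arg.ntot);
  double spansum = 0.0;  // total ancestral-material span, maintained
  for (int s = 0; s < arg.ntot; ++s) {
    Lineage L;
    L.pop = (s < n1 || tau2 <= 0.0) ? 0 : 1;  // split at present = one pool
    L.segs.push_back(Seg{0.0, 1.0, s, 1});
    pops[L.pop].push_back(L);
    spansum += 1.0;
  }

  double t = 0.0;
  while (!pops[0].empty() || !pops[1].empty()) {
    double k0 = (double)pops[0].size(), k1 = (double)pops[1].size();
    bool structured = t < tau2;
    double size1 = (t < tau1) ? np_rel : nb_rel;
    double r_c0 = k0 * (k0 - 1);
    double r_c1 = structured ? k1 * (k1 - 1) / size1 : 0.0;
    double r_rec = rho * spansum;
    double r_m10 = structured ? k1 * mig_cw : 0.0;  // cultivated -> wild (backward)
    double r_m01 = structured ? k0 * mig_wc : 0.0;  // wild -> cultivated (backward)
    double R = r_c0 + r_c1 + r_rec + r_m10 + r_m01;

    double tev = (R > 0) ? t + R::exp_rand() / R : R_PosInf;
    if (t < tau1 && tev >= tau1) { t = tau1; continue; }
    if (t < tau2 && tev >= tau2) {
      t = tau2;
      for (size_t i = 0; i < pops[1].size(); ++i) {
        pops[1][i].pop = 0;
        pops[0].push_back(std::move(pops[1][i]));
      }
      pops[1].clear();
      continue;
    }
    if (!R_FINITE(tev)) stop("coalescent stalled: no event possible");
    t = tev;

    double u = R::unif_rand() * R;
    if (u < r_c0 + r_c1) {
      int pop = (u < r_c0) ? 0 : 1;
      std::vector<Lineage> &P = pops[pop];
      int k = (int)P.size();
      int a = (int)(R::unif_rand() * k); if (a >= k) a = k - 1;
      int b = (int)(R::unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
      if (b >= a) ++b;
      spansum -= P[a].span() + P[b].span();
      Lineage merged = coalesce(P[a], P[b], t, arg);
      if (a < b) std::swap(a, b);  // remove the larger index first
      if (a != (int)P.size() - 1) P[a] = std::move(P.back());
      P.pop_back();
      if (b != (int)P.size() - 1) P[b] = std::move(P.back());
      P.pop_back();
      if (!merged.segs.empty()) {
        spansum += merged.span();
        merged.pop = pop;
        P.push_back(std::move(merged));
      }
    } else if (u < r_c0 + r_c1 + r_rec) {
      // recombination: pick lineage weighted by span
      double v = (u - r_c0 - r_c1) / rho;
      int pick = -1, pp = 0;
      for (pp = 0; pp < 2 && pick < 0; ++pp) {
        for (size_t i = 0; i < pops[pp].size(); ++i) {
          v -= pops[pp][i].span();
          if (v <= 0) { pick = (int)i; break; }
        }
        if (pick >= 0) break;
      }
      if (pick < 0) { pp = pops[1].empty() ? 0 : 1; pick = (int)pops[pp].size() - 1; }
      Lineage &L = pops[pp][pick];
      double lo = L.segs.front().l, hi = L.segs.back().r;
      double cut = lo + R::unif_rand() * (hi - lo);
      if (cut <= lo || cut >= hi) continue;  // measure-zero guard
      SegList keepL, keepR;
      for (size_t s = 0; s < L.segs.size(); ++s) {
        const Seg &sg = L.segs[s];
        if (sg.r <= cut) keepL.push_back(sg);
        else if (sg.l >= cut) keepR.push_back(sg);
        else {
          keepL.push_back(Seg{sg.l, cut, sg.node, sg.ndesc});
          keepR.push_back(Seg{cut, sg.r, sg.node, sg.ndesc});
        }
      }
      if (keepL.empty() || keepR.empty()) continue;
      double span_old = L.span();
      Lineage right;
      right.pop = L.pop;
      right.segs = std::move(keepR);
      L.segs = std::move(keepL);
      spansum += L.span() + right.span() - span_old;
      pops[pp].push_back(std::move(right));
    } else {
      // migration
      int from = (u < r_c0 + r_c1 + r_rec + r_m10) ? 1 : 0;
      std::vector<Lineage> &P = pops[from];
      if (P.empty()) continue;
      int a = (int)(R::unif_rand() * P.size());
      if (a >= (int)P.size()) a = (int)P.size() - 1;
      P[a].pop = 1 - from;
      pops[1 - from].push_back(std::move(P[a]));
      if (a != (int)P.size() - 1) P[a] = std::move(P.back());
      P.pop_back();
    }
  }

  // drop mutations on edges; children-of-parent adjacency in CSR layout
  size_t nnode = arg.node_time.size(), nedge = arg.edges.size();
  std::vector<int> kid_off(nnode + 1, 0), kid_idx(nedge);
  for (size_t e = 0; e < nedge; ++e) kid_off[arg.edges[e].parent + 1]++;
  for (size_t v = 0; v < nnode; ++v) kid_off[v + 1] += kid_off[v];
  {
    std::vector<int> cur(kid_off.begin(), kid_off.end() - 1);
    for (size_t e = 0; e < nedge; ++e)
      kid_idx[cur[arg.edges[e].parent]++] = (int)e;
  }

  std::vector<Mutation> muts;
  if (theta > 0) {
    for (size_t e = 0; e < arg.edges.size(); ++e) {
      const Edge &ed = arg.edges[e];
      double dt = arg.node_time[ed.parent] - arg.node_time[ed.child];
      double lam = theta * dt * (ed.r - ed.l);
      if (lam <= 0) continue;
      int nm = (int)R::rpois(lam);
      for (int m = 0; m < nm; ++m) {
        Mutation mu;
        mu.pos = ed.l + R::unif_rand() * (ed.r - ed.l);
        // collect leaves below ed.child at mu.pos
        std::vector<int> stack;
        stack.push_back(ed.child);
        while (!stack.empty()) {
          int v = stack.back();
          stack.pop_back();
          if (v < arg.ntot) { mu.carriers.push_back(v); continue; }
          for (int q = kid_off[v]; q < kid_off[v + 1]; ++q) {
            const Edge &ce = arg.edges[kid_idx[q]];
            if (ce.l <= mu.pos && mu.pos < ce.r) stack.push_back(ce.child);
          }
        }
        if (!mu.carriers.empty()) muts.push_back(mu);
      }
    }
  }
  std::sort(muts.begin(), muts.end(),
            [](const Mutation &a, const Mutation &b) { return a.pos < b.pos; });
  return muts;
}

// Hill-Weir expectation of r^2 for scaled recombination C and sample size n
inline double er2(double C, double n) {
  double a = (10.0 + C) / ((2.0 + C) * (11.0 + C));
  double b = ((3.0 + C) * (12.0 + 12.0 * C + C * C)) / (n * (2.0 + C) * (11.0 + C));
  return a * (1.0 + b);
}

double rho_sse(double lr, const std::vector<double> &d,
               const std::vector<double> &r2, double n) {
  double rho = std::pow(10.0, lr), s = 0.0;
  for (size_t i = 0; i < d.size(); ++i) {
    double e = er2(rho * d[i], n);
    s += (r2[i] - e) * (r2[i] - e);
  }
  return s;
}

// Least-squares fit of the Hill-Weir curve over pairwise r2.
// Coarse log10 grid then golden-section refinement; must stay in lockstep
// with the R implementation in hw_rho_fit().
double fit_rho(const std::vector<double> &d, const std::vector<double> &r2,
               double n) {
  double best_lr = -8.0, best = R_PosInf;
  for (double lr = -8.0; lr <= 3.0 + 1e-9; lr += 0.25) {
    double s = rho_sse(lr, d, r2, n);
    if (s < best) { best = s; best_lr = lr; }
  }
  double lo = best_lr - 0.25, hi = best_lr + 0.25;
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double c = hi - gr * (hi - lo), dd = lo + gr * (hi - lo);
  double fc = rho_sse(c, d, r2, n), fd = rho_sse(dd, d, r2, n);
  for (int it = 0; it < 60; ++it) {
    if (fc < fd) {
      hi = dd; dd = c; fd = fc;
      c = hi - gr * (hi - lo);
      fc = rho_sse(c, d, r2, n);
    } else {
      lo = c; c = dd; fc = fd;
      dd = lo + gr * (hi - lo);
      fd = rho_sse(dd, d, r2, n);
    }
  }
  return std::pow(10.0, (lo + hi) / 2.0);
}

// summary statistics for rows [a, b) of the binary matrix
void subset_stats(const std::vector<Mutation> &muts, int a, int b,
                  double &S, double &pi, double &hap, double &hdiv) {
  int m = b - a;
  S = 0; pi = 0;
  int M = (int)muts.size();
  std::vector<std::string> rows(m, std::string(M, '0'));
  for (int j = 0; j < M; ++j) {
    int c = 0;
    for (size_t q = 0; q < muts[j].carriers.size(); ++q) {
      int v = muts[j].carriers[q];
      if (v >= a && v < b) { ++c; rows[v - a][j] = '1'; }
    }
    if (c > 0 && c < m) {
      S += 1;
      pi += (double)c * (m - c);
    }
  }
  pi /= (double)m * (m - 1) / 2.0;
  std::map<std::string, int> tab;
  for (int i = 0; i < m; ++i) tab[rows[i]]++;
  hap = (double)tab.size();
  double sp2 = 0.0;
  for (std::map<std::string, int>::iterator it = tab.begin(); it != tab.end(); ++it) {
    double p = (double)it->second / m;
    sp2 += p * p;
  }
  hdiv = (m > 1) ? (1.0 - sp2) * m / (m - 1.0) : 0.0;
}

// Ratio-of-moments objective: total D^2 across pairs against its
// expectation sum er2(rho*d) * pq*pq.  Much less biased than per-pair
// least squares on r2, whose frequency conditioning inflates rho.
double moment_sse(double lr, const std::vector<double> &d,
                  const std::vector<double> &D2, const std::vector<double> &w,
                  double n) {
  double rho = std::pow(10.0, lr), lhs = 0.0, rhs = 0.0;
  for (size_t i = 0; i < d.size(); ++i) {
    lhs += D2[i];
    rhs += er2(rho * d[i], n) * w[i];
  }
  double g = lhs - rhs;
  return g * g;
}

// Solve the moment condition on a log10 grid with golden-section
// refinement; must stay in lockstep with the R implementation.
double fit_rho_moment(const std::vector<double> &d,
                      const std::vector<double> &D2,
                      const std::vector<double> &w, double n) {
  double best_lr = -8.0, best = R_PosInf;
  for (double lr = -8.0; lr <= 3.0 + 1e-9; lr += 0.25) {
    double s = moment_sse(lr, d, D2, w, n);
    if (s < best) { best = s; best_lr = lr; }
  }
  double lo = best_lr - 0.25, hi = best_lr + 0.25;
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double c = hi - gr * (hi - lo), dd = lo + gr * (hi - lo);
  double fc = moment_sse(c, d, D2, w, n), fd = moment_sse(dd, d, D2, w, n);
  for (int it = 0; it < 60; ++it) {
    if (fc < fd) {
      hi = dd; dd = c; fd = fc;
      c = hi - gr * (hi - lo);
      fc = moment_sse(c, d, D2, w, n);
    } else {
      lo = c; c = dd; fc = fd;
      dd = lo + gr * (hi - lo);
      fd = moment_sse(dd, d, D2, w, n);
    }
  }
  return std::pow(10.0, (lo + hi) / 2.0);
}

// per-locus rho estimate for rows [a,b); distances in fractions of the
// locus, so the estimate is a per-locus total rho.  Singleton sites are
// excluded.  Returns NA when fewer than two usable sites exist.
double subset_rho(const std::vector<Mutation> &muts, int a, int b) {
  int m = b - a;
  std::vector<double> pos;
  std::vector<std::vector<char> > cols;
  for (size_t j = 0; j < muts.size(); ++j) {
    std::vector<char> col(m, 0);
    int c = 0;
    for (size_t q = 0; q < muts[j].carriers.size(); ++q) {
      int v = muts[j].carriers[q];
      if (v >= a && v < b) { col[v - a] = 1; ++c; }
    }
    int minor = std::min(c, m - c);
    if (minor >= 2) { pos.push_back(muts[j].pos); cols.push_back(col); }
  }
  int K = (int)pos.size();
  if (K < 2) return NA_REAL;
  std::vector<double> d, D2, w;
  for (int i = 0; i < K; ++i) {
    for (int j = i + 1; j < K; ++j) {
      int ci = 0, cj = 0, cij = 0;
      for (int q = 0; q < m; ++q) {
        ci += cols[i][q];
        cj += cols[j][q];
        cij += cols[i][q] & cols[j][q];
      }
      double pA = (double)ci / m, pB = (double)cj / m, pAB = (double)cij / m;
      double den = pA * (1 - pA) * pB * (1 - pB);
      if (den <= 0) continue;
      double D = pAB - pA * pB;
      d.push_back(pos[j] - pos[i]);
      D2.push_back(D * D);
      w.push_back(den);
    }
  }
  if (d.empty()) return NA_REAL;
  return fit_rho_moment(d, D2, w, (double)m);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".sim_locus_cpp")]]
List sim_locus_cpp(int n1, int n2, double theta, double rho, double tau1,
                   double tau2, double nb_rel, double np_rel, double mig_cw,
                   double mig_wc) {
  std::vector<Mutation> muts =
      simulate_arg(n1, n2, theta, rho, tau1, tau2, nb_rel, np_rel, mig_cw, mig_wc);
  int M = (int)muts.size(), ntot = n1 + n2;
  IntegerMatrix mat(ntot, M);
  NumericVector pos(M);
  for (int j = 0; j < M; ++j) {
    pos[j] = muts[j].pos;
    for (size_t q = 0; q < muts[j].carriers.size(); ++q)
      mat(muts[j].carriers[q], j) = 1;
  }
  return List::create(_["matrix"] = mat, _["positions"] = pos);
}

//' @noRd
// [[Rcpp::export(name = ".sim_panel_stats_cpp")]]
NumericMatrix sim_panel_stats_cpp(IntegerVector n1, IntegerVector n2,
                                  NumericVector theta, NumericVector rho,
                                  double tau1, double tau2, double nb_rel,
                                  double np_rel, double mig_cw, double mig_wc,
                                  bool want_rho) {
  int L = n1.size();
  NumericMatrix out(L, 9);
  colnames(out) = CharacterVector::create("S_w", "pi_w", "hap_w", "hdiv_w",
                                          "S_c", "pi_c", "hap_c", "hdiv_c",
                                          "rho_c");
  for (int i = 0; i < L; ++i) {
    std::vector<Mutation> muts = simulate_arg(
        n1[i], n2[i], theta[i], rho[i], tau1, tau2, nb_rel, np_rel, mig_cw, mig_wc);
    double S, pi, hap, hdiv;
    subset_stats(muts, 0, n1[i], S, pi, hap, hdiv);
    out(i, 0) = S; out(i, 1) = pi; out(i, 2) = hap; out(i, 3) = hdiv;
    if (n2[i] > 0) {
      subset_stats(muts, n1[i], n1[i] + n2[i], S, pi, hap, hdiv);
      out(i, 4) = S; out(i, 5) = pi; out(i, 6) = hap; out(i, 7) = hdiv;
      out(i, 8) = want_rho ? subset_rho(muts, n1[i], n1[i] + n2[i]) : NA_REAL;
    } else {
      out(i, 4) = out(i, 5) = out(i, 6) = out(i, 7) = out(i, 8) = NA_REAL;
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".hw_rho_fit_cpp")]]
double hw_rho_fit_cpp(NumericVector d, NumericVector r2, double n) {
  std::vector<double> dv(d.begin(), d.end()), rv(r2.begin(), r2.end());
  return fit_rho(dv, rv, n);
}

//' @noRd
// [[Rcpp::export(name = ".hw_rho_moment_cpp")]]
double hw_rho_moment_cpp(NumericVector d, NumericVector D2, NumericVector w,
                         double n) {
  std::vector<double> dv(d.begin(), d.end()), D2v(D2.begin(), D2.end()),
      wv(w.begin(), w.end());
  return fit_rho_moment(dv, D2v, wv, n);
}

// multiplicative acceptance band shared by the rejection loops; when the
// observed value is zero the band is |sim| <= tol * scale0
static inline bool within_band(double sim, double obs, double tol,
                               double scale0) {
  return (obs == 0.0) ? std::fabs(sim) <= tol * scale0
                      : std::fabs(sim - obs) <= tol * std::fabs(obs);
}

//' @noRd
// [[Rcpp::export(name = ".abc_standard_loop_cpp")]]
List abc_standard_loop_cpp(IntegerVector n, NumericVector L,
                           NumericVector theta_box, NumericVector rho_box,
                           NumericVector obs, NumericVector sd0, double tol,
                           int min_stats, int n_accept, double max_draws) {
  int nloc = n.size();
  NumericMatrix acc(n_accept, 2);
  double tried = 0;
  int got = 0;
  int allowed = 4 - min_stats;
  std::vector<double> upper(4);
  for (int s = 0; s < 4; ++s)
    upper[s] = (obs[s] == 0 ? tol * sd0[s]
                            : obs[s] + tol * std::fabs(obs[s])) * nloc;
  while (got < n_accept && tried < max_draws) {
    tried += 1;
    if (((long long)tried) % 512 == 0) Rcpp::checkUserInterrupt();
    double th = R::runif(theta_box[0], theta_box[1]);
    double rh = R::runif(rho_box[0], rho_box[1]);
    double sums[4] = {0, 0, 0, 0};
    bool alive = true;
    for (int i = 0; i < nloc; ++i) {
      std::vector<Mutation> muts =
          simulate_arg(n[i], 0, th * L[i], rh * L[i], 0, 0, 1, 1, 0, 0);
      double S, pi, hap, hdiv;
      subset_stats(muts, 0, n[i], S, pi, hap, hdiv);
      sums[0] += S; sums[1] += pi / L[i]; sums[2] += hap; sums[3] += hdiv;
      int over = 0;
      for (int s = 0; s < 4; ++s) if (sums[s] > upper[s]) ++over;
      if (over > allowed) { alive = false; break; }
    }
    if (!alive) continue;
    int pass = 0;
    for (int s = 0; s < 4; ++s)
      if (within_band(sums[s] / nloc, obs[s], tol, sd0[s])) ++pass;
    if (pass >= min_stats) {
      acc(got, 0) = th;
      acc(got, 1) = rh;
      ++got;
    }
  }
  return List::create(_["accepted"] = acc, _["got"] = got,
                      _["tried"] = tried);
}

//' @noRd
// [[Rcpp::export(name = ".abc_bottleneck_loop_cpp")]]
List abc_bottleneck_loop_cpp(IntegerVector n1, IntegerVector n2,
                             NumericVector theta_loc, NumericVector rho_loc,
                             NumericVector L, double Na, double np_rel,
                             NumericVector t2_box, NumericVector d_box,
                             NumericVector k_box, NumericVector m12_box,
                             NumericVector m21_box, NumericVector ow_m,
                             NumericVector ow_v, double tol1, int n_stage1,
                             double max_draws) {
  int nloc = n1.size();
  NumericMatrix acc(n_stage1, 9);
  double tried = 0;
  int got = 0;
  std::vector<double> upper(4), sdm(4);
  for (int s = 0; s < 4; ++s) {
    sdm[s] = std::sqrt(std::max(ow_v[s], 0.0));
    upper[s] = (ow_m[s] == 0 ? tol1 * sdm[s]
                             : ow_m[s] + tol1 * std::fabs(ow_m[s])) * nloc;
  }
  std::vector<std::vector<Mutation> > panel(nloc);
  std::vector<std::array<double, 4> > wst(nloc);
  while (got < n_stage1 && tried < max_draws) {
    tried += 1;
    if (((long long)tried) % 256 == 0) Rcpp::checkUserInterrupt();
    double t2 = R::runif(t2_box[0], t2_box[1]);
    double d = R::runif(d_box[0], d_box[1]);
    double k = R::runif(k_box[0], k_box[1]);
    double m12 = R::runif(m12_box[0], m12_box[1]);
    double m21 = R::runif(m21_box[0], m21_box[1]);
    double tau1 = (t2 - d) / (4.0 * Na), tau2 = t2 / (4.0 * Na);
    double nb_rel = k * d / Na;
    double sums[4] = {0, 0, 0, 0};
    bool alive = true;
    int done = 0;
    for (int i = 0; i < nloc; ++i) {
      panel[i] = simulate_arg(n1[i], n2[i], theta_loc[i], rho_loc[i], tau1,
                              tau2, nb_rel, np_rel, m12, m21);
      double S, pi, hap, hdiv;
      subset_stats(panel[i], 0, n1[i], S, pi, hap, hdiv);
      wst[i] = {S, pi / L[i], hap, hdiv};
      done = i + 1;
      // every wild mean must be in band: one exceeded upper total rejects
      bool over = false;
      for (int s = 0; s < 4; ++s) {
        sums[s] += wst[i][s];
        if (sums[s] > upper[s]) over = true;
      }
      if (over) { alive = false; break; }
    }
    if (!alive) continue;
    bool ok = true;
    for (int s = 0; s < 4 && ok; ++s)
      ok = within_band(sums[s] / nloc, ow_m[s], tol1, sdm[s]);
    for (int s = 0; s < 4 && ok; ++s) {
      double m = sums[s] / nloc, v = 0;
      for (int i = 0; i < nloc; ++i)
        v += (wst[i][s] - m) * (wst[i][s] - m);
      v /= (nloc - 1);
      ok = within_band(v, ow_v[s], tol1, 1.0);
    }
    if (!ok) continue;
    // cultivated summaries (including the per-locus rho estimate) are only
    // computed for stage-1 acceptances
    double Sc = 0, hapc = 0, hdivc = 0, rhoc = 0;
    int nrho = 0;
    for (int i = 0; i < nloc; ++i) {
      double S, pi, hap, hdiv;
      subset_stats(panel[i], n1[i], n1[i] + n2[i], S, pi, hap, hdiv);
      Sc += S; hapc += hap; hdivc += hdiv;
      double rh = subset_rho(panel[i], n1[i], n1[i] + n2[i]);
      if (!ISNAN(rh)) { rhoc += rh; ++nrho; }
    }
    acc(got, 0) = t2; acc(got, 1) = d; acc(got, 2) = k;
    acc(got, 3) = m12; acc(got, 4) = m21;
    acc(got, 5) = Sc / nloc;
    acc(got, 6) = nrho > 0 ? rhoc / nrho : NA_REAL;
    acc(got, 7) = hapc / nloc;
    acc(got, 8) = hdivc / nloc;
    ++got;
    (void)done;
  }
  return List::create(_["accepted"] = acc, _["got"] = got,
                      _["tried"] = tried);
}
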