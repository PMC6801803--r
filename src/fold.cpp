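// Thermodynamic folding kernels: minimum-free-energy dynamic program with
// deterministic traceback, best-first complete suboptimal enumeration
// (priority-queue Wuchty variant over an unambiguous grammar), and the
// McCaskill inside-outside partition function. All three share a single
// energy kernel (stacking + loop-length penalties + linear multibranch +
// per-stacked-nucleotide SHAPE pseudo-energies).
//
// Grammar (unambiguous; identical for MFE, suboptimals and PF):
//   W(j)    : exterior prefix, unpaired bases free
//   V(i,j)  : structure closed by pair (i,j): hairpin | internal(k,l) | ML
//   ML body : M(i+1,u) + M1(u+1,j-1)    (last branch isolated in M1)
//   M(i,j)  : >=1 branch; split at last branch k: [empty|unpaired|M] + M1(k,j)
//   M1(i,j) : exactly one branch starting at i, trailing bases unpaired

#include <Rcpp.h>
#include <queue>
#include <array>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF_E = 1e9;
static const double EPS = 1e-7;

// pair type: 0 none; 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA (A=0,C=1,G=2,U=3)
static const int PTAB[4][4] = {
  {0, 0, 0, 5},
  {0, 0, 1, 0},
  {0, 2, 0, 3},
  {6, 0, 4, 0}};

struct Params {
  std::vector<double> stack;           // 6x6 col-major
  std::vector<double> hairpin, bulge, internal_; // size 30, idx size-1
  double lxc, ml_a, ml_b, ml_c, ninio_m, ninio_max, RT;
  int max_loop;
};

static Params load_params(const List& par) {
  Params p;
  NumericMatrix st = par["stack"];
  p.stack.assign(st.begin(), st.end());
  NumericVector h = par["hairpin"], b = par["bulge"], in = par["internal"];
  p.hairpin.assign(h.begin(), h.end());
  p.bulge.assign(b.begin(), b.end());
  p.internal_.assign(in.begin(), in.end());
  p.lxc = par["lxc"]; p.ml_a = par["ml_a"]; p.ml_b = par["ml_b"];
  p.ml_c = par["ml_c"]; p.ninio_m = par["ninio_m"];
  p.ninio_max = par["ninio_max"]; p.RT = par["RT"];
  p.max_loop = par["max_loop"];
  return p;
}

struct Fold {
  int n;
  std::vector<int> s;            // encoded sequence
  std::vector<double> g;         // per-nucleotide pseudo-energy
  const Params* p;
  std::vector<double> V, M, M1, W;

  inline int pt(int i, int j) const { return PTAB[s[i]][s[j]]; }
  inline double stackE(int i, int j, int k, int l) const {
    // closing (i,j), inner (k,l): table row type(i,j), col type(l,k)
    int a = pt(i, j), b = pt(l, k);
    return p->stack[(b - 1) * 6 + (a - 1)];
  }
  inline double lenpen(const std::vector<double>& tab, int size) const {
    if (size < 1) return INF_E;
    if (size <= 30) return tab[size - 1];
    return tab[29] + p->lxc * std::log((double)size / 30.0);
  }
  inline double e_hairpin(int i, int j) const {
    return lenpen(p->hairpin, j - i - 1);
  }
  // internal/bulge/stack energy of (i,j) enclosing (k,l)
  inline double e_int(int i, int j, int k, int l) const {
    int n1 = k - i - 1, n2 = j - l - 1;
    if (n1 == 0 && n2 == 0)
      return stackE(i, j, k, l) + g[i] + g[j] + g[k] + g[l];
    if (n1 == 0 || n2 == 0) {
      double e = lenpen(p->bulge, n1 + n2);
      if (n1 + n2 == 1) e += stackE(i, j, k, l);
      return e;
    }
    double asym = p->ninio_m * std::abs(n1 - n2);
    if (asym > p->ninio_max) asym = p->ninio_max;
    return lenpen(p->internal_, n1 + n2) + asym;
  }

  inline double vV(int i, int j) const { return V[(size_t)i * n + j]; }
  inline double vM(int i, int j) const {
    return (j < i) ? INF_E : M[(size_t)i * n + j];
  }
  inline double vM1(int i, int j) const {
    return (j < i) ? INF_E : M1[(size_t)i * n + j];
  }

  void run() {
    V.assign((size_t)n * n, INF_E);
    M.assign((size_t)n * n, INF_E);
    M1.assign((size_t)n * n, INF_E);
    for (int i = n - 1; i >= 0; --i) {
      for (int j = i + 1; j < n; ++j) {
        size_t ij = (size_t)i * n + j;
        // ---- V ----
        if (j - i >= 4 && pt(i, j)) {
          double best = e_hairpin(i, j);
          int kmax = std::min(i + 1 + p->max_loop, j - 5);
          for (int k = i + 1; k <= kmax; ++k) {
            int n1 = k - i - 1;
            int lmin = std::max(k + 4, j - 1 - (p->max_loop - n1));
            for (int l = lmin; l <= j - 1; ++l) {
              if (!pt(k, l)) continue;
              double v = vV(k, l);
              if (v >= INF_E / 2) continue;
              double e = e_int(i, j, k, l) + v;
              if (e < best) best = e;
            }
          }
          for (int u = i + 5; u <= j - 6; ++u) {
            double a = vM(i + 1, u), b = vM1(u + 1, j - 1);
            if (a >= INF_E / 2 || b >= INF_E / 2) continue;
            double e = p->ml_a + p->ml_b + a + b;
            if (e < best) best = e;
          }
          V[ij] = best;
        }
        // ---- M1 ----
        {
          double best = INF_E;
          if (j > i) {
            double prev = vM1(i, j - 1);
            if (prev < INF_E / 2) best = prev + p->ml_c;
          }
          if (j - i >= 4 && pt(i, j) && V[ij] < INF_E / 2)
            best = std::min(best, V[ij] + p->ml_b);
          M1[ij] = best;
        }
        // ---- M ----
        {
          double best = INF_E;
          for (int k = i; k <= j - 4; ++k) {
            double m1 = vM1(k, j);
            if (m1 >= INF_E / 2) continue;
            double pre = 0.0;
            if (k > i) {
              pre = p->ml_c * (k - i);
              double mm = vM(i, k - 1);
              if (mm < pre) pre = mm;
            }
            if (pre + m1 < best) best = pre + m1;
          }
          M[ij] = best;
        }
      }
    }
    W.assign(n + 1, 0.0);
    for (int j = 1; j <= n; ++j) {
      double best = W[j - 1];
      for (int k = 1; k + 4 <= j; ++k) {
        int i0 = k - 1, j0 = j - 1;
        if (!pt(i0, j0)) continue;
        double v = vV(i0, j0);
        if (v >= INF_E / 2) continue;
        double e = W[k - 1] + v;
        if (e < best) best = e;
      }
      W[j] = best;
    }
  }

  // deterministic traceback: prefer unpaired, then smallest opening index
  void traceback(std::vector<int>& partner) {
    partner.assign(n, 0); // 1-based partner, 0 = unpaired
    struct Item { int type, i, j; }; // 0 EXT(j), 1 V, 2 M, 3 M1
    std::vector<Item> st;
    st.push_back({0, 0, n});
    while (!st.empty()) {
      Item it = st.back(); st.pop_back();
      if (it.type == 0) {
        int j = it.j;
        if (j < 5) continue;
        if (std::fabs(W[j] - W[j - 1]) <= EPS) { st.push_back({0, 0, j - 1}); continue; }
        bool found = false;
        for (int k = 1; k + 4 <= j && !found; ++k) {
          int i0 = k - 1, j0 = j - 1;
          if (!pt(i0, j0) || vV(i0, j0) >= INF_E / 2) continue;
          if (std::fabs(W[k - 1] + vV(i0, j0) - W[j]) <= EPS) {
            partner[i0] = j0 + 1; partner[j0] = i0 + 1;
            st.push_back({0, 0, k - 1});
            st.push_back({1, i0, j0});
            found = true;
          }
        }
        if (!found) stop("traceback failure (exterior)");
      } else if (it.type == 1) {
        int i = it.i, j = it.j;
        double target = vV(i, j);
        if (std::fabs(e_hairpin(i, j) - target) <= EPS) continue;
        bool found = false;
        int kmax = std::min(i + 1 + p->max_loop, j - 5);
        for (int k = i + 1; k <= kmax && !found; ++k) {
          int n1 = k - i - 1;
          int lmin = std::max(k + 4, j - 1 - (p->max_loop - n1));
          for (int l = lmin; l <= j - 1 && !found; ++l) {
            if (!pt(k, l) || vV(k, l) >= INF_E / 2) continue;
            if (std::fabs(e_int(i, j, k, l) + vV(k, l) - target) <= EPS) {
              partner[k] = l + 1; partner[l] = k + 1;
              st.push_back({1, k, l});
              found = true;
            }
          }
        }
        for (int u = i + 5; u <= j - 6 && !found; ++u) {
          double a = vM(i + 1, u), b = vM1(u + 1, j - 1);
          if (a >= INF_E / 2 || b >= INF_E / 2) continue;
          if (std::fabs(p->ml_a + p->ml_b + a + b - target) <= EPS) {
            st.push_back({2, i + 1, u});
            st.push_back({3, u + 1, j - 1});
            found = true;
          }
        }
        if (!found) stop("traceback failure (V)");
      } else if (it.type == 2) {
        int i = it.i, j = it.j;
        double target = vM(i, j);
        bool found = false;
        for (int k = i; k <= j - 4 && !found; ++k) {
          double m1 = vM1(k, j);
          if (m1 >= INF_E / 2) continue;
          double preu = (k == i) ? 0.0 : p->ml_c * (k - i);
          if (std::fabs(preu + m1 - target) <= EPS) {
            st.push_back({3, k, j});
            found = true;
          } else if (k > i && vM(i, k - 1) < INF_E / 2 &&
                     std::fabs(vM(i, k - 1) + m1 - target) <= EPS) {
            st.push_back({2, i, k - 1});
            st.push_back({3, k, j});
            found = true;
          }
        }
        if (!found) stop("traceback failure (M)");
      } else {
        int i = it.i, j = it.j;
        double target = vM1(i, j);
        if (j > i && vM1(i, j - 1) < INF_E / 2 &&
            std::fabs(vM1(i, j - 1) + p->ml_c - target) <= EPS) {
          st.push_back({3, i, j - 1});
        } else if (pt(i, j) && vV(i, j) < INF_E / 2 &&
                   std::fabs(vV(i, j) + p->ml_b - target) <= EPS) {
          partner[i] = j + 1; partner[j] = i + 1;
          st.push_back({1, i, j});
        } else stop("traceback failure (M1)");
      }
    }
  }
};

static Fold make_fold(const IntegerVector& seq, const NumericVector& g,
                      const Params* p) {
  Fold f;
  f.n = seq.size();
  f.s.assign(seq.begin(), seq.end());
  f.g.assign(g.begin(), g.end());
  f.p = p;
  return f;
}

// [[Rcpp::export]]
List c_fold_mfe(IntegerVector seq, NumericVector g, List par) {
  Params p = load_params(par);
  Fold f = make_fold(seq, g, &p);
  if (f.n < 5) {
    return List::create(_["partner"] = IntegerVector(f.n, 0),
                        _["energy"] = 0.0);
  }
  f.run();
  std::vector<int> partner;
  f.traceback(partner);
  return List::create(_["partner"] = IntegerVector(partner.begin(), partner.end()),
                      _["energy"] = f.W[f.n]);
}

// ---- best-first complete suboptimal enumeration --------------------------

struct SubState {
  std::vector<int> intervals;        // packed triples (type,i,j)
  std::vector<int> pairs;            // packed (i,j) 0-based
  double e, bound;
};
using IV = std::array<int, 3>;

struct SubCmp {
  bool operator()(const SubState& a, const SubState& b) const {
    return a.bound > b.bound;
  }
};

// [[Rcpp::export]]
List c_subopt(IntegerVector seq, NumericVector g, List par,
              int max_models, double window, double max_states) {
  Params p = load_params(par);
  Fold f = make_fold(seq, g, &p);
  int n = f.n;
  List out;
  if (n < 5) {
    out.push_back(List::create(_["partner"] = IntegerVector(n, 0),
                               _["energy"] = 0.0));
    return out;
  }
  f.run();
  double mfe = f.W[n];
  double emax = mfe + window + EPS;
  std::priority_queue<SubState, std::vector<SubState>, SubCmp> pq;
  SubState init;
  init.e = 0.0; init.bound = f.W[n];
  init.intervals = {0, 0, n}; // EXT(n)
  pq.push(init);
  double expansions = 0;
  auto val = [&](int type, int i, int j) -> double {
    switch (type) {
      case 0: return f.W[j];
      case 1: return f.vV(i, j);
      case 2: return f.vM(i, j);
      default: return f.vM1(i, j);
    }
  };
  auto child = [&](const SubState& base, double cost,
                   const std::vector<std::array<int, 3>>& ivs,
                   int pi, int pj) {
    double b = base.bound + cost;
    for (auto& iv : ivs) b += val(iv[0], iv[1], iv[2]);
    if (b > emax) return;
    SubState st = base;
    st.e += cost;
    st.bound = b;
    for (auto& iv : ivs) {
      st.intervals.push_back(iv[0]); st.intervals.push_back(iv[1]);
      st.intervals.push_back(iv[2]);
    }
    if (pi >= 0) { st.pairs.push_back(pi); st.pairs.push_back(pj); }
    pq.push(st);
  };
  while (!pq.empty() && (int)out.size() < max_models) {
    if (++expansions > max_states) {
      warning("suboptimal enumeration state cap reached; list may be truncated");
      break;
    }
    SubState cur = pq.top(); pq.pop();
    if (cur.bound > emax) break;
    if (cur.intervals.empty()) {
      IntegerVector partner(n, 0);
      for (size_t q = 0; q < cur.pairs.size(); q += 2) {
        partner[cur.pairs[q]] = cur.pairs[q + 1] + 1;
        partner[cur.pairs[q + 1]] = cur.pairs[q] + 1;
      }
      out.push_back(List::create(_["partner"] = partner,
                                 _["energy"] = cur.e));
      continue;
    }
    int j = cur.intervals.back(); cur.intervals.pop_back();
    int i = cur.intervals.back(); cur.intervals.pop_back();
    int type = cur.intervals.back(); cur.intervals.pop_back();
    double v = val(type, i, j);
    cur.bound -= v;
    if (type == 0) {
      if (j < 5) { // nothing can pair; all unpaired
        SubState st = cur; pq.push(st); continue;
      }
      if (j - 1 >= 1) child(cur, 0.0, {IV{0, 0, j - 1}}, -1, -1);
      else child(cur, 0.0, {}, -1, -1);
      for (int k = 1; k + 4 <= j; ++k) {
        int i0 = k - 1, j0 = j - 1;
        if (!f.pt(i0, j0) || f.vV(i0, j0) >= INF_E / 2) continue;
        if (k - 1 >= 1)
          child(cur, 0.0, {IV{0, 0, k - 1}, IV{1, i0, j0}}, i0, j0);
        else
          child(cur, 0.0, {IV{1, i0, j0}}, i0, j0);
      }
    } else if (type == 1) {
      double eh = f.e_hairpin(i, j);
      if (eh < INF_E / 2) child(cur, eh, {}, -1, -1);
      int kmax = std::min(i + 1 + p.max_loop, j - 5);
      for (int k = i + 1; k <= kmax; ++k) {
        int n1 = k - i - 1;
        int lmin = std::max(k + 4, j - 1 - (p.max_loop - n1));
        for (int l = lmin; l <= j - 1; ++l) {
          if (!f.pt(k, l) || f.vV(k, l) >= INF_E / 2) continue;
          child(cur, f.e_int(i, j, k, l), {IV{1, k, l}}, k, l);
        }
      }
      for (int u = i + 5; u <= j - 6; ++u)
        child(cur, p.ml_a + p.ml_b, {IV{2, i + 1, u}, IV{3, u + 1, j - 1}},
              -1, -1);
    } else if (type == 2) {
      for (int k = i; k <= j - 4; ++k) {
        if (f.vM1(k, j) >= INF_E / 2) continue;
        child(cur, p.ml_c * (k - i), {IV{3, k, j}}, -1, -1);
        if (k > i && f.vM(i, k - 1) < INF_E / 2)
          child(cur, 0.0, {IV{2, i, k - 1}, IV{3, k, j}}, -1, -1);
      }
    } else {
      if (j > i && f.vM1(i, j - 1) < INF_E / 2)
        child(cur, p.ml_c, {IV{3, i, j - 1}}, -1, -1);
      if (j - i >= 4 && f.pt(i, j) && f.vV(i, j) < INF_E / 2)
        child(cur, p.ml_b, {IV{1, i, j}}, i, j);
    }
  }
  return out;
}

// ---- McCaskill partition function (inside-outside, scaled) ----------------

// [[Rcpp::export]]
NumericMatrix c_partition(IntegerVector seq, NumericVector g, List par) {
  Params p = load_params(par);
  Fold f = make_fold(seq, g, &p);
  int n = f.n;
  NumericMatrix P(n, n);
  if (n < 5) return P;
  f.run();
  double mfe = f.W[n];
  double RT = p.RT;
  double lsc = (mfe < 0) ? 1.05 * mfe / (n * RT) : 0.0; // per-base log scale
  double s1 = std::exp(lsc);
  double eb = std::exp(-p.ml_b / RT);
  double u1 = std::exp(-p.ml_c / RT + lsc);
  std::vector<double> powu1(n + 2, 1.0);
  for (int d = 1; d <= n + 1; ++d) powu1[d] = powu1[d - 1] * u1;

  size_t nn = (size_t)n * n;
  std::vector<double> Q(nn, 0.0), QB(nn, 0.0), QM(nn, 0.0), QM1(nn, 0.0);
  auto idx = [&](int i, int j) { return (size_t)i * n + j; };
  auto Qget = [&](int i, int j) -> double {
    return (j < i) ? 1.0 : Q[idx(i, j)];
  };
  auto QMget = [&](int i, int j) -> double {
    return (j < i) ? 0.0 : QM[idx(i, j)];
  };
  auto QM1get = [&](int i, int j) -> double {
    return (j < i) ? 0.0 : QM1[idx(i, j)];
  };

  for (int i = n - 1; i >= 0; --i) {
    for (int j = i; j < n; ++j) {
      if (j == i) { Q[idx(i, j)] = s1; continue; }
      // QB
      if (j - i >= 4 && f.pt(i, j)) {
        double q = 0.0;
        double eh = f.e_hairpin(i, j);
        if (eh < INF_E / 2)
          q += std::exp(-eh / RT + (j - i + 1) * lsc);
        int kmax = std::min(i + 1 + p.max_loop, j - 5);
        for (int k = i + 1; k <= kmax; ++k) {
          int n1 = k - i - 1;
          int lmin = std::max(k + 4, j - 1 - (p.max_loop - n1));
          for (int l = lmin; l <= j - 1; ++l) {
            if (!f.pt(k, l)) continue;
            double qb = QB[idx(k, l)];
            if (qb <= 0.0) continue;
            int n2 = j - l - 1;
            q += std::exp(-f.e_int(i, j, k, l) / RT + (n1 + n2 + 2) * lsc) * qb;
          }
        }
        double mlsum = 0.0;
        for (int u = i + 5; u <= j - 6; ++u)
          mlsum += QMget(i + 1, u) * QM1get(u + 1, j - 1);
        q += std::exp(-(p.ml_a + p.ml_b) / RT + 2 * lsc) * mlsum;
        QB[idx(i, j)] = q;
      }
      // QM1
      {
        double q = QM1get(i, j - 1) * u1;
        if (QB[idx(i, j)] > 0.0) q += QB[idx(i, j)] * eb;
        QM1[idx(i, j)] = q;
      }
      // QM
      {
        double q = 0.0;
        for (int k = i; k <= j - 4; ++k) {
          double m1 = QM1[idx(k, j)];
          if (m1 <= 0.0) continue;
          double pre = (k == i) ? 1.0 : (powu1[k - i] + QMget(i, k - 1));
          q += pre * m1;
        }
        QM[idx(i, j)] = q;
      }
      // Q (exterior-style)
      {
        double q = Qget(i, j - 1) * s1;
        for (int k = i; k <= j - 4; ++k)
          if (QB[idx(k, j)] > 0.0) q += Qget(i, k - 1) * QB[idx(k, j)];
        Q[idx(i, j)] = q;
      }
    }
  }
  double Qtot = Q[idx(0, n - 1)];
  if (!(Qtot > 0.0) || !std::isfinite(Qtot))
    stop("partition function over/underflow");

  // outside pass
  std::vector<double> Pout(nn, 0.0), A(nn, 0.0), B(nn, 0.0);
  double e_mlclose = std::exp(-(p.ml_a + 2 * p.ml_b) / RT + 2 * lsc);
  for (int span = n - 1; span >= 4; --span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double qb = QB[idx(i, j)];
      if (qb <= 0.0) continue;
      double qx = Qget(0, i - 1) * Qget(j + 1, n - 1) / Qtot;
      // enclosed by (k,l) through a stack/bulge/internal loop
      int kmin = std::max(0, i - 1 - p.max_loop);
      for (int k = kmin; k <= i - 1; ++k) {
        int n1 = i - k - 1;
        int lmax = std::min(n - 1, j + 1 + (p.max_loop - n1));
        for (int l = j + 1; l <= lmax; ++l) {
          if (!f.pt(k, l)) continue;
          double po = Pout[idx(k, l)];
          if (po <= 0.0) continue;
          int n2 = l - j - 1;
          qx += po * std::exp(-f.e_int(k, l, i, j) / RT + (n1 + n2 + 2) * lsc);
        }
      }
      // (i,j) a branch of a multiloop closed by some (k,l)
      double mlsum = 0.0;
      for (int l = j + 1; l < n; ++l) {
        double a = A[idx(i, l)], b = B[idx(i, l)];
        if (a <= 0.0 && b <= 0.0) continue;
        double qmr = QMget(j + 1, l - 1);
        double ur = powu1[l - 1 - j]; // all-unpaired weight of (j, l) gap
        mlsum += a * (ur + qmr) + b * qmr;
      }
      qx += e_mlclose * mlsum;
      Pout[idx(i, j)] = qx;
      double prob = qb * qx;
      if (prob < 0.0) prob = 0.0;
      if (prob > 1.0) prob = 1.0;
      P(i, j) = prob;
      P(j, i) = prob;
    }
    // fold this span's outside weights into the multiloop accumulators
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double po = Pout[idx(i, j)];
      if (po <= 0.0) continue;
      for (int i2 = i + 1; i2 < j; ++i2) {
        A[idx(i2, j)] += po * QMget(i + 1, i2 - 1);
        B[idx(i2, j)] += po * powu1[i2 - i - 1];
      }
    }
  }
  return P;
}
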