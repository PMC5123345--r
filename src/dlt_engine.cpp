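// Core numerical kernels for the DLT process on a discretized species tree:
//  - extinction and single-lineage propagation tables (per-slice ODEs),
//  - the dynamic-programming gene-tree density (sum mode) and its
//    max-product variant used for MAP realizations,
//  - the peeling (pruning) likelihood for sequence data.
// All point/edge/vertex ids arriving from R are 1-based.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  int npt, nE, ntip, rootE, nlevel, nslice, res;
  IntegerVector pt_edge, pt_kind, pt_level, pt_k;
  NumericVector pt_time, pt_delta;
  IntegerVector epts, epts_off;
  IntegerVector below, below_off;
  IntegerVector part, part_off;
  IntegerVector sedge, sedge_off;
  NumericVector slice_lo, slice_hi;
  IntegerVector child1, child2, top_pt;
  IntegerVector spec_top1, spec_top2;
  IntegerVector is_int, is_spec, is_leafp;
  explicit Grid(const List& g)
    : npt(as<int>(g["npt"])), nE(as<int>(g["nE"])), ntip(as<int>(g["ntip"])),
      rootE(as<int>(g["root_edge"])), nlevel(as<int>(g["nlevel"])),
      nslice(as<int>(g["nslice"])), res(as<int>(g["resolution"])),
      pt_edge(as<IntegerVector>(g["pt_edge"])),
      pt_kind(as<IntegerVector>(g["pt_kind"])),
      pt_level(as<IntegerVector>(g["pt_level"])),
      pt_k(as<IntegerVector>(g["pt_k"])),
      pt_time(as<NumericVector>(g["pt_time"])),
      pt_delta(as<NumericVector>(g["pt_delta"])),
      epts(as<IntegerVector>(g["epts"])),
      epts_off(as<IntegerVector>(g["epts_off"])),
      below(as<IntegerVector>(g["below_flat"])),
      below_off(as<IntegerVector>(g["below_off"])),
      part(as<IntegerVector>(g["part_flat"])),
      part_off(as<IntegerVector>(g["part_off"])),
      sedge(as<IntegerVector>(g["sedge_flat"])),
      sedge_off(as<IntegerVector>(g["sedge_off"])),
      slice_lo(as<NumericVector>(g["slice_lo"])),
      slice_hi(as<NumericVector>(g["slice_hi"])),
      child1(as<IntegerVector>(g["edge_child1"])),
      child2(as<IntegerVector>(g["edge_child2"])),
      top_pt(as<IntegerVector>(g["top_pt"])),
      spec_top1(as<IntegerVector>(g["spec_top1"])),
      spec_top2(as<IntegerVector>(g["spec_top2"])),
      is_int(as<IntegerVector>(g["is_int"])),
      is_spec(as<IntegerVector>(g["is_spec"])),
      is_leafp(as<IntegerVector>(g["is_leaf"])) {}
};

// derivative of (E_e, L_e) for the member edges of one slice.
// E: extinction probability; L: log of the single-lineage survival factor.
inline void dlt_deriv(int k, double delta, double mu, double tau,
                      const std::vector<double>& E, std::vector<double>& dE,
                      std::vector<double>& dL) {
  double taueff = (k > 1) ? tau : 0.0;
  double mix = (k > 1) ? tau / (k - 1) : 0.0;
  double SE = 0.0;
  for (int e = 0; e < k; ++e) SE += E[e];
  for (int e = 0; e < k; ++e) {
    double other = SE - E[e];
    dE[e] = mu - (delta + mu + taueff) * E[e] + delta * E[e] * E[e]
            + mix * E[e] * other;
    dL[e] = -(delta + mu + taueff) + 2.0 * delta * E[e] + mix * other;
  }
}

// one RK4 sweep over [t0,t1] with n steps
inline void rk4_sweep(int k, double delta, double mu, double tau,
                      double t0, double t1, int n,
                      std::vector<double>& E, std::vector<double>& L) {
  double h = (t1 - t0) / n;
  std::vector<double> e1(k), e2(k), e3(k), e4(k), tmp(k);
  std::vector<double> l1(k), l2(k), l3(k), l4(k);
  for (int s = 0; s < n; ++s) {
    dlt_deriv(k, delta, mu, tau, E, e1, l1);
    for (int i = 0; i < k; ++i) tmp[i] = E[i] + 0.5 * h * e1[i];
    dlt_deriv(k, delta, mu, tau, tmp, e2, l2);
    for (int i = 0; i < k; ++i) tmp[i] = E[i] + 0.5 * h * e2[i];
    dlt_deriv(k, delta, mu, tau, tmp, e3, l3);
    for (int i = 0; i < k; ++i) tmp[i] = E[i] + h * e3[i];
    dlt_deriv(k, delta, mu, tau, tmp, e4, l4);
    for (int i = 0; i < k; ++i) {
      E[i] += h / 6.0 * (e1[i] + 2 * e2[i] + 2 * e3[i] + e4[i]);
      if (E[i] < 0) E[i] = 0; else if (E[i] > 1) E[i] = 1;
      L[i] += h / 6.0 * (l1[i] + 2 * l2[i] + 2 * l3[i] + l4[i]);
    }
  }
}

// adaptive step doubling until the extinction components agree within tol
inline void integrate_segment(int k, double delta, double mu, double tau,
                              double t0, double t1, double tol,
                              std::vector<double>& E, std::vector<double>& L) {
  int n = 2;
  std::vector<double> E1, L1, E2, L2;
  E1 = E; L1 = L;
  rk4_sweep(k, delta, mu, tau, t0, t1, n, E1, L1);
  for (;;) {
    n *= 2;
    if (n > 4096) { E = E1; L = L1; return; }
    E2 = E; L2 = L;
    rk4_sweep(k, delta, mu, tau, t0, t1, n, E2, L2);
    double diff = 0.0;
    for (int i = 0; i < k; ++i) diff = std::max(diff, std::fabs(E2[i] - E1[i]));
    if (diff < tol) { E = E2; L = L2; return; }
    E1.swap(E2); L1.swap(L2);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_dlt_tables(List g, double delta, double mu, double tau, double tol) {
  Grid G(g);
  int npt = G.npt;
  NumericVector ext(npt), cum(npt);
  std::vector<int> cur(G.nE, 0);   // per-edge cursor into epts

  for (int s = 0; s < G.nslice; ++s) {
    int off = G.sedge_off[s];
    int k = G.sedge_off[s + 1] - off;
    double lo = G.slice_lo[s], hi = G.slice_hi[s];
    std::vector<double> E(k), L(k);
    std::vector<int> eid(k), base(k);
    for (int i = 0; i < k; ++i) {
      int e = G.sedge[off + i];          // 1-based edge id
      eid[i] = e;
      base[i] = G.epts_off[e - 1] + cur[e - 1];
      int bp = G.epts[base[i]];          // bottom boundary point (1-based)
      int kind = G.pt_kind[bp - 1];
      if (kind == 1) { ext[bp - 1] = 0.0; cum[bp - 1] = 0.0; }
      else if (kind == 2) {
        int c1 = G.child1[e - 1], c2 = G.child2[e - 1];
        ext[bp - 1] = ext[G.top_pt[c1 - 1] - 1] * ext[G.top_pt[c2 - 1] - 1];
        cum[bp - 1] = 0.0;
      } // kind 4: carried over from the previous slice
      E[i] = ext[bp - 1];
      L[i] = cum[bp - 1];
    }
    double hsub = (hi - lo) / G.res;
    double t0 = lo;
    for (int j = 1; j <= G.res + 1; ++j) {
      double t1 = (j <= G.res) ? lo + (j - 0.5) * hsub : hi;
      integrate_segment(k, delta, mu, tau, t0, t1, tol, E, L);
      t0 = t1;
      for (int i = 0; i < k; ++i) {
        int pid = G.epts[base[i] + j];   // j-th point after the bottom
        ext[pid - 1] = E[i];
        cum[pid - 1] = L[i];
      }
    }
    for (int i = 0; i < k; ++i) cur[eid[i] - 1] += G.res + 1;
  }

  // full ancestor-to-descendant propagation matrix (0 where unreachable)
  NumericMatrix p11(npt, npt);
  std::vector<int> pos(npt);             // index of each point on its edge
  for (int e = 0; e < G.nE; ++e)
    for (int i = G.epts_off[e]; i < G.epts_off[e + 1]; ++i)
      pos[G.epts[i] - 1] = i - G.epts_off[e];
  for (int x = 0; x < npt; ++x) {
    p11(x, x) = 1.0;
    int e = G.pt_edge[x];                // 1-based
    int eo = G.epts_off[e - 1];
    for (int i = 0; i < pos[x]; ++i) {
      int y = G.epts[eo + i] - 1;
      p11(x, y) = std::exp(cum[x] - cum[y]);
    }
    // descend through speciations below x's edge
    std::vector<std::pair<int, double> > stack;
    double atBottom = std::exp(cum[x]);
    if (G.child1[e - 1] > 0) {
      int c1 = G.child1[e - 1], c2 = G.child2[e - 1];
      stack.push_back(std::make_pair(c1, atBottom * ext[G.top_pt[c2 - 1] - 1]));
      stack.push_back(std::make_pair(c2, atBottom * ext[G.top_pt[c1 - 1] - 1]));
    }
    while (!stack.empty()) {
      int f = stack.back().first;
      double mult = stack.back().second;
      stack.pop_back();
      if (mult <= 0.0) continue;
      double ctf = cum[G.top_pt[f - 1] - 1];
      int fo = G.epts_off[f - 1], fe = G.epts_off[f];
      for (int i = fo; i < fe - 1; ++i) {      // exclude the top anchor
        int y = G.epts[i] - 1;
        p11(x, y) = mult * std::exp(ctf - cum[y]);
      }
      if (G.child1[f - 1] > 0) {
        double atB = mult * std::exp(ctf);
        int c1 = G.child1[f - 1], c2 = G.child2[f - 1];
        stack.push_back(std::make_pair(c1, atB * ext[G.top_pt[c2 - 1] - 1]));
        stack.push_back(std::make_pair(c2, atB * ext[G.top_pt[c1 - 1] - 1]));
      }
    }
  }
  return List::create(_["ext"] = ext, _["cum"] = cum, _["p11"] = p11);
}

// ---------------------------------------------------------------------------
// Gene-tree density DP.
// gene: list(M, children1, children2, postorder (internal, children first),
//            root, leafpt) -- all 1-based, 0 meaning "none".
// lenfacs: list of nlevel x nlevel matrices, lenfacs[[v]](ly, lx) = density of
//          the observed substitution length of the edge above v over the
//          duration levels[lx] - levels[ly].
// mode: 0 = sum over realizations, 1 = max (MAP).
// [[Rcpp::export]]
List cpp_dlt_density(List g, NumericMatrix p11, List gene, double delta,
                     double tau, List lenfacs, int mode, int stemtip,
                     bool want_tables) {
  Grid G(g);
  int npt = G.npt;
  int M = as<int>(gene["M"]);
  IntegerVector ch1 = gene["children1"], ch2 = gene["children2"];
  IntegerVector post = gene["postorder"], leafpt = gene["leafpt"];
  int groot = as<int>(gene["root"]);

  NumericMatrix A(M, npt), D(M, npt);
  NumericVector cs(M);

  for (int pi = 0; pi < post.size(); ++pi) {
    int u = post[pi];                    // 1-based internal gene vertex
    int c[2] = { ch1[u - 1], ch2[u - 1] };
    for (int ci = 0; ci < 2; ++ci) {
      int cc = c[ci];
      NumericMatrix LF = as<NumericMatrix>(lenfacs[cc - 1]);
      if (ch1[cc - 1] == 0) {            // leaf child
        int lp = leafpt[cc - 1] - 1;
        int ly = G.pt_level[lp];
        for (int x = 0; x < npt; ++x) {
          double w = p11(x, lp);
          D(cc - 1, x) = (w > 0) ? w * LF(ly - 1, G.pt_level[x] - 1) : 0.0;
        }
      } else {
        for (int x = 0; x < npt; ++x) {
          double acc = 0.0;
          int lx = G.pt_level[x] - 1;
          for (int bi = G.below_off[x]; bi < G.below_off[x + 1]; ++bi) {
            int y = G.below[bi] - 1;
            double w = p11(x, y);
            if (w <= 0.0) continue;
            double term;
            if (G.is_int[y]) {
              term = w * LF(G.pt_level[y] - 1, lx) * G.pt_delta[y] * A(cc - 1, y);
            } else if (G.is_spec[y]) {
              term = w * LF(G.pt_level[y] - 1, lx) * A(cc - 1, y);
            } else continue;             // leaf points host only gene leaves
            if (mode == 0) acc += term; else if (term > acc) acc = term;
          }
          D(cc - 1, x) = acc;
        }
      }
    }
    double mx = 0.0;
    int k1 = c[0] - 1, k2 = c[1] - 1;
    for (int x = 0; x < npt; ++x) {
      double val = 0.0;
      if (G.is_int[x]) {
        double dup = 2.0 * delta * D(k1, x) * D(k2, x);
        val = dup;
        int kk = G.pt_k[x];
        if (kk > 1 && tau > 0) {
          double mix = tau / (kk - 1);
          double tr = 0.0;
          for (int bi = G.part_off[x]; bi < G.part_off[x + 1]; ++bi) {
            int x2 = G.part[bi] - 1;
            double t1 = mix * D(k1, x) * D(k2, x2);
            double t2 = mix * D(k2, x) * D(k1, x2);
            if (mode == 0) tr += t1 + t2;
            else { if (t1 > tr) tr = t1; if (t2 > tr) tr = t2; }
          }
          if (mode == 0) val = dup + tr; else val = std::max(dup, tr);
        }
      } else if (G.is_spec[x]) {
        int tg = G.spec_top1[x] - 1, th = G.spec_top2[x] - 1;
        double t1 = D(k1, tg) * D(k2, th);
        double t2 = D(k2, tg) * D(k1, th);
        val = (mode == 0) ? (t1 + t2) : std::max(t1, t2);
      }
      A(u - 1, x) = val;
      if (val > mx) mx = val;
    }
    double csum = 0.0;
    if (ch1[c[0] - 1] > 0) csum += cs[c[0] - 1];
    if (ch1[c[1] - 1] > 0) csum += cs[c[1] - 1];
    if (mx > 0) {
      for (int x = 0; x < npt; ++x) A(u - 1, x) /= mx;
      cs[u - 1] = std::log(mx) + csum;
    } else cs[u - 1] = csum;
  }

  // root over points reachable from the stem tip (no edge-length factor)
  int st = stemtip - 1;
  double rho = 0.0;
  for (int bi = G.below_off[st]; bi < G.below_off[st + 1]; ++bi) {
    int y = G.below[bi] - 1;
    double w = p11(st, y);
    if (w <= 0.0) continue;
    double term;
    if (G.is_int[y]) term = w * G.pt_delta[y] * A(groot - 1, y);
    else if (G.is_spec[y]) term = w * A(groot - 1, y);
    else continue;
    if (mode == 0) rho += term; else if (term > rho) rho = term;
  }
  double logdens = (rho > 0) ? std::log(rho) + cs[groot - 1] : R_NegInf;
  if (!want_tables)
    return List::create(_["logdens"] = logdens);
  return List::create(_["logdens"] = logdens, _["A"] = A, _["D"] = D,
                      _["cs"] = cs);
}

// ---------------------------------------------------------------------------
// Peeling likelihood.  patterns: ntip x npat integer codes 0..3 (A,C,G,T),
// 4 = missing.  model: list(type = 0 (JC) or 1 (GTR), pi, U, Uinv, lam).
// [[Rcpp::export]]
double cpp_peel(IntegerMatrix patterns, NumericVector wt, List gene,
                NumericVector lens, List model) {
  int M = as<int>(gene["M"]);
  IntegerVector ch1 = gene["children1"], ch2 = gene["children2"];
  IntegerVector post = gene["postorder"], tiprow = gene["tiprow"];
  int root = as<int>(gene["root"]);
  int npat = patterns.ncol();
  int type = as<int>(model["type"]);
  NumericVector pi = model["pi"];

  std::vector<double> part(static_cast<size_t>(M) * npat * 4);
  std::vector<double> lsc(npat, 0.0);

  // tip partials
  for (int v = 0; v < M; ++v) {
    if (ch1[v] != 0) continue;
    int r = tiprow[v] - 1;
    for (int p = 0; p < npat; ++p) {
      double* pp = &part[(static_cast<size_t>(v) * npat + p) * 4];
      int code = patterns(r, p);
      for (int s = 0; s < 4; ++s) pp[s] = (code == 4 || code == s) ? 1.0 : 0.0;
    }
  }

  NumericMatrix U, Uinv; NumericVector lam;
  if (type == 1) {
    U = as<NumericMatrix>(model["U"]);
    Uinv = as<NumericMatrix>(model["Uinv"]);
    lam = as<NumericVector>(model["lam"]);
  }
  double P1[16], P2[16];
  for (int pi_ = 0; pi_ < post.size(); ++pi_) {
    int u = post[pi_] - 1;
    int c[2] = { ch1[u] - 1, ch2[u] - 1 };
    double* PM[2] = { P1, P2 };
    for (int ci = 0; ci < 2; ++ci) {
      double l = lens[c[ci]];
      double* P = PM[ci];
      if (type == 0) {
        double ee = std::exp(-4.0 * l / 3.0);
        double same = 0.25 + 0.75 * ee, diff = 0.25 - 0.25 * ee;
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b) P[4 * a + b] = (a == b) ? same : diff;
      } else {
        double el[4];
        for (int j = 0; j < 4; ++j) el[j] = std::exp(lam[j] * l);
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b) {
            double s = 0.0;
            for (int j = 0; j < 4; ++j) s += U(a, j) * el[j] * Uinv(j, b);
            P[4 * a + b] = (s > 0) ? s : 0.0;
          }
      }
    }
    for (int p = 0; p < npat; ++p) {
      double* pu = &part[(static_cast<size_t>(u) * npat + p) * 4];
      const double* pc1 = &part[(static_cast<size_t>(c[0]) * npat + p) * 4];
      const double* pc2 = &part[(static_cast<size_t>(c[1]) * npat + p) * 4];
      double mx = 0.0;
      for (int a = 0; a < 4; ++a) {
        double s1 = 0.0, s2 = 0.0;
        for (int b = 0; b < 4; ++b) {
          s1 += P1[4 * a + b] * pc1[b];
          s2 += P2[4 * a + b] * pc2[b];
        }
        pu[a] = s1 * s2;
        if (pu[a] > mx) mx = pu[a];
      }
      if (mx > 0 && mx < 1e-200) {
        for (int a = 0; a < 4; ++a) pu[a] /= mx;
        lsc[p] += std::log(mx);
      }
    }
  }
  double ll = 0.0;
  for (int p = 0; p < npat; ++p) {
    const double* pr = &part[(static_cast<size_t>(root - 1) * npat + p) * 4];
    double s = 0.0;
    for (int a = 0; a < 4; ++a) s += pi[a] * pr[a];
    if (s <= 0) return R_NegInf;
    ll += wt[p] * (std::log(s) + lsc[p]);
  }
  return ll;
}
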