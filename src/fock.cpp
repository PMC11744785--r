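// Screened Coulomb (J) and exchange (K) builders in the primitive
// Cartesian basis, plus Schwarz factor tables.  Screening semantics:
//  - J: [mu nu| and |la si] pair lists presorted by Q_munu and
//    Q_lasi * max|D_lasi|; quartets kept while the product bound exceeds
//    the threshold; only upper-triangular bra shell pairs are computed
//    and mirrored.
//  - K: per-element preselection (preLinK-style) masks whole output
//    shell pairs; surviving contributions screened by
//    Q_mula * Q_nusi * max|D_lasi|.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <numeric>
#include "planeval.h"

using namespace Rcpp;

namespace {

struct ShellTab {
  std::vector<int> L, off;          // angular momentum, primitive AO offset
  std::vector<double> alpha;
  std::vector<std::array<double, 3>> xyz;
  int n() const { return (int)L.size(); }
  int ncomp(int i) const { return (L[i] + 1) * (L[i] + 2) / 2; }
};

ShellTab shells_from_r(List sh) {
  ShellTab t;
  IntegerVector L = sh["L"], off = sh["pao_offset"];
  NumericVector a = sh["alpha"], x = sh["x"], y = sh["y"], z = sh["z"];
  t.L.assign(L.begin(), L.end());
  t.off.assign(off.begin(), off.end());
  t.alpha.assign(a.begin(), a.end());
  for (int i = 0; i < (int)t.L.size(); ++i)
    t.xyz.push_back({x[i], y[i], z[i]});
  return t;
}

inline int class_idx(int La, int Lb, int Lc, int Ld) {
  return ((La * 5 + Lb) * 5 + Lc) * 5 + Ld;
}

inline const Plan &get_plan(PlanSet *ps, int La, int Lb, int Lc, int Ld) {
  return ps->plans[class_idx(La, Lb, Lc, Ld)];
}

// max |Dw| over the (i, j) shell block
double block_max(const ShellTab &t, const NumericMatrix &Dw, int i, int j) {
  double m = 0;
  for (int a = 0; a < t.ncomp(i); ++a)
    for (int b = 0; b < t.ncomp(j); ++b)
      m = std::max(m, std::abs(Dw(t.off[i] + a, t.off[j] + b)));
  return m;
}

} // namespace

// Schwarz factors Q = sqrt([mu nu|mu nu]) for all primitive shell pairs
// i <= j, maximized over Cartesian components of normalized primitives.
// [[Rcpp::export]]
List schwarz_pairs_cpp(List shellr, NumericVector pnorm, SEXP regp) {
  XPtr<PlanSet> reg(regp);
  ShellTab t = shells_from_r(shellr);
  std::vector<double> work, buf;
  std::vector<int> pi, pj;
  std::vector<double> Q;
  for (int i = 0; i < t.n(); ++i)
    for (int j = i; j < t.n(); ++j) {
      const Plan &P = get_plan(reg, t.L[i], t.L[j], t.L[i], t.L[j]);
      buf.resize(P.na * P.nb * P.nc * P.nd);
      eval_plan_quartet(P, t.alpha[i], t.alpha[j], t.alpha[i], t.alpha[j],
                        t.xyz[i].data(), t.xyz[j].data(),
                        t.xyz[i].data(), t.xyz[j].data(), -1.0, work,
                        buf.data());
      double qmax = 0;
      int na = P.na, nb = P.nb;
      for (int a = 0; a < na; ++a)
        for (int b = 0; b < nb; ++b) {
          double raw = buf[((a * nb + b) * na + a) * nb + b];
          double nn = pnorm[t.off[i] + a] * pnorm[t.off[j] + b];
          double val = raw * nn * nn;
          if (val > 0) qmax = std::max(qmax, std::sqrt(val));
        }
      pi.push_back(i + 1); pj.push_back(j + 1); Q.push_back(qmax);
    }
  return List::create(_["i"] = pi, _["j"] = pj, _["Q"] = Q);
}

// Contracted-basis Schwarz matrix Qc[mu, nu] = sqrt(|(mu nu|mu nu)|) over
// contracted Cartesian AOs. pw holds the primitive->contracted expansion
// weight of each primitive Cartesian function (one contracted target per
// primitive), cshell maps primitive shells to contracted shells (1-based),
// cao_off gives contracted AO offsets per contracted shell (0-based).
// [[Rcpp::export]]
NumericMatrix contracted_schwarz_cpp(List shellr, NumericVector pw,
                                     IntegerVector cshell,
                                     IntegerVector cao_off, int n_ao,
                                     SEXP regp) {
  XPtr<PlanSet> reg(regp);
  ShellTab t = shells_from_r(shellr);
  int ncs = cao_off.size();
  std::vector<std::vector<int>> prims(ncs);
  for (int k = 0; k < t.n(); ++k) prims[cshell[k] - 1].push_back(k);
  NumericMatrix Qc(n_ao, n_ao);
  std::vector<double> work, buf, acc;
  for (int I = 0; I < ncs; ++I)
    for (int J = I; J < ncs; ++J) {
      int k0 = prims[I][0], l0 = prims[J][0];
      int La = t.L[k0], Lb = t.L[l0];
      int na = (La + 1) * (La + 2) / 2, nb = (Lb + 1) * (Lb + 2) / 2;
      acc.assign(na * nb, 0.0);
      const Plan &P = get_plan(reg, La, Lb, La, Lb);
      buf.resize(na * nb * na * nb);
      for (int k : prims[I]) for (int l : prims[J])
        for (int k2 : prims[I]) for (int l2 : prims[J]) {
          eval_plan_quartet(P, t.alpha[k], t.alpha[l], t.alpha[k2],
                            t.alpha[l2], t.xyz[k].data(), t.xyz[l].data(),
                            t.xyz[k2].data(), t.xyz[l2].data(), -1.0, work,
                            buf.data());
          for (int a = 0; a < na; ++a)
            for (int b = 0; b < nb; ++b) {
              double w = pw[t.off[k] + a] * pw[t.off[l] + b] *
                         pw[t.off[k2] + a] * pw[t.off[l2] + b];
              acc[a * nb + b] += w * buf[((a * nb + b) * na + a) * nb + b];
            }
        }
      for (int a = 0; a < na; ++a)
        for (int b = 0; b < nb; ++b) {
          double q = std::sqrt(std::abs(acc[a * nb + b]));
          Qc(cao_off[I] + a, cao_off[J] + b) = q;
          Qc(cao_off[J] + b, cao_off[I] + a) = q;
        }
    }
  return Qc;
}

// Coulomb matrix in the primitive basis from a symmetric weighted density.
// Returns the raw (unnormalized-primitive) J plus surviving-quartet counts.
// [[Rcpp::export]]
List build_J_cpp(List shellr, NumericMatrix Dw, List pairs, double thr,
                 SEXP regp) {
  XPtr<PlanSet> reg(regp);
  ShellTab t = shells_from_r(shellr);
  IntegerVector pi = pairs["i"], pj = pairs["j"];
  NumericVector Q = pairs["Q"];
  int np = pi.size();

  // ket sort key: Q * max|D| over the pair block
  std::vector<double> dmax(np), key(np);
  for (int k = 0; k < np; ++k) {
    dmax[k] = block_max(t, Dw, pi[k] - 1, pj[k] - 1);
    key[k] = Q[k] * dmax[k];
  }
  std::vector<int> bra(np), ket(np);
  std::iota(bra.begin(), bra.end(), 0);
  std::iota(ket.begin(), ket.end(), 0);
  std::sort(bra.begin(), bra.end(),
            [&](int a, int b) { return Q[a] > Q[b]; });
  std::sort(ket.begin(), ket.end(),
            [&](int a, int b) { return key[a] > key[b]; });

  int npao = Dw.nrow();
  NumericMatrix J(npao, npao);
  std::vector<double> work, buf;
  double nquart = 0, ncomp_quart = 0;
  for (int bb = 0; bb < np; ++bb) {
    int b = bra[bb];
    if (Q[b] * key[ket[0]] < thr) break;
    int bi = pi[b] - 1, bj = pj[b] - 1;
    const int nboff_i = t.off[bi], nboff_j = t.off[bj];
    const int nbc_i = t.ncomp(bi), nbc_j = t.ncomp(bj);
    for (int kk = 0; kk < np; ++kk) {
      int k = ket[kk];
      if (Q[b] * key[k] < thr) break;
      int ki = pi[k] - 1, kj = pj[k] - 1;
      const Plan &P = get_plan(reg, t.L[bi], t.L[bj], t.L[ki], t.L[kj]);
      buf.resize(P.na * P.nb * P.nc * P.nd);
      eval_plan_quartet(P, t.alpha[bi], t.alpha[bj], t.alpha[ki], t.alpha[kj],
                        t.xyz[bi].data(), t.xyz[bj].data(),
                        t.xyz[ki].data(), t.xyz[kj].data(), -1.0, work,
                        buf.data());
      nquart += 1;
      ncomp_quart += P.na * P.nb * P.nc * P.nd;
      const int nkc_i = t.ncomp(ki), nkc_j = t.ncomp(kj);
      const int koff_i = t.off[ki], koff_j = t.off[kj];
      int idx = 0;
      for (int a = 0; a < nbc_i; ++a)
        for (int bcomp = 0; bcomp < nbc_j; ++bcomp) {
          double s = 0;
          for (int c = 0; c < nkc_i; ++c)
            for (int d = 0; d < nkc_j; ++d) {
              double dfac = Dw(koff_i + c, koff_j + d);
              if (ki != kj) dfac += Dw(koff_j + d, koff_i + c);
              s += buf[idx++] * dfac;
            }
          J(nboff_i + a, nboff_j + bcomp) += s;
        }
    }
  }
  // mirror the strictly-upper shell-pair blocks
  for (int b = 0; b < np; ++b) {
    int bi = pi[b] - 1, bj = pj[b] - 1;
    if (bi == bj) continue;
    for (int a = 0; a < t.ncomp(bi); ++a)
      for (int c = 0; c < t.ncomp(bj); ++c)
        J(t.off[bj] + c, t.off[bi] + a) = J(t.off[bi] + a, t.off[bj] + c);
  }
  return List::create(_["J"] = J, _["n_shell_quartets"] = nquart,
                      _["n_component_quartets"] = ncomp_quart);
}

// Exchange matrix in the primitive basis. sym = +1 (symmetric density) or
// -1 (antisymmetric); skip_pair is an n_shell x n_shell logical matrix of
// output pairs fully suppressed by the preselection bound. omega > 0
// builds the erf-attenuated exchange.
// [[Rcpp::export]]
List build_K_cpp(List shellr, NumericMatrix Dw, NumericMatrix Qs,
                 LogicalMatrix skip_pair, double thr, int sym, double omega,
                 SEXP regp) {
  XPtr<PlanSet> reg(regp);
  ShellTab t = shells_from_r(shellr);
  int ns = t.n(), npao = Dw.nrow();
  NumericMatrix K(npao, npao);
  // density block maxima
  NumericMatrix dmax(ns, ns);
  for (int l = 0; l < ns; ++l)
    for (int s = 0; s < ns; ++s) dmax(l, s) = block_max(t, Dw, l, s);
  std::vector<double> work, buf;
  double nquart = 0, ncomp_quart = 0;
  for (int I = 0; I < ns; ++I)
    for (int J = I; J < ns; ++J) {
      if (skip_pair(I, J)) continue;
      for (int L = 0; L < ns; ++L) {
        double qIL = Qs(I, L);
        if (qIL == 0) continue;
        for (int S = 0; S < ns; ++S) {
          if (qIL * Qs(J, S) * dmax(L, S) < thr) continue;
          const Plan &P = get_plan(reg, t.L[I], t.L[L], t.L[J], t.L[S]);
          buf.resize(P.na * P.nb * P.nc * P.nd);
          eval_plan_quartet(P, t.alpha[I], t.alpha[L], t.alpha[J], t.alpha[S],
                            t.xyz[I].data(), t.xyz[L].data(),
                            t.xyz[J].data(), t.xyz[S].data(), omega, work,
                            buf.data());
          nquart += 1;
          ncomp_quart += P.na * P.nb * P.nc * P.nd;
          int idx = 0;
          for (int a = 0; a < P.na; ++a)
            for (int b = 0; b < P.nb; ++b)
              for (int c = 0; c < P.nc; ++c)
                for (int d = 0; d < P.nd; ++d)
                  K(t.off[I] + a, t.off[J] + c) +=
                      buf[idx++] * Dw(t.off[L] + b, t.off[S] + d);
        }
      }
    }
  // mirror with the density's symmetry sign
  for (int I = 0; I < ns; ++I)
    for (int J = I; J < ns; ++J) {
      if (I == J && sym == 1) continue;
      for (int a = 0; a < t.ncomp(I); ++a)
        for (int c = 0; c < t.ncomp(J); ++c) {
          if (I == J && sym == -1) {
            // enforce exact antisymmetry on the diagonal blocks
            if (c > a) {
              double v = 0.5 * (K(t.off[I] + a, t.off[J] + c) -
                                K(t.off[J] + c, t.off[I] + a));
              K(t.off[I] + a, t.off[J] + c) = v;
              K(t.off[J] + c, t.off[I] + a) = -v;
            } else if (c == a) {
              K(t.off[I] + a, t.off[J] + c) = 0;
            }
          } else {
            K(t.off[J] + c, t.off[I] + a) =
                sym * K(t.off[I] + a, t.off[J] + c);
          }
        }
    }
  return List::create(_["K"] = K, _["n_shell_quartets"] = nquart,
                      _["n_component_quartets"] = ncomp_quart);
}
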