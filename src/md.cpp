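// Reference electron-repulsion-integral evaluator using the
// McMurchie-Davidson scheme (Hermite Gaussian expansion).  Algorithmically
// independent of the unrolled Obara-Saika plans; used as the recursive
// reference in equivalence tests and small brute-force Fock oracles.
#include <Rcpp.h>
#include <cmath>
#include "boys.h"

using namespace Rcpp;

namespace {

// Hermite expansion coefficients E_t^{ij} for one Cartesian dimension
// (includes the pair exponential), table indexed [i][j][t]
struct Etab {
  int imax, jmax;
  std::vector<double> v;
  double &at(int i, int j, int t) {
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
};

Etab build_E(int imax, int jmax, double a, double b, double AB) {
  Etab E;
  E.imax = imax; E.jmax = jmax;
  E.v.assign((imax + 1) * (jmax + 1) * (imax + jmax + 1), 0.0);
  double p = a + b, mu = a * b / p;
  double XPA = -b / p * AB, XPB = a / p * AB;  // P - A, P - B along this axis
  E.at(0, 0, 0) = std::exp(-mu * AB * AB);
  for (int i = 0; i <= imax; ++i)
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val = 0;
        if (i > 0) {
          if (t > 0) val += E.at(i - 1, j, t - 1) / (2 * p);
          if (t <= i - 1 + j) val += XPA * E.at(i - 1, j, t);
          if (t + 1 <= i - 1 + j) val += (t + 1) * E.at(i - 1, j, t + 1);
        } else {
          if (t > 0) val += E.at(i, j - 1, t - 1) / (2 * p);
          if (t <= i + j - 1) val += XPB * E.at(i, j - 1, t);
          if (t + 1 <= i + j - 1) val += (t + 1) * E.at(i, j - 1, t + 1);
        }
        E.at(i, j, t) = val;
      }
    }
  return E;
}

// Hermite Coulomb integrals R^0_{tuv}(alpha, PQ) for t+u+v <= M
struct Rtab {
  int M;
  std::vector<double> v;
  double &at(int t, int u, int w) {
    return v[(t * (M + 1) + u) * (M + 1) + w];
  }
};

Rtab build_R(int M, double alpha, const double *PQ, double omega) {
  int mm = M;
  std::vector<double> F(mm + 1);
  double T = alpha * (PQ[0] * PQ[0] + PQ[1] * PQ[1] + PQ[2] * PQ[2]);
  if (omega > 0) {
    double s2 = omega * omega / (alpha + omega * omega), s = std::sqrt(s2);
    boys_vec(mm, s2 * T, F.data());
    double fac = s;
    for (int m = 0; m <= mm; ++m) { F[m] *= fac; fac *= s2; }
  } else {
    boys_vec(mm, T, F.data());
  }
  // layered DP over the auxiliary index n
  std::vector<Rtab> layers(mm + 1);
  for (int n = mm; n >= 0; --n) {
    layers[n].M = M;
    layers[n].v.assign((M + 1) * (M + 1) * (M + 1), 0.0);
    double c = std::pow(-2.0 * alpha, n);
    layers[n].at(0, 0, 0) = c * F[n];
    int rem = mm - n;  // max t+u+v available at this layer
    for (int t = 0; t <= rem; ++t)
      for (int u = 0; u <= rem - t; ++u)
        for (int w = 0; w <= rem - t - u; ++w) {
          if (t + u + w == 0) continue;
          double val = 0;
          if (t > 0) {
            if (t > 1) val += (t - 1) * layers[n + 1].at(t - 2, u, w);
            val += PQ[0] * layers[n + 1].at(t - 1, u, w);
          } else if (u > 0) {
            if (u > 1) val += (u - 1) * layers[n + 1].at(t, u - 2, w);
            val += PQ[1] * layers[n + 1].at(t, u - 1, w);
          } else {
            if (w > 1) val += (w - 1) * layers[n + 1].at(t, u, w - 2);
            val += PQ[2] * layers[n + 1].at(t, u, w - 1);
          }
          layers[n].at(t, u, w) = val;
        }
  }
  return layers[0];
}

// Unnormalized primitive Cartesian class tensor [ab|cd]; component order
// lexicographic (lx descending, then ly), index d fastest. omega > 0
// selects the erf-attenuated kernel.
std::vector<double> eri_md_class(int La, int Lb, int Lc, int Ld,
                                 double za, double zb, double zc, double zd,
                                 const double *A, const double *B,
                                 const double *C, const double *D,
                                 double omega) {
  double p = za + zb, q = zc + zd;
  double P[3], Q[3], PQ[3];
  for (int k = 0; k < 3; ++k) {
    P[k] = (za * A[k] + zb * B[k]) / p;
    Q[k] = (zc * C[k] + zd * D[k]) / q;
    PQ[k] = P[k] - Q[k];
  }
  double alpha = p * q / (p + q);
  double pref = 2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q));

  Etab Eab[3], Ecd[3];
  for (int k = 0; k < 3; ++k) {
    Eab[k] = build_E(La, Lb, za, zb, A[k] - B[k]);
    Ecd[k] = build_E(Lc, Ld, zc, zd, C[k] - D[k]);
  }
  Rtab R = build_R(La + Lb + Lc + Ld, alpha, PQ, omega);

  auto comps = [](int L) {
    std::vector<std::array<int, 3>> out;
    for (int lx = L; lx >= 0; --lx)
      for (int ly = L - lx; ly >= 0; --ly)
        out.push_back({lx, ly, L - lx - ly});
    return out;
  };
  auto cA = comps(La), cB = comps(Lb), cC = comps(Lc), cD = comps(Ld);
  std::vector<double> out(cA.size() * cB.size() * cC.size() * cD.size());
  int idx = 0;
  for (auto &a : cA) for (auto &b : cB) for (auto &c : cC) for (auto &d : cD) {
    double sum = 0;
    for (int t = 0; t <= a[0] + b[0]; ++t)
      for (int u = 0; u <= a[1] + b[1]; ++u)
        for (int w = 0; w <= a[2] + b[2]; ++w) {
          double e1 = Eab[0].at(a[0], b[0], t) * Eab[1].at(a[1], b[1], u) *
                      Eab[2].at(a[2], b[2], w);
          if (e1 == 0) continue;
          double inner = 0;
          for (int tt = 0; tt <= c[0] + d[0]; ++tt)
            for (int uu = 0; uu <= c[1] + d[1]; ++uu)
              for (int ww = 0; ww <= c[2] + d[2]; ++ww) {
                double e2 = Ecd[0].at(c[0], d[0], tt) *
                            Ecd[1].at(c[1], d[1], uu) *
                            Ecd[2].at(c[2], d[2], ww);
                if (e2 == 0) continue;
                double sign = ((tt + uu + ww) % 2) ? -1.0 : 1.0;
                inner += sign * e2 * R.at(t + tt, u + uu, w + ww);
              }
          sum += e1 * inner;
        }
    out[idx++] = pref * sum;
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
NumericVector eri_md_cpp(IntegerVector Ls, NumericVector exps,
                         NumericMatrix centers, double omega = -1.0) {
  double A[3], B[3], C[3], D[3];
  for (int k = 0; k < 3; ++k) {
    A[k] = centers(0, k); B[k] = centers(1, k);
    C[k] = centers(2, k); D[k] = centers(3, k);
  }
  std::vector<double> v = eri_md_class(Ls[0], Ls[1], Ls[2], Ls[3],
                                       exps[0], exps[1], exps[2], exps[3],
                                       A, B, C, D, omega);
  return NumericVector(v.begin(), v.end());
}

// Full contracted-basis ERI tensor (no screening), flattened with the
// first AO index slowest; brute-force oracle for small systems.
// [[Rcpp::export]]
NumericVector contracted_eri_cpp(IntegerVector L, NumericVector alpha,
                                 NumericMatrix xyz, IntegerVector pao_off,
                                 NumericVector pw, IntegerVector cao_off_prim,
                                 int n_ao, double omega = -1.0) {
  int np = L.size();
  NumericVector out((double)n_ao * n_ao * n_ao * n_ao);
  auto nc = [](int l) { return (l + 1) * (l + 2) / 2; };
  for (int i = 0; i < np; ++i)
    for (int j = 0; j < np; ++j)
      for (int k = 0; k < np; ++k)
        for (int l = 0; l < np; ++l) {
          double A[3] = {xyz(i, 0), xyz(i, 1), xyz(i, 2)};
          double B[3] = {xyz(j, 0), xyz(j, 1), xyz(j, 2)};
          double C[3] = {xyz(k, 0), xyz(k, 1), xyz(k, 2)};
          double D[3] = {xyz(l, 0), xyz(l, 1), xyz(l, 2)};
          std::vector<double> v =
              eri_md_class(L[i], L[j], L[k], L[l], alpha[i], alpha[j],
                           alpha[k], alpha[l], A, B, C, D, omega);
          int na = nc(L[i]), nb = nc(L[j]), ncc = nc(L[k]), nd = nc(L[l]);
          int idx = 0;
          for (int a = 0; a < na; ++a)
            for (int b = 0; b < nb; ++b)
              for (int c = 0; c < ncc; ++c)
                for (int d = 0; d < nd; ++d) {
                  double w = pw[pao_off[i] + a] * pw[pao_off[j] + b] *
                             pw[pao_off[k] + c] * pw[pao_off[l] + d];
                  R_xlen_t mu = cao_off_prim[i] + a, nu = cao_off_prim[j] + b,
                           la = cao_off_prim[k] + c, si = cao_off_prim[l] + d;
                  out[((mu * n_ao + nu) * n_ao + la) * n_ao + si] +=
                      w * v[idx];
                  ++idx;
                }
        }
  return out;
}
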