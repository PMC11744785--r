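#include <Rcpp.h>
#include <cmath>
#include "boys.h"
#include "planeval.h"

using namespace Rcpp;

static const double TWO_PI_POW_2_5 = 2.0 * std::pow(M_PI, 2.5);

void eval_plan_quartet(const Plan &P,
                       double za, double zb, double zc, double zd,
                       const double *A, const double *B,
                       const double *C, const double *D,
                       double omega, std::vector<double> &work, double *out) {
  const double p = za + zb, q = zc + zd;
  double Pc[3], Qc[3], W[3], AB[3], CD[3];
  double ab2 = 0, cd2 = 0, pq2 = 0;
  for (int k = 0; k < 3; ++k) {
    Pc[k] = (za * A[k] + zb * B[k]) / p;
    Qc[k] = (zc * C[k] + zd * D[k]) / q;
    W[k] = (p * Pc[k] + q * Qc[k]) / (p + q);
    AB[k] = A[k] - B[k];
    CD[k] = C[k] - D[k];
    ab2 += AB[k] * AB[k];
    cd2 += CD[k] * CD[k];
    double d = Pc[k] - Qc[k];
    pq2 += d * d;
  }
  const double rho = p * q / (p + q);
  const double Kab = std::exp(-za * zb / p * ab2);
  const double Kcd = std::exp(-zc * zd / q * cd2);
  const double pref = TWO_PI_POW_2_5 / (p * q * std::sqrt(p + q)) * Kab * Kcd;
  double T = rho * pq2;

  if ((int)work.size() < P.nslots) work.resize(P.nslots);
  double *w = work.data();
  std::fill(w, w + P.nslots, 0.0);

  // geometry slots (0-based; layout fixed in R/eri_plans.R)
  w[0] = 1.0;
  w[1] = 0.5 / p;
  w[2] = 0.5 / q;
  w[3] = 0.5 / (p + q);
  w[4] = rho / p;
  w[5] = rho / q;
  for (int k = 0; k < 3; ++k) {
    w[6 + k] = Pc[k] - A[k];
    w[9 + k] = Pc[k] - B[k];
    w[12 + k] = Qc[k] - C[k];
    w[15 + k] = Qc[k] - D[k];
    w[18 + k] = W[k] - Pc[k];
    w[21 + k] = W[k] - Qc[k];
    w[24 + k] = AB[k];
    w[27 + k] = CD[k];
  }
  double F[32];
  if (omega > 0) {
    // erf(omega r12)/r12 kernel: F_m(T) -> s^(2m+1) F_m(s^2 T)
    const double s2 = omega * omega / (rho + omega * omega);
    const double s = std::sqrt(s2);
    boys_vec(P.mmax, s2 * T, F);
    double fac = s;
    for (int m = 0; m <= P.mmax; ++m) {
      F[m] *= fac;
      fac *= s2;
    }
  } else {
    boys_vec(P.mmax, T, F);
  }
  for (int m = 0; m <= P.mmax; ++m) w[30 + m] = pref * F[m];

  const int nterms = (int)P.out.size();
  const int *po = P.out.data(), *pc = P.coef.data(), *p1 = P.f1.data(),
            *p2 = P.f2.data(), *ps = P.src.data();
  for (int t = 0; t < nterms; ++t)
    w[po[t]] += pc[t] * w[p1[t]] * w[p2[t]] * w[ps[t]];

  const int nout = (int)P.out_slots.size();
  for (int t = 0; t < nout; ++t) out[t] = w[P.out_slots[t]];
}

static Plan plan_from_list(List pl) {
  Plan P;
  IntegerMatrix ops = pl["ops"];
  int n = ops.nrow();
  P.out.resize(n); P.coef.resize(n); P.f1.resize(n); P.f2.resize(n);
  P.src.resize(n);
  for (int i = 0; i < n; ++i) {
    P.out[i] = ops(i, 0) - 1;
    P.coef[i] = ops(i, 1);
    P.f1[i] = ops(i, 2) - 1;
    P.f2[i] = ops(i, 3) - 1;
    P.src[i] = ops(i, 4) - 1;
  }
  IntegerVector os = pl["out_slots"];
  P.out_slots.assign(os.begin(), os.end());
  for (auto &s : P.out_slots) s -= 1;
  P.nslots = as<int>(pl["nslots"]);
  P.mmax = as<int>(pl["mmax"]);
  IntegerVector dims = pl["dims"];
  P.na = dims[0]; P.nb = dims[1]; P.nc = dims[2]; P.nd = dims[3];
  return P;
}

// [[Rcpp::export]]
SEXP plan_registry_cpp(List plans) {
  PlanSet *ps = new PlanSet();
  ps->plans.resize(plans.size());
  for (R_xlen_t i = 0; i < plans.size(); ++i) {
    if (plans[i] != R_NilValue) ps->plans[i] = plan_from_list(plans[i]);
  }
  XPtr<PlanSet> ptr(ps, true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector plan_eval_cpp(List plan, NumericVector exps,
                            NumericMatrix centers, double omega) {
  Plan P = plan_from_list(plan);
  std::vector<double> work;
  NumericVector out(P.na * P.nb * P.nc * P.nd);
  double A[3], B[3], C[3], D[3];
  for (int k = 0; k < 3; ++k) {
    A[k] = centers(0, k); B[k] = centers(1, k);
    C[k] = centers(2, k); D[k] = centers(3, k);
  }
  eval_plan_quartet(P, exps[0], exps[1], exps[2], exps[3], A, B, C, D,
                    omega, work, &out[0]);
  return out;
}
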