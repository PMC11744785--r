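#pragma once
#include <vector>

// straight-line evaluation plan for one ERI angular-momentum class,
// produced by the R-side generator (see R/eri_plans.R for the slot layout)
struct Plan {
  std::vector<int> out, coef, f1, f2, src;  // one entry per term, 0-based slots
  std::vector<int> out_slots;               // 0-based output slots
  int nslots = 0;
  int mmax = 0;
  int na = 0, nb = 0, nc = 0, nd = 0;
  bool ready() const { return nslots > 0; }
};

struct PlanSet {
  std::vector<Plan> plans;  // indexed by class id ((La*5+Lb)*5+Lc)*5+Ld
};

// evaluates the class tensor for one primitive shell quartet into out
// (size na*nb*nc*nd, index d fastest); omega > 0 selects the
// erf(omega r12)/r12 attenuated kernel
void eval_plan_quartet(const Plan &P,
                       double za, double zb, double zc, double zd,
                       const double *A, const double *B,
                       const double *C, const double *D,
                       double omega, std::vector<double> &work, double *out);
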