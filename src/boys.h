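#pragma once

// Fills F[0..mmax] with Boys function values F_m(x).
// Three regimes: closed form near x = 0, downward recursion from a
// series-evaluated top order for x <= 35, asymptotic + upward recursion
// beyond.  Relative accuracy ~1e-14 for m <= 16, x in [0, 1e4].
void boys_vec(int mmax, double x, double *F);
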