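---
title: "Simulating electronic circular dichroism with Gaussian orbitals: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating electronic circular dichroism with Gaussian orbitals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

chirospec computes electronic circular dichroism (ECD) spectra of
closed-shell molecules — optionally embedded in classical point charges —
from first principles: a self-consistent field (SCF) reference built from
screened electron-repulsion integrals (ERIs) over contracted Cartesian
Gaussians, followed by linear response theory in either the
generalized-eigenvalue or the damped (complex polarization propagator, CPP)
formulation, and finally the assembly of the observable
$\Delta\varepsilon(\omega)$, the anisotropy of the decadic molar extinction
coefficient in L mol$^{-1}$ cm$^{-1}$. This vignette records the models,
the fixed conventions, the tunable parameters, and the numerical choices a
user or maintainer needs to know. Everything stated here is exercised by
the test suite; no empirical claim is made beyond what the tests compute.

## Basis functions and integrals

All internal math is in Hartree atomic units; XYZ input is Angstrom
(1 Å = 1/0.529177 Bohr). Basis sets are read from Gaussian94 text; SP
shells are split, and angular momenta run up to d. Cartesian components
are ordered lexicographically (s; x, y, z; xx, xy, xz, yy, yz, zz), every
primitive Cartesian component is individually normalized, and each
contracted AO is scaled to unit self-overlap. Cartesian d shells (6
components) are used throughout — no solid-harmonic transformation — so
absolute AO counts are larger than spherical-basis counts (water/def2-SVP
has 25 Cartesian contracted AOs). The span of a d shell is unchanged, so
energies and spectra are unaffected by this representational choice.

Primitive ERIs are evaluated by *unrolled* Obara–Saika plans: for each of
the 81 ordered angular-momentum classes up to $[dd|dd]$, the vertical and
horizontal recurrences are symbolically expanded once into a straight-line
sequence of fused multiply–add operations over a flat workspace (geometry
scalars, prefactored Boys values, intermediates), with one output slot per
Cartesian component quadruple — 9 outputs for $[sp|sp]$, 1296 for
$[dd|dd]$. Plans are generated at first use and cached for the session;
the repository holds the generator, not generated code. Each plan is
self-contained: no intermediate from another class is referenced. A
McMurchie–Davidson (Hermite expansion) evaluator, algorithmically
independent of the plans, serves as the recursive reference, and a third,
fully independent oracle integrates the Gaussian transform of the Coulomb
kernel by quadrature; the three routes agree to $10^{-10}$
(plan/reference) and $10^{-7}$ (quadrature) in the tests.

The Boys function $F_m(x)$ uses three regimes: a closed form near zero, a
series-evaluated top order with downward recursion for $x \le 35$, and the
asymptotic value with upward recursion beyond; relative accuracy is about
$10^{-14}$ over $m \le 16$, $x \in [0, 10^4]$. Range-separated exchange
uses the $\mathrm{erf}(\omega r_{12})/r_{12}$ kernel, implemented by the
standard Boys substitution $F_m(T) \to s^{2m+1} F_m(s^2 T)$ with
$s^2 = \omega^2/(\rho + \omega^2)$, valid unchanged under both evaluation
schemes.

## Screened Coulomb and exchange builds

The two-electron Fock contribution is assembled from tagged densities.
The symmetry tag is load-bearing: ground-state and symmetric trial
densities require Coulomb (J), exchange (K) and XC terms; for
antisymmetric trial densities J vanishes identically (by
$[\mu\nu|\lambda\sigma] = [\mu\nu|\sigma\lambda]$) and its build is
skipped outright.

J is built from presorted primitive shell-pair lists — bra pairs sorted by
the Schwarz factor $Q_{\mu\nu} = \sqrt{[\mu\nu|\mu\nu]}$, ket pairs by
$Q_{\lambda\sigma}\,|D_{\lambda\sigma}|$ — keeping quartets while the
product bound exceeds the cutoff, computing only upper-triangular bra
pairs and mirroring. K uses a preselective elementwise bound
$B = Q_c\,|D|\,Q_c$ (a matrix product of the exact contracted Schwarz
matrix with the density magnitudes, which dominates $|K|$ elementwise);
elements below the preselection threshold are skipped and left exactly
zero, and surviving contributions are screened by
$Q_{\mu\lambda} Q_{\nu\sigma} |D_{\lambda\sigma}|$.

The user-facing `eri_threshold` (default $10^{-12}$) is the *target
accuracy of matrix elements*, not the raw quartet cutoff: skipped-quartet
errors accumulate with random signs roughly as the square root of the
number of contributing pair blocks, so the internal cutoff is the
threshold divided by $8\sqrt{N_\text{pairs}}$ (J) or $8 N_\text{shells}$
(K). The preselection threshold defaults to $10^{-10}$. Both defaults keep
screening error well below SCF convergence noise. Setting both thresholds
to zero disables screening entirely (oracle mode), which the tests use for
brute-force comparisons.

## Exchange–correlation integration

The molecular grid is a Becke fuzzy-cell partition (three smoothing
passes, atomic-size adjustment) over atom-centered products of a mapped
Gauss–Chebyshev radial rule and a Gauss–Legendre × uniform-azimuth
spherical rule. Levels: coarse (30 radial × 200 angular), medium
(55 × 648), fine (80 × 1352) points per atom. Medium integrates Gaussian
test densities to ~$10^{-6}$ relative and electron counts to $10^{-4}$,
which is the tested contract; the angular product rule was chosen over
tabulated Lebedev sets because any rule meeting that contract is
acceptable and the product rule needs no large coefficient tables.

Grid points are partitioned into even batches by recursive bisection of
the bounding box along its longest axis at the median point, until every
batch is at most `max_points` (default 256, configurable). Per batch, AOs
whose maximum absolute value in the box falls below a cutoff
($10^{-12}$) are dropped, and the density and XC Fock contributions are
accumulated by matrix multiplication. Results are invariant to the batch
size to $10^{-10}$ — batching is an execution layout, not an
approximation — and the batch × surviving-AO product count is reported as
the work measure.

Built-in functionals are local only: Dirac–Slater exchange and VWN5
correlation. `hf` uses no functional; `lda-demo` is Slater+VWN5;
`cam-lda-demo` demonstrates range separation with
$\alpha\,K + \beta\,K_{\mathrm{erf}(\omega)}$ exchange
($\alpha = 0.19$, $\beta = 0.46$, $\omega = 0.33$, so the
Hartree–Fock-type fraction is $\alpha$ at short range and
$\alpha + \beta = 0.65$ at long range) next to Slater exchange scaled by
the *global* constant $1 - \alpha - \beta$. A single global weight cannot
reproduce the $r$-dependent DFT complement of a production CAM
functional; `cam-lda-demo` exercises the attenuated-integral machinery,
it is not CAM-B3LYP.

## SCF

Closed-shell restricted formalism only; the electron count must be even.
The density is normalized to $\mathrm{tr}(DS) = N_\text{elec}/2$ and the
Fock matrix is $F = h + 2J - c_x K - c_{lr} K_\omega + V_{xc}$. The
initial guess diagonalizes the core Hamiltonian; convergence is
accelerated by DIIS on the orbital-gradient residual $FDS - SDF$ with an
8-vector window; the generalized eigenproblem is solved densely through
symmetric orthogonalization, refusing overlap condition numbers beyond
$10^{12}$ with advice to prune the basis. Defaults: `tol_E` $10^{-8}$
Hartree, `tol_D` $10^{-6}$ (Frobenius), 100 iterations. MM point charges
enter the one-electron attraction exactly like nuclei, with their
fractional charges; the nuclei–MM interaction joins the nuclear
repulsion, while the MM–MM self-energy is a constant of the embedding and
excluded. Per-iteration wall times for the ERI, XC and diagonalization
stages are logged, along with the number of Fock builds per hour as the
throughput indicator.

## Linear response and the two spectrum routes

Trial vectors live in the occupied–virtual space and are handled in the
paired representation $g = X + Y$, $u = X - Y$: the electronic Hessian
acts blockwise as $(A+B)$ on $g$ and $(A-B)$ on $u$, and the metric swaps
the two. The images of $g$ and $u$ in the AO basis are symmetric and
antisymmetric one-particle densities, so each Hessian action is delivered
by auxiliary Fock builds — J + K (+ XC kernel) for the symmetric
component, K only for the antisymmetric one — which is precisely where
the J-skip for antisymmetric densities pays off. The adiabatic XC kernel
is applied as a symmetric finite-field derivative of $V_{xc}$ (step
$10^{-5}$ on the density scale) rather than via analytic second
derivatives; the explicit dense oracle instead builds
$(ia|f_{xc}|jb)$ by grid quadrature with a pointwise-differentiated
potential, keeping the two routes independent.

Excitation energies come from a Davidson-type reduced-space iteration
with a shared orthonormal real basis for both paired components (modified
Gram–Schmidt with re-orthogonalization), orbital-energy-difference
preconditioning, residual tolerance $10^{-6}$ per root by default, and a
subspace cap of 50 basis vectors per root. The damped solver handles all
frequencies of a window against one shared reduced space, solving the
$2m$-dimensional complex paired system per frequency and expanding with
preconditioned residual components of the worst frequency. On systems
with a few tens of occupied–virtual pairs both solvers are verified
against explicit dense $(A\pm B)$ construction, a spectral sum-over-states
expansion, and a discretized Kramers–Kronig transform.

Velocity-gauge moments use the gradient operator
($\hat p = -i\nabla$) and angular momentum about a configurable origin
(default: center of nuclear charge). With real orbitals both AO matrices
are real antisymmetric, transition moments attach to the $u$ component
with the closed-shell $\sqrt 2$ spin factor, and the rotatory strength is
$R_{n0} = \mathbf P_n \cdot \mathbf M_n / (2\omega_{n0})$ where
$\mathbf P_n = \sqrt2\,\nabla_{ov}\!\cdot u_n$ and
$\mathbf M_n = \sqrt2\,(\mathbf r\times\nabla)_{ov}\!\cdot u_n$. An
origin shift changes $\mathbf M_n$ by $-\mathbf d \times \mathbf P_n$,
which is orthogonal to $\mathbf P_n$: rotatory strengths — not the
magnetic moments themselves — are the origin-independent contract, and
the tests verify it to $10^{-10}$.

The stick route broadens $R_{n0}$ with a unit-area Cauchy (Lorentzian)
profile whose half-width at half-maximum is the damping $\gamma$
(default 0.1240 eV ≡ 1000 cm$^{-1}$):
$\Delta\varepsilon(\omega) = K \sum_n R_n\,\omega\,f(\omega;\omega_n,\gamma)$.
The CPP route solves the damped equations for the three gradient
operators, projects on the angular-momentum gradients to form the mixed
electric–magnetic tensor $G(\omega + i\gamma)$, and uses
$\Delta\varepsilon = K\,\mathrm{Im}\,\mathrm{tr}\,G/(2\pi)$; by the
sum-over-states identity
$\mathrm{tr}\,G(z) = \sum_n 4\omega_n^2 R_n/(\omega_n^2 - z^2)$ the two
routes coincide on resonance up to the antiresonant tail, and the tests
hold them to 2 % of the peak amplitude when every state in the window is
resolved. The conversion constant $K$ to L mol$^{-1}$ cm$^{-1}$ is
assembled at run time from CODATA values — the atomic-unit rotatory
strength in cgs ($4.714\times10^{-38}$ esu cm erg/G) divided by
$3000\,h c \ln 10/(32\pi^3 N_A)$ ($22.97\times10^{-40}$), giving
$K \approx 20.53$ — and only its dimensional consistency and the
spectral contracts are asserted, not a copied constant. Any residual
global sign convention in $\Delta\varepsilon$ cancels in every symmetry
test (enantiomer negation, achiral zero) and is stated here as
convention-dependent.

## Synthetic fixtures: what they emulate and what they do not

`generate_water_droplet(n, seed)` places rigid TIP3P-geometry waters with
uniform random orientations in the smallest sphere consistent with liquid
density (0.997 g/cm³), minimum O–O distance 2.5 Å, growing the sphere in
4 % steps if insertion stalls and failing after bounded retries. It
reproduces the two features that matter for screening studies — a dense
3D system with a 1:2 heavy:hydrogen ratio — but has no hydrogen-bond
network, thermal disorder or electronic polarization; passing scaling
tests therefore demonstrate screening behavior on dense 3D geometry, not
fidelity to liquid water. The scaling experiment uses a
superposition-of-monomers density (block-diagonal converged water
density) because the screening work measure needs realistic density
magnitudes, not a converged droplet wavefunction.

`generate_chiral_fixture` provides hydrogen peroxide at a ±112.5°
H–O–O–H dihedral — the P and M forms are exact coordinate-wise mirror
images, which is what makes the end-to-end sign-flip tests sharp — and a
planar water as the achiral control. One caution learned from those
controls: the mixed electric–magnetic *trace* vanishes identically for
achiral molecules (and for H₂ even componentwise), so solver cross-checks
on such systems must compare tensor components or electric responses,
never the trace.

## Problem sizes and known limitations

The shipped tests run at desk scale: brute-force ERI oracles up to ~14
contracted AOs, screened-versus-unscreened Fock ladders on three
waters/def2-SVP (75 Cartesian AOs), full response oracles up to 27
occupied–virtual pairs, spectrum equivalence on twisted H₂O₂/STO-3G, and
screening-scaling measurements on droplets of 8–32 waters (up to 224
AOs). These sizes were chosen so the whole suite completes in a few
minutes while every contract is still nontrivially exercised.

Known limitations: closed-shell references only; angular momenta up to d;
local (LDA-level) functionals with no gradient corrections; no
length-gauge rotatory strengths (velocity gauge only); no
Tamm–Dancoff mode, no excited-state gradients; single-process execution.
The basis fixtures ship H, He, C, N, O for STO-3G and H, C, N, O for
def2-SVP as hand-transcribed standard parameter sets — other elements
require a user-supplied Gaussian94 file.
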