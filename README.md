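# chirospec

Electronic circular dichroism (ECD) spectra of closed-shell molecules from
first principles, in R. The package is a desk-scale quantum chemistry
stack for people who want to *see the whole pipeline*: Gaussian-basis
integrals, screened Fock builds, SCF, linear response, and the chiroptical
observable, each layer testable against an independent oracle.

What it computes, bottom to top:

- **Electron repulsion integrals** over contracted Cartesian Gaussians up
  to d functions, evaluated through *unrolled* Obara–Saika plans —
  straight-line operation sequences generated symbolically per
  angular-momentum class (9 Coulomb kernel classes up to p, 36 up to d;
  12 and 54 for exchange) — plus erf-attenuated variants for
  range-separated exchange.
- **Coulomb (J) and exchange (K) matrices** from symmetry-tagged
  densities with Cauchy–Schwarz screening, density-weighted presorted
  pair lists for J, and a preselective elementwise bound
  `Q|D|Q` for K; the J build is skipped entirely for antisymmetric
  (response) densities.
- **Numerical exchange–correlation** on a Becke-partitioned molecular
  grid, split into even spatial batches by recursive box bisection, with
  per-batch AO screening and matrix-multiplication evaluation.
- **Closed-shell SCF** (Hartree–Fock, LDA, and a demonstration
  range-separated hybrid with α = 0.19, β = 0.46, ω = 0.33) with DIIS,
  QM/MM point-charge embedding, per-stage timings and a
  Fock-builds-per-hour throughput indicator.
- **Linear response** in the paired symmetric/antisymmetric trial-vector
  representation: a Davidson-type eigensolver for excitation energies and
  velocity-gauge transition moments, and a damped (complex polarization
  propagator, CPP) solver for the complex mixed electric–magnetic tensor
  G(ω + iγ).
- **ECD spectra** two ways: Cauchy-broadened velocity-gauge rotatory
  strengths `R_n = P_n·M_n/(2ω_n)` (gauge-origin independent), or
  Δε(ω) directly from Im tr G — the two routes agree pointwise when all
  states in the window are resolved, which is the pipeline's central
  cross-check.

## Worked example

ECD spectrum of the P enantiomer of twisted hydrogen peroxide (H–O–O–H
dihedral +112.5°), resolving the 10 lowest singlet excitations at
HF/STO-3G with the default damping γ = 0.1240 eV:

```sh
Rscript exec/chirospec ecd-eigen --chiral h2o2_P --basis sto-3g \
    --nstates 10 --lambda-min 100 --lambda-max 200 --lambda-step 5 \
    --out h2o2p
```

The SCF log ends at `E = -148.7589910376` Hartree (11 iterations), and
the run writes a stick table, a broadened curve and a metadata JSON.
`h2o2p_sticks.tsv` starts:

```
energy_ev       R_au
 8.106123899     0.04874054116
 9.480300243    -0.06163436372
13.318623475     0.13413004433
```

i.e. the lowest excitation sits at 8.11 eV with a positive rotatory
strength of 0.0487 atomic units, followed by a negative band at 9.48 eV —
a bisignate onset. The broadened curve (`h2o2p_spectrum.tsv`) gives
Δε in L mol⁻¹ cm⁻¹ against wavelength:

```
wavelength_nm   energy_ev       delta_epsilon
130              9.537246033    -25.40736673628
```

Running the same command with `--chiral h2o2_M` negates every rotatory
strength and the whole curve exactly; with the achiral control
`h2o_planar` everything is numerically zero. The equivalent R calls:

```r
library(chirospec)
mol    <- generate_chiral_fixture("h2o2_P")
scf    <- run_scf(mol, method_config("hf", basis = "sto-3g"))
states <- solve_eigenstates(scf, 10)
sticks <- rotatory_strengths(states)
curve  <- delta_epsilon_sticks(sticks, spectrum_params(gamma = 0.1240))
```

and `solve_cpp()` + `delta_epsilon_cpp()` compute the same spectrum
through the damped-response route without resolving states.

Other entry points: `scf` (energies and timings), `ecd-cpp` (CPP
spectrum over a wavelength window), `fixtures` (water droplets and
chiral test molecules, deterministic per seed), and `scaling`
(screened-quartet work measure versus droplet size with a log–log slope
fit).

## Documentation

The methods vignette (`vignettes/ecd-methods.Rmd`) documents the models
and conventions: normalization and component ordering, screening
semantics, grid construction and batching, the SCF and response
algorithms, the two spectrum routes and their unit conversion, what the
synthetic fixtures do and do not emulate, and known limitations.
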