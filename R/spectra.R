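# ECD spectrum assembly: velocity-gauge rotatory strengths, Cauchy
# (Lorentzian) broadening of stick spectra, and Delta-epsilon directly
# from the damped mixed electric-magnetic response; unit conversions and
# spectrum I/O.
#
# Conventions (atomic units internally):
#   electric transition moment (velocity gauge): P_n = sqrt(2) grad_ov . u_n
#   magnetic transition moment component:        M_n = sqrt(2) (r x grad)_ov . u_n
#   rotatory strength:                           R_n = P_n . M_n / (2 w_n)
# (the 1/w_n is the velocity-gauge factor, the 1/2 the magnetic-dipole
# prefactor; with these, R_n is the Im part of the scalar product of the
# electric and magnetic transition dipoles, gauge-origin independent).

# conversion of R (a.u.) times a unit-area line shape on the energy axis
# into Delta-epsilon in L mol^-1 cm^-1, assembled from CODATA constants:
#   Delta-eps(w) = K_DE * sum_n R_n * w * f(w; w_n, gamma)
# K_DE = [R a.u. in cgs] / [3000 h c ln10 / (32 pi^3 N_A)]  (~20.5)
delta_eps_conversion <- function() {
  c_cgs <- codata$c * 100            # cm/s
  h_cgs <- codata$h * 1e7            # erg s
  C_mosc <- 3000 * h_cgs * c_cgs * log(10) / (32 * pi^3 * codata$N_A)
  e_esu <- codata$e * c_cgs / 10
  a0_cm <- codata$a0 * 100
  m_au_cgs <- codata$hbar * codata$e / codata$m_e * 1e3  # erg/G
  (e_esu * a0_cm * m_au_cgs) / C_mosc
}

#' Spectrum parameters
#'
#' @param gamma damping / half-width at half-maximum.
#' @param gamma_unit unit of `gamma` (`"eV"`, `"cm-1"`, `"hartree"`).
#' @param lambda_min,lambda_max,lambda_step wavelength grid (nm).
#' @return list with gamma in Hartree and the wavelength grid.
#' @export
spectrum_params <- function(gamma = 0.1240, gamma_unit = "eV",
                            lambda_min = 120, lambda_max = 300,
                            lambda_step = 1) {
  g_h <- convert_damping(gamma, gamma_unit, to = "hartree")
  lam <- seq(lambda_min, lambda_max, by = lambda_step)
  list(gamma_hartree = g_h, gamma_ev = convert_energy(g_h, "hartree", "eV"),
       lambda_nm = lam,
       omega_hartree = convert_energy(lam, "nm", "hartree"))
}

#' Velocity-gauge rotatory strengths of an excitation set
#'
#' `R_n = P_n . M_n / (2 w_n)` in atomic units; origin-independent
#' because an origin shift changes `M` by `-d x P`, which is orthogonal
#' to `P`.
#'
#' @param states an `excitation_set` from [solve_eigenstates()].
#' @return object of class `rotatory_spectrum`: data.frame `n`,
#'   `energy_hartree`, `energy_ev`, `R_au`.
#' @export
rotatory_strengths <- function(states) {
  if (any(states$energy_hartree <= 0))
    stop("velocity-gauge rotatory strength is singular at zero ",
         "excitation energy")
  R <- rowSums(states$P * states$M) / (2 * states$energy_hartree)
  structure(data.frame(n = states$n,
                       energy_hartree = states$energy_hartree,
                       energy_ev = states$energy_ev,
                       R_au = R),
            class = c("rotatory_spectrum", "data.frame"))
}

# unit-area Cauchy (Lorentzian) profile on the energy axis, HWHM gamma
cauchy_profile <- function(w, w0, gamma)
  (gamma / pi) / ((w - w0)^2 + gamma^2)

#' Broadened Delta-epsilon from a stick spectrum
#'
#' `Delta-eps(w) = K * sum_n R_n w f(w; w_n, gamma)` with `f` the
#' unit-area Cauchy profile whose HWHM is the damping gamma; linear in
#' every `R_n`. Output in L mol^-1 cm^-1 against wavelength.
#'
#' @param sticks a [rotatory_strengths()] result.
#' @param params a [spectrum_params()].
#' @return data.frame `wavelength_nm, energy_ev, delta_epsilon`.
#' @export
delta_epsilon_sticks <- function(sticks, params = spectrum_params()) {
  w <- params$omega_hartree
  de <- numeric(length(w))
  for (k in seq_len(nrow(sticks)))
    de <- de + sticks$R_au[k] * w *
      cauchy_profile(w, sticks$energy_hartree[k], params$gamma_hartree)
  data.frame(wavelength_nm = params$lambda_nm,
             energy_ev = convert_energy(w, "hartree", "eV"),
             delta_epsilon = delta_eps_conversion() * de)
}

#' Delta-epsilon directly from damped response solutions
#'
#' Uses the trace of the velocity-gauge mixed electric-magnetic response
#' tensor at `w + i gamma`: on resonance its imaginary part reproduces
#' the Cauchy-broadened sticks, so the two spectrum routes agree when
#' every state in the window is resolved.
#'
#' @param cpp a `cpp_set` from [solve_cpp()] (or [solve_cpp_explicit()]).
#' @return data.frame `wavelength_nm, energy_ev, delta_epsilon`.
#' @export
delta_epsilon_cpp <- function(cpp) {
  w <- vapply(cpp$solutions, `[[`, numeric(1), "frequency")
  imT <- vapply(cpp$solutions, function(s) Im(s$trace_T), numeric(1))
  data.frame(wavelength_nm = convert_energy(w, "hartree", "nm"),
             energy_ev = convert_energy(w, "hartree", "eV"),
             delta_epsilon = delta_eps_conversion() * imT / (2 * pi))
}

#' Write spectrum files (curve TSV, sticks TSV, metadata JSON)
#'
#' @param curve data.frame `wavelength_nm, energy_ev, delta_epsilon`.
#' @param sticks a [rotatory_strengths()] data.frame (may have 0 rows).
#' @param path_prefix output prefix; writes `<prefix>_spectrum.tsv`,
#'   `<prefix>_sticks.tsv`, `<prefix>_meta.json`.
#' @param metadata named list merged into the JSON metadata.
#' @export
write_spectrum <- function(curve, sticks, path_prefix, metadata = list()) {
  fs <- paste0(path_prefix, "_spectrum.tsv")
  fk <- paste0(path_prefix, "_sticks.tsv")
  fm <- paste0(path_prefix, "_meta.json")
  utils::write.table(format(curve, digits = 10), fs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sk <- if (nrow(sticks)) data.frame(energy_ev = sticks$energy_ev,
                                     R_au = sticks$R_au)
        else data.frame(energy_ev = numeric(0), R_au = numeric(0))
  utils::write.table(format(sk, digits = 10), fk, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(created_by = "chirospec",
                              n_sticks = nrow(sticks)),
                         metadata), fm, auto_unbox = TRUE, digits = NA)
  invisible(c(fs, fk, fm))
}

#' Read a spectrum TSV back
#' @param path file written by [write_spectrum()].
#' @export
read_spectrum <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t")
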