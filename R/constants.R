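#' Physical constants (CODATA 2018) and unit conversions
#'
#' All internal math is done in Hartree atomic units; these constants convert
#' to and from SI and spectroscopic units. `codata` is a named list with SI
#' values; the `*_PER_*` scalars are the conversion factors used throughout.
#'
#' @format Named list of SI values.
#' @export
codata <- list(
  N_A     = 6.02214076e23,      # 1/mol
  eps0    = 8.8541878128e-12,   # F/m
  c       = 299792458,          # m/s
  hbar    = 1.054571817e-34,    # J s
  h       = 6.62607015e-34,     # J s
  e       = 1.602176634e-19,    # C
  m_e     = 9.1093837015e-31,   # kg
  a0      = 0.529177210903e-10, # m (Bohr radius)
  E_h     = 4.3597447222071e-18 # J (Hartree)
)

#' @rdname codata
#' @export
BOHR_PER_ANGSTROM <- 1e-10 / codata$a0     # 1.8897259886

#' @rdname codata
#' @export
EV_PER_HARTREE <- codata$E_h / codata$e    # 27.211386245988

#' @rdname codata
#' @export
CM1_PER_HARTREE <- codata$E_h / (codata$h * codata$c) / 100  # 219474.63136

#' @rdname codata
#' @export
NM_EV <- 1e9 * codata$h * codata$c / codata$e  # lambda[nm] * E[eV] = 1239.8420

#' Convert an energy-like quantity between spectroscopic units
#'
#' Supported units: `"hartree"`, `"eV"`, `"cm-1"`, and `"nm"` (photon
#' wavelength equivalent, E = hc/lambda). Conversions are assembled from
#' CODATA constants and round-trip exactly to machine precision.
#'
#' @param value numeric vector.
#' @param from,to unit names (case-insensitive).
#' @return numeric vector in the `to` unit.
#' @export
convert_energy <- function(value, from, to) {
  norm_unit <- function(u) {
    u <- tolower(u)
    u <- sub("^cm\\^?-1$|^percm$|^wavenumber$", "cm-1", u)
    if (!u %in% c("hartree", "ev", "cm-1", "nm"))
      stop("unsupported unit: ", u)
    u
  }
  from <- norm_unit(from); to <- norm_unit(to)
  to_hartree <- function(v, u) switch(u,
    hartree = v,
    ev      = v / EV_PER_HARTREE,
    `cm-1`  = v / CM1_PER_HARTREE,
    nm      = (NM_EV / v) / EV_PER_HARTREE)
  from_hartree <- function(v, u) switch(u,
    hartree = v,
    ev      = v * EV_PER_HARTREE,
    `cm-1`  = v * CM1_PER_HARTREE,
    nm      = NM_EV / (v * EV_PER_HARTREE))
  from_hartree(to_hartree(value, from), to)
}

#' Convert a damping / linewidth parameter between units
#'
#' The damping parameter gamma (also the Cauchy half-width at half-maximum)
#' is conventionally quoted in eV or wavenumbers; e.g. 1000 cm^-1
#' corresponds to 0.1240 eV.
#'
#' @param value numeric scalar.
#' @param unit unit `value` is given in: `"eV"`, `"cm-1"`, `"hartree"`, `"nm"`.
#' @param to desired unit (default `"eV"`).
#' @return gamma in the requested unit.
#' @export
convert_damping <- function(value, unit, to = "eV") {
  if (!is.numeric(value) || length(value) != 1L || value <= 0)
    stop("damping must be a positive scalar")
  convert_energy(value, from = unit, to = to)
}
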