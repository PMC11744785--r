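# Exchange-correlation: built-in local functionals (Slater exchange,
# VWN5 correlation), density evaluation on grid batches by matrix
# multiplication with per-batch AO screening, and the XC Fock matrix.

# local functional evaluators: given total density rho (vector), return
# energy density per volume (e) and potential (v = de/drho)
.slater_x <- function(rho) {
  cx <- 0.75 * (3 / pi)^(1 / 3)
  list(e = -cx * rho^(4 / 3), v = -(4 / 3) * cx * rho^(1 / 3))
}

.vwn5_c <- function(rho) {
  # VWN parameterization V (paramagnetic), atomic units
  A <- 0.0310907; b <- 3.72744; c <- 12.9352; x0 <- -0.10498
  rho <- pmax(rho, 1e-300)
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  x <- sqrt(rs)
  X <- function(t) t^2 + b * t + c
  Q <- sqrt(4 * c - b^2)
  ec <- A * (log(x^2 / X(x)) + 2 * b / Q * atan(Q / (2 * x + b)) -
             b * x0 / X(x0) * (log((x - x0)^2 / X(x)) +
                               2 * (b + 2 * x0) / Q * atan(Q / (2 * x + b))))
  # d ec / d x
  dec <- A * (2 / x - (2 * x + b) / X(x) - 4 * b / (Q^2 + (2 * x + b)^2) -
              b * x0 / X(x0) * (2 / (x - x0) - (2 * x + b) / X(x) -
                                4 * (b + 2 * x0) / (Q^2 + (2 * x + b)^2)))
  # vc = ec + rho * d ec / d rho; d rs/d rho = -rs/(3 rho); dx/drs = 1/(2x)
  vc <- ec - (x / 6) * dec
  list(e = ec * rho, v = vc)
}

#' Exchange-correlation functional specification
#'
#' Built-in local (LDA-level) functionals: `"slater_x"` (Dirac-Slater
#' exchange) and `"slater_vwn"` (Slater exchange plus VWN5 correlation).
#' `exchange_scale` globally scales the DFT exchange part (used by the
#' demonstration hybrid/range-separated methods, where part of the
#' exchange is carried by Hartree-Fock-type K builds).
#'
#' @param name functional id.
#' @param exchange_scale multiplier on the Slater exchange term.
#' @export
xc_functional <- function(name = c("slater_x", "slater_vwn"),
                          exchange_scale = 1) {
  name <- match.arg(name)
  structure(list(name = name, exchange_scale = exchange_scale),
            class = "xc_functional")
}

.xc_eval <- function(fun, rho) {
  sx <- .slater_x(rho)
  e <- fun$exchange_scale * sx$e
  v <- fun$exchange_scale * sx$v
  if (fun$name == "slater_vwn") {
    cr <- .vwn5_c(rho)
    e <- e + cr$e
    v <- v + cr$v
  }
  list(e = e, v = v)
}

#' Electron density on a grid batch
#'
#' `rho(r) = 2 * phi(r)' D phi(r)` (closed-shell total density with D
#' normalized to `tr(DS) = N_elec/2`), evaluated by matrix multiplication
#' over the AOs surviving the per-batch screening cutoff on the maximum
#' AO value in the box.
#'
#' @param D density matrix (contracted basis).
#' @param ao an `ao_basis`.
#' @param pts matrix/data.frame with columns `x, y, z` (Bohr).
#' @param ao_cutoff per-batch AO screening threshold (`0` disables).
#' @return list `rho` (vector), `Phi` (AO values), `aos` (surviving AO
#'   indices).
#' @export
density_on_batch <- function(D, ao, pts, ao_cutoff = 1e-12) {
  Phi <- ao_values(ao, as.matrix(pts[, 1:3]))
  amax <- apply(abs(Phi), 2, max)
  aos <- which(amax >= ao_cutoff)
  Phi_s <- Phi[, aos, drop = FALSE]
  Ds <- unclass(D)[aos, aos, drop = FALSE]
  rho <- 2 * rowSums((Phi_s %*% Ds) * Phi_s)
  list(rho = rho, Phi = Phi_s, aos = aos)
}

#' XC Fock matrix and energy by batched numerical integration
#'
#' Splits the grid into even boxes ([partition_boxes()]), evaluates the
#' density per batch, applies the local functional, and accumulates
#' `E_xc = sum w e(rho)` and `(V_xc)_mn = sum w v(rho) phi_m phi_n` by
#' matrix multiplication. Results are independent of the batch size.
#'
#' @param D density matrix (contracted basis, closed-shell convention).
#' @param ao an `ao_basis`.
#' @param grid a [build_grid()] result.
#' @param functional an [xc_functional()].
#' @param max_points box-bisection threshold.
#' @param ao_cutoff per-batch AO screening threshold.
#' @return list `E_xc`, `V_xc`, `n_elec` (integrated electron count),
#'   `n_products` (batch x surviving-AO work measure).
#' @export
xc_fock_and_energy <- function(D, ao, grid, functional = xc_functional(),
                               max_points = 256, ao_cutoff = 1e-12) {
  batches <- partition_boxes(grid, max_points)
  n <- ao$n_ao
  V <- matrix(0, n, n)
  E <- 0; nelec <- 0; nprod <- 0
  for (idx in batches) {
    pts <- as.matrix(grid[idx, c("x", "y", "z")])
    w <- grid$w[idx]
    db <- density_on_batch(D, ao, pts, ao_cutoff)
    rho <- pmax(db$rho, 0)
    fx <- .xc_eval(functional, rho)
    E <- E + sum(w * fx$e)
    nelec <- nelec + sum(w * db$rho)
    wv <- w * fx$v
    V[db$aos, db$aos] <- V[db$aos, db$aos] + crossprod(db$Phi, db$Phi * wv)
    nprod <- nprod + length(idx) * length(db$aos)
  }
  V <- (V + t(V)) / 2
  list(E_xc = E, V_xc = V, n_elec = nelec, n_products = nprod)
}
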