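# Linear response on the closed-shell SCF reference in the paired
# symmetric/antisymmetric trial-vector representation: the electronic
# Hessian action is delivered by auxiliary Fock builds on transition
# densities (J + K + XC for the symmetric component, K-only for the
# antisymmetric one), driving both the reduced-space eigensolver for
# excitation energies and the damped (complex polarization propagator)
# linear solver.
#
# Representation: for a trial (X, Y) in the occupied-virtual space the
# paired components are g = X + Y (symmetric image) and u = X - Y
# (antisymmetric image); E[2] acts blockwise as (A+B) on g and (A-B) on
# u, and S[2] swaps the two. Normalization: g' u = X'X - Y'Y = 1.

# occupied/virtual split helper
.ov_space <- function(scf) {
  nocc <- scf$n_occ
  nmo <- ncol(scf$C)
  list(Co = scf$C[, seq_len(nocc), drop = FALSE],
       Cv = scf$C[, seq(nocc + 1, nmo), drop = FALSE],
       eps_o = scf$eps[seq_len(nocc)],
       eps_v = scf$eps[seq(nocc + 1, nmo)],
       nocc = nocc, nvirt = nmo - nocc, nov = nocc * (nmo - nocc))
}

# We store ov vectors as nocc x nvirt matrices flattened column-major
# (i fastest within a virtual column).
ov_mat <- function(v, sp) matrix(v, sp$nocc, sp$nvirt)
ov_vec <- function(M) as.vector(M)
ov_delta_eps <- function(sp) as.vector(outer(seq_len(sp$nocc),
  seq_len(sp$nvirt), function(i, a) sp$eps_v[a] - sp$eps_o[i]))

# MO occupied-virtual block of a one-electron AO matrix
ov_block <- function(O, sp) crossprod(sp$Co, O %*% sp$Cv)

#' Sigma vector: E[2] action through auxiliary Fock builds
#'
#' Applies `(A+B)` to the symmetric component and `(A-B)` to the
#' antisymmetric component of a paired trial vector. Symmetric
#' components trigger Coulomb + exchange (+ XC kernel) builds on the
#' symmetrized transition density; antisymmetric components trigger
#' exchange-only builds (the Coulomb build is skipped). The XC kernel is
#' applied as a symmetric finite-field derivative of V_xc (step 1e-5).
#'
#' @param scf a converged [run_scf()] state.
#' @param g symmetric-component ov vector (or `NULL`).
#' @param u antisymmetric-component ov vector (or `NULL`).
#' @return list `sg = (A+B) g`, `su = (A-B) u`, `n_J_builds`,
#'   `n_K_builds`.
#' @export
sigma_vector <- function(scf, g = NULL, u = NULL) {
  sp <- .ov_space(scf)
  deps <- ov_delta_eps(sp)
  cfg <- scf$config
  cx <- cfg$weights$cx; clr <- cfg$weights$clr
  nJ <- 0L; nK <- 0L
  sg <- su <- NULL
  if (!is.null(g)) {
    G <- ov_mat(g, sp)
    Ds_raw <- sp$Co %*% G %*% t(sp$Cv)
    Ds <- density_matrix(Ds_raw + t(Ds_raw), "symmetric")
    two <- assemble_two_electron_fock(Ds, scf$ao, cfg$screening, cfg$weights)
    nJ <- nJ + 1L
    nK <- nK + as.integer(cx != 0) + as.integer(clr != 0)
    Gmat <- two$F2e
    if (!is.null(cfg$functional))
      Gmat <- Gmat + .fxc_finite_field(scf, Ds)
    sg <- deps * g + ov_vec(crossprod(sp$Co, Gmat %*% sp$Cv))
  }
  if (!is.null(u)) {
    U <- ov_mat(u, sp)
    Dt_raw <- sp$Co %*% U %*% t(sp$Cv)
    Dt <- density_matrix(Dt_raw - t(Dt_raw), "antisymmetric")
    Gmat <- matrix(0, scf$ao$n_ao, scf$ao$n_ao)
    if (cx != 0)
      Gmat <- Gmat - cx * unclass(build_K(Dt, scf$ao, cfg$screening))
    if (clr != 0)
      Gmat <- Gmat - clr * unclass(build_K(Dt, scf$ao, cfg$screening,
                                           omega = cfg$weights$omega))
    nK <- nK + as.integer(cx != 0) + as.integer(clr != 0)
    su <- deps * u + ov_vec(crossprod(sp$Co, Gmat %*% sp$Cv))
  }
  list(sg = sg, su = su, n_J_builds = nJ, n_K_builds = nK)
}

# XC kernel action by symmetric finite difference of V_xc along Ds
.fxc_finite_field <- function(scf, Ds, step = 1e-5) {
  scale <- max(abs(Ds))
  if (scale == 0) return(matrix(0, scf$ao$n_ao, scf$ao$n_ao))
  t <- step / scale
  xp <- xc_fock_and_energy(unclass(scf$D) + t * unclass(Ds), scf$ao,
                           scf$grid, scf$config$functional,
                           max_points = scf$config$xc_max_points)
  xm <- xc_fock_and_energy(unclass(scf$D) - t * unclass(Ds), scf$ao,
                           scf$grid, scf$config$functional,
                           max_points = scf$config$xc_max_points)
  (xp$V_xc - xm$V_xc) / (2 * t)
}

#' Explicit dense response matrices (oracle mode)
#'
#' Builds `A+B` and `A-B` over the occupied-virtual space from the
#' MO-transformed ERI tensor (plus, for local functionals, the grid
#' representation of the adiabatic XC kernel). Intended for systems with
#' at most a few tens of ov pairs, as the independent reference for the
#' iterative solvers.
#'
#' @param scf a converged [run_scf()] state.
#' @return list `ApB`, `AmB` (nov x nov), `deps`.
#' @export
explicit_response_matrices <- function(scf) {
  sp <- .ov_space(scf)
  cfg <- scf$config
  cx <- cfg$weights$cx; clr <- cfg$weights$clr
  n <- scf$ao$n_ao
  eri <- contracted_eri_tensor(scf$ao)
  C <- scf$C
  # quarter transformations (first AO index -> MO, cycling with aperm)
  tr1 <- function(tns) {
    m <- matrix(tns, n, length(tns) / n)
    aperm(array(crossprod(C, m), dim = rep(n, 4)), c(2, 3, 4, 1))
  }
  mo <- tr1(tr1(tr1(tr1(eri))))
  occ <- seq_len(sp$nocc); vir <- sp$nocc + seq_len(sp$nvirt)
  nov <- sp$nov
  deps <- ov_delta_eps(sp)
  ApB <- matrix(0, nov, nov); AmB <- matrix(0, nov, nov)
  idx <- function(i, a) (a - 1) * sp$nocc + i
  for (i in occ) for (a in seq_len(sp$nvirt)) for (j in occ)
    for (b in seq_len(sp$nvirt)) {
      av <- vir[a]; bv <- vir[b]
      iajb <- mo[i, av, j, bv]
      ijab <- mo[i, j, av, bv]
      ibaj <- mo[i, bv, av, j]
      ap <- 4 * iajb - cx * (ijab + ibaj)
      am <- cx * (ibaj - ijab)
      r <- idx(i, a); s <- idx(j, b)
      ApB[r, s] <- ApB[r, s] + ap
      AmB[r, s] <- AmB[r, s] + am
    }
  if (clr != 0) {
    eril <- contracted_eri_tensor(scf$ao, omega = cfg$weights$omega)
    mol_ <- tr1(tr1(tr1(tr1(eril))))
    for (i in occ) for (a in seq_len(sp$nvirt)) for (j in occ)
      for (b in seq_len(sp$nvirt)) {
        av <- vir[a]; bv <- vir[b]
        ijab <- mol_[i, j, av, bv]
        ibaj <- mol_[i, bv, av, j]
        r <- idx(i, a); s <- idx(j, b)
        ApB[r, s] <- ApB[r, s] - clr * (ijab + ibaj)
        AmB[r, s] <- AmB[r, s] + clr * (ibaj - ijab)
      }
  }
  diag(ApB) <- diag(ApB) + deps
  diag(AmB) <- diag(AmB) + deps
  if (!is.null(cfg$functional)) {
    fxc <- .fxc_kernel_grid(scf, sp)
    ApB <- ApB + 4 * fxc
  }
  list(ApB = (ApB + t(ApB)) / 2, AmB = (AmB + t(AmB)) / 2, deps = deps)
}

# grid-quadrature matrix of the adiabatic local XC kernel over ov pairs:
# (ia|fxc|jb) with fxc = d^2 e / d rho^2 of the ground-state density
# (pointwise numerical derivative of the potential; independent of the
# finite-field matrix route used in sigma_vector)
.fxc_kernel_grid <- function(scf, sp) {
  grid <- scf$grid
  Phi <- ao_values(scf$ao, as.matrix(grid[, c("x", "y", "z")]))
  rho <- pmax(2 * rowSums((Phi %*% unclass(scf$D)) * Phi), 1e-12)
  h <- rho * 1e-4  # keeps rho - h positive everywhere
  vp <- .xc_eval(scf$config$functional, rho + h)$v
  vm <- .xc_eval(scf$config$functional, rho - h)$v
  fxc <- (vp - vm) / (2 * h)
  Po <- Phi %*% sp$Co; Pv <- Phi %*% sp$Cv
  Mov <- matrix(0, nrow(Phi), sp$nov)
  k <- 0
  for (a in seq_len(sp$nvirt)) for (i in seq_len(sp$nocc)) {
    k <- k + 1
    Mov[, k] <- Po[, i] * Pv[, a]
  }
  crossprod(Mov, Mov * (grid$w * fxc))
}

#' Solve for the lowest excitation energies and transition moments
#'
#' Reduced-space (Davidson-type) iteration with paired trial vectors and
#' modified Gram-Schmidt re-orthogonalization; residuals preconditioned
#' by the orbital-energy-difference diagonal. Transition moments for the
#' velocity-gauge operators (linear momentum and angular momentum) are
#' attached to each state.
#'
#' @param scf a converged [run_scf()] state.
#' @param n_states number of roots (<= ov-pair count).
#' @param tol residual 2-norm tolerance per root.
#' @param max_iter iteration cap.
#' @param max_subspace subspace dimension cap (default 50 per root).
#' @return data.frame of class `excitation_set`: `n`, `energy_hartree`,
#'   `energy_ev`, plus matrices of velocity-gauge electric (`P`) and
#'   magnetic (`M`) transition-moment components and the solver log.
#' @export
solve_eigenstates <- function(scf, n_states, tol = 1e-6, max_iter = 60,
                              max_subspace = 50 * n_states) {
  sp <- .ov_space(scf)
  if (n_states > sp$nov)
    stop("n_states exceeds the occupied-virtual pair count (", sp$nov, ")")
  deps <- ov_delta_eps(sp)
  nov <- sp$nov
  # initial basis: unit vectors on the smallest orbital-energy gaps
  nb0 <- min(nov, n_states + min(4, nov - n_states))
  V <- matrix(0, nov, nb0)
  for (k in seq_len(nb0)) V[order(deps)[k], k] <- 1
  SpV <- NULL; SmV <- NULL   # (A+B)V and (A-B)V
  n_J <- 0L; n_K <- 0L
  for (iter in seq_len(max_iter)) {
    new_cols <- seq.int(ncol(SpV %||% matrix(0, nov, 0)) + 1L, ncol(V))
    for (k in new_cols) {
      sv <- sigma_vector(scf, g = V[, k], u = V[, k])
      n_J <- n_J + sv$n_J_builds; n_K <- n_K + sv$n_K_builds
      SpV <- cbind(SpV, sv$sg)
      SmV <- cbind(SmV, sv$su)
    }
    Mp <- crossprod(V, SpV); Mm <- crossprod(V, SmV)
    Mp <- (Mp + t(Mp)) / 2; Mm <- (Mm + t(Mm)) / 2
    ee <- eigen(Mm %*% Mp)
    ord <- order(Re(ee$values))
    w2 <- Re(ee$values[ord][seq_len(n_states)])
    if (any(w2 <= 0)) stop("response eigenproblem is not positive ",
                           "definite (unstable reference)")
    omegas <- sqrt(w2)
    gt <- Re(ee$vectors[, ord[seq_len(n_states)], drop = FALSE])
    resnorm <- numeric(n_states)
    add <- NULL
    G <- U <- matrix(0, nov, n_states)
    for (s in seq_len(n_states)) {
      gs <- gt[, s]
      us <- (Mp %*% gs) / omegas[s]
      gfull <- V %*% gs; ufull <- V %*% us
      nrm <- sqrt(abs(sum(gfull * ufull)))
      gfull <- gfull / nrm; ufull <- ufull / nrm
      G[, s] <- gfull; U[, s] <- ufull
      rg <- SpV %*% gs / nrm - omegas[s] * ufull
      ru <- SmV %*% us / nrm - omegas[s] * gfull
      resnorm[s] <- sqrt(sum(rg^2) + sum(ru^2))
      if (resnorm[s] > tol) {
        pg <- rg / pmax(abs(deps - omegas[s]), 1e-2)
        pu <- ru / pmax(abs(deps - omegas[s]), 1e-2)
        add <- cbind(add, pg, pu)
      }
    }
    if (all(resnorm <= tol)) break
    if (iter == max_iter)
      stop("response eigensolver did not converge (max residual ",
           signif(max(resnorm), 3), ")")
    # orthonormalize additions against V (MGS with re-orthogonalization)
    for (k in seq_len(ncol(add))) {
      v <- add[, k]
      for (pass in 1:2) v <- v - V %*% crossprod(V, v)
      nv <- sqrt(sum(v^2))
      if (nv > 1e-8) V <- cbind(V, v / nv)
    }
    if (ncol(V) > max_subspace)
      stop("response eigensolver subspace exceeded its cap (",
           max_subspace, ") without convergence")
  }
  # transition moments (velocity gauge; antisymmetric operators use the
  # u = X - Y component with the closed-shell sqrt(2) spin factor)
  Pov <- lapply(scf$oe$P, ov_block, sp = sp)
  Lov <- lapply(scf$oe$L, ov_block, sp = sp)
  Pmom <- t(vapply(seq_len(n_states), function(s)
    vapply(Pov, function(O) sqrt(2) * sum(ov_vec(O) * U[, s]), numeric(1)),
    numeric(3)))
  Mmom <- t(vapply(seq_len(n_states), function(s)
    vapply(Lov, function(O) sqrt(2) * sum(ov_vec(O) * U[, s]), numeric(1)),
    numeric(3)))
  structure(list(
    n = seq_len(n_states),
    energy_hartree = omegas,
    energy_ev = omegas * EV_PER_HARTREE,
    P = Pmom, M = Mmom, G = G, U = U,
    origin = scf$oe$origin,
    n_J_builds = n_J, n_K_builds = n_K,
    residuals = resnorm), class = "excitation_set")
}

#' @export
print.excitation_set <- function(x, ...) {
  cat("<excitation_set>\n")
  print(data.frame(n = x$n, E_hartree = x$energy_hartree,
                   E_eV = x$energy_ev))
  invisible(x)
}

#' Damped (CPP) linear response solver
#'
#' Solves `(E[2] - (omega + i gamma) S[2]) X = -B` for the velocity-gauge
#' operator pair at each frequency in the paired representation, by a
#' reduced-space iteration over real basis vectors shared between the
#' symmetric and antisymmetric components, with a complex-shifted
#' orbital-energy-difference preconditioner. The right-hand sides are
#' the gradient (electric, velocity gauge) operators; the mixed
#' electric-magnetic responses are obtained by projection on the
#' angular-momentum gradients.
#'
#' @param scf a converged [run_scf()] state.
#' @param frequencies frequencies (Hartree).
#' @param gamma damping (Hartree), > 0.
#' @param tol relative residual tolerance.
#' @param max_iter iteration cap per frequency batch.
#' @return list of class `cpp_set`: per frequency the complex mixed
#'   electric-magnetic tensor `G_tensor[a, b]` (gradient a, angular
#'   momentum b), the trace response `trace_T`, residual norms, and the
#'   build counters.
#' @export
solve_cpp <- function(scf, frequencies, gamma, tol = 1e-5, max_iter = 80) {
  stopifnot(gamma > 0)
  sp <- .ov_space(scf)
  deps <- ov_delta_eps(sp)
  nov <- sp$nov
  Pov <- lapply(scf$oe$P, function(O) ov_vec(ov_block(O, sp)))
  Lov <- lapply(scf$oe$L, function(O) ov_vec(ov_block(O, sp)))
  # antisymmetric-operator gradients drive only the u equation:
  # b_g = 0, b_u = 2 sqrt(2) O_ov
  B_u <- matrix(unlist(lapply(Pov, function(p) 2 * sqrt(2) * p)), nov, 3)
  # shared real reduced basis
  V <- NULL
  SpV <- NULL; SmV <- NULL
  n_J <- 0L; n_K <- 0L
  add_vec <- function(v) {
    for (pass in 1:2) if (!is.null(V)) v <- v - V %*% crossprod(V, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-10) V <<- cbind(V, v / nv)
  }
  for (k in 1:3) add_vec(B_u[, k])
  # seed with preconditioned variants at the extreme frequencies
  for (w in unique(range(frequencies))) for (k in 1:3) {
    d <- (deps - w)^2 + gamma^2
    add_vec(B_u[, k] * (deps - w) / d)
    add_vec(B_u[, k] * gamma / d)
  }
  out <- vector("list", length(frequencies))
  for (iter in seq_len(max_iter)) {
    ncur <- ncol(SpV %||% matrix(0, nov, 0))
    if (ncol(V) > ncur) for (k in seq.int(ncur + 1L, ncol(V))) {
      sv <- sigma_vector(scf, g = V[, k], u = V[, k])
      n_J <- n_J + sv$n_J_builds; n_K <- n_K + sv$n_K_builds
      SpV <- cbind(SpV, sv$sg)
      SmV <- cbind(SmV, sv$su)
    }
    Mp <- crossprod(V, SpV); Mm <- crossprod(V, SmV)
    Mp <- (Mp + t(Mp)) / 2; Mm <- (Mm + t(Mm)) / 2
    m <- ncol(V)
    I <- diag(m)
    all_ok <- TRUE
    worst <- NULL
    for (fi in seq_along(frequencies)) {
      z <- frequencies[fi] + 1i * gamma
      # reduced paired system: Mp xg - z xu = -bg(=0); Mm xu - z xg = -bu
      bu_red <- crossprod(V, B_u)
      lhs <- rbind(cbind(Mp, -z * I), cbind(-z * I, Mm))
      rhs <- rbind(matrix(0, m, 3), -bu_red)
      sol <- solve(lhs, rhs)
      xg_red <- sol[seq_len(m), , drop = FALSE]
      xu_red <- sol[m + seq_len(m), , drop = FALSE]
      xg <- V %*% xg_red; xu <- V %*% xu_red
      # residuals in full space
      rg <- SpV %*% xg_red - z * xu
      ru <- SmV %*% xu_red - z * xg + B_u
      rn <- sqrt(sum(Mod(rg)^2) + sum(Mod(ru)^2)) / sqrt(sum(B_u^2))
      if (rn > tol) {
        all_ok <- FALSE
        if (is.null(worst) || rn > worst$rn)
          worst <- list(rn = rn, rg = rg, ru = ru, z = z)
      }
      # responses from the gradient RHS: mixed electric-magnetic
      # (projection on the angular-momentum gradients) and electric
      # (projection on the gradient operators themselves)
      Gt <- matrix(0i, 3, 3); At <- matrix(0i, 3, 3)
      for (a in 1:3) for (b in 1:3) {
        Gt[b, a] <- -sqrt(2) * sum(Lov[[b]] * xu[, a])
        At[b, a] <- -sqrt(2) * sum(Pov[[b]] * xu[, a])
      }
      out[[fi]] <- list(frequency = frequencies[fi], gamma = gamma,
                        G_tensor = Gt, alpha_tensor = At,
                        trace_T = sum(diag(Gt)), residual = rn)
    }
    if (all_ok) break
    if (iter == max_iter)
      stop("CPP solver did not converge (residual ",
           signif(worst$rn, 3), " at z = ", format(worst$z), ")")
    d <- (deps - Re(worst$z))^2 + gamma^2
    for (k in 1:3) {
      for (vec in list(Re(worst$rg[, k]), Im(worst$rg[, k]),
                       Re(worst$ru[, k]), Im(worst$ru[, k]))) {
        pre <- vec * 1 / sqrt(d)
        add_vec(pre)
      }
    }
  }
  structure(list(solutions = out, gamma = gamma,
                 frequencies = frequencies,
                 n_J_builds = n_J, n_K_builds = n_K),
            class = "cpp_set")
}

#' @export
print.cpp_set <- function(x, ...) {
  cat(sprintf("<cpp_set: %d frequencies, gamma = %.4g Hartree, %d J + %d K builds>\n",
              length(x$frequencies), x$gamma, x$n_J_builds, x$n_K_builds))
  invisible(x)
}

#' Dense-oracle CPP solution from explicit response matrices
#'
#' Direct complex solve of the paired system with [explicit_response_matrices()];
#' the independent reference for [solve_cpp()].
#'
#' @inheritParams solve_cpp
#' @param mats optional precomputed [explicit_response_matrices()].
#' @export
solve_cpp_explicit <- function(scf, frequencies, gamma, mats = NULL) {
  sp <- .ov_space(scf)
  if (is.null(mats)) mats <- explicit_response_matrices(scf)
  nov <- sp$nov
  Pov <- lapply(scf$oe$P, function(O) ov_vec(ov_block(O, sp)))
  Lov <- lapply(scf$oe$L, function(O) ov_vec(ov_block(O, sp)))
  B_u <- matrix(unlist(lapply(Pov, function(p) 2 * sqrt(2) * p)), nov, 3)
  out <- lapply(frequencies, function(w) {
    z <- w + 1i * gamma
    lhs <- rbind(cbind(mats$ApB, -z * diag(nov)),
                 cbind(-z * diag(nov), mats$AmB))
    sol <- solve(lhs, rbind(matrix(0, nov, 3), -B_u))
    xu <- sol[nov + seq_len(nov), , drop = FALSE]
    Gt <- matrix(0i, 3, 3); At <- matrix(0i, 3, 3)
    for (a in 1:3) for (b in 1:3) {
      Gt[b, a] <- -sqrt(2) * sum(Lov[[b]] * xu[, a])
      At[b, a] <- -sqrt(2) * sum(Pov[[b]] * xu[, a])
    }
    list(frequency = w, gamma = gamma, G_tensor = Gt, alpha_tensor = At,
         trace_T = sum(diag(Gt)), residual = 0)
  })
  structure(list(solutions = out, gamma = gamma, frequencies = frequencies,
                 n_J_builds = NA, n_K_builds = NA), class = "cpp_set")
}
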