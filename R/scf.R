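# Closed-shell SCF: core-Hamiltonian guess, screened Fock assembly,
# generalized-eigenvalue diagonalization, DIIS acceleration, per-stage
# timing and the Fock-builds-per-hour performance indicator.

#' Method configuration for SCF and response
#'
#' Methods: `"hf"` (Hartree-Fock), `"lda-demo"` (Slater exchange + VWN5
#' correlation), `"cam-lda-demo"` (range-separated demonstration hybrid:
#' Hartree-Fock-type exchange alpha + beta*erf(omega r)/r via attenuated
#' integrals, the LDA exchange scaled by 1 - alpha - beta, full VWN5
#' correlation; defaults alpha = 0.19, beta = 0.46, omega = 0.33).
#'
#' @param method method id.
#' @param basis basis name or path.
#' @param screening a [screening_config()].
#' @param grid_level grid quality for the XC quadrature.
#' @param xc_max_points grid box-bisection threshold.
#' @param tol_E,tol_D SCF convergence thresholds (Hartree; Frobenius
#'   density change).
#' @param max_iter iteration cap.
#' @param diis_window DIIS subspace size.
#' @param cam list `alpha, beta, omega` for range separation.
#' @export
method_config <- function(method = c("hf", "lda-demo", "cam-lda-demo"),
                          basis = "sto-3g",
                          screening = screening_config(),
                          grid_level = "medium",
                          xc_max_points = 256,
                          tol_E = 1e-8, tol_D = 1e-6, max_iter = 100,
                          diis_window = 8,
                          cam = list(alpha = 0.19, beta = 0.46,
                                     omega = 0.33)) {
  method <- match.arg(method)
  weights <- switch(method,
    "hf" = list(cx = 1, clr = 0, omega = NULL),
    "lda-demo" = list(cx = 0, clr = 0, omega = NULL),
    "cam-lda-demo" = list(cx = cam$alpha, clr = cam$beta, omega = cam$omega))
  functional <- switch(method,
    "hf" = NULL,
    "lda-demo" = xc_functional("slater_vwn", exchange_scale = 1),
    "cam-lda-demo" = xc_functional("slater_vwn",
                                   exchange_scale = 1 - cam$alpha - cam$beta))
  if (weights$cx + weights$clr < 0)
    stop("config error: negative total exchange weight")
  list(method = method, basis = basis, screening = screening,
       grid_level = grid_level, xc_max_points = xc_max_points,
       tol_E = tol_E, tol_D = tol_D, max_iter = max_iter,
       diis_window = diis_window, cam = cam,
       weights = weights, functional = functional)
}

#' Solve the generalized eigenproblem F C = S C diag(eps)
#'
#' Symmetric orthogonalization (S^-1/2); eigenvalues ascending, columns
#' S-orthonormal.
#'
#' @param F symmetric Fock matrix.
#' @param S overlap matrix (positive definite).
#' @param cond_limit condition-number cap on S.
#' @return list `C`, `eps`.
#' @export
diagonalize_fock <- function(F, S, cond_limit = 1e12) {
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(es$values) <= 0 || max(es$values) / min(es$values) > cond_limit)
    stop("overlap matrix is near-singular (condition > ", cond_limit,
         "); prune the basis")
  Shalf <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  Ft <- t(Shalf) %*% ((F + t(F)) / 2) %*% Shalf
  ef <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
  ord <- order(ef$values)
  list(C = Shalf %*% ef$vectors[, ord, drop = FALSE], eps = ef$values[ord])
}

# one Fock assembly; returns matrices, energy pieces and stage timings
.fock_pass <- function(D, ao, cfg, grid) {
  t0 <- proc.time()[["elapsed"]]
  two <- assemble_two_electron_fock(D, ao, cfg$screening, cfg$weights)
  t_eri <- proc.time()[["elapsed"]] - t0
  E_xc <- 0; V_xc <- 0
  t_xc <- 0
  if (!is.null(cfg$functional)) {
    t0 <- proc.time()[["elapsed"]]
    xc <- xc_fock_and_energy(D, ao, grid, cfg$functional,
                             max_points = cfg$xc_max_points)
    E_xc <- xc$E_xc; V_xc <- xc$V_xc
    t_xc <- proc.time()[["elapsed"]] - t0
  }
  list(F2e = two$F2e + V_xc, J = two$J, K = two$K, K_lr = two$K_lr,
       E_xc = E_xc, V_xc = V_xc, t_eri = t_eri, t_xc = t_xc)
}

#' Run a closed-shell SCF optimization
#'
#' @param mol a [molecule()] with an even electron count.
#' @param config a [method_config()].
#' @param ao optional prebuilt `ao_basis` (with screening tables).
#' @param verbose print per-iteration log lines to stderr.
#' @return object of class `scf_state`: MO coefficients `C` (S-orthonormal),
#'   orbital energies `eps`, density `D` (tagged symmetric,
#'   `tr(DS) = N_elec/2`), total energy `energy` (Hartree), energy
#'   breakdown, iteration log with per-stage wall times, timing report.
#' @export
run_scf <- function(mol, config = method_config(), ao = NULL,
                    verbose = FALSE) {
  nelec <- n_electrons(mol)
  if (nelec <= 0 || nelec %% 2 != 0)
    stop("closed-shell SCF requires a positive even electron count (got ",
         nelec, ")")
  nocc <- nelec / 2
  if (is.null(ao)) ao <- prepare_screening(build_ao_basis(mol, config$basis))
  oe <- compute_one_electron(ao)
  h <- oe$T + oe$V
  grid <- if (!is.null(config$functional))
    build_grid(mol, config$grid_level) else NULL
  Enuc <- nuclear_repulsion(mol)

  dg <- diagonalize_fock(h, oe$S)
  Cocc <- dg$C[, seq_len(nocc), drop = FALSE]
  D <- density_matrix(tcrossprod(Cocc), "symmetric")

  diis_F <- list(); diis_e <- list()
  log <- data.frame()
  E_old <- Inf; D_old <- D
  converged <- FALSE
  fock_builds <- 0L; t_fock_total <- 0
  for (it in seq_len(config$max_iter)) {
    fp <- .fock_pass(D, ao, config, grid)
    fock_builds <- fock_builds + 1L
    t_fock_total <- t_fock_total + fp$t_eri + fp$t_xc
    F <- h + fp$F2e
    E <- 2 * sum(D * h) + 2 * sum(D * fp$J) -
      config$weights$cx * sum(D * unclass(fp$K)) -
      config$weights$clr * sum(D * unclass(fp$K_lr)) +
      fp$E_xc + Enuc

    # DIIS on the orbital-gradient residual F D S - S D F
    err <- F %*% D %*% oe$S - oe$S %*% D %*% F
    diis_F <- c(diis_F, list(F)); diis_e <- c(diis_e, list(err))
    if (length(diis_F) > config$diis_window) {
      diis_F <- diis_F[-1]; diis_e <- diis_e[-1]
    }
    m <- length(diis_F)
    if (m > 1) {
      B <- matrix(0, m + 1, m + 1)
      for (i in 1:m) for (j in 1:m)
        B[i, j] <- sum(diis_e[[i]] * diis_e[[j]])
      B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cf))
        F <- Reduce(`+`, Map(`*`, diis_F, cf))
    }

    t0 <- proc.time()[["elapsed"]]
    dg <- diagonalize_fock(F, oe$S)
    t_diag <- proc.time()[["elapsed"]] - t0
    Cocc <- dg$C[, seq_len(nocc), drop = FALSE]
    D_new <- density_matrix(tcrossprod(Cocc), "symmetric")

    dE <- E - E_old
    dD <- sqrt(sum((D_new - D)^2))
    log <- rbind(log, data.frame(iter = it, E = E, dE = dE, dD = dD,
                                 t_eri = fp$t_eri, t_xc = fp$t_xc,
                                 t_diag = t_diag))
    if (verbose)
      message(sprintf("iter %3d  E=%.10f  dE=%.2e  |dD|=%.2e  t_ERI=%.2fs t_XC=%.2fs t_diag=%.3fs",
                      it, E, dE, dD, fp$t_eri, fp$t_xc, t_diag))
    if (abs(dE) < config$tol_E && dD < config$tol_D) {
      converged <- TRUE
      D <- D_new
      break
    }
    D <- D_new; E_old <- E
  }
  if (!converged)
    stop("SCF failed to converge in ", config$max_iter,
         " iterations (last dE=", signif(log$dE[nrow(log)], 3),
         ", |dD|=", signif(log$dD[nrow(log)], 3), ")")
  structure(list(
    C = dg$C, eps = dg$eps, D = D, energy = E,
    E_nuc = Enuc, E_xc = fp$E_xc,
    n_occ = nocc, ao = ao, oe = oe, grid = grid, config = config,
    log = log, converged = converged,
    timing = timing_report(log, fock_builds, t_fock_total)),
    class = "scf_state")
}

#' @export
print.scf_state <- function(x, ...) {
  cat(sprintf("<scf_state: %s, E = %.10f Hartree, %d iterations, KPI %.1f Fock builds/h>\n",
              x$config$method, x$energy, nrow(x$log), x$timing$kpi))
  invisible(x)
}

#' Timing report with the Fock-builds-per-hour performance indicator
#'
#' @param log per-iteration data.frame with `t_eri, t_xc, t_diag`.
#' @param builds number of Fock matrices constructed.
#' @param t_fock total wall seconds spent in Fock construction.
#' @return list with stage totals and `kpi = 3600 * builds / t_fock`.
#' @export
timing_report <- function(log, builds, t_fock) {
  list(t_eri = sum(log$t_eri), t_xc = sum(log$t_xc),
       t_diag = sum(log$t_diag), fock_builds = builds,
       t_fock = t_fock,
       kpi = if (t_fock > 0) 3600 * builds / t_fock else Inf)
}
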