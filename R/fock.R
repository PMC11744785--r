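# Coulomb/exchange matrix formation from tagged densities with
# Schwarz + density-weighted presorting (J), preselective exchange
# screening (K), and assembly of the two-electron Fock contribution.

#' Tag a density matrix as symmetric or antisymmetric
#'
#' The symmetry tag is the central contract of the Fock builder: ground
#' state and symmetric trial densities need J and K (and XC); for
#' antisymmetric trial densities the Coulomb build is skipped entirely
#' (J is exactly zero by the `[mu nu|la si] = [mu nu|si la]` symmetry).
#'
#' @param D square numeric matrix (contracted basis).
#' @param symmetry `"symmetric"` or `"antisymmetric"`; checked against D.
#' @return matrix with a `symmetry` attribute.
#' @export
density_matrix <- function(D, symmetry = c("symmetric", "antisymmetric")) {
  symmetry <- match.arg(symmetry)
  dev <- if (symmetry == "symmetric") max(abs(D - t(D))) else max(abs(D + t(D)))
  if (dev > 1e-10 * max(1, max(abs(D))))
    stop("density does not match its symmetry tag (deviation ", dev, ")")
  attr(D, "symmetry") <- symmetry
  D
}

density_symmetry <- function(D) {
  s <- attr(D, "symmetry")
  if (is.null(s)) stop("density matrix must carry a symmetry tag; ",
                       "use density_matrix()")
  s
}

#' Screening configuration
#'
#' @param eri_threshold target accuracy of screened matrix elements: the
#'   internal quartet cutoff on the product bound
#'   `Q_munu * Q_lasi * |D_lasi|` is this value divided by the square
#'   root of the number of contributing pair blocks (random-sign error
#'   accumulation) and by a fixed safety factor of 8, so the element
#'   error stays below the threshold itself (0 disables screening:
#'   oracle mode).
#' @param prelink_threshold cutoff on the preselection bound below which
#'   exchange matrix elements are not computed.
#' @export
screening_config <- function(eri_threshold = 1e-12,
                             prelink_threshold = 1e-10) {
  stopifnot(eri_threshold >= 0, prelink_threshold >= 0)
  list(eri_threshold = eri_threshold, prelink_threshold = prelink_threshold)
}

# cache Schwarz tables on the basis object (environment-backed)
.screening_tables <- function(ao) {
  env <- attr(ao, "screen_env")
  if (is.null(env)) stop("use prepare_screening(ao) first")
  env
}

#' Precompute screening tables for a basis
#'
#' Computes Schwarz pair factors and the contracted Schwarz matrix once;
#' returns the basis with the tables attached.
#' @param ao an `ao_basis`.
#' @export
prepare_screening <- function(ao) {
  env <- attr(ao, "screen_env")
  if (!is.null(env)) return(ao)
  env <- new.env(parent = emptyenv())
  sf <- schwarz_factors(ao)
  env$pairs <- sf$pairs
  env$Qc <- sf$Qc
  # raw-scale Schwarz factors matching the unnormalized class tensors the
  # builders contract (Cauchy-Schwarz is exact in any fixed scaling)
  pr <- schwarz_pairs_cpp(ao$prim, rep(1, ao$n_pao), eri_plan_registry())
  env$pairs_raw <- data.frame(i = pr$i, j = pr$j, Q = pr$Q)
  attr(ao, "screen_env") <- env
  ao
}

# primitive density in the raw (unnormalized-primitive) scale; the
# expansion table carries all normalization, so raw class tensors
# contract against this directly
.raw_prim_density <- function(ao, D) expand_matrix(ao, unclass(D))

#' Coulomb matrix J from a tagged density
#'
#' For a symmetric density, contracts screened primitive ERIs with the
#' density using presorted `[mu nu|` and `|la si]` pair lists (sorted by
#' `Q_munu` and by `Q_lasi |D_lasi|`), computing only upper-triangular
#' bra pairs and mirroring. For an antisymmetric density the build is
#' skipped and a zero matrix is returned.
#'
#' @param D tagged density ([density_matrix()]), contracted basis.
#' @param ao an `ao_basis` from [prepare_screening()].
#' @param screening a [screening_config()].
#' @return J (contracted basis) with attributes `n_shell_quartets`,
#'   `n_component_quartets`.
#' @export
build_J <- function(D, ao, screening = screening_config()) {
  sym <- density_symmetry(D)
  if (sym == "antisymmetric") {
    J <- matrix(0, ao$n_ao, ao$n_ao)
    attr(J, "n_shell_quartets") <- 0
    attr(J, "n_component_quartets") <- 0
    return(J)
  }
  env <- .screening_tables(ao)
  Dw <- .raw_prim_density(ao, D)
  thr_eff <- screening$eri_threshold / (8 * sqrt(max(1, nrow(env$pairs_raw))))
  res <- build_J_cpp(ao$prim, Dw,
                     list(i = env$pairs_raw$i, j = env$pairs_raw$j,
                          Q = env$pairs_raw$Q),
                     thr_eff, eri_plan_registry())
  J <- contract_matrix(ao, res$J)
  J <- (J + t(J)) / 2
  attr(J, "n_shell_quartets") <- res$n_shell_quartets
  attr(J, "n_component_quartets") <- res$n_component_quartets
  J
}

#' Preselection (preLinK-style) bound on exchange matrix elements
#'
#' `bound = Qc |D| Qc`, a matrix product of the contracted Schwarz matrix
#' with the density magnitudes; elementwise it bounds `|K|` from above
#' (Cauchy-Schwarz applied to every contributing quartet).
#'
#' @param D density matrix (contracted basis).
#' @param ao an `ao_basis` from [prepare_screening()].
#' @return n_ao x n_ao bound matrix.
#' @export
prelink_bound <- function(D, ao) {
  env <- .screening_tables(ao)
  env$Qc %*% abs(unclass(D)) %*% env$Qc
}

#' Exchange matrix K from a tagged density
#'
#' Exchange elements whose preselection bound falls below the preLinK
#' threshold are skipped (left zero); surviving contributions are
#' screened by `Q_mula * Q_nusi * |D_lasi|`. K inherits the symmetry tag
#' of the density. `omega > 0` builds the erf-attenuated (long-range)
#' exchange used by range-separated hybrids.
#'
#' @inheritParams build_J
#' @param omega attenuation parameter in 1/Bohr, or `NULL` for the full
#'   kernel.
#' @export
build_K <- function(D, ao, screening = screening_config(), omega = NULL) {
  sym <- density_symmetry(D)
  env <- .screening_tables(ao)
  Dw <- .raw_prim_density(ao, D)
  ns <- nrow(ao$prim)
  # shell-level raw-scale Schwarz matrix from the pair list
  Qs <- matrix(0, ns, ns)
  Qs[cbind(env$pairs_raw$i, env$pairs_raw$j)] <- env$pairs_raw$Q
  Qs[cbind(env$pairs_raw$j, env$pairs_raw$i)] <- env$pairs_raw$Q
  # lift the contracted elementwise preselection mask to primitive shells
  bound <- prelink_bound(D, ao)
  st <- shell_table(ao)
  ncs <- nrow(st)
  cs_max <- matrix(0, ncs, ncs)
  for (I in seq_len(ncs)) for (J in seq_len(ncs)) {
    rI <- st$ao_offset[I] + seq_len(st$ncomp[I])
    rJ <- st$ao_offset[J] + seq_len(st$ncomp[J])
    cs_max[I, J] <- max(bound[rI, rJ])
  }
  keep_cs <- cs_max >= screening$prelink_threshold
  cshell <- ao$prim$cshell
  skip <- !keep_cs[cshell, cshell, drop = FALSE]
  thr_eff <- screening$eri_threshold / (8 * max(1, nrow(ao$prim)))
  res <- build_K_cpp(ao$prim, Dw, Qs, skip, thr_eff,
                     if (sym == "symmetric") 1L else -1L,
                     if (is.null(omega)) -1.0 else omega,
                     eri_plan_registry())
  K <- contract_matrix(ao, res$K)
  K <- if (sym == "symmetric") (K + t(K)) / 2 else (K - t(K)) / 2
  # elements masked by the preselection stay exactly zero
  K[bound < screening$prelink_threshold] <- 0
  K <- density_matrix(K, sym)
  attr(K, "n_shell_quartets") <- res$n_shell_quartets
  attr(K, "n_component_quartets") <- res$n_component_quartets
  K
}

#' Two-electron Fock contribution with hybrid/range-separated weights
#'
#' `F_2e = 2 J - c_x K - c_lr K_omega` for a symmetric density (the
#' closed-shell convention with D normalized to `tr(DS) = N_elec / 2`);
#' the J term is absent for antisymmetric densities. For CAM-type range
#' separation with parameters (alpha, beta, omega) the short-range
#' Hartree-Fock-type exchange fraction is alpha and the long-range limit
#' is alpha + beta.
#'
#' @inheritParams build_J
#' @param weights list with `cx` (global exchange weight), `clr`
#'   (long-range attenuated exchange weight) and `omega`; e.g.
#'   `list(cx = 1, clr = 0, omega = NULL)` for Hartree-Fock.
#' @return list `F2e`, `J`, `K`, `K_lr`.
#' @export
assemble_two_electron_fock <- function(D, ao,
                                       screening = screening_config(),
                                       weights = list(cx = 1, clr = 0,
                                                      omega = NULL)) {
  cx <- weights$cx %||% 1
  clr <- weights$clr %||% 0
  if (cx + clr < 0) stop("config error: negative total exchange weight")
  sym <- density_symmetry(D)
  J <- build_J(D, ao, screening)
  K <- if (cx != 0) build_K(D, ao, screening) else matrix(0, ao$n_ao, ao$n_ao)
  Klr <- if (clr != 0) build_K(D, ao, screening, omega = weights$omega)
         else matrix(0, ao$n_ao, ao$n_ao)
  F2e <- -cx * unclass(K) - clr * unclass(Klr)
  if (sym == "symmetric") F2e <- F2e + 2 * unclass(J)
  attributes(F2e) <- list(dim = dim(F2e))
  list(F2e = F2e, J = J, K = K, K_lr = Klr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Brute-force contracted ERI tensor (oracle, small systems only)
#'
#' Builds the full contracted-basis `(mu nu|la si)` tensor through the
#' reference McMurchie-Davidson evaluator with no screening. Intended for
#' oracle comparisons on systems with a few tens of AOs.
#'
#' @param ao an `ao_basis`.
#' @param omega optional erf attenuation.
#' @return 4-d array of dimension `n_ao^4`.
#' @export
contracted_eri_tensor <- function(ao, omega = -1) {
  n <- ao$n_ao
  if (n > 40) stop("oracle tensor limited to 40 AOs (", n, " requested)")
  pw <- prim_weight_vector(ao)
  st <- shell_table(ao)
  v <- contracted_eri_cpp(ao$prim$L, ao$prim$alpha,
                          as.matrix(ao$prim[, c("x", "y", "z")]),
                          ao$prim$pao_offset, pw,
                          st$ao_offset[ao$prim$cshell], n, omega)
  aperm(array(v, dim = rep(n, 4)), 4:1)
}

#' Unscreened J/K oracle from the brute-force tensor
#' @param D density (contracted basis).
#' @param eri tensor from [contracted_eri_tensor()].
#' @return list `J`, `K`.
#' @export
jk_bruteforce <- function(D, eri) {
  n <- dim(eri)[1]
  D <- unclass(D)
  J <- matrix(0, n, n); K <- matrix(0, n, n)
  for (mu in 1:n) for (nu in 1:n) {
    J[mu, nu] <- sum(eri[mu, nu, , ] * D)
    K[mu, nu] <- sum(eri[mu, , nu, ] * D)
  }
  list(J = J, K = K)
}
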