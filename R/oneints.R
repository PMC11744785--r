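# One-electron integrals over contracted Cartesian Gaussians: overlap,
# kinetic, nuclear(+MM) attraction, electric-dipole moment, linear
# momentum (gradient) and angular momentum about a configurable origin.
# Evaluated by Hermite-Gaussian recurrences per shell pair in the
# primitive basis, then contracted through the expansion table.

# 1D integral of (x-A)^la (x-B)^lb exp(-a(x-A)^2 - b(x-B)^2), by binomial
# expansion about the Gaussian product center (exponential factor included)
.s1d <- function(la, lb, a, b, A, B) {
  if (la < 0 || lb < 0) return(0)
  p <- a + b
  P <- (a * A + b * B) / p
  s <- 0
  for (i in 0:la) for (j in 0:lb) {
    k <- i + j
    if (k %% 2 == 1) next
    Mk <- odd_fact2(k / 2) / (2 * p)^(k / 2) * sqrt(pi / p)
    s <- s + choose(la, i) * choose(lb, j) *
      (P - A)^(la - i) * (P - B)^(lb - j) * Mk
  }
  s * exp(-a * b / p * (A - B)^2)
}

# Hermite expansion coefficients E_t^{ij} for one dimension (no K factor;
# the exponential is folded into t = 0 base)
.Etab <- function(imax, jmax, a, b, AB) {
  p <- a + b
  XPA <- -b / p * AB; XPB <- a / p * AB
  E <- array(0, dim = c(imax + 1, jmax + 1, imax + jmax + 1))
  E[1, 1, 1] <- exp(-a * b / p * AB^2)
  for (i in 0:imax) for (j in 0:jmax) {
    if (i == 0 && j == 0) next
    for (t in 0:(i + j)) {
      v <- 0
      if (i > 0) {
        if (t > 0) v <- v + E[i, j + 1, t] / (2 * p)
        if (t <= i - 1 + j) v <- v + XPA * E[i, j + 1, t + 1]
        if (t + 1 <= i - 1 + j) v <- v + (t + 1) * E[i, j + 1, t + 2]
      } else {
        if (t > 0) v <- v + E[i + 1, j, t] / (2 * p)
        if (t <= i + j - 1) v <- v + XPB * E[i + 1, j, t + 1]
        if (t + 1 <= i + j - 1) v <- v + (t + 1) * E[i + 1, j, t + 2]
      }
      E[i + 1, j + 1, t + 1] <- v
    }
  }
  E
}

# Hermite Coulomb integrals R_{tuv}(p, PC) for t+u+v <= M
.Rtab <- function(M, p, PC) {
  Fm <- boys_table_cpp(M, p * sum(PC^2))
  layers <- vector("list", M + 1)
  for (n in M:0) {
    R <- array(0, dim = c(M + 1, M + 1, M + 1))
    R[1, 1, 1] <- (-2 * p)^n * Fm[n + 1]
    rem <- M - n
    if (rem > 0) for (t in 0:rem) for (u in 0:(rem - t)) for (w in 0:(rem - t - u)) {
      if (t + u + w == 0) next
      up <- layers[[n + 2]]
      v <- 0
      if (t > 0) {
        if (t > 1) v <- v + (t - 1) * up[t - 1, u + 1, w + 1]
        v <- v + PC[1] * up[t, u + 1, w + 1]
      } else if (u > 0) {
        if (u > 1) v <- v + (u - 1) * up[t + 1, u - 1, w + 1]
        v <- v + PC[2] * up[t + 1, u, w + 1]
      } else {
        if (w > 1) v <- v + (w - 1) * up[t + 1, u + 1, w - 1]
        v <- v + PC[3] * up[t + 1, u + 1, w]
      }
      R[t + 1, u + 1, w + 1] <- v
    }
    layers[[n + 1]] <- R
  }
  layers[[1]]
}

#' Overlap and kinetic-energy matrices
#'
#' @param ao an `ao_basis`.
#' @return list `S`, `T` (contracted basis, symmetric).
#' @export
compute_overlap_kinetic <- function(ao) {
  np <- nrow(ao$prim)
  Sp <- matrix(0, ao$n_pao, ao$n_pao)
  Tp <- matrix(0, ao$n_pao, ao$n_pao)
  for (i in seq_len(np)) for (j in i:np) {
    ri <- ao$prim[i, ]; rj <- ao$prim[j, ]
    a <- ri$alpha; b <- rj$alpha
    A <- c(ri$x, ri$y, ri$z); B <- c(rj$x, rj$y, rj$z)
    s1 <- function(la, lb, d) .s1d(la, lb, a, b, A[d], B[d])
    ca <- cart_components(ri$L); cb <- cart_components(rj$L)
    oi <- ri$pao_offset; oj <- rj$pao_offset
    for (u in seq_len(nrow(ca))) for (v in seq_len(nrow(cb))) {
      la <- ca[u, ]; lb <- cb[v, ]
      sd <- vapply(1:3, function(d) s1(la[d], lb[d], d), numeric(1))
      sval <- prod(sd)
      # kinetic via second-derivative shifts of the ket
      tval <- 0
      for (d in 1:3) {
        dd <- 4 * b^2 * s1(la[d], lb[d] + 2, d) -
          2 * b * (2 * lb[d] + 1) * sd[d] +
          lb[d] * (lb[d] - 1) * s1(la[d], lb[d] - 2, d)
        tval <- tval + dd * prod(sd[-d])
      }
      tval <- -0.5 * tval
      Sp[oi + u, oj + v] <- sval
      Tp[oi + u, oj + v] <- tval
      if (j > i) {
        Sp[oj + v, oi + u] <- sval
        Tp[oj + v, oi + u] <- tval
      }
    }
  }
  list(S = contract_matrix(ao, Sp), T = contract_matrix(ao, Tp))
}

#' Nuclear-attraction matrix (nuclei plus MM point charges)
#'
#' `V = sum_c (-q_c) * (attraction integrals at center c)`: nuclei enter
#' with their full charge, MM embedding charges with their fractional
#' charges, through the identical integral route.
#'
#' @param ao an `ao_basis`.
#' @param nuclei data.frame with `Z` (or `q`) and `x, y, z` in Bohr;
#'   defaults to the molecule's atoms.
#' @param mm_charges data.frame `q, x, y, z` (Bohr); defaults to the
#'   molecule's MM charges.
#' @return contracted-basis matrix V.
#' @export
compute_nuclear_attraction <- function(ao, nuclei = NULL, mm_charges = NULL) {
  mol <- ao$molecule
  if (is.null(nuclei)) nuclei <- mol$atoms
  if (is.null(mm_charges)) mm_charges <- mol$mm
  centers <- rbind(
    if (nrow(nuclei)) cbind(q = if ("Z" %in% names(nuclei)) nuclei$Z else nuclei$q,
                            nuclei[, c("x", "y", "z")]),
    if (nrow(mm_charges)) cbind(q = mm_charges$q,
                                mm_charges[, c("x", "y", "z")]))
  Vp <- matrix(0, ao$n_pao, ao$n_pao)
  if (is.null(centers) || nrow(centers) == 0)
    return(contract_matrix(ao, Vp))
  np <- nrow(ao$prim)
  for (i in seq_len(np)) for (j in i:np) {
    ri <- ao$prim[i, ]; rj <- ao$prim[j, ]
    a <- ri$alpha; b <- rj$alpha; p <- a + b
    A <- c(ri$x, ri$y, ri$z); B <- c(rj$x, rj$y, rj$z)
    P <- (a * A + b * B) / p
    La <- ri$L; Lb <- rj$L
    E1 <- .Etab(La, Lb, a, b, A[1] - B[1])
    E2 <- .Etab(La, Lb, a, b, A[2] - B[2])
    E3 <- .Etab(La, Lb, a, b, A[3] - B[3])
    ca <- cart_components(La); cb <- cart_components(Lb)
    blk <- matrix(0, nrow(ca), nrow(cb))
    for (cc in seq_len(nrow(centers))) {
      Rt <- .Rtab(La + Lb, p, P - as.numeric(centers[cc, c("x", "y", "z")]))
      qc <- centers$q[cc]
      for (u in seq_len(nrow(ca))) for (v in seq_len(nrow(cb))) {
        la <- ca[u, ]; lb <- cb[v, ]
        acc <- 0
        for (t in 0:(la[1] + lb[1])) for (uu in 0:(la[2] + lb[2]))
          for (w in 0:(la[3] + lb[3])) {
            e <- E1[la[1] + 1, lb[1] + 1, t + 1] *
              E2[la[2] + 1, lb[2] + 1, uu + 1] *
              E3[la[3] + 1, lb[3] + 1, w + 1]
            if (e != 0) acc <- acc + e * Rt[t + 1, uu + 1, w + 1]
          }
        blk[u, v] <- blk[u, v] - qc * 2 * pi / p * acc
      }
    }
    oi <- ri$pao_offset; oj <- rj$pao_offset
    Vp[oi + seq_len(nrow(ca)), oj + seq_len(nrow(cb))] <- blk
    if (j > i) Vp[oj + seq_len(nrow(cb)), oi + seq_len(nrow(ca))] <- t(blk)
  }
  contract_matrix(ao, Vp)
}

#' Velocity-gauge operator matrices: gradient and angular momentum
#'
#' Returns the matrices of the gradient operator `<mu|d/dk|nu>` (the
#' linear momentum is `-i` times these; real antisymmetric in a real AO
#' basis) and of `<mu|((r-O) x grad)_k|nu>` about origin `O` (the
#' magnetic dipole is `i/2` times these). The gradient matrices are
#' origin-independent; the angular-momentum matrices shift as
#' `L' = L - d x P` under an origin displacement `d`.
#'
#' @param ao an `ao_basis`.
#' @param origin 3-vector (Bohr); default: center of nuclear charge.
#' @return list `P` (list of 3 matrices) and `L` (list of 3 matrices),
#'   plus `origin`.
#' @export
compute_velocity_gauge_operators <- function(ao, origin = NULL) {
  mol <- ao$molecule
  if (is.null(origin)) {
    w <- mol$atoms$Z
    origin <- colSums(mol_coords(mol) * w) / sum(w)
  }
  np <- nrow(ao$prim)
  Pp <- replicate(3, matrix(0, ao$n_pao, ao$n_pao), simplify = FALSE)
  Lp <- replicate(3, matrix(0, ao$n_pao, ao$n_pao), simplify = FALSE)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    ri <- ao$prim[i, ]; rj <- ao$prim[j, ]
    a <- ri$alpha; b <- rj$alpha
    A <- c(ri$x, ri$y, ri$z); B <- c(rj$x, rj$y, rj$z)
    s1 <- function(la, lb, d) .s1d(la, lb, a, b, A[d], B[d])
    ca <- cart_components(ri$L); cb <- cart_components(rj$L)
    oi <- ri$pao_offset; oj <- rj$pao_offset
    for (u in seq_len(nrow(ca))) for (v in seq_len(nrow(cb))) {
      la <- ca[u, ]; lb <- cb[v, ]
      S <- vapply(1:3, function(d) s1(la[d], lb[d], d), numeric(1))
      D <- vapply(1:3, function(d)
        lb[d] * s1(la[d], lb[d] - 1, d) - 2 * b * s1(la[d], lb[d] + 1, d),
        numeric(1))
      M <- vapply(1:3, function(d)
        s1(la[d], lb[d] + 1, d) + (B[d] - origin[d]) * s1(la[d], lb[d], d),
        numeric(1))
      for (d in 1:3)
        Pp[[d]][oi + u, oj + v] <- D[d] * prod(S[-d])
      # (r x grad)_x = y d/dz - z d/dy, cyclic
      cyc <- list(c(2, 3), c(3, 1), c(1, 2))
      for (d in 1:3) {
        e1 <- cyc[[d]][1]; e2 <- cyc[[d]][2]
        rest <- setdiff(1:3, c(e1, e2))
        Lp[[d]][oi + u, oj + v] <-
          (M[e1] * D[e2] - M[e2] * D[e1]) * prod(S[rest])
      }
    }
  }
  list(P = lapply(Pp, contract_matrix, ao = ao),
       L = lapply(Lp, contract_matrix, ao = ao),
       origin = origin)
}

#' All one-electron matrices needed by SCF and response
#'
#' @param ao an `ao_basis`.
#' @param origin origin for angular momentum (default: nuclear-charge
#'   center).
#' @return list `S, T, V, P, L, origin`.
#' @export
compute_one_electron <- function(ao, origin = NULL) {
  st <- compute_overlap_kinetic(ao)
  V <- compute_nuclear_attraction(ao)
  vg <- compute_velocity_gauge_operators(ao, origin)
  c(st, list(V = V), vg)
}
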