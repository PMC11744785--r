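# Shared fixtures and independent oracles for the test suite.  Expensive
# objects (SCF states, ERI tensors) are computed once per session.

.tcache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (is.null(.tcache[[name]])) .tcache[[name]] <- force(expr)
  .tcache[[name]]
}

fix_h2 <- function() molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)))
fix_he <- function() molecule("He", matrix(0, 1, 3))

fix_water <- function() generate_chiral_fixture("h2o_planar")

fix_waters <- function(n, seed = 11L) generate_water_droplet(n, seed = seed)

scf_h2 <- function() cached("scf_h2",
  run_scf(fix_h2(), method_config("hf", basis = "sto-3g")))
scf_water <- function() cached("scf_water",
  run_scf(fix_water(), method_config("hf", basis = "sto-3g")))
scf_h2o2 <- function(which = "P") cached(paste0("scf_h2o2_", which),
  run_scf(generate_chiral_fixture(paste0("h2o2_", which)),
          method_config("hf", basis = "sto-3g")))

grid_water <- function(level = "medium") cached(paste0("grid_water_", level),
  build_grid(fix_water(), level))

ao_2water <- function() cached("ao_2water",
  prepare_screening(build_ao_basis(fix_waters(2), "sto-3g")))
eri_2water <- function() cached("eri_2water",
  contracted_eri_tensor(ao_2water()))

random_shell_quartet <- function(lmax = 2, L = NULL) {
  if (is.null(L)) L <- sample(0:lmax, 4, replace = TRUE)
  ex <- runif(4, 0.15, 4)
  cen <- matrix(rnorm(12, sd = 1.2), 4, 3)
  list(bra = list(La = L[1], Lb = L[2], za = ex[1], zb = ex[2],
                  A = cen[1, ], B = cen[2, ]),
       ket = list(La = L[3], Lb = L[4], za = ex[3], zb = ex[4],
                  A = cen[3, ], B = cen[4, ]),
       L = L, ex = ex, cen = cen)
}

# ---- independent quadrature ERI oracle -----------------------------------
# 1/r12 (or erf(omega r12)/r12) via its Gaussian transform; for each
# transform variable the 6D integral factorizes per Cartesian dimension
# into a 2D Gaussian-polynomial integral evaluated exactly by
# Gauss-Hermite quadrature after diagonalizing the quadratic form.
# Completely independent of the Obara-Saika and McMurchie-Davidson paths.
.gh30 <- local({
  n <- 30
  i <- seq_len(n - 1)
  a <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- a; J[cbind(i + 1, i)] <- a
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = as.numeric(e$vectors[1, ])^2 * sqrt(pi))
})

eri_quadrature_component <- function(q, comp, omega = NULL) {
  # comp: list of four length-3 integer vectors (la, lb, lc, ld)
  ex <- q$ex; cen <- q$cen
  gh <- .gh30
  dimint <- function(t2, la, lb, lc, ld, A, B, C, D) {
    M <- matrix(c(ex[1] + ex[2] + t2, -t2, -t2, ex[3] + ex[4] + t2), 2, 2)
    b <- c(2 * (ex[1] * A + ex[2] * B), 2 * (ex[3] * C + ex[4] * D))
    cst <- -(ex[1] * A^2 + ex[2] * B^2 + ex[3] * C^2 + ex[4] * D^2)
    x0 <- solve(M, b / 2)
    E <- eigen(M, symmetric = TRUE)
    v0 <- -sum(x0 * (M %*% x0)) + sum(b * x0) + cst
    xy1 <- outer(gh$x / sqrt(E$values[1]) * E$vectors[1, 1],
                 gh$x / sqrt(E$values[2]) * E$vectors[1, 2], `+`) + x0[1]
    xy2 <- outer(gh$x / sqrt(E$values[1]) * E$vectors[2, 1],
                 gh$x / sqrt(E$values[2]) * E$vectors[2, 2], `+`) + x0[2]
    W <- outer(gh$w, gh$w)
    s <- sum(W * (xy1 - A)^la * (xy1 - B)^lb * (xy2 - C)^lc * (xy2 - D)^ld)
    s * exp(v0) / sqrt(prod(E$values))
  }
  f <- function(tv) vapply(tv, function(t) {
    t2 <- t * t
    prod(vapply(1:3, function(d)
      dimint(t2, comp[[1]][d], comp[[2]][d], comp[[3]][d], comp[[4]][d],
             cen[1, d], cen[2, d], cen[3, d], cen[4, d]), numeric(1)))
  }, numeric(1))
  upper <- if (is.null(omega)) 1 else NA
  if (is.null(omega)) {
    g <- function(u) f(u / (1 - u)) / (1 - u)^2
    val <- stats::integrate(g, 0, 1, rel.tol = 1e-10,
                            subdivisions = 400)$value
  } else {
    # erf kernel: transform variable restricted to t < omega
    val <- stats::integrate(f, 0, omega, rel.tol = 1e-10,
                            subdivisions = 400)$value
  }
  2 / sqrt(pi) * val
}

# dense 3D numerical quadrature oracle for one-electron matrices: AO
# values (and numerical finite-difference AO derivatives) summed over a
# fine atom-centered quadrature grid.  Independent of the Hermite
# recurrence route used by the implementation.
one_electron_quadrature <- function(ao, grid = NULL) {
  if (is.null(grid)) grid <- build_grid(ao$molecule, "fine")
  pts <- as.matrix(grid[, c("x", "y", "z")])
  w <- grid$w
  Phi <- ao_values(ao, pts)
  h <- 1e-4
  dPhi <- lapply(1:3, function(d) {
    pp <- pts; pp[, d] <- pp[, d] + h
    pm <- pts; pm[, d] <- pm[, d] - h
    (ao_values(ao, pp) - ao_values(ao, pm)) / (2 * h)
  })
  quad <- function(Fl, Fr, fac = 1)
    crossprod(Fl, Fr * (w * fac))
  list(
    S = quad(Phi, Phi),
    T = 0.5 * Reduce(`+`, lapply(dPhi, function(dP) quad(dP, dP))),
    P = lapply(dPhi, function(dP) quad(Phi, dP)),
    L = function(origin) {
      cyc <- list(c(2, 3), c(3, 1), c(1, 2))
      lapply(1:3, function(k) {
        e1 <- cyc[[k]][1]; e2 <- cyc[[k]][2]
        quad(Phi, dPhi[[e2]], fac = pts[, e1] - origin[e1]) -
          quad(Phi, dPhi[[e1]], fac = pts[, e2] - origin[e2])
      })
    },
    V_at = function(centers_q) {
      # centers_q: data.frame q, x, y, z
      acc <- 0
      for (k in seq_len(nrow(centers_q))) {
        r <- sqrt((pts[, 1] - centers_q$x[k])^2 +
                  (pts[, 2] - centers_q$y[k])^2 +
                  (pts[, 3] - centers_q$z[k])^2)
        acc <- acc + quad(Phi, Phi, fac = -centers_q$q[k] / pmax(r, 1e-12))
      }
      acc
    })
}
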