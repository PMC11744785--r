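test_that("density tagging enforces the declared symmetry", {
  M <- matrix(rnorm(16), 4, 4)
  expect_error(density_matrix(M, "symmetric"), "symmetry tag")
  Ds <- density_matrix((M + t(M)) / 2, "symmetric")
  expect_identical(attr(Ds, "symmetry"), "symmetric")
  ao <- ao_2water()
  expect_error(build_J(matrix(0, ao$n_ao, ao$n_ao), ao), "symmetry tag")
  expect_error(screening_config(-1), "eri_threshold")
})

test_that("screened J and K reproduce the brute-force oracle", {
  set.seed(42)
  ao <- ao_2water()
  eri <- eri_2water()
  n <- ao$n_ao
  M <- matrix(rnorm(n * n), n, n)
  Ds <- density_matrix((M + t(M)) / 2, "symmetric")
  bf <- jk_bruteforce(Ds, eri)
  J <- build_J(Ds, ao, screening_config(1e-12))
  expect_lt(max(abs(J - bf$J)), 1e-10)
  K <- build_K(Ds, ao, screening_config(1e-12, 0))
  expect_lt(max(abs(K - bf$K)), 1e-10)
  # zero density
  D0 <- density_matrix(matrix(0, n, n), "symmetric")
  expect_equal(max(abs(build_J(D0, ao))), 0)
  expect_equal(max(abs(build_K(D0, ao, screening_config(1e-12, 0)))), 0)
  expect_equal(max(abs(prelink_bound(D0, ao))), 0)
})

test_that("antisymmetric densities give J = 0 and antisymmetric K", {
  set.seed(43)
  ao <- ao_2water()
  eri <- eri_2water()
  n <- ao$n_ao
  M <- matrix(rnorm(n * n), n, n)
  Da <- density_matrix((M - t(M)) / 2, "antisymmetric")
  J <- build_J(Da, ao)
  expect_equal(max(abs(J)), 0)
  expect_equal(attr(J, "n_shell_quartets"), 0)
  # ... and the skip is consistent: brute force J of the same density is 0
  bf <- jk_bruteforce(Da, eri)
  expect_lt(max(abs(bf$J)), 1e-12)
  K <- build_K(Da, ao, screening_config(1e-12, 0))
  expect_lt(max(abs(unclass(K) + t(unclass(K)))), 1e-12)
  expect_lt(max(abs(K - bf$K)), 1e-10)
})

test_that("preLinK bound dominates |K| elementwise and is a matrix product", {
  set.seed(44)
  ao <- ao_2water()
  eri <- eri_2water()
  n <- ao$n_ao
  M <- matrix(rnorm(n * n), n, n)
  Ds <- density_matrix((M + t(M)) / 2, "symmetric")
  bound <- prelink_bound(Ds, ao)
  Kex <- jk_bruteforce(Ds, eri)$K
  expect_equal(sum(bound < abs(Kex) - 1e-12), 0)  # zero violations
  # far-separated fragments: inter-fragment bound is negligible
  b1 <- list(H = list(list(L = 0L, exponents = 0.9, coefficients = 1)))
  far <- prepare_screening(build_ao_basis(
    molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 60))), b1))
  Df <- density_matrix(diag(2), "symmetric")
  bf2 <- prelink_bound(Df, far)
  expect_lt(bf2[1, 2], 1e-20)
  # elements below the preselection threshold are left exactly zero
  Kmask <- build_K(Ds, ao, screening_config(1e-12, prelink_threshold = 1e-1))
  expect_true(all(Kmask[bound < 1e-1] == 0))
})

test_that("screening error decreases monotonically along the threshold ladder", {
  set.seed(45)
  ao <- ao_2water()
  eri <- eri_2water()
  n <- ao$n_ao
  M <- matrix(rnorm(n * n), n, n)
  Ds <- density_matrix((M + t(M)) / 2, "symmetric")
  bf <- jk_bruteforce(Ds, eri)
  errsJ <- errsK <- c()
  quartets <- c()
  for (thr in c(1e-6, 1e-8, 1e-10, 1e-12)) {
    J <- build_J(Ds, ao, screening_config(thr))
    K <- build_K(Ds, ao, screening_config(thr, 0))
    errsJ <- c(errsJ, max(abs(J - bf$J)))
    errsK <- c(errsK, max(abs(K - bf$K)))
    quartets <- c(quartets, attr(J, "n_shell_quartets"))
  }
  expect_true(all(diff(errsJ) <= 1e-12))
  expect_true(all(diff(errsK) <= 1e-12))
  expect_true(all(diff(quartets) >= 0))  # looser screening keeps fewer
  expect_lt(errsJ[1], 10 * 1e-6)
  expect_lt(errsK[1], 10 * 1e-6)
})

test_that("tr(D J(D')) is a symmetric bilinear form", {
  set.seed(46)
  ao <- ao_2water()
  n <- ao$n_ao
  A <- matrix(rnorm(n * n), n, n); B <- matrix(rnorm(n * n), n, n)
  D1 <- density_matrix((A + t(A)) / 2, "symmetric")
  D2 <- density_matrix((B + t(B)) / 2, "symmetric")
  J1 <- build_J(D1, ao); J2 <- build_J(D2, ao)
  expect_equal(sum(unclass(D2) * J1), sum(unclass(D1) * J2),
               tolerance = 1e-9)
})

test_that("two-electron Fock assembly honors hybrid and CAM weights", {
  set.seed(47)
  ao <- ao_2water()
  n <- ao$n_ao
  M <- matrix(rnorm(n * n), n, n)
  Ds <- density_matrix((M + t(M)) / 2, "symmetric")
  noex <- assemble_two_electron_fock(Ds, ao,
                                     weights = list(cx = 0, clr = 0))
  expect_lt(max(abs(noex$F2e - 2 * unclass(noex$J))), 1e-12)
  expect_error(assemble_two_electron_fock(Ds, ao,
                                          weights = list(cx = -2, clr = 1)),
               "config error")
  # CAM weight algebra: short-range HF fraction alpha, long-range
  # alpha + beta (the erf kernel interpolates between 0 and 1)
  alpha <- 0.19; beta <- 0.46
  erf_w <- function(r, omega) 2 * pnorm(r * omega * sqrt(2)) - 1
  frac <- function(r) alpha + beta * erf_w(r, 0.33)
  expect_equal(frac(0), alpha)
  expect_equal(frac(1e6), alpha + beta, tolerance = 1e-12)
  expect_equal(alpha + beta, 0.65)
  # assembled CAM Fock equals its parts
  cam <- assemble_two_electron_fock(Ds, ao, screening_config(1e-12, 0),
                                    weights = list(cx = alpha, clr = beta,
                                                   omega = 0.33))
  expect_lt(max(abs(cam$F2e -
                      (2 * unclass(cam$J) - alpha * unclass(cam$K) -
                         beta * unclass(cam$K_lr)))), 1e-12)
})

test_that("H2 two-electron Fock matches the hand-built two-AO expressions", {
  scf <- scf_h2()
  ao <- scf$ao
  eri <- contracted_eri_tensor(ao)
  D <- scf$D
  # closed-shell 2-AO algebra: F2e[m,n] = sum_ls D[l,s] (2 (mn|ls) - (ml|ns))
  F2e_hand <- matrix(0, 2, 2)
  for (m in 1:2) for (n in 1:2)
    F2e_hand[m, n] <- sum(unclass(D) * (2 * eri[m, n, , ] - eri[m, , n, ]))
  two <- assemble_two_electron_fock(D, ao, screening_config(1e-13, 0))
  expect_lt(max(abs(two$F2e - F2e_hand)), 1e-10)
})
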