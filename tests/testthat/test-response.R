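test_that("sigma vector is zero on zero trials and linear", {
  scf <- scf_water()
  sp <- chirospec:::.ov_space(scf)
  z <- rep(0, sp$nov)
  sv <- sigma_vector(scf, g = z, u = z)
  expect_equal(max(abs(sv$sg)), 0)
  expect_equal(max(abs(sv$su)), 0)
  set.seed(70)
  a <- rnorm(sp$nov); b <- rnorm(sp$nov)
  s1 <- sigma_vector(scf, g = a, u = a)
  s2 <- sigma_vector(scf, g = b, u = b)
  s12 <- sigma_vector(scf, g = 2 * a - 3 * b, u = 2 * a - 3 * b)
  expect_lt(max(abs(s12$sg - (2 * s1$sg - 3 * s2$sg))), 1e-10)
  expect_lt(max(abs(s12$su - (2 * s1$su - 3 * s2$su))), 1e-10)
})

test_that("sigma vector reproduces explicit E[2] columns and J-skip bookkeeping", {
  scf <- scf_h2()
  mats <- cached("mats_h2", explicit_response_matrices(scf))
  sv <- sigma_vector(scf, g = 1, u = 1)
  expect_equal(sv$sg, as.numeric(mats$ApB), tolerance = 1e-10)
  expect_equal(sv$su, as.numeric(mats$AmB), tolerance = 1e-10)
  # symmetric components trigger a J build; antisymmetric do not
  expect_equal(sv$n_J_builds, 1L)
  sv_u <- sigma_vector(scf, u = 1)
  expect_equal(sv_u$n_J_builds, 0L)
  expect_gt(sv_u$n_K_builds, 0L)
  # unconverged/untagged input refused
  expect_error(sigma_vector(scf, g = "x"), "")
  # columns of the water matrices, spot-checked
  scfw <- scf_water()
  matw <- cached("mats_water", explicit_response_matrices(scfw))
  spw <- chirospec:::.ov_space(scfw)
  set.seed(71)
  for (k in sample(spw$nov, 3)) {
    e_k <- replace(rep(0, spw$nov), k, 1)
    sv <- sigma_vector(scfw, g = e_k, u = e_k)
    expect_lt(max(abs(sv$sg - matw$ApB[, k])), 1e-10)
    expect_lt(max(abs(sv$su - matw$AmB[, k])), 1e-10)
  }
})

test_that("eigensolver matches the closed-form two-level and dense oracles", {
  scf <- scf_h2()
  mats <- cached("mats_h2", explicit_response_matrices(scf))
  st <- solve_eigenstates(scf, 1)
  expect_equal(st$energy_hartree,
               sqrt(as.numeric(mats$ApB) * as.numeric(mats$AmB)),
               tolerance = 1e-10)
  scfw <- scf_water()
  matw <- cached("mats_water", explicit_response_matrices(scfw))
  dense <- sort(sqrt(Re(eigen(matw$AmB %*% matw$ApB)$values)))
  stw <- solve_eigenstates(scfw, 5)
  expect_equal(stw$energy_hartree, dense[1:5], tolerance = 1e-8)
  expect_true(all(stw$energy_hartree > 0))
  expect_false(is.unsorted(stw$energy_hartree))
  expect_error(solve_eigenstates(scfw, 1000), "exceeds")
})

test_that("XC response kernel: iterative solver matches dense oracle at LDA", {
  h2 <- fix_h2()
  scf <- cached("scf_h2_lda",
    run_scf(h2, method_config("lda-demo", basis = "sto-3g",
                              grid_level = "coarse")))
  mats <- explicit_response_matrices(scf)
  sv <- sigma_vector(scf, g = 1, u = 1)
  # finite-field matrix route vs grid-quadrature kernel route
  expect_equal(sv$sg, as.numeric(mats$ApB), tolerance = 1e-4)
  expect_equal(sv$su, as.numeric(mats$AmB), tolerance = 1e-8)
  st <- solve_eigenstates(scf, 1)
  expect_equal(st$energy_hartree,
               sqrt(as.numeric(mats$ApB) * as.numeric(mats$AmB)),
               tolerance = 1e-4)
})

test_that("CPP solver: damping-dominated limit and far-from-resonance behavior", {
  scf <- scf_h2()
  mats <- cached("mats_h2", explicit_response_matrices(scf))
  sp <- chirospec:::.ov_space(scf)
  # (H2 has no magnetic response, so these limits are checked on the
  # electric velocity-gauge response, which is nonzero)
  tr_a <- function(res) sum(diag(res$solutions[[1]]$alpha_tensor))
  # damping-dominated regime (gamma = 10 Hartree): iterative and
  # explicit solutions coincide and the response is strongly suppressed
  # relative to resonance
  big_ex <- solve_cpp_explicit(scf, 0.93, gamma = 10, mats = mats)
  big_it <- solve_cpp(scf, 0.93, gamma = 10, tol = 1e-8)
  expect_lt(Mod(tr_a(big_it) - tr_a(big_ex)), 0.01 * Mod(tr_a(big_ex)))
  res_ex <- solve_cpp_explicit(scf, 0.93, gamma = 0.005, mats = mats)
  expect_lt(Mod(Im(tr_a(big_ex))), 0.05 * Mod(Im(tr_a(res_ex))))
  # far below resonance with small gamma: real part matches the undamped
  # response, imaginary part is proportional to gamma
  w0 <- 0.2  # first excitation is ~0.93 Hartree
  und <- solve_cpp_explicit(scf, w0, gamma = 1e-6, mats = mats)
  g1 <- solve_cpp_explicit(scf, w0, gamma = 1e-4, mats = mats)
  g2 <- solve_cpp_explicit(scf, w0, gamma = 2e-4, mats = mats)
  expect_equal(Re(tr_a(g1)), Re(tr_a(und)), tolerance = 1e-6)
  expect_equal(Im(tr_a(g2)) / Im(tr_a(g1)), 2, tolerance = 1e-3)
  expect_error(solve_cpp(scf, 0.2, gamma = -1), "gamma")
})

test_that("iterative CPP equals explicit solve and the sum-over-states identity", {
  # the achiral-water trace vanishes identically, so the comparison is on
  # the full mixed electric-magnetic tensor componentwise
  scfw <- scf_water()
  matw <- cached("mats_water", explicit_response_matrices(scfw))
  gam <- convert_energy(0.1240, "eV", "hartree")
  freqs <- seq(0.3, 0.8, length.out = 7)
  ex <- solve_cpp_explicit(scfw, freqs, gam, mats = matw)
  it <- solve_cpp(scfw, freqs, gam, tol = 1e-7)
  gx <- lapply(ex$solutions, `[[`, "G_tensor")
  gi <- lapply(it$solutions, `[[`, "G_tensor")
  scale <- max(vapply(gx, function(m) max(Mod(m)), numeric(1)))
  dev <- max(mapply(function(a, b) max(Mod(a - b)), gi, gx))
  expect_lt(dev / scale, 1e-5)
  # sum-over-states: G[b, a](z) = sum_n 2 M_nb P_na w_n / (w_n^2 - z^2)
  sp <- chirospec:::.ov_space(scfw)
  states <- cached("states_water_all", solve_eigenstates(scfw, sp$nov))
  for (fi in seq_along(freqs)) {
    z <- freqs[fi] + 1i * gam
    gsos <- matrix(0i, 3, 3)
    for (a in 1:3) for (b in 1:3)
      gsos[b, a] <- sum(2 * states$M[, b] * states$P[, a] *
                          states$energy_hartree /
                          (states$energy_hartree^2 - z^2))
    expect_lt(max(Mod(gsos - gx[[fi]])) / scale, 1e-6)
  }
})

test_that("real and imaginary CPP parts obey Kramers-Kronig consistency", {
  # applied to the largest component of the damped mixed tensor (the
  # trace is identically zero for the achiral control)
  scfw <- scf_water()
  matw <- cached("mats_water", explicit_response_matrices(scfw))
  gam <- 0.02
  grid <- seq(1e-3, 6, by = 0.004)
  ex <- solve_cpp_explicit(scfw, grid, gam, mats = matw)
  Gs <- lapply(ex$solutions, `[[`, "G_tensor")
  pick <- which.max(Mod(Gs[[150]]))
  Tv <- vapply(Gs, function(m) m[[pick]], complex(1))
  # Re T(w) = (2/pi) P.V. int w' Im T(w') / (w'^2 - w^2) dw'
  kk_re <- function(w) {
    integrand <- grid * Im(Tv) / (grid^2 - w^2)
    integrand[abs(grid - w) < 2e-3] <- 0  # principal-value exclusion
    2 / pi * sum(integrand) * 0.004
  }
  for (w in c(0.35, 0.6, 1.1)) {
    expect_equal(kk_re(w), Re(Tv[which.min(abs(grid - w))]),
                 tolerance = 0.05 * max(abs(Re(Tv))))
  }
})
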