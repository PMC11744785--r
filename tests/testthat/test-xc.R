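test_that("the molecular grid integrates Gaussian test densities", {
  h1 <- molecule("H", matrix(0, 1, 3))
  g <- build_grid(h1, "medium")
  expect_true(all(g$w > 0))
  val <- sum(g$w * exp(-(g$x^2 + g$y^2 + g$z^2)))
  expect_equal(val, pi^1.5, tolerance = 1e-6 * pi^1.5)
  # off-center, anisotropic-exponent Gaussian on a molecular (2-atom) grid
  m2 <- molecule(c("O", "H"), rbind(c(0, 0, 0), c(0, 0, 1.8)))
  g2 <- build_grid(m2, "medium")
  r2 <- (g2$x - 0.3)^2 + (g2$y + 0.2)^2 + (g2$z - 1)^2
  expect_equal(sum(g2$w * 1.7^1.5 * exp(-1.7 * r2)) / pi^1.5, 1,
               tolerance = 1e-6)
  # far-separated atoms: partition weight near each nucleus ~ 1
  mfar <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 30)))
  gfar <- build_grid(mfar, "coarse")
  near1 <- gfar$x^2 + gfar$y^2 + gfar$z^2 < 1
  # a tight Gaussian on atom 1 integrates fully from atom-1 points alone
  vfar <- sum(gfar$w * 8^1.5 / pi^1.5 *
                exp(-8 * (gfar$x^2 + gfar$y^2 + gfar$z^2)))
  expect_equal(vfar, 1, tolerance = 1e-6)
})

test_that("box bisection partitions the grid into bounded, even batches", {
  set.seed(50)
  fake <- data.frame(x = runif(100), y = runif(100), z = runif(100),
                     w = runif(100))
  expect_length(partition_boxes(fake, 200), 1)
  big <- data.frame(x = runif(1000), y = runif(1000), z = runif(1000),
                    w = runif(1000))
  b <- partition_boxes(big, 100)
  expect_true(length(b) >= 8 && length(b) <= 16)
  expect_true(max(lengths(b)) <= 100)
  expect_true(max(lengths(b)) / min(lengths(b)) <= 2)
  # exact partition: no loss, no duplication, weights conserved
  idx <- sort(unlist(b))
  expect_identical(idx, seq_len(1000))
  expect_equal(sum(vapply(b, function(i) sum(big$w[i]), numeric(1))),
               sum(big$w), tolerance = 1e-14)
})

test_that("density on batches reproduces orbital densities and electron counts", {
  # hydrogenic 1s-like single-Gaussian orbital: rho = 2 |phi|^2 (two
  # electrons in the closed-shell convention)
  b1 <- list(H = list(list(L = 0L, exponents = 1.0, coefficients = 1)))
  ao1 <- build_ao_basis(molecule("H", matrix(0, 1, 3)), b1)
  D1 <- density_matrix(matrix(1, 1, 1), "symmetric")
  pts <- cbind(x = c(0, 0.3, 1), y = c(0, -0.2, 0.5), z = c(0.1, 0, 2))
  db <- density_on_batch(D1, ao1, pts)
  phi <- chirospec:::prim_norm(1, c(0, 0, 0)) *
    exp(-rowSums((pts - 0)^2))
  expect_equal(db$rho, 2 * phi^2, tolerance = 1e-10)
  # converged water density integrates to 10 electrons
  scf <- scf_water()
  xc <- xc_fock_and_energy(scf$D, scf$ao, grid_water())
  expect_equal(xc$n_elec, 10, tolerance = 1e-4)
  # screening on vs off changes the density by at most ~cutoff
  g <- grid_water("coarse")
  pts2 <- as.matrix(g[1:500, c("x", "y", "z")])
  r_off <- density_on_batch(scf$D, scf$ao, pts2, ao_cutoff = 0)$rho
  r_on <- density_on_batch(scf$D, scf$ao, pts2, ao_cutoff = 1e-8)$rho
  expect_lt(max(abs(r_on - r_off)), 1e-6)
})

test_that("XC energy and potential are mutually consistent", {
  scf <- scf_water()
  grid <- grid_water()
  fun <- xc_functional("slater_vwn")
  xc0 <- xc_fock_and_energy(scf$D, scf$ao, grid, fun)
  # zero density
  n <- scf$ao$n_ao
  z <- xc_fock_and_energy(matrix(0, n, n), scf$ao, grid, fun)
  expect_equal(z$E_xc, 0)
  expect_equal(max(abs(z$V_xc)), 0)
  expect_lt(max(abs(xc0$V_xc - t(xc0$V_xc))), 1e-12)
  # directional derivative: E(D + t Delta) - E(D - t Delta) ~ 2t * 2 tr(V Delta)
  set.seed(51)
  M <- matrix(rnorm(n * n, sd = 0.05), n, n)
  Delta <- (M + t(M)) / 2
  t_ <- 1e-5
  Ep <- xc_fock_and_energy(unclass(scf$D) + t_ * Delta, scf$ao, grid, fun)$E_xc
  Em <- xc_fock_and_energy(unclass(scf$D) - t_ * Delta, scf$ao, grid, fun)$E_xc
  fd <- (Ep - Em) / (2 * t_)
  analytic <- 2 * sum(xc0$V_xc * Delta)
  expect_equal(fd, analytic, tolerance = 1e-3 * abs(analytic))
})

test_that("Slater exchange matches direct quadrature of -Cx rho^(4/3)", {
  scf <- scf_water()
  grid <- grid_water()
  xc <- xc_fock_and_energy(scf$D, scf$ao, grid, xc_functional("slater_x"))
  Phi <- chirospec:::ao_values(scf$ao, as.matrix(grid[, c("x", "y", "z")]))
  rho <- 2 * rowSums((Phi %*% unclass(scf$D)) * Phi)
  cx <- 0.75 * (3 / pi)^(1 / 3)
  expect_equal(xc$E_xc, -cx * sum(grid$w * pmax(rho, 0)^(4 / 3)),
               tolerance = 1e-10)
})

test_that("results are invariant to the batching threshold", {
  scf <- scf_water()
  grid <- grid_water("coarse")
  fun <- xc_functional("slater_vwn")
  res <- lapply(c(64, 256, 1024), function(mp)
    xc_fock_and_energy(scf$D, scf$ao, grid, fun, max_points = mp))
  for (k in 2:3) {
    expect_equal(res[[k]]$E_xc, res[[1]]$E_xc, tolerance = 1e-10)
    expect_lt(max(abs(res[[k]]$V_xc - res[[1]]$V_xc)), 1e-10)
  }
  # work measure exists and grows with batch count
  expect_gt(res[[1]]$n_products, 0)
})
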