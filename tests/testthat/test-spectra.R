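test_that("rotatory strengths vanish for achiral molecules", {
  scf <- scf_water()
  st <- cached("states_water_5", solve_eigenstates(scf, 5))
  R <- rotatory_strengths(st)
  expect_lt(max(abs(R$R_au)), 1e-10)
})

test_that("enantiomers give exactly negated rotatory strengths", {
  sp_ <- scf_h2o2("P"); sm_ <- scf_h2o2("M")
  np <- 8
  stp <- cached("states_p8", solve_eigenstates(sp_, np))
  stm <- cached("states_m8", solve_eigenstates(sm_, np))
  expect_equal(stp$energy_hartree, stm$energy_hartree, tolerance = 1e-8)
  rp <- rotatory_strengths(stp); rm_ <- rotatory_strengths(stm)
  expect_gt(max(abs(rp$R_au)), 1e-3)  # genuinely chiral signal
  expect_lt(max(abs(rp$R_au + rm_$R_au)), 1e-7)
})

test_that("rotatory strengths are invariant under gauge-origin shifts", {
  sp_ <- scf_h2o2("P")
  np <- 8
  rp <- rotatory_strengths(cached("states_p8", solve_eigenstates(sp_, np)))
  shifted <- sp_
  shifted$oe <- compute_one_electron(sp_$ao,
                                     origin = sp_$oe$origin + c(5, -3, 2))
  rp2 <- rotatory_strengths(solve_eigenstates(shifted, np))
  expect_lt(max(abs(rp$R_au - rp2$R_au)), 1e-10)
})

test_that("Cauchy broadening honors HWHM, scaling and linearity contracts", {
  par <- spectrum_params(gamma = 0.1240, gamma_unit = "eV",
                         lambda_min = 80, lambda_max = 400,
                         lambda_step = 0.1)
  # zero sticks -> identically zero curve
  empty <- structure(data.frame(n = integer(0), energy_hartree = numeric(0),
                                energy_ev = numeric(0), R_au = numeric(0)),
                     class = c("rotatory_spectrum", "data.frame"))
  expect_true(all(delta_epsilon_sticks(empty, par)$delta_epsilon == 0))
  # one stick at 8 eV: peak at w0, half-maximum at w0 +- gamma
  one <- empty[0, ]
  one[1, ] <- list(1L, convert_energy(8, "eV", "hartree"), 8, 0.5)
  cur <- delta_epsilon_sticks(one, par)
  wmax <- cur$energy_ev[which.max(cur$delta_epsilon)]
  expect_equal(wmax, 8, tolerance = 0.02)
  peak <- max(cur$delta_epsilon)
  at <- function(ev) cur$delta_epsilon[which.min(abs(cur$energy_ev - ev))]
  expect_equal(at(8 + par$gamma_ev) / peak, 0.5, tolerance = 0.02)
  expect_equal(at(8 - par$gamma_ev) / peak, 0.5, tolerance = 0.02)
  # doubling gamma halves the isolated peak height
  par2 <- spectrum_params(gamma = 2 * 0.1240, gamma_unit = "eV",
                          lambda_min = 80, lambda_max = 400,
                          lambda_step = 0.1)
  expect_equal(max(delta_epsilon_sticks(one, par2)$delta_epsilon) / peak,
               0.5, tolerance = 0.02)
  # linearity in R
  one2 <- one; one2$R_au <- -3 * one2$R_au
  expect_equal(delta_epsilon_sticks(one2, par)$delta_epsilon,
               -3 * cur$delta_epsilon, tolerance = 1e-12)
})

test_that("CPP and broadened-stick spectra agree with all states resolved", {
  sp_ <- scf_h2o2("P")
  spc <- chirospec:::.ov_space(sp_)
  states <- cached("states_p_all", solve_eigenstates(sp_, spc$nov))
  sticks <- rotatory_strengths(states)
  gam <- convert_energy(0.1240, "eV", "hartree")
  wgrid <- seq(min(states$energy_hartree) - 0.05,
               states$energy_hartree[10], length.out = 35)
  cpp <- solve_cpp(sp_, wgrid, gam, tol = 1e-6)
  de_cpp <- delta_epsilon_cpp(cpp)
  de_sticks <- vapply(wgrid, function(w)
    sum(sticks$R_au * w *
          chirospec:::cauchy_profile(w, sticks$energy_hartree, gam)),
    numeric(1)) * chirospec:::delta_eps_conversion()
  peak <- max(abs(de_sticks))
  expect_lt(max(abs(de_cpp$delta_epsilon - de_sticks)), 0.02 * peak)
  # achiral control: CPP Delta-epsilon is numerical noise
  scfw <- scf_water()
  cppw <- solve_cpp(scfw, seq(0.35, 0.6, length.out = 5), gam, tol = 1e-7)
  expect_lt(max(abs(delta_epsilon_cpp(cppw)$delta_epsilon)), 1e-6 * peak)
  # increasing the damping lowers every resolved on-resonance peak
  cpp2 <- solve_cpp(sp_, states$energy_hartree[1:3], 2 * gam, tol = 1e-6)
  cpp1 <- solve_cpp(sp_, states$energy_hartree[1:3], gam, tol = 1e-6)
  expect_true(all(abs(delta_epsilon_cpp(cpp2)$delta_epsilon) <
                    abs(delta_epsilon_cpp(cpp1)$delta_epsilon)))
})

test_that("enantiomer CPP spectra are negated end-to-end", {
  gam <- convert_energy(0.1240, "eV", "hartree")
  wgrid <- seq(0.3, 0.45, length.out = 4)
  cp <- solve_cpp(scf_h2o2("P"), wgrid, gam, tol = 1e-7)
  cm <- solve_cpp(scf_h2o2("M"), wgrid, gam, tol = 1e-7)
  dp <- delta_epsilon_cpp(cp)$delta_epsilon
  dm <- delta_epsilon_cpp(cm)$delta_epsilon
  expect_gt(max(abs(dp)), 0)
  expect_lt(max(abs(dp + dm)), 1e-6 * max(abs(dp)))
})

test_that("spectrum files round-trip and keep unit identities", {
  par <- spectrum_params(lambda_min = 150, lambda_max = 250, lambda_step = 5)
  sticks <- data.frame(n = 1L,
                       energy_hartree = convert_energy(7, "eV", "hartree"),
                       energy_ev = 7, R_au = 0.2)
  curve <- delta_epsilon_sticks(sticks, par)
  expect_equal(curve$wavelength_nm * curve$energy_ev,
               rep(NM_EV, nrow(curve)), tolerance = 1e-10)
  pre <- file.path(withr::local_tempdir(), "spec")
  write_spectrum(curve, sticks, pre, metadata = list(gamma_ev = 0.124))
  back <- read_spectrum(paste0(pre, "_spectrum.tsv"))
  expect_equal(back$delta_epsilon, curve$delta_epsilon, tolerance = 1e-8)
  meta <- jsonlite::read_json(paste0(pre, "_meta.json"))
  expect_equal(meta$gamma_ev, 0.124)
  # empty sticks: header-only sticks file
  write_spectrum(curve, sticks[0, ], pre)
  sk <- readLines(paste0(pre, "_sticks.tsv"))
  expect_equal(length(sk), 1L)
})

test_that("zero excitation energy is rejected in the velocity gauge", {
  fake <- list(energy_hartree = c(0, 0.5), energy_ev = c(0, 13.6),
               P = matrix(1, 2, 3), M = matrix(1, 2, 3), n = 1:2)
  expect_error(rotatory_strengths(fake), "singular")
})
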