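test_that("kernel class enumeration reproduces the published counts", {
  expect_equal(nrow(enumerate_kernel_classes(1, "coulomb")), 9)
  expect_equal(nrow(enumerate_kernel_classes(2, "coulomb")), 36)
  expect_equal(nrow(enumerate_kernel_classes(1, "exchange")), 12)
  expect_equal(nrow(enumerate_kernel_classes(2, "exchange")), 54)
  cls0 <- enumerate_kernel_classes(0, "coulomb")
  expect_equal(nrow(cls0), 1)
  expect_equal(unlist(cls0[1, ]), c(La = 0, Lb = 0, Lc = 0, Ld = 0))
  # unordered bra/ket for Coulomb; ordered summed pair for exchange
  cc <- enumerate_kernel_classes(2, "coulomb")
  expect_true(all(cc$La <= cc$Lb & cc$Lc <= cc$Ld))
  ce <- enumerate_kernel_classes(2, "exchange")
  expect_true(all(ce$La <= ce$Lb))
  expect_error(enumerate_kernel_classes(3, "coulomb"), "unsupported")
})

test_that("unrolled plans have one output slot per component quadruple", {
  p_spsp <- eri_plan(0, 1, 0, 1)
  expect_equal(length(p_spsp$out_slots), 9)     # [sp|sp] -> nine ERIs
  p_ssss <- eri_plan(0, 0, 0, 0)
  expect_equal(length(p_ssss$out_slots), 1)
  expect_equal(nrow(p_ssss$ops), 0)             # reduces to pref * F0
  p_dddd <- eri_plan(2, 2, 2, 2)
  expect_equal(length(p_dddd$out_slots), 6^4)
  # plan is self-contained: ops only reference earlier slots
  for (p in list(p_spsp, p_dddd)) {
    if (nrow(p$ops) == 0) next
    first_def <- tapply(seq_len(nrow(p$ops)), p$ops[, 1], min)
    for (r in seq_len(nrow(p$ops))) {
      src <- p$ops[r, 5]
      if (src > 31 + p$mmax)  # an intermediate, not geometry/Boys input
        expect_lt(first_def[as.character(src)], r + 1)
    }
  }
})

test_that("plan evaluation equals the recursive reference on random quartets", {
  set.seed(101)
  for (trial in 1:60) {
    q <- random_shell_quartet()
    v1 <- primitive_eri(q$bra, q$ket)
    v2 <- reference_eri(q$bra, q$ket)
    expect_lt(max(abs(v1 - v2)) / max(abs(v2), 1e-300), 1e-11)
  }
})

test_that("plan and reference agree with the independent quadrature oracle", {
  set.seed(7)
  # same-center unit-exponent (ss|ss) closed form 2 pi^(5/2) / (p q sqrt(p+q))
  bra <- list(La = 0L, Lb = 0L, za = 1, zb = 1, A = c(0, 0, 0), B = c(0, 0, 0))
  expect_equal(as.numeric(primitive_eri(bra, bra)),
               2 * pi^2.5 / (2 * 2 * sqrt(4)), tolerance = 1e-12)
  for (trial in 1:6) {
    q <- random_shell_quartet()
    v <- primitive_eri(q$bra, q$ket)
    comps <- lapply(q$L, chirospec:::cart_components)
    pick <- vapply(comps, function(m) sample(nrow(m), 1), integer(1))
    comp <- Map(function(m, k) as.integer(m[k, ]), comps, pick)
    qd <- eri_quadrature_component(q, comp)
    expect_equal(v[pick[4], pick[3], pick[2], pick[1]], qd,
                 tolerance = 1e-7)
  }
})

test_that("class tensors vanish when a pair's centers are far apart", {
  set.seed(9)
  q <- random_shell_quartet(L = c(1, 2, 0, 1))
  q$ket$B <- q$ket$A + c(100, 0, 0)   # 100 Bohr within the ket pair
  expect_lt(max(abs(primitive_eri(q$bra, q$ket))), 1e-30)
})

test_that("attenuated ERIs hit both limits and match erf-kernel quadrature", {
  q <- random_shell_quartet(L = c(0, 0, 0, 0))
  full <- as.numeric(primitive_eri(q$bra, q$ket))
  expect_equal(as.numeric(attenuated_primitive_eri(q$bra, q$ket, 1e6)),
               full, tolerance = 1e-6)
  # vanishes linearly in omega as omega -> 0+
  a6 <- abs(as.numeric(attenuated_primitive_eri(q$bra, q$ket, 1e-6)))
  a7 <- abs(as.numeric(attenuated_primitive_eri(q$bra, q$ket, 1e-7)))
  expect_lt(a6, 1e-5 * abs(full))
  expect_equal(a6 / a7, 10, tolerance = 1e-4)
  # omega = 0.33, same-center unit exponents vs quadrature with erf kernel
  q0 <- list(bra = list(La = 0L, Lb = 0L, za = 1, zb = 1,
                        A = c(0, 0, 0), B = c(0, 0, 0)),
             ket = list(La = 0L, Lb = 0L, za = 1, zb = 1,
                        A = c(0, 0, 0), B = c(0, 0, 0)),
             ex = c(1, 1, 1, 1), cen = matrix(0, 4, 3))
  vatt <- as.numeric(attenuated_primitive_eri(q0$bra, q0$ket, 0.33))
  comp <- replicate(4, c(0L, 0L, 0L), simplify = FALSE)
  expect_equal(vatt, eri_quadrature_component(q0, comp, omega = 0.33),
               tolerance = 1e-8)
  # attenuated path agrees with the attenuated recursive reference on
  # higher angular momenta too
  set.seed(12)
  for (t in 1:10) {
    q <- random_shell_quartet()
    v1 <- attenuated_primitive_eri(q$bra, q$ket, 0.33)
    v2 <- reference_eri(q$bra, q$ket, omega = 0.33)
    expect_lt(max(abs(v1 - v2)) / max(abs(v2), 1e-300), 1e-11)
  }
})

test_that("eight-fold permutational symmetry holds on sampled quartets", {
  set.seed(21)
  for (t in 1:10) {
    q <- random_shell_quartet()
    v <- primitive_eri(q$bra, q$ket)
    # bra <-> ket swap (storage is component-d fastest, so the stored
    # arrays relate by swapping the two index pairs)
    vs <- primitive_eri(q$ket, q$bra)
    expect_lt(max(abs(aperm(v, c(3, 4, 1, 2)) - vs)),
              1e-12 * max(abs(v)))
    # within-pair swaps
    bra2 <- list(La = q$bra$Lb, Lb = q$bra$La, za = q$bra$zb, zb = q$bra$za,
                 A = q$bra$B, B = q$bra$A)
    vb <- primitive_eri(bra2, q$ket)
    expect_lt(max(abs(aperm(v, c(1, 2, 4, 3)) - vb)),
              1e-12 * max(abs(v)))
  }
})

test_that("Schwarz factors define an exact upper bound", {
  set.seed(31)
  ao <- ao_2water()
  sf <- schwarz_factors(ao)
  expect_true(all(sf$pairs$Q >= 0))
  expect_false(is.unsorted(rev(sf$pairs$Q)))    # sorted descending
  # Q of a normalized same-center ss pair equals sqrt((ss|ss))
  b1 <- list(H = list(list(L = 0L, exponents = 0.8, coefficients = 1)))
  ao1 <- build_ao_basis(molecule(c("H", "H"),
                                 rbind(c(0, 0, 0), c(0, 0, 40))), b1)
  sf1 <- schwarz_factors(ao1)
  eri1 <- contracted_eri_tensor(ao1)
  expect_equal(max(sf1$Qc), sqrt(eri1[1, 1, 1, 1]), tolerance = 1e-12)
  # distant pair: tiny Schwarz factor
  expect_lt(min(sf1$Qc[1, 2]), 1e-20)
  # the bound |(mu nu|la si)| <= Q_munu Q_lasi over all contracted quartets
  eri <- eri_2water()
  n <- dim(eri)[1]
  bound <- array(outer(as.vector(sf$Qc), as.vector(sf$Qc)), dim = rep(n, 4))
  expect_true(all(abs(eri) <= bound + 1e-12))
})
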