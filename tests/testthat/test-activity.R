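test_that("combinatorial term matches hand values and its dilution limit", {
  expect_equal(combinatorial_lngamma(0.3, 2, 2), 0)
  expect_equal(combinatorial_lngamma(0.5, 2, 1), log(4 / 3) - 1 / 3)
  rho <- 2.7
  expect_equal(combinatorial_lngamma(0, rho * 3, 3), log(rho) + 1 - rho)
  # continuity of the limit
  expect_equal(combinatorial_lngamma(1e-10, rho * 3, 3),
               combinatorial_lngamma(0, rho * 3, 3), tolerance = 1e-8)
})

test_that("dispersion/refraction and polarity contributions match hand values", {
  solv <- psp_solvents()
  bz <- compound_row(solv, "Benzene")
  ch <- compound_row(solv, "Cyclohexane")
  ve <- psptherm:::ve_lngamma(bz$Vx, bz$E, ch$Vx, ch$E, phi2 = 1, T = 298.15)
  expect_equal(ve, 0.0459, tolerance = 2e-3)
  ac <- compound_row(solv, "Acetone")
  an <- compound_row(solv, "Acetonitrile")
  sc <- psptherm:::s_lngamma(ac$Vx, ac$S, an$Vx, an$S, phi2 = 1, T = 298.15)
  expect_equal(sc, 0.2842, tolerance = 2e-3)
  # identical compounds contribute nothing
  expect_equal(psptherm:::ve_lngamma(1, 0.5, 1, 0.5, 1, 298.15), 0)
  # quadratic scaling in phi2, and matched polarity density vanishes
  expect_equal(psptherm:::s_lngamma(1, 0.8, 2, 1.6, 0.5, 298.15),
               0.25 * psptherm:::s_lngamma(1, 0.8, 2, 1.6, 1, 298.15))
  expect_equal(psptherm:::s_lngamma(1, 0.8, 2, 1.6, 1, 298.15), 0)
})

test_that("residual breakdown adds up and both quadratic parts stay nonnegative", {
  solv <- psp_solvents()
  set.seed(5)
  for (i in 1:20) {
    s1 <- solv[sample(nrow(solv), 1), ]
    s2 <- solv[sample(nrow(solv), 1), ]
    x1 <- runif(1, 0.05, 0.95)
    br <- activity_coefficients(s1, s2, x1)
    expect_gte(br$ln_gamma_VE, 0)
    expect_gte(br$ln_gamma_S, 0)
    expect_equal(br$ln_gamma_res,
                 br$ln_gamma_VE + br$ln_gamma_S + br$ln_gamma_H,
                 tolerance = 1e-12)
    expect_equal(br$ln_gamma_total, br$ln_gamma_C + br$ln_gamma_res,
                 tolerance = 1e-12)
    # chi12 consistency: ln gamma_res = r1 chi12 phi2^2
    r1 <- segments_from_mcgowan(s1$Vx)
    r2 <- segments_from_mcgowan(s2$Vx)
    phi2 <- (1 - x1) * r2 / (x1 * r1 + (1 - x1) * r2)
    expect_equal(br$ln_gamma_res, r1 * br$chi12 * phi2^2, tolerance = 1e-10)
  }
  ident <- activity_coefficients(solv[19, ], solv[19, ], 0.4)
  expect_equal(ident$ln_gamma_res, 0, tolerance = 1e-12)
  expect_equal(ident$chi12, 0, tolerance = 1e-12)
})

test_that("hydrogen-bonding contribution has the expected signs", {
  solv <- psp_solvents()
  # inert solute in a self-associating solvent: gamma raised
  hept <- compound_row(solv, "n-Heptane")
  eth <- compound_row(solv, "Ethanol")
  expect_gt(activity_coefficients(hept, eth, 0.1)$ln_gamma_H, 0)
  # pure donor dissolved in pure acceptor: cross-association lowers gamma
  chcl3 <- compound_row(solv, "Chloroform")
  acet <- compound_row(solv, "Acetone")
  expect_lt(activity_coefficients(chcl3, acet, 0.01)$ln_gamma_H, 0)
  # no hydrogen bonding anywhere: exactly zero
  oct <- compound_row(solv, "n-Octane")
  expect_equal(activity_coefficients(hept, oct, 0.3)$ln_gamma_H, 0)
})

test_that("analytic infinite dilution equals the numerical composition limit", {
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    solute <- random_lser(solvent_like = TRUE)
    solvent <- random_lser(solvent_like = FALSE)
    an <- infinite_dilution_gamma(solute, solvent, T = 303.15)$ln_gamma_inf
    num <- activity_coefficients(solute, solvent, x1 = 1e-8,
                                 T = 303.15)$ln_gamma_res
    worst <- max(worst, abs(an - num))
  }
  expect_lt(worst, 1e-5)
})

test_that("infinite dilution reduces to the pure quadratic terms for inert pairs", {
  solv <- psp_solvents()
  hept <- compound_row(solv, "n-Heptane")
  tol_ <- compound_row(solv, "Toluene")
  got <- infinite_dilution_gamma(hept, tol_, T = 303.15)$ln_gamma_inf
  expect_equal(got,
               psptherm:::ve_lngamma(hept$Vx, hept$E, tol_$Vx, tol_$E, 1, 303.15) +
                 psptherm:::s_lngamma(hept$Vx, hept$S, tol_$Vx, tol_$S, 1, 303.15),
               tolerance = 1e-12)
  # matched inert descriptors: exactly zero
  a <- tibble::tibble(Vx = 1, E = 0.4, S = 0.3, A = 0, B = 0)
  expect_equal(infinite_dilution_gamma(a, a)$ln_gamma_inf, 0)
})

test_that("methanol in each drug: analytic limit matches the x1 = 1e-8 evaluation", {
  meoh <- compound_row(psp_solvents(), "Methanol")
  drugs <- psp_drugs()
  for (i in seq_len(nrow(drugs))) {
    an <- infinite_dilution_gamma(meoh, drugs[i, ], T = 303.15)$ln_gamma_inf
    num <- activity_coefficients(meoh, drugs[i, ], 1e-8, T = 303.15)$ln_gamma_res
    expect_lt(abs(an - num), 1e-6)
  }
})
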