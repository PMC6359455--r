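test_that("synthetic generator is exact at zero noise and bit-reproducible per seed", {
  truth <- tibble::tibble(Vx = 3.10, E = 3.08, S = 3.19, A = 0.50, B = 1.45)
  panel <- default_probe_panel()
  clean <- generate_synthetic_igc(truth, panel, noise_sd = 0)
  expect_equal(clean$ln_gamma, clean$ln_gamma_true)
  expect_equal(clean$ln_gamma,
               infinite_dilution_gamma(panel, truth, T = 303.15)$ln_gamma_inf)
  a <- generate_synthetic_igc(truth, panel, noise_sd = 0.1, seed = 77)
  b <- generate_synthetic_igc(truth, panel, noise_sd = 0.1, seed = 77)
  expect_identical(a$ln_gamma, b$ln_gamma)
  c <- generate_synthetic_igc(truth, panel, noise_sd = 0.1, seed = 78)
  expect_false(identical(a$ln_gamma, c$ln_gamma))
})

test_that("noise averages out over replicates at the CLT rate", {
  truth <- tibble::tibble(Vx = 3.43, E = 1.35, S = 4.28, A = 0.20, B = 0.70)
  panel <- default_probe_panel()[1:3, ]
  clean <- generate_synthetic_igc(truth, panel, noise_sd = 0)$ln_gamma
  set.seed(31)
  acc <- matrix(0, 10000, nrow(panel))
  for (i in seq_len(10000)) {
    acc[i, ] <- generate_synthetic_igc(truth, panel, noise_sd = 0.1)$ln_gamma
  }
  expect_true(all(abs(colMeans(acc) - clean) < 0.003))
})

test_that("stage fits recover noise-free descriptors and handle degenerate truths", {
  panel <- default_probe_panel()
  # inert stationary phase: alkane probes see nothing
  inert <- tibble::tibble(Vx = 3.0, E = 0, S = 0, A = 0, B = 0)
  dat0 <- generate_synthetic_igc(inert, panel[1:4, ], noise_sd = 0)
  f0 <- fit_dispersion_polar(dat0, Vx = 3.0)
  expect_equal(c(f0$E, f0$S), c(0, 0), tolerance = 1e-8)
  # known (E,S) with HB descriptors fixed at truth
  truth <- tibble::tibble(Vx = 4.23, E = 3.64, S = 4.66, A = 0.71, B = 2.10)
  dat <- generate_synthetic_igc(truth, panel, noise_sd = 0)
  f1 <- fit_dispersion_polar(dat, Vx = truth$Vx, A = truth$A, B = truth$B)
  expect_equal(c(f1$E, f1$S), c(truth$E, truth$S), tolerance = 1e-6)
  # known (A,B) with E,S fixed at truth
  f2 <- fit_acid_base(dat, Vx = truth$Vx, E = truth$E, S = truth$S)
  expect_equal(c(f2$A, f2$B), c(truth$A, truth$B), tolerance = 1e-5)
  # non-associating truth comes back as zeros
  nohb <- tibble::tibble(Vx = 3.0, E = 2.0, S = 3.0, A = 0, B = 0)
  dat2 <- generate_synthetic_igc(nohb, panel, noise_sd = 0)
  f3 <- fit_acid_base(dat2, Vx = 3.0, E = 2.0, S = 3.0)
  expect_equal(c(f3$A, f3$B), c(0, 0), tolerance = 1e-6)
  expect_error(fit_dispersion_polar(dat[1, ], Vx = 3), "at least 2")
})

test_that("acidic probes carry the basicity signal of a basic-only drug", {
  # sensitivity: d ln gamma / dB is nonzero for an acidic probe
  panel <- psp_solvents()
  dcm <- compound_row(panel, "Dichloromethane")  # acidic, B = 0
  drug0 <- tibble::tibble(Vx = 2.87, E = 2.19, S = 2.96, A = 0, B = 0.6)
  drug1 <- drug0
  drug1$B <- drug0$B + 1e-4
  g0 <- infinite_dilution_gamma(dcm, drug0, T = 303.15)$ln_gamma_inf
  g1 <- infinite_dilution_gamma(dcm, drug1, T = 303.15)$ln_gamma_inf
  expect_gt(abs(g1 - g0) / 1e-4, 0.01)
  # while a pure alkane is insensitive to B except through self-association
  hep <- compound_row(panel, "n-Heptane")
  h0 <- infinite_dilution_gamma(hep, drug0, T = 303.15)$ln_gamma_inf
  h1 <- infinite_dilution_gamma(hep, drug1, T = 303.15)$ln_gamma_inf
  expect_lt(abs(h1 - h0), abs(g1 - g0))
  # identifiability warnings fire for one-sided panels
  dat <- generate_synthetic_igc(drug0, panel[c(17, 18), ], noise_sd = 0)
  expect_warning(fit_acid_base(dat, 2.87, 2.19, 2.96), "basic")
})

test_that("full alternating fit recovers random truths from noise-free panels", {
  panel <- default_probe_panel()
  set.seed(11)
  for (i in 1:5) {
    truth <- random_lser(solvent_like = FALSE, zero_p = 0.3)
    dat <- generate_synthetic_igc(truth, panel, noise_sd = 0)
    fit <- fit_descriptors(dat, Vx = truth$Vx)
    expect_lt(max(abs(fit$descriptors$estimate -
                        c(truth$E, truth$S, truth$A, truth$B))), 1e-4)
    expect_true(fit$converged)
    expect_lt(fit$rms_residual, 1e-8)
  }
})

test_that("objective decreases monotonically across outer rounds", {
  panel <- default_probe_panel()
  truth <- tibble::tibble(Vx = 5.0, E = 2.5, S = 5.0, A = 0.4, B = 1.8)
  dat <- generate_synthetic_igc(truth, panel, noise_sd = 0.05, seed = 5)
  fit <- fit_descriptors(dat, Vx = truth$Vx)
  expect_true(all(diff(fit$trace$rms) < 1e-10))
})

test_that("probes identical to the stationary phase give zero residuals", {
  me <- tibble::tibble(name = "self", Vx = 3.0, E = 2.0, S = 3.0,
                       A = 0.3, B = 1.0)
  panel <- dplyr::bind_rows(me, default_probe_panel()[c(1, 5, 9, 10), ])
  dat <- generate_synthetic_igc(me, panel, noise_sd = 0)
  fit <- fit_descriptors(dat, Vx = 3.0)
  expect_lt(abs(dat$ln_gamma[1]), 1e-12)
  expect_lt(max(abs(fit$residuals$residual)), 1e-6)
})

test_that("jackknife reports one refit per left-out probe with finite estimates", {
  panel <- default_probe_panel()
  truth <- tibble::tibble(Vx = 3.1, E = 3.08, S = 3.19, A = 0.5, B = 1.45)
  dat <- generate_synthetic_igc(truth, panel, noise_sd = 0.02, seed = 9)
  jk <- jackknife_descriptors(dat, Vx = 3.1)
  expect_identical(nrow(jk), nrow(panel))
  expect_true(all(is.finite(unlist(jk[, c("E", "S", "A", "B")]))))
  # dropping one probe perturbs, not destroys, the estimates
  expect_lt(max(apply(jk[, c("E", "S", "A", "B")], 2, sd)), 1.5)
})

test_that("tidy/glance/autoplot expose the fit in broom style", {
  panel <- default_probe_panel()
  truth <- tibble::tibble(Vx = 3.1, E = 3.08, S = 3.19, A = 0.5, B = 1.45)
  dat <- generate_synthetic_igc(truth, panel, noise_sd = 0.03, seed = 21)
  fit <- fit_descriptors(dat, Vx = 3.1)
  td <- tidy(fit)
  expect_identical(td$term, c("E", "S", "A", "B"))
  expect_true(all(td$std_error >= 0, na.rm = TRUE))
  gl <- glance(fit)
  expect_identical(gl$n_probes, nrow(panel))
  expect_s3_class(autoplot(fit), "ggplot")
})
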