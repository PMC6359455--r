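test_that("pair energetics follow the alkanol reference scaling of sqrt(A*B)", {
  z <- hb_pair_energy(0, 0.7, 298.15)
  expect_false(z$exists)
  expect_equal(unlist(z[c("E_HB", "S_HB", "G_HB")]), c(0, 0, 0),
               ignore_attr = TRUE)
  eth <- hb_pair_energy(0.37, 0.48, 298.15)
  w <- sqrt(0.37 * 0.48)
  expect_equal(eth$E_HB, -30450 * w)
  expect_equal(eth$G_HB, -8422.2, tolerance = 1e-4)
  unit <- hb_pair_energy(1, 1, 298.15)
  expect_equal(unit$G_HB, -(30450 - 35.1 * 298.15))
  expect_equal(unit$G_HB, -19984.935, tolerance = 1e-9)
  # G = E - T*S identity
  expect_equal(eth$G_HB, eth$E_HB - 298.15 * eth$S_HB, tolerance = 1e-12)
  expect_error(hb_pair_energy(-0.1, 0.5), ">= 0")
})

test_that("the free-energy identity -G_HB,298 = 2 Vm sigma_Ga sigma_Gb holds", {
  set.seed(3)
  for (i in 1:10) {
    A <- runif(1, 0.05, 1); B <- runif(1, 0.05, 4); Vm <- runif(1, 40, 900)
    p <- psp_from_lser(1, 0, 0, A, B, Vm)
    expect_equal(2 * Vm * p$sigma_Ga * p$sigma_Gb, 20000 * sqrt(A * B),
                 tolerance = 1e-9)
  }
})

test_that("pure-fluid bonded fraction has the right closed form and limits", {
  expect_equal(pure_bond_fraction(2, 0), 0)  # no bond
  eth <- hb_pair_energy(0.37, 0.48)
  f <- pure_bond_fraction(0.449 / 0.213, eth$G_HB)
  expect_equal(f, 0.767, tolerance = 2e-3)
  # saturation: infinitely strong bond bonds every molecule
  expect_equal(pure_bond_fraction(5, -1e6), 1, tolerance = 1e-9)
  # the fraction solves the equilibrium quadratic A11*f = (1-f)^2
  A11 <- (0.449 / 0.213) * exp(eth$G_HB / (8.314 * 298.15))
  expect_equal(A11 * f, (1 - f)^2, tolerance = 1e-12)
})

test_that("hydrogen-bond cohesive energy density matches hand evaluation", {
  expect_equal(hb_ced(0, 0, 58.6)$sigma_hb, 0)
  eth <- hb_pair_energy(0.37, 0.48)
  f <- pure_bond_fraction(0.449 / 0.213, eth$G_HB)
  ced <- hb_ced(f, eth$E_HB, 58.6)
  expect_equal(ced$ced_hb, 168, tolerance = 5e-3)
  expect_equal(ced$sigma_hb, 13.0, tolerance = 5e-3)
})

test_that("equilibrium solver is consistent with the pure closed form and trivial cases", {
  # no facing donor/acceptor pairs: everything zero
  st0 <- solve_hbond(c(0.5, 0.5), c(2, 3), A = c(0.4, 0), B = c(0, 0))
  expect_true(all(st0$nu == 0))
  expect_equal(st0$nu_H, 0)
  # single self-associating species: matches pure_bond_fraction / r
  eth <- hb_pair_energy(0.37, 0.48)
  r <- 0.449 / 0.213
  st1 <- solve_hbond(1, r, 0.37, 0.48)
  expect_equal(st1$nu[1, 1], pure_bond_fraction(r, eth$G_HB) / r,
               tolerance = 1e-10)
  expect_lt(st1$residual, 1e-12)
})

test_that("solution beats a grid of feasible bond numbers on free energy", {
  # ethanol + inert alkane at equimolar composition
  x <- c(0.5, 0.5); r <- c(0.449, 1.095) / 0.213
  A <- c(0.37, 0); B <- c(0.48, 0)
  st <- solve_hbond(x, r, A, B)
  f_opt <- hb_free_energy(st$nu, x, r, A, B)
  cap <- min(x[1] / st$r_total, x[1] / st$r_total)
  grid <- seq(1e-6, cap * (1 - 1e-9), length.out = 200)
  f_grid <- vapply(grid, function(v) {
    nu <- matrix(0, 2, 2); nu[1, 1] <- v
    hb_free_energy(nu, x, r, A, B)
  }, numeric(1))
  expect_true(all(f_opt <= f_grid + 1e-12))
})

test_that("solver matches independent free-energy minimisation on random two-species systems", {
  set.seed(42)
  n_checked <- 0
  while (n_checked < 50) {
    x1 <- runif(1, 0.05, 0.95); x <- c(x1, 1 - x1)
    r <- runif(2, 1, 20)
    A <- ifelse(runif(2) < 0.8, runif(2, 0.05, 1.2), 0)
    B <- ifelse(runif(2) < 0.8, runif(2, 0.05, 1.5), 0)
    if (all(outer(A, B) == 0)) next
    st <- solve_hbond(x, r, A, B)
    nu_bf <- brute_force_hbond(x, r, A, B)
    expect_lt(max(abs(st$nu - nu_bf)), 1e-8)
    # stationarity and balances
    expect_lt(st$residual, 1e-10)
    d <- ifelse(A > 0, x / st$r_total, 0)
    a <- ifelse(B > 0, x / st$r_total, 0)
    expect_equal(st$nu_free_donors, d - rowSums(st$nu), tolerance = 1e-12)
    expect_equal(st$nu_free_acceptors, a - colSums(st$nu), tolerance = 1e-12)
    expect_true(all(st$nu >= 0) && all(st$nu_free_donors >= -1e-12) &&
                  all(st$nu_free_acceptors >= -1e-12))
    n_checked <- n_checked + 1
  }
})

test_that("self-association weakens monotonically on dilution by an inert species", {
  r <- c(0.449, 1.095) / 0.213
  xs <- seq(0.05, 0.95, by = 0.1)
  nu22 <- vapply(xs, function(x_inert) {
    st <- solve_hbond(c(1 - x_inert, x_inert), r,
                      A = c(0.37, 0), B = c(0.48, 0))
    st$nu[1, 1]
  }, numeric(1))
  expect_true(all(diff(nu22) < 0))
})

test_that("tidy() lays the bond matrix out per donor-acceptor pair", {
  st <- solve_hbond(c(0.4, 0.6), c(2, 4), A = c(0.4, 0.1), B = c(0.5, 0.3))
  td <- tidy(st)
  expect_identical(nrow(td), 4L)
  expect_equal(sum(td$nu), st$nu_H)
  expect_true(all(td$exists))
})
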