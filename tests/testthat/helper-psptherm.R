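# Shared helpers: an independent brute-force minimiser of the association
# free energy (barrier-method optimisation, no reuse of the package's
# Gauss-Seidel updates) and random input generators.

brute_force_hbond <- function(x, r, A, B, T = 298.15) {
  r_tot <- sum(x * r)
  d <- ifelse(A > 0, x / r_tot, 0)
  a <- ifelse(B > 0, x / r_tot, 0)
  n <- length(x)
  K <- exp((psp_constants()$E_HB_coef - psp_constants()$S_HB_coef * T) *
             sqrt(outer(A, B)) / (psp_constants()$R * T))
  K[outer(A, B) == 0] <- 0
  act <- which(K > 0, arr.ind = TRUE)
  m <- nrow(act)
  if (m == 0) {
    return(matrix(0, n, n))
  }
  Gbar <- -log(K[act])
  f <- function(v) {
    nu <- matrix(0, n, n)
    nu[act] <- v
    hb_free_energy(nu, x, r, A, B, T)
  }
  gr <- function(v) {
    nu <- matrix(0, n, n)
    nu[act] <- v
    sd <- d - rowSums(nu)
    sa <- a - colSums(nu)
    Gbar + log(v) - log(sd[act[, 1]]) - log(sa[act[, 2]])
  }
  ui <- diag(m)
  ci <- rep(0, m)
  for (i in unique(act[, 1])) {
    ui <- rbind(ui, as.numeric(act[, 1] == i) * -1)
    ci <- c(ci, -d[i])
  }
  for (j in unique(act[, 2])) {
    ui <- rbind(ui, as.numeric(act[, 2] == j) * -1)
    ci <- c(ci, -a[j])
  }
  v0 <- rep(min(c(d[d > 0], a[a > 0])) * 0.2 / m, m)
  opt <- stats::constrOptim(v0, f, gr, ui = ui, ci = ci, method = "BFGS",
                            outer.iterations = 100, outer.eps = 1e-13,
                            control = list(maxit = 2000, reltol = 1e-16))
  nu <- matrix(0, n, n)
  nu[act] <- opt$par
  nu
}

# Random LSER descriptor set in solvent-like ranges; zero_p controls how
# often A or B is exactly zero (inert donor/acceptor sites).
random_lser <- function(solvent_like = TRUE, zero_p = 0.3) {
  if (solvent_like) {
    tibble::tibble(
      Vx = runif(1, 0.2, 2), E = runif(1, 0, 1), S = runif(1, 0, 1),
      A = ifelse(runif(1) > zero_p, runif(1, 0.05, 0.8), 0),
      B = ifelse(runif(1) > zero_p, runif(1, 0.05, 0.8), 0))
  } else {
    tibble::tibble(
      Vx = runif(1, 2.8, 10), E = runif(1, 1.3, 4.3), S = runif(1, 2.7, 7.8),
      A = ifelse(runif(1) > zero_p, runif(1, 0.05, 0.75), 0),
      B = ifelse(runif(1) > zero_p, runif(1, 0.5, 4.5), 0))
  }
}

# The measured ten-probe panel: four alkanes plus six polar/H-bonding probes.
default_probe_panel <- function() {
  panel <- psp_solvents()
  panel[panel$name %in% c("n-Heptane", "n-Octane", "n-Nonane", "n-Decane",
                          "Acetone", "Acetonitrile", "Ethyl acetate",
                          "Dichloromethane", "Methanol", "Ethanol"), ]
}
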