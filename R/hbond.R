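#' Hydrogen-bond formation energetics for a donor/acceptor pair
#'
#' Energy, entropy and Gibbs free-energy change on forming a hydrogen bond
#' between a donor of acidity `A` and an acceptor of basicity `B`, using the
#' lower-alkanol reference scaling:
#' \deqn{E_{HB} = -30450\sqrt{AB},\quad S_{HB} = -35.1\sqrt{AB},\quad
#'       G_{HB} = -(30450 - 35.1\,T)\sqrt{AB}.}
#' A pair with `A * B == 0` forms no bond: all quantities are zero and
#' `exists` is `FALSE`.
#'
#' @param A Donor acidity descriptor(s), >= 0.
#' @param B Acceptor basicity descriptor(s), >= 0.
#' @param T Temperature, K.
#' @return A tibble with columns `E_HB` (J/mol), `S_HB` (J/(K mol)),
#'   `G_HB` (J/mol at `T`), `exists`.
#' @export
#' @examples
#' hb_pair_energy(0.37, 0.48, 298.15) # ethanol self-association
hb_pair_energy <- function(A, B, T = 298.15) {
  if (any(A < 0) || any(B < 0)) {
    stop("Descriptors `A` and `B` must be >= 0.", call. = FALSE)
  }
  if (any(T <= 0)) stop("`T` must be > 0.", call. = FALSE)
  w <- sqrt(A * B)
  tibble::tibble(
    E_HB   = -.psp_const$E_HB_coef * w,
    S_HB   = -.psp_const$S_HB_coef * w,
    G_HB   = -(.psp_const$E_HB_coef - .psp_const$S_HB_coef * T) * w,
    exists = w > 0
  )
}

#' Fraction of molecules hydrogen-bonded in a pure self-associating fluid
#'
#' Closed-form solution of the pure-fluid association equilibrium for a
#' species carrying one donor and one acceptor group. With
#' \eqn{A_{11} = r\,e^{G_{HB}/RT}} the bonded fraction (bonds per molecule,
#' equivalently \eqn{r\nu_{11}}) is
#' \deqn{r\nu_{11} = \frac{A_{11} + 2 - \sqrt{A_{11}(A_{11}+4)}}{2} \in [0,1].}
#'
#' @param r Segment number of the molecule.
#' @param G_HB Gibbs free energy of self-association, J/mol (0 or with
#'   `exists = FALSE` in [hb_pair_energy()] means no association).
#' @param T Temperature, K.
#' @param exists Logical; set `FALSE` to force the no-bond case (default
#'   taken as `G_HB != 0`).
#' @return Bonded fraction in `[0, 1]` (vectorised).
#' @export
#' @examples
#' pe <- hb_pair_energy(0.37, 0.48)
#' pure_bond_fraction(segments_from_mcgowan(0.449), pe$G_HB) # about 0.767
pure_bond_fraction <- function(r, G_HB, T = 298.15, exists = G_HB != 0) {
  if (any(r <= 0)) stop("`r` must be > 0.", call. = FALSE)
  A11 <- r * exp(G_HB / (.psp_const$R * T))
  f <- (A11 + 2 - sqrt(A11 * (A11 + 4))) / 2
  f[!exists] <- 0
  pmin(pmax(f, 0), 1)
}

#' Hydrogen-bonding contribution to the cohesive energy density
#'
#' Converts a bonded fraction and bond energy to a cohesive energy density
#' (J/cm^3, numerically MPa) and the corresponding solvation parameter:
#' \deqn{ced_{HB} = -\,(r\nu_{11})\,E_{HB}/V_m,\quad
#'       \sigma_{hb} = \sqrt{ced_{HB}}.}
#'
#' @param bonded_fraction Bonds per molecule, from [pure_bond_fraction()].
#' @param E_HB Bond energy, J/mol (negative for a real bond).
#' @param Vm Molar volume, cm^3/mol.
#' @return A tibble with columns `ced_hb` (MPa) and `sigma_hb` (MPa^0.5).
#' @export
hb_ced <- function(bonded_fraction, E_HB, Vm) {
  if (any(Vm <= 0)) stop("`Vm` must be > 0.", call. = FALSE)
  ced <- -bonded_fraction * E_HB / Vm
  tibble::tibble(ced_hb = ced, sigma_hb = sqrt(pmax(ced, 0)))
}

# Pair association "constant" K_ij = exp(-G_ij/RT); bonds with A_i*B_j = 0
# do not exist and are excluded from the equilibrium entirely.
hb_K_matrix <- function(A, B, T) {
  n <- length(A)
  G <- -(.psp_const$E_HB_coef - .psp_const$S_HB_coef * T) *
    sqrt(outer(A, B))
  K <- exp(-G / (.psp_const$R * T))
  K[outer(A, B) == 0] <- 0
  K
}

#' Solve the multi-species hydrogen-bonding association equilibrium
#'
#' Computes the equilibrium reduced bond numbers \eqn{\nu_{ij}} (bonds
#' between donors of species i and acceptors of species j per total lattice
#' segment) for a mixture, by minimising the Veytsman association free
#' energy. The stationarity conditions are
#' \deqn{\nu_{ij} = \nu_{i0}\,\nu_{0j}\,e^{-G_{HB,ij}/RT}}
#' with the donor and acceptor balances
#' \eqn{\nu_{i0} = x_i/r - \sum_j \nu_{ij}},
#' \eqn{\nu_{0j} = x_j/r - \sum_i \nu_{ij}}, where \eqn{r = \sum_k x_k r_k}.
#'
#' The solver sweeps the existing donor-acceptor pairs Gauss-Seidel style,
#' solving each pair's scalar quadratic exactly while the other bond
#' numbers are held fixed; each sweep is a descent step on the (strictly
#' convex) free energy, so the iteration is unconditionally feasible and
#' convergent. Pairs with `A[i] * B[j] == 0` are fixed at zero.
#'
#' @param x Mole fractions (must sum to 1).
#' @param r Segment numbers per species.
#' @param A,B Donor/acceptor descriptors per species.
#' @param T Temperature, K.
#' @param tol Convergence tolerance on the maximum stationarity residual.
#' @param max_iter Sweep cap.
#' @return An object of class `hbond_state`: list with the `nu` matrix,
#'   free-donor/acceptor vectors `nu_free_donors`, `nu_free_acceptors`,
#'   total `nu_H`, the `G_HB` matrix (J/mol), `r_total`, `converged`,
#'   `iterations` and `residual`.
#' @export
#' @examples
#' # ethanol diluted by an inert alkane
#' solve_hbond(c(0.5, 0.5), r = c(2.108, 5.141),
#'             A = c(0.37, 0), B = c(0.48, 0))
solve_hbond <- function(x, r, A, B, T = 298.15,
                        tol = 1e-12, max_iter = 10000L) {
  n <- length(x)
  stopifnot(length(r) == n, length(A) == n, length(B) == n, n >= 1)
  if (abs(sum(x) - 1) > 1e-8) stop("Mole fractions must sum to 1.", call. = FALSE)
  validate_lser(rep(1, n), numeric(n), numeric(n), A, B, where = "solve_hbond")
  r_tot <- sum(x * r)
  d <- ifelse(A > 0, x / r_tot, 0)      # reduced donor counts per species
  a <- ifelse(B > 0, x / r_tot, 0)      # reduced acceptor counts
  K <- hb_K_matrix(A, B, T)
  G <- -(.psp_const$E_HB_coef - .psp_const$S_HB_coef * T) * sqrt(outer(A, B))
  nu <- matrix(0, n, n)
  active <- which(K > 0, arr.ind = TRUE)
  iter <- 0L
  res <- 0
  if (nrow(active)) {
    repeat {
      iter <- iter + 1L
      delta <- 0
      for (k in seq_len(nrow(active))) {
        i <- active[k, 1]; j <- active[k, 2]
        di <- d[i] - sum(nu[i, ]) + nu[i, j]   # donors of i free if nu_ij removed
        aj <- a[j] - sum(nu[, j]) + nu[i, j]
        Kij <- K[i, j]
        b <- Kij * (di + aj) + 1
        disc <- b^2 - 4 * Kij^2 * di * aj
        # conjugate form of the smaller quadratic root: no cancellation
        # for strong bonds at high dilution
        root <- 2 * Kij * di * aj / (b + sqrt(max(disc, 0)))
        root <- min(max(root, 0), di, aj)
        delta <- max(delta, abs(root - nu[i, j]))
        nu[i, j] <- root
      }
      nu_i0 <- d - rowSums(nu)
      nu_0j <- a - colSums(nu)
      res <- max(abs(nu[active] - nu_i0[active[, 1]] * nu_0j[active[, 2]] *
                       K[active]))
      if ((res < tol && delta < tol) || iter >= max_iter) break
    }
    # polish sweeps: drive the fixed point to machine precision even when
    # bond numbers are tiny (infinite-dilution compositions)
    for (p in 1:500) {
      delta <- 0
      for (k in seq_len(nrow(active))) {
        i <- active[k, 1]; j <- active[k, 2]
        di <- d[i] - sum(nu[i, ]) + nu[i, j]
        aj <- a[j] - sum(nu[, j]) + nu[i, j]
        Kij <- K[i, j]
        b <- Kij * (di + aj) + 1
        disc <- b^2 - 4 * Kij^2 * di * aj
        root <- min(max(2 * Kij * di * aj / (b + sqrt(max(disc, 0))), 0),
                    di, aj)
        delta <- max(delta, abs(root - nu[i, j]),
                     if (root > 0) abs(root - nu[i, j]) / root else 0)
        nu[i, j] <- root
      }
      if (delta < 1e-14) break
    }
    nu_i0 <- d - rowSums(nu)
    nu_0j <- a - colSums(nu)
    res <- max(abs(nu[active] - nu_i0[active[, 1]] * nu_0j[active[, 2]] *
                     K[active]))
  }
  nu_i0 <- d - rowSums(nu)
  nu_0j <- a - colSums(nu)
  converged <- nrow(active) == 0 || res < tol
  if (!converged) {
    stop(sprintf("Hydrogen-bond equilibrium did not converge in %d sweeps (last residual %.3e).",
                 max_iter, res), call. = FALSE)
  }
  structure(list(
    nu = nu,
    nu_free_donors = nu_i0,
    nu_free_acceptors = nu_0j,
    nu_H = sum(nu),
    G_HB = G,
    K = K,
    r_total = r_tot,
    x = x, r = r, A = A, B = B, T = T,
    converged = converged,
    iterations = iter,
    residual = res
  ), class = "hbond_state")
}

#' @export
print.hbond_state <- function(x, ...) {
  cat(sprintf("<hbond_state> %d species at T = %.2f K\n", length(x$x), x$T))
  cat(sprintf("  nu_H = %.6g (converged in %d sweeps, residual %.2e)\n",
              x$nu_H, x$iterations, x$residual))
  invisible(x)
}

#' Tidy a hydrogen-bond equilibrium state
#'
#' One row per donor-acceptor species pair with its reduced bond number.
#'
#' @param x An `hbond_state` from [solve_hbond()].
#' @param ... Unused.
#' @return Tibble with `donor, acceptor, nu, G_HB, exists`.
#' @export
tidy.hbond_state <- function(x, ...) {
  n <- length(x$x)
  idx <- expand.grid(donor = seq_len(n), acceptor = seq_len(n))
  tibble::tibble(
    donor = idx$donor,
    acceptor = idx$acceptor,
    nu = x$nu[cbind(idx$donor, idx$acceptor)],
    G_HB = x$G_HB[cbind(idx$donor, idx$acceptor)],
    exists = x$K[cbind(idx$donor, idx$acceptor)] > 0
  )
}

#' Veytsman association free energy of a bond configuration
#'
#' Evaluates (per total lattice segment, in units of RT) the association
#' free energy whose minimiser is the equilibrium returned by
#' [solve_hbond()]:
#' \deqn{f(\nu) = \sum_{ij}\nu_{ij}\left(\frac{G_{ij}}{RT} + \ln\nu_{ij} - 1\right)
#'   + \sum_i(\nu_{i0}\ln\nu_{i0} - \nu_{i0})
#'   + \sum_j(\nu_{0j}\ln\nu_{0j} - \nu_{0j}) + const.}
#' Exposed so that independent numerical minimisation can be compared with
#' the Gauss-Seidel solution.
#'
#' @param nu Bond matrix (entries for nonexistent pairs must be 0).
#' @param x,r,A,B,T As in [solve_hbond()].
#' @return Free energy per segment in units of RT (additive constant fixed
#'   by the donor/acceptor totals).
#' @export
hb_free_energy <- function(nu, x, r, A, B, T = 298.15) {
  r_tot <- sum(x * r)
  d <- ifelse(A > 0, x / r_tot, 0)
  a <- ifelse(B > 0, x / r_tot, 0)
  K <- hb_K_matrix(A, B, T)
  Gbar <- -log(K[K > 0])                 # G_ij/RT for existing pairs
  nu_i0 <- d - rowSums(nu)
  nu_0j <- a - colSums(nu)
  if (any(nu < -1e-15) || any(nu_i0 < -1e-12) || any(nu_0j < -1e-12)) {
    return(Inf)
  }
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  sum(nu[K > 0] * Gbar) + sum(xlogx(nu[K > 0]) - nu[K > 0]) +
    sum(xlogx(nu_i0[d > 0]) - nu_i0[d > 0]) +
    sum(xlogx(nu_0j[a > 0]) - nu_0j[a > 0])
}
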