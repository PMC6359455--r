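#' Flory-Huggins combinatorial activity coefficient
#'
#' \eqn{\ln\gamma_1^C = \ln(\phi_1/x_1) + (1 - r_1/r_2)\,\phi_2}, with the
#' analytic limit \eqn{\ln(r_1/r_2) + 1 - r_1/r_2} at infinite dilution
#' (`x1 = 0`).
#'
#' @param x1 Solute mole fraction(s) in `[0, 1]`.
#' @param r1,r2 Segment numbers of solute and solvent.
#' @return `ln gamma_C` (vectorised over `x1`).
#' @export
#' @examples
#' combinatorial_lngamma(0.5, 2, 1) # = log(4/3) - 1/3
combinatorial_lngamma <- function(x1, r1, r2) {
  stopifnot(all(x1 >= 0), all(x1 <= 1), r1 > 0, r2 > 0)
  rho <- r1 / r2
  out <- numeric(length(x1))
  lim <- x1 == 0
  out[lim] <- log(rho) + 1 - rho
  xi <- x1[!lim]
  phi1 <- xi * r1 / (xi * r1 + (1 - xi) * r2)
  out[!lim] <- log(phi1 / xi) + (1 - rho) * (1 - phi1)
  out
}

# Quadratic residual brackets: dispersion/refraction and polarity
# "cohesive density difference" contributions (both always >= 0).
ve_lngamma <- function(Vx1, E1, Vx2, E2, phi2, T) {
  s <- .psp_const$disp_slope
  .psp_const$res_scale * Vx1 * phi2^2 / (.psp_const$R * T) *
    (sqrt(s + E1 / Vx1) - sqrt(s + E2 / Vx2))^2
}

s_lngamma <- function(Vx1, S1, Vx2, S2, phi2, T) {
  .psp_const$res_scale * Vx1 * phi2^2 / (.psp_const$R * T) *
    (sqrt(S1 / Vx1) - sqrt(S2 / Vx2))^2
}

# Hydrogen-bonding contribution for the solute (species 1) of a binary
# mixture from the solved association state, referenced to the pure solute.
hb_lngamma_from_state <- function(state, x1, r1, A1, B1, T) {
  nu <- state$nu
  r <- state$r_total
  term_mix <- r1 * state$nu_H
  don <- x1 - r * (nu[1, 1] + nu[1, 2])
  acc <- x1 - r * (nu[1, 1] + nu[2, 1])
  if (A1 > 0) term_mix <- term_mix - log(x1 / don)
  if (B1 > 0) term_mix <- term_mix - log(x1 / acc)
  f1 <- if (A1 > 0 && B1 > 0) {
    pure_bond_fraction(r1, hb_pair_energy(A1, B1, T)$G_HB, T)
  } else 0
  term_pure <- f1 + 2 * log(1 - f1)
  term_mix - term_pure
}

lngamma_parts_scalar <- function(solute, solvent, x1, T) {
  r1 <- segments_from_mcgowan(solute$Vx)
  r2 <- segments_from_mcgowan(solvent$Vx)
  x2 <- 1 - x1
  phi2 <- x2 * r2 / (x1 * r1 + x2 * r2)
  ve <- ve_lngamma(solute$Vx, solute$E, solvent$Vx, solvent$E, phi2, T)
  sp <- s_lngamma(solute$Vx, solute$S, solvent$Vx, solvent$S, phi2, T)
  hb <- if (all(c(solute$A * solute$B, solute$A * solvent$B,
                  solvent$A * solute$B, solvent$A * solvent$B) == 0)) {
    0
  } else {
    state <- solve_hbond(c(x1, x2), c(r1, r2),
                         c(solute$A, solvent$A), c(solute$B, solvent$B), T)
    hb_lngamma_from_state(state, x1, r1, solute$A, solute$B, T)
  }
  res <- ve + sp + hb
  comb <- combinatorial_lngamma(x1, r1, r2)
  tibble::tibble(
    x1 = x1,
    ln_gamma_C = comb,
    ln_gamma_VE = ve,
    ln_gamma_S = sp,
    ln_gamma_H = hb,
    ln_gamma_res = res,
    ln_gamma_total = comb + res,
    chi12 = res / (r1 * phi2^2)
  )
}

#' Activity-coefficient breakdown for a binary solute/solvent pair
#'
#' Splits \eqn{\ln\gamma_1} of the solute into the Flory-Huggins
#' combinatorial part and the three residual parts: the dispersion/
#' refraction quadratic (`ln_gamma_VE`), the polarity quadratic
#' (`ln_gamma_S`, both always nonnegative) and the hydrogen-bonding part
#' (`ln_gamma_H`, from the Veytsman association equilibrium of the mixture
#' referenced to the pure solute; may be negative for cross-associating
#' pairs). Also reports the Flory-Huggins interaction parameter
#' \eqn{\chi_{12} = \ln\gamma_1^{res} / (r_1 \phi_2^2)}.
#'
#' @param solute,solvent One-row data frames with columns `Vx, E, S, A, B`
#'   (e.g. rows of [psp_solvents()] or [psp_drugs()]).
#' @param x1 Solute mole fraction(s), in `(0, 1]` (vectorised).
#' @param T Temperature, K.
#' @return A tibble, one row per `x1`, with columns `x1, ln_gamma_C,
#'   ln_gamma_VE, ln_gamma_S, ln_gamma_H, ln_gamma_res, ln_gamma_total,
#'   chi12`.
#' @export
#' @examples
#' solv <- psp_solvents()
#' activity_coefficients(compound_row(solv, "Ethanol"),
#'                       compound_row(solv, "n-Heptane"), x1 = 0.25)
activity_coefficients <- function(solute, solvent, x1, T = 298.15) {
  stopifnot(is.data.frame(solute), nrow(solute) == 1,
            is.data.frame(solvent), nrow(solvent) == 1)
  if (any(x1 <= 0) || any(x1 > 1)) {
    stop("`x1` must lie in (0, 1].", call. = FALSE)
  }
  purrr::map_dfr(x1, function(x) lngamma_parts_scalar(solute, solvent, x, T))
}

#' Residual activity coefficient at infinite dilution (analytic)
#'
#' Closed-form infinite-dilution limit (\eqn{x_1 \to 0},
#' \eqn{\phi_2 \to 1}) of the residual activity coefficient. The quadratic
#' dispersion and polarity terms are evaluated at \eqn{\phi_2 = 1}; the
#' hydrogen-bonding terms reduce to the solvent self-association fraction
#' \eqn{r_2\nu_{22}} and the cross-association constants
#' \eqn{A_{ij} = r_2 e^{G_{HB,ij}/RT}}:
#' \deqn{\ln\gamma_1^{res,\infty} = \frac{10^4 V_{x,1}}{RT}\{\cdots\}
#'   + r_1\nu_{22}
#'   - \ln\frac{1 + A_{12} - r_2\nu_{22}}{A_{12}}
#'   - \ln\frac{1 + A_{21} - r_2\nu_{22}}{A_{21}}
#'   - \{r_1\nu_{11} + 2\ln(1 - r_1\nu_{11})\}.}
#' Log terms for nonexistent bond types vanish. The same quantity is
#' available as the numerical `x1 -> 0` limit of
#' [activity_coefficients()]; the two agree to better than 1e-5.
#'
#' @param solutes Data frame of solute compounds (`Vx, E, S, A, B`), one
#'   row per solute.
#' @param solvent One-row data frame for the solvent (for IGC this is the
#'   drug stationary phase).
#' @param T Temperature, K.
#' @return A tibble with one row per solute: `name` (if present),
#'   `ln_gamma_inf`, `chi12`.
#' @export
#' @examples
#' infinite_dilution_gamma(psp_solvents()[1:5, ],
#'                         compound_row(psp_drugs(), "Carvedilol"),
#'                         T = 303.15)
infinite_dilution_gamma <- function(solutes, solvent, T = 298.15) {
  stopifnot(is.data.frame(solutes), is.data.frame(solvent), nrow(solvent) == 1)
  out <- lngamma_inf_vec(solutes$Vx, solutes$E, solutes$S, solutes$A, solutes$B,
                         solvent$Vx, solvent$E, solvent$S, solvent$A, solvent$B,
                         T = T)
  r1 <- segments_from_mcgowan(solutes$Vx)
  res <- tibble::tibble(ln_gamma_inf = out, chi12 = out / r1)
  if ("name" %in% names(solutes)) {
    res <- dplyr::bind_cols(tibble::tibble(name = solutes$name), res)
  }
  res
}

# Vectorised closed-form ln gamma^{res,inf}: solutes are vectors, the
# solvent (stationary phase in IGC) is scalar. Shared by
# infinite_dilution_gamma() and the descriptor-fitting objective.
lngamma_inf_vec <- function(Vx1, E1, S1, A1, B1,
                            Vx2, E2, S2, A2, B2, T) {
  Cg <- .psp_const$E_HB_coef - .psp_const$S_HB_coef * T  # -G per sqrt(AB)
  RT <- .psp_const$R * T
  r1 <- Vx1 / .psp_const$seg_vol
  r2 <- Vx2 / .psp_const$seg_vol
  f2 <- if (A2 > 0 && B2 > 0) {
    pure_bond_fraction(r2, -Cg * sqrt(A2 * B2), T)
  } else 0
  val <- ve_lngamma(Vx1, E1, Vx2, E2, 1, T) +
    s_lngamma(Vx1, S1, Vx2, S2, 1, T) +
    r1 * f2 / r2
  w12 <- sqrt(A1 * B2)
  has12 <- w12 > 0
  if (any(has12)) {
    A12 <- r2 * exp(-Cg * w12[has12] / RT)
    val[has12] <- val[has12] - log((1 + A12 - f2) / A12)
  }
  w21 <- sqrt(A2 * B1)
  has21 <- w21 > 0
  if (any(has21)) {
    A21 <- r2 * exp(-Cg * w21[has21] / RT)
    val[has21] <- val[has21] - log((1 + A21 - f2) / A21)
  }
  w11 <- sqrt(A1 * B1)
  has11 <- w11 > 0
  if (any(has11)) {
    f1 <- pure_bond_fraction(r1[has11], -Cg * w11[has11], T)
    val[has11] <- val[has11] - (f1 + 2 * log1p(-f1))
  }
  val
}
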