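# D = 3.1*Vx + E + S, the nonpolar+polar descriptor sum that carries the
# non-hydrogen-bonding surface energy.
surface_D <- function(Vx, E, S) .psp_const$disp_slope * Vx + E + S

surface_assemble <- function(gamma_VES, Vx, E, S, A, B) {
  D <- surface_D(Vx, E, S)
  if (any(D <= 0)) stop("3.1*Vx + E + S must be > 0.", call. = FALSE)
  k <- gamma_VES / D
  gamma_a <- k * A
  gamma_b <- k * B
  gamma_hb <- 2 * sqrt(gamma_a * gamma_b)
  tibble::tibble(
    gamma_VES = gamma_VES,
    gamma_a = gamma_a,
    gamma_b = gamma_b,
    gamma_hb = gamma_hb,
    gamma_tot = gamma_VES + gamma_hb
  )
}

#' Surface-energy components from the dispersive surface energy
#'
#' Splits a measured dispersive (non-hydrogen-bonding) surface energy into
#' acid/base and hydrogen-bonding components using the compound's LSER
#' descriptors. With \eqn{D = 3.1 V_x + E + S} and the proportionality
#' \eqn{\gamma_a/A = \gamma_b/B = \gamma_{VES}/D}:
#' \deqn{\gamma_{hb} = 2\sqrt{\gamma_a \gamma_b} =
#'   \gamma_d\,\frac{2\sqrt{AB}}{D},\qquad
#'   \gamma_{tot} = \gamma_d\,\frac{D + 2\sqrt{AB}}{D}.}
#' The dispersive energy (e.g. Dorris-Gray from alkane IGC) is an input,
#' identified with the non-hydrogen-bonding component \eqn{\gamma_{VES}}.
#'
#' @param compounds Data frame with columns `Vx, E, S, A, B` and a
#'   dispersive surface energy column (`gamma_d_mJ_m2` by default), or
#'   supply `gamma_d` directly.
#' @param gamma_d Optional numeric vector overriding the column, mJ/m^2.
#' @return The input tibble with `gamma_VES, gamma_a, gamma_b, gamma_hb,
#'   gamma_tot` columns added (all mJ/m^2).
#' @export
#' @examples
#' surface_components(psp_drugs())[, c("name", "gamma_hb", "gamma_tot")]
surface_components <- function(compounds, gamma_d = NULL) {
  stopifnot(is.data.frame(compounds))
  df <- tibble::as_tibble(compounds)
  gd <- if (!is.null(gamma_d)) gamma_d else df$gamma_d_mJ_m2
  if (is.null(gd) || any(!is.finite(gd)) || any(gd < 0)) {
    stop("Dispersive surface energies must be supplied (>= 0) via `gamma_d` or a `gamma_d_mJ_m2` column.",
         call. = FALSE)
  }
  comp <- surface_assemble(gd, df$Vx, df$E, df$S, df$A, df$B)
  dplyr::bind_cols(df[setdiff(names(df), names(comp))], comp)
}

#' Surface-energy components from the total surface energy
#'
#' Inverse of [surface_components()]: recovers the non-hydrogen-bonding
#' component from a total surface energy,
#' \eqn{\gamma_{VES} = \gamma_{tot}\,D/(D + 2\sqrt{AB})}, then assembles
#' the acid/base split.
#'
#' @param compounds Data frame with `Vx, E, S, A, B`.
#' @param gamma_tot Total surface energies, mJ/m^2.
#' @return As [surface_components()].
#' @export
surface_from_total <- function(compounds, gamma_tot) {
  stopifnot(is.data.frame(compounds))
  df <- tibble::as_tibble(compounds)
  if (any(gamma_tot < 0)) stop("`gamma_tot` must be >= 0.", call. = FALSE)
  D <- surface_D(df$Vx, df$E, df$S)
  gves <- gamma_tot * D / (D + 2 * sqrt(df$A * df$B))
  comp <- surface_assemble(gves, df$Vx, df$E, df$S, df$A, df$B)
  dplyr::bind_cols(df[setdiff(names(df), names(comp))], comp)
}

#' Contact angle of a probe liquid on a solid surface
#'
#' Geometric-mean (acid/base) work-of-adhesion model:
#' \deqn{\cos\theta = \frac{2}{\gamma_L}\left(
#'   \sqrt{\gamma_{VES,L}\gamma_{VES,S}} + \sqrt{\gamma_{a,L}\gamma_{b,S}}
#'   + \sqrt{\gamma_{a,S}\gamma_{b,L}}\right) - 1,}
#' with \eqn{\cos\theta} clamped to `[-1, 1]` (complete wetting or
#' dewetting).
#'
#' @param solid,liquid One-row data frames with columns `gamma_VES,
#'   gamma_a, gamma_b` (e.g. from [surface_components()]).
#' @param gamma_L Total surface tension of the liquid, mJ/m^2.
#' @return Contact angle in degrees.
#' @export
#' @examples
#' solid <- tibble::tibble(gamma_VES = 40, gamma_a = 1, gamma_b = 4)
#' liquid <- tibble::tibble(gamma_VES = 30, gamma_a = 10, gamma_b = 10)
#' contact_angle(solid, liquid, gamma_L = 50) # about 40 degrees
contact_angle <- function(solid, liquid, gamma_L) {
  if (any(gamma_L <= 0)) stop("`gamma_L` must be > 0.", call. = FALSE)
  cost <- 2 * (sqrt(liquid$gamma_VES * solid$gamma_VES) +
                 sqrt(liquid$gamma_a * solid$gamma_b) +
                 sqrt(solid$gamma_a * liquid$gamma_b)) / gamma_L - 1
  cost <- pmin(pmax(cost, -1), 1)
  acos(cost) * 180 / pi
}
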