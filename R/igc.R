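#' James-Martin gas compressibility correction
#'
#' Corrects retention for the pressure drop along a packed column:
#' \deqn{j = \frac{3}{2}\,\frac{(P_i/P_o)^2 - 1}{(P_i/P_o)^3 - 1},}
#' with `j = 1` in the limit of no pressure drop.
#'
#' @param Pi Column inlet pressure (any units, same as `Po`).
#' @param Po Column outlet pressure.
#' @return The correction factor in `(0, 1]` (vectorised).
#' @export
#' @examples
#' james_martin(2, 1) # 9/14
james_martin <- function(Pi, Po) {
  if (any(Po <= 0) || any(Pi < Po)) {
    stop("Need inlet pressure >= outlet pressure > 0.", call. = FALSE)
  }
  P <- Pi / Po
  ifelse(abs(P - 1) < 1e-12, 1, 1.5 * (P^2 - 1) / (P^3 - 1))
}

#' Net retention volume per unit mass of stationary phase
#'
#' \deqn{V_N = \frac{j}{m} F (t_R - t_0) \frac{T}{273.15}} with the carrier
#' flow referenced to 1 atm and 273.15 K. All SI: `F` in m^3/s, `m` in kg,
#' times in s; result in m^3/kg.
#'
#' @param tR Probe retention time, s.
#' @param t0 Dead (hold-up) time, s.
#' @param F Carrier gas flow, m^3/s at 273.15 K and 1 atm.
#' @param m Stationary-phase mass, kg.
#' @param T Column temperature, K.
#' @param j James-Martin correction in `(0, 1]`.
#' @return Net retention volume, m^3/kg (vectorised).
#' @export
#' @examples
#' # 10 sccm, 120 s net retention, 0.2 g of drug, 30 C column
#' net_retention_volume(150, 30, F = 10e-6 / 60, m = 2e-4, T = 303.15)
net_retention_volume <- function(tR, t0, F, m, T, j = 1) {
  if (any(tR < t0)) stop("`tR` must be >= `t0`.", call. = FALSE)
  if (any(F <= 0) || any(m <= 0)) stop("`F` and `m` must be > 0.", call. = FALSE)
  if (any(j <= 0) || any(j > 1)) stop("`j` must be in (0, 1].", call. = FALSE)
  (j / m) * F * (tR - t0) * T / .psp_const$T_ice
}

#' Mass activity coefficient at infinite dilution from IGC retention
#'
#' \deqn{\ln\Omega^\infty = \ln\frac{273.15\,R}{p_0 M_1 V_N}
#'   - \frac{p_0 (B_{11} - V_1)}{RT},}
#' all SI (`p0` Pa, `M1` kg/mol, `VN` m^3/kg, `B11`/`V1` m^3/mol), which
#' makes the logarithm's argument dimensionless.
#'
#' @param VN Net retention volume, m^3/kg.
#' @param p0 Probe saturation vapour pressure at the column temperature, Pa.
#' @param M1 Probe molar mass, kg/mol.
#' @param B11 Probe second virial coefficient, m^3/mol.
#' @param V1 Probe liquid molar volume, m^3/mol.
#' @param T Column temperature, K.
#' @return `ln Omega` at infinite dilution (vectorised).
#' @export
mass_activity_coefficient <- function(VN, p0, M1, B11, V1, T) {
  if (any(VN <= 0)) {
    stop("`VN` must be > 0 (no measurable retention).", call. = FALSE)
  }
  if (any(p0 <= 0) || any(M1 <= 0)) stop("`p0` and `M1` must be > 0.", call. = FALSE)
  log(.psp_const$T_ice * .psp_const$R / (p0 * M1 * VN)) -
    p0 * (B11 - V1) / (.psp_const$R * T)
}

#' Mole-fraction residual activity coefficient from the mass coefficient
#'
#' Converts the IGC mass activity coefficient to the residual mole-fraction
#' activity coefficient at infinite dilution by removing the Flory-Huggins
#' combinatorial part:
#' \deqn{\ln\gamma_1^{res,\infty} = \ln\frac{\Omega_1 M_1}{M_2}
#'   - \left(\ln\frac{r_1}{r_2} + 1 - \frac{r_1}{r_2}\right) = r_1\chi_{12}.}
#'
#' @param ln_omega `ln Omega` from [mass_activity_coefficient()].
#' @param M1,M2 Molar masses of probe and stationary phase, kg/mol.
#' @param r1,r2 Segment numbers of probe and stationary phase.
#' @return Tibble with `ln_gamma_inf` and `chi12` (vectorised).
#' @export
mole_fraction_gamma <- function(ln_omega, M1, M2, r1, r2) {
  lg <- ln_omega + log(M1 / M2) - (log(r1 / r2) + 1 - r1 / r2)
  tibble::tibble(ln_gamma_inf = lg, chi12 = lg / r1)
}

#' Reduce a table of raw IGC injections to activity coefficients
#'
#' Full reduction chain for one stationary phase (the drug): net retention
#' volume, mass activity coefficient, and residual mole-fraction activity
#' coefficient at infinite dilution, one row per probe injection.
#'
#' Lab units on input (matching the run-sheet schema): `tR_s`, `t0_s`,
#' `F_sccm` (standard cm^3/min), `m_mg`, `T_K`, and either `j` or
#' `Pi_Pa`/`Po_Pa`. Probe physical properties and descriptors are joined by
#' probe `name`.
#'
#' @param runs Data frame of injections: `probe, tR_s, t0_s, F_sccm, m_mg,
#'   T_K` plus `j` or `Pi_Pa, Po_Pa`.
#' @param drug One-row data frame with `Vx` and molar mass `M_kg_mol`.
#' @param probes Probe property table (default [psp_probe_properties()]).
#' @param descriptors Probe descriptor table (default [psp_solvents()]),
#'   used for the segment numbers.
#' @return Tibble: `probe, VN_mL_per_g, ln_omega, ln_gamma_inf, chi12`.
#' @export
reduce_igc <- function(runs, drug,
                       probes = psp_probe_properties(),
                       descriptors = psp_solvents()) {
  stopifnot(is.data.frame(runs), is.data.frame(drug), nrow(drug) == 1)
  need <- c("probe", "tR_s", "t0_s", "F_sccm", "m_mg", "T_K")
  missing_cols <- setdiff(need, names(runs))
  if (length(missing_cols)) {
    stop(sprintf("IGC run table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  j <- if ("j" %in% names(runs) && all(is.finite(runs$j))) {
    runs$j
  } else if (all(c("Pi_Pa", "Po_Pa") %in% names(runs))) {
    james_martin(runs$Pi_Pa, runs$Po_Pa)
  } else {
    rep(1, nrow(runs))
  }
  VN <- net_retention_volume(runs$tR_s, runs$t0_s,
                             F = runs$F_sccm * 1e-6 / 60,
                             m = runs$m_mg * 1e-6,
                             T = runs$T_K, j = j)
  key <- tolower(runs$probe)
  pidx <- match(key, tolower(probes$name))
  didx <- match(key, tolower(descriptors$name))
  if (anyNA(pidx) || anyNA(didx)) {
    bad <- unique(runs$probe[is.na(pidx) | is.na(didx)])
    stop(sprintf("Unknown probe(s): %s. Available: %s",
                 paste(bad, collapse = ", "),
                 paste(intersect(probes$name, descriptors$name), collapse = ", ")),
         call. = FALSE)
  }
  ln_omega <- mass_activity_coefficient(
    VN, p0 = probes$p0_Pa[pidx], M1 = probes$M_kg_mol[pidx],
    B11 = probes$B11_m3_mol[pidx], V1 = probes$V1_m3_mol[pidx], T = runs$T_K)
  r1 <- segments_from_mcgowan(descriptors$Vx[didx])
  r2 <- segments_from_mcgowan(drug$Vx)
  conv <- mole_fraction_gamma(ln_omega, M1 = probes$M_kg_mol[pidx],
                              M2 = drug$M_kg_mol, r1 = r1, r2 = r2)
  tibble::tibble(
    probe = runs$probe,
    VN_mL_per_g = VN * 1000,
    ln_omega = ln_omega,
    ln_gamma_inf = conv$ln_gamma_inf,
    chi12 = conv$chi12
  )
}
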