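#' Segment number from the McGowan characteristic volume
#'
#' Converts the McGowan volume `Vx` (in the customary (cm^3/mol)/100 units)
#' to the lattice segment number `r = Vx / 0.213` used by the association
#' and activity models.
#'
#' @param Vx McGowan characteristic volume, (cm^3/mol)/100. Vectorised.
#' @return Numeric vector of segment numbers.
#' @export
#' @examples
#' segments_from_mcgowan(0.308) # methanol, about 1.446 segments
segments_from_mcgowan <- function(Vx) {
  if (!is.numeric(Vx) || any(!is.finite(Vx)) || any(Vx <= 0)) {
    stop("`Vx` must be finite and > 0 (got a nonpositive or non-numeric value).",
         call. = FALSE)
  }
  Vx / .psp_const$seg_vol
}

#' Molar volume implied by a dispersion solvation parameter
#'
#' Inverts the dispersion-PSP definition
#' \eqn{\sigma_d = 100\sqrt{(3.1 V_x + E)/V_m}} to recover the molar volume
#' from a known dispersion parameter. Useful for drugs whose molar volume is
#' not tabulated but whose dispersion PSP is.
#'
#' @param sigma_d Dispersion partial solvation parameter, MPa^0.5.
#' @param Vx McGowan volume, (cm^3/mol)/100.
#' @param E Excess molar refraction descriptor.
#' @return Molar volume in cm^3/mol.
#' @export
#' @examples
#' vm_from_sigma_d(19.75, 3.10, 3.08) # about 325.3 cm^3/mol
vm_from_sigma_d <- function(sigma_d, Vx, E) {
  if (any(!is.finite(sigma_d)) || any(sigma_d <= 0)) {
    stop("`sigma_d` must be finite and > 0.", call. = FALSE)
  }
  10000 * (.psp_const$disp_slope * Vx + E) / sigma_d^2
}

# Shared invariant checks on LSER descriptor vectors; `where` labels the
# offending rows in error messages.
validate_lser <- function(Vx, E, S, A, B, where = "input") {
  bad <- which(!is.finite(Vx) | Vx <= 0)
  if (length(bad)) {
    stop(sprintf("%s: `Vx` must be > 0 (violated at row %s).",
                 where, paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (nm in c("E", "S", "A", "B")) {
    v <- switch(nm, E = E, S = S, A = A, B = B)
    bad <- which(is.finite(v) & v < 0)
    if (length(bad)) {
      stop(sprintf("%s: descriptor `%s` must be >= 0 (violated at row %s).",
                   where, nm, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Partial solvation parameters from LSER descriptors
#'
#' Maps Abraham-style LSER descriptors and a molar volume to the dispersion,
#' polarity, acidity and basicity partial solvation parameters:
#' \deqn{\sigma_d = 100\sqrt{(3.1 V_x + E)/V_m},\quad
#'       \sigma_p = 100\sqrt{S/V_m},\quad
#'       \sigma_{Ga} = 100\sqrt{A/V_m},\quad
#'       \sigma_{Gb} = 100\sqrt{B/V_m}.}
#' With `Vm` in cm^3/mol all four come out in MPa^0.5.
#'
#' @param Vx,E,S,A,B LSER descriptors (vectorised; `Vx` in (cm^3/mol)/100).
#' @param Vm Molar volume, cm^3/mol.
#' @param name Optional compound labels used in error messages.
#' @return A tibble with columns `sigma_d`, `sigma_p`, `sigma_Ga`, `sigma_Gb`.
#' @seealso [add_psp()] for the data-frame interface that also fills the
#'   hydrogen-bonding and total parameters.
#' @export
#' @examples
#' psp_from_lser(3.10, 3.08, 3.19, 0.50, 1.45, Vm = 325.3) # carvedilol
psp_from_lser <- function(Vx, E, S, A, B, Vm, name = NULL) {
  validate_lser(Vx, E, S, A, B, where = "psp_from_lser")
  bad <- which(!is.finite(Vm) | Vm <= 0)
  if (length(bad)) {
    lab <- if (!is.null(name)) paste(name[bad], collapse = ", ") else
      paste("row", paste(bad, collapse = ", "))
    stop(sprintf("Missing or nonpositive molar volume for: %s. Supply `Vm` or a `sigma_d` to invert.", lab),
         call. = FALSE)
  }
  k <- .psp_const$psp_scale
  tibble::tibble(
    sigma_d  = k * sqrt((.psp_const$disp_slope * Vx + E) / Vm),
    sigma_p  = k * sqrt(S / Vm),
    sigma_Ga = k * sqrt(A / Vm),
    sigma_Gb = k * sqrt(B / Vm)
  )
}

# Resolve molar volume with the precedence: explicit Vm column, else
# inversion of the dispersion PSP, else error naming the compound.
resolve_vm <- function(df) {
  Vm <- if ("Vm" %in% names(df)) df$Vm else rep(NA_real_, nrow(df))
  sd <- if ("sigma_d" %in% names(df)) df$sigma_d else rep(NA_real_, nrow(df))
  need <- !is.finite(Vm)
  can <- need & is.finite(sd) & sd > 0
  Vm[can] <- vm_from_sigma_d(sd[can], df$Vx[can], df$E[can])
  Vm
}

#' Add partial solvation parameters to a compound table
#'
#' Data-frame-first wrapper over the PSP definitions and the
#' hydrogen-bonding chain. For each row it resolves the molar volume
#' (an explicit `Vm` column wins; otherwise `Vm` is recovered from a
#' `sigma_d` column by inverting the dispersion definition), derives the
#' segment number `r`, the four Gibbs-level parameters, the
#' hydrogen-bonding cohesive parameter `sigma_hb` from the self-association
#' equilibrium, and the total `sigma_tot` in quadrature.
#'
#' @param compounds Data frame with columns `name, Vx, E, S, A, B` and at
#'   least one of `Vm`, `sigma_d`.
#' @param T Temperature in K for the self-association equilibrium
#'   (default 298.15).
#' @return The input as a tibble with columns `r`, `Vm`, `sigma_d`,
#'   `sigma_p`, `sigma_Ga`, `sigma_Gb`, `sigma_hb`, `sigma_tot` added or
#'   recomputed.
#' @export
#' @examples
#' drugs <- psp_drugs()
#' add_psp(drugs)[, c("name", "sigma_d", "sigma_p", "sigma_hb", "sigma_tot")]
add_psp <- function(compounds, T = 298.15) {
  stopifnot(is.data.frame(compounds))
  df <- tibble::as_tibble(compounds)
  validate_lser(df$Vx, df$E, df$S, df$A, df$B, where = "add_psp")
  Vm <- resolve_vm(df)
  if (any(!is.finite(Vm))) {
    who <- if ("name" %in% names(df)) df$name[!is.finite(Vm)] else
      which(!is.finite(Vm))
    stop(sprintf("No molar volume for compound(s): %s. Supply `Vm` or `sigma_d`.",
                 paste(who, collapse = ", ")), call. = FALSE)
  }
  base <- psp_from_lser(df$Vx, df$E, df$S, df$A, df$B, Vm,
                        name = if ("name" %in% names(df)) df$name else NULL)
  r <- segments_from_mcgowan(df$Vx)
  pe <- hb_pair_energy(df$A, df$B, T = T)
  frac <- pure_bond_fraction(r, pe$G_HB, T = T)
  ced <- hb_ced(frac, pe$E_HB, Vm)
  df$r <- r
  df$Vm <- Vm
  df$sigma_d <- base$sigma_d
  df$sigma_p <- base$sigma_p
  df$sigma_Ga <- base$sigma_Ga
  df$sigma_Gb <- base$sigma_Gb
  df$sigma_hb <- ced$sigma_hb
  df$sigma_tot <- sqrt(base$sigma_d^2 + base$sigma_p^2 + ced$sigma_hb^2)
  df
}

#' Read a compound table from CSV or JSON
#'
#' Reads a table with header `name,Vx,E,S,A,B` and optional columns
#' `Vm,M,Tm_K,dHm_J_mol,gamma_d_mJ_m2,sigma_d`. Blank descriptor cells are
#' interpreted as exactly zero (alkane rows legitimately leave E, S, A, B
#' empty); a missing or nonpositive `Vx` is a parse error reported with its
#' row number.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A tibble, one row per compound.
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(df) == 0) {
    return(tibble::as_tibble(df))
  }
  missing_cols <- setdiff(c("name", "Vx"), names(df))
  if (length(missing_cols)) {
    stop(sprintf("Compound table %s lacks required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (nm in c("E", "S", "A", "B")) {
    if (!nm %in% names(df)) df[[nm]] <- 0
    df[[nm]][is.na(df[[nm]])] <- 0
  }
  bad <- which(!is.finite(df$Vx) | df$Vx <= 0)
  if (length(bad)) {
    stop(sprintf("Parse error in %s: nonpositive or missing Vx at row %s.",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  neg <- which(df$E < 0 | df$S < 0 | df$A < 0 | df$B < 0)
  if (length(neg)) {
    stop(sprintf("Parse error in %s: negative descriptor at row %s.",
                 path, paste(neg, collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(df)
}

psp_extdata <- function(file) {
  system.file("extdata", file, package = "psptherm", mustWork = TRUE)
}

#' Bundled solvent and probe descriptor table
#'
#' LSER descriptors of 30 common solvents and IGC probe gases
#' (McGowan volume plus E, S, A, B; blank cells are zero).
#'
#' @return A tibble with columns `name, Vx, E, S, A, B`.
#' @export
#' @examples
#' psp_solvents()
psp_solvents <- function() read_compound_table(psp_extdata("solvents_table2.csv"))

#' Bundled drug descriptor table
#'
#' IGC-derived LSER descriptors of six poorly water-soluble model drugs
#' (carvedilol, cyclosporine A, ketoconazole, loratadine, simvastatin,
#' zafirlukast), together with their molar masses, measured dispersion
#' solvation parameters (`sigma_d`, from which the molar volume is
#' recovered) and dispersive surface energies.
#'
#' @return A tibble with columns
#'   `name, Vx, E, S, A, B, M_kg_mol, sigma_d, gamma_d_mJ_m2`.
#' @export
psp_drugs <- function() read_compound_table(psp_extdata("drugs_table3.csv"))

#' Bundled fusion data for the model drugs
#'
#' Melting onset temperatures and enthalpies of fusion. Cyclosporine A has
#' no entry (primarily amorphous solid).
#'
#' @return A tibble with columns `name, Tm_K, dHm_J_mol`.
#' @export
psp_fusion <- function() {
  readr::read_csv(psp_extdata("fusion_table4.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Reference physical properties of the IGC probe gases
#'
#' Saturation vapour pressures at 303.15 K, second virial coefficients,
#' liquid molar volumes and molar masses of the ten probe gases, compiled
#' reference estimates in SI units. These feed the IGC reduction and are
#' deliberately user-editable: replace any row with better values for your
#' instrument conditions.
#'
#' @return A tibble with columns `name, M_kg_mol, p0_Pa, B11_m3_mol, V1_m3_mol`.
#' @export
psp_probe_properties <- function() {
  readr::read_csv(psp_extdata("probes_physical.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Pick one compound row by name
#'
#' Convenience selector returning the single row of a compound table whose
#' `name` matches (case-insensitively). Unknown names raise an error that
#' lists the available compounds.
#'
#' @param compounds A compound table.
#' @param name Compound name.
#' @return A one-row tibble.
#' @export
#' @examples
#' compound_row(psp_solvents(), "Methanol")
compound_row <- function(compounds, name) {
  hit <- which(tolower(compounds$name) == tolower(name))
  if (length(hit) != 1) {
    stop(sprintf("Unknown compound '%s'. Available: %s", name,
                 paste(compounds$name, collapse = ", ")), call. = FALSE)
  }
  compounds[hit, ]
}
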