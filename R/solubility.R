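#' Ideal mole-fraction solubility of a crystalline solid
#'
#' Classical solid-liquid equilibrium estimate from fusion data only
#' (unit activity coefficients):
#' \deqn{y_1^{id} = \exp\left\{\frac{\Delta H_1^m}{RT}
#'   \left(\frac{T}{T_1^m} - 1\right)\right\},}
#' equal to 1 at the melting point.
#'
#' @param Tm Melting (onset) temperature, K.
#' @param dHm Enthalpy of fusion, J/mol.
#' @param T Temperature, K.
#' @return Ideal mole-fraction solubility (vectorised).
#' @export
#' @examples
#' ideal_solubility(407.29, 27970, 298.15) # loratadine, about 0.0486
ideal_solubility <- function(Tm, dHm, T = 298.15) {
  if (any(Tm <= 0) || any(T <= 0)) stop("`Tm` and `T` must be > 0.", call. = FALSE)
  if (any(dHm < 0)) stop("`dHm` must be >= 0.", call. = FALSE)
  exp(dHm / (.psp_const$R * T) * (T / Tm - 1))
}

#' Solve for the real solubility of a drug in a solvent
#'
#' Fixed-point solution of the solid-liquid equilibrium
#' \deqn{y_1 = \frac{1}{\gamma_1^C \gamma_1^{res}}
#'   \exp\left\{\frac{\Delta H_1^m}{RT}\left(\frac{T}{T_1^m}-1\right)\right\},}
#' with both activity coefficients evaluated at the (saturated) solution
#' composition. Iteration starts from the ideal value, is damped by 0.5,
#' capped at `y1 = 1`, and stops when successive iterates differ by less
#' than `tol`.
#'
#' @param drug One-row data frame with descriptor columns `Vx, E, S, A, B`
#'   and fusion columns `Tm_K`, `dHm_J_mol` (merge [psp_drugs()] with
#'   [psp_fusion()], or supply them directly).
#' @param solvent One-row data frame with `Vx, E, S, A, B`.
#' @param T Temperature, K.
#' @param tol Convergence tolerance on `|dy|`.
#' @param max_iter Iteration cap.
#' @return One-row tibble: `y1`, `ideal_y1`, `gamma_C`, `gamma_res`
#'   (at the converged composition), `chi12`, `iterations`, `converged`.
#' @export
#' @examples
#' drug <- dplyr::left_join(psp_drugs(), psp_fusion(), by = "name")
#' solve_solubility(compound_row(drug, "Loratadine"),
#'                  compound_row(psp_solvents(), "Ethanol"))
solve_solubility <- function(drug, solvent, T = 298.15,
                             tol = 1e-10, max_iter = 500L) {
  stopifnot(is.data.frame(drug), nrow(drug) == 1,
            is.data.frame(solvent), nrow(solvent) == 1)
  if (!all(c("Tm_K", "dHm_J_mol") %in% names(drug)) ||
      !is.finite(drug$Tm_K) || !is.finite(drug$dHm_J_mol)) {
    who <- if ("name" %in% names(drug)) drug$name else "drug"
    stop(sprintf("No fusion data (Tm_K, dHm_J_mol) for %s; cannot compute solubility.", who),
         call. = FALSE)
  }
  ideal <- ideal_solubility(drug$Tm_K, drug$dHm_J_mol, T)
  y <- min(ideal, 1)
  it <- 0L
  conv <- FALSE
  parts <- NULL
  repeat {
    it <- it + 1L
    parts <- lngamma_parts_scalar(drug, solvent, max(y, 1e-12), T)
    y_new <- min(ideal / exp(parts$ln_gamma_total), 1)
    y_damp <- 0.5 * y + 0.5 * y_new
    if (abs(y_damp - y) < tol) {
      y <- y_damp
      conv <- TRUE
      break
    }
    y <- y_damp
    if (it >= max_iter) break
  }
  if (!conv) {
    stop(sprintf("Solubility iteration did not converge in %d steps (last y1 = %.4g).",
                 max_iter, y), call. = FALSE)
  }
  tibble::tibble(
    y1 = y,
    ideal_y1 = ideal,
    gamma_C = exp(parts$ln_gamma_C),
    gamma_res = exp(parts$ln_gamma_res),
    chi12 = parts$chi12,
    iterations = it,
    converged = conv
  )
}

#' Predicted solubility of one drug across a table of solvents
#'
#' Batch wrapper over [solve_solubility()]: one row per solvent, ranked by
#' predicted mole-fraction solubility.
#'
#' @param drug One-row data frame (descriptors + fusion columns).
#' @param solvents Data frame of solvents (`name, Vx, E, S, A, B`).
#' @param T Temperature, K.
#' @return Tibble with `solvent`, the [solve_solubility()] columns and
#'   `log10_y1`, sorted by decreasing `y1`.
#' @export
predict_solubility <- function(drug, solvents, T = 298.15) {
  out <- purrr::map_dfr(seq_len(nrow(solvents)), function(i) {
    res <- solve_solubility(drug, solvents[i, ], T)
    dplyr::bind_cols(tibble::tibble(solvent = solvents$name[i]), res)
  })
  out$log10_y1 <- log10(out$y1)
  dplyr::arrange(out, dplyr::desc(.data$y1))
}

#' Summary statistics for predicted vs. experimental solubilities
#'
#' Ordinary least squares of experimental on predicted log10 solubility,
#' Pearson correlation and the mean absolute error of the log residuals.
#' Rows named in `exclude` (e.g. cases with solvent-mediated solid-form
#' changes) are dropped before fitting.
#'
#' @param data Data frame holding the two columns.
#' @param predicted,experimental Column names (tidy-eval) of predicted and
#'   experimental log10 solubilities.
#' @param exclude Optional character vector of `name`/`label` values to
#'   drop (matched against a `name` column when present).
#' @return One-row glance-style tibble: `n`, `r`, `slope`, `intercept`,
#'   `mae`.
#' @export
#' @examples
#' d <- tibble::tibble(pred = c(-1, 0, 1), obs = c(-1.1, 0.2, 0.9))
#' evaluate_predictions(d, pred, obs)
evaluate_predictions <- function(data, predicted, experimental, exclude = NULL) {
  pred <- rlang::eval_tidy(rlang::enquo(predicted), data)
  obs <- rlang::eval_tidy(rlang::enquo(experimental), data)
  keep <- rep(TRUE, length(pred))
  if (!is.null(exclude) && "name" %in% names(data)) {
    keep <- !(data$name %in% exclude)
  }
  pred <- pred[keep]
  obs <- obs[keep]
  if (length(pred) < 3) stop("Need at least 3 pairs.", call. = FALSE)
  fit <- stats::lm(obs ~ pred)
  tibble::tibble(
    n = length(pred),
    r = stats::cor(pred, obs),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    mae = mean(abs(obs - pred))
  )
}
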