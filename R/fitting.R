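# Model ln gamma^inf for every probe, given the drug's current descriptors.
fit_model_lngamma <- function(probe_data, Vx2, E2, S2, A2, B2, T) {
  lngamma_inf_vec(probe_data$Vx, probe_data$E, probe_data$S,
                  probe_data$A, probe_data$B,
                  Vx2, E2, S2, A2, B2, T)
}

check_probe_data <- function(probe_data, n_min = 2) {
  need <- c("Vx", "E", "S", "A", "B", "ln_gamma")
  missing_cols <- setdiff(need, names(probe_data))
  if (length(missing_cols)) {
    stop(sprintf("Probe data lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(probe_data) < n_min) {
    stop(sprintf("Need at least %d probes (got %d): the fit is underdetermined.",
                 n_min, nrow(probe_data)), call. = FALSE)
  }
  invisible(TRUE)
}

# Bounded Levenberg-Marquardt least squares with deterministic multistart.
# Ties broken by lowest rms, then by the smallest parameter sum.
multistart_lm <- function(resid_fn, starts, lower, upper = NULL) {
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rms <- sqrt(mean(fit$fvec^2))
    if (is.null(best) || rms < best$rms - 1e-12 ||
        (abs(rms - best$rms) <= 1e-12 && sum(fit$par) < sum(best$par))) {
      best <- list(par = pmax(fit$par, 0), rms = rms)
    }
  }
  if (is.null(best)) stop("All least-squares starts failed.", call. = FALSE)
  best
}

#' Fit the refraction and polarity descriptors from IGC data
#'
#' Stage-1 estimation: nonnegative least squares for the stationary phase's
#' `E` and `S` descriptors against measured infinite-dilution activity
#' coefficients, holding the hydrogen-bonding descriptors `A`, `B` fixed
#' (the drug self-association term they induce is part of the model).
#' Hydrocarbon probes alone constrain only the sum of the dispersion and
#' polarity brackets; include polar or aromatic probes to separate `E`
#' from `S`.
#'
#' @param probe_data Tibble with probe descriptors `Vx, E, S, A, B` and the
#'   measured `ln_gamma` (one row per probe).
#' @param Vx McGowan volume of the stationary phase.
#' @param A,B Fixed hydrogen-bonding descriptors of the stationary phase.
#' @param T Column temperature, K.
#' @param starts Optional list of numeric start points for the bounded
#'   least squares; defaults to five deterministic points including zero.
#' @return List with `E`, `S`, `rms_residual`.
#' @export
fit_dispersion_polar <- function(probe_data, Vx, A = 0, B = 0, T = 303.15,
                                 starts = NULL) {
  check_probe_data(probe_data, n_min = 2)
  resid_fn <- function(p) {
    fit_model_lngamma(probe_data, Vx, p[1], p[2], A, B, T) - probe_data$ln_gamma
  }
  if (is.null(starts)) starts <- list(c(0, 0), c(1, 1), c(3, 3), c(1, 5), c(5, 1))
  best <- multistart_lm(resid_fn, starts, lower = c(0, 0))
  list(E = best$par[1], S = best$par[2], rms_residual = best$rms)
}

#' Fit the hydrogen-bond acidity and basicity descriptors from IGC data
#'
#' Stage-2 estimation: bounded nonlinear least squares for `A` and `B` of
#' the stationary phase with `E` and `S` held fixed. The drug's `A` is
#' sensed by basic probes (probe `B > 0`, cross-association) and its `B`
#' by acidic probes (probe `A > 0`); homosolvating probes and the drug's
#' own self-association constrain both. A panel lacking acidic or basic
#' probes triggers an identifiability warning.
#'
#' @inheritParams fit_dispersion_polar
#' @param E,S Fixed refraction/polarity descriptors of the stationary phase.
#' @return List with `A`, `B`, `rms_residual`.
#' @export
fit_acid_base <- function(probe_data, Vx, E, S, T = 303.15, starts = NULL) {
  check_probe_data(probe_data, n_min = 2)
  if (all(probe_data$B == 0)) {
    warning("No basic probes in the panel: the fitted `A` is weakly identified.",
            call. = FALSE)
  }
  if (all(probe_data$A == 0)) {
    warning("No acidic probes in the panel: the fitted `B` is weakly identified.",
            call. = FALSE)
  }
  resid_fn <- function(p) {
    fit_model_lngamma(probe_data, Vx, E, S, p[1], p[2], T) - probe_data$ln_gamma
  }
  if (is.null(starts)) {
    starts <- list(c(0, 0), c(0.5, 0.5), c(0.2, 1.5), c(1, 0.3), c(0.7, 3))
  }
  best <- multistart_lm(resid_fn, starts, lower = c(0, 0))
  list(A = best$par[1], B = best$par[2], rms_residual = best$rms)
}

# Numeric Jacobian of the residual vector at the solution, for Wald
# standard errors of the four descriptors.
fit_std_errors <- function(probe_data, Vx, par, T) {
  n <- nrow(probe_data)
  p <- length(par)
  J <- matrix(0, n, p)
  h <- pmax(1e-6, 1e-6 * abs(par))
  for (k in seq_len(p)) {
    up <- par; up[k] <- up[k] + h[k]
    dn <- par; dn[k] <- max(dn[k] - h[k], 0)
    J[, k] <- (fit_model_lngamma(probe_data, Vx, up[1], up[2], up[3], up[4], T) -
                 fit_model_lngamma(probe_data, Vx, dn[1], dn[2], dn[3], dn[4], T)) /
      (up[k] - dn[k])
  }
  res <- fit_model_lngamma(probe_data, Vx, par[1], par[2], par[3], par[4], T) -
    probe_data$ln_gamma
  df <- max(n - p, 1)
  sigma2 <- sum(res^2) / df
  se <- tryCatch(sqrt(diag(sigma2 * solve(crossprod(J)))),
                 error = function(e) rep(NA_real_, p))
  se
}

#' Estimate all four LSER descriptors of a stationary phase from IGC data
#'
#' Alternates [fit_dispersion_polar()] (stage 1: `E`, `S`) and
#' [fit_acid_base()] (stage 2: `A`, `B`), both evaluated on the full probe
#' panel so each stage is an exact block-coordinate-descent step on one
#' least-squares objective, until the descriptors change by less than
#' `tol` or `max_outer` rounds are reached.
#'
#' @inheritParams fit_dispersion_polar
#' @param tol Convergence tolerance on the largest descriptor change.
#' @param max_outer Cap on outer alternation rounds.
#' @return An object of class `psp_fit` with elements `descriptors`
#'   (tibble `term, estimate, std_error`), `residuals` (per-probe tibble),
#'   `rms_residual`, `trace` (per-round descriptor values and rms),
#'   `converged`, `iterations`, `Vx`, `T`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' truth <- tibble::tibble(Vx = 3.10, E = 3.08, S = 3.19, A = 0.50, B = 1.45)
#' dat <- generate_synthetic_igc(truth, psp_solvents()[c(2:5, 11, 17:20), ])
#' fit <- fit_descriptors(dat, Vx = 3.10)
#' tidy(fit)
fit_descriptors <- function(probe_data, Vx, T = 303.15,
                            tol = 1e-8, max_outer = 50L) {
  check_probe_data(probe_data, n_min = 4)
  par <- c(E = 0, S = 0, A = 0, B = 0)
  trace <- vector("list", max_outer)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_outer)) {
    # full multistart on the first round; warm single start afterwards
    st1 <- if (it > 1) list(unname(par[c("E", "S")])) else NULL
    st2 <- if (it > 1) list(unname(par[c("A", "B")])) else NULL
    s1 <- fit_dispersion_polar(probe_data, Vx, A = par["A"], B = par["B"],
                               T = T, starts = st1)
    s2 <- suppressWarnings(
      fit_acid_base(probe_data, Vx, E = s1$E, S = s1$S, T = T, starts = st2))
    new <- c(E = s1$E, S = s1$S, A = s2$A, B = s2$B)
    trace[[it]] <- tibble::tibble(
      outer = it, E = new["E"], S = new["S"], A = new["A"], B = new["B"],
      rms = s2$rms_residual)
    delta <- max(abs(new - par))
    par <- new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # joint refinement: the alternation can park E or S on the zero bound in
  # a shallow local minimum; polish all four descriptors together from the
  # alternation result plus deterministic multistart points
  joint_resid <- function(p) {
    fit_model_lngamma(probe_data, Vx, p[1], p[2], p[3], p[4], T) -
      probe_data$ln_gamma
  }
  joint_starts <- list(unname(par), c(0, 0, 0, 0), c(2, 4, 0.3, 1),
                       c(4, 6, 0.6, 3), c(1, 3, 0.1, 0.5), c(3, 5, 0.7, 2))
  joint <- multistart_lm(joint_resid, joint_starts, lower = rep(0, 4))
  if (joint$rms <= sqrt(mean(joint_resid(unname(par))^2)) + 1e-12) {
    par <- setNames(joint$par, c("E", "S", "A", "B"))
  }
  if (!converged) {
    # one verification round from the polished point
    v1 <- fit_dispersion_polar(probe_data, Vx, A = par["A"], B = par["B"],
                               T = T, starts = list(unname(par[c("E", "S")])))
    v2 <- suppressWarnings(
      fit_acid_base(probe_data, Vx, E = v1$E, S = v1$S, T = T,
                    starts = list(unname(par[c("A", "B")]))))
    converged <- max(abs(c(v1$E, v1$S, v2$A, v2$B) - unname(par))) < sqrt(tol)
  }
  trace[[it]] <- dplyr::bind_rows(
    trace[[it]],
    tibble::tibble(outer = it + 1L, E = par["E"], S = par["S"],
                   A = par["A"], B = par["B"], rms = joint$rms))
  fitted <- fit_model_lngamma(probe_data, Vx, par["E"], par["S"],
                              par["A"], par["B"], T)
  resid <- fitted - probe_data$ln_gamma
  se <- fit_std_errors(probe_data, Vx, unname(par), T)
  out <- list(
    descriptors = tibble::tibble(
      term = c("E", "S", "A", "B"),
      estimate = unname(par),
      std_error = se),
    residuals = tibble::tibble(
      probe = if ("name" %in% names(probe_data)) probe_data$name else
        paste0("probe", seq_len(nrow(probe_data))),
      observed = probe_data$ln_gamma,
      fitted = fitted,
      residual = resid),
    rms_residual = sqrt(mean(resid^2)),
    trace = dplyr::bind_rows(trace[seq_len(it)]),
    converged = converged,
    iterations = it,
    Vx = Vx,
    T = T)
  class(out) <- "psp_fit"
  out
}

#' @export
print.psp_fit <- function(x, ...) {
  cat(sprintf("<psp_fit> LSER descriptors from %d probes (Vx = %.3g, T = %.2f K)\n",
              nrow(x$residuals), x$Vx, x$T))
  print(x$descriptors)
  cat(sprintf("rms residual %.4g (ln gamma units), %d outer rounds%s\n",
              x$rms_residual, x$iterations,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' Tidy a descriptor fit
#'
#' Descriptor estimates and Wald standard errors, one row per term.
#'
#' @param x A `psp_fit` from [fit_descriptors()].
#' @param ... Unused.
#' @return Tibble with `term, estimate, std_error`.
#' @export
tidy.psp_fit <- function(x, ...) x$descriptors

#' Glance at a descriptor fit
#'
#' One-row fit summary.
#'
#' @param x A `psp_fit` from [fit_descriptors()].
#' @param ... Unused.
#' @return Tibble with `rms_residual, n_probes, iterations, converged`.
#' @export
glance.psp_fit <- function(x, ...) {
  tibble::tibble(
    rms_residual = x$rms_residual,
    n_probes = nrow(x$residuals),
    iterations = x$iterations,
    converged = x$converged)
}

#' Drop-one-probe stability of a descriptor fit
#'
#' Refits the descriptors leaving each probe out in turn (the jackknife),
#' reporting the descriptor estimates per leave-out. Large swings flag
#' probes that dominate the fit.
#'
#' @inheritParams fit_descriptors
#' @return Tibble: `left_out`, `E`, `S`, `A`, `B`, `rms_residual`.
#' @export
jackknife_descriptors <- function(probe_data, Vx, T = 303.15) {
  purrr::map_dfr(seq_len(nrow(probe_data)), function(i) {
    f <- fit_descriptors(probe_data[-i, ], Vx, T = T)
    est <- f$descriptors$estimate
    tibble::tibble(
      left_out = if ("name" %in% names(probe_data)) probe_data$name[i] else i,
      E = est[1], S = est[2], A = est[3], B = est[4],
      rms_residual = f$rms_residual)
  })
}

#' Generate a synthetic IGC infinite-dilution data set
#'
#' Computes noise-free infinite-dilution activity coefficients of a probe
#' panel in a hypothetical stationary phase with known ("truth")
#' descriptors, then adds i.i.d. Gaussian noise of standard deviation
#' `noise_sd` (in ln-gamma units). Regenerating with the same seed
#' reproduces the values bit-identically.
#'
#' @param truth One-row data frame with the stationary phase's
#'   `Vx, E, S, A, B`.
#' @param probes Probe descriptor table (`name, Vx, E, S, A, B`), e.g. a
#'   subset of [psp_solvents()].
#' @param noise_sd Gaussian noise standard deviation, ln-gamma units.
#' @param seed Optional integer seed (local to this call).
#' @param T Column temperature, K.
#' @return A tibble (`name, Vx, E, S, A, B, ln_gamma_true, ln_gamma`) with
#'   attributes `truth`, `noise_sd`, `seed`, ready for [fit_descriptors()].
#' @export
generate_synthetic_igc <- function(truth, probes, noise_sd = 0, seed = NULL,
                                   T = 303.15) {
  stopifnot(is.data.frame(truth), nrow(truth) == 1, is.data.frame(probes))
  clean <- lngamma_inf_vec(probes$Vx, probes$E, probes$S, probes$A, probes$B,
                           truth$Vx, truth$E, truth$S, truth$A, truth$B, T)
  noise <- if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      } else NULL
      on.exit(
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
        add = TRUE)
      set.seed(seed)
    }
    stats::rnorm(length(clean), 0, noise_sd)
  } else {
    numeric(length(clean))
  }
  out <- tibble::tibble(
    name = if ("name" %in% names(probes)) probes$name else
      paste0("probe", seq_len(nrow(probes))),
    Vx = probes$Vx, E = probes$E, S = probes$S,
    A = probes$A, B = probes$B,
    ln_gamma_true = clean,
    ln_gamma = clean + noise)
  attr(out, "truth") <- truth
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  out
}

#' Monte-Carlo recovery study for the descriptor-fitting pipeline
#'
#' Draws random truth descriptor sets (in drug-like ranges, away from the
#' nonnegativity bounds so sampling theory applies), simulates `n_rep`
#' noisy IGC data sets per truth with [generate_synthetic_igc()], refits
#' each with [fit_descriptors()], and measures recovery. The standard
#' error per truth and coordinate is the empirical sampling standard
#' deviation over the replicates; `hit` records whether every coordinate
#' of a replicate's estimate lies within 3 such standard errors of the
#' truth.
#'
#' @param panel Probe descriptor table (default the measured ten-probe
#'   panel rows of [psp_solvents()]).
#' @param n_truth Number of random truth vectors.
#' @param n_rep Noisy replicates per truth.
#' @param noise_sd Gaussian noise SD on ln gamma.
#' @param seed Integer seed controlling truths and noise.
#' @param T Column temperature, K.
#' @return Tibble, one row per replicate: truth id, truth and estimated
#'   `E, S, A, B`, per-truth empirical `se_*`, and `hit`.
#' @export
descriptor_recovery_study <- function(panel, n_truth = 8, n_rep = 25,
                                      noise_sd = 0.05, seed = 1, T = 303.15) {
  set.seed(seed)
  out <- vector("list", n_truth)
  for (tr in seq_len(n_truth)) {
    truth <- tibble::tibble(
      Vx = stats::runif(1, 2.8, 8), E = stats::runif(1, 1.3, 4.3),
      S = stats::runif(1, 2.7, 7.8), A = stats::runif(1, 0.2, 0.8),
      B = stats::runif(1, 0.6, 2.5))
    tvec <- c(truth$E, truth$S, truth$A, truth$B)
    est <- matrix(0, n_rep, 4)
    for (b in seq_len(n_rep)) {
      dat <- generate_synthetic_igc(truth, panel, noise_sd = noise_sd,
                                    seed = seed * 100000L + tr * 1000L + b,
                                    T = T)
      est[b, ] <- fit_descriptors(dat, Vx = truth$Vx, T = T)$descriptors$estimate
    }
    se <- apply(est, 2, stats::sd)
    out[[tr]] <- tibble::tibble(
      truth_id = tr, rep = seq_len(n_rep),
      E_true = tvec[1], S_true = tvec[2], A_true = tvec[3], B_true = tvec[4],
      E = est[, 1], S = est[, 2], A = est[, 3], B = est[, 4],
      se_E = se[1], se_S = se[2], se_A = se[3], se_B = se[4],
      hit = apply(est, 1, function(e) all(abs(e - tvec) <= 3 * se)))
  }
  dplyr::bind_rows(out)
}
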