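#' Fixed constants of the enzyme-limited C4 model
#'
#' The bundle-sheath oxygen partial pressure, bundle-sheath conductance,
#' mesophyll conductance and mesophyll respiration are held fixed across
#' water and temperature treatments in the enzyme-limited C4 model.
#' Defaults: O = 210 mbar (21 kPa), \eqn{g_{bs}} = 3 mmol m-2 s-1,
#' \eqn{g_m} = 2 mol m-2 s-1.  \eqn{R_m}, the mesophyll fraction of day
#' respiration, defaults to \eqn{0.5 R_L} at fit time when left `NA`.
#'
#' @param O_Pa bundle-sheath/mesophyll oxygen partial pressure, Pa.
#' @param gbs bundle-sheath conductance to CO2, mol m-2 s-1.
#' @param gm mesophyll conductance to CO2, mol m-2 s-1 (mole-fraction
#'   basis).
#' @param Rm mesophyll respiration, umol m-2 s-1, or `NA` for the
#'   \eqn{0.5 R_L} convention.
#' @return A list of class `c4_constants`.
#' @export
c4_constants <- function(O_Pa = 21000, gbs = 0.003, gm = 2, Rm = NA_real_) {
  .stopifnot_positive(O_Pa = O_Pa, gbs = gbs, gm = gm)
  structure(list(O_Pa = O_Pa, gbs = gbs, gm = gm, Rm = Rm),
            class = "c4_constants")
}

#' Enzyme-limited C4 forward model
#'
#' Solves the coupled mesophyll/bundle-sheath system for net assimilation
#' at each intercellular CO2 level:
#' \deqn{A = g_m (C_i - C_m)}
#' \deqn{A = \frac{C_s V_{cmax}}{C_s + K_c(1+O/K_o)}
#'           \left(1 - \frac{\gamma^* O}{C_s}\right) - R_L}
#' \deqn{A = \frac{C_m V_{pmax}}{C_m + K_p} - g_{bs}(C_s - C_m) - R_m}
#' `Ci`, `Cm` and `Cs` are carried as mole fractions (umol mol-1), matching
#' the conductance bases; the Rubisco and PEPC kinetic terms convert to
#' partial pressures through `Patm_kPa`.  \eqn{\gamma^*} enters as the
#' dimensionless \eqn{\Gamma^*/O}.  The solution is found by monotone
#' bisection on A within the physical bracket (the bundle-sheath supply
#' makes the residual strictly decreasing in A), vectorized over points.
#'
#' @param Ci intercellular CO2, umol mol-1.
#' @param Vcmax,Vpmax maximum Rubisco and PEPC carboxylation velocities,
#'   umol m-2 s-1.
#' @param RL day respiration, umol m-2 s-1.
#' @param kin a [kinetic_set()] carrying `Kc`, `Ko`, `gammastar` and `Kp`.
#' @param const a [c4_constants()].
#' @param Patm_kPa atmospheric pressure, kPa.
#' @return A data frame with columns `Ci`, `A` (umol m-2 s-1), `Cm`, `Cs`
#'   (umol mol-1).
#' @export
c4_forward <- function(Ci, Vcmax, Vpmax, RL = 0, kin, const = c4_constants(),
                       Patm_kPa = 101.325) {
  .stopifnot_positive(Ci = Ci, Vcmax = Vcmax, Vpmax = Vpmax)
  if (is.na(kin$Kp)) stop("kinetic set lacks Kp (PEPC constant)", call. = FALSE)
  Rm <- if (is.na(const$Rm)) 0.5 * RL else const$Rm
  to_pa <- Patm_kPa / 1000
  Km_Pa <- kin$Kc * (1 + (const$O_Pa / 1000) / kin$Ko)
  gstar_frac <- kin$gammastar / .O2_PA  # dimensionless gamma*
  n <- length(Ci)

  bs_rate <- function(A) {
    Cm <- Ci - A / const$gm
    Cm_Pa <- Cm * to_pa
    Vp <- ifelse(Cm > 0, Cm_Pa * Vpmax / (Cm_Pa + kin$Kp), 0)
    Cs <- Cm + (Vp - A - Rm) / const$gbs
    Cs_Pa <- Cs * to_pa
    Ar <- ifelse(Cs > 0,
                 Vcmax * Cs_Pa / (Cs_Pa + Km_Pa) *
                   (1 - gstar_frac * const$O_Pa / Cs_Pa) - RL,
                 -1e6)
    list(Ar = Ar, Cm = Cm, Cs = Cs)
  }
  lo <- rep(-RL - Rm - 5, n)
  hi <- rep(Vcmax, n)
  f_lo <- bs_rate(lo)$Ar - lo
  f_hi <- bs_rate(hi)$Ar - hi
  if (any(f_lo < 0) || any(f_hi > 0)) {
    bad <- which(f_lo < 0 | f_hi > 0)
    stop(sprintf(
      "no assimilation root in [%.1f, %.1f] for Ci = %s (residuals %g, %g)",
      lo[1], hi[1], paste(signif(Ci[bad], 3), collapse = ", "),
      f_lo[bad[1]], f_hi[bad[1]]), call. = FALSE)
  }
  for (iter in 1:70) {
    mid <- 0.5 * (lo + hi)
    fm <- bs_rate(mid)$Ar - mid
    up <- fm > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  A <- 0.5 * (lo + hi)
  st <- bs_rate(A)
  data.frame(Ci = Ci, A = A, Cm = st$Cm, Cs = st$Cs)
}

#' Smooth an A-Ci curve onto a regular grid
#'
#' Fits a non-rectangular hyperbola
#' \eqn{A(C_i) = \frac{\phi C_i + A_{max} - \sqrt{(\phi C_i + A_{max})^2 -
#' 4\theta\phi C_i A_{max}}}{2\theta} - R_d}
#' to the observed points and evaluates it on a grid spanning the observed
#' Ci range with the given step (default 5 umol mol-1).  If the hyperbola
#' fit does not converge the function falls back to monotone linear
#' interpolation with a warning.
#'
#' @param Ci,A observed curve.
#' @param step grid step, umol mol-1.
#' @return A data frame `Ci`, `A` on the grid, with the fit's residual RMS
#'   in the `"rms"` attribute.
#' @export
smooth_aci <- function(Ci, A, step = 5) {
  ok <- is.finite(Ci) & is.finite(A)
  Ci <- Ci[ok]; A <- A[ok]
  if (length(Ci) < 6) stop("at least 6 points are required", call. = FALSE)
  grid <- seq(min(Ci), max(Ci), by = step)
  nrh <- function(Ci, phi, Amax, theta, Rd) {
    s <- phi * Ci + Amax
    (s - sqrt(pmax(s^2 - 4 * theta * phi * Ci * Amax, 0))) / (2 * theta) - Rd
  }
  start <- list(phi = max((max(A) - min(A)) / (stats::quantile(Ci, 0.4) - min(Ci)), 0.01),
                Amax = max(A) + max(0, -min(A)) + 1,
                theta = 0.7, Rd = max(0.5, -min(A)))
  fit <- tryCatch(
    minpack.lm::nlsLM(A ~ nrh(Ci, phi, Amax, theta, Rd),
                      data = data.frame(Ci = Ci, A = A), start = start,
                      lower = c(1e-4, 1e-3, 0.01, 0), upper = c(10, 200, 0.999, 20),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("non-rectangular hyperbola did not converge; ",
            "falling back to linear interpolation")
    out <- data.frame(Ci = grid,
                      A = stats::approx(Ci, A, xout = grid, ties = mean)$y)
    attr(out, "rms") <- NA_real_
    return(out)
  }
  out <- data.frame(Ci = grid, A = stats::predict(fit, list(Ci = grid)))
  attr(out, "rms") <- sqrt(mean(stats::resid(fit)^2))
  out
}

#' Fit the enzyme-limited C4 model
#'
#' Joint least-squares estimation of \eqn{V_{cmax}} and \eqn{V_{pmax}}
#' through the coupled forward model [c4_forward()].  By default the
#' observed curve is first smoothed onto a 5 umol mol-1 grid with
#' [smooth_aci()] and the model is fitted to the gridded curve; set
#' `smooth = FALSE` to fit the raw points (sensitivity checks).  The fit is
#' a deterministic multi-start bounded optimization.  \eqn{V_{pmax}} is
#' identified by the initial slope: a curve without points at
#' Ci <= 100 umol mol-1 is flagged.
#'
#' @param Ci,A observed curve (umol mol-1, umol m-2 s-1), or pass an
#'   [aci_curve()] as `Ci`.
#' @param kin a [kinetic_set()] with `Kp`.
#' @param const a [c4_constants()].
#' @param RL day respiration, umol m-2 s-1.
#' @param smooth fit on the smoothed grid (default) or the raw points.
#' @param step grid step for smoothing.
#' @param Patm_kPa atmospheric pressure, kPa.
#' @return A `c4_fit` object: estimates, standard errors, per-point `Cm`
#'   and `Cs`, residual SSE and identifiability flag.
#' @export
fit_c4 <- function(Ci, A = NULL, kin, const = c4_constants(), RL = 0,
                   smooth = TRUE, step = 5, Patm_kPa = 101.325) {
  if (inherits(Ci, "aci_curve")) {
    curve <- Ci
    A <- curve$points$AN
    Patm_kPa <- stats::median(curve$points$Patm_kPa)
    Ci <- curve$points$Ci
  }
  ok <- is.finite(Ci) & is.finite(A)
  Ci <- Ci[ok]; A <- A[ok]
  vpmax_identifiable <- min(Ci) <= 100
  if (!vpmax_identifiable) {
    warning("no points at Ci <= 100 umol mol-1: Vpmax poorly identified")
  }
  if (smooth) {
    sm <- smooth_aci(Ci, A, step = step)
    Ci_fit <- sm$Ci; A_fit <- sm$A
  } else {
    Ci_fit <- Ci; A_fit <- A
  }
  model <- function(par) {
    c4_forward(Ci_fit, par[1], par[2], RL, kin, const, Patm_kPa)$A
  }
  sse <- function(par) {
    r <- tryCatch(sum((A_fit - model(par))^2), error = function(e) Inf)
    if (!is.finite(r)) Inf else r
  }
  grid <- expand.grid(Vcmax = c(10, 20, 35, 55, 80),
                      Vpmax = c(30, 70, 130, 220))
  best <- .multistart_optim(sse, grid, lower = c(1, 1), upper = c(500, 1500),
                            n_polish = 2)
  if (is.null(best) || !is.finite(best$value)) {
    stop("C4 fit failed to converge from every start", call. = FALSE)
  }
  par <- best$par
  sol <- c4_forward(Ci, par[1], par[2], RL, kin, const, Patm_kPa)
  se <- .ls_se(function(p) A_fit - model(p), par, best$value, length(A_fit))
  structure(
    list(Vcmax = par[1], Vpmax = par[2],
         Vcmax_SE = se[1], Vpmax_SE = se[2], RL = RL,
         Cm = sol$Cm, Cs = sol$Cs, Ci = Ci, A = A, fitted = sol$A,
         residual_sse = best$value,
         vpmax_identifiable = vpmax_identifiable,
         smoothed = smooth, kin = kin, const = const),
    class = "c4_fit")
}

#' @export
print.c4_fit <- function(x, ...) {
  cat("Enzyme-limited C4 fit\n")
  cat(sprintf("  Vcmax = %.1f +/- %.1f, Vpmax = %.1f +/- %.1f umol m-2 s-1\n",
              x$Vcmax, x$Vcmax_SE, x$Vpmax, x$Vpmax_SE))
  cat(sprintf("  RL = %.2f, SSE = %.3g%s\n", x$RL, x$residual_sse,
              if (x$vpmax_identifiable) "" else ", Vpmax NOT identifiable"))
  invisible(x)
}

#' Full C4 pipeline on an A-Ci curve
#'
#' Resolves the kinetic constants at the measurement temperature
#' (species-specific maize constants or the von Caemmerer standards), takes
#' \eqn{R_L = R_{dark}/2} and fits the enzyme-limited C4 model.
#'
#' @param curve an [aci_curve()].
#' @param kinetics `"own"` or `"voncaemmerer"`.
#' @param const a [c4_constants()].
#' @param ... passed to [fit_c4()].
#' @return A `c4_fit`.
#' @export
fit_aci_c4 <- function(curve, kinetics = "own", const = c4_constants(), ...) {
  stopifnot(inherits(curve, "aci_curve"))
  kin <- resolve_kinetics(kinetics, curve$species, curve$meas_T)
  fit <- fit_c4(curve, kin = kin, const = const,
                RL = rl_from_rdark(curve$Rdark), ...)
  fit$kinetics_source <- kinetics
  fit$curve_id <- curve$curve_id
  fit$species <- curve$species
  fit$meas_T <- curve$meas_T
  fit
}
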