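#' Day respiration from pre-dawn dark respiration
#'
#' The non-photorespiratory CO2 release in the light (\eqn{R_L}) is taken as
#' half of the pre-dawn mitochondrial dark respiration measured at the same
#' leaf temperature.
#'
#' @param Rdark pre-dawn dark respiration, umol m-2 s-1 (non-negative).
#' @return \eqn{R_L}, umol m-2 s-1.
#' @export
rl_from_rdark <- function(Rdark) {
  .stopifnot_positive(Rdark = Rdark, .allow_zero = TRUE)
  Rdark / 2
}

#' Variable-J mesophyll conductance
#'
#' Per-point estimation of mesophyll conductance from combined gas exchange
#' and fluorescence:
#' \deqn{g_m = \frac{A_N}{C_i - \Gamma^* \frac{ETR + 8(A_N + R_L)}
#'   {ETR - 4(A_N + R_L)}}}
#' `Ci` and `gamma_star` must share one unit (Pa or umol mol-1); the
#' returned conductance is then per that unit (e.g. mol m-2 s-1 on a
#' mole-fraction basis when both are in umol mol-1).
#'
#' Points violating the admissibility conditions (\eqn{ETR > 4(A_N+R_L)},
#' positive denominator, positive resulting conductance) are returned as
#' `NA` and flagged in the `"admissible"` attribute rather than raising an
#' error: a measured curve routinely contains a few such points near the
#' compensation point or at saturating CO2.
#'
#' @param AN net assimilation, umol m-2 s-1.
#' @param Ci intercellular CO2 (Pa or umol mol-1).
#' @param ETR linear electron transport rate, umol m-2 s-1.
#' @param RL day respiration, umol m-2 s-1.
#' @param gamma_star \eqn{\Gamma^*} in the same unit as `Ci`.
#' @return Numeric vector of per-point \eqn{g_m} with a logical
#'   `"admissible"` attribute.
#' @export
gm_variable_j <- function(AN, Ci, ETR, RL, gamma_star) {
  .stopifnot_positive(Ci = Ci, gamma_star = gamma_star)
  surplus <- ETR - 4 * (AN + RL)
  denom <- Ci - gamma_star * (ETR + 8 * (AN + RL)) / surplus
  gm <- ifelse(AN == 0, 0, AN / denom)
  ok <- is.finite(gm) & surplus > 0 & denom > 0 & gm >= 0
  gm[!ok] <- NA_real_
  attr(gm, "admissible") <- ok
  gm
}

#' Chloroplastic CO2 from intercellular CO2
#'
#' \eqn{C_c = C_i - A_N/g_m}.  Units of `Ci` and of the conductance basis
#' must agree (both mole-fraction or both pressure).  Points whose resulting
#' \eqn{C_c} is non-positive are returned as computed but flagged in the
#' `"valid"` attribute.
#'
#' @param Ci intercellular CO2.
#' @param AN net assimilation, umol m-2 s-1.
#' @param gm mesophyll conductance (scalar or per-point).
#' @return \eqn{C_c} in the unit of `Ci`, with a logical `"valid"` attribute.
#' @export
cc_from_ci <- function(Ci, AN, gm) {
  .stopifnot_positive(gm = gm)
  Cc <- Ci - AN / gm
  attr(Cc, "valid") <- Cc > 0
  Cc
}

# Kinetic constants expressed on the basis of the CO2 variable:
# "umol_mol" converts the stored Pa values through Patm; "Pa" passes them
# through.  The effective Michaelis-Menten constant KcO = Kc (1 + O/Ko)
# uses O = 21 kPa against Ko in kPa, a unit-free ratio.
.kin_basis <- function(kin, units, Patm_kPa) {
  conv <- if (units == "Pa") 1 else 1000 / Patm_kPa
  list(gammastar = kin$gammastar * conv,
       KcO = kin$Kc * conv * (1 + .O2_KPA / kin$Ko),
       Kp = if (is.na(kin$Kp)) NA_real_ else kin$Kp * conv)
}

#' FvCB forward model of C3 assimilation
#'
#' Net assimilation as the minimum of the Rubisco-limited and
#' RuBP-regeneration-limited rates at chloroplastic CO2 \eqn{C_c}:
#' \deqn{A_c = V_{cmax}\frac{C_c-\Gamma^*}{C_c + K_c(1+O/K_o)}, \quad
#'       A_j = \frac{J}{4}\frac{C_c-\Gamma^*}{C_c + 2\Gamma^*}, \quad
#'       A_N = \min(A_c, A_j) - R_L.}
#' The electron-transport stoichiometry uses the NADPH-basis coefficients
#' 4 and 8.  At \eqn{C_c = \Gamma^*} the model returns exactly \eqn{-R_L}.
#'
#' @param Cc chloroplastic CO2, in `units`.
#' @param Vcmax maximum Rubisco carboxylation velocity, umol m-2 s-1.
#' @param Jmax electron transport rate at the measurement light, umol m-2 s-1.
#' @param RL day respiration, umol m-2 s-1.
#' @param kin a [kinetic_set()].
#' @param Patm_kPa atmospheric pressure, used when `units = "umol_mol"`.
#' @param units basis of `Cc`: `"umol_mol"` (default) or `"Pa"`.
#' @param details if `TRUE` return a data frame with `A`, `Ac`, `Aj` and the
#'   per-point limitation label.
#' @return Net assimilation (umol m-2 s-1), or a data frame when
#'   `details = TRUE`.
#' @examples
#' kin <- rubisco_kinetics("rice", 25)
#' c3_forward(20, 100, 180, 0, kin, units = "Pa")  # ~25.3 (Rubisco-limited)
#' @export
c3_forward <- function(Cc, Vcmax, Jmax, RL = 0, kin,
                       Patm_kPa = 101.325, units = c("umol_mol", "Pa"),
                       details = FALSE) {
  units <- match.arg(units)
  k <- .kin_basis(kin, units, Patm_kPa)
  Ac <- Vcmax * (Cc - k$gammastar) / (Cc + k$KcO)
  Aj <- (Jmax / 4) * (Cc - k$gammastar) / (Cc + 2 * k$gammastar)
  A <- pmin(Ac, Aj) - RL
  if (!details) return(A)
  data.frame(Cc = Cc, A = A, Ac = Ac - RL, Aj = Aj - RL,
             limitation = ifelse(Ac <= Aj, "rubisco", "rubp"))
}

# Deterministic multi-start bounded least squares: evaluate the objective
# on a coarse grid, polish the best starts with L-BFGS-B, then refine the
# winner with a Nelder-Mead pass (robust to the kink the hard min() in the
# limitation transition leaves in the surface).
.multistart_optim <- function(sse, starts, lower, upper, n_polish = 3) {
  sse_safe <- function(par) {
    if (any(par < lower) || any(par > upper)) {
      return(1e10 * (1 + sum(pmax(lower - par, 0) + pmax(par - upper, 0))))
    }
    sse(par)
  }
  vals <- vapply(seq_len(nrow(starts)), function(i) sse_safe(as.numeric(starts[i, ])),
                 numeric(1))
  ord <- order(vals)
  best <- NULL
  for (i in ord[seq_len(min(n_polish, length(ord)))]) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), sse, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (!is.null(best)) {
    nm <- tryCatch(
      stats::optim(best$par, sse_safe, method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(nm) && nm$value < best$value) {
      best <- list(par = pmin(pmax(nm$par, lower), upper), value = nm$value,
                   convergence = nm$convergence)
    }
  }
  best
}

# Standard errors from the residual covariance: numerically differentiate
# the residual vector at the optimum and invert J'J.
.ls_se <- function(resid_fun, par, sse_val, n) {
  p <- length(par)
  if (n <= p) return(rep(NA_real_, p))
  J <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    h <- max(1e-6, abs(par[j]) * 1e-6)
    pp <- par; pp[j] <- par[j] + h
    pm <- par; pm[j] <- par[j] - h
    J[, j] <- (resid_fun(pp) - resid_fun(pm)) / (2 * h)
  }
  sigma2 <- sse_val / (n - p)
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov)) rep(NA_real_, p) else sqrt(pmax(diag(cov), 0))
}

#' Fit Vcmax and Jmax to an A-Cc curve
#'
#' Least-squares fit of the FvCB model ([c3_forward()]) to assimilation
#' observed against chloroplastic CO2.  The fit is a deterministic
#' multi-start bounded optimization (coarse grid of initial
#' \eqn{(V_{cmax}, J_{max})} followed by L-BFGS-B polishing), so repeated
#' runs on the same data give identical results.  The limitation-state
#' crossover is a hard minimum, giving reproducible per-point limitation
#' labels.
#'
#' @param Cc chloroplastic CO2, in `units`.
#' @param A observed net assimilation, umol m-2 s-1.
#' @param kin a [kinetic_set()].
#' @param RL day respiration held fixed during the fit, or `NA` to estimate
#'   it as a free third parameter.
#' @param Patm_kPa,units as in [c3_forward()].
#' @return A `c3_fit` object: estimates with standard errors, per-point
#'   fitted values, limitation labels and residual sum of squares, plus an
#'   identifiability flag for \eqn{J_{max}} when the curve never reaches the
#'   RuBP-regeneration-limited region.
#' @export
fit_vcmax_jmax <- function(Cc, A, kin, RL = 0, Patm_kPa = 101.325,
                           units = c("umol_mol", "Pa")) {
  units <- match.arg(units)
  ok <- is.finite(Cc) & is.finite(A) & Cc > 0
  Cc <- Cc[ok]; A <- A[ok]
  if (length(Cc) < 5) {
    stop("at least 5 valid points are required to fit Vcmax/Jmax",
         call. = FALSE)
  }
  free_rl <- is.na(RL)
  model <- function(par) {
    rl <- if (free_rl) par[3] else RL
    c3_forward(Cc, par[1], par[2], rl, kin, Patm_kPa, units)
  }
  sse <- function(par) sum((A - model(par))^2)
  # The hard min() of the limitation transition leaves a kinked surface
  # with a flat ridge in Vcmax once every point is RuBP-limited, so plain
  # multi-start descent can stall.  Instead, profile over a fine Vcmax grid
  # (inner 1-D optimization of Jmax is cheap and well-behaved) and polish
  # the profile winner.
  rl0 <- if (free_rl) 1 else RL
  vc_grid <- exp(seq(log(8), log(600), length.out = 30))
  jm_grid <- exp(seq(log(10), log(2000), length.out = 40))
  prof <- lapply(vc_grid, function(vc) {
    f1 <- function(jm) sse(c(vc, jm, rl0)[seq_len(2 + free_rl)])
    v <- vapply(jm_grid, f1, numeric(1))
    j <- which.min(v)
    # refine inside the bracketing grid cells (the SSE is flat in Jmax
    # beyond the point where Rubisco limitation binds everywhere, which
    # defeats a naive golden-section search over the whole range)
    op <- stats::optimize(f1, interval = jm_grid[c(max(1, j - 1),
                                                   min(length(jm_grid), j + 1))],
                          tol = 1e-6)
    if (op$objective <= v[j]) {
      list(par = c(vc, op$minimum, if (free_rl) rl0), val = op$objective)
    } else {
      list(par = c(vc, jm_grid[j], if (free_rl) rl0), val = v[j])
    }
  })
  vals <- vapply(prof, `[[`, numeric(1), "val")
  # Pick polish starts in SSE order but force diversity in Vcmax, so the
  # flat all-RuBP-limited ridge (many equal-SSE grid points at high Vcmax)
  # cannot crowd out a narrow valley at a lower Vcmax.
  sel <- integer(0)
  for (i in order(vals)) {
    if (all(abs(log(vc_grid[i] / vc_grid[sel])) > log(1.3))) sel <- c(sel, i)
    if (length(sel) >= 5) break
  }
  starts <- do.call(rbind, lapply(prof[sel], `[[`, "par"))
  lower <- c(1, 1, if (free_rl) 0)
  upper <- c(1000, 2000, if (free_rl) 10)
  best <- .multistart_optim(sse, as.data.frame(starts), lower, upper,
                            n_polish = 5)
  if (is.null(best)) {
    stop("Vcmax/Jmax fit failed to converge from every start", call. = FALSE)
  }
  par <- best$par
  rl_hat <- if (free_rl) par[3] else RL
  det <- c3_forward(Cc, par[1], par[2], rl_hat, kin, Patm_kPa, units,
                    details = TRUE)
  n_rubp <- sum(det$limitation == "rubp")
  n_rub <- sum(det$limitation == "rubisco")
  if (n_rubp < 3 || n_rub < 3) {
    warning(sprintf(
      "degraded fit: only %d Rubisco-limited / %d RuBP-limited points",
      n_rub, n_rubp))
  }
  se <- .ls_se(function(p) A - model(p), par, best$value, length(A))
  structure(
    list(Vcmax = par[1], Jmax = par[2], RL = rl_hat,
         Vcmax_SE = se[1], Jmax_SE = se[2],
         RL_SE = if (free_rl) se[3] else NA_real_,
         jmax_identifiable = n_rubp >= 2,
         Cc = Cc, A = A, fitted = det$A, limitation = det$limitation,
         residual_sse = best$value, convergence = best$convergence == 0,
         kin = kin, units = units, gm = NA_real_),
    class = "c3_fit")
}

#' @export
print.c3_fit <- function(x, ...) {
  cat("FvCB fit (A-Cc basis)\n")
  cat(sprintf("  Vcmax = %.1f +/- %.1f, Jmax = %.1f +/- %.1f umol m-2 s-1\n",
              x$Vcmax, x$Vcmax_SE, x$Jmax, x$Jmax_SE))
  cat(sprintf("  RL = %.2f, gm = %s, SSE = %.3g, Jmax %sidentifiable\n",
              x$RL,
              if (is.na(x$gm)) "n/a" else sprintf("%.3f", x$gm),
              x$residual_sse, if (x$jmax_identifiable) "" else "NOT "))
  invisible(x)
}

# Ethier-style forward model: finite mesophyll conductance folded into the
# FvCB equations, each limitation giving a quadratic in A whose physical
# root is the finite branch as gm -> Inf.
.ethier_rate <- function(Ci, V, K, gm, RL, gammastar) {
  a <- -1 / gm
  b <- (V - RL) / gm + Ci + K
  cc <- RL * (Ci + K) - V * (Ci - gammastar)
  disc <- pmax(b^2 - 4 * a * cc, 0)
  (-b + sqrt(disc)) / (2 * a)
}

#' Single-gm (Ethier) fit of the FvCB model on an A-Ci basis
#'
#' Fits the finite-mesophyll-conductance quadratic form of the FvCB model,
#' treating \eqn{g_m} as one parameter shared along the whole curve,
#' together with \eqn{V_{cmax}} and \eqn{J_{max}}.  This is the standard
#' alternative to the per-point variable-J estimate; on data generated with
#' a constant \eqn{g_m} the two agree.
#'
#' @param Ci intercellular CO2, in `units`.
#' @param A observed net assimilation, umol m-2 s-1.
#' @param kin a [kinetic_set()].
#' @param RL day respiration, umol m-2 s-1.
#' @param Patm_kPa,units as in [c3_forward()].
#' @return A list with `gm` (on the basis of `units`), `gm_SE`, and `fit`
#'   (a `c3_fit` on the implied Cc basis).
#' @export
gm_ethier <- function(Ci, A, kin, RL = 0, Patm_kPa = 101.325,
                      units = c("umol_mol", "Pa")) {
  units <- match.arg(units)
  ok <- is.finite(Ci) & is.finite(A) & Ci > 0
  Ci <- Ci[ok]; A <- A[ok]
  if (length(Ci) < 5) {
    stop("at least 5 valid points are required for the single-gm fit",
         call. = FALSE)
  }
  k <- .kin_basis(kin, units, Patm_kPa)
  model <- function(par) {
    gm <- exp(par[3])
    Ac <- .ethier_rate(Ci, par[1], k$KcO, gm, RL, k$gammastar)
    Aj <- .ethier_rate(Ci, par[2] / 4, 2 * k$gammastar, gm, RL, k$gammastar)
    pmin(Ac, Aj)
  }
  sse <- function(par) sum((A - model(par))^2)
  grid <- expand.grid(Vcmax = c(30, 60, 100, 160, 240),
                      Jmax = c(60, 120, 200, 300),
                      log_gm = log(c(0.05, 0.2, 0.8)))
  best <- .multistart_optim(sse, grid,
                            lower = c(1, 1, log(1e-3)),
                            upper = c(1000, 2000, log(1e4)),
                            n_polish = 4)
  if (is.null(best)) {
    stop("single-gm fit failed to converge from every start", call. = FALSE)
  }
  par <- best$par
  gm <- exp(par[3])
  se <- .ls_se(function(p) A - model(p), par, best$value, length(A))
  Cc <- cc_from_ci(Ci, A, gm)
  fit <- fit_vcmax_jmax(Cc, A, kin, RL, Patm_kPa, units)
  fit$gm <- gm
  list(gm = gm, gm_SE = gm * se[3],
       Vcmax = par[1], Jmax = par[2],
       Vcmax_SE = se[1], Jmax_SE = se[2],
       residual_sse = best$value, fit = fit)
}

#' Full C3 pipeline: from an A-Ci curve to Vcmax/Jmax on a Cc basis
#'
#' Runs the complete C3 parameterization chain on one [aci_curve()]:
#' \enumerate{
#'   \item resolve the kinetic constants (species-specific or a standard
#'     source) at the measurement temperature;
#'   \item \eqn{R_L} from pre-dawn dark respiration (half, by default);
#'   \item ETR per point, from an `ETR` column if present, otherwise from
#'     \eqn{F_s}/\eqn{F_m'} fluorescence via [phi_psii()] and [etr()];
#'   \item per-point variable-J \eqn{g_m}, summarized to a curve-level
#'     scalar (median of admissible points inside `gm_ci_window`) unless
#'     `gm_mode = "per-point"`;
#'   \item conversion to a \eqn{C_c} basis and FvCB fit of
#'     \eqn{V_{cmax}}/\eqn{J_{max}}.
#' }
#' Non-estimable points are excluded with a recorded reason; the surviving
#' curve must retain at least 5 points.
#'
#' @param curve an [aci_curve()].
#' @param kinetics `"own"`, `"bernacchi"` or `"voncaemmerer"`.
#' @param variant tobacco-constants variant for `"bernacchi"`.
#' @param rl_mode `"half-rdark"` (default) or `"free"`.
#' @param gm_mode `"scalar"` (default) or `"per-point"`.
#' @param gm_ci_window Ci range (umol mol-1) whose admissible points feed
#'   the scalar gm summary.
#' @param alpha,beta leaf optics for the ETR calculation.
#' @return A `c3_fit` with the mesophyll-conductance estimate in `$gm`
#'   (mole-fraction basis, mol m-2 s-1), per-point values in `$gm_points`,
#'   and the excluded-point log in `$excluded`.
#' @export
fit_aci_c3 <- function(curve, kinetics = "own", variant = "cc_basis",
                       rl_mode = c("half-rdark", "free"),
                       gm_mode = c("scalar", "per-point"),
                       gm_ci_window = c(150, 1500),
                       alpha = 0.865, beta = 0.5) {
  rl_mode <- match.arg(rl_mode)
  gm_mode <- match.arg(gm_mode)
  stopifnot(inherits(curve, "aci_curve"))
  p <- curve$points
  kin <- resolve_kinetics(kinetics, curve$species, curve$meas_T, variant)
  RL <- rl_from_rdark(curve$Rdark)
  ETR <- if ("ETR" %in% names(p) && all(is.finite(p$ETR))) {
    p$ETR
  } else {
    etr(phi_psii(p$Fs, p$Fm_prime), p$PPFD, alpha, beta)
  }
  gs_ppm <- kin$gammastar * 1000 / p$Patm_kPa
  gm_pts <- gm_variable_j(p$AN, p$Ci, ETR, RL, gs_ppm)
  adm <- attr(gm_pts, "admissible")
  in_window <- p$Ci >= gm_ci_window[1] & p$Ci <= gm_ci_window[2]
  usable <- adm & in_window
  if (sum(usable) < 3) usable <- adm
  if (!any(usable)) {
    stop("no admissible points for variable-J gm estimation", call. = FALSE)
  }
  gm_scalar <- stats::median(gm_pts[usable])
  gm_for_cc <- if (gm_mode == "per-point") {
    ifelse(adm, gm_pts, gm_scalar)
  } else {
    gm_scalar
  }
  Cc <- cc_from_ci(p$Ci, p$AN, gm_for_cc)
  valid <- attr(Cc, "valid")
  excluded <- data.frame(
    index = which(!valid | !adm),
    reason = c(rep("non-positive Cc", sum(!valid)),
               rep("variable-J inadmissible", sum(!adm & valid))))
  if (sum(valid) < 5) {
    stop("fewer than 5 points survive Cc conversion", call. = FALSE)
  }
  fit <- fit_vcmax_jmax(Cc[valid], p$AN[valid], kin,
                        RL = if (rl_mode == "free") NA else RL,
                        Patm_kPa = stats::median(p$Patm_kPa))
  fit$gm <- gm_scalar
  fit$gm_points <- gm_pts
  fit$excluded <- excluded
  fit$kinetics_source <- kinetics
  fit$curve_id <- curve$curve_id
  fit$species <- curve$species
  fit$meas_T <- curve$meas_T
  fit
}
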