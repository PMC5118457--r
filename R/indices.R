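#' Temperature sensitivity and acclimation indices
#'
#' Two ratio indices summarize how a gas-exchange parameter \eqn{Y} responds
#' to temperature:
#' \describe{
#'   \item{TSI}{\eqn{Y_{CT,25} / Y_{CT,38}} - the short-term sensitivity of
#'     control-grown (25 C) plants to a jump in measurement temperature;
#'     1 means temperature-insensitive.}
#'   \item{TAI}{\eqn{Y_{HT,38} / Y_{CT,25}} - plants grown and measured at
#'     their own temperature, ratioed across growth regimes; 1 means perfect
#'     thermal homeostasis.}
#' }
#' Both indices are scale-invariant in \eqn{Y}.  Standard errors, when the
#' component SEs are supplied, are propagated with the delta method for a
#' ratio of independent means.
#'
#' @param y_ct25,y_ct38,y_ht38 treatment means of the parameter.
#' @param se_num,se_den standard errors of numerator and denominator
#'   (optional).
#' @return The index value; with SEs supplied, a named vector
#'   `c(value, SE)`.
#' @examples
#' tsi(10, 5)    # 2
#' tai(22, 10)   # 2.2
#' @export
tsi <- function(y_ct25, y_ct38, se_num = NULL, se_den = NULL) {
  .ratio_index(y_ct25, y_ct38, se_num, se_den)
}

#' @rdname tsi
#' @export
tai <- function(y_ht38, y_ct25, se_num = NULL, se_den = NULL) {
  .ratio_index(y_ht38, y_ct25, se_num, se_den)
}

.ratio_index <- function(num, den, se_num, se_den) {
  if (any(den == 0)) {
    stop("index undefined: zero denominator", call. = FALSE)
  }
  r <- num / den
  if (is.null(se_num) || is.null(se_den)) return(r)
  se <- abs(r) * sqrt((se_num / num)^2 + (se_den / den)^2)
  c(value = r, SE = se)
}

#' Gross assimilation
#'
#' \eqn{A_G = A_N + 0.5 R_{dark}}: gross photosynthesis approximated as net
#' assimilation plus half of the pre-dawn dark respiration (the
#' non-photorespiratory CO2 release in the light).
#'
#' @param AN net assimilation, umol m-2 s-1.
#' @param Rdark pre-dawn dark respiration, umol m-2 s-1.
#' @return \eqn{A_G}, umol m-2 s-1.
#' @export
gross_assimilation <- function(AN, Rdark) {
  .stopifnot_positive(Rdark = Rdark, .allow_zero = TRUE)
  AN + 0.5 * Rdark
}

#' Total leaf conductance to CO2
#'
#' Series combination of the stomatal and mesophyll conductances:
#' \eqn{1/g_t = 1.6/g_s + 1/g_m}, with the factor 1.6 converting the
#' stomatal conductance from a water-vapour to a CO2 basis (diffusivity
#' ratio).  The result is always below both component conductances.
#'
#' @param gs stomatal conductance to H2O, mol m-2 s-1.
#' @param gm mesophyll conductance to CO2, mol m-2 s-1.
#' @return \eqn{g_t}, mol CO2 m-2 s-1.
#' @examples
#' total_conductance(0.32, 0.2)  # 0.1
#' @export
total_conductance <- function(gs, gm) {
  .stopifnot_positive(gs = gs, gm = gm)
  1 / (1.6 / gs + 1 / gm)
}

#' Regression of gross assimilation on the chloroplastic CO2/O2 ratio
#'
#' Ordinary least squares (with intercept) of \eqn{A_G} on \eqn{C_c/O}.
#' The slope of this relationship reflects the operating
#' carboxylase/oxygenase balance of Rubisco within a treatment group.
#'
#' @param cc_o \eqn{C_c/O} values (dimensionless; both in the same pressure
#'   unit).
#' @param ag gross assimilation, umol m-2 s-1.
#' @return A list with `slope`, `intercept`, `r_squared` and `n`.
#' @export
ag_ccO_regression <- function(cc_o, ag) {
  ok <- is.finite(cc_o) & is.finite(ag)
  cc_o <- cc_o[ok]; ag <- ag[ok]
  if (length(cc_o) < 3) stop("at least 3 points are required", call. = FALSE)
  if (stats::var(cc_o) == 0) {
    stop("degenerate regressor: Cc/O has zero variance", call. = FALSE)
  }
  fit <- stats::lm(ag ~ cc_o)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = length(cc_o))
}
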