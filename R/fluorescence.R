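#' PSII operating efficiency from modulated fluorescence
#'
#' \eqn{\Phi_{PSII} = (F_m' - F_s)/F_m'}: the operating quantum yield of
#' photosystem II from the steady-state fluorescence yield \eqn{F_s} and the
#' light-adapted maximal yield \eqn{F_m'} obtained with a saturating pulse.
#'
#' @param Fs steady-state fluorescence yield (arbitrary units).
#' @param Fm_prime light-adapted maximal fluorescence yield (same units).
#' @return \eqn{\Phi_{PSII}}, dimensionless in \[0, 1\].
#' @examples
#' phi_psii(500, 2000)  # 0.75
#' @export
phi_psii <- function(Fs, Fm_prime) {
  .stopifnot_positive(Fs = Fs, .allow_zero = TRUE)
  .stopifnot_positive(Fm_prime = Fm_prime)
  if (any(Fs > Fm_prime)) {
    stop("Fs must not exceed Fm_prime", call. = FALSE)
  }
  (Fm_prime - Fs) / Fm_prime
}

#' Linear electron transport rate
#'
#' \eqn{ETR = \Phi_{PSII} \cdot PPFD \cdot \alpha \cdot \beta}, where
#' \eqn{\alpha} is the leaf absorptance and \eqn{\beta} the fraction of
#' absorbed quanta partitioned to PSII.  Defaults: \eqn{\alpha} = 0.865 (the
#' midpoint of the 0.86-0.87 range measured for the three crops, which did
#' not differ between species or treatments) and \eqn{\beta} = 0.5.
#'
#' @param phi \eqn{\Phi_{PSII}} from [phi_psii()], in \[0, 1\].
#' @param PPFD incident photon flux density, umol m-2 s-1.
#' @param alpha leaf absorptance (0-1).
#' @param beta PSII partitioning fraction (0-1).
#' @return ETR, umol electrons m-2 s-1.
#' @examples
#' etr(0.75, 1500, alpha = 0.86)  # 483.75
#' @export
etr <- function(phi, PPFD, alpha = 0.865, beta = 0.5) {
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]", call. = FALSE)
  .stopifnot_positive(PPFD = PPFD, .allow_zero = TRUE)
  if (any(alpha <= 0 | alpha > 1)) stop("alpha must lie in (0, 1]", call. = FALSE)
  if (any(beta <= 0 | beta >= 1)) stop("beta must lie in (0, 1)", call. = FALSE)
  phi * PPFD * alpha * beta
}
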