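#' Enzyme kinetic constants for photosynthesis modelling
#'
#' The package bundles in vitro Michaelis-Menten constants of Rubisco
#' (\eqn{K_c}, \eqn{K_o}) and PEPC (\eqn{K_p}), and the CO2 compensation
#' point in the absence of mitochondrial respiration (\eqn{\Gamma^*}),
#' measured for rice, wheat and maize at 25 and 38 degrees C, alongside the
#' standard tobacco constants of Bernacchi and the C4-model defaults of
#' von Caemmerer.  All constants are expressed as partial pressures:
#' \eqn{K_c}, \eqn{\Gamma^*} and \eqn{K_p} in Pa, \eqn{K_o} in kPa.
#'
#' @return `kinetics_table()` returns the bundled species-specific constants
#'   as a data frame with one row per species x temperature and columns
#'   `species`, `source`, `temperature_C`, `Kc_Pa`, `Kc_SE`, `Ko_kPa`,
#'   `Ko_SE`, `gammastar_Pa`, `gammastar_SE`, `Kp_Pa`, `Kp_SE`.
#' @examples
#' kinetics_table()
#' @export
kinetics_table <- function() {
  utils::read.csv(.extdata("rubisco_pepc_kinetics.csv"),
                  stringsAsFactors = FALSE)
}

#' Construct a kinetic parameter set
#'
#' A `kinetic_set` carries the Rubisco (and optionally PEPC) constants of one
#' species at one temperature.  The Rubisco specificity factor
#' \eqn{S_{c/o}} is not stored independently: it is back-derived from
#' \eqn{\Gamma^*} through \eqn{\Gamma^* = 0.5\,O/S_{c/o}} at the reference
#' oxygen partial pressure of 21 kPa, so the two are consistent by
#' construction.
#'
#' @param species species label (e.g. "rice").
#' @param temperature leaf temperature, degrees C.
#' @param Kc Michaelis-Menten constant of Rubisco for CO2, Pa.
#' @param Ko Michaelis-Menten constant of Rubisco for O2, kPa.
#' @param gammastar CO2 compensation point without mitochondrial
#'   respiration, Pa.
#' @param Kp Michaelis-Menten constant of PEPC for CO2, Pa (`NA` for C3
#'   species).
#' @param source provenance label: `"own"`, `"bernacchi"` or
#'   `"voncaemmerer"`.
#' @return An object of class `kinetic_set`: a list with the above fields
#'   plus the derived `Sco`.
#' @export
kinetic_set <- function(species, temperature, Kc, Ko, gammastar,
                        Kp = NA_real_, source = "own") {
  .stopifnot_positive(Kc = Kc, Ko = Ko, gammastar = gammastar)
  if (!is.na(Kp)) .stopifnot_positive(Kp = Kp)
  structure(
    list(species = species, temperature = temperature,
         Kc = Kc, Ko = Ko, gammastar = gammastar,
         Sco = sco_from_gamma_star(gammastar),
         Kp = Kp, source = source),
    class = "kinetic_set")
}

#' @export
print.kinetic_set <- function(x, ...) {
  cat(sprintf("Kinetic set: %s (%s) at %g C\n", x$species, x$source,
              x$temperature))
  cat(sprintf("  Kc = %.3g Pa, Ko = %.3g kPa, Gamma* = %.3g Pa (Sc/o = %.0f)\n",
              x$Kc, x$Ko, x$gammastar, x$Sco))
  if (!is.na(x$Kp)) cat(sprintf("  Kp = %.3g Pa\n", x$Kp))
  invisible(x)
}

#' Compensation point and Rubisco specificity
#'
#' \eqn{\Gamma^* = 0.5\,O/S_{c/o}}: the chloroplastic CO2 compensation point
#' in the absence of mitochondrial respiration follows from the Rubisco
#' specificity factor and the oxygen partial pressure, and vice versa.
#'
#' @param Sco Rubisco CO2/O2 specificity factor (dimensionless,
#'   partial-pressure basis).
#' @param gammastar \eqn{\Gamma^*}, Pa.
#' @param O oxygen partial pressure, Pa; defaults to the ambient 21 kPa.
#' @return \eqn{\Gamma^*} in Pa, or \eqn{S_{c/o}} (dimensionless).
#' @examples
#' gamma_star_from_sco(2506, 21000)  # ~4.19 Pa
#' @export
gamma_star_from_sco <- function(Sco, O = .O2_PA) {
  .stopifnot_positive(Sco = Sco, O = O)
  0.5 * O / Sco
}

#' @rdname gamma_star_from_sco
#' @export
sco_from_gamma_star <- function(gammastar, O = .O2_PA) {
  .stopifnot_positive(gammastar = gammastar, O = O)
  0.5 * O / gammastar
}

#' Apparent Kc under competitive oxygen inhibition
#'
#' Oxygen competes with CO2 at the Rubisco active site, so the apparent
#' Michaelis-Menten constant for CO2 measured at an oxygen partial pressure
#' \eqn{O} is \eqn{K_c(O) = K_c(0)\,(1 + O/K_o)}.  `ko_from_kc_pair()`
#' inverts the relation: from assays run at 0% and 21% O2 it recovers
#' \eqn{K_o = O / (K_c^{21}/K_c^{0} - 1)}.
#'
#' @param Kc0 \eqn{K_c} measured without oxygen, Pa.
#' @param Ko \eqn{K_o}, kPa.
#' @param Kc21 apparent \eqn{K_c} measured at oxygen partial pressure `O`, Pa.
#' @param O oxygen partial pressure of the assay, kPa.
#' @return `kc_apparent()`: apparent \eqn{K_c} in Pa.  `ko_from_kc_pair()`:
#'   \eqn{K_o} in kPa.
#' @examples
#' kc_apparent(29.1, 45.7, 21)       # ~42.5 Pa
#' ko_from_kc_pair(29.1, 42.47, 21)  # ~45.7 kPa
#' @export
kc_apparent <- function(Kc0, Ko, O = .O2_KPA) {
  .stopifnot_positive(Kc0 = Kc0, Ko = Ko)
  .stopifnot_positive(O = O, .allow_zero = TRUE)
  Kc0 * (1 + O / Ko)
}

#' @rdname kc_apparent
#' @export
ko_from_kc_pair <- function(Kc0, Kc21, O = .O2_KPA) {
  .stopifnot_positive(Kc0 = Kc0, Kc21 = Kc21, O = O)
  if (any(Kc21 <= Kc0)) {
    stop("Kc at 21% O2 must exceed Kc at 0% O2: ",
         "oxygen inhibition not detected, Ko is not identifiable",
         call. = FALSE)
  }
  O / (Kc21 / Kc0 - 1)
}

#' Gas solubility and concentration/partial-pressure conversion
#'
#' In vitro kinetic constants are measured as dissolved-gas concentrations;
#' gas-exchange modelling needs partial pressures.  Henry's law links the
#' two through the solubility: \eqn{p = c / s}, with \eqn{c} in mol/L and
#' \eqn{s} in mol/(L bar).  The bundled solubilities are those used for the
#' packaged constants: CO2 0.0334 (25 C) and 0.0243 (38 C) mol/(L bar); O2
#' 0.00126 (25 C) and 0.00102 (38 C) mol/(L bar).
#'
#' @param gas `"CO2"` or `"O2"`.
#' @param temperature_C assay temperature; only the bundled 25 and 38 C
#'   pairs are available unless `solubility` is supplied.
#' @param conc dissolved concentration, micromolar.
#' @param pressure_Pa partial pressure, Pa.
#' @param solubility optional explicit solubility, mol/(L bar).
#' @return `gas_solubility()`: solubility in mol/(L bar).
#'   `conc_to_partial_pressure()`: Pa.  `partial_pressure_to_conc()`:
#'   micromolar.
#' @examples
#' conc_to_partial_pressure(9.72, "CO2", 25)  # ~29.1 Pa
#' @export
gas_solubility <- function(gas, temperature_C) {
  tab <- utils::read.csv(.extdata("gas_solubility.csv"),
                         stringsAsFactors = FALSE)
  hit <- tab$gas == gas & tab$temperature_C == temperature_C
  if (sum(hit) != 1) {
    stop(sprintf("no bundled solubility for %s at %g C", gas, temperature_C),
         call. = FALSE)
  }
  tab$solubility_mol_L_bar[hit]
}

#' @rdname gas_solubility
#' @export
conc_to_partial_pressure <- function(conc, gas = "CO2", temperature_C = 25,
                                     solubility = NULL) {
  .stopifnot_positive(conc = conc, .allow_zero = TRUE)
  if (is.null(solubility)) solubility <- gas_solubility(gas, temperature_C)
  # conc [1e-6 mol/L] / s [mol/(L bar)] = 1e-6 bar = 0.1 Pa
  conc / solubility * 0.1
}

#' @rdname gas_solubility
#' @export
partial_pressure_to_conc <- function(pressure_Pa, gas = "CO2",
                                     temperature_C = 25, solubility = NULL) {
  .stopifnot_positive(pressure_Pa = pressure_Pa, .allow_zero = TRUE)
  if (is.null(solubility)) solubility <- gas_solubility(gas, temperature_C)
  pressure_Pa * solubility / 0.1
}

# Two-point temperature scaling.  With rate constants known at exactly two
# temperatures the Arrhenius form k = exp(c - Ea/(R Tk)) is exactly
# constrained; a Q10 form is offered as an alternative.  Both return the
# endpoint values bit-exactly.
.two_point_scale <- function(k1, k2, T1, T2, T, method = c("arrhenius", "q10")) {
  method <- match.arg(method)
  if (T == T1) return(k1)
  if (T == T2) return(k2)
  if (method == "arrhenius") {
    Tk1 <- .celsius_to_kelvin(T1); Tk2 <- .celsius_to_kelvin(T2)
    Tk <- .celsius_to_kelvin(T)
    Ea <- .Rgas * log(k2 / k1) / (1 / Tk1 - 1 / Tk2)
    k1 * exp(Ea / .Rgas * (1 / Tk1 - 1 / Tk))
  } else {
    q10 <- (k2 / k1)^(10 / (T2 - T1))
    k1 * q10^((T - T1) / 10)
  }
}

#' Interpolate kinetic constants between two measured temperatures
#'
#' Each constant is scaled with a two-point Arrhenius law
#' \eqn{k(T) = \exp(c - E_a/(R\,T_K))} whose coefficients are solved exactly
#' from the pair of measured temperatures (default 25 and 38 C); the
#' interpolation therefore reproduces both measured sets exactly and is
#' strictly monotone between them.  A Q10 form is available as an
#' alternative.
#'
#' @param set25,set38 `kinetic_set` objects for the same species and source
#'   at the two measured temperatures.
#' @param temperature target leaf temperature, degrees C (0-60).
#' @param method `"arrhenius"` (default) or `"q10"`.
#' @return A `kinetic_set` at `temperature`.
#' @examples
#' k <- kinetics_at_temperature(
#'   rubisco_kinetics("rice", 25), rubisco_kinetics("rice", 38), 31.5)
#' k$Kc  # ~51.1 Pa, strictly between the 25 and 38 C values
#' @export
kinetics_at_temperature <- function(set25, set38, temperature,
                                    method = c("arrhenius", "q10")) {
  method <- match.arg(method)
  stopifnot(inherits(set25, "kinetic_set"), inherits(set38, "kinetic_set"))
  if (set25$species != set38$species || set25$source != set38$source) {
    stop("the two kinetic sets must share species and source", call. = FALSE)
  }
  if (temperature <= 0 || temperature >= 60) {
    stop("temperature must lie in (0, 60) C", call. = FALSE)
  }
  T1 <- set25$temperature; T2 <- set38$temperature
  sc <- function(k1, k2) {
    if (is.na(k1) || is.na(k2)) return(NA_real_)
    .two_point_scale(k1, k2, T1, T2, temperature, method)
  }
  kinetic_set(species = set25$species, temperature = temperature,
              Kc = sc(set25$Kc, set38$Kc),
              Ko = sc(set25$Ko, set38$Ko),
              gammastar = sc(set25$gammastar, set38$gammastar),
              Kp = sc(set25$Kp, set38$Kp),
              source = set25$source)
}

#' Species-specific Rubisco/PEPC kinetics at a given temperature
#'
#' Convenience accessor over the bundled constants: returns the measured set
#' at 25 or 38 C verbatim, or the two-point Arrhenius interpolation (see
#' [kinetics_at_temperature()]) at any other temperature.
#'
#' @param species `"rice"`, `"wheat"` or `"maize"`.
#' @param temperature leaf temperature, degrees C.
#' @param method passed to [kinetics_at_temperature()].
#' @return A `kinetic_set`.
#' @examples
#' rubisco_kinetics("maize", 38)
#' @export
rubisco_kinetics <- function(species, temperature = 25,
                             method = c("arrhenius", "q10")) {
  tab <- kinetics_table()
  rows <- tab[tab$species == species, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("no bundled kinetics for species: ", species, call. = FALSE)
  }
  as_set <- function(r) {
    kinetic_set(species = r$species, temperature = r$temperature_C,
                Kc = r$Kc_Pa, Ko = r$Ko_kPa, gammastar = r$gammastar_Pa,
                Kp = r$Kp_Pa, source = r$source)
  }
  exact <- rows[rows$temperature_C == temperature, , drop = FALSE]
  if (nrow(exact) == 1) return(as_set(exact[1, ]))
  kinetics_at_temperature(as_set(rows[rows$temperature_C == 25, ]),
                          as_set(rows[rows$temperature_C == 38, ]),
                          temperature, method = match.arg(method))
}

#' Standard ("literature") kinetic parameter sets
#'
#' Two widely used standard parameterizations are packaged for the
#' own-vs-standard comparison analysis:
#' \describe{
#'   \item{`"bernacchi"`}{The tobacco constants with their published
#'     exponential temperature responses, \eqn{k(T) = k_{25}\exp[\Delta H_a
#'     (T_K - 298.15)/(298.15\,R\,T_K)]}.  Two published variants are
#'     selectable: `"cc_basis"` (default; the mesophyll-conductance
#'     corrected, chloroplastic-CO2 constants) and `"ci_basis"` (the
#'     earlier intercellular-CO2 constants).}
#'   \item{`"voncaemmerer"`}{The C4-model defaults at 25 C:
#'     \eqn{K_c} = 65 Pa, \eqn{K_o} = 45 kPa, \eqn{K_p} = 8 Pa and
#'     dimensionless \eqn{\gamma^*} = 0.000193 (i.e. \eqn{\Gamma^*} =
#'     4.053 Pa at O = 21 kPa).  Rubisco constants are scaled to other
#'     temperatures with the Bernacchi activation energies; \eqn{K_p} is
#'     held invariant with temperature.}
#' }
#'
#' @param source `"bernacchi"` or `"voncaemmerer"`.
#' @param temperature leaf temperature, degrees C.
#' @param variant tobacco constants variant, `"cc_basis"` or `"ci_basis"`.
#' @return A `kinetic_set` (with `Kp` populated for `"voncaemmerer"`).
#' @examples
#' standard_kinetics("voncaemmerer", 25)
#' standard_kinetics("bernacchi", 38)
#' @export
standard_kinetics <- function(source = c("bernacchi", "voncaemmerer"),
                              temperature = 25,
                              variant = c("cc_basis", "ci_basis")) {
  source <- match.arg(source)
  variant <- match.arg(variant)
  bern <- utils::read.csv(.extdata("tobacco_temperature_response.csv"),
                          stringsAsFactors = FALSE)
  scale_T <- function(v25, dHa_kJ) {
    if (temperature == 25) return(v25)
    Tk <- .celsius_to_kelvin(temperature)
    v25 * exp(dHa_kJ * 1000 * (Tk - 298.15) / (298.15 * .Rgas * Tk))
  }
  if (source == "bernacchi") {
    b <- bern[bern$variant == variant, , drop = FALSE]
    val <- function(p) {
      r <- b[b$parameter == p, ]
      scale_T(r$value_25C, r$dHa_kJ_mol)
    }
    kinetic_set(species = "tobacco", temperature = temperature,
                Kc = val("Kc"), Ko = val("Ko"), gammastar = val("gammastar"),
                source = "bernacchi")
  } else {
    # Activation energies follow the ci_basis tobacco responses.
    b <- bern[bern$variant == "ci_basis", , drop = FALSE]
    dHa <- function(p) b$dHa_kJ_mol[b$parameter == p]
    kinetic_set(species = "maize-standard", temperature = temperature,
                Kc = scale_T(65, dHa("Kc")),
                Ko = scale_T(45, dHa("Ko")),
                gammastar = scale_T(0.000193 * .O2_PA, dHa("gammastar")),
                Kp = 8,  # assumed invariant with temperature
                source = "voncaemmerer")
  }
}

#' Resolve a kinetics source to a parameter set
#'
#' Internal-facing convenience used by the fitting pipelines: `"own"` maps
#' to the bundled species-specific constants, anything else to
#' [standard_kinetics()].
#'
#' @param source `"own"`, `"bernacchi"` or `"voncaemmerer"`.
#' @param species species label (used for `"own"`).
#' @param temperature leaf temperature, degrees C.
#' @param variant tobacco variant for `"bernacchi"`.
#' @return A `kinetic_set`.
#' @export
resolve_kinetics <- function(source, species, temperature,
                             variant = "cc_basis") {
  if (source == "own") {
    rubisco_kinetics(species, temperature)
  } else {
    standard_kinetics(source, temperature, variant = variant)
  }
}
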