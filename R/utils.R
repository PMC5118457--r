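# Internal helpers shared across modules.

# Universal gas constant, J mol-1 K-1
.Rgas <- 8.314

# Reference oxygen partial pressure at the sites of oxygenation.
# 21 kPa (= 210 mbar): the same value serves the C3 leaf-level
# calculations and the C4 bundle-sheath model; only the unit helpers differ.
.O2_KPA <- 21
.O2_PA <- 21000

.celsius_to_kelvin <- function(T) T + 273.15

# Mole fraction (umol mol-1) <-> partial pressure (Pa) at a given
# atmospheric pressure (kPa).  1 umol mol-1 at 101.325 kPa = 0.101325 Pa.
ppm_to_pa <- function(x, Patm_kPa = 101.325) x * Patm_kPa / 1000
pa_to_ppm <- function(x, Patm_kPa = 101.325) x * 1000 / Patm_kPa

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "photokin")
  if (!nzchar(path)) stop("bundled data file not found: ", file)
  path
}

.stopifnot_positive <- function(..., .allow_zero = FALSE) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    x <- args[[i]]
    bad <- if (.allow_zero) any(x < 0, na.rm = TRUE) else any(x <= 0, na.rm = TRUE)
    if (any(!is.finite(x)) || bad) {
      stop(sprintf("'%s' must be %s and finite", nms[i],
                   if (.allow_zero) "non-negative" else "strictly positive"),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
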