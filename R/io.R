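#' CO2-response curve container
#'
#' An `aci_curve` holds one CO2-response (A-Ci) sweep: an ordered set of
#' gas-exchange points, optionally with paired fluorescence, plus the
#' treatment metadata needed by the fitting pipelines.
#'
#' @param points data frame with one row per measurement point.  Required
#'   columns: `Ca`, `Ci` (umol mol-1), `AN` (umol m-2 s-1), `gs`
#'   (mol H2O m-2 s-1).  Optional: `PPFD`, `Tleaf_C`, `Patm_kPa`
#'   (default 101.325), `Fs`, `Fm_prime`, `ETR`.
#' @param species species label.
#' @param growth_T growth temperature, degrees C.
#' @param irrigation `"WW"` (well-watered) or `"WD"` (water deficit).
#' @param meas_T measurement leaf temperature, degrees C.
#' @param Rdark pre-dawn mitochondrial dark respiration at the measurement
#'   temperature, umol m-2 s-1.
#' @param curve_id identifier used in the flat-file representation.
#' @return An object of class `aci_curve`.
#' @export
aci_curve <- function(points, species, growth_T = NA_real_,
                      irrigation = NA_character_, meas_T = NA_real_,
                      Rdark = 0, curve_id = NA_character_) {
  req <- c("Ca", "Ci", "AN", "gs")
  missing_cols <- setdiff(req, names(points))
  if (length(missing_cols)) {
    stop("points is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"Patm_kPa" %in% names(points)) points$Patm_kPa <- 101.325
  if (Rdark < 0) stop("Rdark must be non-negative", call. = FALSE)
  if (any(!is.finite(points$Ci)) || any(points$Ci <= 0)) {
    stop("Ci must be positive and finite", call. = FALSE)
  }
  structure(
    list(points = points, species = species, growth_T = growth_T,
         irrigation = irrigation, meas_T = meas_T, Rdark = Rdark,
         curve_id = curve_id),
    class = "aci_curve")
}

#' @export
print.aci_curve <- function(x, ...) {
  cat(sprintf("A-Ci curve '%s': %s, growth %g C, %s, measured at %g C\n",
              x$curve_id, x$species, x$growth_T, x$irrigation, x$meas_T))
  cat(sprintf("  %d points, Ci %.0f-%.0f umol mol-1, Rdark = %.2f\n",
              nrow(x$points), min(x$points$Ci), max(x$points$Ci), x$Rdark))
  invisible(x)
}

# Flat-file schema for gas-exchange tables (Li-6400-style export, one row
# per measurement point).
.ge_required <- c("curve_id", "species", "growth_T_C", "irrigation",
                  "meas_T_C", "Ca_umol_mol", "Ci_umol_mol", "AN_umol_m2_s",
                  "gs_mol_m2_s", "PPFD", "Tleaf_C", "Fs", "Fm_prime",
                  "Patm_kPa", "Rdark_umol_m2_s")
.ge_numeric <- setdiff(.ge_required, c("curve_id", "species", "irrigation"))

#' Read and write gas-exchange tables
#'
#' `read_gas_exchange()` parses a schema-conformant CSV (UTF-8, decimal
#' point) into a list of [aci_curve()] objects, grouped by `curve_id` in
#' order of appearance.  Rows with non-numeric values in numeric columns are
#' dropped with a warning carrying the line numbers; a missing required
#' column is an error.  `write_gas_exchange()` is its inverse.
#'
#' @param path CSV file path.
#' @param curves a list of `aci_curve` objects (or a `photokin_dataset`).
#' @return `read_gas_exchange()`: a named list of `aci_curve` objects with a
#'   `"validation"` attribute describing dropped rows.
#'   `write_gas_exchange()`: the path, invisibly.
#' @export
read_gas_exchange <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(.ge_required, names(raw))
  if (length(missing_cols)) {
    stop("gas-exchange file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("empty gas-exchange file: ", path)
    out <- list()
    attr(out, "validation") <- data.frame(line = integer(), reason = character())
    return(out)
  }
  num <- raw
  bad_rows <- rep(FALSE, nrow(raw))
  for (col in .ge_numeric) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad_rows <- bad_rows | (is.na(v) & !raw[[col]] %in% c("", "NA"))
    num[[col]] <- v
  }
  if (any(bad_rows)) {
    warning(sprintf("dropped %d row(s) with non-numeric values (lines %s)",
                    sum(bad_rows),
                    paste(which(bad_rows) + 1L, collapse = ", ")))
  }
  keep <- num[!bad_rows, , drop = FALSE]
  ids <- unique(keep$curve_id)
  curves <- lapply(ids, function(id) {
    g <- keep[keep$curve_id == id, , drop = FALSE]
    pts <- data.frame(Ca = g$Ca_umol_mol, Ci = g$Ci_umol_mol,
                      AN = g$AN_umol_m2_s, gs = g$gs_mol_m2_s,
                      PPFD = g$PPFD, Tleaf_C = g$Tleaf_C,
                      Fs = g$Fs, Fm_prime = g$Fm_prime,
                      Patm_kPa = g$Patm_kPa)
    aci_curve(pts, species = g$species[1], growth_T = g$growth_T_C[1],
              irrigation = g$irrigation[1], meas_T = g$meas_T_C[1],
              Rdark = g$Rdark_umol_m2_s[1], curve_id = id)
  })
  names(curves) <- ids
  attr(curves, "validation") <-
    data.frame(line = which(bad_rows) + 1L,
               reason = rep("non-numeric value", sum(bad_rows)))
  curves
}

#' @rdname read_gas_exchange
#' @export
write_gas_exchange <- function(curves, path) {
  if (inherits(curves, "photokin_dataset")) curves <- curves$curves
  if (inherits(curves, "aci_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    p <- cv$points
    data.frame(curve_id = cv$curve_id, species = cv$species,
               growth_T_C = cv$growth_T, irrigation = cv$irrigation,
               meas_T_C = cv$meas_T, Ca_umol_mol = p$Ca, Ci_umol_mol = p$Ci,
               AN_umol_m2_s = p$AN, gs_mol_m2_s = p$gs,
               PPFD = if ("PPFD" %in% names(p)) p$PPFD else NA_real_,
               Tleaf_C = if ("Tleaf_C" %in% names(p)) p$Tleaf_C else cv$meas_T,
               Fs = if ("Fs" %in% names(p)) p$Fs else NA_real_,
               Fm_prime = if ("Fm_prime" %in% names(p)) p$Fm_prime else NA_real_,
               Patm_kPa = p$Patm_kPa, Rdark_umol_m2_s = cv$Rdark)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
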