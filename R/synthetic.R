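#' Factorial design for a synthetic gas-exchange experiment
#'
#' Describes the study layout emulated by the generator: three crops
#' (rice and wheat, C3; maize, C4) grown at control (25 C) or high (38 C)
#' temperature, well-watered or under water deficit, each measured at 25
#' and 38 C across a CO2 sweep.  Water deficit is expressed as a 40%
#' reduction of stomatal conductance relative to the matched well-watered
#' cell.  Gaussian measurement noise is added to net assimilation only.
#'
#' @param species character vector from `c("rice", "wheat", "maize")`.
#' @param growth_T growth temperature levels, degrees C.
#' @param irrigation irrigation levels, `"WW"` and/or `"WD"`.
#' @param meas_T measurement temperature levels, degrees C.
#' @param replicates plants per cell.
#' @param Ca ambient CO2 sweep, umol mol-1.
#' @param noise_sd_AN Gaussian noise s.d. on AN, umol m-2 s-1.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(species = c("rice", "wheat", "maize"),
                              growth_T = c(25, 38),
                              irrigation = c("WW", "WD"),
                              meas_T = c(25, 38),
                              replicates = 4,
                              Ca = c(50, 100, 150, 200, 250, 300, 400,
                                     550, 700, 900, 1200, 1600, 2000),
                              noise_sd_AN = 0.5,
                              seed = 1) {
  if (replicates < 0) stop("replicates must be >= 0", call. = FALSE)
  if (noise_sd_AN < 0) stop("noise_sd_AN must be >= 0", call. = FALSE)
  structure(list(species = species, growth_T = growth_T,
                 irrigation = irrigation, meas_T = meas_T,
                 replicates = replicates, Ca = Ca,
                 noise_sd_AN = noise_sd_AN, seed = seed),
            class = "experiment_design")
}

#' Cell means of the generating ("true") parameters
#'
#' The per-cell photosynthetic capacities (\eqn{V_{cmax}}, \eqn{J_{max}}
#' for the C3 crops; \eqn{V_{cmax}}, \eqn{V_{pmax}} for maize) are seeded
#' from the bundled own-kinetics comparison tables, so the synthetic curves
#' are physiologically scaled per treatment.  Conductances and dark
#' respiration are scenario presets: \eqn{g_s} = 0.35 (C3) / 0.25 (maize)
#' mol m-2 s-1 under WW, reduced by exactly 40% under WD; \eqn{g_m} = 0.30
#' (WW) / 0.18 (WD) mol m-2 s-1 for the C3 crops; \eqn{R_{dark}} rises
#' steeply with measurement temperature in control-grown plants and less so
#' in heat-acclimated ones.
#'
#' @return A data frame with one row per factorial cell and columns
#'   `species`, `growth_T`, `irrigation`, `meas_T`, `Vcmax`, `Jmax`,
#'   `Vpmax`, `gs`, `gm`, `Rdark`.
#' @export
true_parameter_table <- function() {
  c3 <- comparison_table("c3")
  c4 <- comparison_table("c4")
  base <- rbind(
    data.frame(species = c3$species, growth_T = c3$growth_T_C,
               irrigation = c3$irrigation, meas_T = c3$meas_T_C,
               Vcmax = c3$Vcmax_own, Jmax = c3$Jmax_own, Vpmax = NA_real_),
    data.frame(species = c4$species, growth_T = c4$growth_T_C,
               irrigation = c4$irrigation, meas_T = c4$meas_T_C,
               Vcmax = c4$Vcmax_own, Jmax = NA_real_, Vpmax = c4$Vpmax_own))
  gs_ww <- ifelse(base$species == "maize", 0.25, 0.35)
  base$gs <- ifelse(base$irrigation == "WD", 0.6 * gs_ww, gs_ww)
  base$gm <- ifelse(base$species == "maize", NA_real_,
                    ifelse(base$irrigation == "WD", 0.18, 0.30))
  base$Rdark <- ifelse(base$growth_T == 25,
                       ifelse(base$meas_T == 25, 1.0, 3.5),
                       ifelse(base$meas_T == 25, 1.8, 2.5))
  base
}

# ETR consistent with the operating electron transport at each point: all
# linear electron flow serves carboxylation + oxygenation, so
# J = (A + RL)(4Cc + 8G*)/(Cc - G*).  Near and below the compensation
# point the expression degenerates; a small floor keeps the emitted
# fluorescence physical (those points are inadmissible for variable-J
# anyway).
.operating_etr <- function(A, RL, Cc, gammastar, floor = 5) {
  J <- ifelse(Cc > gammastar & (A + RL) > 0,
              (A + RL) * (4 * Cc + 8 * gammastar) / (Cc - gammastar),
              NA_real_)
  pmax(ifelse(is.finite(J), J, floor), floor)
}

.fluor_from_etr <- function(ETR, PPFD, alpha, beta, Fm = 1800) {
  phi <- pmin(ETR / (PPFD * alpha * beta), 0.95)
  data.frame(Fs = Fm * (1 - phi), Fm_prime = Fm)
}

#' Simulate one C3 CO2-response curve
#'
#' For each ambient CO2 level the steady state of the coupled
#' supply/demand system is solved: stomatal supply
#' \eqn{A = (g_s/1.6)(C_a - C_i)}, mesophyll transfer
#' \eqn{C_c = C_i - A/g_m}, and FvCB demand ([c3_forward()]) with the
#' species' own kinetics at the measurement temperature.  Gaussian noise is
#' added to \eqn{A_N} only.  Fluorescence (`Fs`, `Fm_prime`) is emitted
#' consistently with the operating electron transport rate, so the
#' variable-J method is admissible by construction at all points above the
#' compensation point.
#'
#' @param Vcmax,Jmax generating capacities, umol m-2 s-1.
#' @param gs stomatal conductance to H2O, mol m-2 s-1.
#' @param gm mesophyll conductance, mol m-2 s-1 (mole-fraction basis).
#' @param Rdark dark respiration, umol m-2 s-1 (RL = Rdark/2).
#' @param species,growth_T,irrigation,meas_T treatment metadata; the
#'   species picks the kinetic constants.
#' @param Ca ambient CO2 sweep, umol mol-1.
#' @param noise_sd Gaussian noise s.d. on AN.
#' @param seed optional integer seed (`NULL` continues the current RNG
#'   stream).
#' @param PPFD,alpha,beta,Patm_kPa measurement settings.
#' @param curve_id identifier.
#' @return An [aci_curve()] with a `"truth"` attribute carrying the
#'   generating parameters.
#' @export
simulate_c3_curve <- function(Vcmax, Jmax, gs, gm, Rdark,
                              species = "rice", growth_T = 25,
                              irrigation = "WW", meas_T = 25,
                              Ca = c(50, 100, 150, 200, 250, 300, 400,
                                     550, 700, 900, 1200, 1600, 2000),
                              noise_sd = 0.5, seed = NULL,
                              PPFD = 1500, alpha = 0.865, beta = 0.5,
                              Patm_kPa = 101.325, curve_id = "c3-sim") {
  .stopifnot_positive(Vcmax = Vcmax, Jmax = Jmax, gs = gs, gm = gm)
  if (!is.null(seed)) set.seed(seed)
  kin <- rubisco_kinetics(species, meas_T)
  RL <- rl_from_rdark(Rdark)
  k <- 1 / gm + 1.6 / gs
  demand <- function(Cc) c3_forward(Cc, Vcmax, Jmax, RL, kin, Patm_kPa)
  sol <- vapply(Ca, function(ca) {
    root <- stats::uniroot(function(Cc) Cc + demand(Cc) * k - ca,
                           lower = 1e-3, upper = ca + (RL + 2) * k,
                           tol = 1e-10)$root
    root
  }, numeric(1))
  A <- demand(sol)
  Ci <- sol + A / gm
  G_ppm <- kin$gammastar * 1000 / Patm_kPa
  ETR <- .operating_etr(A, RL, sol, G_ppm)
  fl <- .fluor_from_etr(ETR, PPFD, alpha, beta)
  AN <- A + stats::rnorm(length(A), 0, noise_sd)
  pts <- data.frame(Ca = Ca, Ci = Ci, AN = AN, gs = gs, PPFD = PPFD,
                    Tleaf_C = meas_T, Fs = fl$Fs, Fm_prime = fl$Fm_prime,
                    ETR = ETR, Patm_kPa = Patm_kPa)
  out <- aci_curve(pts, species = species, growth_T = growth_T,
                   irrigation = irrigation, meas_T = meas_T,
                   Rdark = Rdark, curve_id = curve_id)
  attr(out, "truth") <- list(Vcmax = Vcmax, Jmax = Jmax, gs = gs, gm = gm,
                             Rdark = Rdark, A_true = A, Cc_true = sol)
  out
}

#' Simulate one C4 (maize) CO2-response curve
#'
#' As [simulate_c3_curve()] but with the enzyme-limited C4 demand function
#' ([c4_forward()]) and the fixed C4 constants.  Fluorescence is emitted
#' with an electron cost of 6 per net carboxylation, keeping the recorded
#' ETR above the variable-J admissibility bound.
#'
#' @param Vcmax,Vpmax generating capacities, umol m-2 s-1.
#' @param gs stomatal conductance to H2O, mol m-2 s-1.
#' @param Rdark dark respiration, umol m-2 s-1.
#' @param const a [c4_constants()].
#' @inheritParams simulate_c3_curve
#' @return An [aci_curve()] with a `"truth"` attribute.
#' @export
simulate_c4_curve <- function(Vcmax, Vpmax, gs, Rdark,
                              species = "maize", growth_T = 25,
                              irrigation = "WW", meas_T = 25,
                              Ca = c(50, 100, 150, 200, 250, 300, 400,
                                     550, 700, 900, 1200, 1600, 2000),
                              noise_sd = 0.5, seed = NULL,
                              const = c4_constants(),
                              PPFD = 1500, alpha = 0.865, beta = 0.5,
                              Patm_kPa = 101.325, curve_id = "c4-sim") {
  .stopifnot_positive(Vcmax = Vcmax, Vpmax = Vpmax, gs = gs)
  if (!is.null(seed)) set.seed(seed)
  kin <- rubisco_kinetics(species, meas_T)
  RL <- rl_from_rdark(Rdark)
  Rm <- if (is.na(const$Rm)) 0.5 * RL else const$Rm
  demand <- function(Ci) c4_forward(Ci, Vcmax, Vpmax, RL, kin, const,
                                    Patm_kPa)$A
  Ci <- vapply(Ca, function(ca) {
    stats::uniroot(function(ci) gs / 1.6 * (ca - ci) - demand(ci),
                   lower = 0.5, upper = ca + 1.6 * (RL + Rm + 2) / gs,
                   tol = 1e-10)$root
  }, numeric(1))
  A <- demand(Ci)
  ETR <- pmax(6 * (A + RL), 5)
  fl <- .fluor_from_etr(ETR, PPFD, alpha, beta)
  AN <- A + stats::rnorm(length(A), 0, noise_sd)
  pts <- data.frame(Ca = Ca, Ci = Ci, AN = AN, gs = gs, PPFD = PPFD,
                    Tleaf_C = meas_T, Fs = fl$Fs, Fm_prime = fl$Fm_prime,
                    ETR = ETR, Patm_kPa = Patm_kPa)
  out <- aci_curve(pts, species = species, growth_T = growth_T,
                   irrigation = irrigation, meas_T = meas_T,
                   Rdark = Rdark, curve_id = curve_id)
  attr(out, "truth") <- list(Vcmax = Vcmax, Vpmax = Vpmax, gs = gs,
                             Rdark = Rdark, A_true = A)
  out
}

#' Simulate a full factorial gas-exchange experiment
#'
#' Emits every curve of the design with independent per-curve random
#' streams: the design seed generates one sub-seed per (cell, replicate)
#' which drives both the small replicate-level parameter variation
#' (lognormal, 5% CV on capacities and conductances) and the measurement
#' noise, so cells are independent and the whole dataset is reproduced
#' exactly by the same design seed.
#'
#' @param design an [experiment_design()].
#' @param replicate_cv lognormal coefficient of variation of the true
#'   parameters between replicate plants.
#' @return A `photokin_dataset`: list with `curves` (named list of
#'   [aci_curve()]), `truth` (data frame of realized generating parameters
#'   per curve) and `design`.
#' @export
simulate_experiment <- function(design = experiment_design(),
                                replicate_cv = 0.05) {
  stopifnot(inherits(design, "experiment_design"))
  params <- true_parameter_table()
  cells <- expand.grid(species = design$species, growth_T = design$growth_T,
                       irrigation = design$irrigation, meas_T = design$meas_T,
                       rep = seq_len(design$replicates),
                       stringsAsFactors = FALSE)
  if (nrow(cells) == 0) {
    return(structure(list(curves = list(),
                          truth = data.frame(), design = design),
                     class = "photokin_dataset"))
  }
  set.seed(design$seed)
  subseeds <- sample.int(2147483646L, nrow(cells))
  curves <- vector("list", nrow(cells))
  truth <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    pr <- params[params$species == cl$species & params$growth_T == cl$growth_T &
                 params$irrigation == cl$irrigation & params$meas_T == cl$meas_T, ]
    if (nrow(pr) != 1) stop("no generating parameters for cell ", i)
    set.seed(subseeds[i])
    jit <- function(x) {
      if (replicate_cv == 0) return(x)
      x * stats::rlnorm(1, -0.5 * log(1 + replicate_cv^2),
                        sqrt(log(1 + replicate_cv^2)))
    }
    id <- sprintf("%s_G%g_%s_M%g_r%d", cl$species, cl$growth_T,
                  cl$irrigation, cl$meas_T, cl$rep)
    if (cl$species == "maize") {
      vc <- jit(pr$Vcmax); vp <- jit(pr$Vpmax); g <- jit(pr$gs)
      curves[[i]] <- simulate_c4_curve(
        vc, vp, g, pr$Rdark, species = cl$species, growth_T = cl$growth_T,
        irrigation = cl$irrigation, meas_T = cl$meas_T, Ca = design$Ca,
        noise_sd = design$noise_sd_AN, curve_id = id)
      truth[[i]] <- data.frame(curve_id = id, species = cl$species,
                               growth_T = cl$growth_T,
                               irrigation = cl$irrigation, meas_T = cl$meas_T,
                               rep = cl$rep, Vcmax = vc, Jmax = NA_real_,
                               Vpmax = vp, gs = g, gm = NA_real_,
                               Rdark = pr$Rdark)
    } else {
      vc <- jit(pr$Vcmax); jm <- jit(pr$Jmax)
      g <- jit(pr$gs); gmm <- jit(pr$gm)
      curves[[i]] <- simulate_c3_curve(
        vc, jm, g, gmm, pr$Rdark, species = cl$species,
        growth_T = cl$growth_T, irrigation = cl$irrigation,
        meas_T = cl$meas_T, Ca = design$Ca,
        noise_sd = design$noise_sd_AN, curve_id = id)
      truth[[i]] <- data.frame(curve_id = id, species = cl$species,
                               growth_T = cl$growth_T,
                               irrigation = cl$irrigation, meas_T = cl$meas_T,
                               rep = cl$rep, Vcmax = vc, Jmax = jm,
                               Vpmax = NA_real_, gs = g, gm = gmm,
                               Rdark = pr$Rdark)
    }
  }
  names(curves) <- vapply(curves, function(cv) cv$curve_id, character(1))
  structure(list(curves = curves, truth = do.call(rbind, truth),
                 design = design),
            class = "photokin_dataset")
}

#' @export
print.photokin_dataset <- function(x, ...) {
  cat(sprintf("Synthetic gas-exchange dataset: %d curves (seed %d)\n",
              length(x$curves), x$design$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the flat gas-exchange CSV (schema of [read_gas_exchange()]) and a
#' `truth.json` sidecar with the realized generating parameters.
#'
#' @param dataset a `photokin_dataset`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "photokin_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gas_exchange(dataset$curves, file.path(dir, "gas_exchange.csv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Parameter-recovery report over a synthetic dataset
#'
#' Fits every curve of a synthetic dataset with the full pipeline (C3 for
#' rice/wheat, C4 for maize, own kinetics) and scores the estimates against
#' the recorded generating parameters.
#'
#' @param dataset a `photokin_dataset` from [simulate_experiment()].
#' @return A list with `table` (per-curve estimates, truths and relative
#'   errors) and `summary` (median absolute relative error per parameter).
#' @export
recovery_report <- function(dataset) {
  stopifnot(inherits(dataset, "photokin_dataset"))
  rows <- lapply(dataset$curves, function(cv) {
    tr <- dataset$truth[dataset$truth$curve_id == cv$curve_id, ]
    res <- tryCatch({
      if (cv$species == "maize") {
        f <- fit_aci_c4(cv)
        data.frame(parameter = c("Vcmax", "Vpmax"),
                   estimate = c(f$Vcmax, f$Vpmax),
                   truth = c(tr$Vcmax, tr$Vpmax))
      } else {
        f <- fit_aci_c3(cv)
        data.frame(parameter = c("Vcmax", "Jmax"),
                   estimate = c(f$Vcmax, f$Jmax),
                   truth = c(tr$Vcmax, tr$Jmax))
      }
    }, error = function(e) data.frame(parameter = character(),
                                      estimate = numeric(), truth = numeric()))
    if (nrow(res)) {
      res$curve_id <- cv$curve_id
      res$species <- cv$species
      res$rel_error <- res$estimate / res$truth - 1
    }
    res
  })
  tab <- do.call(rbind, rows)
  summ <- stats::aggregate(abs(tab$rel_error),
                           by = list(parameter = tab$parameter),
                           FUN = stats::median)
  names(summ)[2] <- "median_abs_rel_error"
  list(table = tab, summary = summ)
}
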