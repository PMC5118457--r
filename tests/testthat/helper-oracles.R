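# Independent oracles used by the tests.  These deliberately avoid the
# package's own solution paths: the C4 oracle locates the assimilation root
# by dense scanning and nested grid refinement (no derivative, no
# bisection), and the two-point Arrhenius oracle is a direct transcription
# of the closed form.

# Dense-scan solver for the enzyme-limited C4 system: scan the residual of
# the bundle-sheath equation over a grid of candidate A values, then refine
# the sign change on successively finer grids.
brute_force_c4 <- function(Ci, Vcmax, Vpmax, RL, kin, const, Patm_kPa = 101.325,
                           Rm = 0.5 * RL) {
  Km_Pa <- kin$Kc * (1 + (const$O_Pa / 1000) / kin$Ko)
  gfrac <- kin$gammastar / 21000
  resid <- function(A) {
    Cm <- Ci - A / const$gm
    Cm_Pa <- Cm * Patm_kPa / 1000
    Vp <- ifelse(Cm > 0, Cm_Pa * Vpmax / (Cm_Pa + kin$Kp), 0)
    Cs <- Cm + (Vp - A - Rm) / const$gbs
    Cs_Pa <- Cs * Patm_kPa / 1000
    Ar <- ifelse(Cs > 0,
                 Vcmax * Cs_Pa / (Cs_Pa + Km_Pa) * (1 - gfrac * const$O_Pa / Cs_Pa) - RL,
                 -1e6)
    Ar - A
  }
  lo <- -RL - Rm - 5
  hi <- Vcmax
  for (pass in 1:6) {
    grid <- seq(lo, hi, length.out = 201)
    r <- resid(grid)
    flip <- which(r[-1] <= 0 & r[-length(r)] > 0)[1]
    if (is.na(flip)) stop("brute-force scan found no sign change")
    lo <- grid[flip]
    hi <- grid[flip + 1]
  }
  0.5 * (lo + hi)
}

# Closed-form two-point Arrhenius evaluation.
arrhenius_oracle <- function(k1, k2, T1, T2, T) {
  R <- 8.314
  Tk1 <- T1 + 273.15; Tk2 <- T2 + 273.15; Tk <- T + 273.15
  Ea <- R * log(k2 / k1) / (1 / Tk1 - 1 / Tk2)
  k1 * exp(Ea / R * (1 / Tk1 - 1 / Tk))
}

# Closed-form two-point OLS check.
ols_two_point <- function(x, y) {
  slope <- (y[2] - y[1]) / (x[2] - x[1])
  c(slope = slope, intercept = y[1] - slope * x[1])
}
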