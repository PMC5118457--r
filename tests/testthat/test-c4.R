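maize25 <- rubisco_kinetics("maize", 25)
cst <- c4_constants()

test_that("C4 forward solver agrees with the dense-scan oracle", {
  set.seed(30)
  n_draws <- 300
  for (i in seq_len(n_draws)) {
    Ci <- runif(1, 20, 1500)
    Vcmax <- runif(1, 10, 80)
    Vpmax <- runif(1, 30, 250)
    RL <- runif(1, 0, 3)
    sol <- c4_forward(Ci, Vcmax, Vpmax, RL, maize25, cst)
    ora <- brute_force_c4(Ci, Vcmax, Vpmax, RL, maize25, cst)
    expect_equal(sol$A, ora, tolerance = 1e-6)
  }
})

test_that("C4 forward model satisfies its structural limits", {
  # Rubisco-saturated asymptote: A -> Vcmax - RL at large Ci (the approach
  # is slow because Cs enters both the Michaelis-Menten and gamma* terms)
  hi <- c4_forward(1e7, 40, 500, 1.5, maize25, cst)
  expect_equal(hi$A, 40 - 1.5, tolerance = 1e-3)
  # PEPC half-saturation: Cm at Kp gives a pump rate of Vpmax/2
  Kp_ppm <- maize25$Kp * 1000 / 101.325
  Vp <- (Kp_ppm * 101.325 / 1000) * 120 /
    ((Kp_ppm * 101.325 / 1000) + maize25$Kp)
  expect_equal(Vp, 60)
  # monotone in Ci; Cm below Ci wherever A > 0
  Ci <- seq(20, 1500, by = 20)
  sol <- c4_forward(Ci, 35, 120, 1, maize25, cst)
  expect_true(all(diff(sol$A) > -1e-9))
  expect_true(all(sol$Cm[sol$A > 0] < Ci[sol$A > 0]))
  # bundle sheath accumulates CO2 above the mesophyll while the pump runs
  Rm <- 0.5
  pump_on <- (sol$Cm * 101.325 / 1000 * 120 /
                (sol$Cm * 101.325 / 1000 + maize25$Kp) - sol$A - Rm) > 0
  expect_true(all(sol$Cs[pump_on] >= sol$Cm[pump_on]))
})

test_that("A-Ci smoothing reproduces an exact hyperbola and counts its grid", {
  nrh <- function(Ci, phi, Amax, theta, Rd) {
    s <- phi * Ci + Amax
    (s - sqrt(s^2 - 4 * theta * phi * Ci * Amax)) / (2 * theta) - Rd
  }
  Ci <- c(50, 80, 120, 180, 250, 350, 500, 700, 1000, 1400)
  A <- nrh(Ci, 0.3, 40, 0.7, 1.2)
  sm <- smooth_aci(Ci, A, step = 5)
  expect_equal(sm$A, nrh(sm$Ci, 0.3, 40, 0.7, 1.2), tolerance = 1e-6)
  expect_lt(attr(sm, "rms"), 1e-6)
  # grid counting: [50, 400] at step 5 -> 71 points
  sm2 <- smooth_aci(seq(50, 400, length.out = 8), nrh(seq(50, 400, length.out = 8),
                                                      0.3, 40, 0.7, 1.2))
  expect_equal(nrow(sm2), 71)
  expect_error(smooth_aci(c(50, 100), c(5, 10)), "at least 6")
})

test_that("noiseless C4 curves return the generating Vcmax and Vpmax", {
  cv <- simulate_c4_curve(35, 120, 0.25, 2, meas_T = 25, noise_sd = 0, seed = 31)
  fit <- fit_aci_c4(cv)
  expect_equal(fit$Vcmax, 35, tolerance = 0.02)
  expect_equal(fit$Vpmax, 120, tolerance = 0.02)
  expect_true(fit$vpmax_identifiable)
  # raw-points mode agrees even closer on noiseless data
  fit_raw <- fit_aci_c4(cv, smooth = FALSE)
  expect_equal(fit_raw$Vcmax, 35, tolerance = 5e-3)
  expect_equal(fit_raw$Vpmax, 120, tolerance = 5e-3)
})

test_that("a curve without an initial slope flags Vpmax as unidentifiable", {
  cv <- simulate_c4_curve(35, 120, 0.25, 2, meas_T = 25, noise_sd = 0,
                          seed = 32, Ca = seq(600, 2000, by = 140))
  expect_warning(fit <- fit_aci_c4(cv), "poorly identified")
  expect_false(fit$vpmax_identifiable)
})

test_that("refitting with altered bundle-sheath conductance moves Vpmax more than Vcmax", {
  cv <- simulate_c4_curve(35, 120, 0.25, 2, meas_T = 25, noise_sd = 0, seed = 33)
  f1 <- fit_aci_c4(cv)
  f2 <- fit_aci_c4(cv, const = c4_constants(gbs = 0.006))
  rel_vc <- abs(f2$Vcmax / f1$Vcmax - 1)
  rel_vp <- abs(f2$Vpmax / f1$Vpmax - 1)
  expect_lt(rel_vc, rel_vp)
})
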