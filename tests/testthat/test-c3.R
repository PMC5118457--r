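rice25 <- rubisco_kinetics("rice", 25)

test_that("day respiration is half of pre-dawn dark respiration", {
  expect_equal(rl_from_rdark(2), 1)
  expect_equal(rl_from_rdark(0), 0)
  expect_equal(rl_from_rdark(1.7), 0.85)
  expect_error(rl_from_rdark(-1), "non-negative")
})

test_that("variable-J gm matches hand arithmetic and flags inadmissible points", {
  # all quantities on a Pa basis
  gm <- gm_variable_j(AN = 20, Ci = 30, ETR = 160, RL = 1, gamma_star = 4.19)
  expect_equal(as.numeric(gm), 20 / (30 - 4.19 * 328 / 76), tolerance = 1e-12)
  expect_equal(as.numeric(gm), 1.678, tolerance = 1e-3)
  # zero flux -> zero conductance
  expect_equal(as.numeric(gm_variable_j(0, 30, 160, 1, 4.19)), 0)
  # ETR below the admissibility bound is flagged, not an error
  g2 <- gm_variable_j(c(20, 20), c(30, 30), c(160, 80), 1, 4.19)
  expect_true(is.na(g2[2]))
  expect_identical(attr(g2, "admissible"), c(TRUE, FALSE))
})

test_that("Ci to Cc conversion behaves at its limits", {
  expect_equal(as.numeric(cc_from_ci(300, 20, 0.2)), 200)
  expect_equal(as.numeric(cc_from_ci(317, 0, 0.1)), 317)
  expect_equal(as.numeric(cc_from_ci(300, 20, 1e12)), 300, tolerance = 1e-9)
  flagged <- cc_from_ci(30, 20, 0.2)
  expect_false(attr(flagged, "valid"))
})

test_that("FvCB forward model reproduces its closed-form anchors", {
  # at Cc = gamma*, net assimilation is exactly -RL
  g_pa <- rice25$gammastar
  expect_equal(c3_forward(g_pa, 100, 180, 1.3, rice25, units = "Pa"), -1.3)
  expect_equal(c3_forward(g_pa, 37, 91, 0, rice25, units = "Pa"), 0)
  # Rubisco-limited branch at Cc = 20 Pa, rice 25 C kinetics
  det <- c3_forward(20, 100, 1e6, 0, rice25, units = "Pa", details = TRUE)
  expect_equal(det$A, 100 * (20 - 4.19) / (20 + kc_apparent(29.1, 45.7, 21)),
               tolerance = 1e-12)
  expect_equal(det$A, 25.31, tolerance = 1e-3)
  expect_identical(det$limitation, "rubisco")
  # RuBP-regeneration asymptote: A -> J/4 - RL as Cc grows
  expect_equal(c3_forward(1e9, 100, 180, 2, rice25, units = "Pa"),
               180 / 4 - 2, tolerance = 1e-4)
  # min structure and monotonicity above gamma*
  Cc <- seq(5, 200, by = 1)
  det2 <- c3_forward(Cc, 90, 160, 1, rice25, units = "Pa", details = TRUE)
  expect_true(all(det2$A <= det2$Ac + 1e-12))
  expect_true(all(det2$A <= det2$Aj + 1e-12))
  expect_true(all(diff(det2$A) > 0))
})

test_that("noiseless forward curves invert exactly through the variable-J chain", {
  cv <- simulate_c3_curve(100, 180, 0.35, 0.25, 2, species = "rice",
                          meas_T = 25, noise_sd = 0, seed = 5)
  tr <- attr(cv, "truth")
  p <- cv$points
  G_ppm <- rice25$gammastar * 1000 / p$Patm_kPa[1]
  gm <- gm_variable_j(p$AN, p$Ci, p$ETR, 1, G_ppm)
  adm <- attr(gm, "admissible")
  expect_gt(sum(adm), 8)
  expect_equal(gm[adm], rep(0.25, sum(adm)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # Cc recovered from Ci equals the generating Cc
  Cc <- cc_from_ci(p$Ci, p$AN, 0.25)
  expect_equal(as.numeric(Cc), tr$Cc_true, tolerance = 1e-8)
})

test_that("Vcmax/Jmax are recovered from noiseless curves and identifiability is flagged", {
  cv <- simulate_c3_curve(100, 180, 0.35, 0.25, 2, species = "rice",
                          meas_T = 25, noise_sd = 0, seed = 1)
  fit <- fit_aci_c3(cv)
  expect_equal(fit$Vcmax, 100, tolerance = 5e-3)
  expect_equal(fit$Jmax, 180, tolerance = 5e-3)
  expect_equal(fit$gm, 0.25, tolerance = 1e-6)
  expect_true(fit$jmax_identifiable)
  expect_s3_class(fit, "c3_fit")
  # a curve restricted to the Rubisco-limited region cannot see Jmax
  tr <- attr(cv, "truth")
  low <- tr$Cc_true < 150 & tr$Cc_true > 45
  expect_warning(
    f2 <- fit_vcmax_jmax(tr$Cc_true[low], tr$A_true[low], rice25, RL = 1),
    "degraded")
  expect_false(f2$jmax_identifiable)
  expect_error(fit_vcmax_jmax(c(100, 200), c(10, 15), rice25, RL = 1),
               "at least 5")
})

test_that("wheat and 38 C cells also invert cleanly", {
  cv <- simulate_c3_curve(120, 200, 0.35, 0.3, 3.5, species = "wheat",
                          meas_T = 38, noise_sd = 0, seed = 2)
  fit <- fit_aci_c3(cv)
  expect_equal(fit$Vcmax, 120, tolerance = 5e-3)
  expect_equal(fit$Jmax, 200, tolerance = 5e-3)
})

test_that("single-gm (Ethier) fit recovers a constant generating gm", {
  cv <- simulate_c3_curve(100, 180, 0.35, 0.25, 2, species = "rice",
                          meas_T = 25, noise_sd = 0, seed = 3)
  tr <- attr(cv, "truth")
  e <- gm_ethier(cv$points$Ci, tr$A_true, rice25, RL = 1)
  expect_equal(e$gm, 0.25, tolerance = 0.02)
  expect_equal(e$Vcmax, 100, tolerance = 0.02 * 100)
  # essentially-infinite gm: fitted Vcmax matches the infinite-gm fit
  cv2 <- simulate_c3_curve(100, 180, 0.35, 500, 2, species = "rice",
                           meas_T = 25, noise_sd = 0, seed = 4)
  tr2 <- attr(cv2, "truth")
  e2 <- gm_ethier(cv2$points$Ci, tr2$A_true, rice25, RL = 1)
  finf <- fit_vcmax_jmax(cv2$points$Ci, tr2$A_true, rice25, RL = 1)
  expect_equal(e2$Vcmax, finf$Vcmax, tolerance = 0.02)
})

test_that("Harley and Ethier gm estimates agree on a noisy ensemble", {
  set.seed(20)
  harley <- ethier <- numeric(12)
  for (i in 1:12) {
    gm_true <- runif(1, 0.15, 0.4)
    cv <- simulate_c3_curve(100, 180, 0.35, gm_true, 2, species = "rice",
                            meas_T = 25, noise_sd = 0.2)
    f <- fit_aci_c3(cv)
    harley[i] <- f$gm
    ethier[i] <- gm_ethier(cv$points$Ci, cv$points$AN, rice25, RL = 1)$gm
  }
  ct <- cor.test(harley, ethier)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
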