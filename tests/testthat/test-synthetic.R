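test_that("noiseless curves lie exactly on the forward model and are deterministic", {
  cv1 <- simulate_c3_curve(100, 180, 0.35, 0.25, 2, species = "rice",
                           meas_T = 25, noise_sd = 0, seed = 60)
  cv2 <- simulate_c3_curve(100, 180, 0.35, 0.25, 2, species = "rice",
                           meas_T = 25, noise_sd = 0, seed = 60)
  expect_identical(cv1$points, cv2$points)
  tr <- attr(cv1, "truth")
  expect_equal(cv1$points$AN, tr$A_true, tolerance = 1e-12)
  # supply/demand consistency: stomatal flux equals assimilation at each point
  p <- cv1$points
  expect_equal(p$gs / 1.6 * (p$Ca - p$Ci), tr$A_true, tolerance = 1e-6)
  # same seed with noise: identical noisy draws
  n1 <- simulate_c3_curve(100, 180, 0.35, 0.25, 2, meas_T = 25,
                          noise_sd = 0.5, seed = 61)
  n2 <- simulate_c3_curve(100, 180, 0.35, 0.25, 2, meas_T = 25,
                          noise_sd = 0.5, seed = 61)
  expect_identical(n1$points$AN, n2$points$AN)
})

test_that("generated fluorescence keeps the variable-J method admissible above compensation", {
  for (seed in 1:3) {
    cv <- simulate_c3_curve(120, 200, 0.35, 0.3, 2, species = "wheat",
                            meas_T = 38, noise_sd = 0, seed = seed)
    p <- cv$points
    RL <- cv$Rdark / 2
    kin <- rubisco_kinetics("wheat", 38)
    G_ppm <- kin$gammastar * 1000 / p$Patm_kPa
    above <- attr(cv, "truth")$Cc_true > G_ppm
    expect_true(all(p$ETR[above] > 4 * (p$AN[above] + RL)))
    # fluorescence round-trips to the recorded ETR
    etr_back <- etr(phi_psii(p$Fs, p$Fm_prime), p$PPFD)
    expect_equal(etr_back, p$ETR, tolerance = 1e-9)
  }
})

test_that("C4 generator applies the water-deficit conductance rule and is deterministic", {
  c1 <- simulate_c4_curve(35, 120, 0.25, 2, meas_T = 25, noise_sd = 0.5, seed = 62)
  c2 <- simulate_c4_curve(35, 120, 0.25, 2, meas_T = 25, noise_sd = 0.5, seed = 62)
  expect_identical(c1$points, c2$points)
  pt <- true_parameter_table()
  ww <- pt[pt$irrigation == "WW", ]
  wd <- pt[pt$irrigation == "WD", ]
  key <- function(d) paste(d$species, d$growth_T, d$meas_T)
  m <- match(key(wd), key(ww))
  expect_true(all(wd$gs <= 0.6 * ww$gs[m] + 1e-12))
})

test_that("the full factorial has the expected layout and reproducibility", {
  des <- experiment_design(seed = 99)
  ds <- simulate_experiment(des)
  expect_equal(length(ds$curves), 3 * 2 * 2 * 2 * 4)
  expect_equal(nrow(ds$truth), 96)
  ds2 <- simulate_experiment(experiment_design(seed = 99))
  expect_identical(ds$truth, ds2$truth)
  expect_identical(ds$curves[[37]]$points, ds2$curves[[37]]$points)
  # different seeds decorrelate the noise
  ds3 <- simulate_experiment(experiment_design(seed = 100))
  expect_false(identical(ds$curves[[1]]$points$AN, ds3$curves[[1]]$points$AN))
  # empty species list: valid empty dataset
  e <- simulate_experiment(experiment_design(species = character(0)))
  expect_s3_class(e, "photokin_dataset")
  expect_equal(length(e$curves), 0)
})

test_that("a reduced factorial recovers its generating parameters", {
  des <- experiment_design(species = c("rice", "maize"), growth_T = 25,
                           irrigation = "WW", meas_T = 25, replicates = 2,
                           seed = 63)
  ds <- simulate_experiment(des)
  rep <- recovery_report(ds)
  expect_true(all(rep$summary$median_abs_rel_error < 0.05))
  expect_equal(sort(unique(rep$table$parameter)),
               c("Jmax", "Vcmax", "Vpmax"))
})
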