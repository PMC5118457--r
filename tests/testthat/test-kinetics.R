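test_that("gamma-star / specificity relation matches the bundled constants and round-trips", {
  # rice at 25 C: Sco back-derived from the bundled gamma* must round-trip
  expect_equal(gamma_star_from_sco(2506, 21000), 4.19, tolerance = 1e-3)
  expect_equal(gamma_star_from_sco(1, 2), 1)
  # maize 38 C
  expect_equal(gamma_star_from_sco(1623, 21000), 6.47, tolerance = 1e-3)
  # inverse composition is the identity to near machine precision
  for (sco in c(1, 80, 975, 2506, 10000)) {
    expect_equal(sco_from_gamma_star(gamma_star_from_sco(sco)), sco,
                 tolerance = 1e-12)
  }
  expect_error(gamma_star_from_sco(-1, 21000), "positive")
  expect_error(gamma_star_from_sco(2506, 0), "positive")
})

test_that("apparent Kc under oxygen and its inverse compose to the identity", {
  expect_equal(kc_apparent(29.1, 45.7, 21), 42.5, tolerance = 1e-3)
  expect_equal(kc_apparent(10, 37, 0), 10)
  expect_equal(kc_apparent(85.8, 39.8, 21), 131.1, tolerance = 1e-3)
  expect_equal(ko_from_kc_pair(29.1, kc_apparent(29.1, 45.7, 21), 21), 45.7)
  expect_equal(ko_from_kc_pair(1, 2, 21), 21)
  # property: composition is the identity over random positive inputs
  set.seed(101)
  for (i in 1:50) {
    Kc0 <- runif(1, 1, 200); Ko <- runif(1, 5, 100); O <- runif(1, 1, 40)
    expect_equal(ko_from_kc_pair(Kc0, kc_apparent(Kc0, Ko, O), O), Ko,
                 tolerance = 1e-10)
  }
  expect_error(ko_from_kc_pair(5, 5, 21), "not identifiable")
  expect_error(ko_from_kc_pair(5, 4, 21), "not identifiable")
})

test_that("concentration <-> partial pressure conversion uses the bundled solubilities", {
  expect_equal(conc_to_partial_pressure(9.72, "CO2", 25), 29.1, tolerance = 1e-3)
  expect_equal(conc_to_partial_pressure(0, "CO2", 25), 0)
  expect_equal(conc_to_partial_pressure(2.13, "CO2", 38), 8.8, tolerance = 1e-2)
  # round-trip identity
  set.seed(7)
  x <- runif(20, 0.1, 50)
  expect_equal(partial_pressure_to_conc(conc_to_partial_pressure(x, "O2", 38),
                                        "O2", 38),
               x, tolerance = 1e-12)
  expect_error(gas_solubility("CO2", 30), "no bundled solubility")
  expect_error(gas_solubility("N2", 25), "no bundled solubility")
})

test_that("bundled constants table matches the transcription verbatim and is internally consistent", {
  tab <- kinetics_table()
  expect_equal(nrow(tab), 6)
  rice25 <- tab[tab$species == "rice" & tab$temperature_C == 25, ]
  expect_identical(rice25$Kc_Pa, 29.1)
  expect_identical(rice25$Ko_kPa, 45.7)
  expect_identical(rice25$gammastar_Pa, 4.19)
  maize38 <- tab[tab$species == "maize" & tab$temperature_C == 38, ]
  expect_identical(maize38$Kc_Pa, 188.3)
  expect_identical(maize38$Kp_Pa, 13.2)
  # every constant rises from 25 to 38 C within species
  for (sp in unique(tab$species)) {
    t25 <- tab[tab$species == sp & tab$temperature_C == 25, ]
    t38 <- tab[tab$species == sp & tab$temperature_C == 38, ]
    for (col in c("Kc_Pa", "Ko_kPa", "gammastar_Pa")) {
      expect_gt(t38[[col]], t25[[col]])
    }
  }
  # gamma* and the derived Sco are mutually consistent at O = 21 kPa
  for (i in seq_len(nrow(tab))) {
    ks <- rubisco_kinetics(tab$species[i], tab$temperature_C[i])
    expect_equal(0.5 * 21000 / ks$Sco, ks$gammastar, tolerance = 1e-9)
  }
  # solubilities decrease with temperature
  expect_lt(gas_solubility("CO2", 38), gas_solubility("CO2", 25))
  expect_lt(gas_solubility("O2", 38), gas_solubility("O2", 25))
})

test_that("two-point Arrhenius interpolation hits both endpoints exactly and is monotone between", {
  s25 <- rubisco_kinetics("rice", 25)
  s38 <- rubisco_kinetics("rice", 38)
  expect_identical(kinetics_at_temperature(s25, s38, 25)$Kc, 29.1)
  expect_identical(kinetics_at_temperature(s25, s38, 38)$Kc, 87.7)
  mid <- kinetics_at_temperature(s25, s38, 31.5)
  expect_equal(mid$Kc, arrhenius_oracle(29.1, 87.7, 25, 38, 31.5),
               tolerance = 1e-12)
  expect_equal(mid$Kc, 51.116, tolerance = 1e-4)
  # strict monotonicity across the bracket for every constant
  Ts <- seq(25, 38, by = 0.5)
  for (field in c("Kc", "Ko", "gammastar")) {
    vals <- vapply(Ts, function(T) kinetics_at_temperature(s25, s38, T)[[field]],
                   numeric(1))
    expect_true(all(diff(vals) > 0))
  }
  # Q10 alternative also reproduces the endpoints
  expect_identical(kinetics_at_temperature(s25, s38, 38, method = "q10")$Kc, 87.7)
  expect_error(
    kinetics_at_temperature(s25, rubisco_kinetics("maize", 38), 30),
    "share species")
  expect_error(kinetics_at_temperature(s25, s38, 70), "0, 60")
})

test_that("standard kinetic sources return the published constants", {
  vc <- standard_kinetics("voncaemmerer", 25)
  expect_equal(vc$Kc, 65)
  expect_equal(vc$Ko, 45)
  expect_equal(vc$Kp, 8)
  expect_equal(vc$gammastar / 21000, 0.000193, tolerance = 1e-12)
  # Kp held invariant with temperature
  expect_equal(standard_kinetics("voncaemmerer", 38)$Kp, vc$Kp)
  # but Kc responds
  expect_gt(standard_kinetics("voncaemmerer", 38)$Kc, vc$Kc)
  # tobacco constants at the reference temperature equal the stored values
  b <- standard_kinetics("bernacchi", 25)
  expect_identical(b$Kc, 27.238)
  expect_identical(b$Ko, 16.582)
  b1 <- standard_kinetics("bernacchi", 25, variant = "ci_basis")
  expect_identical(b1$Kc, 40.49)
  expect_error(standard_kinetics("nonsense", 25))
})
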