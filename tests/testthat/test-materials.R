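test_that("mixture laws reproduce independent hand arithmetic", {
  # linear density mixing, Table-of-constants values
  expect_equal(density_mixture("blood", "Cu", 0), 1050)
  expect_equal(density_mixture("blood", "Cu", 1), 8933)
  expect_equal(density_mixture("blood", "Cu", 0.1), 0.9 * 1050 + 0.1 * 8933)
  expect_equal(density_mixture("blood", "Cu", 0.1), 1838.3)

  # Brinkman factor, oracle computed via exp/log arithmetic
  expect_equal(viscosity_ratio(0, 0), 1)
  expect_equal(viscosity_ratio(0.1, 0), exp(-2.5 * log(0.9)))
  expect_equal(viscosity_ratio(0.1, 0), 1.3013488, tolerance = 1e-7)

  # Maxwell ratio for alumina in blood at 5 percent:
  # (40 + 1.04 + 3.948) / (40 + 1.04 - 1.974)
  expect_equal(maxwell_conductivity_ratio(0.52, 40, 0.05),
               44.988 / 39.066)
  expect_equal(maxwell_conductivity_ratio(0.52, 40, 0.05),
               1.1515896, tolerance = 1e-6)
  expect_equal(maxwell_conductivity_ratio(0.52, 40, 0), 1)
  expect_equal(maxwell_conductivity_ratio(3, 3, 0.4), 1)

  # two-stage hybrid density: 0.95*(0.95*1050 + 0.05*3970) + 0.05*8933
  mix <- hybrid_mixture(0.05, 0.05)
  expect_equal(mix$rho_hnf, 1582.85)
  expect_equal(mix$C1, 0.95^5)
  expect_equal(mix$C1, 0.7737809, tolerance = 1e-7)
  expect_equal(mix$C2, 1582.85 / 1050)
})

test_that("viscosity ratio is symmetric and guards the jamming limit", {
  grid <- expand.grid(a = c(0, 0.05, 0.3, 0.9), b = c(0, 0.1, 0.7))
  for (i in seq_len(nrow(grid))) {
    expect_identical(viscosity_ratio(grid$a[i], grid$b[i]),
                     viscosity_ratio(grid$b[i], grid$a[i]))
  }
  expect_error(viscosity_ratio(1, 0), "phi1")
  expect_error(viscosity_ratio(0.2, 1.2), "phi2")
  expect_error(density_mixture("blood", "Cu", -0.1), "phi")
  expect_error(maxwell_conductivity_ratio(-1, 40, 0.1), "positive")
})

test_that("base-fluid limit recovers blood properties exactly", {
  mix <- hybrid_mixture(0, 0)
  expect_equal(mix$rho_hnf, 1050)
  expect_equal(mix$rhocp_hnf, 1050 * 3617)
  expect_equal(mix$mu_ratio, 1)
  expect_equal(mix$k_ratio, 1)
  expect_equal(mix$k_ratio_mono, 1)
  expect_equal(unname(model_coefficients(mix)), c(1, 1, 1))
})

test_that("hybrid formulas reduce to the mono-nanofluid laws at phi2 = 0", {
  for (phi1 in c(0.01, 0.05, 0.12)) {
    mix <- hybrid_mixture(phi1, 0)
    expect_equal(mix$rho_hnf, density_mixture("blood", "Al2O3", phi1))
    expect_equal(mix$rhocp_hnf,
                 heat_capacity_mixture("blood", "Al2O3", phi1))
    expect_equal(mix$mu_ratio, (1 - phi1)^-2.5)
    expect_equal(mix$k_ratio,
                 maxwell_conductivity_ratio(0.52, 40, phi1))
  }
})

test_that("Maxwell ratio stays within the dilute-suspension bounds", {
  k_cont <- 0.52
  for (k_part in c(5, 40, 400)) {
    ratio <- maxwell_conductivity_ratio(k_cont, k_part, seq(0, 1, by = 0.05))
    expect_true(all(ratio >= 1 - 1e-12))
    expect_true(all(ratio <= k_part / k_cont + 1e-12))
    expect_true(all(diff(ratio) > 0)) # more particles, more conductive
  }
})

test_that("C2 equals the independently mixed density ratio", {
  grid <- expand.grid(phi1 = c(0, 0.02, 0.1), phi2 = c(0, 0.05, 0.15))
  for (i in seq_len(nrow(grid))) {
    mix <- hybrid_mixture(grid$phi1[i], grid$phi2[i])
    rho_two_stage <- (1 - grid$phi2[i]) *
      density_mixture("blood", "Al2O3", grid$phi1[i]) +
      grid$phi2[i] * 8933
    expect_equal(mix$C2, rho_two_stage / 1050)
  }
})

test_that("density is non-decreasing in phi2 for a heavy second species", {
  rho <- purrr::map_dbl(seq(0, 0.3, by = 0.05),
                        ~ hybrid_mixture(0.05, .x)$rho_hnf)
  expect_true(all(diff(rho) > 0))
})

test_that("material registry is extendable but built-ins are immutable", {
  reg <- material_registry()
  expect_equal(reg$name, c("blood", "Al2O3", "Cu"))
  ext <- material_registry(tibble::tibble(name = "TiO2", rho = 4250,
                                          cp = 686.2, k = 8.9538))
  expect_equal(nrow(ext), 4)
  expect_equal(get_material("TiO2", ext)$k, 8.9538)
  expect_error(material_registry(tibble::tibble(name = "blood", rho = 1,
                                                cp = 1, k = 1)),
               "cannot be redefined")
  expect_error(get_material("unobtainium"), "unknown material")
  expect_error(material_registry(tibble::tibble(name = "bad", rho = -1,
                                                cp = 1, k = 1)),
               "positive")
})
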