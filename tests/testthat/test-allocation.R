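params <- default_ecoli_params()

test_that("default parameter sets reproduce the published mass and kinetic constants", {
  expect_equal(params$a, 2307.0 / 69.6)
  expect_equal(round(params$a, 1), 33.1)
  expect_equal(round(params$r, 2), 0.58)
  expect_equal(params$K_m, 102)
  expect_equal(params$k_on, 0.216)
  expect_equal(params$P_conc, 1.16e6)
  expect_equal(params$k_deg, 0)

  yeast <- default_yeast_mass_params()
  expect_equal(round(yeast$a, 1), 40.3)
  expect_equal(round(yeast$r, 2), 0.59)
  expect_true(is.na(yeast$k_cat))

  unit <- translation_params(1, 1, 1, 1)
  expect_equal(unit$a, 1)
  expect_equal(unit$r, 1)
})

test_that("parameter validation enforces positivity and the K_m ~ k_cat/k_on consistency", {
  expect_error(translation_params(-1, 1, 1, 1), "positive")
  expect_error(translation_params(1, 1, 1, 1, k_deg = -0.1), "k_deg")
  # 102 vs 22/0.216 = 101.85: within 1 percent, silent
  expect_silent(translation_params(2307, 69.6, 25.8, 1480,
                                   k_cat = 22, K_m = 102, k_on = 0.216))
  expect_warning(translation_params(2307, 69.6, 25.8, 1480,
                                    k_cat = 22, K_m = 150, k_on = 0.216),
                 "explicit K_m")
})

test_that("parameter sets survive a flat-file round trip", {
  path <- withr::local_tempfile(fileext = ".cfg")
  write_params(params, path)
  back <- read_params(path)
  for (f in c("m_R", "m_TC", "m_tRNA", "m_rRNA", "k_cat", "K_m", "k_on",
              "P_conc", "k_deg", "a", "r"))
    expect_equal(back[[f]], params[[f]], info = f)
  writeLines("nonsense = 1", path)
  expect_error(read_params(path), "unknown parameter")
})

test_that("protein synthesis flux is (mu + k_deg)[P] with h^-1 to s^-1 conversion", {
  expect_equal(protein_synthesis_flux(0, params), 0)
  expect_equal(protein_synthesis_flux(1, params), 1.16e6 / 3600)
  pdeg <- default_ecoli_params(k_deg = 0.03)
  expect_equal(protein_synthesis_flux(1, pdeg),
               1.03 * protein_synthesis_flux(1, params))
  expect_error(protein_synthesis_flux(-0.1, params), "mu")
})

test_that("closed-form optima match the golden-section oracle over 50 flux values", {
  v_grid <- 10^seq(-2, 3, length.out = 50)
  for (v in v_grid) {
    tc_star <- optimal_tc_conc(v, params)
    oracle <- golden_section(function(tc) mass_density_at_tc(tc, v, params),
                             lower = 1e-8, upper = 1e5, tol = 1e-9)
    expect_lt(abs(tc_star - oracle) / oracle, 1e-6)
  }
  v <- protein_synthesis_flux(1, params)
  expect_equal(optimal_tc_conc(v, params), 222.528514, tolerance = 1e-6)
  expect_equal(optimal_rib_conc(v, params), 21.359939, tolerance = 1e-6)
})

test_that("optimal concentrations obey the zero-flux and scaling limits", {
  expect_equal(optimal_tc_conc(0, params), 0)
  expect_equal(optimal_rib_conc(0, params), 0)
  expect_equal(optimal_tc_conc(4 * 322.2, params),
               2 * optimal_tc_conc(322.2, params))
  v <- c(0.5, 5, 50, 500)
  expect_true(all(optimal_rib_conc(v, params) > v / params$k_cat))
  expect_error(optimal_tc_conc(-1, params), "v")
  expect_error(optimal_rib_conc(-1, params), "v")
})

test_that("the analytic optimum beats perturbed allocations at the same flux", {
  v <- protein_synthesis_flux(1, params)
  tc_star <- optimal_tc_conc(v, params)
  c_star <- mass_density_at_tc(tc_star, v, params)
  expect_equal(c_star,
               combined_mass_density(tc_star, optimal_rib_conc(v, params),
                                     params))
  for (eps in c(0.01, 0.1, 0.5)) {
    expect_lte(c_star, mass_density_at_tc(tc_star * (1 + eps), v, params))
    expect_lte(c_star, mass_density_at_tc(tc_star * (1 - eps), v, params))
  }
})

test_that("combined mass density is the stated linear combination", {
  expect_equal(combined_mass_density(0, 0, params), 0)
  expect_equal(combined_mass_density(1, 0, params), 69.6)
  expect_equal(combined_mass_density(0, 1, params), 2307.0)
  expect_error(combined_mass_density(-1, 0, params), ">= 0")
})

test_that("the TC/ribosome growth law is decreasing with the correct limits and values", {
  mu <- seq(0.05, 3, by = 0.05)
  ratio <- optimal_tc_per_ribosome(mu, params)
  expect_true(all(diff(ratio) < 0))
  expect_equal(optimal_tc_per_ribosome(1e-9, params), params$a,
               tolerance = 1e-4)
  expect_equal(trna_rrna_mass_ratio(1e-9, params), params$r,
               tolerance = 1e-4)
  expect_equal(optimal_tc_per_ribosome(1.5, params), 9.022146,
               tolerance = 1e-6)
  expect_equal(optimal_tc_per_ribosome(1.0, params), 10.41284,
               tolerance = 1e-5)
  # consistency with the two closed-form optima: exact once K_m equals
  # k_cat/k_on; within the diffusion-limit approximation (102 vs 101.85 uM)
  # for the default set
  v <- protein_synthesis_flux(1, params)
  expect_equal(optimal_tc_per_ribosome(1, params),
               optimal_tc_conc(v, params) / optimal_rib_conc(v, params),
               tolerance = 1e-2)
  exact <- translation_params(2307, 69.6, 25.8, 1480, k_cat = 22,
                              k_on = 0.216, P_conc = 1.16e6)
  ve <- protein_synthesis_flux(1, exact)
  expect_equal(optimal_tc_per_ribosome(1, exact),
               optimal_tc_conc(ve, exact) / optimal_rib_conc(ve, exact))
})

test_that("mass ratio scales the molar ratio by m_tRNA/m_rRNA and is mass-scale invariant", {
  expect_equal(trna_rrna_mass_ratio(1.5, params),
               optimal_tc_per_ribosome(1.5, params) * 25.8 / 1480)
  expect_equal(trna_rrna_mass_ratio(1.5, params), 0.157278, tolerance = 1e-5)
  doubled <- translation_params(2307, 69.6, 2 * 25.8, 2 * 1480,
                                k_cat = 22, K_m = 102, k_on = 0.216,
                                P_conc = 1.16e6)
  expect_equal(trna_rrna_mass_ratio(1.5, doubled),
               trna_rrna_mass_ratio(1.5, params))
})

test_that("degradation shifts the growth law by k_deg", {
  pdeg <- default_ecoli_params(k_deg = 0.03)
  for (mu in c(0, 0.2, 1, 2))
    expect_equal(optimal_tc_per_ribosome(mu, pdeg),
                 optimal_tc_per_ribosome(mu + 0.03, params))
})

test_that("protein concentration follows Eq-14 arithmetic", {
  # Avogadro cancellation: 6.02214076e2 copies x 100 aa in 1 fL = 100 uM
  expect_equal(protein_concentration(6.02214076e2, 100, 1e-15), 100)
  one <- protein_concentration(1e4, 300, 2e-15)
  expect_equal(protein_concentration(1e4, 300, 4e-15), one / 2)
  expect_equal(protein_concentration(c(1e4, 1e4), c(300, 300), 2e-15),
               2 * one)
  expect_error(protein_concentration(numeric(), numeric(), 1e-15), "empty")
})

test_that("predict_allocation returns a consistent prediction table", {
  exact <- translation_params(2307, 69.6, 25.8, 1480, k_cat = 22,
                              k_on = 0.216, P_conc = 1.16e6)
  grid <- predict_allocation(c(0.5, 1, 1.5), exact)
  expect_named(grid, c("mu", "v", "tc_conc", "rib_conc", "tc_per_ribosome",
                       "trna_rrna_mass_ratio"))
  expect_equal(grid$tc_per_ribosome, grid$tc_conc / grid$rib_conc)
})
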