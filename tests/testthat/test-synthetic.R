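test_that("spectrum generator places lethargy peaks at the component energies", {
  g <- build_energy_grid()
  # all amplitudes zero -> zero spectrum
  zero <- spectrum_components(thermal_amplitude = 0, epithermal_amplitude = 0,
                              evaporation_amplitude = 0, direct_amplitude = 0)
  expect_equal(generate_spectrum(zero, g)$values, rep(0, 114))
  # direct-only component centered at 15.36 MeV
  direct <- spectrum_components(thermal_amplitude = 0,
                                epithermal_amplitude = 0,
                                evaporation_amplitude = 0,
                                direct_center = 15.36)
  sp <- generate_spectrum(direct, g)
  k <- which.max(to_lethargy(sp))
  expect_true(g$edges[k] <= 15.36 && 15.36 <= g$edges[k + 1])
  # thermal Maxwellian with kT = 2.59e-8 MeV peaks at 2 kT = 5.18e-8 MeV
  th <- spectrum_components(thermal_kT = 2.59e-8, epithermal_amplitude = 0,
                            evaporation_amplitude = 0, direct_amplitude = 0)
  k <- which.max(to_lethargy(generate_spectrum(th, g)))
  expect_true(g$edges[k] <= 5.18e-8 && 5.18e-8 <= g$edges[k + 1])
  # evaporation Maxwellian with T = 0.15 MeV peaks at 0.3 MeV
  ev <- spectrum_components(thermal_amplitude = 0, epithermal_amplitude = 0,
                            evaporation_temperature = 0.15,
                            direct_amplitude = 0)
  k <- which.max(to_lethargy(generate_spectrum(ev, g)))
  expect_true(g$edges[k] <= 0.3 && 0.3 <= g$edges[k + 1])
})

test_that("spectrum generation is additive in the components", {
  g <- build_energy_grid()
  full <- generate_spectrum(spectrum_components(), g)
  parts <- list(
    spectrum_components(epithermal_amplitude = 0, evaporation_amplitude = 0,
                        direct_amplitude = 0),
    spectrum_components(thermal_amplitude = 0, evaporation_amplitude = 0,
                        direct_amplitude = 0),
    spectrum_components(thermal_amplitude = 0, epithermal_amplitude = 0,
                        direct_amplitude = 0),
    spectrum_components(thermal_amplitude = 0, epithermal_amplitude = 0,
                        evaporation_amplitude = 0))
  summed <- Reduce(`+`, lapply(parts, function(cm)
    generate_spectrum(cm, g)$values))
  expect_equal(full$values, summed, tolerance = 1e-14)
  expect_true(all(full$values >= 0))
})

test_that("conventional sphere response peaks increase with diameter", {
  g <- build_energy_grid()
  for (seed in c(1, 42)) {
    resp <- generate_response_matrix(g, seed = seed)
    expect_true(all(resp$values >= 0))
    peaks <- apply(resp$values[1:6, ], 1,
                   function(r) g$centers[which.max(r)])
    expect_true(all(diff(peaks) > 0))
  }
})

test_that("only extended spheres respond substantially above 20 MeV", {
  g <- build_energy_grid()
  resp <- generate_response_matrix(g, seed = 1)
  frac <- apply(resp$values, 1,
                function(r) sum(r[g$centers > 20]) / sum(r))
  expect_true(all(frac[1:6] < 0.05))
  expect_true(all(frac[7:10] > 0.20))
  # sphere 9 carries the largest high-energy response integral
  he <- apply(resp$values, 1, function(r) sum(r[g$centers > 20]))
  expect_equal(which.max(he), 9L)
})

test_that("response generation is deterministic given the seed", {
  g <- build_energy_grid()
  a <- generate_response_matrix(g, seed = 7)
  b <- generate_response_matrix(g, seed = 7)
  expect_identical(a$values, b$values)
  c2 <- generate_response_matrix(g, seed = 8)
  expect_false(identical(a$values, c2$values))
})

test_that("a narrow grid is rejected for extended spheres", {
  narrow <- build_energy_grid(1e-9, 10, 40)
  expect_error(generate_response_matrix(narrow, seed = 1), "too narrow")
  expect_silent(generate_response_matrix(narrow, n_extended = 0, seed = 1))
})

test_that("simulated counts follow the folded means at large exposure", {
  g <- build_energy_grid()
  resp <- generate_response_matrix(g, seed = 1)
  sp <- generate_spectrum(spectrum_components(), g)
  mu <- fold_counts(sp, resp)$counts
  cv <- simulate_counts(sp, resp, exposure = 1e8, seed = 3)
  expect_true(all(abs(cv$counts / 1e8 - mu) / mu < 1e-3))
  # zero spectrum -> all counts zero, undefined uncertainties
  z <- fluence_spectrum(g, rep(0, 114))
  cz <- simulate_counts(z, resp, exposure = 10, seed = 1)
  expect_equal(cz$counts, rep(0, 10))
  expect_true(all(is.na(cz$rel_unc)))
})

test_that("count simulation is reproducible and flat uncertainty applies", {
  g <- build_energy_grid()
  resp <- generate_response_matrix(g, seed = 1)
  sp <- generate_spectrum(spectrum_components(), g)
  a <- simulate_counts(sp, resp, exposure = 2000, seed = 5)
  b <- simulate_counts(sp, resp, exposure = 2000, seed = 5)
  expect_identical(a$counts, b$counts)
  expect_equal(a$rel_unc, 1 / sqrt(a$counts))
  flat <- simulate_counts(sp, resp, exposure = 2000, seed = 5,
                          flat_rel_unc = 0.10)
  expect_equal(flat$rel_unc, rep(0.10, 10))
  expect_equal(flat$source, rep("experimental", 10))
})

test_that("synthetic depth-dose curves are deterministic without noise", {
  a <- generate_depth_dose("200")
  b <- generate_depth_dose("200")
  expect_identical(a$doses, b$doses)
  expect_equal(length(a$depths), 500L)
  expect_equal(diff(a$depths)[1], 0.1)
  n1 <- generate_depth_dose("200", noise_rel = 0.01, seed = 9)
  n2 <- generate_depth_dose("200", noise_rel = 0.01, seed = 9)
  expect_identical(n1$doses, n2$doses)
  expect_false(identical(n1$doses, a$doses))
})
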