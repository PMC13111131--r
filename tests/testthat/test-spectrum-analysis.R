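test_that("lethargy conversion divides by the log bin width and inverts", {
  g <- build_energy_grid()
  expect_equal(to_lethargy(fluence_spectrum(g, rep(0, 114))), rep(0, 114))
  # constant per-bin fluence on a log grid -> constant lethargy value
  r <- (250 / 1e-9)^(1 / 114)
  sp <- fluence_spectrum(g, rep(4.2, 114))
  expect_equal(to_lethargy(sp), rep(4.2 / log(r), 114), tolerance = 1e-12)
  # a 1/E spectrum (bin integral = c * log width) is flat in lethargy
  vals <- 0.7 * diff(log(g$edges))
  expect_equal(to_lethargy(fluence_spectrum(g, vals)), rep(0.7, 114),
               tolerance = 1e-6)
  # invertible: multiplying back recovers the input exactly
  sp2 <- random_spectrum(g, 91)
  expect_equal(to_lethargy(sp2) * diff(log(g$edges)), sp2$values,
               tolerance = 1e-14)
})

test_that("adjacent-bin smoothing averages the stated window", {
  expect_equal(smooth_adjacent(c(0, 3, 0)), c(1.5, 1, 1.5))
  expect_equal(smooth_adjacent(rep(2.5, 10)), rep(2.5, 10))
  expect_error(smooth_adjacent(c(1, 2)), "3 bins")
  # interior-only mass conservation of the moving average
  set.seed(17)
  x <- runif(50)
  y <- smooth_adjacent(x)
  expect_equal(sum(y[3:48]),
               sum((x[2:47] + x[3:48] + x[4:49]) / 3), tolerance = 1e-12)
  # range contraction over repeated passes
  z <- x
  for (k in 1:5) {
    z2 <- smooth_adjacent(z)
    expect_lte(max(z2), max(z) + 1e-12)
    expect_gte(min(z2), min(z) - 1e-12)
    z <- z2
  }
})

test_that("regional peaks are found in the lethargy representation", {
  g <- build_energy_grid()
  cm <- spectrum_components()
  sp <- generate_spectrum(cm, g)
  pk <- find_peaks(sp)
  expect_equal(pk$region, c("thermal", "evaporation", "direct"))
  expect_equal(pk$rel_intensity[pk$region == "direct"], 1)
  # the generator dials in the relative peak intensities directly
  expect_equal(pk$rel_intensity[pk$region == "thermal"], 0.55,
               tolerance = 0.05)
  expect_equal(pk$rel_intensity[pk$region == "evaporation"], 0.59,
               tolerance = 0.06)
  # peak energies: thermal 2 kT, evaporation 2 T, direct center
  expect_equal(pk$energy_MeV, c(5.18e-8, 0.30, 15.36), tolerance = 0.12)
  # rel_intensity invariant under uniform rescaling
  pk2 <- find_peaks(fluence_spectrum(g, 100 * sp$values))
  expect_equal(pk2$rel_intensity, pk$rel_intensity, tolerance = 1e-12)
})

test_that("single peak, tie-break and empty regions behave as documented", {
  g <- build_energy_grid()
  # exactly-zero regions are omitted with a warning
  vals <- rep(0, 114)
  vals[g$centers > 5] <- to_lethargy(generate_spectrum(
    spectrum_components(thermal_amplitude = 0, epithermal_amplitude = 0,
                        evaporation_amplitude = 0, direct_center = 15.36),
    g))[g$centers > 5] * lethargy_widths(g)[g$centers > 5]
  w <- capture_warnings(pk <- find_peaks(fluence_spectrum(g, vals)))
  expect_match(w, "thermal", all = FALSE)
  expect_equal(pk$region, "direct")
  expect_equal(pk$rel_intensity, 1)
  expect_lt(abs(log10(pk$energy_MeV / 15.36)), 0.1)
  # two equal maxima in a region: the lower-energy bin is reported
  vals <- rep(0, 114)
  idx <- which(g$centers > 5 & g$centers < 250)
  vals[idx[c(2, 5)]] <- 7
  suppressWarnings(pk2 <- find_peaks(fluence_spectrum(g, vals)))
  expect_equal(pk2$energy_MeV, g$centers[idx[2]])
})

test_that("peak intensity excess reproduces simple ratio arithmetic", {
  pk <- data.frame(region = c("thermal", "direct"),
                   rel_intensity = c(0.5, 1))
  expect_equal(peak_intensity_excess(pk), 100)
  expect_error(peak_intensity_excess(
    data.frame(region = "direct", rel_intensity = 1)), "present")
})

test_that("region fluence sums whole bins and pro-rates partial ones", {
  g <- decade_grid()  # edges on exact decades
  sp <- random_spectrum(g, 23)
  # full-range window equals the plain sum
  expect_equal(region_fluence(sp, 1e-9, 1e3), sum(sp$values),
               tolerance = 1e-12)
  expect_equal(region_fluence(fluence_spectrum(g, rep(0, 120)), 1e-6, 1), 0)
  # uniform-in-lethargy spectrum: half the decades -> half the total
  u <- fluence_spectrum(g, rep(1, 120))
  expect_equal(region_fluence(u, 1e-9, 1e-3), sum(u$values) / 2,
               tolerance = 1e-9)
  # pro-rating: window covering half of one log bin
  e_mid <- sqrt(g$edges[1] * g$edges[2])
  expect_equal(region_fluence(u, g$edges[1], e_mid), 0.5, tolerance = 1e-9)
  # additive over disjoint windows, monotone in width
  expect_equal(region_fluence(sp, 1e-9, 1e-4) + region_fluence(sp, 1e-4, 10),
               region_fluence(sp, 1e-9, 10), tolerance = 1e-12)
  expect_lte(region_fluence(sp, 1e-6, 1e-3), region_fluence(sp, 1e-6, 1e-2))
  expect_error(region_fluence(sp, 1e-12, 1), "outside")
})

test_that("spectrum comparison matches a hand-coded loop oracle", {
  g <- build_energy_grid()
  a <- random_spectrum(g, 33)
  expect_equal(compare_spectra(a, a), 0)
  b <- fluence_spectrum(g, 1.10 * a$values)
  expect_equal(compare_spectra(a, b), 10, tolerance = 1e-9)
  b2 <- random_spectrum(g, 34)
  oracle <- {
    s <- 0; n <- 0
    for (j in 1:114) {
      if (g$centers[j] > 12) next
      if (a$values[j] == 0 && b2$values[j] == 0) next
      s <- s + abs(a$values[j] - b2$values[j]) / max(a$values[j], 1e-30)
      n <- n + 1
    }
    100 * s / n
  }
  expect_equal(compare_spectra(a, b2, e_max = 12), oracle, tolerance = 1e-12)
  expect_error(compare_spectra(a, random_spectrum(decade_grid(), 35)),
               "grids")
})

test_that("region ratio report recovers constructed enhancement factors", {
  g <- decade_grid()
  base <- generate_spectrum(spectrum_components(direct_center = 15.36), g)
  # identical spectra -> all ratios 1
  same <- region_ratio_report(base, base)
  expect_equal(same$peak_ratio_quotient, 1)
  expect_equal(same$fluence_ratios$ratio, rep(1, 3))
  # thermal region x 2.3 (whole bins: decade-aligned window)
  v <- base$values
  th <- g$centers > 1e-9 & g$centers < 1e-6
  v[th] <- 2.3 * v[th]
  up <- fluence_spectrum(g, v)
  rep1 <- region_ratio_report(up, base)
  fr <- rep1$fluence_ratios
  expect_equal(fr$ratio[fr$region == "thermal"], 2.3, tolerance = 1e-9)
  expect_equal(rep1$peak_ratio_quotient, 2.3, tolerance = 1e-9)
  # moderation region x 8.8
  v2 <- base$values
  mod <- g$centers > 1e-6 & g$centers < 0.1
  v2[mod] <- 8.8 * v2[mod]
  rep2 <- region_ratio_report(fluence_spectrum(g, v2), base)
  fr2 <- rep2$fluence_ratios
  expect_equal(fr2$ratio[fr2$region == "moderation"], 8.8, tolerance = 1e-9)
})
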