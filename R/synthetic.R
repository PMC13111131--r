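#' Spectral components of a secondary neutron field
#'
#' Parametric decomposition of the characteristic secondary-neutron
#' spectrum around a proton therapy beam, expressed as additive lethargy
#' densities E*phi(E):
#' \itemize{
#'   \item thermal: Maxwellian, phi(E) ~ (E/kT^2) exp(-E/kT); its
#'     lethargy-representation peak sits at E = 2 kT (~5e-8 MeV for
#'     room-thermalized neutrons);
#'   \item epithermal/moderation: 1/E slowing-down continuum (flat in
#'     lethargy) between the thermal region and 0.1 MeV, with smooth
#'     logistic roll-offs;
#'   \item evaporation: Maxwellian with nuclear temperature `T_evap`
#'     (lethargy peak at 2 T_evap, typically ~0.3-1 MeV);
#'   \item direct (intranuclear-cascade): Gaussian in log10 E centered
#'     between a few and a couple hundred MeV.
#' }
#' Amplitudes are the peak heights of each component in the lethargy
#' representation, so relative peak intensities can be dialed in directly.
#' Defaults reproduce a 210 MeV, detector-off-axis measurement geometry
#' (thermal peak 5.18e-8 MeV at 0.55 relative intensity, evaporation peak
#' 0.30 MeV at 0.59, direct peak 15.36 MeV at 1).
#'
#' @param thermal_amplitude,thermal_kT Thermal peak height and Maxwellian
#'   temperature (MeV).
#' @param epithermal_amplitude Height of the flat 1/E lethargy plateau.
#' @param epithermal_e_min,epithermal_e_max Plateau bounds (MeV).
#' @param evaporation_amplitude,evaporation_temperature Evaporation peak
#'   height and nuclear temperature (MeV).
#' @param direct_amplitude,direct_center,direct_log_width Direct peak
#'   height, center energy (MeV) and Gaussian width in decades of energy.
#' @return An object of class `spectrum_components`.
#' @export
spectrum_components <- function(thermal_amplitude = 0.55,
                                thermal_kT = 2.59e-8,
                                epithermal_amplitude = 0.15,
                                epithermal_e_min = 1e-6,
                                epithermal_e_max = 0.1,
                                evaporation_amplitude = 0.59,
                                evaporation_temperature = 0.15,
                                direct_amplitude = 1,
                                direct_center = 15.36,
                                direct_log_width = 0.35) {
  for (nm in c("thermal_amplitude", "epithermal_amplitude",
               "evaporation_amplitude", "direct_amplitude"))
    check_scalar(get(nm), nm, nonneg = TRUE)
  for (nm in c("thermal_kT", "epithermal_e_min", "epithermal_e_max",
               "evaporation_temperature", "direct_center",
               "direct_log_width"))
    check_scalar(get(nm), nm, positive = TRUE)
  if (epithermal_e_min >= epithermal_e_max)
    stopf("epithermal bounds must satisfy e_min < e_max")
  structure(list(thermal_amplitude = thermal_amplitude,
                 thermal_kT = thermal_kT,
                 epithermal_amplitude = epithermal_amplitude,
                 epithermal_e_min = epithermal_e_min,
                 epithermal_e_max = epithermal_e_max,
                 evaporation_amplitude = evaporation_amplitude,
                 evaporation_temperature = evaporation_temperature,
                 direct_amplitude = direct_amplitude,
                 direct_center = direct_center,
                 direct_log_width = direct_log_width),
            class = "spectrum_components")
}

# lethargy density E*phi(E) of the component sum, evaluated at energies E
component_lethargy_density <- function(components, energy) {
  cm <- components
  maxwell <- function(amp, kT) {
    # E^2 exp(-E/kT) peaks at 2kT with value (2kT)^2 e^-2; normalize to amp
    amp * (energy / (2 * kT))^2 * exp(2 - energy / kT)
  }
  out <- maxwell(cm$thermal_amplitude, cm$thermal_kT) +
    maxwell(cm$evaporation_amplitude, cm$evaporation_temperature)
  if (cm$epithermal_amplitude > 0) {
    w <- 0.25  # roll-off width, decades
    x <- log10(energy)
    out <- out + cm$epithermal_amplitude *
      stats::plogis((x - log10(cm$epithermal_e_min)) / w) *
      stats::plogis((log10(cm$epithermal_e_max) - x) / w)
  }
  if (cm$direct_amplitude > 0) {
    z <- (log10(energy) - log10(cm$direct_center)) / cm$direct_log_width
    out <- out + cm$direct_amplitude * exp(-z^2 / 2)
  }
  out
}

#' Generate a synthetic secondary-neutron spectrum
#'
#' Evaluates the component lethargy density at the grid bin centers and
#' converts to bin-integrated fluence by multiplying with the per-bin
#' lethargy width.  Generation is additive in the components: summing the
#' spectra of individual components equals generating with all of them.
#'
#' @param components A [spectrum_components()] object.
#' @param grid An `energy_grid`.
#' @param rel_unc Optional per-bin relative uncertainty to attach (e.g.
#'   0.025 to mimic tally statistics).
#' @return A `fluence_spectrum`.
#' @export
generate_spectrum <- function(components, grid, rel_unc = NULL) {
  stopifnot(inherits(components, "spectrum_components"),
            inherits(grid, "energy_grid"))
  l <- component_lethargy_density(components, grid$centers)
  fluence_spectrum(grid, l * lethargy_widths(grid), rel_unc = rel_unc)
}

#' Generate a synthetic Bonner-sphere response matrix
#'
#' Surrogate for a transport-computed response library.  Each
#' conventional sphere (ids 1..`n_conventional`) gets a smooth log-normal
#' bell in energy whose peak energy increases strictly with sphere
#' diameter (larger spheres moderate harder neutrons best), spanning
#' ~1e-7 MeV to ~1.5 MeV.  Extended-range spheres
#' (ids `n_conventional+1` ...) add a saturating high-energy component
#' above ~20 MeV -- the spallation response of their lead/aluminium
#' layers -- with the third extended sphere (id 9 in the default set)
#' carrying the largest high-energy response.  A seed applies a small
#' reproducible jitter to peak positions and amplitudes so matrices are
#' not artificially identical across facilities; the same seed always
#' returns the identical matrix.
#'
#' These shapes are synthetic surrogates: they reproduce the moderation
#' ordering, energy coverage and magnitudes of real response functions,
#' not any specific published matrix.
#'
#' @param grid An `energy_grid`; must span at least ~1e-8 to 100 MeV when
#'   extended spheres are requested.
#' @param n_conventional,n_extended Number of conventional and
#'   extended-range spheres.
#' @param seed Integer seed controlling the jitter.
#' @param rel_unc Relative uncertainty attached to the matrix (scalar).
#' @return A `response_matrix` with sphere ids `1:(n_conventional+n_extended)`.
#' @export
generate_response_matrix <- function(grid, n_conventional = 6L,
                                     n_extended = 4L, seed = 1L,
                                     rel_unc = 0.03) {
  stopifnot(inherits(grid, "energy_grid"))
  n_conventional <- as.integer(n_conventional)
  n_extended <- as.integer(n_extended)
  if (n_conventional < 1L) stopf("need at least one conventional sphere")
  if (n_extended > 0L &&
      (grid$edges[1L] > 1e-8 || grid$edges[grid$n_bins + 1L] < 100))
    stopf(paste("grid too narrow for extended-range spheres; span at least",
                "1e-8 to 100 MeV"))
  n <- n_conventional + n_extended
  x <- log10(grid$centers)

  # deterministic base parameters
  peak_log <- seq(-7, log10(1.5), length.out = n_conventional)
  width <- 0.45 + 0.03 * seq_len(n_conventional)
  amp <- c(1.2, 2.0, 3.2, 3.0, 2.6, 2.2)[
    ((seq_len(n_conventional) - 1L) %% 6L) + 1L]
  he_amp_base <- c(1.0, 1.8, 2.6, 2.2)
  he_amp <- if (n_extended > 0L)
    he_amp_base[((seq_len(n_extended) - 1L) %% 4L) + 1L] else numeric(0)

  jit <- with_seed(seed, list(
    peak = stats::rnorm(n, 0, 0.01),
    amp = exp(stats::rnorm(n, 0, 0.02)),
    he = if (n_extended > 0L) exp(stats::rnorm(n_extended, 0, 0.02)) else NULL
  ))

  vals <- matrix(0, n, grid$n_bins)
  for (k in seq_len(n_conventional)) {
    z <- (x - (peak_log[k] + jit$peak[k])) / width[k]
    vals[k, ] <- amp[k] * jit$amp[k] * exp(-z^2 / 2)
  }
  for (k in seq_len(n_extended)) {
    i <- n_conventional + k
    # moderation bell like a large sphere, peak ~0.5-3 MeV
    pk <- log10(0.5) + 0.25 * (k - 1) + jit$peak[i]
    z <- (x - pk) / 0.6
    bell <- 1.5 * jit$amp[i] * exp(-z^2 / 2)
    # saturating spallation response above ~25 MeV
    he <- he_amp[k] * jit$he[k] * stats::plogis((x - log10(25)) / 0.25)
    vals[i, ] <- bell + he
  }
  response_matrix(grid, vals, sphere_ids = seq_len(n), rel_unc = rel_unc)
}

#' Simulate detector counts with Poisson noise
#'
#' Draws per-sphere counts from Poisson(exposure * folded mean).  The
#' default relative uncertainty is the counting-statistics estimate
#' 1/sqrt(counts); alternatively a flat relative uncertainty can be
#' imposed (0.10 is the usual manufacturer figure for a neutron ball cart
#' detector).  Spheres with zero counts get `rel_unc = NA` (undefined).
#'
#' @param spectrum A `fluence_spectrum`.
#' @param response A `response_matrix` on the same grid.
#' @param exposure Positive scale factor (source particles delivered);
#'   the default gives conventional-sphere counts of order 1e3-1e4 for the
#'   default spectrum and response.
#' @param seed Integer seed.
#' @param flat_rel_unc If non-NULL, use this flat relative uncertainty for
#'   every sphere instead of 1/sqrt(counts).
#' @param source Provenance flag for the output (default
#'   `"experimental"`: this operation stands in for the physical
#'   measurement).
#' @return A `count_vector`.
#' @export
simulate_counts <- function(spectrum, response, exposure = 2000, seed = 1L,
                            flat_rel_unc = NULL, source = "experimental") {
  check_scalar(exposure, "exposure", positive = TRUE)
  mu <- exposure * fold_counts(spectrum, response)$counts
  counts <- with_seed(seed, {
    out <- numeric(length(mu))
    small <- mu <= 2^30
    out[small] <- stats::rpois(sum(small), mu[small])
    # normal approximation for means beyond integer range
    if (any(!small))
      out[!small] <- round(stats::rnorm(sum(!small), mu[!small],
                                        sqrt(mu[!small])))
    out
  })
  counts <- pmax(counts, 0)
  rel <- if (is.null(flat_rel_unc)) {
    ifelse(counts > 0, 1 / sqrt(counts), NA_real_)
  } else {
    check_scalar(flat_rel_unc, "flat_rel_unc", nonneg = TRUE)
    rep(flat_rel_unc, length(counts))
  }
  count_vector(response$sphere_ids, counts, rel_unc = rel, source = source)
}
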