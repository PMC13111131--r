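#' Convert a spectrum to fluence per unit lethargy
#'
#' Divides each bin-integrated fluence by the bin's lethargy width
#' ln(edges[j+1]/edges[j]); on a log-equispaced grid this is a constant
#' divisor.  The lethargy representation (an E*phi(E)-like quantity) is
#' the standard way to display and analyze neutron spectra spanning many
#' decades: log-energy structure appears as peaks.
#'
#' @param spectrum A `fluence_spectrum`.
#' @return Numeric per-bin values (fluence per unit lethargy).
#' @export
to_lethargy <- function(spectrum) {
  stopifnot(inherits(spectrum, "fluence_spectrum"))
  spectrum$values / lethargy_widths(spectrum$grid)
}

#' Smooth per-bin values by adjacent-bin averaging
#'
#' Replaces each interior bin by the mean of itself and its two
#' neighbors; endpoints are averaged over their single existing neighbor
#' (a two-point mean).  Used to remove artificial single-bin peaks from
#' unfolded spectra before region analysis.  The operation never widens
#' the range of the data (max never increases, min never decreases).
#'
#' @param values Numeric vector, length >= 3.
#' @param passes Number of smoothing passes (default 1).
#' @return Smoothed vector of the same length.
#' @export
smooth_adjacent <- function(values, passes = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stopf("need at least 3 bins to smooth")
  if (passes < 0) stopf("`passes` must be >= 0")
  for (k in seq_len(passes)) {
    out <- values
    out[1L] <- mean(values[1:2])
    out[n] <- mean(values[(n - 1L):n])
    i <- 2:(n - 1L)
    out[i] <- (values[i - 1L] + values[i] + values[i + 1L]) / 3
    values <- out
  }
  values
}

#' Default spectral regions for secondary neutron fields
#'
#' Thermal 1e-9 to 1e-6 MeV; evaporation 0.1 to 5 MeV; direct 5 to
#' 250 MeV.  The moderation (slowing-down) region 1 eV to 0.1 MeV is
#' provided for fluence bookkeeping.  The 5 MeV evaporation/direct split
#' is a package choice (published tables place evaporation peaks at
#' 0.3-0.94 MeV and direct peaks at 7.6-124 MeV) and is configurable
#' wherever regions are taken.
#'
#' @return Named list of `c(e_lo, e_hi)` windows in MeV.
#' @export
default_regions <- function() {
  list(thermal = c(1e-9, 1e-6),
       evaporation = c(0.1, 5),
       direct = c(5, 250))
}

#' Locate regional peaks in the lethargy representation
#'
#' For every configured energy window, reports the bin-center energy and
#' per-lethargy intensity of the regional maximum, plus the intensity
#' relative to the direct peak.  Peak intensities are read in the
#' lethargy representation because that is the representation in which
#' spectra are plotted and peak tables quoted.  Ties are broken toward
#' the lowest-energy bin.  Regions that contain no positive values are
#' omitted with a warning.
#'
#' @param spectrum A non-negative `fluence_spectrum`.
#' @param regions Named list of `c(e_lo, e_hi)` windows (MeV); defaults
#'   to [default_regions()].
#' @param reference Region used to normalize `rel_intensity`
#'   (default `"direct"`).
#' @return Data frame with columns `region`, `energy_MeV`, `intensity`,
#'   `rel_intensity`.
#' @export
find_peaks <- function(spectrum, regions = default_regions(),
                       reference = "direct") {
  stopifnot(inherits(spectrum, "fluence_spectrum"))
  leth <- to_lethargy(spectrum)
  centers <- spectrum$grid$centers
  rows <- lapply(names(regions), function(nm) {
    win <- regions[[nm]]
    idx <- which(centers >= win[1L] & centers <= win[2L])
    if (length(idx) == 0L || all(leth[idx] == 0)) {
      warning(sprintf("region '%s' contains no positive values; omitted", nm),
              call. = FALSE)
      return(NULL)
    }
    k <- idx[which.max(leth[idx])]  # which.max: first (lowest-energy) tie
    data.frame(region = nm, energy_MeV = centers[k], intensity = leth[k],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no peaks found in any region")
  ref_int <- out$intensity[match(reference, out$region)]
  if (length(ref_int) == 0L || is.na(ref_int)) {
    warning(sprintf("reference region '%s' has no peak; rel_intensity is NA",
                    reference), call. = FALSE)
    out$rel_intensity <- NA_real_
  } else {
    out$rel_intensity <- out$intensity / ref_int
  }
  out
}

#' Percent intensity excess of one peak over another
#'
#' Convenience for statements of the form "the direct peak is X% more
#' intense than the thermal peak": returns
#' `100 * (I_ref - I_other) / I_other` from a peak table's relative (or
#' absolute) intensities.
#'
#' @param peaks Data frame with columns `region` and `rel_intensity`
#'   (as returned by [find_peaks()]).
#' @param reference,other Region names to compare.
#' @return Percent excess (positive when `reference` is more intense).
#' @export
peak_intensity_excess <- function(peaks, reference = "direct",
                                  other = "thermal") {
  ir <- peaks$rel_intensity[match(reference, peaks$region)]
  io <- peaks$rel_intensity[match(other, peaks$region)]
  if (is.na(ir) || is.na(io)) stopf("both regions must be present")
  if (io == 0) stopf("'%s' peak intensity is zero: excess undefined", other)
  100 * (ir - io) / io
}

#' Integrated fluence over an energy window
#'
#' Sums bin-integrated fluence over all bins inside `[e_lo, e_hi]`;
#' partially covered bins contribute in proportion to the covered
#' fraction of their log-energy width (i.e. the spectrum is taken
#' uniform in lethargy within a bin).
#'
#' @param spectrum A `fluence_spectrum`.
#' @param e_lo,e_hi Window bounds in MeV, inside the grid span.
#' @return Fluence (cm^-2).
#' @export
region_fluence <- function(spectrum, e_lo, e_hi) {
  stopifnot(inherits(spectrum, "fluence_spectrum"))
  check_scalar(e_lo, "e_lo", positive = TRUE)
  check_scalar(e_hi, "e_hi", positive = TRUE)
  if (e_lo >= e_hi) stopf("`e_lo` must be smaller than `e_hi`")
  edges <- spectrum$grid$edges
  n <- spectrum$grid$n_bins
  tol <- 1 + 1e-12
  if (e_lo < edges[1L] / tol || e_hi > edges[n + 1L] * tol)
    stopf("window [%.4g, %.4g] MeV lies outside the grid span [%.4g, %.4g]",
          e_lo, e_hi, edges[1L], edges[n + 1L])
  lo <- log(pmax(edges[-(n + 1L)], e_lo))
  hi <- log(pmin(edges[-1L], e_hi))
  cover <- pmax(hi - lo, 0) / diff(log(edges))
  sum(spectrum$values * cover)
}

#' Average relative difference between two spectra
#'
#' Mean over bins with center energy at or below `e_max` of
#' `|a_j - b_j| / max(a_j, eps)`, expressed in percent.  Bins where both
#' spectra are zero are excluded.  By convention the first argument is
#' the reference (e.g. the experimentally unfolded spectrum).
#'
#' @param a,b `fluence_spectrum`s on a common grid.
#' @param e_max Upper energy cut in MeV (default 12, the validity limit
#'   of a conventional Bonner sphere set).
#' @param eps Denominator floor.
#' @return Average relative difference in percent.
#' @export
compare_spectra <- function(a, b, e_max = 12, eps = 1e-30) {
  stopifnot(inherits(a, "fluence_spectrum"), inherits(b, "fluence_spectrum"))
  if (!grids_identical(a$grid, b$grid))
    stopf("spectra are on different grids")
  idx <- which(a$grid$centers <= e_max)
  av <- a$values[idx]; bv <- b$values[idx]
  keep <- !(av == 0 & bv == 0)
  if (!any(keep)) return(0)
  100 * mean(abs(av[keep] - bv[keep]) / pmax(av[keep], eps))
}

#' Compare two spectra's region structure (e.g. with/without room walls)
#'
#' Quantifies how the environment reshapes a spectrum: the
#' thermal-peak-to-broad-peak intensity ratio of each spectrum and their
#' quotient, plus the ratios of integrated fluence in the thermal,
#' moderation and total windows between the two spectra.  Zero
#' denominators yield `NA` entries.
#'
#' @param spectrum_with,spectrum_without `fluence_spectrum`s on a common
#'   grid (conventionally "with" includes the feature under study, e.g.
#'   bunker walls).
#' @param thermal,moderation Windows in MeV for the thermal and
#'   moderation (slowing-down) regions.
#' @param broad Window containing the fast broad peak.
#' @return A list with `peak_ratio_with`, `peak_ratio_without`,
#'   `peak_ratio_quotient`, and a data frame `fluence_ratios` with
#'   columns `region`, `with`, `without`, `ratio`.
#' @export
region_ratio_report <- function(spectrum_with, spectrum_without,
                                thermal = c(1e-9, 1e-6),
                                moderation = c(1e-6, 0.1),
                                broad = c(0.1, 250)) {
  stopifnot(inherits(spectrum_with, "fluence_spectrum"),
            inherits(spectrum_without, "fluence_spectrum"))
  if (!grids_identical(spectrum_with$grid, spectrum_without$grid))
    stopf("spectra are on different grids")
  grid <- spectrum_with$grid
  broad <- c(broad[1L], min(broad[2L], grid$edges[grid$n_bins + 1L]))
  peak_in <- function(spec, win) {
    leth <- to_lethargy(spec)
    idx <- which(grid$centers >= win[1L] & grid$centers <= win[2L])
    if (length(idx) == 0L) return(NA_real_)
    max(leth[idx])
  }
  ratio_or_na <- function(num, den) if (is.na(den) || den == 0) NA_real_
    else num / den
  pw <- ratio_or_na(peak_in(spectrum_with, thermal),
                    peak_in(spectrum_with, broad))
  po <- ratio_or_na(peak_in(spectrum_without, thermal),
                    peak_in(spectrum_without, broad))
  total <- c(grid$edges[1L], grid$edges[grid$n_bins + 1L])
  wins <- list(thermal = thermal, moderation = moderation, total = total)
  fr <- do.call(rbind, lapply(names(wins), function(nm) {
    w <- region_fluence(spectrum_with, wins[[nm]][1L], wins[[nm]][2L])
    o <- region_fluence(spectrum_without, wins[[nm]][1L], wins[[nm]][2L])
    data.frame(region = nm, with = w, without = o,
               ratio = ratio_or_na(w, o), stringsAsFactors = FALSE)
  }))
  list(peak_ratio_with = pw,
       peak_ratio_without = po,
       peak_ratio_quotient = ratio_or_na(pw, po),
       fluence_ratios = fr)
}
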