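#' Build a logarithmic energy grid
#'
#' Constructs the energy binning shared by fluence spectra and response
#' matrices: `n_bins` bins whose edges are equally spaced in log10 energy.
#' Bin centers are the geometric means of adjacent edges, so that
#' point-evaluated spectral functions are read at the log-midpoint of each
#' bin.  The default grid is the one used for secondary-neutron tallies in
#' proton therapy rooms: 114 bins from 0.001 eV (1e-9 MeV) to 250 MeV.
#'
#' @param e_min,e_max Lowest and highest bin edge, in MeV. Must satisfy
#'   `0 < e_min < e_max`.
#' @param n_bins Number of energy bins (at least 2).
#' @return An object of class `energy_grid` with fields `n_bins`, `edges`
#'   (length `n_bins + 1`, strictly increasing, MeV) and `centers`
#'   (length `n_bins`, MeV).
#' @examples
#' g <- build_energy_grid()           # 114 bins, 1e-9 to 250 MeV
#' g2 <- build_energy_grid(1, 100, 2) # edges 1, 10, 100
#' @export
build_energy_grid <- function(e_min = 1e-9, e_max = 250, n_bins = 114L) {
  check_scalar(e_min, "e_min", positive = TRUE)
  check_scalar(e_max, "e_max", positive = TRUE)
  if (e_min >= e_max) stopf("`e_min` must be smaller than `e_max`")
  if (!is.numeric(n_bins) || length(n_bins) != 1L || !is.finite(n_bins) ||
      n_bins != round(n_bins) || n_bins < 2)
    stopf("`n_bins` must be an integer >= 2")
  n_bins <- as.integer(n_bins)
  edges <- 10^seq(log10(e_min), log10(e_max), length.out = n_bins + 1L)
  # pin the endpoints exactly (seq leaves them exact, but be explicit)
  edges[1L] <- e_min
  edges[n_bins + 1L] <- e_max
  centers <- sqrt(edges[-1L] * edges[-(n_bins + 1L)])
  structure(
    list(n_bins = n_bins, edges = edges, centers = centers),
    class = "energy_grid"
  )
}

#' Per-bin lethargy widths of a grid
#'
#' Lethargy is u = ln(E_ref / E); the lethargy width of bin j is
#' ln(edges[j+1] / edges[j]).  For a log-equispaced grid this is constant.
#'
#' @param grid An `energy_grid`.
#' @return Numeric vector of length `grid$n_bins`.
#' @export
lethargy_widths <- function(grid) {
  stopifnot(inherits(grid, "energy_grid"))
  diff(log(grid$edges))
}

#' Test whether two grids share the same binning
#'
#' Edges must agree within a small relative tolerance; anything else is a
#' different grid and requires explicit interpolation (no silent
#' re-binning anywhere in the package).
#'
#' @param a,b `energy_grid` objects.
#' @param tol Maximum allowed relative edge difference.
#' @return Logical scalar.
#' @export
grids_identical <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "energy_grid"), inherits(b, "energy_grid"))
  if (a$n_bins != b$n_bins) return(FALSE)
  max(abs(a$edges - b$edges) / b$edges) <= tol
}

#' @export
print.energy_grid <- function(x, ...) {
  cat(sprintf("<energy_grid> %d bins, %.4g to %.4g MeV (log10-equispaced)\n",
              x$n_bins, x$edges[1L], x$edges[x$n_bins + 1L]))
  invisible(x)
}
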