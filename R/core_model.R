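#' Fluence spectrum on an energy grid
#'
#' A per-bin, bin-integrated neutron fluence (cm^-2; per source particle
#' when normalized).  Values are bin integrals, not densities: the folding
#' sum `m_i = sum_j R_ij * phi_j` applies no additional bin-width weight.
#' Use [to_lethargy()] for the per-unit-lethargy representation used in
#' plots and peak analysis.
#'
#' @param grid An `energy_grid`.
#' @param values Non-negative fluence per bin (length `grid$n_bins`).
#' @param rel_unc Optional per-bin relative (fractional) statistical
#'   uncertainty, all >= 0.
#' @return An object of class `fluence_spectrum`.
#' @export
fluence_spectrum <- function(grid, values, rel_unc = NULL) {
  stopifnot(inherits(grid, "energy_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_bins)
    stopf("`values` must have length %d (one per bin)", grid$n_bins)
  if (any(!is.finite(values)) || any(values < 0))
    stopf("fluence values must be finite and non-negative")
  if (!is.null(rel_unc)) {
    rel_unc <- as.numeric(rel_unc)
    if (length(rel_unc) == 1L) rel_unc <- rep(rel_unc, grid$n_bins)
    if (length(rel_unc) != grid$n_bins || any(!is.finite(rel_unc)) ||
        any(rel_unc < 0))
      stopf("`rel_unc` must be non-negative, length 1 or one per bin")
  }
  structure(list(grid = grid, values = values, rel_unc = rel_unc),
            class = "fluence_spectrum")
}

#' Bonner sphere response matrix
#'
#' Expected detector counts per unit fluence (cm^2), one row per moderator
#' sphere, one column per energy bin.  Sphere ids 1-6 conventionally label
#' the polyethylene spheres of increasing diameter (5.08 to 30.48 cm);
#' 7-10 label extended-range spheres with lead/aluminium inserts that stay
#' sensitive above 20 MeV.
#'
#' @param grid An `energy_grid`.
#' @param values Non-negative matrix, `length(sphere_ids)` x `grid$n_bins`.
#' @param sphere_ids Ordered sphere labels (default `1:nrow(values)`).
#' @param rel_unc Relative uncertainty of the response: a scalar, one value
#'   per sphere, or a full matrix; optional.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(grid, values, sphere_ids = NULL, rel_unc = NULL) {
  stopifnot(inherits(grid, "energy_grid"))
  values <- as.matrix(values)
  if (ncol(values) != grid$n_bins)
    stopf("response must have %d columns (one per bin)", grid$n_bins)
  if (any(!is.finite(values)) || any(values < 0))
    stopf("response values must be finite and non-negative")
  sphere_ids <- sphere_ids %||% seq_len(nrow(values))
  if (length(sphere_ids) != nrow(values))
    stopf("`sphere_ids` must have one entry per response row")
  if (!is.null(rel_unc)) {
    if (is.matrix(rel_unc)) {
      if (!all(dim(rel_unc) == dim(values)))
        stopf("matrix `rel_unc` must match the response dimensions")
    } else if (!length(rel_unc) %in% c(1L, nrow(values))) {
      stopf("`rel_unc` must be scalar, per-sphere, or a full matrix")
    }
    if (any(!is.finite(rel_unc)) || any(rel_unc < 0))
      stopf("`rel_unc` must be finite and non-negative")
  }
  structure(list(grid = grid, sphere_ids = sphere_ids, values = values,
                 rel_unc = rel_unc),
            class = "response_matrix")
}

#' Per-sphere count vector
#'
#' @param sphere_ids Ordered sphere labels.
#' @param counts Non-negative counts (or counts per emitted particle).
#' @param rel_unc Per-sphere relative uncertainty; `NA` marks spheres
#'   whose uncertainty is undefined (e.g. zero counts).
#' @param source Per-sphere provenance flag, `"experimental"` or
#'   `"simulated"` (recycled if scalar).
#' @return An object of class `count_vector`.
#' @export
count_vector <- function(sphere_ids, counts, rel_unc = NULL,
                         source = "simulated") {
  counts <- as.numeric(counts)
  n <- length(counts)
  if (length(sphere_ids) != n)
    stopf("`sphere_ids` and `counts` must have the same length")
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("counts must be finite and non-negative")
  if (!is.null(rel_unc)) {
    rel_unc <- as.numeric(rel_unc)
    if (length(rel_unc) == 1L) rel_unc <- rep(rel_unc, n)
    if (length(rel_unc) != n) stopf("`rel_unc` must have one entry per sphere")
    if (any(rel_unc < 0, na.rm = TRUE)) stopf("`rel_unc` must be non-negative")
  }
  source <- as.character(source)
  if (length(source) == 1L) source <- rep(source, n)
  if (length(source) != n || !all(source %in% c("experimental", "simulated")))
    stopf("`source` must be 'experimental' or 'simulated', one per sphere")
  structure(list(sphere_ids = sphere_ids, counts = counts, rel_unc = rel_unc,
                 source = source),
            class = "count_vector")
}

#' @export
print.count_vector <- function(x, ...) {
  df <- data.frame(sphere_id = x$sphere_ids, counts = x$counts,
                   rel_unc = if (is.null(x$rel_unc)) NA_real_ else x$rel_unc,
                   source = x$source)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.count_vector <- function(x, ...) {
  data.frame(sphere_id = x$sphere_ids, counts = x$counts,
             rel_unc = if (is.null(x$rel_unc)) NA_real_ else x$rel_unc,
             source = x$source, stringsAsFactors = FALSE)
}

#' Fold a fluence spectrum through a response matrix
#'
#' Computes the expected counts of every sphere, `m_i = sum_j R_ij phi_j`,
#' the discrete forward model linking the neutron fluence spectrum to the
#' Bonner sphere readings.  The spectrum and response must share the same
#' grid; folding never re-interpolates silently (use
#' [interpolate_response()] first if the grids differ).
#'
#' The folded relative uncertainties combine the spectrum's per-bin
#' statistical uncertainty with the response-matrix uncertainty in
#' quadrature; see [propagate_count_uncertainty()].
#'
#' @param spectrum A `fluence_spectrum`.
#' @param response A `response_matrix` on the same grid.
#' @return A `count_vector` with `source = "simulated"`.
#' @export
fold_counts <- function(spectrum, response) {
  stopifnot(inherits(spectrum, "fluence_spectrum"),
            inherits(response, "response_matrix"))
  if (!grids_identical(spectrum$grid, response$grid))
    stopf(paste("spectrum and response are tabulated on different energy",
                "grids; interpolate the response explicitly with",
                "interpolate_response()"))
  m <- as.vector(response$values %*% spectrum$values)
  rel <- propagate_count_uncertainty(spectrum, response)
  count_vector(response$sphere_ids, m, rel_unc = rel, source = "simulated")
}

#' Propagate fluence and response uncertainties to folded counts
#'
#' The per-sphere fluence contribution is the response-fluence-weighted
#' RMS of the per-bin relative uncertainties,
#' `u_i = sqrt( sum_j w_ij u_j^2 / sum_j w_ij )` with `w_ij = R_ij phi_j`
#' (a conservative rule that returns `u` exactly for a uniform per-bin
#' uncertainty `u`).  It is combined in quadrature with the
#' response-matrix relative uncertainty.
#'
#' @param spectrum A `fluence_spectrum`.
#' @param response A `response_matrix` on the same grid.
#' @param spectrum_rel_unc Per-bin relative uncertainties; defaults to
#'   `spectrum$rel_unc` (zero when absent).
#' @param response_rel_unc Response relative uncertainty (scalar,
#'   per-sphere, or full matrix); defaults to `response$rel_unc`
#'   (zero when absent).
#' @param folded Optional `count_vector` from [fold_counts()]; when given,
#'   a copy with the propagated `rel_unc` is returned instead of the bare
#'   uncertainty vector.
#' @return Per-sphere relative uncertainties, or an updated `count_vector`.
#' @export
propagate_count_uncertainty <- function(spectrum, response,
                                        spectrum_rel_unc = NULL,
                                        response_rel_unc = NULL,
                                        folded = NULL) {
  stopifnot(inherits(spectrum, "fluence_spectrum"),
            inherits(response, "response_matrix"))
  n_s <- nrow(response$values)
  u_bin <- spectrum_rel_unc %||% spectrum$rel_unc %||% 0
  if (length(u_bin) == 1L) u_bin <- rep(u_bin, spectrum$grid$n_bins)
  if (any(u_bin < 0)) stopf("spectrum uncertainties must be non-negative")
  u_resp <- response_rel_unc %||% response$rel_unc %||% 0
  if (any(u_resp < 0)) stopf("response uncertainties must be non-negative")

  w <- sweep(response$values, 2L, spectrum$values, `*`)  # w_ij = R_ij phi_j
  wsum <- rowSums(w)
  u_fl <- sqrt(rowSums(sweep(w, 2L, u_bin^2, `*`)) / ifelse(wsum > 0, wsum, 1))
  u_fl[wsum <= 0] <- 0

  if (is.matrix(u_resp)) {
    u_r <- sqrt(rowSums(w * u_resp^2) / ifelse(wsum > 0, wsum, 1))
    u_r[wsum <= 0] <- 0
  } else {
    u_r <- rep(u_resp, length.out = n_s)
  }
  rel <- sqrt(u_fl^2 + u_r^2)
  if (is.null(folded)) return(rel)
  stopifnot(inherits(folded, "count_vector"))
  folded$rel_unc <- rel
  folded
}

#' Interpolate a response matrix onto a new energy grid
#'
#' Each sphere's response is interpolated log-log (log E against log R)
#' at the target bin centers; segments with a zero response at either end
#' are interpolated linearly in R instead, so zero-padded tabulations do
#' not produce -Inf logs.  Extrapolation outside the span of the source
#' bin centers is refused.
#'
#' @param response A `response_matrix`.
#' @param target Target `energy_grid` (centers must lie inside the source
#'   centers' span).
#' @return A `response_matrix` on `target`.
#' @export
interpolate_response <- function(response, target) {
  stopifnot(inherits(response, "response_matrix"),
            inherits(target, "energy_grid"))
  x <- log10(response$grid$centers)
  xo <- log10(target$centers)
  if (min(xo) < min(x) || max(xo) > max(x))
    stopf(paste("target grid centers extend beyond the tabulated response",
                "(%.4g to %.4g MeV); refusing to extrapolate"),
          10^min(x), 10^max(x))
  idx <- findInterval(xo, x, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx >= length(x)] <- length(x) - 1L
  interp_row <- function(y) {
    y0 <- y[idx]; y1 <- y[idx + 1L]
    t <- (xo - x[idx]) / (x[idx + 1L] - x[idx])
    out <- y0 + t * (y1 - y0)                    # linear fallback
    pos <- y0 > 0 & y1 > 0
    out[pos] <- exp(log(y0[pos]) + t[pos] * (log(y1[pos]) - log(y0[pos])))
    out
  }
  vals <- t(apply(response$values, 1L, interp_row))
  rel <- response$rel_unc
  if (is.matrix(rel)) rel <- t(apply(rel, 1L, function(y) {
    y[idx] + (xo - x[idx]) / (x[idx + 1L] - x[idx]) * (y[idx + 1L] - y[idx])
  }))
  response_matrix(target, vals, sphere_ids = response$sphere_ids,
                  rel_unc = rel)
}
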