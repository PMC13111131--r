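# CSV readers/writers.  All files carry explicit units in the header
# (energy_MeV) and round-trip losslessly: numbers are written with 17
# significant digits.

fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

write_df <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read and write count vectors as CSV
#'
#' Columns: `sphere_id`, `counts`, `rel_unc`, `source`.  When the
#' `rel_unc` column is missing or empty, a default relative uncertainty
#' is applied: 0.10 for experimental counts (the usual manufacturer
#' figure for a neutron ball cart detector) and 0.025 for simulated
#' counts (typical tally statistics).  Malformed rows are rejected with
#' their line number.
#'
#' @param path File path.
#' @return [read_counts()] returns a `count_vector`.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sphere_id", "counts")
  if (!all(need %in% names(df)))
    stopf("'%s' must have columns sphere_id and counts", path)
  if (!"source" %in% names(df)) df$source <- "experimental"
  bad <- which(!is.finite(df$counts) | df$counts < 0)
  if (length(bad))
    stopf("invalid count at line %d of '%s' (counts must be >= 0)",
          bad[1L] + 1L, path)
  if (!"rel_unc" %in% names(df)) df$rel_unc <- NA_real_
  df$rel_unc <- as.numeric(df$rel_unc)
  miss <- is.na(df$rel_unc)
  df$rel_unc[miss] <- ifelse(df$source[miss] == "experimental", 0.10, 0.025)
  count_vector(df$sphere_id, df$counts, rel_unc = df$rel_unc,
               source = df$source)
}

#' @param counts A `count_vector`.
#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "count_vector"))
  df <- data.frame(sphere_id = counts$sphere_ids,
                   counts = fmt_num(counts$counts),
                   rel_unc = fmt_num(counts$rel_unc %||%
                                       rep(NA_real_, length(counts$counts))),
                   source = counts$source)
  write_df(df, path)
  invisible(path)
}

#' Read and write response matrices as CSV
#'
#' First column is the bin-center energy (`energy_MeV`, or `energy_eV`
#' which is converted to MeV on read); remaining columns are one sphere
#' each, named `sphere_<id>`.  Energies must be strictly increasing; the
#' grid edges are reconstructed assuming log-equispaced centers.
#'
#' @param path File path.
#' @param rel_unc Relative uncertainty to attach on read (scalar;
#'   default 0).
#' @return [read_response()] returns a `response_matrix`.
#' @export
read_response <- function(path, rel_unc = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ecol <- names(df)[1L]
  energy <- as.numeric(df[[1L]])
  if (grepl("_eV$", ecol)) energy <- energy / 1e6
  else if (!grepl("_MeV$", ecol))
    stopf("first column of '%s' must be energy_MeV or energy_eV", path)
  if (any(!is.finite(energy)) || any(diff(energy) <= 0))
    stopf("energies in '%s' must be finite and strictly increasing", path)
  n <- length(energy)
  # reconstruct a log-equispaced grid from the centers
  r <- (energy[n] / energy[1L])^(1 / (n - 1L))
  grid <- build_energy_grid(energy[1L] / sqrt(r), energy[n] * sqrt(r), n)
  if (max(abs(grid$centers - energy) / energy) > 1e-6)
    stopf("energies in '%s' are not log-equispaced bin centers", path)
  ids <- sub("^sphere_", "", names(df)[-1L])
  ids <- ifelse(grepl("^[0-9]+$", ids), as.integer(ids), ids)
  vals <- t(as.matrix(df[, -1L, drop = FALSE]))
  if (any(!is.finite(vals)) || any(vals < 0))
    stopf("response values in '%s' must be finite and non-negative", path)
  response_matrix(grid, vals, sphere_ids = ids, rel_unc = rel_unc)
}

#' @param response A `response_matrix`.
#' @rdname read_response
#' @export
write_response <- function(response, path) {
  stopifnot(inherits(response, "response_matrix"))
  df <- data.frame(energy_MeV = fmt_num(response$grid$centers))
  for (k in seq_along(response$sphere_ids))
    df[[paste0("sphere_", response$sphere_ids[k])]] <-
      fmt_num(response$values[k, ])
  write_df(df, path)
  invisible(path)
}

#' Read and write fluence spectra as CSV
#'
#' Columns: `e_low`, `e_high`, `e_center` (MeV), `fluence`, `rel_unc`.
#' The grid is rebuilt exactly from `e_low`/`e_high`.
#'
#' @param path File path.
#' @return [read_spectrum()] returns a `fluence_spectrum`.
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("e_low", "e_high", "fluence")
  if (!all(need %in% names(df)))
    stopf("'%s' must have columns e_low, e_high, fluence", path)
  edges <- c(df$e_low, df$e_high[nrow(df)])
  if (any(abs(df$e_high[-nrow(df)] - df$e_low[-1L]) >
            1e-9 * df$e_low[-1L]))
    stopf("bins in '%s' are not contiguous", path)
  if (any(diff(edges) <= 0))
    stopf("bin edges in '%s' must be strictly increasing", path)
  bad <- which(!is.finite(df$fluence) | df$fluence < 0)
  if (length(bad))
    stopf("invalid fluence at line %d of '%s'", bad[1L] + 1L, path)
  n <- nrow(df)
  grid <- structure(list(n_bins = n, edges = edges,
                         centers = sqrt(edges[-1L] * edges[-(n + 1L)])),
                    class = "energy_grid")
  rel <- if ("rel_unc" %in% names(df) && !all(is.na(df$rel_unc)))
    ifelse(is.na(df$rel_unc), 0, df$rel_unc) else NULL
  fluence_spectrum(grid, df$fluence, rel_unc = rel)
}

#' @param spectrum A `fluence_spectrum`.
#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "fluence_spectrum"))
  g <- spectrum$grid
  df <- data.frame(e_low = fmt_num(g$edges[-(g$n_bins + 1L)]),
                   e_high = fmt_num(g$edges[-1L]),
                   e_center = fmt_num(g$centers),
                   fluence = fmt_num(spectrum$values),
                   rel_unc = fmt_num(spectrum$rel_unc %||%
                                       rep(NA_real_, g$n_bins)))
  write_df(df, path)
  invisible(path)
}

#' Read and write depth-dose curves as CSV
#'
#' Columns: `depth_cm`, `dose`.
#'
#' @param path File path.
#' @return [read_depth_dose()] returns a `depth_dose_curve`.
#' @export
read_depth_dose <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("depth_cm", "dose") %in% names(df)))
    stopf("'%s' must have columns depth_cm and dose", path)
  depth_dose_curve(df$depth_cm, df$dose)
}

#' @param curve A `depth_dose_curve`.
#' @rdname read_depth_dose
#' @export
write_depth_dose <- function(curve, path) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  write_df(data.frame(depth_cm = fmt_num(curve$depths),
                      dose = fmt_num(curve$doses)), path)
  invisible(path)
}
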