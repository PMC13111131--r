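#' Average proportional factor between experimental and simulated counts
#'
#' Experimental counts and per-source-particle simulated counts live on
#' different scales; before they can be mixed into one hybrid vector, the
#' simulated counts must be rescaled by the average ratio
#' (experimental / simulated) over the spheres measured with both
#' systems.
#'
#' @param experimental,simulated `count_vector`s sharing the subset
#'   spheres.
#' @param sphere_subset Sphere ids over which to average (default: the
#'   ids common to both vectors).
#' @param method `"arithmetic"` (default) or `"geometric"` mean of the
#'   per-sphere ratios.
#' @return Positive scalar: experimental counts per simulated count.
#' @export
compute_scaling_factor <- function(experimental, simulated,
                                   sphere_subset = NULL,
                                   method = c("arithmetic", "geometric")) {
  stopifnot(inherits(experimental, "count_vector"),
            inherits(simulated, "count_vector"))
  method <- match.arg(method)
  subset <- sphere_subset %||%
    intersect(experimental$sphere_ids, simulated$sphere_ids)
  if (length(subset) == 0L) stopf("no common spheres to average over")
  ie <- match(subset, experimental$sphere_ids)
  is_ <- match(subset, simulated$sphere_ids)
  if (anyNA(ie) || anyNA(is_))
    stopf("sphere(s) %s missing from one of the count vectors",
          paste(subset[is.na(ie) | is.na(is_)], collapse = ", "))
  sim <- simulated$counts[is_]
  if (any(sim == 0))
    stopf("simulated counts are zero for sphere(s) %s: ratio undefined",
          paste(subset[sim == 0], collapse = ", "))
  ratios <- experimental$counts[ie] / sim
  if (method == "arithmetic") mean(ratios) else exp(mean(log(ratios)))
}

#' Assemble a hybrid experimental/simulated count vector
#'
#' Builds the count vector handed to the unfolder when only the
#' conventional spheres were physically measured: experimental counts are
#' kept verbatim for the spheres they cover, and the simulated counts of
#' the remaining (extended-range) spheres are multiplied by the scaling
#' factor from [compute_scaling_factor()].  Relative uncertainties and
#' provenance flags travel with their counts (an exact scale factor does
#' not change a relative uncertainty).
#'
#' @param experimental `count_vector` for the measured spheres.
#' @param simulated `count_vector` covering every sphere of the final set.
#' @param factor Positive scaling factor (experimental per simulated).
#' @return A `count_vector` over `simulated$sphere_ids`.
#' @export
assemble_hybrid_counts <- function(experimental, simulated, factor) {
  stopifnot(inherits(experimental, "count_vector"),
            inherits(simulated, "count_vector"))
  check_scalar(factor, "factor", positive = TRUE)
  ids <- simulated$sphere_ids
  ie <- match(ids, experimental$sphere_ids)
  if (!all(experimental$sphere_ids %in% ids))
    stopf("experimental spheres %s are absent from the simulated set",
          paste(setdiff(experimental$sphere_ids, ids), collapse = ", "))
  counts <- ifelse(!is.na(ie), experimental$counts[ie],
                   factor * simulated$counts)
  eu <- if (is.null(experimental$rel_unc)) rep(NA_real_, length(ie)) else
    experimental$rel_unc[ie]
  su <- if (is.null(simulated$rel_unc)) rep(NA_real_, length(ids)) else
    simulated$rel_unc
  rel <- ifelse(!is.na(ie), eu, su)
  src <- ifelse(!is.na(ie), experimental$source[ie], simulated$source)
  count_vector(ids, counts, rel_unc = rel, source = src)
}

#' Configuration for MLEM unfolding
#'
#' @param max_iterations Iteration cap (>= 1, default 5000).
#' @param tolerance Convergence threshold on the maximum relative per-bin
#'   change of the spectrum between iterations (default 1e-5).
#' @param initial_guess Optional `fluence_spectrum` used as the starting
#'   estimate (e.g. a transport-predicted spectrum).  When absent, a flat
#'   -in-lethargy strictly positive spectrum is used, scaled to roughly
#'   match the total counts.
#' @param record_history If TRUE, keep the per-iteration log-likelihood
#'   and maximum relative change.
#' @return An object of class `mlem_config`.
#' @export
mlem_config <- function(max_iterations = 5000L, tolerance = 1e-5,
                        initial_guess = NULL, record_history = FALSE) {
  if (!is.numeric(max_iterations) || max_iterations < 1)
    stopf("`max_iterations` must be >= 1")
  check_scalar(tolerance, "tolerance", positive = TRUE)
  if (!is.null(initial_guess) &&
      !inherits(initial_guess, "fluence_spectrum"))
    stopf("`initial_guess` must be a fluence_spectrum or NULL")
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, initial_guess = initial_guess,
                 record_history = isTRUE(record_history)),
            class = "mlem_config")
}

#' MLEM unfolding of a Bonner-sphere count vector
#'
#' Maximum Likelihood Expectation Maximization estimate of the fluence
#' spectrum n from counts m under the Poisson forward model
#' `m_i ~ Poisson((R n)_i)`, via the canonical multiplicative update with
#' sensitivity normalization:
#' \deqn{n_j \leftarrow n_j \frac{\sum_i R_{ij}\, m_i / (Rn)_i}{\sum_i R_{ij}}.}
#' The update preserves non-negativity and the support of the initial
#' guess (bins starting at zero stay zero), and never decreases the
#' Poisson log-likelihood.  Iteration stops when the maximum relative
#' per-bin change falls below `config$tolerance` or after
#' `config$max_iterations`.
#'
#' With far fewer spheres than energy bins the problem is under-
#' determined: the converged spectrum depends on the initial guess, and
#' the refolded-count residuals (`refolded` vs the input counts) are the
#' primary quality metric.  Per-sphere uncertainties are carried through
#' for reporting only; the update itself is unweighted.
#'
#' @param counts `count_vector` (non-negative) over the response's
#'   spheres.
#' @param response `response_matrix`.
#' @param config An [mlem_config()].
#' @return An object of class `mlem_result` with fields `spectrum`,
#'   `iterations`, `converged`, `refolded` (a `count_vector`),
#'   `log_likelihood`, and `history` (data frame or NULL).
#' @export
mlem_unfold <- function(counts, response, config = mlem_config()) {
  stopifnot(inherits(counts, "count_vector"),
            inherits(response, "response_matrix"),
            inherits(config, "mlem_config"))
  m <- counts$counts[match(response$sphere_ids, counts$sphere_ids)]
  if (anyNA(m))
    stopf("counts missing for sphere(s) %s",
          paste(response$sphere_ids[is.na(m)], collapse = ", "))
  if (any(m < 0)) stopf("counts must be non-negative")
  R <- response$values
  grid <- response$grid

  if (all(m == 0)) {
    spec <- fluence_spectrum(grid, rep(0, grid$n_bins))
    return(structure(list(spectrum = spec, iterations = 0L,
                          converged = TRUE,
                          refolded = fold_counts(spec, response),
                          log_likelihood = 0, history = NULL),
                     class = "mlem_result"))
  }

  if (!is.null(config$initial_guess)) {
    if (!grids_identical(config$initial_guess$grid, grid))
      stopf("initial guess is on a different grid than the response")
    n <- config$initial_guess$values
  } else {
    # flat in lethargy, scaled so total refolded counts ~ total counts
    n <- lethargy_widths(grid)
    s <- sum(R %*% n)
    if (s > 0) n <- n * sum(m) / s
  }

  sens <- colSums(R)
  eps <- 1e-30
  hist_ll <- hist_delta <- if (config$record_history)
    numeric(config$max_iterations) else NULL
  converged <- FALSE
  iter <- 0L
  ll <- -Inf
  for (iter in seq_len(config$max_iterations)) {
    q <- as.vector(R %*% n)
    ratio <- ifelse(q > 0, m / q, 0)
    corr <- as.vector(crossprod(R, ratio))
    corr <- ifelse(sens > 0, corr / sens, 1)
    n_new <- n * corr
    delta <- max(abs(n_new - n) / pmax(n, eps))
    n <- n_new
    qn <- as.vector(R %*% n)
    ll <- sum(m[qn > 0] * log(qn[qn > 0])) - sum(qn)
    if (config$record_history) {
      hist_ll[iter] <- ll
      hist_delta[iter] <- delta
    }
    if (delta < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  spec <- fluence_spectrum(grid, n)
  structure(list(
    spectrum = spec,
    iterations = iter,
    converged = converged,
    refolded = fold_counts(spec, response),
    log_likelihood = ll,
    history = if (config$record_history)
      data.frame(iteration = seq_len(iter),
                 log_likelihood = hist_ll[seq_len(iter)],
                 max_rel_change = hist_delta[seq_len(iter)]) else NULL
  ), class = "mlem_result")
}

#' @export
print.mlem_result <- function(x, ...) {
  cat(sprintf("<mlem_result> %d iterations, %s (log-likelihood %.6g)\n",
              x$iterations,
              if (x$converged) "converged" else "iteration cap reached",
              x$log_likelihood))
  invisible(x)
}
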