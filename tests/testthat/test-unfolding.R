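test_that("scaling factor is the mean experimental/simulated ratio", {
  ex <- count_vector(1:3, c(10, 20, 30), source = "experimental")
  sim <- count_vector(1:3, c(1, 4, 5), source = "simulated")
  expect_equal(compute_scaling_factor(ex, sim), mean(c(10, 5, 6)))
  expect_equal(compute_scaling_factor(ex, sim, method = "geometric"),
               exp(mean(log(c(10, 5, 6)))))
  # identical counts -> factor 1; doubled -> factor 2
  expect_equal(compute_scaling_factor(ex, ex), 1)
  ex2 <- count_vector(1:3, 2 * sim$counts, source = "experimental")
  expect_equal(compute_scaling_factor(ex2, sim), 2)
  sim0 <- count_vector(1:3, c(1, 0, 5))
  expect_error(compute_scaling_factor(ex, sim0), "sphere")
})

test_that("hybrid counts keep experimental spheres verbatim and scale the rest", {
  ex <- count_vector(1:6, c(100, 200, 300, 400, 500, 600),
                     rel_unc = 0.10, source = "experimental")
  sim <- count_vector(1:10, c(5, 10, 15, 20, 25, 30, 1, 2, 3, 4),
                      rel_unc = 0.025, source = "simulated")
  factor <- 3.45e3
  hy <- assemble_hybrid_counts(ex, sim, factor)
  expect_equal(hy$counts[1:6], ex$counts)
  expect_equal(hy$counts[7:10], c(3.45e3, 6.90e3, 1.035e4, 1.38e4))
  expect_equal(hy$source, c(rep("experimental", 6), rep("simulated", 4)))
  expect_equal(hy$rel_unc, c(rep(0.10, 6), rep(0.025, 4)))
  # identity: factor 1 with simulated == experimental on 1-6
  sim2 <- count_vector(1:10, c(ex$counts, 7:10), source = "simulated")
  hy2 <- assemble_hybrid_counts(ex, sim2, 1)
  expect_equal(hy2$counts, c(ex$counts, 7:10))
  # missing sphere -> error
  expect_error(assemble_hybrid_counts(ex, count_vector(2:10, 2:10), 1),
               "absent")
})

test_that("scaling round trip recenters the mean ratio at one", {
  set.seed(14)
  ex <- count_vector(1:6, runif(6, 100, 1000), source = "experimental")
  sim <- count_vector(1:10, runif(10, 0.01, 0.1), source = "simulated")
  f <- compute_scaling_factor(ex, sim, sphere_subset = 1:6)
  scaled <- f * sim$counts[1:6]
  expect_equal(mean(ex$counts / scaled), 1, tolerance = 1e-12)
})

test_that("MLEM converges to the exact solution of an invertible system", {
  g <- build_energy_grid(1, 100, 2)
  resp <- response_matrix(g, diag(2))
  counts <- count_vector(1:2, c(4, 6))
  res <- mlem_unfold(counts, resp,
                     mlem_config(max_iterations = 10000, tolerance = 1e-12))
  expect_true(res$converged)
  expect_equal(res$spectrum$values, c(4, 6), tolerance = 1e-6)
  # general invertible 3x3 system, checked against a direct solve
  g3 <- build_energy_grid(1, 1000, 3)
  R <- matrix(c(2, 1, 0,
                0, 3, 1,
                1, 0, 2), 3, byrow = TRUE)
  truth <- c(1.5, 2.0, 0.5)
  m <- as.vector(R %*% truth)
  expect_equal(solve(R, m), truth)  # oracle: the system is invertible
  res3 <- mlem_unfold(count_vector(1:3, m), response_matrix(g3, R),
                      mlem_config(max_iterations = 50000,
                                  tolerance = 1e-13))
  expect_equal(res3$spectrum$values, truth, tolerance = 1e-4)
})

test_that("an exactly consistent initial guess is an MLEM fixed point", {
  g <- build_energy_grid(1e-9, 250, 30)
  resp <- random_response(g, 8, 51)
  n0 <- random_spectrum(g, 52)
  m <- fold_counts(n0, resp)
  res <- mlem_unfold(m, resp,
                     mlem_config(max_iterations = 1, tolerance = 1e-30,
                                 initial_guess = n0))
  expect_equal(res$spectrum$values, n0$values, tolerance = 1e-12)
})

test_that("MLEM preserves non-negativity, support, and the Poisson likelihood", {
  g <- build_energy_grid(1e-9, 250, 40)
  resp <- random_response(g, 8, 61)
  set.seed(62)
  truth <- fluence_spectrum(g, runif(40, 0, 2))
  m <- fold_counts(truth, resp)
  init_vals <- runif(40, 0.5, 2)
  init_vals[c(3, 17, 30)] <- 0
  init <- fluence_spectrum(g, init_vals)
  res <- mlem_unfold(m, resp,
                     mlem_config(max_iterations = 300, tolerance = 1e-12,
                                 initial_guess = init,
                                 record_history = TRUE))
  expect_true(all(res$spectrum$values >= 0))
  expect_equal(res$spectrum$values[c(3, 17, 30)], c(0, 0, 0))
  ll <- res$history$log_likelihood
  expect_true(all(diff(ll) >= -1e-8 * abs(ll[-length(ll)])))
})

test_that("MLEM is scale-equivariant", {
  g <- build_energy_grid(1e-9, 250, 30)
  resp <- random_response(g, 6, 71)
  set.seed(72)
  m <- count_vector(1:6, runif(6, 10, 100))
  n0 <- fluence_spectrum(g, runif(30, 0.1, 1))
  c0 <- 137.5
  res1 <- mlem_unfold(m, resp,
                      mlem_config(max_iterations = 200, tolerance = 1e-30,
                                  initial_guess = n0))
  m2 <- count_vector(1:6, c0 * m$counts)
  n02 <- fluence_spectrum(g, c0 * n0$values)
  res2 <- mlem_unfold(m2, resp,
                      mlem_config(max_iterations = 200, tolerance = 1e-30,
                                  initial_guess = n02))
  expect_equal(res2$spectrum$values, c0 * res1$spectrum$values,
               tolerance = 1e-10)
})

test_that("degenerate MLEM inputs are handled explicitly", {
  g <- build_energy_grid(1e-9, 250, 20)
  resp <- random_response(g, 4, 81)
  res <- mlem_unfold(count_vector(1:4, rep(0, 4)), resp)
  expect_true(res$converged)
  expect_equal(res$spectrum$values, rep(0, 20))
  expect_error(mlem_unfold(count_vector(1:3, 1:3), resp), "missing")
})
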