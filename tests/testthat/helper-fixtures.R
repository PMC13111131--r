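# Small builders shared across test files.

# grid whose edges land on exact decades (12 decades / 120 bins)
decade_grid <- function() build_energy_grid(1e-9, 1e3, 120)

random_spectrum <- function(grid, seed) {
  set.seed(seed)
  fluence_spectrum(grid, runif(grid$n_bins, 0, 5))
}

random_response <- function(grid, n_spheres, seed) {
  set.seed(seed)
  response_matrix(grid,
                  matrix(runif(n_spheres * grid$n_bins, 0, 2),
                         nrow = n_spheres))
}

# reference Bragg-curve range tables for the 200/210 MeV beams (cm)
mc_r_table <- function() {
  data.frame(energy = c(200, 210),
             r90 = c(25.85, 28.08),
             r80 = c(25.92, 28.17),
             r20 = c(26.27, 28.56))
}

exp_r_table <- function() {
  data.frame(energy = c(200, 210),
             r90 = c(25.83, 28.10),
             r80 = c(25.87, 28.14),
             r20 = c(26.37, 28.64),
             r90_unc = c(0.06, 0.06),
             r80_unc = c(0.05, 0.05),
             r20_unc = c(0.03, 0.03))
}

# unique scratch path (parent dir created, leaf left to the writer)
local_path <- function(name) {
  d <- tempfile("bonnerspec")
  dir.create(d)
  file.path(d, name)
}
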