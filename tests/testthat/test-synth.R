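test_that("the separation generator hits the noise-free and Rayleigh limits", {
  g <- chain_geometry(9, 40)
  dimer <- oligomer_composition(c(0, 1))
  sch <- labeling_scheme("internal_1to1", 1)
  ds <- simulate_flimp_measurements(g, dimer, sch, loc_sigma_nm = 1e-9,
                                    n_measurements = 30, seed = 41)
  expect_equal(ds$r_obs_nm, rep(9, 30), tolerance = 1e-6)

  # coincident sites: observed distance is Rayleigh with scale sqrt(2)*sigma
  g0 <- chain_geometry(1e-9)
  ds0 <- simulate_flimp_measurements(g0, dimer, sch, loc_sigma_nm = 2,
                                     n_measurements = 4000, seed = 42)
  sc <- 2 * sqrt(2)
  expect_equal(mean(ds0$r_obs_nm), sc * sqrt(pi / 2),
               tolerance = 3 * sc * sqrt((4 - pi) / 2) / sqrt(4000))

  # end scheme never samples monomers and keeps one pair per chain
  mix <- oligomer_composition(c(0.5, 0.3, 0.2))
  dse <- simulate_flimp_measurements(g, mix, labeling_scheme("end_2Nto2"),
                                     loc_sigma_nm = 1, n_measurements = 50,
                                     seed = 43)
  expect_true(all(attr(dse, "truth")$size >= 2))

  # bit-reproducible given the seed
  ds_a <- simulate_flimp_measurements(g, mix, sch, 1.5, 20, seed = 44)
  ds_b <- simulate_flimp_measurements(g, mix, sch, 1.5, 20, seed = 44)
  expect_identical(ds_a$r_obs_nm, ds_b$r_obs_nm)

  # a scheme that can never label a pair exhausts the generator
  mono <- oligomer_composition(c(1))
  expect_error(simulate_flimp_measurements(g, mono,
                                           labeling_scheme("end_2Nto2"),
                                           1, 1, seed = 45, max_tries = 50),
               "generator-exhausted")
})

test_that("photobleaching stacks respect survival statistics", {
  comp <- oligomer_composition(c(0.6, 0.4))
  st <- simulate_pbics_stack(comp, 0.5, 0.5, n_rounds = 4, image_px = 256,
                             omega_px = 3, seed = 46)
  alive <- st$truth$alive
  # survival is monotone non-increasing per fluorophore
  expect_true(all(alive[, -1] <= alive[, -ncol(alive)]))
  # truth survival fraction after round t is ~ 0.5^t
  fr <- colMeans(alive)
  for (t in 1:4)
    expect_lte(abs(fr[t + 1] - 0.5^t), 3 * sqrt(0.5^t / nrow(alive)) + 0.01)
  # mean image intensity tracks the realised survival fraction
  m <- vapply(st$rounds, mean, numeric(1))
  expect_equal(m[2] / m[1], fr[2], tolerance = 0.05)
  # reproducibility
  st2 <- simulate_pbics_stack(comp, 0.5, 0.5, n_rounds = 4, image_px = 256,
                              omega_px = 3, seed = 46)
  expect_identical(st$rounds[[1]], st2$rounds[[1]])
})

test_that("track simulation produces labelled co-diffusion truth", {
  sim0 <- simulate_tracks(n_free_per_channel = 10, n_pairs = 0,
                          n_frames = 20, seed = 47)
  expect_equal(sum(sim0$truth$is_pair), 0)

  simI <- simulate_tracks(n_free_per_channel = 0, n_pairs = 5,
                          tau_on_mean_s = Inf, n_frames = 20, seed = 48)
  expect_equal(simI$truth$bound_frames, rep(20, 5))

  # empirical mean bound duration matches the generator within 3 SE
  simT <- simulate_tracks(n_free_per_channel = 0, n_pairs = 500,
                          tau_on_mean_s = 0.5, n_frames = 100, seed = 49)
  b_s <- simT$truth$bound_frames * 0.05
  expect_equal(mean(b_s), 0.5, tolerance = 3 * 0.5 / sqrt(500) + 0.025)
})

test_that("FRET titrations are monotone and clipped to [0, 1]", {
  expect_equal(mc_efficiency(8, 0, 5), 0)
  dens <- c(2000, 10000, 50000)
  resp <- fret_response(dens, R0 = 5, h_grid = seq(2, 20, by = 0.5),
                        n_config = 150, seed = 50)
  # decreasing in h at fixed density, increasing in density at fixed h
  for (j in seq_along(dens))
    expect_true(all(diff(resp$E[, j]) <= 1e-9))
  expect_true(all(resp$E[, 1] <= resp$E[, 3] + 0.02))
  obs <- simulate_fret(8, dens, n_cells_per_density = 20, noise_sd = 0.3,
                       seed = 51, response = resp)
  expect_true(all(obs$efficiency >= 0 & obs$efficiency <= 1))
})
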