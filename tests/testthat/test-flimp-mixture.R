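test_that("a single Rician component is recovered from seeded data", {
  ds <- make_rice_dataset(13, 100, 2, seed = 21)
  fit <- fit_mixture(ds, 1, seed = 22)
  expect_equal(fit$nu, 13, tolerance = 0.6)   # 3 SE at n = 100, sigma = 2
  expect_equal(fit$weight, 1)
})

test_that("duplicating every measurement leaves the fitted positions unchanged", {
  ds <- make_rice_dataset(c(5, 13), 120, 2, seed = 23)
  dup <- flimp_dataset(rep(ds$r_obs_nm, 2), rep(ds$sigma_nm, 2))
  f1 <- fit_mixture(ds, 2, seed = 24)
  f2 <- fit_mixture(dup, 2, seed = 24)
  expect_equal(f1$nu, f2$nu, tolerance = 0.05)
  expect_error(fit_mixture(ds, 200), "exceed")
})

test_that("BIC selects parsimonious K and never splits truncated data", {
  ds2 <- make_rice_dataset(c(5, 13), 200, 2, seed = 25)
  sel2 <- select_K(ds2, K_max = 4, restarts = 2, seed = 26)
  expect_equal(sel2$K, 2)
  expect_equal(sort(sel2$components$nu), c(5, 13), tolerance = 0.8)
  expect_equal(sum(sel2$components$n_measurements), 200)

  ds1 <- make_rice_dataset(13, 150, 2, seed = 27)
  sel1 <- select_K(ds1, K_max = 4, restarts = 2, seed = 28)
  expect_equal(sel1$K, 1)

  # K = 2 on single-component data: no BIC-beating likelihood gain
  f2 <- fit_mixture(ds1, 2, restarts = 2, seed = 29)
  f1 <- fit_mixture(ds1, 1, restarts = 2, seed = 29)
  expect_lt(2 * (f2$loglik - f1$loglik), 2 * log(nrow(ds1)))

  # n = 1 forces K = 1
  tiny <- flimp_dataset(10, 2)
  expect_equal(select_K(tiny, K_max = 4)$K, 1)

  # truncating to one component's measurements does not increase K
  near5 <- ds2[ds2$r_obs_nm < 9, , drop = FALSE]
  class(near5) <- class(ds2)
  expect_equal(select_K(near5, K_max = 3, restarts = 2, seed = 30)$K, 1)
})

test_that("bootstrap errors are zero for degenerate data and shrink with n", {
  dg <- flimp_dataset(rep(10, 20), rep(1e-6, 20))
  be <- bootstrap_errors(dg, 1, n_boot = 10, seed = 31, check_K = FALSE)
  expect_equal(be$sd_nu, 0, tolerance = 1e-6)

  small <- make_rice_dataset(13, 50, 2, seed = 32)
  large <- make_rice_dataset(13, 400, 2, seed = 33)
  sd_small <- bootstrap_errors(small, 1, n_boot = 40, seed = 34,
                               check_K = FALSE)$sd_nu
  sd_large <- bootstrap_errors(large, 1, n_boot = 40, seed = 35,
                               check_K = FALSE)$sd_nu
  expect_lt(sd_large, sd_small)
  # K-stability on clean two-component data
  ds2 <- make_rice_dataset(c(5, 13), 200, 2, seed = 36)
  be2 <- bootstrap_errors(ds2, 2, n_boot = 8, seed = 37, restarts = 1,
                          K_max = 3, check_K = TRUE)
  expect_gte(be2$k_stability, 0.5)
})

test_that("range fractions follow the documented overlap conventions", {
  ds <- flimp_dataset(c(5, 17.5, 18), c(1, 1, 1),
                      ci_lo_nm = c(4, 16, 14), ci_hi_nm = c(6, 19, 22))
  fr <- range_fractions(ds, list(five = 5, dimer = c(0, 15),
                                 oligomer = c(20, 60)))
  expect_equal(unname(fr["five"]), 1 / 3)       # CI (4,6) contains 5
  expect_equal(unname(fr["oligomer"]), 1 / 3)   # only (14,22) reaches 20
  # (14,22) overlaps both the dimer and oligomer ranges: classes not exclusive
  expect_equal(unname(fr["dimer"]), 2 / 3)
  expect_error(range_fractions(ds, list(c(10, 5))), "lo <= hi")
})
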