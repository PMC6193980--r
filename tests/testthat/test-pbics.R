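test_that("the bleach-curve model evaluates its closed form", {
  expect_equal(cd_model(c(1), 0.5), 0.5)              # monomers: linear in p
  expect_equal(cd_model(c(0, 1), 1), 1)               # CD(1) = cluster density
  expect_equal(cd_model(c(0, 1), 0.5), 2 / 3)
  expect_error(cd_model(c(0, 0), 0.5), "not all zero")
  expect_error(cd_model(c(1, -1), 0.5), "non-negative")
})

test_that("the model matches the binomial-survival oracle", {
  set.seed(61)
  for (i in 1:25) {
    c_j <- runif(8) * 2
    p <- runif(1)
    expect_equal(cd_model(c_j, p), cd_binomial_oracle(c_j, p),
                 tolerance = 1e-12)
  }
})

test_that("model invariants: limits, Cauchy-Schwarz bound, monotonicity", {
  set.seed(62)
  for (i in 1:10) {
    c_j <- runif(8)
    expect_equal(cd_model(c_j, 0), 0)
    expect_equal(cd_model(c_j, 1e-9) / 1e-9, sum(seq_len(8) * c_j),
                 tolerance = 1e-6)
    expect_lte(cd_model(c_j, 1), sum(c_j) + 1e-12)
    p <- seq(0.05, 1, by = 0.05)
    expect_true(all(diff(cd_model(c_j, p)) > 0))
  }
  one <- c(0, 0, 1, 0)
  expect_equal(cd_model(one, 1), sum(one))           # equality: one species
})

test_that("ICS cluster density recovers truth and is scale invariant", {
  st <- simulate_pbics_stack(oligomer_composition(c(1)), 0.5, 0.6,
                             n_rounds = 1, image_px = 256, omega_px = 3,
                             seed = 63)
  img <- st$rounds[[1]]
  truth <- length(st$truth$sizes) / (256 * 0.1)^2
  est <- cluster_density(img, 3, 0.1)
  expect_true(est$qc_pass)
  expect_equal(est$cd, truth, tolerance = 0.1 * truth)
  est2 <- cluster_density(2 * img, 3, 0.1)
  expect_equal(est2$cd, est$cd, tolerance = 1e-6)
  flat <- matrix(5, 128, 128)
  expect_false(cluster_density(flat, 3, 0.1)$qc_pass)
})

test_that("surviving intensity fractions track the bleach truth", {
  st <- simulate_pbics_stack(oligomer_composition(c(0.7, 0.3)), 0.5, 0.5,
                             n_rounds = 4, image_px = 192, omega_px = 3,
                             seed = 64)
  p <- bleach_fraction(st)
  expect_equal(p[1], 1)
  surv <- colMeans(st$truth$alive)   # realised survival, sizes weighted in
  expect_equal(p[-1], (surv[-1] / surv[1]), tolerance = 0.08)
  # identical frames give p = 1 throughout
  same <- list(st$rounds[[1]], st$rounds[[1]])
  expect_equal(bleach_fraction(same), c(1, 1))
})

test_that("composition fitting recovers single species exactly and mixtures
           through the identifiable functionals", {
  p <- seq(1, 0.125, length.out = 8)
  for (j in c(1, 2, 3, 5)) {
    c_true <- numeric(8); c_true[j] <- 1
    fit <- fit_composition(pbics_curve(p, cd_model(c_true, p)), seed = 65)
    expect_gte(fit$fractions[j], 0.99)
  }
  # mixed truth with noise: molecule-normalised oligomer fraction recovered
  truth <- c(0.6, 0.25, 0.1, 0.05)
  set.seed(66)
  cdv <- cd_model(truth, p) * (1 + rnorm(8, 0, 0.01))
  fit <- fit_composition(pbics_curve(p, cdv), seed = 67)
  expect_lte(abs(fit$oligomer_fraction - oligomer_resident_fraction(truth)),
             0.1)
  # the identifiable functionals are matched regardless of structure
  jj <- 1:8
  expect_equal(fit$A, sum(jj[1:4] * truth), tolerance = 0.05 * 1.6)
  free <- fit_composition(pbics_curve(p, cdv), seed = 68,
                          structure = "free")
  expect_equal(free$A, fit$A, tolerance = 0.05 * 1.6)
  expect_error(fit_composition(pbics_curve(c(1, 0.5), c(1, 0.6))),
               ">= 3|nrow")
})

test_that("replicate aggregation reports mean and SD per size", {
  p <- seq(1, 0.2, length.out = 8)
  truth <- exponential_composition(8, 0.4)$fractions
  set.seed(69)
  fits <- lapply(1:7, function(i) {
    cdv <- cd_model(truth, p) * (1 + rnorm(8, 0, 0.02))
    fit_composition(pbics_curve(p, cdv), seed = 70 + i)
  })
  agg <- aggregate_replicates(fits)
  expect_equal(agg$n, 7)
  truth_olig <- oligomer_resident_fraction(truth)
  expect_lte(abs(agg$mean_oligomer_fraction - truth_olig),
             2 * agg$sd_oligomer_fraction + 0.02)
  # identical fits have zero SD
  agg0 <- aggregate_replicates(list(fits[[1]], fits[[1]]))
  expect_equal(agg0$sd_fractions, rep(0, 8))
  expect_equal(aggregate_replicates(fits[1:2])$mean_fractions,
               (fits[[1]]$fractions + fits[[2]]$fractions) / 2)
})
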