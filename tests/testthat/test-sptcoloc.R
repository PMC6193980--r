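make_set <- function(coords, fov = c(100, 100), dt = 0.05) {
  track_set(coords, fov_px = fov, frame_interval_s = dt)
}

test_that("registration recovers identity, affine, and warped maps", {
  set.seed(71)
  xy <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  reg_id <- fit_registration(xy, xy)
  expect_equal(reg_id$rms_px, 0, tolerance = 1e-9)
  expect_equal(apply_registration(reg_id, xy), xy, tolerance = 1e-9)

  A <- matrix(c(0.98, 0.02, -0.015, 1.01), 2)
  b <- c(2.5, -1.0)
  to <- t(A %*% t(xy) + b)
  reg_aff <- fit_registration(xy, to)
  expect_lt(reg_aff$rms_px, 1e-9)

  warp <- function(p) cbind(p[, 1] + 1e-4 * p[, 2]^2 + 5e-7 * p[, 1]^3,
                            p[, 2] - 2e-4 * p[, 1] * p[, 2])
  to_w <- warp(xy) + matrix(rnorm(80, 0, 0.05), ncol = 2)
  reg_w <- fit_registration(xy, to_w)
  expect_lte(reg_w$rms_px, 0.1)
  expect_error(fit_registration(xy[1:4, ], xy[1:4, ]), "not enough|rank")
})

test_that("temporal smoothing preserves constants and damps white noise", {
  const <- data.frame(track = 1, frame = 1:20, x_px = 3, y_px = 7)
  sm <- smooth_track(const)
  expect_equal(sm$x_px, rep(3, 20))
  one <- data.frame(track = 1, frame = 1, x_px = 4, y_px = 4)
  expect_equal(smooth_track(one), one)

  set.seed(72)
  n <- 800
  noisy <- data.frame(track = 1, frame = 1:n,
                      x_px = rnorm(n), y_px = rnorm(n))
  sm <- smooth_track(noisy, fwhm_frames = 4)
  # linear-filter variance factor: sum of squared (normalised) kernel weights
  sigma <- 4 / (2 * sqrt(2 * log(2)))
  k <- exp(-(-25:25)^2 / (2 * sigma^2)); k <- k / sum(k)
  mid <- 100:(n - 100)
  expect_equal(var(sm$x_px[mid]), sum(k^2), tolerance = 0.05 * 3)
})

test_that("proximity linking follows particles and never merges distant ones", {
  # one particle, small steps
  det1 <- data.frame(frame = 1:30, x_px = cumsum(rnorm(30, 0, 0.2)) + 50,
                     y_px = 50)
  linked <- link_features(det1, max_step_px = 2)
  expect_equal(length(unique(linked$track)), 1)

  # two far-apart particles stay distinct
  det2 <- rbind(data.frame(frame = 1:30, x_px = 10, y_px = 10),
                data.frame(frame = 1:30, x_px = 90, y_px = 90))
  linked2 <- link_features(det2, max_step_px = 3)
  expect_equal(length(unique(linked2$track)), 2)
  expect_equal(length(unique(linked2$track[linked2$x_px < 50])), 1)

  # seeded Brownian particles at low density: links match truth
  set.seed(73)
  n_part <- 8; n_fr <- 40
  truth <- do.call(rbind, lapply(seq_len(n_part), function(i)
    data.frame(id = i, frame = 1:n_fr,
               x_px = cumsum(rnorm(n_fr, 0, 0.4)) + runif(1, 10, 90),
               y_px = cumsum(rnorm(n_fr, 0, 0.4)) + runif(1, 10, 90))))
  truth <- truth[order(truth$frame), ]   # align with frame-ordered output
  linked3 <- link_features(truth[, -1], max_step_px = 3)
  tab <- table(truth$id, linked3$track)
  purity <- sum(apply(tab, 2, max)) / nrow(truth)
  expect_gte(purity, 0.95)
})

test_that("colocalisation detection applies the total-frames and run rules", {
  tr <- function(id, x, nf = 10) data.frame(track = id, frame = seq_len(nf),
                                            x_px = x, y_px = 5)
  A <- make_set(tr(1, 5))
  B <- make_set(tr(1, 5.1))
  s <- detect_coloc(A, B)
  expect_equal(s$fraction_A, 1)
  expect_equal(nrow(s$events), 1)
  expect_equal(s$events$tau_on_s, 0.5)       # 10 frames x 50 ms

  far <- detect_coloc(A, make_set(tr(1, 8)))
  expect_equal(far$fraction_A, 0)
  expect_length(far$tau_on_s, 0)

  # within a pixel for exactly 4 frames: below the >= 5 threshold
  xb <- c(5.1, 5.1, 5.1, 5.1, 8, 8, 8, 8, 8, 8)
  four <- detect_coloc(A, make_set(data.frame(track = 1, frame = 1:10,
                                              x_px = xb, y_px = 5)))
  expect_equal(four$fraction_A, 0)

  # empty input produces an explicit empty result
  emptyB <- make_set(data.frame(track = integer(0), frame = integer(0),
                                x_px = numeric(0), y_px = numeric(0)))
  se <- detect_coloc(A, emptyB)
  expect_true(is.na(se$fraction_A))
  expect_equal(nrow(se$events), 0)
})

test_that("track randomisation is an isometry with a fair flip", {
  set.seed(74)
  path <- data.frame(track = 1, frame = 1:12,
                     x_px = cumsum(runif(12, -1, 1)) + 50,
                     y_px = cumsum(runif(12, -1, 1)) + 50)
  set <- make_set(path)
  rnd <- randomize_tracks(set, seed = 75)
  step_lengths <- function(d) sqrt(diff(d$x_px)^2 + diff(d$y_px)^2)
  expect_equal(sort(step_lengths(as.data.frame(rnd$detections))),
               sort(step_lengths(path)), tolerance = 1e-9)

  # flip probability 0.5: chirality sign of an L-shaped 3-point track
  ell <- do.call(rbind, lapply(1:10000, function(i)
    data.frame(track = i, frame = 1:3, x_px = c(10, 11, 11),
               y_px = c(10, 10, 11))))
  rnd2 <- randomize_tracks(make_set(ell), seed = 76)
  d <- rnd2$detections
  chir <- d[, {
    v1 <- c(x_px[2] - x_px[1], y_px[2] - y_px[1])
    v2 <- c(x_px[3] - x_px[2], y_px[3] - y_px[2])
    sign(v1[1] * v2[2] - v1[2] * v2[1])
  }, by = track]$V1
  expect_equal(mean(chir < 0), 0.5, tolerance = 0.015)

  # single-point tracks scatter across the field of view
  pts <- do.call(rbind, lapply(1:400, function(i)
    data.frame(track = i, frame = 1, x_px = 50, y_px = 50)))
  rnd3 <- randomize_tracks(make_set(pts), seed = 77)
  expect_true(all(rnd3$detections$x_px >= 0 & rnd3$detections$x_px <= 100))
  expect_gt(diff(range(rnd3$detections$x_px)), 80)
})

test_that("coincidence correction nulls independent channels", {
  sim <- simulate_tracks(n_free_per_channel = 120, n_pairs = 0,
                         n_frames = 60, fov_px = c(200, 100), seed = 78)
  res <- coloc_analysis(sim$channelA, sim$channelB, n_rand = 15, seed = 79)
  n <- res$raw$n_tracks_A
  expect_lt(abs(res$corrected_A), 3 * sqrt(0.01 * 0.99 / n) + 0.03)
  # empty channel B: coincidental fraction 0 by convention
  emptyB <- track_set(data.frame(track = integer(0), frame = integer(0),
                                 x_px = numeric(0), y_px = numeric(0)),
                      c(200, 100))
  cf <- coincidental_fraction(sim$channelA, emptyB, n_rand = 2)
  expect_equal(cf$coincidental_A, 0)
})

test_that("the two-sample KS wrapper matches its reference behaviour", {
  x <- c(1, 2, 3, 4, 5)
  same <- ks_two_tailed(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  disj <- ks_two_tailed(1:50, 101:150)
  expect_equal(disj$D, 1)
  expect_lt(disj$p, 1e-6)
  expect_warning(ks_two_tailed(1, c(1, 2)), "unreliable")
})
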