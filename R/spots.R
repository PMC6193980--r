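# Spot-movie rendering and two-emitter extraction: the movie-level route to a
# FLImP separation measurement. A spot holds 1-2 emitters that photobleach in
# single steps; localising the last survivor and the difference image of the
# earlier segment gives the two positions whose distance is the measurement.

#' Simulate a TIRF spot movie with stepwise photobleaching
#'
#' Renders two Gaussian-PSF emitters separated by `separation_nm` on a
#' constant background. Each emitter contributes a constant photon rate until
#' its bleach frame, after which it is dark for good; shot noise is Poisson
#' and camera read noise Gaussian.
#'
#' @param separation_nm true emitter separation (nm).
#' @param photons_per_frame expected photons per emitter per frame (> 0).
#' @param background expected background photons per pixel per frame.
#' @param psf_sigma_px PSF Gaussian sigma (pixels).
#' @param pixel_size_nm pixel size (nm).
#' @param n_frames movie length (frames).
#' @param frame_interval_s frame interval (s); default 0.28.
#' @param bleach_frames integer vector length 2: last bright frame of each
#'   emitter. Drawn geometrically from `mean_bleach_frames` when NULL.
#' @param mean_bleach_frames mean bleach frames used when `bleach_frames` is
#'   NULL (kept distinct so the two steps are resolvable).
#' @param img_size image side (pixels, odd recommended).
#' @param read_noise_sd Gaussian read noise sd (photons).
#' @param noise disable all noise with FALSE (deterministic render).
#' @param seed integer seed.
#' @return list of class `spot_movie`: `frames` (array T x H x W),
#'   `pixel_size_nm`, `frame_interval_s`, `psf_sigma_px`, and `truth`
#'   (emitter positions in px, bleach frames, photon budget).
#' @export
simulate_spot_movie <- function(separation_nm, photons_per_frame = 2000,
                                background = 5, psf_sigma_px = 1.3,
                                pixel_size_nm = 100, n_frames = 60,
                                frame_interval_s = 0.28,
                                bleach_frames = NULL,
                                mean_bleach_frames = c(15, 35),
                                img_size = 15, read_noise_sd = 1,
                                noise = TRUE, seed = NULL) {
  if (photons_per_frame <= 0) stop("photons_per_frame must be positive")
  stopifnot(separation_nm >= 0, n_frames >= 3, img_size >= 7)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bleach_frames)) {
    bleach_frames <- pmin(pmax(stats::rgeom(2, 1 / mean_bleach_frames) + 1, 2),
                          n_frames - 2)
    bleach_frames <- sort(bleach_frames)
    if (diff(bleach_frames) < 3)          # keep the two steps resolvable
      bleach_frames[2] <- min(bleach_frames[1] + 3, n_frames - 2)
  }
  stopifnot(length(bleach_frames) == 2, all(bleach_frames < n_frames))
  c0 <- (img_size + 1) / 2
  half <- separation_nm / pixel_size_nm / 2
  pos <- rbind(c(c0 - half, c0), c(c0 + half, c0))  # (x, y) in px
  px <- seq_len(img_size)
  render_one <- function(p) {
    gx <- exp(-(px - p[1])^2 / (2 * psf_sigma_px^2))
    gy <- exp(-(px - p[2])^2 / (2 * psf_sigma_px^2))
    img <- outer(gy, gx)                  # rows = y, cols = x
    img / sum(img)
  }
  base <- lapply(1:2, function(i) render_one(pos[i, ]))
  frames <- array(0, dim = c(n_frames, img_size, img_size))
  for (t in seq_len(n_frames)) {
    mu <- matrix(background, img_size, img_size)
    for (i in 1:2) if (t <= bleach_frames[i])
      mu <- mu + photons_per_frame * base[[i]]
    if (noise) {
      fr <- matrix(stats::rpois(img_size^2, mu), img_size) +
        matrix(stats::rnorm(img_size^2, 0, read_noise_sd), img_size)
      frames[t, , ] <- pmax(fr, 0)
    } else frames[t, , ] <- mu
  }
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 psf_sigma_px = psf_sigma_px,
                 truth = list(positions_px = pos,
                              bleach_frames = bleach_frames,
                              photons_per_frame = photons_per_frame,
                              background = background)),
            class = "spot_movie")
}

# Binary-segmentation change-point detection on a 1-D trace. Splits are
# accepted while the SSE reduction exceeds a noise-scaled penalty; minimum
# segment length keeps the post-bleach statistics estimable.
find_steps <- function(y, min_seg = 3L, max_steps = 4L, penalty_scale = 8) {
  n <- length(y)
  sigma2 <- (stats::median(abs(diff(y))) / (sqrt(2) * 0.6745))^2
  penalty <- max(penalty_scale * sigma2 * log(n), 1e-12)
  seg_sse <- function(a, b) {
    v <- y[a:b]; sum((v - mean(v))^2)
  }
  best_split <- function(a, b) {
    cands <- seq(a + min_seg - 1, b - min_seg)
    if (length(cands) < 1 || a + min_seg - 1 > b - min_seg) return(NULL)
    red <- vapply(cands, function(s)
      seg_sse(a, b) - seg_sse(a, s) - seg_sse(s + 1, b), numeric(1))
    i <- which.max(red)
    list(at = cands[i], reduction = red[i])
  }
  steps <- integer(0)
  segments <- list(c(1L, n))
  while (length(steps) < max_steps) {
    props <- lapply(segments, function(sg) best_split(sg[1], sg[2]))
    ok <- !vapply(props, is.null, logical(1))
    if (!any(ok)) break
    reds <- vapply(props[ok], `[[`, numeric(1), "reduction")
    if (max(reds) <= penalty) break
    j <- which(ok)[which.max(reds)]
    at <- props[[j]]$at
    sg <- segments[[j]]
    segments[[j]] <- c(sg[1], at)
    segments[[length(segments) + 1]] <- c(at + 1L, sg[2])
    steps <- sort(c(steps, at))
  }
  steps
}

# Weighted least-squares fit of a single symmetric 2-D Gaussian plus
# constant offset. With a per-pixel variance image the objective is the
# Gaussian -2 log-likelihood and the position covariance comes from its
# curvature (times a misfit inflation factor >= 1); without one the fit is
# unweighted and the covariance residual-scaled (shot-noise heteroskedasticity
# then makes sigma_loc optimistic, so callers pass var_img when they can).
fit_gaussian_spot <- function(img, init_sigma = 1.3, var_img = NULL) {
  H <- nrow(img); W <- ncol(img)
  xs <- seq_len(W); ys <- seq_len(H)
  b0 <- stats::median(img)
  w0 <- pmax(img - b0, 0)
  if (sum(w0) <= 0) stop("no signal above background in spot image")
  x0 <- sum(t(w0) * xs) / sum(w0)  # cols = x
  y0 <- sum(w0 * ys) / sum(w0)
  a0 <- max(img) - b0
  par0 <- c(x0, y0, log(init_sigma), a0, b0)
  wts <- NULL
  if (!is.null(var_img) && any(var_img > 0))
    wts <- 1 / pmax(var_img, 0.01 * mean(var_img[var_img > 0]))
  model <- function(p) {
    g <- outer(exp(-(ys - p[2])^2 / (2 * exp(2 * p[3]))),
               exp(-(xs - p[1])^2 / (2 * exp(2 * p[3]))))
    p[4] * g + p[5]
  }
  fn <- if (is.null(wts)) function(p) sum((model(p) - img)^2) else
    function(p) sum(wts * (model(p) - img)^2)
  fit <- stats::optim(par0, fn, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  hess <- stats::optimHess(fit$par, fn)
  dof <- max(H * W - 5, 1)
  s2 <- if (is.null(wts)) fit$value / dof else max(1, fit$value / dof)
  cov_xy <- tryCatch(2 * s2 * solve(hess)[1:2, 1:2],
                     error = function(e) matrix(NA_real_, 2, 2))
  sigma_loc <- sqrt(mean(pmax(diag(cov_xy), 0)))
  list(x = fit$par[1], y = fit$par[2], sigma = exp(fit$par[3]),
       amplitude = fit$par[4], offset = fit$par[5],
       sigma_loc_px = sigma_loc, sse = fit$value)
}

#' Extract the two emitter positions from a photobleaching spot movie
#'
#' Change-points of the summed-intensity trace split the movie into a
#' two-emitter segment, a one-emitter segment and background. The last
#' surviving emitter is localised by a Gaussian fit to the mean image of the
#' final bright segment; the first-bleaching emitter from the difference of
#' the segment mean images (which isolates its PSF). Localisation
#' uncertainties come from the fit covariances, scaled down by the number of
#' frames averaged.
#'
#' @param movie a [simulate_spot_movie()] result (or a compatible list with
#'   `frames`, `pixel_size_nm`).
#' @param min_seg minimum frames per segment for the change-point search.
#' @return list of two [localization()]s (nm units, relative to the pixel
#'   grid origin) plus the detected `bleach_frames`.
#' @export
extract_two_emitter_positions <- function(movie, min_seg = 3L) {
  fr <- movie$frames
  trace <- apply(fr, 1, sum)
  steps <- find_steps(trace, min_seg = min_seg, max_steps = 4L)
  # keep downward steps only
  down <- steps[vapply(steps, function(s) {
    mean(trace[max(1, s - min_seg + 1):s]) >
      mean(trace[(s + 1):min(length(trace), s + min_seg)])
  }, logical(1))]
  if (length(down) < 2)
    stop("not-a-pair: fewer than two photobleaching steps detected")
  if (length(down) > 2)
    stop("not-a-pair: more than two photobleaching steps detected")
  s1 <- down[1]; s2 <- down[2]
  if (s1 < min_seg || s2 - s1 < min_seg || length(trace) - s2 < min_seg)
    stop("insufficient-data: a segment is shorter than the minimum length")
  mean_img <- function(a, b) apply(fr[a:b, , , drop = FALSE], c(2, 3), mean)
  # empirical per-pixel variance of each segment's mean image
  var_img <- function(a, b) {
    if (b - a < 1) return(NULL)
    apply(fr[a:b, , , drop = FALSE], c(2, 3), stats::var) / (b - a + 1)
  }
  m1 <- mean_img(1, s1)
  m2 <- mean_img(s1 + 1, s2)
  v1 <- var_img(1, s1)
  v2 <- var_img(s1 + 1, s2)
  psf0 <- movie$psf_sigma_px %||% 1.3
  fit_last <- fit_gaussian_spot(m2, init_sigma = psf0, var_img = v2)
  fit_first <- fit_gaussian_spot(m1 - m2, init_sigma = psf0,
                                 var_img = if (!is.null(v1) && !is.null(v2))
                                   v1 + v2)
  pxnm <- movie$pixel_size_nm %||% 1
  n1 <- s1; n2 <- s2 - s1
  loc <- function(f, nfr) localization(f$x * pxnm, f$y * pxnm,
                                       ifelse(is.na(f$sigma_loc_px), 0,
                                              f$sigma_loc_px) * pxnm)
  list(first_bleached = loc(fit_first, n1),
       last_bleached = loc(fit_last, n2),
       bleach_frames = c(s1, s2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
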