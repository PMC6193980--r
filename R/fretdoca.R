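# FRET distance of closest approach (DOCA). A donor on a receptor domain
# sits at height h above a plane of acceptor dyes in the membrane at surface
# density sigma. With acceptors at lateral radii rho_i (spatial Poisson
# process), the per-configuration transfer sum is
#   S = sum_i (R0 / r_i)^6,  r_i = sqrt(h^2 + rho_i^2)
# and the efficiency E = S / (1 + S). Averaging over configurations gives
# the MC response E(h, sigma); at high density S concentrates around the
# continuum value S_bar = pi sigma R0^6 / (2 h^4) and E -> S_bar/(1+S_bar).

#' Monte-Carlo FRET efficiency of a donor above an acceptor plane
#'
#' @param h donor height above the acceptor plane (nm), > 0.
#' @param density_um2 acceptor surface density (per um^2), >= 0.
#' @param R0 Forster radius (nm); default 5 (illustrative for an Alexa
#'   488/DiI-class pair; the orientation factor kappa^2 = 2/3 is absorbed
#'   into R0).
#' @param n_config number of acceptor configurations averaged.
#' @param seed integer seed.
#' @return mean efficiency in [0, 1].
#' @export
mc_efficiency <- function(h, density_um2, R0 = 5, n_config = 500L,
                          seed = NULL) {
  stopifnot(h > 0, density_um2 >= 0, R0 > 0)
  if (n_config < 1) stop("n_config must be >= 1")
  if (density_um2 == 0) return(0)
  if (!is.null(seed)) set.seed(seed)
  rmax <- max(10 * R0, 10 * h)                  # nm
  sigma_nm2 <- density_um2 / 1e6
  # acceptors within r_sim are simulated individually; the far annulus
  # [r_sim, rmax] contributes < (h^2/(h^2+r_sim^2))^2 of the plane integral
  # per configuration and is replaced by its expectation (its fluctuations
  # are negligible against the near-field terms)
  r_sim <- min(rmax, max(3 * R0, 1.5 * h))
  tail_mean <- sigma_nm2 * pi * R0^6 / 2 *
    (1 / (h^2 + r_sim^2)^2 - 1 / (h^2 + rmax^2)^2)
  lambda <- sigma_nm2 * pi * r_sim^2
  n_acc <- stats::rpois(n_config, lambda)
  total <- sum(n_acc)
  S <- rep(tail_mean, n_config)
  if (total > 0) {
    rho2 <- r_sim^2 * stats::runif(total)       # uniform in the disk
    s_terms <- (R0^2 / (h^2 + rho2))^3
    cfg <- rep.int(seq_len(n_config), n_acc)
    sums <- rowsum(s_terms, cfg)
    S[as.integer(rownames(sums))] <- S[as.integer(rownames(sums))] + sums[, 1]
  }
  mean(S / (1 + S))
}

#' Continuum closed-form FRET efficiency (high-density limit)
#'
#' `E = S_bar / (1 + S_bar)` with `S_bar = pi sigma R0^6 / (2 h^4)` (the
#' integral of the r^-6 transfer rate over the acceptor plane).
#'
#' @inheritParams mc_efficiency
#' @export
continuum_efficiency <- function(h, density_um2, R0 = 5) {
  sbar <- pi * (density_um2 / 1e6) * R0^6 / (2 * h^4)
  sbar / (1 + sbar)
}

#' Precompute the MC FRET response over a height grid
#'
#' Tabulates [mc_efficiency()] on a grid of donor heights (default 1-30 nm
#' at 0.25 nm steps) at each requested acceptor density. The grid is the
#' lookup used by [fit_doca()]; heights between grid points are linearly
#' interpolated.
#'
#' @param densities_um2 acceptor densities (per um^2) to tabulate.
#' @param R0 Forster radius (nm).
#' @param h_grid height grid (nm).
#' @param n_config configurations per grid point.
#' @param seed integer seed.
#' @return list of class `fret_response`: `h_grid`, `densities_um2`, `E`
#'   (matrix, heights x densities), `R0`.
#' @export
fret_response <- function(densities_um2, R0 = 5,
                          h_grid = seq(1, 30, by = 0.25),
                          n_config = 300L, seed = NULL) {
  stopifnot(length(densities_um2) >= 1, all(densities_um2 >= 0))
  if (!is.null(seed)) set.seed(seed)
  E <- matrix(NA_real_, length(h_grid), length(densities_um2))
  for (j in seq_along(densities_um2))
    for (i in seq_along(h_grid))
      E[i, j] <- mc_efficiency(h_grid[i], densities_um2[j], R0, n_config)
  # enforce the physical monotone decay in h against residual MC jitter
  for (j in seq_along(densities_um2))
    E[, j] <- rev(cummax(rev(E[, j])))
  structure(list(h_grid = h_grid, densities_um2 = densities_um2, E = E,
                 R0 = R0, n_config = n_config),
            class = "fret_response")
}

#' Simulate a FRET efficiency vs acceptor-density titration
#'
#' Per cell, efficiency = MC response at (`h_true_nm`, its density) plus
#' Gaussian noise, truncated to [0, 1].
#'
#' @param h_true_nm true donor height (nm).
#' @param densities_um2 acceptor densities of the titration (per um^2).
#' @param R0 Forster radius (nm).
#' @param n_cells_per_density cells measured at each density.
#' @param noise_sd sd of the per-cell efficiency noise.
#' @param seed integer seed.
#' @param response optional precomputed [fret_response()] covering
#'   `densities_um2` (saves recomputing the MC response).
#' @return data.frame of class `fret_observations`: `cell_id`,
#'   `density_um2`, `efficiency`; attribute `truth`.
#' @export
simulate_fret <- function(h_true_nm, densities_um2, R0 = 5,
                          n_cells_per_density = 8, noise_sd = 0.05,
                          seed = NULL, response = NULL) {
  stopifnot(h_true_nm > 0, length(densities_um2) >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(response))
    response <- fret_response(densities_um2, R0)
  Etrue <- vapply(densities_um2, function(d)
    response_at(response, h_true_nm, d), numeric(1))
  n <- length(densities_um2) * n_cells_per_density
  dens <- rep(densities_um2, each = n_cells_per_density)
  Eobs <- rep(Etrue, each = n_cells_per_density) +
    stats::rnorm(n, 0, noise_sd)
  Eobs <- pmin(pmax(Eobs, 0), 1)
  out <- data.frame(cell_id = seq_len(n), density_um2 = dens,
                    efficiency = Eobs)
  class(out) <- c("fret_observations", "data.frame")
  attr(out, "truth") <- list(h_true_nm = h_true_nm, R0 = R0,
                             noise_sd = noise_sd, seed = seed)
  out
}

# linear interpolation of the response at height h and a tabulated density
response_at <- function(response, h, density_um2) {
  j <- match(density_um2, response$densities_um2)
  if (is.na(j)) stop("density not tabulated in the response grid")
  stats::approx(response$h_grid, response$E[, j], xout = h, rule = 2)$y
}

#' Bootstrap-regression estimate of the distance of closest approach
#'
#' Each bootstrap resample draws cells with replacement; the resampled
#' dataset is fitted to the MC response by least squares over the height
#' grid, `h_hat = argmin_h sum_i (E_i - E_response(h, density_i))^2`. The
#' reported DOCA is the mean of the bootstrap h distribution and its error
#' the SD (default 3000 resamples).
#'
#' @param observations a [simulate_fret()]-style data.frame (`cell_id`,
#'   `density_um2`, `efficiency`), >= 2 observations spanning >= 2 densities
#'   (a single density leaves h poorly identified: warning).
#' @param R0 Forster radius (nm).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param response optional precomputed [fret_response()]; built from the
#'   observed densities when NULL.
#' @return list of class `doca_estimate`: `mean_h`, `sd_h`, `h_point`
#'   (full-data fit), `n_boot`, `boot_h`.
#' @export
fit_doca <- function(observations, R0 = 5, n_boot = 3000L, seed = NULL,
                     response = NULL) {
  obs <- observations
  stopifnot(nrow(obs) >= 2)
  if (length(unique(obs$density_um2)) < 2)
    warning("all observations at one acceptor density: h is poorly identified")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(response))
    response <- fret_response(sort(unique(obs$density_um2)), R0)
  n <- nrow(obs)
  jdx <- match(obs$density_um2, response$densities_um2)
  if (anyNA(jdx)) stop("response grid does not cover the observed densities")
  # Err[h, i] = squared error of observation i at grid height h
  Err <- (response$E[, jdx, drop = FALSE] -
            matrix(obs$efficiency, length(response$h_grid), n,
                   byrow = TRUE))^2
  h_point <- response$h_grid[which.min(rowSums(Err))]
  counts <- matrix(0L, n, n_boot)
  for (b in seq_len(n_boot))
    counts[, b] <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
  sse <- Err %*% counts
  boot_h <- response$h_grid[max.col(-t(sse))]
  structure(list(mean_h = mean(boot_h), sd_h = stats::sd(boot_h),
                 h_point = h_point, n_boot = n_boot, boot_h = boot_h,
                 R0 = R0),
            class = "doca_estimate")
}

#' @export
print.doca_estimate <- function(x, ...) {
  cat(sprintf("DOCA: %.2f +/- %.2f nm (point fit %.2f nm, %d bootstrap resamples)\n",
              x$mean_h, x$sd_h, x$h_point, x$n_boot))
  invisible(x)
}

#' Pooled-bootstrap test for a difference in DOCA between two datasets
#'
#' The test statistic is the absolute difference between the two fitted
#' DOCAs. The null distribution is built by resampling, with replacement
#' from the pooled data points, two datasets of the original sizes and
#' refitting both (default 10,000 replicates); the p-value is the proportion
#' of null statistics at least as large as the observed statistic (ties
#' count toward the null since the height grid discretises the statistic).
#'
#' @param obsA,obsB observation data.frames as for [fit_doca()].
#' @param R0 Forster radius (nm).
#' @param n_rep null replicates (default 10000).
#' @param seed integer seed.
#' @param response optional precomputed [fret_response()] covering both
#'   datasets' densities.
#' @return list: `p`, `statistic` (observed |h_A - h_B|), `h_A`, `h_B`,
#'   `null_stats`.
#' @export
doca_difference_test <- function(obsA, obsB, R0 = 5, n_rep = 10000L,
                                 seed = NULL, response = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- rbind(obsA[, c("density_um2", "efficiency")],
                obsB[, c("density_um2", "efficiency")])
  if (is.null(response))
    response <- fret_response(sort(unique(pool$density_um2)), R0)
  nA <- nrow(obsA); nB <- nrow(obsB); n <- nA + nB
  jdx <- match(pool$density_um2, response$densities_um2)
  Err <- (response$E[, jdx, drop = FALSE] -
            matrix(pool$efficiency, length(response$h_grid), n,
                   byrow = TRUE))^2
  fit_idx <- function(w) response$h_grid[which.min(Err %*% w)]
  wA <- c(rep(1, nA), rep(0, nB)); wB <- 1 - wA
  hA <- fit_idx(wA); hB <- fit_idx(wB)
  observed <- abs(hA - hB)
  # resample both datasets from the pool, refit, collect |h_A* - h_B*|
  cA <- matrix(0L, n, n_rep); cB <- matrix(0L, n, n_rep)
  for (b in seq_len(n_rep)) {
    cA[, b] <- tabulate(sample.int(n, nA, replace = TRUE), nbins = n)
    cB[, b] <- tabulate(sample.int(n, nB, replace = TRUE), nbins = n)
  }
  hAs <- response$h_grid[max.col(-t(Err %*% cA))]
  hBs <- response$h_grid[max.col(-t(Err %*% cB))]
  null_stats <- abs(hAs - hBs)
  # ties at the observed value count toward the null (the height grid makes
  # the statistic discrete; >= is the conservative bootstrap convention)
  list(p = mean(null_stats >= observed), statistic = observed,
       h_A = hA, h_B = hB, null_stats = null_stats)
}
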