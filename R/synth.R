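# Synthetic-data generators. Each generator is seeded, bit-reproducible, and
# returns its generating parameters ("truth") alongside the data so recovery
# tests compare estimates against truth rather than against other estimates.

#' Simulate a set of FLImP separation measurements
#'
#' Each measurement draws a chain size from the species composition, places
#' the probe sites with the chain geometry, labels them under the labelling
#' scheme, picks one labelled pair uniformly at random, perturbs both sites
#' with independent 2-D Gaussian localisation error of scale `loc_sigma_nm`,
#' and records the observed distance together with its combined scale
#' `sqrt(2) * loc_sigma_nm` and 69% credible interval.
#'
#' @param geometry a [chain_geometry()].
#' @param composition an [oligomer_composition()] (species-number fractions).
#' @param scheme a [labeling_scheme()].
#' @param loc_sigma_nm per-site localisation error (nm), > 0 (may be a
#'   length-2 range: each measurement draws its sigma uniformly, emulating
#'   variable photon budgets).
#' @param n_measurements number of accepted measurements to produce.
#' @param seed integer seed.
#' @param max_tries cap on chain draws per accepted measurement before a
#'   generator-exhausted error (schemes can yield chains with no labelled
#'   pair, e.g. monomers under end labelling).
#' @return a [flimp_dataset()] with attribute `truth`: per-measurement chain
#'   size and true pair separation, plus the generator parameters.
#' @export
simulate_flimp_measurements <- function(geometry, composition, scheme,
                                        loc_sigma_nm, n_measurements,
                                        seed = NULL, max_tries = 10000L) {
  stopifnot(all(loc_sigma_nm > 0), n_measurements >= 1)
  if (!is.null(seed)) set.seed(seed)
  f <- composition$fractions
  sizes <- seq_along(f)
  r_obs <- sig <- true_sep <- numeric(n_measurements)
  size_drawn <- integer(n_measurements)
  for (i in seq_len(n_measurements)) {
    sep <- NULL
    for (try in seq_len(max_tries)) {
      n <- sample(sizes, 1, prob = f)
      d <- pairwise_separations(geometry, n, scheme)
      if (length(d) >= 1) {
        sep <- if (length(d) == 1) d else sample(d, 1)
        size_drawn[i] <- n
        break
      }
    }
    if (is.null(sep))
      stop("generator-exhausted: scheme yielded no labelled pair in ",
           max_tries, " tries")
    s <- if (length(loc_sigma_nm) == 2)
      stats::runif(1, loc_sigma_nm[1], loc_sigma_nm[2]) else loc_sigma_nm
    # both sites get independent isotropic error: observed distance is Rician
    dx <- sep + stats::rnorm(1, 0, s * sqrt(2))
    dy <- stats::rnorm(1, 0, s * sqrt(2))
    r_obs[i] <- sqrt(dx^2 + dy^2)
    sig[i] <- s * sqrt(2)
    true_sep[i] <- sep
  }
  ds <- flimp_dataset(r_obs, sig)
  attr(ds, "truth") <- list(size = size_drawn, true_sep = true_sep,
                            geometry = geometry, composition = f,
                            scheme = scheme, loc_sigma_nm = loc_sigma_nm,
                            seed = seed)
  ds
}

#' Simulate a confocal photobleaching image series for pbICS
#'
#' Clusters are placed by a homogeneous spatial Poisson process; a cluster of
#' size j carries j fluorophores at the cluster position. Every fluorophore
#' survives each photobleaching round independently with probability
#' `survival_per_round`; round t images the survivors with a Gaussian beam
#' profile `exp(-2 r^2 / omega^2)` plus white Gaussian noise.
#'
#' @param composition an [oligomer_composition()]: relative cluster-species
#'   fractions.
#' @param cluster_density_per_um2 total cluster density (clusters / um^2).
#' @param survival_per_round per-fluorophore per-round survival in (0, 1).
#' @param n_rounds number of bleach rounds after the initial image.
#' @param image_px image side (pixels).
#' @param pixel_size_um pixel size (um).
#' @param omega_px Gaussian beam waist (pixels): the rendered spot profile is
#'   `exp(-2 r^2 / omega^2)`.
#' @param amp peak intensity of a single fluorophore.
#' @param noise_sd white-noise sd (intensity units).
#' @param seed integer seed.
#' @return list of class `pbics_stack`: `rounds` (list of matrices, length
#'   n_rounds + 1), `omega_px`, `pixel_size_um`, and `truth` (cluster
#'   positions/sizes, per-round per-fluorophore survival matrix, parameters).
#' @export
simulate_pbics_stack <- function(composition, cluster_density_per_um2,
                                 survival_per_round, n_rounds = 7,
                                 image_px = 256, pixel_size_um = 0.1,
                                 omega_px = 4, amp = 100, noise_sd = 0,
                                 seed = NULL) {
  stopifnot(survival_per_round > 0, survival_per_round < 1,
            cluster_density_per_um2 > 0, n_rounds >= 1)
  if (!is.null(seed)) set.seed(seed)
  area_um2 <- (image_px * pixel_size_um)^2
  n_clusters <- stats::rpois(1, cluster_density_per_um2 * area_um2)
  f <- composition$fractions
  sizes <- sample(seq_along(f), n_clusters, replace = TRUE, prob = f)
  # warn when clusters are too crowded for the ICS amplitude to resolve them
  beam_area_px2 <- pi * omega_px^2
  if (n_clusters * beam_area_px2 > 0.5 * image_px^2)
    warning("cluster density high relative to the beam waist; ",
            "ICS amplitude may be biased")
  pos <- cbind(stats::runif(n_clusters, 0.5, image_px + 0.5),
               stats::runif(n_clusters, 0.5, image_px + 0.5))
  n_fluor <- sum(sizes)
  cluster_of <- rep.int(seq_len(n_clusters), sizes)
  alive <- matrix(TRUE, n_fluor, n_rounds + 1)
  for (t in seq_len(n_rounds) + 1)
    alive[, t] <- alive[, t - 1] &
      (stats::runif(n_fluor) < survival_per_round)
  rounds <- vector("list", n_rounds + 1)
  sd_px <- omega_px / 2  # exp(-2 r^2/omega^2) == Gaussian with sd omega/2
  for (t in seq_len(n_rounds + 1)) {
    counts <- vapply(seq_len(n_clusters), function(ci)
      sum(alive[cluster_of == ci, t]), numeric(1))
    img <- render_gaussians(pos, counts * amp, image_px, sd_px)
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(image_px^2, 0, noise_sd), image_px)
    rounds[[t]] <- img
  }
  structure(list(rounds = rounds, omega_px = omega_px,
                 pixel_size_um = pixel_size_um,
                 truth = list(positions_px = pos, sizes = sizes,
                              alive = alive,
                              survival_per_round = survival_per_round,
                              cluster_density_per_um2 = cluster_density_per_um2,
                              amp = amp, seed = seed)),
            class = "pbics_stack")
}

# Render point emitters with Gaussian profiles onto an image_px^2 grid.
# Peak amplitude per emitter is `amps`; profile sd in pixels.
render_gaussians <- function(pos, amps, image_px, sd_px, support = 5) {
  img <- matrix(0, image_px, image_px)
  if (nrow(pos) == 0) return(img)
  w <- ceiling(support * sd_px)
  for (i in seq_len(nrow(pos))) {
    if (amps[i] <= 0) next
    x0 <- pos[i, 1]; y0 <- pos[i, 2]
    xr <- max(1, floor(x0 - w)):min(image_px, ceiling(x0 + w))
    yr <- max(1, floor(y0 - w)):min(image_px, ceiling(y0 + w))
    g <- outer(exp(-(yr - y0)^2 / (2 * sd_px^2)),
               exp(-(xr - x0)^2 / (2 * sd_px^2)))
    img[yr, xr] <- img[yr, xr] + amps[i] * g
  }
  img
}
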