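# Photobleaching image correlation spectroscopy. The apparent cluster density
# (from the zero-lag amplitude of the spatial image autocorrelation) drops as
# fluorophores bleach, and the shape of CD versus surviving intensity
# fraction p encodes the oligomer composition:
#
#   CD(p) = (sum_j j c_j)^2 p / sum_j [ j c_j + j (j - 1) c_j p ]
#
# which is the binomial-survival moment ratio (sum_j c_j E B_j)^2 /
# (sum_j c_j E B_j^2) with B_j ~ Binomial(j, p).

#' Model cluster density at surviving intensity fraction p
#'
#' @param c_j non-negative concentrations of species j = 1..length(c_j)
#'   (clusters per unit area), not all zero.
#' @param p surviving intensity fraction(s) in [0, 1]; vectorised.
#' @return model CD, same units as `c_j`.
#' @export
cd_model <- function(c_j, p) {
  c_j <- as.numeric(c_j)
  if (any(c_j < 0) || all(c_j == 0)) stop("c_j must be non-negative, not all zero")
  stopifnot(all(p >= 0), all(p <= 1))
  j <- seq_along(c_j)
  num <- sum(j * c_j)^2 * p
  den <- vapply(p, function(pp) sum(j * c_j + j * (j - 1) * c_j * pp),
                numeric(1))
  out <- num / den
  out[p == 0] <- 0
  out
}

#' Apparent cluster density of one image by ICS
#'
#' Computes the normalised spatial autocorrelation
#' `g(xi, eta) = <dI dI> / <I>^2` by FFT, fits the central peak with a 2-D
#' Gaussian `g0 exp(-(xi^2 + eta^2) / omega^2) + offset` excluding the
#' zero-lag pixel (shot-noise spike), and converts the amplitude to a density
#' with the standard ICS normalisation `CD = 1 / (g0 pi omega^2)`, in
#' clusters per unit area of the supplied pixel size.
#'
#' @param image numeric matrix of intensities.
#' @param omega_px beam waist (pixels): the image of a point emitter is
#'   assumed `exp(-2 r^2 / omega^2)`.
#' @param pixel_size_um pixel size (um); `NULL` returns clusters per px^2.
#' @param fit_radius_px lag radius used in the Gaussian peak fit (defaults to
#'   `3 * omega_px`).
#' @return list: `cd` (clusters per um^2, or per px^2), `g0`, `omega_fit_px`,
#'   `qc_pass` (FALSE when no positive correlation peak is found, e.g. a
#'   featureless image).
#' @export
cluster_density <- function(image, omega_px, pixel_size_um = NULL,
                            fit_radius_px = NULL) {
  stopifnot(is.matrix(image), min(dim(image)) > 6 * omega_px)
  if (is.null(fit_radius_px)) fit_radius_px <- max(3 * omega_px, 4)
  mu <- mean(image)
  if (mu <= 0) return(list(cd = NA_real_, g0 = NA_real_,
                           omega_fit_px = NA_real_, qc_pass = FALSE))
  dI <- image - mu
  H <- nrow(image); W <- ncol(image)
  ac <- Re(stats::fft(stats::fft(dI) * Conj(stats::fft(dI)), inverse = TRUE)) /
    (H * W)                     # circular sum_r dI(r) dI(r+lag)
  g <- ac / (H * W) / mu^2      # <dI dI>(lag) / <I>^2
  # collect lags within the fit radius (cyclic indexing)
  r <- floor(fit_radius_px)
  lags <- expand.grid(dx = -r:r, dy = -r:r)
  lags <- lags[lags$dx^2 + lags$dy^2 <= fit_radius_px^2 &
                 !(lags$dx == 0 & lags$dy == 0), ]
  idx <- cbind((lags$dy %% H) + 1, (lags$dx %% W) + 1)
  gv <- g[idx]
  rho2 <- lags$dx^2 + lags$dy^2
  # linearised start: log(g - min) vs rho2, then nonlinear refinement
  ord0 <- c(max(gv, na.rm = TRUE), omega_px, 0)
  fn <- function(par) {
    pred <- par[1] * exp(-rho2 / par[2]^2) + par[3]
    sum((pred - gv)^2)
  }
  fit <- stats::optim(ord0, fn, method = "L-BFGS-B",
                      lower = c(-Inf, 0.3, -Inf),
                      upper = c(Inf, 10 * omega_px, Inf),
                      control = list(maxit = 500))
  g0 <- fit$par[1]
  if (!is.finite(g0) || g0 <= 0)
    return(list(cd = NA_real_, g0 = g0, omega_fit_px = fit$par[2],
                qc_pass = FALSE))
  cd_px2 <- 1 / (g0 * pi * omega_px^2)
  cd <- if (is.null(pixel_size_um)) cd_px2 else cd_px2 / pixel_size_um^2
  list(cd = cd, g0 = g0, omega_fit_px = fit$par[2], qc_pass = TRUE)
}

#' Surviving intensity fraction per bleach round
#'
#' `p_t` is the mean background-subtracted intensity of round t divided by
#' that of round 0 (so `p_0 = 1`). The background is estimated from a border
#' strip of each image.
#'
#' @param stack a [simulate_pbics_stack()] result or list of image matrices.
#' @param border_px border width used for the background estimate; 0 disables
#'   background subtraction.
#' @return numeric vector of p values, one per round, starting at 1.
#' @export
bleach_fraction <- function(stack, border_px = 8L) {
  rounds <- if (inherits(stack, "pbics_stack")) stack$rounds else stack
  means <- vapply(rounds, function(img) {
    bg <- if (border_px > 0) {
      H <- nrow(img); W <- ncol(img)
      edge <- c(img[seq_len(border_px), ], img[H - seq_len(border_px) + 1, ],
                img[, seq_len(border_px)], img[, W - seq_len(border_px) + 1])
      stats::median(edge)
    } else 0
    mean(img) - bg
  }, numeric(1))
  if (means[1] <= 0) stop("round-0 mean intensity must be positive")
  p <- means / means[1]
  if (any(p < 0)) {
    warning("negative background-subtracted intensity clipped to 0")
    p <- pmax(p, 0)
  }
  p[1] <- 1
  p
}

#' Assemble a pbICS bleach curve
#'
#' @param p surviving intensity fractions in (0, 1], strictly decreasing.
#' @param cd apparent cluster densities (same length).
#' @export
pbics_curve <- function(p, cd) {
  stopifnot(length(p) == length(cd), all(p > 0), all(p <= 1),
            all(diff(p) < 0), all(cd >= 0))
  structure(data.frame(p = p, cd = cd), class = c("pbics_curve", "data.frame"))
}

#' Measure the bleach curve of a photobleaching stack
#'
#' Convenience wrapper: [bleach_fraction()] plus per-round
#' [cluster_density()]. Rounds with p = 0 or failing ICS QC are dropped.
#'
#' @inheritParams bleach_fraction
#' @param omega_px beam waist (pixels).
#' @param pixel_size_um pixel size (um).
#' @export
measure_bleach_curve <- function(stack, omega_px = stack$omega_px,
                                 pixel_size_um = stack$pixel_size_um,
                                 border_px = 8L) {
  rounds <- if (inherits(stack, "pbics_stack")) stack$rounds else stack
  p <- bleach_fraction(stack, border_px = border_px)
  cd <- vapply(rounds, function(img)
    cluster_density(img, omega_px, pixel_size_um)$cd, numeric(1))
  keep <- p > 0 & is.finite(cd)
  pbics_curve(p[keep], cd[keep])
}

#' Fit an oligomer composition to a pbICS bleach curve
#'
#' Minimises `sum_t (CD_t - CD_model(c, p_t))^2` over non-negative
#' concentrations `c_1..c_jmax`. Because the bleach-curve model reduces to
#' `CD(p) = A^2 p / (A + B p)` with `A = sum_j j c_j` (molecular density)
#' and `B = sum_j j (j - 1) c_j`, one curve identifies exactly two
#' functionals of the composition; compositions sharing (A, B) fit
#' identically. The default `structure = "auto"` therefore reports, among
#' least-squares-optimal compositions, the most parsimonious one consistent
#' with the data: a single species when one attains the optimum, otherwise
#' the two-parameter geometric family `c_j = c_1 q^(j-1)` expected from
#' step-wise polymerisation. `structure = "free"` runs the literal
#' j_max-concentration bounded multi-start fit (useful for the raw (A, B)
#' functionals, but its split of mass across sizes is start-dependent).
#'
#' @param curve a [pbics_curve()] (>= 3 points).
#' @param j_max largest species size fitted (default 8).
#' @param restarts number of random multi-starts for the free fit.
#' @param seed integer seed for the starts.
#' @param structure `"auto"` (default), `"free"`, `"geometric"`, or
#'   `"single"`.
#' @return list of class `composition_fit`: `c_j`, `fractions`
#'   (species-normalised), `oligomer_fraction` (molecule-normalised mass at
#'   j >= 2), `residual_norm`, `structure` (the form actually reported),
#'   `A`, `B` (the identifiable functionals of the reported fit).
#' @export
fit_composition <- function(curve, j_max = 8L, restarts = 30L, seed = NULL,
                            structure = c("auto", "free", "geometric",
                                          "single")) {
  stopifnot(nrow(curve) >= 3, j_max >= 1)
  structure <- match.arg(structure)
  if (!is.null(seed)) set.seed(seed)
  p <- curve$p; cd <- curve$cd
  scale0 <- max(cd)
  sse <- function(cc) sum((cd - cd_model(pmax(cc, 0) + 1e-300, p))^2)

  # single species j: CD = j c p / (1 + (j-1) p), linear in c
  fit_single <- function() {
    best <- NULL
    for (j in seq_len(j_max)) {
      v <- j * p / (1 + (j - 1) * p)
      ch <- max(sum(cd * v) / sum(v^2), 0)
      cc <- numeric(j_max); cc[j] <- ch
      s <- sse(cc)
      if (is.null(best) || s < best$sse) best <- list(c_j = cc, sse = s)
    }
    best
  }
  # geometric (step-wise polymerisation): c_j = c1 * q^(j-1)
  fit_geometric <- function() {
    obj <- function(par) sse(exp(par[1]) * par[2]^(seq_len(j_max) - 1))
    best <- NULL
    for (q0 in c(0.05, 0.2, 0.45, 0.7)) {
      fit <- tryCatch(
        stats::optim(c(log(scale0), q0), obj, method = "L-BFGS-B",
                     lower = c(log(scale0) - 15, 1e-6),
                     upper = c(log(scale0) + 15, 0.97),
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$sse))
        best <- list(c_j = exp(fit$par[1]) * fit$par[2]^(seq_len(j_max) - 1),
                     sse = fit$value)
    }
    best
  }
  fit_free <- function() {
    best <- NULL
    starts <- c(list(rep(scale0 / j_max, j_max)),
                replicate(restarts, scale0 * stats::runif(j_max)^2,
                          simplify = FALSE))
    for (s in starts) {
      fit <- tryCatch(
        stats::optim(s, sse, method = "L-BFGS-B", lower = 0,
                     upper = rep(20 * scale0, j_max),
                     control = list(maxit = 1000, factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$sse))
        best <- list(c_j = pmax(fit$par, 0), sse = fit$value)
    }
    best
  }

  tol <- 1e-9 * nrow(curve) * scale0^2
  chosen <- switch(structure,
    single = c(fit_single(), form = "single"),
    geometric = c(fit_geometric(), form = "geometric"),
    free = c(fit_free(), form = "free"),
    auto = {
      fs <- fit_single(); fg <- fit_geometric(); ff <- fit_free()
      best_sse <- min(fs$sse, fg$sse, ff$sse)
      # parsimony: a single species that exactly attains the optimum wins
      # (noise-free identification); otherwise the geometric family when it
      # matches the free fit (it reaches the same identifiable (A, B) unless
      # B/A exceeds its range); else the free fit
      if (fs$sse <= best_sse + tol) c(fs, form = "single")
      else if (fg$sse <= 1.05 * best_sse + tol) c(fg, form = "geometric")
      else c(ff, form = "free")
    })
  c_j <- chosen$c_j
  if (sum(c_j) == 0) c_j[1] <- scale0
  j <- seq_len(j_max)
  structure(list(c_j = c_j, fractions = c_j / sum(c_j),
                 oligomer_fraction = sum(j[-1] * c_j[-1]) / sum(j * c_j),
                 residual_norm = sqrt(chosen$sse),
                 structure = chosen$form,
                 A = sum(j * c_j), B = sum(j * (j - 1) * c_j),
                 n_points = nrow(curve)),
            class = "composition_fit")
}

#' Average replicate composition fits
#'
#' Per-size mean and SD of the species-normalised fractions across replicate
#' curves, plus mean/SD of the molecule-normalised oligomer fraction (the
#' convention of reporting seven-replicate means with SD error bars).
#'
#' @param fits list of [fit_composition()] results (>= 2).
#' @return list: `mean_fractions`, `sd_fractions`, `mean_oligomer_fraction`,
#'   `sd_oligomer_fraction`, `n`.
#' @export
aggregate_replicates <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  M <- do.call(rbind, lapply(fits, `[[`, "fractions"))
  of <- vapply(fits, `[[`, numeric(1), "oligomer_fraction")
  list(mean_fractions = colMeans(M),
       sd_fractions = apply(M, 2, stats::sd),
       mean_oligomer_fraction = mean(of),
       sd_oligomer_fraction = stats::sd(of),
       n = length(fits))
}
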