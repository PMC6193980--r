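# -- single-measurement posterior ---------------------------------------------

#' Posterior for one pairwise separation measurement
#'
#' Given two localisations with isotropic Gaussian uncertainties, the observed
#' distance `r_obs = |mu_a - mu_b|` follows a Rice law with combined scale
#' `sigma = sqrt(sigma_a^2 + sigma_b^2)`. Under a flat prior on the true
#' separation nu >= 0 the posterior is proportional to `Rice(r_obs | nu,
#' sigma)` viewed as a function of nu; the reported interval is the 69%
#' (~1 sigma) highest-density interval of that posterior, which handles the
#' boundary at nu = 0 naturally (the lower bound is 0 for near-coincident
#' emitters).
#'
#' @param a,b localisations: lists or vectors with elements `x`, `y` (nm) and
#'   `sigma_loc` (nm); see [localization()].
#' @param level credible level (default 0.69).
#' @param grid_n number of posterior grid points.
#' @return a one-row data.frame with class `separation_measurement`: columns
#'   `r_obs_nm`, `sigma_nm`, `ci_lo_nm`, `ci_hi_nm`.
#' @export
separation_posterior <- function(a, b, level = 0.69, grid_n = 2000L) {
  a <- localization(a$x, a$y, a$sigma_loc)
  b <- localization(b$x, b$y, b$sigma_loc)
  r_obs <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  sigma <- sqrt(a$sigma_loc^2 + b$sigma_loc^2)
  if (sigma == 0) {
    if (r_obs == 0)
      warning("degenerate measurement: zero uncertainty and coincident positions")
    ci <- c(r_obs, r_obs)
  } else {
    ci <- rice_hdi(r_obs, sigma, level = level, grid_n = grid_n)
  }
  out <- data.frame(r_obs_nm = r_obs, sigma_nm = sigma,
                    ci_lo_nm = ci[1], ci_hi_nm = ci[2])
  class(out) <- c("separation_measurement", "data.frame")
  out
}

#' A point localisation with isotropic uncertainty
#'
#' @param x,y coordinates (nm).
#' @param sigma_loc isotropic localisation uncertainty (nm), >= 0.
#' @export
localization <- function(x, y, sigma_loc) {
  stopifnot(is.finite(x), is.finite(y), is.finite(sigma_loc), sigma_loc >= 0)
  list(x = as.numeric(x), y = as.numeric(y), sigma_loc = as.numeric(sigma_loc))
}

# Highest-density interval of the nu-posterior p(nu) ~ Rice(r | nu, sigma),
# flat prior on nu >= 0, computed on a dense grid. The posterior is unimodal
# in nu so the HDI is a single interval.
rice_hdi <- function(r, sigma, level = 0.69, grid_n = 2000L) {
  hi <- r + 6 * sigma
  nu <- seq(0, hi, length.out = grid_n)
  # log posterior up to nu-independent constants (valid down to r = 0,
  # where the posterior is the half-normal exp(-nu^2 / 2 sigma^2))
  z <- r * nu / sigma^2
  ld <- -nu^2 / (2 * sigma^2) + log_bessel_i0(z)
  w <- exp(ld - max(ld))
  w <- w / sum(w)
  ord <- order(w, decreasing = TRUE)
  k <- which(cumsum(w[ord]) >= level)[1]
  sel <- sort(ord[seq_len(k)])
  c(nu[sel[1]], nu[sel[length(sel)]])
}

# -- dataset container and CI filter ------------------------------------------

#' Assemble a FLImP dataset
#'
#' @param r_obs_nm observed separations (nm).
#' @param sigma_nm per-measurement combined localisation scales (nm).
#' @param ci_lo_nm,ci_hi_nm 69% credible bounds (nm); computed from the Rice
#'   posterior when omitted.
#' @param condition optional condition label recycled across rows.
#' @return data.frame with class `flimp_dataset`.
#' @export
flimp_dataset <- function(r_obs_nm, sigma_nm, ci_lo_nm = NULL, ci_hi_nm = NULL,
                          condition = NA_character_) {
  stopifnot(length(r_obs_nm) == length(sigma_nm),
            all(r_obs_nm >= 0), all(sigma_nm >= 0))
  if (is.null(ci_lo_nm) || is.null(ci_hi_nm)) {
    ci <- t(mapply(function(r, s) {
      if (s == 0) c(r, r) else rice_hdi(r, s)
    }, r_obs_nm, sigma_nm))
    ci_lo_nm <- ci[, 1]; ci_hi_nm <- ci[, 2]
  }
  stopifnot(all(ci_lo_nm <= ci_hi_nm + 1e-12))
  out <- data.frame(r_obs_nm = r_obs_nm, sigma_nm = sigma_nm,
                    ci_lo_nm = ci_lo_nm, ci_hi_nm = ci_hi_nm,
                    condition = rep_len(condition, length(r_obs_nm)))
  class(out) <- c("flimp_dataset", "data.frame")
  out
}

#' Quality-filter a FLImP dataset on credible-interval width
#'
#' Retains measurements whose 69% CI width `hi - lo` is at most `ci_max_nm`
#' (boundary inclusive, matching the "CI <= 7 nm" selection convention);
#' order is preserved.
#'
#' @param dataset a [flimp_dataset()].
#' @param ci_max_nm maximum CI width (nm), > 0 (0 keeps only degenerate
#'   noise-free measurements).
#' @export
filter_ci <- function(dataset, ci_max_nm) {
  stopifnot(is.numeric(ci_max_nm), ci_max_nm >= 0)
  keep <- (dataset$ci_hi_nm - dataset$ci_lo_nm) <= ci_max_nm
  out <- dataset[keep, , drop = FALSE]
  class(out) <- class(dataset)
  out
}

# -- Rician mixture fitting ---------------------------------------------------

# log-likelihood of a K-component Rician mixture with per-measurement sigma_i
# treated as known: L = sum_i log sum_k w_k Rice(r_i | nu_k, sigma_i)
rice_mix_loglik <- function(r, sigma, nu, w) {
  n <- length(r); K <- length(nu)
  ll <- matrix(NA_real_, n, K)
  for (k in seq_len(K))
    ll[, k] <- log(w[k]) + drice_vec_sigma(r, nu[k], sigma, log = TRUE)
  m <- apply(ll, 1, max)
  sum(m + log(rowSums(exp(ll - m))))
}

# drice with vectorised sigma (one per observation)
drice_vec_sigma <- function(r, nu, sigma, log = FALSE) {
  z <- r * nu / sigma^2
  ld <- log(r) - 2 * log(sigma) - (r^2 + nu^2) / (2 * sigma^2) +
    log_bessel_i0(z)
  ld[r <= 0] <- -Inf
  if (log) ld else exp(ld)
}

#' Fit a K-component Rician mixture to a FLImP dataset
#'
#' Maximises `sum_i log sum_k w_k Rice(r_i | nu_k, sigma_i)` over component
#' separations `nu_k` in [0, nu_max] and mixture weights on the simplex, with
#' per-measurement sigma treated as known. Optimisation is
#' expectation-maximisation: responsibilities update the weights in closed
#' form and each `nu_k` by a bounded one-dimensional search; multi-start
#' (k-means-style quantile initialisation plus random restarts) guards
#' against local optima.
#'
#' @param dataset a [flimp_dataset()] (or data.frame with `r_obs_nm`,
#'   `sigma_nm`).
#' @param K number of components, 1 <= K <= nrow(dataset).
#' @param restarts number of random restarts beyond the quantile start.
#' @param seed integer seed for the restarts.
#' @param nu_max upper bound on component positions (nm); default 60, the
#'   working range of the measurement.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param init_nu optional list of additional starting position vectors
#'   (each length K), tried alongside the quantile and random starts.
#' @return list with `nu` (sorted), `weight`, `loglik`, `K`.
#' @export
fit_mixture <- function(dataset, K, restarts = 5L, seed = NULL, nu_max = 60,
                        max_iter = 100L, tol = 1e-5, init_nu = NULL) {
  r <- dataset$r_obs_nm; sigma <- dataset$sigma_nm
  n <- length(r)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K must not exceed the number of measurements")
  sigma <- pmax(sigma, 1e-3)  # guard degenerate zero-noise measurements
  if (!is.null(seed)) set.seed(seed)

  run_em <- function(nu0) {
    nu <- pmin(pmax(nu0, 0), nu_max)
    w <- rep(1 / K, K)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      lw <- matrix(NA_real_, n, K)
      for (k in seq_len(K))
        lw[, k] <- log(w[k]) + drice_vec_sigma(r, nu[k], sigma, log = TRUE)
      m <- lw[, 1]
      if (K > 1) for (k in 2:K) m <- pmax(m, lw[, k])
      den <- m + log(rowSums(exp(lw - m)))
      gam <- exp(lw - den)
      w <- colMeans(gam)
      w <- pmax(w, 1e-12); w <- w / sum(w)
      # M-step for nu: fixed point of d/dnu sum_i gamma_i log Rice = 0,
      #   nu = sum_i gamma_i (r_i / sigma_i^2) A(r_i nu / sigma_i^2)
      #        / sum_i gamma_i / sigma_i^2,  A = I1/I0
      for (k in seq_len(K)) {
        g <- gam[, k]
        if (sum(g) < 1e-10) next
        wi <- g / sigma^2
        for (inner in 1:2) {
          z <- r * nu[k] / sigma^2
          A <- bessel_i1_i0(z)
          nu[k] <- min(max(sum(wi * r * A) / sum(wi), 0), nu_max)
        }
      }
      ll <- sum(den)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(nu = nu, w = w, loglik = ll_old)
  }

  # quantile ("k-means style") start plus random restarts on observed r
  starts <- list(stats::quantile(r, probs = (seq_len(K) - 0.5) / K,
                                 names = FALSE))
  for (i in seq_len(restarts))
    starts[[length(starts) + 1]] <- sample(r, K, replace = K > n)
  if (!is.null(init_nu))
    for (s in init_nu) if (length(s) == K)
      starts[[length(starts) + 1]] <- s
  best <- NULL
  for (s in starts) {
    fit <- run_em(s)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$nu)
  list(nu = best$nu[ord], weight = best$w[ord], loglik = best$loglik, K = K)
}

#' Choose the number of Rician components by BIC
#'
#' Fits mixtures for K = 1..K_max and selects the K minimising
#' `BIC(K) = -2 L + (2K - 1) log n` (K positions plus K - 1 free weights);
#' BIC ties break toward smaller K (parsimony). Per-component measurement
#' counts are hard assignments by maximum responsibility.
#'
#' @inheritParams fit_mixture
#' @param K_max largest K tried (capped at the dataset size).
#' @param early_stop stop scanning K after two consecutive BIC increases
#'   (the BIC table then covers only the scanned K).
#' @return list of class `flimp_decomposition`: `K`, `components` (data.frame
#'   nu, weight, n_measurements), `bic_table`, `loglik`, `n`, `fits`.
#' @export
select_K <- function(dataset, K_max = 8L, restarts = 5L, seed = NULL,
                     nu_max = 60, early_stop = TRUE) {
  n <- nrow(dataset)
  stopifnot(K_max >= 1, n >= 1)
  K_max <- min(K_max, n)
  fits <- vector("list", K_max)
  bic <- rep(NA_real_, K_max)
  rises <- 0L
  for (K in seq_len(K_max)) {
    # warm start from the previous solution with its heaviest component
    # split: the likelihood is then non-decreasing in K, so BIC can only
    # grow K when the extra component genuinely earns its penalty
    init <- if (K > 1) {
      prev <- fits[[K - 1]]
      hv <- which.max(prev$weight)
      list(sort(c(prev$nu, prev$nu[hv] + 1)),
           sort(c(prev$nu, max(prev$nu[hv] - 1, 0))))
    }
    fits[[K]] <- fit_mixture(dataset, K, restarts = restarts,
                             seed = if (is.null(seed)) NULL else seed + K,
                             nu_max = nu_max, init_nu = init)
    bic[K] <- -2 * fits[[K]]$loglik + (2 * K - 1) * log(n)
    if (K > 1) rises <- if (bic[K] > bic[K - 1]) rises + 1L else 0L
    if (early_stop && rises >= 2L) break
  }
  scanned <- which(!is.na(bic))
  bic <- bic[scanned]
  fits <- fits[scanned]
  # backward pruning: merging the closest pair of the K-component solution
  # seeds the (K-1)-fit, so a K-fit whose extra component is redundant can
  # never beat the merged fit on BIC
  for (K in rev(seq_along(fits))[seq_len(max(length(fits) - 1, 0))]) {
    f <- fits[[K]]
    if (f$K < 2) next
    gap <- which.min(diff(f$nu))
    merged <- f$nu[-gap]
    refit <- fit_mixture(dataset, K - 1, restarts = 0L, nu_max = nu_max,
                         init_nu = list(merged))
    if (refit$loglik > fits[[K - 1]]$loglik) {
      fits[[K - 1]] <- refit
      bic[K - 1] <- -2 * refit$loglik + (2 * (K - 1) - 1) * log(n)
    }
  }
  K_star <- which(bic <= min(bic) + 1e-9)[1]  # ties toward smaller K
  best <- fits[[K_star]]
  counts <- mixture_assignment_counts(dataset, best)
  out <- list(K = K_star,
              components = data.frame(nu = best$nu, weight = best$weight,
                                      n_measurements = counts),
              bic_table = data.frame(K = scanned, bic = bic),
              loglik = best$loglik, n = n, fits = fits)
  class(out) <- "flimp_decomposition"
  out
}

mixture_assignment_counts <- function(dataset, fit) {
  r <- dataset$r_obs_nm; sigma <- pmax(dataset$sigma_nm, 1e-3)
  K <- fit$K
  lw <- sapply(seq_len(K), function(k)
    log(fit$weight[k]) + drice_vec_sigma(r, fit$nu[k], sigma, log = TRUE))
  lw <- matrix(lw, nrow = length(r))
  tabulate(max.col(lw), nbins = K)
}

#' @export
print.flimp_decomposition <- function(x, ...) {
  cat(sprintf("Rician mixture decomposition: K = %d (n = %d measurements)\n",
              x$K, x$n))
  print(x$components, ...)
  invisible(x)
}

#' Bootstrap errors for a Rician-mixture decomposition
#'
#' Resamples measurements with replacement, refits at the selected K, and
#' reports the standard deviation of each component position (resampled
#' components are matched to the original by nearest nu). The model-selection
#' stability is the fraction of resamples in which BIC reproduces the
#' original K.
#'
#' @inheritParams fit_mixture
#' @param n_boot number of bootstrap resamples (>= 2).
#' @param K_max K range used for the per-resample BIC stability check; set
#'   `check_K = FALSE` to skip it.
#' @param check_K whether to re-run BIC selection per resample.
#' @return list: `sd_nu` (length K), `k_stability` (fraction, NA if
#'   unchecked), `boot_nu` (n_boot x K matrix).
#' @export
bootstrap_errors <- function(dataset, K, n_boot = 200L, seed = NULL,
                             restarts = 2L, K_max = 8L, check_K = TRUE,
                             nu_max = 60) {
  stopifnot(n_boot >= 2)
  if (!is.null(seed)) set.seed(seed)
  base_fit <- fit_mixture(dataset, K, restarts = restarts, nu_max = nu_max)
  n <- nrow(dataset)
  boot_nu <- matrix(NA_real_, n_boot, K)
  k_hits <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    ds <- dataset[idx, , drop = FALSE]
    fit <- fit_mixture(ds, K, restarts = restarts, nu_max = nu_max)
    # match resampled components to the originals by nearest nu
    boot_nu[b, ] <- fit$nu[vapply(base_fit$nu, function(v)
      which.min(abs(fit$nu - v)), integer(1))]
    if (check_K) {
      sel <- select_K(ds, K_max = min(K_max, nrow(ds)), restarts = restarts,
                      nu_max = nu_max)
      k_hits[b] <- sel$K == K
    }
  }
  list(sd_nu = apply(boot_nu, 2, stats::sd),
       k_stability = if (check_K) mean(k_hits) else NA_real_,
       boot_nu = boot_nu, nu = base_fit$nu)
}

# -- range-overlap post-analysis ----------------------------------------------

#' Fractions of measurements whose 69% CIs overlap query separations
#'
#' Classifies measurements by whether their credible interval is consistent
#' with a query: a point query (e.g. the 5 nm or 13 nm component position)
#' counts a measurement iff `lo <= value <= hi`; an interval query (e.g. the
#' dimer range 0-15 nm or oligomer range 20-60 nm) iff the intervals
#' intersect. Queries are not exclusive: one measurement can count toward
#' several.
#'
#' @param dataset a [flimp_dataset()].
#' @param queries list whose elements are single numbers (point queries) or
#'   length-2 numeric vectors `c(lo, hi)`.
#' @return named numeric vector of fractions in [0, 1].
#' @export
range_fractions <- function(dataset, queries) {
  stopifnot(is.list(queries), length(queries) >= 1)
  lo <- dataset$ci_lo_nm; hi <- dataset$ci_hi_nm
  n <- nrow(dataset)
  out <- vapply(queries, function(q) {
    if (length(q) == 1) {
      mean(lo <= q & q <= hi)
    } else if (length(q) == 2) {
      if (q[1] > q[2]) stop("interval query must have lo <= hi")
      mean(lo <= q[2] & q[1] <= hi)
    } else stop("queries must be points or (lo, hi) intervals")
  }, numeric(1))
  names(out) <- if (!is.null(names(queries))) names(queries) else
    vapply(queries, function(q) paste(format(q), collapse = "-"), character(1))
  if (n == 0) out[] <- NA_real_
  out
}
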