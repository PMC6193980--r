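#' Rice distribution density
#'
#' Sampling law of the Euclidean distance between two points each measured
#' with isotropic Gaussian error: `Rice(r | nu, sigma) =
#' (r / sigma^2) exp(-(r^2 + nu^2) / (2 sigma^2)) I0(r nu / sigma^2)`,
#' reducing to Rayleigh at nu = 0. Computed via the exponentially scaled
#' Bessel function so large `r nu / sigma^2` does not overflow.
#'
#' @param r observed distance(s), >= 0.
#' @param nu true separation, >= 0.
#' @param sigma combined Gaussian scale, > 0.
#' @param log return the log density.
#' @return density values, 0 (or -Inf) where r < 0.
#' @export
drice <- function(r, nu, sigma, log = FALSE) {
  stopifnot(sigma > 0, all(nu >= 0))
  n <- max(length(r), length(nu))
  r <- rep_len(r, n); nu <- rep_len(nu, n)
  z <- r * nu / sigma^2
  ld <- log(r) - 2 * log(sigma) - (r^2 + nu^2) / (2 * sigma^2) +
    log_bessel_i0(z)
  ld[r < 0] <- -Inf
  ld[r == 0] <- -Inf  # density vanishes at r = 0 (2-D Jacobian)
  if (log) ld else exp(ld)
}

# log I0(z), switching to the asymptotic expansion where R's besselI
# underflows (expon.scaled fails above z ~ 1e5)
log_bessel_i0 <- function(z) {
  out <- numeric(length(z))
  big <- z > 1e4
  if (any(!big))
    out[!big] <- log(besselI(z[!big], 0, expon.scaled = TRUE)) + z[!big]
  if (any(big)) {
    zb <- z[big]
    out[big] <- zb - 0.5 * log(2 * pi * zb) + log1p(1 / (8 * zb))
  }
  out
}

# I1(z) / I0(z), asymptotically 1 - 1/(2z) for large z
bessel_i1_i0 <- function(z) {
  out <- numeric(length(z))
  big <- z > 1e4
  if (any(!big))
    out[!big] <- besselI(z[!big], 1, expon.scaled = TRUE) /
      besselI(z[!big], 0, expon.scaled = TRUE)
  if (any(big)) out[big] <- 1 - 1 / (2 * z[big])
  out
}

#' Draw Rician-distributed distances
#'
#' @param n number of draws.
#' @inheritParams drice
#' @export
rrice <- function(n, nu, sigma) {
  sqrt((nu + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}
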