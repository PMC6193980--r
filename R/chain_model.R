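#' Polymer-chain geometry for head-to-head receptor oligomers
#'
#' A ligand-free receptor oligomer is modelled as a chain of protomers built
#' by repeating a single head-to-head extracellular interface. Because the
#' probed-site spacing between nearest neighbours differs between domains,
#' the chain curves in the membrane plane; the geometry is reduced to two
#' parameters: the nearest-neighbour spacing between label sites along the
#' chain and the in-plane turn angle between successive repeats. Probe sites
#' then sit on a circular arc (a straight line at zero turn angle).
#'
#' @param repeat_spacing_nm nearest-neighbour label-site distance (nm), > 0.
#' @param turn_angle_deg in-plane angle between successive repeats (degrees),
#'   absolute value below 180. Zero gives a straight chain.
#' @param site_offset_nm radial offset of the probed site from the chain
#'   backbone (nm); positive moves sites away from the arc centre. Lateral
#'   separations between equivalent sites are unchanged by a common offset,
#'   so this matters only when comparing different probed domains.
#' @return an object of class `chain_geometry`.
#' @examples
#' g <- chain_geometry(repeat_spacing_nm = 9, turn_angle_deg = 40)
#' chain_site_positions(g, n = 3)
#' @export
chain_geometry <- function(repeat_spacing_nm, turn_angle_deg = 0,
                           site_offset_nm = 0) {
  stopifnot(is.numeric(repeat_spacing_nm), length(repeat_spacing_nm) == 1L,
            is.finite(repeat_spacing_nm))
  if (repeat_spacing_nm <= 0)
    stop("repeat_spacing_nm must be positive")
  if (!is.finite(turn_angle_deg) || abs(turn_angle_deg) >= 180)
    stop("turn_angle_deg must satisfy 0 <= |angle| < 180")
  structure(list(repeat_spacing_nm = repeat_spacing_nm,
                 turn_angle_deg = turn_angle_deg,
                 site_offset_nm = site_offset_nm),
            class = "chain_geometry")
}

#' @export
print.chain_geometry <- function(x, ...) {
  cat(sprintf("chain geometry: spacing %.3g nm, turn %.3g deg, offset %.3g nm\n",
              x$repeat_spacing_nm, x$turn_angle_deg, x$site_offset_nm))
  invisible(x)
}

#' Planar coordinates of the probed sites of an n-chain
#'
#' Sites are placed on a circular arc of radius `R = s / (2 sin(theta/2))`
#' (s = repeat spacing, theta = turn angle), so that the chord between
#' consecutive sites equals the repeat spacing; at theta = 0 the chain is a
#' straight line with spacing s. The chord between sites i and k is
#' `2 R sin(|k - i| theta / 2)`. A non-zero `site_offset_nm` is added
#' radially (outwards from the arc centre) at every site.
#'
#' @param geometry a [chain_geometry()].
#' @param n chain size (number of protomers), >= 1.
#' @return an `n x 2` matrix of (x, y) coordinates in nm; the first site is
#'   at the origin.
#' @export
chain_site_positions <- function(geometry, n) {
  stopifnot(inherits(geometry, "chain_geometry"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be an integer >= 1")
  n <- as.integer(n)
  s <- geometry$repeat_spacing_nm
  theta <- geometry$turn_angle_deg * pi / 180
  off <- geometry$site_offset_nm
  if (abs(theta) < 1e-12) {
    xy <- cbind(s * (seq_len(n) - 1), rep(off, n))
  } else {
    R <- s / (2 * sin(abs(theta) / 2))
    # site i at angle (i-1)*theta around centre (0, R); offset moves radially
    phi <- (seq_len(n) - 1) * theta
    r <- R + off
    xy <- cbind(r * sin(phi), R - r * cos(phi))
    # shift so site 1 is at the origin
    xy <- sweep(xy, 2, xy[1, ])
  }
  dimnames(xy) <- list(NULL, c("x_nm", "y_nm"))
  xy
}

#' Labelling scheme for chain probe sites
#'
#' `internal_1to1` emulates a 1:1 probe binder (e.g. an anti-receptor
#' affibody) that labels each site independently with probability `p_label`;
#' `end_2Nto2` emulates an end-capping 2N:2 stoichiometry (e.g. a growth
#' factor ligand) in which a chain of N protomers carries exactly two probes,
#' one at each end, so each chain contributes at most one separation.
#'
#' @param mode `"internal_1to1"` or `"end_2Nto2"`.
#' @param p_label per-site labelling probability in [0, 1]; only used by the
#'   internal scheme. Default 0.2 (a probe concentration labelling ~20% of
#'   receptors).
#' @export
labeling_scheme <- function(mode = c("internal_1to1", "end_2Nto2"),
                            p_label = 0.2) {
  mode <- match.arg(mode)
  if (!is.numeric(p_label) || p_label < 0 || p_label > 1)
    stop("p_label must be in [0, 1]")
  structure(list(mode = mode, p_label = p_label), class = "labeling_scheme")
}

#' Label-site pairwise separations of one chain
#'
#' Labels the probe sites of an n-chain under the given scheme and returns
#' every unordered label-label distance. Under the internal 1:1 scheme every
#' pair of Bernoulli(p_label)-labelled sites contributes one distance; under
#' the end 2N:2 scheme a chain of size >= 2 contributes exactly the end-to-end
#' distance and a monomer contributes none.
#'
#' @inheritParams chain_site_positions
#' @param scheme a [labeling_scheme()].
#' @param seed optional integer seed for the Bernoulli labelling.
#' @return numeric vector of distances (nm), possibly empty.
#' @export
pairwise_separations <- function(geometry, n, scheme, seed = NULL) {
  stopifnot(inherits(scheme, "labeling_scheme"))
  xy <- chain_site_positions(geometry, n)
  if (scheme$mode == "end_2Nto2") {
    if (n < 2) return(numeric(0))
    return(sqrt(sum((xy[n, ] - xy[1, ])^2)))
  }
  if (!is.null(seed)) set.seed(seed)
  lab <- which(stats::runif(n) < scheme$p_label)
  if (length(lab) < 2) return(numeric(0))
  as.numeric(stats::dist(xy[lab, , drop = FALSE]))
}

#' Oligomer species composition
#'
#' Fractions `f_j` of assemblies of size j = 1..J (species-number fractions:
#' each assembly counts once whatever its size). Non-negative and summing
#' to one.
#'
#' @param fractions numeric vector of species fractions over sizes
#'   1..length(fractions); normalised if `normalize = TRUE`.
#' @param normalize divide by the sum (default TRUE).
#' @export
oligomer_composition <- function(fractions, normalize = TRUE) {
  f <- as.numeric(fractions)
  if (length(f) < 1 || any(!is.finite(f)) || any(f < 0))
    stop("fractions must be finite and non-negative")
  s <- sum(f)
  if (s <= 0) stop("fractions must not be all zero")
  if (normalize) f <- f / s
  else if (abs(s - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(fractions = f), class = "oligomer_composition")
}

#' Approximately exponential default composition
#'
#' Step-wise polymerisation gives a roughly geometric decay of species
#' fractions with size; this helper builds `f_j` proportional to `decay^(j-1)`.
#'
#' @param j_max largest species size (default 8).
#' @param decay per-step retention factor in (0, 1).
#' @export
exponential_composition <- function(j_max = 8, decay = 0.45) {
  stopifnot(j_max >= 1, decay > 0, decay < 1)
  oligomer_composition(decay^(seq_len(j_max) - 1))
}

#' Species-number to molecule-number fractions
#'
#' A species-number composition counts each assembly once; the
#' molecule-number view asks what fraction of receptors resides in each
#' size class: `m_j = j f_j / sum_k k f_k`.
#'
#' @param composition an [oligomer_composition()] or a bare fraction vector.
#' @return numeric vector `m_j` summing to 1.
#' @export
species_to_molecular <- function(composition) {
  f <- if (inherits(composition, "oligomer_composition"))
    composition$fractions else oligomer_composition(composition)$fractions
  j <- seq_along(f)
  m <- j * f
  m / sum(m)
}

#' Molecule-number to species-number fractions (inverse of
#' [species_to_molecular()] up to normalisation)
#'
#' @param molecular numeric vector of molecule-number fractions `m_j`.
#' @return numeric vector `f_j` summing to 1.
#' @export
molecular_to_species <- function(molecular) {
  m <- as.numeric(molecular)
  if (length(m) < 1 || any(!is.finite(m)) || any(m < 0) || sum(m) <= 0)
    stop("molecular fractions must be non-negative, not all zero")
  j <- seq_along(m)
  f <- m / j
  f / sum(f)
}

#' Fraction of receptors residing in oligomers (size >= 2)
#'
#' Convenience wrapper: molecule-normalises a species composition and sums
#' the mass above the monomer class.
#'
#' @inheritParams species_to_molecular
#' @export
oligomer_resident_fraction <- function(composition) {
  m <- species_to_molecular(composition)
  sum(m[-1])
}
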