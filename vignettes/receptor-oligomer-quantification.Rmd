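---
title: "Quantifying receptor oligomers from single-molecule fluorescence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor oligomers from single-molecule fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoscope)
```

`oligoscope` bundles four complementary quantifications of cell-surface
receptor oligomerisation — pairwise-separation decomposition (FLImP),
photobleaching image correlation spectroscopy (pbICS), two-colour
single-particle-tracking (SPT) colocalisation, and FRET-based distance of
closest approach (DOCA) — together with a polymer-chain geometry model and
synthetic-data generators that emulate each experimental input. This
vignette records the models, their assumptions, and the design decisions
behind the numerical choices.

## Chain geometry and composition bookkeeping

A ligand-free oligomer is modelled as a chain of protomers built by
repeating one asymmetric head-to-head extracellular contact. Because the
probed-site spacing differs between receptor domains, the chain curves in
the membrane plane. The package reduces this to a two-parameter arc:
`repeat_spacing_nm` (nearest-neighbour label-site distance, nm) and
`turn_angle_deg` (in-plane angle per repeat). Sites sit on a circle of
radius $R = s / (2\sin(\theta/2))$ and the distance between sites $i$ and
$k$ is the chord $2R\sin(|k-i|\theta/2)$; $\theta = 0$ recovers a straight
chain. Chains are modelled in-plane only, because the lateral-separation
measurement is insensitive to label height. The default parameters are
illustrative configuration values, not measured quantities: the structural
model that motivates them is not part of this package.

Two labelling stoichiometries are supported. A 1:1 internal binder labels
each protomer independently with probability `p_label` (default 0.2,
matching a probe concentration that labels roughly a fifth of receptors),
so an internally probed chain shows the whole "ladder" of chord distances.
An end-capping 2N:2 probe (a ligand-like stoichiometry) marks exactly the
two chain ends, so each chain contributes a single, long separation. For
chains subtending more than half the arc circle the end-to-end chord stops
being the longest distance, so the end-versus-internal density shift is a
property of the composition-weighted mean, not of every size separately.

Compositions come in two normalisations. Species-number fractions $f_j$
count each assembly once; molecule-number fractions
$m_j = j f_j / \sum_k k f_k$ count receptors. `species_to_molecular()` and
`molecular_to_species()` convert between them exactly (they are inverse
bijections on the simplex); `oligomer_resident_fraction()` reports
$\sum_{j\ge2} m_j$, the share of receptors living in oligomers. Applying
this to species fractions of 60/25/10/5% (sizes 1–4) gives 62.5% of
receptors in dimers or larger.

## FLImP: Rician separations, BIC, bootstrap

A pairwise separation between two identically labelled molecules, each
localised with isotropic Gaussian error, follows a Rice law:
$\mathrm{Rice}(r \mid \nu, \sigma) = (r/\sigma^2)
e^{-(r^2+\nu^2)/2\sigma^2} I_0(r\nu/\sigma^2)$, with combined scale
$\sigma = \sqrt{\sigma_A^2 + \sigma_B^2}$ and Rayleigh limit at $\nu = 0$.
Under a flat prior on $\nu \ge 0$, `separation_posterior()` reports the 69%
(~1 s.d.) highest-density interval of the posterior; the HDI handles the
boundary at zero separation naturally, and the posterior is evaluated up to
$\nu$-independent constants so the coincident-emitter case ($r \to 0$,
half-normal posterior) is well defined. Quality filtering retains
measurements with CI width at most the threshold (boundary inclusive). For
$I_0$ at large argument the implementation switches to the asymptotic
expansion, since the standard Bessel routine underflows above
$z \approx 10^5$.

The separation histogram is decomposed as a mixture
$\sum_k w_k\,\mathrm{Rice}(r_i \mid \nu_k, \sigma_i)$ with per-measurement
$\sigma_i$ treated as known from the localisation fits — a plug-in
approximation to a fully hierarchical treatment of per-measurement
posteriors, leaving $2K-1$ free parameters for $K$ components. Fitting is
expectation–maximisation: weights update in closed form and each $\nu_k$ by
the Rician fixed-point step
$\nu \leftarrow \sum_i \gamma_i (r_i/\sigma_i^2) A(r_i\nu/\sigma_i^2) /
\sum_i \gamma_i/\sigma_i^2$ with $A = I_1/I_0$, under quantile
initialisation plus random restarts. EM was preferred over a generic
bounded quasi-Newton run because it respects the simplex and the
$[0, 60]$ nm position bounds by construction and is monotone in practice.
Model order is chosen by $\mathrm{BIC}(K) = -2\hat L + (2K-1)\ln n$, ties
broken toward smaller $K$; the scan stops after two consecutive BIC
increases. Bootstrap resampling of measurements yields position s.d.s
(components matched by nearest $\nu$) and the fraction of resamples
reproducing $K$. Component "fractions" are reported as measurement counts
by maximum responsibility, a documented convention.

The movie-level route renders two-emitter spots with Gaussian PSFs,
constant background, Poisson shot noise and Gaussian read noise, and
stepwise bleaching. Change points of the summed-intensity trace are found
by binary segmentation with a minimum segment of 3 frames and a
noise-scaled penalty; exactly two downward steps are required. The last
survivor is localised from the mean image of the final bright segment, the
first-bleaching emitter from the difference of segment means. Both fits are
variance-weighted least squares using the empirical per-pixel variance of
the segment mean — the weighting matters because unweighted residual
scaling underestimates the localisation error of a shot-noise-limited peak
by about a factor of three.

## pbICS: what one bleach curve can and cannot identify

The apparent cluster density after photobleaching to surviving intensity
fraction $p$ is

$$\mathrm{CD}(p) = \frac{(\sum_j j c_j)^2\, p}
{\sum_j [\, j c_j + j(j-1) c_j p\,]},$$

which equals the binomial-survival moment ratio
$(\sum_j c_j \mathbb E B_j)^2 / \sum_j c_j \mathbb E B_j^2$ with
$B_j \sim \mathrm{Binomial}(j, p)$ — the package tests verify this
equivalence against direct moment enumeration and Monte-Carlo cluster
simulation. Cluster density itself is measured from the spatial
autocorrelation $g(\xi,\eta) = \langle \delta I\,\delta I\rangle /
\langle I\rangle^2$ (FFT), fitting the central peak with a 2-D Gaussian
while excluding the shot-noise spike at zero lag, and converting via the
standard normalisation $\mathrm{CD} = 1/(g_0 \pi \omega^2)$. The beam
waist $\omega$ and the border-region background estimate are configuration
inputs. ICS is a sparse-regime method: the generator warns when clusters
per beam area grow large enough to bias the amplitude.

A point the package makes explicit: the model above is algebraically
$A^2 p/(A + Bp)$ with $A = \sum_j j c_j$ (total molecular density) and
$B = \sum_j j(j-1) c_j$. **A single bleach curve therefore identifies
exactly two functionals of the composition**, and the popular
"model-free" fit of eight free concentrations is degenerate: any
non-negative composition matching $(A, B)$ fits identically. The default
`fit_composition(structure = "auto")` therefore reports, among
least-squares-optimal compositions, the most parsimonious one consistent
with the data: a single species when one attains the optimum exactly
(which is how noise-free single-species curves are recovered with all mass
on the true size), otherwise the two-parameter geometric family
$c_j = c_1 q^{\,j-1}$ expected from step-wise polymerisation — the same
family the approximately exponential measured size distributions suggest.
The literal multi-start non-negative 8-concentration fit remains available
as `structure = "free"`; its $(A, B)$ agree with the constrained fits but
its split of mass across sizes is start-dependent. The headline
molecule-normalised oligomer fraction is exact for geometric truths and
biased by a few points for mixtures that deviate from geometric decay
(about $-0.05$ for a 60/25/10/5 truth), which is inside the ±10-point
tolerance used in the recovery tests. Replicate curves are aggregated as
per-size means with s.d. error bars, mirroring the seven-replicate
reporting convention.

## Two-colour SPT colocalisation

Channels are registered by cubic polynomial surfaces fitted to matched bead
coordinates, and position traces are smoothed with a temporal Gaussian of
FWHM 4 frames (200 ms at 50 ms/frame) before any distance test. A track
pair is colocalised when the particles spend **at least 5 frames in total
within (strictly) 1 pixel**; maximal contiguous runs of qualifying frames
are individual events whose durations are the $\tau_{ON}$ statistics. Where
the "in total" and "contiguous" readings of the rule differ, the total-frame
count decides the colocalised-track call and contiguous runs define events.
Fractions are reported per channel (the denominator convention is not
universal, so both are given).

Chance colocalisation is estimated by rebuilding both channels from tracks
resampled with replacement, recentred uniformly over the field of view,
rotated uniformly, and flipped in $x$ with probability 0.5 — isometries
that preserve durations and path shape while destroying spatial
correlations; positions leaving the field of view wrap toroidally. The
corrected fraction is raw minus the mean over 50 randomisation rounds and
is deliberately not clamped at zero so that averages of null data stay
unbiased. The dwell-time comparison uses the standard two-sample
Kolmogorov–Smirnov test, two-tailed.

The track generator emulates a sparse acquisition: free tracks are
independent Brownian walks, bound pairs co-diffuse at a fixed 0.2 px offset
for exponential bound times (infinite mean keeps them bound throughout),
and each track occupies a random window of a longer movie (default ten
track lengths), since it is the instantaneous particle density — not the
cumulative track count — that sets the coincidence rate in a real
experiment. Localisation noise is Gaussian per frame. Proximity testing
uses cell-binned neighbour joins, so the cost scales with true coincidences
rather than with all track pairs.

## FRET distance of closest approach

A donor at height $h$ above a plane of acceptors at surface density
$\sigma$ transfers with per-configuration sum
$S = \sum_i (R_0/r_i)^6$, $r_i = \sqrt{h^2 + \rho_i^2}$, and efficiency
$E = S/(1+S)$. `mc_efficiency()` draws acceptors from a spatial Poisson
process under the donor; acceptors beyond an inner radius
$\max(3R_0,\, 1.5h)$ contribute through their (tiny-variance) expectation
$\pi\sigma R_0^6/2 \cdot [(h^2+r^2)^{-2}]$ rather than individually, which
keeps the response grid affordable without measurable bias. At high density
$E \to \bar S/(1+\bar S)$ with $\bar S = \pi\sigma R_0^6/(2h^4)$, the
continuum law used as an independent check (2% agreement). The orientation
factor is absorbed into $R_0$ (default 5 nm, an illustrative value for a
green-dye/lipid-dye pair); a single acceptor plane represents the labelled
leaflet.

`fit_doca()` precomputes the Monte-Carlo response on a height grid
(1–30 nm, 0.25 nm steps) at the exact acceptor densities present in the
data — a titration has few distinct densities, so tabulating them directly
is both cheaper and exact in density, with linear interpolation in $h$
only. Each of 3000 bootstrap resamples redraws cells with replacement and
refits $h$ by least squares over the grid; the DOCA is reported as the mean
± s.d. of the bootstrap distribution. The difference test pools both
datasets, resamples two sets of the original sizes (10,000 replicates), and
compares the absolute difference of the two fitted DOCAs against its null
distribution; the per-replicate fits are point fits on the shared response
(a nested bootstrap inside every replicate would multiply the cost
10,000-fold for no change in the statistic's null behaviour), and ties at
the observed value count toward the null because the height grid makes the
statistic discrete.

## Synthetic data, reproducibility, and what the tests show

Every generator takes a seed, is bit-reproducible given (parameters, seed),
and returns the generating truth alongside the data; recovery tests always
compare estimates to truth. The generators reproduce the statistical
structure of the experiments — Rician separations from labelled chains,
binomial photobleach survival of clustered fluorophores, co-diffusing track
pairs, noisy efficiency titrations — but not their full physics: no EMCCD
gain-register noise, no cell morphology or mask, no drift, no
photophysics beyond single-step bleaching, at most two emitters per FLImP
spot. Passing tests therefore validate the estimators on data that satisfy
the models' assumptions; they do not certify performance on raw microscopy
data with untreated systematics.

Default problem sizes in the test-suite simulations were chosen as the
smallest that make the statistical claims sharp: mixture-selection studies
use 50 datasets of 200 measurements; posterior calibration uses 2000
draws; the SPT recovery uses 1000 tracks per channel with 50 randomisation
rounds; FRET size/power studies use 40-cell titrations with 1000 null
replicates per test. The acceptance script recomputes the printed-number
worked example (the molecule-normalised oligomer-resident fraction) from
the species fractions; the headline experimental decompositions themselves
require the original raw data, which is not publicly deposited, and are
deliberately out of scope.

## Known limitations

* The mixture likelihood is plug-in in $\sigma_i$; severely misestimated
  localisation errors propagate directly into component widths.
* A single pbICS curve cannot distinguish compositions sharing $(A, B)$;
  the reported composition is a documented model choice beyond those two
  functionals.
* The colocalisation correction subtracts the all-track coincidence
  estimate, which slightly over-corrects when a large fraction of tracks is
  genuinely bound (a bound track cannot also be counted coincidentally);
  at a 30% bound fraction the effect is below one percentage point.
* Toroidal wrapping in the randomisation and in the Brownian generator is a
  convention; tracks that straddle a boundary contribute a handful of
  spurious large steps to diffusion summaries (not used by the estimators
  here).
* The DOCA estimate inherits the grid resolution (0.25 nm) and the MC error
  of the tabulated response; both are kept below the reported bootstrap
  s.d. at the default settings.
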