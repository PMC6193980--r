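# oligoscope

Quantifying membrane-receptor oligomerisation from single-molecule
fluorescence data.

Resting cell-surface receptors of the EGFR class are not simple monomers:
single-molecule microscopy shows mixtures of monomers, dimers and larger
chain-like oligomers whose architecture matters for how activation is kept
in check. `oligoscope` is an R implementation of the four quantifications
used to establish that picture, with synthetic-data generators that make
every stage testable without raw microscopy data:

* **FLImP-style separation analysis** — pairwise lateral separations
  between two identical fluorophores, each localised with Gaussian error,
  follow a Rice law
  `Rice(r | ν, σ) = (r/σ²) exp(−(r²+ν²)/2σ²) I₀(rν/σ²)`.
  The package computes per-measurement 69% highest-density credible
  intervals, quality-filters on CI width, decomposes separation datasets
  into Rician mixtures by EM with BIC model selection
  (`BIC(K) = −2L̂ + (2K−1) ln n`), attaches bootstrap errors, and reports
  range-overlap fractions (e.g. how many measurements are consistent with
  a dimer at 0–15 nm versus oligomers at 20–60 nm).
* **pbICS** — photobleaching image correlation spectroscopy. The apparent
  cluster density after bleaching to surviving intensity fraction *p* is
  `CD(p) = (Σⱼ j cⱼ)² p / Σⱼ [j cⱼ + j(j−1) cⱼ p]`;
  fitting CD-versus-*p* curves with non-negative concentrations for sizes
  1–8 yields the oligomer composition, reported molecule-normalised
  (`mⱼ = j fⱼ / Σₖ k fₖ`).
* **Two-colour SPT colocalisation** — cubic-polynomial channel
  registration, temporal Gaussian smoothing (FWHM 4 frames), a
  colocalisation rule of ≥5 frames in total within <1 pixel, τ_ON event
  durations, and a coincidence correction built from 50 rounds of
  resampled, recentred, rotated and flipped tracks.
* **FRET distance of closest approach** — Monte-Carlo efficiency of a
  donor at height *h* above a plane of acceptors
  (`E = S/(1+S)`, `S = Σᵢ (R₀/rᵢ)⁶`), inverted by 3000-resample bootstrap
  regression, with a 10,000-replicate pooled-bootstrap test for DOCA
  differences.

A two-parameter polymer-chain geometry model (repeat spacing, in-plane turn
angle) connects the measured separation ladders to head-to-head chain
architecture, and handles the bookkeeping between species-number and
molecule-number oligomer fractions.

## Worked example

Simulate an internally probed (20% labelled) population of chains —
60% monomers, 25% dimers, 10% trimers, 5% tetramers on an 11 nm / 32°
arc — measure separations with 1.5 nm localisation error, filter at
CI ≤ 7 nm, and decompose:

```r
library(oligoscope)

geom <- chain_geometry(repeat_spacing_nm = 11, turn_angle_deg = 32)
comp <- oligomer_composition(c(0.60, 0.25, 0.10, 0.05))
ds <- simulate_flimp_measurements(geom, comp,
                                  labeling_scheme("internal_1to1", 0.2),
                                  loc_sigma_nm = 1.5,
                                  n_measurements = 150, seed = 7)
ds <- filter_ci(ds, ci_max_nm = 7)
(dec <- select_K(ds, K_max = 5, restarts = 2, seed = 8))
#> Rician mixture decomposition: K = 3 (n = 150 measurements)
#>         nu     weight n_measurements
#> 1 11.16790 0.75899314            113
#> 2 21.37349 0.19174016             30
#> 3 27.85492 0.04926669              7

range_fractions(ds, list(dimer = c(0, 15), oligomer = c(20, 60)))
#>    dimer oligomer
#>     0.76     0.23

100 * oligomer_resident_fraction(comp)
#> [1] 62.5
```

The three components recover the chain's chord ladder (truth: 11, 21.2 and
29.7 nm for neighbour, next-neighbour and end pairs): BIC places 113 of 150
measurements on the nearest-neighbour separation, and the range-overlap
fractions say 76% of measurements are consistent with dimer-scale
separations while 23% reach into the oligomer range. The last line is the
species-to-molecule conversion: with 25/10/5% of species being
dimers/trimers/tetramers, 62.5% of *receptors* reside in oligomers even
though most *species* are monomers.

The other stages follow the same pattern — see `?simulate_pbics_stack`,
`?fit_composition`, `?simulate_tracks`, `?coloc_analysis`,
`?simulate_fret`, `?fit_doca`, and `run_pipeline()` for a seeded
simulate→analyse→report wrapper around each stage. The methods vignette
(`vignettes/receptor-oligomer-quantification.Rmd`) documents the models,
parameter conventions and numerical design decisions, including what one
pbICS bleach curve can and cannot identify.

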