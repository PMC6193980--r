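# Brute-force oracle: walk the chain turning by theta at each repeat and
# accumulate coordinates directly, independent of the arc construction.
walk_chain <- function(s, theta_deg, n) {
  th <- theta_deg * pi / 180
  xy <- matrix(0, n, 2)
  heading <- 0
  for (i in seq_len(n)[-1]) {
    xy[i, ] <- xy[i - 1, ] + s * c(cos(heading), sin(heading))
    heading <- heading + th
  }
  xy
}

test_that("chain site positions reproduce the arc chord formula", {
  g <- chain_geometry(9, 40)
  xy <- chain_site_positions(g, 3)
  expect_equal(unname(sqrt(sum((xy[2, ] - xy[1, ])^2))), 9, tolerance = 1e-12)
  R <- 9 / (2 * sin(20 * pi / 180))
  expect_equal(unname(sqrt(sum((xy[3, ] - xy[1, ])^2))),
               2 * R * sin(40 * pi / 180), tolerance = 1e-12)
  # against the independent coordinate walk
  ref <- walk_chain(9, 40, 6)
  got <- chain_site_positions(g, 6)
  dref <- as.numeric(dist(ref)); dgot <- as.numeric(dist(got))
  expect_equal(sort(dgot), sort(dref), tolerance = 1e-9)
})

test_that("degenerate and straight chains behave", {
  g0 <- chain_geometry(9, 0)
  expect_equal(unname(chain_site_positions(g0, 1)), matrix(c(0, 0), 1))
  xy <- chain_site_positions(g0, 4)
  expect_equal(unname(xy[, 1]), c(0, 9, 18, 27))
  expect_error(chain_site_positions(g0, 0), "integer >= 1")
  expect_error(chain_geometry(-1), "positive")
  expect_error(chain_geometry(9, 180), "angle")
})

test_that("arc chains are bounded by the diameter and grow while n*theta <= pi", {
  g <- chain_geometry(9, 30)
  R <- 9 / (2 * sin(15 * pi / 180))
  prev <- 0
  for (n in 2:12) {  # n*theta <= pi up to n = 12 at 30 deg per repeat
    dmax <- max(dist(chain_site_positions(g, n)))
    expect_lte(dmax, 2 * R + 1e-9)
    if ((n - 1) * 30 * pi / 180 <= pi) expect_gte(dmax, prev - 1e-9)
    prev <- dmax
  }
})

test_that("labelling schemes produce the expected pair counts", {
  g <- chain_geometry(9, 40)
  expect_length(pairwise_separations(g, 4,
                                     labeling_scheme("internal_1to1", 1)), 6)
  endsep <- pairwise_separations(g, 4, labeling_scheme("end_2Nto2"))
  expect_length(endsep, 1)
  # the end pair is the longest chord of the chain while the arc is convex
  expect_equal(endsep, max(dist(chain_site_positions(g, 4))),
               tolerance = 1e-12)
  expect_length(pairwise_separations(g, 1, labeling_scheme("end_2Nto2")), 0)
  # Binomial(4, 0.2) labelling: check the mean pair count per tetramer
  sch <- labeling_scheme("internal_1to1", 0.2)
  set.seed(8)
  counts <- replicate(4000, length(pairwise_separations(g, 4, sch)))
  # E[C(L,2)] with L ~ Bin(4, .2): sum over l
  expected_pairs <- sum(choose(0:4, 2) * dbinom(0:4, 4, 0.2))
  expect_equal(mean(counts), expected_pairs, tolerance = 0.15)
})

test_that("end labelling of longer chains shifts density to long separations", {
  g <- chain_geometry(9, 40)
  internal <- labeling_scheme("internal_1to1", 0.5)
  set.seed(11)
  means <- vapply(3:8, function(n) {
    ends <- pairwise_separations(g, n, labeling_scheme("end_2Nto2"))
    ints <- unlist(replicate(300, pairwise_separations(g, n, internal),
                             simplify = FALSE))
    c(mean(ends), mean(ints))
  }, numeric(2))
  # while the chain subtends <= half the circle the end pair is the longest
  # chord, so the shift holds per size
  per_size_ok <- (3:8 - 1) * 40 <= 180
  expect_true(all(means[1, per_size_ok] > means[2, per_size_ok]))
  # across a step-wise-polymerisation composition of sizes >= 3 the pooled
  # end-labelled mean still exceeds the internally labelled mean
  w <- exponential_composition(8, 0.45)$fractions[3:8]
  expect_gt(sum(w * means[1, ]) / sum(w), sum(w * means[2, ]) / sum(w))
})

test_that("species/molecular normalisation is a simplex bijection", {
  expect_equal(species_to_molecular(c(1, 0, 0)), c(1, 0, 0))
  m <- species_to_molecular(c(0, 1, 0))
  expect_equal(sum(m[-1]), 1)
  expect_equal(100 * oligomer_resident_fraction(c(0.60, 0.25, 0.10, 0.05)),
               62.5, tolerance = 1e-9)
  set.seed(3)
  for (i in 1:20) {
    f <- runif(8); f <- f / sum(f)
    expect_equal(molecular_to_species(species_to_molecular(f)), f,
                 tolerance = 1e-9)
  }
  expect_error(oligomer_composition(c(0, 0, 0)), "all zero")
  expect_error(species_to_molecular(c(0, 0)), "all zero")
})
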