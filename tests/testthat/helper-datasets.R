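# Synthetic separation datasets drawn straight from the Rice law: mixture of
# true components `nus` with equal weights, common measurement scale `sigma`.
make_rice_dataset <- function(nus, n, sigma, seed) {
  set.seed(seed)
  comp <- sample(seq_along(nus), n, replace = TRUE)
  flimp_dataset(rrice(n, nus[comp], sigma), rep(sigma, n))
}

# Independent oracle for the bleach-curve model: survivors of a j-mer after
# bleaching to fraction p are Binomial(j, p); the apparent cluster density is
# (sum_j c_j E[B_j])^2 / (sum_j c_j E[B_j^2]) with moments enumerated from
# dbinom, never from the closed-form identity under test.
cd_binomial_oracle <- function(c_j, p) {
  vapply(p, function(pp) {
    if (pp == 0) return(0)
    EB <- EB2 <- 0
    for (j in seq_along(c_j)) {
      k <- 0:j
      pk <- dbinom(k, j, pp)
      EB <- EB + c_j[j] * sum(k * pk)
      EB2 <- EB2 + c_j[j] * sum(k^2 * pk)
    }
    EB^2 / EB2
  }, numeric(1))
}

# Monte-Carlo cluster oracle for the same quantity: simulate clusters,
# bleach fluorophores individually, and form the moment ratio empirically.
cd_mc_oracle <- function(c_j, p, n_clusters = 2e5, seed = 1) {
  set.seed(seed)
  sizes <- sample(seq_along(c_j), n_clusters, replace = TRUE,
                  prob = c_j / sum(c_j))
  B <- rbinom(n_clusters, sizes, p)
  dens_scale <- sum(c_j)  # clusters per unit area represented by the sample
  dens_scale * mean(B)^2 / mean(B^2)
}
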