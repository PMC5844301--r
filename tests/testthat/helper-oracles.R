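# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package implementation.

# Brute-force SAF: enumerate all 3^n genotype configurations, weight each by
# its product of genotype likelihoods and the multivariate hypergeometric
# probability of assigning j derived alleles to the n diploids.
saf_bruteforce <- function(gl_lin) {
  n <- nrow(gl_lin)
  m <- 2L * n
  configs <- as.matrix(expand.grid(rep(list(0:2), n)))
  L <- numeric(m + 1)
  for (r in seq_len(nrow(configs))) {
    g <- configs[r, ]
    j <- sum(g)
    w <- prod(gl_lin[cbind(seq_len(n), g + 1)]) * prod(choose(2, g))
    L[j + 1] <- L[j + 1] + w
  }
  L <- L / choose(m, 0:m)
  L / max(L)
}

# Type-7 percentile by explicit sort-and-interpolate arithmetic.
pct7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# Direct SNP likelihood-ratio statistic via stats::optimize on [0, 1].
lrt_oracle <- function(k0, k1, e) {
  ll <- function(f) {
    sum(mapply(function(a, b) {
      g0 <- (1 - e)^a * e^b
      g1 <- 0.5^(a + b)
      g2 <- e^a * (1 - e)^b
      log(g0 * (1 - f)^2 + g1 * 2 * f * (1 - f) + g2 * f^2)
    }, k0, k1))
  }
  null <- max(ll(0), ll(1))
  opt <- optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-10)
  2 * (max(opt$objective, null) - null)
}

# Random unrooted additive tree and its exact path-length distance matrix.
random_additive <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# average pairwise difference per site from a 0/1 haplotype matrix
hap_pi <- function(hapm, L) {
  m <- nrow(hapm)
  j <- colSums(hapm)
  sum(2 * j * (m - j) / (m * (m - 1))) / L
}
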