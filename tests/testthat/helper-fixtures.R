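# Shared fixtures: small synthetic configurations and independent oracles
# used across the suite.

# cell_allometry_b defaults to 0 here so that the linear-Gaussian closed
# forms are exact; tests of the body-size scaling set it explicitly.
tiny_cfg <- function(seed = 1, n_per_site = 30, sites = c("BM", "HW", "PF"),
                     n_loci = 120, cell_allometry_b = 0, ...) {
  synthetic_config(seed = seed,
                   site_sizes = setNames(rep(n_per_site, length(sites)),
                                         sites),
                   n_loci = n_loci, cell_allometry_b = cell_allometry_b,
                   ...)
}

# Exact biallelic Hardy-Weinberg test by full enumeration over all
# heterozygote counts compatible with the allele counts (independent
# oracle for the Markov-chain estimator).
hwe_exact_enum <- function(counts) {
  nA <- 2 * counts[3] + counts[2]
  n <- sum(counts)
  hmax <- min(nA, 2 * n - nA)
  hs <- seq(nA %% 2, hmax, by = 2)
  lp <- sapply(hs, function(h) {
    nAA <- (nA - h) / 2
    naa <- n - nAA - h
    h * log(2) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(naa + 1)
  })
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  lp_obs <- lp[hs == counts[2]]
  sum(pr[lp <= lp_obs + 1e-9])
}

# Exhaustive Mantel oracle: correlation of off-diagonal pairs under every
# relabeling of one matrix, done with nothing but base loops.
mantel_enum_oracle <- function(a, b) {
  n <- nrow(a)
  off <- function(m) m[lower.tri(m)]
  r_obs <- cor(off(a), off(b))
  perms <- NULL
  rec <- function(prefix, rest) {
    if (length(rest) == 0) {
      perms[[length(perms) + 1]] <<- prefix
    } else {
      for (k in rest) rec(c(prefix, k), setdiff(rest, k))
    }
  }
  perms <- list(); rec(integer(0), seq_len(n))
  rs <- sapply(perms, function(p) cor(off(a), off(b[p, p])))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12), all_r = rs)
}

# Random point configuration -> Euclidean distance matrix with labels.
points_dm <- function(n, d = 2, seed = 1) {
  set.seed(seed)
  xy <- matrix(rnorm(n * d), n)
  rownames(xy) <- paste0("p", seq_len(n))
  list(xy = xy, dm = distance_matrix(as.matrix(dist(xy)), rownames(xy)))
}
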