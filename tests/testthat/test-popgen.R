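# dosage matrix from genotype counts (nAA refs, nAa hets, naa alts)
counts_to_g <- function(n0, n1, n2, site = "A") {
  d <- matrix(c(rep(0, n0), rep(1, n1), rep(2, n2)), nrow = 1)
  genotype_matrix(d, locus_ids = "L1", sites = rep(site, n0 + n1 + n2))
}

test_that("locus statistics count alleles and heterozygotes correctly", {
  g <- counts_to_g(25, 50, 25)
  st <- locus_stats(g)
  expect_equal(st$p, 0.5)
  expect_equal(st$ho, 0.5)
  expect_equal(st$he, 0.5 * 200 / 199)     # unbiased He at p = 0.5, n = 100
  # at n = 50 individuals the correction is 2n/(2n-1) = 100/99
  g50 <- counts_to_g(12, 26, 12)
  expect_equal(locus_stats(g50)$he, 0.5 * 100 / 99)
  g2 <- counts_to_g(0, 10, 0)
  expect_equal(locus_stats(g2)$ho, 1)
  g3 <- counts_to_g(50, 0, 0)
  expect_true(locus_stats(g3)$monomorphic)
})

test_that("the Markov-chain Hardy-Weinberg test matches full enumeration", {
  cases <- list(c(25, 50, 25), c(40, 20, 40), c(10, 40, 10), c(3, 5, 12))
  for (cnt in cases) {
    mc <- hwe_exact_mc(cnt, chain_length = 2e5, seed = 7)
    exact <- hwe_exact_enum(cnt)
    expect_lt(abs(mc$p - exact), 3 * max(mc$se, 1e-4))
  }
  # maximal disequilibrium: no heterozygotes at p = 0.5
  dis <- hwe_exact_mc(c(50, 0, 50), chain_length = 2e5, seed = 1)
  expect_lt(dis$p, 1e-4)
  expect_lt(hwe_exact_enum(c(50, 0, 50)), 1e-10)
  # determinism under a fixed seed
  a <- hwe_exact_mc(c(25, 50, 25), chain_length = 1e4, seed = 3)
  b <- hwe_exact_mc(c(25, 50, 25), chain_length = 1e4, seed = 3)
  expect_identical(a$p, b$p)
  expect_error(hwe_exact_mc(c(10, 0, 0)), "monomorphic")
})

test_that("randomized Hardy-Weinberg p-values are uniform under equilibrium", {
  set.seed(41)
  n <- 100
  pvals <- replicate(500, {
    p <- runif(1, 0.2, 0.8)
    dos <- rbinom(n, 2, p)
    cnt <- c(sum(dos == 0), sum(dos == 1), sum(dos == 2))
    if (cnt[1] + cnt[2] == 0 || cnt[2] + cnt[3] == 0) return(NA)
    hwe_exact_mc(cnt, chain_length = 2e4,
                 seed = sample.int(1e6, 1))$p_randomized
  })
  pvals <- pvals[!is.na(pvals)]
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Weir-Cockerham theta is exact for fixed populations and label-invariant", {
  d <- cbind(matrix(0, 5, 20), matrix(2, 5, 20))
  g <- genotype_matrix(d, sites = rep(c("A", "B"), each = 20))
  res <- pairwise_fst(g, "A", "B")
  expect_equal(res$theta, 1)
  expect_equal(res$components$a[1], 0.5)    # hand-evaluated components
  expect_equal(res$components$b[1], 0)
  expect_equal(res$components$c[1], 0)

  # swapping allele labels at any locus leaves theta unchanged
  cfg <- tiny_cfg(seed = 13, n_per_site = 20, sites = c("A", "B"),
                  n_loci = 200, fst_target = 0.3)
  gg <- gen_genotypes(cfg)$genotypes
  th <- pairwise_fst(gg, "A", "B")$theta
  flip <- sample(200, 80)
  gg$dosage[flip, ] <- 2 - gg$dosage[flip, ]
  expect_equal(pairwise_fst(gg, "A", "B")$theta, th, tolerance = 1e-12)
  expect_error(pairwise_fst(gg, "A", "ZZ"), "absent")
})

test_that("theta is near zero for a panmictic pair and near F under Balding-Nichols", {
  null_thetas <- sapply(1:5, function(s) {
    cfg <- synthetic_config(seed = 100 + s, site_sizes = c(A = 100, B = 100),
                            n_loci = 1000, panmixia = TRUE)
    pairwise_fst(gen_genotypes(cfg)$genotypes, "A", "B")$theta
  })
  expect_true(all(null_thetas > -0.01 & null_thetas < 0.02))
})

test_that("F_IS is near zero in Hardy-Weinberg proportions and -1 for all heterozygotes", {
  # exact HWE proportions at p = 0.5, n = 100 per site
  d <- matrix(rep(c(rep(0, 25), rep(1, 50), rep(2, 25)), 3),
              nrow = 3, byrow = TRUE)
  g <- genotype_matrix(d, sites = rep("A", 100))
  out <- fis(g)
  expect_lt(abs(out$average), 0.02)         # He bias correction only
  gh <- counts_to_g(0, 500, 0)
  expect_equal(fis(gh)$average, -1, tolerance = 0.01)
})

test_that("individual genetic distance counts allele differences", {
  d <- matrix(c(0, 2,
                1, 1), nrow = 2, byrow = TRUE)
  g <- genotype_matrix(d, sites = c("A", "A"))
  dm <- individual_distance(g)
  expect_equal(dm[1, 2], 2)                 # |0-2| + |1-1| over 2 loci
  gsame <- genotype_matrix(cbind(c(1, 2), c(1, 2)), sites = c("A", "A"))
  expect_equal(individual_distance(gsame)[1, 2], 0)
  # missing data: rescaled to the panel size from typed loci
  dmiss <- matrix(c(0, 1, 2, NA), 2)   # ind1 = (0,1), ind2 = (2,NA)
  gm <- genotype_matrix(dmiss, sites = c("A", "A"))
  expect_equal(individual_distance(gm)[1, 2], 2 * 2)  # mean |0-2| x 2 loci
  gnone <- genotype_matrix(matrix(c(1, NA, NA, 1), 2), sites = c("A", "A"))
  expect_error(individual_distance(gnone), "no typed loci")
})

test_that("neighbour joining recovers additive four-taxon trees exactly", {
  # additive distances from a known unrooted topology ((A,B),(C,D)) with
  # branch lengths A:2 B:3 C:4 D:5 and internal 6
  dm <- distance_matrix(
    matrix(c(0, 5, 12, 13,
             5, 0, 13, 14,
             12, 13, 0, 9,
             13, 14, 9, 0), 4, byrow = TRUE), c("A", "B", "C", "D"))
  tr <- nj_tree(dm, bootstraps = 0)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(dm),
                                                    rownames(dm)],
               unclass(dm), tolerance = 1e-9, ignore_attr = TRUE)

  # on an ultrametric matrix NJ agrees with the UPGMA topology
  pd <- points_dm(6, seed = 8)
  up <- upgma(pd$dm)
  um <- distance_matrix(ape::cophenetic.phylo(up)[rownames(pd$dm),
                                                  rownames(pd$dm)],
                        rownames(pd$dm), tol = 1e-6)
  nj_t <- nj_tree(um, bootstraps = 0)
  expect_equal(ape::dist.topo(ape::unroot(up), ape::unroot(nj_t)), 0,
               ignore_attr = TRUE)
})

test_that("locus bootstrap assigns high support to well-separated groups", {
  cfg <- tiny_cfg(seed = 21, n_per_site = 5, sites = c("A", "B"),
                  n_loci = 150, fst_target = 0.6)
  g <- gen_genotypes(cfg)$genotypes
  tr <- nj_tree(g, bootstraps = 50, seed = 2)
  expect_s3_class(tr, "phylo")
  expect_true(any(tr$node.label >= 0.9))
})
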