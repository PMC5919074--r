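test_that("standardized PCA handles rank-1 data, known correlations, and permutations", {
  set.seed(1)
  base <- rnorm(30)
  # rank-1: all columns proportional -> PC1 carries all the variance
  m1 <- outer(base, runif(10, 0.5, 2))
  colnames(m1) <- paste0("v", 1:10)
  p1 <- immune_pca(m1)
  expect_equal(p1$variance_explained[1], 1, tolerance = 1e-12)

  # two variables with sample correlation exactly 0.5: eigenvalues of the
  # 2x2 correlation matrix are 1 +/- rho
  x <- as.numeric(scale(rnorm(40)))
  z <- as.numeric(scale(residuals(lm(rnorm(40) ~ x))))
  y <- 0.5 * x + sqrt(1 - 0.25) * z
  p2 <- immune_pca(cbind(a = x, b = y), n_pc = 2)
  expect_equal(p2$variance_explained, c(0.75, 0.25), tolerance = 1e-9)

  # row-permutation equivariance
  set.seed(2)
  m <- matrix(rnorm(200), 20)
  colnames(m) <- paste0("v", 1:10)
  rownames(m) <- paste0("m", 1:20)
  pa <- immune_pca(m)
  perm <- sample(20)
  pb <- immune_pca(m[perm, ])
  expect_equal(pb$scores, pa$scores[perm, ], tolerance = 1e-9)

  expect_error(immune_pca(m[1:3, ]), "fewer than 4")
  m[, 3] <- 1
  expect_error(immune_pca(m), "constant")
})

test_that("complete-case exclusion is applied and reported", {
  set.seed(3)
  m <- matrix(rnorm(100), 10)
  colnames(m) <- paste0("v", 1:10)
  m[c(2, 7), 4] <- NA
  p <- immune_pca(m)
  expect_equal(p$n_excluded, 2)
  expect_equal(nrow(p$scores), 8)
})

test_that("immunological distance is the 3-PC Euclidean metric", {
  sc <- rbind(a = c(0, 0, 0), b = c(3, 4, 0), c = c(0, 0, 0))
  dm <- immune_distance(sc)
  expect_equal(dm["a", "b"], 5)
  expect_equal(dm["a", "c"], 0)
  # triangle inequality on random score sets
  set.seed(4)
  for (i in 1:5) {
    d <- immune_distance(matrix(rnorm(30), 10))
    n <- nrow(d)
    for (k in 1:n) {
      expect_true(all(d <= outer(d[, k], d[k, ], `+`) + 1e-12))
    }
  }
})

test_that("site summaries decompose all pairs into within and among", {
  set.seed(5)
  sc <- matrix(rnorm(60), 20)
  rownames(sc) <- paste0("m", 1:20)
  dm <- immune_distance(sc)
  sites <- setNames(rep(c("BM", "HW", "PF", "ST"), each = 5),
                    rownames(dm))
  s <- site_distance_summary(dm, sites)
  n <- 20
  expect_equal(sum(s$overall$n_pairs), n * (n - 1) / 2)
  expect_equal(s$per_site$n_pairs,
               rep(choose(5, 2), 4))
  # overall within mean is the pair-weighted mean of per-site means
  expect_equal(s$overall$mean[1],
               weighted.mean(s$per_site$within_mean, s$per_site$n_pairs))
  # two mice: within mean is their distance, SE undefined
  dm2 <- dm[1:2, 1:2]
  s2 <- site_distance_summary(dm2, setNames(c("A", "A"), rownames(dm2)))
  expect_equal(s2$per_site$within_mean, dm2[1, 2])
  expect_true(is.na(s2$per_site$within_se))
})

test_that("within-site distance vs sample size correlation behaves at the edges", {
  ps <- data.frame(site = letters[1:5], n_mice = c(3, 5, 8, 13, 21),
                   within_mean = c(3, 5, 8, 13, 21))
  out <- within_distance_vs_n(ps)
  expect_equal(out$r, 1)
  ps$within_mean <- rep(2, 5)
  out2 <- within_distance_vs_n(ps)
  expect_true(out2$degenerate)
  expect_error(within_distance_vs_n(ps[1:2, ]), "at least 3 sites")
})

test_that("classical MDS reproduces Euclidean-realizable configurations", {
  pd <- points_dm(8, d = 2, seed = 6)
  emb <- classical_mds(pd$dm, k = 2)
  expect_equal(as.matrix(dist(emb)), unclass(pd$dm), tolerance = 1e-9,
               ignore_attr = TRUE)
  # unit equilateral triangle
  tri <- distance_matrix(matrix(1, 3, 3) - diag(3), c("a", "b", "c"))
  emb3 <- classical_mds(tri, k = 2)
  expect_equal(as.numeric(dist(emb3)), rep(1, 3), tolerance = 1e-9)
  # two points at distance d
  two <- distance_matrix(matrix(c(0, 4.2, 4.2, 0), 2), c("a", "b"))
  expect_equal(as.numeric(dist(classical_mds(two, k = 1))), 4.2,
               tolerance = 1e-9)
  expect_error(classical_mds(two, k = 2), "positive eigenvalues")
})

test_that("infection descriptives count positives with score >= 1", {
  df <- data.frame(noro = c(0, 1, 4), minute = c(0, 0, 2),
                   parvo = c(0, 0, 0), sendai = c(0, 2, 0),
                   corona = c(0, 0, 0), mhv = c(0, 0, 0),
                   m_pulmonis = c(0, 0, 1), worm_count = c(0, 5, 2))
  out <- infection_descriptives(df)
  expect_equal(out$burden, c(0, 2, 3))
  expect_equal(out$seroprevalence, 2 / 3)
  expect_equal(unname(out$prevalence["noro"]), 2 / 3)
  expect_equal(out$syphacia_prevalence, 2 / 3)
  zero <- df
  zero[1:7] <- 0
  out0 <- infection_descriptives(zero)
  expect_equal(out0$burden, c(0, 0, 0))
  expect_equal(out0$seroprevalence, 0)
  expect_equal(sum(out0$prevalence), 0)
})

test_that("PCA recovers the generator's loading structure on a large cohort", {
  cfg <- tiny_cfg(seed = 12, n_per_site = 1700, sites = c("A", "B", "C"),
                  site_sd = 0)
  co <- gen_cohort(cfg)$cohort
  p <- immune_pca(co[c("mouse_id", names(cfg$loadings))])
  # reference: eigenvectors of the implied correlation matrix
  S <- generator_implied_cov(cfg)[names(cfg$loadings),
                                  names(cfg$loadings)]
  ev <- eigen(cov2cor(S))
  for (k in 1:3) {
    cosine <- abs(sum(p$loadings[, k] * ev$vectors[, k])) /
      sqrt(sum(p$loadings[, k]^2) * sum(ev$vectors[, k]^2))
    expect_gt(cosine, 0.95)
  }
  # the three components separate cells, serum antibodies, and IgA
  expect_gt(min(abs(p$loadings[1:7, 1])), 0.2)
  expect_gt(max(abs(p$loadings[c("igg", "ige"), 2])), 0.4)
  expect_gt(abs(p$loadings["iga", 3]), 0.5)
})
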