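test_that("sma_slope matches its closed form", {
  expect_equal(sma_slope(1:3, 1:3), 1)
  expect_equal(sma_slope(1:3, -(1:3)), -1)
  set.seed(1)
  x <- rnorm(50)
  y <- 2 * x + rnorm(50, 0, 0.1)        # sd(y) ~ 2 sd(x), r > 0
  expect_equal(sma_slope(x, y), sd(y) / sd(x))
  expect_error(sma_slope(rep(1, 5), 1:5), "zero variance")
  expect_error(sma_slope(1:2, 1:2), "at least 3")
})

test_that("SMI recovers exact power-law allometry and degenerates correctly", {
  # noiseless mass = 2 * length^3: SMA exponent is exactly 3 and every
  # mouse has the same standardized mass
  df <- data.frame(mouse_id = as.character(1:3),
                   body_length = c(80, 100, 120))
  df$body_mass <- 2 * df$body_length^3
  out <- compute_smi(df, group = rep("all", 3))
  fit <- attr(out, "allometric_fit")
  expect_equal(fit$b_sma, 3, tolerance = 1e-12)
  expect_equal(fit$L0, 100)
  expect_equal(out$smi, rep(2 * 100^3, 3), tolerance = 1e-9)

  # all lengths equal: smi = mass requires no allometry at all, but the
  # SMA fit needs length variance, so check through the formula at b = 1
  df2 <- data.frame(body_length = c(90, 100, 110),
                    body_mass = c(18, 20, 22))
  b <- sma_slope(log(df2$body_length), log(df2$body_mass))
  L0 <- mean(df2$body_length)
  manual <- df2$body_mass * (L0 / df2$body_length)^b
  out2 <- compute_smi(df2, group = rep("all", 3))
  expect_equal(out2$smi, manual, tolerance = 1e-12)

  # missing mass gives missing smi without aborting
  df3 <- rbind(df2, data.frame(body_length = 95, body_mass = NA))
  out3 <- compute_smi(df3, group = rep("all", 4))
  expect_true(is.na(out3$smi[4]))
  expect_error(compute_smi(df3[4, , drop = FALSE], group = "q"),
               "fewer than 3")
})

test_that("SMI is permutation-equivariant and correlates with mass and BMI", {
  cfg <- tiny_cfg(seed = 5, n_per_site = 40)
  co <- gen_cohort(cfg)$cohort
  out <- compute_smi(co)
  perm <- sample(nrow(co))
  out_p <- compute_smi(co[perm, ])
  expect_equal(out_p$smi, out$smi[perm], tolerance = 1e-12)
  bmi <- compute_bmi(co$body_mass, co$body_length)
  expect_gt(cor(out$smi, bmi, use = "complete.obs"), 0)
  expect_gt(cor(out$smi, co$body_mass, use = "complete.obs"), 0)
})

test_that("BMI arithmetic and scale invariance", {
  expect_equal(compute_bmi(20, 100), 2)
  expect_equal(compute_bmi(40, 100), 4)
  set.seed(2)
  m <- runif(20, 10, 30); l <- runif(20, 60, 100); k <- runif(20, 0.5, 2)
  expect_equal(compute_bmi(k * m, sqrt(k) * l), compute_bmi(m, l),
               tolerance = 1e-12)
  expect_error(compute_bmi(20, 0), "non-positive length")
})

test_that("cell-count scaling mirrors the SMI algebra", {
  df <- data.frame(body_length = c(80, 100, 120))
  df$cd4 <- 5 * df$body_length^1.7          # noiseless power law
  out <- scale_cell_counts(df, cell_cols = "cd4")
  expect_equal(attr(out, "scaling_fit")$b_sma, 1.7, tolerance = 1e-12)
  expect_equal(diff(range(out$cd4)), 0, tolerance = 1e-9)

  # supplied exponent 0 leaves counts unchanged
  df$cd4 <- c(100, 200, 300)
  out0 <- scale_cell_counts(df, cell_cols = "cd4", b = c(cd4 = 0))
  expect_equal(out0$cd4, df$cd4)

  # a mouse at the reference length keeps its raw count
  df2 <- data.frame(body_length = c(90, 100, 110),
                    cd4 = c(120, 150, 170))
  out2 <- scale_cell_counts(df2, cell_cols = "cd4")
  expect_equal(out2$cd4[2], 150, tolerance = 1e-12)

  # zero counts are scaled but excluded from the fit
  df3 <- data.frame(body_length = c(80, 90, 100, 110),
                    cd4 = c(0, 90, 100, 110))
  out3 <- scale_cell_counts(df3, cell_cols = "cd4")
  expect_equal(out3$cd4[1], 0)
  expect_equal(attr(out3, "scaling_fit")$n, 3)
  expect_error(scale_cell_counts(data.frame(body_length = 1:3 * 10,
                                            cd4 = c(0, 0, 0)),
                                 cell_cols = "cd4"), "all-zero")
})

test_that("power-of-ten rescaling picks the exponent from the median and is idempotent", {
  out <- pow10_rescale(c(230, 450, 780))
  expect_equal(as.numeric(out), c(2.3, 4.5, 7.8))
  expect_equal(attr(out, "k"), 2L)
  expect_equal(as.numeric(pow10_rescale(c(2, 5, 8))), c(2, 5, 8))
  set.seed(3)
  for (i in 1:10) {
    v <- runif(20, 0, 10^sample(-3:6, 1))
    once <- as.numeric(pow10_rescale(v))
    expect_equal(as.numeric(pow10_rescale(once)), once, tolerance = 1e-12)
    expect_true(median(once[once > 0]) >= 1 && median(once[once > 0]) < 10)
  }
  z <- pow10_rescale(c(0, 0))
  expect_equal(as.numeric(z), c(0, 0))
  expect_equal(attr(z, "k"), 0L)
})

test_that("lens-mass ageing is monotone and inverts its forward calibration", {
  cal <- lens_calibration()
  ages_wk <- c(3, 7.4, 12, 30, 80)
  lens <- lens_forward(ages_wk * 7, cal)
  expect_true(all(diff(lens) > 0))
  back <- lens_age(lens, cal)
  expect_equal(as.numeric(back), ages_wk, tolerance = 1e-9)
  # strictly increasing in lens mass
  expect_true(all(diff(as.numeric(lens_age(seq(0.5, 8, 0.5), cal))) > 0))
  # extrapolation below calibration support is flagged
  young <- lens_age(lens_forward(5, cal), cal)
  expect_true(attr(young, "extrapolated"))
  expect_error(lens_age(-1), "positive")
  # identity-in-logs calibration: lens mass 1 mg maps to e days
  cal01 <- lens_calibration(alpha = 0, beta = 1, min_age_days = 0.1)
  expect_equal(as.numeric(lens_age(1, cal01)) * 7, exp(1), tolerance = 1e-12)
})
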