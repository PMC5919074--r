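test_that("the model language reproduces the published model dimensions", {
  m <- default_models()
  expect_equal(m$adaptive$df, 8)
  expect_equal(m$adaptive$n_free, 20)
  expect_equal(m$innate$df, 14)
  expect_equal(m$innate$n_free, 22)
  expect_equal(m$humoral$df, 8)
  expect_error(sem_model("y ~ x\nx ~ y"), "cycle")
  expect_error(sem_model("F =~ a + b\nG =~ b + c"), "exactly one latent")
})

test_that("implied covariance follows path-tracing algebra", {
  spec <- sem_model("y ~ x")
  # free parameters in table order: path x->y, var x, var y
  expect_equal(implied_covariance(spec, c(0, 1, 1)), diag(2),
               ignore_attr = TRUE)
  beta <- 0.7
  S <- implied_covariance(spec, c(beta, 1, 1))
  expect_equal(S["x", "y"], beta)
  expect_equal(S["y", "y"], beta^2 + 1)
})

test_that("implied covariance at the generator's true parameters matches its closed form", {
  cfg <- tiny_cfg(seed = 1, site_sd = 0, shared_cell_sd = 0)
  mo <- ecoimmune:::.gen_moments(cfg)
  tru <- sem_truth_adaptive(cfg)
  spec <- default_models()$adaptive
  pt <- spec$param_table
  theta <- numeric(spec$n_free)
  free <- which(pt$free)
  s1 <- cfg$indicator_scale[["cd4"]] * cfg$loadings[["cd4"]]
  g <- cfg$gamma_cellular
  b <- cfg$beta_condition
  resid_ind <- function(k) cfg$indicator_scale[[k]]^2 *
    cfg$indicator_resid_sd[[k]]^2
  for (i in seq_along(free)) {
    r <- free[i]
    key <- paste0(pt$from[r], "->", pt$to[r])
    theta[i] <- if (pt$type[r] == "path") {
      tru$path[[key]]
    } else if (pt$type[r] == "loading") {
      tru$loading[[pt$to[r]]]
    } else if (pt$type[r] == "cov") {
      0
    } else {
      v <- pt$from[r]
      slope_sum <- cfg$infection_age_slope * length(cfg$infection_base)
      switch(v,
        day_length = mo$var_dl,
        age = mo$var_age,
        burden = mo$var_b - slope_sum^2 * mo$var_age,
        smi = cfg$smi_sd^2 * cfg$condition_resid_sd^2,
        ImmuneState = s1^2 * cfg$zeta_sd^2,
        resid_ind(v))
    }
  }
  S_sem <- implied_covariance(spec, theta)
  S_gen <- generator_implied_cov(cfg)[spec$observed, spec$observed]
  expect_lt(max(abs(S_sem - S_gen)), 1e-12 * max(abs(S_gen)))
})

test_that("a just-identified factor model reproduces the target covariance exactly", {
  skip_if_not_installed("MASS")
  lam <- c(0.7, 0.8, 0.9)
  Sigma <- tcrossprod(lam) + diag(1 - lam^2)   # unit-variance indicators
  colnames(Sigma) <- rownames(Sigma) <- c("x1", "x2", "x3")
  set.seed(20)
  X <- MASS::mvrnorm(200, rep(0, 3), Sigma, empirical = TRUE)
  colnames(X) <- colnames(Sigma)
  spec <- sem_model("F =~ x1 + x2 + x3")
  fit <- fit_ml(spec, as.data.frame(X), rescale = FALSE, seed = 4)
  expect_equal(fit$df, 0)
  expect_lt(fit$chi2, 1e-6)
  expect_equal(fit$rmsea, 0)
  expect_equal(fit$cfi, 1)
  expect_lt(fit$srmr, 1e-4)
  et <- fit$estimates
  std_load <- et$std[et$type == "loading"]
  expect_equal(sort(std_load), sort(lam), tolerance = 1e-6)
})

test_that("fit-index arithmetic is exact and the RMSEA CI inverts the noncentral chi-square", {
  S <- diag(3); Sigma <- diag(3)
  idx <- fit_indices(20, 10, 110, 15, 101, S, Sigma)
  expect_equal(idx$rmsea, 0.1)
  expect_equal(idx$cfi, 1 - 10 / 95)
  # independent bisection on the noncentral chi-square CDF
  bisect_ncp <- function(chi2, df, target) {
    if (pchisq(chi2, df, ncp = 0) < target) return(0)
    lo <- 0; hi <- 1
    while (pchisq(chi2, df, ncp = hi) > target) hi <- hi * 2
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (pchisq(chi2, df, ncp = mid) > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (case in list(c(20, 10, 101), c(35, 8, 150), c(9, 8, 60))) {
    chi2 <- case[1]; df <- case[2]; n <- case[3]
    ci <- fit_indices(chi2, df, 10 * chi2, df + 5, n, S, Sigma)$rmsea_ci
    lo <- sqrt(bisect_ncp(chi2, df, 0.95) / (df * (n - 1)))
    hi <- sqrt(bisect_ncp(chi2, df, 0.05) / (df * (n - 1)))
    expect_equal(ci, c(lo, hi), tolerance = 1e-6)
  }
  # SRMR on a known residual
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  Sg2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  idx2 <- fit_indices(1, 0, 2, 1, 50, S2, Sg2)
  expect_equal(idx2$srmr, sqrt(0.1^2 / 3))
})

test_that("chi-square is scale-equivariant and standardized estimates are rescale-invariant", {
  cfg <- tiny_cfg(seed = 23, n_per_site = 150, site_sd = 0)
  co <- gen_cohort(cfg)
  frame <- data.frame(day_length = co$truth$day_length,
                      age = co$truth$true_age,
                      smi = co$truth$condition_smi,
                      burden = co$truth$burden,
                      co$cohort[c("cd4", "cd8", "cd19")])
  spec <- default_models()$adaptive
  f1 <- fit_ml(spec, frame, rescale = FALSE, seed = 5, n_starts = 3)
  frame2 <- frame
  frame2$cd4 <- frame2$cd4 / 1e6
  frame2$age <- frame2$age * 10
  f2 <- fit_ml(spec, frame2, rescale = FALSE, seed = 5, n_starts = 3)
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-4)
  expect_equal(f2$estimates$std, f1$estimates$std, tolerance = 1e-4)
  # pow10 rescaling likewise leaves the standardized solution alone
  f3 <- fit_ml(spec, frame, rescale = TRUE, seed = 5, n_starts = 3)
  expect_equal(f3$estimates$std, f1$estimates$std, tolerance = 1e-4)
})

test_that("the fit-acceptance rules are applied as published", {
  mk <- function(rmsea, lo, cfi, srmr, p) {
    structure(list(rmsea = rmsea, rmsea_ci = c(lo, rmsea + 0.08),
                   cfi = cfi, srmr = srmr, chi2_p = p,
                   warnings = character(0)), class = "sem_fit")
  }
  # RMSEA above 0.05 rescued by a zero lower confidence limit
  r1 <- acceptance_report(mk(0.058, 0, 0.987, 0.031, 0.22))
  expect_true(r1$verdict %in% c("good", "acceptable"))
  expect_true(any(grepl("lower 90% CI = 0.000", r1$reasons)))
  # significant chi-square flagged
  r2 <- acceptance_report(mk(0.137, 0.089, 0.891, 0.082, 0.0002))
  expect_equal(r2$verdict, "not_good_fit")
  expect_true(any(grepl("significant lack of fit", r2$reasons)))
  # ideal indices
  r3 <- acceptance_report(mk(0.0, 0, 1.0, 0.01, 0.7))
  expect_equal(r3$verdict, "good")
})

test_that("fitting agrees with the independent reduced-form oracle", {
  cfg <- tiny_cfg(seed = 29, n_per_site = 250, site_sd = 0,
                  shared_cell_sd = 0)
  co <- gen_cohort(cfg)
  frame <- data.frame(day_length = co$truth$day_length,
                      age = co$truth$true_age,
                      burden = co$truth$burden,
                      smi = co$truth$condition_smi,
                      co$cohort[c("cd4", "cd8", "cd19")])
  frame_s <- as.data.frame(scale(frame))     # common scale for both routes
  spec <- default_models()$adaptive
  fit <- fit_ml(spec, frame_s, rescale = FALSE, seed = 6)
  orc <- oracle_fit_default(frame_s[c("day_length", "age", "burden", "smi",
                                      "cd4", "cd8", "cd19")], k = 3)
  expect_equal(fit$f_ml, orc$f_ml, tolerance = 1e-3)
  nm <- c("day_length", "age", "burden", "smi", "cd4", "cd8", "cd19")
  expect_lt(max(abs(fit$sigma[nm, nm] - orc$Sigma)), 1e-3)
})
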