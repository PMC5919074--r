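# Independent reference fitter for the default immune-state model
# structure, used only as a cross-check oracle. Deliberately written as a
# separate code path from the package engine: the implied covariance is
# built by reduced-form substitution (never RAM matrix inversion), the
# parameter vector is ordered differently, and optim() is used instead of
# nlminb().
#
# Variables, in order: season s, age a, infection i, condition c,
# indicators x_1..x_k measuring a latent L (first loading fixed to 1).
# Parameters: var_s, var_a, cov_sa, i~s, i~a, var_ei, c~s, c~a, c~i,
# var_ec, L~s, L~a, L~c, L~i, var_eL, loadings 2..k, residuals 1..k.

oracle_implied <- function(th, k) {
  var_s <- th[1]; var_a <- th[2]; cov_sa <- th[3]
  b_is <- th[4]; b_ia <- th[5]; v_ei <- th[6]
  b_cs <- th[7]; b_ca <- th[8]; b_ci <- th[9]; v_ec <- th[10]
  g_s <- th[11]; g_a <- th[12]; g_c <- th[13]; g_i <- th[14]; v_eL <- th[15]
  lam <- c(1, th[16:(14 + k)])
  v_ex <- th[(15 + k):(14 + 2 * k)]
  # shocks: s0, a0, ei, ec, eL, e1..ek; rows = s, a, i, c, L, x1..xk
  n_sh <- 5 + k
  M <- matrix(0, 5 + k, n_sh)
  M[1, 1] <- 1                                   # s
  M[2, 2] <- 1                                   # a
  M[3, ] <- b_is * M[1, ] + b_ia * M[2, ]        # i
  M[3, 3] <- 1
  M[4, ] <- b_cs * M[1, ] + b_ca * M[2, ] + b_ci * M[3, ]
  M[4, 4] <- 1                                   # c
  L_row <- g_s * M[1, ] + g_a * M[2, ] + g_c * M[4, ] + g_i * M[3, ]
  L_row[5] <- 1                                  # L
  M[5, ] <- L_row
  for (j in seq_len(k)) {
    M[5 + j, ] <- lam[j] * L_row
    M[5 + j, 5 + j] <- 1
  }
  Psi <- diag(c(var_s, var_a, v_ei, v_ec, v_eL, v_ex))
  Psi[1, 2] <- Psi[2, 1] <- cov_sa
  V <- M %*% Psi %*% t(M)
  V[-5, -5, drop = FALSE]                        # drop the latent row
}

oracle_fml <- function(th, S, k, log_det_S) {
  Sigma <- oracle_implied(th, k)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) return(1e9)
  sol <- solve(Sigma, S)
  v <- sum(log(ev)) + sum(diag(sol)) - log_det_S - nrow(S)
  if (!is.finite(v)) 1e9 else v
}

# data columns must be ordered: season, age, infection, condition,
# indicators.
oracle_fit_default <- function(data, k, n_restarts = 8, seed = 99) {
  X <- as.matrix(data)
  S <- cov(X)
  log_det_S <- determinant(S, logarithm = TRUE)$modulus[1]
  v <- diag(S)
  start <- c(v[1], v[2], 0.2 * S[1, 2], 0.1, 0.1, 0.7 * v[3],
             0.1, 0.1, 0.1, 0.7 * v[4], 0.1, 0.1, 0.1, 0.1, 0.5 * v[5],
             rep(1, k - 1), 0.5 * v[5:(4 + k)])
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts + 1)) {
    th0 <- if (r == 1) start else start * runif(length(start), 0.6, 1.5)
    f <- tryCatch(optim(th0, oracle_fml, S = S, k = k,
                        log_det_S = log_det_S, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  n <- nrow(X)
  list(f_ml = best$value, chi2 = (n - 1) * best$value,
       theta = best$par, Sigma = oracle_implied(best$par, k), S = S, n = n)
}

# Independent fit-index arithmetic for cross-checks.
oracle_indices <- function(chi2, df, chi2_b, df_b, n, S, Sigma) {
  rmsea <- if (df == 0) 0 else sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  denom <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi2 - df, 0) / denom
  sres <- (S - Sigma) / sqrt(outer(diag(S), diag(S)))
  srmr <- sqrt(mean(sres[lower.tri(sres, diag = TRUE)]^2))
  list(rmsea = rmsea, cfi = cfi, srmr = srmr)
}

# True natural-scale parameters of the default adaptive model implied by a
# generator configuration (independent path algebra; see the generator's
# moment helpers). Returns values keyed the way fit_ml() tables them.
sem_truth_adaptive <- function(cfg) {
  mo <- ecoimmune:::.gen_moments(cfg)
  sd_age <- sqrt(mo$var_age); sd_dl <- sqrt(mo$var_dl)
  sd_b <- sqrt(mo$var_b)
  slope_sum <- cfg$infection_age_slope * length(cfg$infection_base)
  b <- cfg$beta_condition
  g <- cfg$gamma_cellular
  s1 <- cfg$indicator_scale[["cd4"]] * cfg$loadings[["cd4"]]
  list(
    path = c(
      "day_length->burden" = 0,
      "age->burden" = slope_sum,
      "day_length->smi" = cfg$smi_sd * b[["season"]] / sd_dl,
      "age->smi" = cfg$smi_sd * b[["age"]] / sd_age,
      "burden->smi" = cfg$smi_sd * b[["infection"]] / sd_b,
      "day_length->ImmuneState" = s1 * g[["season"]] / sd_dl,
      "age->ImmuneState" = s1 * g[["age"]] / sd_age,
      "smi->ImmuneState" = s1 * g[["condition"]] / cfg$smi_sd,
      "burden->ImmuneState" = s1 * g[["infection"]] / sd_b),
    loading = c(
      "cd8" = cfg$indicator_scale[["cd8"]] * cfg$loadings[["cd8"]] / s1,
      "cd19" = cfg$indicator_scale[["cd19"]] * cfg$loadings[["cd19"]] / s1))
}
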