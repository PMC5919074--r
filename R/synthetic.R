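# Derived per-stream seeds: one RNG stream per generator call, split
# per site, so adding a site never perturbs earlier sites' draws.
.stream_seed <- function(seed, idx) {
  s <- (as.numeric(seed) * 1000003 + idx * 7919) %% 2147483629
  as.integer(s + 1)
}

# Gamma age distribution matched to a target median and 75th percentile
# (weeks); shape found by root-finding on the quantile ratio.
.age_gamma <- function(median_wk = 7.4, q75_wk = 12) {
  ratio <- q75_wk / median_wk
  f <- function(shape) qgamma(0.75, shape) / qgamma(0.5, shape) - ratio
  shape <- uniroot(f, c(0.05, 50))$root
  scale <- median_wk / qgamma(0.5, shape)
  c(shape = shape, scale = scale)
}

#' Synthetic-cohort configuration
#'
#' All generator parameters, with defaults set to the study conditions the
#' analyses assume: 12 sites of unequal size (the deposited per-site
#' genotyping counts), a male:female odds of 1.18, a right-skewed
#' (gamma) age distribution with median 7.4 and upper quartile 12 weeks,
#' seven serological infections whose probability rises with age (overall
#' seroprevalence around 95\%), ten immune measures structured as three
#' latent compartments (adaptive cellular, innate cellular, humoral)
#' driven by condition, age, season and infection with site-level
#' intercepts, a power-law mass-length allometry, and Balding-Nichols
#' genotypes with very high among-site differentiation (F = 0.48).
#'
#' @param seed master seed; every stream is derived from it.
#' @param site_sizes named integer vector of mice per site.
#' @param sex_odds male:female odds.
#' @param age_median_wk,age_q75_wk age distribution anchors (weeks).
#' @param day_length_range annual day-length range in minutes.
#' @param infection_base named baseline prevalences of the 7 microbes at
#'   the mean age.
#' @param infection_age_slope per-week increase in each microbe's
#'   probability.
#' @param worm_prevalence,mite_prevalence macroparasite presence rates.
#' @param n_loci,fst_target,panmixia genotype panel size, Balding-Nichols
#'   differentiation parameter F in (0,1), and the F->0 panmixia flag.
#' @param allometry_b,length_mean,length_sd mass-length power-law exponent
#'   and body-length distribution (mm).
#' @param cell_allometry_b power-law exponent linking splenic cell counts
#'   to body length (bigger mice carry more splenocytes); the allometric
#'   count scaling removes exactly this dependence.
#' @param smi_mean,smi_sd scaled-mass-index location/scale (g).
#' @param beta_condition paths into Condition (on standardized scales):
#'   `age`, `season`, `infection`.
#' @param condition_resid_sd structural residual SD of Condition (z-scale).
#' @param gamma_cellular,gamma_humoral paths into the cellular / humoral
#'   immune-state latents: `condition`, `age`, `season`, `infection`.
#' @param zeta_sd latent residual SD; `shared_cell_sd` SD of the residual
#'   component shared by the two cellular latents (drives the cell
#'   measures' common principal component); `site_sd` SD of per-site
#'   latent intercepts.
#' @param loadings,indicator_resid_sd,indicator_mean,indicator_scale
#'   per-measure loading, residual SD (z-scale), location and scale for
#'   the 10 immune measures.
#' @param lens_noise_sd,mass_noise_sd measurement noise SDs (mg on the
#'   lens-mass scale; lognormal SD on mass).
#' @param geo_extent_km side of the square region over which site
#'   coordinates are drawn.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1,
    site_sizes = c(HW = 167, PH = 63, JB = 36, BM = 33, GL = 30, SK = 30,
                   WF = 18, LU = 18, ST = 15, PF = 10, WT = 7, SP = 6),
    sex_odds = 1.18,
    age_median_wk = 7.4, age_q75_wk = 12,
    day_length_range = c(470, 1000),
    infection_base = c(noro = 0.60, minute = 0.45, parvo = 0.40,
                       sendai = 0.30, corona = 0.25, mhv = 0.20,
                       m_pulmonis = 0.15),
    infection_age_slope = 0.0074,
    worm_prevalence = 0.79, mite_prevalence = 0.67,
    n_loci = 1168, fst_target = 0.48, panmixia = FALSE,
    allometry_b = 2.7, cell_allometry_b = 1.7,
    length_mean = 82, length_sd = 6,
    smi_mean = 18, smi_sd = 2.5,
    beta_condition = c(age = 0.35, season = 0.10, infection = 0.10),
    condition_resid_sd = 0.9,
    gamma_cellular = c(condition = 0.5, age = -0.3, season = -0.15,
                       infection = 0.1),
    gamma_humoral = c(condition = 0, age = 0.4, season = -0.1,
                      infection = 0.25),
    zeta_sd = 0.35, shared_cell_sd = 1.0, site_sd = 0.7,
    loadings = c(cd4 = 1, cd8 = 0.9, cd19 = 0.85, nk = 0.8,
                 neutrophil = 0.85, dc = 0.75, macrophage = 0.7,
                 igg = 0.9, ige = 0.85, iga = 0.45),
    indicator_resid_sd = c(cd4 = 0.5, cd8 = 0.5, cd19 = 0.5, nk = 0.5,
                           neutrophil = 0.5, dc = 0.5, macrophage = 0.5,
                           igg = 0.5, ige = 0.5, iga = 0.9),
    indicator_mean = c(cd4 = 5e6, cd8 = 3e6, cd19 = 8e6, nk = 1e6,
                       neutrophil = 2e6, dc = 5e5, macrophage = 8e5,
                       igg = 800, ige = 4000, iga = 50),
    indicator_scale = NULL,
    lens_noise_sd = 0.03, mass_noise_sd = 0,
    geo_extent_km = 40) {
  if (is.null(indicator_scale)) indicator_scale <- indicator_mean * 0.25
  cfg <- list(seed = seed, site_sizes = site_sizes, sex_odds = sex_odds,
              age_median_wk = age_median_wk, age_q75_wk = age_q75_wk,
              age_gamma = .age_gamma(age_median_wk, age_q75_wk),
              day_length_range = day_length_range,
              infection_base = infection_base,
              infection_age_slope = infection_age_slope,
              worm_prevalence = worm_prevalence,
              mite_prevalence = mite_prevalence,
              n_loci = n_loci, fst_target = fst_target, panmixia = panmixia,
              allometry_b = allometry_b,
              cell_allometry_b = cell_allometry_b,
              length_mean = length_mean,
              length_sd = length_sd, smi_mean = smi_mean, smi_sd = smi_sd,
              beta_condition = beta_condition,
              condition_resid_sd = condition_resid_sd,
              gamma_cellular = gamma_cellular,
              gamma_humoral = gamma_humoral,
              zeta_sd = zeta_sd, shared_cell_sd = shared_cell_sd,
              site_sd = site_sd, loadings = loadings,
              indicator_resid_sd = indicator_resid_sd,
              indicator_mean = indicator_mean,
              indicator_scale = indicator_scale,
              lens_noise_sd = lens_noise_sd, mass_noise_sd = mass_noise_sd,
              geo_extent_km = geo_extent_km)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' @rdname synthetic_config
#' @param cfg configuration to validate.
#' @export
validate_synthetic_config <- function(cfg) {
  if (!cfg$panmixia && (cfg$fst_target <= 0 || cfg$fst_target >= 1)) {
    stop("degenerate config: fst_target must lie strictly in (0,1); use ",
         "panmixia = TRUE for the F -> 0 limit", call. = FALSE)
  }
  if (any(cfg$site_sizes < 2)) stop("site_sizes must all be >= 2",
                                    call. = FALSE)
  if (any(cfg$infection_base <= 0 | cfg$infection_base >= 1)) {
    stop("infection baseline prevalences must lie in (0,1)", call. = FALSE)
  }
  sds <- c(cfg$condition_resid_sd, cfg$zeta_sd, cfg$shared_cell_sd,
           cfg$site_sd, cfg$indicator_resid_sd, cfg$lens_noise_sd,
           cfg$mass_noise_sd)
  if (any(sds < 0)) stop("residual SDs must be non-negative", call. = FALSE)
  if (any(!is.finite(cfg$loadings))) stop("loadings must be finite",
                                          call. = FALSE)
  invisible(cfg)
}

.compartment_of <- c(cd4 = "adaptive", cd8 = "adaptive", cd19 = "adaptive",
                     nk = "innate", neutrophil = "innate", dc = "innate",
                     macrophage = "innate", igg = "humoral", ige = "humoral",
                     iga = "humoral")

# Theoretical moments of age, burden and their coupling (p linear in age).
.gen_moments <- function(cfg) {
  g <- cfg$age_gamma
  mu_age <- g["shape"] * g["scale"]
  var_age <- g["shape"] * g["scale"]^2
  dl <- cfg$day_length_range
  mu_dl <- mean(dl); var_dl <- diff(dl)^2 / 12
  base <- cfg$infection_base
  slope <- rep(cfg$infection_age_slope, length(base))
  mu_b <- sum(base)
  var_b <- sum(base * (1 - base)) +
    (sum(slope)^2 - sum(slope^2)) * var_age
  cov_ab <- sum(slope) * var_age
  list(mu_age = unname(mu_age), var_age = unname(var_age),
       mu_dl = mu_dl, var_dl = var_dl,
       mu_b = unname(mu_b), var_b = unname(var_b),
       cov_age_burden = unname(cov_ab))
}

#' Generate Balding-Nichols genotypes
#'
#' Per site and locus the allele frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around a global frequency p, and
#' genotypes are Hardy-Weinberg binomial draws within site; `F` is the
#' target differentiation recovered (in expectation) by the
#' Weir-Cockerham estimator. With `panmixia = TRUE` all sites share the
#' global frequencies (the F -> 0 limit).
#'
#' @param cfg a [synthetic_config()].
#' @return List with `genotypes` (a [genotype_matrix()]), `site_freqs`
#'   (loci x sites true frequencies) and `p_bar` (global frequencies).
#' @export
gen_genotypes <- function(cfg) {
  validate_synthetic_config(cfg)
  set.seed(.stream_seed(cfg$seed, 0))
  p_bar <- runif(cfg$n_loci, 0.1, 0.9)
  F <- cfg$fst_target
  sites <- names(cfg$site_sizes)
  freqs <- matrix(NA_real_, cfg$n_loci, length(sites),
                  dimnames = list(NULL, sites))
  dosage <- NULL
  ids <- character(0)
  lab <- character(0)
  for (i in seq_along(sites)) {
    set.seed(.stream_seed(cfg$seed, i))
    p_s <- if (cfg$panmixia) p_bar else
      rbeta(cfg$n_loci, p_bar * (1 - F) / F, (1 - p_bar) * (1 - F) / F)
    freqs[, i] <- p_s
    n_i <- cfg$site_sizes[[i]]
    d <- matrix(rbinom(cfg$n_loci * n_i, 2, rep(p_s, n_i)),
                nrow = cfg$n_loci)
    dosage <- cbind(dosage, d)
    ids <- c(ids, sprintf("%s_%03d", sites[i], seq_len(n_i)))
    lab <- c(lab, rep(sites[i], n_i))
  }
  colnames(dosage) <- ids
  g <- genotype_matrix(dosage,
                       locus_ids = sprintf("L%04d", seq_len(cfg$n_loci)),
                       chromosome = as.character(
                         rep_len(1:19, cfg$n_loci)),
                       position = seq_len(cfg$n_loci) * 1000L,
                       sites = lab)
  list(genotypes = g, site_freqs = freqs, p_bar = p_bar)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws, per mouse: capture day length (uniform over the annual range),
#' age (gamma), sex, seven age-dependent Bernoulli infections, a
#' Condition variable (the scaled mass index on the gram scale) driven by
#' age, season and infection, three latent immune-state compartments
#' driven by condition, age, season and infection with per-site
#' intercepts, ten immune indicators loading on their compartment, body
#' length and a power-law body mass constructed so the scaled mass index
#' recovers Condition, and a lens mass from the age calibration. True
#' latent values are returned for recovery tests.
#'
#' @param cfg a [synthetic_config()].
#' @return List with `cohort` (canonical-schema data frame) and `truth`
#'   (data frame of true age, structural condition, latent compartment
#'   values, burden and z-scale drivers).
#' @export
gen_cohort <- function(cfg) {
  validate_synthetic_config(cfg)
  mo <- .gen_moments(cfg)
  sites <- names(cfg$site_sizes)
  comps <- c("adaptive", "innate", "humoral")
  rows <- list(); truths <- list()
  for (i in seq_along(sites)) {
    set.seed(.stream_seed(cfg$seed, 1000 + i))
    n <- cfg$site_sizes[[i]]
    site <- sites[i]
    site_eff <- setNames(rnorm(3, 0, cfg$site_sd), comps)
    sex <- ifelse(runif(n) < cfg$sex_odds / (1 + cfg$sex_odds),
                  "male", "female")
    dl <- runif(n, cfg$day_length_range[1], cfg$day_length_range[2])
    age <- rgamma(n, shape = cfg$age_gamma["shape"],
                  scale = cfg$age_gamma["scale"])
    season_z <- (dl - mo$mu_dl) / sqrt(mo$var_dl)
    age_z <- (age - mo$mu_age) / sqrt(mo$var_age)
    pmat <- outer(age - mo$mu_age, rep(cfg$infection_age_slope,
                                       length(cfg$infection_base))) +
      matrix(cfg$infection_base, n, length(cfg$infection_base),
             byrow = TRUE)
    pmat <- pmin(pmax(pmat, 0.01), 0.99)
    inf_pos <- matrix(runif(length(pmat)) < pmat, n)
    colnames(inf_pos) <- names(cfg$infection_base)
    # ordinal severity 1-4 assigned uniformly to positives; only
    # presence/absence feeds downstream models
    scores <- inf_pos * matrix(sample(1:4, length(inf_pos), TRUE),
                               nrow = n)
    burden <- rowSums(inf_pos)
    inf_z <- (burden - mo$mu_b) / sqrt(mo$var_b)
    b <- cfg$beta_condition
    cond_z <- b[["age"]] * age_z + b[["season"]] * season_z +
      b[["infection"]] * inf_z + rnorm(n, 0, cfg$condition_resid_sd)
    smi <- cfg$smi_mean + cfg$smi_sd * cond_z
    smi <- pmax(smi, 0.2 * cfg$smi_mean)
    u_cell <- rnorm(n, 0, cfg$shared_cell_sd)
    lat <- sapply(comps, function(cm) {
      gpar <- if (cm == "humoral") cfg$gamma_humoral else cfg$gamma_cellular
      gpar[["condition"]] * cond_z + gpar[["age"]] * age_z +
        gpar[["season"]] * season_z + gpar[["infection"]] * inf_z +
        (if (cm == "humoral") 0 else u_cell) +
        rnorm(n, 0, cfg$zeta_sd) + site_eff[[cm]]
    })
    len <- pmax(rnorm(n, cfg$length_mean, cfg$length_sd),
                0.6 * cfg$length_mean)
    cell_types <- names(.compartment_of)[.compartment_of != "humoral"]
    meas <- sapply(names(cfg$loadings), function(k) {
      z <- cfg$loadings[[k]] * lat[, .compartment_of[[k]]] +
        rnorm(n, 0, cfg$indicator_resid_sd[[k]])
      m <- pmax(cfg$indicator_mean[[k]] + cfg$indicator_scale[[k]] * z,
                0.001 * cfg$indicator_mean[[k]])
      # splenic counts scale with body size; antibody concentrations do not
      if (k %in% cell_types) {
        m <- m * (len / cfg$length_mean)^cfg$cell_allometry_b
      }
      m
    })
    mass <- smi * (len / cfg$length_mean)^cfg$allometry_b *
      exp(rnorm(n, 0, cfg$mass_noise_sd))
    lens <- lens_forward(pmax(age, 1) * 7) + rnorm(n, 0, cfg$lens_noise_sd)
    lens <- pmax(lens, 0.05)
    age_rec <- as.numeric(lens_age(lens))
    worm_pos <- runif(n) < cfg$worm_prevalence
    worms <- ifelse(worm_pos, stats::rnbinom(n, size = 0.6, mu = 25) + 1, 0)
    mite_pos <- runif(n) < cfg$mite_prevalence
    mites <- ifelse(mite_pos, sample(1:8, n, TRUE), 0)
    ids <- sprintf("%s_%03d", site, seq_len(n))
    df <- data.frame(mouse_id = ids, site = site, sex = sex,
                     day_length = dl, body_mass = mass, body_length = len,
                     abdominal_fat = pmax(0.02 * mass +
                                            rnorm(n, 0, 0.1), 0.01),
                     lens_mass = lens, age = round(age_rec, 1),
                     leptin = pmax(2 + 0.3 * cond_z + rnorm(n, 0, 1), 0.1),
                     haemoglobin = pmax(rnorm(n, 140, 12), 60))
    df <- cbind(df, as.data.frame(scores),
                data.frame(mite_count_class = mites, worm_count = worms),
                as.data.frame(meas))
    rows[[site]] <- df
    truths[[site]] <- data.frame(mouse_id = ids, site = site,
                                 true_age = age, day_length = dl,
                                 burden = burden, condition_smi = smi,
                                 age_z = age_z, season_z = season_z,
                                 inf_z = inf_z, cond_z = cond_z,
                                 adaptive = lat[, "adaptive"],
                                 innate = lat[, "innate"],
                                 humoral = lat[, "humoral"])
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  list(cohort = cohort, truth = truth)
}

#' Synthetic site geography
#'
#' Site coordinates drawn uniformly over a square region; returns the
#' inter-site Euclidean distance matrix in km.
#'
#' @param cfg a [synthetic_config()].
#' @return Site-labelled [distance_matrix()] (km).
#' @export
gen_geography <- function(cfg) {
  set.seed(.stream_seed(cfg$seed, 999999))
  sites <- sort(names(cfg$site_sizes))
  xy <- matrix(runif(2 * length(sites), 0, cfg$geo_extent_km), ncol = 2)
  rownames(xy) <- sites
  distance_matrix(as.matrix(dist(xy)), sites)
}

#' Closed-form covariance implied by the generating model
#'
#' The generator is linear in its exogenous drivers (age, season,
#' infection burden), so the covariance of the observed variables
#' (day length, true age, burden, the scaled mass index and the ten
#' immune measures) follows in closed form from the path coefficients,
#' loadings and residual variances. Site intercepts contribute their
#' variance to the latent compartments. The cell-count rows refer to
#' length-standardized counts: the matrix is exact when
#' `cell_allometry_b = 0`, since body-size scaling of raw counts is a
#' multiplicative length factor outside this linear system. Used to check
#' the generator
#' against its own algebra and to seed exact-covariance tests of the SEM
#' engine.
#'
#' @param cfg a [synthetic_config()].
#' @return Named 14 x 14 covariance matrix.
#' @export
generator_implied_cov <- function(cfg) {
  mo <- .gen_moments(cfg)
  b <- cfg$beta_condition
  sd_age <- sqrt(mo$var_age); sd_dl <- sqrt(mo$var_dl)
  sd_b <- sqrt(mo$var_b)
  rho_ia <- mo$cov_age_burden / (sd_age * sd_b)
  # covariance of the z-scale drivers (age_z, season_z, inf_z)
  Sz <- matrix(c(1, 0, rho_ia,
                 0, 1, 0,
                 rho_ia, 0, 1), 3, 3,
               dimnames = list(c("age", "season", "infection"),
                               c("age", "season", "infection")))
  bv <- c(b[["age"]], b[["season"]], b[["infection"]])
  var_c <- drop(t(bv) %*% Sz %*% bv) + cfg$condition_resid_sd^2
  cov_c_z <- drop(Sz %*% bv)                      # cov(cond_z, drivers)
  # latent compartments: coefficients on (cond_z, age_z, season_z, inf_z)
  lat_coef <- function(cm) {
    g <- if (cm == "humoral") cfg$gamma_humoral else cfg$gamma_cellular
    c(g[["condition"]], g[["age"]], g[["season"]], g[["infection"]])
  }
  # full covariance over (cond_z, age_z, season_z, inf_z)
  S4 <- rbind(c(var_c, cov_c_z), cbind(cov_c_z, Sz))
  comps <- c("adaptive", "innate", "humoral")
  Lcov <- matrix(0, 3, 3, dimnames = list(comps, comps))
  cov_L_z <- matrix(0, 3, 4)                       # vs (cond,age,seas,inf)
  for (i in 1:3) {
    ci <- lat_coef(comps[i])
    cov_L_z[i, ] <- drop(S4 %*% ci)
    for (j in 1:3) {
      cj <- lat_coef(comps[j])
      v <- drop(t(ci) %*% S4 %*% cj)
      if (i != j && comps[i] != "humoral" && comps[j] != "humoral") {
        v <- v + cfg$shared_cell_sd^2
      }
      if (i == j) {
        v <- v + cfg$zeta_sd^2 + cfg$site_sd^2 +
          (if (comps[i] != "humoral") cfg$shared_cell_sd^2 else 0)
      }
      Lcov[i, j] <- v
    }
  }
  vars <- c("day_length", "age", "burden", "smi", names(cfg$loadings))
  p <- length(vars)
  S <- matrix(0, p, p, dimnames = list(vars, vars))
  # natural-scale blocks for the structural variables
  S["day_length", "day_length"] <- mo$var_dl
  S["age", "age"] <- mo$var_age
  S["burden", "burden"] <- mo$var_b
  S["age", "burden"] <- S["burden", "age"] <- mo$cov_age_burden
  S["smi", "smi"] <- cfg$smi_sd^2 * var_c
  S["smi", "age"] <- S["age", "smi"] <- cfg$smi_sd * cov_c_z[1] * sd_age
  S["smi", "day_length"] <- S["day_length", "smi"] <-
    cfg$smi_sd * cov_c_z[2] * sd_dl
  S["smi", "burden"] <- S["burden", "smi"] <-
    cfg$smi_sd * cov_c_z[3] * sd_b
  for (k in names(cfg$loadings)) {
    cm <- .compartment_of[[k]]
    ci <- match(cm, comps)
    lam <- cfg$loadings[[k]]; sc <- cfg$indicator_scale[[k]]
    # vs structural observables: cov(L, cond_z/age_z/...) scaled out
    cov_L <- cov_L_z[ci, ]                         # (cond, age, seas, inf)
    S[k, "smi"] <- S["smi", k] <- sc * lam * cov_L[1] * cfg$smi_sd
    S[k, "age"] <- S["age", k] <- sc * lam * cov_L[2] * sd_age
    S[k, "day_length"] <- S["day_length", k] <- sc * lam * cov_L[3] * sd_dl
    S[k, "burden"] <- S["burden", k] <- sc * lam * cov_L[4] * sd_b
    for (l in names(cfg$loadings)) {
      cj <- match(.compartment_of[[l]], comps)
      v <- sc * cfg$indicator_scale[[l]] * lam * cfg$loadings[[l]] *
        Lcov[ci, cj]
      if (k == l) v <- v + sc^2 * cfg$indicator_resid_sd[[k]]^2
      S[k, l] <- v
    }
  }
  S
}
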