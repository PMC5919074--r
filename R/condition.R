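#' Standardized major axis slope
#'
#' Symmetric (SMA) regression slope used for allometric scaling:
#' `sign(r(x, y)) * sd(y) / sd(x)`.
#'
#' @param x,y numeric vectors of equal length (pairs with missing values are
#'   dropped); at least 3 complete pairs and non-zero variance in both.
#' @return The SMA slope (scalar).
#' @export
sma_slope <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("sma_slope needs at least 3 complete pairs",
                          call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("sma_slope: zero variance", call. = FALSE)
  r <- cor(x, y)
  s <- if (r < 0) -1 else 1
  s * sd(y) / sd(x)
}

#' Scaled mass index (SMI)
#'
#' Standardizes each animal's body mass to the population mean body length
#' L0 via the allometric exponent b fitted by standardized major axis
#' regression of ln(mass) on ln(length):
#' `smi_i = mass_i * (L0 / length_i)^b`. Fitting groups default to sex
#' (the allometry "population under study"); mice missing mass or length
#' get a missing SMI but do not abort the fit.
#'
#' @param df cohort data frame with `body_mass` (g) and `body_length` (mm).
#' @param group optional grouping factor/column name (default `"sex"` when
#'   present, otherwise a single group).
#' @return `df` with an `smi` column added, plus attribute
#'   `"allometric_fit"`: one row per group with `b_sma`, `L0`, `r_ols`
#'   (correlation of log mass and log length) and `n`.
#' @export
compute_smi <- function(df, group = NULL) {
  if (is.null(group)) {
    grp <- if ("sex" %in% names(df)) df$sex else rep("all", nrow(df))
  } else if (is.character(group) && length(group) == 1 &&
             group %in% names(df)) {
    grp <- df[[group]]
  } else {
    grp <- group
  }
  grp <- as.character(grp)
  grp[is.na(grp)] <- "(unknown)"
  smi <- rep(NA_real_, nrow(df))
  fits <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    ok <- idx[!is.na(df$body_mass[idx]) & !is.na(df$body_length[idx]) &
              df$body_mass[idx] > 0 & df$body_length[idx] > 0]
    if (length(ok) < 3) {
      stop("group '", g, "' has fewer than 3 mice with complete ",
           "mass/length", call. = FALSE)
    }
    lx <- log(df$body_length[ok]); ly <- log(df$body_mass[ok])
    b <- sma_slope(lx, ly)
    L0 <- mean(df$body_length[ok])
    smi[ok] <- df$body_mass[ok] * (L0 / df$body_length[ok])^b
    fits[[g]] <- data.frame(group = g, b_sma = b, L0 = L0,
                            r_ols = cor(lx, ly), n = length(ok))
  }
  df$smi <- smi
  attr(df, "allometric_fit") <- do.call(rbind, fits)
  df
}

#' Body mass index
#'
#' `body mass in kg / (body length in m)^2`, with inputs in the cohort's
#' field units (g, mm).
#'
#' @param mass_g body mass in grams (positive).
#' @param length_mm body length in millimetres (positive).
#' @return BMI in kg/m^2; missing where either input is missing.
#' @export
compute_bmi <- function(mass_g, length_mm) {
  bad <- !is.na(length_mm) & length_mm <= 0
  if (any(bad)) stop("compute_bmi: non-positive length", call. = FALSE)
  bad <- !is.na(mass_g) & mass_g <= 0
  if (any(bad)) stop("compute_bmi: non-positive mass", call. = FALSE)
  (mass_g / 1000) / (length_mm / 1000)^2
}

#' Allometric scaling of immune cell counts
#'
#' Each splenic cell count is standardized to the mean body length exactly
#' as the scaled mass index standardizes body mass, with its own SMA
#' exponent per cell type: `scaled_i = count_i * (L0 / length_i)^(b_c)`.
#' Zero counts cannot enter the log-log SMA fit, but are still scaled using
#' the fitted exponent so the mouse stays in downstream analyses.
#'
#' @param df cohort data frame containing `body_length` and the count
#'   columns.
#' @param cell_cols character vector of count columns to scale (defaults to
#'   the seven cell-count measures).
#' @param b optional named numeric vector of exponents to use instead of
#'   fitting (e.g. `c(cd4 = 0)` leaves counts unscaled).
#' @return `df` with scaled columns replacing the originals, plus attribute
#'   `"scaling_fit"` (per cell type: `b_sma`, `L0`, `n`).
#' @export
scale_cell_counts <- function(df, cell_cols = c("cd4", "cd8", "cd19", "nk",
                                                "neutrophil", "dc",
                                                "macrophage"),
                              b = NULL) {
  fits <- list()
  for (cc in cell_cols) {
    cnt <- df[[cc]]
    len <- df$body_length
    ok <- !is.na(cnt) & !is.na(len) & len > 0
    if (!any(ok & cnt > 0)) stop("all-zero or missing counts for ", cc,
                                 call. = FALSE)
    fit_idx <- ok & cnt > 0
    L0 <- mean(len[ok])
    b_c <- if (!is.null(b) && cc %in% names(b)) {
      unname(b[cc])
    } else {
      sma_slope(log(len[fit_idx]), log(cnt[fit_idx]))
    }
    scaled <- rep(NA_real_, nrow(df))
    scaled[ok] <- cnt[ok] * (L0 / len[ok])^b_c
    df[[cc]] <- scaled
    fits[[cc]] <- data.frame(cell_type = cc, b_sma = b_c, L0 = L0,
                             n = sum(fit_idx))
  }
  attr(df, "scaling_fit") <- do.call(rbind, fits)
  df
}

#' Rescale a variable by a power of ten
#'
#' Divides by `10^k` with integer `k` chosen so the median of the non-zero
#' values falls in [1, 10); idempotent, and an all-zero vector is returned
#' unchanged with `k = 0`.
#'
#' @param values non-negative numeric vector (missing values passed
#'   through).
#' @return Rescaled vector with attribute `"k"` (the exponent used).
#' @export
pow10_rescale <- function(values) {
  nz <- values[!is.na(values) & values > 0]
  if (length(nz) == 0) {
    attr(values, "k") <- 0L
    return(values)
  }
  k <- as.integer(floor(log10(median(nz))))
  out <- values / 10^k
  attr(out, "k") <- k
  out
}

#' Eye-lens-mass age calibration
#'
#' Dried eye-lens mass grows monotonically with age; the default calibration
#' is log-linear, `lens_mg = alpha + beta * ln(age_days)`, inverted to give
#' age. The shipped coefficients are provisional placeholders chosen to span
#' a plausible house-mouse lens-growth range and should be replaced with a
#' species-specific calibration when one is available.
#'
#' @param alpha,beta calibration intercept/slope (mg vs ln days); `beta > 0`.
#' @param min_age_days lower edge of calibration support; lens masses
#'   implying younger ages are flagged as extrapolation.
#' @return A calibration object for [lens_age()].
#' @export
lens_calibration <- function(alpha = -2.0, beta = 1.8, min_age_days = 14) {
  stopifnot(beta > 0, min_age_days > 0)
  structure(list(alpha = alpha, beta = beta, min_age_days = min_age_days),
            class = "lens_calibration")
}

#' @rdname lens_calibration
#' @param age_days age in days.
#' @return `lens_forward()`: predicted lens mass in mg.
#' @export
lens_forward <- function(age_days, calibration = lens_calibration()) {
  calibration$alpha + calibration$beta * log(age_days)
}

#' Age from eye-lens mass
#'
#' @param lens_mg dried lens mass in mg (positive).
#' @param calibration a [lens_calibration()].
#' @return Age in weeks (strictly increasing in lens mass), with attribute
#'   `"extrapolated"`: logical flag per mouse for lens masses below the
#'   calibration support.
#' @export
lens_age <- function(lens_mg, calibration = lens_calibration()) {
  if (any(!is.na(lens_mg) & lens_mg <= 0)) {
    stop("lens mass must be positive", call. = FALSE)
  }
  age_days <- exp((lens_mg - calibration$alpha) / calibration$beta)
  out <- age_days / 7
  attr(out, "extrapolated") <- !is.na(age_days) &
    age_days < calibration$min_age_days
  out
}
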