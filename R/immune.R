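#' Principal component analysis of the ten immune measures
#'
#' Standardized (correlation-matrix) PCA of the ten immune measures (seven
#' scaled splenic cell counts, serum IgG and IgE, faecal IgA). Mice missing
#' any measure are excluded (complete-case analysis) and the exclusion count
#' is reported. The first three components are retained. A deterministic
#' sign convention is applied: within each component the largest-magnitude
#' loading is made positive.
#'
#' @param measures numeric matrix or data frame, mice x measures (rownames
#'   or `mouse_id` column used as mouse ids).
#' @param n_pc number of components to retain (default 3).
#' @return List of class `immune_pca` with `scores` (complete-case mice x
#'   `n_pc`), `variance_explained` (fractions), `loadings`, `mouse_id`,
#'   `n_excluded`.
#' @export
immune_pca <- function(measures, n_pc = 3) {
  if (is.data.frame(measures)) {
    ids <- if ("mouse_id" %in% names(measures)) {
      as.character(measures$mouse_id)
    } else rownames(measures)
    measures <- as.matrix(measures[setdiff(names(measures), "mouse_id")])
    rownames(measures) <- ids
  }
  if (is.null(rownames(measures))) {
    rownames(measures) <- paste0("m", seq_len(nrow(measures)))
  }
  keep <- complete.cases(measures)
  n_excluded <- sum(!keep)
  x <- measures[keep, , drop = FALSE]
  if (nrow(x) < 4) stop("fewer than 4 mice with complete immune measures",
                        call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("constant immune measure: ", colnames(x)[which(sds == 0)[1]],
         call. = FALSE)
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  n_pc <- min(n_pc, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(n_pc), drop = FALSE]
  sc <- pc$x[, seq_len(n_pc), drop = FALSE]
  for (k in seq_len(n_pc)) {            # sign convention
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) {
      rot[, k] <- -rot[, k]
      sc[, k] <- -sc[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = sc,
                 variance_explained = ve[seq_len(n_pc)],
                 loadings = rot,
                 mouse_id = rownames(x),
                 n_excluded = n_excluded),
            class = "immune_pca")
}

#' Immunological distance among mice
#'
#' Euclidean pairwise distance among mice in the space of the first three
#' immune principal components. Supplying an externally computed score table
#' (e.g. the deposited per-mouse PC scores) bypasses the PCA and is the
#' reproduction path for published distances.
#'
#' @param pcs an [immune_pca()] result, or a matrix/data frame whose columns
#'   `pc1..pc3` (or first three numeric columns) are scores, with mouse ids
#'   as rownames or a `mouse_id` column.
#' @return A labelled [distance_matrix()] over mice.
#' @export
immune_distance <- function(pcs) {
  if (inherits(pcs, "immune_pca")) {
    m <- pcs$scores
    rownames(m) <- pcs$mouse_id
  } else if (is.data.frame(pcs)) {
    ids <- if ("mouse_id" %in% names(pcs)) as.character(pcs$mouse_id) else
      rownames(pcs)
    cols <- intersect(c("pc1", "pc2", "pc3"), names(pcs))
    if (length(cols) == 0) cols <- names(pcs)[vapply(pcs, is.numeric,
                                                     logical(1))][1:3]
    m <- as.matrix(pcs[cols])
    rownames(m) <- ids
  } else {
    m <- as.matrix(pcs)
  }
  if (any(!is.finite(m))) stop("non-finite principal-component scores",
                               call. = FALSE)
  d <- as.matrix(dist(m, method = "euclidean"))
  distance_matrix(d, rownames(m))
}

#' Within- and among-site immunological distance summaries
#'
#' For each site: the mean and standard error of all pairwise distances
#' among its mice (within) and of all pairs spanning that site and any
#' other (among). The SE is sd/sqrt(n_pairs) over pairwise distances,
#' ignoring their non-independence (a presentation convention, reported as
#' such). Sites with a single pair have a missing SE; sites with fewer than
#' 2 mice are dropped with a warning.
#'
#' @param dm mouse-level distance matrix.
#' @param sites named character vector (names = mouse ids) or vector
#'   aligned with `rownames(dm)`.
#' @return List with `per_site` data frame (`site`, `n_mice`, `n_pairs`,
#'   `within_mean`, `within_se`, `among_mean`, `among_se`) and `overall`
#'   (within/among grand means +/- SE over all pairs).
#' @export
site_distance_summary <- function(dm, sites) {
  if (!is.null(names(sites))) sites <- sites[rownames(dm)]
  sites <- as.character(sites)
  stopifnot(length(sites) == nrow(dm))
  n <- nrow(dm)
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  d <- dm[cbind(pair_i, pair_j)]
  same <- sites[pair_i] == sites[pair_j]
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  tab <- table(sites)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning("site(s) with < 2 mice excluded from within-site summaries: ",
            paste(small, collapse = ", "))
  }
  per_site <- do.call(rbind, lapply(sort(names(tab)), function(s) {
    win <- d[same & sites[pair_i] == s]
    amg <- d[!same & (sites[pair_i] == s | sites[pair_j] == s)]
    data.frame(site = s, n_mice = as.integer(tab[[s]]),
               n_pairs = length(win),
               within_mean = if (length(win)) mean(win) else NA_real_,
               within_se = se(win),
               among_mean = if (length(amg)) mean(amg) else NA_real_,
               among_se = se(amg))
  }))
  per_site <- per_site[!(per_site$site %in% small) |
                         !is.na(per_site$among_mean), ]
  overall <- data.frame(
    scope = c("within", "among"),
    mean = c(mean(d[same]), mean(d[!same])),
    se = c(se(d[same]), se(d[!same])),
    n_pairs = c(sum(same), sum(!same)))
  list(per_site = per_site, overall = overall)
}

#' Correlation of within-site distance with site sample size
#'
#' Tests whether immunologically diverse sites are simply the well-sampled
#' ones: Pearson r between per-site within-site mean distance and the
#' number of mice at the site, with a label-permutation p-value.
#'
#' @param summaries result of [site_distance_summary()] (or its `per_site`
#'   component).
#' @param n_perm permutations for the two-sided permutation p.
#' @param seed RNG seed.
#' @return List with `r`, `p`, `n_sites`; `r` is `NA` with a
#'   `degenerate = TRUE` flag when either vector is constant.
#' @export
within_distance_vs_n <- function(summaries, n_perm = 9999, seed = 1) {
  ps <- if (is.data.frame(summaries)) summaries else summaries$per_site
  ps <- ps[!is.na(ps$within_mean), ]
  if (nrow(ps) < 3) stop("need at least 3 sites", call. = FALSE)
  x <- ps$within_mean; y <- ps$n_mice
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n_sites = nrow(ps),
                degenerate = TRUE))
  }
  r <- cor(x, y)
  set.seed(seed)
  rstar <- replicate(n_perm, cor(x, sample(y)))
  p <- (1 + sum(abs(rstar) >= abs(r) - 1e-12)) / (n_perm + 1)
  list(r = r, p = p, n_sites = nrow(ps), degenerate = FALSE)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a distance matrix in `k` dimensions by double-centering the
#' squared distances and scaling the top eigenvectors by the square roots
#' of their eigenvalues. Negative eigenvalues (non-Euclidean input) are
#' truncated with a warning.
#'
#' @param dm symmetric distance matrix.
#' @param k embedding dimension.
#' @return Matrix of coordinates (entities x k) with attribute
#'   `"eigenvalues"`.
#' @export
classical_mds <- function(dm, k = 2) {
  dm <- distance_matrix(dm)
  fit <- cmdscale(as.dist(dm), k = min(k, nrow(dm) - 1), eig = TRUE)
  eig <- fit$eig
  n_pos <- sum(eig > max(eig) * 1e-12)
  if (k > n_pos) {
    stop("k = ", k, " exceeds the number of positive eigenvalues (", n_pos,
         ")", call. = FALSE)
  }
  if (any(eig < -max(eig) * 1e-8)) {
    warning("distance matrix is not Euclidean-realizable; negative ",
            "eigenvalues truncated")
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(dm)
  attr(coords, "eigenvalues") <- eig
  coords
}

#' Cohort infection descriptives
#'
#' Per-mouse microparasite burden (count of the seven serological scores
#' that are positive, i.e. >= 1), per-infection prevalence, overall
#' seroprevalence (fraction of mice positive for at least one microbe), and
#' the burden-age correlation per sex when age is available.
#'
#' @param df cohort data frame with the seven infection-score columns and
#'   optionally `worm_count`, `mite_count_class`, `age`, `sex`.
#' @return List with `burden` (per mouse), `prevalence` (per infection),
#'   `seroprevalence`, `syphacia_prevalence` / `mite_prevalence` (when
#'   present), and `burden_age_cor` (per sex: r, p, n).
#' @export
infection_descriptives <- function(df) {
  scores <- as.matrix(df[intersect(.infection_cols, names(df))])
  if (ncol(scores) == 0) stop("no infection-score columns present",
                              call. = FALSE)
  pos <- scores >= 1
  tested <- rowSums(!is.na(scores)) > 0
  burden <- ifelse(tested, rowSums(pos, na.rm = TRUE), NA_real_)
  prevalence <- colSums(pos, na.rm = TRUE) / colSums(!is.na(scores))
  sero <- mean(burden[tested] >= 1)
  out <- list(burden = burden, prevalence = prevalence,
              seroprevalence = sero, n_tested = sum(tested))
  if ("worm_count" %in% names(df)) {
    w <- df$worm_count
    out$syphacia_prevalence <- mean(w[!is.na(w)] > 0)
  }
  if ("mite_count_class" %in% names(df)) {
    m <- df$mite_count_class
    out$mite_prevalence <- mean(m[!is.na(m)] > 0)
  }
  if (all(c("age", "sex") %in% names(df))) {
    out$burden_age_cor <- do.call(rbind, lapply(
      c("male", "female"), function(s) {
        idx <- which(df$sex == s & !is.na(df$age) & !is.na(burden))
        if (length(idx) < 3) return(NULL)
        ct <- stats::cor.test(df$age[idx], burden[idx])
        data.frame(sex = s, r = unname(ct$estimate), p = ct$p.value,
                   n = length(idx))
      }))
  }
  out
}
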