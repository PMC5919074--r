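# Per-locus allele frequencies and heterozygosities for one group of
# individuals (columns of the dosage matrix).
.locus_stats_one <- function(dosage) {
  n <- rowSums(!is.na(dosage))
  alt <- rowSums(dosage, na.rm = TRUE)
  p <- ifelse(n > 0, alt / (2 * n), NA_real_)
  ho <- ifelse(n > 0, rowSums(dosage == 1, na.rm = TRUE) / n, NA_real_)
  he <- ifelse(n > 1, 2 * p * (1 - p) * (2 * n) / (2 * n - 1), NA_real_)
  data.frame(n = n, p = p, ho = ho, he = he)
}

#' Per-locus summary statistics
#'
#' Alt-allele frequency, observed heterozygosity and unbiased expected
#' heterozygosity (`2pq * 2n/(2n-1)`) per locus, optionally per site, with
#' missing calls excluded locus-wise. Monomorphic loci are flagged
#' (`monomorphic = TRUE`; the Hardy-Weinberg test is undefined there).
#' Because strong between-site structure inflates apparent Hardy-Weinberg
#' departures when sites are pooled (Wahlund effect), the per-site variant
#' is the default for equilibrium testing.
#'
#' @param g a [genotype_matrix()].
#' @param per_site split by site label (default `FALSE`: all individuals as
#'   one group).
#' @param hwe also run the Markov-chain Hardy-Weinberg exact test per
#'   (polymorphic) locus.
#' @param chain_length,seed passed to [hwe_exact_mc()] when `hwe = TRUE`.
#' @return Data frame with columns `locus_id`, (`site`), `n`, `p`, `ho`,
#'   `he`, `monomorphic`, and `hwe_p` when requested.
#' @export
locus_stats <- function(g, per_site = FALSE, hwe = FALSE,
                        chain_length = 1e6, seed = 1) {
  groups <- if (per_site) {
    sp <- split(seq_along(g$sites), g$sites)
    sp
  } else {
    list(all = seq_len(ncol(g$dosage)))
  }
  out <- do.call(rbind, lapply(names(groups), function(nm) {
    idx <- groups[[nm]]
    if (length(idx) < 2) stop("group '", nm, "' has fewer than 2 ",
                              "individuals", call. = FALSE)
    st <- .locus_stats_one(g$dosage[, idx, drop = FALSE])
    st <- cbind(data.frame(locus_id = g$locus_ids, site = nm), st)
    st$monomorphic <- is.na(st$p) | st$p == 0 | st$p == 1
    if (hwe) {
      st$hwe_p <- NA_real_
      for (l in which(!st$monomorphic)) {
        d <- g$dosage[l, idx]
        cnt <- c(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                 sum(d == 2, na.rm = TRUE))
        st$hwe_p[l] <- hwe_exact_mc(cnt, chain_length = chain_length,
                                    seed = seed + l)$p
      }
    }
    st
  }))
  if (!per_site) out$site <- NULL
  rownames(out) <- NULL
  out
}

#' Markov-chain Hardy-Weinberg exact test
#'
#' Monte-Carlo estimate of the conditional exact p-value for a biallelic
#' locus (probability, given the allele counts, of a genotype table as or
#' less probable than the observed one), using a Metropolis chain over
#' heterozygote counts. Alongside the plain exact p-value the mid-p and a
#' randomized p-value are returned; the randomized version is exactly
#' uniform under equilibrium and is the one used in calibration checks,
#' while the plain exact p (discrete, conservative) is the inferential
#' default.
#'
#' @param counts genotype counts `c(n_refref, n_het, n_altalt)` (order of
#'   the two homozygote classes is immaterial).
#' @param chain_length Markov-chain iterations (default 1e6).
#' @param seed RNG seed (chain and randomized-p draw).
#' @return List with `p` (exact), `p_mid`, `p_randomized`, `se` (batch-means
#'   Monte-Carlo standard error of `p`), `chain_length`.
#' @export
hwe_exact_mc <- function(counts, chain_length = 1e6, seed = 1) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  nA <- 2 * counts[3] + counts[2]
  n <- sum(counts)
  if (nA == 0 || nA == 2 * n) {
    stop("monomorphic locus: Hardy-Weinberg test undefined", call. = FALSE)
  }
  set.seed(seed)
  res <- .hwe_chain_cpp(counts[1], counts[2], counts[3], chain_length)
  p <- res$n_leq / res$steps
  p_lt <- res$n_lt / res$steps
  se <- sd(res$batch_means) / sqrt(length(res$batch_means))
  list(p = p,
       p_mid = (p + p_lt) / 2,
       p_randomized = p_lt + runif(1) * (p - p_lt),
       se = se,
       chain_length = res$steps)
}

# Weir-Cockerham (1984) per-locus variance components a (among sites),
# b (among individuals within sites), c (within individuals) for two
# groups of columns; vectors over loci.
.wc_components <- function(d1, d2) {
  s1 <- .locus_stats_one(d1)
  s2 <- .locus_stats_one(d2)
  n1 <- s1$n; n2 <- s2$n
  ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * s1$p + n2 * s2$p) / (n1 + n2)
  s2v <- (n1 * (s1$p - pbar)^2 + n2 * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * s1$ho + n2 * s2$ho) / (n1 + n2)
  a <- (nbar / nc) *
    (s2v - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2v * (r - 1) / r -
                                 hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar * (2 * nbar - 1) /
       (4 * nbar))
  c_ <- hbar / 2
  # loci monomorphic across the pair carry zero components
  mono <- pbar %in% c(0, 1)
  a[mono] <- 0; b[mono] <- 0; c_[mono] <- 0
  a[!ok] <- NA; b[!ok] <- NA; c_[!ok] <- NA
  data.frame(a = a, b = b, c = c_)
}

#' Pairwise Weir-Cockerham F_ST
#'
#' Weir-Cockerham (1984) theta between two sites, combining loci by ratio
#' of sums of the variance components. Negative estimates are reported as
#' computed.
#'
#' @param g a [genotype_matrix()] with site labels.
#' @param site_a,site_b site codes.
#' @return List of class `fst_result`: `site_a`, `site_b`, `theta`,
#'   `components` (per-locus a, b, c), `n_loci_used`.
#' @export
pairwise_fst <- function(g, site_a, site_b) {
  for (s in c(site_a, site_b)) {
    if (sum(g$sites == s, na.rm = TRUE) < 2) {
      stop("site '", s, "' absent or has < 2 individuals", call. = FALSE)
    }
  }
  d1 <- g$dosage[, which(g$sites == site_a), drop = FALSE]
  d2 <- g$dosage[, which(g$sites == site_b), drop = FALSE]
  comp <- .wc_components(d1, d2)
  ok <- complete.cases(comp)
  theta <- sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  structure(list(site_a = site_a, site_b = site_b, theta = theta,
                 components = comp, n_loci_used = sum(ok)),
            class = "fst_result")
}

#' All pairwise F_ST values and their average
#'
#' @param g a [genotype_matrix()].
#' @return `fst_matrix()`: symmetric site x site matrix of pairwise theta.
#'   `average_fst()`: unweighted mean over all site pairs.
#' @export
fst_matrix <- function(g) {
  sites <- sort(unique(g$sites[!is.na(g$sites)]))
  m <- matrix(0, length(sites), length(sites),
              dimnames = list(sites, sites))
  for (i in seq_along(sites)) {
    for (j in seq_len(i - 1)) {
      th <- pairwise_fst(g, sites[i], sites[j])$theta
      m[i, j] <- m[j, i] <- th
    }
  }
  m
}

#' @rdname fst_matrix
#' @export
average_fst <- function(g) {
  m <- fst_matrix(g)
  mean(m[lower.tri(m)])
}

#' Within-site inbreeding coefficient F_IS
#'
#' Per site, `f = 1 - sum(Ho) / sum(He)` over polymorphic loci (ratio of
#' sums; He is the unbiased expected heterozygosity), plus the unweighted
#' average over sites.
#'
#' @param g a [genotype_matrix()].
#' @return List with `per_site` data frame (`site`, `fis`, `n_loci`) and
#'   `average`.
#' @export
fis <- function(g) {
  sites <- sort(unique(g$sites[!is.na(g$sites)]))
  per <- do.call(rbind, lapply(sites, function(s) {
    st <- .locus_stats_one(g$dosage[, g$sites == s, drop = FALSE])
    use <- !is.na(st$he) & st$he > 0
    data.frame(site = s,
               fis = 1 - sum(st$ho[use]) / sum(st$he[use]),
               n_loci = sum(use))
  }))
  list(per_site = per, average = mean(per$fis))
}

#' Genetic distance among individuals
#'
#' Allele-difference count between individuals: the L1 distance between
#' alt-allele dosages, summed over loci typed in both individuals and
#' rescaled to the full locus count (`n_loci * mean per-locus difference`),
#' so pairs with different amounts of missing data are comparable.
#'
#' @param g a [genotype_matrix()].
#' @param rescale rescale to the full panel size (default) or report the
#'   raw per-pair mean (`rescale = FALSE`).
#' @return Labelled [distance_matrix()] over individuals.
#' @export
individual_distance <- function(g, rescale = TRUE) {
  d <- g$dosage
  A <- list(`0` = (d == 0), `1` = (d == 1), `2` = (d == 2))
  A <- lapply(A, function(m) {
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  typed <- A[["0"]] + A[["1"]] + A[["2"]]
  n_typed <- crossprod(typed)
  if (any(n_typed == 0)) {
    stop("some pair of individuals shares no typed loci", call. = FALSE)
  }
  sum_abs <- crossprod(A[["0"]], A[["1"]]) + crossprod(A[["1"]], A[["0"]]) +
    crossprod(A[["1"]], A[["2"]]) + crossprod(A[["2"]], A[["1"]]) +
    2 * (crossprod(A[["0"]], A[["2"]]) + crossprod(A[["2"]], A[["0"]]))
  m <- sum_abs / n_typed
  if (rescale) m <- m * nrow(d)
  diag(m) <- 0
  distance_matrix(m, g$individuals, tol = 1e-6)
}

#' Neighbour-joining tree with locus bootstrap
#'
#' Saitou-Nei neighbour joining (via \pkg{ape}) on the individual genetic
#' distance. When a genotype matrix is supplied, bipartition support is
#' computed by resampling loci with replacement, rebuilding the tree, and
#' counting the fraction of replicates containing each internal
#' bipartition.
#'
#' @param x a [genotype_matrix()] (enables bootstrapping) or a distance
#'   matrix (`bootstraps` must then be 0).
#' @param bootstraps number of locus-resampling replicates.
#' @param seed RNG seed for resampling.
#' @return An `ape::phylo` tree; with bootstrapping, node labels hold the
#'   support fractions.
#' @export
nj_tree <- function(x, bootstraps = 1000, seed = 1) {
  if (inherits(x, "genotype_matrix")) {
    dm <- individual_distance(x)
  } else {
    dm <- distance_matrix(x)
    if (bootstraps > 0) {
      stop("bootstrapping needs the genotype matrix, not a distance matrix",
           call. = FALSE)
    }
  }
  tree <- ape::nj(as.dist(dm))
  if (bootstraps > 0) {
    set.seed(seed)
    n_loci <- nrow(x$dosage)
    boot_trees <- vector("list", bootstraps)
    for (b in seq_len(bootstraps)) {
      idx <- sample.int(n_loci, n_loci, replace = TRUE)
      gb <- x
      gb$dosage <- x$dosage[idx, , drop = FALSE]
      rownames(gb$dosage) <- paste0("bl", seq_len(n_loci))
      boot_trees[[b]] <- ape::nj(as.dist(individual_distance(gb)))
    }
    class(boot_trees) <- "multiPhylo"
    cl <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
    cl[is.na(cl)] <- 0
    tree$node.label <- cl / bootstraps
  }
  tree
}
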