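#' Site-level distance matrix from a mouse-level one
#'
#' Entry (s, t) is the mean pairwise distance over all mouse pairs with one
#' mouse in site s and the other in site t; the diagonal is 0.
#'
#' @param dm_mice mouse-level distance matrix.
#' @param sites named character vector (names = mouse ids) or vector
#'   aligned with `rownames(dm_mice)`.
#' @return Labelled site x site [distance_matrix()].
#' @export
among_site_distance <- function(dm_mice, sites) {
  if (!is.null(names(sites))) sites <- sites[rownames(dm_mice)]
  sites <- as.character(sites)
  stopifnot(length(sites) == nrow(dm_mice))
  lvl <- sort(unique(sites))
  if (any(table(sites) < 1)) stop("empty site", call. = FALSE)
  m <- matrix(0, length(lvl), length(lvl), dimnames = list(lvl, lvl))
  for (i in seq_along(lvl)) {
    for (j in seq_len(i - 1)) {
      block <- dm_mice[sites == lvl[i], sites == lvl[j], drop = FALSE]
      m[i, j] <- m[j, i] <- mean(block)
    }
  }
  distance_matrix(m, lvl, tol = 1e-6)
}

.offdiag_pairs <- function(m) m[lower.tri(m)]

#' Mantel matrix-permutation test
#'
#' Pearson correlation between the unique off-diagonal entries of two
#' distance matrices over the same entities, with significance from random
#' permutations of one matrix's labels. The default tail is one-sided
#' (permuted r >= observed r), with the add-one convention
#' `p = (1 + #{r* >= r}) / (n_perm + 1)`; for four or fewer entities an
#' exhaustive enumeration over all relabelings is available.
#'
#' @param a,b distance matrices with identical labels in identical order.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param transform `"log1p"` applies `log(d + 1)` element-wise to `b`
#'   (conventional for skewed geographic distances) before correlating.
#' @param tail `"greater"` (default, one-sided positive association) or
#'   `"two.sided"` (on |r|).
#' @param exhaustive enumerate all `n!` relabelings instead of sampling
#'   (only sensible for small n; p then has no add-one correction).
#' @return List of class `mantel_result`: `r`, `p`, `n_perm`, `n_entities`,
#'   `tail`, `transform`.
#' @export
mantel <- function(a, b, n_perm = 999, seed = 1,
                   transform = c("none", "log1p"),
                   tail = c("greater", "two.sided"), exhaustive = FALSE) {
  transform <- match.arg(transform)
  tail <- match.arg(tail)
  a <- distance_matrix(a, tol = 1e-6)
  b <- distance_matrix(b, tol = 1e-6)
  if (!identical(rownames(a), rownames(b))) {
    stop("label mismatch between the two matrices", call. = FALSE)
  }
  n <- nrow(a)
  if (n < 4) stop("mantel needs at least 4 entities", call. = FALSE)
  if (transform == "log1p") b <- log1p(b)
  va <- .offdiag_pairs(a)
  if (sd(va) == 0 || sd(.offdiag_pairs(b)) == 0) {
    stop("constant distance matrix: correlation undefined", call. = FALSE)
  }
  r_obs <- cor(va, .offdiag_pairs(b))
  stat <- function(perm) cor(va, .offdiag_pairs(b[perm, perm]))
  cmp <- function(r) {
    if (tail == "greater") r >= r_obs - 1e-12 else
      abs(r) >= abs(r_obs) - 1e-12
  }
  if (exhaustive) {
    perms <- .permutations(n)
    rstar <- apply(perms, 1, stat)
    p <- mean(vapply(rstar, cmp, logical(1)))
    n_used <- nrow(perms)
  } else {
    set.seed(seed)
    rstar <- replicate(n_perm, stat(sample.int(n)))
    p <- (1 + sum(vapply(rstar, cmp, logical(1)))) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p, n_perm = n_used, n_entities = n,
                 tail = tail, transform = transform),
            class = "mantel_result")
}

# all permutations of 1..n (n small)
.permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; node heights are half the merge distance,
#' so on ultrametric input the cophenetic distances reproduce the matrix
#' exactly. Ties are broken towards the smallest label order (inputs are
#' reordered by label before clustering).
#'
#' @param dm distance matrix.
#' @return Rooted ultrametric `ape::phylo` tree.
#' @export
upgma <- function(dm) {
  dm <- distance_matrix(dm, tol = 1e-6)
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  hc <- hclust(as.dist(dm), method = "average")
  # as.phylo places each node at half its merge distance, so cophenetic
  # tip-to-tip distances reproduce the merge distances
  ape::as.phylo(hc)
}
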