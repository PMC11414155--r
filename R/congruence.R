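align_two_dist <- function(d1, d2) {
  shared <- intersect(dm_labels(d1), dm_labels(d2))
  if (length(shared) < 3L) {
    stop("need at least 3 shared labels; found ", length(shared))
  }
  list(d1 = subset_dist(d1, shared), d2 = subset_dist(d2, shared), labels = shared)
}

#' Mantel test of association between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries after restriction to the
#' label intersection (order-aligned), with a permutation null obtained by
#' jointly permuting rows and columns of the second matrix. The p-value is
#' one-tailed for positive association (the direction of genealogical
#' coupling under clonality) and uses the `(1 + exceedances)/(1 + n_perm)`
#' estimator, so it is never 0.
#'
#' @param d1,d2 `dist_matrix` objects with >= 3 shared labels.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return An object of class `mantel_result`: list with `r`, `p`, `n_perm`,
#'   `seed`, `n` (shared labels).
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = 1L) {
  al <- align_two_dist(d1, d2)
  v1 <- upper_tri_values(al$d1)
  m2 <- unclass(al$d2)
  ut <- upper.tri(m2)
  v2 <- m2[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("zero-variance distance matrix; Mantel correlation undefined")
  }
  r_obs <- stats::cor(v1, v2)
  n <- length(al$labels)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    v2p <- m2[idx, idx][ut]
    if (stats::cor(v1, v2p) >= r_obs) exceed <- exceed + 1L
  }
  structure(
    list(r = r_obs, p = (1 + exceed) / (1 + n_perm),
         n_perm = as.integer(n_perm), seed = as.integer(seed), n = n),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (one-tailed, %d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}

#' Pearson correlation of two distance matrices with a parametric p-value
#'
#' Reported alongside (never instead of) the Mantel permutation test: the
#' upper-triangle entries of a distance matrix are not independent, so the
#' t-distribution p-value on `n(n-1)/2 - 2` degrees of freedom is
#' anti-conservative; a message records the caveat.
#'
#' @param d1,d2 `dist_matrix` objects with >= 3 shared labels.
#' @return List with `rho`, `p`, `n_pairs`.
#' @export
pearson_distance_correlation <- function(d1, d2) {
  al <- align_two_dist(d1, d2)
  v1 <- upper_tri_values(al$d1)
  v2 <- upper_tri_values(al$d2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("zero-variance distance matrix; correlation undefined")
  }
  rho <- stats::cor(v1, v2)
  m <- length(v1)
  tval <- rho * sqrt((m - 2) / (1 - rho^2))
  p <- 2 * stats::pt(abs(tval), df = m - 2, lower.tail = FALSE)
  message("pearson_distance_correlation: pair entries are non-independent; ",
          "the parametric p-value is a descriptive companion to the Mantel test")
  list(rho = rho, p = p, n_pairs = m)
}

#' Ward dendrogram of a distance matrix
#'
#' Agglomerative clustering under the Ward criterion in the Ward.D2
#' convention (Lance-Williams updates on squared dissimilarities, heights on
#' the original scale). Labels are sorted lexicographically before
#' clustering so that ties between equal merge costs break toward the
#' lexicographically smallest labels, deterministically.
#'
#' @param d A `dist_matrix` with >= 2 labels.
#' @return An `hclust` object with ultrametric (non-decreasing) heights.
#' @export
ward_dendrogram <- function(d) {
  labs <- sort(dm_labels(d))
  if (length(labs) < 2L) stop("need at least 2 labels")
  ds <- subset_dist(d, labs)
  stats::hclust(stats::as.dist(unclass(ds)), method = "ward.D2")
}

# Pairwise merge-depth matrix of an hclust tree: entry (i, j) is the largest
# number of clusters k at which leaves i and j are in the same cluster,
# i.e. the k at which the pair first co-clusters as clusters merge.
merge_depth_matrix <- function(tree) {
  n <- length(tree$labels)
  M <- stats::cutree(tree, k = seq_len(n))
  depth <- matrix(1L, n, n)
  for (k in 2:n) {
    eq <- outer(M[, k], M[, k], "==")
    depth[eq] <- k
  }
  dimnames(depth) <- list(tree$labels, tree$labels)
  depth
}

#' Baker's gamma congruence of two dendrograms
#'
#' For every unordered leaf pair, the merge depth (number of clusters at
#' which the pair first co-clusters) is computed in each tree; gamma is the
#' Spearman rank correlation between the two merge-depth vectors. The null
#' distribution is obtained by randomly permuting the leaf labels of the
#' second tree; the p-value is two-sided on `|gamma|` with the
#' `(1 + exceedances)/(1 + n_perm)` estimator.
#'
#' @param t1,t2 `hclust` objects over identical leaf sets.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @return An object of class `bakers_gamma_result`: list with `gamma`, `p`,
#'   `n_perm`, `seed`, `n`.
#' @export
bakers_gamma <- function(t1, t2, n_perm = 1000, seed = 1L) {
  l1 <- t1$labels
  l2 <- t2$labels
  if (!setequal(l1, l2)) {
    diff <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop("leaf sets differ: ", paste(diff, collapse = ", "))
  }
  labs <- sort(l1)
  D1 <- merge_depth_matrix(t1)[labs, labs]
  D2 <- merge_depth_matrix(t2)[labs, labs]
  ut <- upper.tri(D1)
  v1 <- rank(D1[ut])
  v2 <- rank(D2[ut])
  gamma_of <- function(vb) stats::cor(v1, vb)
  g_obs <- gamma_of(rank(D2[ut]))
  n <- length(labs)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    gp <- stats::cor(v1, rank(D2[idx, idx][ut]))
    if (abs(gp) >= abs(g_obs)) exceed <- exceed + 1L
  }
  structure(
    list(gamma = g_obs, p = (1 + exceed) / (1 + n_perm),
         n_perm = as.integer(n_perm), seed = as.integer(seed), n = n),
    class = "bakers_gamma_result"
  )
}

#' @export
print.bakers_gamma_result <- function(x, ...) {
  cat(sprintf("Baker's gamma: %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$gamma, x$p, x$n_perm, x$n))
  invisible(x)
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Anderson's permutational multivariate analysis of variance:
#' `SS_total = sum(d^2)/n` over all unordered pairs, `SS_within` the
#' group-wise analogue, pseudo-F `= (SS_between/(a-1)) / (SS_within/(n-a))`,
#' with significance by permuting the group labels.
#'
#' @param d A `dist_matrix`.
#' @param groups Named character/factor vector of group labels covering all
#'   matrix labels (names = isolate ids), or an unnamed vector in matrix
#'   label order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param factor_name Label for the factor in reports.
#' @return An object of class `permanova_result`: list with `pseudo_F`,
#'   `R2`, `p`, `n_perm`, `seed`, `factor_name`, `n`, `n_groups`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L, factor_name = "group") {
  labs <- dm_labels(d)
  if (!is.null(names(groups))) {
    if (!all(labs %in% names(groups))) {
      stop("groups must cover all matrix labels")
    }
    groups <- groups[labs]
  } else if (length(groups) != length(labs)) {
    stop("unnamed groups must match the matrix label count")
  }
  g <- as.factor(as.character(groups))
  a <- nlevels(g)
  if (a < 2L) stop("need at least 2 groups")
  n <- length(labs)
  d2 <- unclass(d)^2
  ut <- upper.tri(d2)
  ss_total <- sum(d2[ut]) / n
  within_ss <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1L) {
        sub <- d2[idx, idx]
        s <- s + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    s
  }
  f_stat <- function(g) {
    ssw <- within_ss(g)
    ssb <- ss_total - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  F_obs <- f_stat(g)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (f_stat(g[sample.int(n)]) >= F_obs) exceed <- exceed + 1L
  }
  structure(
    list(pseudo_F = F_obs, R2 = (ss_total - within_ss(g)) / ss_total,
         p = (1 + exceed) / (1 + n_perm),
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         factor_name = factor_name, n = n, n_groups = a),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s): pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$factor_name, x$pseudo_F, x$R2, x$p, x$n_perm))
  invisible(x)
}
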