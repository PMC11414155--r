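test_that("Mantel detects perfect linear association", {
  set.seed(1)
  d1 <- random_euclidean_dist(6)
  d2 <- dist_matrix(unclass(d1) * 2, rownames(d1))
  r <- mantel_test(d1, d2, n_perm = 999, seed = 4)
  expect_equal(r$r, 1.0, tolerance = 1e-12)
  # only a drawn identity permutation can match r = 1, so p sits at the
  # attainable minimum up to the ~1/n! identity draws
  expect_lte(r$p, 5 / 1000)
  expect_equal(r$n, 6)
})

test_that("Mantel restricts to the shared label set and errors sensibly", {
  set.seed(2)
  d1 <- random_euclidean_dist(6, labels = sprintf("A%d", 1:6))
  d2 <- random_euclidean_dist(6, labels = c(sprintf("A%d", 1:4), "B1", "B2"))
  r <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  expect_equal(r$n, 4)
  d3 <- random_euclidean_dist(6, labels = sprintf("C%d", 1:6))
  expect_error(mantel_test(d1, d3), "shared labels")
  dz <- dist_matrix(matrix(0.3, 4, 4) - diag(0.3, 4), sprintf("A%d", 1:4))
  expect_error(mantel_test(d1, dz, n_perm = 9), "zero-variance")
})

test_that("Mantel permutation p converges to the exact enumeration p on 4 labels", {
  set.seed(3)
  for (rep in 1:3) {
    d1 <- random_euclidean_dist(4)
    d2 <- random_euclidean_dist(4)
    exact <- oracle_mantel_exact_p(d1, d2)
    r <- mantel_test(d1, d2, n_perm = 20000, seed = 50 + rep)
    expect_equal(r$p, exact, tolerance = 0.015)
  }
})

test_that("Pearson-on-distances matches direct arithmetic and flags zero variance", {
  set.seed(4)
  d1 <- random_euclidean_dist(4)
  d2 <- random_euclidean_dist(4)
  res <- suppressMessages(pearson_distance_correlation(d1, d2))
  v1 <- upper_tri_values(d1); v2 <- upper_tri_values(d2)
  expect_equal(res$rho, cor(v1, v2), tolerance = 1e-12)
  tval <- res$rho * sqrt((6 - 2) / (1 - res$rho^2))
  expect_equal(res$p, 2 * pt(abs(tval), 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(suppressMessages(pearson_distance_correlation(d1, d1))$rho, 1)
  dz <- dist_matrix(matrix(0.3, 4, 4) - diag(0.3, 4), rownames(d1))
  expect_error(suppressMessages(pearson_distance_correlation(d1, dz)), "zero-variance")
})

test_that("Ward dendrograms obey base cases and match the brute-force criterion", {
  d2 <- dist_matrix(matrix(c(0, 0.4, 0.4, 0), 2, 2), c("A", "B"))
  h <- ward_dendrogram(d2)
  expect_equal(h$height, 0.4)
  # nearest-pair property
  m <- matrix(c(0, .1, .9, .1, 0, .85, .9, .85, 0), 3, 3)
  h3 <- ward_dendrogram(dist_matrix(m, c("A", "B", "C")))
  expect_equal(sort(hclust_merge_sequence(h3)[[1]]), c("A", "B"))
  # heights non-decreasing along every path (ultrametric)
  set.seed(6)
  for (rep in 1:10) {
    d <- random_euclidean_dist(sample(5:8, 1))
    h <- ward_dendrogram(d)
    expect_true(all(diff(h$height) >= -1e-12))
    expect_identical(hclust_merge_sequence(h),
                     oracle_ward_merge_sequence(unclass(d)))
  }
})

test_that("Baker's gamma is 1 for identical trees and matches hand enumeration", {
  set.seed(7)
  d <- random_euclidean_dist(8)
  t1 <- ward_dendrogram(d)
  r <- bakers_gamma(t1, t1, n_perm = 99, seed = 2)
  expect_equal(r$gamma, 1.0, tolerance = 1e-12)
  expect_lte(r$p, 0.05)

  # 4-leaf hand enumeration: ((A,B),(C,D)) vs ((A,C),(B,D))
  make_tree <- function(first, second, labels) {
    # two tight pairs merging at the root; built from an explicit matrix
    m <- matrix(0.9, 4, 4); diag(m) <- 0
    m[first[1], first[2]] <- m[first[2], first[1]] <- 0.1
    m[second[1], second[2]] <- m[second[2], second[1]] <- 0.2
    ward_dendrogram(dist_matrix(m, labels))
  }
  labs <- c("A", "B", "C", "D")
  t_ab <- make_tree(c(1, 2), c(3, 4), labs)  # ((A,B),(C,D))
  t_ac <- make_tree(c(1, 3), c(2, 4), labs)  # ((A,C),(B,D))
  r2 <- bakers_gamma(t_ab, t_ac, n_perm = 99, seed = 3)
  # merge depths (k at first co-clustering), pairs in order AB AC AD BC BD CD:
  #   t_ab: AB 3, AC 1, AD 1, BC 1, BD 1, CD 2
  #   t_ac: AB 1, AC 3, AD 1, BC 1, BD 2, CD 1
  hand <- cor(rank(c(3, 1, 1, 1, 1, 2)), rank(c(1, 3, 1, 1, 2, 1)))
  expect_equal(r2$gamma, hand, tolerance = 1e-12)

  # invariance to leaf-order rotations: reordering labels of the input
  # matrix must not change gamma
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  d_perm <- dist_matrix(unclass(d)[perm, perm], rownames(d)[perm])
  t1b <- ward_dendrogram(d_perm)
  expect_equal(bakers_gamma(t1, t1b, n_perm = 9, seed = 1)$gamma, 1.0,
               tolerance = 1e-12)

  # leaf-set mismatch lists the symmetric difference
  d_bad <- random_euclidean_dist(8, labels = sprintf("Z%02d", 1:8))
  expect_error(bakers_gamma(t1, ward_dendrogram(d_bad)), "Z01")
})

test_that("PERMANOVA pseudo-F matches a from-scratch sum-of-squares computation", {
  set.seed(8)
  pts <- rbind(matrix(rnorm(9, 0), 3), matrix(rnorm(9, 4), 3))
  labs <- sprintf("p%d", 1:6)
  dmat <- as.matrix(dist(pts)); dimnames(dmat) <- list(labs, labs)
  d <- dist_matrix(dmat, labs)
  g <- setNames(rep(c("x", "y"), each = 3), labs)
  res <- permanova(d, g, n_perm = 999, seed = 5)
  # from-scratch: SS_total = sum d^2 / n; SS_within = per-group sum d^2 / n_g
  d2 <- dmat^2
  ss_t <- sum(d2[upper.tri(d2)]) / 6
  ss_w <- sum(d2[1:3, 1:3][upper.tri(d2[1:3, 1:3])]) / 3 +
    sum(d2[4:6, 4:6][upper.tri(d2[4:6, 4:6])]) / 3
  f_hand <- ((ss_t - ss_w) / 1) / (ss_w / 4)
  expect_equal(res$pseudo_F, f_hand, tolerance = 1e-12)
  expect_equal(res$R2, (ss_t - ss_w) / ss_t, tolerance = 1e-12)
  # perfect separation: only relabelings recreating the same partition
  # (72 of 720) reach the observed F, so p sits at its attainable minimum ~0.1
  expect_lt(res$p, 0.15)
  expect_gt(res$p, 0.06)
  expect_error(permanova(d, setNames(rep("x", 6), labs)), "at least 2 groups")
})

test_that("PERMANOVA agrees with vegan::adonis2 on pseudo-F and R2", {
  set.seed(9)
  d <- random_euclidean_dist(9)
  g <- setNames(sample(c("u", "v", "w"), 9, TRUE), rownames(d))
  g[1:3] <- c("u", "v", "w")  # guarantee >= 2 groups
  res <- permanova(d, g, n_perm = 99, seed = 1)
  av <- vegan::adonis2(as.dist(unclass(d)) ~ grp,
                       data = data.frame(grp = unname(g)), permutations = 99)
  expect_equal(res$pseudo_F, av$F[1], tolerance = 1e-9)
  expect_equal(res$R2, av$R2[1], tolerance = 1e-9)
})

test_that("permutation p-values always exceed zero and use the +1 estimator", {
  set.seed(10)
  d1 <- random_euclidean_dist(5)
  d2 <- dist_matrix(unclass(d1) * 3, rownames(d1))
  expect_equal(mantel_test(d1, d2, n_perm = 49, seed = 1)$p, 1 / 50)
  t1 <- ward_dendrogram(d1)
  expect_gt(bakers_gamma(t1, t1, n_perm = 49, seed = 1)$p, 0)
})
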