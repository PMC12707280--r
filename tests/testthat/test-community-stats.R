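test_that("euclidean distance matches hand geometry and is permutation-safe", {
  m <- matrix(c(0, 0, 3, 4), 2, 2,
              dimnames = list(c("f1", "f2"), c("a", "b")))
  d <- euclidean_distance(m)
  expect_equal(d["a", "b"], 5)
  expect_equal(diag(d), c(a = 0, b = 0))

  # identical columns -> 0; feature order irrelevant
  m2 <- cbind(m, c = m[, "a"])
  d2 <- euclidean_distance(m2)
  expect_equal(d2["a", "c"], 0)
  expect_equal(euclidean_distance(m2[c(2, 1), ]), d2)

  expect_error(euclidean_distance(matrix(c(1, NA, 1, 1), 2, 2)), "non-finite")
})

test_that("pca_scores agrees with hand SVD and orders variance", {
  # rank-1 data: PC1 carries all the variance
  base <- c(1, 2, 3)
  m <- rbind(f1 = base, f2 = 2 * base)
  colnames(m) <- paste0("s", 1:3)
  p1 <- pca_scores(m, 1)
  expect_equal(p1$explained_variance[1], 1)

  set.seed(9)
  m2 <- matrix(rnorm(40), 8, 5,
               dimnames = list(paste0("f", 1:8), paste0("s", 1:5)))
  p2 <- pca_scores(m2, 4)
  expect_true(all(diff(p2$explained_variance) <= 1e-12))
  expect_lte(sum(p2$explained_variance), 1 + 1e-12)
  # scores reproduce centered sample geometry: pairwise distances in full
  # component space equal distances of the centered data
  pfull <- pca_scores(m2, 4)
  dc <- dist(scale(t(m2), center = TRUE, scale = FALSE))
  ds <- dist(pfull$scores)
  expect_equal(as.numeric(ds), as.numeric(dc), tolerance = 1e-9)

  expect_error(pca_scores(matrix(1, 3, 3,
                                 dimnames = list(1:3, 1:3)), 1),
               "constant")
  expect_error(pca_scores(m2, 5), "n_components")
})

test_that("permanova partitions SS, matches the enumeration oracle", {
  # 4 samples at (0,0),(0,0),(1,1),(1,1); grouping {1,2} | {3,4}:
  # 3 distinct splits, only the true one maximizes F -> exact p = 1/3
  coords <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  rownames(coords) <- paste0("s", 1:4)
  d <- as.matrix(dist(coords))
  meta <- data.frame(grp = c("A", "A", "B", "B"))
  res <- permanova(d, meta, "grp", permutations = "exhaustive")
  expect_equal(res$p[1], 1 / 3, tolerance = 1e-12)
  expect_equal(sum(res$R2), 1, tolerance = 1e-9)

  # pseudo-F equals the classical one-way statistic from group centroids
  set.seed(11)
  coords2 <- matrix(rnorm(6 * 3), 6, 3)
  rownames(coords2) <- paste0("s", 1:6)
  grp <- c("A", "A", "A", "B", "B", "B")
  res2 <- permanova(as.matrix(dist(coords2)), data.frame(grp = grp), "grp",
                    n_perm = 10, seed = 1)
  expect_equal(res2$F[1], oracle_oneway_F(coords2, grp), tolerance = 1e-9)

  # duplicating every sample leaves R2 unchanged
  dup <- c(1:6, 1:6)
  res3 <- permanova(as.matrix(dist(coords2[dup, ])),
                    data.frame(grp = grp[dup]), "grp",
                    n_perm = 10, seed = 1)
  expect_equal(res3$R2[1], res2$R2[1], tolerance = 1e-9)

  expect_error(permanova(d, data.frame(grp = rep("A", 4)), "grp"),
               "fewer than two levels")
})

test_that("multi-term permanova uses sequential SS and matches vegan", {
  skip_if_not_installed("vegan")
  set.seed(5)
  n <- 16
  coords <- matrix(rnorm(n * 4), n, 4)
  rownames(coords) <- paste0("s", 1:n)
  meta <- data.frame(a = rep(c("x", "y"), each = n / 2),
                     b = rep(c("u", "v"), n / 2))
  d <- as.matrix(dist(coords))
  mine <- permanova(d, meta, c("a", "b"), n_perm = 19, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ a + b, data = meta,
                        permutations = 19, by = "terms")
  expect_equal(mine$SS, ref$SumOfSqs[1:3], tolerance = 1e-9)
  expect_equal(mine$R2, ref$R2[1:3], tolerance = 1e-9)
  expect_equal(mine$F[1:2], ref$F[1:2], tolerance = 1e-9)
  # all terms + residual account for the total
  expect_equal(sum(mine$R2), 1, tolerance = 1e-9)
})

test_that("mantel statistic is the triangle Spearman, rank-invariant", {
  set.seed(21)
  coords <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  d1 <- as.matrix(dist(coords))
  r <- mantel(d1, d1, n_perm = 99, seed = 1)
  expect_equal(r$statistic, 1)

  # monotone transform of distances: Spearman unchanged
  r2 <- mantel(d1, d1^2, n_perm = 99, seed = 1)
  expect_equal(r2$statistic, 1)

  # brute-force triangle extraction on a 5-sample instance
  coords2 <- matrix(rnorm(10), 5, 2)
  d2 <- as.matrix(dist(coords2))
  rownames(d2) <- colnames(d2) <- rownames(d1)
  v1 <- d1[upper.tri(d1)]
  v2 <- d2[upper.tri(d2)]
  expect_equal(mantel(d1, d2, n_perm = 9, seed = 1)$statistic,
               oracle_spearman(v1, v2), tolerance = 1e-12)

  expect_error(mantel(d1 * 0, d1, n_perm = 9), "zero variance")
})

test_that("mantel agrees with vegan on statistic and permutation scheme", {
  skip_if_not_installed("vegan")
  set.seed(31)
  c1 <- matrix(rnorm(24), 8, 3)
  c2 <- c1 + matrix(rnorm(24, sd = 2), 8, 3)
  rownames(c1) <- rownames(c2) <- paste0("s", 1:8)
  d1 <- as.matrix(dist(c1)); d2 <- as.matrix(dist(c2))
  mine <- mantel(d1, d2, n_perm = 999, seed = 2)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), method = "spearman",
                       permutations = 999)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  # both use the one-sided add-one convention; p-values should be close
  expect_lt(abs(mine$p - ref$signif), 0.1)
})

test_that("platform slope test handles identity, scaling, and noise", {
  ref <- c(1, 2, 4, 8, 16, 32)
  r1 <- platform_slope_test(ref, ref)
  expect_equal(r1$slope, 1)
  expect_equal(r1$t, 0)
  expect_equal(r1$p, 0.5)
  expect_equal(r1$spearman_rho, 1)

  r2 <- platform_slope_test(ref, 0.5 * ref)
  expect_equal(r2$slope, 0.5, tolerance = 1e-12)
  expect_equal(r2$p, 0)

  # closed-form t against stats::lm / summary on a noisy instance
  set.seed(4)
  alt <- ref + rnorm(6, sd = 2)
  r3 <- platform_slope_test(ref, alt)
  sm <- summary(lm(alt ~ ref))$coefficients
  expect_equal(r3$t, (sm[2, 1] - 1) / sm[2, 2], tolerance = 1e-9)
  expect_equal(r3$p, pt((sm[2, 1] - 1) / sm[2, 2], df = 4), tolerance = 1e-9)

  expect_error(platform_slope_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(platform_slope_test(c(1, 2), c(1, 2)), "three")
})
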