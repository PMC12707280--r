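test_that("fisher_z matches closed form, is odd, and guards its domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-9)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- c(-0.9, -0.3, 0.2, 0.77)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), "clamp")
  expect_equal(fisher_z(1, clamp = TRUE), atanh(1 - 1e-7))
})

test_that("pairwise_spearman uses midranks and flags constant features", {
  tp <- toy_pair(list(c(1, 2, 3, 4)),
                 list(c(1, 2, 2, 4),        # tied values
                      c(10, 20, 30, 40),    # monotone transform
                      c(8, 6, 4, 2),        # reversed
                      c(5, 5, 5, 5)))       # constant
  expect_message(rho <- pairwise_spearman(tp$plant, tp$microbe),
                 "constant feature")
  expect_equal(rho["p1", "m1"], 0.9486833, tolerance = 1e-7)
  expect_equal(rho["p1", "m2"], 1)
  expect_equal(rho["p1", "m3"], -1)
  expect_true(is.na(rho["p1", "m4"]))
  expect_identical(attr(rho, "n_constant"), 1L)

  expect_error(pairwise_spearman(tp$plant[, 1:3, drop = FALSE],
                                 tp$microbe[, 1:3, drop = FALSE]),
               "4 samples")
})

test_that("pairwise_spearman equals the brute-force oracle on small instances", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    tp <- toy_pair(
      lapply(1:4, function(i) sample(1:4, n, replace = TRUE)),
      lapply(1:5, function(i) rnorm(n)))
    rho <- suppressMessages(pairwise_spearman(tp$plant, tp$microbe))
    for (i in rownames(rho)) for (j in colnames(rho)) {
      x <- tp$plant[i, ]; y <- tp$microbe[j, ]
      expected <- if (length(unique(x)) == 1 || length(unique(y)) == 1)
        NA_real_ else oracle_spearman(x, y)
      expect_equal(rho[i, j], expected, tolerance = 1e-12)
    }
  }
})

test_that("bh_adjust matches the step-up definition and the rejection oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  for (rep in 1:20) {
    p <- runif(sample(1:12, 1))
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    # monotone in p
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    # q-threshold rejections equal the brute-force step-up set at any alpha
    for (alpha in c(0.01, 0.05, 0.2, 0.5)) {
      expect_identical(q <= alpha, oracle_bh_reject(p, alpha))
    }
  }
})

test_that("differential correlation reproduces the closed-form chain", {
  # rho_A = 0.9, rho_B = -0.9, n = 10 per condition
  zA <- fisher_z(0.9)
  dz <- fisher_z(-0.9) - zA
  se <- sqrt(1 / 7 + 1 / 7)
  expect_equal(dz, -2.94444, tolerance = 1e-5)
  expect_equal(se, 0.534522, tolerance = 1e-6)
  expect_equal(abs(dz / se), 5.50857, tolerance = 1e-5)
  expect_equal(2 * pnorm(abs(dz / se), lower.tail = FALSE), 3.62e-8,
               tolerance = 1e-2)

  # the table's columns obey the same chain on arbitrary data
  set.seed(3)
  tp <- toy_pair(lapply(1:3, function(i) rnorm(20)),
                 lapply(1:2, function(i) rnorm(20)))
  dc <- differential_correlation(tp$plant, tp$microbe, 1:10, 11:20)
  expect_equal(dc$z_A, atanh(dc$rho_A))
  expect_equal(dc$delta_z, dc$z_B - dc$z_A)
  expect_equal(dc$se, rep(sqrt(2 / 7), nrow(dc)))
  expect_equal(dc$p, 2 * pnorm(abs(dc$delta_z / dc$se), lower.tail = FALSE))
  expect_equal(dc$q, p.adjust(dc$p, "BH"), tolerance = 1e-12)
})

test_that("identical conditions give a null table; label swap is antisymmetric", {
  set.seed(6)
  tp <- toy_pair(lapply(1:3, function(i) rnorm(12)),
                 lapply(1:3, function(i) rnorm(12)))
  # same samples in both conditions -> rho_A = rho_B, delta_z = 0, p = 1
  dc0 <- differential_correlation(tp$plant, tp$microbe, 1:12, 1:12)
  expect_true(all(dc0$delta_z == 0))
  expect_true(all(dc0$p == 1))
  expect_identical(sum(dc0$significant), 0L)

  # swapping the condition labels negates delta_z and Z, keeps p/q/sig
  ab <- differential_correlation(tp$plant, tp$microbe, 1:6, 7:12)
  ba <- differential_correlation(tp$plant, tp$microbe, 7:12, 1:6)
  expect_equal(ba$delta_z, -ab$delta_z)
  expect_equal(ba$Z_stat, -ab$Z_stat)
  expect_equal(ba$p, ab$p)
  expect_equal(ba$q, ab$q)
  expect_identical(ba$significant, ab$significant)

  expect_error(differential_correlation(tp$plant, tp$microbe, 1:3, 4:12),
               "at least 4")
})

test_that("untestable pairs are excluded from the BH family", {
  tp <- toy_pair(list(c(1, 3, 2, 4, 5, 7, 6, 8)),
                 list(c(2, 1, 4, 3, 6, 5, 8, 7),
                      c(9, 9, 9, 9, 1, 2, 3, 4)))  # constant in condition A
  dc <- differential_correlation(tp$plant, tp$microbe, 1:4, 5:8)
  expect_identical(nrow(dc), 1L)
  expect_identical(attr(dc, "n_untestable"), 1L)
  expect_identical(dc$microbial_feature, "m1")
})

test_that("bipartite network applies the edge rule and degree summary", {
  corr <- matrix(c(0.9, 0.71, 0.69, -0.95), 2, 2,
                 dimnames = list(c("p1", "p2"), c("m1", "m2")))
  net <- bipartite_network(corr, rho_threshold = 0.7)
  expect_identical(nrow(net$edges), 2L)      # 0.9 and 0.71; -0.95 excluded
  expect_setequal(net$edges$rho, c(0.9, 0.71))

  # absolute-rho flag admits the strong negative edge
  net2 <- bipartite_network(corr, rho_threshold = 0.7, use_abs = TRUE)
  expect_identical(nrow(net2$edges), 3L)

  # restriction to one microbial feature yields its star
  net3 <- bipartite_network(corr, rho_threshold = 0.5, restrict_to = "m1")
  expect_true(all(net3$edges$microbial_feature == "m1"))
  expect_identical(unname(net3$degree["m1"]),
                   as.integer(nrow(net3$edges)))

  # all below threshold -> empty, not an error
  expect_identical(nrow(bipartite_network(corr, 0.99)$edges), 0L)
})

test_that("hypergeometric overlap matches direct combinatorics", {
  u <- paste0("g", 1:10)
  A <- u[1:5]
  B <- u[6:9]             # disjoint: k = 0
  r <- overlap_hypergeom(A, B, u, tail = "lower")
  expect_identical(r$overlap, 0L)
  expect_equal(r$p, 5 / 210, tolerance = 1e-12)
  expect_equal(r$p, oracle_hyper_lower(0, 10, 5, 4), tolerance = 1e-12)

  # saturation: A = B = universe
  r2 <- overlap_hypergeom(u, u, u, tail = "lower")
  expect_equal(r2$p, 1)
  # upper + lower at k partition the mass: P(X>=k) + P(X<=k-1) = 1
  r3u <- overlap_hypergeom(A, u[3:8], u, tail = "upper")
  k <- length(intersect(A, u[3:8]))
  expect_equal(r3u$p, 1 - oracle_hyper_lower(k - 1, 10, 5, 6),
               tolerance = 1e-12)

  expect_error(overlap_hypergeom(c("zz"), B, u), "universe")
})
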