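test_that("low-expression filter retains exactly the qualifying features", {
  m <- toy_counts(c(80, 80, 80, 80, 0,
                    80, 80, 80, 0, 0,
                    74, 74, 74, 74, 74), nrow = 3,
                  features = c("A", "B", "C"))
  out <- filter_low_expression(m, 75, 4)
  expect_identical(rownames(out), "A")
  expect_identical(colnames(out), colnames(m))

  # all-zero gene removed under any rule with thresholds >= 1
  z <- toy_counts(c(0, 0, 0, 5, 5, 5), nrow = 2)
  expect_identical(rownames(filter_low_expression(z, 1, 1)), "f2")

  # (0, 0) rule is the identity
  expect_equal(unclass(filter_low_expression(m, 0, 0)), unclass(m),
               ignore_attr = TRUE)

  # idempotence
  once <- filter_low_expression(m, 75, 4)
  twice <- filter_low_expression(once, 75, 4)
  expect_identical(unclass(once), unclass(twice))

  expect_warning(filter_low_expression(m, 1e6, 5), "no features pass")
})

test_that("taxa filter combines presence and abundance rules", {
  tx <- toy_counts(c(50, 0, 0,
                     9, 9, 9,
                     10, 10, 0,
                     12, 3, 0), nrow = 4, kind = "taxon",
                   features = c("one_sample", "below10", "keep", "one_abund"))
  out <- filter_taxa(tx)
  expect_identical(rownames(out), "keep")
  expect_identical(unclass(filter_taxa(out)), unclass(out))   # idempotent
  expect_error(filter_taxa(toy_counts(c(1, 1), 1)), "taxon")
})

test_that("relative abundance divides by column totals", {
  m <- toy_counts(c(2, 1, 2, 3), nrow = 2)
  ra <- relative_abundance(m)
  expect_equal(unname(ra[, 1]), c(0.5, 0.5))
  expect_equal(unname(ra[, 2]), c(0.25, 0.75))
  expect_equal(unname(colSums(ra)), c(1, 1))
  expect_identical(attr(ra, "transform"), "relative")

  z <- toy_counts(c(1, 0, 1, 0), nrow = 2)
  expect_error(relative_abundance(z), "s2")
})

test_that("CLR matches closed form and is scale invariant", {
  m <- toy_counts(c(1, 1, 10, 1, 100, 1), nrow = 3)
  cl <- clr_transform(m, pseudocount = 0)
  expect_equal(unname(cl[, 1]), c(-log(10), 0, log(10)), tolerance = 1e-9)
  expect_equal(unname(cl[, 2]), c(0, 0, 0))
  expect_lt(max(abs(colSums(cl))), 1e-9)

  # scaling a column by any constant leaves its CLR unchanged; in
  # particular clr(relative_abundance(x)) == clr(x) for positive counts
  m2 <- m
  m2[, 1] <- m2[, 1] * 7
  expect_equal(unclass(clr_transform(m2, 0)), unclass(cl),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(clr_transform(relative_abundance(m), 0)),
               unclass(cl), ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(clr_transform(toy_counts(c(0, 1), 2), pseudocount = 0),
               "pseudocount")
})

test_that("median-of-ratios recovers multiplicative size factors", {
  base <- c(10, 50, 200, 5)
  m <- count_matrix(cbind(s1 = base, s2 = 2 * base, s3 = 4 * base) |>
                      (\(x) { rownames(x) <- paste0("g", 1:4); x })(),
                    "plant_gene")
  res <- median_ratio_normalize(m)
  expect_equal(unname(res$size_factors), c(0.5, 1, 2), tolerance = 1e-12)
  expect_equal(exp(mean(log(res$size_factors))), 1, tolerance = 1e-12)
  # normalized matrix is identical across samples after rescaling
  expect_equal(unname(res$matrix[, 1]), unname(res$matrix[, 3]),
               tolerance = 1e-12)

  # two identical samples -> equal size factors (1, 1)
  m2 <- toy_counts(c(3, 3, 8, 8), nrow = 2)
  expect_equal(unname(median_ratio_normalize(m2)$size_factors), c(1, 1))

  # single sample -> s = 1 by the geometric-mean convention
  m1 <- count_matrix(matrix(c(4, 9), 2, 1,
                            dimnames = list(c("a", "b"), "s1")),
                     "plant_gene")
  expect_equal(unname(median_ratio_normalize(m1)$size_factors), 1)

  # no feature positive everywhere -> error
  bad <- toy_counts(c(1, 0, 0, 1), nrow = 2)
  expect_error(median_ratio_normalize(bad), "reference")
})

test_that("rarefaction subsamples to exact depth and drops shallow samples", {
  m <- count_matrix(matrix(c(100, 100, 100,   # s1: total 300
                             40, 30, 30),     # s2: total 100 (dropped)
                           3, 2, dimnames = list(paste0("t", 1:3),
                                                 c("s1", "s2"))),
                    "taxon")
  depth <- 150
  expect_warning(r <- rarefy(m, depth, seed = 3), "below depth")
  expect_identical(colnames(r), "s1")
  expect_true(all(colSums(r) == depth))

  # sample exactly at depth is unchanged
  col <- c(70, 50, 30)
  m2 <- count_matrix(matrix(col, 3, 1,
                            dimnames = list(paste0("t", 1:3), "s1")),
                     "taxon")
  expect_identical(unname(rarefy(m2, 150, seed = 1)[, 1]), as.double(col))

  # all below depth -> empty + warning
  expect_warning(e <- rarefy(m2, 1e6), "below the rarefaction depth")
  expect_identical(ncol(e), 0L)

  # reproducible per seed, different across seeds (same totals though)
  r1 <- suppressWarnings(rarefy(m, depth, seed = 5))
  r2 <- suppressWarnings(rarefy(m, depth, seed = 5))
  expect_identical(unclass(r1), unclass(r2))
})

test_that("rarefaction preserves expected proportions (hypergeometric mean)", {
  col <- c(a = 300, b = 100, c = 600)
  m <- count_matrix(matrix(col, 3, 1, dimnames = list(names(col), "s1")),
                    "taxon")
  depth <- 200
  draws <- vapply(1:500, function(s) rarefy(m, depth, seed = s)[1, 1],
                  numeric(1))
  p_true <- col[["a"]] / sum(col)
  # hypergeometric variance of the count, SE of the mean over 500 seeds
  N <- sum(col); K <- col[["a"]]
  v <- depth * (K / N) * (1 - K / N) * (N - depth) / (N - 1)
  se <- sqrt(v / 500) / depth
  expect_lt(abs(mean(draws) / depth - p_true), 2 * se + 1e-12)
})

test_that("pathway collapse sums members and bins unannotated genes", {
  m <- toy_counts(c(5, 0, 3, 2, 7, 1), nrow = 3, kind = "microbial_gene",
                  features = c("g1", "g2", "g3"))
  ann <- data.frame(gene_id = c("g1", "g2"), pathway_id = c("P", "P"))
  out <- collapse_pathways(m, ann)
  expect_equal(unname(out["P", ]), c(8, 2))
  expect_equal(unname(out["unassigned", ]), c(7, 1))

  # one-to-one mapping: output equals input up to renaming
  ann2 <- data.frame(gene_id = c("g1", "g2", "g3"),
                     pathway_id = c("A", "B", "C"))
  out2 <- collapse_pathways(m, ann2)
  expect_equal(unname(unclass(out2)[c("A", "B", "C"), ]),
               unname(unclass(m)), ignore_attr = TRUE)

  # multi-pathway gene counted once per pathway (total exceeds input)
  ann3 <- data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                     pathway_id = c("P1", "P2", "P1", "P2"))
  out3 <- collapse_pathways(m, ann3)
  expect_equal(unname(out3["P1", ]), c(8, 2))
  expect_equal(unname(out3["P2", ]), c(12, 1))
  expect_gt(sum(out3), sum(m) - sum(m["g3", ]))

  expect_error(collapse_pathways(m, ann[0, ]), "empty annotation")
})
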