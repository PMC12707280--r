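#' Fisher z-transformation
#'
#' \eqn{z = \frac{1}{2}\ln\frac{1+\rho}{1-\rho} = \mathrm{atanh}(\rho)};
#' variance-stabilizes correlation coefficients so two correlations can be
#' compared on a normal scale.
#'
#' @param rho correlation value(s), `|rho| < 1`.
#' @param clamp if `TRUE`, values at or beyond ±1 are clamped to
#'   ±(1 - 1e-7) instead of raising an error.
#' @return transformed value(s).
#' @export
fisher_z <- function(rho, clamp = FALSE) {
  if (any(!is.finite(rho)))
    stop("rho must be finite")
  if (any(abs(rho) >= 1)) {
    if (!clamp) stop("|rho| >= 1: Fisher z undefined (set clamp = TRUE)")
    rho <- pmin(pmax(rho, -(1 - 1e-7)), 1 - 1e-7)
  }
  atanh(rho)
}

#' Cross-kingdom pairwise Spearman correlations
#'
#' Spearman rho (average ranks for ties) for every plant feature x microbial
#' feature pair, over a subset of samples. Intra-kingdom pairs are never
#' formed. Features constant within the subset get `NA` for all their pairs;
#' their count is attached as attribute `"n_constant"` and reported via a
#' message.
#'
#' @param plant,microbe features x samples matrices sharing sample order.
#' @param sample_subset sample ids (or indices) to use; default all.
#' @return matrix of rho, plant features in rows, microbial features in
#'   columns.
#' @export
pairwise_spearman <- function(plant, microbe, sample_subset = NULL) {
  p <- unclass(as.matrix(plant))
  m <- unclass(as.matrix(microbe))
  if (ncol(p) != ncol(m) || !identical(colnames(p), colnames(m)))
    stop("plant and microbe matrices must share sample order")
  if (!is.null(sample_subset)) {
    p <- p[, sample_subset, drop = FALSE]
    m <- m[, sample_subset, drop = FALSE]
  }
  n <- ncol(p)
  if (n < 4) stop("need at least 4 samples")
  rank_rows <- function(x) t(apply(x, 1, rank))
  rp <- rank_rows(p)
  rm_ <- rank_rows(m)
  const_p <- apply(p, 1, function(v) length(unique(v)) == 1)
  const_m <- apply(m, 1, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(stats::cor(t(rp), t(rm_)))
  rho[const_p, ] <- NA_real_
  rho[, const_m] <- NA_real_
  n_const <- sum(const_p) + sum(const_m)
  if (n_const > 0)
    message(sprintf("%d constant feature(s): correlations recorded as NA",
                    n_const))
  attr(rho, "n_constant") <- n_const
  attr(rho, "n_samples") <- n
  rho
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values: \eqn{q_{(i)} = \min_{j \ge i} (m\,p_{(j)}/j)}
#' capped at 1, mapped back to input order.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Fisher-z differential correlation between two conditions
#'
#' The pipeline's core statistic. For every plant x microbial pair: Spearman
#' rho within each condition, Fisher z per condition, \eqn{\Delta z = z_B -
#' z_A} (so positive values mean the association strengthened in condition
#' B, e.g. under heat), standard error assuming independent sampling
#' \eqn{SE = \sqrt{1/(n_A-3) + 1/(n_B-3)}}, two-tailed z-test
#' \eqn{p = 2\,\Phi(-|\Delta z / SE|)}, and BH q-values over all tested
#' pairs. A pair is significant iff `q < q_threshold` and
#' `|delta_z| > dz_threshold`. Pairs with a missing rho in either condition
#' (constant feature) are excluded from testing and from the BH family.
#'
#' Empirical rho of exactly ±1 (possible at finite n) is clamped before the
#' z-transform by default so one degenerate pair does not abort a scan.
#'
#' @param plant,microbe features x samples matrices (shared sample order).
#' @param samples_A,samples_B sample ids/indices per condition, >= 4 each.
#' @param q_threshold FDR threshold (default 0.05).
#' @param dz_threshold minimum `|delta_z|` (default 1).
#' @param clamp passed to [fisher_z()] (default `TRUE`).
#' @return data frame with one row per tested pair: `plant_feature`,
#'   `microbial_feature`, `rho_A`, `rho_B`, `n_A`, `n_B`, `z_A`, `z_B`,
#'   `delta_z`, `se`, `Z_stat`, `p`, `q`, `significant`. The number of
#'   untestable (dropped) pairs is attached as attribute `"n_untestable"`.
#' @export
differential_correlation <- function(plant, microbe, samples_A, samples_B,
                                     q_threshold = 0.05, dz_threshold = 1,
                                     clamp = TRUE) {
  n_A <- length(samples_A)
  n_B <- length(samples_B)
  if (n_A < 4 || n_B < 4)
    stop("each condition needs at least 4 samples")
  rho_A <- suppressMessages(pairwise_spearman(plant, microbe, samples_A))
  rho_B <- suppressMessages(pairwise_spearman(plant, microbe, samples_B))
  tab <- data.frame(
    plant_feature = rep(rownames(rho_A), times = ncol(rho_A)),
    microbial_feature = rep(colnames(rho_A), each = nrow(rho_A)),
    rho_A = as.vector(rho_A),
    rho_B = as.vector(rho_B),
    n_A = n_A, n_B = n_B,
    stringsAsFactors = FALSE
  )
  untestable <- !stats::complete.cases(tab[, c("rho_A", "rho_B")])
  n_untestable <- sum(untestable)
  tab <- tab[!untestable, , drop = FALSE]
  tab$z_A <- fisher_z(tab$rho_A, clamp = clamp)
  tab$z_B <- fisher_z(tab$rho_B, clamp = clamp)
  tab$delta_z <- tab$z_B - tab$z_A
  tab$se <- sqrt(1 / (n_A - 3) + 1 / (n_B - 3))
  tab$Z_stat <- tab$delta_z / tab$se
  # pnorm(lower.tail = FALSE) uses an erfc-based tail: accurate for |Z| >> 8
  tab$p <- 2 * stats::pnorm(abs(tab$Z_stat), lower.tail = FALSE)
  tab$q <- bh_adjust(tab$p)
  tab$significant <- tab$q < q_threshold & abs(tab$delta_z) > dz_threshold
  rownames(tab) <- NULL
  attr(tab, "n_untestable") <- n_untestable
  tab
}

#' Bipartite host-microbe network extraction
#'
#' Edges are cross-kingdom pairs whose correlation exceeds the threshold.
#' Following the positive-only convention of "rho > threshold", only
#' positive correlations form edges by default; set `use_abs = TRUE` to
#' threshold `|rho|` instead. Optionally restricted to a focus feature set
#' (e.g. one microbial pathway) and its partners.
#'
#' @param corr correlation matrix from [pairwise_spearman()] (plant rows,
#'   microbial columns).
#' @param rho_threshold edge threshold (default 0.7).
#' @param restrict_to ids (plant or microbial); when given, only edges
#'   touching these features are kept.
#' @param use_abs threshold `|rho|` rather than signed rho.
#' @param condition optional condition label stamped on every edge.
#' @return list with `edges` (data frame: `plant_feature`,
#'   `microbial_feature`, `condition`, `rho`) and `degree` (named counts
#'   per node).
#' @export
bipartite_network <- function(corr, rho_threshold = 0.7, restrict_to = NULL,
                              use_abs = FALSE, condition = NA_character_) {
  if (length(corr) == 0 || is.null(dim(corr))) {
    return(list(edges = data.frame(plant_feature = character(),
                                   microbial_feature = character(),
                                   condition = character(),
                                   rho = numeric()),
                degree = integer(0)))
  }
  val <- if (use_abs) abs(corr) else corr
  hit <- which(!is.na(val) & val > rho_threshold, arr.ind = TRUE)
  edges <- data.frame(
    plant_feature = rownames(corr)[hit[, 1]],
    microbial_feature = colnames(corr)[hit[, 2]],
    condition = rep(condition, nrow(hit)),
    rho = corr[hit],
    stringsAsFactors = FALSE
  )
  if (!is.null(restrict_to)) {
    keep <- edges$plant_feature %in% restrict_to |
      edges$microbial_feature %in% restrict_to
    edges <- edges[keep, , drop = FALSE]
  }
  rownames(edges) <- NULL
  degree <- table(c(edges$plant_feature, edges$microbial_feature))
  list(edges = edges, degree = c(degree))
}

#' One-tailed hypergeometric overlap test
#'
#' Tests whether the overlap of two feature sets drawn from a common
#' universe is smaller (lower tail) or larger (upper tail) than expected
#' under independence: with \eqn{X \sim}
#' Hypergeometric(N = |universe|, K = |A|, n = |B|), lower-tail
#' \eqn{p = P(X \le k)}, upper-tail \eqn{p = P(X \ge k)}, k = |A ∩ B|.
#'
#' @param set_A,set_B id vectors, both subsets of `universe`.
#' @param universe id vector.
#' @param tail `"lower"` or `"upper"`.
#' @return list with `overlap` (k) and `p`.
#' @export
overlap_hypergeom <- function(set_A, set_B, universe,
                              tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  set_A <- unique(set_A)
  set_B <- unique(set_B)
  universe <- unique(universe)
  if (!all(set_A %in% universe) || !all(set_B %in% universe))
    stop("sets must be contained in the universe")
  k <- length(intersect(set_A, set_B))
  N <- length(universe)
  K <- length(set_A)
  n <- length(set_B)
  p <- if (tail == "lower") {
    stats::phyper(k, K, N - K, n)
  } else {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  list(overlap = k, p = p)
}
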