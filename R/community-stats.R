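#' Euclidean distance between samples
#'
#' Pairwise Euclidean distance over feature values per sample, as used for
#' beta-diversity on CLR-transformed tables (Aitchison distance).
#'
#' @param x `abundance_matrix` (or any features x samples matrix).
#' @return symmetric square matrix with sample ids, zero diagonal.
#' @export
euclidean_distance <- function(x) {
  m <- unclass(as.matrix(x))
  if (any(!is.finite(m))) stop("non-finite values in abundance matrix")
  if (ncol(m) < 2) stop("need at least two samples")
  d <- as.matrix(stats::dist(t(m), method = "euclidean"))
  diag(d) <- 0
  d
}

# Validate / coerce a square distance matrix.
as_distance_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distances must be non-negative")
  d
}

#' Principal component scores
#'
#' PCA of samples on centered feature values (the analysis applied to
#' CLR-transformed microbial expression to visualize transcriptional
#' profiles).
#'
#' @param x features x samples matrix.
#' @param n_components number of components, at most
#'   `min(features, samples - 1)`.
#' @return list with `scores` (samples x components) and
#'   `explained_variance` (proportions, non-increasing).
#' @export
pca_scores <- function(x, n_components = 2L) {
  m <- t(unclass(as.matrix(x)))              # samples x features
  kmax <- min(ncol(m), nrow(m) - 1L)
  if (n_components > kmax)
    stop("n_components exceeds min(features, samples - 1)")
  mc <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(mc) < 1e-12)) stop("matrix is constant; PCA undefined")
  sv <- svd(mc)
  ev <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(n_components)))
  list(scores = scores, explained_variance = ev[seq_len(n_components)])
}

# All permutations of 1..n (exhaustive mode; guarded to small n).
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive permutation only supported for n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

#' Permutational multivariate analysis of variance
#'
#' Sequential (Type-I) partition of the distance matrix's total sum of
#' squares by the given design terms, with significance by permutation of
#' sample labels. The partition follows the Gower-centered inner-product
#' formulation: \eqn{G = -\frac{1}{2} C D^{(2)} C}, `SS_total = tr(G) =`
#' \eqn{\sum d^2 / n}, and each term's SS is the increment in `tr(H G)` as
#' the term's columns join the hat matrix. Pseudo-F uses the residual mean
#' square; permutation p-values use the add-one convention
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}.
#'
#' @param dist square distance matrix (or `dist`) over samples.
#' @param design data frame of sample factors, rows aligned with `dist`.
#' @param terms ordered character vector of design columns; order matters
#'   (sequential sums of squares).
#' @param n_perm number of permutations (default 999), or
#'   `permutations = "exhaustive"` for complete enumeration on small n (p is
#'   then the exact fraction of the n! label orderings with `F* >= F`).
#' @param seed integer seed for the permutation stream.
#' @param permutations `"random"` or `"exhaustive"`.
#' @return data frame with one row per term plus a `Residual` row: `term`,
#'   `df`, `SS`, `R2`, `F`, `p`, `n_perm`, `seed`.
#' @export
permanova <- function(dist, design, terms, n_perm = 999L, seed = 1L,
                      permutations = c("random", "exhaustive")) {
  permutations <- match.arg(permutations)
  d <- as_distance_matrix(dist)
  n <- nrow(d)
  if (nrow(design) != n) stop("design rows must match distance matrix")
  if (!all(terms %in% colnames(design)))
    stop("unknown term(s): ",
         paste(setdiff(terms, colnames(design)), collapse = ", "))
  for (tm in terms) {
    if (length(unique(design[[tm]])) < 2)
      stop(sprintf("term '%s' has fewer than two levels", tm))
  }
  if (permutations == "random" && n_perm < 1) stop("n_perm must be >= 1")

  A <- d^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% A %*% C
  ss_total <- sum(diag(G))

  # Cumulative hat matrices per term (intercept first).
  hats <- vector("list", length(terms))
  dfs <- integer(length(terms))
  X <- matrix(1, n, 1)
  rank_prev <- 1L
  H_prev <- X %*% solve(crossprod(X)) %*% t(X)
  for (k in seq_along(terms)) {
    f <- stats::as.formula(paste("~", paste(terms[seq_len(k)],
                                            collapse = " + ")))
    df_model <- as.data.frame(lapply(design[terms[seq_len(k)]], factor))
    X <- stats::model.matrix(f, df_model)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    H <- tcrossprod(Q)
    hats[[k]] <- H
    dfs[k] <- q$rank - rank_prev
    rank_prev <- q$rank
    H_prev <- H
  }
  H_full <- hats[[length(terms)]]
  df_res <- n - rank_prev

  stat_fun <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss_term <- diff(c(0, tr))
    ss_res <- sum(diag(Gp)) - tr[length(tr)]
    Fv <- (ss_term / dfs) / (ss_res / df_res)
    list(ss = ss_term, ss_res = ss_res, F = Fv)
  }
  obs <- stat_fun(G)

  if (permutations == "exhaustive") {
    perms <- all_permutations(n)
    exceed <- numeric(length(terms))
    for (i in seq_len(nrow(perms))) {
      p <- perms[i, ]
      Fp <- stat_fun(G[p, p])$F
      exceed <- exceed + (Fp >= obs$F - 1e-12)
    }
    pval <- exceed / nrow(perms)
    n_used <- nrow(perms)
  } else {
    set.seed(seed)
    exceed <- numeric(length(terms))
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      Fp <- stat_fun(G[p, p])$F
      exceed <- exceed + (Fp >= obs$F)
    }
    pval <- (1 + exceed) / (1 + n_perm)
    n_used <- n_perm
  }

  data.frame(
    term = c(terms, "Residual"),
    df = c(dfs, df_res),
    SS = c(obs$ss, obs$ss_res),
    R2 = c(obs$ss, obs$ss_res) / ss_total,
    F = c(obs$F, NA_real_),
    p = c(pval, NA_real_),
    n_perm = n_used,
    seed = seed,
    stringsAsFactors = FALSE
  )
}

# Spearman correlation of two numeric vectors (midranks), without the
# overhead of cor(..., method = "spearman") on long loops.
spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

#' Mantel test (Spearman)
#'
#' Association between two distance matrices over the same samples: the
#' statistic is the Spearman correlation of the upper-triangle entries;
#' significance comes from jointly permuting rows and columns of the second
#' matrix. One-sided (greater), add-one p convention.
#'
#' @param d1,d2 square distance matrices with identical sample order.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @return list with `statistic`, `p`, `n_perm`, `seed`.
#' @export
mantel <- function(d1, d2, n_perm = 5000L, seed = 1L) {
  m1 <- as_distance_matrix(d1)
  m2 <- as_distance_matrix(d2)
  if (!identical(dim(m1), dim(m2)))
    stop("distance matrices must have the same samples")
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- nrow(m1)
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  v2 <- m2[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero variance in a distance triangle")
  r1 <- rank(v1)
  obs <- spearman_rho(v1, v2)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    rp <- stats::cor(r1, rank(m2[p, p][ut]))
    if (rp >= obs) exceed <- exceed + 1L
  }
  list(statistic = obs, p = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, seed = seed)
}

#' Platform-comparison slope test
#'
#' Regresses per-taxon mean abundances from an alternative platform on those
#' from a reference platform (OLS with intercept) and tests, one-sided,
#' whether the slope is below the expected value of 1
#' (\eqn{t = (b - 1)/SE(b)}, df = n - 2, \eqn{p = P(T \le t)}). Also reports
#' the Spearman correlation of the paired means. A degenerate noise-free fit
#' (SE = 0) reports p = 0.5 at b = 1, else p = 0 or 1 by the sign of b - 1.
#'
#' @param mean_abund_ref,mean_abund_alt per-taxon mean abundances, same
#'   taxon order, length >= 3.
#' @return list with `slope`, `t`, `p`, `spearman_rho`, `n`.
#' @export
platform_slope_test <- function(mean_abund_ref, mean_abund_alt) {
  x <- as.numeric(mean_abund_ref)
  y <- as.numeric(mean_abund_alt)
  if (length(x) != length(y)) stop("mismatched taxon vectors")
  n <- length(x)
  if (n < 3) stop("need at least three shared taxa")
  if (stats::sd(x) == 0) stop("zero variance in reference means")
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit)[2])
  se <- sqrt(sum(stats::residuals(fit)^2) / (n - 2) / sum((x - mean(x))^2))
  if (se < .Machine$double.eps^0.75) {
    tstat <- if (abs(b - 1) < 1e-12) 0 else sign(b - 1) * Inf
  } else {
    tstat <- (b - 1) / se
  }
  p <- stats::pt(tstat, df = n - 2)
  list(slope = b, t = tstat, p = p,
       spearman_rho = spearman_rho(x, y), n = n)
}
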