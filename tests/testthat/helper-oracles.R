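# Independent brute-force oracles. These deliberately avoid the package's
# code paths: midranks are computed by explicit enumeration, Pearson by the
# sum formulas, and rejection sets / F statistics from first principles.

# midranks without rank(): average position among sorted values
oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    less + (eq + 1) / 2
  }, numeric(1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_spearman <- function(x, y)
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))

# BH as a rejection set: largest j with p_(j) <= j * alpha / m
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * alpha / m)
  if (length(ok) == 0) return(logical(m))
  reject <- logical(m)
  reject[o[seq_len(max(ok))]] <- TRUE
  reject
}

# classical one-way F from group centroids in Euclidean coordinate space
oracle_oneway_F <- function(coords, groups) {
  groups <- as.character(groups)
  n <- nrow(coords)
  k <- length(unique(groups))
  grand <- colMeans(coords)
  ssw <- 0; ssb <- 0
  for (g in unique(groups)) {
    sub <- coords[groups == g, , drop = FALSE]
    cen <- colMeans(sub)
    ssw <- ssw + sum(sweep(sub, 2, cen)^2)
    ssb <- ssb + nrow(sub) * sum((cen - grand)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# lower-tail hypergeometric by direct combinatorics
oracle_hyper_lower <- function(k, N, K, n) {
  sum(vapply(0:k, function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n), numeric(1)))
}

# small labelled count matrix builder
toy_counts <- function(values, nrow, kind = "plant_gene",
                       features = NULL, samples = NULL) {
  m <- matrix(values, nrow = nrow, byrow = TRUE)
  rownames(m) <- features %||% paste0("f", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  count_matrix(m, kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared-sample matrix pair for correlation tests
toy_pair <- function(plant_rows, microbe_rows) {
  ns <- length(plant_rows[[1]])
  p <- do.call(rbind, plant_rows)
  m <- do.call(rbind, microbe_rows)
  dimnames(p) <- list(paste0("p", seq_len(nrow(p))), paste0("s", seq_len(ns)))
  dimnames(m) <- list(paste0("m", seq_len(nrow(m))), paste0("s", seq_len(ns)))
  list(plant = p, microbe = m)
}
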