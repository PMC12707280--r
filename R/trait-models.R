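#' Univariate prefilter for trait modeling
#'
#' Retains features whose absolute Spearman correlation with the response
#' exceeds `rho_min` (default 0.05 — a deliberately weak bar whose purpose
#' is dimensionality reduction, not discovery). Constant features are
#' dropped.
#'
#' @param features features x samples matrix.
#' @param trait numeric response, one value per sample.
#' @param rho_min retention threshold on `|rho|`.
#' @return character vector of retained feature ids.
#' @export
univariate_prefilter <- function(features, trait, rho_min = 0.05) {
  m <- unclass(as.matrix(features))
  if (length(trait) != ncol(m))
    stop("trait length must match sample count")
  if (ncol(m) < 4) stop("need at least 4 samples")
  if (stats::sd(trait) == 0) stop("constant trait: correlations undefined")
  rt <- rank(trait)
  keep <- vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    if (length(unique(v)) == 1) return(FALSE)
    abs(stats::cor(rank(v), rt)) > rho_min
  }, logical(1))
  rownames(m)[keep]
}

#' Elastic-net trait association
#'
#' Penalized regression with a mixed L1/L2 penalty (`alpha_mix = 0.5` gives
#' the 50:50 mixture). Features are standardized (mean 0, sd 1), the
#' regularization parameter is chosen by k-fold cross-validation with a
#' fold assignment fixed by `seed`, and features with nonzero coefficients
#' at the chosen lambda are returned with sign and magnitude.
#'
#' @param X samples x features numeric matrix (column names = feature ids).
#' @param y numeric response.
#' @param alpha_mix elastic-net mixing parameter in `[0, 1]` (default 0.5).
#' @param folds number of CV folds (default 10); requires `n >= folds`.
#' @param seed integer seed fixing the fold assignment.
#' @param lambda_rule `"min"` (minimum CV error, default) or `"1se"`.
#' @return data frame with `feature` and `coefficient` for nonzero terms
#'   (empty for a constant response); chosen lambda attached as attribute
#'   `"lambda"`.
#' @export
elastic_net_associate <- function(X, y, alpha_mix = 0.5, folds = 10L,
                                  seed = 1L, lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("response length must match rows of X")
  if (n < folds) stop("fewer samples than folds")
  if (stats::sd(y) == 0) {
    out <- data.frame(feature = character(), coefficient = numeric())
    attr(out, "lambda") <- NA_real_
    return(out)
  }
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  Xs <- scale(X)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), n))
  cvfit <- glmnet::cv.glmnet(Xs, y, alpha = alpha_mix, foldid = foldid,
                             standardize = FALSE)
  lam <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  cf <- as.matrix(stats::coef(cvfit, s = lam))[-1, 1]
  nz <- cf[cf != 0]
  out <- data.frame(feature = names(nz), coefficient = unname(nz),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lambda") <- lam
  out
}

#' Random-forest trait association
#'
#' Regression forest (bagged CART with per-node feature subsampling) ranking
#' features by mean decrease in node impurity. The top `top_k` features are
#' retained per feature-type stratum (e.g. plant genes and microbial
#' pathways ranked separately) when `feature_type` is supplied.
#'
#' @param X samples x features numeric matrix (column names = feature ids).
#' @param y numeric response.
#' @param n_trees number of trees (default 2000).
#' @param top_k features retained per stratum (default 25). If a stratum has
#'   fewer features, all are returned with a warning.
#' @param feature_type optional character vector (one per feature) defining
#'   strata; default one stratum.
#' @param mtry features tried per split; default `max(floor(p/3), 1)`.
#' @param min_node minimum node size (default 5).
#' @param seed integer seed.
#' @return data frame with `feature`, `type`, `importance`, `rank` (rank
#'   within stratum), sorted by stratum then importance; out-of-bag
#'   predictions attached as attribute `"oob_prediction"`.
#' @export
random_forest_associate <- function(X, y, n_trees = 2000L, top_k = 25L,
                                    feature_type = NULL, mtry = NULL,
                                    min_node = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("response length must match rows of X")
  if (n < 5) stop("need at least 5 samples")
  if (is.null(mtry)) mtry <- max(floor(p / 3), 1L)
  if (is.null(feature_type)) feature_type <- rep("feature", p)
  if (length(feature_type) != p)
    stop("feature_type must have one entry per feature")
  set.seed(seed)
  fit <- rf_regression_cpp(X, as.numeric(y), as.integer(n_trees),
                           as.integer(mtry), as.integer(min_node))
  imp <- data.frame(feature = colnames(X), type = feature_type,
                    importance = fit$importance, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(imp, imp$type), function(d) {
    d <- d[order(-d$importance), , drop = FALSE]
    if (top_k > nrow(d))
      warning(sprintf("top_k (%d) exceeds available features (%d) in '%s'",
                      top_k, nrow(d), d$type[1]))
    d <- d[seq_len(min(top_k, nrow(d))), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(out) <- NULL
  attr(out, "oob_prediction") <- fit$oob_prediction
  out
}

#' Cross-method consensus of trait-associated features
#'
#' Compiles the per-method hit sets (differential correlation, elastic net,
#' random forest) for each trait and selects features identified by at least
#' `min_methods` methods. Also tallies, per feature, the total number of
#' (method, trait) cells in which it appears — the "k of methods x traits
#' tests" count.
#'
#' @param sets_by_trait named list: trait -> named list: method -> character
#'   vector of feature ids. Methods must be among `diffcorr`, `elastic_net`,
#'   `random_forest`.
#' @param min_methods selection threshold (default 2).
#' @param feature_types optional named character vector mapping feature id
#'   to type (plant gene / microbial pathway / microbial gene).
#' @return list with `table` (feature, type, trait, methods_hit, n_hits,
#'   selected) and `tally` (feature, total_hits, n_tests).
#' @export
#' @examples
#' consensus_features(list(biomass = list(
#'   diffcorr = c("A", "B"), elastic_net = c("B", "C"),
#'   random_forest = "B")))$table
consensus_features <- function(sets_by_trait, min_methods = 2L,
                               feature_types = NULL) {
  if (length(sets_by_trait) == 0) stop("empty trait map")
  allowed <- c("diffcorr", "elastic_net", "random_forest")
  rows <- list()
  for (trait in names(sets_by_trait)) {
    sets <- sets_by_trait[[trait]]
    if (length(sets) == 0) stop("empty method map for trait ", trait)
    if (!all(names(sets) %in% allowed))
      stop("unknown method(s): ",
           paste(setdiff(names(sets), allowed), collapse = ", "))
    feats <- unique(unlist(sets, use.names = FALSE))
    if (length(feats) == 0) next
    hit <- vapply(names(sets),
                  function(m) feats %in% sets[[m]],
                  logical(length(feats)))
    hit <- matrix(hit, nrow = length(feats),
                  dimnames = list(feats, names(sets)))
    rows[[trait]] <- data.frame(
      feature = feats,
      trait = trait,
      methods_hit = apply(hit, 1, function(h)
        paste(colnames(hit)[h], collapse = ",")),
      n_hits = rowSums(hit),
      stringsAsFactors = FALSE
    )
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), trait = character(),
               methods_hit = character(), n_hits = integer())
  tab$selected <- tab$n_hits >= min_methods
  tab$type <- if (is.null(feature_types)) NA_character_ else
    unname(feature_types[tab$feature])
  tab <- tab[, c("feature", "type", "trait", "methods_hit", "n_hits",
                 "selected")]
  rownames(tab) <- NULL

  n_tests <- sum(vapply(sets_by_trait, length, integer(1)))
  tally <- stats::aggregate(n_hits ~ feature, data = tab, FUN = sum)
  names(tally)[2] <- "total_hits"
  tally$n_tests <- n_tests
  tally <- tally[order(-tally$total_hits, tally$feature), ]
  rownames(tally) <- NULL
  list(table = tab, tally = tally)
}
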