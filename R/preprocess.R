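#' Low-expression filter
#'
#' Retains exactly the features having at least `min_count` reads in at least
#' `min_samples` samples. This is the rule applied to plant genes (75 reads in
#' 4 samples) and, with a (250, 3) rule, to microbial genes before modeling.
#'
#' @param counts a [count_matrix()].
#' @param min_count minimum reads a sample must contribute (>= 0).
#' @param min_samples minimum number of qualifying samples (>= 0).
#' @return filtered `count_matrix`; the sample set and feature order are
#'   unchanged. If nothing survives, an empty matrix is returned with a
#'   warning.
#' @export
#' @examples
#' m <- count_matrix(matrix(c(80, 80, 80, 80, 0,
#'                            80, 80, 80, 0, 0), 2, 5, byrow = TRUE,
#'                   dimnames = list(c("a", "b"), paste0("s", 1:5))),
#'                   "plant_gene")
#' filter_low_expression(m, 75, 4)   # keeps "a" only
filter_low_expression <- function(counts, min_count, min_samples) {
  stopifnot(inherits(counts, "count_matrix"))
  if (min_count < 0 || min_samples < 0)
    stop("filter rule requires min_count >= 0 and min_samples >= 0")
  keep <- rowSums(counts >= min_count) >= min_samples
  if (!any(keep))
    warning("no features pass the filter; returning an empty matrix")
  out <- unclass(counts)[keep, , drop = FALSE]
  structure(out, kind = attr(counts, "kind"),
            class = c("count_matrix", class(matrix())))
}

#' Rare-taxon filter
#'
#' Drops low-abundance and rare taxa from an amplicon-style table: a taxon is
#' kept iff it is present (count > 0) in at least two samples AND has at
#' least 10 reads in at least two samples.
#'
#' @param counts a `count_matrix` of kind `"taxon"`.
#' @param min_reads read threshold (default 10).
#' @param min_samples sample threshold (default 2).
#' @return filtered `count_matrix`.
#' @export
filter_taxa <- function(counts, min_reads = 10, min_samples = 2) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!identical(feature_kind(counts), "taxon"))
    stop("filter_taxa expects a taxon table")
  present <- rowSums(counts > 0) >= min_samples
  abundant <- rowSums(counts >= min_reads) >= min_samples
  out <- unclass(counts)[present & abundant, , drop = FALSE]
  structure(out, kind = "taxon", class = c("count_matrix", class(matrix())))
}

#' Relative abundance (total-sum scaling)
#'
#' @param counts a `count_matrix`.
#' @return [abundance_matrix()] with transform `"relative"`; every column
#'   sums to 1.
#' @export
relative_abundance <- function(counts) {
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    stop("sample(s) with zero total counts: ", paste(bad, collapse = ", "))
  }
  abundance_matrix(sweep(unclass(counts), 2, totals, "/"), "relative")
}

#' Centered log-ratio transform
#'
#' Per sample j: \eqn{clr(x)_i = \ln(x_{ij} + pc) - \frac{1}{p}\sum_k
#' \ln(x_{kj} + pc)}. Because the CLR is invariant to per-sample scaling,
#' applying it to raw counts or to relative abundances gives the same result
#' (for matching pseudocount handling), which the tests demonstrate.
#'
#' @param x `count_matrix` or `abundance_matrix`.
#' @param pseudocount added before taking logs. Default 0.5 when zeros are
#'   present, 0 otherwise. Must be > 0 if any zero is present.
#' @return `abundance_matrix` with transform `"clr"`; columns sum to 0
#'   (within 1e-9).
#' @export
clr_transform <- function(x, pseudocount = NULL) {
  m <- unclass(as.matrix(x))
  if (is.null(pseudocount))
    pseudocount <- if (any(m == 0)) 0.5 else 0
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (any(m + pseudocount <= 0))
    stop("non-positive values present; supply a positive pseudocount")
  lx <- log(m + pseudocount)
  out <- sweep(lx, 2, colMeans(lx), "-")
  abundance_matrix(out, "clr")
}

#' Median-of-ratios normalization
#'
#' Size factor for sample j is the median, over reference features i (those
#' with positive counts in every sample), of \eqn{k_{ij} / g_i} where
#' \eqn{g_i} is feature i's geometric mean across samples. Size factors are
#' rescaled so their geometric mean is 1; normalized values are
#' \eqn{k_{ij} / s_j}.
#'
#' @param counts a `count_matrix`.
#' @return list with `matrix` (an `abundance_matrix`, transform
#'   `"median_ratio"`) and `size_factors` (named per sample).
#' @export
median_ratio_normalize <- function(counts) {
  m <- unclass(as.matrix(counts))
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("no reference feature with positive counts in every sample")
  logm <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(logm)
  s <- apply(logm - loggeo, 2, function(v) exp(stats::median(v)))
  s <- s / exp(mean(log(s)))          # geometric mean of size factors = 1
  norm <- sweep(m, 2, s, "/")
  list(matrix = abundance_matrix(norm, "median_ratio"), size_factors = s)
}

#' Rarefy samples to a common depth
#'
#' Each sample is subsampled without replacement to exactly `depth` total
#' reads; samples whose total is below `depth` are dropped with a warning.
#'
#' @param counts a `count_matrix`.
#' @param depth target total per sample (>= 1).
#' @param seed integer seed; subsampling is reproducible per seed.
#' @return rarefied `count_matrix` (possibly with fewer samples).
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  m <- unclass(as.matrix(counts))
  totals <- colSums(m)
  keep <- totals >= depth
  if (!any(keep)) {
    warning("all samples are below the rarefaction depth")
    out <- m[, keep, drop = FALSE]
    return(structure(out, kind = attr(counts, "kind"),
                     class = c("count_matrix", class(matrix()))))
  }
  if (any(!keep))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(colnames(m)[!keep], collapse = ", ")))
  m <- m[, keep, drop = FALSE]
  set.seed(seed)
  nf <- nrow(m)
  for (j in seq_len(ncol(m))) {
    if (totals[keep][j] == depth) next      # already at depth: unchanged
    pool <- rep.int(seq_len(nf), m[, j])
    draw <- sample(pool, depth, replace = FALSE)
    m[, j] <- tabulate(draw, nbins = nf)
  }
  structure(m, kind = attr(counts, "kind"),
            class = c("count_matrix", class(matrix())))
}

#' Collapse gene counts into pathways
#'
#' Pathway count = sum of member-gene counts per sample. A gene mapping to
#' several pathways contributes to each (so the output total can exceed the
#' input total). Genes absent from the mapping are aggregated into an
#' `"unassigned"` bin, which is kept and reportable.
#'
#' @param counts a `count_matrix` of kind `"microbial_gene"`.
#' @param annotation data frame with columns `gene_id`, `pathway_id` (a gene
#'   may appear on several rows).
#' @return `count_matrix` of kind `"pathway"`.
#' @export
collapse_pathways <- function(counts, annotation) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!identical(feature_kind(counts), "microbial_gene"))
    stop("collapse_pathways expects a microbial gene table")
  if (is.null(annotation) || nrow(annotation) == 0)
    stop("empty annotation mapping")
  ann <- annotation[annotation$gene_id %in% rownames(counts), , drop = FALSE]
  m <- unclass(as.matrix(counts))
  paths <- sort(unique(as.character(ann$pathway_id)))
  out <- matrix(0, length(paths), ncol(m),
                dimnames = list(paths, colnames(m)))
  for (p in paths) {
    g <- unique(ann$gene_id[ann$pathway_id == p])
    out[p, ] <- colSums(m[g, , drop = FALSE])
  }
  unmapped <- setdiff(rownames(m), unique(ann$gene_id))
  if (length(unmapped)) {
    out <- rbind(out, unassigned = colSums(m[unmapped, , drop = FALSE]))
  }
  count_matrix(out, "pathway")
}
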