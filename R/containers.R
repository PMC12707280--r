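#' Construct a count matrix
#'
#' A count matrix is the package's basic container for read counts: a
#' non-negative integer matrix with features in rows and samples in columns,
#' tagged with the kind of feature it holds. All preprocessing operations
#' consume and return this class.
#'
#' @param x numeric matrix of non-negative integers, features x samples, with
#'   unique row and column names.
#' @param kind one of `"plant_gene"`, `"microbial_gene"`, `"pathway"`,
#'   `"taxon"`.
#' @return an object of class `count_matrix` (a base matrix with a `kind`
#'   attribute).
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' count_matrix(m, "plant_gene")
count_matrix <- function(x, kind = c("plant_gene", "microbial_gene",
                                     "pathway", "taxon")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("count matrix needs at least one feature and one sample")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count matrix requires feature (row) and sample (column) names")
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop("feature and sample ids must be unique")
  if (any(!is.finite(x)) || any(x < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(x - round(x)) > 1e-8))
    stop("counts must be integers")
  storage.mode(x) <- "double"
  structure(x, kind = kind, class = c("count_matrix", class(matrix())))
}

#' Construct an abundance matrix
#'
#' Real-valued transformed matrix (features x samples) carrying the transform
#' that produced it, so downstream stages can check they receive data on the
#' scale they expect.
#'
#' @param x numeric matrix, features x samples, named.
#' @param transform one of `"relative"`, `"clr"`, `"median_ratio"`, `"raw"`.
#' @return an object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(x, transform = c("relative", "clr",
                                              "median_ratio", "raw")) {
  transform <- match.arg(transform)
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance matrix requires feature and sample names")
  if (any(!is.finite(x)))
    stop("abundance values must be finite")
  storage.mode(x) <- "double"
  structure(x, transform = transform,
            class = c("abundance_matrix", class(matrix())))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d features x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix [%s]: %d features x %d samples\n",
              attr(x, "transform"), nrow(x), ncol(x)))
  invisible(x)
}

# Subsetting follows base-matrix semantics (including drop); the class and
# tag are preserved only while the result is still a matrix.
#' @export
`[.count_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, kind = attr(x, "kind"),
                     class = c("count_matrix", class(matrix())))
  out
}

#' @export
`[.abundance_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, transform = attr(x, "transform"),
                     class = c("abundance_matrix", class(matrix())))
  out
}

feature_kind <- function(x) attr(x, "kind")
transform_tag <- function(x) attr(x, "transform")

# Coerce a plain matrix-with-names into the container when a user passes one.
as_count_matrix <- function(x, kind) {
  if (inherits(x, "count_matrix")) return(x)
  count_matrix(x, kind)
}

#' Read a feature table from TSV/CSV
#'
#' Expects the first column to hold feature ids and the header to hold sample
#' ids (the layout `write_matrix()` produces). Comment lines starting with
#' `#` are skipped.
#'
#' @param path file path.
#' @param kind feature kind for [count_matrix()], or `NULL` to return a plain
#'   numeric matrix.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return `count_matrix` (or plain matrix when `kind` is `NULL`).
#' @export
read_matrix <- function(path, kind = NULL, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (is.null(kind)) m else count_matrix(m, kind)
}

#' Write a feature table as TSV
#'
#' First column = feature id, header = sample ids. An optional commented
#' header block records provenance (transform tags, thresholds, seeds) so
#' outputs are self-describing.
#'
#' @param x matrix with row and column names.
#' @param path output path.
#' @param header optional character vector written as `# `-prefixed lines.
#' @export
write_matrix <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  df <- data.frame(feature_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
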