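#' Construct a labelled distance matrix
#'
#' The common currency of the congruence tests: a symmetric, zero-diagonal
#' matrix of non-negative dissimilarities with unique isolate labels.
#'
#' @param values Square numeric matrix.
#' @param labels Character labels; taken from `rownames(values)` if missing.
#' @return An object of class `dist_matrix` (a labelled numeric matrix).
#' @export
dist_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) stop("labels required")
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels")
  n <- length(labels)
  if (!all(dim(values) == c(n, n))) stop("matrix size does not match labels")
  if (any(values < 0)) stop("distances must be non-negative")
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero")
  if (any(abs(values - t(values)) > 1e-9 * (1 + abs(values)))) {
    stop("distance matrix is not symmetric")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix over %d labels\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

dm_labels <- function(d) rownames(d)

#' Restrict a distance matrix to a label subset (in the given order)
#' @param d A `dist_matrix`.
#' @param labels Labels to keep.
#' @return A `dist_matrix`.
#' @export
subset_dist <- function(d, labels) {
  idx <- match(labels, dm_labels(d))
  if (anyNA(idx)) stop("unknown labels: ", paste(labels[is.na(idx)], collapse = ", "))
  dist_matrix(unclass(d)[idx, idx, drop = FALSE], labels)
}

#' Upper-triangle vector of a distance matrix
#' @param d A `dist_matrix`.
#' @return Numeric vector of the n(n-1)/2 off-diagonal entries (column-major
#'   upper triangle), the vectorisation used by all correlation-type tests.
#' @export
upper_tri_values <- function(d) {
  m <- unclass(d)
  m[upper.tri(m)]
}

#' Write a distance matrix as labelled square TSV
#'
#' Values are written with enough digits that `read_distance_matrix()`
#' reproduces them to at least 10 significant digits. Labels are written
#' verbatim (tab is the only separator, so labels may contain spaces).
#'
#' @param d A `dist_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  labs <- dm_labels(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", labs), collapse = "\t"), con)
  m <- unclass(d)
  for (i in seq_along(labs)) {
    writeLines(paste(c(labs[i], format(m[i, ], digits = 15, trim = TRUE,
                                       scientific = TRUE)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#' @param path Input TSV.
#' @return A `dist_matrix`; asymmetric input is an error.
#' @export
read_distance_matrix <- function(path) {
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  header <- fields[[1]][-1]
  n <- length(header)
  rows <- fields[-1]
  if (length(rows) != n) stop("distance matrix file is not square")
  m <- matrix(NA_real_, n, n)
  row_labs <- character(n)
  for (i in seq_len(n)) {
    if (length(rows[[i]]) != n + 1L) stop("row ", i, " has wrong column count")
    row_labs[i] <- rows[[i]][1]
    m[i, ] <- as.numeric(rows[[i]][-1])
  }
  if (!identical(row_labs, header)) stop("row and column labels disagree")
  if (any(abs(m - t(m)) > 1e-9 * (1 + abs(m)))) stop("asymmetric distance matrix in ", path)
  dist_matrix(m, header)
}

#' Serialise a dendrogram to Newick
#'
#' Writes an `hclust` dendrogram (as produced by [ward_dendrogram()]) as a
#' Newick string in which each branch length is the difference between the
#' parent merge height and the child's own height (leaves sit at height 0),
#' so a two-leaf dendrogram merging at height `h` becomes `(A:h,B:h);`.
#'
#' @param dendrogram An `hclust` object.
#' @param path Output file.
#' @return The Newick string, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  if (!inherits(dendrogram, "hclust")) stop("dendrogram must be an hclust object")
  labs <- dendrogram$labels
  if (is.null(labs) || length(labs) < 2L) stop("empty or single-leaf dendrogram")
  merge <- dendrogram$merge
  height <- dendrogram$height
  node_str <- function(node) {
    # node < 0: leaf index; node > 0: merge row
    if (node < 0) {
      list(str = quote_newick(labs[-node]), h = 0)
    } else {
      l <- node_str(merge[node, 1])
      r <- node_str(merge[node, 2])
      h <- height[node]
      list(str = sprintf("(%s:%.10g,%s:%.10g)", l$str, h - l$h, r$str, h - r$h),
           h = h)
    }
  }
  root <- node_str(nrow(merge))
  nwk <- paste0(root$str, ";")
  writeLines(nwk, path)
  invisible(nwk)
}

quote_newick <- function(lab) {
  if (grepl("[ ():,;'\\[\\]]", lab)) {
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  } else {
    lab
  }
}
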