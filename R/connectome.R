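#' Construct a connectome
#'
#' A connectome is a weighted, undirected brain network: nodes are atlas
#' regions (84 in the Desikan-Killiany parcellation commonly used for
#' structural connectomes) and edge weights count tractography streamlines
#' between regions. The object stores a symmetric nonnegative matrix with a
#' zero diagonal plus ordered node labels.
#'
#' @param weights square numeric matrix of nonnegative edge weights.
#' @param node_labels character vector of region names; defaults to
#'   `"node_1" ... "node_n"` or the matrix dimnames when present.
#' @param symmetrize if `TRUE`, small asymmetries (relative magnitude at most
#'   `asym_tol`) are averaged out as `(w + t(w)) / 2`; larger asymmetries are
#'   an error, since a structural connectome is undirected by construction.
#' @param asym_tol relative asymmetry tolerance before symmetrizing.
#' @return an object of class `"connectome"` with elements `weights`,
#'   `node_labels` and `n`.
#' @export
connectome <- function(weights, node_labels = NULL, symmetrize = TRUE,
                       asym_tol = 1e-6) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix", call. = FALSE)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop(sprintf("connectome matrix must be square, got %d x %d",
                 n, ncol(weights)), call. = FALSE)
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("connectome weights must be finite and non-missing", call. = FALSE)
  if (any(weights < 0))
    stop("connectome weights must be nonnegative", call. = FALSE)

  asym <- max(abs(weights - t(weights)))
  scale <- max(abs(weights), 1)
  if (asym > 0) {
    if (asym / scale > asym_tol || !symmetrize)
      stop(sprintf(
        "matrix asymmetry %.3g exceeds relative tolerance %.1g; data corrupt?",
        asym, asym_tol), call. = FALSE)
    weights <- (weights + t(weights)) / 2
  }
  diag(weights) <- 0

  if (is.null(node_labels)) {
    node_labels <- rownames(weights)
    if (is.null(node_labels)) node_labels <- paste0("node_", seq_len(n))
  }
  if (length(node_labels) != n)
    stop("length(node_labels) must equal the node count", call. = FALSE)
  dimnames(weights) <- NULL

  structure(list(weights = weights, node_labels = as.character(node_labels),
                 n = n),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  pos <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<connectome> %d nodes, %d edges, total weight %.4g\n",
              x$n, pos, sum(x$weights) / 2))
  invisible(x)
}

is_connectome <- function(x) inherits(x, "connectome")

#' Read a connectome matrix from delimited text
#'
#' Reads an `n x n` square matrix of streamline counts as written by
#' connectome-construction tools such as MRtrix `tck2connectome`
#' (comma- or whitespace-delimited, no header). The matrix is validated,
#' lightly symmetrized (averaging, within a relative tolerance of 1e-6) and
#' its diagonal zeroed.
#'
#' @param path path to the matrix file.
#' @param delimiter `"auto"` (default), `"comma"` or `"whitespace"`.
#' @return a [connectome()].
#' @export
read_connectome <- function(path, delimiter = c("auto", "comma", "whitespace")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path))
    stop(sprintf("connectome file not found: %s", path), call. = FALSE)
  if (delimiter == "auto") {
    first <- readLines(path, n = 1L)
    delimiter <- if (grepl(",", first, fixed = TRUE)) "comma" else "whitespace"
  }
  sep <- if (delimiter == "comma") "," else ""
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           strip.white = TRUE, colClasses = "numeric")
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m))
    stop(sprintf("connectome file %s is not square (%d x %d)",
                 path, nrow(m), ncol(m)), call. = FALSE)
  connectome(m)
}

#' Write a connectome matrix as delimited text
#'
#' @param conn a [connectome()].
#' @param path output file path.
#' @param delimiter `"comma"` or `"whitespace"`.
#' @export
write_connectome <- function(conn, path, delimiter = c("comma", "whitespace")) {
  stopifnot(is_connectome(conn))
  delimiter <- match.arg(delimiter)
  sep <- if (delimiter == "comma") "," else " "
  utils::write.table(conn$weights, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Filter weak connections
#'
#' Removes edges carrying fewer streamlines than a fixed fraction of the
#' total streamline count of the tractogram: with the conventional 10 million
#' generated streamlines and the default fraction 1e-7 (i.e. 0.00001%), the
#' cutoff is one streamline. An edge is removed when its weight is strictly
#' below the cutoff; equality is retained.
#'
#' @param conn a [connectome()].
#' @param total_streamlines total streamlines generated by tractography
#'   (default 1e7).
#' @param fraction fraction of `total_streamlines` defining the cutoff
#'   (default 1e-7).
#' @return the thresholded [connectome()].
#' @export
threshold_connectome <- function(conn, total_streamlines = 1e7,
                                 fraction = 1e-7) {
  stopifnot(is_connectome(conn))
  if (!is.numeric(total_streamlines) || length(total_streamlines) != 1 ||
      total_streamlines <= 0)
    stop("`total_streamlines` must be a positive number", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  cutoff <- fraction * total_streamlines
  w <- conn$weights
  w[w < cutoff] <- 0
  conn$weights <- w
  conn
}

#' Flatten a connectome to its upper-triangle feature vector
#'
#' The model consumes the strict upper triangle in row-major order, of length
#' `n(n-1)/2` (3486 for the 84-node atlas). `devectorize()` inverts the map,
#' rebuilding a symmetric zero-diagonal matrix.
#'
#' @param conn a [connectome()].
#' @return numeric vector of length `n(n-1)/2`.
#' @export
vectorize <- function(conn) {
  stopifnot(is_connectome(conn))
  # row-major upper triangle == column-major lower triangle of the transpose;
  # the matrix is symmetric, so lower.tri in column-major order suffices
  conn$weights[lower.tri(conn$weights)]
}

#' @rdname vectorize
#' @param vec upper-triangle vector as produced by `vectorize()`.
#' @param n node count.
#' @param node_labels optional region names for the rebuilt connectome.
#' @export
devectorize <- function(vec, n, node_labels = NULL) {
  expected <- n * (n - 1) / 2
  if (length(vec) != expected)
    stop(sprintf("expected a vector of length %d for n = %d, got %d",
                 expected, n, length(vec)), call. = FALSE)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- vec
  m <- m + t(m)
  connectome(m, node_labels = node_labels)
}
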