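#' Sparse symmetric connectivity matrix
#'
#' The package's core container: an undirected, weighted or binary graph over
#' `n_nodes` nodes, stored as the strict upper triangle of a symmetric matrix
#' with a zero diagonal. It plays every matrix role in the pipeline: an
#' individual connectome, the group consistency index, its distance-normalized
#' form, the binarized anatomical structure, the spatial structure, and the
#' final clustering topology.
#'
#' Node indices are 1-based (the R convention); Matrix Market files on disk are
#' also 1-based, so disk indices are used verbatim.
#'
#' @param i,j Integer vectors of node indices for each edge. Order within a
#'   pair is irrelevant; pairs are canonicalized to `i < j`.
#' @param w Numeric edge weights, recycled if scalar. Ignored (forced to 1)
#'   when `binary = TRUE`.
#' @param n_nodes Total number of nodes.
#' @param binary Logical; if `TRUE` all weights are exactly 1.
#' @return An object of class `conn_matrix` with fields `i`, `j`, `w`
#'   (parallel vectors, `i < j`), `n_nodes` and `binary`.
#' @examples
#' m <- conn_matrix(c(1, 1), c(2, 3), c(0.5, 1), n_nodes = 4)
#' conn_density(m)
#' @export
conn_matrix <- function(i, j, w = 1, n_nodes, binary = FALSE) {
  i <- as.integer(i)
  j <- as.integer(j)
  stopifnot(length(i) == length(j))
  if (length(w) == 1L) w <- rep(as.numeric(w), length(i)) else w <- as.numeric(w)
  stopifnot(length(w) == length(i))
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1L)
    stop("n_nodes must be a positive integer", call. = FALSE)
  if (length(i) > 0L) {
    if (anyNA(i) || anyNA(j) || min(i, j) < 1L || max(i, j) > n_nodes)
      stop("edge indices out of range [1, n_nodes]", call. = FALSE)
    self <- i == j
    if (any(self)) {
      warning("dropping ", sum(self), " self-edge(s); the diagonal is zero by construction")
      i <- i[!self]; j <- j[!self]; w <- w[!self]
    }
    swap <- i > j
    if (any(swap)) {
      tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    }
    key <- (i - 1) * as.double(n_nodes) + j
    if (anyDuplicated(key)) {
      dup <- duplicated(key)
      agree <- vapply(which(dup), function(k) {
        first <- which(key == key[k])[1L]
        isTRUE(all.equal(w[first], w[k]))
      }, logical(1))
      if (!all(agree))
        stop("duplicate edges with conflicting weights", call. = FALSE)
      i <- i[!dup]; j <- j[!dup]; w <- w[!dup]
      key <- key[!dup]
    }
    ord <- order(key)
    i <- i[ord]; j <- j[ord]; w <- w[ord]
  }
  if (binary) w <- rep(1, length(i))
  if (any(w == 0)) { # explicit zeros are non-edges
    keep <- w != 0
    i <- i[keep]; j <- j[keep]; w <- w[keep]
  }
  structure(list(i = i, j = j, w = w, n_nodes = n_nodes, binary = binary),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %d nodes, %d edges (%s), density %.4g\n",
              x$n_nodes, length(x$i), if (x$binary) "binary" else "weighted",
              conn_density(x)))
  invisible(x)
}

#' Edge density of a connectivity matrix
#'
#' Fraction of possible undirected node pairs carrying an edge:
#' `2 |E| / (n (n - 1))`.
#'
#' @param m A [conn_matrix].
#' @return A number in `[0, 1]`.
#' @export
conn_density <- function(m) {
  stopifnot(inherits(m, "conn_matrix"))
  n <- as.double(m$n_nodes)
  if (n < 2) return(0)
  2 * length(m$i) / (n * (n - 1))
}

#' Number of edges
#' @param m A [conn_matrix].
#' @return Integer edge count.
#' @export
conn_n_edges <- function(m) {
  stopifnot(inherits(m, "conn_matrix"))
  length(m$i)
}

#' Convert to a symmetric sparse 'Matrix' object
#'
#' Expands the stored upper triangle into a full symmetric sparse matrix for
#' linear algebra (e.g. kernel smoothing).
#'
#' @param m A [conn_matrix].
#' @return A symmetric `Matrix::sparseMatrix`.
#' @export
as_sparse <- function(m) {
  stopifnot(inherits(m, "conn_matrix"))
  Matrix::sparseMatrix(i = m$i, j = m$j, x = m$w,
                       dims = c(m$n_nodes, m$n_nodes), symmetric = TRUE)
}

#' Convert a symmetric 'Matrix' (or dense matrix) to a conn_matrix
#'
#' The strict upper triangle is taken; the input must be symmetric within
#' `tol`. Diagonal values are discarded (self-edges are not represented).
#'
#' @param x A square base matrix or `Matrix` sparse matrix.
#' @param binary Mark the result as binary (weights forced to 1).
#' @param tol Absolute tolerance for the symmetry check.
#' @return A [conn_matrix].
#' @export
as_conn_matrix <- function(x, binary = FALSE, tol = 1e-8) {
  if (inherits(x, "conn_matrix")) return(x)
  x <- methods::as(x, "CsparseMatrix")
  if (nrow(x) != ncol(x)) stop("matrix must be square", call. = FALSE)
  if (!Matrix::isSymmetric(x, tol = tol))
    stop("matrix is not symmetric within tolerance", call. = FALSE)
  x <- Matrix::forceSymmetric((x + Matrix::t(x)) / 2, uplo = "U")
  tri <- Matrix::triu(methods::as(x, "generalMatrix"), k = 1)
  tri <- methods::as(tri, "TsparseMatrix")
  conn_matrix(tri@i + 1L, tri@j + 1L, tri@x, n_nodes = nrow(x), binary = binary)
}

#' Elementwise union of two binary structures
#'
#' The clustering topology is the union of the spatial structure and the
#' binarized anatomical structure: nodes are topologically connected when
#' there is either a spatial or an anatomical link between them.
#'
#' @param a,b Binary [conn_matrix] objects over the same node set.
#' @return A binary [conn_matrix]; its edge set is the union of the inputs'.
#' @examples
#' s <- conn_matrix(1, 2, n_nodes = 3, binary = TRUE)
#' a <- conn_matrix(2, 3, n_nodes = 3, binary = TRUE)
#' conn_n_edges(combine_topology(s, a)) # 2
#' @export
combine_topology <- function(a, b) {
  stopifnot(inherits(a, "conn_matrix"), inherits(b, "conn_matrix"))
  if (a$n_nodes != b$n_nodes)
    stop("topologies have different node counts", call. = FALSE)
  conn_matrix(c(a$i, b$i), c(a$j, b$j), 1, n_nodes = a$n_nodes, binary = TRUE)
}

#' Keep the heaviest edges to reach a target density
#'
#' Retains the `k = round(target_density * n(n-1)/2)` largest-weight edges and
#' binarizes the result. This converts the smoothed, distance-normalized
#' consistency matrix into a fixed-density binary anatomical structure,
#' discarding connections with lower group-level evidence. Ties at the cut are
#' broken deterministically by weight, then by the lexicographic node pair.
#'
#' @param m A weighted [conn_matrix].
#' @param target_density Desired density in `(0, current density]`.
#' @return A binary [conn_matrix] whose density equals the target up to
#'   rounding to a whole number of edges.
#' @export
threshold_to_density <- function(m, target_density) {
  stopifnot(inherits(m, "conn_matrix"))
  if (!is.numeric(target_density) || target_density <= 0)
    stop("target_density must be positive", call. = FALSE)
  cur <- conn_density(m)
  if (target_density > cur + 1e-12)
    stop(sprintf("target density %.4g exceeds current density %.4g",
                 target_density, cur), call. = FALSE)
  n <- as.double(m$n_nodes)
  k <- round(target_density * n * (n - 1) / 2)
  k <- min(k, length(m$i))
  ord <- order(-m$w, m$i, m$j)
  keep <- ord[seq_len(k)]
  conn_matrix(m$i[keep], m$j[keep], 1, n_nodes = m$n_nodes, binary = TRUE)
}

# Internal: edge matrix (two columns, i < j) for graph traversal.
edge_matrix <- function(m) {
  cbind(m$i, m$j)
}
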