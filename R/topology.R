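#' Spatial adjacency from a triangular surface mesh
#'
#' Surface nodes are connected to their spatially adjacent nodes by the direct
#' edges of the triangle mesh: an edge is present whenever two vertices
#' co-occur in at least one triangle.
#'
#' @param triangles Integer matrix with three columns (one row per triangle) or
#'   a list of length-3 index vectors; 1-based vertex indices.
#' @param n_vertices Total number of mesh vertices.
#' @return A binary [conn_matrix] over the vertices.
#' @export
build_surface_adjacency <- function(triangles, n_vertices) {
  if (is.list(triangles)) triangles <- do.call(rbind, triangles)
  if (is.null(triangles) || length(triangles) == 0L) {
    warning("empty triangle list: returning an edgeless spatial structure")
    return(conn_matrix(integer(0), integer(0), n_nodes = n_vertices, binary = TRUE))
  }
  triangles <- as.matrix(triangles)
  if (ncol(triangles) != 3L)
    stop("triangles must have three vertex indices per row", call. = FALSE)
  storage.mode(triangles) <- "integer"
  if (min(triangles) < 1L || max(triangles) > n_vertices)
    stop("triangle vertex index out of range", call. = FALSE)
  if (any(triangles[, 1] == triangles[, 2] | triangles[, 1] == triangles[, 3] |
            triangles[, 2] == triangles[, 3]))
    stop("degenerate triangle: vertices must be distinct", call. = FALSE)
  i <- c(triangles[, 1], triangles[, 1], triangles[, 2])
  j <- c(triangles[, 2], triangles[, 3], triangles[, 3])
  conn_matrix(i, j, 1, n_nodes = n_vertices, binary = TRUE)
}

#' Spatial adjacency from a volumetric mask (26-neighborhood)
#'
#' Voxel nodes are connected to all in-mask voxels of their 26-neighborhood
#' (Chebyshev distance 1). In-mask voxels are linearized in R's column-major
#' array order (first array index fastest); the mapping is returned in the
#' `voxel_index` attribute so callers can relate nodes back to grid positions.
#'
#' @param mask Logical 3D array; `TRUE` marks in-mask voxels.
#' @return A binary [conn_matrix] over the in-mask voxels, with attribute
#'   `voxel_index` (linear indices into `mask` for each node).
#' @export
build_volume_adjacency <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(mask))
  lin <- which(mask)
  if (length(lin) == 0L) stop("mask is empty", call. = FALSE)
  dims <- dim(mask)
  node_of <- array(0L, dims)
  node_of[lin] <- seq_along(lin)
  coords <- arrayInd(lin, dims)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  # forward half of the 26-neighborhood: each undirected pair visited once
  offs <- offs[offs[, 1] + 3 * offs[, 2] + 9 * offs[, 3] > 0, , drop = FALSE]
  ei <- integer(0); ej <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] + (nb[ok, 3] - 1L) * dims[1] * dims[2]
    tgt <- node_of[nb_lin]
    src <- which(ok)
    present <- tgt > 0L
    ei <- c(ei, src[present])
    ej <- c(ej, tgt[present])
  }
  out <- conn_matrix(ei, ej, 1, n_nodes = length(lin), binary = TRUE)
  attr(out, "voxel_index") <- lin
  out
}

#' Group consensus (consistency index) of individual connectomes
#'
#' For each node pair, the fraction of subjects in whom the connection is
#' observed (nonzero): `C(i,j) = (1/S) * #\{s : A_s(i,j) > 0\}`. The result is
#' invariant to subject order and its sparsity pattern is the union of the
#' individual patterns.
#'
#' @param connectomes Non-empty list of [conn_matrix] objects sharing
#'   `n_nodes`; weights are interpreted as presence (`> 0`).
#' @return A weighted [conn_matrix] with weights in `(0, 1]`.
#' @export
compute_consensus <- function(connectomes) {
  if (!is.list(connectomes) || length(connectomes) == 0L)
    stop("a non-empty list of connectomes is required", call. = FALSE)
  n <- vapply(connectomes, function(m) {
    stopifnot(inherits(m, "conn_matrix")); m$n_nodes
  }, integer(1))
  if (length(unique(n)) != 1L)
    stop("all connectomes must share n_nodes", call. = FALSE)
  S <- length(connectomes)
  acc <- Reduce(`+`, lapply(connectomes, function(m) {
    Matrix::sparseMatrix(i = m$i, j = m$j, x = as.numeric(m$w > 0),
                         dims = c(m$n_nodes, m$n_nodes), symmetric = TRUE)
  }))
  out <- as_conn_matrix(acc / S)
  out
}

#' Average density of individual connectomes
#'
#' Arithmetic mean of each connectome's edge density (nonzero fraction of the
#' off-diagonal upper triangle). Used as the default target density when
#' binarizing the group anatomical structure, so that the group topology keeps
#' the sparsity of a typical individual network.
#'
#' @inheritParams compute_consensus
#' @return A number in `[0, 1]`.
#' @export
average_individual_density <- function(connectomes) {
  if (!is.list(connectomes) || length(connectomes) == 0L)
    stop("a non-empty list of connectomes is required", call. = FALSE)
  mean(vapply(connectomes, conn_density, numeric(1)))
}

#' Fit a distance model for one connection class
#'
#' The consistency index is biased by inter-node distance (short-range
#' connections are observed more often). To model this, the consistencies of
#' one connection class are grouped into equal-count distance bins; cubic
#' splines are fitted through the per-bin means and standard deviations as a
#' function of the bin's mean distance. The standard-deviation fit is floored
#' at a small positive constant so that later standardization never divides by
#' zero. Evaluation outside the fitted distance range is clamped to the range
#' endpoints.
#'
#' @param C Weighted [conn_matrix] of consistencies.
#' @param geometry A [node_geometry].
#' @param n_bins Number of equal-count distance bins (default 100; at least 4).
#' @param class Connection class to fit (`"intrahemispheric"`,
#'   `"interhemispheric"` or `"subcortical"`); `NULL` fits all observed edges
#'   as one class.
#' @param sigma_floor Lower bound applied to the fitted standard deviation.
#' @return An object of class `distance_model` with elements `f_mu`, `f_sigma`
#'   (functions of distance), `class`, `bin_centers`, `bin_mu`, `bin_sigma`,
#'   `range` and residual summaries `resid_mu`, `resid_sigma`.
#' @export
fit_distance_model <- function(C, geometry, n_bins = 100, class = NULL,
                               sigma_floor = 1e-6) {
  stopifnot(inherits(C, "conn_matrix"), inherits(geometry, "node_geometry"))
  if (geometry$n_nodes != C$n_nodes)
    stop("geometry and matrix disagree on n_nodes", call. = FALSE)
  if (n_bins < 4) stop("n_bins must be at least 4", call. = FALSE)
  sel <- rep(TRUE, length(C$i))
  if (!is.null(class))
    sel <- connection_class(geometry, C$i, C$j) == class
  if (sum(sel) < n_bins)
    stop(sprintf("too few edges (%d) in class '%s' for %d bins", sum(sel),
                 if (is.null(class)) "all" else class, n_bins), call. = FALSE)
  d <- edge_distances(geometry, C$i[sel], C$j[sel])
  w <- C$w[sel]
  # equal-count bins via rank: stabilizes per-bin sd at all distances
  bin <- ceiling(rank(d, ties.method = "first") / (length(d) / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  centers <- tapply(d, bin, mean)
  mu <- tapply(w, bin, mean)
  sg <- tapply(w, bin, stats::sd)
  sg[is.na(sg)] <- 0
  if (any(sg < sigma_floor))
    warning("zero-variance distance bin(s): sd fit floored at ", sigma_floor)
  ord <- order(centers)
  centers <- as.numeric(centers[ord]); mu <- as.numeric(mu[ord])
  sg <- as.numeric(sg[ord])
  # evaluation is clamped at the observed distance range; between that range
  # and the outermost bin centers the natural spline extrapolates linearly,
  # which tracks steep short-range trends far better than a flat clamp
  rng <- range(d)
  if (length(unique(centers)) < length(centers)) {
    keep <- !duplicated(centers)
    centers <- centers[keep]; mu <- mu[keep]; sg <- sg[keep]
  }
  mu_fun <- stats::splinefun(centers, mu, method = "natural")
  sg_fun <- stats::splinefun(centers, sg, method = "natural")
  f_mu <- function(x) mu_fun(pmin(pmax(x, rng[1]), rng[2]))
  f_sigma <- function(x) pmax(sg_fun(pmin(pmax(x, rng[1]), rng[2])), sigma_floor)
  structure(list(f_mu = f_mu, f_sigma = f_sigma,
                 class = if (is.null(class)) "all" else class,
                 bin_centers = centers, bin_mu = mu, bin_sigma = pmax(sg, sigma_floor),
                 range = rng,
                 resid_mu = stats::sd(mu - f_mu(centers)),
                 resid_sigma = stats::sd(sg - sg_fun(centers))),
            class = "distance_model")
}

#' Distance-normalize a consistency matrix
#'
#' Standardizes every consistency value against the fitted distance trend of
#' its connection class: `C_n(i,j) = (C(i,j) - f_mu(ED(i,j))) / f_sigma(ED(i,j))`.
#' The sparsity pattern of `C` is preserved; normalized weights may be
#' negative.
#'
#' @param C Weighted [conn_matrix] of consistencies.
#' @param geometry A [node_geometry].
#' @param models A single `distance_model` (applied to every edge) or a named
#'   list of models keyed by connection class.
#' @return A weighted [conn_matrix] of standardized consistencies.
#' @export
normalize_consistency <- function(C, geometry, models) {
  stopifnot(inherits(C, "conn_matrix"), inherits(geometry, "node_geometry"))
  d <- edge_distances(geometry, C$i, C$j)
  if (inherits(models, "distance_model")) {
    z <- (C$w - models$f_mu(d)) / models$f_sigma(d)
  } else {
    cls <- connection_class(geometry, C$i, C$j)
    missing <- setdiff(unique(cls), names(models))
    if (length(missing) > 0L)
      stop("no distance model for connection class(es): ",
           paste(missing, collapse = ", "), call. = FALSE)
    z <- numeric(length(d))
    for (cl in unique(cls)) {
      idx <- cls == cl
      mdl <- models[[cl]]
      z[idx] <- (C$w[idx] - mdl$f_mu(d[idx])) / mdl$f_sigma(d[idx])
    }
  }
  m <- conn_matrix(C$i, C$j, z, n_nodes = C$n_nodes)
  m
}

#' Build a Gaussian connectome-smoothing kernel
#'
#' Row-stochastic node-by-node Gaussian kernel used for connectome spatial
#' smoothing: weights `exp(-ED^2 / (2 sigma^2))` with
#' `sigma = fwhm / (2 sqrt(2 ln 2))`, truncated where the unnormalized weight
#' falls below `weight_floor` (or beyond an explicit `truncation_radius`), then
#' normalized so every row sums to one.
#'
#' @param geometry A [node_geometry]; Euclidean distances between its
#'   coordinates define the kernel. A precomputed symmetric distance matrix
#'   (e.g. geodesic) may be supplied via `distances` instead.
#' @param fwhm Full width at half maximum of the kernel, in the units of the
#'   coordinates (mm for real data); must be positive.
#' @param truncation_radius Distance beyond which weights are zeroed; default
#'   is the distance at which the Gaussian weight reaches `weight_floor`.
#' @param distances Optional dense distance matrix overriding Euclidean
#'   distances.
#' @param weight_floor Unnormalized-weight cutoff defining the default radius.
#' @return An object of class `smoothing_kernel`: list with the sparse
#'   row-stochastic matrix `F` (class `Matrix`), `fwhm`, `sigma` and `radius`.
#' @export
build_smoothing_kernel <- function(geometry, fwhm, truncation_radius = NULL,
                                   distances = NULL, weight_floor = 1e-6) {
  if (!is.numeric(fwhm) || fwhm <= 0)
    stop("fwhm must be positive", call. = FALSE)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (is.null(truncation_radius))
    truncation_radius <- sigma * sqrt(-2 * log(weight_floor))
  if (is.null(distances)) {
    stopifnot(inherits(geometry, "node_geometry"))
    n <- geometry$n_nodes
    distances <- as.matrix(stats::dist(geometry$coordinates))
  } else {
    distances <- as.matrix(distances)
    n <- nrow(distances)
  }
  w <- exp(-distances^2 / (2 * sigma^2))
  w[distances > truncation_radius] <- 0
  Fs <- methods::as(Matrix::Matrix(w / rowSums(w), sparse = TRUE), "CsparseMatrix")
  structure(list(F = Fs, fwhm = fwhm, sigma = sigma, radius = truncation_radius),
            class = "smoothing_kernel")
}

#' Connectome spatial smoothing
#'
#' Applies a smoothing kernel to both margins of a connectivity matrix:
#' `F C F'`. The product is re-symmetrized, `(M + M') / 2`, to absorb
#' floating-point asymmetry, and the diagonal is discarded (self-edges are not
#' represented in [conn_matrix]).
#'
#' @param C A [conn_matrix] (typically the distance-normalized consistency).
#' @param kernel A [build_smoothing_kernel()] result, or any row-stochastic
#'   matrix of matching dimension.
#' @return A weighted [conn_matrix].
#' @export
smooth_connectome <- function(C, kernel) {
  stopifnot(inherits(C, "conn_matrix"))
  Fs <- if (inherits(kernel, "smoothing_kernel")) kernel$F else kernel
  if (nrow(Fs) != C$n_nodes || ncol(Fs) != C$n_nodes)
    stop("kernel dimension does not match the connectome", call. = FALSE)
  M <- Fs %*% as_sparse(C) %*% Matrix::t(Fs)
  M <- (M + Matrix::t(M)) / 2
  as_conn_matrix(M)
}

#' Build the full anatomical structure and clustering topology
#'
#' Convenience pipeline: consensus over individual connectomes,
#' distance-dependent normalization per connection class, connectome spatial
#' smoothing, density-matched thresholding/binarization (yielding the
#' anatomical structure), and union with the spatial structure (yielding the
#' clustering topology).
#'
#' @param connectomes List of individual [conn_matrix] connectomes.
#' @param geometry A [node_geometry].
#' @param spatial Binary [conn_matrix]: the spatial structure.
#' @param fwhm Smoothing kernel FWHM (same units as the coordinates; 0 or
#'   `NULL` disables smoothing).
#' @param density Target density for binarization; default is the average
#'   individual connectome density.
#' @param n_bins Distance bins per connection class.
#' @return List with elements `consensus`, `normalized`, `smoothed`,
#'   `anatomical` (binary `C_Dist`), `topology` (binary `T`) and `models`.
#' @export
build_topology <- function(connectomes, geometry, spatial, fwhm = 6,
                           density = NULL, n_bins = 100) {
  C <- compute_consensus(connectomes)
  classes <- unique(connection_class(geometry, C$i, C$j))
  models <- lapply(classes, function(cl)
    fit_distance_model(C, geometry, n_bins = n_bins, class = cl))
  names(models) <- classes
  Cn <- normalize_consistency(C, geometry, models)
  smoothed <- if (is.null(fwhm) || fwhm <= 0) Cn else
    smooth_connectome(Cn, build_smoothing_kernel(geometry, fwhm))
  if (is.null(density)) density <- average_individual_density(connectomes)
  density <- min(density, conn_density(smoothed))
  anatomical <- threshold_to_density(smoothed, density)
  list(consensus = C, normalized = Cn, smoothed = smoothed,
       anatomical = anatomical, topology = combine_topology(anatomical, spatial),
       models = models)
}
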