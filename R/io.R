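#' Read a sparse symmetric matrix from Matrix Market format
#'
#' Accepts coordinate-format files with a `symmetric` header (one triangle
#' stored) or a `general` header, in which case both `(i,j)` and `(j,i)`
#' entries may appear and must agree. Indices on disk are 1-based, matching
#' the internal convention.
#'
#' @param path Path to a `.mtx` file.
#' @param binary Mark the result as binary.
#' @return A [conn_matrix].
#' @export
read_sparse_matrix <- function(path, binary = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop("malformed Matrix Market file '", path,
                                         "': ", conditionMessage(e), call. = FALSE))
  if (nrow(m) != ncol(m))
    stop("matrix in ", path, " is not square", call. = FALSE)
  if (!Matrix::isSymmetric(m, tol = 1e-10))
    stop("general-format matrix in ", path,
         " has asymmetric entries", call. = FALSE)
  out <- as_conn_matrix(m, binary = binary)
  if (binary) out$w <- rep(1, length(out$w))
  out
}

#' Write a sparse symmetric matrix in Matrix Market format
#'
#' The upper triangle is written with a `symmetric` header and 1-based
#' indices, so files round-trip exactly through [read_sparse_matrix()].
#'
#' @param m A [conn_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sparse_matrix <- function(m, path) {
  stopifnot(inherits(m, "conn_matrix"))
  Matrix::writeMM(as_sparse(m), path)
  invisible(path)
}

#' Read node geometry and group labels from TSV
#'
#' Expects columns `node_id`, `x`, `y`, optionally `z`, and `group_label`.
#' Rows may be in any order; they are sorted by `node_id`, which must be the
#' contiguous range `1..n`.
#'
#' @param path Path to a tab-separated file.
#' @return A [node_geometry].
#' @export
read_geometry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_id", "x", "y", "group_label")
  if (!all(need %in% names(df)))
    stop("geometry file must have columns node_id, x, y[, z], group_label",
         call. = FALSE)
  df <- df[order(df$node_id), ]
  if (!identical(as.integer(df$node_id), seq_len(nrow(df))))
    stop("node_id must cover 1..n exactly once", call. = FALSE)
  coords <- if ("z" %in% names(df)) cbind(df$x, df$y, df$z) else cbind(df$x, df$y)
  node_geometry(coords, df$group_label)
}

#' Write node geometry to TSV
#' @param geometry A [node_geometry].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "node_geometry"))
  co <- geometry$coordinates
  df <- data.frame(node_id = seq_len(geometry$n_nodes),
                   x = co[, 1], y = co[, 2])
  if (ncol(co) == 3L) df$z <- co[, 3]
  df$group_label <- geometry$group_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read multi-subject maps from TSV
#'
#' One wide table: a `node_id` column plus one column per subject. All nodes
#' must be present exactly once; `node_id` must cover `1..n`. Alternatively a
#' character vector of per-subject files (each `node_id` + `value`) may be
#' given; their node sets must agree exactly, otherwise an alignment error
#' lists the offenders.
#'
#' @param path A single wide TSV path, or a vector of per-subject TSV paths.
#' @return A [subject_sample].
#' @export
read_maps <- function(path) {
  if (length(path) == 1L) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"node_id" %in% names(df))
      stop("maps file must have a node_id column", call. = FALSE)
    df <- df[order(df$node_id), ]
    if (!identical(as.integer(df$node_id), seq_len(nrow(df))))
      stop("node_id must cover 1..n exactly once", call. = FALSE)
    vals <- as.matrix(df[, setdiff(names(df), "node_id"), drop = FALSE])
    return(subject_sample(t(vals), subject_ids = colnames(vals)))
  }
  tabs <- lapply(path, function(p) {
    df <- utils::read.delim(p, stringsAsFactors = FALSE)
    if (!all(c("node_id", "value") %in% names(df)))
      stop("per-subject file ", p, " must have node_id and value columns",
           call. = FALSE)
    df[order(df$node_id), ]
  })
  ids <- lapply(tabs, function(df) df$node_id)
  ref <- ids[[1L]]
  bad <- which(!vapply(ids, function(x) identical(x, ref), logical(1)))
  if (length(bad) > 0L)
    stop("subject files with mismatching node sets: ",
         paste(path[bad], collapse = ", "), call. = FALSE)
  if (!identical(as.integer(ref), seq_along(ref)))
    stop("node_id must cover 1..n exactly once", call. = FALSE)
  vals <- do.call(rbind, lapply(tabs, function(df) df$value))
  subject_sample(vals, subject_ids = basename(path))
}

#' Write a subject sample to wide TSV
#' @param sample A [subject_sample].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maps <- function(sample, path) {
  stopifnot(inherits(sample, "subject_sample"))
  df <- data.frame(node_id = seq_len(sample$n_nodes))
  vals <- as.data.frame(t(sample$values))
  names(vals) <- sample$subject_ids
  utils::write.table(cbind(df, vals), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an atlas labeling from TSV
#'
#' Expects columns `node_id` and `region_id`; an optional companion region
#' metadata table (columns `region_id`, `name`) supplies region names.
#'
#' @param path Node-to-region TSV.
#' @param region_path Optional region metadata TSV.
#' @return An [atlas_labeling].
#' @export
read_atlas <- function(path, region_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node_id", "region_id") %in% names(df)))
    stop("atlas file must have node_id and region_id columns", call. = FALSE)
  df <- df[order(df$node_id), ]
  if (!identical(as.integer(df$node_id), seq_len(nrow(df))))
    stop("node_id must cover 1..n exactly once", call. = FALSE)
  nm <- NULL
  if (!is.null(region_path)) {
    reg <- utils::read.delim(region_path, stringsAsFactors = FALSE)
    nm <- reg$name[order(reg$region_id)]
  }
  atlas_labeling(df$region_id, nm)
}

#' Write an inference result to TSV plus a JSON sidecar
#'
#' The TSV holds the per-node table (`node_id`, `cluster_id`, `sign`,
#' `p_fwer`, `significant`); the JSON sidecar holds the per-cluster table, the
#' permutation null distribution and the full provenance (CDT, alpha, number
#' of permutations, seed).
#'
#' @param result A [run_inference()] result.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_inference_result <- function(result, path) {
  stopifnot(inherits(result, "inference_result"))
  cid <- result$cluster_id
  sgn <- integer(length(cid))
  p <- rep(NA_real_, length(cid))
  pos <- cid > 0L
  sgn[pos] <- result$cluster_sign[cid[pos]]
  p[pos] <- result$p_fwer[cid[pos]]
  utils::write.table(
    data.frame(node_id = seq_along(cid), cluster_id = cid, sign = sgn,
               p_fwer = p, significant = result$significant),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(
    clusters = data.frame(cluster = seq_along(result$extent),
                          sign = result$cluster_sign, extent = result$extent,
                          p_fwer = result$p_fwer),
    null_max_extents = result$null_max_extents,
    provenance = list(cdt = result$cdt, cdt_scale = result$cdt_scale,
                      alpha = result$alpha, n_perm = result$n_perm,
                      seed = result$seed, exhaustive = result$exhaustive,
                      package = "tcstat",
                      version = as.character(utils::packageVersion("tcstat"))))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read back a per-node inference table written by [write_inference_result()]
#'
#' @param path TSV path.
#' @return Data frame with the per-node columns.
#' @export
read_inference_result <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$significant <- as.logical(df$significant)
  df
}
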