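#' Node geometry and grouping
#'
#' Per-node coordinates (2D or 3D, in mm or grid units) plus a categorical
#' group label used to partition connections into classes. Labels follow the
#' convention `"left"`, `"right"` for the two cortical hemispheres and
#' `"subcortical"` for everything else; any other label is treated as its own
#' cortical group.
#'
#' @param coordinates Numeric matrix, one row per node, 2 or 3 columns.
#' @param group_label Character vector of per-node labels (recycled if scalar).
#' @return An object of class `node_geometry`.
#' @export
node_geometry <- function(coordinates, group_label = "left") {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (!ncol(coordinates) %in% c(2L, 3L))
    stop("coordinates must have 2 or 3 columns", call. = FALSE)
  n <- nrow(coordinates)
  if (length(group_label) == 1L) group_label <- rep(group_label, n)
  if (length(group_label) != n)
    stop("one group label per node is required", call. = FALSE)
  structure(list(coordinates = coordinates,
                 group_label = as.character(group_label),
                 n_nodes = n),
            class = "node_geometry")
}

#' @export
print.node_geometry <- function(x, ...) {
  cat(sprintf("<node_geometry> %d nodes, %dD, groups: %s\n", x$n_nodes,
              ncol(x$coordinates), paste(unique(x$group_label), collapse = ", ")))
  invisible(x)
}

#' Euclidean distances for a set of node pairs
#'
#' @param geometry A [node_geometry].
#' @param i,j Parallel integer vectors of node indices.
#' @return Numeric vector of pairwise Euclidean distances.
#' @export
edge_distances <- function(geometry, i, j) {
  stopifnot(inherits(geometry, "node_geometry"))
  d2 <- (geometry$coordinates[i, , drop = FALSE] -
           geometry$coordinates[j, , drop = FALSE])^2
  sqrt(rowSums(d2))
}

#' Connection class of each node pair
#'
#' Distance-dependent normalization of the consistency index is carried out
#' independently for interhemispheric, intrahemispheric and subcortical
#' connections. An edge touching a subcortical node is "subcortical"; an edge
#' between two cortical nodes of the same hemisphere is "intrahemispheric";
#' one between different hemispheres is "interhemispheric".
#'
#' @inheritParams edge_distances
#' @return Character vector with values `"subcortical"`, `"intrahemispheric"`
#'   or `"interhemispheric"`.
#' @export
connection_class <- function(geometry, i, j) {
  stopifnot(inherits(geometry, "node_geometry"))
  gi <- geometry$group_label[i]
  gj <- geometry$group_label[j]
  out <- ifelse(gi == "subcortical" | gj == "subcortical", "subcortical",
                ifelse(gi == gj, "intrahemispheric", "interhemispheric"))
  out
}
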