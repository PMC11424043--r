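#' Two-dimensional ribbon phantom
#'
#' A synthetic axial-slice phantom for exercising the whole pipeline without
#' external data: a square grid masked by a circular ribbon (an annulus of
#' "gray matter" pixels), divided into 11 hypothetical atlas regions -- five
#' per hemisphere plus a brain-stem sector at the bottom. A ground-truth
#' signal with peak 1 and background 0 spans three active regions of distinct
#' spatial extents (large, medium, small), and a list of long-range fiber
#' connections represents hypothetical white matter: short-range association
#' fibers between neighboring regions, projection fibers radiating from the
#' brain stem, and homotopic commissural fibers between mirrored left/right
#' regions. One extra long association fiber links the small active region to
#' the large one, and the commissural fiber between the large region and its
#' mirror links it to the medium one, so the three active regions are
#' anatomically wired together.
#'
#' Ribbon pixels are linearized in column-major grid order; all returned node
#' indices refer to that ordering.
#'
#' @param grid_shape Integer 2-vector, default `c(80, 80)`.
#' @param inner_frac,outer_frac Annulus radii as fractions of half the smaller
#'   grid dimension (defaults 0.55 and 0.95).
#' @param brainstem_halfwidth_deg Angular half-width of the brain-stem sector.
#' @param active_radii Radii (pixels) of the large and medium active discs.
#' @param small_block Side length (pixels) of the small square active region.
#' @return An object of class `ribbon_phantom`: `grid_shape`, `ribbon_mask`
#'   (logical matrix), `node_index` (linear grid indices per node),
#'   `coordinates` (x = column, y = row), `region_label` (per-node, 1..11; 11
#'   is the brain stem), `geometry` (a [node_geometry] with hemisphere labels),
#'   `ground_truth` (per-node, in `[0, 1]`), `active_regions` (list of node
#'   sets: large, medium, small), `fiber_edges` (data frame `i`, `j`, `class`)
#'   and `n_nodes`.
#' @export
make_ribbon_phantom <- function(grid_shape = c(80L, 80L),
                                inner_frac = 0.55, outer_frac = 0.95,
                                brainstem_halfwidth_deg = 15,
                                active_radii = c(large = 5.5, medium = 3),
                                small_block = 2L) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 20L)) stop("grid must be at least 20x20", call. = FALSE)
  if (!(inner_frac > 0 && inner_frac < outer_frac && outer_frac <= 1))
    stop("need 0 < inner_frac < outer_frac <= 1", call. = FALSE)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  half <- min(nr, nc) / 2
  r_in <- inner_frac * half; r_out <- outer_frac * half

  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  dx <- col - cx; dy <- row - cy
  rad <- sqrt(dx^2 + dy^2)
  mask_vec <- rad >= r_in & rad <= r_out
  node_index <- which(mask_vec)
  n_nodes <- length(node_index)
  x <- col[node_index]; y <- row[node_index]

  # angle measured from the brain-stem axis (pointing down the grid), in
  # [0, 360); mirroring across the vertical midline maps phi -> 360 - phi
  theta <- atan2(y[seq_len(n_nodes)] - cy, x - cx) * 180 / pi
  phi <- (theta - 90) %% 360
  bw <- brainstem_halfwidth_deg
  sector_width <- (360 - 2 * bw) / 10
  region <- integer(n_nodes)
  is_bs <- phi < bw | phi >= 360 - bw
  region[is_bs] <- 11L
  k <- floor((phi[!is_bs] - bw) / sector_width)
  k <- pmin(pmax(k, 0), 9)
  region_of_sector <- c(1L, 2L, 3L, 4L, 5L, 10L, 9L, 8L, 7L, 6L)
  region[!is_bs] <- region_of_sector[k + 1L]

  hemi <- c(rep("right", 5), rep("left", 5), "subcortical")[region]
  geometry <- node_geometry(cbind(x = x, y = y), hemi)

  # a region's anchor: the ribbon pixel nearest the sector's polar centroid
  anchor <- function(reg) {
    if (reg == 11L) phi0 <- 0 else {
      sec <- which(region_of_sector == reg) - 1L
      phi0 <- bw + (sec + 0.5) * sector_width
    }
    r0 <- (r_in + r_out) / 2
    px <- cx + r0 * cos((phi0 + 90) * pi / 180)
    py <- cy + r0 * sin((phi0 + 90) * pi / 180)
    which.min((x - px)^2 + (y - py)^2)
  }
  anchors <- vapply(1:11, anchor, integer(1))
  mirror_of <- function(node) which.min((x - (2 * cx - x[node]))^2 + (y - y[node])^2)

  # active regions: large disc in left region 8, medium disc at its mirror
  # (right region 3), small block in left region 6
  large <- which((x - x[anchors[8]])^2 + (y - y[anchors[8]])^2 <= active_radii[["large"]]^2)
  med_c <- mirror_of(anchors[8])
  medium <- which((x - x[med_c])^2 + (y - y[med_c])^2 <= active_radii[["medium"]]^2)
  sb <- small_block - 1L
  small <- which(x >= x[anchors[6]] & x <= x[anchors[6]] + sb &
                   y >= y[anchors[6]] & y <= y[anchors[6]] + sb)
  ground_truth <- numeric(n_nodes)
  ground_truth[c(large, medium, small)] <- 1

  # hypothetical white matter fibers between region anchor pixels
  fib <- list()
  for (h in list(1:5, 6:10)) # short-range association between neighbors
    for (q in seq_len(4))
      fib[[length(fib) + 1L]] <- c(anchors[h[q]], anchors[h[q + 1]], "association")
  fib[[length(fib) + 1L]] <- c(anchors[6], anchors[8], "association") # small-to-large link
  for (reg in 1:10) # projection fibers from the brain stem
    fib[[length(fib) + 1L]] <- c(anchors[11], anchors[reg], "projection")
  for (reg in 6:10) # homotopic commissural fibers (mirrored endpoints)
    fib[[length(fib) + 1L]] <- c(anchors[reg], mirror_of(anchors[reg]), "commissural")
  fiber_edges <- data.frame(i = as.integer(vapply(fib, `[`, "", 1)),
                            j = as.integer(vapply(fib, `[`, "", 2)),
                            class = vapply(fib, `[`, "", 3),
                            stringsAsFactors = FALSE)
  fiber_edges <- fiber_edges[fiber_edges$i != fiber_edges$j, ]

  structure(list(grid_shape = grid_shape,
                 ribbon_mask = matrix(mask_vec, nr, nc),
                 node_index = node_index,
                 coordinates = cbind(x = x, y = y),
                 region_label = region, geometry = geometry,
                 ground_truth = ground_truth,
                 active_regions = list(large = large, medium = medium, small = small),
                 fiber_edges = fiber_edges, n_nodes = n_nodes),
            class = "ribbon_phantom")
}

#' @export
print.ribbon_phantom <- function(x, ...) {
  cat(sprintf("<ribbon_phantom> %dx%d grid, %d ribbon pixels, 11 regions, %d fibers\n",
              x$grid_shape[1], x$grid_shape[2], x$n_nodes, nrow(x$fiber_edges)))
  invisible(x)
}

#' Spatial structure and clustering topology of a phantom
#'
#' The spatial structure `S` is the four-neighborhood lattice over ribbon
#' pixels; the clustering topology `T` adds the phantom's long-range fiber
#' connections to it.
#'
#' @param phantom A [make_ribbon_phantom()] result.
#' @return List with binary [conn_matrix] elements `S` and `T`.
#' @export
make_phantom_topology <- function(phantom) {
  stopifnot(inherits(phantom, "ribbon_phantom"))
  nr <- phantom$grid_shape[1]
  x <- phantom$coordinates[, "x"]; y <- phantom$coordinates[, "y"]
  node_of <- integer(nr * phantom$grid_shape[2])
  node_of[phantom$node_index] <- seq_len(phantom$n_nodes)
  ei <- integer(0); ej <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L))) { # forward half of 4-neighborhood
    ny <- y + off[1]; nx <- x + off[2]
    ok <- ny <= nr & nx <= phantom$grid_shape[2]
    lin <- ny[ok] + (nx[ok] - 1L) * nr
    tgt <- node_of[lin]
    src <- which(ok)
    ei <- c(ei, src[tgt > 0L]); ej <- c(ej, tgt[tgt > 0L])
  }
  S <- conn_matrix(ei, ej, 1, n_nodes = phantom$n_nodes, binary = TRUE)
  fibers <- conn_matrix(phantom$fiber_edges$i, phantom$fiber_edges$j, 1,
                        n_nodes = phantom$n_nodes, binary = TRUE)
  list(S = S, T = combine_topology(S, fibers))
}

# Ribbon-restricted Gaussian smoothing operator: truncated discrete kernel
# (radius 4 sigma), rows renormalized over in-ribbon neighbors so the border
# does not leak mass.
ribbon_smoother <- function(phantom, sigma) {
  n <- phantom$n_nodes
  if (sigma <= 0) return(Matrix::Diagonal(n))
  nr <- phantom$grid_shape[1]; nc <- phantom$grid_shape[2]
  node_of <- integer(nr * nc)
  node_of[phantom$node_index] <- seq_len(n)
  x <- phantom$coordinates[, "x"]; y <- phantom$coordinates[, "y"]
  r <- max(1L, ceiling(4 * sigma))
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  ti <- integer(0); tj <- integer(0); tw <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    dyk <- offs$dy[k]; dxk <- offs$dx[k]
    w <- exp(-(dyk^2 + dxk^2) / (2 * sigma^2))
    if (w < 1e-12) next
    ny <- y + dyk; nx <- x + dxk
    ok <- ny >= 1L & ny <= nr & nx >= 1L & nx <= nc
    lin <- ny[ok] + (nx[ok] - 1L) * nr
    tgt <- node_of[lin]
    src <- which(ok)
    keep <- tgt > 0L
    ti <- c(ti, src[keep]); tj <- c(tj, tgt[keep])
    tw <- c(tw, rep(w, sum(keep)))
  }
  M <- Matrix::sparseMatrix(i = ti, j = tj, x = tw, dims = c(n, n))
  M / Matrix::rowSums(M)
}

#' Simulate one noisy phantom statistical map
#'
#' Gaussian white noise is added to the ground-truth signal and the sum is
#' spatially smoothed (signal and noise together), restricted to the ribbon.
#' Defaults follow the phantom's nominal contamination: noise standard
#' deviation 2, smoothing sigma 0.5 pixels.
#'
#' @param phantom A [make_ribbon_phantom()] result.
#' @param noise_sd Standard deviation of the additive white noise.
#' @param smooth_sigma Gaussian smoothing sigma in pixels (0 disables).
#' @param seed RNG seed.
#' @param effect_scale Multiplier on the ground-truth signal (default 1).
#' @return Numeric per-node map over the ribbon pixels.
#' @export
simulate_noisy_map <- function(phantom, noise_sd = 2, smooth_sigma = 0.5,
                               seed = 1L, effect_scale = 1) {
  stopifnot(inherits(phantom, "ribbon_phantom"))
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  set.seed(seed)
  sm <- ribbon_smoother(phantom, smooth_sigma)
  raw <- effect_scale * phantom$ground_truth +
    stats::rnorm(phantom$n_nodes, sd = noise_sd)
  as.numeric(sm %*% raw)
}

#' Simulate a multi-subject phantom sample
#'
#' Each subject's map is `effect_scale * ground_truth` plus independent
#' Gaussian white noise, smoothed together (as in [simulate_noisy_map()]).
#' `effect_scale = 0` gives a pure-null sample for family-wise error checks.
#'
#' @inheritParams simulate_noisy_map
#' @param n_subjects Number of subjects (at least 2).
#' @param effect_scale Per-subject signal amplitude (default 1; 0 for null).
#' @return A [subject_sample] of dimension `n_subjects x n_nodes`.
#' @export
simulate_subject_sample <- function(phantom, n_subjects, effect_scale = 1,
                                    noise_sd = 2, smooth_sigma = 0.5,
                                    seed = 1L) {
  stopifnot(inherits(phantom, "ribbon_phantom"))
  if (n_subjects < 2L) stop("at least 2 subjects are required", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  set.seed(seed)
  sm <- ribbon_smoother(phantom, smooth_sigma)
  noise <- matrix(stats::rnorm(n_subjects * phantom$n_nodes, sd = noise_sd),
                  nrow = phantom$n_nodes)
  raw <- effect_scale * phantom$ground_truth + noise
  subject_sample(t(as.matrix(sm %*% raw)))
}
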