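#' Multi-subject sample of per-node contrast values
#'
#' @param values Numeric matrix, `n_subjects x n_nodes`: one first-level
#'   contrast value per subject and node.
#' @param subject_ids Optional identifiers (default `s1, s2, ...`).
#' @return An object of class `subject_sample`.
#' @export
subject_sample <- function(values, subject_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L)
    stop("at least 2 subjects are required", call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(nrow(values)))
  if (length(subject_ids) != nrow(values))
    stop("one subject id per row is required", call. = FALSE)
  structure(list(values = values, subject_ids = as.character(subject_ids),
                 n_subjects = nrow(values), n_nodes = ncol(values)),
            class = "subject_sample")
}

#' One-sample group t statistic per node
#'
#' Computes `t(i) = mean_i / (sd_i / sqrt(n))` per node, the matching Cohen's
#' d (`d = t / sqrt(n)`), and the two-sided z equivalent of each t value
#' (probit of the t-distribution CDF, sign preserved). Zero-variance nodes are
#' marked missing and are never suprathreshold.
#'
#' @param sample A [subject_sample] or a plain subjects-by-nodes matrix.
#' @return An object of class `stat_map`: list with `t`, `z`, `d`, `n`,
#'   `missing` (logical).
#' @export
group_t_statistic <- function(sample) {
  if (!inherits(sample, "subject_sample")) sample <- subject_sample(sample)
  X <- sample$values
  n <- nrow(X)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0 # guard tiny negative round-off
  missing <- v <= 0
  t <- rep(NA_real_, ncol(X))
  t[!missing] <- m[!missing] / sqrt(v[!missing] / n)
  structure(list(t = t, z = t_to_z(t, n - 1), d = t / sqrt(n), n = n,
                 missing = missing),
            class = "stat_map")
}

# Two-sided z equivalent of a t statistic: monotone map through log tail
# probabilities, stable far into the tails.
t_to_z <- function(t, df) {
  z <- rep(NA_real_, length(t))
  ok <- !is.na(t)
  lp <- stats::pt(abs(t[ok]), df = df, lower.tail = FALSE, log.p = TRUE)
  z[ok] <- sign(t[ok]) * stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  z
}

# t-scale threshold equivalent to a z-scale CDT (monotone map, equality
# preserved), so permutations can threshold t directly.
z_cdt_to_t <- function(cdt, df) {
  lp <- stats::pnorm(cdt, lower.tail = FALSE, log.p = TRUE)
  stats::qt(lp, df = df, lower.tail = FALSE, log.p = TRUE)
}

#' Threshold a statistical map into a signed suprathreshold mask
#'
#' Nodes with statistic `>= cdt` get sign `+1`, `<= -cdt` get `-1`, all others
#' (including missing nodes) get `0`. The boundary is inclusive.
#'
#' @param stat A [group_t_statistic()] result, or a plain numeric vector
#'   thresholded on its own scale.
#' @param cdt Positive cluster-defining threshold.
#' @param scale Which scale `cdt` refers to for a `stat_map`: `"z"` (default;
#'   e.g. z = 3.3 for two-sided p = 0.001), or `"t"`.
#' @return Integer vector of per-node signs in `\{-1, 0, 1\}`.
#' @export
threshold_map <- function(stat, cdt, scale = c("z", "t")) {
  if (!is.numeric(cdt) || cdt <= 0)
    stop("cdt must be positive", call. = FALSE)
  scale <- match.arg(scale)
  x <- if (inherits(stat, "stat_map")) {
    if (scale == "z") stat$z else stat$t
  } else as.numeric(stat)
  sgn <- integer(length(x))
  sgn[!is.na(x) & x >= cdt] <- 1L
  sgn[!is.na(x) & x <= -cdt] <- -1L
  sgn
}

# ---- fast connected components (union-find with path halving) -------------

# Component label (1..k) for each of `nodes`, given an edge list (columns of
# node ids, both endpoints guaranteed to be in `nodes`).
uf_components <- function(nodes, ea, eb) {
  k <- length(nodes)
  parent <- seq_len(k)
  if (length(ea) > 0L) {
    a <- match(ea, nodes)
    b <- match(eb, nodes)
    for (e in seq_along(a)) {
      x <- a[e]
      while (parent[x] != x) {
        parent[x] <- parent[parent[x]]
        x <- parent[x]
      }
      y <- b[e]
      while (parent[y] != y) {
        parent[y] <- parent[parent[y]]
        y <- parent[y]
      }
      if (x != y) parent[max(x, y)] <- min(x, y)
    }
  }
  root <- seq_len(k)
  for (x in seq_len(k)) {
    r <- x
    while (parent[r] != r) r <- parent[r]
    root[x] <- r
  }
  match(root, unique(root))
}

# Largest component size among `nodes` under the induced subgraph of the
# preselected edges (ea, eb). 0 when no nodes.
max_component_size <- function(nodes, ea, eb) {
  if (length(nodes) == 0L) return(0L)
  if (length(ea) == 0L) return(1L)
  comp <- uf_components(nodes, ea, eb)
  max(tabulate(comp))
}

#' Label signed suprathreshold clusters on a topology
#'
#' Connected components are computed separately within the positive and
#' negative suprathreshold node sets, using only topology edges whose two
#' endpoints are suprathreshold with the same sign. Spatially disjoint regions
#' joined by an anatomical edge of the topology therefore receive one cluster
#' label. Cluster ids are dense (1..K), ordered by decreasing extent and then
#' by smallest member node.
#'
#' @param mask Signed per-node vector in `\{-1, 0, 1\}` (see [threshold_map()]).
#' @param topology Binary [conn_matrix] over the same nodes.
#' @return List with `cluster_id` (per-node integer, 0 = background),
#'   `cluster_sign` (per-cluster) and `extent` (per-cluster node counts).
#' @export
label_clusters <- function(mask, topology) {
  stopifnot(inherits(topology, "conn_matrix"))
  mask <- as.integer(mask)
  if (length(mask) != topology$n_nodes)
    stop("mask length does not match the topology", call. = FALSE)
  cluster_id <- integer(length(mask))
  ext <- integer(0); sgn <- integer(0); first <- integer(0)
  next_id <- 0L
  for (s in c(1L, -1L)) {
    nodes <- which(mask == s)
    if (length(nodes) == 0L) next
    inset <- logical(length(mask)); inset[nodes] <- TRUE
    keep <- inset[topology$i] & inset[topology$j]
    comp <- uf_components(nodes, topology$i[keep], topology$j[keep])
    sizes <- tabulate(comp)
    cluster_id[nodes] <- next_id + comp
    ext <- c(ext, sizes)
    sgn <- c(sgn, rep(s, length(sizes)))
    first <- c(first, vapply(seq_along(sizes),
                             function(k) min(nodes[comp == k]), integer(1)))
    next_id <- next_id + length(sizes)
  }
  if (next_id > 0L) {
    ord <- order(-ext, first)
    relabel <- integer(next_id)
    relabel[ord] <- seq_len(next_id)
    pos <- cluster_id > 0L
    cluster_id[pos] <- relabel[cluster_id[pos]]
    ext <- ext[ord]; sgn <- sgn[ord]
  }
  list(cluster_id = cluster_id, cluster_sign = sgn, extent = ext)
}

#' Sign-flip matrices for one-sample permutation
#'
#' Permutation 1 is always the identity (all `+1`). In Monte-Carlo mode the
#' remaining rows are drawn after `set.seed(seed)` row by row, each as
#' `n_subjects` independent fair `+/-1` draws. In exhaustive mode all `2^n`
#' sign patterns are enumerated exactly once (identity first).
#'
#' @param n_subjects Number of subjects.
#' @param n_perm Number of permutations (ignored in exhaustive mode).
#' @param seed Integer RNG seed (Monte-Carlo mode).
#' @param exhaustive Enumerate all `2^n_subjects` patterns (requires
#'   `n_subjects <= 20`).
#' @return A `n_perm x n_subjects` matrix of `+/-1`.
#' @export
sign_flip_matrix <- function(n_subjects, n_perm, seed = 1L, exhaustive = FALSE) {
  if (exhaustive) {
    if (n_subjects > 20L)
      stop("exhaustive enumeration limited to 20 subjects", call. = FALSE)
    n_perm <- 2L^n_subjects
    P <- matrix(1, n_perm, n_subjects)
    for (s in seq_len(n_subjects))
      P[, s] <- rep(c(1, -1), each = 2L^(n_subjects - s), length.out = n_perm)
    return(P)
  }
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  P <- matrix(1, n_perm, n_subjects)
  if (n_perm > 1L) {
    set.seed(seed)
    P[-1L, ] <- matrix(sample(c(1, -1), (n_perm - 1L) * n_subjects, replace = TRUE),
                       nrow = n_perm - 1L, byrow = TRUE)
  }
  P
}

# Permutation engine shared by permutation_null() and run_inference(): for
# each sign-flip row, the per-node one-sample t statistic is recomputed in
# closed form (squared values are flip-invariant, so one matrix product gives
# all permutation means), thresholded at the t equivalent of the z-scale CDT,
# and the maximum same-sign component extent on the topology is recorded.
perm_max_extents <- function(X, topology, cdt, signs, cdt_scale = "z") {
  n <- nrow(X)
  df <- n - 1L
  t_thr <- if (cdt_scale == "z") z_cdt_to_t(cdt, df) else cdt
  sumsq <- colSums(X^2)
  M <- (signs %*% X) / n                      # n_perm x n_nodes means
  V <- sweep(-n * M^2, 2, sumsq, "+") / df    # flip-invariant variances
  V[V < 1e-300] <- NA_real_                   # zero variance: never suprathreshold
  Tm <- M / sqrt(V / n)
  Ei <- topology$i; Ej <- topology$j
  n_perm <- nrow(signs)
  out <- integer(n_perm)
  inset <- logical(ncol(X))
  for (p in seq_len(n_perm)) {
    tp <- Tm[p, ]
    best <- 0L
    for (s in c(1L, -1L)) {
      nodes <- if (s == 1L) which(!is.na(tp) & tp >= t_thr) else
        which(!is.na(tp) & tp <= -t_thr)
      if (length(nodes) == 0L) next
      if (length(nodes) == 1L) { best <- max(best, 1L); next }
      inset[nodes] <- TRUE
      keep <- inset[Ei] & inset[Ej]
      best <- max(best, max_component_size(nodes, Ei[keep], Ej[keep]))
      inset[nodes] <- FALSE
    }
    out[p] <- best
  }
  out
}

#' Null distribution of the maximum cluster extent under sign flipping
#'
#' For every permutation each subject's map is multiplied by an independent
#' random sign, the group t map is recomputed, thresholded at the CDT, and
#' clusters are labeled on the topology; the maximum cluster extent across
#' both signs is recorded. Permutation 1 is the identity (observed data), so
#' the observed maximum is always part of the null.
#'
#' @param sample A [subject_sample].
#' @param topology Binary [conn_matrix].
#' @param cdt Cluster-defining threshold (z scale by default).
#' @param n_perm Number of permutations (including the identity).
#' @param seed RNG seed for the sign draws.
#' @param exhaustive Enumerate all `2^n_subjects` sign patterns.
#' @param cdt_scale `"z"` or `"t"`.
#' @return Integer vector of maximum extents, one per permutation.
#' @export
permutation_null <- function(sample, topology, cdt, n_perm = 1000L, seed = 1L,
                             exhaustive = FALSE, cdt_scale = c("z", "t")) {
  if (!inherits(sample, "subject_sample")) sample <- subject_sample(sample)
  stopifnot(inherits(topology, "conn_matrix"))
  if (sample$n_nodes != topology$n_nodes)
    stop("sample and topology disagree on n_nodes", call. = FALSE)
  if (!exhaustive && n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  cdt_scale <- match.arg(cdt_scale)
  signs <- sign_flip_matrix(sample$n_subjects, n_perm, seed, exhaustive)
  perm_max_extents(sample$values, topology, cdt, signs, cdt_scale)
}

#' Family-wise-error corrected p-values for observed cluster extents
#'
#' `p(k) = #\{perm : null_max >= extent(k)\} / n_perm`. Because the identity
#' permutation is part of the null, p-values are bounded below by
#' `1 / n_perm` and the test is exact at its attainable levels.
#'
#' @param observed_extents Integer vector of observed cluster extents.
#' @param null_max_extents Integer vector from [permutation_null()].
#' @return Numeric vector of corrected p-values, one per cluster.
#' @export
fwer_pvalues <- function(observed_extents, null_max_extents) {
  if (length(null_max_extents) == 0L)
    stop("empty null distribution", call. = FALSE)
  vapply(observed_extents,
         function(e) mean(null_max_extents >= e),
         numeric(1))
}

#' Topological cluster-extent inference with sign-flip FWER correction
#'
#' Full pipeline: one-sample t map, CDT thresholding, signed cluster labeling
#' on the topology, permutation null of the maximum cluster extent (pooled
#' over both signs), corrected p-values and a significance mask. With the
#' spatial structure as topology this reduces exactly to conventional spatial
#' cluster-extent inference.
#'
#' @inheritParams permutation_null
#' @param alpha Cluster-level significance level (default 0.05).
#' @return An object of class `inference_result`: per-node `cluster_id`,
#'   `significant`; per-cluster `cluster_sign`, `extent`, `p_fwer`;
#'   `null_max_extents`, `stat` (the [group_t_statistic()] map) and provenance
#'   fields `cdt`, `cdt_scale`, `alpha`, `n_perm`, `seed`, `exhaustive`.
#' @export
run_inference <- function(sample, topology, cdt = 3.3, alpha = 0.05,
                          n_perm = 1000L, seed = 1L, exhaustive = FALSE,
                          cdt_scale = c("z", "t")) {
  if (!inherits(sample, "subject_sample")) sample <- subject_sample(sample)
  cdt_scale <- match.arg(cdt_scale)
  stat <- group_t_statistic(sample)
  mask <- threshold_map(stat, cdt, scale = cdt_scale)
  lab <- label_clusters(mask, topology)
  null_max <- permutation_null(sample, topology, cdt, n_perm = n_perm,
                               seed = seed, exhaustive = exhaustive,
                               cdt_scale = cdt_scale)
  p <- fwer_pvalues(lab$extent, null_max)
  significant <- lab$cluster_id > 0L & lab$cluster_id %in% which(p < alpha)
  structure(list(cluster_id = lab$cluster_id, cluster_sign = lab$cluster_sign,
                 extent = lab$extent, p_fwer = p, significant = significant,
                 null_max_extents = null_max, stat = stat,
                 cdt = cdt, cdt_scale = cdt_scale, alpha = alpha,
                 n_perm = length(null_max), seed = seed,
                 exhaustive = exhaustive),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("<inference_result> %d nodes, %d cluster(s), %d significant at alpha = %g\n",
              length(x$cluster_id), length(x$extent), sum(x$p_fwer < x$alpha),
              x$alpha))
  if (length(x$extent) > 0L)
    print(utils::head(data.frame(cluster = seq_along(x$extent),
                                 sign = x$cluster_sign, extent = x$extent,
                                 p_fwer = x$p_fwer), 10))
  invisible(x)
}

#' Per-node predicted sign of an inference result
#'
#' `cluster_sign` of the node's cluster where the node is significant, else 0.
#' This is the binary-classification view used by the evaluation module.
#'
#' @param result An [run_inference()] result.
#' @return Integer vector in `\{-1, 0, 1\}`.
#' @export
predicted_sign <- function(result) {
  stopifnot(inherits(result, "inference_result"))
  out <- integer(length(result$cluster_id))
  sig <- result$significant
  out[sig] <- result$cluster_sign[result$cluster_id[sig]]
  out
}
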