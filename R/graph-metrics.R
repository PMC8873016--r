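#' Density grid over sparsity thresholds
#'
#' The grid of network densities (fraction of possible edges retained) at
#' which topological metrics are evaluated. The default spans 10\% to 34\%
#' in steps of 1\% (25 levels), the density range over which case-control
#' efficiency curves are typically summarized by their area under the
#' curve.
#'
#' @param kappa_min,kappa_max density bounds, \code{0 < kappa_min <
#'   kappa_max < 1}.
#' @param step density increment; must tile the range exactly (the last
#'   grid point falls on \code{kappa_max} within 1e-12).
#' @return numeric vector of densities, class \code{fc_density_grid}.
#' @export
density_grid <- function(kappa_min = 0.10, kappa_max = 0.34, step = 0.01) {
  check_number(kappa_min, "kappa_min", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(kappa_max, "kappa_max", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (kappa_min >= kappa_max) stop_fc("need kappa_min < kappa_max")
  check_number(step, "step", lower = 0, strict_lower = TRUE)
  m <- round((kappa_max - kappa_min) / step)
  if (m < 1 || abs(kappa_min + m * step - kappa_max) > 1e-9)
    stop_fc("step %g does not tile [%g, %g]", step, kappa_min, kappa_max)
  grid <- kappa_min + step * seq(0, m)
  grid[m + 1] <- kappa_max
  structure(grid, class = "fc_density_grid")
}

#' Proportional (density) thresholding
#'
#' Keeps the strongest positive connections at a fixed edge density:
#' negative and zero Fisher-z values are removed first (configurable to
#' absolute values), then the \code{K = round(kappa * N(N-1)/2)} largest
#' remaining upper-triangular weights are retained and all others zeroed.
#' Ties are broken by lexicographic (row, column) order so the retained set
#' is deterministic.
#'
#' By default the retained weights are kept on the raw Fisher-z scale:
#' between-subject differences in overall connectivity strength are part of
#' the case-control signal and survive into the path-based metrics.
#' \code{normalize = TRUE} divides retained weights by their per-graph
#' maximum instead, which bounds efficiencies in \code{[0, 1]} but makes
#' every metric invariant to a subject's overall connectivity scale.
#'
#' @param z an \code{fc_connectivity} (or symmetric numeric matrix, zero
#'   diagonal).
#' @param kappa target density in (0, 1).
#' @param negative how to treat negative z values: \code{"zero"} (drop,
#'   default) or \code{"absolute"}.
#' @param normalize divide retained weights by their per-graph maximum
#'   (default FALSE; see Details).
#' @return An \code{fc_graph}: list with \code{w} (weight matrix),
#'   \code{density} (realized), \code{n_edges}, \code{kappa}, and
#'   \code{saturated} (TRUE when fewer than K positive edges existed, in
#'   which case all of them are kept and a warning is raised).
#' @export
proportional_threshold <- function(z, kappa, negative = c("zero", "absolute"),
                                   normalize = FALSE) {
  negative <- match.arg(negative)
  check_number(kappa, "kappa", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  n <- nrow(z)
  w0 <- unclass(z)
  if (negative == "absolute") w0 <- abs(w0)
  n_possible <- n * (n - 1) / 2
  K <- round(kappa * n_possible)
  if (K < 1) stop_fc("kappa = %g yields zero edges on %d nodes", kappa, n)
  ut <- which(upper.tri(w0), arr.ind = TRUE)
  wt <- w0[ut]
  pos <- wt > 0
  ut <- ut[pos, , drop = FALSE]
  wt <- wt[pos]
  saturated <- length(wt) < K
  if (saturated) {
    warning(sprintf("only %d positive edges available for K = %d (kappa = %g); keeping all",
                    length(wt), K, kappa), call. = FALSE)
    keep <- seq_along(wt)
  } else {
    ord <- order(-wt, ut[, 1], ut[, 2])
    keep <- ord[seq_len(K)]
  }
  w <- matrix(0, n, n, dimnames = dimnames(w0))
  w[ut[keep, , drop = FALSE]] <- wt[keep]
  w <- w + t(w)
  if (normalize && any(w > 0)) w <- w / max(w)
  structure(list(w = w, density = length(keep) / n_possible,
                 n_edges = length(keep), kappa = kappa,
                 saturated = saturated),
            class = "fc_graph")
}

as_weight_matrix <- function(g) {
  if (inherits(g, "fc_graph")) g$w
  else if (is.matrix(g)) g
  else stop_fc("expected an fc_graph or weight matrix")
}

#' Weight-to-length conversion
#'
#' Path-based metrics read edge weights as conductances: the length of an
#' edge is the reciprocal of its weight, absent edges have infinite
#' length, and the diagonal is zero.
#'
#' @param g an \code{fc_graph} or non-negative weight matrix.
#' @return length matrix.
#' @export
to_length_matrix <- function(g) {
  w <- as_weight_matrix(g)
  if (any(w < 0)) stop_fc("weights must be non-negative")
  L <- ifelse(w > 0, 1 / w, Inf)
  diag(L) <- 0
  L
}

#' All-pairs shortest path distances
#'
#' Dijkstra from every source on the length matrix; unreachable pairs are
#' \code{Inf}.
#'
#' @param length_matrix non-negative lengths (see [to_length_matrix()]).
#' @return distance matrix.
#' @export
shortest_path_matrix <- function(length_matrix) {
  if (any(length_matrix < 0)) stop_fc("lengths must be non-negative")
  D <- cpp_shortest_paths(length_matrix)
  dimnames(D) <- dimnames(length_matrix)
  D
}

#' Global efficiency
#'
#' Average inverse shortest-path distance over all ordered node pairs,
#' \code{E_glob = sum(1/d_ij) / (N (N-1))} with \code{1/Inf = 0}.
#' Disconnected pairs therefore contribute zero.
#'
#' @param g an \code{fc_graph} or weight matrix.
#' @param D optional precomputed distance matrix.
#' @return scalar in \code{[0, 1]} for max-normalized weights.
#' @export
global_efficiency <- function(g, D = NULL) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  if (n < 2) stop_fc("need at least 2 nodes")
  D <- D %||% shortest_path_matrix(to_length_matrix(w))
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' Per-node average inverse distance to every other node,
#' \code{E_nodal(i) = sum_j 1/d_ij / (N-1)}.
#'
#' @inheritParams global_efficiency
#' @return numeric vector, one value per node.
#' @export
nodal_efficiency <- function(g, D = NULL) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  if (n < 2) stop_fc("need at least 2 nodes")
  D <- D %||% shortest_path_matrix(to_length_matrix(w))
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' Weighted local efficiency
#'
#' Mean over nodes of the neighbourhood efficiency in the
#' connectivity-toolbox weighted form: for node \code{u} with neighbours
#' \code{N(u)}, the cube-root-weighted sum of inverse shortest-path
#' distances between neighbour pairs on the subgraph induced by
#' \code{N(u)}, normalized by \code{k_u (k_u - 1)}. Nodes with fewer than
#' two neighbours contribute zero.
#'
#' @inheritParams global_efficiency
#' @param nodal return the per-node vector instead of the mean.
#' @return scalar (or vector when \code{nodal = TRUE}).
#' @export
local_efficiency <- function(g, nodal = FALSE) {
  w <- as_weight_matrix(g)
  if (nrow(w) < 2) stop_fc("need at least 2 nodes")
  e <- as.numeric(cpp_local_efficiency(w))
  if (nodal) e else mean(e)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over connected ordered pairs. Disconnected
#' pairs are excluded from the mean; their count is attached as attribute
#' \code{n_infinite} so disconnection never passes silently.
#'
#' @inheritParams global_efficiency
#' @return scalar with attribute \code{n_infinite}.
#' @export
characteristic_path_length <- function(g, D = NULL) {
  w <- as_weight_matrix(g)
  if (nrow(w) < 2) stop_fc("need at least 2 nodes")
  D <- D %||% shortest_path_matrix(to_length_matrix(w))
  off <- D[row(D) != col(D)]
  fin <- is.finite(off)
  if (!any(fin)) stop_fc("graph has no connected pair; path length undefined")
  structure(mean(off[fin]), n_infinite = sum(!fin))
}

#' Weighted clustering coefficient
#'
#' Geometric-mean (cube root) triangle weight form on max-normalized
#' weights: \code{C_i = sum_{j,h} (w_ij w_ih w_jh)^{1/3} / (k_i (k_i-1))},
#' zero for nodes with degree below 2; the global value is the mean over
#' nodes.
#'
#' @inheritParams local_efficiency
#' @return scalar (or per-node vector when \code{nodal = TRUE}).
#' @export
clustering_coefficient <- function(g, nodal = FALSE) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  if (n < 3 && !nodal) stop_fc("need at least 3 nodes")
  mx <- max(w)
  wh <- if (mx > 0) (w / mx)^(1 / 3) else w
  cyc3 <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, cyc3 / (k * (k - 1)), 0)
  if (nodal) ci else mean(ci)
}

#' Nodal degree
#'
#' Count of suprathreshold (nonzero) edges incident to each node. The
#' weighted analogue (strength, the sum of incident weights) is available
#' via \code{type = "strength"}.
#'
#' @param g an \code{fc_graph} or weight matrix.
#' @param type \code{"binary"} (count, default) or \code{"strength"}.
#' @return numeric vector per node (integers for \code{"binary"}).
#' @export
nodal_degree <- function(g, type = c("binary", "strength")) {
  type <- match.arg(type)
  w <- as_weight_matrix(g)
  if (type == "binary") as.integer(rowSums(w > 0)) else rowSums(w)
}

#' Betweenness centrality
#'
#' Fraction of all-pairs shortest paths (on reciprocal-weight lengths)
#' passing through each node, normalized by the \code{(N-1)(N-2)} ordered
#' pairs of other nodes; equal-length path multiplicities share credit
#' fractionally.
#'
#' @inheritParams global_efficiency
#' @return numeric vector per node, each value in \code{[0, 1]}.
#' @export
betweenness <- function(g) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  if (n < 3) return(rep(0, n))
  bc <- as.numeric(cpp_betweenness(to_length_matrix(w)))
  2 * bc / ((n - 1) * (n - 2))
}

# Internal fast path for metric_curves: rank the positive upper-triangle
# weights once and materialize each density's graph as a prefix of that
# ranking. Exactly equivalent to calling proportional_threshold() per
# density (same tie rule: weight descending, then lexicographic (i, j)).
threshold_prefix <- function(z, kappas, negative = "zero",
                             normalize = FALSE) {
  n <- nrow(z)
  w0 <- unclass(z)
  if (negative == "absolute") w0 <- abs(w0)
  n_possible <- n * (n - 1) / 2
  ut <- which(upper.tri(w0), arr.ind = TRUE)
  wt <- w0[ut]
  pos <- wt > 0
  ut <- ut[pos, , drop = FALSE]
  wt <- wt[pos]
  ord <- order(-wt, ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]
  wt <- wt[ord]
  lapply(kappas, function(kappa) {
    K <- round(kappa * n_possible)
    if (K < 1) stop_fc("kappa = %g yields zero edges on %d nodes", kappa, n)
    saturated <- length(wt) < K
    if (saturated)
      warning(sprintf("only %d positive edges available for K = %d (kappa = %g); keeping all",
                      length(wt), K, kappa), call. = FALSE)
    keep <- seq_len(min(K, length(wt)))
    w <- matrix(0, n, n, dimnames = dimnames(w0))
    w[ut[keep, , drop = FALSE]] <- wt[keep]
    w <- w + t(w)
    if (normalize && length(keep)) w <- w / wt[1]
    structure(list(w = w, density = length(keep) / n_possible,
                   n_edges = length(keep), kappa = kappa,
                   saturated = saturated),
              class = "fc_graph")
  })
}

ALL_METRICS <- c("e_glob", "e_loc", "l_p", "c_p",
                 "degree", "e_nodal", "betweenness")
GLOBAL_METRICS <- c("e_glob", "e_loc", "l_p", "c_p")
NODAL_METRICS <- c("degree", "e_nodal", "betweenness")

#' Metric curves across the density grid
#'
#' Thresholds one connectivity matrix at every grid density and evaluates
#' the requested global and nodal metrics, logging the number of
#' disconnected node pairs per density.
#'
#' @param z an \code{fc_connectivity}.
#' @param grid an \code{fc_density_grid}.
#' @param metrics subset of \code{c("e_glob", "e_loc", "l_p", "c_p",
#'   "degree", "e_nodal", "betweenness")}.
#' @param negative passed to [proportional_threshold()].
#' @return list of class \code{fc_metric_curves}: \code{kappa} (the grid),
#'   \code{global} (density x metric matrix), \code{nodal} (list of node x
#'   density matrices), \code{n_disconnected} (per density).
#' @export
metric_curves <- function(z, grid, metrics = ALL_METRICS,
                          negative = "zero") {
  metrics <- match.arg(metrics, ALL_METRICS, several.ok = TRUE)
  kappa <- as.numeric(grid)
  n <- nrow(z)
  gmet <- intersect(GLOBAL_METRICS, metrics)
  nmet <- intersect(NODAL_METRICS, metrics)
  gl <- matrix(NA_real_, length(kappa), length(gmet),
               dimnames = list(NULL, gmet))
  nd <- lapply(nmet, function(m) matrix(NA_real_, n, length(kappa)))
  names(nd) <- nmet
  n_disc <- integer(length(kappa))
  need_dist <- length(intersect(c("e_glob", "e_nodal", "l_p"), metrics)) > 0
  graphs <- threshold_prefix(z, kappa, negative = negative)
  for (i in seq_along(kappa)) {
    g <- graphs[[i]]
    D <- if (need_dist) shortest_path_matrix(to_length_matrix(g)) else NULL
    if (!is.null(D)) {
      off <- D[row(D) != col(D)]
      n_disc[i] <- sum(!is.finite(off))
    }
    if ("e_glob" %in% gmet) gl[i, "e_glob"] <- global_efficiency(g, D = D)
    if ("e_loc" %in% gmet) gl[i, "e_loc"] <- local_efficiency(g)
    if ("l_p" %in% gmet)
      gl[i, "l_p"] <- as.numeric(characteristic_path_length(g, D = D))
    if ("c_p" %in% gmet) gl[i, "c_p"] <- clustering_coefficient(g)
    if ("degree" %in% nmet) nd$degree[, i] <- nodal_degree(g)
    if ("e_nodal" %in% nmet) nd$e_nodal[, i] <- nodal_efficiency(g, D = D)
    if ("betweenness" %in% nmet) nd$betweenness[, i] <- betweenness(g)
  }
  structure(list(kappa = kappa, global = gl, nodal = nd,
                 n_disconnected = n_disc),
            class = "fc_metric_curves")
}

#' Area under a metric curve over the density grid
#'
#' Trapezoidal integral of the curve against density; the standard
#' single-number summary of a metric across sparsity levels (a constant
#' curve \code{c} integrates to \code{c * (kappa_max - kappa_min)}).
#'
#' @param curve numeric vector, one value per grid point.
#' @param grid an \code{fc_density_grid} (length >= 2, matching the curve).
#' @return scalar.
#' @export
auc <- function(curve, grid) {
  kappa <- as.numeric(grid)
  if (length(curve) != length(kappa))
    stop_fc("curve length (%d) != grid length (%d)",
            length(curve), length(kappa))
  if (length(kappa) < 2) stop_fc("need at least 2 grid points for AUC")
  dk <- diff(kappa)
  sum(dk * (head(curve, -1) + curve[-1]) / 2)
}

#' AUC summaries for one subject's metric curves
#'
#' @param curves an \code{fc_metric_curves}.
#' @return list with \code{global} (named scalars) and \code{nodal} (list
#'   of per-node vectors).
#' @export
curve_aucs <- function(curves) {
  grid <- curves$kappa
  global <- vapply(colnames(curves$global),
                   function(m) auc(curves$global[, m], grid), numeric(1))
  nodal <- lapply(curves$nodal, function(mat)
    apply(mat, 1, auc, grid = grid))
  list(global = global, nodal = nodal)
}

#' AUC table for a whole cohort
#'
#' Runs connectivity construction, density thresholding, metric curves and
#' AUC for every subject; the per-subject AUCs are the outcomes the group
#' inference consumes.
#'
#' @param cohort an \code{fc_cohort}.
#' @param grid an \code{fc_density_grid}.
#' @param metrics metric subset (see [metric_curves()]).
#' @param scrub_fd_mm optional FD scrubbing threshold (mm).
#' @param negative negative-edge policy for thresholding.
#' @return list of class \code{fc_auc_table}: \code{global} (data.frame,
#'   subject_id + one column per global metric), \code{nodal} (list of
#'   subject x node matrices), \code{node_ids}.
#' @export
cohort_auc_table <- function(cohort, grid = density_grid(),
                             metrics = ALL_METRICS, scrub_fd_mm = NULL,
                             negative = "zero") {
  ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  node_ids <- cohort$nodes$node_id
  gmet <- intersect(GLOBAL_METRICS, metrics)
  nmet <- intersect(NODAL_METRICS, metrics)
  gtab <- matrix(NA_real_, length(ids), length(gmet),
                 dimnames = list(NULL, gmet))
  ntab <- lapply(nmet, function(m)
    matrix(NA_real_, length(ids), length(node_ids),
           dimnames = list(ids, node_ids)))
  names(ntab) <- nmet
  for (i in seq_along(cohort$subjects)) {
    z <- subject_connectivity(cohort$subjects[[i]], scrub_fd_mm = scrub_fd_mm)
    a <- curve_aucs(metric_curves(z, grid, metrics = metrics,
                                  negative = negative))
    if (length(gmet)) gtab[i, ] <- a$global[gmet]
    for (m in nmet) ntab[[m]][i, ] <- a$nodal[[m]]
  }
  structure(list(global = data.frame(subject_id = ids, gtab,
                                     stringsAsFactors = FALSE),
                 nodal = ntab, node_ids = node_ids,
                 kappa = as.numeric(grid)),
            class = "fc_auc_table")
}

#' Write / read an AUC table as tidy CSV
#'
#' Tidy long format: \code{subject_id, metric, node_id} (\code{GLOBAL} for
#' global metrics), \code{auc}.
#'
#' @param auc_table an \code{fc_auc_table}.
#' @param path CSV path.
#' @export
write_auc_table <- function(auc_table, path) {
  gl <- auc_table$global
  rows <- do.call(rbind, lapply(setdiff(names(gl), "subject_id"), function(m)
    data.frame(subject_id = gl$subject_id, metric = m, node_id = "GLOBAL",
               auc = gl[[m]], stringsAsFactors = FALSE)))
  for (m in names(auc_table$nodal)) {
    mat <- auc_table$nodal[[m]]
    rows <- rbind(rows, data.frame(
      subject_id = rep(rownames(mat), times = ncol(mat)),
      metric = m,
      node_id = rep(colnames(mat), each = nrow(mat)),
      auc = as.vector(mat), stringsAsFactors = FALSE))
  }
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_auc_table
#' @export
read_auc_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  gl <- df[df$node_id == "GLOBAL", ]
  ids <- unique(df$subject_id)
  global <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (m in unique(gl$metric))
    global[[m]] <- gl$auc[gl$metric == m][match(ids, gl$subject_id[gl$metric == m])]
  nd <- df[df$node_id != "GLOBAL", ]
  nodal <- list()
  node_ids <- unique(nd$node_id)
  for (m in unique(nd$metric)) {
    sub <- nd[nd$metric == m, ]
    mat <- matrix(NA_real_, length(ids), length(node_ids),
                  dimnames = list(ids, node_ids))
    mat[cbind(match(sub$subject_id, ids), match(sub$node_id, node_ids))] <- sub$auc
    nodal[[m]] <- mat
  }
  structure(list(global = global, nodal = nodal,
                 node_ids = if (length(node_ids)) node_ids else character(0),
                 kappa = NULL),
            class = "fc_auc_table")
}
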