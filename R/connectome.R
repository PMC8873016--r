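#' Pearson correlation matrix of node time series
#'
#' @param timeseries numeric node-by-time matrix with at least 3 timepoints;
#'   every node must have nonzero temporal variance.
#' @param node_ids optional character vector naming the rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(timeseries, node_ids = NULL) {
  if (!is.matrix(timeseries) || !is.numeric(timeseries))
    stop_fc("'timeseries' must be a numeric matrix (nodes x time)")
  if (ncol(timeseries) < 3)
    stop_fc("need at least 3 timepoints, got %d", ncol(timeseries))
  if (any(!is.finite(timeseries)))
    stop_fc("time series contains non-finite values")
  v <- apply(timeseries, 1, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    ids <- if (!is.null(node_ids)) node_ids[bad] else as.character(bad)
    stop_fc("zero-variance node(s): %s", paste(ids, collapse = ", "))
  }
  r <- cor(t(timeseries))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  if (!is.null(node_ids)) dimnames(r) <- list(node_ids, node_ids)
  r
}

#' Fisher z transform of a correlation matrix
#'
#' Off-diagonal entries are transformed as \code{atanh(r)} after clipping
#' \code{|r|} at \code{1 - 1e-7} (keeps z finite at perfect correlation);
#' the diagonal is set exactly to zero.
#'
#' @param r_matrix symmetric correlation matrix, entries in \code{[-1, 1]}.
#' @return A \code{fc_connectivity} object: the z matrix with class
#'   attributes; symmetric, zero diagonal.
#' @export
fisher_z <- function(r_matrix) {
  if (any(abs(r_matrix) > 1 + 1e-12, na.rm = TRUE))
    stop_fc("correlations must lie in [-1, 1]")
  r <- pmin(pmax(r_matrix, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  class(z) <- c("fc_connectivity", class(z))
  z
}

#' Overall functional connectivity strength
#'
#' Mean of the upper-triangular Fisher-z values. The default is the signed
#' mean; \code{positive_only = TRUE} averages only positive edges (both
#' summaries are in circulation; the choice is an analysis covariate, so it
#' is exposed).
#'
#' @param z an \code{fc_connectivity} matrix.
#' @param positive_only average positive z values only.
#' @return scalar.
#' @export
overall_fc_strength <- function(z, positive_only = FALSE) {
  ut <- z[upper.tri(z)]
  if (positive_only) ut <- ut[ut > 0]
  if (!length(ut)) return(0)
  mean(ut)
}

#' Motion scrubbing by framewise displacement
#'
#' Removes timepoints whose framewise displacement (FD) strictly exceeds
#' the threshold (a timepoint exactly at the threshold is kept), preserving
#' temporal order.
#'
#' @param timeseries node-by-time matrix.
#' @param fd_series per-timepoint FD in millimetres, length =
#'   \code{ncol(timeseries)}.
#' @param fd_threshold_mm threshold, default 0.2 mm.
#' @param min_timepoints minimum surviving timepoints (default 3); fewer is
#'   an error because the downstream correlation is degenerate.
#' @return list with \code{timeseries} (scrubbed), \code{n_removed}, and
#'   \code{kept} (logical index).
#' @export
scrub_timepoints <- function(timeseries, fd_series, fd_threshold_mm = 0.2,
                             min_timepoints = 3L) {
  if (length(fd_series) != ncol(timeseries))
    stop_fc("fd_series length (%d) != number of timepoints (%d)",
            length(fd_series), ncol(timeseries))
  keep <- fd_series <= fd_threshold_mm
  if (sum(keep) < min_timepoints)
    stop_fc("only %d timepoints survive FD > %g scrubbing (minimum %d)",
            sum(keep), fd_threshold_mm, min_timepoints)
  list(timeseries = timeseries[, keep, drop = FALSE],
       n_removed = sum(!keep), kept = keep)
}

#' Extract spherical-ROI time series from a 4D image
#'
#' For each node, averages the time courses of all voxels whose centre lies
#' within \code{radius_mm} (Euclidean distance in millimetre space,
#' inclusive boundary) of the node's MNI coordinate. Voxel centres are
#' mapped to millimetres through the image affine; no resampling is done.
#'
#' @param image_4d 4D numeric array (x, y, z, time).
#' @param affine 4x4 voxel-to-millimetre affine (0-based voxel indices).
#' @param nodes an \code{fc_node_set}.
#' @param radius_mm sphere radius, default 5 mm.
#' @return node-by-time matrix, rows ordered as \code{nodes}.
#' @export
extract_sphere_timeseries <- function(image_4d, affine, nodes,
                                      radius_mm = 5) {
  if (length(dim(image_4d)) != 4L)
    stop_fc("'image_4d' must be a 4D array")
  check_number(radius_mm, "radius_mm", lower = 0, strict_lower = TRUE)
  if (!is.matrix(affine) || any(dim(affine) != 4) ||
      abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop_fc("'affine' must be an invertible 4x4 matrix")
  dm <- dim(image_4d)
  # voxel-centre coordinates in mm (0-based indices, NIfTI convention)
  grid <- as.matrix(expand.grid(i = seq_len(dm[1]) - 1L,
                                j = seq_len(dm[2]) - 1L,
                                k = seq_len(dm[3]) - 1L))
  mm <- grid %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(grid), 3, byrow = TRUE)
  tsmat <- matrix(NA_real_, nrow(nodes), dm[4])
  vol <- matrix(image_4d, nrow = prod(dm[1:3]), ncol = dm[4])
  r2 <- radius_mm^2
  empty <- character(0)
  for (i in seq_len(nrow(nodes))) {
    d2 <- (mm[, 1] - nodes$x_mm[i])^2 + (mm[, 2] - nodes$y_mm[i])^2 +
      (mm[, 3] - nodes$z_mm[i])^2
    inside <- d2 <= r2
    if (!any(inside)) { empty <- c(empty, nodes$node_id[i]); next }
    tsmat[i, ] <- colMeans(vol[inside, , drop = FALSE])
  }
  if (length(empty))
    stop_fc("no voxels within %g mm of node(s): %s (poor coverage)",
            radius_mm, paste(empty, collapse = ", "))
  rownames(tsmat) <- nodes$node_id
  tsmat
}

#' @rdname extract_sphere_timeseries
#' @param path path to a 4D NIfTI file.
#' @export
extract_sphere_timeseries_nifti <- function(path, nodes, radius_mm = 5) {
  img <- RNifti::readNifti(path)
  extract_sphere_timeseries(unclass(img), unname(RNifti::xform(img)),
                            nodes = nodes, radius_mm = radius_mm)
}

#' Read / write a connectivity matrix as delimited text
#'
#' CSV with node ids as header row and first column; lossless round-trip
#' (full double precision).
#'
#' @param z an \code{fc_connectivity} (or plain symmetric matrix).
#' @param path file path.
#' @export
write_connectivity <- function(z, path) {
  ids <- rownames(z) %||% sprintf("n%03d", seq_len(nrow(z)))
  df <- data.frame(node_id = ids,
                   format(unclass(z), digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("node_id", ids)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df$node_id
  z <- as.matrix(df[, -1, drop = FALSE])
  dimnames(z) <- list(ids, ids)
  storage.mode(z) <- "double"
  class(z) <- c("fc_connectivity", class(z))
  z
}

#' Connectivity matrix for one subject record
#'
#' Convenience path: optional FD scrubbing, Pearson correlation, Fisher z.
#'
#' @param subject an \code{fc_subject}.
#' @param scrub_fd_mm if non-NULL, scrub timepoints with FD above this
#'   value first (requires \code{fd_series}).
#' @param node_ids optional row names.
#' @return an \code{fc_connectivity}.
#' @export
subject_connectivity <- function(subject, scrub_fd_mm = NULL,
                                 node_ids = NULL) {
  ts <- subject$timeseries
  if (!is.null(scrub_fd_mm)) {
    if (is.null(subject$fd_series))
      stop_fc("subject %s has no fd_series; cannot scrub", subject$subject_id)
    ts <- scrub_timepoints(ts, subject$fd_series, scrub_fd_mm)$timeseries
  }
  fisher_z(correlation_matrix(ts, node_ids = node_ids))
}
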