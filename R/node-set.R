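#' Node set tables
#'
#' A node set binds node identifiers to MNI millimetre coordinates and a
#' functional network label drawn from the seven-category vocabulary used
#' throughout the package: the six cortical networks of the canonical
#' seven-network cortical parcellation that are covered by typical
#' coordinate-based atlases (somatomotor \code{SMN}, ventral attention
#' \code{VAN}, visual \code{VN}, dorsal attention \code{DAN}, default mode
#' \code{DMN}, frontoparietal \code{FPN}) plus a \code{subcortical}
#' network; \code{other} is accepted for nodes outside the vocabulary.
#'
#' @param node_id character vector of unique node identifiers.
#' @param x_mm,y_mm,z_mm finite MNI coordinates in millimetres.
#' @param network_label character vector of network labels.
#' @return A \code{data.frame} of class \code{fc_node_set} with columns
#'   \code{node_id}, \code{x_mm}, \code{y_mm}, \code{z_mm},
#'   \code{network_label}.
#' @seealso [synthetic_node_set()] for a generated stand-in table,
#'   [read_node_set()] to load a real atlas table from CSV.
#' @export
node_set <- function(node_id, x_mm, y_mm, z_mm, network_label) {
  node_id <- as.character(node_id)
  if (anyDuplicated(node_id))
    stop_fc("node_ids must be unique")
  coords <- cbind(x_mm, y_mm, z_mm)
  if (!is.numeric(coords) || any(!is.finite(coords)))
    stop_fc("node coordinates must be finite numbers")
  network_label <- as.character(network_label)
  bad <- setdiff(unique(network_label), c(NETWORK_LABELS, "other"))
  if (length(bad))
    stop_fc("unknown network label(s): %s", paste(bad, collapse = ", "))
  ns <- data.frame(node_id = node_id, x_mm = as.numeric(x_mm),
                   y_mm = as.numeric(y_mm), z_mm = as.numeric(z_mm),
                   network_label = network_label,
                   stringsAsFactors = FALSE)
  class(ns) <- c("fc_node_set", "data.frame")
  ns
}

#' Synthetic node set
#'
#' Generates a deterministic stand-in node table for simulation work. Real
#' coordinate atlases are third-party data and are not shipped with the
#' package; this table only reproduces their *shape* (unique ids, MNI-range
#' coordinates on a lattice, seven-network labels assigned contiguously so
#' that network membership aligns with the modular blocks of the synthetic
#' covariance template). Supply a real atlas via [read_node_set()] for real
#' data.
#'
#' @param n_nodes number of nodes (default 160).
#' @param n_modules number of contiguous label blocks (default 7, one per
#'   network label).
#' @return An \code{fc_node_set}.
#' @export
synthetic_node_set <- function(n_nodes = 160L, n_modules = 7L) {
  check_number(n_nodes, "n_nodes", lower = 1, integer = TRUE)
  check_number(n_modules, "n_modules", lower = 1, integer = TRUE)
  ids <- sprintf("n%03d", seq_len(n_nodes))
  # deterministic lattice folded into MNI-plausible ranges
  i <- seq_len(n_nodes) - 1L
  x <- -70 + (i * 17L) %% 141L
  y <- -100 + (i * 29L) %% 171L
  z <- -60 + (i * 23L) %% 131L
  labels <- rep(NETWORK_LABELS, length.out = n_modules)
  sizes <- module_sizes(n_nodes, n_modules)
  network_label <- rep(labels, times = sizes)
  node_set(ids, x, y, z, network_label)
}

#' Read / write node set CSV
#'
#' CSV columns: \code{node_id}, \code{x_mm}, \code{y_mm}, \code{z_mm},
#' \code{network_label}.
#'
#' @param path file path.
#' @return [read_node_set()] returns an \code{fc_node_set};
#'   [write_node_set()] returns \code{path} invisibly.
#' @export
read_node_set <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_id", "x_mm", "y_mm", "z_mm", "network_label")
  if (!all(need %in% names(df)))
    stop_fc("node set CSV must have columns: %s", paste(need, collapse = ", "))
  node_set(df$node_id, df$x_mm, df$y_mm, df$z_mm, df$network_label)
}

#' @rdname read_node_set
#' @param nodes an \code{fc_node_set}.
#' @export
write_node_set <- function(nodes, path) {
  write.csv(as.data.frame(nodes), path, row.names = FALSE)
  invisible(path)
}

# split n_nodes into n_modules contiguous blocks; remainder goes to the
# last module
module_sizes <- function(n_nodes, n_modules) {
  base <- n_nodes %/% n_modules
  if (base < 1L) stop_fc("more modules (%d) than nodes (%d)", n_modules, n_nodes)
  sizes <- rep(base, n_modules)
  sizes[n_modules] <- sizes[n_modules] + n_nodes %% n_modules
  sizes
}
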