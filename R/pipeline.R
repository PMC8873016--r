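#' Pipeline run configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()]:
#' which stages to run, the synthetic-cohort spec, the density grid,
#' scrubbing, model options and the output root. Unknown keys are rejected
#' so that a typo never silently changes an analysis. The configuration
#' round-trips losslessly through YAML ([read_run_config()] /
#' [write_run_config()]).
#'
#' @param stages character subset of
#'   \code{c("simulate", "construct", "metrics", "stats")}, in pipeline
#'   order.
#' @param synthetic list of arguments for [synthetic_spec()].
#' @param kappa_min,kappa_max,kappa_step density grid (see
#'   [density_grid()]).
#' @param scrub_fd_mm optional FD scrubbing threshold in mm (NULL = no
#'   scrubbing).
#' @param metrics metric subset (see [metric_curves()]).
#' @param contrasts contrasts to run in the stats stage.
#' @param run_hamd also run the symptom-association model.
#' @param fdr_level FDR level.
#' @param min_per_group site filter threshold.
#' @param seed root seed; per-stage streams are derived from it.
#' @return list of class \code{fc_run_config}.
#' @export
run_config <- function(stages = c("simulate", "construct", "metrics", "stats"),
                       synthetic = list(),
                       kappa_min = 0.10, kappa_max = 0.34, kappa_step = 0.01,
                       scrub_fd_mm = NULL,
                       metrics = ALL_METRICS,
                       contrasts = "mdd-vs-nc",
                       run_hamd = FALSE,
                       fdr_level = 0.05,
                       min_per_group = 10L,
                       seed = 1L) {
  stages <- match.arg(stages, c("simulate", "construct", "metrics", "stats"),
                      several.ok = TRUE)
  density_grid(kappa_min, kappa_max, kappa_step)  # validate early
  metrics <- match.arg(metrics, ALL_METRICS, several.ok = TRUE)
  ok_contrasts <- c("mdd-vs-nc", "fedn-vs-nc", "recurrent-vs-nc",
                    "recurrent-vs-fedn")
  if (!all(contrasts %in% ok_contrasts))
    stop_fc("unknown contrast(s): %s",
            paste(setdiff(contrasts, ok_contrasts), collapse = ", "))
  check_number(fdr_level, "fdr_level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (!is.null(scrub_fd_mm))
    check_number(scrub_fd_mm, "scrub_fd_mm", lower = 0, strict_lower = TRUE)
  cfg <- list(stages = stages, synthetic = synthetic,
              kappa_min = kappa_min, kappa_max = kappa_max,
              kappa_step = kappa_step, scrub_fd_mm = scrub_fd_mm,
              metrics = metrics, contrasts = contrasts,
              run_hamd = isTRUE(run_hamd), fdr_level = fdr_level,
              min_per_group = as.integer(min_per_group),
              seed = as.integer(seed))
  class(cfg) <- "fc_run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_fc("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config an \code{fc_run_config}.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# derive a per-stage integer seed from the root seed, stable across runs
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, construct = 211L, metrics = 307L,
               stats = 401L)
  (seed * 7919L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full pipeline
#'
#' Executes simulate, construct, metrics and stats in order under
#' \code{out_dir}; each stage reads the previous stage's serialized outputs
#' so every stage is individually re-runnable. A JSON manifest records the
#' package version, seed, configuration hash, per-stage row counts, dropped
#' sites and any mixed-model fallbacks.
#'
#' @param config an \code{fc_run_config} or path to its YAML file.
#' @param out_dir output root directory.
#' @return the manifest (invisibly), a list; also written to
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "fc_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(
    package = "fctopo",
    version = as.character(packageVersion("fctopo")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = list())

  cohort_dir <- file.path(out_dir, "cohort")
  fc_dir <- file.path(out_dir, "fc")
  auc_path <- file.path(out_dir, "auc.csv")

  if ("simulate" %in% config$stages) {
    args <- config$synthetic
    args$seed <- stage_seed(config$seed, "simulate")
    spec <- do.call(synthetic_spec, args)
    cohort <- synthesize_cohort(spec)
    write_cohort(cohort, cohort_dir)
    manifest$stages$simulate <- list(
      n_subjects = length(cohort$subjects),
      n_sites = spec$n_sites, n_nodes = spec$n_nodes,
      n_timepoints = spec$n_timepoints)
  }

  if ("construct" %in% config$stages) {
    cohort <- read_cohort(cohort_dir)
    dir.create(fc_dir, showWarnings = FALSE)
    for (s in cohort$subjects) {
      z <- subject_connectivity(s, scrub_fd_mm = config$scrub_fd_mm,
                                node_ids = cohort$nodes$node_id)
      write_connectivity(z, file.path(fc_dir, paste0(s$subject_id, ".csv")))
    }
    manifest$stages$construct <- list(
      n_matrices = length(cohort$subjects),
      scrub_fd_mm = config$scrub_fd_mm)
  }

  if ("metrics" %in% config$stages) {
    cohort <- read_cohort(cohort_dir)
    grid <- density_grid(config$kappa_min, config$kappa_max,
                         config$kappa_step)
    ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
    gmet <- intersect(GLOBAL_METRICS, config$metrics)
    nmet <- intersect(NODAL_METRICS, config$metrics)
    gtab <- matrix(NA_real_, length(ids), length(gmet),
                   dimnames = list(NULL, gmet))
    ntab <- lapply(nmet, function(m)
      matrix(NA_real_, length(ids), length(cohort$nodes$node_id),
             dimnames = list(ids, cohort$nodes$node_id)))
    names(ntab) <- nmet
    for (i in seq_along(ids)) {
      z <- read_connectivity(file.path(fc_dir, paste0(ids[i], ".csv")))
      a <- curve_aucs(metric_curves(z, grid, metrics = config$metrics))
      if (length(gmet)) gtab[i, ] <- a$global[gmet]
      for (m in nmet) ntab[[m]][i, ] <- a$nodal[[m]]
    }
    auc_table <- structure(list(
      global = data.frame(subject_id = ids, gtab, stringsAsFactors = FALSE),
      nodal = ntab, node_ids = cohort$nodes$node_id,
      kappa = as.numeric(grid)), class = "fc_auc_table")
    write_auc_table(auc_table, auc_path)
    manifest$stages$metrics <- list(
      n_subjects = length(ids),
      n_densities = length(grid),
      metrics = config$metrics)
  }

  if ("stats" %in% config$stages) {
    auc_table <- read_auc_table(auc_path)
    covariates <- read.csv(file.path(cohort_dir, "covariates.csv"),
                           stringsAsFactors = FALSE)
    nodes <- read_node_set(file.path(cohort_dir, "nodes.csv"))
    stats_info <- list()
    for (ct in config$contrasts) {
      res <- contrast_all_outcomes(auc_table, covariates, contrast = ct,
                                   fdr_level = config$fdr_level,
                                   min_per_group = config$min_per_group)
      write.csv(as.data.frame(res),
                file.path(out_dir, paste0("contrast_", ct, ".csv")),
                row.names = FALSE)
      if (any(res$node_id != "GLOBAL")) {
        net <- map_significant_nodes(res, nodes)
        write.csv(net, file.path(out_dir, paste0("networks_", ct, ".csv")),
                  row.names = FALSE)
      }
      stats_info[[ct]] <- list(
        n_outcomes = nrow(res),
        n_significant = sum(res$significant),
        dropped_sites = as.list(attr(res, "dropped_sites")),
        fallbacks = as.list(table(res$random_structure)))
    }
    if (config$run_hamd) {
      res <- symptom_association(auc_table, covariates,
                                 fdr_level = config$fdr_level,
                                 min_per_site = config$min_per_group)
      write.csv(as.data.frame(res), file.path(out_dir, "contrast_hamd.csv"),
                row.names = FALSE)
      stats_info$hamd <- list(n_outcomes = nrow(res),
                              n_significant = sum(res$significant))
    }
    manifest$stages$stats <- stats_info
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
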