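#' Specification of a synthetic multi-site case-control cohort
#'
#' Describes the generative model used to emulate a multi-site resting-state
#' case-control study at desk scale: per-site samples of patients (MDD, with
#' first-episode drug-naive \code{FEDN} / \code{recurrent} / \code{unknown}
#' subtypes) and normal controls (\code{NC}), each subject carrying a
#' node-by-time BOLD-like series drawn from a modular Gaussian covariance
#' template. Group status attenuates off-diagonal covariance by the factor
#' \code{group_effect_delta} (1 = null); sites perturb connectivity through
#' log-normal random intercepts and patient-specific random slopes, matching
#' the random-effects structure the downstream mixed model assumes.
#'
#' Default sizes mirror the multi-site consortium design the generator
#' emulates: 16 sites, two groups per site, 160 nodes, and subtype mixture
#' fractions close to the published composition (roughly 28\% FEDN and 23\%
#' recurrent among patients, the remainder unlabelled).
#'
#' @param n_sites number of acquisition sites.
#' @param n_per_group_per_site subjects per group per site; either a single
#'   count or a vector of length \code{n_sites}.
#' @param n_nodes number of network nodes.
#' @param n_timepoints time series length per subject.
#' @param n_modules number of covariance modules (community blocks).
#' @param within_module_r,between_module_r correlation levels inside/between
#'   modules; \code{0 <= between < within < 1}.
#' @param group_effect_delta multiplicative attenuation of patient
#'   off-diagonal connectivity, in \code{[0, 1]}; 1 means no group effect.
#' @param subtype_deltas optional named numeric (\code{FEDN},
#'   \code{recurrent}, \code{unknown}) overriding \code{group_effect_delta}
#'   per patient subtype, e.g. to confine the effect to recurrent patients.
#' @param site_intercept_sd,site_slope_sd standard deviations of the
#'   site random intercept and site-specific group slope on the log
#'   connectivity scale.
#' @param covariate_effects named numeric of slopes (log connectivity scale
#'   per standard deviation of the covariate) for \code{age}, \code{sex},
#'   \code{education}, \code{mean_fd}.
#' @param subtype_fractions named numeric (\code{FEDN}, \code{recurrent})
#'   of patient subtype proportions; remainder is labelled \code{unknown}.
#' @param hamd_base,hamd_slope,hamd_sd symptom-score model for patients:
#'   \code{HAMD = hamd_base + hamd_slope * (1 - connectivity scale) + noise}.
#' @param prop_female proportion of female subjects.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return An object of class \code{fc_synth_spec}.
#' @export
synthetic_spec <- function(n_sites = 16L,
                           n_per_group_per_site = 50L,
                           n_nodes = 160L,
                           n_timepoints = 200L,
                           n_modules = 7L,
                           within_module_r = 0.4,
                           between_module_r = 0.05,
                           group_effect_delta = 0.9,
                           subtype_deltas = NULL,
                           site_intercept_sd = 0.1,
                           site_slope_sd = 0.05,
                           covariate_effects = c(),
                           subtype_fractions = c(FEDN = 0.28, recurrent = 0.23),
                           hamd_base = 22,
                           hamd_slope = 10,
                           hamd_sd = 4,
                           prop_female = 0.6,
                           seed = 1L) {
  check_number(n_sites, "n_sites", lower = 1, integer = TRUE)
  if (!is.numeric(n_per_group_per_site) ||
      !length(n_per_group_per_site) %in% c(1L, n_sites) ||
      any(n_per_group_per_site < 1) ||
      any(n_per_group_per_site != round(n_per_group_per_site)))
    stop_fc("'n_per_group_per_site' must be positive integer(s), length 1 or n_sites")
  check_number(n_nodes, "n_nodes", lower = 2, integer = TRUE)
  check_number(n_timepoints, "n_timepoints", lower = 2, integer = TRUE)
  check_number(n_modules, "n_modules", lower = 1, integer = TRUE)
  check_number(within_module_r, "within_module_r", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(between_module_r, "between_module_r", lower = 0,
               upper = within_module_r,
               strict_upper = within_module_r > 0)
  if (between_module_r > within_module_r)
    stop_fc("between_module_r must not exceed within_module_r")
  check_number(group_effect_delta, "group_effect_delta", lower = 0, upper = 1)
  check_number(site_intercept_sd, "site_intercept_sd", lower = 0)
  check_number(site_slope_sd, "site_slope_sd", lower = 0)
  if (!is.null(subtype_deltas)) {
    if (is.null(names(subtype_deltas)) ||
        !all(names(subtype_deltas) %in% c("FEDN", "recurrent", "unknown")))
      stop_fc("'subtype_deltas' must be named with patient subtypes")
    stopifnot(all(subtype_deltas >= 0 & subtype_deltas <= 1))
  }
  if (length(covariate_effects) &&
      (is.null(names(covariate_effects)) ||
       !all(names(covariate_effects) %in% c("age", "sex", "education", "mean_fd"))))
    stop_fc("'covariate_effects' must be named with known covariates")
  sf <- c(FEDN = 0, recurrent = 0)
  sf[names(subtype_fractions)] <- subtype_fractions
  if (any(sf < 0) || sum(sf) > 1)
    stop_fc("subtype fractions must be non-negative and sum to at most 1")
  check_number(prop_female, "prop_female", lower = 0, upper = 1)
  check_number(seed, "seed", integer = TRUE)
  spec <- list(n_sites = as.integer(n_sites),
               n_per_group_per_site = as.integer(rep(n_per_group_per_site,
                                                     length.out = n_sites)),
               n_nodes = as.integer(n_nodes),
               n_timepoints = as.integer(n_timepoints),
               n_modules = as.integer(n_modules),
               within_module_r = within_module_r,
               between_module_r = between_module_r,
               group_effect_delta = group_effect_delta,
               subtype_deltas = subtype_deltas,
               site_intercept_sd = site_intercept_sd,
               site_slope_sd = site_slope_sd,
               covariate_effects = covariate_effects,
               subtype_fractions = sf,
               hamd_base = hamd_base, hamd_slope = hamd_slope,
               hamd_sd = hamd_sd,
               prop_female = prop_female,
               seed = as.integer(seed))
  class(spec) <- "fc_synth_spec"
  spec
}

#' Modular covariance template
#'
#' Builds the block-structured correlation matrix from which synthetic BOLD
#' series are drawn: \code{within_module_r} inside each of \code{n_modules}
#' contiguous blocks, \code{between_module_r} elsewhere off-diagonal, unit
#' diagonal. If the raw block matrix is not positive semi-definite it is
#' repaired deterministically by clipping negative eigenvalues at zero and
#' re-normalizing to unit diagonal.
#'
#' @inheritParams synthetic_spec
#' @return A symmetric PSD \code{n_nodes x n_nodes} matrix with unit
#'   diagonal and attribute \code{modules} (module index per node).
#' @export
build_covariance_template <- function(n_nodes, n_modules,
                                      within_module_r, between_module_r) {
  check_number(n_nodes, "n_nodes", lower = 2, integer = TRUE)
  check_number(n_modules, "n_modules", lower = 1, integer = TRUE)
  check_number(within_module_r, "within_module_r", lower = 0, upper = 1,
               strict_upper = TRUE)
  if (between_module_r < 0 || between_module_r > within_module_r ||
      (within_module_r > 0 && between_module_r >= within_module_r &&
       between_module_r != 0))
    stop_fc("need 0 <= between_module_r < within_module_r (or both 0)")
  sizes <- module_sizes(n_nodes, n_modules)
  modules <- rep(seq_len(n_modules), times = sizes)
  S <- matrix(between_module_r, n_nodes, n_nodes)
  same <- outer(modules, modules, "==")
  S[same] <- within_module_r
  diag(S) <- 1
  S <- repair_psd(S)
  attr(S, "modules") <- modules
  S
}

# Deterministic PSD repair: clip eigenvalues at zero, reconstruct,
# re-normalize to unit diagonal. Errors if the result is still indefinite
# beyond tolerance.
repair_psd <- function(S, tol = 1e-10) {
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) >= -tol) {
    return((S + t(S)) / 2)
  }
  lam <- pmax(ev$values, 0)
  R <- ev$vectors %*% (lam * t(ev$vectors))
  d <- sqrt(diag(R))
  if (any(d <= 0)) stop_fc("PSD repair produced a zero-variance node")
  R <- R / (d %o% d)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  emin <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (emin < -tol)
    stop_fc("matrix not PSD after repair (smallest eigenvalue %.3e)", emin)
  R
}

# covariate standardization constants used when covariate_effects enter the
# connectivity scale (theoretical moments of the default sampling laws)
COVARIATE_SCALE <- list(
  age       = c(center = 39,   scale = 12.124),  # uniform(18, 60)
  education = c(center = 13,   scale = 4.041),   # uniform(6, 20)
  mean_fd   = c(center = 0.11, scale = 0.06),    # folded normal(0.10, 0.06)
  sex       = c(center = 0.4,  scale = 0.49)     # male indicator
)

sample_covariates <- function(spec) {
  sex <- if (runif(1) < spec$prop_female) "female" else "male"
  list(age = runif(1, 18, 60),
       sex = sex,
       education = runif(1, 6, 20),
       mean_fd = abs(rnorm(1, 0.10, 0.06)))
}

covariate_log_effect <- function(covariates, effects) {
  if (!length(effects)) return(0)
  tot <- 0
  for (nm in names(effects)) {
    x <- if (nm == "sex") as.numeric(covariates$sex == "male") else covariates[[nm]]
    sc <- COVARIATE_SCALE[[nm]]
    tot <- tot + effects[[nm]] * (x - sc["center"]) / sc["scale"]
  }
  unname(tot)
}

#' Synthesize one subject
#'
#' Draws a subject record from the generative model: the template's
#' off-diagonal covariance is scaled by the subtype-specific group
#' attenuation times \code{exp(site intercept + site slope * patient +
#' covariate effects)}, clipped to the valid correlation range and
#' PSD-repaired, then \code{n_timepoints} independent multivariate-normal
#' samples are drawn. Consumes only R's current random number stream.
#'
#' @param template PSD correlation template (see
#'   [build_covariance_template()]).
#' @param group \code{"NC"} or \code{"MDD"}.
#' @param site_effects list with elements \code{intercept} and \code{slope}
#'   (log connectivity scale).
#' @param covariates optional list (\code{age}, \code{sex},
#'   \code{education}, \code{mean_fd}); sampled from documented defaults
#'   when missing (age ~ U(18,60), education ~ U(6,20), mean FD folded
#'   normal(0.10, 0.06) mm).
#' @param spec an \code{fc_synth_spec}.
#' @param subject_id,site_id,subtype identifiers; subtype defaults to
#'   \code{"none"} for NC and \code{"unknown"} for MDD.
#' @return A list of class \code{fc_subject} with the subject's covariates,
#'   \code{timeseries} (\code{n_nodes x n_timepoints}), \code{fd_series},
#'   \code{hamd} (patients only) and \code{on_medication}.
#' @export
synthesize_subject <- function(template, group, site_effects, spec,
                               covariates = NULL,
                               subject_id = "s001", site_id = "site01",
                               subtype = NULL) {
  if (!group %in% c("NC", "MDD")) stop_fc("invalid group label '%s'", group)
  subtype <- subtype %||% if (group == "MDD") "unknown" else "none"
  if (group == "NC" && subtype != "none")
    stop_fc("NC subjects must have subtype 'none'")
  if (group == "MDD" && !subtype %in% c("FEDN", "recurrent", "unknown"))
    stop_fc("invalid MDD subtype '%s'", subtype)
  covariates <- covariates %||% sample_covariates(spec)
  if (!all(is.finite(c(covariates$age, covariates$education, covariates$mean_fd))))
    stop_fc("non-finite covariate for subject %s", subject_id)
  is_patient <- group == "MDD"
  delta <- if (is_patient) {
    sd_ <- spec$subtype_deltas
    if (!is.null(sd_) && subtype %in% names(sd_)) sd_[[subtype]]
    else spec$group_effect_delta
  } else 1
  log_scale <- site_effects$intercept + site_effects$slope * is_patient +
    covariate_log_effect(covariates, spec$covariate_effects)
  scale <- delta * exp(log_scale)
  S <- template
  off <- row(S) != col(S)
  S[off] <- pmin(pmax(S[off] * scale, -0.99), 0.99)
  S <- repair_psd(S)
  ev <- eigen(S, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S))
  ts <- A %*% matrix(rnorm(nrow(S) * spec$n_timepoints),
                     nrow(S), spec$n_timepoints)
  fd <- abs(rnorm(spec$n_timepoints, covariates$mean_fd, 0.04))
  hamd <- if (is_patient) {
    max(0, round(spec$hamd_base + spec$hamd_slope * (1 - scale) +
                   rnorm(1, 0, spec$hamd_sd)))
  } else NA_real_
  on_med <- if (is_patient) {
    if (runif(1) < 0.3) NA else runif(1) < 0.4   # reported for ~70% of patients
  } else NA
  structure(list(subject_id = subject_id, site_id = site_id,
                 group = group, subtype = subtype,
                 age = covariates$age, sex = covariates$sex,
                 education = covariates$education,
                 mean_fd = covariates$mean_fd,
                 hamd = hamd, on_medication = on_med,
                 timeseries = ts, fd_series = fd,
                 connectivity_scale = scale),
            class = "fc_subject")
}

#' Synthesize a multi-site cohort
#'
#' Draws site random effects once per site, then generates all subjects.
#' Patient subtype labels are assigned deterministically by rounded
#' fractions within each site. Fully reproducible from \code{spec$seed};
#' the caller's RNG state is preserved.
#'
#' @param spec an \code{fc_synth_spec}.
#' @return A list of class \code{fc_cohort} with elements \code{subjects}
#'   (list of \code{fc_subject}), \code{nodes} (an \code{fc_node_set}),
#'   \code{site_effects}, and \code{spec}.
#' @export
synthesize_cohort <- function(spec) {
  stopifnot(inherits(spec, "fc_synth_spec"))
  if (spec$n_sites < 1 || any(spec$n_per_group_per_site < 1))
    stop_fc("need at least one site and one subject per group per site")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  template <- build_covariance_template(spec$n_nodes, spec$n_modules,
                                        spec$within_module_r,
                                        spec$between_module_r)
  nodes <- synthetic_node_set(spec$n_nodes, spec$n_modules)
  site_ids <- sprintf("site%02d", seq_len(spec$n_sites))
  site_effects <- lapply(seq_len(spec$n_sites), function(s)
    list(intercept = rnorm(1, 0, spec$site_intercept_sd),
         slope = rnorm(1, 0, spec$site_slope_sd)))
  names(site_effects) <- site_ids
  subjects <- list()
  idx <- 0L
  for (s in seq_len(spec$n_sites)) {
    n_g <- spec$n_per_group_per_site[s]
    subtypes <- assign_subtypes(n_g, spec$subtype_fractions)
    for (grp in c("NC", "MDD")) {
      for (k in seq_len(n_g)) {
        idx <- idx + 1L
        subjects[[idx]] <- synthesize_subject(
          template, grp, site_effects[[s]], spec,
          subject_id = sprintf("sub%04d", idx),
          site_id = site_ids[s],
          subtype = if (grp == "MDD") subtypes[k] else "none")
      }
    }
  }
  structure(list(subjects = subjects, nodes = nodes,
                 site_effects = site_effects, spec = spec),
            class = "fc_cohort")
}

# deterministic subtype assignment by rounded fractions
assign_subtypes <- function(n, fractions) {
  n_fedn <- round(n * fractions[["FEDN"]])
  n_rec <- round(n * fractions[["recurrent"]])
  if (n_fedn + n_rec > n) n_rec <- n - n_fedn
  c(rep("FEDN", n_fedn), rep("recurrent", n_rec),
    rep("unknown", n - n_fedn - n_rec))
}

#' @export
print.fc_cohort <- function(x, ...) {
  cov <- cohort_covariates(x)
  cat(sprintf("fc_cohort: %d subjects (%d MDD / %d NC), %d sites, %d nodes x %d timepoints\n",
              nrow(cov), sum(cov$group == "MDD"), sum(cov$group == "NC"),
              length(unique(cov$site_id)), x$spec$n_nodes, x$spec$n_timepoints))
  invisible(x)
}

#' Cohort covariate table
#'
#' @param cohort an \code{fc_cohort}.
#' @return data.frame with one row per subject: \code{subject_id},
#'   \code{site_id}, \code{group}, \code{subtype}, \code{age}, \code{sex},
#'   \code{education}, \code{mean_fd}, \code{hamd}, \code{on_medication}.
#' @export
cohort_covariates <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$subject_id, site_id = s$site_id,
               group = s$group, subtype = s$subtype,
               age = s$age, sex = s$sex, education = s$education,
               mean_fd = s$mean_fd, hamd = s$hamd,
               on_medication = s$on_medication,
               stringsAsFactors = FALSE)))
}

#' Serialize / load a cohort as delimited text
#'
#' Writes \code{covariates.csv}, \code{nodes.csv} and one tab-delimited
#' node-by-time matrix per subject under \code{timeseries/}; FD series go
#' under \code{fd/}. [read_cohort()] restores the same structure (the
#' generative spec and latent site effects are not serialized).
#'
#' @param cohort an \code{fc_cohort}.
#' @param dir output directory (created if needed).
#' @return the directory (invisibly) / an \code{fc_cohort}.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "fd"), showWarnings = FALSE)
  write.csv(cohort_covariates(cohort), file.path(dir, "covariates.csv"),
            row.names = FALSE)
  write_node_set(cohort$nodes, file.path(dir, "nodes.csv"))
  for (s in cohort$subjects) {
    write.table(format(s$timeseries, digits = 15, trim = TRUE),
                file.path(dir, "timeseries", paste0(s$subject_id, ".tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    if (!is.null(s$fd_series))
      write.table(format(s$fd_series, digits = 15, trim = TRUE),
                  file.path(dir, "fd", paste0(s$subject_id, ".tsv")),
                  sep = "\t", row.names = FALSE, col.names = FALSE,
                  quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cov <- read.csv(file.path(dir, "covariates.csv"), stringsAsFactors = FALSE)
  nodes <- read_node_set(file.path(dir, "nodes.csv"))
  subjects <- lapply(seq_len(nrow(cov)), function(i) {
    row <- cov[i, ]
    ts <- as.matrix(read.table(
      file.path(dir, "timeseries", paste0(row$subject_id, ".tsv")),
      sep = "\t"))
    dimnames(ts) <- NULL
    fd_path <- file.path(dir, "fd", paste0(row$subject_id, ".tsv"))
    fd <- if (file.exists(fd_path)) as.numeric(read.table(fd_path)[[1]]) else NULL
    structure(c(as.list(row),
                list(timeseries = ts, fd_series = fd)),
              class = "fc_subject")
  })
  structure(list(subjects = subjects, nodes = nodes,
                 site_effects = NULL, spec = NULL),
            class = "fc_cohort")
}
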