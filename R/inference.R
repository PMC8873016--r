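#' Site-size filtering
#'
#' Drops every subject from sites where either group has fewer than
#' \code{min_per_group} members (sites with exactly the minimum in both
#' groups are retained). Mirrors the usual multi-site exclusion rule that
#' keeps the per-site mixed-model contrasts estimable.
#'
#' @param covariates covariate data.frame with \code{site_id} and
#'   \code{group} columns (or an \code{fc_cohort}).
#' @param min_per_group minimum subjects per group per site (default 10).
#' @return filtered object of the same type, with attribute
#'   \code{dropped_sites}.
#' @export
filter_sites <- function(covariates, min_per_group = 10L) {
  check_number(min_per_group, "min_per_group", lower = 1, integer = TRUE)
  if (inherits(covariates, "fc_cohort")) {
    cov <- cohort_covariates(covariates)
    keep_sites <- surviving_sites(cov, min_per_group)
    keep <- cov$site_id %in% keep_sites
    if (!any(keep)) stop_fc("no site survives the %d-per-group filter", min_per_group)
    out <- covariates
    out$subjects <- covariates$subjects[keep]
    attr(out, "dropped_sites") <- setdiff(unique(cov$site_id), keep_sites)
    return(out)
  }
  keep_sites <- surviving_sites(covariates, min_per_group)
  out <- covariates[covariates$site_id %in% keep_sites, , drop = FALSE]
  if (!nrow(out)) stop_fc("no site survives the %d-per-group filter", min_per_group)
  attr(out, "dropped_sites") <- setdiff(unique(covariates$site_id), keep_sites)
  out
}

surviving_sites <- function(cov, min_per_group) {
  tab <- table(cov$site_id, cov$group)
  groups <- colnames(tab)
  if (length(groups) < 2) return(character(0))
  rownames(tab)[apply(tab >= min_per_group, 1, all)]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment:
#' \code{q_(i) = min_{j >= i} p_(j) m / j}, capped at 1.
#'
#' @param p numeric vector of p-values.
#' @return vector of q-values, same order as \code{p}.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Build the modelling frame for one contrast. Returns a data.frame with
# the binary effect column `grp` (reference level coded 0) plus covariates
# and site_id.
prepare_contrast_data <- function(covariates, contrast, min_per_group = 10L) {
  sel <- switch(contrast,
    "mdd-vs-nc" = list(keep = covariates$group %in% c("MDD", "NC"),
                       one = covariates$group == "MDD",
                       levels = c("NC", "MDD")),
    "fedn-vs-nc" = list(keep = covariates$group == "NC" |
                          covariates$subtype == "FEDN",
                        one = covariates$subtype == "FEDN",
                        levels = c("NC", "FEDN")),
    "recurrent-vs-nc" = list(keep = covariates$group == "NC" |
                               covariates$subtype == "recurrent",
                             one = covariates$subtype == "recurrent",
                             levels = c("NC", "recurrent")),
    "recurrent-vs-fedn" = list(keep = covariates$subtype %in%
                                 c("FEDN", "recurrent"),
                               one = covariates$subtype == "recurrent",
                               levels = c("FEDN", "recurrent")),
    stop_fc("unknown contrast '%s'", contrast))
  df <- covariates[sel$keep, , drop = FALSE]
  df$grp <- as.numeric(sel$one[sel$keep])
  for (lev in c(0, 1))
    if (!any(df$grp == lev))
      stop_fc("contrast '%s': subgroup '%s' is empty in this cohort",
              contrast, sel$levels[lev + 1])
  df$group <- ifelse(df$grp == 1, sel$levels[2], sel$levels[1])
  df <- filter_sites(df, min_per_group)
  for (lev in c(0, 1))
    if (!any(df$grp == lev))
      stop_fc("contrast '%s': subgroup '%s' empty after site filtering",
              contrast, sel$levels[lev + 1])
  attr(df, "levels") <- sel$levels
  df
}

#' Fit the site-random-slope mixed model for one outcome
#'
#' Fits \code{y ~ effect + covariates + (1 + effect | site)} by REML and
#' reports the Wald t for the effect of interest. If the random-slope fit
#' fails to converge or is singular it refits with a site random intercept
#' only, and as a last resort with ordinary least squares using site fixed
#' effects; the structure actually used is always recorded.
#'
#' Degrees of freedom default to the residual convention
#' (\code{n - p} fixed-effect coefficients), the default of the
#' mixed-model tooling this analysis family is usually run with. The
#' Satterthwaite approximation is available via \code{df_method}; note
#' that with a handful of sites it collapses the group-effect df towards
#' the site count whenever a (possibly spurious) random slope is retained,
#' which is markedly conservative.
#'
#' @param y outcome vector, aligned with \code{data} rows.
#' @param data model frame containing the effect column, covariates and
#'   \code{site_id}.
#' @param effect name of the column whose coefficient is tested (e.g. the
#'   0/1 group code \code{"grp"}, or \code{"hamd"}).
#' @param covariate_names fixed covariates of no interest; \code{"sex"} is
#'   coded as a male indicator.
#' @param interaction optional extra term, e.g. \code{"grp:sex_male"}.
#' @param df_method \code{"residual"} (default) or \code{"satterthwaite"}.
#' @return one-row data.frame: \code{beta}, \code{se}, \code{t}, \code{df},
#'   \code{p}, \code{n_used}, \code{converged}, \code{random_structure}.
#' @export
fit_lme <- function(y, data, effect = "grp",
                    covariate_names = c("age", "sex", "education", "mean_fd"),
                    interaction = NULL,
                    df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  df <- data
  df$.y <- y
  if ("sex" %in% covariate_names) {
    df$sex_male <- as.numeric(df$sex == "male")
    covariate_names[covariate_names == "sex"] <- "sex_male"
  }
  terms <- c(effect, covariate_names, interaction)
  use <- stats::complete.cases(df[, c(".y", terms, "site_id")])
  df <- df[use, , drop = FALSE]
  n_used <- nrow(df)
  if (n_used < length(terms) + 2)
    stop_fc("insufficient data for the mixed model (%d usable rows)", n_used)
  if (stats::var(df$.y) == 0) stop_fc("outcome is constant; nothing to test")
  if (length(unique(df[[effect]])) < 2)
    stop_fc("effect column '%s' is constant in the analysis sample", effect)
  if (length(unique(df$site_id)) < 2)
    stop_fc("need at least 2 sites for the mixed model")
  fixed <- paste(c(terms), collapse = " + ")
  f_slope <- stats::as.formula(sprintf(
    ".y ~ %s + (1 + %s | site_id)", fixed, effect))
  f_int <- stats::as.formula(sprintf(".y ~ %s + (1 | site_id)", fixed))
  f_ols <- stats::as.formula(sprintf(".y ~ %s + factor(site_id)", fixed))

  try_fit <- function(formula) {
    ok <- TRUE
    fit <- withCallingHandlers(
      tryCatch(lmerTest::lmer(formula, data = df, REML = TRUE),
               error = function(e) NULL),
      warning = function(w) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage"))
    if (is.null(fit)) return(NULL)
    msgs <- fit@optinfo$conv$lme4$messages
    if (!is.null(msgs) && length(msgs)) ok <- FALSE
    if (lme4::isSingular(fit, tol = 1e-5)) ok <- FALSE
    if (!ok) return(NULL)
    fit
  }

  fit <- try_fit(f_slope)
  structure_used <- "intercept_and_slope"
  if (is.null(fit)) {
    fit <- try_fit(f_int)
    structure_used <- "intercept_only"
  }
  if (is.null(fit)) {
    fit <- stats::lm(f_ols, data = df)
    structure_used <- "site_fixed"
  }
  if (inherits(fit, "lmerModLmerTest")) {
    co <- summary(fit)$coefficients
    row <- co[effect, ]
    if (df_method == "satterthwaite") {
      res <- data.frame(beta = row[["Estimate"]], se = row[["Std. Error"]],
                        t = row[["t value"]], df = row[["df"]],
                        p = row[["Pr(>|t|)"]])
    } else {
      dfr <- stats::nobs(fit) - nrow(co)
      tval <- row[["t value"]]
      res <- data.frame(beta = row[["Estimate"]], se = row[["Std. Error"]],
                        t = tval, df = dfr,
                        p = 2 * stats::pt(-abs(tval), dfr))
    }
    converged <- TRUE
  } else {
    co <- summary(fit)$coefficients
    row <- co[effect, ]
    res <- data.frame(beta = row[["Estimate"]], se = row[["Std. Error"]],
                      t = row[["t value"]], df = stats::df.residual(fit),
                      p = row[["Pr(>|t|)"]])
    converged <- structure_used != "site_fixed"
  }
  res$n_used <- n_used
  res$converged <- converged
  res$random_structure <- structure_used
  rownames(res) <- NULL
  res
}

#' Group contrasts for every AUC outcome
#'
#' Runs the site-random-slope mixed model for each global metric AUC and
#' each node of each nodal metric. Global metrics are reported with raw
#' p-values (no pooling into a correction family); each nodal metric forms
#' one Benjamini-Hochberg family across its nodes.
#'
#' @param auc_table an \code{fc_auc_table}.
#' @param covariates covariate data.frame (see [cohort_covariates()]).
#' @param contrast one of \code{"mdd-vs-nc"} (default), \code{"fedn-vs-nc"},
#'   \code{"recurrent-vs-nc"}, \code{"recurrent-vs-fedn"}.
#' @param fdr_level FDR significance level (default 0.05).
#' @param min_per_group site filter threshold (default 10).
#' @param covariate_names fixed covariates of no interest.
#' @param interaction optional interaction term passed to [fit_lme()].
#' @return data.frame of class \code{fc_contrast_result}: one row per
#'   outcome with \code{metric}, \code{node_id} (\code{"GLOBAL"} for global
#'   metrics), \code{family}, \code{beta}, \code{se}, \code{t}, \code{df},
#'   \code{p}, \code{q}, \code{significant}, \code{n_used},
#'   \code{converged}, \code{random_structure}; attribute
#'   \code{dropped_sites}.
#' @export
contrast_all_outcomes <- function(auc_table, covariates,
                                  contrast = "mdd-vs-nc",
                                  fdr_level = 0.05,
                                  min_per_group = 10L,
                                  covariate_names = c("age", "sex",
                                                      "education", "mean_fd"),
                                  interaction = NULL) {
  df <- prepare_contrast_data(covariates, contrast, min_per_group)
  run <- function(metric, node_id, y_all, ids_all) {
    y <- y_all[match(df$subject_id, ids_all)]
    fit <- fit_lme(y, df, effect = "grp",
                   covariate_names = covariate_names,
                   interaction = interaction)
    cbind(data.frame(metric = metric, node_id = node_id,
                     stringsAsFactors = FALSE), fit)
  }
  out <- list()
  gl <- auc_table$global
  for (m in setdiff(names(gl), "subject_id")) {
    r <- run(m, "GLOBAL", gl[[m]], gl$subject_id)
    r$family <- "global"
    out[[length(out) + 1L]] <- r
  }
  for (m in names(auc_table$nodal)) {
    mat <- auc_table$nodal[[m]]
    rows <- lapply(colnames(mat), function(nid)
      run(m, nid, mat[, nid], rownames(mat)))
    fam <- do.call(rbind, rows)
    fam$family <- paste0("nodal_", m)
    out[[length(out) + 1L]] <- fam
  }
  res <- do.call(rbind, out)
  res$q <- NA_real_
  for (fam in unique(res$family)) {
    sel <- res$family == fam
    res$q[sel] <- if (fam == "global") res$p[sel] else bh_adjust(res$p[sel])
  }
  res$significant <- res$q < fdr_level
  attr(res, "dropped_sites") <- attr(df, "dropped_sites")
  attr(res, "contrast") <- contrast
  attr(res, "fdr_level") <- fdr_level
  class(res) <- c("fc_contrast_result", "data.frame")
  res
}

#' Subgroup contrasts
#'
#' Same machinery as [contrast_all_outcomes()] restricted to a patient
#' subgroup pair; the site filter is re-applied within the subset.
#'
#' @inheritParams contrast_all_outcomes
#' @param contrast \code{"fedn-vs-nc"}, \code{"recurrent-vs-nc"} or
#'   \code{"recurrent-vs-fedn"}.
#' @export
subgroup_contrast <- function(auc_table, covariates,
                              contrast = c("fedn-vs-nc", "recurrent-vs-nc",
                                           "recurrent-vs-fedn"),
                              fdr_level = 0.05, min_per_group = 10L, ...) {
  contrast <- match.arg(contrast)
  contrast_all_outcomes(auc_table, covariates, contrast = contrast,
                        fdr_level = fdr_level,
                        min_per_group = min_per_group, ...)
}

#' Symptom-severity association
#'
#' Replaces the group term with the symptom score (HAMD) in the same mixed
#' model, restricted to patients with a recorded score. Sites need
#' \code{min_per_site} usable patients to enter.
#'
#' @inheritParams contrast_all_outcomes
#' @param min_per_site minimum patients with HAMD per site (default 10).
#' @export
symptom_association <- function(auc_table, covariates, fdr_level = 0.05,
                                min_per_site = 10L,
                                covariate_names = c("age", "sex",
                                                    "education", "mean_fd")) {
  df <- covariates[covariates$group == "MDD" & !is.na(covariates$hamd), ,
                   drop = FALSE]
  if (nrow(df) < 3) stop_fc("insufficient patients with HAMD scores (%d)", nrow(df))
  tab <- table(df$site_id)
  keep_sites <- names(tab)[tab >= min_per_site]
  df <- df[df$site_id %in% keep_sites, , drop = FALSE]
  if (nrow(df) < 3 || length(keep_sites) < 2)
    stop_fc("fewer than 2 sites have %d+ patients with HAMD", min_per_site)
  run <- function(metric, node_id, y_all, ids_all) {
    y <- y_all[match(df$subject_id, ids_all)]
    fit <- fit_lme(y, df, effect = "hamd", covariate_names = covariate_names)
    cbind(data.frame(metric = metric, node_id = node_id,
                     stringsAsFactors = FALSE), fit)
  }
  out <- list()
  gl <- auc_table$global
  for (m in setdiff(names(gl), "subject_id")) {
    r <- run(m, "GLOBAL", gl[[m]], gl$subject_id)
    r$family <- "global"
    out[[length(out) + 1L]] <- r
  }
  for (m in names(auc_table$nodal)) {
    mat <- auc_table$nodal[[m]]
    fam <- do.call(rbind, lapply(colnames(mat), function(nid)
      run(m, nid, mat[, nid], rownames(mat))))
    fam$family <- paste0("nodal_", m)
    out[[length(out) + 1L]] <- fam
  }
  res <- do.call(rbind, out)
  res$q <- NA_real_
  for (fam in unique(res$family)) {
    sel <- res$family == fam
    res$q[sel] <- if (fam == "global") res$p[sel] else bh_adjust(res$p[sel])
  }
  res$significant <- res$q < fdr_level
  attr(res, "contrast") <- "hamd"
  attr(res, "fdr_level") <- fdr_level
  class(res) <- c("fc_contrast_result", "data.frame")
  res
}

#' Map significant nodes onto the seven-network parcellation
#'
#' Tallies significant nodal results per functional network, split by
#' direction of the group effect (negative beta = lower in the coded-1
#' group, i.e. patients below controls for case-control contrasts).
#'
#' @param results an \code{fc_contrast_result}.
#' @param nodes an \code{fc_node_set} resolving every node id.
#' @param metric optionally restrict to one nodal metric.
#' @return data.frame: \code{network_label}, \code{n_significant},
#'   \code{n_lower}, \code{n_higher}, \code{mean_abs_t} (NA when no node is
#'   significant); every label of the vocabulary appears, zeros included.
#' @export
map_significant_nodes <- function(results, nodes, metric = NULL) {
  nod <- results[results$node_id != "GLOBAL", , drop = FALSE]
  if (!is.null(metric)) nod <- nod[nod$metric == metric, , drop = FALSE]
  unknown <- setdiff(unique(nod$node_id), nodes$node_id)
  if (length(unknown))
    stop_fc("node id(s) not in the node set: %s",
            paste(head(unknown, 5), collapse = ", "))
  nod$network_label <- nodes$network_label[match(nod$node_id, nodes$node_id)]
  labels <- c(NETWORK_LABELS, "other")
  sig <- nod[nod$significant, , drop = FALSE]
  summarize <- function(lab) {
    s <- sig[sig$network_label == lab, , drop = FALSE]
    data.frame(network_label = lab,
               n_significant = nrow(s),
               n_lower = sum(s$beta < 0),
               n_higher = sum(s$beta > 0),
               mean_abs_t = if (nrow(s)) mean(abs(s$t)) else NA_real_,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(labels, summarize))
}
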