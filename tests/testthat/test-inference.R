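make_cov <- function(counts) {
  # counts: named list site -> c(nc, mdd)
  rows <- list()
  for (site in names(counts)) {
    nc <- counts[[site]][1]
    mdd <- counts[[site]][2]
    rows[[site]] <- data.frame(
      subject_id = paste0(site, "_", seq_len(nc + mdd)),
      site_id = site,
      group = c(rep("NC", nc), rep("MDD", mdd)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("site filter applies the per-group minimum with >= boundary", {
  cov <- make_cov(list(s1 = c(12, 9), s2 = c(10, 10), s3 = c(15, 15)))
  out <- filter_sites(cov, 10)
  expect_setequal(unique(out$site_id), c("s2", "s3"))
  expect_equal(attr(out, "dropped_sites"), "s1")
  # hand count: (12/11, 9/20, 15/15) -> 2 sites survive
  cov2 <- make_cov(list(a = c(12, 11), b = c(9, 20), c = c(15, 15)))
  expect_equal(length(unique(filter_sites(cov2, 10)$site_id)), 2)
  expect_error(filter_sites(make_cov(list(a = c(2, 2))), 10), "no site")
})

test_that("BH adjustment matches the hand example and the reference step-up", {
  p <- c(0.001, 0.02, 0.03, 0.8)
  q <- bh_adjust(p)
  expect_equal(sum(q < 0.05), 3)   # thresholds 0.0125/0.025/0.0375/0.05
  expect_true(all(bh_adjust(rep(1, 6)) == 1))
  expect_true(all(q >= p))
  set.seed(41)
  for (rep in 1:50) {
    pv <- runif(sample(2:40, 1))
    expect_equal(bh_adjust(pv), oracle_bh(pv), tolerance = 1e-14)
    expect_equal(bh_adjust(pv), p.adjust(pv, "BH"), tolerance = 1e-14)
    # q monotone non-decreasing in sorted p
    expect_true(all(diff(bh_adjust(pv)[order(pv)]) >= -1e-14))
  }
})

test_that("mixed model recovers an injected covariate slope", {
  set.seed(42)
  co <- tiny_cohort(seed = 8, n_sites = 4, n_per = 20, n_nodes = 4,
                    n_timepoints = 5)
  df <- contrast_frame(co)
  betas <- replicate(60, {
    y <- 0.02 * df$age + rnorm(nrow(df), 0, 0.3)
    r <- fit_lme(y, df, effect = "age",
                 covariate_names = c("sex", "education", "mean_fd"))
    r$beta
  })
  expect_lt(abs(mean(betas) - 0.02) / 0.02, 0.05)
  # and the group effect stays null when only age drives the outcome
  y <- 0.02 * df$age + rnorm(nrow(df), 0, 0.3)
  r <- fit_lme(y, df)
  expect_gt(r$p, 0.001)
})

test_that("t statistics are symmetric under label permutation", {
  set.seed(43)
  co <- tiny_cohort(seed = 9, n_sites = 3, n_per = 15, n_nodes = 4,
                    n_timepoints = 5)
  df <- contrast_frame(co)
  y <- rnorm(nrow(df))
  ts <- replicate(100, {
    df$grp <- sample(df$grp)
    fit_lme(y, df)$t
  })
  expect_lt(abs(mean(ts)), 2.5 / sqrt(100) * 3)  # mean of ~N(0,1)/sqrt(100)
  expect_gt(min(ts) * max(ts), -Inf)
  expect_true(any(ts < 0) && any(ts > 0))
})

test_that("fit_lme records its fallback chain and rejects degenerate input", {
  set.seed(44)
  co <- tiny_cohort(seed = 10, n_sites = 3, n_per = 12, n_nodes = 4,
                    n_timepoints = 5)
  df <- contrast_frame(co)
  r <- fit_lme(rnorm(nrow(df)), df)
  expect_true(r$random_structure %in%
                c("intercept_and_slope", "intercept_only", "site_fixed"))
  expect_equal(sign(r$t), sign(r$beta))
  expect_error(fit_lme(rep(1, nrow(df)), df), "constant")
  df1 <- df[df$site_id == df$site_id[1], ]
  expect_error(fit_lme(rnorm(nrow(df1)), df1), "2 sites")
  dfn <- df
  dfn$grp <- 0
  expect_error(fit_lme(rnorm(nrow(dfn)), dfn), "constant")
})

test_that("contrast results satisfy their invariants and FDR families", {
  set.seed(45)
  co <- tiny_cohort(seed = 11, delta = 0.8, n_sites = 3, n_per = 12,
                    n_nodes = 12, n_timepoints = 60)
  at <- cohort_auc_table(co, density_grid(0.10, 0.34, 0.06),
                         metrics = c("e_glob", "degree", "e_nodal"))
  res <- contrast_all_outcomes(at, cohort_covariates(co), min_per_group = 10)
  expect_s3_class(res, "fc_contrast_result")
  expect_equal(nrow(res), 1 + 12 + 12)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$q >= res$p - 1e-14))
  expect_equal(res$significant, res$q < 0.05)
  expect_true(all(sign(res$t) == sign(res$beta)))
  expect_equal(res$q[res$family == "global"], res$p[res$family == "global"])
  nodal <- res[res$family == "nodal_degree", ]
  expect_equal(nodal$q, bh_adjust(nodal$p))
})

test_that("subgroup contrasts subset correctly and fail on empty subsets", {
  set.seed(46)
  co <- tiny_cohort(seed = 12, n_sites = 3, n_per = 12, n_nodes = 8,
                    n_timepoints = 40,
                    subtype_fractions = c(FEDN = 0, recurrent = 1))
  at <- cohort_auc_table(co, density_grid(0.10, 0.34, 0.12),
                         metrics = "e_glob")
  cov <- cohort_covariates(co)
  expect_error(subgroup_contrast(at, cov, "fedn-vs-nc", min_per_group = 5),
               "FEDN")
  res <- subgroup_contrast(at, cov, "recurrent-vs-nc", min_per_group = 5)
  expect_equal(unique(res$family), "global")
})

test_that("symptom association requires patients with scores", {
  set.seed(47)
  co <- tiny_cohort(seed = 13, n_sites = 3, n_per = 12, n_nodes = 8,
                    n_timepoints = 40)
  at <- cohort_auc_table(co, density_grid(0.10, 0.34, 0.12),
                         metrics = "e_glob")
  cov <- cohort_covariates(co)
  res <- symptom_association(at, cov, min_per_site = 5)
  expect_true(all(c("beta", "t", "p", "q") %in% names(res)))
  cov_none <- cov
  cov_none$hamd <- NA_real_
  expect_error(symptom_association(at, cov_none), "HAMD")
  cov_one <- cov
  cov_one$hamd[-which(cov_one$group == "MDD")[1]] <- NA_real_
  expect_error(symptom_association(at, cov_one, min_per_site = 5))
})

test_that("HAMD slope direction is recovered when injected", {
  set.seed(48)
  co <- tiny_cohort(seed = 14, n_sites = 3, n_per = 15, n_nodes = 4,
                    n_timepoints = 5)
  cov <- cohort_covariates(co)
  pat <- cov[cov$group == "MDD", ]
  hits <- replicate(40, {
    y <- setNames(-0.02 * cov$hamd + rnorm(nrow(cov), 0, 0.1),
                  cov$subject_id)
    at <- structure(list(global = data.frame(subject_id = cov$subject_id,
                                             e_glob = unname(y),
                                             stringsAsFactors = FALSE),
                         nodal = list(), node_ids = character(0),
                         kappa = NULL), class = "fc_auc_table")
    r <- symptom_association(at, cov, min_per_site = 5)
    r$beta[1] < 0
  })
  expect_gte(mean(hits), 0.9)
})

test_that("significant nodes map onto the network vocabulary conservatively", {
  nodes <- synthetic_node_set(14, 7)
  res <- data.frame(metric = "degree", node_id = nodes$node_id,
                    beta = c(rep(-1, 3), rep(1, 11)),
                    t = c(rep(-3, 3), rep(3, 11)),
                    p = 0.5, q = c(rep(0.01, 3), rep(0.9, 11)),
                    significant = c(rep(TRUE, 3), rep(FALSE, 11)),
                    stringsAsFactors = FALSE)
  class(res) <- c("fc_contrast_result", "data.frame")
  tab <- map_significant_nodes(res, nodes)
  expect_setequal(tab$network_label,
                  c("SMN", "VAN", "VN", "DAN", "DMN", "FPN", "subcortical",
                    "other"))
  expect_equal(sum(tab$n_significant), 3)
  expect_equal(sum(tab$n_lower), 3)
  expect_equal(sum(tab$n_higher), 0)
  # no significant nodes: all-zero table, full vocabulary
  res$significant <- FALSE
  tab0 <- map_significant_nodes(res, nodes)
  expect_true(all(tab0$n_significant == 0))
  expect_equal(nrow(tab0), 8)
  # unknown node id is an error
  res$node_id[1] <- "nope"
  expect_error(map_significant_nodes(res, nodes), "nope")
})
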