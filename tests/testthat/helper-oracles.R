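# Independent brute-force oracles for the graph metrics. These share no
# code with the package's implementations: distances come from
# Floyd-Warshall, betweenness from the path-count definition applied to
# the distance matrix, clustering and local efficiency from direct
# summation of their formulas.

rand_weighted_graph <- function(n, p_edge = 0.5) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- runif(sum(ut))
  vals[runif(sum(ut)) > p_edge] <- 0
  w[ut] <- vals
  w + t(w)
}

oracle_lengths <- function(w) {
  L <- ifelse(w > 0, 1 / w, Inf)
  diag(L) <- 0
  L
}

oracle_fw <- function(L) {
  D <- L
  n <- nrow(D)
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

oracle_global_eff <- function(w) {
  D <- oracle_fw(oracle_lengths(w))
  n <- nrow(w)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_nodal_eff <- function(w) {
  D <- oracle_fw(oracle_lengths(w))
  n <- nrow(w)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

oracle_lp <- function(w) {
  D <- oracle_fw(oracle_lengths(w))
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  wn <- if (max(w) > 0) w / max(w) else w
  k <- rowSums(w > 0)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    term <- (outer(wn[i, ], wn[i, ]) * wn)^(1 / 3)
    term[i, ] <- 0
    term[, i] <- 0
    diag(term) <- 0
    ci[i] <- sum(term) / (k[i] * (k[i] - 1))
  }
  mean(ci)
}

oracle_local_eff <- function(w) {
  n <- nrow(w)
  e <- numeric(n)
  for (u in seq_len(n)) {
    V <- which(w[u, ] > 0)
    V <- V[V != u]
    if (length(V) < 2) next
    Ds <- oracle_fw(oracle_lengths(w[V, V, drop = FALSE]))
    s <- 0
    for (a in seq_along(V)) for (b in seq_along(V)) {
      if (a == b || !is.finite(Ds[a, b])) next
      s <- s + (w[u, V[a]] * w[u, V[b]] / Ds[a, b])^(1 / 3)
    }
    e[u] <- s / (length(V) * (length(V) - 1))
  }
  mean(e)
}

# betweenness straight from the definition: count shortest paths through
# each node using shortest-path counts sigma derived from the distance
# matrix, then sum pair dependencies over ordered (s, t) pairs.
oracle_betweenness <- function(w) {
  n <- nrow(w)
  L <- oracle_lengths(w)
  D <- oracle_fw(L)
  tol <- 1e-9
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (v in order(D[s, ])) {
      if (v == s || !is.finite(D[s, v])) next
      tot <- 0
      for (u in seq_len(n)) {
        if (u == v || !is.finite(L[u, v]) || L[u, v] <= 0) next
        if (is.finite(D[s, u]) &&
            abs(D[s, u] + L[u, v] - D[s, v]) <= tol * max(1, D[s, v]))
          tot <- tot + sigma[s, u]
      }
      sigma[s, v] <- tot
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == v || t == v || s == t || !is.finite(D[s, t])) next
      if (abs(D[s, v] + D[v, t] - D[s, t]) <= tol * max(1, D[s, t]))
        bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  bc / ((n - 1) * (n - 2))
}

# reference step-up FDR adjustment written as the literal textbook loop
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  q
}

# small binary graphs with known closed forms
complete_graph <- function(n) {
  w <- matrix(1, n, n)
  diag(w) <- 0
  w
}

star_graph <- function(n) {
  w <- matrix(0, n, n)
  w[1, 2:n] <- 1
  w[2:n, 1] <- 1
  w
}

path_graph <- function(n) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    w[i, i + 1] <- 1
    w[i + 1, i] <- 1
  }
  w
}

# a tiny cohort used by several test files
tiny_cohort <- function(seed = 42, delta = 1, n_sites = 3, n_per = 12,
                        n_nodes = 16, n_timepoints = 50, ...) {
  synthesize_cohort(synthetic_spec(
    n_sites = n_sites, n_per_group_per_site = n_per, n_nodes = n_nodes,
    n_timepoints = n_timepoints, n_modules = 4,
    group_effect_delta = delta, seed = seed, ...))
}

# simulate an AUC-level outcome carrying the cohort's latent connectivity
# scale (site + group structure) plus noise
scale_outcome <- function(cohort, noise_sd = 0.1, coef = 1) {
  sc <- vapply(cohort$subjects, `[[`, numeric(1), "connectivity_scale")
  coef * sc + rnorm(length(sc), 0, noise_sd)
}

contrast_frame <- function(cohort) {
  cov <- cohort_covariates(cohort)
  cov$grp <- as.numeric(cov$group == "MDD")
  cov
}
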