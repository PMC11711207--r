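# Brute-force oracles, kept deliberately naive and independent of the
# package's vectorised implementations.

oracle_pearson_matrix <- function(ts) {
  # ts: timepoints x nodes
  n <- ncol(ts)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- ts[, i] - mean(ts[, i])
      xj <- ts[, j] - mean(ts[, j])
      m[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  m
}

oracle_strength <- function(edges, positive, negative) {
  n <- nrow(edges)
  out <- matrix(0, n, 3, dimnames = list(NULL, c("pos", "neg", "comb")))
  for (s in seq_len(n)) {
    ps <- 0
    ns <- 0
    for (e in seq_len(ncol(edges))) {
      if (positive[e]) ps <- ps + edges[s, e]
      if (negative[e]) ns <- ns + edges[s, e]
    }
    out[s, ] <- c(ps, ns, ps - ns)
  }
  out
}

oracle_screen <- function(edges, scores, threshold) {
  E <- ncol(edges)
  r <- numeric(E)
  p <- numeric(E)
  for (e in seq_len(E)) {
    ct <- cor.test(edges[, e], scores)
    r[e] <- unname(ct$estimate)
    p[e] <- ct$p.value
  }
  list(r = r, p = p,
       positive = r > 0 & p < threshold,
       negative = r < 0 & p < threshold)
}

oracle_degree <- function(mask, n_nodes) {
  adj <- matrix(0, n_nodes, n_nodes)
  k <- 0
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      k <- k + 1
      if (mask[k]) {
        adj[i, j] <- 1
        adj[j, i] <- 1
      }
    }
  }
  rowSums(adj)
}

oracle_pair_counts <- function(mask, labels) {
  nets <- sort(unique(labels))
  m <- matrix(0L, length(nets), length(nets), dimnames = list(nets, nets))
  n_nodes <- length(labels)
  k <- 0
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      k <- k + 1
      if (mask[k]) {
        a <- labels[i]
        b <- labels[j]
        m[a, b] <- m[a, b] + 1L
        if (a != b) m[b, a] <- m[b, a] + 1L
      }
    }
  }
  m
}

oracle_mse <- function(pred, obs) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (pred[i] - obs[i])^2
  s / length(pred)
}

# random symmetric zero-diagonal matrix
rand_sym <- function(n_nodes) {
  m <- matrix(0, n_nodes, n_nodes)
  m[lower.tri(m)] <- rnorm(n_nodes * (n_nodes - 1) / 2)
  m + t(m)
}

# tiny single-site cohort shortcut
small_cohort <- function(n = 60, n_nodes = 20, pos = 5, neg = 5,
                         effect_r = 0.5, seed = 1, ...) {
  generate_cohort(cohort_config(
    n_nodes = n_nodes,
    sites = list(a = list(n = n, score_mean = 130, score_sd = 16)),
    planted_positive = pos, planted_negative = neg,
    effect_r = effect_r, seed = seed, ...
  ))
}
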