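#' Edge-wise correlation screening into positive and negative networks
#'
#' Correlates every unique edge with the behavioral score across subjects.
#' Edges with positive r and two-tailed p below the threshold form the
#' positive network; edges with negative r and p below it the negative network
#' (strict inequality at the threshold). p-values use the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param edges Numeric matrix, subjects x edges (canonical edge order).
#' @param scores Numeric vector of behavioral scores, one per subject.
#' @param threshold Two-tailed p threshold for selection (default 0.01).
#' @return An object of class `edge_screen`: list with `stats` (tibble of
#'   per-edge `edge`, `r`, `p`), logical masks `positive` and `negative`,
#'   `n_zero_variance` (edges ineligible for selection because they are
#'   constant across subjects), `threshold` and `n`.
#' @export
screen_edges <- function(edges, scores, threshold = 0.01) {
  edges <- as.matrix(edges)
  n <- nrow(edges)
  if (length(scores) != n) abort("scores length must match rows of edges")
  if (n < 4) abort("need at least 4 subjects to screen")
  if (stats::sd(scores) == 0) abort("scores have zero variance")
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")

  r <- suppressWarnings(drop(stats::cor(scores, edges)))
  zero_var <- is.na(r)
  rp <- edge_p_values(r, n)
  pos <- !zero_var & r > 0 & rp < threshold
  neg <- !zero_var & r < 0 & rp < threshold
  pos[is.na(pos)] <- FALSE
  neg[is.na(neg)] <- FALSE
  if (any(zero_var)) {
    warn(sprintf("%d zero-variance edge(s) ineligible for selection",
                 sum(zero_var)))
  }
  structure(
    list(
      stats = tibble(edge = seq_along(r), r = r, p = rp),
      positive = pos, negative = neg,
      n_zero_variance = sum(zero_var),
      threshold = threshold, n = n
    ),
    class = "edge_screen"
  )
}

# Two-tailed p for a Pearson r at sample size n via the exact t transform.
# |r| = 1 maps to p = 0.
edge_p_values <- function(r, n) {
  df <- n - 2
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  rr <- pmin(pmax(r[ok], -1), 1)
  tt <- abs(rr) * sqrt(df / pmax(1 - rr^2, 0))
  p[ok] <- 2 * stats::pt(tt, df, lower.tail = FALSE)
  p[ok][is.infinite(tt) | (1 - rr^2) == 0] <- 0
  p
}

#' @export
print.edge_screen <- function(x, ...) {
  cat(sprintf(
    "<edge_screen> n = %d, p < %g: %d positive, %d negative of %d edges\n",
    x$n, x$threshold, sum(x$positive), sum(x$negative), nrow(x$stats)
  ))
  if (x$n_zero_variance > 0) {
    cat(sprintf("  %d zero-variance edge(s) ineligible\n", x$n_zero_variance))
  }
  invisible(x)
}

#' Network strength features
#'
#' For each subject, sums the subject's Fisher-z edge values over the positive
#' mask and over the negative mask; the combined strength is the positive sum
#' minus the negative sum. An empty mask yields a sum of 0 with a warning
#' (such a model is degenerate on that variant).
#'
#' @param edges Numeric matrix, subjects x edges.
#' @param positive,negative Logical masks over the edge space.
#' @return Tibble with `pos_sum`, `neg_sum`, `combined` (one row per subject,
#'   plus `subject_id` when `edges` has rownames).
#' @export
network_strength <- function(edges, positive, negative) {
  edges <- as.matrix(edges)
  E <- ncol(edges)
  if (length(positive) != E || length(negative) != E) {
    abort("mask length must match the edge space")
  }
  if (any(positive & negative)) abort("positive and negative masks must be disjoint")
  if (!any(positive)) warn("empty positive mask: pos_sum is 0")
  if (!any(negative)) warn("empty negative mask: neg_sum is 0")
  pos_sum <- if (any(positive))
    unname(rowSums(edges[, positive, drop = FALSE])) else rep(0, nrow(edges))
  neg_sum <- if (any(negative))
    unname(rowSums(edges[, negative, drop = FALSE])) else rep(0, nrow(edges))
  out <- tibble(pos_sum = pos_sum, neg_sum = neg_sum,
                combined = pos_sum - neg_sum)
  if (!is.null(rownames(edges))) {
    out <- bind_cols(tibble(subject_id = rownames(edges)), out)
  }
  out
}

#' Fit the network-strength linear model
#'
#' Ordinary least squares fit of `score = beta * strength + c`.
#'
#' @param strength Numeric predictor (per-subject network strength).
#' @param scores Numeric response.
#' @return Named numeric vector `c(beta, intercept)`.
#' @export
fit_strength_model <- function(strength, scores) {
  if (length(strength) != length(scores)) abort("lengths differ")
  if (length(strength) < 2) abort("need at least 2 subjects")
  vx <- stats::var(strength)
  if (vx == 0) abort("degenerate predictor: strength is constant")
  beta <- stats::cov(strength, scores) / vx
  c(beta = beta, intercept = mean(scores) - beta * mean(strength))
}
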