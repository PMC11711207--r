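# Internal cross-validation engines.
#
# The LOOCV engine avoids an explicit per-fold screening loop: the Pearson r
# of every edge with the score in each leave-one-out training set is obtained
# by downdating full-sample sums (remove one subject from sum(x), sum(x^2),
# colSums(edges), colSums(edges^2) and crossprod(edges, x)), giving an
# n x E matrix of fold-wise correlations in a handful of vectorised
# operations. Fold-wise network strengths then come from one matrix product
# per mask sign, and the per-fold OLS fits are closed-form column operations.
# Tests verify equality with a direct per-fold cor() computation.

cpm_loocv_engine <- function(edges, scores, threshold, keep_masks = FALSE) {
  M <- edges
  x <- as.numeric(scores)
  n <- nrow(M)
  E <- ncol(M)
  nt <- n - 1
  df <- nt - 2

  Sx <- sum(x)
  Sxx <- sum(x * x)
  Se <- colSums(M)
  See <- colSums(M * M)
  Sxe <- drop(crossprod(M, x))

  Se_i <- matrix(Se, n, E, byrow = TRUE) - M
  See_i <- matrix(See, n, E, byrow = TRUE) - M * M
  Sxe_i <- matrix(Sxe, n, E, byrow = TRUE) - M * x
  Sx_i <- Sx - x
  Sxx_i <- Sxx - x * x

  varx_i <- Sxx_i - Sx_i^2 / nt              # length n
  vare_i <- See_i - Se_i^2 / nt              # n x E
  cov_i <- Sxe_i - Se_i * (Sx_i / nt)        # n x E (row-wise recycling)

  eligible <- vare_i > 1e-10 * See_i         # constant training edges drop out
  r <- cov_i / sqrt(pmax(vare_i * varx_i, 0))
  r[!eligible] <- NA_real_
  r[r > 1] <- 1
  r[r < -1] <- -1

  tt <- abs(r) * sqrt(df / pmax(1 - r * r, 0))
  p <- 2 * stats::pt(tt, df, lower.tail = FALSE)
  p[!is.na(r) & (1 - r * r) == 0] <- 0

  mask_pos <- !is.na(r) & r > 0 & p < threshold
  mask_neg <- !is.na(r) & r < 0 & p < threshold

  P_pos <- tcrossprod(M, mask_pos)           # [subject, fold] positive strength
  P_neg <- tcrossprod(M, mask_neg)

  variants <- list(
    combined = P_pos - P_neg,
    positive = P_pos,
    negative = P_neg
  )
  fits <- lapply(variants, loocv_fold_ols, x = x)

  list(
    pred = lapply(fits, `[[`, "pred"),
    r = vapply(fits, function(f) safe_cor(f$pred, x), numeric(1)),
    degenerate = vapply(fits, function(f) f$degenerate, logical(n)),
    fold = seq_len(n),
    mask_pos = if (keep_masks) mask_pos else NULL,
    mask_neg = if (keep_masks) mask_neg else NULL
  )
}

# Closed-form per-fold OLS of score on strength, all folds at once.
# P[s, i] = strength of subject s under fold i's masks; fold i holds out
# subject i. A fold with (numerically) constant training strength is
# degenerate: beta = 0 and the prediction falls back to the training mean.
loocv_fold_ols <- function(P, x) {
  n <- nrow(P)
  nt <- n - 1
  d <- diag(P)
  Ss <- colSums(P) - d
  Sxy <- colSums(P * x) - x * d
  Sss <- colSums(P * P) - d * d
  Sx_t <- sum(x) - x
  varS <- Sss - Ss^2 / nt
  covSx <- Sxy - Ss * Sx_t / nt
  degenerate <- !(varS > 1e-10 * Sss)
  beta <- ifelse(degenerate, 0, covSx / varS)
  intercept <- Sx_t / nt - beta * Ss / nt
  list(
    pred = beta * d + intercept,
    beta = beta, intercept = intercept, degenerate = degenerate
  )
}

cpm_kfold_engine <- function(edges, scores, threshold, fold_id,
                             keep_masks = FALSE) {
  M <- edges
  x <- as.numeric(scores)
  n <- nrow(M)
  E <- ncol(M)
  k <- max(fold_id)
  pred <- list(combined = numeric(n), positive = numeric(n),
               negative = numeric(n))
  degenerate <- matrix(FALSE, k, 3,
                       dimnames = list(NULL, names(pred)))
  mask_pos <- if (keep_masks) matrix(FALSE, k, E) else NULL
  mask_neg <- if (keep_masks) matrix(FALSE, k, E) else NULL

  for (f in seq_len(k)) {
    tr <- fold_id != f
    te <- !tr
    r <- suppressWarnings(drop(stats::cor(x[tr], M[tr, , drop = FALSE])))
    p <- edge_p_values(r, sum(tr))
    pos <- !is.na(r) & r > 0 & p < threshold
    neg <- !is.na(r) & r < 0 & p < threshold
    if (keep_masks) {
      mask_pos[f, ] <- pos
      mask_neg[f, ] <- neg
    }
    sp <- if (any(pos)) rowSums(M[, pos, drop = FALSE]) else numeric(n)
    sn <- if (any(neg)) rowSums(M[, neg, drop = FALSE]) else numeric(n)
    strengths <- list(combined = sp - sn, positive = sp, negative = sn)
    for (v in names(strengths)) {
      s_tr <- strengths[[v]][tr]
      if (stats::var(s_tr) > 1e-10 * mean(s_tr^2)) {
        beta <- stats::cov(s_tr, x[tr]) / stats::var(s_tr)
        intercept <- mean(x[tr]) - beta * mean(s_tr)
        pred[[v]][te] <- beta * strengths[[v]][te] + intercept
      } else {
        degenerate[f, v] <- TRUE
        pred[[v]][te] <- mean(x[tr])
      }
    }
  }
  list(
    pred = pred,
    r = vapply(pred, function(p) safe_cor(p, x), numeric(1)),
    degenerate = degenerate,
    fold = fold_id,
    mask_pos = mask_pos,
    mask_neg = mask_neg
  )
}

# Pearson r that returns 0 (instead of NA) for a constant prediction vector;
# such predictions carry no ranking information, so 0 is the honest summary
# and keeps permutation counting well defined.
safe_cor <- function(pred, obs) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(0)
  stats::cor(pred, obs)
}

make_folds <- function(n, k, seed = NULL) {
  if (k < 2) abort("k must be >= 2")
  if (k > n) abort("k cannot exceed the number of subjects")
  assign_fold <- function() sample(rep(seq_len(k), length.out = n))
  if (is.null(seed)) assign_fold() else withr::with_seed(seed, assign_fold())
}
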