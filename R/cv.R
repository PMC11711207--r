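# Subject alignment: edge rows are matched to the phenotype table by id
# (never by file/row order) whenever both carry ids.
align_edges <- function(pheno, edges) {
  edges <- as.matrix(edges)
  if (!is.null(rownames(edges)) && "subject_id" %in% names(pheno)) {
    ids <- as.character(pheno$subject_id)
    miss_e <- setdiff(ids, rownames(edges))
    miss_p <- setdiff(rownames(edges), ids)
    if (length(miss_e) > 0 || length(miss_p) > 0) {
      abort(paste0(
        "subject mismatch between phenotypes and edges",
        if (length(miss_e)) paste0("; missing edges for: ",
                                   paste(miss_e, collapse = ", ")),
        if (length(miss_p)) paste0("; missing phenotypes for: ",
                                   paste(miss_p, collapse = ", "))
      ))
    }
    edges <- edges[ids, , drop = FALSE]
  } else if (nrow(edges) != nrow(pheno)) {
    abort("edges and phenotypes have different row counts and no ids to join on")
  }
  edges
}

get_target <- function(pheno, target) {
  if (!target %in% names(pheno)) {
    abort(sprintf("target column '%s' not found in phenotypes", target))
  }
  x <- pheno[[target]]
  if (!is.numeric(x)) abort(sprintf("target '%s' is not numeric", target))
  if (anyNA(x)) abort(sprintf("target '%s' contains missing values", target))
  as.numeric(x)
}

#' Cross-validated connectome-based predictive modeling
#'
#' Runs the full CPM procedure under leave-one-out or k-fold cross-validation:
#' in every fold, edges are screened on the training subjects only
#' ([screen_edges()] semantics), network strengths are computed, the linear
#' strength model is fitted on the training subjects for all three strength
#' variants (combined = positive minus negative sum, positive-only,
#' negative-only), and the held-out subjects are predicted. The headline
#' predicted-vs-observed correlation uses the combined variant; the other two
#' are always recorded alongside.
#'
#' @param pheno Phenotype data frame with `subject_id` and the target column.
#' @param edges Subjects x edges numeric matrix (canonical edge order);
#'   rownames are matched to `pheno$subject_id` when present.
#' @param target Name of the score column to predict.
#' @param threshold Edge-screening two-tailed p threshold (default 0.01).
#' @param cv `"loocv"` (default) or `"kfold"`.
#' @param k Number of folds for `cv = "kfold"` (default 10). Fold membership
#'   is a seeded uniform shuffle into near-equal folds.
#' @param seed Seed for the fold shuffle (k-fold only; LOOCV is deterministic).
#' @param keep_masks Keep the per-fold selection masks (needed by
#'   [edge_presence()]; default `TRUE`).
#' @return Object of class `cpm_cv`: `predictions` tibble (one row per subject
#'   with `observed`, `predicted`, `predicted_positive`, `predicted_negative`,
#'   `fold`, `degenerate`), `r` (named vector of predicted-vs-observed Pearson
#'   correlations per variant), per-fold `masks`, and the configuration.
#' @export
cpm_cv <- function(pheno, edges, target, threshold = 0.01,
                   cv = c("loocv", "kfold"), k = 10, seed = NULL,
                   keep_masks = TRUE) {
  cv <- match.arg(cv)
  pheno <- as_tibble(pheno)
  edges <- align_edges(pheno, edges)
  x <- get_target(pheno, target)
  n <- nrow(edges)
  if (n < 10) abort("need at least 10 subjects for cross-validation")
  if (stats::sd(x) == 0) abort("scores have zero variance")

  if (cv == "loocv") {
    res <- cpm_loocv_engine(edges, x, threshold, keep_masks = keep_masks)
    degen <- res$degenerate[, "combined"]
  } else {
    fold_id <- make_folds(n, k, seed)
    res <- cpm_kfold_engine(edges, x, threshold, fold_id,
                            keep_masks = keep_masks)
    degen <- res$degenerate[res$fold, "combined"]
  }

  ids <- if (!is.null(rownames(edges))) rownames(edges) else
    as.character(seq_len(n))
  predictions <- tibble(
    subject_id = ids,
    fold = res$fold,
    observed = x,
    predicted = res$pred$combined,
    predicted_positive = res$pred$positive,
    predicted_negative = res$pred$negative,
    degenerate = degen
  )

  structure(
    list(
      predictions = predictions,
      r = res$r,
      masks = list(positive = res$mask_pos, negative = res$mask_neg),
      cfg = list(target = target, threshold = threshold, cv = cv,
                 k = if (cv == "kfold") k else NA_integer_,
                 seed = seed, n = n, E = ncol(edges)),
      n_degenerate_folds = sum(rowSums(matrix(res$degenerate, ncol = 3)) > 0)
    ),
    class = "cpm_cv"
  )
}

#' Permutation p-value from a null distribution
#'
#' The probability of finding a null correlation at or above the observed one:
#' `count(null >= observed) / n_perm`. The `(count + 1) / (n + 1)` variant is
#' available via `plus_one = TRUE` but off by default.
#'
#' @param null Numeric vector of null statistics.
#' @param observed Observed statistic.
#' @param plus_one Use the add-one estimator.
#' @return A single p-value.
#' @export
#' @examples
#' perm_pvalue(c(rep(1, 17), rep(-1, 983)), 0.5) # 0.017
perm_pvalue <- function(null, observed, plus_one = FALSE) {
  if (length(null) < 1) abort("need at least one permutation")
  if (plus_one) {
    (sum(null >= observed) + 1) / (length(null) + 1)
  } else {
    mean(null >= observed)
  }
}

#' Permutation test of the cross-validated CPM correlation
#'
#' Re-runs the *entire* cross-validation (screening inside folds) on score
#' vectors permuted across subjects, building the null distribution of
#' predicted-vs-observed correlations for the combined-strength model; the
#' p-value is the fraction of null correlations at or above the observed one.
#'
#' @inheritParams cpm_cv
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed controlling the permutations (and fold shuffle for k-fold;
#'   folds are held fixed across permutations).
#' @param plus_one See [perm_pvalue()].
#' @return Object of class `cpm_perm`: `observed_r`, `null` (length `n_perm`),
#'   `p`, and the configuration.
#' @export
cpm_permute <- function(pheno, edges, target, threshold = 0.01,
                        cv = c("loocv", "kfold"), k = 10,
                        n_perm = 1000, seed = 1, plus_one = FALSE) {
  cv <- match.arg(cv)
  if (n_perm < 1) abort("n_perm must be >= 1")
  pheno <- as_tibble(pheno)
  edges <- align_edges(pheno, edges)
  x <- get_target(pheno, target)
  n <- nrow(edges)
  if (n < 10) abort("need at least 10 subjects for cross-validation")

  run <- function() {
    fold_id <- if (cv == "kfold") make_folds(n, k) else NULL
    engine <- function(sc) {
      if (cv == "loocv") {
        cpm_loocv_engine(edges, sc, threshold)$r[["combined"]]
      } else {
        cpm_kfold_engine(edges, sc, threshold, fold_id)$r[["combined"]]
      }
    }
    observed <- engine(x)
    null <- vapply(seq_len(n_perm), function(b) engine(sample(x)), numeric(1))
    list(observed = observed, null = null)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  structure(
    list(
      observed_r = res$observed,
      null = res$null,
      p = perm_pvalue(res$null, res$observed, plus_one = plus_one),
      n_perm = n_perm, seed = seed, plus_one = plus_one,
      cfg = list(target = target, threshold = threshold, cv = cv,
                 k = if (cv == "kfold") k else NA_integer_, n = n)
    ),
    class = "cpm_perm"
  )
}

#' Partial Pearson correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after OLS regression on
#' the covariates (with intercept); the p-value uses the t transform with
#' `n - 2 - q` degrees of freedom for `q` covariates. Used to control
#' evaluation correlations for head motion, asthma/clinical status, scan
#' resolution, or site means.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric vector, matrix or data frame of covariates.
#' @return Tibble with `estimate` (partial r), `statistic`, `df`, `p.value`.
#' @export
partial_correlation <- function(x, y, covariates) {
  Z <- as.matrix(covariates)
  storage.mode(Z) <- "double"
  n <- length(x)
  q <- ncol(Z)
  if (length(y) != n || nrow(Z) != n) abort("lengths differ")
  if (n <= q + 2) abort("need n > q + 2 observations")
  X <- cbind(1, Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) abort("collinear covariates")
  rx <- qr.resid(qrX, x)
  ry <- qr.resid(qrX, y)
  if (stats::sd(rx) < 1e-12 * stats::sd(x) || stats::sd(rx) == 0) {
    abort("x has zero residual variance after covariate regression")
  }
  if (stats::sd(ry) < 1e-12 * stats::sd(y) || stats::sd(ry) == 0) {
    abort("y has zero residual variance after covariate regression")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - q
  t <- r * sqrt(df / (1 - r^2))
  tibble(estimate = r, statistic = t, df = df,
         p.value = 2 * stats::pt(-abs(t), df))
}

#' Fit the final single-fold CPM on all subjects
#'
#' Edge screening and the three strength-variant linear fits on the full
#' sample (a "single fold"), producing the frozen model that is exported and
#' applied unchanged to external datasets.
#'
#' @inheritParams cpm_cv
#' @return Object of class `cpm_model` with logical masks `positive` and
#'   `negative` over the canonical edge space, a `coefficients` tibble (one
#'   row per strength variant with `beta`, `intercept`, `degenerate`), the
#'   per-edge screening `stats`, and training metadata.
#' @export
cpm_fit <- function(pheno, edges, target, threshold = 0.01) {
  pheno <- as_tibble(pheno)
  edges <- align_edges(pheno, edges)
  x <- get_target(pheno, target)
  scr <- suppressWarnings(screen_edges(edges, x, threshold))
  if (!any(scr$positive) && !any(scr$negative)) {
    abort("no edges survive threshold")
  }
  st <- suppressWarnings(network_strength(edges, scr$positive, scr$negative))
  strengths <- list(combined = st$combined, positive = st$pos_sum,
                    negative = st$neg_sum)
  coefs <- purrr::imap(strengths, function(s, v) {
    if (stats::var(s) > 0) {
      f <- fit_strength_model(s, x)
      tibble(variant = v, beta = f[["beta"]], intercept = f[["intercept"]],
             degenerate = FALSE)
    } else {
      tibble(variant = v, beta = 0, intercept = mean(x), degenerate = TRUE)
    }
  }) %>% bind_rows()

  structure(
    list(
      positive = scr$positive,
      negative = scr$negative,
      coefficients = coefs,
      stats = scr$stats,
      target = target, threshold = threshold,
      n = nrow(edges), E = ncol(edges),
      n_nodes = tryCatch(nodes_from_edges(ncol(edges)),
                         error = function(e) NA_integer_)
    ),
    class = "cpm_model"
  )
}

#' Predict scores from a frozen CPM
#'
#' @param object A `cpm_model`.
#' @param edges Subjects x edges matrix in the model's edge space.
#' @param variant Strength variant: `"combined"` (default), `"positive"` or
#'   `"negative"`.
#' @param ... Unused.
#' @return Numeric vector of predicted scores.
#' @export
predict.cpm_model <- function(object, edges, variant = "combined", ...) {
  edges <- as.matrix(edges)
  if (ncol(edges) != object$E) {
    abort(sprintf("edge-space mismatch: model has %d edges, data %d",
                  object$E, ncol(edges)))
  }
  st <- suppressWarnings(network_strength(edges, object$positive,
                                          object$negative))
  s <- switch(variant,
              combined = st$combined,
              positive = st$pos_sum,
              negative = st$neg_sum,
              abort("variant must be combined, positive or negative"))
  cf <- object$coefficients[object$coefficients$variant == variant, ]
  drop(cf$beta * s + cf$intercept)
}

#' Fraction of cross-validation folds containing the final model's edges
#'
#' For each edge of the final single-fold mask, the fraction of CV folds whose
#' same-sign mask contains it; reported as the mean per sign, in percent.
#'
#' @param cv A `cpm_cv` run with `keep_masks = TRUE`.
#' @param model The final `cpm_model` from the same data and configuration.
#' @return Tibble with `sign`, `n_edges` and `presence` (percent; `NA` when
#'   the final mask of that sign is empty).
#' @export
edge_presence <- function(cv, model) {
  if (is.null(cv$masks$positive)) {
    abort("cpm_cv was run with keep_masks = FALSE")
  }
  if (ncol(cv$masks$positive) != model$E) abort("edge-space mismatch")
  one_sign <- function(sign) {
    final <- model[[sign]]
    if (!any(final)) return(NA_real_)
    fold_frac <- colMeans(cv$masks[[sign]][, final, drop = FALSE])
    100 * mean(fold_frac)
  }
  tibble(
    sign = c("positive", "negative"),
    n_edges = c(sum(model$positive), sum(model$negative)),
    presence = c(one_sign("positive"), one_sign("negative"))
  )
}

#' Select models by permutation p-value
#'
#' Keeps candidate models whose permutation p is strictly below `alpha`
#' (uncorrected); ties at the threshold are excluded.
#'
#' @param p Named numeric vector of permutation p-values, one per candidate.
#' @param alpha Selection threshold (default 0.05).
#' @return Character vector of selected model labels.
#' @export
#' @examples
#' select_models(c(AA = 0.017, NJ = 0.025, O = 0.31)) # AA, NJ
select_models <- function(p, alpha = 0.05) {
  if (is.null(names(p))) abort("p must be named by candidate model")
  if (any(p < 0 | p > 1)) abort("p values must lie in [0, 1]")
  names(p)[p < alpha]
}
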