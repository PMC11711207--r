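#' Apply a frozen CPM to an independent dataset
#'
#' Masks each subject's connectome with the model's positive and negative
#' masks, forms network strengths, and applies the stored linear coefficients
#' — the model is never re-screened or re-fitted on the test data. Reports
#' the predicted-vs-observed Pearson correlation, two-tailed p (t transform,
#' `n - 2` df), mean squared error, and, when covariates are requested,
#' partial correlations.
#'
#' @param model A `cpm_model` from [cpm_fit()].
#' @param pheno Phenotype data frame of the test dataset.
#' @param edges Test subjects x edges matrix in the model's edge space.
#' @param target Observed score column to compare against; defaults to the
#'   model's training target. Supplying a different column evaluates
#'   cross-prediction (e.g. the NJ model predicting AA).
#' @param covariates Character vector of `pheno` columns to control for via
#'   [partial_correlation()] (e.g. `"mean_fd"`, `"asthma"`), or `NULL`.
#' @param label Optional dataset label carried into the report.
#' @return Object of class `cpm_evaluation`: `summary` tibble (one row per
#'   strength variant with `r`, `p.value`, `mse`, and `partial_r` /
#'   `partial_p` when covariates were given) and `predictions` tibble.
#' @export
cpm_apply <- function(model, pheno, edges, target = model$target,
                      covariates = NULL, label = NULL) {
  pheno <- as_tibble(pheno)
  edges <- align_edges(pheno, edges)
  if (ncol(edges) != model$E) {
    abort(sprintf("edge-space mismatch: model has %d edges, data %d",
                  model$E, ncol(edges)))
  }
  obs <- get_target(pheno, target)
  n <- nrow(edges)
  covmat <- NULL
  if (!is.null(covariates)) {
    missing <- setdiff(covariates, names(pheno))
    if (length(missing) > 0) {
      abort(paste0("covariate column(s) not in phenotypes: ",
                   paste(missing, collapse = ", ")))
    }
    covmat <- as.matrix(pheno[covariates])
  }

  variants <- c("combined", "positive", "negative")
  preds <- lapply(setNames(variants, variants), function(v) {
    stats::predict(model, edges, variant = v)
  })
  summary <- purrr::imap(preds, function(pr, v) {
    r <- if (stats::sd(pr) == 0) NA_real_ else stats::cor(pr, obs)
    p <- if (is.na(r)) NA_real_ else edge_p_values(r, n)
    row <- tibble(
      variant = v, n = n, r = r, p.value = p,
      mse = mean((pr - obs)^2)
    )
    if (!is.null(covmat) && !is.na(r)) {
      pc <- partial_correlation(pr, obs, covmat)
      row$partial_r <- pc$estimate
      row$partial_p <- pc$p.value
    } else if (!is.null(covmat)) {
      row$partial_r <- NA_real_
      row$partial_p <- NA_real_
    }
    row
  }) %>% bind_rows()

  predictions <- tibble(
    subject_id = if (!is.null(rownames(edges))) rownames(edges) else
      as.character(seq_len(n)),
    observed = obs,
    predicted = preds$combined,
    predicted_positive = preds$positive,
    predicted_negative = preds$negative
  )

  structure(
    list(summary = summary, predictions = predictions,
         target = target, model_target = model$target,
         covariates = covariates, label = label, n = n),
    class = "cpm_evaluation"
  )
}

#' Cross-predict a different facet with a frozen CPM
#'
#' Convenience wrapper around [cpm_apply()] that evaluates a model trained on
#' one facet against the observed scores of another facet in the test data
#' (specificity analysis).
#'
#' @inheritParams cpm_apply
#' @param target The *other* facet's column name in `pheno`.
#' @return A `cpm_evaluation`.
#' @export
cross_predict <- function(model, pheno, edges, target, covariates = NULL,
                          label = NULL) {
  cpm_apply(model, pheno, edges, target = target, covariates = covariates,
            label = label)
}

#' Correlation between two models' network strengths
#'
#' Pearson correlation of the combined (positive minus negative) strengths of
#' two CPMs over the same subjects, typically pooled across datasets.
#'
#' @param model_a,model_b `cpm_model` objects sharing the edge space.
#' @param edges Pooled subjects x edges matrix.
#' @return Tibble with `r`, `df` (`n - 2`), `statistic`, `p.value`, `n`.
#' @export
strength_correlation <- function(model_a, model_b, edges) {
  edges <- as.matrix(edges)
  if (model_a$E != model_b$E || ncol(edges) != model_a$E) {
    abort("edge-space mismatch between models and data")
  }
  sa <- suppressWarnings(
    network_strength(edges, model_a$positive, model_a$negative))$combined
  sb <- suppressWarnings(
    network_strength(edges, model_b$positive, model_b$negative))$combined
  n <- nrow(edges)
  r <- stats::cor(sa, sb)
  t <- r * sqrt((n - 2) / (1 - r^2))
  tibble(r = r, df = n - 2, statistic = t,
         p.value = 2 * stats::pt(-abs(t), n - 2), n = n)
}

#' Percent overlap of two edge masks
#'
#' `100 * shared / (size_a + size_b)` — the denominator is the sum of both
#' mask sizes.
#'
#' @param shared Number of shared edges.
#' @param size_a,size_b Mask sizes.
#' @return Percent overlap.
#' @export
#' @examples
#' overlap_percent(20, 328, 664) # 2.02
overlap_percent <- function(shared, size_a, size_b) {
  if (shared > min(size_a, size_b)) abort("shared exceeds a mask size")
  100 * shared / (size_a + size_b)
}

#' Overlap between two models' masks with a permutation null
#'
#' Counts edges shared between the same-sign masks of two models and tests
#' whether the overlap exceeds chance by shuffling the edges: each permutation
#' draws two uniformly random masks of the observed sizes over the common edge
#' space and records their overlap; `p = P(null shared >= observed)`.
#'
#' @param model_a,model_b `cpm_model` objects, or logical masks over a common
#'   edge space.
#' @param sign `"positive"` or `"negative"` (ignored when logical masks are
#'   supplied directly).
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return Object of class `overlap_report` with `shared`, `size_a`, `size_b`,
#'   `percent`, `p`, and the null distribution.
#' @export
mask_overlap <- function(model_a, model_b, sign = c("positive", "negative"),
                         n_perm = 1000, seed = NULL) {
  sign <- match.arg(sign)
  ma <- extract_mask(model_a, sign)
  mb <- extract_mask(model_b, sign)
  if (length(ma) != length(mb)) abort("edge-space mismatch between masks")
  E <- length(ma)
  size_a <- sum(ma)
  size_b <- sum(mb)
  if (size_a > E || size_b > E) abort("mask size exceeds edge space")
  shared <- sum(ma & mb)

  draw_null <- function() {
    vapply(seq_len(n_perm), function(i) {
      sum(sample.int(E, size_b) %in% sample.int(E, size_a))
    }, numeric(1))
  }
  null <- if (is.null(seed)) draw_null() else withr::with_seed(seed, draw_null())

  structure(
    list(
      sign = sign, shared = shared, size_a = size_a, size_b = size_b,
      percent = overlap_percent(shared, size_a, size_b),
      p = mean(null >= shared),
      null = null, n_perm = n_perm, seed = seed, E = E
    ),
    class = "overlap_report"
  )
}

extract_mask <- function(x, sign) {
  if (inherits(x, "cpm_model")) return(x[[sign]])
  if (is.logical(x)) return(x)
  abort("expected a cpm_model or a logical mask")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> %s masks: %d shared of %d + %d (%.2f%%), permutation p = %.4g (%d perms)\n",
    x$sign, x$shared, x$size_a, x$size_b, x$percent, x$p, x$n_perm
  ))
  invisible(x)
}

#' Split-half stability of network strength versus single edges
#'
#' Correlates, across subjects, the combined network strength computed from
#' one half of the scan data (e.g. runs 1-2) with that from the other half
#' (runs 3-4), and benchmarks it against the split-half correlations of
#' randomly sampled individual edges. One-sided by default
#' (`p = P(null r >= r_split)`, i.e. "is the aggregate *more* stable than
#' single edges"); a two-sided option exists.
#'
#' @param model A `cpm_model` providing the masks.
#' @param edges_a,edges_b Subjects x edges matrices from the two splits; rows
#'   must cover the same subjects (matched by rownames when present).
#' @param n_random_edges Number of single edges sampled for the null
#'   (default 1000; sampled without replacement when the edge space allows).
#' @param seed RNG seed for the edge sample.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return Object of class `stability_report` with `r_split`, the `null`
#'   distribution, and `p`.
#' @export
split_half_stability <- function(model, edges_a, edges_b,
                                 n_random_edges = 1000, seed = NULL,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  edges_a <- as.matrix(edges_a)
  edges_b <- as.matrix(edges_b)
  if (!is.null(rownames(edges_a)) && !is.null(rownames(edges_b))) {
    if (!setequal(rownames(edges_a), rownames(edges_b))) {
      abort("subject mismatch between the two splits")
    }
    edges_b <- edges_b[rownames(edges_a), , drop = FALSE]
  } else if (nrow(edges_a) != nrow(edges_b)) {
    abort("subject mismatch between the two splits")
  }
  if (ncol(edges_a) != model$E || ncol(edges_b) != model$E) {
    abort("edge-space mismatch")
  }
  sa <- suppressWarnings(
    network_strength(edges_a, model$positive, model$negative))$combined
  sb <- suppressWarnings(
    network_strength(edges_b, model$positive, model$negative))$combined
  r_split <- stats::cor(sa, sb)

  E <- model$E
  draw <- function() {
    idx <- if (E >= n_random_edges) sample.int(E, n_random_edges)
    else sample.int(E, n_random_edges, replace = TRUE)
    vapply(idx, function(e) stats::cor(edges_a[, e], edges_b[, e]), numeric(1))
  }
  null <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  p <- if (alternative == "greater") mean(null >= r_split)
  else mean(abs(null) >= abs(r_split))

  structure(
    list(r_split = r_split, null = null, p = p,
         n_random_edges = n_random_edges, seed = seed,
         alternative = alternative),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> strength split-half r = %.3f; single-edge null median = %.3f; p = %.3f (%s)\n",
    x$r_split, stats::median(x$null), x$p, x$alternative
  ))
  invisible(x)
}

#' Combined-sample shuffle and 80-20 train-test split
#'
#' Sensitivity analysis for multi-scanner generalization: pools subjects
#' across datasets, shuffles them, trains a CPM (cross-validation, optional
#' permutation inference, then a final single-fold fit) on the training
#' fraction, and applies the frozen model to the held-out fraction. With
#' `site_mean_control = TRUE`, the evaluation adds a partial correlation
#' controlling for the per-site mean of the observed score (computed over the
#' pooled sample), absorbing between-dataset score differences.
#'
#' @param pheno Pooled phenotype data frame with a site/dataset column.
#' @param edges Pooled subjects x edges matrix (common edge space).
#' @param target Score column to predict.
#' @param site Name of the site column (default `"site"`).
#' @param train_frac Training fraction (default 0.8).
#' @param threshold Edge-screening p threshold.
#' @param n_perm Permutations for training-set inference (0 skips it).
#' @param seed Seed for the shuffle (and permutations).
#' @param site_mean_control Add the per-site mean-score partial correlation.
#' @return List of class `shuffle_split` with the training `cv`, optional
#'   `perm`, the frozen `model`, the held-out `evaluation`, and the split ids.
#' @export
combined_shuffle_split <- function(pheno, edges, target, site = "site",
                                   train_frac = 0.8, threshold = 0.01,
                                   n_perm = 0, seed = 1,
                                   site_mean_control = FALSE) {
  pheno <- as_tibble(pheno)
  edges <- align_edges(pheno, edges)
  if (!site %in% names(pheno)) {
    abort(sprintf("site column '%s' not found", site))
  }
  n <- nrow(pheno)
  ord <- withr::with_seed(seed, sample.int(n))
  n_train <- round(train_frac * n)
  if (n_train < 10 || n - n_train < 10) {
    abort("each split needs at least 10 subjects")
  }
  tr <- ord[seq_len(n_train)]
  te <- ord[-seq_len(n_train)]

  pheno_te <- pheno[te, , drop = FALSE]
  if (site_mean_control) {
    site_means <- pheno %>%
      group_by(site = .data[[site]]) %>%
      summarise(.site_mean_score = mean(.data[[target]]), .groups = "drop")
    pheno_te$.site_mean_score <-
      site_means$.site_mean_score[match(pheno_te[[site]], site_means$site)]
  }

  cv <- cpm_cv(pheno[tr, , drop = FALSE], edges[tr, , drop = FALSE], target,
               threshold = threshold, keep_masks = FALSE)
  perm <- if (n_perm > 0) {
    cpm_permute(pheno[tr, , drop = FALSE], edges[tr, , drop = FALSE], target,
                threshold = threshold, n_perm = n_perm, seed = seed)
  }
  model <- cpm_fit(pheno[tr, , drop = FALSE], edges[tr, , drop = FALSE],
                   target, threshold = threshold)
  evaluation <- cpm_apply(
    model, pheno_te, edges[te, , drop = FALSE],
    covariates = if (site_mean_control) ".site_mean_score",
    label = "held-out 20%"
  )

  structure(
    list(cv = cv, perm = perm, model = model, evaluation = evaluation,
         train_ids = cv$predictions$subject_id,
         test_ids = evaluation$predictions$subject_id,
         n_train = n_train, n_test = n - n_train,
         seed = seed, site_mean_control = site_mean_control),
    class = "shuffle_split"
  )
}

#' @export
print.shuffle_split <- function(x, ...) {
  cat(sprintf(
    "<shuffle_split> train n = %d (CV r = %.3f%s), test n = %d (r = %.3f)\n",
    x$n_train, x$cv$r[["combined"]],
    if (!is.null(x$perm)) sprintf(", permutation p = %.3f", x$perm$p) else "",
    x$n_test, x$evaluation$summary$r[x$evaluation$summary$variant == "combined"]
  ))
  invisible(x)
}
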