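#' @export
print.cpm_model <- function(x, ...) {
  cf <- x$coefficients[x$coefficients$variant == "combined", ]
  cat(sprintf(
    "<cpm_model> target '%s', n = %d, p < %g screen: %d positive / %d negative edges\n",
    x$target, x$n, x$threshold, sum(x$positive), sum(x$negative)
  ))
  cat(sprintf("  combined model: score = %.4g * strength + %.4g\n",
              cf$beta, cf$intercept))
  invisible(x)
}

#' @export
print.cpm_cv <- function(x, ...) {
  cat(sprintf(
    "<cpm_cv> %s, target '%s', n = %d: r(pred, obs) = %.3f (positive %.3f, negative %.3f)\n",
    if (x$cfg$cv == "loocv") "LOOCV" else sprintf("%d-fold CV", x$cfg$k),
    x$cfg$target, x$cfg$n,
    x$r[["combined"]], x$r[["positive"]], x$r[["negative"]]
  ))
  if (x$n_degenerate_folds > 0) {
    cat(sprintf("  %d fold(s) fell back to the training mean\n",
                x$n_degenerate_folds))
  }
  invisible(x)
}

#' @export
print.cpm_perm <- function(x, ...) {
  cat(sprintf(
    "<cpm_perm> observed r = %.3f vs %d permutations: p = %.3f\n",
    x$observed_r, x$n_perm, x$p
  ))
  invisible(x)
}

#' @export
print.cpm_evaluation <- function(x, ...) {
  cat(sprintf("<cpm_evaluation> model '%s' -> observed '%s'%s, n = %d\n",
              x$model_target, x$target,
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              x$n))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidiers for fitted CPM objects
#'
#' `tidy()` returns the informative per-unit table of each object (selected
#' edges for a model, per-subject predictions for a CV run or evaluation, the
#' null distribution for a permutation test); `glance()` returns a one-row
#' summary.
#'
#' @param x A `cpm_model`, `cpm_cv`, `cpm_perm` or `cpm_evaluation`.
#' @param ... Unused.
#' @return A tibble.
#' @name cpm-tidiers
NULL

#' @rdname cpm-tidiers
#' @export
tidy.cpm_model <- function(x, ...) {
  pairs <- if (!is.na(x$n_nodes)) edge_index(x$n_nodes) else
    tibble(edge = seq_len(x$E), node_i = NA_integer_, node_j = NA_integer_)
  sel <- bind_rows(
    pairs[x$positive, ] %>% mutate(sign = "positive"),
    pairs[x$negative, ] %>% mutate(sign = "negative")
  )
  if (!is.null(x$stats)) {
    sel <- left_join(sel, x$stats, by = "edge")
  }
  sel %>% arrange(.data$edge)
}

#' @rdname cpm-tidiers
#' @export
glance.cpm_model <- function(x, ...) {
  cf <- x$coefficients[x$coefficients$variant == "combined", ]
  tibble(
    target = x$target, n = x$n, threshold = x$threshold,
    n_positive = sum(x$positive), n_negative = sum(x$negative),
    beta = cf$beta, intercept = cf$intercept
  )
}

#' @rdname cpm-tidiers
#' @export
tidy.cpm_cv <- function(x, ...) x$predictions

#' @rdname cpm-tidiers
#' @export
glance.cpm_cv <- function(x, ...) {
  tibble(
    target = x$cfg$target, cv = x$cfg$cv, n = x$cfg$n,
    r = x$r[["combined"]],
    r_positive = x$r[["positive"]], r_negative = x$r[["negative"]],
    n_degenerate_folds = x$n_degenerate_folds
  )
}

#' @rdname cpm-tidiers
#' @export
tidy.cpm_perm <- function(x, ...) tibble(null_r = x$null)

#' @rdname cpm-tidiers
#' @export
glance.cpm_perm <- function(x, ...) {
  tibble(observed_r = x$observed_r, p = x$p, n_perm = x$n_perm,
         seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' @rdname cpm-tidiers
#' @export
tidy.cpm_evaluation <- function(x, ...) x$summary

#' @rdname cpm-tidiers
#' @export
glance.cpm_evaluation <- function(x, ...) {
  x$summary %>%
    filter(.data$variant == "combined") %>%
    mutate(target = x$target, model_target = x$model_target,
           .before = 1)
}

#' Plot methods for CPM results
#'
#' `autoplot()` draws the standard display for each result type: predicted
#' versus observed scatter for cross-validation runs and evaluations, the
#' permutation null histogram with the observed statistic, and per-node
#' degree profiles for fitted models.
#'
#' @param object A fitted CPM object.
#' @param variant Strength variant to display where applicable.
#' @param ... Unused.
#' @return A ggplot object.
#' @name cpm-autoplot
NULL

pred_obs_plot <- function(df, r, subtitle) {
  ggplot(df, aes(x = .data$predicted, y = .data$observed)) +
    geom_point(alpha = 0.6) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "steelblue") +
    labs(x = "Predicted score", y = "Observed score",
         title = sprintf("Predicted vs observed (r = %.3f)", r),
         subtitle = subtitle) +
    theme_minimal()
}

#' @rdname cpm-autoplot
#' @export
autoplot.cpm_cv <- function(object, ...) {
  pred_obs_plot(object$predictions, object$r[["combined"]],
                sprintf("%s, target '%s'",
                        if (object$cfg$cv == "loocv") "LOOCV"
                        else sprintf("%d-fold CV", object$cfg$k),
                        object$cfg$target))
}

#' @rdname cpm-autoplot
#' @export
autoplot.cpm_evaluation <- function(object, ...) {
  r <- object$summary$r[object$summary$variant == "combined"]
  pred_obs_plot(object$predictions, r,
                sprintf("model '%s' applied to observed '%s'",
                        object$model_target, object$target))
}

#' @rdname cpm-autoplot
#' @export
autoplot.cpm_perm <- function(object, ...) {
  ggplot(tibble(null_r = object$null), aes(x = .data$null_r)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed_r, colour = "firebrick",
               linewidth = 1) +
    labs(x = "Null CV correlation", y = "Count",
         title = sprintf("Permutation null (p = %.3f, %d permutations)",
                         object$p, object$n_perm)) +
    theme_minimal()
}

#' @rdname cpm-autoplot
#' @export
autoplot.cpm_model <- function(object, ...) {
  deg <- node_degree(object)
  ggplot(deg, aes(x = .data$node, y = .data$degree, fill = .data$sign)) +
    geom_col(width = 1) +
    facet_wrap(~sign, ncol = 1) +
    scale_fill_manual(values = c(positive = "firebrick",
                                 negative = "steelblue"), guide = "none") +
    labs(x = "Node", y = "Degree",
         title = sprintf("Mask degree profile, target '%s'", object$target)) +
    theme_minimal()
}

#' Heatmap of within/between-network edge counts
#'
#' @param counts Matrix from [network_pair_counts()].
#' @return A ggplot object.
#' @export
plot_network_counts <- function(counts) {
  df <- as_tibble(counts, rownames = "network_a") %>%
    pivot_longer(-"network_a", names_to = "network_b", values_to = "count")
  ggplot(df, aes(x = .data$network_a, y = .data$network_b,
                 fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), size = 3) +
    scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, title = "Mask edges by network pair") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
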