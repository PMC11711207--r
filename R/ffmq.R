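# Standard published FFMQ-39 item assignment (shipped as an editable CSV in
# inst/extdata so the scoring is auditable and swappable).

#' Load and validate an FFMQ-39 scoring map
#'
#' The Five Facet Mindfulness Questionnaire (FFMQ) has 39 five-point items
#' scored into the facets Acting with Awareness (AA), Non-judging (NJ),
#' Non-reactivity (NR), Describing (D) and Observing (O). The packaged default
#' is the standard published FFMQ-39 assignment; a custom map (same columns)
#' can be supplied for translated or revised instruments.
#'
#' @param path CSV with columns `item` (1..39), `facet` (AA/NJ/NR/D/O) and
#'   `reverse` (logical). Default: the packaged map.
#' @return A validated tibble with one row per item.
#' @export
ffmq_scoring_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ffmq39_scoring.csv", package = "mindcpm")
  }
  map <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           item = readr::col_integer(),
                           facet = readr::col_character(),
                           reverse = readr::col_logical()
                         ))
  validate_scoring_map(map)
  map
}

validate_scoring_map <- function(map) {
  if (!all(c("item", "facet", "reverse") %in% names(map))) {
    abort("scoring map needs columns item, facet, reverse")
  }
  if (nrow(map) != 39 || !setequal(map$item, 1:39)) {
    abort("scoring map must assign exactly items 1..39 (a partition)")
  }
  if (!all(map$facet %in% c("AA", "NJ", "NR", "D", "O")) ||
      !all(c("AA", "NJ", "NR", "D", "O") %in% map$facet)) {
    abort("facets must partition the items into AA, NJ, NR, D, O (all five non-empty)")
  }
  for (f in c("AA", "NJ", "D")) {
    if (!any(map$reverse[map$facet == f])) {
      abort(sprintf("facet %s must contain at least one reverse-scored item", f))
    }
  }
  invisible(map)
}

#' Score FFMQ-39 item responses
#'
#' Reverse-scored items contribute `6 - raw`; facet scores are sums of their
#' items' scored values. Totals range from 39 to 195; higher means more
#' mindful. `total_without_observing` drops the Observing facet, which shows
#' limited validity in some samples.
#'
#' @param responses Data frame with a `subject_id` column and 39 item columns
#'   `item_01` .. `item_39`, each an integer in 1..5.
#' @param map Scoring map from [ffmq_scoring_map()].
#' @return Tibble with `subject_id`, facet scores `AA`, `NJ`, `NR`, `D`, `O`,
#'   `total` and `total_without_observing`.
#' @export
score_ffmq <- function(responses, map = ffmq_scoring_map()) {
  validate_scoring_map(map)
  responses <- as_tibble(responses)
  item_cols <- sprintf("item_%02d", 1:39)
  missing <- setdiff(item_cols, names(responses))
  if (length(missing) > 0) {
    abort(paste0("missing item columns: ", paste(missing, collapse = ", ")))
  }
  if (!"subject_id" %in% names(responses)) {
    responses$subject_id <- seq_len(nrow(responses))
  }
  vals <- as.matrix(responses[item_cols])
  bad <- !is.finite(vals) | vals < 1 | vals > 5 | vals != round(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    abort(sprintf(
      "invalid response(s), e.g. subject %s item %d = %s (must be an integer in 1..5)",
      responses$subject_id[idx[1, 1]], idx[1, 2], vals[idx[1, , drop = FALSE]]
    ))
  }
  map <- map[order(map$item), ]
  scored <- vals
  rev_items <- map$item[map$reverse]
  scored[, rev_items] <- 6 - scored[, rev_items]
  facet_of <- map$facet
  out <- tibble(subject_id = responses$subject_id)
  for (f in c("AA", "NJ", "NR", "D", "O")) {
    out[[f]] <- as.integer(rowSums(scored[, facet_of == f, drop = FALSE]))
  }
  out$total <- out$AA + out$NJ + out$NR + out$D + out$O
  out$total_without_observing <- out$total - out$O
  out
}

#' Welch's unpaired heteroskedastic t-test from group summaries
#'
#' Two-sample t-test without the equal-variance assumption, computed from
#' summary statistics (as when comparing published site means). Degrees of
#' freedom by Welch–Satterthwaite; two-tailed p from the t distribution.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group A.
#' @param mean_b,sd_b,n_b Summary statistics of group B.
#' @return Tibble with `t`, `df`, `p.value`.
#' @export
#' @examples
#' welch_t(134.8, 17.8, 206, 126.8, 17.4, 82) # t ~ 3.50
welch_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) abort("each group needs n >= 2")
  if (sd_a < 0 || sd_b < 0) abort("sd must be nonnegative")
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  se2 <- va + vb
  if (se2 == 0) abort("zero standard error: both groups have zero variance")
  t <- (mean_a - mean_b) / sqrt(se2)
  df <- se2^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  tibble(t = t, df = df, p.value = 2 * stats::pt(-abs(t), df))
}

#' Cohen's d from group summaries (pooled SD)
#'
#' `d = (mean_a - mean_b) / s_pooled` with
#' `s_pooled^2 = ((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2)`.
#'
#' @inheritParams welch_t
#' @return The effect size as a single number.
#' @export
cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) abort("each group needs n >= 2")
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  if (sp2 == 0) abort("zero pooled SD")
  (mean_a - mean_b) / sqrt(sp2)
}

#' Pearson correlations among FFMQ facets (and with the total)
#'
#' @param scores Data frame with facet columns `AA`, `NJ`, `NR`, `D`, `O`
#'   (e.g. from [score_ffmq()]); a `total` column is used when present and
#'   computed otherwise.
#' @return A list with `facets` (5x5 symmetric correlation matrix, unit
#'   diagonal) and `with_total` (named vector of facet-vs-total correlations).
#' @export
subscale_correlations <- function(scores) {
  scores <- as_tibble(scores)
  facets <- c("AA", "NJ", "NR", "D", "O")
  missing <- setdiff(facets, names(scores))
  if (length(missing) > 0) {
    abort(paste0("missing facet columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(scores) < 3) abort("need at least 3 subjects")
  m <- as.matrix(scores[facets])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance facet(s): ",
                 paste(facets[sds == 0], collapse = ", ")))
  }
  total <- if ("total" %in% names(scores)) scores$total else rowSums(m)
  list(
    facets = stats::cor(m),
    with_total = drop(stats::cor(total, m))
  )
}
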