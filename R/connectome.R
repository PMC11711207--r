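#' Build a Fisher-z functional connectome from node timeseries
#'
#' Computes the Pearson correlation between every pair of node timeseries and
#' applies the Fisher z transform (`atanh`). The diagonal is set to zero. The
#' timeseries are used as supplied: detrending, nuisance regression and
#' filtering are upstream preprocessing concerns, not repeated here.
#'
#' @param ts Numeric matrix or data frame of node timeseries with
#'   **rows = timepoints, columns = nodes** (the on-disk layout). At least 3
#'   timepoints and 2 nodes.
#' @return An `n_nodes x n_nodes` symmetric numeric matrix of Fisher-z
#'   correlations with exact zero diagonal. Column names, when present, are
#'   carried over as node names.
#' @details Degenerate inputs fail loudly rather than being clipped: a node
#'   with zero variance, a missing value, or an off-diagonal correlation with
#'   `|r| >= 1 - 1e-12` (no finite Fisher z) each raise an error naming the
#'   offending node(s).
#' @export
#' @examples
#' ts <- cbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
#' build_connectome(ts) # atanh(0.6) off-diagonal
build_connectome <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) abort("timeseries must be numeric")
  if (nrow(ts) < 3) abort("need at least 3 timepoints")
  if (ncol(ts) < 2) abort("need at least 2 nodes")
  if (anyNA(ts)) abort("timeseries contain missing values")
  node_names <- colnames(ts)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    lab <- if (is.null(node_names)) bad else node_names[bad]
    abort(paste0("zero-variance node(s): ", paste(lab, collapse = ", ")))
  }
  r <- stats::cor(ts)
  off <- abs(r) >= 1 - 1e-12
  diag(off) <- FALSE
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pair <- if (is.null(node_names)) {
      paste0("(", idx[, 1], ",", idx[, 2], ")")
    } else {
      paste0("(", node_names[idx[, 1]], ",", node_names[idx[, 2]], ")")
    }
    abort(paste0(
      "perfect correlation between node pair(s) ",
      paste(pair, collapse = ", "),
      ": Fisher z is undefined (degenerate input)"
    ))
  }
  z <- atanh(r)
  diag(z) <- 0
  dimnames(z) <- list(node_names, node_names)
  z
}

#' Average retained runs of one subject
#'
#' Element-wise arithmetic mean of the Fisher-z matrices of the runs retained
#' after motion exclusion. Averaging happens on the Fisher-z scale (the stored
#' representation), not on raw correlations.
#'
#' @param cms List of connectivity matrices with identical dimensions.
#' @return A single connectivity matrix.
#' @export
average_runs <- function(cms) {
  if (length(cms) == 0) abort("no retained runs")
  dims <- vapply(cms, function(m) dim(as.matrix(m)), integer(2))
  if (any(dims != dims[, 1])) abort("runs have mismatched node counts")
  Reduce(`+`, lapply(cms, as.matrix)) / length(cms)
}

#' Exclude subjects (and runs) by mean framewise displacement
#'
#' Implements strict-threshold head-motion exclusion: a run or subject is
#' dropped when its mean framewise displacement (FD) exceeds `fd_threshold`
#' (strictly greater; a value exactly at the threshold is retained). In
#' `run_level` mode (multi-run acquisitions), runs above threshold are dropped
#' first and the subject-level decision then uses the mean of `mean_fd` across
#' runs — by default across the *retained* runs (`subject_mean = "retained"`),
#' with the across-all-runs reading available via `subject_mean = "all"`.
#'
#' @param records Data frame with columns `subject_id`, `mean_fd` and, for
#'   multi-run data, `run_id`. Every run of every subject must have a record.
#' @param fd_threshold Positive FD threshold in millimetres (default 0.15).
#' @param run_level If `TRUE`, apply per-run exclusion before the subject-level
#'   decision.
#' @param subject_mean Which runs enter the subject-level mean in `run_level`
#'   mode: `"retained"` (default) or `"all"`.
#' @return A list of class `motion_exclusion` with elements `retained` (tibble
#'   of retained `subject_id`/`run_id` rows) and `log` (tibble of every
#'   exclusion with its reason and FD value).
#' @export
apply_motion_exclusion <- function(records, fd_threshold = 0.15,
                                   run_level = FALSE,
                                   subject_mean = c("retained", "all")) {
  subject_mean <- match.arg(subject_mean)
  stopifnot(fd_threshold > 0)
  records <- as_tibble(records)
  if (!all(c("subject_id", "mean_fd") %in% names(records))) {
    abort("records need columns subject_id and mean_fd")
  }
  if (!"run_id" %in% names(records)) records$run_id <- 1L
  if (anyNA(records$mean_fd)) {
    bad <- records$subject_id[is.na(records$mean_fd)]
    abort(paste0("missing mean_fd record for: ", paste(bad, collapse = ", ")))
  }
  if (any(records$mean_fd < 0)) abort("mean_fd must be nonnegative")

  log <- tibble(
    subject_id = character(), run_id = as.character(integer()),
    reason = character(), value = numeric()
  )

  if (run_level) {
    run_excl <- records %>% filter(.data$mean_fd > fd_threshold)
    if (nrow(run_excl) > 0) {
      log <- bind_rows(log, tibble(
        subject_id = as.character(run_excl$subject_id),
        run_id = as.character(run_excl$run_id),
        reason = "run mean FD above threshold",
        value = run_excl$mean_fd
      ))
    }
    kept_runs <- records %>% filter(.data$mean_fd <= fd_threshold)
    subj <- records %>%
      group_by(.data$subject_id) %>%
      summarise(
        mean_all = mean(.data$mean_fd),
        mean_retained = mean(.data$mean_fd[.data$mean_fd <= fd_threshold]),
        n_retained = sum(.data$mean_fd <= fd_threshold),
        .groups = "drop"
      )
    subj$decision_mean <- if (subject_mean == "retained") {
      subj$mean_retained
    } else {
      subj$mean_all
    }
    drop_none <- subj$n_retained == 0
    drop_mean <- !drop_none & subj$decision_mean > fd_threshold
    if (any(drop_none)) {
      log <- bind_rows(log, tibble(
        subject_id = as.character(subj$subject_id[drop_none]),
        run_id = NA_character_,
        reason = "no runs retained",
        value = subj$mean_all[drop_none]
      ))
    }
    if (any(drop_mean)) {
      log <- bind_rows(log, tibble(
        subject_id = as.character(subj$subject_id[drop_mean]),
        run_id = NA_character_,
        reason = paste0("subject mean FD (", subject_mean, " runs) above threshold"),
        value = subj$decision_mean[drop_mean]
      ))
    }
    dropped <- subj$subject_id[drop_none | drop_mean]
    retained <- kept_runs %>%
      filter(!.data$subject_id %in% dropped) %>%
      select("subject_id", "run_id", "mean_fd")
  } else {
    subj <- records %>%
      group_by(.data$subject_id) %>%
      summarise(overall = mean(.data$mean_fd), .groups = "drop")
    drop <- subj$overall > fd_threshold
    if (any(drop)) {
      log <- bind_rows(log, tibble(
        subject_id = as.character(subj$subject_id[drop]),
        run_id = NA_character_,
        reason = "subject mean FD above threshold",
        value = subj$overall[drop]
      ))
    }
    retained <- records %>%
      filter(!.data$subject_id %in% subj$subject_id[drop]) %>%
      select("subject_id", "run_id", "mean_fd")
  }

  structure(
    list(retained = retained, log = log, fd_threshold = fd_threshold,
         run_level = run_level, subject_mean = subject_mean),
    class = "motion_exclusion"
  )
}

#' @export
print.motion_exclusion <- function(x, ...) {
  cat(sprintf(
    "<motion_exclusion> threshold %.3g mm (%s)\n", x$fd_threshold,
    if (x$run_level) paste0("run-level, subject mean over ", x$subject_mean, " runs")
    else "subject-level"
  ))
  cat(sprintf(
    "  retained: %d runs from %d subjects; %d exclusions\n",
    nrow(x$retained), length(unique(x$retained$subject_id)), nrow(x$log)
  ))
  invisible(x)
}
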