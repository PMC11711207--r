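#' Load a phenotype table
#'
#' Reads a CSV with one row per subject. When the 39 FFMQ item columns
#' (`item_01` .. `item_39`) are present and the facet columns are not, the
#' items are scored through [score_ffmq()] automatically; precomputed facet
#' or total columns pass through unchanged.
#'
#' @param path Phenotype CSV with a `subject_id` column.
#' @param map Scoring map used when items are auto-scored.
#' @return A tibble keyed by `subject_id`.
#' @export
load_phenotypes <- function(path, map = ffmq_scoring_map()) {
  pheno <- readr::read_csv(path, show_col_types = FALSE)
  if (!"subject_id" %in% names(pheno)) abort("phenotype CSV needs a subject_id column")
  pheno$subject_id <- as.character(pheno$subject_id)
  dup <- pheno$subject_id[duplicated(pheno$subject_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate subject id(s): ", paste(unique(dup), collapse = ", ")))
  }
  item_cols <- sprintf("item_%02d", 1:39)
  facet_cols <- c("AA", "NJ", "NR", "D", "O")
  if (all(item_cols %in% names(pheno)) && !any(facet_cols %in% names(pheno))) {
    scores <- score_ffmq(pheno[c("subject_id", item_cols)], map = map)
    pheno <- left_join(pheno, scores, by = "subject_id")
  }
  score_like <- intersect(c(facet_cols, "total", "total_without_observing",
                            "mean_fd"), names(pheno))
  non_num <- score_like[!vapply(pheno[score_like], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort(paste0("non-numeric score field(s): ", paste(non_num, collapse = ", ")))
  }
  pheno
}

# Square connectome CSV: node-id header row plus a leading node-id column.
read_connectome_csv <- function(path, tol = 1e-8) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- as.character(df[[1]])
  if (nrow(m) != ncol(m)) {
    abort(sprintf("connectome file '%s' is not square", basename(path)))
  }
  if (max(abs(m - t(m))) > tol) {
    abort(sprintf("connectome file '%s' is not symmetric", basename(path)))
  }
  if (max(abs(diag(m))) > tol) {
    abort(sprintf("connectome file '%s' has a nonzero diagonal", basename(path)))
  }
  diag(m) <- 0
  m
}

# Timeseries TSV: rows = timepoints, columns = nodes (header of node ids).
read_timeseries_tsv <- function(path) {
  as.matrix(readr::read_tsv(path, show_col_types = FALSE))
}

#' Load subject edge vectors from a manifest
#'
#' The manifest CSV has columns `subject_id`, `run_id`, `file` and optionally
#' `mean_fd` and `type` (`"matrix"`, the default, or `"timeseries"`); file
#' paths are resolved relative to the manifest. Timeseries files are routed
#' through [build_connectome()]; matrix files are validated (square,
#' symmetric, zero diagonal) and Fisher-z values are taken as stored. Multiple
#' runs of a subject are averaged with [average_runs()]. When a phenotype
#' table is supplied, subjects are matched by id — never by file order — and
#' any id present on only one side is an error.
#'
#' @param manifest Manifest CSV path, or a manifest data frame (e.g. after
#'   filtering out excluded runs) with `dir` giving the file root.
#' @param phenotypes Optional phenotype tibble to align against.
#' @param dir Root for relative file paths when `manifest` is a data frame;
#'   ignored (taken from the manifest location) for a path.
#' @return Subjects x edges matrix in canonical order, rownames = subject ids,
#'   with attribute `n_nodes`.
#' @export
load_edges <- function(manifest, phenotypes = NULL, dir = ".") {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  manifest <- as_tibble(manifest)
  if (!all(c("subject_id", "file") %in% names(manifest))) {
    abort("manifest needs subject_id and file columns")
  }
  manifest$subject_id <- as.character(manifest$subject_id)
  if (!"run_id" %in% names(manifest)) manifest$run_id <- "run1"
  if (!"type" %in% names(manifest)) manifest$type <- "matrix"
  base <- dir

  ids <- unique(manifest$subject_id)
  if (!is.null(phenotypes)) {
    pids <- as.character(phenotypes$subject_id)
    only_m <- setdiff(ids, pids)
    only_p <- setdiff(pids, ids)
    if (length(only_m) > 0 || length(only_p) > 0) {
      abort(paste0(
        "subject sets differ between manifest and phenotypes",
        if (length(only_m)) paste0("; only in manifest: ",
                                   paste(only_m, collapse = ", ")),
        if (length(only_p)) paste0("; only in phenotypes: ",
                                   paste(only_p, collapse = ", "))
      ))
    }
    ids <- pids
  }

  read_one <- function(row) {
    path <- file.path(base, row$file)
    if (row$type == "timeseries") {
      build_connectome(read_timeseries_tsv(path))
    } else {
      read_connectome_csv(path)
    }
  }
  mats <- lapply(ids, function(id) {
    sub <- manifest[manifest$subject_id == id, , drop = FALSE]
    cms <- lapply(seq_len(nrow(sub)), function(i) read_one(sub[i, ]))
    vectorize_edges(average_runs(cms))
  })
  lens <- lengths(mats)
  if (length(unique(lens)) != 1) {
    abort("subjects have mismatched node counts")
  }
  edges <- do.call(rbind, mats)
  rownames(edges) <- ids
  attr(edges, "n_nodes") <- nodes_from_edges(lens[1])
  edges
}

#' Export a fitted CPM to an interchange directory
#'
#' Writes `model.json` (target, coefficients per strength variant, threshold,
#' training n, edge space) plus two canonical-order edge-list TSVs
#' (`edges_positive.tsv`, `edges_negative.tsv`). [read_cpm_model()] restores
#' the model exactly.
#'
#' @param model A `cpm_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cpm_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    target = model$target, threshold = model$threshold,
    n = model$n, E = model$E, n_nodes = model$n_nodes,
    coefficients = model$coefficients,
    package_version = as.character(utils::packageVersion("mindcpm"))
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  nn <- model$n_nodes
  if (is.na(nn)) abort("cannot export a model with a non-triangular edge space")
  pairs <- edge_index(nn)
  for (s in c("positive", "negative")) {
    readr::write_tsv(
      pairs[model[[s]], c("node_i", "node_j")] %>%
        mutate(sign = s, weight = 1),
      file.path(dir, sprintf("edges_%s.tsv", s))
    )
  }
  invisible(dir)
}

#' Read a CPM written by [write_cpm_model()]
#'
#' @param dir Model directory.
#' @return A `cpm_model` (without the per-edge screening stats, which are a
#'   training-time artifact).
#' @export
read_cpm_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  masks <- read_edge_list_pair(dir, meta$n_nodes)
  structure(
    list(
      positive = masks$positive, negative = masks$negative,
      coefficients = as_tibble(meta$coefficients),
      stats = NULL,
      target = meta$target, threshold = meta$threshold,
      n = meta$n, E = meta$E, n_nodes = meta$n_nodes
    ),
    class = "cpm_model"
  )
}

read_edge_list_pair <- function(dir, n_nodes) {
  out <- list(positive = logical(n_edges(n_nodes)),
              negative = logical(n_edges(n_nodes)))
  for (s in c("positive", "negative")) {
    f <- file.path(dir, sprintf("edges_%s.tsv", s))
    masks <- read_edge_list(f, n_nodes)
    out[[s]] <- masks[[s]]
  }
  out
}

#' Run the full training pipeline from a configuration
#'
#' Orchestrates motion exclusion, phenotype loading/scoring, cross-validated
#' training, permutation inference, model selection and the final single-fold
#' fit, writing all reports (JSON), the exported model(s) and the exclusion
#' log into the output directory. Every output embeds the seed and a hash of
#' the configuration so reruns are reproducible and auditable.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `phenotypes` (CSV path), `manifest` (CSV path), `out` (output directory),
#'   `target` (character vector of score columns to train), and optionally
#'   `threshold` (default 0.01), `cv` (`"loocv"`/`"kfold"`), `k`, `n_perm`
#'   (default 100), `alpha` (default 0.05), `fd_threshold` (default 0.15),
#'   `run_level` (default `FALSE`), `seed` (default 1).
#' @return A list of class `cpm_pipeline` with the per-target results
#'   (invisibly writes its artifacts to `config$out`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(threshold = 0.01, cv = "loocv", k = 10, n_perm = 100,
                   alpha = 0.05, fd_threshold = 0.15, run_level = FALSE,
                   seed = 1)
  config <- utils::modifyList(defaults, config)
  for (f in c("phenotypes", "manifest", "out", "target")) {
    if (is.null(config[[f]])) {
      abort(sprintf("config validation: missing field '%s'", f))
    }
  }
  for (f in c("phenotypes", "manifest")) {
    if (!file.exists(config[[f]])) {
      abort(sprintf("config validation: path '%s' does not exist", config[[f]]))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  pheno <- stage("phenotypes", load_phenotypes(config$phenotypes))
  manifest <- readr::read_csv(config$manifest, show_col_types = FALSE)
  excl <- stage("motion_exclusion", {
    records <- manifest %>%
      transmute(subject_id = as.character(.data$subject_id),
                run_id = if ("run_id" %in% names(manifest)) .data$run_id else "run1",
                mean_fd = .data$mean_fd)
    apply_motion_exclusion(records, fd_threshold = config$fd_threshold,
                           run_level = config$run_level)
  })
  keep <- unique(excl$retained$subject_id)
  pheno <- pheno[pheno$subject_id %in% keep, , drop = FALSE]
  retained_key <- paste(excl$retained$subject_id, excl$retained$run_id)
  manifest_kept <- manifest %>%
    filter(paste(as.character(.data$subject_id),
                 if ("run_id" %in% names(manifest)) .data$run_id else "run1")
           %in% retained_key)
  edges <- stage("edges", load_edges(manifest_kept, phenotypes = pheno,
                                     dir = dirname(config$manifest)))

  results <- lapply(setNames(config$target, config$target), function(tg) {
    cv <- stage("train", cpm_cv(pheno, edges, tg,
                                threshold = config$threshold,
                                cv = config$cv, k = config$k,
                                seed = config$seed))
    perm <- stage("permute", cpm_permute(pheno, edges, tg,
                                         threshold = config$threshold,
                                         cv = config$cv, k = config$k,
                                         n_perm = config$n_perm,
                                         seed = config$seed))
    model <- stage("finalize", cpm_fit(pheno, edges, tg,
                                       threshold = config$threshold))
    list(cv = cv, perm = perm, model = model)
  })
  p_values <- vapply(results, function(r) r$perm$p, numeric(1))
  selected <- select_models(p_values, alpha = config$alpha)

  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- digest_config(config)
  readr::write_csv(excl$log, file.path(config$out, "exclusion_log.csv"))
  for (tg in names(results)) {
    write_cpm_model(results[[tg]]$model,
                    file.path(config$out, paste0("model_", tg)))
    jsonlite::write_json(
      list(
        target = tg, seed = config$seed, config_hash = cfg_hash,
        n = results[[tg]]$cv$cfg$n,
        r = as.list(results[[tg]]$cv$r),
        permutation_p = results[[tg]]$perm$p,
        n_perm = config$n_perm,
        predictions = results[[tg]]$cv$predictions
      ),
      file.path(config$out, paste0("report_", tg, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  jsonlite::write_json(
    list(seed = config$seed, config_hash = cfg_hash,
         targets = config$target, permutation_p = as.list(p_values),
         selected = selected,
         n_excluded = length(unique(excl$log$subject_id))),
    file.path(config$out, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )

  structure(
    list(results = results, selected = selected, p_values = p_values,
         exclusion = excl, config = config, config_hash = cfg_hash),
    class = "cpm_pipeline"
  )
}

# Small stable config fingerprint (no external digest dependency).
digest_config <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(as.character(s))) %% 251)) %% .Machine$integer.max)
}

#' @export
print.cpm_pipeline <- function(x, ...) {
  cat(sprintf("<cpm_pipeline> %d target(s); selected: %s\n",
              length(x$results),
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)"))
  for (tg in names(x$results)) {
    cat(sprintf("  %s: CV r = %.3f, permutation p = %.3f\n",
                tg, x$results[[tg]]$cv$r[["combined"]], x$p_values[[tg]]))
  }
  invisible(x)
}
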