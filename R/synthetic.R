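#' Configuration for the synthetic multi-site cohort generator
#'
#' Describes the statistical structure the CPM analysis assumes: site-specific
#' Gaussian trait distributions (defaults mirror the three published site
#' summaries: 134.8/17.8, 126.8/17.4, 107.2/11.3), a set of planted positive
#' and negative signal edges whose values correlate with the trait at
#' `effect_r`, equicorrelated facets, motion covariates with optional
#' edge/score coupling, optional multi-run structure with a set split-half
#' edge reliability, and a seed making everything reproducible.
#'
#' @param n_nodes Atlas size (default 100; use 268 for full-scale parity).
#' @param sites Named list of sites, each `list(n, score_mean, score_sd)`.
#' @param planted_positive,planted_negative Counts of signal edges, or
#'   explicit canonical edge indices.
#' @param effect_r Target per-edge correlation with the trait (default 0.3;
#'   stronger than the weak effects implied by published prediction r ~ 0.2,
#'   see the methods vignette).
#' @param target Trait column the signal edges track (default `"total"`).
#' @param facet_corr Equicorrelation of the five facet latents (default 0.4).
#' @param fd_mean,fd_sd Mean framewise displacement distribution (mm).
#' @param fd_score_r Correlation between FD and the trait (0 = no motion
#'   confounding of the phenotype).
#' @param confound_strength Coupling of planted edges to standardized FD.
#' @param n_runs Runs per subject (default 1; 4 emulates a four-run protocol).
#' @param edge_reliability Split-half reliability of a null edge between
#'   two-run averages (default 0.4); drives the run-noise variance.
#' @param site_edge_sd SD of per-site edge offsets (scanner shift).
#' @param seed RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_nodes = 100,
                          sites = list(
                            wisconsin = list(n = 206, score_mean = 134.8, score_sd = 17.8),
                            stanford = list(n = 82, score_mean = 126.8, score_sd = 17.4),
                            leipzig = list(n = 79, score_mean = 107.2, score_sd = 11.3)
                          ),
                          planted_positive = 30, planted_negative = 30,
                          effect_r = 0.3, target = "total",
                          facet_corr = 0.4,
                          fd_mean = 0.10, fd_sd = 0.04, fd_score_r = 0,
                          confound_strength = 0,
                          n_runs = 1, edge_reliability = 0.4,
                          site_edge_sd = 0.1,
                          seed = 1L) {
  stopifnot(
    n_nodes >= 3, length(sites) >= 1,
    effect_r > -1, effect_r < 1,
    facet_corr >= 0, facet_corr < 1,
    n_runs >= 1, edge_reliability > 0, edge_reliability < 1
  )
  for (s in sites) {
    if (s$n < 2) abort("each site needs n >= 2")
  }
  structure(
    list(
      n_nodes = n_nodes, sites = sites,
      planted_positive = planted_positive,
      planted_negative = planted_negative,
      effect_r = effect_r, target = target,
      facet_corr = facet_corr,
      fd_mean = fd_mean, fd_sd = fd_sd, fd_score_r = fd_score_r,
      confound_strength = confound_strength,
      n_runs = n_runs, edge_reliability = edge_reliability,
      site_edge_sd = site_edge_sd, seed = seed
    ),
    class = "cohort_config"
  )
}

# Phenotypes shared by both generator modes: equicorrelated facet latents are
# scaled so the facet sums reproduce the configured site total means/SDs.
generate_phenotypes <- function(cfg) {
  facets <- c("AA", "NJ", "NR", "D", "O")
  rho <- cfg$facet_corr
  norm <- sqrt(5 + 20 * rho) # sd of the sum of 5 equicorrelated latents
  site_names <- names(cfg$sites)
  if (is.null(site_names)) site_names <- paste0("site", seq_along(cfg$sites))

  out <- purrr::imap(cfg$sites, function(s, nm) {
    g <- rnorm(s$n)
    f <- sqrt(rho) * matrix(g, s$n, 5) +
      sqrt(1 - rho) * matrix(rnorm(s$n * 5), s$n, 5)
    colnames(f) <- facets
    scale_f <- s$score_sd / norm
    sc <- tibble(site = rep(nm, s$n))
    for (k in facets) sc[[k]] <- s$score_mean / 5 + scale_f * f[, k]
    sc$total <- rowSums(as.matrix(sc[facets]))
    sc$total_without_observing <- sc$total - sc$O
    sc
  }) %>% bind_rows()

  n <- nrow(out)
  z_t <- as.numeric(scale(out[[cfg$target]]))
  fd_noise <- rnorm(n)
  # rounded to 1 nm: keeps CSV round trips exact, far below any meaningful FD
  out$mean_fd <- round(pmax(
    cfg$fd_mean + cfg$fd_sd *
      (cfg$fd_score_r * z_t + sqrt(1 - cfg$fd_score_r^2) * fd_noise),
    0.001
  ), 6)
  out$asthma <- rbinom(n, 1, 0.34)
  out$clinical <- rbinom(n, 1, 0.25)
  out$resolution <- rbinom(n, 1, 0.10)
  out <- bind_cols(tibble(subject_id = sprintf("s%04d", seq_len(n))), out)
  out
}

resolve_planted <- function(requested, E, exclude = integer()) {
  if (length(requested) == 1 && requested == round(requested) && requested >= 0 &&
      !inherits(requested, "AsIs")) {
    pool <- setdiff(seq_len(E), exclude)
    if (requested > length(pool)) abort("planted count exceeds available edges")
    sort(sample(pool, requested))
  } else {
    idx <- as.integer(requested)
    if (any(idx < 1 | idx > E)) abort("planted edge index outside edge space")
    if (any(idx %in% exclude)) abort("planted masks must be disjoint")
    sort(idx)
  }
}

#' Generate a synthetic multi-site connectome cohort
#'
#' Draws phenotypes per site, then builds subject x edge matrices in which the
#' planted positive edges follow `a * z(score) + site offset + motion coupling
#' + unit Gaussian noise` (negative edges use `-a`), with
#' `a = effect_r / sqrt(1 - effect_r^2)` so the expected edge-score
#' correlation is `effect_r`; all other edges are independent noise plus the
#' site offset. With `n_runs > 1`, per-run matrices add independent run noise
#' calibrated so a null edge's two-run-average split-half reliability equals
#' `edge_reliability`, and `edges` holds the across-run average. When the
#' pooled n is at least 200 the realized planted-edge correlations are checked
#' against `effect_r` (warning beyond +/- 0.1).
#'
#' @param cfg A [cohort_config()].
#' @return Object of class `cpm_cohort`: `phenotype` tibble, `edges` matrix
#'   (subjects x E, canonical order, rownames = subject ids), `runs` (list of
#'   per-run matrices when `n_runs > 1`), and `truth` (planted masks and
#'   coupling; never read by the analysis path).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  pheno <- generate_phenotypes(cfg)
  n <- nrow(pheno)
  E <- n_edges(cfg$n_nodes)
  pos <- resolve_planted(cfg$planted_positive, E)
  neg <- resolve_planted(cfg$planted_negative, E, exclude = pos)
  a <- cfg$effect_r / sqrt(1 - cfg$effect_r^2)
  z_t <- as.numeric(scale(pheno[[cfg$target]]))
  z_fd <- as.numeric(scale(pheno$mean_fd))

  edges <- matrix(rnorm(n * E), n, E)
  for (nm in unique(pheno$site)) {
    rows <- which(pheno$site == nm)
    offs <- rnorm(E, sd = cfg$site_edge_sd)
    edges[rows, ] <- edges[rows, ] + matrix(offs, length(rows), E, byrow = TRUE)
  }
  if (length(pos) > 0) {
    edges[, pos] <- edges[, pos] + a * z_t +
      cfg$confound_strength * z_fd
  }
  if (length(neg) > 0) {
    edges[, neg] <- edges[, neg] - a * z_t -
      cfg$confound_strength * z_fd
  }
  rownames(edges) <- pheno$subject_id

  runs <- NULL
  if (cfg$n_runs > 1) {
    rho <- cfg$edge_reliability
    run_sd <- sqrt(2 * (1 - rho) / rho)
    runs <- lapply(seq_len(cfg$n_runs), function(r) {
      m <- edges + matrix(rnorm(n * E, sd = run_sd), n, E)
      rownames(m) <- pheno$subject_id
      m
    })
    names(runs) <- paste0("run", seq_len(cfg$n_runs))
    edges <- Reduce(`+`, runs) / cfg$n_runs
    rownames(edges) <- pheno$subject_id
  }

  if (n >= 200 && (length(pos) + length(neg)) > 0) {
    sc <- pheno[[cfg$target]]
    realized <- c(
      if (length(pos)) drop(stats::cor(sc, edges[, pos, drop = FALSE])),
      if (length(neg)) -drop(stats::cor(sc, edges[, neg, drop = FALSE]))
    )
    if (abs(mean(realized) - cfg$effect_r) > 0.1) {
      warn(sprintf(
        "realized planted-edge correlation %.3f deviates from target %.3f by more than 0.1",
        mean(realized), cfg$effect_r
      ))
    }
  }

  structure(
    list(
      phenotype = pheno, edges = edges, runs = runs,
      truth = list(positive = pos, negative = neg, a = a,
                   effect_r = cfg$effect_r, target = cfg$target),
      config = cfg
    ),
    class = "cpm_cohort"
  )
}

#' Generate a cohort of node timeseries with planted connectivity structure
#'
#' Exercises the full pipeline from raw node signals: each subject's target
#' edge values are drawn from the same model as [generate_cohort()], converted
#' to node-pair correlations (tanh of the target Fisher z), and realized by sampling
#' timeseries from the implied node covariance. Planted edges are assigned to
#' disjoint node pairs so the covariance is positive definite by construction
#' (a Cholesky check still guards against infeasible structures). Running the
#' result through [build_connectome()] and the CPM path recovers the planted
#' masks at reduced power (sampling noise of order `1/sqrt(n_timepoints - 3)`
#' on each Fisher-z edge).
#'
#' @param cfg A [cohort_config()]; `planted_positive`/`planted_negative` must
#'   be counts with `2 * (pos + neg) <= n_nodes`.
#' @param n_timepoints Timepoints per subject (>= 50).
#' @return Object of class `cpm_ts_cohort`: `phenotype`, `timeseries` (list of
#'   timepoints x nodes matrices, one per subject), and `truth` (planted edge
#'   indices, signs, and per-subject target Fisher-z values).
#' @export
generate_timeseries_cohort <- function(cfg, n_timepoints = 200) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (n_timepoints < 50) abort("need n_timepoints >= 50")
  withr::with_seed(cfg$seed, {
    pheno <- generate_phenotypes(cfg)
    n <- nrow(pheno)
    nn <- cfg$n_nodes
    npos <- cfg$planted_positive
    nneg <- cfg$planted_negative
    if (length(npos) != 1 || length(nneg) != 1) {
      abort("timeseries mode takes planted counts, not explicit indices")
    }
    if (2 * (npos + nneg) > nn) {
      abort("infeasible target correlation structure: need 2*(planted pairs) <= n_nodes")
    }
    pair_nodes <- matrix(seq_len(2 * (npos + nneg)), ncol = 2, byrow = TRUE)
    pairs <- edge_index(nn)
    pair_key <- paste(pairs$node_i, pairs$node_j)
    planted_edges <- match(paste(pair_nodes[, 1], pair_nodes[, 2]), pair_key)
    sign <- rep(c(1, -1), c(npos, nneg))

    a <- cfg$effect_r / sqrt(1 - cfg$effect_r^2)
    z_t <- as.numeric(scale(pheno[[cfg$target]]))
    # per-subject target Fisher-z for each planted edge
    v <- matrix(rnorm(n * length(planted_edges)), n, length(planted_edges))
    v <- v + outer(z_t, sign * a)

    ts <- lapply(seq_len(n), function(i) {
      C <- diag(nn)
      r <- tanh(v[i, ])
      for (k in seq_along(planted_edges)) {
        C[pair_nodes[k, 1], pair_nodes[k, 2]] <- r[k]
        C[pair_nodes[k, 2], pair_nodes[k, 1]] <- r[k]
      }
      U <- tryCatch(chol(C), error = function(e) {
        abort("infeasible target correlation structure: implied node covariance is not positive definite")
      })
      X <- matrix(rnorm(n_timepoints * nn), n_timepoints, nn) %*% U
      colnames(X) <- sprintf("n%03d", seq_len(nn))
      X
    })
    names(ts) <- pheno$subject_id

    structure(
      list(
        phenotype = pheno, timeseries = ts,
        truth = list(
          positive = sort(planted_edges[sign > 0]),
          negative = sort(planted_edges[sign < 0]),
          planted = tibble(edge = planted_edges,
                           node_i = pair_nodes[, 1], node_j = pair_nodes[, 2],
                           sign = ifelse(sign > 0, "positive", "negative")),
          target_z = v, a = a, target = cfg$target
        ),
        config = cfg, n_timepoints = n_timepoints
      ),
      class = "cpm_ts_cohort"
    )
  })
}

#' @export
print.cpm_cohort <- function(x, ...) {
  cat(sprintf(
    "<cpm_cohort> %d subjects, %d sites, %d nodes (%d edges)%s\n",
    nrow(x$phenotype), length(unique(x$phenotype$site)),
    x$config$n_nodes, ncol(x$edges),
    if (!is.null(x$runs)) sprintf(", %d runs", length(x$runs)) else ""
  ))
  cat(sprintf("  planted: %d positive, %d negative edges at effect r = %.2f on %s\n",
              length(x$truth$positive), length(x$truth$negative),
              x$truth$effect_r, x$truth$target))
  invisible(x)
}

#' Write a synthetic cohort to disk in the interchange formats
#'
#' Produces `phenotype.csv`, a `manifest.csv` (subject, run, file, mean FD,
#' file type) pointing at per-subject-and-run square connectome CSVs (or
#' timeseries TSVs for a timeseries cohort), and a `truth.json` sidecar with
#' the planted ground truth — the sidecar is never read by the analysis path.
#' [read_cohort()] round-trips the result exactly.
#'
#' @param cohort A `cpm_cohort` or `cpm_ts_cohort`.
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    abort(sprintf("directory '%s' is not empty (use overwrite = TRUE)", dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$phenotype, file.path(dir, "phenotype.csv"))

  is_ts <- inherits(cohort, "cpm_ts_cohort")
  rows <- list()
  if (is_ts) {
    for (id in names(cohort$timeseries)) {
      fn <- sprintf("%s_run1_timeseries.tsv", id)
      readr::write_tsv(as_tibble(cohort$timeseries[[id]]), file.path(dir, fn))
      rows[[length(rows) + 1]] <- tibble(
        subject_id = id, run_id = "run1", file = fn,
        mean_fd = cohort$phenotype$mean_fd[cohort$phenotype$subject_id == id],
        type = "timeseries"
      )
    }
  } else {
    nn <- cohort$config$n_nodes
    node_ids <- sprintf("n%03d", seq_len(nn))
    per_run <- if (is.null(cohort$runs)) list(run1 = cohort$edges) else cohort$runs
    for (rn in names(per_run)) {
      m <- per_run[[rn]]
      for (id in rownames(m)) {
        fn <- sprintf("%s_%s_matrix.csv", id, rn)
        cm <- devectorize_edges(m[id, ], nn)
        df <- as_tibble(cm, .name_repair = ~node_ids)
        df <- bind_cols(tibble(node = node_ids), df)
        readr::write_csv(df, file.path(dir, fn))
        rows[[length(rows) + 1]] <- tibble(
          subject_id = id, run_id = rn, file = fn,
          mean_fd = cohort$phenotype$mean_fd[cohort$phenotype$subject_id == id],
          type = "matrix"
        )
      }
    }
  }
  manifest <- bind_rows(rows) %>% arrange(.data$subject_id, .data$run_id)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  jsonlite::write_json(
    list(truth = cohort$truth,
         config = unclass(cohort$config)),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `cpm_cohort` (matrix cohorts only; timeseries fixtures are read
#'   through [load_edges()] instead).
#' @export
read_cohort <- function(dir) {
  pheno <- readr::read_csv(file.path(dir, "phenotype.csv"),
                           show_col_types = FALSE)
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  if (any(manifest$type != "matrix")) {
    abort("read_cohort() handles matrix cohorts; use load_edges() for timeseries")
  }
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  run_ids <- unique(manifest$run_id)
  runs <- lapply(run_ids, function(rn) {
    sub <- manifest[manifest$run_id == rn, ]
    m <- t(vapply(seq_len(nrow(sub)), function(i) {
      vectorize_edges(read_connectome_csv(file.path(dir, sub$file[i])))
    }, numeric(n_edges(tr$config$n_nodes))))
    rownames(m) <- sub$subject_id
    m[as.character(pheno$subject_id), , drop = FALSE]
  })
  names(runs) <- run_ids
  edges <- Reduce(`+`, runs) / length(runs)
  cfg <- do.call(cohort_config, tr$config[setdiff(names(tr$config), "sites")] |>
                   c(list(sites = tr$config$sites)))
  structure(
    list(
      phenotype = pheno, edges = edges,
      runs = if (length(runs) > 1) runs else NULL,
      truth = tr$truth, config = cfg
    ),
    class = "cpm_cohort"
  )
}
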