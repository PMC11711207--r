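test_that("the generator is seed-deterministic", {
  cfg <- cohort_config(n_nodes = 15, sites = list(
    a = list(n = 30, score_mean = 130, score_sd = 16),
    b = list(n = 20, score_mean = 110, score_sd = 12)
  ), planted_positive = 5, planted_negative = 5, n_runs = 2, seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$edges, c2$edges)
  expect_identical(c1$phenotype, c2$phenotype)
  expect_identical(c1$runs, c2$runs)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(cohort_config(n_nodes = 15, sites = cfg$sites,
                                      planted_positive = 5,
                                      planted_negative = 5, n_runs = 2,
                                      seed = 8))
  expect_false(identical(c1$edges, c3$edges))
})

test_that("site score distributions match the configured means", {
  cfg <- cohort_config(n_nodes = 10, planted_positive = 0,
                       planted_negative = 0, seed = 9)
  co <- generate_cohort(cfg)
  for (nm in names(cfg$sites)) {
    s <- cfg$sites[[nm]]
    sub <- co$phenotype[co$phenotype$site == nm, ]
    expect_equal(nrow(sub), s$n)
    expect_lt(abs(mean(sub$total) - s$score_mean),
              2 * s$score_sd / sqrt(s$n))
  }
  expect_equal(co$phenotype$total,
               with(co$phenotype, AA + NJ + NR + D + O))
  expect_true(all(co$phenotype$mean_fd > 0))
})

test_that("planted edges realize the target correlation on average", {
  devs <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(
      n_nodes = 40,
      sites = list(a = list(n = 200, score_mean = 134.8, score_sd = 17.8)),
      planted_positive = 10, planted_negative = 10, effect_r = 0.3,
      seed = 200 + s
    ))
    sc <- co$phenotype$total
    mean(c(cor(sc, co$edges[, co$truth$positive]),
           -cor(sc, co$edges[, co$truth$negative])))
  }, numeric(1))
  expect_equal(mean(devs), 0.3, tolerance = 0.03)
})

test_that("a zero-effect cohort is a pure null for the screen", {
  set.seed(53)
  fracs <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_config(
      n_nodes = 40,
      sites = list(a = list(n = 150, score_mean = 130, score_sd = 16)),
      planted_positive = 0, planted_negative = 0, seed = 300 + s
    ))
    scr <- screen_edges(co$edges, co$phenotype$total, 0.01)
    (sum(scr$positive) + sum(scr$negative)) / ncol(co$edges)
  }, numeric(1))
  expect_gt(mean(fracs), 0.002)
  expect_lt(mean(fracs), 0.025)
})

test_that("motion confounding inflates naive correlations", {
  cfg <- cohort_config(
    n_nodes = 20,
    sites = list(a = list(n = 250, score_mean = 130, score_sd = 16)),
    planted_positive = 8, planted_negative = 8, effect_r = 0.2,
    fd_score_r = 0.5, confound_strength = 0.6, seed = 19
  )
  co <- suppressWarnings(generate_cohort(cfg))
  model <- cpm_fit(co$phenotype, co$edges, "total")
  ev <- cpm_apply(model, co$phenotype, co$edges, covariates = "mean_fd")
  s <- ev$summary[ev$summary$variant == "combined", ]
  expect_gt(s$r, s$partial_r) # partialling FD removes the confound share
})

test_that("multi-run cohorts have the configured split-half edge reliability", {
  cfg <- cohort_config(
    n_nodes = 25,
    sites = list(a = list(n = 300, score_mean = 130, score_sd = 16)),
    planted_positive = 0, planted_negative = 0, n_runs = 4,
    edge_reliability = 0.4, site_edge_sd = 0, seed = 20
  )
  co <- generate_cohort(cfg)
  a <- (co$runs$run1 + co$runs$run2) / 2
  b <- (co$runs$run3 + co$runs$run4) / 2
  rel <- vapply(seq_len(ncol(a)), function(e) cor(a[, e], b[, e]),
                numeric(1))
  expect_equal(mean(rel), 0.4, tolerance = 0.03)
  # the averaged matrix equals the mean of the runs
  expect_equal(co$edges,
               (co$runs$run1 + co$runs$run2 + co$runs$run3 + co$runs$run4) / 4)
})

test_that("timeseries cohorts realize the planted connectivity targets", {
  cfg <- cohort_config(
    n_nodes = 20,
    sites = list(a = list(n = 40, score_mean = 130, score_sd = 16)),
    planted_positive = 3, planted_negative = 3, effect_r = 0.3, seed = 21
  )
  tsco <- generate_timeseries_cohort(cfg, n_timepoints = 500)
  expect_length(tsco$timeseries, 40)
  z_real <- t(vapply(seq_len(40), function(i) {
    cm <- build_connectome(tsco$timeseries[[i]])
    vectorize_edges(cm)[tsco$truth$planted$edge]
  }, numeric(6)))
  # realized Fisher z tracks each subject's target (sampling sd ~ 1/sqrt(T-3))
  err <- z_real - tsco$truth$target_z
  expect_lt(abs(mean(err)), 0.05)
  expect_gt(cor(as.vector(z_real), as.vector(tsco$truth$target_z)), 0.95)
  # unplanted edges stay near zero
  null_edges <- setdiff(seq_len(n_edges(20)), tsco$truth$planted$edge)[1:30]
  z_null <- vapply(1:10, function(i) {
    mean(abs(vectorize_edges(build_connectome(tsco$timeseries[[i]]))[null_edges]))
  }, numeric(1))
  expect_lt(mean(z_null), 0.1)
})

test_that("the full pipeline recovers most planted edges from timeseries", {
  hits <- vapply(1:10, function(s) {
    cfg <- cohort_config(
      n_nodes = 30,
      sites = list(a = list(n = 150, score_mean = 130, score_sd = 16)),
      planted_positive = 5, planted_negative = 5, effect_r = 0.3,
      seed = 400 + s
    )
    tsco <- generate_timeseries_cohort(cfg, n_timepoints = 200)
    edges <- t(vapply(tsco$timeseries, function(ts) {
      vectorize_edges(build_connectome(ts))
    }, numeric(n_edges(30))))
    rownames(edges) <- tsco$phenotype$subject_id
    scr <- screen_edges(edges, tsco$phenotype$total, 0.01)
    (sum(which(scr$positive) %in% tsco$truth$positive) +
        sum(which(scr$negative) %in% tsco$truth$negative)) / 10
  }, numeric(1))
  expect_gte(mean(hits), 0.6)
})

test_that("infeasible timeseries configurations are rejected", {
  cfg <- cohort_config(n_nodes = 10,
                       sites = list(a = list(n = 10, score_mean = 100,
                                             score_sd = 10)),
                       planted_positive = 4, planted_negative = 4, seed = 1)
  expect_error(generate_timeseries_cohort(cfg, n_timepoints = 100),
               "infeasible")
  expect_error(generate_timeseries_cohort(
    cohort_config(n_nodes = 10, sites = cfg$sites, seed = 1),
    n_timepoints = 10
  ), "n_timepoints")
})
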