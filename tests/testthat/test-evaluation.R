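fit_small_model <- function(seed = 9, n = 80, n_nodes = 15, effect_r = 0.5) {
  co <- small_cohort(n = n, n_nodes = n_nodes, pos = 4, neg = 4,
                     effect_r = effect_r, seed = seed)
  list(cohort = co, model = cpm_fit(co$phenotype, co$edges, "total"))
}

test_that("applying a model to its training data reproduces the in-sample fit", {
  fm <- fit_small_model()
  ev <- cpm_apply(fm$model, fm$cohort$phenotype, fm$cohort$edges)
  st <- suppressWarnings(network_strength(fm$cohort$edges, fm$model$positive,
                                          fm$model$negative))
  fit <- lm(fm$cohort$phenotype$total ~ st$combined)
  expect_equal(ev$predictions$predicted, unname(fitted(fit)),
               tolerance = 1e-10)
  r_in <- cor(fitted(fit), fm$cohort$phenotype$total)
  expect_equal(ev$summary$r[ev$summary$variant == "combined"], r_in,
               tolerance = 1e-10)
})

test_that("a zero-noise test set from the model's own line gives r = 1, MSE = 0", {
  fm <- fit_small_model(seed = 10)
  m <- fm$model
  set.seed(101)
  edges_te <- matrix(rnorm(40 * m$E), 40, m$E)
  pred <- predict(m, edges_te)
  pheno_te <- tibble::tibble(subject_id = as.character(1:40), total = pred)
  rownames(edges_te) <- pheno_te$subject_id
  ev <- cpm_apply(m, pheno_te, edges_te)
  s <- ev$summary[ev$summary$variant == "combined", ]
  expect_equal(s$r, 1, tolerance = 1e-10)
  expect_equal(s$mse, 0, tolerance = 1e-14)
})

test_that("MSE matches the brute-force loop and null application gives r near 0", {
  fm <- fit_small_model(seed = 11)
  m <- fm$model
  set.seed(102)
  rs <- vapply(1:30, function(i) {
    edges_te <- matrix(rnorm(80 * m$E), 80, m$E)
    pheno_te <- tibble::tibble(subject_id = as.character(1:80),
                               total = rnorm(80, 130, 16))
    rownames(edges_te) <- pheno_te$subject_id
    ev <- cpm_apply(m, pheno_te, edges_te)
    s <- ev$summary[ev$summary$variant == "combined", ]
    expect_equal(s$mse, oracle_mse(ev$predictions$predicted,
                                   ev$predictions$observed),
                 tolerance = 1e-10)
    s$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.06)
})

test_that("external validation on a second site recovers the shared signal", {
  cfg <- cohort_config(
    n_nodes = 20,
    sites = list(train = list(n = 120, score_mean = 134.8, score_sd = 17.8),
                 test = list(n = 120, score_mean = 126.8, score_sd = 17.4)),
    planted_positive = 6, planted_negative = 6, effect_r = 0.35, seed = 12
  )
  co <- generate_cohort(cfg)
  tr <- co$phenotype$site == "train"
  model <- cpm_fit(co$phenotype[tr, ], co$edges[tr, ], "total")
  ev <- cpm_apply(model, co$phenotype[!tr, ], co$edges[!tr, ],
                  covariates = "mean_fd")
  s <- ev$summary[ev$summary$variant == "combined", ]
  expect_gt(s$r, 0.4)
  # FD is unconfounded here, so the partial r barely moves
  expect_equal(s$partial_r, s$r, tolerance = 0.1)
  expect_error(cpm_apply(model, co$phenotype[!tr, ],
                         co$edges[!tr, 1:100]), "edge-space mismatch")
})

test_that("cross-prediction mirrors apply and vanishes for independent targets", {
  fm <- fit_small_model(seed = 13)
  co <- fm$cohort
  same <- cpm_apply(fm$model, co$phenotype, co$edges)
  crossed <- cross_predict(fm$model, co$phenotype, co$edges, target = "total")
  expect_equal(same$summary$r, crossed$summary$r)
  set.seed(103)
  rs <- vapply(1:20, function(i) {
    ph <- co$phenotype
    ph$unrelated <- rnorm(nrow(ph))
    cross_predict(fm$model, ph, co$edges,
                  target = "unrelated")$summary$r[1]
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.08)
})

test_that("strength correlation is 1 for self and -1 for sign-swapped masks", {
  fm <- fit_small_model(seed = 14)
  m <- fm$model
  swapped <- m
  swapped$positive <- m$negative
  swapped$negative <- m$positive
  edges <- fm$cohort$edges
  expect_equal(strength_correlation(m, m, edges)$r, 1)
  expect_equal(strength_correlation(m, swapped, edges)$r, -1)
  # disjoint random masks on independent edges decorrelate
  set.seed(104)
  E <- m$E
  edges_big <- matrix(rnorm(400 * E), 400, E)
  a <- m
  b <- m
  idx <- sample(E, 40)
  a$positive <- seq_len(E) %in% idx[1:10]
  a$negative <- seq_len(E) %in% idx[11:20]
  b$positive <- seq_len(E) %in% idx[21:30]
  b$negative <- seq_len(E) %in% idx[31:40]
  expect_lt(abs(strength_correlation(a, b, edges_big)$r), 0.1)
})

test_that("mask overlap reproduces the printed percent arithmetic", {
  E <- n_edges(268)
  mk <- function(idx) seq_len(E) %in% idx
  ov1 <- mask_overlap(mk(1:328), mk(c(1:20, 400:1043)), n_perm = 10, seed = 1)
  expect_equal(ov1$shared, 20)
  expect_equal(round(ov1$percent, 2), 2.02)
  ov2 <- mask_overlap(mk(1:758), mk(c(1:58, 1000:1569)), n_perm = 10, seed = 1)
  expect_equal(ov2$shared, 58)
  expect_equal(round(ov2$percent, 2), 4.18)
  expect_equal(overlap_percent(20, 328, 664), 100 * 20 / 992)
})

test_that("identical masks overlap maximally with a tiny permutation p", {
  set.seed(105)
  mask <- seq_len(500) %in% sample(500, 60)
  ov <- mask_overlap(mask, mask, n_perm = 500, seed = 2)
  expect_equal(ov$shared, 60)
  expect_lt(ov$p, 0.01)
})

test_that("the overlap null matches the hypergeometric expectation", {
  set.seed(106)
  E <- 1000
  a <- seq_len(E) %in% sample(E, 40)
  b <- seq_len(E) %in% sample(E, 60)
  ov <- mask_overlap(a, b, n_perm = 3000, seed = 3)
  expect_equal(mean(ov$null), 40 * 60 / E, tolerance = 0.1 * 40 * 60 / E)
  # determinism
  ov2 <- mask_overlap(a, b, n_perm = 3000, seed = 3)
  expect_identical(ov$null, ov2$null)
})

test_that("split-half stability: identical splits give r = 1", {
  fm <- fit_small_model(seed = 15)
  st <- split_half_stability(fm$model, fm$cohort$edges, fm$cohort$edges,
                             n_random_edges = 50, seed = 4)
  expect_equal(st$r_split, 1)
  expect_equal(st$p, mean(st$null >= 1))
  wrong <- fm$cohort$edges[1:40, ]
  expect_error(split_half_stability(fm$model, fm$cohort$edges, wrong),
               "subject mismatch")
})

test_that("aggregate strength beats single edges only when signal is shared", {
  # planted cohort: mask edges share the trait-driven component
  cfg <- cohort_config(
    n_nodes = 30,
    sites = list(a = list(n = 120, score_mean = 107.2, score_sd = 11.3)),
    planted_positive = 10, planted_negative = 10, effect_r = 0.3,
    n_runs = 4, edge_reliability = 0.4, seed = 16
  )
  co <- generate_cohort(cfg)
  split_a <- (co$runs$run1 + co$runs$run2) / 2
  split_b <- (co$runs$run3 + co$runs$run4) / 2
  model <- cpm_fit(co$phenotype, co$edges, "total")
  st <- split_half_stability(model, split_a, split_b,
                             n_random_edges = 400, seed = 5)
  expect_gt(st$r_split, median(st$null))
  expect_lt(st$p, 0.2)
})

test_that("combined shuffle split generalizes shared-signal sites", {
  cfg <- cohort_config(
    n_nodes = 30,
    sites = list(s1 = list(n = 100, score_mean = 130, score_sd = 16),
                 s2 = list(n = 100, score_mean = 128, score_sd = 16)),
    planted_positive = 10, planted_negative = 10, effect_r = 0.3, seed = 17
  )
  co <- generate_cohort(cfg)
  ss <- combined_shuffle_split(co$phenotype, co$edges, "total", seed = 6,
                               site_mean_control = TRUE)
  s <- ss$evaluation$summary[ss$evaluation$summary$variant == "combined", ]
  expect_gt(s$r, 0.3)
  expect_equal(ss$n_train, 160)
  expect_equal(ss$n_test, 40)
  # without site structure in the scores, site-mean control barely moves r
  expect_equal(s$partial_r, s$r, tolerance = 0.1)
  # determinism of the split
  ss2 <- combined_shuffle_split(co$phenotype, co$edges, "total", seed = 6,
                                site_mean_control = TRUE)
  expect_identical(ss$test_ids, ss2$test_ids)
  expect_error(combined_shuffle_split(co$phenotype[1:20, ],
                                      co$edges[1:20, ], "total",
                                      seed = 1), "at least 10")
})
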