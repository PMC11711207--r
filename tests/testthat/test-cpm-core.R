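test_that("edge screening matches the per-edge cor.test oracle", {
  set.seed(13)
  n <- 40
  E <- 150
  edges <- matrix(rnorm(n * E), n, E)
  scores <- rnorm(n) + edges[, 1] # one real association
  scr <- screen_edges(edges, scores, threshold = 0.01)
  oracle <- oracle_screen(edges, scores, 0.01)
  expect_equal(scr$stats$r, oracle$r, tolerance = 1e-10)
  expect_equal(scr$stats$p, oracle$p, tolerance = 1e-10)
  expect_identical(scr$positive, oracle$positive)
  expect_identical(scr$negative, oracle$negative)
  expect_false(any(scr$positive & scr$negative))
})

test_that("an edge equal to the score vector lands in the positive mask", {
  set.seed(14)
  n <- 30
  edges <- cbind(rnorm(n), rnorm(n))
  scores <- edges[, 1]
  scr <- screen_edges(edges, scores, 0.01)
  expect_true(scr$positive[1])
  expect_equal(scr$stats$p[1], 0)
})

test_that("the minimal selectable |r| at n = 188 is about 0.187", {
  # invert the t threshold: r_min = t / sqrt(df + t^2), t = qt(0.995, 186)
  t_crit <- qt(0.995, 186)
  r_min <- t_crit / sqrt(186 + t_crit^2)
  expect_equal(r_min, 0.187, tolerance = 0.005)
  expect_lt(mindcpm:::edge_p_values(r_min * 1.01, 188), 0.01)
  expect_gt(mindcpm:::edge_p_values(r_min * 0.99, 188), 0.01)
})

test_that("null edges are selected at the nominal type-I rate", {
  set.seed(15)
  fracs <- vapply(1:5, function(i) {
    edges <- matrix(rnorm(200 * 1000), 200, 1000)
    scr <- screen_edges(edges, rnorm(200), 0.01)
    (sum(scr$positive) + sum(scr$negative)) / 1000
  }, numeric(1))
  expect_gt(mean(fracs), 0.004)
  expect_lt(mean(fracs), 0.02)
})

test_that("zero-variance edges are ineligible with a warning", {
  set.seed(16)
  edges <- cbind(matrix(rnorm(40 * 5), 40, 5), 7)
  expect_warning(scr <- screen_edges(edges, rnorm(40), 0.5),
                 "zero-variance")
  expect_equal(scr$n_zero_variance, 1)
  expect_false(scr$positive[6] || scr$negative[6])
  expect_error(screen_edges(edges, rep(1, 40)), "zero variance")
})

test_that("network strength matches the brute-force summation oracle", {
  set.seed(17)
  n <- 25
  E <- 120
  edges <- matrix(rnorm(n * E), n, E)
  pos <- seq_len(E) %in% sample(E, 20)
  neg <- !pos & seq_len(E) %in% sample(E, 35)
  st <- network_strength(edges, pos, neg)
  orc <- oracle_strength(edges, pos, neg)
  expect_equal(st$pos_sum, orc[, "pos"], tolerance = 1e-10)
  expect_equal(st$neg_sum, orc[, "neg"], tolerance = 1e-10)
  expect_equal(st$combined, orc[, "comb"], tolerance = 1e-10)

  hand <- network_strength(
    rbind(c(0.2, 0.3, 0.1)), c(TRUE, TRUE, FALSE), c(FALSE, FALSE, TRUE)
  )
  expect_equal(hand$pos_sum, 0.5)
  expect_equal(hand$neg_sum, 0.1)
  expect_equal(hand$combined, 0.4)

  w <- capture_warnings(
    empty <- network_strength(edges, rep(FALSE, E), rep(FALSE, E))
  )
  expect_match(w, "empty", all = TRUE)
  expect_true(all(empty$combined == 0))
  expect_error(network_strength(edges, pos, pos), "disjoint")
})

test_that("the strength model is plain OLS", {
  f <- fit_strength_model(c(1, 2), c(2, 4))
  expect_equal(unname(f["beta"]), 2)
  expect_equal(unname(f["intercept"]), 0)
  f2 <- fit_strength_model(c(1, 2, 3), c(5, 5, 5))
  expect_equal(unname(f2["beta"]), 0)
  expect_equal(unname(f2["intercept"]), 5)
  expect_error(fit_strength_model(rep(1, 5), rnorm(5)), "degenerate")
  # recovers a planted line within 3 SE
  set.seed(18)
  s <- rnorm(500)
  y <- 1.7 * s + 4 + rnorm(500, sd = 2)
  f3 <- fit_strength_model(s, y)
  se_beta <- 2 / (sd(s) * sqrt(500))
  expect_lt(abs(f3[["beta"]] - 1.7), 3 * se_beta)
  ols <- coef(lm(y ~ s))
  expect_equal(unname(f3), unname(c(ols[2], ols[1])), tolerance = 1e-10)
})

test_that("partial correlation equals the closed-form single-covariate formula", {
  set.seed(19)
  n <- 80
  for (i in 1:10) {
    x <- rnorm(n)
    z <- rnorm(n)
    y <- 0.4 * x + 0.3 * z + rnorm(n)
    pc <- partial_correlation(x, y, z)
    rxy <- cor(x, y)
    rxz <- cor(x, z)
    ryz <- cor(y, z)
    closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(pc$estimate, closed, tolerance = 1e-10)
  }
})

test_that("exact-correlation construction gives partial r = 1/3", {
  # orthonormal centered basis with sample correlations r_xy=r_xz=r_yz=0.5
  set.seed(20)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(30 * 3), 30, 3))))[, 2:4]
  z <- q[, 1]
  x <- 0.5 * q[, 1] + sqrt(0.75) * q[, 2]
  y <- 0.5 * q[, 1] + 0.25 / sqrt(0.75) * q[, 2] +
    sqrt(0.75 - 0.0625 / 0.75) * q[, 3]
  expect_equal(cor(x, y), 0.5, tolerance = 1e-10)
  expect_equal(cor(x, z), 0.5, tolerance = 1e-10)
  expect_equal(cor(y, z), 0.5, tolerance = 1e-10)
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$estimate, 1 / 3, tolerance = 1e-10)
})

test_that("partial correlation degenerate and orthogonal cases", {
  set.seed(22)
  n <- 50
  x <- rnorm(n)
  y <- rnorm(n)
  # covariate orthogonal to both by construction
  z <- residuals(lm(rnorm(n) ~ x + y))
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$estimate, cor(x, y), tolerance = 1e-10)
  expect_error(partial_correlation(x, y, x), "zero residual")
  expect_error(partial_correlation(x, y, cbind(z, 2 * z)), "collinear")
})

test_that("model selection uses a strict alpha threshold", {
  expect_setequal(select_models(c(AA = 0.017, NJ = 0.025, O = 0.31)),
                  c("AA", "NJ"))
  expect_length(select_models(c(A = 0.05)), 0)
  expect_length(select_models(c(A = 0.6, B = 0.9)), 0)
  expect_error(select_models(c(0.01)), "named")
})

test_that("the final single-fold model stores masks and coefficients", {
  set.seed(23)
  n <- 60
  E <- 45
  edges <- matrix(rnorm(n * E), n, E)
  scores <- 3 * edges[, 7] + 10 # exact linear in edge 7, slope via strength
  pheno <- tibble::tibble(subject_id = as.character(1:n), total = scores)
  rownames(edges) <- pheno$subject_id
  model <- cpm_fit(pheno, edges, "total", threshold = 1e-6)
  expect_true(model$positive[7])
  expect_equal(sum(model$positive), 1)
  cf <- model$coefficients[model$coefficients$variant == "combined", ]
  expect_equal(cf$beta, 3, tolerance = 1e-8)
  expect_equal(cf$intercept, 10, tolerance = 1e-8)
  expect_error(cpm_fit(pheno, matrix(rnorm(n * 10), n), "total",
                       threshold = 1e-12), "no edges survive")
})

test_that("edge presence is the mean fold-membership of final-mask edges", {
  set.seed(24)
  co <- small_cohort(n = 60, n_nodes = 15, pos = 4, neg = 4,
                     effect_r = 0.6, seed = 4)
  cv <- cpm_cv(co$phenotype, co$edges, "total")
  model <- cpm_fit(co$phenotype, co$edges, "total")
  pres <- edge_presence(cv, model)
  expect_equal(pres$sign, c("positive", "negative"))
  expect_true(all(pres$presence >= 0 & pres$presence <= 100, na.rm = TRUE))
  # strong planted signal: final-mask edges appear in nearly every fold
  expect_gt(pres$presence[1], 80)
  expect_gt(pres$presence[2], 80)
  # hand check against the stored fold masks
  fold_frac <- colMeans(cv$masks$positive[, model$positive, drop = FALSE])
  expect_equal(pres$presence[1], 100 * mean(fold_frac))
})
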