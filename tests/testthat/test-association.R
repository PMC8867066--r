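test_that("collinearity filter retains 18 of 21 on the three-pair table", {
  X <- collinear_feature_table()
  res <- collinearity_filter(X, threshold = 0.95)
  expect_length(res$retained, 18L)
  expect_equal(nrow(res$dropped), 3L)
  # no surviving pair at or above the threshold
  R <- abs(cor(X[, res$retained])); diag(R) <- 0
  expect_lt(max(R), 0.95)
})

test_that("filter edge cases: threshold 1, duplicates, constant columns", {
  set.seed(8)
  X <- matrix(rnorm(300), 50, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  expect_length(collinearity_filter(X, threshold = 1)$retained, 6L)
  Xd <- cbind(X, f7 = X[, 1], f8 = X[, 1])
  res <- collinearity_filter(Xd, threshold = 0.95)
  expect_length(intersect(res$retained, c("f1", "f7", "f8")), 1L)
  Xc <- cbind(X, fc = 0)
  expect_warning(res2 <- collinearity_filter(Xc), "constant")
  expect_true("fc" %in% res2$retained)
  # random policy is reproducible under a seed
  set.seed(1); a <- collinearity_filter(Xd, policy = "random")$retained
  set.seed(1); b <- collinearity_filter(Xd, policy = "random")$retained
  expect_identical(a, b)
})

test_that("MLR recovers exact linear structure and flags rank deficiency", {
  set.seed(9)
  X <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 2 * X[, 1] - 3 * X[, 2]
  fit <- suppressWarnings(fit_mlr(X, y))
  expect_true(all(fit$coefficients$p_value[1:2] < 1e-10))
  expect_equal(fit$coefficients$estimate_raw[1:2], c(2, -3), tolerance = 1e-8)
  Xr <- cbind(X, f7 = X[, 1] + X[, 2])
  expect_error(fit_mlr(Xr, y), "dependent")
})

test_that("orthogonal design: multiple equals simple regression", {
  set.seed(10)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(50 * 4), 50, 4))))[, -1]
  colnames(Q) <- paste0("q", 1:4)
  y <- rnorm(50)
  fit <- fit_mlr(Q, y)
  simple <- vapply(1:4, function(j) {
    coef(stats::lm(y ~ scale(Q[, j])))[2]
  }, numeric(1))
  expect_equal(fit$coefficients$estimate, unname(simple), tolerance = 1e-10)
})

test_that("MLR p-values are calibrated under a permutation null", {
  set.seed(11)
  n <- 108
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rnorm(n)
  hits <- 0L; total <- 0L
  for (b in 1:100) {
    fit <- fit_mlr(X, sample(y))
    hits <- hits + sum(fit$coefficients$p_value < 0.05)
    total <- total + 10L
  }
  expect_lt(abs(hits / total - 0.05), 0.02)
})

test_that("shadow importance separates signal from noise", {
  set.seed(12)
  n <- 80
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- X[, 1] + rnorm(n, 0, 0.3)
  # 30 iterations give the Bonferroni-adjusted binomial test room both to
  # confirm the informative feature (9 straight hits) and to reject noise
  res <- shadow_importance(X, y, ntree = 150L, max_iterations = 30L)
  expect_equal(unname(as.character(res$decision["f1"])), "confirmed")
  expect_gte(sum(res$decision[paste0("f", 2:10)] == "rejected"), 8L)
  # duplicated informative feature: both copies confirmed
  Xd <- cbind(X[, 1:5], f1b = X[, 1])
  colnames(Xd) <- c(paste0("f", 1:5), "f1b")
  res2 <- shadow_importance(Xd, y, ntree = 150L)
  expect_true(all(res2$decision[c("f1", "f1b")] == "confirmed"))
})

test_that("shadow importance controls type I error on pure noise", {
  set.seed(13)
  false_conf <- replicate(25, {
    X <- matrix(rnorm(100 * 8), 100, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    y <- rnorm(100)
    sum(shadow_importance(X, y, ntree = 80L, max_iterations = 10L)$decision ==
          "confirmed")
  })
  expect_gte(mean(false_conf == 0), 0.95)
  expect_warning(shadow_importance(
    matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("a", "b"))),
    rep(1, 40)), "constant response")
})

test_that("partial dependence reflects the fitted surface", {
  set.seed(14)
  n <- 150
  X <- matrix(runif(n * 3, -2, 2), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- sin(X[, 1]) + 0.5 * X[, 2] + rnorm(n, 0, 0.1)
  rf <- rf_fit(X, y, ntree = 300L)
  pd <- partial_dependence(rf, X, "a", grid_size = 20L)
  expect_gte(cor(pd$prediction, sin(pd$value)), 0.95)
  # constant model gives a flat curve
  rf0 <- rf_fit(X, rep(2, n), ntree = 50L)
  pd0 <- partial_dependence(rf0, X, "b")
  expect_equal(pd0$prediction, rep(2, nrow(pd0)), tolerance = 1e-9)
  expect_error(partial_dependence(rf, X, "zz"), "unknown feature")
})

test_that("path interactions rank multiplicative over additive structure", {
  set.seed(15)
  n <- 300
  X <- matrix(runif(n * 4, -1, 1), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y_mult <- X[, 1] * X[, 2] + rnorm(n, 0, 0.1)
  y_add <- X[, 1] + X[, 2] + rnorm(n, 0, 0.1)
  rf_m <- rf_fit(X, y_mult, ntree = 200L, importance = FALSE)
  rf_a <- rf_fit(X, y_add, ntree = 200L, importance = FALSE)
  s_m <- path_interactions(rf_m)
  s_a <- path_interactions(rf_a)
  expect_gt(s_m["x1", "x2"], s_a["x1", "x2"])
  expect_true(all(s_m >= 0 & s_m <= 1))
  # depth-1 trees cannot co-occur
  rf_stump <- rf_fit(X, y_add, ntree = 50L, max_depth = 1L,
                     importance = FALSE)
  expect_true(all(path_interactions(rf_stump) == 0))
})

test_that("cross-validation shares folds, is seeded, and ranks models", {
  set.seed(16)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y_lin <- X %*% c(1, -1, 0.5, 0, 0) + rnorm(n, 0, 0.2)
  set.seed(99)
  cv1 <- cross_validate(X, y_lin, ntree = 150L)
  set.seed(99)
  cv2 <- cross_validate(X, y_lin, ntree = 150L)
  expect_identical(cv1$per_repeat, cv2$per_repeat)
  expect_gte(cv1$summary$mean_r[cv1$summary$model == "MLR"], 0.95)
  # strong interaction structure favours the forest
  y_int <- 2 * sign(X[, 1]) * sign(X[, 2]) + rnorm(n, 0, 0.3)
  set.seed(100)
  cv3 <- cross_validate(X, y_int, ntree = 150L)
  expect_gt(cv3$summary$mean_r[cv3$summary$model == "RF"],
            cv3$summary$mean_r[cv3$summary$model == "MLR"])
})

test_that("partial correlations: identities and regression oracle", {
  set.seed(17)
  # two variables: partial equals marginal
  M2 <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  pc <- partial_correlations(M2)
  expect_equal(pc$partial["a", "b"], pc$apparent["a", "b"],
               tolerance = 1e-12)
  # Gaussian chain: X -> Z -> Y gives partial(X, Y | Z) ~ 0
  n <- 10000
  x <- rnorm(n); z <- x + rnorm(n); y <- z + rnorm(n)
  pc2 <- partial_correlations(cbind(X = x, Z = z, Y = y))
  expect_lt(abs(pc2$partial["X", "Y"]), 0.05)
  expect_gt(abs(pc2$apparent["X", "Y"]), 0.4)
  # precision-matrix route equals double-regression residual correlation
  for (i in 1:20) {
    M <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("v", 1:6)))
    pcm <- partial_correlations(M)
    r1 <- resid(stats::lm(M[, 1] ~ M[, 3:6]))
    r2 <- resid(stats::lm(M[, 2] ~ M[, 3:6]))
    expect_equal(pcm$partial["v1", "v2"], cor(r1, r2), tolerance = 1e-10)
  }
  expect_error(partial_correlations(M2[1:3, ]), "n >")
})

test_that("trait-model world: direct effects survive partialling, shared-latent color shrinks", {
  set.seed(18)
  n <- 120
  degc <- runif(n, 0, 0.06)
  seed_a <- runif(n, 0, 0.05)
  latent <- rnorm(n)                      # shared maturity latent
  flesh_a <- 20 + 2 * latent + rnorm(n, 0, 0.3)
  peeling <- 3 - 35 * degc + 0.8 * latent + rnorm(n, 0, 0.3)
  fruh <- 2 + 30 * seed_a - 20 * degc + 0.6 * latent + rnorm(n, 0, 0.3)
  M <- cbind("DegCenter area" = degc, "Seed area" = seed_a,
             "Flesh Lab (a)" = flesh_a, latent = latent,
             Peeling = peeling, FruH = fruh)
  pc <- partial_correlations(M)
  expect_lt(pc$partial_p["DegCenter area", "Peeling"], 0.05)
  expect_lt(pc$partial_p["Seed area", "FruH"], 0.05)
  # color correlates only through the latent: partial shrinks vs apparent
  expect_lt(abs(pc$partial["Flesh Lab (a)", "Peeling"]),
            abs(pc$apparent["Flesh Lab (a)", "Peeling"]))
})
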