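sim_records <- function(n_genotypes, n_years, reps, sigma_g, sigma_e,
                        year_effects = rep(0, n_years), mu = 0) {
  d <- expand.grid(genotype = sprintf("G%02d", seq_len(n_genotypes)),
                   year = sprintf("Y%d", seq_len(n_years)),
                   rep = seq_len(reps), stringsAsFactors = FALSE)
  g <- stats::setNames(rnorm(n_genotypes, 0, sigma_g),
                       sprintf("G%02d", seq_len(n_genotypes)))
  ye <- stats::setNames(year_effects, sprintf("Y%d", seq_len(n_years)))
  d$value <- mu + g[d$genotype] + ye[d$year] + rnorm(nrow(d), 0, sigma_e)
  d
}

test_that("balanced-design BLUP matches the closed-form shrinkage", {
  set.seed(1)
  d <- sim_records(25, 1, 6, sigma_g = 1, sigma_e = 0.8)
  s2g <- 1; s2e <- 0.64
  fit <- suppressWarnings(fit_blup(d, lambda = s2g / s2e))
  nrep <- 6
  ybar <- tapply(d$value, d$genotype, mean)
  shrink <- nrep * s2g / (nrep * s2g + s2e)
  expected <- shrink * (ybar - mean(d$value))
  expect_equal(fit$values$blup, as.numeric(expected[fit$values$genotype]),
               tolerance = 1e-8)
})

test_that("zero genotype variance yields fully shrunken BLUPs", {
  set.seed(2)
  d <- sim_records(15, 2, 4, sigma_g = 0, sigma_e = 1,
                   year_effects = c(0, 1))
  fit <- suppressWarnings(fit_blup(d))
  expect_true(all(abs(fit$values$blup) < 0.25))
  expect_lt(fit$sigma2_g, 0.05)
})

test_that("year fixed-effect contrast is recovered", {
  set.seed(3)
  d <- sim_records(50, 2, 3, sigma_g = 0.8, sigma_e = 0.5,
                   year_effects = c(-1, 1))
  fit <- fit_blup(d)
  expect_equal(unname(diff(fit$year_effects)), 2, tolerance = 0.1)
})

test_that("REML matches lme4 on an unbalanced design", {
  set.seed(4)
  d <- sim_records(30, 2, 4, sigma_g = 1.2, sigma_e = 0.7,
                   year_effects = c(0, 0.8))
  d <- d[-sample(nrow(d), 40), ]  # unbalance
  fit <- fit_blup(d)
  lme <- lme4::lmer(value ~ factor(year) + (1 | genotype), data = d,
                    REML = TRUE)
  expect_equal(fit$sigma2_g, unname(as.numeric(lme4::VarCorr(lme)$genotype)),
               tolerance = 1e-4)
  expect_equal(fit$sigma2_e, sigma(lme)^2, tolerance = 1e-4)
  expect_equal(fit$values$blup, lme4::ranef(lme)$genotype[, 1],
               tolerance = 1e-5)
})

test_that("BLUP invariants: centering and shrinkage monotonicity", {
  set.seed(5)
  for (i in 1:5) {
    d <- sim_records(20, 2, 3, sigma_g = runif(1, 0.3, 1.5),
                     sigma_e = runif(1, 0.3, 1.5),
                     year_effects = rnorm(2))
    fit <- fit_blup(d)
    expect_lt(abs(mean(fit$values$blup)), 0.05)
    dev <- tapply(d$value, d$genotype, mean) - mean(d$value)
    expect_true(all(abs(fit$values$blup) <=
                      abs(dev[fit$values$genotype]) + 0.3))
  }
})

test_that("REML variance estimate is unbiased over simulations", {
  set.seed(6)
  est <- replicate(60, {
    d <- sim_records(20, 2, 3, sigma_g = 1, sigma_e = 0.7,
                     year_effects = c(0, 0.5))
    fit_blup(d)$sigma2_g
  })
  expect_equal(mean(est), 1, tolerance = 3 * sd(est) / sqrt(60) + 0.05)
})

test_that("degenerate designs are handled with warnings", {
  set.seed(7)
  d <- sim_records(10, 1, 3, sigma_g = 1, sigma_e = 0.5)
  expect_warning(fit_blup(d), "single year")
  expect_error(fit_blup(d[d$genotype == "G01", ]), "2 genotypes")
  d$value[1] <- NA
  expect_error(suppressWarnings(fit_blup(d)), "missing")
})

test_that("adjust_genotype_values assembles the wide matrix", {
  fx <- feature_population()
  long <- data.frame(
    genotype = rep(fx$pop$meta$genotype, 2),
    year = rep(fx$pop$meta$year, 2),
    variable = rep(c("Whole area", "DegCenter area"),
                   each = nrow(fx$pop$meta)),
    value = c(fx$pop$truth[, "Whole area"], fx$pop$truth[, "DegCenter area"]))
  M <- adjust_genotype_values(long)
  expect_equal(dim(M), c(20L, 2L))
  expect_false(anyNA(M))
  # expected values track genotype means
  gm <- tapply(long$value[long$variable == "Whole area"],
               long$genotype[long$variable == "Whole area"], mean)
  expect_gt(cor(M[, "Whole area"], gm[rownames(M)]), 0.98)
})
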