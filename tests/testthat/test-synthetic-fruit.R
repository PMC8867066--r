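test_that("fruit_spec validation names the violated invariant", {
  expect_error(fruit_spec(flavedo_thickness = 0.5, albedo_thickness = 0.4,
                          center_radius = 0.2), "rings overlap")
  expect_error(fruit_spec(locule_count = 0), "locule_count")
  expect_error(fruit_spec(degcenter_frac = 0.2, center_radius = 0.2),
               "Center disc capacity")
  expect_error(fruit_spec(degalbedo_frac = 0.3), "Albedo annulus capacity")
  expect_error(fruit_spec(fruit_radius = -0.1), "fractions")
  expect_silent(validate_fruit_spec(fruit_spec()))
})

test_that("absent regions give all-zero masks", {
  fr <- render_fruit(fruit_spec(degcenter_frac = 0, degalbedo_frac = 0,
                                seed_count = 0), seed = 5)
  expect_false(any(fr$masks$DegCenter))
  expect_false(any(fr$masks$DegAlbedo))
  expect_false(any(fr$masks$Seed))
})

test_that("locule construction yields the configured sector geometry", {
  fr <- render_fruit(fruit_spec(locule_count = 10, septum_angle = 4,
                                seed_count = 0), seed = 7)
  cen <- mask_centroid(fr$masks$Whole)
  loc <- find_locules(fr$masks$Flesh, cen)
  expect_equal(length(loc$angles), 10L)
  expect_equal(loc$angles, rep(32, 10), tolerance = 0.08)
})

test_that("mask area fractions match the spec targets within tolerance", {
  spec <- fruit_spec()
  fr <- render_fruit(spec, seed = 11)
  wa <- sum(fr$masks$Whole)
  f_flav <- 1 - (1 - spec$flavedo_thickness)^2
  expect_lt(abs(sum(fr$masks$Flavedo) / wa - f_flav), 0.02)
  expect_lt(abs(sum(fr$masks$DegCenter) / wa - spec$degcenter_frac), 0.02)
  expect_lt(abs(sum(fr$masks$DegAlbedo) / wa - spec$degalbedo_frac), 0.02)
})

test_that("region masks are disjoint, contained and partition Whole", {
  set.seed(42)
  for (i in 1:5) {
    sp <- fruit_spec(locule_count = sample(6:12, 1),
                     seed_count = sample(0:10, 1),
                     degcenter_frac = runif(1, 0, 0.02),
                     degalbedo_frac = runif(1, 0, 0.02))
    fr <- render_fruit(sp)
    expect_true(check_region_masks(fr$masks))
    subs <- Reduce(`+`, fr$masks[setdiff(REGIONS, "Whole")])
    septa <- fr$labels == REGION_LABELS[["Septum"]]
    expect_identical(unname(subs + septa > 0), unname(fr$masks$Whole))
    expect_true(all((subs + septa)[fr$masks$Whole] == 1L))
    # degradation containment within its bounding region's disc/annulus
    expect_true(all(fr$labels[fr$masks$DegCenter] ==
                      REGION_LABELS[["DegCenter"]]))
  }
})

test_that("rendering is deterministic under a seed", {
  a <- render_fruit(fruit_spec(), seed = 33)
  b <- render_fruit(fruit_spec(), seed = 33)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
})

test_that("sample_population respects design counts and jitter contract", {
  set.seed(9)
  pop <- sample_population(2, n_years = 1, fruits_per_genotype_year = 1,
                           render = TRUE, image_size = 96L)
  expect_equal(length(pop$images), 2L)
  expect_equal(length(pop$masks), 2L)
  expect_equal(nrow(pop$meta), 2L)

  set.seed(10)
  pop0 <- sample_population(3, n_years = 1, fruits_per_genotype_year = 4,
                            jitter = 0, render = FALSE)
  for (g in unique(pop0$meta$genotype)) {
    tr <- pop0$truth[pop0$meta$genotype == g, ]
    expect_equal(max(apply(tr, 2, function(x) diff(range(x)))), 0)
  }
  expect_error(sample_population(2, spec_prior = list(fruit_radius = c(0.9, 0.2)),
                                 render = FALSE), "invalid prior")
})

test_that("dataset writing is byte-identical under a fixed seed", {
  build <- function(dir) {
    set.seed(77)
    pop <- sample_population(2, n_years = 2, fruits_per_genotype_year = 1,
                             image_size = 64L, render = TRUE)
    ph <- generate_traits(pop$truth, pop$meta, trait_model("Peeling"))
    write_fruit_dataset(pop, ph, dir)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  build(d1); build(d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("trait generation follows the stated generative model", {
  fx <- feature_population()
  pop <- fx$pop
  # deterministic case: no genotype effect, no noise, one year
  m0 <- trait_model("Peeling", genotype_sd = 0, residual_sd = 0,
                    year_effects = c(y1 = 0))
  one_year <- pop$meta$year == "Y1"
  ph <- generate_traits(pop$truth[one_year, ], pop$meta[one_year, ], m0)
  lin <- m0$intercept +
    as.numeric(pop$truth[one_year, names(m0$coefficients)] %*% m0$coefficients)
  expect_equal(ph$continuous, lin, tolerance = 1e-12)
  expect_true(all(ph$ordinal %in% 1:5))
  expect_equal(sort(unique(ph$binary)), c(0L, 1L))
  # all-zero coefficients make scores independent of features
  mz <- trait_model("Peeling", coefficients = c("Whole area" = 0),
                    genotype_sd = 0, residual_sd = 1)
  set.seed(1)
  phz <- generate_traits(pop$truth, pop$meta, mz)
  fit <- fit_mlr(pop$truth[, c("Whole area", "DegCenter area", "Seed area")],
                 phz$continuous)
  expect_true(all(abs(fit$coefficients$estimate) < 0.5))
  expect_error(generate_traits(pop$truth[, 1:3], pop$meta,
                               trait_model("Peeling")), "schema error")
})

test_that("OLS on generated traits recovers the coefficient signs", {
  set.seed(303)
  pop <- sample_population(40, n_years = 1, fruits_per_genotype_year = 5,
                           render = FALSE)
  ph <- generate_traits(pop$truth, pop$meta,
                        trait_model("Peeling", year_effects = c(y1 = 0)))
  X <- pop$truth[, c("DegCenter area", "DegAlbedo area", "Whole area")]
  fit <- stats::lm(ph$continuous ~ X)
  co <- coef(fit)[-1]
  expect_lt(co[1], 0)  # DegCenter eases peeling
  expect_lt(co[2], 0)  # DegAlbedo eases peeling
  expect_gt(co[3], 0)  # larger fruit peel harder
})
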