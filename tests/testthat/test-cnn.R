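tiny_config <- function(epochs = 2L) {
  train_config(input_size = 16L, learning_rate = 1e-3, epochs = epochs,
               batch_size = 8L, channels = c(4L, 4L, 4L))
}

tiny_images <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cl <- i %% 2
    img <- array(runif(16 * 16 * 3, 0, 0.3), dim = c(16, 16, 3))
    if (cl == 1) img[6:11, 6:11, ] <- 0.95  # bright central square
    img
  })
}

test_that("dataset splitting is stratified and training validates it", {
  set.seed(31)
  labels <- rep(c(0, 1), c(30, 10))
  sp <- split_dataset(labels, c(0.7, 0.15, 0.15))
  expect_setequal(unlist(sp), seq_along(labels))
  for (part in sp) expect_true(all(0:1 %in% labels[part]))
  imgs <- tiny_images(12)
  expect_error(train_classifier(imgs, rep(0, 12), tiny_config()),
               "stratification error")
})

test_that("training runs, records history and checkpoints at min val loss", {
  imgs <- tiny_images(24)
  labels <- rep(c(0L, 1L), 12)
  set.seed(32)
  m <- train_classifier(imgs, labels, tiny_config(epochs = 4L))
  expect_equal(nrow(m$history), 4L)
  expect_equal(m$best_epoch,
               which.min(m$history$validation_loss))
  pr <- predict(m, imgs[1:4])
  expect_true(all(pr >= 0 & pr <= 1))
  # seeded training is reproducible end to end
  set.seed(32)
  m2 <- train_classifier(imgs, labels, tiny_config(epochs = 4L))
  expect_equal(m$params, m2$params)
  expect_equal(m$history, m2$history)
})

test_that("classifier evaluation: confusion, accuracy, rank AUC", {
  imgs <- tiny_images(20)
  labels <- rep(c(0L, 1L), 10)
  set.seed(33)
  m <- train_classifier(imgs, labels, tiny_config())
  ev <- evaluate_classifier(m, imgs, labels)
  expect_equal(sum(ev$confusion), 20)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  expect_error(evaluate_classifier(m, imgs[c(1, 3)], c(0, 0)),
               "single class")
  # rank-statistic identities on controlled scores
  auc_of <- function(scores, labels) {
    r <- rank(scores)
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  expect_equal(auc_of(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  set.seed(34)
  null_auc <- auc_of(runif(1000), rep(c(0, 1), 500))
  expect_equal(null_auc, 0.5, tolerance = 0.05)
})

test_that("Grad-CAM is zero for a zero head and proportional for one channel", {
  cfg <- train_config(input_size = 16L, channels = c(2L, 2L, 1L),
                      epochs = 1L)
  set.seed(35)
  params <- citrusect:::.init_params(cfg)
  idxs <- list(citrusect:::.im2col_index(16L, 16L, 3L),
               citrusect:::.im2col_index(8L, 8L, 2L),
               citrusect:::.im2col_index(4L, 4L, 2L))
  model <- structure(list(params = params, config = cfg, idxs = idxs),
                     class = "cnn_model")
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  # zero head -> zero gradient -> all-zero map
  m0 <- model
  m0$params$Wd2[] <- 0
  expect_true(all(gradcam(m0, img) == 0))
  # positive head weights, single final channel -> map is the rectified
  # feature map itself, up to normalization (analytic oracle)
  m1 <- model
  m1$params$Wd1 <- abs(m1$params$Wd1)
  m1$params$Wd2 <- abs(m1$params$Wd2)
  map <- gradcam(m1, img, target_class = 1)
  fw <- citrusect:::.cnn_forward(m1$params,
                                 array(img, dim = c(16, 16, 3, 1)), idxs,
                                 keep = TRUE)
  ref <- pmax(fw$cache$r3[, , 1, 1], 0)
  ref <- resize_image(ref, 16L); ref <- pmax(ref, 0)
  if (max(ref) > 0) ref <- ref / max(ref)
  expect_equal(map, ref, tolerance = 1e-10)
  expect_true(all(map >= 0 & map <= 1))
})

test_that("region relevance means and class comparison behave", {
  fr <- default_fruit()
  masks <- resize_masks(fr$masks, 64L)
  uni <- matrix(0.4, 64, 64)
  rr <- region_relevance(uni, masks)
  expect_true(all(abs(rr[!is.na(rr)] - 0.4) < 1e-12))
  ind <- matrix(0, 64, 64); ind[masks$Seed] <- 1
  rr2 <- region_relevance(ind, masks)
  expect_equal(unname(rr2["Seed"]), 1)
  expect_equal(unname(rr2["Flavedo"]), 0)
  empty <- masks; empty$DegAlbedo[] <- FALSE
  expect_true(is.na(region_relevance(uni, empty)["DegAlbedo"]))
  expect_error(region_relevance(matrix(0, 10, 10), masks), "shapes")

  set.seed(36)
  rm_ <- matrix(runif(40 * 3), 40, 3,
                dimnames = list(NULL, c("DegCenter", "Flesh", "Seed")))
  same <- compare_classes(rbind(rm_, rm_), rep(c(0, 1), each = 40))
  expect_true(all(same$p_value > 0.5))
  expect_error(compare_classes(rm_[1:4, ], c(0, 0, 1, 1)), "at least 3")
})
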