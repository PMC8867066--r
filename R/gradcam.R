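#' Grad-CAM relevance map for one image
#'
#' Computes the gradient of the target-class score with respect to the last
#' convolutional layer's (post-ReLU) feature maps, spatially averages it
#' into per-channel weights, forms the rectified weighted sum of the
#' feature maps, upsamples it bilinearly to the input resolution and
#' normalizes the maximum to 1 (an identically-zero map is left at zero).
#' For the single-logit binary head, the class-1 score is the logit and the
#' class-0 score its negative.
#'
#' @param model a `cnn_model` from [train_classifier()].
#' @param image H x W x 3 array (resized internally to the input size).
#' @param target_class 0 or 1.
#' @return matrix (input_size x input_size) of relevance values in \[0, 1\].
#' @export
gradcam <- function(model, image, target_class = 1L) {
  stopifnot(target_class %in% 0:1)
  size <- model$config$input_size
  if (dim(image)[1] != size) image <- resize_image(image, size)
  A <- array(image, dim = c(size, size, 3, 1))
  fw <- .cnn_forward(model$params, A, model$idxs, keep = TRUE)
  cache <- fw$cache
  # d(score)/d(last conv activations) through the dense head and pool
  sgn <- if (target_class == 1L) 1 else -1
  dz <- matrix(sgn, 1, 1)
  da1 <- t(model$params$Wd2) %*% dz
  dh1 <- da1 * .lrelu_grad(cache$h1)
  dflat <- t(model$params$Wd1) %*% dh1
  dp3 <- array(dflat, dim = dim(cache$p3$out))
  dr3 <- .maxpool_backward(dp3, cache$p3, dim(cache$r3))
  d3 <- dim(cache$r3)
  alpha <- apply(dr3[, , , 1, drop = FALSE], 3, mean)  # per-channel weight
  fmap <- cache$r3[, , , 1, drop = TRUE]
  dim(fmap) <- c(d3[1] * d3[2], d3[3])
  cam <- matrix(pmax(fmap %*% alpha, 0), d3[1], d3[2])
  cam_up <- resize_image(cam, size)
  cam_up <- pmax(cam_up, 0)
  m <- max(cam_up)
  if (m > 0) cam_up <- cam_up / m
  cam_up
}

#' Mean Grad-CAM relevance per fruit region
#'
#' Averages the relevance map inside each of the seven non-Whole region
#' masks. An empty region mask is recorded as NA (missing), not 0.
#'
#' @param map relevance matrix from [gradcam()].
#' @param masks a `region_masks` list at the same resolution as `map`
#'   (resize label images with nearest assignment before calling if
#'   necessary; see [resize_masks()]).
#' @return named numeric vector over the 7 non-Whole regions.
#' @export
region_relevance <- function(map, masks) {
  if (!all(dim(map) == dim(masks$Whole)))
    stop("relevance map and masks have different shapes")
  regions <- setdiff(REGIONS, "Whole")
  vapply(regions, function(r) {
    m <- masks[[r]]
    if (!any(m)) NA_real_ else mean(map[m])
  }, numeric(1))
}

#' Resize region masks to a target resolution
#'
#' Nearest-neighbour resampling of the label image, preserving the
#' disjointness invariants.
#'
#' @param masks a `region_masks` list.
#' @param size target square side.
#' @return a `region_masks` list at the new resolution.
#' @export
resize_masks <- function(masks, size) {
  lab <- labels_from_masks(masks)
  nr <- nrow(lab)
  src <- pmin(pmax(round((seq_len(size) - 0.5) * nr / size + 0.5), 1L), nr)
  masks_from_labels(lab[src, src])
}

#' Between-class comparison of per-region relevance
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per region between the
#' two classification classes, computed over per-image region means of
#' correctly predicted prediction-set images only. Benjamini-Hochberg
#' adjusted p-values are reported alongside the raw ones.
#'
#' @param region_means matrix or data.frame, one row per image, one column
#'   per region (NAs allowed for missing regions).
#' @param classes 0/1 vector of true classes, one per row.
#' @return data.frame: region, median difference (class 1 minus class 0),
#'   statistic, p_value, p_adjusted.
#' @export
compare_classes <- function(region_means, classes) {
  region_means <- as.matrix(region_means)
  stopifnot(nrow(region_means) == length(classes))
  if (min(table(classes)) < 3)
    stop("need at least 3 correctly predicted images per class")
  out <- do.call(rbind, lapply(colnames(region_means), function(rg) {
    x <- region_means[classes == 1, rg]
    y <- region_means[classes == 0, rg]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3 || length(y) < 3) {
      return(data.frame(region = rg, median_diff = NA_real_,
                        statistic = NA_real_, p_value = NA_real_))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    data.frame(region = rg,
               median_diff = stats::median(x) - stats::median(y),
               statistic = unname(wt$statistic), p_value = wt$p.value)
  }))
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Region relevance over correctly predicted prediction images
#'
#' End-to-end relevance quantification: scores the prediction-set images,
#' keeps only the correctly predicted ones (asserted), computes each
#' image's Grad-CAM map for its true class and the per-region means.
#'
#' @param model a `cnn_model`.
#' @param images list of images (full dataset order).
#' @param labels 0/1 vector.
#' @param masks_list list of `region_masks`, parallel to `images`.
#' @return list: `region_means` (rows = correctly predicted prediction
#'   images), `classes`, `kept` (indices into the dataset), `comparison`
#'   (from [compare_classes()], when both classes have >= 3 images).
#' @export
relevance_analysis <- function(model, images, labels, masks_list) {
  pred_idx <- model$split$prediction
  scores <- predict.cnn_model(model, images[pred_idx])
  correct <- (scores >= 0.5) == (labels[pred_idx] == 1)
  kept <- pred_idx[correct]
  stopifnot(all(kept %in% pred_idx))
  size <- model$config$input_size
  rm_ <- t(vapply(kept, function(i) {
    map <- gradcam(model, images[[i]], target_class = labels[i])
    region_relevance(map, resize_masks(masks_list[[i]], size))
  }, numeric(7)))
  classes <- labels[kept]
  comparison <- if (min(table(classes)) >= 3)
    compare_classes(rm_, classes) else NULL
  list(region_means = rm_, classes = classes, kept = kept,
       comparison = comparison)
}
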