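#' Segmentation configuration
#'
#' Thresholds for the rule-based recovery of the eight fruit regions from an
#' RGB cross-section image. The rules operate in CIE L*a*b*: the whole fruit
#' is the largest bright connected component on the dark scanner background
#' (holes filled); flavedo is the high-a* outer annulus; albedo and the
#' central core are bright low-a* tissue, told apart by normalized radial
#' position; seeds are yellowish low-a* compact components in the flesh;
#' cavity-colored (near-white, low-chroma) pixels inside the core disc or
#' the albedo annulus are DegCenter / DegAlbedo, and elsewhere are septa
#' (part of Whole only).
#'
#' @param bg_luminance mean-RGB threshold separating fruit from background.
#' @param flavedo_a minimum a* for flavedo tissue.
#' @param white_L minimum L* for albedo/core tissue.
#' @param white_a maximum a* for albedo/core tissue.
#' @param cavity_L minimum L* for cavity color.
#' @param cavity_chroma maximum chroma (sqrt(a*^2+b*^2)) for cavity color.
#' @param seed_b minimum b* for seed tissue.
#' @param seed_L_max maximum L* for seed tissue.
#' @param flesh_a minimum a* for flesh tissue.
#' @param min_size minimum component size in pixels (despeckle).
#' @param morph_radius radius of the morphological cleanup element.
#' @param rho_margin tolerance on normalized radial position when assigning
#'   cavity components to DegCenter / DegAlbedo.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(bg_luminance = 0.15,
                                flavedo_a = 33,
                                white_L = 85, white_a = 8,
                                cavity_L = 96.5, cavity_chroma = 8,
                                seed_b = 25, seed_L_max = 88,
                                flesh_a = 10,
                                min_size = 25L,
                                morph_radius = 1L,
                                rho_margin = 0.05) {
  stopifnot(bg_luminance > 0, bg_luminance < 1, min_size >= 1,
            morph_radius >= 0, cavity_L <= 100, white_L <= 100)
  structure(as.list(environment()), class = "segmentation_config")
}

#' Find the whole-fruit mask
#'
#' Largest non-background connected component with holes filled (internal
#' cavities belong to Whole).
#'
#' @param image H x W x 3 sRGB array.
#' @param config a [segmentation_config()].
#' @return logical matrix.
#' @export
find_whole <- function(image, config = segmentation_config()) {
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  fg <- lum > config$bg_luminance
  lab <- label_components(fg, connectivity = 4L)
  if (max(lab) == 0 || sum(lab == 1L) < config$min_size)
    stop("empty scene: no fruit component of at least ", config$min_size,
         " pixels found")
  fill_holes(lab == 1L)
}

#' Label locules and measure their central angles
#'
#' Connected components of the flesh mask are locules. Each locule's
#' central angle is the circular angular extent of its pixels' polar angles
#' about the whole-fruit centroid: 360 minus the largest angular gap
#' between member pixels, which is robust to locules wrapping across 0.
#'
#' @param flesh_mask logical matrix.
#' @param centroid (row, col) whole-fruit centroid.
#' @param min_size smallest component counted as a locule.
#' @return list with `labels` (integer matrix) and `angles` (degrees, one
#'   per locule). An empty flesh mask gives zero locules.
#' @export
find_locules <- function(flesh_mask, centroid, min_size = 25L) {
  if (!any(flesh_mask)) {
    return(list(labels = matrix(0L, nrow(flesh_mask), ncol(flesh_mask)),
                angles = numeric(0)))
  }
  lab <- label_components(despeckle(flesh_mask, min_size, 4L), 4L)
  k <- max(lab)
  if (k == 0) return(list(labels = lab, angles = numeric(0)))
  idx <- which(lab > 0L, arr.ind = TRUE)
  ang <- .wrap_deg(atan2(idx[, 1] - centroid[1], idx[, 2] - centroid[2]) *
                     180 / pi)
  comp <- lab[lab > 0L]
  angles <- vapply(seq_len(k), function(i) {
    a <- sort(ang[comp == i])
    if (length(a) == 1) return(0)
    gaps <- c(diff(a), a[1] + 360 - a[length(a)])
    360 - max(gaps)
  }, numeric(1))
  list(labels = lab, angles = angles)
}

# per-angular-bin outer radius of a mask about a centroid
.radial_profile <- function(mask, centroid, n_bins = 72L) {
  idx <- which(mask, arr.ind = TRUE)
  dy <- idx[, 1] - centroid[1]; dx <- idx[, 2] - centroid[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- .wrap_deg(atan2(dy, dx) * 180 / pi)
  bin <- pmin(floor(ang / (360 / n_bins)) + 1L, n_bins)
  prof <- rep(NA_real_, n_bins)
  agg <- tapply(r, bin, max)
  prof[as.integer(names(agg))] <- agg
  # fill empty bins by nearest neighbour on the circle
  if (anyNA(prof)) {
    ok <- which(!is.na(prof))
    for (i in which(is.na(prof))) {
      d <- pmin(abs(ok - i), n_bins - abs(ok - i))
      prof[i] <- prof[ok[which.min(d)]]
    }
  }
  prof
}

#' Segment the eight fruit regions from an RGB image
#'
#' Recovers `region_masks` when ground-truth masks are not available. Any
#' region that cannot be detected is returned as an all-zero mask (never an
#' error), so downstream feature extraction applies the set-to-0 rule. Only
#' a scene with no fruit at all is an error.
#'
#' @param image H x W x 3 sRGB array in \[0, 1\].
#' @param config a [segmentation_config()].
#' @return a `region_masks` list (see [masks_from_labels()]).
#' @export
segment <- function(image, config = segmentation_config()) {
  whole <- find_whole(image, config)
  S1 <- nrow(whole); S2 <- ncol(whole)
  centroid <- mask_centroid(whole)
  n_bins <- 72L
  Rprof <- .radial_profile(whole, centroid, n_bins)

  idx <- which(whole)
  rgb <- cbind(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
  lab3 <- srgb_to_lab(rgb)
  L <- lab3[, 1]; a <- lab3[, 2]; b <- lab3[, 3]
  chroma <- sqrt(a^2 + b^2)

  ii <- arrayInd(idx, c(S1, S2))
  dy <- ii[, 1] - centroid[1]; dx <- ii[, 2] - centroid[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- .wrap_deg(atan2(dy, dx) * 180 / pi)
  bin <- pmin(floor(ang / (360 / n_bins)) + 1L, n_bins)
  rho <- r / pmax(Rprof[bin], 1)

  to_mask <- function(sel) {
    m <- matrix(FALSE, S1, S2); m[idx[sel]] <- TRUE; m
  }

  is_cavity <- L >= config$cavity_L & chroma <= config$cavity_chroma
  is_flavedo <- a >= config$flavedo_a & rho >= 0.5
  is_white <- !is_cavity & !is_flavedo & L >= config$white_L & a <= config$white_a
  is_seed <- !is_cavity & !is_flavedo & !is_white &
    b >= config$seed_b & L <= config$seed_L_max & a < config$flavedo_a &
    a < config$flesh_a + 10 & rho < 0.85
  is_flesh <- !is_cavity & !is_flavedo & !is_white & !is_seed &
    a >= config$flesh_a

  flavedo <- despeckle(to_mask(is_flavedo), config$min_size, 8L)

  # split bright low-a* tissue into albedo (outer) and center (inner)
  white_m <- to_mask(is_white)
  wlab <- label_components(white_m, 8L)
  albedo <- matrix(FALSE, S1, S2); center <- matrix(FALSE, S1, S2)
  rho_full <- matrix(NA_real_, S1, S2); rho_full[idx] <- rho
  if (max(wlab) > 0) {
    for (k in seq_len(max(wlab))) {
      sel <- wlab == k
      if (sum(sel) < config$min_size) next
      mrho <- mean(rho_full[sel])
      if (mrho >= 0.55) albedo <- albedo | sel else center <- center | sel
    }
  }

  # seed components: compact, inside the flesh band
  seed <- despeckle(open_mask(to_mask(is_seed), config$morph_radius),
                    config$min_size, 8L)
  flesh <- to_mask(is_flesh) & !seed
  flesh <- despeckle(flesh, config$min_size, 4L)

  # cavity components: DegCenter inside the core disc, DegAlbedo inside the
  # albedo annulus, septa elsewhere (remain Whole-only)
  degc <- matrix(FALSE, S1, S2); dega <- matrix(FALSE, S1, S2)
  cav <- to_mask(is_cavity)
  clab <- label_components(cav, 8L)
  rho_alb_in <- if (any(albedo)) stats::quantile(rho_full[albedo], 0.02) else NA
  rho_center <- if (any(center)) stats::quantile(rho_full[center], 0.98) else
    0.4
  if (max(clab) > 0) {
    for (k in seq_len(max(clab))) {
      sel <- clab == k
      if (sum(sel) < config$min_size) next
      rr <- rho_full[sel]
      if (!is.na(rho_alb_in) && min(rr) >= rho_alb_in - config$rho_margin) {
        dega <- dega | sel
      } else if (max(rr) <= rho_center + config$rho_margin) {
        degc <- degc | sel
      }
    }
  }

  masks <- list(Whole = whole, Flavedo = flavedo, Albedo = albedo,
                DegAlbedo = dega, Flesh = flesh, Seed = seed,
                Center = center, DegCenter = degc)
  class(masks) <- "region_masks"
  check_region_masks(masks)
  masks
}
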