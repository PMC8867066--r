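#' Names of the 21 morphological features
#'
#' Area features marked with a dagger in the source table are fractions of
#' the whole cross-section area; albedo thickness is divided by the radius.
#'
#' @return character vector of length 21, in stable order.
#' @export
feature_names <- function() {
  c("Whole area", "Radius", "Circularity", "Locule number", "Locule angle",
    "Locule angleVar", "Flavedo area", "Flavedo Lab (L)", "Flavedo Lab (a)",
    "Flavedo Lab (b)", "Albedo area", "Albedo thickness", "DegAlbedo area",
    "Flesh area", "Flesh Lab (L)", "Flesh Lab (a)", "Flesh Lab (b)",
    "Seed area", "Seed number", "Center area", "DegCenter area")
}

#' Circularity of a binary mask
#'
#' 4 * pi * Area / Perimeter^2 with the perimeter from the smoothed
#' marching-squares boundary ([mask_perimeter()]); 1 for a perfect circle.
#' Clipped at 1.05 (rasterization can push a large disc slightly above 1).
#' An empty mask returns 0 (set-to-0 rule).
#'
#' @param mask logical matrix.
#' @return scalar in \[0, 1.05\].
#' @export
circularity <- function(mask) {
  A <- sum(mask)
  if (A == 0) return(0)
  P <- mask_perimeter(mask)
  min(4 * pi * A / P^2, 1.05)
}

#' Mean radial thickness of the albedo annulus
#'
#' The radial extent (max - min radius + 0.5 pixel discretization
#' correction) of albedo pixels is
#' computed per angular bin about the centroid and averaged over nonempty
#' bins, then divided by `radius`. An empty mask returns 0.
#'
#' @param albedo_mask logical matrix.
#' @param centroid (row, col) of the whole-fruit centroid.
#' @param radius equivalent-circle radius of the whole fruit (pixels).
#' @param n_bins number of angular bins.
#' @return thickness as a fraction of `radius`.
#' @export
albedo_thickness <- function(albedo_mask, centroid, radius, n_bins = 72L) {
  if (!any(albedo_mask) || radius <= 0) return(0)
  idx <- which(albedo_mask, arr.ind = TRUE)
  dy <- idx[, 1] - centroid[1]; dx <- idx[, 2] - centroid[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- .wrap_deg(atan2(dy, dx) * 180 / pi)
  bin <- pmin(floor(ang / (360 / n_bins)) + 1L, n_bins)
  ext <- tapply(r, bin, function(v) max(v) - min(v) + 0.5)
  mean(ext) / radius
}

#' Per-locule summary statistics
#'
#' @param angles numeric vector of per-locule central angles (degrees), as
#'   returned by [find_locules()].
#' @return named vector: count, arithmetic mean, population variance
#'   (divide by n). An empty list returns (0, 0, 0).
#' @export
locule_statistics <- function(angles) {
  if (length(angles) == 0) {
    return(c("Locule number" = 0, "Locule angle" = 0, "Locule angleVar" = 0))
  }
  m <- mean(angles)
  c("Locule number" = length(angles), "Locule angle" = m,
    "Locule angleVar" = mean((angles - m)^2))
}

#' Extract the 21 morphological features from an image and its region masks
#'
#' Region masks may be ground truth (from [render_fruit()]) or recovered by
#' [segment()]. Any all-zero region mask yields 0 for that region's
#' features (the set-to-0 convention for regions that could not be clearly
#' extracted).
#'
#' @param image H x W x 3 sRGB array in \[0, 1\].
#' @param masks a `region_masks` list.
#' @param min_locule_size smallest flesh component counted as a locule.
#' @param locule_angle "mean" (default) or "total" aggregate of the
#'   per-locule central angles reported as `Locule angle`.
#' @return named numeric vector of length 21 ([feature_names()]).
#' @export
extract_features <- function(image, masks, min_locule_size = 25L,
                             locule_angle = c("mean", "total")) {
  locule_angle <- match.arg(locule_angle)
  stopifnot(length(dim(image)) == 3)
  if (!all(dim(image)[1:2] == dim(masks$Whole)))
    stop("image and masks have different shapes")
  check_region_masks(masks)

  npx <- prod(dim(masks$Whole))
  wa <- sum(masks$Whole)
  if (wa == 0) {
    out <- stats::setNames(numeric(21), feature_names())
    return(out)
  }
  radius <- sqrt(wa / pi)
  centroid <- mask_centroid(masks$Whole)
  circ <- circularity(masks$Whole)

  loc <- find_locules(masks$Flesh, centroid, min_size = min_locule_size)
  ls <- locule_statistics(loc$angles)
  if (locule_angle == "total" && length(loc$angles) > 0)
    ls["Locule angle"] <- sum(loc$angles)

  frac <- function(r) sum(masks[[r]]) / wa
  lab_flav <- mean_lab(image, masks$Flavedo)
  lab_flesh <- mean_lab(image, masks$Flesh)
  seed_cc <- if (any(masks$Seed)) {
    lab <- label_components(despeckle(masks$Seed, min_size = 9L,
                                      connectivity = 8L), 8L)
    max(lab)
  } else 0

  out <- c(wa / npx, radius, circ,
           ls[["Locule number"]], ls[["Locule angle"]], ls[["Locule angleVar"]],
           frac("Flavedo"), lab_flav[["L"]], lab_flav[["a"]], lab_flav[["b"]],
           frac("Albedo"),
           albedo_thickness(masks$Albedo, centroid, radius),
           frac("DegAlbedo"),
           frac("Flesh"), lab_flesh[["L"]], lab_flesh[["a"]], lab_flesh[["b"]],
           frac("Seed"), seed_cc,
           frac("Center"), frac("DegCenter"))
  names(out) <- feature_names()
  out
}
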