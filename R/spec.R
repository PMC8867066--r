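#' Region names and label codes
#'
#' The eight canonical fruit cross-section regions. `Whole` is the union of
#' all fruit pixels; the remaining seven plus the septum/other class (label 8)
#' partition it. Label images use 0 = background and these codes.
#'
#' @export
REGIONS <- c("Whole", "Flavedo", "Albedo", "DegAlbedo", "Flesh",
             "Seed", "Center", "DegCenter")

#' @rdname REGIONS
#' @export
REGION_LABELS <- c(Flavedo = 1L, Albedo = 2L, DegAlbedo = 3L, Flesh = 4L,
                   Seed = 5L, Center = 6L, DegCenter = 7L, Septum = 8L)

#' Default per-region sRGB palette
#'
#' Near-black scanner-like background; a deep-orange flavedo (high a*),
#' pale yellowish albedo, lighter orange flesh, cream seeds, whitish central
#' core, and near-white cavity color shared by septa and degradation areas
#' so that "degradation" is operationally the non-flesh, non-peel white
#' inside Center/Albedo.
#'
#' @return named list of sRGB triplets in \[0, 1\].
#' @export
default_palette <- function() {
  list(
    background = c(0.06, 0.06, 0.06),
    flavedo    = c(0.92, 0.45, 0.08),
    albedo     = c(0.97, 0.93, 0.78),
    flesh      = c(0.96, 0.63, 0.22),
    seed       = c(0.86, 0.78, 0.55),
    center     = c(0.96, 0.92, 0.80),
    cavity     = c(0.995, 0.99, 0.97)
  )
}

#' Parametric specification of one synthetic fruit cross-section
#'
#' All radial quantities are fractions: `fruit_radius` of the half image
#' side, `flavedo_thickness`, `albedo_thickness` and `center_radius` of the
#' fruit radius, and the two degradation targets of the whole cross-section
#' area. `septum_angle` is the full angular width of one septum in degrees;
#' `seed_axes` are the seed ellipse semi-axes in pixels (at the given
#' `image_size`); `ellipticity` is the minor/major axis ratio;
#' `boundary_jitter` is the relative amplitude of a low-order sinusoidal
#' perturbation of the fruit outline.
#'
#' @param image_size square image side in pixels.
#' @param fruit_radius fraction of the half image side.
#' @param flavedo_thickness,albedo_thickness,center_radius fractions of the
#'   fruit radius.
#' @param locule_count number of flesh locules (>= 1).
#' @param septum_angle degrees per septum.
#' @param seed_count number of seeds.
#' @param seed_axes seed ellipse semi-axes (pixels).
#' @param degcenter_frac,degalbedo_frac target degradation areas as fractions
#'   of the whole cross-section area.
#' @param palette per-region sRGB palette, see [default_palette()].
#' @param boundary_jitter relative outline perturbation amplitude.
#' @param ellipticity minor/major axis ratio in (0, 1].
#' @return object of class `fruit_spec`.
#' @export
fruit_spec <- function(image_size = 256L,
                       fruit_radius = 0.675,
                       flavedo_thickness = 0.08,
                       albedo_thickness = 0.10,
                       locule_count = 10L,
                       septum_angle = 4,
                       seed_count = 6L,
                       seed_axes = c(7, 4),
                       center_radius = 0.22,
                       degcenter_frac = 0.02,
                       degalbedo_frac = 0.01,
                       palette = default_palette(),
                       boundary_jitter = 0.015,
                       ellipticity = 0.97) {
  spec <- list(image_size = as.integer(image_size),
               fruit_radius = fruit_radius,
               flavedo_thickness = flavedo_thickness,
               albedo_thickness = albedo_thickness,
               locule_count = as.integer(locule_count),
               septum_angle = septum_angle,
               seed_count = as.integer(seed_count),
               seed_axes = seed_axes,
               center_radius = center_radius,
               degcenter_frac = degcenter_frac,
               degalbedo_frac = degalbedo_frac,
               palette = palette,
               boundary_jitter = boundary_jitter,
               ellipticity = ellipticity)
  class(spec) <- "fruit_spec"
  validate_fruit_spec(spec)
  spec
}

#' Validate a fruit_spec against its geometric invariants
#'
#' @param spec a `fruit_spec`.
#' @return the spec, invisibly; signals an error naming the violated
#'   invariant otherwise.
#' @export
validate_fruit_spec <- function(spec) {
  with(spec, {
    fr <- c(fruit_radius, flavedo_thickness, albedo_thickness, center_radius,
            degcenter_frac, degalbedo_frac, boundary_jitter)
    if (any(!is.finite(fr)) || any(fr < 0) || any(fr[1:4] > 1))
      stop("fruit_spec: all fractions must lie in [0, 1]")
    if (flavedo_thickness + albedo_thickness + center_radius >= 1)
      stop("fruit_spec: rings overlap (flavedo_thickness + albedo_thickness + center_radius must be < 1)")
    if (locule_count < 1L)
      stop("fruit_spec: locule_count must be >= 1")
    if (septum_angle < 0 || locule_count * septum_angle >= 360)
      stop("fruit_spec: septum angles must leave positive locule extent")
    if (ellipticity <= 0 || ellipticity > 1)
      stop("fruit_spec: ellipticity must be in (0, 1]")
    # capacity checks: degradation must fit inside its bounding region
    cap_center <- center_radius^2
    if (degcenter_frac > 0.95 * cap_center)
      stop("fruit_spec: degcenter_frac exceeds the Center disc capacity")
    cap_albedo <- (1 - flavedo_thickness)^2 -
      (1 - flavedo_thickness - albedo_thickness)^2
    if (degalbedo_frac > 0.9 * cap_albedo)
      stop("fruit_spec: degalbedo_frac exceeds the Albedo annulus capacity")
  })
  invisible(spec)
}

#' Linear generative model for breeder-style trait scores
#'
#' Continuous score = intercept + sum(coef * ground-truth feature) +
#' genotype effect + year effect + residual noise; the ordinal 1-5 category
#' is read off strictly increasing cut points, and the binary class by the
#' configured rule. Coefficient signs follow the association structure the
#' downstream analyses are expected to recover: central-core degradation
#' eases peeling and softens fruit; seed and flavedo area harden it; larger
#' fruit are harder to peel and harder.
#'
#' @param trait "Peeling" or "FruH".
#' @param intercept trait intercept on the 1-5 score scale.
#' @param coefficients named numeric vector over ground-truth feature names.
#' @param genotype_sd genotype (random) effect standard deviation.
#' @param year_effects named numeric vector of per-year shifts.
#' @param residual_sd residual standard deviation (> 0 unless exactly 0 is
#'   wanted for deterministic checks).
#' @param cut_points strictly increasing cut points defining 5 ordinal bins.
#' @param binary_rule "median" (below-median continuous score = easy/soft) or
#'   "tails" (lower 40% vs upper 40%, middles dropped as NA).
#' @return object of class `trait_model`.
#' @export
trait_model <- function(trait = c("Peeling", "FruH"),
                        intercept = NULL,
                        coefficients = NULL,
                        genotype_sd = 0.3,
                        year_effects = c(y1 = -0.2, y2 = 0.2),
                        residual_sd = 0.3,
                        cut_points = c(1.5, 2.5, 3.5, 4.5),
                        binary_rule = c("median", "tails")) {
  trait <- match.arg(trait)
  binary_rule <- match.arg(binary_rule)
  if (is.null(coefficients)) {
    coefficients <- if (trait == "Peeling") {
      c("DegCenter area" = -35, "DegAlbedo area" = -25, "Whole area" = 6)
    } else {
      c("DegCenter area" = -35, "Seed area" = 30,
        "Flavedo area" = 6, "Whole area" = 5)
    }
  }
  if (is.null(intercept)) intercept <- if (trait == "Peeling") 2.4 else 0.6
  stopifnot(length(cut_points) == 4, all(diff(cut_points) > 0),
            residual_sd >= 0, genotype_sd >= 0)
  structure(list(trait = trait, intercept = intercept,
                 coefficients = coefficients, genotype_sd = genotype_sd,
                 year_effects = year_effects, residual_sd = residual_sd,
                 cut_points = cut_points, binary_rule = binary_rule),
            class = "trait_model")
}
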