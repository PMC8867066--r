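#' Default prior ranges for genotype-level fruit specs
#'
#' Uniform ranges from which each genotype's latent [fruit_spec()] fields
#' are drawn. The ranges describe a diverse citrus panel: fruit size varies
#' about two-fold in area, peel thickness and core degradation vary widely
#' (degradation is absent in part of the panel), seed counts run from
#' seedless to many-seeded.
#'
#' @return named list of c(min, max) ranges (integer fields are rounded).
#' @export
default_spec_prior <- function() {
  list(fruit_radius = c(0.55, 0.8),
       flavedo_thickness = c(0.04, 0.12),
       albedo_thickness = c(0.05, 0.16),
       center_radius = c(0.16, 0.3),
       locule_count = c(8, 12),
       septum_angle = c(3, 6),
       seed_count = c(0, 12),
       degcenter_frac = c(0, 0.06),
       degalbedo_frac = c(0, 0.04))
}

.draw_spec <- function(prior, image_size) {
  f <- lapply(prior, function(rg) stats::runif(1, rg[1], rg[2]))
  # seed size tracks resolution (constant physical size at varying dpi)
  seed_axes <- c(7, 4) * image_size / 256
  # keep degradation within its bounding region's capacity
  f$degcenter_frac <- min(f$degcenter_frac, 0.9 * f$center_radius^2)
  cap_alb <- (1 - f$flavedo_thickness)^2 -
    (1 - f$flavedo_thickness - f$albedo_thickness)^2
  f$degalbedo_frac <- min(f$degalbedo_frac, 0.85 * cap_alb)
  fruit_spec(image_size = image_size,
             fruit_radius = f$fruit_radius,
             flavedo_thickness = f$flavedo_thickness,
             albedo_thickness = f$albedo_thickness,
             locule_count = round(f$locule_count),
             septum_angle = f$septum_angle,
             seed_count = round(f$seed_count),
             seed_axes = seed_axes,
             center_radius = f$center_radius,
             degcenter_frac = f$degcenter_frac,
             degalbedo_frac = f$degalbedo_frac)
}

.jitter_spec <- function(spec, rel_sd) {
  if (rel_sd <= 0) return(spec)
  jf <- function(x, lo = 0, hi = Inf)
    min(max(x * (1 + stats::rnorm(1, 0, rel_sd)), lo), hi)
  spec$fruit_radius <- jf(spec$fruit_radius, 0.3, 0.95)
  spec$flavedo_thickness <- jf(spec$flavedo_thickness, 0.01, 0.3)
  spec$albedo_thickness <- jf(spec$albedo_thickness, 0.01, 0.3)
  spec$center_radius <- jf(spec$center_radius, 0.05, 0.45)
  spec$degcenter_frac <- min(jf(spec$degcenter_frac),
                             0.9 * spec$center_radius^2)
  cap_alb <- (1 - spec$flavedo_thickness)^2 -
    (1 - spec$flavedo_thickness - spec$albedo_thickness)^2
  spec$degalbedo_frac <- min(jf(spec$degalbedo_frac), 0.85 * cap_alb)
  validate_fruit_spec(spec)
  spec
}

#' Sample a population of synthetic fruits
#'
#' Each genotype gets a latent [fruit_spec()] drawn from the prior; each
#' fruit jitters multiplicatively around it; each year shifts the
#' degradation fractions and the fruit radius multiplicatively, so a known
#' year effect exists for the BLUP stage to remove.
#'
#' @param n_genotypes,n_years,fruits_per_genotype_year design counts (>= 1).
#' @param spec_prior named list of c(min, max) ranges, see
#'   [default_spec_prior()].
#' @param image_size rendered image side in pixels.
#' @param jitter relative within-genotype standard deviation.
#' @param year_deg_mult,year_radius_mult per-year multipliers applied to
#'   the degradation fractions / fruit radius (recycled to `n_years`).
#' @param render rasterize images and masks (set FALSE for fast
#'   feature-level simulations that only need ground-truth bookkeeping).
#' @return list of class `fruit_population`: `meta` (data.frame fruit_id,
#'   genotype, year), `specs` (per-fruit specs), `truth` (matrix of
#'   ground-truth feature vectors), `images`, `masks` (NULL when
#'   `render = FALSE`).
#' @export
sample_population <- function(n_genotypes, n_years = 2L,
                              fruits_per_genotype_year = 5L,
                              spec_prior = default_spec_prior(),
                              image_size = 256L, jitter = 0.03,
                              year_deg_mult = c(0.8, 1.25),
                              year_radius_mult = c(0.98, 1.02),
                              render = TRUE) {
  stopifnot(n_genotypes >= 1, n_years >= 1, fruits_per_genotype_year >= 1)
  bad <- names(spec_prior)[vapply(spec_prior, function(r)
    length(r) != 2 || r[1] > r[2], logical(1))]
  if (length(bad)) stop("invalid prior range for: ", paste(bad, collapse = ", "))
  year_deg_mult <- rep_len(year_deg_mult, n_years)
  year_radius_mult <- rep_len(year_radius_mult, n_years)

  latent <- lapply(seq_len(n_genotypes), function(i)
    .draw_spec(spec_prior, image_size))
  meta <- NULL; specs <- list(); truth <- NULL
  images <- if (render) list() else NULL
  masks <- if (render) list() else NULL
  fid <- 0L
  for (gi in seq_len(n_genotypes)) {
    for (yi in seq_len(n_years)) {
      for (fi in seq_len(fruits_per_genotype_year)) {
        fid <- fid + 1L
        sp <- latent[[gi]]
        sp$degcenter_frac <- min(sp$degcenter_frac * year_deg_mult[yi],
                                 0.9 * sp$center_radius^2)
        cap_alb <- (1 - sp$flavedo_thickness)^2 -
          (1 - sp$flavedo_thickness - sp$albedo_thickness)^2
        sp$degalbedo_frac <- min(sp$degalbedo_frac * year_deg_mult[yi],
                                 0.85 * cap_alb)
        sp$fruit_radius <- min(sp$fruit_radius * year_radius_mult[yi], 0.95)
        sp <- .jitter_spec(sp, jitter)
        specs[[fid]] <- sp
        truth <- rbind(truth, ground_truth_features(sp))
        meta <- rbind(meta, data.frame(
          fruit_id = sprintf("F%04d", fid),
          genotype = sprintf("G%03d", gi),
          year = sprintf("Y%d", yi), stringsAsFactors = FALSE))
        if (render) {
          fr <- render_fruit(sp)
          images[[fid]] <- fr$image
          masks[[fid]] <- fr$masks
        }
      }
    }
  }
  rownames(truth) <- meta$fruit_id
  structure(list(meta = meta, specs = specs, truth = truth,
                 images = images, masks = masks),
            class = "fruit_population")
}

#' Generate trait scores from ground-truth features
#'
#' Applies a [trait_model()] to a table of ground-truth feature vectors:
#' continuous score = intercept + sum(coefficient * feature) + genotype
#' effect + year effect + residual noise; the ordinal category reads the
#' score off the cut points (clipped to 1..5) and the binary class follows
#' the model's rule (binary = 1 for the difficult/hard side).
#'
#' @param truth matrix or data.frame of feature columns (rows = fruits).
#' @param meta data.frame with `fruit_id`, `genotype`, `year` rows parallel
#'   to `truth`.
#' @param model a [trait_model()].
#' @return data.frame: fruit_id, genotype, year, trait, continuous,
#'   ordinal, binary (NA in the "tails" rule's dropped middle).
#' @export
generate_traits <- function(truth, meta, model) {
  truth <- as.matrix(truth)
  miss <- setdiff(names(model$coefficients), colnames(truth))
  if (length(miss))
    stop("schema error: missing feature column(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(truth)
  g <- factor(meta$genotype)
  yrs <- sort(unique(as.character(meta$year)))
  ge <- stats::rnorm(nlevels(g), 0, model$genotype_sd)
  ye <- rep_len(model$year_effects, length(yrs))
  names(ye) <- yrs
  lin <- as.numeric(truth[, names(model$coefficients), drop = FALSE] %*%
                      model$coefficients)
  continuous <- model$intercept + lin + ge[as.integer(g)] +
    ye[as.character(meta$year)] + stats::rnorm(n, 0, model$residual_sd)
  ordinal <- pmin(pmax(findInterval(continuous, model$cut_points) + 1L, 1L), 5L)
  if (model$binary_rule == "median") {
    binary <- as.integer(continuous >= stats::median(continuous))
  } else {
    lo <- stats::quantile(continuous, 0.4)
    hi <- stats::quantile(continuous, 0.6)
    binary <- ifelse(continuous <= lo, 0L,
                     ifelse(continuous >= hi, 1L, NA_integer_))
  }
  data.frame(fruit_id = meta$fruit_id, genotype = meta$genotype,
             year = meta$year, trait = model$trait,
             continuous = continuous, ordinal = ordinal, binary = binary,
             stringsAsFactors = FALSE)
}
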