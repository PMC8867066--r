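#' Convert a label image to the list of eight region masks
#'
#' @param labels integer matrix with codes 0 (background) and
#'   [REGION_LABELS] (1..8; 8 = septum/other fruit tissue, part of Whole
#'   only).
#' @return named list of 8 logical matrices (class `region_masks`), one per
#'   entry of [REGIONS]. A missing region is an all-zero mask.
#' @export
masks_from_labels <- function(labels) {
  m <- list(Whole = labels > 0L)
  for (r in names(REGION_LABELS)[1:7]) m[[r]] <- labels == REGION_LABELS[[r]]
  m <- m[REGIONS]
  class(m) <- "region_masks"
  m
}

#' Convert region masks back to a label image
#' @param masks a `region_masks` list.
#' @return integer label matrix (0 = background, 1..8 as [REGION_LABELS]).
#' @export
labels_from_masks <- function(masks) {
  lab <- matrix(0L, nrow(masks$Whole), ncol(masks$Whole))
  lab[masks$Whole] <- REGION_LABELS[["Septum"]]
  for (r in names(REGION_LABELS)[1:7]) lab[masks[[r]]] <- REGION_LABELS[[r]]
  lab
}

#' Check region-mask invariants
#'
#' The seven sub-region masks must be subsets of Whole and mutually
#' disjoint; DegCenter must lie inside the disc bounding Center, DegAlbedo
#' inside the annulus bounding Albedo (both checked loosely via Whole
#' containment plus disjointness here; geometric containment is the
#' generator's responsibility).
#'
#' @param masks a `region_masks` list.
#' @return TRUE, or stops with the violated invariant.
#' @export
check_region_masks <- function(masks) {
  stopifnot(identical(names(masks), REGIONS))
  sub <- REGIONS[-1]
  acc <- matrix(0L, nrow(masks$Whole), ncol(masks$Whole))
  for (r in sub) {
    if (any(masks[[r]] & !masks$Whole)) stop("region ", r, " not contained in Whole")
    acc <- acc + masks[[r]]
  }
  if (any(acc > 1L)) stop("region masks overlap")
  TRUE
}

.wrap_deg <- function(a) ((a %% 360) + 360) %% 360

#' Render a synthetic citrus fruit cross-section
#'
#' Rasterizes the parametric fruit of a [fruit_spec()]: a jittered elliptical
#' outline, concentric flavedo/albedo rings, radially arranged flesh locules
#' separated by near-white septa, seeds placed inside locules, a central
#' core, and optional near-white degradation cavities in the core and the
#' albedo. All ring boundaries are defined as fractions of the local
#' (jittered) fruit radius, so area fractions are preserved under jitter and
#' ellipticity.
#'
#' @param spec a [fruit_spec()].
#' @param seed integer seed for the jitter phases and degradation placement;
#'   pass NULL to use the current RNG state.
#' @return list with `image` (H x W x 3 sRGB array in \[0,1\]), `masks`
#'   (a `region_masks` list), and `labels` (integer label matrix).
#' @export
render_fruit <- function(spec, seed = NULL) {
  validate_fruit_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  S <- spec$image_size
  cx <- (S + 1) / 2
  ax <- spec$fruit_radius * S / 2          # semi-axis along columns (x)
  ay <- ax * spec$ellipticity              # semi-axis along rows (y)

  xs <- matrix(rep(seq_len(S), each = S), S, S)   # column index
  ys <- matrix(rep(seq_len(S), times = S), S, S)  # row index
  dx <- xs - cx; dy <- ys - cx
  theta <- .wrap_deg(atan2(dy, dx) * 180 / pi)

  # low-order sinusoidal boundary jitter
  ph <- stats::runif(2, 0, 2 * pi)
  amp <- stats::runif(2, 0.4, 1)
  amp <- amp / sum(amp)
  jit <- 1 + spec$boundary_jitter *
    (amp[1] * sin(2 * theta * pi / 180 + ph[1]) +
     amp[2] * sin(3 * theta * pi / 180 + ph[2]))
  rho <- sqrt((dx / ax)^2 + (dy / ay)^2) / jit  # 1 at the fruit outline

  whole <- rho <= 1
  ft <- spec$flavedo_thickness; at <- spec$albedo_thickness
  cr <- spec$center_radius
  rho_alb_out <- 1 - ft
  rho_in <- 1 - ft - at

  lab <- matrix(0L, S, S)
  lab[whole & rho > rho_alb_out] <- REGION_LABELS[["Flavedo"]]
  lab[whole & rho <= rho_alb_out & rho > rho_in] <- REGION_LABELS[["Albedo"]]

  # interior: center disc, septa, flesh
  lab[rho <= rho_in & rho > cr] <- REGION_LABELS[["Flesh"]]
  lab[rho <= cr] <- REGION_LABELS[["Center"]]
  n <- spec$locule_count
  sector <- 360 / n
  offset <- stats::runif(1, 0, sector)
  bd <- .wrap_deg(theta - offset) %% sector
  dist_bd <- pmin(bd, sector - bd)
  # septa taper towards the core where their angular width would fall
  # below one pixel; enforce a minimum arc width of ~1 px so locules stay
  # topologically separated at any rendering resolution
  r_px <- sqrt(dx^2 + dy^2)
  arc_px <- r_px * dist_bd * pi / 180
  septum <- (dist_bd <= spec$septum_angle / 2 | arc_px <= 0.9) &
    rho <= rho_in & rho > cr
  lab[septum] <- REGION_LABELS[["Septum"]]

  # seeds: radially oriented ellipses at locule centres, clipped to flesh
  if (spec$seed_count > 0L) {
    sa <- spec$seed_axes[1]; sb <- spec$seed_axes[2]
    r_mid <- (cr + rho_in) / 2
    for (k in seq_len(spec$seed_count)) {
      loc <- (k - 1L) %% n
      tier <- (k - 1L) %/% n
      ang <- (offset + (loc + 0.5) * sector) * pi / 180
      rr <- r_mid * (1 + 0.18 * (tier - 0.5 * (spec$seed_count > n)))
      px <- cx + cos(ang) * rr * ax
      py <- cx + sin(ang) * rr * ay
      u <- c(cos(ang) * ax, sin(ang) * ay); u <- u / sqrt(sum(u^2))
      v <- c(-u[2], u[1])
      ddx <- xs - px; ddy <- ys - py
      seed_px <- ((ddx * u[1] + ddy * u[2]) / sa)^2 +
                 ((ddx * v[1] + ddy * v[2]) / sb)^2 <= 1
      lab[seed_px & lab == REGION_LABELS[["Flesh"]]] <- REGION_LABELS[["Seed"]]
    }
  }

  whole_px <- sum(whole)
  # central degradation cavity: slightly lobed disc at the fruit axis
  if (spec$degcenter_frac > 0) {
    r_dc <- sqrt(spec$degcenter_frac * whole_px / pi)
    ph_dc <- stats::runif(1, 0, 2 * pi)
    rr <- sqrt(dx^2 + dy^2) / (1 + 0.08 * sin(3 * theta * pi / 180 + ph_dc))
    degc <- rr <= r_dc & rho <= cr
    lab[degc] <- REGION_LABELS[["DegCenter"]]
  }

  # albedo degradation: angular gaps in the albedo annulus
  if (spec$degalbedo_frac > 0) {
    f_alb <- rho_alb_out^2 - rho_in^2
    total_deg <- spec$degalbedo_frac / f_alb * 360
    n_gap <- sample.int(3L, 1L)
    w <- stats::runif(n_gap, 0.5, 1); w <- w / sum(w) * total_deg
    centers <- .wrap_deg(stats::runif(1, 0, 360) +
                         (seq_len(n_gap) - 1L) * 360 / n_gap)
    for (g in seq_len(n_gap)) {
      d <- abs(.wrap_deg(theta - centers[g] + 180) - 180)
      gap <- d <= w[g] / 2 & lab == REGION_LABELS[["Albedo"]]
      lab[gap] <- REGION_LABELS[["DegAlbedo"]]
    }
  }

  masks <- masks_from_labels(lab)
  image <- .paint(lab, spec$palette)
  list(image = image, masks = masks, labels = lab)
}

.paint <- function(lab, palette, noise_sd = 0.012) {
  S <- nrow(lab)
  cols <- list(palette$background, palette$flavedo, palette$albedo,
               palette$cavity, palette$flesh, palette$seed, palette$center,
               palette$cavity, palette$cavity)
  # index: label 0..8 -> cols[[label+1]]
  img <- array(0, dim = c(S, S, 3))
  for (ch in 1:3) {
    lut <- vapply(cols, `[`, numeric(1), ch)
    plane <- matrix(lut[lab + 1L], S, S)
    plane <- plane + stats::rnorm(S * S, 0, noise_sd)
    img[, , ch] <- pmin(pmax(plane, 0), 1)
  }
  img
}

#' Analytic ground-truth features of a fruit spec
#'
#' Computes the 21 morphological features directly from the parametric
#' geometry (generator bookkeeping), without rasterization. Area features
#' are fractions of the whole cross-section area; `Radius` is the
#' equivalent-circle radius in pixels; colors are the palette colors
#' converted to CIE L*a*b*.
#'
#' @param spec a [fruit_spec()].
#' @return named numeric vector with the 21 entries of [feature_names()].
#' @export
ground_truth_features <- function(spec) {
  S <- spec$image_size
  ax <- spec$fruit_radius * S / 2
  ay <- ax * spec$ellipticity
  A <- pi * ax * ay
  ft <- spec$flavedo_thickness; at <- spec$albedo_thickness
  cr <- spec$center_radius
  rho_in <- 1 - ft - at
  n <- spec$locule_count
  sector <- 360 / n

  f_flav <- 1 - (1 - ft)^2
  f_alb_band <- (1 - ft)^2 - rho_in^2
  f_interior <- rho_in^2 - cr^2
  # septa: angular width septum_angle, but rendered with a minimum arc
  # width of 1.8 px near the core (see render_fruit) — account for the
  # extra area analytically
  R <- sqrt(ax * ay)
  w_ang <- spec$septum_angle * pi / 180
  r_cr <- cr * R; r_in <- rho_in * R
  f_septa <- f_interior * n * spec$septum_angle / 360
  r0 <- min(max(1.8 / max(w_ang, 1e-9), r_cr), r_in)
  corr <- 1.8 * (r0 - r_cr) - w_ang * (r0^2 - r_cr^2) / 2
  f_septa <- f_septa + n * corr / (pi * R^2)
  f_seed <- spec$seed_count * pi * spec$seed_axes[1] * spec$seed_axes[2] / A
  f_flesh <- f_interior - f_septa - f_seed

  # circularity of the (unjittered) ellipse outline, Ramanujan perimeter
  h <- ((ax - ay) / (ax + ay))^2
  P <- pi * (ax + ay) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  circ <- 4 * pi * A / P^2

  lab_flav <- srgb_to_lab(spec$palette$flavedo)
  lab_flesh <- srgb_to_lab(spec$palette$flesh)

  out <- c(A / S^2,                      # Whole area (fraction of image)
           sqrt(ax * ay),                # Radius (px)
           circ,
           n,
           sector - spec$septum_angle,   # Locule angle (mean)
           0,                            # Locule angleVar (equal sectors)
           f_flav,
           lab_flav[1], lab_flav[2], lab_flav[3],
           f_alb_band - spec$degalbedo_frac,
           at,                           # thickness / Radius
           spec$degalbedo_frac,
           f_flesh,
           lab_flesh[1], lab_flesh[2], lab_flesh[3],
           f_seed,
           spec$seed_count,
           cr^2 - spec$degcenter_frac,
           spec$degcenter_frac)
  names(out) <- feature_names()
  out
}
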