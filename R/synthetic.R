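#' Configuration for the synthetic organoid scene generator
#'
#' The generator emulates the brightfield regime the pipeline is built for:
#' bright cystic (ellipsoidal) organoids with a dark rim on a noisy,
#' unevenly illuminated background, plus heavily blurred low-contrast
#' out-of-focus distractors that the ground truth deliberately excludes.
#' Organoid sizes follow a truncated lognormal in microns.
#'
#' @param height,width scene size in pixels.
#' @param n_organoids number of in-focus organoids per scene.
#' @param diameter_median_um median equivalent diameter (um).
#' @param diameter_sigma lognormal sigma (log scale).
#' @param diameter_range_um truncation bounds (um), both positive.
#' @param ecc_range eccentricity range, a sub-interval of \code{[0, 1)}.
#' @param um_per_px micron-per-pixel calibration of the simulated optics.
#' @param n_outfocus_distractors number of out-of-focus distractor blobs.
#' @param allow_border_crop if \code{TRUE}, organoid centers may fall close
#'   enough to the frame edge that the object is cropped.
#' @param noise_sd Gaussian background noise, 8-bit intensity units.
#' @param bg_level mean background intensity.
#' @param illum_gradient peak-to-center amplitude of the linear
#'   illumination ramp, intensity units.
#' @param lumen_brightness interior (lumen) brightness above background.
#' @param rim_darkness rim darkness below background.
#' @param rim_width_px rim thickness in pixels.
#' @param distractor_contrast peak contrast of distractors before blurring.
#' @param seed RNG seed; the same (config, seed) pair reproduces a scene
#'   bit-identically.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(height = 512L, width = 512L,
                       n_organoids = 8L,
                       diameter_median_um = 110,
                       diameter_sigma = 0.45,
                       diameter_range_um = c(30, 350),
                       ecc_range = c(0, 0.8),
                       um_per_px = 1.5,
                       n_outfocus_distractors = 2L,
                       allow_border_crop = FALSE,
                       noise_sd = 7,
                       bg_level = 115,
                       illum_gradient = 8,
                       lumen_brightness = 45,
                       rim_darkness = 60,
                       rim_width_px = 2.5,
                       distractor_contrast = 14,
                       seed = 1L) {
  stopifnot(height >= 1, width >= 1, n_organoids >= 0,
            all(diameter_range_um > 0),
            diameter_range_um[1] <= diameter_range_um[2],
            um_per_px > 0, noise_sd >= 0, n_outfocus_distractors >= 0)
  if (ecc_range[1] < 0 || ecc_range[2] >= 1 || ecc_range[1] > ecc_range[2])
    stop("ecc_range must be a sub-interval of [0, 1)")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Rasterize a rotated ellipse
#'
#' A pixel belongs to the ellipse iff its center satisfies the rotated
#' ellipse inequality. Also the analytic oracle behind the morphometry
#' tests: the true area is \eqn{\pi a b} and the true eccentricity
#' \eqn{\sqrt{1 - b^2/a^2}}.
#'
#' @param center numeric (row, col) center, 1-based pixel coordinates.
#' @param semi_axes numeric (a, b) semi-axes in pixels, \code{a >= b > 0}.
#' @param orientation rotation of the major axis, radians.
#' @param shape (height, width) of the raster.
#' @return logical matrix of the given shape.
#' @export
rasterize_ellipse <- function(center, semi_axes, orientation, shape) {
  a <- semi_axes[1L]; b <- semi_axes[2L]
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("degenerate semi-axes")
  if (b > a) stop("semi-axes must satisfy a >= b")
  H <- shape[1L]; W <- shape[2L]
  # restrict to the bounding box for speed
  r0 <- max(1L, floor(center[1L] - a)); r1 <- min(H, ceiling(center[1L] + a))
  c0 <- max(1L, floor(center[2L] - a)); c1 <- min(W, ceiling(center[2L] + a))
  out <- matrix(FALSE, H, W)
  if (r0 > r1 || c0 > c1) return(out)
  dy <- (r0:r1) - center[1L]
  dx <- (c0:c1) - center[2L]
  DY <- matrix(dy, length(dy), length(dx))
  DX <- matrix(dx, length(dy), length(dx), byrow = TRUE)
  ct <- cos(orientation); st <- sin(orientation)
  u <- DX * ct + DY * st
  v <- -DX * st + DY * ct
  out[r0:r1, c0:c1] <- (u / a)^2 + (v / b)^2 <= 1
  out
}

# Ramanujan approximation to the ellipse perimeter
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# sample truncated lognormal diameters (um) -> semi-axes (px)
sample_geometry <- function(n, cfg) {
  if (n == 0L)
    return(data.frame(a = numeric(0), b = numeric(0),
                      orientation = numeric(0)))
  d_um <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      d <- rlnorm(1L, meanlog = log(cfg$diameter_median_um),
                  sdlog = cfg$diameter_sigma)
      if (d >= cfg$diameter_range_um[1] && d <= cfg$diameter_range_um[2]) break
    }
    d_um[i] <- d
  }
  r_px <- d_um / 2 / cfg$um_per_px
  e <- runif(n, cfg$ecc_range[1], cfg$ecc_range[2])
  q <- sqrt(sqrt(1 - e^2))                # (b/a)^(1/2)
  data.frame(a = r_px / q, b = r_px * q,
             orientation = runif(n, 0, pi))
}

# rejection-sampled non-overlapping layout (bounding-circle separation)
place_objects <- function(geom, H, W, allow_border, occupied = NULL,
                          max_tries = 3000L) {
  n <- nrow(geom)
  centers <- matrix(NA_real_, n, 2L)
  prev <- occupied  # matrix: row, col, radius
  ord <- order(geom$a, decreasing = TRUE)
  for (i in ord) {
    a <- geom$a[i]
    if (!allow_border && (2 * a + 6 > H || 2 * a + 6 > W))
      stop("organoid larger than image frame")
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      if (allow_border) {
        cen <- c(runif(1, 1, H), runif(1, 1, W))
      } else {
        cen <- c(runif(1, a + 3, H - a - 2), runif(1, a + 3, W - a - 2))
      }
      ok <- TRUE
      if (!is.null(prev) && nrow(prev) > 0L) {
        dd <- sqrt((prev[, 1L] - cen[1L])^2 + (prev[, 2L] - cen[2L])^2)
        ok <- all(dd > prev[, 3L] + a + 4)
      }
      if (ok) { centers[i, ] <- cen; prev <- rbind(prev, c(cen, a)); placed <- TRUE; break }
    }
    if (!placed) stop("could not place all objects without overlap; ",
                      "reduce n_organoids or sizes")
  }
  centers
}

# gaussian blur via EBImage (column-major transpose handled here)
blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m)), sigma = sigma)))
}

#' Generate one synthetic organoid scene with exact ground truth
#'
#' Renders in-focus organoids (bright lumen, dark rim) and out-of-focus
#' distractors (blurred, low contrast) on a noisy background. The
#' ground-truth mask is the union of the in-focus organoid rasterizations
#' only — distractors are excluded, matching the annotation rule that
#' out-of-focus objects are not organoids. Border-cropped and small objects
#' ARE in the truth; the selection filters are applied downstream.
#'
#' @param config a [sim_config()].
#' @return list with \code{image} (an [organoid_image()]), \code{mask}
#'   (logical matrix), and \code{objects} (data.frame of every rendered
#'   entity: center, semi-axes, orientation, flags, analytic area and
#'   eccentricity).
#' @export
generate_scene <- function(config) {
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  H <- cfg$height; W <- cfg$width
  n <- cfg$n_organoids; nd <- cfg$n_outfocus_distractors

  # an unlucky size draw can be unplaceable without overlap; redraw the
  # geometry a bounded number of times (single RNG stream: deterministic)
  for (attempt in 1:25) {
    geom <- sample_geometry(n, cfg)
    dgeom <- sample_geometry(nd, cfg)
    placed <- tryCatch({
      centers <- place_objects(geom, H, W, cfg$allow_border_crop)
      occupied <- if (n > 0L) cbind(centers, geom$a) else NULL
      dcenters <- place_objects(dgeom, H, W, allow_border = FALSE,
                                occupied = occupied)
      TRUE
    }, error = function(e) {
      if (grepl("larger than image", conditionMessage(e)) || attempt == 25L)
        stop(e)
      FALSE
    })
    if (placed) break
  }

  # background with mild linear illumination ramp
  theta <- runif(1, 0, 2 * pi)
  ramp <- outer((seq_len(H) / H - 0.5) * cos(theta),
                rep(1, W)) +
          outer(rep(1, H), (seq_len(W) / W - 0.5) * sin(theta))
  img <- cfg$bg_level + cfg$illum_gradient * 2 * ramp
  mask <- matrix(FALSE, H, W)
  touches <- logical(n)

  if (n > 0L) {
    for (i in seq_len(n)) {
      E <- rasterize_ellipse(centers[i, ], c(geom$a[i], geom$b[i]),
                             geom$orientation[i], c(H, W))
      inner <- c(max(geom$a[i] - cfg$rim_width_px, 0.5),
                 max(geom$b[i] - cfg$rim_width_px, 0.5))
      I <- rasterize_ellipse(centers[i, ], inner, geom$orientation[i], c(H, W))
      jit <- runif(1, 0.85, 1.15)
      img[E & !I] <- cfg$bg_level - cfg$rim_darkness * jit
      img[I] <- cfg$bg_level + cfg$lumen_brightness * jit
      mask <- mask | E
      touches[i] <- any(E[1L, ]) || any(E[H, ]) || any(E[, 1L]) || any(E[, W])
    }
  }

  if (nd > 0L) {
    for (i in seq_len(nd)) {
      B <- rasterize_ellipse(dcenters[i, ], c(dgeom$a[i], dgeom$b[i]),
                             dgeom$orientation[i], c(H, W))
      layer <- matrix(0, H, W)
      layer[B] <- cfg$distractor_contrast
      img <- img + blur_matrix(layer, sigma = max(dgeom$b[i] / 2, 1))
    }
  }

  if (cfg$noise_sd > 0) img <- img + rnorm(H * W, sd = cfg$noise_sd)
  img <- round(pmin(pmax(img, 0), 255))

  all_centers <- rbind(centers, dcenters)
  all_geom <- rbind(geom, dgeom)
  objects <- data.frame(
    id = seq_len(n + nd),
    center_row = all_centers[, 1L], center_col = all_centers[, 2L],
    a = all_geom$a, b = all_geom$b, orientation = all_geom$orientation,
    is_distractor = rep(c(FALSE, TRUE), c(n, nd)),
    touches_border = c(touches, logical(nd)),
    area_px = pi * all_geom$a * all_geom$b,
    perimeter_px = ellipse_perimeter(all_geom$a, all_geom$b),
    eccentricity = sqrt(1 - (all_geom$b / all_geom$a)^2)
  )
  list(image = organoid_image(img, um_per_px = cfg$um_per_px),
       mask = mask, objects = objects)
}

#' Generate a multi-day growth series with paired pseudo-viability
#'
#' Each well starts from a seeded layout; day over day, semi-axes scale by
#' \code{sqrt(daily_growth)} so projected areas scale by
#' \code{daily_growth}, until an optional plateau day after which growth
#' drops to \code{plateau_growth} (emulating the slow-down that marks the
#' subculture time point). The viability readout is proportional to total
#' true organoid area with multiplicative Gaussian noise:
#' \code{viability = k * total_area * (1 + eps)}, \code{eps ~ N(0, noise^2)}.
#'
#' @param config a [sim_config()]; its \code{seed} seeds the whole series.
#' @param days number of days (>= 2).
#' @param daily_growth day-over-day area growth factor (> 0).
#' @param noise relative noise SD on viability.
#' @param n_wells replicate wells.
#' @param plateau_day optional day from which growth tapers.
#' @param plateau_growth area growth factor applied from the plateau day on.
#' @param k viability units per px^2 of organoid area.
#' @param render if \code{TRUE}, render images/masks per day and well
#'   (geometry and viability are always produced).
#' @return list: \code{records} (data.frame of day, well, count, analytic
#'   total area/perimeter, mean eccentricity, viability) and \code{scenes}
#'   (nested list \code{[[well]][[day]]} of rendered scenes, or NULL).
#' @export
generate_growth_series <- function(config, days, daily_growth, noise = 0.05,
                                   n_wells = 3L, plateau_day = NULL,
                                   plateau_growth = 1.05, k = 1,
                                   render = FALSE) {
  if (days < 2L) stop("days must be >= 2")
  if (daily_growth <= 0) stop("daily_growth must be > 0")
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  H <- cfg$height; W <- cfg$width

  growth_mult <- function(d) {
    if (!is.null(plateau_day) && d >= plateau_day) plateau_growth else daily_growth
  }

  records <- NULL
  scenes <- if (render) vector("list", n_wells) else NULL
  for (w in seq_len(n_wells)) {
    geom1 <- sample_geometry(cfg$n_organoids, cfg)
    if (render) scenes[[w]] <- vector("list", days)
    cum <- 1
    for (d in seq_len(days)) {
      if (d > 1L) cum <- cum * growth_mult(d)
      gd <- geom1
      gd$a <- gd$a * sqrt(cum); gd$b <- gd$b * sqrt(cum)
      total_area <- sum(pi * gd$a * gd$b)
      eps <- rnorm(1L, 0, noise)
      rec <- data.frame(
        day = d, well = w, count = nrow(gd),
        total_area_px = total_area,
        total_perimeter_px = sum(ellipse_perimeter(gd$a, gd$b)),
        mean_eccentricity = if (nrow(gd)) mean(sqrt(1 - (gd$b / gd$a)^2)) else NA_real_,
        viability = k * total_area * (1 + eps))
      records <- rbind(records, rec)
      if (render) {
        # re-layout each day at the day's sizes (growth can invalidate the
        # day-1 layout); rendering reuses the scene machinery
        centers <- place_objects(gd, H, W, cfg$allow_border_crop)
        scn <- render_from_geometry(cfg, gd, centers)
        scn$image$meta$day <- d
        scn$image$meta$well <- as.character(w)
        scenes[[w]][[d]] <- scn
      }
    }
  }
  list(records = records, scenes = scenes)
}

# render an image + truth mask from explicit geometry (no distractors)
render_from_geometry <- function(cfg, geom, centers) {
  H <- cfg$height; W <- cfg$width
  theta <- runif(1, 0, 2 * pi)
  ramp <- outer((seq_len(H) / H - 0.5) * cos(theta), rep(1, W)) +
          outer(rep(1, H), (seq_len(W) / W - 0.5) * sin(theta))
  img <- cfg$bg_level + cfg$illum_gradient * 2 * ramp
  mask <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(geom))) {
    E <- rasterize_ellipse(centers[i, ], c(geom$a[i], geom$b[i]),
                           geom$orientation[i], c(H, W))
    inner <- c(max(geom$a[i] - cfg$rim_width_px, 0.5),
               max(geom$b[i] - cfg$rim_width_px, 0.5))
    I <- rasterize_ellipse(centers[i, ], inner, geom$orientation[i], c(H, W))
    jit <- runif(1, 0.85, 1.15)
    img[E & !I] <- cfg$bg_level - cfg$rim_darkness * jit
    img[I] <- cfg$bg_level + cfg$lumen_brightness * jit
    mask <- mask | E
  }
  if (cfg$noise_sd > 0) img <- img + rnorm(H * W, sd = cfg$noise_sd)
  img <- round(pmin(pmax(img, 0), 255))
  list(image = organoid_image(img, um_per_px = cfg$um_per_px), mask = mask)
}

#' Simulate independent wells with viability proportional to organoid area
#'
#' Emulates the plate designs used for viability correlation studies: wells
#' are drawn across culture days (sizes scaled by a per-day growth factor)
#' and, optionally, across a two-fold serial dilution of seeding density.
#' Viability is \code{k * total_true_area * (1 + eps)},
#' \code{eps ~ N(0, noise^2)}. Only geometry is generated — per-well
#' summaries come from the analytic truth, which is what makes the design
#' an oracle for the correlation analytics.
#'
#' @param config a [sim_config()]; its \code{seed} seeds the plate.
#' @param n_wells number of wells.
#' @param days number of culture days the wells are spread across.
#' @param daily_growth day-over-day area growth factor.
#' @param noise relative viability noise SD.
#' @param dilution_levels if > 1, wells are additionally spread across a
#'   two-fold serial dilution: at level L the organoid count halves L-1
#'   times (rounded, min 1).
#' @param k viability units per px^2.
#' @return data.frame: well, day, dilution_level, count, total_area_px,
#'   total_perimeter_px, mean_eccentricity, viability.
#' @export
simulate_wells <- function(config, n_wells = 90L, days = 5L,
                           daily_growth = 1.8, noise = 0.05,
                           dilution_levels = 1L, k = 1) {
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  out <- NULL
  for (w in seq_len(n_wells)) {
    day <- ((w - 1L) %% days) + 1L
    lev <- (((w - 1L) %/% days) %% dilution_levels) + 1L
    n_org <- max(1L, round(cfg$n_organoids / 2^(lev - 1L)))
    geom <- sample_geometry(n_org, cfg)
    g <- daily_growth^(day - 1L)
    geom$a <- geom$a * sqrt(g); geom$b <- geom$b * sqrt(g)
    total_area <- sum(pi * geom$a * geom$b)
    out <- rbind(out, data.frame(
      well = w, day = day, dilution_level = lev, count = n_org,
      total_area_px = total_area,
      total_perimeter_px = sum(ellipse_perimeter(geom$a, geom$b)),
      mean_eccentricity = mean(sqrt(1 - (geom$b / geom$a)^2)),
      viability = k * total_area * (1 + rnorm(1L, 0, noise))))
  }
  out
}
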