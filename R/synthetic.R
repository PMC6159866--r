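# Seeded synthetic-micrograph generators with exact ground truth.
# They emulate the three kinds of electron-micrograph input the morphometry
# needs: cross-section bump profiles of papillose epidermal cells, top views
# of the nano-wax tubule mat (bright tips), and partially eroded wax
# coverage maps. Ground truth is always measured from the emitted object
# (mask pixel counts, high-resolution arc length), never assumed from the
# request parameters.

# evaluate code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# one-sided exponential texture snapped to a 256-bin boundary: the binned
# histogram mode then sits in the full bin just below the level, so pixels
# brighter than that bin's center are (almost) only classes above this one
edge_level <- function(n, level, spread) {
  top <- ceiling(level * 256) / 256
  # exponential truncated at `top` so the texture stays positive (no clamp
  # spike at zero that could masquerade as a histogram peak)
  top - stats::qexp(stats::runif(n) * stats::pexp(top, 1 / spread), 1 / spread)
}

#' Generate a synthetic epidermal-bump cross-section
#'
#' Builds an analytic train of identical bumps (papillose epidermal cells;
#' summer defaults: height 8 um, width 25 um), samples it as a clean
#' [surface_profile()], computes the true roughness by numerical arc length
#' at 10x the emitted sampling density, and renders a binary-ish
#' cross-section raster (tissue bright) with optional SEM-like intensity
#' noise.
#'
#' @param bump_height_um,bump_width_um Bump height and width, micrometres.
#' @param shape `"sinusoid"`, `"gaussian"` (sd = width/6) or `"hemisphere"`
#'   (semi-ellipse; a true semicircle when height = width/2).
#' @param count Number of bumps tiled along the axis.
#' @param base_um Tissue thickness below the bumps (raster margin).
#' @param dx_um Horizontal sampling of the emitted profile.
#' @param raster_pixel_um Pixel size of the rendered raster.
#' @param noise_sd Intensity noise (sd, on the \[0, 1\] scale) added to the
#'   raster; the emitted profile stays clean.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return List with `profile` ([surface_profile()]), `true_r` (dimensionless
#'   roughness from high-resolution arc length) and `raster`
#'   ([grayscale_image()]).
#' @export
gen_bump_profile <- function(bump_height_um = 8, bump_width_um = 25,
                             shape = c("sinusoid", "gaussian", "hemisphere"),
                             count = 6L, base_um = 3, dx_um = 0.05,
                             raster_pixel_um = 0.1, noise_sd = 0.03,
                             seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(bump_height_um >= 0, bump_width_um > 0, count >= 1,
            dx_um > 0, raster_pixel_um > 0, noise_sd >= 0)
  H <- bump_height_um; W <- bump_width_um
  hfun <- function(x) {
    u <- x %% W
    switch(shape,
      sinusoid = H * sin(pi * u / W),
      gaussian = H * exp(-(u - W / 2)^2 / (2 * (W / 6)^2)),
      hemisphere = H * sqrt(pmax(0, 1 - ((u - W / 2) / (W / 2))^2)))
  }
  total <- count * W
  x <- seq(0, total, by = dx_um)
  profile <- surface_profile(base_um + hfun(x), dx_um)
  # ground truth from a 10x denser numerical arc length of the same curve
  xf <- seq(0, total, by = dx_um / 10)
  hf <- hfun(xf)
  true_r <- sum(sqrt(diff(xf)^2 + diff(hf)^2)) / (total)
  # raster rendering: column centers sample the curve, rows fill downward
  px <- raster_pixel_um
  nc <- ceiling(total / px)
  nr <- ceiling((base_um + H + 2) / px)
  xc <- (seq_len(nc) - 0.5) * px
  hc <- base_um + hfun(xc)
  rowh <- (nr - seq_len(nr) + 0.5) * px  # height of each row's pixel center
  fg <- outer(rowh, hc, `<=`)
  raster <- with_seed(seed, {
    m <- ifelse(fg, 0.85, 0.15)
    if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
    matrix(pmin(pmax(m, 0), 1), nr, nc)
  })
  list(profile = profile, true_r = true_r,
       raster = grayscale_image(raster, px))
}

#' Generate a synthetic nano-wax tip top view
#'
#' Dark leaf floor, mid-gray wax texture and non-overlapping bright discs
#' standing for the wax tubule tips the droplet would touch. Discs are
#' placed by random sequential adsorption until their summed pixel area
#' reaches the requested fraction; `true_phi` is counted exactly from the
#' placed mask. The floor and wax textures use one-sided (downward-skewed)
#' intensity spreads so their histogram modes sit at the level itself, and
#' the tips span a broad brightness band above the wax level without a mode
#' of their own — the histogram then shows exactly the two material peaks
#' (floor, wax) with the liquid/solid contact area brighter than the upper
#' one, which is what makes "brighter than the upper peak" a faithful tip
#' count. Gaussian intensity noise is added last.
#'
#' @param target_phi Requested tip areal fraction, in \[0, 1).
#' @param tip_radius_px Disc radius in pixels.
#' @param size_px Image side length in pixels (square image).
#' @param pixel_size_um Micrometres per pixel.
#' @param levels Named intensities `floor`, `wax`, `tip`, strictly
#'   increasing on \[0, 1\].
#' @param wax_coverage Fraction of the non-tip background carrying wax
#'   texture rather than bare floor.
#' @param noise_sd Final Gaussian intensity noise (sd).
#' @param seed Integer seed.
#' @return List with `image` ([grayscale_image()]), `true_phi` (exact mask
#'   fraction) and `tip_mask` (logical matrix).
#' @export
gen_waxtip_image <- function(target_phi = 0.25, tip_radius_px = 6L,
                             size_px = 512L, pixel_size_um = 0.02,
                             levels = c(floor = 0.15, wax = 0.45, tip = 0.85),
                             wax_coverage = 0.2, noise_sd = 0.002,
                             seed = 1L) {
  stopifnot(target_phi >= 0, target_phi < 1, tip_radius_px >= 1,
            size_px > 4 * tip_radius_px,
            all(diff(levels[c("floor", "wax", "tip")]) > 0))
  if (target_phi > 0.45)
    stop_leafwet(sprintf(
      "packing failure: target_phi = %.2f exceeds what non-overlapping discs can reach",
      target_phi), "leafwet_packing")
  n <- as.integer(size_px); r <- tip_radius_px
  with_seed(seed, {
    # wax texture mask: thresholded smoothed noise
    field <- EBImage::imageData(EBImage::gblur(
      EBImage::Image(matrix(stats::rnorm(n * n), n, n)), sigma = 4))
    wax_mask <- field > stats::quantile(field, 1 - wax_coverage)
    base <- matrix(edge_level(n * n, levels[["floor"]], 0.12), n, n)
    base[wax_mask] <- edge_level(sum(wax_mask), levels[["wax"]], 0.12)
    # random sequential adsorption of non-overlapping discs
    tip_mask <- matrix(FALSE, n, n)
    disc_px <- sum(outer(-r:r, -r:r, function(a, b) a^2 + b^2 <= r^2))
    area <- n * n
    centers <- matrix(numeric(0), ncol = 2)
    placed <- 0
    attempts <- 0L
    max_attempts <- max(2000L, 400L * ceiling(target_phi * area / disc_px))
    while (placed * disc_px / area < target_phi && attempts < max_attempts) {
      attempts <- attempts + 1L
      cy <- stats::runif(1, r + 1, n - r)
      cx <- stats::runif(1, r + 1, n - r)
      if (nrow(centers) &&
          min((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) < (2 * r + 1)^2)
        next
      centers <- rbind(centers, c(cy, cx))
      placed <- placed + 1
    }
    if (placed * disc_px / area < target_phi - 0.005)
      stop_leafwet(sprintf(
        "packing failure: reached phi = %.3f of requested %.3f",
        placed * disc_px / area, target_phi), "leafwet_packing")
    if (nrow(centers)) {
      for (k in seq_len(nrow(centers))) {
        cy <- centers[k, 1]; cx <- centers[k, 2]
        ys <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
        xs <- max(1, floor(cx - r)):min(n, ceiling(cx + r))
        d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
        tip_mask[ys, xs] <- tip_mask[ys, xs] | (d2 <= r^2)
      }
    }
    true_phi <- mean(tip_mask)
    # tips: broad uniform brightness band centred loosely on the tip level,
    # bounded below safely above the wax edge so no tip hides under the peak
    tip_lo <- ceiling(levels[["wax"]] * 256) / 256 + 3 / 256
    base[tip_mask] <- stats::runif(sum(tip_mask), tip_lo,
                                   min(1, 2 * levels[["tip"]] - tip_lo))
    if (noise_sd > 0)
      base <- base + stats::rnorm(length(base), 0, noise_sd)
    list(image = grayscale_image(matrix(pmin(pmax(base, 0), 1), n, n),
                                 pixel_size_um),
         true_phi = true_phi, tip_mask = tip_mask)
  })
}

# paint a disc into a logical matrix; returns the matrix
paint_disc <- function(mask, cy, cx, r, value = TRUE) {
  n_r <- nrow(mask); n_c <- ncol(mask)
  ys <- max(1, cy - r):min(n_r, cy + r)
  xs <- max(1, cx - r):min(n_c, cx + r)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  mask[ys, xs][d2 <= r^2] <- value
  mask
}

#' Generate a synthetic wax-erosion coverage map
#'
#' A smooth correlated random field is thresholded at the quantile giving
#' the requested intact fraction; `true_alpha` is counted from that mask
#' before any speckle is injected. Sub-threshold speckles of both polarities
#' (intact flecks below 5 um^2 inside eroded regions, eroded pinholes below
#' 22.5 um^2 inside intact regions) are then added to exercise the
#' morphometry area filters; a correct filter recovers the pre-speckle
#' fraction. Intensities: intact bright, eroded dark, Gaussian noise drawn
#' before speckle injection so the speckled and speckle-free renderings of
#' the same seed differ only at speckle pixels.
#'
#' @param target_alpha Requested intact areal fraction, in \[0, 1\].
#' @param size_px Image side length, pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @param correlation_um Correlation length of the erosion pattern.
#' @param levels Named intensities `eroded`, `intact`.
#' @param noise_sd Gaussian intensity noise (sd).
#' @param n_speckle Number of speckles attempted per polarity.
#' @param seed Integer seed.
#' @return List with `image`, `true_alpha` (pre-speckle mask fraction),
#'   `mask` (pre-speckle logical intact mask) and `image_clean` (the
#'   speckle-free rendering of the same field and noise).
#' @export
gen_erosion_image <- function(target_alpha = 0.46, size_px = 384L,
                              pixel_size_um = 0.2, correlation_um = 6,
                              levels = c(eroded = 0.30, intact = 0.75),
                              noise_sd = 0.02, n_speckle = 25L, seed = 1L) {
  stopifnot(target_alpha >= 0, target_alpha <= 1, size_px >= 32,
            pixel_size_um > 0, levels[["intact"]] > levels[["eroded"]])
  n <- as.integer(size_px)
  with_seed(seed, {
    mask <- if (target_alpha == 1) {
      matrix(TRUE, n, n)
    } else if (target_alpha == 0) {
      matrix(FALSE, n, n)
    } else {
      field <- EBImage::imageData(EBImage::gblur(
        EBImage::Image(matrix(stats::rnorm(n * n), n, n)),
        sigma = correlation_um / pixel_size_um))
      field > stats::quantile(field, 1 - target_alpha)
    }
    true_alpha <- mean(mask)
    noise <- if (noise_sd > 0) stats::rnorm(n * n, 0, noise_sd) else 0
    render <- function(m) {
      v <- ifelse(m, levels[["intact"]], levels[["eroded"]]) + noise
      grayscale_image(matrix(pmin(pmax(v, 0), 1), n, n), pixel_size_um)
    }
    image_clean <- render(mask)
    # speckle injection (after ground-truth recording)
    spk <- mask
    # radii in px kept strictly under the 5 / 22.5 um^2 area filters
    r_fleck <- max(1L, floor(sqrt(5 / pi) / pixel_size_um * 0.6))
    r_hole <- max(1L, floor(sqrt(22.5 / pi) / pixel_size_um * 0.6))
    place_speckles <- function(m, host, r, value) {
      for (k in seq_len(n_speckle)) {
        for (try in 1:20) {
          cy <- sample(seq(r + 2, n - r - 1), 1)
          cx <- sample(seq(r + 2, n - r - 1), 1)
          patch <- m[(cy - r - 1):(cy + r + 1), (cx - r - 1):(cx + r + 1)]
          if (all(patch == host)) {       # whole disc + margin inside host
            m <- paint_disc(m, cy, cx, r, value)
            break
          }
        }
      }
      m
    }
    if (n_speckle > 0 && target_alpha > 0 && target_alpha < 1) {
      spk <- place_speckles(spk, host = FALSE, r = r_fleck, value = TRUE)
      spk <- place_speckles(spk, host = TRUE, r = r_hole, value = FALSE)
    }
    list(image = render(spk), true_alpha = true_alpha, mask = mask,
         image_clean = image_clean)
  })
}

#' Generate noisy goniometer angle readings
#'
#' Emulates replicate tilted-plate measurements: advancing/receding pairs
#' drawn around the true angles with Gaussian scatter, truncated to (0, 180)
#' degrees and to advancing > receding (invalid draws are redrawn).
#'
#' @param true_adv,true_rec True advancing/receding angles, degrees,
#'   `true_rec < true_adv`.
#' @param sd Measurement scatter, degrees (>= 0).
#' @param n Number of replicate pairs.
#' @param seed Integer seed.
#' @return Data frame with columns `theta_adv`, `theta_rec`, `theta_bar`.
#' @export
gen_goniometer_readings <- function(true_adv, true_rec, sd = 4, n = 10L,
                                    seed = 1L) {
  stopifnot(true_rec < true_adv, true_rec > 0, true_adv < 180, sd >= 0, n >= 1)
  with_seed(seed, {
    adv <- numeric(n); rec <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        a <- stats::rnorm(1, true_adv, sd)
        r <- stats::rnorm(1, true_rec, sd)
        if (a > r && r > 0 && a < 180) break
      }
      adv[i] <- a; rec[i] <- r
    }
    data.frame(theta_adv = adv, theta_rec = rec,
               theta_bar = (adv + rec) / 2)
  })
}
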