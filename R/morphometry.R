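# Morphometry: estimate the three wetting-model parameters from calibrated
# grayscale micrographs.
#   r_micro   — arc-length/chord ratio of a surface profile traced from a
#               cross-section image
#   phi_nano  — fraction of pixels brighter than the upper histogram peak in
#               a top-view image of the wax tubule mat
#   alpha     — intact-wax areal fraction after physical-unit area filtering
#               of a segmented top-view erosion map

# centered moving average with edge renormalization (window w, odd)
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1, w)
  num <- stats::filter(c(rep(0, w), x, rep(0, w)), k, sides = 2)
  den <- stats::filter(c(rep(0, w), rep(1, length(x)), rep(0, w)), k, sides = 2)
  idx <- seq_along(x) + w
  as.numeric(num[idx] / den[idx])
}

otsu_threshold <- function(v) {
  EBImage::otsu(EBImage::Image(matrix(pmin(pmax(v, 0), 1), nrow = 1)),
                range = c(0, 1), levels = 256L)
}

label_components <- function(mask) {
  # 4-connected labelling keeps diagonally touching regions distinct,
  # matching the conservative reading of the physical area filters
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(lab) <- "integer"
  lab
}

#' Trace the top surface boundary from a cross-section micrograph
#'
#' Globally thresholds the image into tissue (foreground) and vacuum, drops
#' small spurious foreground specks, and records per image column the height
#' of the topmost foreground pixel, measured upward from the bottom image
#' edge at pixel centers. Columns with no foreground (fewer than 10% of
#' columns) are filled by linear interpolation from their neighbours; more
#' than 10% empty columns aborts with an error. The traced boundary is
#' smoothed with a short moving average to suppress single-pixel
#' quantization stair-steps, which would otherwise bias the downstream
#' arc-length roughness upward.
#'
#' @param image A [grayscale_image()] cross-section view.
#' @param foreground `"bright"` (default) if tissue is brighter than the
#'   background, `"dark"` otherwise.
#' @param threshold Global intensity threshold in \[0, 1\]; `NULL` (default)
#'   uses Otsu's automatic bimodal split.
#' @param min_object_px Foreground connected components smaller than this
#'   many pixels are treated as noise and removed before tracing.
#' @param smooth_window Moving-average window (columns) applied to the traced
#'   boundary; set to 1 to disable.
#' @return A [surface_profile()] with `dx_um` equal to the pixel size.
#' @export
extract_surface_profile <- function(image, foreground = c("bright", "dark"),
                                    threshold = NULL, min_object_px = 20L,
                                    smooth_window = 5L) {
  stopifnot(inherits(image, "grayscale_image"))
  foreground <- match.arg(foreground)
  v <- image$pixels
  if (foreground == "dark") v <- 1 - v
  thr <- if (is.null(threshold)) otsu_threshold(as.vector(v)) else threshold
  mask <- v > thr
  if (min_object_px > 0 && any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_object_px)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  nr <- nrow(mask); nc <- ncol(mask)
  top <- apply(mask, 2, function(col) {
    i <- which(col)
    if (length(i)) i[1] else NA_integer_
  })
  empty <- is.na(top)
  if (mean(empty) > 0.10)
    stop_leafwet(sprintf(
      "profile not extractable: %.0f%% of columns contain no foreground",
      100 * mean(empty)), "leafwet_profile")
  if (any(empty)) {
    filled <- stats::approx(which(!empty), top[!empty], xout = seq_len(nc),
                            rule = 2)$y
    top[empty] <- filled[empty]
  }
  heights <- (nr - top + 0.5) * image$pixel_size_um
  heights <- moving_average(heights, as.integer(smooth_window))
  surface_profile(heights, image$pixel_size_um)
}

#' Microscale roughness from a surface profile
#'
#' The roughness is the profile arc length over its horizontal extent:
#' `r = sum(sqrt(dx^2 + dh^2)) / ((n - 1) * dx)`. It is 1 exactly when the
#' profile is constant and >= 1 always. The line-profile ratio is used
#' directly as `r_micro` (no squaring for areal isotropy): the model
#' parameter is calibrated against cross-section profiles, so the profile
#' ratio is the measured quantity.
#'
#' @param profile A [surface_profile()].
#' @return Roughness estimate, dimensionless, >= 1.
#' @examples
#' roughness_from_profile(surface_profile(rep(2, 100), 0.1))  # flat: 1
#' @export
roughness_from_profile <- function(profile) {
  stopifnot(inherits(profile, "surface_profile"))
  dh <- diff(profile$heights)
  sum(sqrt(profile$dx_um^2 + dh^2)) / ((length(profile$heights) - 1) * profile$dx_um)
}

# locate the two dominant, separated peaks of an intensity histogram;
# returns bin indices (1..n_bins) sorted ascending, or NULL if fewer than 2
find_two_peaks <- function(counts, smooth_window = 5L, min_separation = 20L,
                           min_height_frac = 0.05) {
  s <- moving_average(counts, smooth_window)
  n <- length(s)
  # interior local maxima of the smoothed histogram (plateau-tolerant);
  # stray counts in a distribution tail make spurious tiny maxima, so a
  # qualifying peak must reach a fraction of the dominant peak's height
  cand <- which(s >= c(-Inf, s[-n]) & s > c(s[-1], -Inf))
  cand <- cand[s[cand] >= min_height_frac * max(s)]
  if (!length(cand)) return(NULL)
  # refine each candidate to the raw-count argmax nearby; ties go to the
  # brighter bin so a flat-topped smoothed peak lands on the true mode
  cand <- vapply(cand, function(i) {
    win <- max(1L, i - 2L):min(n, i + 2L)
    w <- win[counts[win] == max(counts[win])]
    w[length(w)]
  }, integer(1))
  cand <- unique(cand)
  cand <- cand[order(s[cand], cand, decreasing = TRUE)]
  picked <- integer(0)
  for (i in cand) {
    if (all(abs(i - picked) >= min_separation)) picked <- c(picked, i)
    if (length(picked) == 2L) break
  }
  if (length(picked) < 2L) return(NULL)
  sort(picked)
}

#' Wax-tip contact fraction from a top-view micrograph
#'
#' In a top view of the nano-wax tubule mat the droplet is assumed to touch
#' only the tubule tips, which image brighter than both the wax body and the
#' leaf floor. The intensity histogram (256 bins) typically shows two
#' dominant peaks — the dark leaf floor and the mid-gray wax; the pixels
#' strictly brighter than the upper peak are taken as the liquid/solid
#' contact area, so `phi_nano` is their areal fraction.
#'
#' @param image A [grayscale_image()] top view.
#' @param smooth_window Moving-average window (bins) for histogram smoothing.
#' @param min_separation Minimum distance (bins) between the two peaks.
#' @return `phi_nano` in \[0, 1\], with attributes `peaks` (the two peak bin
#'   indices) and `threshold` (the intensity cut used).
#' @export
phi_from_topview <- function(image, smooth_window = 5L, min_separation = 20L) {
  stopifnot(inherits(image, "grayscale_image"))
  v <- as.vector(image$pixels)
  n_bins <- 256L
  bins <- pmin(pmax(ceiling(v * n_bins), 1L), n_bins)
  counts <- tabulate(bins, n_bins)
  peaks <- find_two_peaks(counts, smooth_window, min_separation)
  if (is.null(peaks))
    stop_leafwet(
      "histogram has no two separated peaks; cannot locate the wax level",
      "leafwet_unimodal")
  cut <- (peaks[2] - 0.5) / n_bins  # center of the upper peak's bin
  phi <- mean(v > cut)
  structure(phi, peaks = peaks, threshold = cut)
}

#' Physical-unit area filter for intact/eroded wax masks
#'
#' Reassigns small connected components to the surrounding class rather than
#' deleting them, so the total area (the denominator of `alpha`) is stable:
#' intact patches below `min_intact_um2` become eroded, then eroded patches
#' below `min_eroded_um2` become intact. Idempotent: a second application
#' changes nothing.
#'
#' @param mask Logical matrix, `TRUE` = intact wax.
#' @param pixel_size_um Micrometres per pixel.
#' @param min_intact_um2 Minimum intact patch area kept, in square
#'   micrometres (default 5).
#' @param min_eroded_um2 Minimum eroded patch area kept, in square
#'   micrometres (default 22.5).
#' @return The filtered logical mask.
#' @export
filter_small_regions <- function(mask, pixel_size_um,
                                 min_intact_um2 = 5, min_eroded_um2 = 22.5) {
  stopifnot(is.logical(mask), is.matrix(mask), pixel_size_um > 0)
  px_area <- pixel_size_um^2
  reassign <- function(m, min_um2) {
    if (!any(m)) return(m)
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes * px_area < min_um2)
    if (length(small)) m[lab %in% small] <- FALSE
    m
  }
  mask <- reassign(mask, min_intact_um2)          # small intact -> eroded
  !reassign(!mask, min_eroded_um2)                # small eroded -> intact
}

#' Intact-wax areal fraction from a top-view micrograph
#'
#' Segments the image into intact wax (bright) and eroded (dark) classes by
#' a global threshold, cleans the segmentation with the physical area
#' filters of [filter_small_regions()] (patches below 5 um^2 of intact or
#' 22.5 um^2 of eroded area are treated as segmentation speckle), and
#' returns the intact areal fraction.
#'
#' @param image A [grayscale_image()] with a trustworthy `pixel_size_um`
#'   (the area filters are in physical units).
#' @param threshold Global intensity threshold; `NULL` (default) uses Otsu's
#'   automatic bimodal split.
#' @param intact `"bright"` (default) if intact wax images brighter than
#'   eroded regions; `"dark"` flips the polarity.
#' @param min_intact_um2,min_eroded_um2 Area filters, square micrometres.
#' @return `alpha` in \[0, 1\], with attributes `threshold` and `qa` (a
#'   character vector of warnings, e.g. when one class is empty).
#' @export
alpha_from_topview <- function(image, threshold = NULL,
                               intact = c("bright", "dark"),
                               min_intact_um2 = 5, min_eroded_um2 = 22.5) {
  stopifnot(inherits(image, "grayscale_image"))
  intact <- match.arg(intact)
  v <- image$pixels
  if (intact == "dark") v <- 1 - v
  if (is.null(threshold)) {
    # a uniform (single-class) image has no bimodal split: Otsu would cut
    # through the noise at ~50%. Detect unimodality and assign the whole
    # image to one class by its brightness side.
    counts <- tabulate(pmin(pmax(ceiling(as.vector(v) * 256), 1L), 256L), 256L)
    if (is.null(find_two_peaks(counts))) {
      alpha <- if (mean(v) > 0.5) 1 else 0
      return(structure(alpha, threshold = NA_real_,
                       qa = sprintf("unimodal image: assigned wholly %s",
                                    if (alpha == 1) "intact" else "eroded")))
    }
    threshold <- otsu_threshold(as.vector(v))
  }
  thr <- threshold
  mask <- v > thr
  mask <- filter_small_regions(mask, image$pixel_size_um,
                               min_intact_um2, min_eroded_um2)
  alpha <- mean(mask)
  qa <- character(0)
  if (alpha == 0) qa <- c(qa, "no intact class after filtering (alpha = 0)")
  if (alpha == 1) qa <- c(qa, "no eroded class after filtering (alpha = 1)")
  structure(alpha, threshold = thr, qa = qa)
}

#' Run all three morphometry estimators over replicate micrographs
#'
#' Each image carries a role: `cross_section` feeds the roughness estimator,
#' `topview_wax` the wax-tip fraction estimator, `topview_erosion` the
#' intact-fraction estimator. Replicates are averaged (arithmetic mean, with
#' the sample standard deviation reported); images on which an estimator
#' fails are recorded as QA flags and excluded, but every role must yield at
#' least one valid estimate.
#'
#' @param images List of [grayscale_image()] objects.
#' @param roles Character vector (same length) with values in
#'   `cross_section`, `topview_wax`, `topview_erosion`.
#' @param ids Optional image identifiers for QA messages (default index).
#' @param ... Passed on to the individual estimators (matched by role:
#'   `extract_surface_profile` options for cross sections are not
#'   forwarded; use the estimators directly for fine control).
#' @return A list of class `morphometry_result` with elements `morphology`
#'   (a [surface_morphology()]), `estimates` (per-parameter mean, sd, n) and
#'   `qa` (character vector of per-image failures).
#' @export
morphometry_pipeline <- function(images, roles, ids = NULL, ...) {
  stopifnot(is.list(images), length(images) == length(roles))
  if (length(images) == 0L) stop("empty image set")
  roles <- match.arg(roles, c("cross_section", "topview_wax",
                              "topview_erosion"), several.ok = TRUE)
  if (is.null(ids)) ids <- as.character(seq_along(images))
  need <- c("cross_section", "topview_wax", "topview_erosion")
  missing_roles <- setdiff(need, roles)
  if (length(missing_roles))
    stop_leafwet(sprintf("manifest is missing role(s): %s",
                         paste(missing_roles, collapse = ", ")),
                 "leafwet_missing_role")
  qa <- character(0)
  run_one <- function(img, role, id) {
    tryCatch(switch(role,
      cross_section = roughness_from_profile(extract_surface_profile(img)),
      topview_wax = as.numeric(phi_from_topview(img)),
      topview_erosion = {
        a <- alpha_from_topview(img)
        qa <<- c(qa, sprintf("[%s %s] %s", role, id, attr(a, "qa")))
        as.numeric(a)
      }),
      error = function(e) {
        qa <<- c(qa, sprintf("[%s %s] %s", role, id, conditionMessage(e)))
        NA_real_
      })
  }
  vals <- mapply(run_one, images, roles, ids)
  agg <- function(role) {
    x <- vals[roles == role]
    x <- x[!is.na(x)]
    if (!length(x))
      stop_leafwet(sprintf("no valid estimate for role '%s'", role),
                   "leafwet_missing_role")
    c(mean = mean(x), sd = stats::sd(x), n = length(x))
  }
  est <- list(r_micro = agg("cross_section"),
              phi_nano = agg("topview_wax"),
              alpha = agg("topview_erosion"))
  morph <- surface_morphology(max(1, est$r_micro["mean"]),
                              min(1, max(0, est$phi_nano["mean"])),
                              min(1, max(0, est$alpha["mean"])))
  structure(list(morphology = morph, estimates = est, qa = qa),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("morphometry result\n")
  for (p in names(x$estimates)) {
    e <- x$estimates[[p]]
    cat(sprintf("  %-8s %.4f (sd %.4f, n = %d)\n", p, e["mean"],
                e["sd"], as.integer(e["n"])))
  }
  if (length(x$qa)) cat("  QA:", paste(x$qa, collapse = "; "), "\n")
  invisible(x)
}
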