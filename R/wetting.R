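# Closed-form wetting physics: Wenzel / Cassie-Baxter limits, the combined
# two-tier model with an intact-wax fraction, predicted hysteresis, and
# nanoscale meniscus penetration.

#' Wenzel apparent contact angle
#'
#' A droplet that fully wets a rough texture (no trapped air) obeys
#' `cos(theta_star) = r * cos(theta)`, where `r >= 1` is the ratio of actual
#' to projected surface area and `theta` the contact angle on the flat
#' material.
#'
#' @param r Roughness, dimensionless, >= 1.
#' @param theta Flat-surface contact angle, degrees, in (0, 180).
#' @return Apparent contact angle in degrees.
#' @details When `|r * cos(theta)| > 1` the Wenzel relation has no solution
#'   (the droplet would fully spread or fully ball up); this is raised as an
#'   error of class `leafwet_nonphysical` rather than clamped, so parameter
#'   sweeps see the regime breakdown explicitly.
#' @examples
#' wenzel_angle(1.13, 101)  # heat-treated leaf, wax gone: ~102.5 deg
#' @export
wenzel_angle <- function(r, theta) {
  stopifnot(is.numeric(r), is.numeric(theta))
  if (r < 1) stop("'r' must be >= 1")
  if (theta <= 0 || theta >= 180) stop("'theta' must lie in (0, 180) degrees")
  x <- r * cos(deg2rad(theta))
  if (abs(x) > 1)
    stop_leafwet(sprintf(
      "non-physical Wenzel regime: |r * cos(theta)| = %.4f > 1", abs(x)),
      "leafwet_nonphysical")
  rad2deg(acos(x))
}

#' Cassie-Baxter apparent contact angle
#'
#' A droplet resting partly on trapped air obeys
#' `cos(theta_star) = phi_s * (cos(theta) + 1) - 1`, with `phi_s` the areal
#' fraction of solid in contact with the liquid.
#'
#' @param phi_s Solid/liquid contact fraction, in \[0, 1\].
#' @param theta Flat-surface contact angle, degrees, in (0, 180).
#' @return Apparent contact angle in degrees (always defined for valid
#'   inputs; `phi_s = 0` gives 180).
#' @examples
#' cassie_baxter_angle(0.25, 101)  # ~142.9 deg
#' @export
cassie_baxter_angle <- function(phi_s, theta) {
  stopifnot(is.numeric(phi_s), is.numeric(theta))
  if (phi_s < 0 || phi_s > 1) stop("'phi_s' must lie in [0, 1]")
  if (theta <= 0 || theta >= 180) stop("'theta' must lie in (0, 180) degrees")
  rad2deg(acos(phi_s * (cos(deg2rad(theta)) + 1) - 1))
}

#' Combined two-tier apparent contact angle
#'
#' Apparent contact angle for a surface that is Wenzel at the microscale
#' (epidermal bumps, roughness `r_micro`) and Cassie-Baxter at the nanoscale
#' over the fraction `alpha` of the area where wax tubules are intact:
#'
#' `cos(theta_star) = alpha * r * (phi * (cos(theta) + 1) - 1)
#'                    + (1 - alpha) * r * cos(theta)`
#'
#' With `alpha = 1` this reduces algebraically to
#' `r * phi * cos(theta) - r * (1 - phi)` (the uniformly wax-covered green
#' leaf); with `alpha = 0` it is the pure Wenzel relation (wax fully eroded
#' or removed).
#'
#' @param morph A [surface_morphology()] object (or a list with fields
#'   `r_micro`, `phi_nano`, `alpha`).
#' @param theta Flat-wax contact angle, degrees, in (0, 180).
#' @return Apparent contact angle in degrees.
#' @examples
#' combined_angle(surface_morphology(1.16, 0.25, 1), 101)     # green, ~158
#' combined_angle(surface_morphology(1.07, 0.25, 0.46), 101)  # brown, ~120
#' @export
combined_angle <- function(morph, theta) {
  morph <- as_surface_morphology(morph)
  if (theta <= 0 || theta >= 180) stop("'theta' must lie in (0, 180) degrees")
  ct <- cos(deg2rad(theta))
  x <- morph$alpha * morph$r_micro * (morph$phi_nano * (ct + 1) - 1) +
    (1 - morph$alpha) * morph$r_micro * ct
  if (abs(x) > 1)
    stop_leafwet(sprintf(
      "non-physical regime: |cos(theta_star)| = %.4f > 1", abs(x)),
      "leafwet_nonphysical")
  rad2deg(acos(x))
}

as_surface_morphology <- function(x) {
  if (inherits(x, "surface_morphology")) return(x)
  if (is.list(x) && all(c("r_micro", "phi_nano", "alpha") %in% names(x)))
    return(surface_morphology(x$r_micro, x$phi_nano, x$alpha))
  stop("'morph' must be a surface_morphology object")
}

#' Predicted contact-angle hysteresis on a leaf
#'
#' Propagates the hysteresis measured on the flat wax surface
#' (`delta_flat = theta_adv - theta_rec`) through the two-tier model. The
#' default `"printed"` form is
#'
#' `delta_leaf = r * (alpha * (phi - 1) + 1) * delta_flat *
#'               sin(theta_star) / sin(theta_flat)`
#'
#' The `"derivative"` variant places the sine factors the other way around,
#' `sin(theta_flat) / sin(theta_star)`, which is what differentiating the
#' combined contact-angle relation with respect to `theta` yields. Both are
#' exposed because the two readings cannot be adjudicated from the available
#' hysteresis data; reports carry both.
#'
#' @param morph A [surface_morphology()].
#' @param flat A [flat_wax_angles()].
#' @param theta_star Apparent mean contact angle on the leaf, degrees.
#' @param form `"printed"` (default) or `"derivative"`.
#' @return Predicted leaf hysteresis in degrees.
#' @examples
#' m <- surface_morphology(1.16, 0.25, 1)
#' f <- flat_wax_angles(101, 117, 86)
#' hysteresis_leaf(m, f, combined_angle(m, f$theta_mean))
#' @export
hysteresis_leaf <- function(morph, flat, theta_star,
                            form = c("printed", "derivative")) {
  morph <- as_surface_morphology(morph)
  stopifnot(inherits(flat, "flat_wax_angles"))
  form <- match.arg(form)
  if (theta_star <= 0 || theta_star >= 180)
    stop("'theta_star' must lie in (0, 180) degrees")
  sf <- sin(deg2rad(flat$theta_mean))
  if (abs(sf) < .Machine$double.eps)
    stop("sin(theta_flat) is zero; hysteresis undefined")
  k <- morph$r_micro * (morph$alpha * (morph$phi_nano - 1) + 1)
  ratio <- if (form == "printed") {
    sin(deg2rad(theta_star)) / sf
  } else {
    sf / sin(deg2rad(theta_star))
  }
  k * flat$hysteresis * ratio
}

#' Meniscus penetration depth between wax tubules
#'
#' Depth to which the air/water meniscus sags between vertically aligned wax
#' tubules of half-gap `d_wax = spacing / 2`, for a wall advancing angle
#' `theta > 90` degrees:
#'
#' `h = d_wax * (1/sin(theta - 90) - sqrt((1/sin(theta - 90))^2 - 1))`
#'
#' The meniscus radius of curvature is `d_wax / sin(theta - 90)`.
#'
#' @param geom A [nano_wax_geometry()].
#' @return Penetration depth in nm; satisfies `0 < h <= d_wax`.
#' @examples
#' meniscus_depth(nano_wax_geometry(75, 1000, 117))
#' @export
meniscus_depth <- function(geom) {
  stopifnot(inherits(geom, "nano_wax_geometry"))
  s <- sin(deg2rad(geom$theta_adv_wall) - pi / 2)
  # constructor guarantees theta in (90, 180) so s in (0, 1]
  inv <- 1 / s
  geom$d_wax * (inv - sqrt(inv^2 - 1))
}

#' Classify the nanoscale wetting state
#'
#' Cassie-Baxter if the meniscus penetration depth is strictly less than the
#' wax tubule height (air pockets survive); Wenzel otherwise. The boundary
#' `h == tubule_height` classifies as Wenzel (conservative).
#'
#' @param h Meniscus penetration depth, nm.
#' @param tubule_height Wax tubule height, nm.
#' @return `"CASSIE_BAXTER"` or `"WENZEL"`.
#' @examples
#' classify_nano_state(25, 1000)   # green leaf: CASSIE_BAXTER
#' classify_nano_state(277, 134)   # brown leaf: WENZEL
#' @export
classify_nano_state <- function(h, tubule_height) {
  stopifnot(is.numeric(h), is.numeric(tubule_height),
            h > 0, tubule_height > 0)
  if (h < tubule_height) "CASSIE_BAXTER" else "WENZEL"
}
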