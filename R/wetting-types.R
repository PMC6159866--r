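# Constructors and validators for the wetting-model parameter objects.
# Plain S3 lists: cheap to build, validated at construction.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stop_leafwet <- function(msg, class) {
  stop(structure(class = c(class, "leafwet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Surface morphology parameters of one leaf state
#'
#' The three quantities the combined Wenzel/Cassie-Baxter model needs:
#' microscale roughness of the epidermal bumps, the liquid/solid contact
#' fraction on top of the nano-wax tubule tips, and the areal fraction of the
#' leaf still covered by intact (non-eroded) wax.
#'
#' @param r_micro Microscale roughness, actual over projected surface area
#'   (dimensionless, >= 1).
#' @param phi_nano Areal fraction of liquid/solid contact atop wax tips,
#'   in \[0, 1\].
#' @param alpha Areal fraction of intact wax, in \[0, 1\] (1 for green leaves,
#'   < 1 after erosion).
#' @return An object of class `surface_morphology`.
#' @examples
#' surface_morphology(r_micro = 1.16, phi_nano = 0.25, alpha = 1)
#' @export
surface_morphology <- function(r_micro, phi_nano, alpha) {
  stopifnot(is.numeric(r_micro), length(r_micro) == 1L, is.finite(r_micro),
            is.numeric(phi_nano), length(phi_nano) == 1L, is.finite(phi_nano),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (r_micro < 1)
    stop("'r_micro' must be >= 1 (actual area cannot be below projected area)")
  if (phi_nano < 0 || phi_nano > 1) stop("'phi_nano' must lie in [0, 1]")
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  structure(list(r_micro = r_micro, phi_nano = phi_nano, alpha = alpha),
            class = "surface_morphology")
}

#' @export
print.surface_morphology <- function(x, ...) {
  cat(sprintf("surface morphology: r_micro = %.3f, phi_nano = %.3f, alpha = %.3f\n",
              x$r_micro, x$phi_nano, x$alpha))
  invisible(x)
}

#' Contact angles of the chemically flat wax reference surface
#'
#' Mean, advancing and receding contact angles (degrees) measured on wax
#' deposited flat on glass; the flat hysteresis is `theta_adv - theta_rec`.
#'
#' @param theta_mean,theta_adv,theta_rec Angles in degrees, with
#'   `0 < theta_rec <= theta_mean <= theta_adv < 180`.
#' @return An object of class `flat_wax_angles` with a `hysteresis` field.
#' @examples
#' flat_wax_angles(101, 117, 86)
#' @export
flat_wax_angles <- function(theta_mean, theta_adv, theta_rec) {
  stopifnot(is.numeric(theta_mean), is.numeric(theta_adv), is.numeric(theta_rec))
  if (!(theta_rec > 0 && theta_rec <= theta_mean &&
        theta_mean <= theta_adv && theta_adv < 180))
    stop("need 0 < theta_rec <= theta_mean <= theta_adv < 180 (degrees)")
  structure(list(theta_mean = theta_mean, theta_adv = theta_adv,
                 theta_rec = theta_rec, hysteresis = theta_adv - theta_rec),
            class = "flat_wax_angles")
}

#' Nanoscale wax tubule geometry
#'
#' Geometry controlling meniscus penetration between vertically aligned wax
#' tubules: the center-to-center tubule spacing (twice the half-gap `d_wax`),
#' the tubule height, and the advancing contact angle on the tubule wall that
#' sets the meniscus curvature.
#'
#' @param spacing Tubule center-to-center spacing in nm (> 0).
#' @param tubule_height Tubule height in nm (> 0).
#' @param theta_adv_wall Advancing angle on the wax wall, degrees; must exceed
#'   90 for a non-wetting (sagging-free) meniscus.
#' @return An object of class `nano_wax_geometry`; `d_wax = spacing / 2`.
#' @examples
#' nano_wax_geometry(spacing = 75, tubule_height = 1000, theta_adv_wall = 117)
#' @export
nano_wax_geometry <- function(spacing, tubule_height, theta_adv_wall) {
  stopifnot(is.numeric(spacing), is.numeric(tubule_height),
            is.numeric(theta_adv_wall))
  if (spacing <= 0) stop("'spacing' must be positive (nm)")
  if (tubule_height <= 0) stop("'tubule_height' must be positive (nm)")
  if (theta_adv_wall <= 90 || theta_adv_wall >= 180)
    stop("'theta_adv_wall' must lie in (90, 180) degrees")
  structure(list(spacing = spacing, d_wax = spacing / 2,
                 tubule_height = tubule_height,
                 theta_adv_wall = theta_adv_wall),
            class = "nano_wax_geometry")
}

#' Droplet and fluid constants for tilt mechanics
#'
#' @param volume_uL Droplet volume in microlitres (converted to m^3
#'   internally).
#' @param gamma_LA Liquid/air surface tension, N/m. Default 0.072 (water near
#'   room temperature).
#' @param rho Liquid density, kg/m^3. Default 1000.
#' @param g Gravitational acceleration, m/s^2. Default 9.81.
#' @param beta Substrate tilt angle in degrees, in (0, 90\].
#' @return An object of class `droplet_spec`; `volume_m3` holds the SI volume.
#' @examples
#' droplet_spec(volume_uL = 10, beta = 90)
#' @export
droplet_spec <- function(volume_uL = 10, gamma_LA = 0.072, rho = 1000,
                         g = 9.81, beta = 90) {
  vals <- c(volume_uL, gamma_LA, rho, g, beta)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (any(vals <= 0)) stop("all droplet constants must be positive")
  if (beta > 90) stop("'beta' must lie in (0, 90] degrees")
  structure(list(volume_uL = volume_uL, volume_m3 = volume_uL * 1e-9,
                 gamma_LA = gamma_LA, rho = rho, g = g, beta = beta),
            class = "droplet_spec")
}

#' Advancing/receding contact angles from a tilted-plate measurement
#'
#' The mean angle `theta_bar` is the arithmetic mean of the advancing and
#' receding angles, the convention used throughout the droplet-retention
#' mechanics here.
#'
#' @param theta_adv,theta_rec Advancing and receding angles, degrees, both in
#'   (0, 180) with `theta_rec <= theta_adv`.
#' @return An object of class `tilt_angles` with fields `theta_adv`,
#'   `theta_rec`, `theta_bar` and `hysteresis`.
#' @examples
#' tilt_angles(157, 137)  # summer green leaf
#' tilt_angles(151, 96)   # fall brown leaf
#' @export
tilt_angles <- function(theta_adv, theta_rec) {
  stopifnot(is.numeric(theta_adv), is.numeric(theta_rec))
  if (!(theta_rec > 0 && theta_adv < 180 && theta_rec <= theta_adv))
    stop("need 0 < theta_rec <= theta_adv < 180 (degrees)")
  structure(list(theta_adv = theta_adv, theta_rec = theta_rec,
                 theta_bar = (theta_adv + theta_rec) / 2,
                 hysteresis = theta_adv - theta_rec),
            class = "tilt_angles")
}

#' @export
print.tilt_angles <- function(x, ...) {
  cat(sprintf("tilt angles: adv %.1f deg / rec %.1f deg (mean %.1f, hysteresis %.1f)\n",
              x$theta_adv, x$theta_rec, x$theta_bar, x$hysteresis))
  invisible(x)
}
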