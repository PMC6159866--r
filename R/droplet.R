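# Droplet retention mechanics on a tilted leaf: spherical-cap geometry,
# the hysteresis-vs-gravity force balance, critical volumes and roll-off.

#' Spherical-cap geometry of a sessile droplet
#'
#' For a droplet of volume `V` sitting as a spherical cap with mean contact
#' angle `theta_bar`, the cap radius `R` solves
#' `V = pi/3 * R^3 * (1 - cos(theta_bar))^2 * (2 + cos(theta_bar))`
#' and the contact-line radius is `a = R * sin(theta_bar)`.
#'
#' @param volume_m3 Droplet volume in m^3 (> 0).
#' @param theta_bar Mean contact angle, degrees, in (0, 180).
#' @return A list with `R_m` (cap radius, m) and `a_m` (contact radius, m).
#' @examples
#' cap_geometry(10e-9, 147)  # 10 uL droplet on a green leaf
#' @export
cap_geometry <- function(volume_m3, theta_bar) {
  stopifnot(is.numeric(volume_m3), volume_m3 > 0,
            is.numeric(theta_bar), theta_bar > 0, theta_bar < 180)
  ct <- cos(deg2rad(theta_bar))
  R <- (3 * volume_m3 / (pi * (1 - ct)^2 * (2 + ct)))^(1 / 3)
  list(R_m = R, a_m = R * sin(deg2rad(theta_bar)))
}

#' Critical (maximum pinned) droplet volume on a tilted leaf
#'
#' The largest droplet that contact-angle hysteresis can pin against gravity
#' on a substrate tilted by `beta`. Balancing the retention force
#' `pi * a * gamma_LA * (cos(theta_rec) - cos(theta_adv))` against the weight
#' component `V * rho * g * sin(beta)` and eliminating the contact radius
#' `a` through the spherical-cap relations at the mean angle
#' `theta_bar = (theta_adv + theta_rec) / 2` gives
#'
#' `V_c = (pi * gamma * sin(theta_bar) * (cos(theta_rec) - cos(theta_adv)) /
#'         (rho * g * sin(beta)))^(3/2)
#'        * (3 / (pi * (1 - cos(theta_bar))^2 * (2 + cos(theta_bar))))^(1/2)`
#'
#' @param angles A [tilt_angles()] measurement.
#' @param drop A [droplet_spec()]; its `volume_uL` is ignored here (the
#'   output is the volume), only the fluid constants and tilt are used.
#' @return Critical volume in m^3. Zero when `theta_adv == theta_rec` (no
#'   hysteresis, nothing pins).
#' @examples
#' critical_volume(tilt_angles(157, 137), droplet_spec(beta = 90))
#' @export
critical_volume <- function(angles, drop = droplet_spec()) {
  stopifnot(inherits(angles, "tilt_angles"), inherits(drop, "droplet_spec"))
  if (angles$hysteresis == 0) return(0)
  tb <- deg2rad(angles$theta_bar)
  dcos <- cos(deg2rad(angles$theta_rec)) - cos(deg2rad(angles$theta_adv))
  ct <- cos(tb)
  (pi * drop$gamma_LA * sin(tb) * dcos /
      (drop$rho * drop$g * sin(deg2rad(drop$beta))))^(3 / 2) *
    (3 / (pi * (1 - ct)^2 * (2 + ct)))^(1 / 2)
}

#' Ratio of critical droplet volumes between two leaf states
#'
#' `critical_volume(angles_a) / critical_volume(angles_b)` evaluated with
#' common fluid constants and tilt, which cancel exactly: the ratio depends
#' only on the two angle pairs. A brown fall leaf over a green summer leaf
#' gives roughly 17.
#'
#' @param angles_a Numerator [tilt_angles()].
#' @param angles_b Denominator [tilt_angles()] (must have nonzero
#'   hysteresis).
#' @return Dimensionless volume ratio.
#' @examples
#' volume_ratio(tilt_angles(151, 96), tilt_angles(157, 137))  # ~16.5
#' @export
volume_ratio <- function(angles_a, angles_b) {
  stopifnot(inherits(angles_a, "tilt_angles"), inherits(angles_b, "tilt_angles"))
  if (angles_b$hysteresis == 0)
    stop("denominator leaf has zero hysteresis; ratio undefined")
  drop <- droplet_spec()
  critical_volume(angles_a, drop) / critical_volume(angles_b, drop)
}

#' Sentinel for a droplet that never rolls off
#'
#' A droplet is pinned when the hysteresis retention force exceeds the
#' droplet's full weight even at 90 degrees tilt; `rolloff_tilt()` then
#' returns this distinguished value instead of an angle. Serialised as the
#' string `"PINNED"` in reports.
#'
#' @return The pinned sentinel (an `NA` angle carrying class
#'   `leafwet_pinned`).
#' @seealso [is_pinned()]
#' @export
PINNED <- function() structure(NA_real_, class = c("leafwet_pinned", "numeric"))

#' @export
print.leafwet_pinned <- function(x, ...) {
  cat("PINNED (no roll-off at any tilt up to 90 deg)\n")
  invisible(x)
}

#' Test for the pinned sentinel
#' @param x An object, typically a `rolloff_tilt()` result.
#' @return `TRUE` if `x` is the [PINNED()] sentinel.
#' @export
is_pinned <- function(x) inherits(x, "leafwet_pinned")

#' Roll-off tilt angle of a droplet
#'
#' Inverts the hysteresis-gravity force balance for the tilt at which a
#' droplet of given volume starts to slide:
#' `beta = asin(pi * a * gamma_LA * (cos(theta_rec) - cos(theta_adv)) /
#' (V * rho * g))`, with the contact radius `a` from [cap_geometry()] at the
#' mean angle. When the arcsine argument exceeds 1 the droplet stays pinned
#' at every tilt and [PINNED()] is returned — a valid outcome, not an error.
#'
#' @param volume_m3 Droplet volume, m^3.
#' @param angles A [tilt_angles()] measurement.
#' @param drop A [droplet_spec()] supplying `gamma_LA`, `rho`, `g` (its
#'   volume and tilt fields are ignored).
#' @return Roll-off tilt in degrees, or [PINNED()].
#' @examples
#' rolloff_tilt(10e-9, tilt_angles(157, 137))            # ~18.6 deg
#' is_pinned(rolloff_tilt(10e-9, tilt_angles(151, 96)))  # TRUE
#' @export
rolloff_tilt <- function(volume_m3, angles, drop = droplet_spec()) {
  stopifnot(is.numeric(volume_m3), volume_m3 > 0,
            inherits(angles, "tilt_angles"), inherits(drop, "droplet_spec"))
  a <- cap_geometry(volume_m3, angles$theta_bar)$a_m
  dcos <- cos(deg2rad(angles$theta_rec)) - cos(deg2rad(angles$theta_adv))
  arg <- pi * a * drop$gamma_LA * dcos / (volume_m3 * drop$rho * drop$g)
  if (arg > 1) return(PINNED())
  rad2deg(asin(arg))
}
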