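# Shared fixtures and independent oracles for the test suite.

# independent scalar solver: find the angle (degrees) whose cosine equals x,
# by root-finding on cos instead of calling acos
solve_angle_deg <- function(x) {
  stats::uniroot(function(a) cos(a * pi / 180) - x, c(1e-9, 180 - 1e-9),
                 tol = 1e-12)$root
}

# the four characterised leaf states: printed morphology parameters and
# measured tilt angles, used across tests
fixture_states <- function() {
  list(
    green        = list(r = 1.16, phi = 0.25, alpha = 1.00, adv = 157, rec = 137),
    brown        = list(r = 1.07, phi = 0.25, alpha = 0.46, adv = 151, rec =  96),
    heat_treated = list(r = 1.13, phi = 0.25, alpha = 0.00, adv = 127, rec =  86),
    vacuum_dried = list(r = 1.10, phi = 0.25, alpha = 1.00, adv = 162, rec = 131))
}

# write a green-leaf synthetic image set + manifest into dir; returns the
# manifest path. Bump height 6.73 um (within the observed 8 +/- 5 um cell
# height spread) gives a ground-truth microscale roughness of ~1.16.
make_green_manifest <- function(dir, seed = 1L) {
  b <- gen_bump_profile(bump_height_um = 6.73, seed = seed)
  w <- gen_waxtip_image(seed = seed + 1L)
  e <- gen_erosion_image(target_alpha = 1, seed = seed + 2L)
  write_grayscale_image(b$raster, file.path(dir, "cs.tif"))
  write_grayscale_image(w$image, file.path(dir, "wax.tif"))
  write_grayscale_image(e$image, file.path(dir, "ero.tif"))
  man <- data.frame(
    filename = c("cs.tif", "wax.tif", "ero.tif"),
    role = c("cross_section", "topview_wax", "topview_erosion"),
    pixel_size_um = c(b$raster$pixel_size_um, w$image$pixel_size_um,
                      e$image$pixel_size_um))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  path
}
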