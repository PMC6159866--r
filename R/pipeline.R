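# Leaf-state presets, headline-table reproduction, per-leaf prediction
# reports and the end-to-end image pipeline.

round_half_up <- function(x) floor(x + 0.5)

#' Built-in leaf-state parameter presets
#'
#' The four characterised leaf states with their measured surface morphology
#' (microscale roughness, wax-tip fraction, intact-wax fraction), the flat
#' wax reference angles (mean 101 deg, advancing/receding 117/86 deg) and
#' the measured leaf advancing/receding angles used for comparison:
#' green summer leaves (r = 1.16, alpha = 1, measured 157/137), brown fall
#' leaves (r = 1.07, alpha = 0.46, measured 151/96), heat-treated leaves
#' (r = 1.13, alpha = 0, measured 127/86) and vacuum-dried leaves
#' (r = 1.10, alpha = 1, measured 162/131); phi_nano = 0.25 throughout.
#'
#' @return Named list of presets; each has `name`, `morphology`
#'   ([surface_morphology()]), `flat` ([flat_wax_angles()]), `measured`
#'   ([tilt_angles()]) and `measured_mean` (the reported mean contact
#'   angle, degrees).
#' @examples
#' names(leaf_presets())
#' @export
leaf_presets <- function() {
  flat <- flat_wax_angles(101, 117, 86)
  mk <- function(name, r, phi, alpha, adv, rec, mean_meas)
    list(name = name,
         morphology = surface_morphology(r, phi, alpha),
         flat = flat,
         measured = tilt_angles(adv, rec),
         measured_mean = mean_meas)
  list(
    green        = mk("green",        1.16, 0.25, 1.00, 157, 137, 147),
    brown        = mk("brown",        1.07, 0.25, 0.46, 151,  96, 123),
    heat_treated = mk("heat_treated", 1.13, 0.25, 0.00, 127,  86, 106),
    vacuum_dried = mk("vacuum_dried", 1.10, 0.25, 1.00, 162, 131, 147))
}

resolve_preset <- function(state) {
  p <- leaf_presets()
  if (is.character(state)) {
    if (!state %in% names(p))
      stop_leafwet(sprintf("unknown preset '%s' (have: %s)", state,
                           paste(names(p), collapse = ", ")),
                   "leafwet_config")
    return(p[[state]])
  }
  if (inherits(state, "surface_morphology"))
    return(list(name = "custom", morphology = state,
                flat = flat_wax_angles(101, 117, 86),
                measured = NULL, measured_mean = NA_real_))
  stop_leafwet("'state' must be a preset name or a surface_morphology",
               "leafwet_config")
}

#' Reproduce the headline contact-angle table
#'
#' Computes the theoretical apparent contact angle for each preset leaf
#' state through the combined two-tier model and sets it against the
#' measured mean contact angle. Display values are rounded half-up to whole
#' degrees; the exact values are kept in the `theoretical_exact` column.
#'
#' @param presets A preset list as returned by [leaf_presets()].
#' @return A data frame with one row per state: `state`, `theoretical`
#'   (rounded degrees), `theoretical_exact`, `experimental` (measured mean),
#'   `abs_diff`.
#' @examples
#' reproduce_table1()
#' @export
reproduce_table1 <- function(presets = leaf_presets()) {
  rows <- lapply(presets, function(p) {
    th <- combined_angle(p$morphology, p$flat$theta_mean)
    data.frame(state = p$name,
               theoretical = round_half_up(th),
               theoretical_exact = th,
               experimental = p$measured_mean,
               abs_diff = abs(round_half_up(th) - p$measured_mean))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full wettability prediction for one leaf state
#'
#' Composes the combined contact-angle model, both hysteresis variants, the
#' derived advancing/receding split (theta_star +/- hysteresis/2), the
#' critical pinned volume and the roll-off tilt of the specified droplet,
#' and (when a reference state is named) the critical-volume ratio against
#' that reference.
#'
#' @param state A preset name (see [leaf_presets()]) or a
#'   [surface_morphology()].
#' @param flat Flat wax reference angles; defaults to the preset's.
#' @param drop A [droplet_spec()] for the tilt mechanics.
#' @param reference Optional preset name to compute the critical-volume
#'   ratio against (using measured angles of both states).
#' @return An object of class `wettability_report` (a list; see
#'   [write_report()] for serialisation).
#' @examples
#' predict_leaf("brown", reference = "green")
#' @export
predict_leaf <- function(state, flat = NULL, drop = droplet_spec(),
                         reference = NULL) {
  p <- resolve_preset(state)
  if (!is.null(flat)) p$flat <- flat
  stopifnot(inherits(p$flat, "flat_wax_angles"),
            inherits(drop, "droplet_spec"))
  theta_star <- combined_angle(p$morphology, p$flat$theta_mean)
  hyst_printed <- hysteresis_leaf(p$morphology, p$flat, theta_star, "printed")
  hyst_deriv <- hysteresis_leaf(p$morphology, p$flat, theta_star, "derivative")
  pred <- tilt_angles(min(theta_star + hyst_printed / 2, 180 - 1e-9),
                      max(theta_star - hyst_printed / 2, 1e-9))
  report <- list(
    state = p$name,
    morphology = unclass(p$morphology),
    flat_wax = unclass(p$flat)[c("theta_mean", "theta_adv", "theta_rec")],
    theta_star = theta_star,
    hysteresis = list(printed = hyst_printed, derivative = hyst_deriv),
    predicted_angles = list(theta_adv = pred$theta_adv,
                            theta_rec = pred$theta_rec),
    droplet = list(volume_uL = drop$volume_uL, gamma_LA = drop$gamma_LA,
                   rho = drop$rho, g = drop$g, beta = drop$beta))
  if (!is.null(p$measured)) {
    report$measured <- list(theta_adv = p$measured$theta_adv,
                            theta_rec = p$measured$theta_rec,
                            theta_bar = p$measured$theta_bar,
                            hysteresis = p$measured$hysteresis)
    report$critical_volume_uL <- critical_volume(p$measured, drop) * 1e9
    b <- rolloff_tilt(drop$volume_m3, p$measured, drop)
    report$rolloff_tilt <- if (is_pinned(b)) "PINNED" else b
  }
  if (!is.null(reference)) {
    ref <- resolve_preset(reference)
    if (is.null(p$measured) || is.null(ref$measured))
      stop_leafwet("volume ratio needs measured angles for both states",
                   "leafwet_config")
    report$reference <- ref$name
    report$volume_ratio_vs_reference <- volume_ratio(p$measured, ref$measured)
  }
  structure(report, class = "wettability_report")
}

#' @export
print.wettability_report <- function(x, ...) {
  cat(sprintf("wettability report: %s\n", x$state))
  cat(sprintf("  apparent contact angle  %.1f deg (predicted adv/rec %.1f/%.1f)\n",
              x$theta_star, x$predicted_angles$theta_adv,
              x$predicted_angles$theta_rec))
  cat(sprintf("  predicted hysteresis    %.2f deg (printed) / %.2f deg (derivative form)\n",
              x$hysteresis$printed, x$hysteresis$derivative))
  if (!is.null(x$measured))
    cat(sprintf("  measured                %.0f/%.0f deg (hysteresis %.0f)\n",
                x$measured$theta_adv, x$measured$theta_rec,
                x$measured$hysteresis))
  if (!is.null(x$critical_volume_uL))
    cat(sprintf("  critical volume         %.3g uL at beta = %.0f deg\n",
                x$critical_volume_uL, x$droplet$beta))
  if (!is.null(x$rolloff_tilt)) {
    ro <- if (identical(x$rolloff_tilt, "PINNED")) "PINNED"
          else sprintf("%.1f deg", x$rolloff_tilt)
    cat(sprintf("  roll-off tilt (%g uL)   %s\n", x$droplet$volume_uL, ro))
  }
  if (!is.null(x$volume_ratio_vs_reference))
    cat(sprintf("  critical-volume ratio   %.2f x vs %s\n",
                x$volume_ratio_vs_reference, x$reference))
  invisible(x)
}

#' Serialise a wettability report to JSON (and optionally CSV)
#'
#' JSON keeps full precision and round-trips through [read_report()]. The
#' pinned roll-off outcome is serialised as the string `"PINNED"`.
#'
#' @param report A `wettability_report`.
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "wettability_report"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else if (ext == "csv") {
    flat <- unlist(unclass(report))
    utils::write.csv(data.frame(field = names(flat),
                                value = as.character(flat)),
                     path, row.names = FALSE)
  } else stop("unsupported report extension (need .json or .csv)")
  invisible(path)
}

#' Read back a JSON wettability report
#' @param path Path written by [write_report()].
#' @return A `wettability_report`.
#' @export
read_report <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyVector = TRUE),
            class = "wettability_report")
}

#' Read leaf parameter sets from a flat CSV
#'
#' Columns: `leaf_state`, `r_micro`, `phi_nano`, `alpha`, `theta_flat_mean`,
#' `theta_flat_adv`, `theta_flat_rec`.
#'
#' @param path CSV path.
#' @return Named list (by `leaf_state`) of lists with `morphology` and
#'   `flat` components.
#' @export
read_leaf_params <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("leaf_state", "r_micro", "phi_nano", "alpha",
            "theta_flat_mean", "theta_flat_adv", "theta_flat_rec")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_leafwet(paste("parameter CSV is missing column(s):",
                       paste(missing, collapse = ", ")), "leafwet_config")
  out <- lapply(seq_len(nrow(df)), function(i)
    list(morphology = surface_morphology(df$r_micro[i], df$phi_nano[i],
                                         df$alpha[i]),
         flat = flat_wax_angles(df$theta_flat_mean[i], df$theta_flat_adv[i],
                                df$theta_flat_rec[i])))
  names(out) <- df$leaf_state
  out
}

#' Write leaf parameter sets to a flat CSV
#' @param params Named list as from [read_leaf_params()] (or presets with
#'   `morphology`/`flat` fields).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_leaf_params <- function(params, path) {
  rows <- lapply(names(params), function(nm) {
    p <- params[[nm]]
    data.frame(leaf_state = nm,
               r_micro = p$morphology$r_micro,
               phi_nano = p$morphology$phi_nano,
               alpha = p$morphology$alpha,
               theta_flat_mean = p$flat$theta_mean,
               theta_flat_adv = p$flat$theta_adv,
               theta_flat_rec = p$flat$theta_rec)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Run the full image-to-report pipeline
#'
#' Reads an image manifest (CSV with columns `filename`, `role`,
#' `pixel_size_um`; roles `cross_section`, `topview_wax`,
#' `topview_erosion`), runs the three morphometry estimators, assembles the
#' surface morphology and produces a [predict_leaf()]-style report.
#'
#' @param manifest Path to a manifest CSV, or a data frame with the same
#'   columns. Relative filenames are resolved against the manifest's
#'   directory (or `image_dir`).
#' @param flat A [flat_wax_angles()] for the flat wax reference.
#' @param drop A [droplet_spec()].
#' @param image_dir Optional base directory for image paths.
#' @return A `wettability_report` with an extra `morphometry` element
#'   (estimates, dispersions and QA flags).
#' @export
run_end_to_end <- function(manifest, flat = flat_wax_angles(101, 117, 86),
                           drop = droplet_spec(), image_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(image_dir)) image_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("filename", "role", "pixel_size_um")
  missing <- setdiff(need, names(manifest))
  if (length(missing))
    stop_leafwet(paste("manifest is missing column(s):",
                       paste(missing, collapse = ", ")), "leafwet_config")
  paths <- manifest$filename
  if (!is.null(image_dir)) {
    rel <- !grepl("^(/|[A-Za-z]:)", paths)
    paths[rel] <- file.path(image_dir, paths[rel])
  }
  images <- mapply(read_grayscale_image, paths, manifest$pixel_size_um,
                   SIMPLIFY = FALSE)
  morpho <- morphometry_pipeline(images, manifest$role,
                                 ids = basename(manifest$filename))
  report <- predict_leaf(morpho$morphology, flat = flat, drop = drop)
  report$morphometry <- list(estimates = morpho$estimates, qa = morpho$qa)
  report
}
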