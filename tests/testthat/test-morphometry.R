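test_that("profile extraction: flat half-plane, degenerate input, bump recovery", {
  # flat half-plane: bottom 40 of 100 rows are tissue
  m <- matrix(0.1, 100, 120); m[61:100, ] <- 0.9
  img <- grayscale_image(m, 0.5)
  prof <- extract_surface_profile(img)
  expect_true(all(abs(prof$heights - 20) < 0.5))
  expect_equal(roughness_from_profile(prof), 1, tolerance = 1e-9)
  # all-background image: nothing to trace
  expect_error(extract_surface_profile(grayscale_image(matrix(0.1, 50, 50), 0.5),
                                       threshold = 0.5),
               class = "leafwet_profile")
  # synthetic bump raster: boundary recovered within 1 px RMS
  b <- gen_bump_profile(seed = 4)
  prof <- extract_surface_profile(b$raster)
  truth <- approx(seq(0, by = b$profile$dx_um,
                      length.out = length(b$profile$heights)),
                  b$profile$heights,
                  xout = (seq_along(prof$heights) - 0.5) * prof$dx_um,
                  rule = 2)$y
  rms_px <- sqrt(mean((prof$heights - truth)^2)) / b$raster$pixel_size_um
  expect_lt(rms_px, 1)
})

test_that("roughness: semicircular bump gives pi/2, with invariances", {
  # dense analytic semicircle spanning its own diameter
  R <- 10
  x <- seq(0, 2 * R, by = 0.001)
  h <- sqrt(pmax(0, R^2 - (x - R)^2))
  prof <- surface_profile(h, 0.001)
  expect_equal(roughness_from_profile(prof), pi / 2, tolerance = 2e-3)
  # invariant to vertical offset
  expect_equal(roughness_from_profile(surface_profile(h + 37, 0.001)),
               roughness_from_profile(prof), tolerance = 1e-12)
  # invariant under simultaneous (x, h) rescaling
  expect_equal(roughness_from_profile(surface_profile(h * 3.5, 0.0035)),
               roughness_from_profile(prof), tolerance = 1e-12)
  # flat profile is exactly 1; anything else exceeds 1
  expect_equal(roughness_from_profile(surface_profile(rep(5, 50), 0.1)), 1)
  expect_gt(roughness_from_profile(surface_profile(c(rep(5, 25), rep(6, 25)), 0.1)), 1)
})

test_that("wax-tip fraction: counting oracle, unimodal error, generator truth", {
  # two-level image with exactly 40% at the bright level
  m <- matrix(0.3, 100, 100); m[1:40, ] <- 0.8
  expect_equal(as.numeric(phi_from_topview(grayscale_image(m, 0.1))), 0.40,
               tolerance = 1e-9)
  # uniform image: no second histogram peak
  expect_error(phi_from_topview(grayscale_image(matrix(0.5, 60, 60), 0.1)),
               class = "leafwet_unimodal")
  # synthetic wax-tip images: recovery against the placed-disc mask
  for (s in c(2, 9)) {
    w <- gen_waxtip_image(seed = s)
    expect_lt(abs(as.numeric(phi_from_topview(w$image)) - w$true_phi), 0.03)
  }
})

test_that("intact fraction: full coverage, area-filter forcing, polarity flip", {
  # fully intact image
  full <- gen_erosion_image(target_alpha = 1, seed = 5)
  expect_equal(as.numeric(alpha_from_topview(full$image)), 1)
  # isolated 4 um^2 intact patches must all fall to the 5 um^2 filter
  px <- 0.5  # um/px: a 2x4-px patch is 2 um^2... use 4x4 px = 4 um^2
  m <- matrix(0.2, 80, 80)
  for (i in seq(1, 73, by = 12)) for (j in seq(1, 73, by = 12))
    m[i:(i + 3), j:(j + 3)] <- 0.8
  a <- alpha_from_topview(grayscale_image(m, px), threshold = 0.5)
  expect_equal(as.numeric(a), 0)
  # polarity flip: inverted image with intact = "dark" gives the same answer
  e <- gen_erosion_image(seed = 6)
  a1 <- as.numeric(alpha_from_topview(e$image))
  inv <- grayscale_image(1 - e$image$pixels, e$image$pixel_size_um)
  a2 <- as.numeric(alpha_from_topview(inv, intact = "dark"))
  expect_equal(a1, a2)
  expect_true(a1 >= 0 && a1 <= 1)
})

test_that("area filter is idempotent and robust to sub-threshold speckle", {
  set.seed(11)
  for (i in 1:5) {
    mask <- matrix(runif(80 * 80) > 0.4, 80, 80)
    once <- filter_small_regions(mask, 0.5)
    twice <- filter_small_regions(once, 0.5)
    expect_identical(once, twice)
  }
  # injected sub-threshold speckles do not move the estimate at all,
  # while the unfiltered segmentation does move
  e <- gen_erosion_image(seed = 8)
  a_speckled <- as.numeric(alpha_from_topview(e$image))
  a_clean <- as.numeric(alpha_from_topview(e$image_clean))
  expect_equal(a_speckled, a_clean)
  raw_speckled <- mean(e$image$pixels > 0.5)
  raw_clean <- mean(e$image_clean$pixels > 0.5)
  expect_gt(abs(raw_speckled - raw_clean), 0)  # speckle is really there
})

test_that("morphometry pipeline aggregates replicates and flags failures", {
  imgs <- list(gen_bump_profile(seed = 1)$raster,
               gen_bump_profile(seed = 2)$raster,
               gen_waxtip_image(seed = 3)$image,
               gen_erosion_image(seed = 4)$image)
  roles <- c("cross_section", "cross_section", "topview_wax", "topview_erosion")
  res <- morphometry_pipeline(imgs, roles)
  expect_s3_class(res$morphology, "surface_morphology")
  expect_equal(unname(res$estimates$r_micro["n"]), 2)
  expect_lt(abs(res$morphology$phi_nano - 0.25), 0.05)
  expect_lt(abs(res$morphology$alpha - 0.46), 0.05)
  # a degenerate wax image is excluded with a QA flag, not fatal
  imgs2 <- c(imgs, list(grayscale_image(matrix(0.5, 64, 64), 0.02)))
  roles2 <- c(roles, "topview_wax")
  res2 <- morphometry_pipeline(imgs2, roles2)
  expect_equal(unname(res2$estimates$phi_nano["n"]), 1)
  expect_true(any(grepl("topview_wax 5", res2$qa)))
  # missing role and empty set are errors naming the problem
  expect_error(morphometry_pipeline(imgs[1:2], roles[1:2]),
               class = "leafwet_missing_role")
  expect_error(morphometry_pipeline(list(), character(0)))
})
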