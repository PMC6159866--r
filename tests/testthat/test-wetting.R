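test_that("Wenzel relation reproduces limits and printed leaf values", {
  expect_equal(wenzel_angle(1, 101), 101)        # r = 1 is the flat surface
  expect_equal(wenzel_angle(1.2, 90), 90)        # cos 90 = 0 kills roughness
  # heat-treated leaf: wax gone, pure Wenzel on crumpled cells
  expect_equal(wenzel_angle(1.13, 101), 102.4516, tolerance = 1e-4)
  expect_lt(abs(wenzel_angle(1.13, 101) - 103), 2)
})

test_that("Wenzel breakdown raises a non-physical error instead of clamping", {
  expect_error(wenzel_angle(3, 10), class = "leafwet_nonphysical")
  expect_error(wenzel_angle(1.5, 170), class = "leafwet_nonphysical")
})

test_that("Cassie-Baxter relation matches limits and an independent solver", {
  expect_equal(cassie_baxter_angle(1, 101), 101)
  expect_equal(cassie_baxter_angle(0, 101), 180)
  expect_equal(cassie_baxter_angle(0, 37), 180)
  # independent oracle: root-find the angle whose cosine equals the mix
  x <- 0.25 * (cos(101 * pi / 180) + 1) - 1
  expect_equal(cassie_baxter_angle(0.25, 101), solve_angle_deg(x),
               tolerance = 1e-8)
  expect_equal(cassie_baxter_angle(0.25, 101), 142.9229, tolerance = 1e-4)
})

test_that("combined model reduces to its three classical limits", {
  set.seed(42)
  for (i in 1:50) {
    repeat {  # stay inside the physical regime |cos(theta*)| <= 1
      r <- runif(1, 1, 1.5)
      phi <- runif(1)
      theta <- runif(1, 91, 150)
      ct0 <- cos(theta * pi / 180)
      if (abs(r * ct0) <= 1 && abs(r * (phi * (ct0 + 1) - 1)) <= 1) break
    }
    # alpha = 0: pure Wenzel
    expect_equal(combined_angle(surface_morphology(r, phi, 0), theta),
                 wenzel_angle(r, theta), tolerance = 1e-12)
    # alpha = 1: the uniformly waxed form r*phi*cos(theta) - r*(1 - phi)
    ct <- cos(theta * pi / 180)
    expect_equal(cos(combined_angle(surface_morphology(r, phi, 1), theta) * pi / 180),
                 r * phi * ct - r * (1 - phi), tolerance = 1e-12)
    # r = 1, alpha = 1: plain Cassie-Baxter
    expect_equal(combined_angle(surface_morphology(1, phi, 1), theta),
                 cassie_baxter_angle(phi, theta), tolerance = 1e-12)
  }
})

test_that("combined angle is non-increasing in the wax-tip contact fraction", {
  phis <- seq(0.2, 1, by = 0.05)  # phi -> 0 at alpha = 1 exits the regime
  for (alpha in c(0.3, 0.7, 1)) {
    th <- vapply(phis, function(p)
      combined_angle(surface_morphology(1.16, p, alpha), 101), numeric(1))
    expect_true(all(diff(th) <= 1e-12))
  }
})

test_that("combined model raises non-physical error outside |cos| <= 1", {
  expect_error(combined_angle(surface_morphology(1.5, 0.25, 0), 170),
               class = "leafwet_nonphysical")
})

test_that("leaf hysteresis: structureless limit and frozen evaluations", {
  flat <- flat_wax_angles(101, 117, 86)
  # r = 1, phi = 1, alpha = 1 is the flat surface itself
  expect_equal(hysteresis_leaf(surface_morphology(1, 1, 1), flat, 101), 31)
  # green leaf at theta* = 158: 1.16 * 0.25 * 31 * sin158/sin101
  expect_equal(hysteresis_leaf(surface_morphology(1.16, 0.25, 1), flat, 158),
               3.430746, tolerance = 1e-6)
  # brown leaf at theta* = 121
  expect_equal(hysteresis_leaf(surface_morphology(1.07, 0.25, 0.46), flat, 121),
               18.97168, tolerance = 1e-5)
})

test_that("derivative-form hysteresis matches finite differences of the model", {
  # propagating a small flat-angle hysteresis through the combined relation
  # numerically must agree with the derivative-form variant
  for (st in fixture_states()[c("green", "brown")]) {
    m <- surface_morphology(st$r, st$phi, st$alpha)
    d <- 0.05  # small flat hysteresis, degrees
    flat <- flat_wax_angles(101, 101 + d / 2, 101 - d / 2)
    ts <- combined_angle(m, 101)
    fd <- combined_angle(m, 101 + d / 2) - combined_angle(m, 101 - d / 2)
    pred <- hysteresis_leaf(m, flat, ts, form = "derivative")
    expect_equal(pred, abs(fd), tolerance = 1e-4)
  }
})

test_that("both hysteresis variants appear and differ by the sine-ratio square", {
  m <- surface_morphology(1.16, 0.25, 1)
  flat <- flat_wax_angles(101, 117, 86)
  ts <- combined_angle(m, 101)
  hp <- hysteresis_leaf(m, flat, ts, "printed")
  hd <- hysteresis_leaf(m, flat, ts, "derivative")
  ratio <- (sin(ts * pi / 180) / sin(101 * pi / 180))^2
  expect_equal(hp / hd, ratio, tolerance = 1e-12)
})

test_that("meniscus depth: closed forms, frozen value, and bounds", {
  # theta -> 180: bracket -> 1, h -> d_wax
  g <- nano_wax_geometry(75, 1000, 179.9999)
  expect_equal(meniscus_depth(g) / g$d_wax, 1, tolerance = 1e-3)
  # theta = 135: h/d = sqrt(2) - 1
  g <- nano_wax_geometry(200, 500, 135)
  expect_equal(meniscus_depth(g) / g$d_wax, sqrt(2) - 1, tolerance = 1e-12)
  # wall angle 117 deg over a 37.5 nm half-gap
  g <- nano_wax_geometry(75, 1000, 117)
  expect_equal(meniscus_depth(g), 9.002953, tolerance = 1e-6)
  # no sagging-meniscus solution at or below 90 degrees
  expect_error(nano_wax_geometry(75, 1000, 90))
  # 0 < h <= d_wax over the whole valid wall-angle range
  for (th in seq(90.5, 179.5, by = 4)) {
    g <- nano_wax_geometry(100, 500, th)
    h <- meniscus_depth(g)
    expect_true(h > 0 && h <= g$d_wax)
  }
})

test_that("nanoscale state classification separates green from brown", {
  # green: 25 nm penetration vs 1 um tall tubules -> air pockets survive
  expect_identical(classify_nano_state(25, 1000), "CASSIE_BAXTER")
  # brown: 277 nm penetration vs 134 nm tubules -> flooded
  expect_identical(classify_nano_state(277, 134), "WENZEL")
  # boundary is conservative
  expect_identical(classify_nano_state(100, 100), "WENZEL")
})

test_that("parameter constructors enforce physical invariants", {
  expect_error(surface_morphology(0.9, 0.25, 1))
  expect_error(surface_morphology(1.1, 1.25, 1))
  expect_error(surface_morphology(1.1, 0.25, -0.1))
  expect_error(flat_wax_angles(101, 86, 117))   # adv < rec
  expect_error(tilt_angles(96, 151))            # adv < rec
  expect_error(droplet_spec(volume_uL = -1))
  expect_error(droplet_spec(beta = 95))
  expect_equal(tilt_angles(157, 137)$theta_bar, 147)
  expect_equal(droplet_spec(volume_uL = 10)$volume_m3, 1e-8)
})
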