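test_that("spherical-cap geometry: hemisphere closed form and resubstitution", {
  V <- 7e-9
  g <- cap_geometry(V, 90)
  expect_equal(g$R_m, (3 * V / (2 * pi))^(1 / 3), tolerance = 1e-12)
  expect_equal(g$a_m, g$R_m, tolerance = 1e-12)
  # near the full-ball limit the contact radius collapses
  expect_lt(cap_geometry(V, 179.9)$a_m, 2e-3 * cap_geometry(V, 179.9)$R_m)
  # 10 uL at 147 deg (green leaf mean angle); verified by resubstituting R
  # into the cap-volume relation
  g <- cap_geometry(1e-8, 147)
  expect_equal(g$R_m, 1.344836e-3, tolerance = 1e-6)
  expect_equal(g$a_m, 7.324502e-4, tolerance = 1e-6)
  ct <- cos(147 * pi / 180)
  expect_equal(pi / 3 * g$R_m^3 * (1 - ct)^2 * (2 + ct), 1e-8,
               tolerance = 1e-12)
})

test_that("critical volume matches an independent force-balance root", {
  drop <- droplet_spec(beta = 90)
  green <- tilt_angles(157, 137)
  vc <- critical_volume(green, drop)
  # independent oracle: solve the un-eliminated force balance
  # pi * a(V) * gamma * (cos rec - cos adv) = V * rho * g * sin(beta) for V
  dcos <- cos(green$theta_rec * pi / 180) - cos(green$theta_adv * pi / 180)
  bal <- function(V)
    pi * cap_geometry(V, green$theta_bar)$a_m * drop$gamma_LA * dcos -
      V * drop$rho * drop$g * sin(drop$beta * pi / 180)
  v_oracle <- uniroot(bal, c(1e-12, 1e-4), tol = 1e-18)$root
  expect_equal(vc, v_oracle, tolerance = 1e-7)
  # a 10 uL droplet exceeds it: green leaves shed 10 uL at modest tilt
  expect_lt(vc, 1e-8)
})

test_that("critical volume vanishes without hysteresis and grows with it", {
  drop <- droplet_spec()
  expect_equal(critical_volume(tilt_angles(120, 120), drop), 0)
  # strictly increasing in (cos rec - cos adv) at fixed mean angle
  tbar <- 130
  vols <- vapply(seq(2, 40, by = 2), function(d)
    critical_volume(tilt_angles(tbar + d / 2, tbar - d / 2), drop), numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("brown/green critical-volume ratio is ~17-fold and constant-free", {
  green <- tilt_angles(157, 137)
  brown <- tilt_angles(151, 96)
  expect_equal(volume_ratio(green, green), 1, tolerance = 1e-12)
  ratio <- volume_ratio(brown, green)
  expect_equal(round(ratio), 17)
  expect_gt(ratio, 16.4); expect_lt(ratio, 16.8)
  # the fluid constants and tilt cancel exactly
  r1 <- critical_volume(brown, droplet_spec(gamma_LA = 0.072, beta = 90)) /
    critical_volume(green, droplet_spec(gamma_LA = 0.072, beta = 90))
  r2 <- critical_volume(brown, droplet_spec(gamma_LA = 0.144, rho = 900,
                                            g = 3.7, beta = 25)) /
    critical_volume(green, droplet_spec(gamma_LA = 0.144, rho = 900,
                                        g = 3.7, beta = 25))
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(ratio, r1, tolerance = 1e-12)
  expect_error(volume_ratio(brown, tilt_angles(120, 120)))
})

test_that("roll-off tilt: green slides near 18.6 deg, brown stays pinned", {
  green <- tilt_angles(157, 137)
  brown <- tilt_angles(151, 96)
  b <- rolloff_tilt(1e-8, green)
  expect_false(is_pinned(b))
  expect_equal(as.numeric(b), 18.62956, tolerance = 1e-5)
  expect_true(is_pinned(rolloff_tilt(1e-8, brown)))
  # larger droplets roll off at shallower tilt (sin beta ~ V^(-2/3))
  betas <- vapply(c(1, 2, 5, 10, 20) * 1e-8, function(v)
    as.numeric(rolloff_tilt(v, green)), numeric(1))
  expect_true(all(diff(betas) < 0))
})

test_that("roll-off tilt and critical volume are exact inverses", {
  set.seed(7)
  for (i in 1:25) {
    adv <- runif(1, 100, 170)
    rec <- runif(1, adv - 40, adv - 1)
    if (rec <= 0) next
    ang <- tilt_angles(adv, rec)
    V <- 10^runif(1, -9.5, -7.5)
    b <- rolloff_tilt(V, ang)
    if (is_pinned(b)) next
    vc <- critical_volume(ang, droplet_spec(beta = as.numeric(b)))
    expect_equal(vc, V, tolerance = 1e-9)
  }
})
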