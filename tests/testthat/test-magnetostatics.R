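test_that("the magnet field has the right symmetry and limits", {
  mag <- magnet_spec()
  # mirror symmetry: no transverse component anywhere on the magnet axis
  y <- c(0, -0.005, 0.004, 0.009, -0.009)
  f <- field_of_rect_magnet(rep(0, length(y)), y, mag)
  expect_equal(f$Hx, rep(0, length(y)))
  expect_equal(f$dHxy, rep(0, length(y)))  # J diagonal on the axis
  # field points away from the near (north) face below the magnet
  expect_true(all(f$Hy < 0))
  # force gradient pulls toward the magnet (+y side)
  expect_true(all(f$gradH2y > 0))
  # B = mu0 H outside the magnet
  expect_equal(f$By, 4e-7 * pi * f$Hy)
  # no remanence, no field
  f0 <- field_of_rect_magnet(c(0, 0.003), c(0, -0.002), magnet_spec(B_rem = 0))
  expect_identical(f0$Hx, c(0, 0))
  expect_identical(f0$Hy, c(0, 0))
  expect_identical(f0$gradH2x, c(0, 0))
  # evaluation inside the magnet body is refused
  expect_error(field_of_rect_magnet(0, 0.06, mag), "inside the magnet")
})

test_that("closed-form field matches Biot-Savart quadrature at random points", {
  mag <- magnet_spec()
  set.seed(42)
  # 20 random points in and around the tumor disk (all exterior to magnet)
  r <- sqrt(runif(20)) * 0.012
  th <- runif(20, -pi, pi)
  x <- r * cos(th); y <- r * sin(th)
  f <- field_of_rect_magnet(x, y, mag)
  o <- biot_savart_oracle(mag, x, y)
  Hn <- sqrt(o$Hx^2 + o$Hy^2)
  err <- sqrt((f$Hx - o$Hx)^2 + (f$Hy - o$Hy)^2) / Hn
  expect_lt(max(err), 1e-3)  # field accuracy requirement: < 0.1%
})

test_that("the analytic field is numerically curl-free and divergence-free", {
  mag <- magnet_spec()
  h <- 1e-6
  pts <- cbind(x = c(0.002, -0.004, 0.007, 0, -0.009),
               y = c(0.003, -0.006, 0.001, -0.008, 0.004))
  for (k in seq_len(nrow(pts))) {
    x <- pts[k, 1]; y <- pts[k, 2]
    fE <- field_of_rect_magnet(x + h, y, mag); fW <- field_of_rect_magnet(x - h, y, mag)
    fN <- field_of_rect_magnet(x, y + h, mag); fS <- field_of_rect_magnet(x, y - h, mag)
    div <- (fE$Hx - fW$Hx + fN$Hy - fS$Hy) / (2 * h)
    curl <- (fE$Hy - fW$Hy - fN$Hx + fS$Hx) / (2 * h)
    f0 <- field_of_rect_magnet(x, y, mag)
    scale <- sqrt(f0$Hx^2 + f0$Hy^2) / 0.01   # |H| over the tumor length scale
    expect_lt(abs(div) / scale, 1e-6)
    expect_lt(abs(curl) / scale, 1e-6)
    # the analytic Jacobian agrees with finite differences
    expect_equal(unname((fE$Hx - fW$Hx) / (2 * h)), unname(f0$dHxx),
                 tolerance = 1e-5)
    expect_equal(unname((fN$Hx - fS$Hx) / (2 * h)), unname(f0$dHxy),
                 tolerance = 1e-5)
  }
})

test_that("particle magnetization is linear, clamped, and field-aligned", {
  p <- nanoparticle_spec(chi = 1, mu0_Msat = 0.5)
  # zero field, zero magnetization
  m0 <- particle_magnetization(0, 0, p)
  expect_identical(c(m0$Mx, m0$My), c(0, 0))
  # far above the threshold, |mu0 M| is clamped at 0.5 T
  mbig <- particle_magnetization(1e9, 0, p)
  expect_true(mbig$saturated)
  expect_equal(4e-7 * pi * mbig$Mmag, 0.5)
  # chi -> infinity: chi_eff -> 3, unsaturated M -> 3 H
  pinf <- nanoparticle_spec(chi = 1e12, mu0_Msat = 1e6)
  minf <- particle_magnetization(100, 0, pinf)
  expect_equal(minf$Mx / 100, 3, tolerance = 1e-9)
  # magnetization parallel to H
  m <- particle_magnetization(3, 4, p)
  expect_equal(m$Mx / m$My, 3 / 4)
})

test_that("magnetic force: branches, scaling, and potential consistency", {
  mag <- magnet_spec()
  p1 <- nanoparticle_spec(radius_a = 1e-7)
  p2 <- nanoparticle_spec(radius_a = 2e-7)
  F1 <- magnetic_force(0.002, -0.004, mag, p1)
  F2 <- magnetic_force(0.002, -0.004, mag, p2)
  # unsaturated force scales with particle volume: doubling a gives 8x
  expect_equal(F2$Fy / F1$Fy, 8, tolerance = 1e-12)
  expect_equal(F2$Fx / F1$Fx, 8, tolerance = 1e-12)
  # zero remanence: zero force
  F0 <- magnetic_force(0.002, -0.004, magnet_spec(B_rem = 0), p1)
  expect_identical(c(F0$Fx, F0$Fy), c(0, 0))
  # saturated and unsaturated branches give the same direction
  psat <- nanoparticle_spec(chi = 100)
  Fs <- magnetic_force(0, 0.009, mag, psat)
  Fu <- magnetic_force(0, 0.009, mag, p1)
  expect_true(Fs$saturated); expect_false(Fu$saturated)
  expect_equal(sign(Fs$Fy), sign(Fu$Fy))
  # branch continuity at the saturation threshold
  fld <- field_of_rect_magnet(0, 0, mag)
  H <- sqrt(fld$Hx^2 + fld$Hy^2)
  chieff_star <- (0.5 / (4e-7 * pi)) / H
  chi_star <- 3 * chieff_star / (3 - chieff_star)
  Fa <- magnetic_force(0, 0, mag, nanoparticle_spec(chi = chi_star * (1 - 1e-6)))
  Fb <- magnetic_force(0, 0, mag, nanoparticle_spec(chi = chi_star * (1 + 1e-6)))
  expect_false(Fa$saturated); expect_true(Fb$saturated)
  expect_equal(Fa$Fy, Fb$Fy, tolerance = 1e-5)
  # unsaturated force is the gradient of 1/4 V mu0 chi_eff |H|^2
  h <- 1e-6
  mu0 <- 4e-7 * pi
  chi_eff <- 1 / (1 + 1 / 3)
  pot <- function(x, y) {
    f <- field_of_rect_magnet(x, y, mag)
    0.25 * p1$volume * mu0 * chi_eff * 2 * (f$Hx^2 + f$Hy^2) / 2
  }
  Fx_fd <- (pot(0.002 + h, -0.004) - pot(0.002 - h, -0.004)) / (2 * h)
  Fy_fd <- (pot(0.002, -0.004 + h) - pot(0.002, -0.004 - h)) / (2 * h)
  expect_equal(F1$Fx, Fx_fd, tolerance = 1e-5)
  expect_equal(F1$Fy, Fy_fd, tolerance = 1e-5)
})

test_that("force magnitude decays monotonically with distance from the magnet", {
  mag <- magnet_spec()
  p <- nanoparticle_spec()
  y <- seq(0.0095, -0.0095, length.out = 30)  # down-axis ray through the tumor
  F <- magnetic_force(rep(0, 30), y, mag, p)
  Fmag <- sqrt(F$Fx^2 + F$Fy^2)
  expect_true(all(diff(Fmag) < 0))
})

test_that("Stokes equilibrium velocity balances drag against the force", {
  p <- nanoparticle_spec(radius_a = 1e-7)
  # zero force, zero drift
  expect_identical(equilibrium_velocity(0, 0, p, 1.12e-3)$vx, 0)
  # direct evaluation: F / (6 pi a eta)
  v <- equilibrium_velocity(0, 2.111e-15, p, 1.12e-3)
  expect_equal(v$vy, 1.0e-6, tolerance = 1e-4)
  expect_equal(v$vx, 0)
  # doubling the radius at fixed force halves the drift
  v2 <- equilibrium_velocity(0, 2.111e-15, nanoparticle_spec(radius_a = 2e-7),
                             1.12e-3)
  expect_equal(v$vy / v2$vy, 2)
  # drift is parallel to the force
  v3 <- equilibrium_velocity(3e-15, 4e-15, p, 1.12e-3)
  expect_equal(v3$vx / v3$vy, 3 / 4)
})

test_that("field map export covers the probe grid and masks the magnet body", {
  mag <- magnet_spec(height_h = 0.02, distance_d = 0.01)
  df <- export_field_map(mag, xlim = c(-0.05, 0.05), ylim = c(0, 0.04), n = 21)
  expect_equal(nrow(df), 21^2)
  expect_true(any(is.na(df$Hx)))        # points inside the body masked
  expect_true(any(is.finite(df$Hmag)))  # exterior points evaluated
})
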