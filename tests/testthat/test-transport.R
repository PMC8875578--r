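test_that("pore-model exchange has the right limits", {
  cfg <- quick_conventional()
  g <- polar_grid(cfg$geometry, cfg$solver)
  nr <- g$n_r; nt <- g$n_theta
  tis <- cfg$tissue
  # plateau (phi_B = 0), C_p = 0: pure washout at P * S/V = 0.06 / s
  phiB0 <- matrix(0, nr, nt)
  C <- matrix(2, nr, nt)
  Phi <- transvascular_exchange(C, phiB0, vascular_params(), tis, g)
  expect_equal(unique(as.numeric(Phi)), -0.06 * 2)
  # sigma_f = 1 forces Pe = 0 and the limit value Pe/(e^Pe - 1) -> 1
  Phi1 <- transvascular_exchange(C, matrix(6e-4, nr, nt),
                                 vascular_params(sigma_f = 1), tis, g)
  expect_equal(unique(as.numeric(Phi1)), -0.06 * 2)
  # no gradient, no filtration: C = C_p and phi_B = 0 gives Phi = 0
  vp <- vascular_params(C_p = 2)
  Phi2 <- transvascular_exchange(C, phiB0, vp, tis, g)
  expect_equal(max(abs(Phi2)), 0)
  # necrotic cells exchange nothing
  gn <- polar_grid(geometry_spec(Rn = 0.005), cfg$solver)
  Phin <- transvascular_exchange(matrix(2, gn$n_r, gn$n_theta),
                                 matrix(6e-4, gn$n_r, gn$n_theta),
                                 vascular_params(), tis, gn)
  expect_true(all(Phin[gn$necrotic, ] == 0))
  expect_true(all(Phin[!gn$necrotic, ] != 0))
})

test_that("binding kinetics conserve total drug and equilibrate at the
           tabulated ratio", {
  kin <- kinetic_params()
  # equilibrium ratio K_ON C_rec / (phi K_OFF) = 0.625 when K_INT = 0
  kin0 <- kinetic_params(K_INT = 0)
  st <- list(CF = 1, CB = 0.625, CI = 0)
  r <- reaction_rates(st, kin0)
  expect_equal(r$dCF, 0, tolerance = 1e-15)
  expect_equal(r$dCB, 0, tolerance = 1e-15)
  # zero state is a fixed point
  r0 <- reaction_rates(list(CF = 0, CB = 0, CI = 0), kin)
  expect_identical(c(r0$dCF, r0$dCB, r0$dCI), c(0, 0, 0))
  # the three derivatives sum to zero for arbitrary states
  set.seed(7)
  for (k in 1:20) {
    st <- list(CF = runif(5), CB = runif(5), CI = runif(5))
    r <- reaction_rates(st, kin)
    expect_equal(r$dCF + r$dCB + r$dCI, rep(0, 5), tolerance = 1e-18)
  }
})

test_that("zero boundary concentration is a fixed point of the stepper", {
  cfg <- quick_conventional()
  cfg$bc$C_outer <- 0
  fl <- solve_flow(cfg)
  sys <- transport_system(cfg, fl)
  st <- zero_state(fl$grid)
  for (i in 1:5) st <- step_transport(st, sys)
  expect_identical(max(abs(st$CF)), 0)
  expect_identical(max(abs(st$CI)), 0)
})

test_that("the concentration system is linear in the boundary value", {
  cfg1 <- quick_conventional()
  cfg2 <- quick_conventional()
  cfg2$bc$C_outer <- 2
  r1 <- run_transient(cfg1)
  r2 <- run_transient(cfg2)
  expect_equal(r2$final$CF, 2 * r1$final$CF, tolerance = 1e-12)
  expect_equal(r2$final$CB, 2 * r1$final$CB, tolerance = 1e-12)
  expect_equal(r2$final$CI, 2 * r1$final$CI, tolerance = 1e-12)
})

test_that("fields stay non-negative and internalized drug grows cell-wise", {
  run <- run_transient(quick_magnetic(t_end = 900))
  expect_true(all(run$final$CF >= 0))
  expect_true(all(run$final$CB >= 0))
  expect_true(all(run$final$CI >= 0))
  # C_I monotone in time at every cell
  CIs <- lapply(run$checkpoints, function(s) s$CI)
  for (k in seq_along(CIs)[-1]) {
    expect_true(all(CIs[[k]] - CIs[[k - 1]] >= -1e-18))
  }
  # tumor-mean C_F and C_B rise to a plateau; C_I strictly increasing
  expect_true(all(diff(run$means$CF) > -1e-12))
  expect_true(all(diff(run$means$CI) > 0))
})

test_that("a conventional hour reproduces the shallow penetration layer", {
  cfg <- conventional_scenario(solver = solver_settings(n_theta = 16, dt = 5))
  run <- run_transient(cfg)
  wh <- penetration_half_depth(run$final$CF, run$grid, cfg$bc, "average")
  # half-depth in the tens of microns: the drug is confined to the rim
  expect_gt(wh$w_half, 40e-6)
  expect_lt(wh$w_half, 75e-6)
  # cross-check against the independent 1D slab integration
  orc <- slab_transport_oracle(cfg$kinetics, loss = 0.06, v_const = 0,
                               t_end = 3600, L = 0.002, nx = 300)
  expect_equal(wh$w_half, orc$w_half, tolerance = 0.10)
  # mean concentrations from the two discretizations agree
  prof <- radial_profile(run$final$CF, run$grid)
  near <- prof$r > 0.0095
  orcC <- stats::approx(0.01 - orc$x, orc$CF, xout = prof$r[near], rule = 2)$y
  expect_equal(prof$value[near], orcC, tolerance = 0.08)
})

test_that("the step-by-step mass audit closes and degrades with coarser dt", {
  run <- run_transient(quick_conventional())
  expect_lt(mass_balance_audit(run)$max_residual, 1e-10)
  # zero-concentration run has zero residual
  cfg0 <- quick_conventional(); cfg0$bc$C_outer <- 0
  expect_equal(mass_balance_audit(run_transient(cfg0))$max_residual, 0)
})

test_that("magnetic drift enters the combined velocity with the right sign", {
  cfg <- quick_magnetic(t_end = 600)
  fl <- solve_flow(cfg)
  sys <- transport_system(cfg, fl)
  nr <- fl$grid$n_r
  j_bot <- which.min(abs(fl$grid$theta + pi / 2))
  j_top <- which.min(abs(fl$grid$theta - pi / 2))
  # rim face velocity: inward (negative) at the bottom, outward at the top
  expect_lt(sys$v_rad_tot[nr + 1, j_bot], 0)
  expect_gt(sys$v_rad_tot[nr + 1, j_top], 0)
  # drug enters from below: the bottom column carries far more drug
  run <- run_transient(cfg, flow = fl)
  expect_gt(sum(run$final$CF[, j_bot]), 10 * sum(run$final$CF[, j_top]))
})

test_that("Crank-Nicolson weighting agrees with backward Euler on the
           resolved solution", {
  sBE <- quick_solver(t_end = 900)
  sCN <- solver_settings(n_theta = 16, dr_max = 2e-4, dt = 5, t_end = 900,
                         theta_scheme = 0.5)
  rBE <- run_transient(conventional_scenario(solver = sBE))
  rCN <- run_transient(conventional_scenario(solver = sCN))
  expect_equal(tumor_mean(rCN$final$CF, rCN$grid),
               tumor_mean(rBE$final$CF, rBE$grid), tolerance = 1e-4)
  expect_lt(mass_balance_audit(rCN)$max_residual, 1e-10)
})
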