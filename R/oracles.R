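# Independent reference computations used by the test suite and the
# `verify` CLI subcommand. The oracles deliberately use different
# discretization families than the production solvers (dense 1D finite
# differences and adaptive quadrature instead of 2D finite volumes and
# closed forms) so shared bugs cannot hide.

#' 1D radial Darcy-Starling oracle
#'
#' Dense finite-difference solve of the radially symmetric pressure problem
#' `(1/r) d/dr (r kappa dP/dr) = -phi_B(P)` on (0, R] with `dP/dr = 0` at
#' the center and `P = Pi_outer` at the rim; the Starling source is switched
#' off for `r < Rn`. Independent of [solve_darcy()].
#'
#' @param tissue a [tissue_params()]
#' @param geometry a [geometry_spec()]
#' @param bc a [boundary_conditions()]
#' @param n_points number of uniform radial nodes
#' @return list with `r`, `Pi`, `v` (outward velocity at nodes),
#'   `plateau` (center pressure) and `rim_velocity`
#' @export
radial_darcy_oracle <- function(tissue, geometry, bc, n_points = 4000) {
  R <- geometry$R; Rn <- geometry$Rn
  h <- R / n_points
  r <- seq(h / 2, R - h / 2, by = h)   # staggered nodes
  n <- length(r)
  Pe <- starling_equilibrium_pressure(tissue)
  alpha <- tissue$Lp * tissue$SV
  viable <- r >= Rn
  kap <- tissue$kappa
  # tridiagonal assembly: -(1/r) d/dr(r kap dP/dr) + alpha*viable*P = alpha*viable*Pe
  # per-unit-volume form: flux divergence terms divided by r*h
  lo <- numeric(n); di <- numeric(n); hi <- numeric(n); rhs <- numeric(n)
  r_lo <- r - h / 2; r_hi <- r + h / 2
  for (i in seq_len(n)) {
    w_lo <- if (i == 1) 0 else kap * r_lo[i] / h   # symmetry: no flux at r=0
    w_hi <- kap * r_hi[i] / h
    di[i] <- (w_lo + w_hi) / (r[i] * h) + alpha * viable[i]
    if (i > 1) lo[i] <- -w_lo / (r[i] * h)
    if (i < n) hi[i] <- -w_hi / (r[i] * h)
    rhs[i] <- alpha * viable[i] * Pe
  }
  # rim: Dirichlet ghost at r = R, half spacing
  w_lo <- kap * r_lo[n] / h
  w_rim <- kap * R / (h / 2)
  di[n] <- (w_lo + w_rim) / (r[n] * h) + alpha * viable[n]
  lo[n] <- -w_lo / (r[n] * h)
  hi[n] <- 0
  rhs[n] <- alpha * viable[n] * Pe + w_rim / (r[n] * h) * bc$Pi_outer
  # Thomas algorithm
  for (i in 2:n) {
    m <- lo[i] / di[i - 1]
    di[i] <- di[i] - m * hi[i - 1]
    rhs[i] <- rhs[i] - m * rhs[i - 1]
  }
  P <- numeric(n)
  P[n] <- rhs[n] / di[n]
  for (i in (n - 1):1) P[i] <- (rhs[i] - hi[i] * P[i + 1]) / di[i]
  v <- c(-kap * diff(P) / h, -kap * (bc$Pi_outer - P[n]) / (h / 2))
  list(r = r, Pi = P, v = v, plateau = P[1], rim_velocity = v[n])
}

#' 1D slab transport oracle
#'
#' Fine-grid explicit (forward-Euler, sub-stepped to respect the diffusive
#' CFL limit) integration of the free/bound/internalized system on a 1D
#' slab with constant inward velocity, uniform loss coefficient and the
#' standard kinetics; Dirichlet unit concentration at the entry face.
#' Independent of the implicit finite-volume scheme.
#'
#' @param kinetics a [kinetic_params()]
#' @param loss uniform vascular loss coefficient (s^-1), e.g. `P_perm * SV`
#' @param v_const constant inward velocity (m/s)
#' @param t_end horizon (s)
#' @param L domain depth (m)
#' @param nx grid points
#' @param D diffusivity (m^2/s); defaults to `kinetics$D_eff`
#' @return list with `x` (depth), `CF`, `CB`, `CI` profiles and `w_half`
#' @export
slab_transport_oracle <- function(kinetics, loss, v_const = 0, t_end = 3600,
                                  L = 0.005, nx = 400, D = kinetics$D_eff) {
  dx <- L / nx
  x <- (seq_len(nx) - 0.5) * dx
  kon <- kinetics$K_ON * kinetics$C_rec / kinetics$phi
  # explicit stability: diffusion + advection + stiff loss
  dt <- 0.4 / (2 * D / dx^2 + abs(v_const) / dx + loss + kon + kinetics$K_OFF)
  n_steps <- ceiling(t_end / dt)
  dt <- t_end / n_steps
  CF <- numeric(nx); CB <- numeric(nx); CI <- numeric(nx)
  for (s in seq_len(n_steps)) {
    Cl <- c(1, CF[-nx])       # ghost at entry = 1 (Dirichlet)
    Cr <- c(CF[-1], CF[nx])   # zero-gradient far end
    adv <- if (v_const >= 0) v_const * (CF - Cl) / dx else
      v_const * (Cr - CF) / dx
    diff2 <- D * (Cl - 2 * CF + Cr) / dx^2
    # entry face half-spacing correction for the Dirichlet ghost
    diff2[1] <- D * (2 * (1 - CF[1]) / dx - (CF[1] - CF[2]) / dx) / dx
    exch <- kon * CF - kinetics$K_OFF * CB
    dCF <- -adv + diff2 - loss * CF - exch
    dCB <- exch - kinetics$K_INT * CB
    dCI <- kinetics$K_INT * CB
    CF <- CF + dt * dCF
    CB <- CB + dt * dCB
    CI <- CI + dt * dCI
  }
  below <- which(CF < 0.5)
  w_half <- if (length(below)) {
    i <- below[1]
    x0 <- if (i == 1) 0 else x[i - 1]
    c0 <- if (i == 1) 1 else CF[i - 1]
    x0 + (x[i] - x0) * (c0 - 0.5) / (c0 - CF[i])
  } else NA_real_
  list(x = x, CF = CF, CB = CB, CI = CI, w_half = w_half)
}

#' Biot-Savart quadrature oracle for the magnet field
#'
#' Numerical integration of the 2D line-current kernel over the magnet's two
#' equivalent surface-current sheets by adaptive quadrature, independent of
#' the closed-form expressions in [field_of_rect_magnet()].
#'
#' @param magnet a [magnet_spec()]
#' @param x,y evaluation points (m), exterior to the magnet
#' @return list of vectors `Hx`, `Hy` (A/m)
#' @export
biot_savart_oracle <- function(magnet, x, y) {
  stopifnot(length(x) == length(y))
  M0 <- magnet$B_rem / MU0
  body <- .magnet_body(magnet)
  sheets <- list(list(x0 = body$x2, K = +M0), list(x0 = body$x1, K = -M0))
  Hx <- numeric(length(x)); Hy <- numeric(length(x))
  for (p in seq_along(x)) {
    for (s in sheets) {
      dx <- x[p] - s$x0
      hx <- stats::integrate(function(yp) {
        -(y[p] - yp) / (dx^2 + (y[p] - yp)^2)
      }, body$y1, body$y2, rel.tol = 1e-10, abs.tol = 1e-12)$value
      hy <- stats::integrate(function(yp) {
        dx / (dx^2 + (y[p] - yp)^2)
      }, body$y1, body$y2, rel.tol = 1e-10, abs.tol = 1e-12)$value
      Hx[p] <- Hx[p] + s$K / (2 * pi) * hx
      Hy[p] <- Hy[p] + s$K / (2 * pi) * hy
    }
  }
  list(Hx = Hx, Hy = Hy)
}

#' Mass-balance audit of a transport run
#'
#' Checks, step by step, that the change in total drug mass (free + bound +
#' internalized, area-integrated) equals the rim influx minus the net
#' vascular loss recorded for that step. Residuals are normalized by the
#' maximum mass seen in the run.
#'
#' @param run a [run_transient()] result
#' @return list with `max_residual` (relative), and the per-step `residuals`
#' @export
mass_balance_audit <- function(run) {
  a <- run$audit
  expected <- run$sys$dt * (a$influx - a$loss)
  denom <- max(a$mass, 1e-300)
  res <- abs(a$dmass - expected) / denom
  list(max_residual = max(res), residuals = data.frame(t = a$t, residual = res))
}

#' Run the verification oracle battery
#'
#' Compares the production solvers against the independent oracles on the
#' default configuration: radial flow profile, magnet field at probe points,
#' and the mass balance of a short conventional run. Intended for the
#' `verify` CLI subcommand.
#'
#' @param solver optional [solver_settings()] (reduced resolutions run faster)
#' @return list of named checks, each with a measured value, its tolerance
#'   and a pass flag
#' @export
verify_oracles <- function(solver = solver_settings(n_theta = 16, dt = 5)) {
  cfg <- conventional_scenario(solver = solver)
  flow <- solve_flow(cfg)
  orc <- radial_darcy_oracle(cfg$tissue, cfg$geometry, cfg$bc)
  prof <- radial_profile(flow$pressure$Pi, flow$grid)
  Pi_orc <- stats::approx(orc$r, orc$Pi, xout = prof$r, rule = 2)$y
  flow_err <- max(abs(prof$value - Pi_orc)) /
    max(starling_equilibrium_pressure(cfg$tissue), 1e-300)

  mag <- magnet_spec()
  set_pts <- cbind(x = c(0, 0.004, -0.006, 0.009, 0.002),
                   y = c(0, -0.005, 0.003, 0.001, 0.009))
  f <- field_of_rect_magnet(set_pts[, 1], set_pts[, 2], mag)
  o <- biot_savart_oracle(mag, set_pts[, 1], set_pts[, 2])
  Hn <- sqrt(o$Hx^2 + o$Hy^2)
  mag_err <- max(sqrt((f$Hx - o$Hx)^2 + (f$Hy - o$Hy)^2) / Hn)

  run <- run_transient(cfg, t_end = 600)
  mb <- mass_balance_audit(run)

  checks <- list(
    radial_flow = list(value = flow_err, tol = 5e-3, pass = flow_err < 5e-3),
    magnet_field = list(value = mag_err, tol = 1e-3, pass = mag_err < 1e-3),
    mass_balance = list(value = mb$max_residual, tol = 1e-2,
                        pass = mb$max_residual < 1e-2))
  checks$all_pass <- all(vapply(checks, function(c) isTRUE(c$pass), logical(1)))
  checks
}
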