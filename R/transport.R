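# Coupled transport of the drug-carrier in the tumor interstitium.
#
# Free drug C_F obeys a convection-diffusion-reaction equation with the
# combined velocity v = v_i + v_e (interstitial fluid + magnetic drift),
# pore-model transvascular exchange Phi, and reversible receptor binding;
# bound drug C_B internalizes into cells at rate K_INT, feeding C_I:
#
#   dC_F/dt = -div(v C_F) + D lap(C_F) - (1/phi) K_ON C_rec C_F
#             + K_OFF C_B + Phi
#   dC_B/dt = +(1/phi) K_ON C_rec C_F - K_OFF C_B - K_INT C_B
#   dC_I/dt = K_INT C_B
#
# Discretization: conservative finite volumes on the polar grid, first-order
# upwind convection, implicit (theta-scheme) time stepping with the binding
# kinetics folded in by a per-cell Schur complement, so each step is one
# sparse back-solve with a constant, pre-factorized matrix. The operator is
# an M-matrix: concentrations stay non-negative for any time step.

#' Pore-model transvascular drug exchange
#'
#' Net rate of free-drug gain from the microvasculature (mol m^-3 s^-1):
#' `Phi_B = phi_B (1 - sigma_f) C_p + P (S/V) (C_p - C) Pe / (e^Pe - 1)`
#' with the transcapillary Peclet number
#' `Pe = phi_B (1 - sigma_f) / (P S/V)`; the lymphatic term `Phi_L =
#' phi_L C` vanishes with the lymphatics. Necrotic cells exchange nothing.
#' The small-Pe limit `Pe/(e^Pe - 1) -> 1` is evaluated by series below
#' 1e-6 to avoid cancellation.
#'
#' @param C free-drug concentration per cell (mol m^-3)
#' @param phiB Starling fluid source per cell (s^-1), from
#'   [starling_source()]
#' @param vascular a [vascular_params()]
#' @param tissue a [tissue_params()]
#' @param grid a [polar_grid()]
#' @return per-cell `Phi` (mol m^-3 s^-1), same shape as `C`
#' @export
transvascular_exchange <- function(C, phiB, vascular, tissue, grid) {
  co <- transvascular_coefficients(phiB, vascular, tissue, grid)
  out <- co$const - co$loss * matrix(C, grid$n_r, grid$n_theta)
  if (is.matrix(C)) out else as.numeric(out)
}

# decomposition Phi = const - loss * C used by the implicit scheme
transvascular_coefficients <- function(phiB, vascular, tissue, grid) {
  PSV <- vascular$P_perm * tissue$SV
  phiB <- matrix(phiB, grid$n_r, grid$n_theta)
  if (PSV == 0) {
    flt <- phiB * (1 - vascular$sigma_f) * vascular$C_p
    flt[grid$necrotic, ] <- 0
    return(list(loss = matrix(0, grid$n_r, grid$n_theta), const = flt))
  }
  Pe <- phiB * (1 - vascular$sigma_f) / PSV
  f <- ifelse(abs(Pe) < 1e-6, 1 - Pe / 2 + Pe^2 / 12, Pe / expm1(Pe))
  loss <- PSV * f
  const <- phiB * (1 - vascular$sigma_f) * vascular$C_p + loss * vascular$C_p
  loss[grid$necrotic, ] <- 0
  const[grid$necrotic, ] <- 0
  list(loss = loss, const = const)
}

#' Binding/internalization reaction rates
#'
#' Time derivatives of the three concentration fields from the kinetics
#' alone. The binding exchange conserves `C_F + C_B + C_I` exactly.
#'
#' @param state list with fields `CF`, `CB`, `CI` (mol m^-3)
#' @param kinetics a [kinetic_params()]
#' @return list with `dCF`, `dCB`, `dCI` (mol m^-3 s^-1)
#' @export
reaction_rates <- function(state, kinetics) {
  kon <- kinetics$K_ON * kinetics$C_rec / kinetics$phi
  exch <- kon * state$CF - kinetics$K_OFF * state$CB
  list(dCF = -exch,
       dCB = exch - kinetics$K_INT * state$CB,
       dCI = kinetics$K_INT * state$CB)
}

#' Assemble the implicit transport system for a scenario
#'
#' Builds the finite-volume transport operator on the grid: combined face
#' velocities (interstitial Darcy flux plus magnetic carrier drift evaluated
#' analytically at face midpoints), size-dependent diffusivity, pore-model
#' loss coefficients and the implicit binding Schur complement; factorizes
#' the (time-constant) step matrix once.
#'
#' @param config an [scenario_config()]
#' @param flow a [solve_flow()] result for the same grid
#' @return object of class `transport_system`
#' @export
transport_system <- function(config, flow) {
  grid <- flow$grid
  n_r <- grid$n_r; n_t <- grid$n_theta; N <- n_r * n_t
  sv <- config$solver
  fg <- .face_geometry(grid)
  D <- nanoparticle_diffusivity(config$particle, config$kinetics)

  # --- face velocities: fluid + magnetic drift ------------------------------
  v_rad <- flow$velocity$v_rad   # (n_r+1) x n_t, outward positive
  v_ang <- flow$velocity$v_ang   # n_r x n_t, toward increasing theta
  eta <- config$tissue$eta
  # radial faces (r_faces[i], theta_j), i = 2..n_r+1 (skip zero-length r = 0)
  rf <- grid$r_faces[-1]
  th <- grid$theta
  xr <- outer(rf, cos(th)); yr <- outer(rf, sin(th))
  dv <- carrier_drift_velocity(as.numeric(xr), as.numeric(yr),
                               config$magnet, config$particle, eta)
  ct <- matrix(cos(th), n_r, n_t, byrow = TRUE)
  st <- matrix(sin(th), n_r, n_t, byrow = TRUE)
  v_rad_tot <- v_rad
  v_rad_tot[-1, ] <- v_rad[-1, , drop = FALSE] +
    matrix(dv$vx, n_r, n_t) * ct + matrix(dv$vy, n_r, n_t) * st
  # angular faces at (r_i, theta_j + dtheta/2)
  thf <- th + grid$dtheta / 2
  xa <- outer(grid$r, cos(thf)); ya <- outer(grid$r, sin(thf))
  dva <- carrier_drift_velocity(as.numeric(xa), as.numeric(ya),
                                config$magnet, config$particle, eta)
  ctf <- matrix(cos(thf), n_r, n_t, byrow = TRUE)
  stf <- matrix(sin(thf), n_r, n_t, byrow = TRUE)
  v_ang_tot <- v_ang + matrix(dva$vy, n_r, n_t) * ctf -
    matrix(dva$vx, n_r, n_t) * stf

  # --- loss / source coefficients ------------------------------------------
  tv <- transvascular_coefficients(flow$phiB, config$vascular, config$tissue,
                                   grid)
  area <- as.numeric(grid$area)

  # --- assemble the transport operator L (1/s) and rim source --------------
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(N)
  b_rim_unit <- numeric(N)   # rim contribution per unit C_outer
  rim_g <- numeric(n_t); rim_qp <- numeric(n_t); rim_qm <- numeric(n_t)
  push <- function(i, j, v) { ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v) }

  for (j in seq_len(n_t)) {
    base <- (j - 1L) * n_r
    if (n_r > 1) {
      q <- v_rad_tot[2:n_r, j] * fg$rad_len       # m^2/s per unit depth
      gd <- D * fg$rad_len / fg$rad_dist
      qp <- pmax(q, 0); qm <- pmin(q, 0)
      c1 <- base + seq_len(n_r - 1L); c2 <- c1 + 1L
      a1 <- area[c1]; a2 <- area[c2]
      # flux c1 -> c2: (qp+gd) C1 + (qm-gd) C2
      diag_acc[c1] <- diag_acc[c1] - (qp + gd) / a1
      push(c1, c2, (gd - qm) / a1)
      push(c2, c1, (qp + gd) / a2)
      diag_acc[c2] <- diag_acc[c2] + (qm - gd) / a2
    }
    # rim Dirichlet face
    q <- v_rad_tot[n_r + 1L, j] * fg$rim_len
    gd <- D * fg$rim_len / fg$rim_dist
    qp <- max(q, 0); qm <- min(q, 0)
    k <- base + n_r
    diag_acc[k] <- diag_acc[k] - (qp + gd) / area[k]
    b_rim_unit[k] <- (gd - qm) / area[k]
    rim_g[j] <- gd; rim_qp[j] <- qp; rim_qm[j] <- qm
  }
  for (j in seq_len(n_t)) {
    jn <- if (j == n_t) 1L else j + 1L
    q <- v_ang_tot[, j] * fg$ang_len
    gd <- D * fg$ang_len / fg$ang_dist
    qp <- pmax(q, 0); qm <- pmin(q, 0)
    c1 <- (j - 1L) * n_r + seq_len(n_r)
    c2 <- (jn - 1L) * n_r + seq_len(n_r)
    a1 <- area[c1]; a2 <- area[c2]
    diag_acc[c1] <- diag_acc[c1] - (qp + gd) / a1
    push(c1, c2, (gd - qm) / a1)
    push(c2, c1, (qp + gd) / a2)
    diag_acc[c2] <- diag_acc[c2] + (qm - gd) / a2
  }
  L <- Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                            x = c(xx, diag_acc), dims = c(N, N))

  # --- implicit step matrix -------------------------------------------------
  kin <- config$kinetics
  kon <- kin$K_ON * kin$C_rec / kin$phi
  dt <- sv$dt; th_w <- sv$theta_scheme
  beta <- 1 / (1 + dt * (kin$K_OFF + kin$K_INT))
  loss <- as.numeric(tv$loss)
  # A x = rhs with x = C_F^{n+1}; binding folded in via Schur complement
  A <- Matrix::Diagonal(N, 1 / dt + loss * th_w +
                          kon - kin$K_OFF * beta * dt * kon) - th_w * L
  A <- methods::as(A, "CsparseMatrix")
  fac <- Matrix::lu(A)

  structure(list(
    grid = grid, L = L, A = A, factor = fac,
    b_rim_unit = b_rim_unit, phi_const = as.numeric(tv$const), loss = loss,
    kon = kon, koff = kin$K_OFF, kint = kin$K_INT, beta = beta,
    dt = dt, theta_w = th_w, D = D,
    v_rad_tot = v_rad_tot, v_ang_tot = v_ang_tot,
    rim_g = rim_g, rim_qp = rim_qp, rim_qm = rim_qm,
    C_outer = config$bc$C_outer, lin_tol = sv$lin_tol,
    area = area
  ), class = "transport_system")
}

#' Initial (zero) concentration state
#'
#' @param grid a [polar_grid()]
#' @return list of class `concentration_state` with `t = 0` and zero fields
#' @export
zero_state <- function(grid) {
  z <- matrix(0, grid$n_r, grid$n_theta)
  structure(list(t = 0, CF = z, CB = z, CI = z), class = "concentration_state")
}

#' Advance the concentration state by one implicit step
#'
#' One theta-scheme step of the coupled system; binding kinetics are
#' integrated implicitly (unconditionally stable, conserves
#' `C_F + C_B + C_I` under pure exchange), and `C_I` is updated from the
#' new bound concentration so it is non-decreasing cell-wise.
#'
#' @param state a `concentration_state`
#' @param sys a [transport_system()]
#' @return the next `concentration_state`
#' @export
step_transport <- function(state, sys) {
  dt <- sys$dt; th_w <- sys$theta_w
  CF <- as.numeric(state$CF); CB <- as.numeric(state$CB)
  b <- sys$b_rim_unit * sys$C_outer + sys$phi_const
  rhs <- CF / dt + th_w * b + sys$koff * sys$beta * CB
  if (th_w < 1) {
    rhs <- rhs + (1 - th_w) *
      (as.numeric(sys$L %*% CF) + b - sys$loss * CF)
  }
  x <- as.numeric(Matrix::solve(sys$factor, rhs))
  res <- sqrt(sum((as.numeric(sys$A %*% x) - rhs)^2))
  scale <- max(sqrt(sum(rhs^2)), 1e-300)
  if (res / scale > max(sys$lin_tol, 1e-12) * 1e3) {
    stop("step_transport(): linear solve failed, relative residual = ",
         format(res / scale), call. = FALSE)
  }
  CB_new <- sys$beta * (CB + dt * sys$kon * x)
  CI_new <- as.numeric(state$CI) + dt * sys$kint * CB_new
  n_r <- sys$grid$n_r; n_t <- sys$grid$n_theta
  structure(list(t = state$t + dt,
                 CF = matrix(x, n_r, n_t),
                 CB = matrix(CB_new, n_r, n_t),
                 CI = matrix(CI_new, n_r, n_t)),
            class = "concentration_state")
}

# mass bookkeeping for the balance audit: rim influx and vascular loss
# evaluated from the states by the same quadratures an external auditor
# would use (conservative face fluxes at the theta-weighted concentration)
.step_fluxes <- function(sys, CF_old, CF_new) {
  th_w <- sys$theta_w
  n_r <- sys$grid$n_r
  mix <- th_w * CF_new + (1 - th_w) * CF_old
  rimC <- matrix(mix, n_r, sys$grid$n_theta)[n_r, ]
  influx <- sum((sys$rim_g - sys$rim_qm) * sys$C_outer -
                  (sys$rim_g + sys$rim_qp) * rimC)
  loss <- sum((sys$loss * mix - sys$phi_const) * sys$area)
  c(influx = influx, loss = loss)
}

#' Run the transient drug-delivery simulation
#'
#' Integrates the concentration system from a drug-free tumor to `t_end`,
#' recording checkpoints, tumor-mean concentrations and per-step mass-balance
#' tallies (total drug mass, rim influx, net vascular loss) for the
#' mass-balance audit.
#'
#' @param config an [scenario_config()]
#' @param flow optional precomputed [solve_flow()] result
#' @param t_end horizon (s); defaults to the solver setting
#' @return list of class `transport_run`: `final` state, `checkpoints`
#'   (list of states), `means` (data frame t, CF, CB, CI), `audit`
#'   (data frame of per-step tallies), `sys` (the transport system)
#' @export
run_transient <- function(config, flow = NULL, t_end = NULL) {
  flow <- flow %||% solve_flow(config)
  sys <- transport_system(config, flow)
  t_end <- t_end %||% config$solver$t_end
  dt <- sys$dt
  n_steps <- ceiling(t_end / dt - 1e-9)
  ck_every <- max(1L, round(config$solver$checkpoint_dt / dt))
  state <- zero_state(flow$grid)
  checkpoints <- list()
  means <- data.frame(t = 0, CF = 0, CB = 0, CI = 0)
  mass0 <- 0
  audit <- data.frame(t = numeric(n_steps), mass = numeric(n_steps),
                      influx = numeric(n_steps), loss = numeric(n_steps),
                      dmass = numeric(n_steps))
  for (n in seq_len(n_steps)) {
    old_CF <- state$CF
    old_mass <- sum((state$CF + state$CB + state$CI) * flow$grid$area)
    state <- step_transport(state, sys)
    fl <- .step_fluxes(sys, as.numeric(old_CF), as.numeric(state$CF))
    mass <- sum((state$CF + state$CB + state$CI) * flow$grid$area)
    audit$t[n] <- state$t
    audit$mass[n] <- mass
    audit$influx[n] <- fl["influx"]
    audit$loss[n] <- fl["loss"]
    audit$dmass[n] <- mass - old_mass
    if (n %% ck_every == 0 || n == n_steps) {
      checkpoints[[length(checkpoints) + 1L]] <- state
      means <- rbind(means, data.frame(
        t = state$t,
        CF = tumor_mean(state$CF, flow$grid),
        CB = tumor_mean(state$CB, flow$grid),
        CI = tumor_mean(state$CI, flow$grid)))
    }
  }
  structure(list(final = state, checkpoints = checkpoints, means = means,
                 audit = audit, sys = sys, grid = flow$grid, flow = flow),
            class = "transport_run")
}
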