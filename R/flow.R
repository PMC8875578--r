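# Steady interstitial fluid flow: Darcy's law with a Starling transvascular
# source, solved once per scenario and then frozen for the transport stage.
#
#   v_i = -kappa grad(P_i)
#   div(v_i) = phi_B - phi_L
#   phi_B = Lp (S/V) (P_B - P_i - sigma_s (pi_B - pi_i))   (viable tissue)
#   phi_L = Lpl (S_LV) (P_i - P_L)                          (0 in tumors)
#
# The necrotic core has no functional vessels: phi_B = 0 there; kappa is
# unchanged, so pressure and flux are continuous across the interface.
# The source is linear in P_i, so the discrete problem is a single sparse
# symmetric linear solve (finite volumes on the polar grid).

#' Starling transvascular fluid source
#'
#' Net fluid gain per unit volume, `phi_B - phi_L` (s^-1). In viable cells
#' `phi_B = Lp (S/V) (P_e - P_i)` with `P_e` the Starling equilibrium
#' pressure; necrotic cells exchange no fluid. Lymphatic drainage uses the
#' `Lpl * SLV` product, zero by default (tumors lack functional lymphatics).
#'
#' @param Pi interstitial pressure per cell (Pa), vector or matrix
#' @param tissue a [tissue_params()]
#' @param grid a [polar_grid()] (supplies the necrotic mask)
#' @return per-cell net source (s^-1), same shape as `Pi`
#' @export
starling_source <- function(Pi, tissue, grid) {
  Pe <- starling_equilibrium_pressure(tissue)
  m <- matrix(Pi, grid$n_r, grid$n_theta)
  phiB <- tissue$Lp * tissue$SV * (Pe - m)
  phiB[grid$necrotic, ] <- 0
  phiL <- tissue$Lpl * tissue$SLV * (m - tissue$PL)
  phiL[grid$necrotic, ] <- 0
  out <- phiB - phiL
  if (is.matrix(Pi)) out else as.numeric(out)
}

# geometric face data shared by the flow and transport assemblies:
# radial faces between (i,j) and (i+1,j), plus the rim Dirichlet face;
# angular faces between (i,j) and (i,j+1 mod n_theta).
.face_geometry <- function(grid) {
  n_r <- grid$n_r
  list(
    # interior radial faces i = 1..n_r-1 (face at r_faces[i+1])
    rad_len  = grid$r_faces[2:n_r] * grid$dtheta,          # length n_r-1
    rad_dist = diff(grid$r),                               # center spacing
    # rim face
    rim_len  = grid$r_faces[n_r + 1] * grid$dtheta,
    rim_dist = grid$r_faces[n_r + 1] - grid$r[n_r],
    # angular faces at every radius
    ang_len  = grid$dr,                                    # length n_r
    ang_dist = grid$r * grid$dtheta
  )
}

#' Solve the steady Darcy-Starling pressure problem
#'
#' Finite-volume discretization of `-kappa lap(P) = phi_B(P)` on the polar
#' grid with the Dirichlet rim value `bc$Pi_outer`; the linear-in-pressure
#' Starling source is assembled implicitly and the sparse system solved
#' directly. The discrete operator is an M-matrix, so the solution obeys
#' the maximum principle `Pi_outer <= P <= P_e`.
#'
#' @param grid a [polar_grid()]
#' @param tissue a [tissue_params()]
#' @param bc a [boundary_conditions()]
#' @param lin_tol residual tolerance used to verify the direct solve
#' @return object of class `pressure_field`: list with `Pi` (n_r x n_theta
#'   matrix, Pa) and `residual`
#' @export
solve_darcy <- function(grid, tissue, bc, lin_tol = 1e-10) {
  n_r <- grid$n_r; n_t <- grid$n_theta
  N <- n_r * n_t
  fg <- .face_geometry(grid)
  kap <- tissue$kappa
  Pe <- starling_equilibrium_pressure(tissue)
  alpha <- tissue$Lp * tissue$SV  # source coefficient, viable cells only

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(N)
  diag_acc <- numeric(N)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  # radial couplings (same for every angular column)
  for (j in seq_len(n_t)) {
    base <- (j - 1L) * n_r
    if (n_r > 1) {
      g <- kap * fg$rad_len / fg$rad_dist           # conductance, length n_r-1
      i1 <- base + seq_len(n_r - 1L)
      i2 <- i1 + 1L
      add(i1, i2, -g); add(i2, i1, -g)
      diag_acc[i1] <- diag_acc[i1] + g
      diag_acc[i2] <- diag_acc[i2] + g
    }
    # rim Dirichlet
    grim <- kap * fg$rim_len / fg$rim_dist
    diag_acc[base + n_r] <- diag_acc[base + n_r] + grim
    rhs[base + n_r] <- rhs[base + n_r] + grim * bc$Pi_outer
  }
  # angular couplings (periodic)
  gang <- kap * fg$ang_len / fg$ang_dist            # per radius, length n_r
  for (j in seq_len(n_t)) {
    jn <- if (j == n_t) 1L else j + 1L
    i1 <- (j - 1L) * n_r + seq_len(n_r)
    i2 <- (jn - 1L) * n_r + seq_len(n_r)
    add(i1, i2, -gang); add(i2, i1, -gang)
    diag_acc[i1] <- diag_acc[i1] + gang
    diag_acc[i2] <- diag_acc[i2] + gang
  }
  # Starling source: area * alpha * (Pe - P) on viable cells
  viable <- rep(!grid$necrotic, n_t)
  src <- as.numeric(grid$area) * alpha * viable
  diag_acc <- diag_acc + src
  rhs <- rhs + src * Pe

  A <- Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                            x = c(xx, diag_acc), dims = c(N, N))
  P <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                error = function(e) stop("solve_darcy(): singular assembly: ",
                                         conditionMessage(e), call. = FALSE))
  res <- sqrt(sum((as.numeric(A %*% P) - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  if (res > lin_tol) {
    warning("solve_darcy(): relative residual ", format(res), " above lin_tol")
  }
  structure(list(Pi = matrix(P, n_r, n_t), residual = res),
            class = "pressure_field")
}

#' Interstitial fluid velocity from the pressure field
#'
#' Face-centered Darcy fluxes `v = -kappa dP/dn` on the radial faces
#' (including the rim Dirichlet face) and angular faces, plus interpolated
#' cell-center velocity vectors for output.
#'
#' @param pressure a [solve_darcy()] result
#' @param grid a [polar_grid()]
#' @param tissue a [tissue_params()]
#' @param bc the [boundary_conditions()] used in the solve
#' @return object of class `velocity_field`: `v_rad` ((n_r+1) x n_theta,
#'   outward-positive radial velocity at radial faces; row 1 is the r = 0
#'   face, row n_r+1 the rim), `v_ang` (n_r x n_theta, velocity across the
#'   angular face between j and j+1), and cell-center `vx`, `vy`, `vmag`
#' @export
velocity_from_pressure <- function(pressure, grid, tissue, bc) {
  P <- pressure$Pi
  n_r <- grid$n_r; n_t <- grid$n_theta
  kap <- tissue$kappa
  v_rad <- matrix(0, n_r + 1L, n_t)
  if (n_r > 1) {
    dP <- (P[-1, , drop = FALSE] - P[-n_r, , drop = FALSE])
    v_rad[2:n_r, ] <- -kap * dP / diff(grid$r)
  }
  v_rad[n_r + 1L, ] <- -kap * (bc$Pi_outer - P[n_r, ]) /
    (grid$r_faces[n_r + 1L] - grid$r[n_r])
  Pnext <- P[, c(2:n_t, 1L), drop = FALSE]
  v_ang <- -kap * (Pnext - P) / (grid$r * grid$dtheta)
  # cell-center radial velocity: average of the two bounding faces
  v_rc <- (v_rad[-1, , drop = FALSE] + v_rad[-(n_r + 1L), , drop = FALSE]) / 2
  v_tc <- (v_ang + v_ang[, c(n_t, 1:(n_t - 1L)), drop = FALSE]) / 2
  ct <- matrix(cos(grid$theta), n_r, n_t, byrow = TRUE)
  st <- matrix(sin(grid$theta), n_r, n_t, byrow = TRUE)
  vx <- v_rc * ct - v_tc * st
  vy <- v_rc * st + v_tc * ct
  structure(list(v_rad = v_rad, v_ang = v_ang, vx = vx, vy = vy,
                 vmag = sqrt(vx^2 + vy^2)),
            class = "velocity_field")
}

#' Solve the flow stage of a scenario
#'
#' Convenience wrapper: builds the grid (unless given), solves the pressure
#' problem and derives the velocity field. Also reports the global fluid
#' balance: total Starling inflow vs. outward rim Darcy flux.
#'
#' @param config an [scenario_config()]
#' @param grid optional prebuilt [polar_grid()]
#' @return list with `grid`, `pressure`, `velocity`, `phiB` (net source,
#'   s^-1), `balance` (relative fluid-balance mismatch)
#' @export
solve_flow <- function(config, grid = NULL) {
  grid <- grid %||% polar_grid(config$geometry, config$solver)
  pressure <- solve_darcy(grid, config$tissue, config$bc,
                          lin_tol = config$solver$lin_tol)
  velocity <- velocity_from_pressure(pressure, grid, config$tissue, config$bc)
  phiB <- starling_source(pressure$Pi, config$tissue, grid)
  inflow <- sum(phiB * grid$area)
  rim_flux <- sum(velocity$v_rad[grid$n_r + 1L, ] *
                    grid$r_faces[grid$n_r + 1L] * grid$dtheta)
  balance <- abs(inflow - rim_flux) / max(abs(inflow), 1e-300)
  list(grid = grid, pressure = pressure, velocity = velocity,
       phiB = phiB, balance = balance)
}
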