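# Plane magnetostatics of a uniformly magnetized rectangular permanent magnet,
# the saturable force it exerts on a magnetic nanoparticle, and the Stokes
# equilibrium drift velocity.
#
# The magnet body occupies x in [-l/2, l/2], y in [d, d+h] (tumor center at
# the origin), with magnetization M0 = B_rem / mu0 along -y. With zero free
# current (curl H = 0, div B = 0 outside), the field is that of two
# equivalent surface-current sheets on the vertical faces: K = +M0 z at
# x = +l/2 and K = -M0 z at x = -l/2. Each sheet integrates the 2D line-
# current kernel in closed form (log/arctan), and the Jacobian of H follows
# analytically; off the sheets the Jacobian is symmetric (curl-free) and
# trace-free (divergence-free).

MU0 <- 4e-7 * pi

# closed-form field + Jacobian of one vertical current sheet at x = x0,
# y in [y1, y2], surface current K (A/m, along +z). Vectorized over x, y.
.sheet_field <- function(x, y, x0, y1, y2, K) {
  dx <- x - x0
  a <- y - y1
  b <- y - y2
  ra2 <- dx^2 + a^2
  rb2 <- dx^2 + b^2
  Hx <- -K / (4 * pi) * (log(ra2) - log(rb2))
  # atan((y2-y)/dx) - atan((y1-y)/dx), continuous across dx = 0 off the sheet
  Hy <- K / (2 * pi) * sign(dx) * (atan2(y2 - y, abs(dx)) - atan2(y1 - y, abs(dx)))
  dHxx <- -K / (2 * pi) * dx * (1 / ra2 - 1 / rb2)
  dHxy <- -K / (2 * pi) * (a / ra2 - b / rb2)
  list(Hx = Hx, Hy = Hy, dHxx = dHxx, dHxy = dHxy)
}

.magnet_body <- function(magnet) {
  list(x1 = -magnet$length_l / 2, x2 = magnet$length_l / 2,
       y1 = magnet$distance_d, y2 = magnet$distance_d + magnet$height_h)
}

#' Magnetostatic field of the rectangular permanent magnet
#'
#' Closed-form 2D field `H`, flux density `B = mu0 H`, Jacobian of `H`, and
#' the gradient of `|H|^2` at points outside the magnet body. Vectorized
#' over points.
#'
#' @param x,y evaluation coordinates (m), tumor center at the origin
#' @param magnet a [magnet_spec()]
#' @return list with numeric vectors `Hx`, `Hy` (A/m), `Bx`, `By` (T),
#'   Jacobian entries `dHxx`, `dHxy`, `dHyy` (A/m^2; symmetric, `dHyx = dHxy`),
#'   and `gradH2x`, `gradH2y` (gradient of `|H|^2`, A^2/m^3)
#' @export
field_of_rect_magnet <- function(x, y, magnet) {
  stopifnot(inherits(magnet, "magnet_spec"), length(x) == length(y))
  body <- .magnet_body(magnet)
  inside <- x >= body$x1 & x <= body$x2 & y >= body$y1 & y <= body$y2
  if (any(inside)) {
    stop("field_of_rect_magnet(): point(s) inside the magnet body; ",
         "the tumor domain excludes the magnet interior", call. = FALSE)
  }
  M0 <- magnet$B_rem / MU0
  sR <- .sheet_field(x, y, body$x2, body$y1, body$y2, +M0)
  sL <- .sheet_field(x, y, body$x1, body$y1, body$y2, -M0)
  Hx <- sR$Hx + sL$Hx
  Hy <- sR$Hy + sL$Hy
  dHxx <- sR$dHxx + sL$dHxx
  dHxy <- sR$dHxy + sL$dHxy
  dHyy <- -dHxx  # div H = 0 off the sheets
  list(Hx = Hx, Hy = Hy, Bx = MU0 * Hx, By = MU0 * Hy,
       dHxx = dHxx, dHxy = dHxy, dHyy = dHyy,
       gradH2x = 2 * (Hx * dHxx + Hy * dHxy),
       gradH2y = 2 * (Hx * dHxy + Hy * dHyy))
}

#' Magnetization of a nanoparticle in a field
#'
#' Linear response with self-demagnetization, sharply clamped at saturation:
#' `M = min(chi_eff |H|, M_sat) * H / |H|` with `chi_eff = chi / (1 + chi/3)`
#' and `M_sat = mu0_Msat / mu0`. Continuous at the saturation threshold; the
#' magnetization always lines up with `H`.
#'
#' @param Hx,Hy field components (A/m), vectorized
#' @param particle a [nanoparticle_spec()]
#' @return list with `Mx`, `My` (A/m), `Mmag` (|M|), and logical `saturated`
#' @export
particle_magnetization <- function(Hx, Hy, particle) {
  chi_eff <- particle$chi / (1 + particle$chi / 3)
  Msat <- particle$mu0_Msat / MU0
  Hmag <- sqrt(Hx^2 + Hy^2)
  Mlin <- chi_eff * Hmag
  saturated <- Mlin > Msat
  Mmag <- pmin(Mlin, Msat)
  scale <- ifelse(Hmag > 0, Mmag / Hmag, 0)
  list(Mx = scale * Hx, My = scale * Hy, Mmag = Mmag, saturated = saturated)
}

#' Magnetic force on a nanoparticle
#'
#' `F = mu0 V (dH/dx)^T M(H)`, which in the unsaturated branch equals
#' `1/2 V mu0 chi_eff grad(|H|^2)` and in the saturated branch keeps the same
#' direction with magnitude capped by `M_sat` (saturation changes only the
#' magnitude of the force, never its direction). The two branches agree at
#' the saturation threshold.
#'
#' @param x,y evaluation points (m), outside the magnet body
#' @param magnet a [magnet_spec()]
#' @param particle a [nanoparticle_spec()]
#' @return list with force components `Fx`, `Fy` (N) and logical `saturated`
#' @export
magnetic_force <- function(x, y, magnet, particle) {
  f <- field_of_rect_magnet(x, y, magnet)
  m <- particle_magnetization(f$Hx, f$Hy, particle)
  V <- particle$volume
  # J is symmetric: (dH/dx)^T M = J M
  list(Fx = MU0 * V * (f$dHxx * m$Mx + f$dHxy * m$My),
       Fy = MU0 * V * (f$dHxy * m$Mx + f$dHyy * m$My),
       saturated = m$saturated)
}

#' Stokes equilibrium velocity of a particle under a force
#'
#' The drift velocity at which viscous Stokes drag `6 pi a eta v` balances
#' the applied force: `v_e = F / (6 pi a eta)`, componentwise and parallel
#' to `F`.
#'
#' @param Fx,Fy force components (N)
#' @param particle a [nanoparticle_spec()]
#' @param eta fluid dynamic viscosity (Pa s)
#' @return list with velocity components `vx`, `vy` (m/s)
#' @export
equilibrium_velocity <- function(Fx, Fy, particle, eta) {
  stopifnot(particle$radius_a > 0, eta > 0)
  drag <- 6 * pi * particle$radius_a * eta
  list(vx = Fx / drag, vy = Fy / drag)
}

#' Carrier drift velocity inside tumor tissue
#'
#' The magnetically driven drift of the drug carrier in tissue: the Stokes
#' equilibrium velocity of [magnetic_force()], multiplied by the calibrated
#' magnetophoretic mobility scale and by the tissue hindrance factor
#' `exp(-(a - a_ref)/L)` (hindered drag; see [hindrance_factor()]).
#' With no magnet or `B_rem = 0` the drift is identically zero.
#'
#' @param x,y evaluation points (m)
#' @param magnet a [magnet_spec()] or `NULL`
#' @param particle a [nanoparticle_spec()]
#' @param eta interstitial fluid viscosity (Pa s)
#' @return list with `vx`, `vy` (m/s)
#' @export
carrier_drift_velocity <- function(x, y, magnet, particle, eta) {
  if (is.null(magnet) || magnet$B_rem == 0) {
    z <- numeric(length(x))
    return(list(vx = z, vy = z))
  }
  F <- magnetic_force(x, y, magnet, particle)
  v <- equilibrium_velocity(F$Fx, F$Fy, particle, eta)
  s <- particle$mobility_scale * hindrance_factor(particle)
  list(vx = s * v$vx, vy = s * v$vy)
}

#' Export the magnet field on a rectilinear probe grid
#'
#' Evaluates the field on a regular grid for field-map visualization and
#' writes a CSV with columns `x, y, Hx, Hy, Hmag`. Points inside the magnet
#' body are reported as `NA`.
#'
#' @param magnet a [magnet_spec()]
#' @param xlim,ylim ranges (m)
#' @param n number of points per axis
#' @param path output CSV path
#' @return the data frame, invisibly
#' @export
export_field_map <- function(magnet, xlim, ylim, n = 101, path = NULL) {
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  g <- expand.grid(x = xs, y = ys)
  body <- .magnet_body(magnet)
  inside <- g$x >= body$x1 & g$x <= body$x2 & g$y >= body$y1 & g$y <= body$y2
  Hx <- Hy <- rep(NA_real_, nrow(g))
  if (any(!inside)) {
    f <- field_of_rect_magnet(g$x[!inside], g$y[!inside], magnet)
    Hx[!inside] <- f$Hx
    Hy[!inside] <- f$Hy
  }
  out <- data.frame(x = g$x, y = g$y, Hx = Hx, Hy = Hy,
                    Hmag = sqrt(Hx^2 + Hy^2))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
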