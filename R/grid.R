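# Graded polar finite-volume grid on the tumor disk.
#
# Cell (i, j): radial interval [r_faces[i], r_faces[i+1]], angular interval
# of width dtheta centered on theta[j]. Linear index k = (j-1) * n_r + i.
# Radial spacing is dr_rim at the tumor rim, growing geometrically inward
# (factor `growth`) up to dr_max; the innermost cell absorbs the remainder.

#' Build the polar grid for a tumor geometry
#'
#' @param geometry a [geometry_spec()]
#' @param solver a [solver_settings()] (grid grading parameters)
#' @return object of class `polar_grid` with fields
#'   `r_faces` (length n_r+1, increasing, from 0 to R), `r` (cell-center
#'   radii), `dr`, `theta` (cell-center angles, one exactly at -pi/2, the
#'   penetration axis), `dtheta`, `area` (n_r x n_theta matrix of cell areas),
#'   `necrotic` (logical, r < Rn), `x`/`y` (cell-center Cartesian matrices),
#'   `n_r`, `n_theta`
#' @export
polar_grid <- function(geometry = geometry_spec(), solver = solver_settings()) {
  R <- geometry$R
  Rn <- geometry$Rn
  # radial faces from the rim inward
  dr <- solver$dr_rim
  faces <- R
  pos <- R
  while (pos > 0) {
    step <- min(dr, solver$dr_max)
    if (pos - step < step * 0.5) step <- pos  # absorb remainder at center
    pos <- pos - step
    faces <- c(faces, max(pos, 0))
    dr <- dr * solver$growth
  }
  r_faces <- rev(faces)
  if (Rn > 0 && !any(abs(r_faces - Rn) < 1e-12)) {
    # snap the closest face onto the necrotic interface so the source
    # switch is flux-conservative across it
    i <- which.min(abs(r_faces - Rn))
    i <- max(2L, min(length(r_faces) - 1L, i))
    r_faces[i] <- Rn
    r_faces <- sort(unique(r_faces))
  }
  n_r <- length(r_faces) - 1L
  r <- (r_faces[-1] + r_faces[-(n_r + 1)]) / 2
  drv <- diff(r_faces)
  n_theta <- solver$n_theta
  dtheta <- 2 * pi / n_theta
  theta <- -pi + (seq_len(n_theta) - 1L) * dtheta  # center at -pi/2 when 4|n_theta
  ring_area <- 0.5 * (r_faces[-1]^2 - r_faces[-(n_r + 1)]^2) * dtheta
  area <- matrix(ring_area, n_r, n_theta)
  xy_x <- outer(r, cos(theta))
  xy_y <- outer(r, sin(theta))
  structure(list(r_faces = r_faces, r = r, dr = drv, theta = theta,
                 dtheta = dtheta, area = area,
                 necrotic = r < Rn,
                 x = xy_x, y = xy_y,
                 n_r = n_r, n_theta = n_theta,
                 R = R, Rn = Rn),
            class = "polar_grid")
}

#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf("<polar_grid> %d x %d cells, R = %g mm (Rn = %g mm)\n",
              x$n_r, x$n_theta, x$R * 1e3, x$Rn * 1e3))
  cat(sprintf("  dr: %.3g um (rim) .. %.3g um (interior)\n",
              min(x$dr) * 1e6, max(x$dr) * 1e6))
  invisible(x)
}

# linear index helper
.cell_index <- function(grid, i, j) (j - 1L) * grid$n_r + i

#' Angle-averaged radial profile of a cell field
#'
#' @param values numeric vector (length n_r * n_theta) or n_r x n_theta matrix
#' @param grid a [polar_grid()]
#' @return data frame with columns `r` (m, increasing) and `value`
#' @export
radial_profile <- function(values, grid) {
  m <- matrix(values, grid$n_r, grid$n_theta)
  data.frame(r = grid$r, value = rowMeans(m))
}

#' Area-weighted tumor mean of a cell field
#'
#' @param values cell field (vector or matrix)
#' @param grid a [polar_grid()]
#' @return scalar mean over the whole tumor disk
#' @export
tumor_mean <- function(values, grid) {
  sum(values * grid$area) / sum(grid$area)
}
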