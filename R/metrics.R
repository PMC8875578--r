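# Treatment-efficacy metrics: cell survival, penetration half-depth w1/2,
# relative penetration area PA_rel, and the kill fractions FK_PA / FK_eff.

#' Fraction of surviving cells from internalized drug
#'
#' Exponential cell-survival model `SF = exp(-1e6 * omega * C_I)` with the
#' internalized concentration `C_I` entered on the molar scale (mol/L) of
#' the in vitro dose-response the survival constant derives from. With
#' `C_I` supplied in the package's SI unit (mol m^-3) this is
#' `SF = exp(-1e3 * omega * C_I)`. The fraction of killed cells is
#' `FK = 1 - SF`.
#'
#' @param C_I internalized drug concentration (mol m^-3), vector or matrix
#' @param omega cell-survival constant (m^3 mol^-1), default 0.4938
#' @return survival fraction in (0, 1], same shape as `C_I`
#' @export
survival_fraction <- function(C_I, omega = 0.4938) {
  if (any(C_I < 0)) stop("survival_fraction(): negative C_I", call. = FALSE)
  exp(-1e6 * omega * C_I / 1e3)
}

#' Penetration half-depth w1/2
#'
#' Distance from the tumor rim, along a ray, at which the free-drug
#' concentration first falls to 50% of its value at the tumor border.
#' For conventional IPC the field is radially symmetric and the
#' angle-averaged radial profile is used; for magnet-assisted delivery the
#' ray is the vertical diameter on the penetration side (the tumor face away
#' from the magnet, where the magnetic force pushes drug inward), continued
#' through the center to the opposite rim. If the profile never crosses the
#' half value the full ray length is returned with `full_penetration = TRUE`.
#'
#' @param CF free-drug field (n_r x n_theta)
#' @param grid a [polar_grid()]
#' @param bc the [boundary_conditions()] of the run (rim concentration)
#' @param ray `"average"` (angle-averaged radial profile, conventional) or
#'   `"penetration-axis"` (vertical diameter from the bottom rim)
#' @return list with `w_half` (m), `w_half_rel` (% of R),
#'   `full_penetration`, and the sampled `profile` (depth, value)
#' @export
penetration_half_depth <- function(CF, grid, bc,
                                   ray = c("penetration-axis", "average")) {
  ray <- match.arg(ray)
  if (bc$C_outer <= 0) {
    stop("penetration_half_depth(): rim concentration is zero", call. = FALSE)
  }
  CF <- matrix(CF, grid$n_r, grid$n_theta)
  if (ray == "average") {
    depth <- grid$R - rev(grid$r)
    vals <- rev(rowMeans(CF))
    ray_len <- grid$R
  } else {
    j_bot <- which.min(abs(grid$theta + pi / 2))
    j_top <- which.min(abs(grid$theta - pi / 2))
    depth <- c(grid$R - rev(grid$r), grid$R + grid$r)
    vals <- c(rev(CF[, j_bot]), CF[, j_top])
    ray_len <- 2 * grid$R
  }
  depth <- c(0, depth)
  vals <- c(bc$C_outer, vals)
  half <- 0.5 * bc$C_outer
  below <- which(vals < half)
  if (!length(below)) {
    return(list(w_half = ray_len, w_half_rel = ray_len / grid$R * 100,
                full_penetration = TRUE,
                profile = data.frame(depth = depth, value = vals)))
  }
  i <- below[1]
  # linear interpolation between the last point above and first below
  w <- depth[i - 1] + (depth[i] - depth[i - 1]) *
    (vals[i - 1] - half) / (vals[i - 1] - vals[i])
  list(w_half = w, w_half_rel = w / grid$R * 100, full_penetration = FALSE,
       profile = data.frame(depth = depth, value = vals))
}

#' Drug penetration area
#'
#' Total area of cells whose free-drug concentration is at least
#' `threshold_frac` of the rim concentration, and its percentage of the
#' tumor cross-section. The default threshold, 0.5% of the border
#' concentration, is the package's operational definition of "drug-reached"
#' tissue (see the methods vignette for its calibration and sensitivity).
#'
#' @param CF free-drug field (n_r x n_theta)
#' @param grid a [polar_grid()]
#' @param bc run boundary conditions (rim concentration)
#' @param threshold_frac threshold as a fraction of `C_outer`, in (0, 1)
#' @return list with `PA` (m^2), `PA_rel` (%), logical `mask`
#'   (n_r x n_theta), and `threshold_used`
#' @export
penetration_area <- function(CF, grid, bc, threshold_frac = 0.005) {
  stopifnot(threshold_frac > 0, threshold_frac < 1)
  CF <- matrix(CF, grid$n_r, grid$n_theta)
  mask <- CF >= threshold_frac * bc$C_outer
  PA <- sum(grid$area[mask])
  list(PA = PA, PA_rel = PA / sum(grid$area) * 100, mask = mask,
       threshold_used = threshold_frac)
}

#' Kill fractions over the penetration area
#'
#' `FK_PA`: area-weighted mean fraction of killed cells `1 - SF(C_I)` over
#' the penetration area, in percent. `FK_eff = FK_PA * PA_rel / 100`: the
#' effective kill fraction referred to the whole tumor (the product identity
#' the efficacy tables obey). An empty penetration area reports zero with a
#' flag.
#'
#' @param CI internalized-drug field (n_r x n_theta)
#' @param pa a [penetration_area()] result
#' @param grid a [polar_grid()]
#' @param omega cell-survival constant
#' @return list with `FK_PA` (%), `FK_eff` (%), `empty_PA`
#' @export
kill_metrics <- function(CI, pa, grid, omega = 0.4938) {
  CI <- matrix(CI, grid$n_r, grid$n_theta)
  if (!any(pa$mask)) {
    return(list(FK_PA = 0, FK_eff = 0, empty_PA = TRUE))
  }
  FK <- 1 - survival_fraction(CI, omega)
  FK_PA <- sum(FK[pa$mask] * grid$area[pa$mask]) / sum(grid$area[pa$mask]) * 100
  list(FK_PA = FK_PA, FK_eff = FK_PA * pa$PA_rel / 100, empty_PA = FALSE)
}

#' Full efficacy report for a finished run
#'
#' Computes w1/2 (on the ray appropriate to the scenario), PA_rel, FK_PA,
#' FK_eff, the final tumor-mean concentrations, and a small threshold
#' sensitivity table for the penetration area.
#'
#' @param run a [run_transient()] result
#' @param config the scenario it came from
#' @param threshold_frac penetration-area threshold (fraction of `C_outer`)
#' @return object of class `efficacy_report`
#' @export
efficacy_report <- function(run, config, threshold_frac = 0.005) {
  grid <- run$grid
  bc <- config$bc
  magnetic <- !is.null(config$magnet) && config$magnet$B_rem > 0
  wh <- penetration_half_depth(run$final$CF, grid, bc,
                               ray = if (magnetic) "penetration-axis" else "average")
  pa <- penetration_area(run$final$CF, grid, bc, threshold_frac)
  km <- kill_metrics(run$final$CI, pa, grid, config$kinetics$omega)
  sens <- vapply(c(0.001, 0.0025, 0.005, 0.01, 0.05),
                 function(f) penetration_area(run$final$CF, grid, bc, f)$PA_rel,
                 numeric(1))
  structure(list(
    w_half = wh$w_half, w_half_rel = wh$w_half_rel,
    full_penetration = wh$full_penetration,
    PA = pa$PA, PA_rel = pa$PA_rel, threshold_used = threshold_frac,
    FK_PA = km$FK_PA, FK_eff = km$FK_eff, empty_PA = km$empty_PA,
    mean_CF = tumor_mean(run$final$CF, grid),
    mean_CB = tumor_mean(run$final$CB, grid),
    mean_CI = tumor_mean(run$final$CI, grid),
    PA_rel_vs_threshold = data.frame(
      threshold_frac = c(0.001, 0.0025, 0.005, 0.01, 0.05), PA_rel = sens)
  ), class = "efficacy_report")
}

#' @export
print.efficacy_report <- function(x, ...) {
  cat("<efficacy_report>\n")
  cat(sprintf("  w1/2   = %.4g cm (%.3g%% of R)%s\n", x$w_half * 100,
              x$w_half_rel, if (x$full_penetration) " [full penetration]" else ""))
  cat(sprintf("  PA_rel = %.4g%%  (threshold %.2g%% of C_outer)\n",
              x$PA_rel, x$threshold_used * 100))
  cat(sprintf("  FK_PA  = %.4g%%, FK_eff = %.4g%%\n", x$FK_PA, x$FK_eff))
  cat(sprintf("  mean C_F/C_B/C_I = %.4g / %.4g / %.4g mol m^-3\n",
              x$mean_CF, x$mean_CB, x$mean_CI))
  invisible(x)
}

#' Calibrate the rim drug concentration
#'
#' The transport system is linear in the concentrations, so the rim value
#' that makes the 60-min tumor-mean free-drug concentration hit a target is
#' obtained exactly from one unit-boundary run:
#' `C_outer = target / mean_CF(unit run)`.
#'
#' @param config a conventional-IPC [scenario_config()]
#' @param target_mean_CF target tumor-mean free-drug concentration at the
#'   end of the run (mol m^-3)
#' @param unit_run optional precomputed [run_transient()] of `config` with
#'   `C_outer = 1`
#' @return list with `C_outer` (mol m^-3), the `unit_mean` it was derived
#'   from, and the `unit_run`
#' @export
calibrate_boundary_concentration <- function(config, target_mean_CF = 0.0013,
                                             unit_run = NULL) {
  stopifnot(target_mean_CF > 0)
  if (is.null(unit_run)) {
    cfg1 <- config
    cfg1$bc$C_outer <- 1
    unit_run <- run_transient(cfg1)
  }
  m <- tumor_mean(unit_run$final$CF, unit_run$grid)
  if (m <= 0) {
    stop("calibrate_boundary_concentration(): degenerate unit run ",
         "(zero mean concentration)", call. = FALSE)
  }
  list(C_outer = target_mean_CF / m, unit_mean = m, unit_run = unit_run)
}
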