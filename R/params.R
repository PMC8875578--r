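#' @title Model parameter containers
#' @description Constructors for the parameter groups of the IP drug-targeting
#'   model. All values are stored in SI units (m, s, Pa, mol m^-3, T). The
#'   defaults are the tumor-tissue and solute-transport parameter sets commonly
#'   used for doxorubicin transport in solid tumors (hydraulic conductivities,
#'   Starling pressures, binding/internalization kinetics), unit-normalized.
#' @name mcdtsim-params
NULL

stop_invalid <- function(errors) {
  if (length(errors)) {
    stop("invalid parameters:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
}

#' Tissue and interstitial-flow parameters
#'
#' @param kappa interstitium hydraulic conductivity (m^2 Pa^-1 s^-1)
#' @param Lp microvascular wall hydraulic conductivity (m Pa^-1 s^-1)
#' @param SV vascular surface area per tissue volume (m^-1)
#' @param PB vascular fluid pressure (Pa)
#' @param piB plasma osmotic pressure (Pa)
#' @param pii interstitial fluid osmotic pressure (Pa)
#' @param sigma_s osmotic reflection coefficient for plasma proteins (0..1)
#' @param Lpl lymphatic wall hydraulic conductivity (m Pa^-1 s^-1); solid
#'   tumors lack a functional lymphatic system, so the default is 0
#' @param SLV lymphatic surface area per volume (m^-1)
#' @param PL lymphatic pressure (Pa)
#' @param eta interstitial fluid dynamic viscosity (Pa s)
#' @return object of class `tissue_params`
#' @export
tissue_params <- function(kappa = 3e-14, Lp = 2.10e-11, SV = 2e4,
                          PB = 2.1e3, piB = 2.7e3, pii = 2e3, sigma_s = 0.9,
                          Lpl = 0, SLV = 0, PL = 0, eta = 1.12e-3) {
  p <- list(kappa = kappa, Lp = Lp, SV = SV, PB = PB, piB = piB, pii = pii,
            sigma_s = sigma_s, Lpl = Lpl, SLV = SLV, PL = PL, eta = eta)
  errors <- character()
  for (f in c("kappa", "Lp", "SV", "Lpl", "SLV", "eta"))
    if (p[[f]] < 0) errors <- c(errors, paste0(f, " must be >= 0"))
  if (sigma_s < 0 || sigma_s > 1) errors <- c(errors, "sigma_s must be in [0, 1]")
  if (eta <= 0) errors <- c(errors, "eta must be > 0")
  stop_invalid(errors)
  structure(p, class = "tissue_params")
}

#' Effective Starling equilibrium pressure
#'
#' The interstitial pressure at which transvascular filtration vanishes:
#' `P_e = PB - sigma_s * (piB - pii)`. It is the upper bound of the interstitial
#' fluid pressure (discrete maximum principle).
#'
#' @param tissue a [tissue_params()] object
#' @return scalar pressure (Pa)
#' @export
starling_equilibrium_pressure <- function(tissue) {
  tissue$PB - tissue$sigma_s * (tissue$piB - tissue$pii)
}

#' Drug binding/internalization kinetics and cell-survival parameters
#'
#' @param K_ON binding rate constant (m^3 mol^-1 s^-1); default 0.15
#'   (= 1.5e2 per molar per second)
#' @param K_OFF unbinding rate constant (s^-1)
#' @param K_INT internalization rate constant (s^-1)
#' @param C_rec cell-surface receptor concentration (mol m^-3); default 1e-2
#'   (= 10 micromolar)
#' @param phi tumor volume fraction accessible to the drug (0..1]
#' @param D_eff reference effective diffusion coefficient of the carrier in
#'   tissue at the 100 nm reference radius (m^2 s^-1)
#' @param omega cell-survival constant (m^3 mol^-1); see [survival_fraction()]
#' @return object of class `kinetic_params`
#' @export
kinetic_params <- function(K_ON = 0.15, K_OFF = 8e-3, K_INT = 5e-5,
                           C_rec = 1e-2, phi = 0.3, D_eff = 3.40e-10,
                           omega = 0.4938) {
  p <- list(K_ON = K_ON, K_OFF = K_OFF, K_INT = K_INT, C_rec = C_rec,
            phi = phi, D_eff = D_eff, omega = omega)
  errors <- character()
  for (f in c("K_ON", "K_OFF", "K_INT", "C_rec", "D_eff", "omega"))
    if (p[[f]] < 0) errors <- c(errors, paste0(f, " must be >= 0"))
  if (phi <= 0 || phi > 1) errors <- c(errors, "phi must be in (0, 1]")
  stop_invalid(errors)
  structure(p, class = "kinetic_params")
}

#' Transvascular solute-exchange parameters (pore model)
#'
#' @param P_perm microvessel permeability coefficient (m s^-1); default 3e-6
#'   (= 3.00e-4 cm/s)
#' @param sigma_f osmotic reflection coefficient for the nanoparticles (0..1)
#' @param C_p drug concentration in blood plasma (mol m^-3); 0 for
#'   intraperitoneal administration (plasma acts as a pure sink)
#' @return object of class `vascular_params`
#' @export
vascular_params <- function(P_perm = 3.00e-6, sigma_f = 0, C_p = 0) {
  errors <- character()
  if (P_perm < 0) errors <- c(errors, "P_perm must be >= 0")
  if (sigma_f < 0 || sigma_f > 1) errors <- c(errors, "sigma_f must be in [0, 1]")
  if (C_p < 0) errors <- c(errors, "C_p must be >= 0")
  stop_invalid(errors)
  structure(list(P_perm = P_perm, sigma_f = sigma_f, C_p = C_p),
            class = "vascular_params")
}

#' Permanent-magnet specification
#'
#' The magnet is a uniformly magnetized rectangle (plane magnetostatics,
#' infinitely long cross-section) centered on the vertical axis through the
#' tumor center, on the +y side, with remanence along -y (toward the tumor).
#' `distance_d` is measured from the tumor center to the nearest magnet face.
#' The drug therefore enters the tumor from its lower (-y) face and is pushed
#' up toward the magnet.
#'
#' @param length_l in-plane magnet length, the dimension transverse to the
#'   tumor axis (m)
#' @param height_h in-plane magnet height, along the tumor axis (m)
#' @param distance_d separation from tumor center to the nearest face (m)
#' @param B_rem remnant magnetic flux density (T); 0 disables the magnet
#' @param mu_r relative permeability of the magnet body (>= 1). It is absorbed
#'   by the equivalent surface-current representation and retained for
#'   provenance only.
#' @return object of class `magnet_spec`
#' @export
magnet_spec <- function(length_l = 0.20, height_h = 0.10, distance_d = 0.05,
                        B_rem = 1.5, mu_r = 1000) {
  errors <- character()
  if (length_l <= 0) errors <- c(errors, "length_l must be > 0")
  if (height_h <= 0) errors <- c(errors, "height_h must be > 0")
  if (distance_d <= 0) errors <- c(errors, "distance_d must be > 0")
  if (B_rem < 0) errors <- c(errors, "B_rem must be >= 0")
  if (mu_r < 1) errors <- c(errors, "mu_r must be >= 1")
  stop_invalid(errors)
  structure(list(length_l = length_l, height_h = height_h,
                 distance_d = distance_d, B_rem = B_rem, mu_r = mu_r,
                 placement = "axis+y_remanence-y"),
            class = "magnet_spec")
}

#' Magnetic-nanoparticle (drug carrier) specification
#'
#' @param radius_a hydrodynamic particle radius (m)
#' @param chi magnetic susceptibility of the particle material (> 0). The
#'   effective susceptibility entering the force is `chi / (1 + chi/3)`
#'   (self-demagnetization of a sphere).
#' @param mu0_Msat saturation magnetization expressed as flux density
#'   `mu0 * M_sat` (T); well-made magnetite particles saturate near 0.5 T
#' @param mobility_scale dimensionless magnetophoretic mobility amplification
#'   applied to the carrier drift velocity (default 1). The effective magnetic
#'   moment per hydrodynamic radius of drug-coated carriers (clusters,
#'   multi-core beads) is poorly constrained; this single scalar absorbs it
#'   and is set by [calibrate_mobility()] against a penetration-depth anchor.
#' @param hindrance_scale length scale L (m) of the exponential
#'   extracellular-matrix hindrance of carrier motion in tissue: the tissue
#'   drag on a carrier of radius a is `6 pi a eta * exp((a - a_ref)/L)`, so
#'   both diffusivity and drift are reduced by `exp(-(a - a_ref)/L)` relative
#'   to free Stokes drag, with `a_ref` = 100 nm. Default 160 nm, which places
#'   the drift-mobility optimum `a* = 2L` near a 300 nm radius.
#' @return object of class `nanoparticle_spec`, with derived field `volume`
#' @export
nanoparticle_spec <- function(radius_a = 100e-9, chi = 1, mu0_Msat = 0.5,
                              mobility_scale = 1, hindrance_scale = 160e-9) {
  errors <- character()
  if (radius_a <= 0) errors <- c(errors, "radius_a must be > 0")
  if (chi <= 0) errors <- c(errors, "chi must be > 0")
  if (mu0_Msat < 0) errors <- c(errors, "mu0_Msat must be >= 0")
  if (mobility_scale < 0) errors <- c(errors, "mobility_scale must be >= 0")
  if (hindrance_scale <= 0) errors <- c(errors, "hindrance_scale must be > 0")
  stop_invalid(errors)
  structure(list(radius_a = radius_a, chi = chi, mu0_Msat = mu0_Msat,
                 mobility_scale = mobility_scale,
                 hindrance_scale = hindrance_scale,
                 volume = 4 / 3 * pi * radius_a^3),
            class = "nanoparticle_spec")
}

#' Tumor geometry
#'
#' @param R tumor radius (m)
#' @param Rn necrotic core radius (m), `0 <= Rn < R`. The core lacks
#'   functional blood and lymph vessels: no fluid or solute exchange there.
#'   Default 0 (no core); see the methods vignette for the sensitivity of
#'   deep-penetration scenarios to this choice.
#' @param center tumor center coordinates (m); the magnet placement convention
#'   is defined relative to this point
#' @return object of class `geometry_spec`
#' @export
geometry_spec <- function(R = 0.01, Rn = 0, center = c(0, 0)) {
  errors <- character()
  if (R <= 0) errors <- c(errors, "R must be > 0")
  if (Rn < 0 || Rn >= R) errors <- c(errors, "Rn must satisfy 0 <= Rn < R")
  if (length(center) != 2L) errors <- c(errors, "center must have length 2")
  stop_invalid(errors)
  structure(list(R = R, Rn = Rn, center = as.numeric(center)),
            class = "geometry_spec")
}

#' Dirichlet boundary values at the tumor rim
#'
#' @param Pi_outer interstitial fluid pressure at the tumor rim (Pa); the
#'   peritoneal fluid is the pressure gauge, so the default is 0
#' @param C_outer free-drug concentration at the tumor rim (mol m^-3), held
#'   constant over the treatment hour (continuous IP instillation); typically
#'   set by [calibrate_boundary_concentration()]
#' @return object of class `boundary_conditions`
#' @export
boundary_conditions <- function(Pi_outer = 0, C_outer = 1) {
  errors <- character()
  if (C_outer < 0) errors <- c(errors, "C_outer must be >= 0")
  stop_invalid(errors)
  structure(list(Pi_outer = Pi_outer, C_outer = C_outer),
            class = "boundary_conditions")
}

#' Discretization and solver settings
#'
#' The polar grid is graded in radius: spacing `dr_rim` at the tumor rim
#' (resolving the ~60 um convection-diffusion boundary layer with several
#' cells) growing geometrically inward by `growth` up to `dr_max`.
#'
#' @param n_theta number of uniform angular cells (multiple of 4 so a cell
#'   center lies exactly on the penetration axis)
#' @param dr_rim radial spacing of the outermost cell (m)
#' @param dr_max interior radial spacing cap (m)
#' @param growth geometric grading factor (> 1)
#' @param dt transport time step (s)
#' @param t_end treatment horizon (s)
#' @param checkpoint_dt interval for recorded concentration checkpoints (s)
#' @param theta_scheme implicitness weight in \[0.5, 1\]; 1 = backward Euler
#'   (default), 0.5 = Crank-Nicolson for the transport/loss terms (binding
#'   kinetics are always integrated implicitly)
#' @param lin_tol residual tolerance for the linear solves
#' @return object of class `solver_settings`
#' @export
solver_settings <- function(n_theta = 48, dr_rim = 8e-6, dr_max = 1e-4,
                            growth = 1.15, dt = 2, t_end = 3600,
                            checkpoint_dt = 300, theta_scheme = 1,
                            lin_tol = 1e-10) {
  errors <- character()
  if (n_theta < 4 || n_theta %% 4 != 0)
    errors <- c(errors, "n_theta must be a positive multiple of 4")
  if (dr_rim <= 0 || dr_rim > 1e-5)
    errors <- c(errors, "dr_rim must be in (0, 1e-5] m")
  if (dr_max < dr_rim) errors <- c(errors, "dr_max must be >= dr_rim")
  if (growth <= 1) errors <- c(errors, "growth must be > 1")
  if (dt <= 0 || dt > 5) errors <- c(errors, "dt must be in (0, 5] s")
  if (t_end <= 0) errors <- c(errors, "t_end must be > 0")
  if (theta_scheme < 0.5 || theta_scheme > 1)
    errors <- c(errors, "theta_scheme must be in [0.5, 1]")
  if (lin_tol <= 0) errors <- c(errors, "lin_tol must be > 0")
  stop_invalid(errors)
  structure(list(n_theta = as.integer(n_theta), dr_rim = dr_rim,
                 dr_max = dr_max, growth = growth, dt = dt, t_end = t_end,
                 checkpoint_dt = checkpoint_dt, theta_scheme = theta_scheme,
                 lin_tol = lin_tol),
            class = "solver_settings")
}

#' Assemble a full scenario configuration
#'
#' A scenario bundles every parameter group needed by [run_scenario()].
#' Passing `magnet = NULL` (or `B_rem = 0`) yields conventional IP
#' chemotherapy with no magnetic drift.
#'
#' @param tissue,kinetics,vascular,magnet,particle,geometry,bc,solver parameter
#'   objects; `NULL` fields are filled with the package defaults
#' @param label free-form scenario label used in reports
#' @return object of class `mcdt_scenario`
#' @export
scenario_config <- function(tissue = NULL, kinetics = NULL, vascular = NULL,
                            magnet = NULL, particle = NULL, geometry = NULL,
                            bc = NULL, solver = NULL, label = "scenario") {
  cfg <- list(
    tissue   = tissue   %||% tissue_params(),
    kinetics = kinetics %||% kinetic_params(),
    vascular = vascular %||% vascular_params(),
    magnet   = magnet,  # NULL means: no magnet
    particle = particle %||% nanoparticle_spec(),
    geometry = geometry %||% geometry_spec(),
    bc       = bc       %||% boundary_conditions(),
    solver   = solver   %||% solver_settings(),
    label    = label
  )
  structure(cfg, class = "mcdt_scenario")
}

#' Conventional-IPC scenario (no magnet)
#'
#' @param ... overrides forwarded to [scenario_config()]
#' @return `mcdt_scenario` with `magnet = NULL`
#' @export
conventional_scenario <- function(...) {
  scenario_config(..., magnet = NULL, label = "conventional")
}

#' Baseline magnet-assisted scenario
#'
#' 100 nm particles, a 20 x 10 cm magnet of 1.5 T remanence at 5 cm from the
#' tumor center.
#'
#' @param ... overrides forwarded to [scenario_config()]
#' @return `mcdt_scenario`
#' @export
magnetic_baseline_scenario <- function(...) {
  args <- list(...)
  if (is.null(args$magnet)) args$magnet <- magnet_spec()
  if (is.null(args$label)) args$label <- "magnetic-baseline"
  do.call(scenario_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mcdt_scenario <- function(x, ...) {
  cat("<mcdt_scenario>", x$label, "\n")
  cat("  tumor R =", x$geometry$R * 1e3, "mm, Rn =", x$geometry$Rn * 1e3, "mm\n")
  if (is.null(x$magnet) || x$magnet$B_rem == 0) {
    cat("  magnet: none (conventional IPC)\n")
  } else {
    cat(sprintf("  magnet: %.2g x %.2g m, B_rem = %.3g T at d = %.3g m\n",
                x$magnet$length_l, x$magnet$height_h, x$magnet$B_rem,
                x$magnet$distance_d))
    cat(sprintf("  particle: a = %.3g nm, mobility_scale = %.4g\n",
                x$particle$radius_a * 1e9, x$particle$mobility_scale))
  }
  cat(sprintf("  bc: Pi_outer = %g Pa, C_outer = %.4g mol/m^3\n",
              x$bc$Pi_outer, x$bc$C_outer))
  invisible(x)
}
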