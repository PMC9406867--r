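#' IEC-style exposure limits
#'
#' Whole-body and local 10 g SAR limits in the normal operating mode of a
#' local transmit coil, the 6-minute temporal averaging window, the
#' anatomical K2 exception for knee implants, and the gradient-coil
#' temperature-rise thresholds (trunk vs limb normal temperature).
#'
#' @param K1 Whole-body SAR limit, W/kg.
#' @param K2 Local 10 g SAR limit, W/kg.
#' @param K2_knee_multiplier Multiplier applied to `K2` for knee implants.
#' @param TIEC SAR temporal averaging window, s.
#' @param gc_threshold_trunk Temperature-rise threshold for hip/shoulder, degC.
#' @param gc_threshold_limb Temperature-rise threshold for knee, degC.
#' @return An object of class `iec_limits`.
#' @export
iec_limits <- function(K1 = 2, K2 = 10, K2_knee_multiplier = 2, TIEC = 360,
                       gc_threshold_trunk = 2, gc_threshold_limb = 3) {
  vals <- c(K1, K2, K2_knee_multiplier, TIEC, gc_threshold_trunk,
            gc_threshold_limb)
  if (any(vals <= 0)) stop("all limits must be positive")
  structure(list(K1 = K1, K2 = K2, K2_knee_multiplier = K2_knee_multiplier,
                 TIEC = TIEC, gc_threshold_trunk = gc_threshold_trunk,
                 gc_threshold_limb = gc_threshold_limb),
            class = "iec_limits")
}

#' RF exposure configuration
#'
#' Bundles the voxel fields describing one RF configuration (coil, subject,
#' imaging region, implant): complex transmit-sensitivity map at nominal
#' drive, nominal SAR map, density map and body mask, plus the central-slab
#' thickness used by the flip-angle calibration.
#'
#' @param b1_map Complex `voxel_field` (tesla at nominal drive).
#' @param sar_map `voxel_field` of nominal SAR (W/kg).
#' @param density_map `voxel_field` of mass density (kg/m^3).
#' @param body_mask `voxel_field` mask of the subject.
#' @param slab_thickness Central-slab thickness (m) for calibration.
#' @param beta Optional pre-computed scaling factor (see [calibrate_beta()]).
#' @return An object of class `rf_configuration`.
#' @export
rf_configuration <- function(b1_map, sar_map, density_map, body_mask,
                             slab_thickness = 0.05, beta = NULL) {
  stop_grid_mismatch(b1_map, sar_map, "b1/sar")
  stop_grid_mismatch(b1_map, density_map, "b1/density")
  stop_grid_mismatch(b1_map, body_mask, "b1/mask")
  if (!is.null(beta) && beta <= 0) stop("beta must be positive")
  structure(list(b1_map = b1_map, sar_map = sar_map,
                 density_map = density_map, body_mask = body_mask,
                 slab_thickness = slab_thickness, beta = beta),
            class = "rf_configuration")
}

#' Calibrate the drive scaling factor of an RF configuration
#'
#' Finds the factor \eqn{\beta_C} applied to the nominal transmit
#' sensitivity such that a 1 ms hard pulse produces a 90-degree flip angle,
#' defined as the maximiser of the complex free-induction-decay signal
#' \deqn{\left| \int_V \sin(\beta_C |B_1^+(x)| \gamma \Delta t)\,
#'   e^{i\varphi^+(x)} \, dv \right|}
#' over a central axial slab of the body.  The search brackets the maximum
#' on a dense grid (expanded until the maximum is interior) and refines it
#' with bounded 1-d optimisation; ties resolve to the smallest
#' \eqn{\beta_C}.
#'
#' @param cfg An [rf_configuration()].
#' @param n_grid Dense-grid size per bracket.
#' @return The scaling factor (numeric); the attribute `objective` carries
#'   the attained maximum.
#' @export
calibrate_beta <- function(cfg, n_grid = 1024) {
  cst <- mri_constants()
  zc <- voxel_coords(cfg$b1_map)$z
  slab <- abs(zc) <= cfg$slab_thickness / 2 & cfg$body_mask$values > 0
  if (!any(slab)) stop("no signal region: empty central slab")
  b <- Mod(cfg$b1_map$values[slab])
  ph <- Arg(cfg$b1_map$values[slab])
  if (max(b) == 0) stop("no signal region: B1 is zero in the central slab")
  eiphi <- complex(modulus = 1, argument = ph)
  objective <- function(beta)
    Mod(sum(sin(beta * b * cst$gamma * cst$dt_ref) * eiphi))
  upper <- 4 * (pi / 2) / (cst$gamma * cst$dt_ref * stats::median(b[b > 0]))
  for (i in 1:30) {
    grid <- seq(0, upper, length.out = n_grid)[-1]
    vals <- vapply(grid, objective, numeric(1))
    if (max(vals) <= 1e-12 * length(b)) {
      warning("degenerate phase distribution: objective vanishes for all beta")
      return(structure(grid[1], objective = 0))
    }
    i_max <- which.max(vals)            # first (smallest-beta) maximum
    if (i_max < n_grid - 1) break
    upper <- 2 * upper
  }
  lo <- grid[max(1, i_max - 1)]
  hi <- grid[min(length(grid), i_max + 1)]
  opt <- stats::optimize(objective, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5 * upper)
  structure(opt$maximum, objective = opt$objective)
}

#' Configuration index \eqn{\xi_C(x)}
#'
#' Elementwise rescaling of the nominal SAR map by the squared calibration
#' factor: \eqn{\xi_C(x) = \beta_C^2\, SAR^C(x)}, the SAR distribution a
#' 90-degree/1 ms hard pulse train of unit duty would deposit.
#'
#' @param cfg An [rf_configuration()]; `cfg$beta` must be set (assign the
#'   result of [calibrate_beta()]).
#' @return A `voxel_field` of kind `"xi"` (W/kg).
#' @export
configuration_index <- function(cfg) {
  if (is.null(cfg$beta))
    stop("uncalibrated configuration: set cfg$beta with calibrate_beta()")
  voxel_field(as.numeric(cfg$beta)^2 * cfg$sar_map$values,
              spacing = cfg$sar_map$spacing, origin = cfg$sar_map$origin,
              kind = "xi")
}

#' Mass-weighted whole-body average of a configuration index
#'
#' @param xi `voxel_field` of \eqn{\xi_C} values (W/kg).
#' @param density `voxel_field` of mass density (kg/m^3).
#' @param mask `voxel_field` body mask.
#' @return Whole-body averaged value, W/kg.
#' @export
whole_body_average <- function(xi, density, mask) {
  stop_grid_mismatch(xi, density, "xi/density")
  stop_grid_mismatch(xi, mask, "xi/mask")
  m <- density$values * mask$values
  if (sum(m) == 0) stop("empty mask")
  sum(xi$values * m) / sum(m)
}

# 3-d summed-area table padded with a zero slab on the low side of each axis.
sat3d <- function(a) {
  d <- dim(a)
  p <- array(0, d + 1L)
  p[-1, -1, -1] <- a
  p <- aperm(apply(p, c(2, 3), cumsum), c(1, 2, 3))
  p <- aperm(apply(p, c(1, 3), cumsum), c(2, 1, 3))
  aperm(apply(p, c(1, 2), cumsum), c(2, 3, 1))
}

# Vectorized box sums over [i1..i2, j1..j2, k1..k2] given a padded SAT.
sat_box <- function(sat, i1, i2, j1, j2, k1, k2) {
  dp <- dim(sat)
  at <- function(i, j, k) sat[cbind(i, j, k)]
  at(i2 + 1, j2 + 1, k2 + 1) - at(i1, j2 + 1, k2 + 1) -
    at(i2 + 1, j1, k2 + 1) - at(i2 + 1, j2 + 1, k1) +
    at(i1, j1, k2 + 1) + at(i1, j2 + 1, k1) + at(i2 + 1, j1, k1) -
    at(i1, j1, k1)
}

#' Peak 10 g averaged configuration index
#'
#' For every in-mask voxel, averages \eqn{\xi} (mass-weighted) over the
#' smallest grid-aligned cube centred on the voxel whose in-mask mass
#' reaches `target_mass`; cubes reaching the grid boundary are clipped and
#' keep growing along the valid directions.  Returns the maximum over
#' voxels — the regulatory "maximum 10 g SAR" surrogate (simplified
#' IEC 62704-1 style centred-cube scheme).
#'
#' @inheritParams whole_body_average
#' @param target_mass Averaging mass in kg (default 0.010).
#' @return Peak 10 g averaged value, W/kg.
#' @export
sar10g_peak <- function(xi, density, mask, target_mass = 0.010) {
  stop_grid_mismatch(xi, density, "xi/density")
  stop_grid_mismatch(xi, mask, "xi/mask")
  dV <- voxel_volume(xi)
  m <- density$values * mask$values * dV
  if (sum(m) < target_mass)
    stop("object too small: total in-mask mass below the averaging mass")
  s <- xi$values * m
  satm <- sat3d(m)
  sats <- sat3d(s)
  d <- xi$dims
  idx <- which(mask$values > 0)
  ai <- arrayInd(idx, d)
  n <- nrow(ai)
  h <- rep.int(0L, n)
  avg <- rep.int(NA_real_, n)
  pending <- seq_len(n)
  hw <- 0L
  hmax <- max(d)
  while (length(pending) && hw <= hmax) {
    i1 <- pmax(ai[pending, 1] - hw, 1L); i2 <- pmin(ai[pending, 1] + hw, d[1])
    j1 <- pmax(ai[pending, 2] - hw, 1L); j2 <- pmin(ai[pending, 2] + hw, d[2])
    k1 <- pmax(ai[pending, 3] - hw, 1L); k2 <- pmin(ai[pending, 3] + hw, d[3])
    mass <- sat_box(satm, i1, i2, j1, j2, k1, k2)
    done <- mass >= target_mass
    if (any(done)) {
      sel <- pending[done]
      avg[match(sel, seq_len(n))] <-
        sat_box(sats, i1[done], i2[done], j1[done], j2[done],
                k1[done], k2[done]) / mass[done]
      pending <- pending[!done]
    }
    hw <- hw + 1L
  }
  if (anyNA(avg)) {
    # cubes that swallowed the whole grid without reaching the mass: skip
    avg <- avg[!is.na(avg)]
    if (!length(avg)) stop("object too small: no valid averaging cube")
  }
  max(avg)
}

#' Temporal SAR averages of a scenario
#'
#' The TR-averaged SAR (which also represents the IEC 10 s average, since
#' clinical TR << 10 s << sequence duration) and the 6-minute average.  For
#' a sequence of duration `TS` shorter than the window the 6-minute average
#' is the TR average scaled by `TS / TIEC`; longer sequences use the full TR
#' average.
#'
#' @param psi Sequence stress index \eqn{\psi_S}.
#' @param xi_value A configuration-index value (W/kg): whole-body average or
#'   peak 10 g.
#' @param TS Sequence duration, s.
#' @param limits An [iec_limits()].
#' @return List with elements `tr` and `tiec` (W/kg).
#' @export
temporal_averages <- function(psi, xi_value, TS, limits = iec_limits()) {
  if (TS <= 0) stop("TS must be positive")
  tr_avg <- psi * xi_value
  list(tr = tr_avg, tiec = min(1, TS / limits$TIEC) * tr_avg)
}

#' Admissible 10 g configuration-index threshold for a sequence
#'
#' Combining the two local-SAR limits (6-minute vs `K2`, TR-average vs
#' `2 K2`) gives the largest admissible peak 10 g configuration index for a
#' sequence of stress index `psi` and duration `TS`:
#' \deqn{\xi_{10g,S}^* = \min(2, T_{IEC}/T_S)\, K_2^{eff} / \psi_S.}
#' For `TS <= TIEC/2` the threshold depends only on `psi`.
#'
#' @param psi Sequence stress index (> 0).
#' @param TS Sequence duration, s.
#' @param K2_eff Effective local limit (W/kg), i.e. `K2` times any
#'   anatomical multiplier.
#' @param limits An [iec_limits()].
#' @return Threshold in W/kg.
#' @export
xi_threshold <- function(psi, TS, K2_eff = NULL, limits = iec_limits()) {
  if (psi <= 0)
    stop("unbounded threshold: sequence deposits no RF power (psi = 0)")
  if (is.null(K2_eff)) K2_eff <- limits$K2
  min(2, limits$TIEC / TS) * K2_eff / psi
}

#' Sensitivity of the SAR averages to the RF pulse length
#'
#' Rescales every pulse duration by `1 + rel_change` at fixed flip angle and
#' fixed time-bandwidth product (the envelope shape is unchanged in
#' normalized time), recomputes \eqn{\psi_S} and returns the relative SAR
#' change \eqn{\psi'/\psi - 1}.  Analytically this equals
#' \eqn{1/(1+\delta) - 1}: to first order the power deposition scales
#' inversely-linearly with pulse length (|d ln SAR / d ln T| = 1).
#'
#' @param seq A [sequence_model()] with RF pulses.
#' @param rel_change Relative duration change (> -1).
#' @return Relative change of the TR-averaged SAR.
#' @export
pulse_length_sensitivity <- function(seq, rel_change) {
  if (rel_change <= -1) stop("rel_change must be > -1")
  if (!length(seq$rf_pulses))
    stop("pulse-train route unavailable: sequence has no RF pulses")
  cst <- mri_constants()
  psi_of <- function(pulses) {
    sum(vapply(pulses, function(p) {
      pulse_energy_ratio(p) * p$duration *
        (p$flip_angle / cst$alpha_ref * cst$dt_ref / p$duration)^2
    }, numeric(1))) / seq$tr
  }
  psi0 <- psi_of(seq$rf_pulses)
  pulses2 <- lapply(seq$rf_pulses, function(p) {
    p$duration <- p$duration * (1 + rel_change)
    p
  })
  psi_of(pulses2) / psi0 - 1
}
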