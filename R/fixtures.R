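#' ASTM-like phantom specification
#'
#' Homogeneous gel parallelepiped used as the imaging subject: 440 x 178 x
#' 1190 mm, gel conductivity 0.47 S/m, relative permittivity 80, bone-like
#' thermal properties.  The height exceeds the standard ASTM box so the
#' phantom stays centred in the scanner while the implant moves to emulate
#' different imaging regions.
#'
#' @param size Phantom edge lengths (m), x/y/z.
#' @param conductivity Gel electrical conductivity, S/m.
#' @param permittivity Relative electric permittivity.
#' @param density Gel density, kg/m^3.
#' @param thermal A [thermal_params()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(0.440, 0.178, 1.190), conductivity = 0.47,
                         permittivity = 80, density = 1000,
                         thermal = thermal_params()) {
  if (any(size <= 0)) stop("phantom sizes must be positive")
  structure(list(size = size, conductivity = conductivity,
                 permittivity = permittivity, density = density,
                 thermal = thermal),
            class = "phantom_spec")
}

#' Voxelize the phantom
#'
#' @param spec A [phantom_spec()].
#' @param spacing Voxel spacing (m), scalar or length 3.
#' @return List of `voxel_field`s: `density`, `conductivity`, `mask`.
#' @export
make_phantom <- function(spec = phantom_spec(), spacing = 0.01) {
  spacing <- rep_len(spacing, 3)
  if (any(spacing > spec$size))
    stop("spacing exceeds the smallest phantom dimension")
  d <- pmax(1L, as.integer(round(spec$size / spacing)))
  list(
    density = voxel_field(array(spec$density, d), spacing, kind = "density"),
    conductivity = voxel_field(array(spec$conductivity, d), spacing,
                               kind = "conductivity"),
    mask = voxel_field(array(1, d), spacing, kind = "mask"),
    spec = spec
  )
}

#' Voxelized implant geometry
#'
#' Simple stand-in geometries for prosthesis components (no vendor CAD):
#' sphere, cylinder, or capsule "stem" (cylinder with hemispherical caps).
#' Surfaces are voxelized by centre inclusion on a grid aligned so the
#' implant centre is a voxel centre.
#'
#' @param shape `"sphere"`, `"cylinder"` or `"capsule_stem"`.
#' @param radius Radius (m).
#' @param length Cylinder height / capsule inner length (m); ignored for
#'   spheres.
#' @param axis Long axis for cylinder/capsule: `"x"`, `"y"`, `"z"`.
#' @param position Implant centre (m) relative to the isocentre.
#' @param spacing Voxel spacing (m).
#' @param material,anatomy,conductivity Passed to [implant_model()].
#' @param phantom Optional [make_phantom()] result; when given, the implant
#'   must fit inside the phantom.
#' @return An [implant_model()].
#' @export
make_implant <- function(shape = c("sphere", "cylinder", "capsule_stem"),
                         radius, length = NULL, axis = "z",
                         position = c(0, 0, 0), spacing = radius / 12,
                         material = "CoCrMo", anatomy = "hip",
                         conductivity = NULL, phantom = NULL) {
  shape <- match.arg(shape)
  if (radius <= 0) stop("radius must be positive")
  axis_i <- match(axis, c("x", "y", "z"))
  half <- rep(radius, 3)
  if (shape != "sphere") {
    if (is.null(length) || length <= 0)
      stop("cylinder/capsule shapes need a positive length")
    half[axis_i] <- length / 2 + if (shape == "capsule_stem") radius else 0
  }
  if (!is.null(phantom)) {
    lim <- phantom$mask$dims * phantom$mask$spacing / 2
    if (any(abs(position) + half > lim))
      stop("implant exits phantom")
  }
  spacing <- rep_len(spacing, 3)
  # odd cell counts so `position` lands on a voxel centre
  nh <- ceiling(half / spacing) + 1L
  d <- 2L * nh + 1L
  origin <- position - nh * spacing
  xs <- origin[1] + (seq_len(d[1]) - 1) * spacing[1] - position[1]
  ys <- origin[2] + (seq_len(d[2]) - 1) * spacing[2] - position[2]
  zs <- origin[3] + (seq_len(d[3]) - 1) * spacing[3] - position[3]
  X <- array(rep(xs, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(zs, each = d[1] * d[2]), dim = d)
  ax_coord <- list(X, Y, Z)[[axis_i]]
  perp <- list(X, Y, Z)[-axis_i]
  rho2 <- perp[[1]]^2 + perp[[2]]^2
  inside <- switch(shape,
    sphere = X^2 + Y^2 + Z^2 <= radius^2,
    cylinder = rho2 <= radius^2 & abs(ax_coord) <= length / 2,
    capsule_stem = {
      core <- rho2 <= radius^2 & abs(ax_coord) <= length / 2
      caps <- rho2 + (abs(ax_coord) - length / 2)^2 <= radius^2 &
        abs(ax_coord) > length / 2
      core | caps
    })
  mask <- voxel_field(array(as.numeric(inside), d), spacing, origin = origin,
                      kind = "mask")
  implant_model(mask, conductivity = conductivity, material = material,
                anatomy = anatomy)
}

# Seeded smooth random field: a few low-order cosine modes, normalized to
# max |.| = 1.  Deterministic for a given seed and grid.
smooth_random_field <- function(dims, seed, n_modes = 4) {
  set.seed(seed)
  d <- dims
  u <- list(seq(0, 1, length.out = d[1]), seq(0, 1, length.out = d[2]),
            seq(0, 1, length.out = d[3]))
  f <- array(0, d)
  for (m in seq_len(n_modes)) {
    k <- sample(0:2, 3, replace = TRUE)
    ph <- stats::runif(3, 0, 2 * pi)
    a <- stats::rnorm(1)
    cx <- cos(pi * k[1] * u[[1]] + ph[1])
    cy <- cos(pi * k[2] * u[[2]] + ph[2])
    cz <- cos(pi * k[3] * u[[3]] + ph[3])
    f <- f + a * outer(outer(cx, cy), cz)
  }
  f / max(abs(f))
}

#' Surrogate B1+ and nominal SAR maps
#'
#' Deterministic (seeded) smooth fields emulating the outputs of a
#' full-wave birdcage body-coil simulation at nominal drive: a transmit
#' sensitivity with a coil-like longitudinal roll-off and gentle transverse
#' phase variation, and a nominal SAR map with an optional implant-adjacent
#' hotspot of configurable amplitude.  These are explicitly non-physical
#' plumbing surrogates: they exercise the calibration/averaging pipeline
#' but carry no RF-scattering physics.
#'
#' @param phantom A [make_phantom()] result.
#' @param implant Optional [implant_model()]; anchors the SAR hotspot.
#' @param field_strength `"1.5T"` or `"3T"` (scales nominal B1 and SAR).
#' @param hotspot_amplitude Peak added SAR of the hotspot, W/kg.
#' @param hotspot_sigma Gaussian width of the hotspot, m.
#' @param seed Integer seed; identical seeds reproduce bit-identical fields.
#' @return List with `b1_map` (complex `voxel_field`), `sar_map`,
#'   `density_map`, `body_mask`.
#' @export
make_rf_surrogate <- function(phantom, implant = NULL,
                              field_strength = c("1.5T", "3T"),
                              hotspot_amplitude = 0, hotspot_sigma = 0.02,
                              seed = 1) {
  field_strength <- match.arg(field_strength)
  mask <- phantom$mask
  d <- mask$dims
  co <- voxel_coords(mask)
  b0 <- if (field_strength == "1.5T") 3e-6 else 1.5e-6   # nominal-drive B1, T
  s0 <- if (field_strength == "1.5T") 1 else 4           # nominal SAR scale
  sm1 <- smooth_random_field(d, seed)
  sm2 <- smooth_random_field(d, seed + 1000L)
  roll <- 0.7 + 0.3 * exp(-(co$z / 0.3)^2)
  b1_mag <- b0 * roll * (1 + 0.05 * sm1)
  phase <- 0.3 * co$x / 0.22 + 0.2 * co$y / 0.09 + 0.1 * sm1
  sar <- s0 * (0.9 + 0.1 * exp(-(co$z / 0.4)^2)) * (1 + 0.05 * sm2)
  if (hotspot_amplitude > 0) {
    centre <- if (!is.null(implant)) implant$barycentre else c(0, 0, 0)
    d2 <- (co$x - centre[1])^2 + (co$y - centre[2])^2 + (co$z - centre[3])^2
    sar <- sar + hotspot_amplitude * exp(-d2 / (2 * hotspot_sigma^2))
  }
  list(
    b1_map = voxel_field(array(complex(modulus = b1_mag, argument = phase),
                               d),
                         mask$spacing, origin = mask$origin,
                         kind = "b1_plus"),
    sar_map = voxel_field(sar * 1, mask$spacing, origin = mask$origin,
                          kind = "sar_nominal"),
    density_map = voxel_field(array(phantom$spec$density, d), mask$spacing,
                              origin = mask$origin, kind = "density"),
    body_mask = mask
  )
}

# Sampled alternating EPI readout train as one event per channel.
epi_readout_event <- function(channel, amplitude, lobe_flat, ramp, n_lobes,
                              start_time, sample_dt = 1e-6) {
  lobe <- 2 * ramp + lobe_flat
  total <- n_lobes * lobe
  t <- seq(0, total, by = sample_dt)
  k <- pmin(floor(t / lobe), n_lobes - 1)
  tt <- t - k * lobe
  shape <- ifelse(tt < ramp, tt / ramp,
                  ifelse(tt < ramp + lobe_flat, 1,
                         pmax(0, (lobe - tt) / ramp)))
  g <- amplitude * shape * ifelse(k %% 2 == 0, 1, -1)
  gradient_event(channel, "sampled", samples = g, sample_dt = sample_dt,
                 start_time = start_time)
}

trap_event <- function(channel, amplitude, flat, start,
                       slew = 200, max_amp = 0.040) {
  ramp <- max(abs(amplitude) / slew, 1e-5)
  gradient_event(channel, "trapezoid", amplitude = amplitude,
                 ramp_time = ramp, flat_time = flat, start_time = start,
                 max_amplitude = max_amp, max_slew = slew)
}

readout_amplitude <- function(bw_khz, fov_m) {
  2 * bw_khz * 1e3 / (42.577e6 * fov_m)   # full bandwidth = 2 x printed +/-
}

#' Library of the seven reference MRI pulse sequences
#'
#' The seven sequences of the scenario study (T2 FRFSE, T1 FSE, T2* GRE,
#' 3D FSPGR, DWI SE-EPI, PERF GRE-EPI, TrueFISP) with their published TR,
#' duration, flip angle and declared B1+ rms, plus representative gradient
#' event trains derived from the matrix / field-of-view / readout-bandwidth
#' parameters under default hardware limits (40 mT/m, 200 T/m/s).  The RF
#' side also carries a representative apodized-sinc pulse train; the
#' declared B1+ rms remains the authoritative route for the stress index.
#'
#' @return Named list of seven [sequence_model()]s.
#' @export
sequence_library <- function() {
  tab <- data.frame(
    name = c("T2 FRFSE", "T1 FSE", "T2* GRE", "3D FSPGR", "DWI SE-EPI",
             "PERF GRE-EPI", "TrueFISP"),
    flip_deg = c(90, 90, 20, 12, 90, 90, 45),
    b1rms_uT = c(1.27, 1.74, 0.44, 0.36, 0.02, 0.02, 2.05),
    tr_ms = c(3160, 840, 500, 14.6, 5625, 1500, 6.4),
    bw_khz = c(20.83, 31.25, 15.63, 27.78, 250, 250, 126.3),
    nx = c(256, 256, 256, 256, 128, 128, 256),
    fov_read = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.18),
    duration_s = c(200, 215, 192, 336, 240, 180, 130),
    echo_train = c(16, 4, 1, 1, 128, 128, 1),
    family = c("SE", "SE", "GRE", "GRE", "EPI", "EPI", "bSSFP"),
    stringsAsFactors = FALSE
  )
  out <- vector("list", nrow(tab))
  names(out) <- tab$name
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    tr <- r$tr_ms * 1e-3
    amp <- readout_amplitude(r$bw_khz, r$fov_read)
    flat <- r$nx / (2 * r$bw_khz * 1e3)
    ramp <- max(amp / 200, 1e-5)
    ev <- list()
    if (r$family == "EPI") {
      ev <- c(ev, list(epi_readout_event("x", amp, flat, ramp, r$echo_train,
                                         start_time = 0.1 * tr)))
      # blipped phase encoding (small z-free, y blips folded into one event)
      ev <- c(ev, list(trap_event("y", amp / 30, flat * r$echo_train,
                                  start = 0.1 * tr)))
      if (r$name == "DWI SE-EPI") {
        # three-direction diffusion lobes, one per axis (b = 500 s/mm^2)
        for (chn in c("x", "y", "z"))
          ev <- c(ev, list(trap_event(chn, 0.030, 0.015,
                                      start = 0.02 * tr)))
      }
    } else {
      esp <- tr / max(r$echo_train, 1)
      for (e in seq_len(r$echo_train))
        ev <- c(ev, list(trap_event("x", amp, flat,
                                    start = (e - 1) * esp + 0.2 * esp)))
      ev <- c(ev, list(trap_event("y", amp / 4, flat / 2,
                                  start = 0.05 * tr)))
      ev <- c(ev, list(trap_event("z", amp / 2, flat / 2,
                                  start = 0.01 * tr)))
    }
    # representative RF train: apodized sinc pulses of the declared flip
    n_rf <- if (r$family == "SE") r$echo_train + 1 else 1
    p_dur <- min(2e-3, 0.2 * tr / n_rf)
    pulses <- replicate(n_rf, rf_pulse(r$flip_deg * pi / 180, p_dur,
                                       "apodized_sinc"),
                        simplify = FALSE)
    duty <- min(1, sum(vapply(ev, function(e) {
      if (e$kind == "sampled") length(e$samples) * e$sample_dt
      else 2 * e$ramp_time + e$flat_time
    }, numeric(1))) / tr)
    out[[i]] <- sequence_model(
      name = r$name, tr = tr, duration = r$duration_s, rf_pulses = pulses,
      gradient_events = ev, duty_cycle = max(duty, 0.05),
      b1rms = r$b1rms_uT * 1e-6,
      freq_encode_axis = "x", family = r$family)
    if (r$name == "DWI SE-EPI")
      out[[i]]$specific <- list(diffusion_directions = 3, b_value = 500)
  }
  out
}

#' Imaging-region layout
#'
#' Body-axis positions (m, from the head) of the seven imaging regions and
#' the implied implant offset from the isocentre when the named region is
#' centred in the scanner.  The numeric positions are declared package
#' assumptions (anatomically plausible, not published values).
#'
#' @param anatomy Implant anatomy: `"hip"`, `"knee"`, `"shoulder"`.
#' @return Data frame with `region`, `region_position`, `implant_offset`.
#' @export
region_layout <- function(anatomy = c("hip", "knee", "shoulder")) {
  anatomy <- match.arg(anatomy)
  regions <- data.frame(
    region = c("head", "shoulder", "chest", "abdomen", "pelvis", "femur",
               "knee"),
    region_position = c(0, 0.25, 0.45, 0.60, 0.75, 0.95, 1.25)
  )
  implant_pos <- c(hip = 0.75, knee = 1.25, shoulder = 0.25)[[anatomy]]
  regions$implant_offset <- implant_pos - regions$region_position
  regions
}

#' Registry counts of MRI exams by category
#'
#' Published counts of MRI exams performed within three years of surgery by
#' patients carrying hip, knee or shoulder prostheses, by exam category.
#' Inputs for [category_percentages()].
#'
#' @return Data frame with `category` and per-prosthesis count columns.
#' @export
mri_exam_counts <- function() {
  data.frame(
    category = c("head", "chest", "spine", "musculoskeletal",
                 "abdomen_pelvis", "other"),
    hip = c(390, 34, 749, 641, 125, 30),
    knee = c(361, 25, 716, 607, 119, 31),
    shoulder = c(26, 3, 51, 68, 9, 1),
    stringsAsFactors = FALSE
  )
}
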