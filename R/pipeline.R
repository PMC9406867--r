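#' Default demo run configuration
#'
#' A complete, small run configuration exercising both exposure channels on
#' synthetic fixtures: an ASTM-like phantom, one spherical implant moved to
#' two imaging-region offsets, surrogate B1+/SAR maps and two library
#' sequences.  Grid resolutions are chosen for smoke-test speed, not
#' accuracy.
#'
#' @param out_dir Output directory for reports and artifacts.
#' @param seed Seed for the surrogate-field generator.
#' @return A `run_config` list (JSON-serialisable).
#' @export
make_demo_config <- function(out_dir = tempfile("implantheat-demo-"),
                             seed = 1) {
  list(
    seed = seed,
    out_dir = out_dir,
    phantom = list(spacing = 0.01),
    implant = list(shape = "sphere", radius = 0.015, spacing = 0.0025,
                   anatomy = "hip", material = "CoCrMo"),
    regions = list(
      list(region = "pelvis", implant_offset = 0.0),
      list(region = "head", implant_offset = 0.35)
    ),
    field_strength = "1.5T",
    rf = list(hotspot_amplitude = 20, hotspot_sigma = 0.02,
              slab_thickness = 0.05),
    sequences = c("TrueFISP", "T2* GRE"),
    thermal = list(margin = 0.02, spacing = 0.003, dt = 0.5,
                   boundary = "robin"),
    limits = list()
  )
}

validate_run_config <- function(config) {
  known <- c("seed", "out_dir", "phantom", "implant", "regions",
             "field_strength", "rf", "sequences", "thermal", "limits",
             "gc")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  for (key in c("out_dir", "implant", "regions", "sequences"))
    if (is.null(config[[key]]))
      stop("config is missing the required key '", key, "'")
  invisible(config)
}

#' Run the full heating-risk pipeline
#'
#' Executes the RF branch (surrogate fields, flip-angle calibration,
#' configuration index, whole-body and 10 g averages, temporal averages,
#' RF tier) and the GC branch (unit eddy-current solves, Q-matrix assembly,
#' spectral power, unit Pennes solve, temperature scaling, GC tier) for
#' every scenario (region x sequence), writes `report.csv` and
#' `report.json` to the configured output directory, and returns the tier
#' report.  Deterministic and idempotent for a fixed configuration.
#'
#' @param config A `run_config` list (see [make_demo_config()]) or the path
#'   of a JSON file containing one.
#' @param quiet Suppress progress messages.
#' @return A [classify_matrix()] tier report (invisibly also written to
#'   disk).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  validate_run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  limits <- do.call(iec_limits, config$limits %||% list())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  phantom <- make_phantom(spacing = config$phantom$spacing %||% 0.01)
  lib <- sequence_library()
  seqs <- lib[unlist(config$sequences)]
  if (anyNA(names(seqs))) stop("unknown sequence name in config")
  ic <- config$implant

  # GC geometry solve: the unit solutions depend only on the implant shape,
  # so solve once with the implant at the isocentre and reuse per region.
  implant0 <- make_implant(ic$shape, radius = ic$radius,
                           length = ic$length, axis = ic$axis %||% "z",
                           position = c(0, 0, 0),
                           spacing = ic$spacing %||% (ic$radius / 8),
                           material = ic$material %||% "CoCrMo",
                           anatomy = ic$anatomy %||% "hip")
  say("solving unit eddy currents (3 axes)")
  sols <- lapply(c("x", "y", "z"), function(ax)
    solve_unit_current(implant0, ax))
  thc <- config$thermal %||% list()
  th_spacing <- thc$spacing %||% implant0$mask$spacing[1]
  implant_th <- make_implant(ic$shape, radius = ic$radius,
                             length = ic$length, axis = ic$axis %||% "z",
                             position = c(0, 0, 0), spacing = th_spacing,
                             material = ic$material %||% "CoCrMo",
                             anatomy = ic$anatomy %||% "hip")
  t_end <- max(vapply(seqs, `[[`, numeric(1), "duration"))
  say("solving unit Pennes problem to t = %g s", t_end)
  theta_hat <- pennes_solve_unit(
    implant_th, thermal_params(), t_end = t_end,
    dt = thc$dt %||% 0.5, boundary = thc$boundary %||% "robin",
    margin = thc$margin)

  rows <- list()
  for (rg in config$regions) {
    pos <- c(0, 0, rg$implant_offset)
    implant <- make_implant(ic$shape, radius = ic$radius,
                            length = ic$length, axis = ic$axis %||% "z",
                            position = pos,
                            spacing = ic$spacing %||% (ic$radius / 8),
                            material = ic$material %||% "CoCrMo",
                            anatomy = ic$anatomy %||% "hip",
                            phantom = phantom)
    say("region %s: RF surrogate + calibration", rg$region)
    sur <- make_rf_surrogate(
      phantom, implant, config$field_strength %||% "1.5T",
      hotspot_amplitude = config$rf$hotspot_amplitude %||% 0,
      hotspot_sigma = config$rf$hotspot_sigma %||% 0.02,
      seed = config$seed %||% 1)
    cfg <- rf_configuration(sur$b1_map, sur$sar_map, sur$density_map,
                            sur$body_mask,
                            slab_thickness = config$rf$slab_thickness %||%
                              0.05)
    cfg$beta <- as.numeric(calibrate_beta(cfg))
    xi <- configuration_index(cfg)
    xi_wb <- whole_body_average(xi, sur$density_map, sur$body_mask)
    xi_10g <- sar10g_peak(xi, sur$density_map, sur$body_mask)
    coeffs <- coil_field_coefficients(implant$barycentre)
    q <- assemble_q(sols, coeffs, implant0)
    for (sq in seqs) {
      psi <- rf_stress_index(sq, route = "b1rms")
      if (identical(sq$family, "EPI")) {
        wc <- worst_case_epi(sq, q, implant0)
        p <- wc$p_max
      } else {
        p <- average_power(q, gradient_spectrum(sq), implant0,
                           sq$duty_cycle)
      }
      tres <- scale_and_extract(theta_hat, p, sq$duration)
      rows[[length(rows) + 1]] <- data.frame(
        id = paste(rg$region, sq$name, sep = " / "),
        anatomy = implant$anatomy, region = rg$region,
        field_strength = config$field_strength %||% "1.5T",
        sequence = sq$name, beta = cfg$beta, psi = psi, TS = sq$duration,
        xi_wb = xi_wb, xi_10g = xi_10g, p = p,
        theta_end_max = tres$theta_end_max,
        theta_inf_max = tres$theta_inf_max,
        stringsAsFactors = FALSE)
    }
  }
  scen <- do.call(rbind, rows)
  report <- classify_matrix(scen, limits)
  out_csv <- file.path(config$out_dir, "report.csv")
  rep_out <- report$report
  num <- vapply(rep_out, is.numeric, logical(1)) &
    !names(rep_out) %in% c("rf_tier", "gc_tier")
  rep_csv <- rep_out
  rep_csv[num] <- lapply(rep_csv[num], signif, digits = 4)
  utils::write.csv(rep_csv, out_csv, row.names = FALSE)
  jsonlite::write_json(rep_out, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  report
}
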