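#' Physical constants used throughout the package
#'
#' The RF calibration is referenced to a hard pulse of length 1 ms producing a
#' 90 degree flip angle, and all gyromagnetic conversions assume proton
#' imaging.  These are fixed model constants, not configuration.
#'
#' @return A list with elements `gamma` (proton gyromagnetic ratio,
#'   rad/s/T), `alpha_ref` (reference flip angle, rad), `dt_ref` (reference
#'   hard-pulse length, s) and `t_iec` (default 6-minute SAR averaging
#'   window, s).
#' @export
#' @examples
#' mri_constants()$gamma / (2 * pi)  # 42.577 MHz/T
mri_constants <- function() {
  list(
    gamma = 2 * pi * 42.577e6,
    alpha_ref = pi / 2,
    dt_ref = 1e-3,
    t_iec = 360
  )
}

#' Voxel field on a regular cell-centred grid
#'
#' The common spatial container of the package: scalar, complex or 3-vector
#' data on a regular grid.  The z axis runs along the scanner bore (B0) and
#' the default origin centres the grid on the isocentre.
#'
#' @param values A 3-d array (scalar or complex field) or a 4-d array whose
#'   fourth dimension has extent 3 (vector field).
#' @param spacing Voxel spacing in metres; scalar or length-3 vector.
#' @param origin Coordinates (m) of the centre of voxel `[1, 1, 1]`.  Default
#'   centres the grid on the isocentre.
#' @param kind One of `"b1_plus"`, `"sar_nominal"`, `"xi"`, `"density"`,
#'   `"conductivity"`, `"mask"`, `"temperature"`, `"current_density"`,
#'   `"generic"`.
#' @return An object of class `voxel_field`.
#' @export
voxel_field <- function(values, spacing, origin = NULL,
                        kind = c("generic", "b1_plus", "sar_nominal", "xi",
                                 "density", "conductivity", "mask",
                                 "temperature", "current_density")) {
  kind <- match.arg(kind)
  nd <- length(dim(values))
  if (is.null(dim(values)) || !(nd %in% c(3L, 4L)))
    stop("`values` must be a 3-d array or a 4-d array with last extent 3")
  if (nd == 4L && dim(values)[4] != 3L)
    stop("vector fields must have a fourth dimension of extent 3")
  dims <- dim(values)[1:3]
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (is.null(origin)) origin <- -(dims - 1) / 2 * spacing
  origin <- rep_len(as.numeric(origin), 3L)
  if (anyNA(values) || any(!is.finite(Re(values))) ||
      (is.complex(values) && any(!is.finite(Im(values)))))
    stop("voxel values must be finite")
  if (kind == "mask" && !all(values %in% c(0, 1)))
    stop("mask fields must contain only 0 and 1")
  structure(
    list(dims = as.integer(dims), spacing = spacing, origin = origin,
         values = values, kind = kind),
    class = "voxel_field"
  )
}

#' @export
print.voxel_field <- function(x, ...) {
  cat(sprintf("<voxel_field> kind=%s dims=%s spacing=%s m\n", x$kind,
              paste(x$dims, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  v <- x$values
  cat(sprintf("  range: [%.4g, %.4g]\n", min(Mod(v)), max(Mod(v))))
  invisible(x)
}

#' Cell-centre coordinates along one axis of a voxel field
#' @param field A `voxel_field`.
#' @param axis Axis index 1..3 (x, y, z).
#' @return Numeric vector of coordinates in metres.
#' @export
axis_coords <- function(field, axis) {
  field$origin[axis] + (seq_len(field$dims[axis]) - 1) * field$spacing[axis]
}

#' Coordinate arrays of a voxel field
#'
#' @param field A `voxel_field`.
#' @param origin Optional reference point subtracted from all coordinates.
#' @return List of three arrays `x`, `y`, `z` with the field's dims.
#' @export
voxel_coords <- function(field, origin = c(0, 0, 0)) {
  d <- field$dims
  xs <- axis_coords(field, 1) - origin[1]
  ys <- axis_coords(field, 2) - origin[2]
  zs <- axis_coords(field, 3) - origin[3]
  list(
    x = array(rep(xs, times = d[2] * d[3]), dim = d),
    y = array(rep(rep(ys, each = d[1]), times = d[3]), dim = d),
    z = array(rep(zs, each = d[1] * d[2]), dim = d)
  )
}

#' Voxel volume of a field (m^3)
#' @param field A `voxel_field`.
#' @export
voxel_volume <- function(field) prod(field$spacing)

same_grid <- function(a, b) {
  identical(a$dims, b$dims) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-12)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9))
}

stop_grid_mismatch <- function(a, b, what) {
  if (!same_grid(a, b)) stop(sprintf("grid mismatch between %s fields", what))
  invisible(TRUE)
}
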