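#' Conductive implant model
#'
#' A voxelized metallic implant with uniform electrical conductivity.  The
#' volume and barycentre are derived from the mask; the anatomy tag selects
#' the applicable limit exceptions (knee: doubled K2 and 3 degC threshold).
#'
#' @param mask A `voxel_field` mask (1 inside the metal).
#' @param conductivity Electrical conductivity in S/m; defaults to the
#'   CoCrMo preset.
#' @param material `"CoCrMo"` (1.16e6 S/m) or `"Ti"` (5.95e5 S/m); ignored
#'   when `conductivity` is given explicitly.
#' @param anatomy `"hip"`, `"knee"` or `"shoulder"`.
#' @param check_connected Warn when the mask is not 6-connected.
#' @return An object of class `implant_model` with derived `volume` (m^3)
#'   and `barycentre` (m).
#' @export
implant_model <- function(mask, conductivity = NULL,
                          material = c("CoCrMo", "Ti"),
                          anatomy = c("hip", "knee", "shoulder"),
                          check_connected = TRUE) {
  material <- match.arg(material)
  anatomy <- match.arg(anatomy)
  if (mask$kind != "mask") stop("implant mask must be a mask voxel_field")
  if (!any(mask$values > 0)) stop("implant mask is empty")
  if (is.null(conductivity))
    conductivity <- switch(material, CoCrMo = 1.16e6, Ti = 5.95e5)
  if (conductivity <= 0) stop("conductivity must be positive")
  dV <- voxel_volume(mask)
  idx <- which(mask$values > 0)
  co <- voxel_coords(mask)
  bary <- c(mean(co$x[idx]), mean(co$y[idx]), mean(co$z[idx]))
  if (check_connected && !mask_connected(mask$values))
    warning("implant mask is not 6-connected")
  structure(
    list(mask = mask, conductivity = conductivity, material = material,
         anatomy = anatomy, volume = length(idx) * dV, barycentre = bary),
    class = "implant_model")
}

# 6-connectivity check by vectorized flood fill (frontier dilation).
mask_connected <- function(m) {
  d <- dim(m)
  visited <- array(FALSE, d)
  seed <- which(m > 0)[1]
  visited[seed] <- TRUE
  shift <- function(a, axis, by) {
    out <- array(FALSE, d)
    if (axis == 1) {
      if (by > 0) out[-1, , ] <- a[-d[1], , ] else out[-d[1], , ] <- a[-1, , ]
    } else if (axis == 2) {
      if (by > 0) out[, -1, ] <- a[, -d[2], ] else out[, -d[2], ] <- a[, -1, ]
    } else {
      if (by > 0) out[, , -1] <- a[, , -d[3]] else out[, , -d[3]] <- a[, , -1]
    }
    out
  }
  repeat {
    grown <- visited
    for (ax in 1:3) for (by in c(1, -1))
      grown <- grown | shift(visited, ax, by)
    grown <- grown & (m > 0)
    if (sum(grown) == sum(visited)) break
    visited <- grown
  }
  sum(visited) == sum(m > 0)
}

#' @export
print.implant_model <- function(x, ...) {
  cat(sprintf("<implant_model> %s (%s): V = %.3g cm^3, sigma = %.3g S/m, barycentre = (%.3g, %.3g, %.3g) m\n",
              x$anatomy, x$material, x$volume * 1e6, x$conductivity,
              x$barycentre[1], x$barycentre[2], x$barycentre[3]))
  invisible(x)
}

#' Unit eddy-current solution for a uniform AC field along one axis
#'
#' Quasi-static (skin-effect-free) current density induced in the implant by
#' a spatially uniform 1 T magnetic flux density oscillating at 1 Hz along
#' the given axis.  The source electric field is \eqn{E_A = -\partial
#' A/\partial t} with \eqn{A = \tfrac12 B \times (x - x_0)}; the scalar
#' potential correction solves the charge-conservation problem
#' \eqn{\nabla \cdot \sigma (E_A - \nabla\varphi) = 0} with zero normal
#' current on the implant surface (finite-volume discretisation, sparse
#' Cholesky).  Peak-phasor convention.
#'
#' @param implant An [implant_model()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param gauge_origin Reference point of the vector potential; defaults to
#'   the barycentre (the solution is gauge-invariant).
#' @return An object of class `unit_current_solution`: list with `axis`,
#'   `j_field` (vector `voxel_field`, A/m^2 peak at 1 Hz / 1 T) and `phi`.
#' @export
solve_unit_current <- function(implant, axis = c("x", "y", "z"),
                               gauge_origin = NULL) {
  axis <- match.arg(axis)
  mask <- implant$mask
  d <- mask$dims
  hp <- mask$spacing
  sig <- implant$conductivity
  if (is.null(gauge_origin)) gauge_origin <- implant$barycentre
  idx <- which(mask$values > 0)
  if (!length(idx)) stop("empty implant mask")
  # warn on poor resolution of the smallest implant dimension
  ai <- arrayInd(idx, d)
  ext <- apply(ai, 2, function(v) diff(range(v)) + 1)
  if (min(ext) < 4)
    warning("implant resolved by fewer than 4 voxels along one axis")
  cellno <- array(0L, d)
  cellno[idx] <- seq_along(idx)
  n <- length(idx)
  co <- voxel_coords(mask, origin = gauge_origin)
  bvec <- c(x = 0, y = 0, z = 0)
  bvec[axis] <- 1
  # source field, peak phasor at f = 1 Hz: E = -omega * A0, A0 = (B x r)/2
  omega <- 2 * pi
  Efun <- function(x, y, z) {
    ax <- 0.5 * (bvec[2] * z - bvec[3] * y)
    ay <- 0.5 * (bvec[3] * x - bvec[1] * z)
    az <- 0.5 * (bvec[1] * y - bvec[2] * x)
    cbind(-omega * ax, -omega * ay, -omega * az)
  }
  # assemble Neumann Laplacian over masked cells and source divergence
  ii <- jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(n)
  rhs <- numeric(n)
  for (ax in 1:3) {
    h <- hp[ax]
    area <- prod(hp) / h
    g <- sig * area / h
    nb <- ai
    nb[, ax] <- nb[, ax] + 1L
    valid <- nb[, ax] <= d[ax]
    nb_id <- rep.int(0L, n)
    nb_id[valid] <- cellno[nb[valid, , drop = FALSE]]
    inter <- which(nb_id > 0L)          # interior +ax faces (owner side)
    if (length(inter)) {
      a <- inter
      b <- nb_id[inter]
      ii <- c(ii, a, b); jj <- c(jj, b, a); xx <- c(xx, rep(-g, 2 * length(a)))
      diag_acc[a] <- diag_acc[a] + g
      diag_acc[b] <- diag_acc[b] + g
      # face-centre coordinates and source flux through the face
      fx <- co$x[idx[a]]; fy <- co$y[idx[a]]; fz <- co$z[idx[a]]
      if (ax == 1) fx <- fx + h / 2
      if (ax == 2) fy <- fy + h / 2
      if (ax == 3) fz <- fz + h / 2
      En <- Efun(fx, fy, fz)[, ax]
      flux <- sig * area * En
      rhs[a] <- rhs[a] + flux           # outward through +face of a
      rhs[b] <- rhs[b] - flux           # inward for b
    }
  }
  phi <- numeric(n)
  if (n > 1) {
    L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n)) +
      Matrix::Diagonal(n, diag_acc)
    # pin cell 1 (pure-Neumann nullspace); rhs is exactly compatible
    keep <- 2:n
    Ls <- Matrix::forceSymmetric(L[keep, keep, drop = FALSE])
    # conservation reads sum_f sigma (E - grad phi) . n A = 0, i.e.
    # L phi = -b with L the (positive) Neumann Laplacian
    phi[keep] <- cg_solve(Ls, -rhs[keep], tol = 1e-10)$x
  }
  # J = sigma (E - grad phi) at cell centres; grad phi by centred/one-sided
  # differences within the mask
  Jc <- Efun(co$x[idx], co$y[idx], co$z[idx]) * sig
  phif <- array(NA_real_, d)
  phif[idx] <- phi
  for (ax in 1:3) {
    h <- hp[ax]
    nbp <- ai; nbp[, ax] <- nbp[, ax] + 1L
    nbm <- ai; nbm[, ax] <- nbm[, ax] - 1L
    okp <- nbp[, ax] <= d[ax]
    okm <- nbm[, ax] >= 1L
    vp <- rep(NA_real_, n); vm <- rep(NA_real_, n)
    vp[okp] <- phif[nbp[okp, , drop = FALSE]]
    vm[okm] <- phif[nbm[okm, , drop = FALSE]]
    hasp <- !is.na(vp); hasm <- !is.na(vm)
    grad <- numeric(n)
    both <- hasp & hasm
    grad[both] <- (vp[both] - vm[both]) / (2 * h)
    onlyp <- hasp & !hasm
    grad[onlyp] <- (vp[onlyp] - phi[onlyp]) / h
    onlym <- hasm & !hasp
    grad[onlym] <- (phi[onlym] - vm[onlym]) / h
    Jc[, ax] <- Jc[, ax] - sig * grad
    # single-voxel protrusions: both faces carry zero normal current, so
    # the cell's through-current along this axis vanishes
    Jc[!hasp & !hasm, ax] <- 0
  }
  jv <- array(0, c(d, 3))
  for (ax in 1:3) {
    tmp <- array(0, d)
    tmp[idx] <- Jc[, ax]
    jv[, , , ax] <- tmp
  }
  j_field <- voxel_field(jv, spacing = hp, origin = mask$origin,
                         kind = "current_density")
  structure(list(axis = axis, j_field = j_field, phi = phi, cells = idx),
            class = "unit_current_solution")
}

#' Gradient-coil field coefficients at a point
#'
#' The 3x3 matrix `B` whose row `k` gives the magnetic flux density (T)
#' generated at the implant barycentre by the `k`-th gradient coil per unit
#' gradient (T/m).  The built-in `ideal_maxwell` model uses ideal linear
#' gradients with their lowest-order concomitant terms:
#' z-coil: `(-x/2, -y/2, z)`; x-coil: `(z, 0, x)`; y-coil: `(0, z, y)`.
#'
#' @param position Evaluation point (m), typically the implant barycentre.
#' @param model `"ideal_maxwell"` or `"user_supplied"`.
#' @param user_B 3x3 matrix for `model = "user_supplied"`.
#' @param working_radius Radius (m) of the coil working volume; positions
#'   outside trigger an extrapolation warning.
#' @return 3x3 numeric matrix with rows `x`, `y`, `z` (coils) and columns
#'   `x`, `y`, `z` (field components).
#' @export
coil_field_coefficients <- function(position,
                                    model = c("ideal_maxwell",
                                              "user_supplied"),
                                    user_B = NULL, working_radius = 0.335) {
  model <- match.arg(model)
  if (model == "user_supplied") {
    if (is.null(user_B) || !all(dim(user_B) == c(3, 3)))
      stop("user_supplied model requires a 3x3 user_B matrix")
    return(user_B)
  }
  if (sqrt(sum(position[1:2]^2)) > working_radius)
    warning("position outside the coil working volume: extrapolating")
  x <- position[1]; y <- position[2]; z <- position[3]
  B <- rbind(
    x = c(z, 0, x),
    y = c(0, z, y),
    z = c(-x / 2, -y / 2, z)
  )
  colnames(B) <- c("x", "y", "z")
  B
}

#' Assemble the volume-averaged Q matrix
#'
#' Superposes the unit current solutions with the coil field coefficients,
#' \eqn{J_k(x) = \sum_i B_{k,i} \hat J_i(x)}, and volume-averages the
#' correlation matrix over the implant:
#' \eqn{Q_V[m,n] = (1/V_P) \int_{V_P} J_m^H \cdot J_n \, dv}.
#' Real unit solutions give a real symmetric positive-semidefinite matrix.
#'
#' @param unit_solutions List of three [solve_unit_current()] results for
#'   axes x, y, z (in that order).
#' @param coeffs 3x3 coefficient matrix from [coil_field_coefficients()].
#' @param implant The [implant_model()].
#' @return An object of class `q_matrix`: list with `QV` (3x3), `Ghat`
#'   (unit-solution Gram matrix) and `conductivity`.
#' @export
assemble_q <- function(unit_solutions, coeffs, implant) {
  if (length(unit_solutions) != 3)
    stop("three unit solutions (x, y, z) are required")
  grids <- lapply(unit_solutions, function(s) s$j_field)
  stop_grid_mismatch(grids[[1]], grids[[2]], "unit-solution")
  stop_grid_mismatch(grids[[1]], grids[[3]], "unit-solution")
  stop_grid_mismatch(grids[[1]], implant$mask, "solution/implant")
  idx <- which(implant$mask$values > 0)
  dV <- voxel_volume(implant$mask)
  # J matrices: n_cells x 3 per unit solution
  Jm <- lapply(unit_solutions, function(s) {
    jv <- s$j_field$values
    cbind(jv[, , , 1][idx], jv[, , , 2][idx], jv[, , , 3][idx])
  })
  Ghat <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    v <- sum(Conj(Jm[[i]]) * Jm[[j]]) * dV / implant$volume
    Ghat[i, j] <- Re(v)
    Ghat[j, i] <- Re(v)
  }
  QV <- coeffs %*% Ghat %*% t(coeffs)
  QV <- (QV + t(QV)) / 2
  dimnames(QV) <- list(c("x", "y", "z"), c("x", "y", "z"))
  structure(list(QV = QV, Ghat = Ghat, conductivity = implant$conductivity),
            class = "q_matrix")
}

#' @export
print.q_matrix <- function(x, ...) {
  cat("<q_matrix> volume-averaged QV ((A/m^2)^2 per (T/m)^2 at 1 Hz):\n")
  print(signif(x$QV, 4))
  invisible(x)
}

#' Average eddy-current power density deposited in the implant
#'
#' Spectral quadratic form over the gradient waveform harmonics:
#' \deqn{p = D \, \frac{1}{2\sigma} \sum_f f^2 \, G(f)^H Q_V G(f)}
#' with `D` the sequence duty cycle and peak-phasor coefficients `G(f)`
#' (T/m).
#'
#' @param q A [assemble_q()] result.
#' @param spectrum A [gradient_spectrum()] result.
#' @param implant The [implant_model()].
#' @param duty_cycle Duty-cycle coefficient in `(0, 1]`.
#' @return Volume-averaged power density, W/m^3.
#' @export
average_power <- function(q, spectrum, implant, duty_cycle = 1) {
  if (!length(spectrum$frequencies)) return(0)
  G <- spectrum$coefficients
  f2 <- spectrum$frequencies^2
  quad <- Re(rowSums((Conj(G) %*% q$QV) * G))
  p <- duty_cycle * sum(f2 * quad) / (2 * implant$conductivity)
  if (p < -1e-9 * max(abs(f2 * quad), 1e-300))
    stop("negative computed power: Q matrix is not positive semidefinite")
  max(p, 0)
}

#' Worst-case frequency-encoding direction for EPI sequences
#'
#' Evaluates the average deposited power with the frequency-encoding
#' gradient train assigned to each Cartesian axis in turn and returns the
#' maximum (ties resolve in x < y < z order), implementing the conservative
#' worst-case treatment of EPI readout direction.
#'
#' @param seq A [sequence_model()] with `freq_encode_axis` set.
#' @param q A [assemble_q()] result.
#' @param implant The [implant_model()].
#' @return List with `p_max` (W/m^3), `axis`, and the per-axis powers `p`.
#' @export
worst_case_epi <- function(seq, q, implant) {
  fe <- seq$freq_encode_axis
  if (is.na(fe)) stop("sequence has no frequency-encoding axis set")
  axes <- c("x", "y", "z")
  p <- vapply(axes, function(ax) {
    seq2 <- seq
    seq2$gradient_events <- lapply(seq$gradient_events, function(ev) {
      if (ev$channel == fe) ev$channel <- ax
      ev
    })
    average_power(q, gradient_spectrum(seq2), implant, seq$duty_cycle)
  }, numeric(1))
  k <- which.max(p)                     # first max: x < y < z tie-break
  list(p_max = unname(p[k]), axis = axes[k], p = p)
}
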