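#' Thermal material parameters
#'
#' Medium (gel/tissue) and implant thermal properties for the Pennes
#' bioheat model \eqn{\rho c \,\partial\vartheta/\partial t =
#' \nabla\cdot(k\nabla\vartheta) - w\vartheta + q}.  Medium defaults match
#' bone-like gel (k = 0.3 W/m/K, perfusion w = 600 W/m^3/K, rho = 1000
#' kg/m^3, c = 2500 J/kg/K); the metal region defaults to CoCrMo handbook
#' values with zero perfusion.
#'
#' @param conductivity Medium thermal conductivity, W/m/K.
#' @param perfusion Medium perfusion coefficient, W/m^3/K.
#' @param density Medium density, kg/m^3.
#' @param heat_capacity Medium specific heat capacity, J/kg/K.
#' @param implant_conductivity,implant_density,implant_heat_capacity,implant_perfusion
#'   Same properties for the metal region.
#' @return An object of class `thermal_params`.
#' @export
thermal_params <- function(conductivity = 0.3, perfusion = 600,
                           density = 1000, heat_capacity = 2500,
                           implant_conductivity = 14,
                           implant_density = 8300,
                           implant_heat_capacity = 450,
                           implant_perfusion = 0) {
  if (min(conductivity, density, heat_capacity, implant_conductivity,
          implant_density, implant_heat_capacity) <= 0)
    stop("conductivities, densities and heat capacities must be positive")
  if (perfusion < 0 || implant_perfusion < 0)
    stop("perfusion must be >= 0")
  structure(list(conductivity = conductivity, perfusion = perfusion,
                 density = density, heat_capacity = heat_capacity,
                 implant_conductivity = implant_conductivity,
                 implant_density = implant_density,
                 implant_heat_capacity = implant_heat_capacity,
                 implant_perfusion = implant_perfusion),
            class = "thermal_params")
}

# Build the computation domain: implant mask re-embedded in a padded box
# centred on the barycentre, same spacing.
thermal_domain <- function(implant, params, margin = NULL) {
  mask <- implant$mask
  hp <- mask$spacing
  idx <- which(mask$values > 0)
  ai <- arrayInd(idx, mask$dims)
  co <- voxel_coords(mask, origin = implant$barycentre)
  rmax <- sqrt(max(co$x[idx]^2 + co$y[idx]^2 + co$z[idx]^2))
  if (is.null(margin)) margin <- max(0.05, 3 * rmax)
  npad <- ceiling(margin / hp)
  lo <- apply(ai, 2, min) - npad
  hi <- apply(ai, 2, max) + npad
  d <- as.integer(hi - lo + 1L)
  inmask <- array(FALSE, d)
  inmask[cbind(ai[, 1] - lo[1] + 1L, ai[, 2] - lo[2] + 1L,
               ai[, 3] - lo[3] + 1L)] <- TRUE
  origin <- mask$origin + (lo - 1L) * hp
  kf <- array(params$conductivity, d)
  kf[inmask] <- params$implant_conductivity
  wf <- array(params$perfusion, d)
  wf[inmask] <- params$implant_perfusion
  rcf <- array(params$density * params$heat_capacity, d)
  rcf[inmask] <- params$implant_density * params$implant_heat_capacity
  list(dims = d, spacing = hp, origin = origin, inmask = inmask,
       k = kf, w = wf, rc = rcf, barycentre = implant$barycentre)
}

# Sparse FVM operator A such that A theta = q*V at steady state.
# boundary: "robin" (monopole-matched open boundary), "dirichlet", "adiabatic".
pennes_operator <- function(dom, boundary) {
  d <- dom$dims
  hp <- dom$spacing
  n <- prod(d)
  kf <- dom$k
  dV <- prod(hp)
  ii <- jj <- integer(0); xx <- numeric(0)
  diag_acc <- as.numeric(dom$w) * dV
  id <- array(seq_len(n), d)
  for (ax in 1:3) {
    h <- hp[ax]
    area <- dV / h
    sl_a <- switch(ax,
      list(1:(d[1] - 1), 1:d[2], 1:d[3]),
      list(1:d[1], 1:(d[2] - 1), 1:d[3]),
      list(1:d[1], 1:d[2], 1:(d[3] - 1)))
    sl_b <- sl_a
    sl_b[[ax]] <- sl_a[[ax]] + 1L
    a <- as.vector(id[sl_a[[1]], sl_a[[2]], sl_a[[3]]])
    b <- as.vector(id[sl_b[[1]], sl_b[[2]], sl_b[[3]]])
    ka <- kf[a]; kb <- kf[b]
    g <- (2 * ka * kb / (ka + kb)) * area / h
    ii <- c(ii, a, b); jj <- c(jj, b, a); xx <- c(xx, -g, -g)
    diag_acc[a] <- diag_acc[a] + g
    diag_acc[b] <- diag_acc[b] + g
  }
  bflux_g <- numeric(n)                  # boundary conductances (for balance)
  if (boundary != "adiabatic") {
    xs <- dom$origin[1] + (seq_len(d[1]) - 1) * hp[1] - dom$barycentre[1]
    ys <- dom$origin[2] + (seq_len(d[2]) - 1) * hp[2] - dom$barycentre[2]
    zs <- dom$origin[3] + (seq_len(d[3]) - 1) * hp[3] - dom$barycentre[3]
    for (ax in 1:3) {
      h <- hp[ax]
      area <- dV / h
      for (side in c(1L, 2L)) {
        sl <- list(1:d[1], 1:d[2], 1:d[3])
        sl[[ax]] <- if (side == 1L) 1L else d[ax]
        cells <- as.vector(id[sl[[1]], sl[[2]], sl[[3]]])
        ki <- kf[cells]
        if (boundary == "dirichlet") {
          g <- ki * area / (h / 2)
        } else {
          # Robin matched to a monopole decay theta ~ 1/|x|:
          # -k dtheta/dn = k * c * theta with c = (x_f . n_hat)/|x_f|^2,
          # in series with the half-cell conduction.
          ci <- arrayInd(cells, d)
          px <- xs[ci[, 1]]; py <- ys[ci[, 2]]; pz <- zs[ci[, 3]]
          nrm <- c(0, 0, 0)
          nrm[ax] <- if (side == 1L) -1 else 1
          pf <- cbind(px, py, pz)
          pf[, ax] <- pf[, ax] + nrm[ax] * h / 2
          cc <- (pf %*% nrm) / rowSums(pf^2)
          cc <- pmax(as.numeric(cc), 0)
          g <- ifelse(cc > 0, area * ki * cc / (1 + cc * h / 2), 0)
        }
        diag_acc[cells] <- diag_acc[cells] + g
        bflux_g[cells] <- bflux_g[cells] + g
      }
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            symmetric = FALSE) +
    Matrix::Diagonal(n, diag_acc)
  list(A = Matrix::forceSymmetric(A), bflux_g = bflux_g)
}

#' Transient Pennes bioheat solution at unit volumetric power
#'
#' Solves \eqn{\rho c\, \partial\vartheta/\partial t = \nabla\cdot(k\nabla
#' \vartheta) - w\vartheta + q} by unconditionally stable implicit (backward
#' Euler) stepping on a uniform finite-volume grid, with \eqn{q = 1} W/m^3
#' inside the implant (or everywhere, for verification), zero initial
#' condition and the selected outer boundary condition.  The computation
#' domain is the implant bounding box padded by `margin` (default
#' `max(5 cm, 3 x implant max radius)`).  Any scenario's temperature rise
#' follows by linear rescaling: \eqn{\vartheta(x, t) = p\, \hat\vartheta(x,
#' t)} (see [scale_and_extract()]).
#'
#' @param implant An [implant_model()].
#' @param params A [thermal_params()].
#' @param t_end Simulated horizon, s.
#' @param checkpoints Times (s) at which full fields are stored.
#' @param dt Time step, s (default 0.5; must be <= 0.5).
#' @param boundary `"robin"` (default; monopole-matched open boundary),
#'   `"dirichlet"` (theta = 0) or `"adiabatic"`.
#' @param margin Domain padding around the implant, m.
#' @param source `"implant"` or `"uniform"` (q = 1 W/m^3 everywhere).
#' @param compute_steady Also compute the steady-state field by direct
#'   linear solve (default TRUE when a steady state exists).
#' @return An object of class `pennes_solution` with elements `times`,
#'   `max_curve` (max temperature rise per step, degC per unit W/m^3),
#'   `checkpoint_fields` (list of `voxel_field`s), `theta_end`
#'   (`voxel_field` at `t_end`), `steady` (`voxel_field` or NULL) and grid
#'   metadata.
#' @export
pennes_solve_unit <- function(implant, params = thermal_params(),
                              t_end, checkpoints = numeric(0), dt = 0.5,
                              boundary = c("robin", "dirichlet",
                                           "adiabatic"),
                              margin = NULL, source = c("implant", "uniform"),
                              compute_steady = TRUE) {
  boundary <- match.arg(boundary)
  source <- match.arg(source)
  if (dt <= 0 || dt > 0.5) stop("dt must be in (0, 0.5] s")
  dom <- thermal_domain(implant, params, margin)
  op <- pennes_operator(dom, boundary)
  n <- prod(dom$dims)
  dV <- prod(dom$spacing)
  q <- if (source == "uniform") rep(1, n) else as.numeric(dom$inmask)
  b <- q * dV
  cap <- as.numeric(dom$rc) * dV / dt
  At <- op$A + Matrix::Diagonal(n, cap)
  diag_At <- Matrix::diag(At)
  nstep <- max(1L, ceiling(t_end / dt))
  times <- seq_len(nstep) * dt
  theta <- numeric(n)
  max_curve <- numeric(nstep)
  cps <- sort(unique(checkpoints))
  cp_fields <- vector("list", length(cps))
  names(cp_fields) <- as.character(cps)
  cp_next <- 1L
  as_field <- function(v)
    voxel_field(array(v, dom$dims), spacing = dom$spacing,
                origin = dom$origin, kind = "temperature")
  for (s in seq_len(nstep)) {
    theta <- cg_solve(At, cap * theta + b, x0 = theta, tol = 1e-10,
                      diag_A = diag_At)$x
    max_curve[s] <- max(theta)
    while (cp_next <= length(cps) && cps[cp_next] <= times[s] + 1e-9) {
      cp_fields[[cp_next]] <- as_field(theta)
      cp_next <- cp_next + 1L
    }
  }
  steady <- NULL
  if (compute_steady) {
    st <- try(pennes_steady_core(dom, op, b, x0 = theta), silent = TRUE)
    if (!inherits(st, "try-error")) steady <- as_field(st)
  }
  structure(
    list(times = times, max_curve = max_curve,
         checkpoint_fields = cp_fields, theta_end = as_field(theta),
         steady = steady, dims = dom$dims, spacing = dom$spacing,
         origin = dom$origin, inmask = dom$inmask, boundary = boundary,
         t_end = nstep * dt, source = source, bflux_g = op$bflux_g),
    class = "pennes_solution")
}

pennes_steady_core <- function(dom, op, b, x0 = NULL) {
  if (all(dom$w == 0) && all(op$bflux_g == 0))
    stop("no steady state: zero perfusion with adiabatic boundary")
  cg_solve(op$A, b, x0 = x0, tol = 1e-10)$x
}

#' Steady-state Pennes solution at unit volumetric power
#'
#' Direct sparse linear solve of \eqn{\nabla\cdot(k\nabla\vartheta) -
#' w\vartheta + q = 0}; equals the long-time limit of
#' [pennes_solve_unit()].
#'
#' @inheritParams pennes_solve_unit
#' @return A `voxel_field` of the unit-power steady temperature rise.
#' @export
pennes_steady_state <- function(implant, params = thermal_params(),
                                boundary = c("robin", "dirichlet",
                                             "adiabatic"),
                                margin = NULL,
                                source = c("implant", "uniform")) {
  boundary <- match.arg(boundary)
  source <- match.arg(source)
  dom <- thermal_domain(implant, params, margin)
  op <- pennes_operator(dom, boundary)
  dV <- prod(dom$spacing)
  q <- if (source == "uniform") rep(1, prod(dom$dims)) else
    as.numeric(dom$inmask)
  theta <- pennes_steady_core(dom, op, q * dV)
  voxel_field(array(theta, dom$dims), spacing = dom$spacing,
              origin = dom$origin, kind = "temperature")
}

#' Rescale a unit-power thermal solution to a scenario
#'
#' Applies the linearity of the bioheat problem: \eqn{\vartheta(x, t) = p\,
#' \hat\vartheta(x, t)}.  The end-of-sequence metric interpolates the
#' per-step domain maximum at `TS`; the steady metric scales the direct
#' steady solve.
#'
#' @param theta_hat A [pennes_solve_unit()] result (with `steady`).
#' @param p Average deposited power density, W/m^3.
#' @param TS Sequence duration, s; must not exceed the solved horizon.
#' @return An object of class `temperature_result`: list with
#'   `theta_end_max`, `theta_inf_max` (degC), `p_applied` and `TS`.
#' @export
scale_and_extract <- function(theta_hat, p, TS) {
  if (p < 0) stop("p must be >= 0")
  if (TS > theta_hat$t_end + 1e-9)
    stop("TS beyond the computed horizon: re-solve with a larger t_end")
  mx <- stats::approx(c(0, theta_hat$times), c(0, theta_hat$max_curve),
                      xout = TS, rule = 2)$y
  inf_max <- if (!is.null(theta_hat$steady)) p * max(theta_hat$steady$values)
             else NA_real_
  structure(
    list(theta_end_max = p * mx, theta_inf_max = inf_max, p_applied = p,
         TS = TS),
    class = "temperature_result")
}

#' @export
print.temperature_result <- function(x, ...) {
  cat(sprintf("<temperature_result> p = %.4g W/m^3: theta(TS=%.4g s) max = %.4g degC, theta_inf max = %.4g degC\n",
              x$p_applied, x$TS, x$theta_end_max, x$theta_inf_max))
  invisible(x)
}
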