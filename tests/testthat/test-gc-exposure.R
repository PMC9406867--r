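# Frozen oracle values (conducting sphere of radius a in a uniform axial
# AC field, quasi-static):
# - |J_hat(x)| = pi sigma rho at 1 Hz / 1 T (azimuthal), so
#   QV[z,z] = (pi sigma)^2 <rho^2> = (pi sigma)^2 (2 a^2 / 5), and the
#   volume-averaged power of a single z tone of amplitude B at frequency f
#   is sigma (2 pi f)^2 B^2 a^2 / 20.

test_that("unit current solution matches the sphere closed form", {
  a <- 0.008
  imp <- small_sphere(a, nvox = 12)
  sol <- solve_unit_current(imp, "z")
  idx <- which(imp$mask$values > 0)
  co <- voxel_coords(imp$mask, origin = imp$barycentre)
  rho <- sqrt(co$x[idx]^2 + co$y[idx]^2)
  jv <- sol$j_field$values
  jx <- jv[, , , 1][idx]; jy <- jv[, , , 2][idx]; jz <- jv[, , , 3][idx]
  jmag <- sqrt(jx^2 + jy^2 + jz^2)
  # energy-weighted agreement with pi sigma rho (interior staircase error)
  expect_equal(mean(jmag^2) / ((pi * imp$conductivity)^2 * mean(rho^2)), 1,
               tolerance = 0.08)
  # azimuthal direction: J . rho_hat ~ 0, J_z ~ 0
  keep <- rho > a / 4
  radial <- abs(jx[keep] * co$x[idx][keep] + jy[keep] * co$y[idx][keep]) /
    (rho[keep] * pmax(jmag[keep], 1e-9))
  expect_lt(stats::median(radial), 0.05)
  expect_lt(stats::median(abs(jz[keep]) / pmax(jmag[keep], 1e-9)), 0.05)
})

test_that("solution rotates with the implant and is gauge invariant", {
  # 90 deg rotation about z maps a cylinder along x onto one along y and
  # the x-axis unit solution onto the y-axis one (on a symmetric grid)
  impx <- make_implant("cylinder", radius = 0.004, length = 0.016,
                       axis = "x", spacing = 0.001, anatomy = "hip")
  impy <- make_implant("cylinder", radius = 0.004, length = 0.016,
                       axis = "y", spacing = 0.001, anatomy = "hip")
  solx <- solve_unit_current(impx, "x")
  soly <- solve_unit_current(impy, "y")
  jx <- solx$j_field$values
  jy <- soly$j_field$values
  d <- dim(jx)[1:3]
  # rotate solx by +90 deg about z: (x,y) -> (-y,x), (Jx,Jy) -> (-Jy,Jx)
  rot <- function(a) aperm(a, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  expect_equal(max(abs(rot(jx[, , , 2]) * -1 - jy[, , , 1])),
               0, tolerance = 1e-6 * max(abs(jy)))
  expect_equal(max(abs(rot(jx[, , , 1]) - jy[, , , 2])),
               0, tolerance = 1e-6 * max(abs(jy)))
  # gauge invariance: shifting the vector-potential origin leaves J unchanged
  imp <- small_sphere(0.006, nvox = 10)
  s0 <- solve_unit_current(imp, "y")
  s1 <- solve_unit_current(imp, "y", gauge_origin = imp$barycentre +
                             c(0.004, -0.003, 0.002))
  expect_equal(s1$j_field$values, s0$j_field$values,
               tolerance = 1e-6)
})

test_that("coil_field_coefficients implements the concomitant-field model", {
  expect_equal(coil_field_coefficients(c(0, 0, 0)),
               matrix(0, 3, 3, dimnames = list(c("x", "y", "z"),
                                               c("x", "y", "z"))))
  B <- coil_field_coefficients(c(0, 0, 0.3))
  expect_equal(unname(B["z", ]), c(0, 0, 0.3))
  B2 <- coil_field_coefficients(c(0.1, 0, 0.3))
  expect_equal(unname(B2["x", ]), c(0.3, 0, 0.1))
  expect_equal(unname(B2["z", ]), c(-0.05, 0, 0.3))
  expect_warning(coil_field_coefficients(c(0.4, 0, 0)), "working volume")
  U <- matrix(rnorm(9), 3)
  expect_equal(coil_field_coefficients(c(0, 0, 0), "user_supplied",
                                       user_B = U), U)
})

test_that("assemble_q builds a symmetric PSD matrix with bilinear scaling", {
  a <- 0.008
  imp <- small_sphere(a, nvox = 12)
  sols <- lapply(c("x", "y", "z"), function(ax) solve_unit_current(imp, ax))
  # identity coefficients: orthogonal sphere solutions -> diagonal QV
  qI <- assemble_q(sols, diag(3), imp)
  offd <- max(abs(qI$QV[upper.tri(qI$QV)]))
  expect_lt(offd, 5e-3 * max(diag(qI$QV)))   # staircase asymmetry only
  expect_equal(qI$QV[3, 3],
               (pi * imp$conductivity)^2 * 2 * a^2 / 5,
               tolerance = 0.08)
  # symmetric PSD on a generic coefficient set
  coeffs <- coil_field_coefficients(c(0.05, 0.02, 0.25))
  q <- assemble_q(sols, coeffs, imp)
  expect_equal(q$QV, t(q$QV))
  ev <- eigen(q$QV, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12 * sum(diag(q$QV)))
  # doubling all coefficients multiplies QV by 4
  q2 <- assemble_q(sols, 2 * coeffs, imp)
  expect_equal(q2$QV, 4 * q$QV, tolerance = 1e-12)
})

test_that("average_power matches hand formula, sphere form and the oracle", {
  a <- 0.008
  imp <- small_sphere(a, nvox = 12)
  sols <- lapply(c("x", "y", "z"), function(ax) solve_unit_current(imp, ax))
  # single tone on channel 1 with diagonal QV: p = duty f^2 A^2 q11 / (2 s)
  qd <- structure(list(QV = diag(c(5e8, 0, 0)),
                       conductivity = imp$conductivity), class = "q_matrix")
  sp1 <- tone_spectrum(1000, list(c(0.01, 0, 0)))
  expect_equal(average_power(qd, sp1, imp, 0.7),
               0.7 * 1000^2 * 0.01^2 * 5e8 / (2 * imp$conductivity))
  # sphere closed form via a z tone of uniform field amplitude B
  uB <- matrix(0, 3, 3); uB[3, 3] <- 1   # coil z -> uniform 1 T per T/m
  qs <- assemble_q(sols, uB, imp)
  f0 <- 1500; Bamp <- 0.02
  p <- average_power(qs, tone_spectrum(f0, list(c(0, 0, Bamp))), imp, 1)
  expect_equal(p, imp$conductivity * (2 * pi * f0)^2 * Bamp^2 * a^2 / 20,
               tolerance = 0.08)
  # conductivity scaling: p is linear in sigma at fixed geometry
  impt <- make_implant("sphere", radius = a, spacing = 2 * a / 12,
                       material = "Ti", anatomy = "hip")
  solt <- lapply(c("x", "y", "z"), function(ax) solve_unit_current(impt, ax))
  qt <- assemble_q(solt, uB, impt)
  pt <- average_power(qt, tone_spectrum(f0, list(c(0, 0, Bamp))), impt, 1)
  expect_equal(pt / p, impt$conductivity / imp$conductivity,
               tolerance = 1e-9)
  # two-tone time-domain brute-force oracle
  coeffs <- coil_field_coefficients(c(0.05, 0.02, 0.25))
  q <- assemble_q(sols, coeffs, imp)
  trr <- 2e-3
  G <- list(c(0.01, 0, 0), c(0, 0, 0.005 * exp(1i * 0.7)))
  freqs <- c(1 / trr, 3 / trr)
  spec <- tone_spectrum(freqs, G)
  p_impl <- average_power(q, spec, imp, 1)
  idx <- which(imp$mask$values > 0)
  Jk <- lapply(1:3, function(k) {
    jm <- 0
    for (i in 1:3) {
      jv <- sols[[i]]$j_field$values
      jm <- jm + coeffs[k, i] *
        cbind(jv[, , , 1][idx], jv[, , , 2][idx], jv[, , , 3][idx])
    }
    jm
  })
  nt <- 512
  ts <- (0:(nt - 1)) * trr / nt
  pacc <- 0
  for (it in seq_len(nt)) {
    Jt <- matrix(0, length(idx), 3)
    for (fi in 1:2) for (k in 1:3) {
      gk <- Re(spec$coefficients[fi, k] *
                 exp(2i * pi * freqs[fi] * ts[it]))
      if (gk != 0) Jt <- Jt + freqs[fi] * gk * Jk[[k]]
    }
    pacc <- pacc + mean(rowSums(Jt^2)) / imp$conductivity
  }
  expect_equal(p_impl, pacc / nt, tolerance = 0.01)
})

test_that("worst_case_epi picks the maximum axis with x<y<z tie-break", {
  imp <- small_sphere(0.006, nvox = 8)
  tr <- 1e-3
  mk_epi <- function() sequence_model(
    "epi", tr, 10, gradient_events = list(
      gradient_event("x", "trapezoid", amplitude = 0.02, ramp_time = 1e-4,
                     flat_time = 2e-4, start_time = 1e-4)),
    freq_encode_axis = "x", family = "EPI")
  s <- mk_epi()
  iso <- structure(list(QV = diag(3) * 4e8, conductivity = imp$conductivity),
                   class = "q_matrix")
  wc <- worst_case_epi(s, iso, imp)
  expect_equal(wc$axis, "x")
  expect_equal(max(wc$p) / min(wc$p), 1, tolerance = 1e-9)
  zdom <- structure(list(QV = diag(c(1e6, 1e6, 9e8)),
                         conductivity = imp$conductivity),
                    class = "q_matrix")
  wcz <- worst_case_epi(s, zdom, imp)
  expect_equal(wcz$axis, "z")
  # equals exhaustive three-way evaluation
  sols <- lapply(c("x", "y", "z"), function(ax) solve_unit_current(imp, ax))
  q <- assemble_q(sols, coil_field_coefficients(c(0.03, -0.01, 0.2)), imp)
  wcq <- worst_case_epi(s, q, imp)
  brute <- vapply(c("x", "y", "z"), function(ax) {
    s2 <- s
    s2$gradient_events[[1]]$channel <- ax
    average_power(q, gradient_spectrum(s2), imp, s$duty_cycle)
  }, numeric(1))
  expect_equal(wcq$p_max, max(brute))
  expect_equal(wcq$axis, names(which.max(brute)))
})
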