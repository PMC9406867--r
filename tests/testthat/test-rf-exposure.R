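# Frozen oracle values:
# - two-compartment calibration: maximising |V sin(th) + V sin(2 th)| gives
#   cos(th) + 2 cos(2 th) = 0, i.e. th* = acos((-1 + sqrt(33))/8)
#   (root of the 4 c^2 + c - 2 quadratic in c = cos th).
# - single hot voxel, 2 mm voxels, 1000 kg/m^3: the smallest centred cube
#   with >= 10 g is 11^3 = 1331 voxels (10.648 g), so the peak is S/1331.
# - TrueFISP worked example: psi = 0.12, xi = 349 W/kg, TS = 130 s gives
#   TR-average 41.88 and 6-min average 130/360 * 41.88 = 15.12 W/kg.

test_that("calibrate_beta matches closed forms and tie/degenerate rules", {
  cst <- mri_constants()
  b <- 2e-6
  cfg <- uniform_rf_config(b1 = b)
  beta <- as.numeric(calibrate_beta(cfg))
  expect_equal(beta, (pi / 2) / (cst$gamma * b * cst$dt_ref),
               tolerance = 1e-6)
  # two equal-volume compartments |B1| = b and 2b
  d <- c(20, 11, 11)
  v <- array(complex(real = b), d)
  v[1:10, , ] <- 2 * b
  cfg2 <- rf_configuration(
    voxel_field(v, 0.01, kind = "b1_plus"),
    uniform_field(1, d), uniform_field(1000, d, kind = "density"),
    uniform_field(1, d, kind = "mask"))
  beta2 <- as.numeric(calibrate_beta(cfg2))
  theta_star <- acos((-1 + sqrt(33)) / 8)
  expect_equal(beta2 * cst$gamma * b * cst$dt_ref, theta_star,
               tolerance = 1e-5)
  # antipodal phases: zero objective for all beta -> warning, smallest beta
  va <- array(complex(real = b), c(10, 11, 11))
  va[1:5, , ] <- complex(modulus = b, argument = pi)
  cfg3 <- rf_configuration(
    voxel_field(va, 0.01, kind = "b1_plus"),
    uniform_field(1, c(10, 11, 11)),
    uniform_field(1000, c(10, 11, 11), kind = "density"),
    uniform_field(1, c(10, 11, 11), kind = "mask"))
  expect_warning(b3 <- calibrate_beta(cfg3), "degenerate phase")
  expect_true(as.numeric(b3) > 0)
  # all-zero B1
  cfg4 <- uniform_rf_config(b1 = 0)
  expect_error(calibrate_beta(cfg4), "no signal region")
})

test_that("calibrate_beta agrees with a dense grid-search oracle", {
  cst <- mri_constants()
  for (seed in 1:3) {
    set.seed(seed)
    d <- c(15, 15, 9)
    co <- voxel_coords(uniform_field(0, d))
    mag <- 2e-6 * (1 + 0.4 * sin(2 * pi * co$x / 0.2 + seed) *
                     cos(2 * pi * co$y / 0.2))
    ph <- 0.5 * sin(2 * pi * co$z / 0.3) + 0.3 * co$x / 0.15
    cfg <- rf_configuration(
      voxel_field(array(complex(modulus = mag, argument = ph), d), 0.01,
                  kind = "b1_plus"),
      uniform_field(1, d), uniform_field(1000, d, kind = "density"),
      uniform_field(1, d, kind = "mask"))
    beta <- as.numeric(calibrate_beta(cfg))
    # independent dense grid search at 1e-6 relative resolution
    zc <- voxel_coords(cfg$b1_map)$z
    slab <- abs(zc) <= 0.025
    bb <- Mod(cfg$b1_map$values[slab])
    ei <- exp(1i * Arg(cfg$b1_map$values[slab]))
    obj <- function(bt) Mod(sum(sin(bt * bb * cst$gamma * cst$dt_ref) * ei))
    grid <- seq(beta * 0.9, beta * 1.1, by = beta * 1e-6)
    oracle <- grid[which.max(vapply(grid, obj, numeric(1)))]
    expect_equal(beta, oracle, tolerance = 1e-5)
  }
})

test_that("configuration_index scales the SAR map by beta^2", {
  cfg <- uniform_rf_config(sar = 3)
  expect_error(configuration_index(cfg), "uncalibrated")
  cfg$beta <- 2
  expect_equal(unique(as.vector(configuration_index(cfg)$values)), 12)
  hot <- uniform_rf_config(sar = 1)
  hot$sar_map$values[6, 6, 6] <- 100
  hot$beta <- 0.5
  xi <- configuration_index(hot)
  expect_equal(xi$values[6, 6, 6], 25)
  expect_equal(xi$values[1, 1, 1], 0.25)
})

test_that("whole_body_average is the mass-weighted mean", {
  d <- c(8, 8, 8)
  xi <- uniform_field(5, d, kind = "xi")
  rho <- uniform_field(1000, d, kind = "density")
  msk <- uniform_field(1, d, kind = "mask")
  expect_equal(whole_body_average(xi, rho, msk), 5)
  # half the mass at 0, half at 10
  xi2 <- xi; xi2$values[1:4, , ] <- 0; xi2$values[5:8, , ] <- 10
  expect_equal(whole_body_average(xi2, rho, msk), 5)
  # nonuniform density vs brute-force sum
  set.seed(42)
  xv <- array(stats::runif(prod(d)), d)
  rv <- array(stats::runif(prod(d), 800, 1200), d)
  mv <- array(rbinom(prod(d), 1, 0.8), d)
  oracle <- sum(xv * rv * mv) / sum(rv * mv)
  expect_equal(
    whole_body_average(voxel_field(xv, 0.01, kind = "xi"),
                       voxel_field(rv, 0.01, kind = "density"),
                       voxel_field(mv, 0.01, kind = "mask")),
    oracle)
  msk0 <- uniform_field(0, d, kind = "mask")
  expect_error(whole_body_average(xi, rho, msk0), "empty mask")
})

test_that("sar10g_peak implements centred-cube mass growth", {
  d <- c(31, 31, 31); sp <- 0.002
  rho <- voxel_field(array(1000, d), sp, kind = "density")
  msk <- voxel_field(array(1, d), sp, kind = "mask")
  # uniform field is preserved
  expect_equal(sar10g_peak(voxel_field(array(7, d), sp, kind = "xi"),
                           rho, msk), 7)
  # single hot voxel: 11^3 cube (10.648 g) -> S/1331
  xi <- array(0, d); xi[16, 16, 16] <- 100
  expect_equal(sar10g_peak(voxel_field(xi, sp, kind = "xi"), rho, msk),
               100 / 1331)
  # two disjoint hotspots: exhaustive brute-force oracle (includes the
  # boundary-clipped growth rule) on a smaller grid
  d2 <- c(21, 21, 21)
  rho2 <- voxel_field(array(1000, d2), sp, kind = "density")
  msk2 <- voxel_field(array(1, d2), sp, kind = "mask")
  xi2 <- array(0, d2); xi2[7, 7, 7] <- 50; xi2[15, 15, 15] <- 80
  nv_target <- ceiling(0.010 / (1000 * sp^3))      # 1250 voxels for 10 g
  brute <- 0
  for (i in 1:21) for (j in 1:21) for (k in 1:21) {
    for (hw in 0:20) {
      i1 <- max(i - hw, 1); i2 <- min(i + hw, 21)
      j1 <- max(j - hw, 1); j2 <- min(j + hw, 21)
      k1 <- max(k - hw, 1); k2 <- min(k + hw, 21)
      nv <- (i2 - i1 + 1) * (j2 - j1 + 1) * (k2 - k1 + 1)
      if (nv >= nv_target) {
        s <- sum(xi2[i1:i2, j1:j2, k1:k2])
        brute <- max(brute, s / nv)
        break
      }
    }
  }
  expect_equal(sar10g_peak(voxel_field(xi2, sp, kind = "xi"), rho2, msk2),
               brute)
  # max semantics: the larger hotspot dominates the peak
  xi_small <- array(0, d2); xi_small[7, 7, 7] <- 50
  expect_gt(sar10g_peak(voxel_field(xi2, sp, kind = "xi"), rho2, msk2),
            sar10g_peak(voxel_field(xi_small, sp, kind = "xi"), rho2, msk2))
  # linearity and bounds
  xi3 <- array(stats::runif(prod(d)), d)
  p1 <- sar10g_peak(voxel_field(xi3, sp, kind = "xi"), rho, msk)
  p3 <- sar10g_peak(voxel_field(3 * xi3, sp, kind = "xi"), rho, msk)
  expect_equal(p3, 3 * p1, tolerance = 1e-12)
  wb <- whole_body_average(voxel_field(xi3, sp, kind = "xi"), rho, msk)
  expect_gte(p1, 0)
  expect_lte(p1, max(xi3))
  expect_gte(p1, wb * 0.5)  # peak of 10 g map is at least near the mean
  # object smaller than 10 g
  tiny <- c(2, 2, 2)
  expect_error(
    sar10g_peak(voxel_field(array(1, tiny), 0.001, kind = "xi"),
                voxel_field(array(1000, tiny), 0.001, kind = "density"),
                voxel_field(array(1, tiny), 0.001, kind = "mask")),
    "object too small")
})

test_that("temporal_averages applies the min(1, TS/TIEC) factor", {
  lim <- iec_limits()
  ta <- temporal_averages(0.1, 10, 180, lim)
  expect_equal(ta$tr, 1.0)
  expect_equal(ta$tiec, 0.5)
  ta2 <- temporal_averages(0.1, 10, 360, lim)
  expect_equal(ta2$tr, ta2$tiec)
  ta3 <- temporal_averages(0.1, 10, 720, lim)      # longer than the window
  expect_equal(ta3$tiec, ta3$tr)
  # TrueFISP worked example (psi and xi from the published study)
  ta4 <- temporal_averages(0.12, 349, 130, lim)
  expect_equal(ta4$tr, 41.88)
  expect_equal(ta4$tiec, 130 / 360 * 41.88)
  # Eq-consistency property
  for (ts in c(10, 100, 359, 361, 1000))
    expect_equal(temporal_averages(0.3, 7, ts, lim)$tiec /
                   temporal_averages(0.3, 7, ts, lim)$tr,
                 min(1, ts / lim$TIEC))
})

test_that("xi_threshold implements min(2, TIEC/TS) K2 / psi", {
  lim <- iec_limits()
  expect_equal(xi_threshold(0.12, 130, 10, lim), 2 * 10 / 0.12)
  expect_equal(xi_threshold(0.1, 360, 10, lim), 100)
  # below TIEC/2 the threshold is duration independent
  expect_equal(xi_threshold(0.05, 100, 10, lim),
               xi_threshold(0.05, 179, 10, lim))
  expect_error(xi_threshold(0, 100, 10, lim), "unbounded threshold")
})

test_that("pulse_length_sensitivity matches the 1/(1+x) closed form", {
  s <- sequence_model("t", 0.02, 1, rf_pulses = random_pulse_train(7))
  expect_equal(pulse_length_sensitivity(s, 0), 0)
  expect_equal(pulse_length_sensitivity(s, 0.30), 1 / 1.3 - 1,
               tolerance = 1e-12)
  # central-difference log derivative at +/- 1 % equals -1
  sp <- pulse_length_sensitivity(s, 0.01)
  sm <- pulse_length_sensitivity(s, -0.01)
  dlog <- (log1p(sp) - log1p(sm)) / (log(1.01) - log(0.99))
  expect_equal(dlog, -1, tolerance = 1e-10)
  expect_error(pulse_length_sensitivity(s, -1), "rel_change")
})
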