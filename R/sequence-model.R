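#' RF pulse description
#'
#' An RF excitation pulse is characterised by its expected flip angle, its
#' duration and the shape of its amplitude modulation.  The shape enters the
#' SAR model only through the energy ratio between the modulated pulse and a
#' hard pulse of the same duration and flip angle (see
#' [pulse_energy_ratio()]).
#'
#' @param flip_angle Flip angle in radians (>= 0).
#' @param duration Pulse duration in seconds (> 0).
#' @param shape One of `"hard"`, `"apodized_sinc"`, `"rect_window"`,
#'   `"custom_envelope"`.
#' @param time_bandwidth Time-bandwidth product for sinc shapes (number of
#'   zero crossings spanned); default 4.
#' @param apodization Window applied to sinc shapes: `"hanning"`,
#'   `"hamming"` or `"none"`.
#' @param window_fraction For `rect_window`, the fraction of the duration the
#'   envelope is on (centred); in `(0, 1]`.
#' @param envelope_samples For `custom_envelope`, numeric samples of the
#'   normalized amplitude (peak 1) covering the full duration uniformly.
#' @return An object of class `rf_pulse`.
#' @export
rf_pulse <- function(flip_angle, duration,
                     shape = c("hard", "apodized_sinc", "rect_window",
                               "custom_envelope"),
                     time_bandwidth = 4, apodization = "hanning",
                     window_fraction = 1, envelope_samples = NULL) {
  shape <- match.arg(shape)
  if (flip_angle < 0) stop("flip_angle must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  if (shape == "rect_window" &&
      (window_fraction <= 0 || window_fraction > 1))
    stop("window_fraction must be in (0, 1]")
  if (shape == "custom_envelope") {
    if (is.null(envelope_samples) || length(envelope_samples) < 2)
      stop("custom_envelope requires envelope_samples")
    if (any(!is.finite(envelope_samples)))
      stop("envelope samples must be finite")
    if (abs(max(abs(envelope_samples)) - 1) > 1e-8)
      stop("envelope samples must be peak-normalized to 1")
  }
  structure(
    list(flip_angle = flip_angle, duration = duration, shape = shape,
         time_bandwidth = time_bandwidth, apodization = apodization,
         window_fraction = window_fraction,
         envelope_samples = envelope_samples),
    class = "rf_pulse"
  )
}

# Normalized envelope e(u), u in [0,1], peak 1, sampled at n points
# (midpoint rule sampling: u_j = (j - 1/2)/n).
pulse_envelope <- function(pulse, n = 8192) {
  u <- (seq_len(n) - 0.5) / n
  switch(pulse$shape,
    hard = rep(1, n),
    rect_window = {
      lo <- (1 - pulse$window_fraction) / 2
      hi <- 1 - lo
      as.numeric(u >= lo & u < hi)
    },
    apodized_sinc = {
      x <- pulse$time_bandwidth * (u - 0.5)
      e <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
      w <- switch(pulse$apodization,
        hanning = 0.5 - 0.5 * cos(2 * pi * u),
        hamming = 0.54 - 0.46 * cos(2 * pi * u),
        none = rep(1, n),
        stop("unknown apodization")
      )
      e * w
    },
    custom_envelope = {
      s <- pulse$envelope_samples
      stats::approx(seq(0, 1, length.out = length(s)), s, xout = u,
                    rule = 2)$y
    }
  )
}

#' Energy ratio of a modulated RF pulse relative to a hard pulse
#'
#' For a normalized envelope \eqn{e(t)} over duration \eqn{T}, returns
#' \eqn{r = T \int e^2 dt / (\int e\, dt)^2}: the ratio between the energies
#' of the modulated pulse and of the hard pulse delivering the same flip
#' angle in the same duration.  By Cauchy-Schwarz \eqn{r \ge 1}, with
#' equality for the hard pulse.
#'
#' @param pulse An [rf_pulse()].
#' @param n Number of quadrature samples for shaped pulses.
#' @return Dimensionless energy ratio (>= 1).
#' @export
#' @examples
#' pulse_energy_ratio(rf_pulse(pi / 2, 1e-3))                       # 1
#' pulse_energy_ratio(rf_pulse(pi / 2, 1e-3, "rect_window",
#'                             window_fraction = 0.5))              # 2
pulse_energy_ratio <- function(pulse, n = 8192) {
  if (pulse$shape == "hard") return(1)
  if (pulse$shape == "rect_window") return(1 / pulse$window_fraction)
  e <- pulse_envelope(pulse, n)
  i1 <- mean(e)        # (1/T) int e dt in normalized time
  i2 <- mean(e^2)
  if (abs(i1) < 1e-12 * max(abs(e)))
    stop("degenerate envelope: integral is zero, flip angle unreachable")
  i2 / i1^2
}

#' Gradient waveform event on one coil channel
#'
#' Either an analytic trapezoid (ramp up, flat top, ramp down) or a sampled
#' waveform.  Events on one channel are summed where they overlap.
#'
#' @param channel `"x"`, `"y"` or `"z"`.
#' @param kind `"trapezoid"` or `"sampled"`.
#' @param amplitude Peak amplitude in T/m (trapezoid).
#' @param ramp_time Ramp duration in s (trapezoid).
#' @param flat_time Flat-top duration in s (trapezoid).
#' @param start_time Event start within the TR, s.
#' @param samples Numeric samples in T/m for `kind = "sampled"`.
#' @param sample_dt Uniform sampling interval in s for `samples`.
#' @param times Optional explicit sample times; must be uniform (a
#'   non-uniform series signals `resample required`).
#' @param max_amplitude,max_slew Hardware limits used for validation
#'   (defaults 40 mT/m and 200 T/m/s).
#' @return An object of class `gradient_event`.
#' @export
gradient_event <- function(channel = c("x", "y", "z"),
                           kind = c("trapezoid", "sampled"),
                           amplitude = 0, ramp_time = 0, flat_time = 0,
                           start_time = 0, samples = NULL, sample_dt = NULL,
                           times = NULL,
                           max_amplitude = 0.040, max_slew = 200) {
  channel <- match.arg(channel)
  kind <- match.arg(kind)
  if (kind == "trapezoid") {
    if (abs(amplitude) > max_amplitude * (1 + 1e-9))
      stop("gradient amplitude exceeds the hardware maximum")
    if (abs(amplitude) > 0 && ramp_time < abs(amplitude) / max_slew * (1 - 1e-9))
      stop("ramp_time shorter than the slew-rate limit allows")
  } else {
    if (is.null(samples)) stop("sampled events require samples")
    if (!is.null(times)) {
      dts <- diff(times)
      if (length(dts) == 0 || diff(range(dts)) > 1e-9 * max(dts))
        stop("resample required: sampled waveform is not uniformly sampled")
      sample_dt <- dts[1]
    }
    if (is.null(sample_dt)) stop("sampled events require sample_dt or times")
  }
  structure(
    list(channel = channel, kind = kind, amplitude = amplitude,
         ramp_time = ramp_time, flat_time = flat_time,
         start_time = start_time, samples = samples, sample_dt = sample_dt),
    class = "gradient_event"
  )
}

# Evaluate one event's contribution at times t (s, within the TR).
eval_gradient_event <- function(ev, t) {
  if (ev$kind == "trapezoid") {
    tt <- t - ev$start_time
    r <- ev$ramp_time
    f <- ev$flat_time
    g <- numeric(length(t))
    up <- tt >= 0 & tt < r
    fl <- tt >= r & tt < r + f
    dn <- tt >= r + f & tt < 2 * r + f
    if (r > 0) g[up] <- ev$amplitude * tt[up] / r else g[up] <- 0
    g[fl] <- ev$amplitude
    if (r > 0) g[dn] <- ev$amplitude * (2 * r + f - tt[dn]) / r
    g
  } else {
    ts <- ev$start_time + (seq_along(ev$samples) - 1) * ev$sample_dt
    out <- stats::approx(ts, ev$samples, xout = t, method = "linear",
                         yleft = 0, yright = 0)$y
    out
  }
}

#' MR pulse-sequence model
#'
#' Carrier of the RF pulse train, the periodic gradient waveform of one TR,
#' and the sequence timing.  Sequences may declare a B1+ rms value (as
#' scanner consoles report) instead of, or in addition to, an explicit pulse
#' train; [rf_stress_index()] accepts either route.
#'
#' @param name Sequence name.
#' @param tr Repetition time in seconds (> 0).
#' @param duration Total sequence duration in seconds (>= tr).
#' @param rf_pulses List of [rf_pulse()] objects played in one TR.
#' @param gradient_events List of [gradient_event()] objects describing one
#'   TR (the maximum-intensity TR for TR-varying sequences).
#' @param duty_cycle Fraction of the sequence during which gradients are
#'   active, in `(0, 1]`.
#' @param b1rms Declared B1+ rms in tesla (optional).
#' @param freq_encode_axis Frequency-encoding axis (`"x"`, `"y"`, `"z"`) or
#'   `NA`.
#' @param family Sequence family tag (e.g. `"SE"`, `"GRE"`, `"EPI"`,
#'   `"bSSFP"`); `"EPI"` enables [worst_case_epi()].
#' @return An object of class `sequence_model`.
#' @export
sequence_model <- function(name, tr, duration, rf_pulses = list(),
                           gradient_events = list(), duty_cycle = 1,
                           b1rms = NULL, freq_encode_axis = NA_character_,
                           family = NA_character_) {
  if (tr <= 0) stop("TR must be > 0")
  if (duration < tr) stop("duration must be >= TR")
  if (duty_cycle <= 0 || duty_cycle > 1) stop("duty_cycle must be in (0, 1]")
  if (length(rf_pulses)) {
    tot <- sum(vapply(rf_pulses, `[[`, numeric(1), "duration"))
    if (tot > tr) stop("sum of RF pulse durations exceeds TR")
  }
  structure(
    list(name = name, tr = tr, duration = duration, rf_pulses = rf_pulses,
         gradient_events = gradient_events, duty_cycle = duty_cycle,
         b1rms = b1rms, freq_encode_axis = freq_encode_axis, family = family),
    class = "sequence_model"
  )
}

#' @export
print.sequence_model <- function(x, ...) {
  cat(sprintf("<sequence_model> %s: TR=%.4g ms, duration=%.4g s, %d RF pulse(s), %d gradient event(s)\n",
              x$name, x$tr * 1e3, x$duration, length(x$rf_pulses),
              length(x$gradient_events)))
  if (!is.null(x$b1rms))
    cat(sprintf("  declared B1+rms = %.3g uT\n", x$b1rms * 1e6))
  invisible(x)
}

#' Sequence RF stress index
#'
#' The dimensionless multiplier \eqn{\psi_S} such that the TR-averaged SAR in
#' any configuration equals \eqn{\psi_S \, \xi_C(x)}, where \eqn{\xi_C} is
#' the configuration index calibrated to a 90-degree, 1 ms hard pulse.
#'
#' Two provably identical routes are available:
#' \describe{
#'   \item{pulse train}{\eqn{\psi_S = (1/TR)\sum_i r_i T_i
#'     (\alpha_i/\alpha_{90} \cdot \Delta t/T_i)^2} over the pulses of one
#'     TR, with \eqn{r_i} the pulse energy ratio.}
#'   \item{b1rms}{\eqn{\psi_S = (\gamma \Delta t B_{1rms} / (\pi/2))^2},
#'     used when only a console-declared B1+ rms is available.}
#' }
#'
#' @param seq A [sequence_model()].
#' @param route `"auto"` (pulse train when pulses are present, else b1rms),
#'   `"pulse_train"` or `"b1rms"`.
#' @return Dimensionless stress index.
#' @export
#' @examples
#' s <- sequence_model("ref", tr = 1e-3, duration = 1,
#'                     rf_pulses = list(rf_pulse(pi / 2, 1e-3)))
#' rf_stress_index(s)  # 1: the reference hard pulse
rf_stress_index <- function(seq, route = c("auto", "pulse_train", "b1rms")) {
  route <- match.arg(route)
  cst <- mri_constants()
  if (route == "auto")
    route <- if (length(seq$rf_pulses)) "pulse_train" else "b1rms"
  if (route == "pulse_train") {
    if (!length(seq$rf_pulses))
      stop("underspecified sequence: no RF pulses for the pulse-train route")
    terms <- vapply(seq$rf_pulses, function(p) {
      r <- pulse_energy_ratio(p)
      r * p$duration *
        (p$flip_angle / cst$alpha_ref * cst$dt_ref / p$duration)^2
    }, numeric(1))
    sum(terms) / seq$tr
  } else {
    if (is.null(seq$b1rms))
      stop("underspecified sequence: neither RF pulses nor b1rms declared")
    (cst$gamma * cst$dt_ref * seq$b1rms / cst$alpha_ref)^2
  }
}

#' B1+ rms equivalent of a pulse train (tesla)
#'
#' Root-mean-square over one TR of the amplitude-scaled pulse envelopes; the
#' b1rms route applied to this value reproduces the pulse-train stress index
#' exactly.
#'
#' @param seq A [sequence_model()] with RF pulses.
#' @export
b1rms_from_pulses <- function(seq) {
  if (!length(seq$rf_pulses)) stop("sequence has no RF pulses")
  cst <- mri_constants()
  ssq <- sum(vapply(seq$rf_pulses, function(p) {
    r <- pulse_energy_ratio(p)
    # B1peak = alpha / (gamma T i1); int B1^2 dt = alpha^2 r / (gamma^2 T)
    p$flip_angle^2 * r / (cst$gamma^2 * p$duration)
  }, numeric(1)))
  sqrt(ssq / seq$tr)
}

#' Harmonic spectrum of the periodic gradient waveform
#'
#' Fourier-series coefficients (peak phasors: the waveform equals
#' \eqn{\sum_f \mathrm{Re}\{G(f) e^{i 2\pi f t}\}}) of the per-channel
#' gradient waveform over one TR, treated as the periodic unit.  The DC term
#' deposits no eddy-current power and is discarded; the harmonic list is
#' truncated once the cumulative \eqn{f^2 |G|^2} weight reaches
#' `energy_fraction` of the total, or the frequency exceeds `f_max`
#' (quasi-static validity), whichever comes first.
#'
#' @param seq A [sequence_model()].
#' @param dt Target sampling interval (s); the actual interval divides the
#'   TR exactly.  Default `1e-6`, coarsened if it would exceed `max_samples`.
#' @param energy_fraction Retained fraction of f^2-weighted spectral energy.
#' @param f_max Maximum retained frequency in Hz.
#' @param max_samples Cap on the number of waveform samples.
#' @return An object of class `gradient_spectrum`: list with `frequencies`
#'   (Hz, increasing) and `coefficients` (complex n x 3 matrix, T/m peak).
#' @export
gradient_spectrum <- function(seq, dt = 1e-6, energy_fraction = 0.999,
                              f_max = 1e5, max_samples = 2^21) {
  empty <- structure(
    list(frequencies = numeric(0),
         coefficients = matrix(complex(0), 0, 3,
                               dimnames = list(NULL, c("x", "y", "z"))),
         tr = seq$tr),
    class = "gradient_spectrum")
  if (!length(seq$gradient_events)) return(empty)
  n <- min(max(1024L, 2^ceiling(log2(seq$tr / dt))), max_samples)
  t <- (seq_len(n) - 1) * (seq$tr / n)
  g <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (ev in seq$gradient_events) {
    j <- match(ev$channel, c("x", "y", "z"))
    g[, j] <- g[, j] + eval_gradient_event(ev, t)
  }
  if (all(g == 0)) return(empty)
  co <- apply(g, 2, stats::fft) / n
  m <- seq_len(floor(n / 2) - 1)          # harmonics 1 .. Nyquist-1
  freqs <- m / seq$tr
  coef <- 2 * co[m + 1, , drop = FALSE]   # peak phasors
  w <- freqs^2 * rowSums(Mod(coef)^2)
  wtot <- sum(w)
  keep <- seq_along(freqs)
  if (wtot > 0) {
    cum <- cumsum(w) / wtot
    n_keep <- which(cum >= energy_fraction | freqs > f_max)[1]
    if (is.na(n_keep)) n_keep <- length(freqs)
    keep <- seq_len(n_keep)
    keep <- keep[w[keep] > 0]             # drop exact-zero lines
  }
  structure(
    list(frequencies = freqs[keep],
         coefficients = coef[keep, , drop = FALSE], tr = seq$tr),
    class = "gradient_spectrum")
}

#' @export
print.gradient_spectrum <- function(x, ...) {
  cat(sprintf("<gradient_spectrum> %d harmonic(s)", length(x$frequencies)))
  if (length(x$frequencies))
    cat(sprintf(", f in [%.4g, %.4g] Hz", min(x$frequencies),
                max(x$frequencies)))
  cat("\n")
  invisible(x)
}

#' Export a gradient spectrum as a data frame (CSV-ready)
#'
#' @param spectrum A [gradient_spectrum()] result.
#' @return Data frame with frequency and Re/Im columns per channel.
#' @export
spectrum_as_data_frame <- function(spectrum) {
  co <- spectrum$coefficients
  data.frame(
    frequency_hz = spectrum$frequencies,
    gx_re = Re(co[, 1]), gx_im = Im(co[, 1]),
    gy_re = Re(co[, 2]), gy_im = Im(co[, 2]),
    gz_re = Re(co[, 3]), gz_im = Im(co[, 3])
  )
}
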