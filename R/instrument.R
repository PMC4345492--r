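# Instrument simulator: the platform as a set of lightly damped structural
# modes in series with statically determinate load cells that split the
# vertical reaction, add preload and noise, quantize, and sample.

#' Modal model of the instrumented structure
#'
#' A sum of second-order resonators with unit total DC gain: the vertical
#' force transmitted to the load cells is the input filtered through
#' `sum_i participation_i * H_i(s)` with
#' `H_i(s) = w_i^2 / (s^2 + 2 zeta_i w_i s + w_i^2)`.
#'
#' @param frequency Natural frequencies, Hz.
#' @param damping Damping ratios in (0, 1); default 0.03 per mode (light
#'   damping typical of stiff balsa sandwich construction).
#' @param participation Modal participations; must sum to 1.
#' @return An object of class `modal_model`.
#' @export
modal_model <- function(frequency, damping = rep(0.03, length(frequency)),
                        participation = NULL) {
  assert_that(is.numeric(frequency) && all(frequency > 0), "frequencies must be > 0")
  assert_that(length(damping) == length(frequency) && all(damping > 0 & damping < 1),
              "damping ratios must lie in (0, 1)")
  if (is.null(participation))
    participation <- rep(1 / length(frequency), length(frequency))
  assert_that(length(participation) == length(frequency) &&
                abs(sum(participation) - 1) < 1e-9,
              "participations must sum to 1")
  structure(data.frame(frequency = frequency, damping = damping,
                       participation = participation),
            class = c("modal_model", "data.frame"))
}

#' @describeIn modal_model Platform structure: dominant 132 Hz vertical mode
#'   weakly coupled to a small-amplitude 105 Hz mode (5 per cent
#'   participation).
#' @export
afp_platform_modes <- function() {
  modal_model(frequency = c(132, 105), damping = c(0.03, 0.03),
              participation = c(0.95, 0.05))
}

#' @describeIn modal_model Reference beam (with suspended load): a single
#'   138 Hz mode.
#' @export
beam_modes <- function() modal_model(frequency = 138, damping = 0.03)

#' Load-cell sensor specification
#'
#' @param n_channels Number of load cells sharing the (equally preloaded,
#'   statically determinate) support.
#' @param resolution Force resolution of each channel, N.
#' @param sampling_interval Sampling interval, s.
#' @param calibration_coefficient Linear calibration coefficient mapping raw
#'   channel readings to calibrated force (`true = coefficient * raw`); the
#'   simulator applies the inverse as the raw sensor gain.
#' @param noise_rms RMS of additive per-channel Gaussian noise, N; default
#'   one resolution step.
#' @param preload_total Static preload carried by all channels together, N.
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(n_channels, resolution = 2e-3, sampling_interval = 1e-3,
                        calibration_coefficient = 1, noise_rms = resolution,
                        preload_total = 0) {
  assert_that(is.numeric(n_channels) && n_channels >= 1, "n_channels must be >= 1")
  assert_scalar_pos(resolution, "resolution")
  assert_scalar_pos(sampling_interval, "sampling_interval")
  assert_that(calibration_coefficient > 0.9 && calibration_coefficient <= 1.1,
              "calibration_coefficient must lie in (0.9, 1.1]")
  assert_scalar_pos(noise_rms, "noise_rms", strict = FALSE)
  assert_scalar_pos(preload_total, "preload_total", strict = FALSE)
  structure(list(n_channels = as.integer(n_channels), resolution = resolution,
                 sampling_interval = sampling_interval,
                 calibration_coefficient = calibration_coefficient,
                 noise_rms = noise_rms, preload_total = preload_total),
            class = "sensor_spec")
}

#' @describeIn sensor_spec Platform sensing: three 6-axis load cells, 2 mN
#'   resolution, 1 ms sampling, calibration coefficient 0.989, preloaded by
#'   the 1.79 kg platform weight.
#' @export
afp_platform_sensor <- function() {
  sensor_spec(n_channels = 3, resolution = 2e-3, sampling_interval = 1e-3,
              calibration_coefficient = 0.989, noise_rms = 2e-3,
              preload_total = 1.79 * 9.81)
}

#' @describeIn sensor_spec Reference beam sensing: two load cells,
#'   calibration coefficient 0.997, preloaded by the suspended vehicle
#'   weight (0.6 N nominal).
#' @export
beam_sensor <- function() {
  sensor_spec(n_channels = 2, resolution = 2e-3, sampling_interval = 1e-3,
              calibration_coefficient = 0.997, noise_rms = 2e-3,
              preload_total = 0.6)
}

# exact zero-order-hold discretization of one resonator: returns the
# difference-equation coefficients of y[n] = a1 y[n-1] + a2 y[n-2]
#                                          + b1 u[n-1] + b2 u[n-2]
.zoh_resonator <- function(f0, zeta, dt) {
  w <- 2 * pi * f0
  A <- rbind(c(0, 1), c(-w^2, -2 * zeta * w))
  ev <- eigen(A)
  Ad <- Re(ev$vectors %*% diag(exp(ev$values * dt)) %*% solve(ev$vectors))
  B <- c(0, w^2)
  Bd <- as.numeric(solve(A, (Ad - diag(2)) %*% B))
  list(a1 = Ad[1, 1] + Ad[2, 2],
       a2 = -(Ad[1, 1] * Ad[2, 2] - Ad[1, 2] * Ad[2, 1]),
       b1 = Bd[1],
       b2 = Ad[1, 2] * Bd[2] - Ad[2, 2] * Bd[1])
}

# filter u (sampled at dt) through the modal transfer function
modal_response <- function(u, dt, modal) {
  y <- numeric(length(u))
  for (i in seq_len(nrow(modal))) {
    cf <- .zoh_resonator(modal$frequency[i], modal$damping[i], dt)
    n <- length(u)
    m <- cf$b1 * c(0, u[-n]) + cf$b2 * c(0, 0, u[-c(n - 1, n)])
    y <- y + modal$participation[i] *
      as.numeric(stats::filter(m, c(cf$a1, cf$a2), method = "recursive"))
  }
  y
}

#' Simulate a load-cell recording of a true force trace
#'
#' The true (vertical) force is resampled to the sensor clock, filtered
#' through the structural modal transfer function, split equally across the
#' channels together with the preload, scaled by the raw sensor gain (the
#' inverse of the calibration coefficient), corrupted by seeded Gaussian
#' noise, and mid-tread quantized at the channel resolution. The result is a
#' raw recording; [apply_calibration()] maps it back to calibrated units.
#'
#' @param true_force A [force_trace] of the ground-truth force, N.
#' @param modal A [modal_model].
#' @param sensor A [sensor_spec].
#' @param seed Integer seed making the noise reproducible.
#' @return An object of class `recording`: `time`, `channels` matrix
#'   (samples x channels), the specs, `calibrated = FALSE`, and the seed.
#' @export
#' @examples
#' tr <- gen_thrust_profile(thrust_profile_spec(kind = "constant",
#'                                              n_periods = 2, frequency = 0.5))
#' rec <- simulate_recording(tr, afp_platform_modes(), afp_platform_sensor(), seed = 1)
simulate_recording <- function(true_force, modal, sensor, seed = 1L) {
  assert_that(inherits(true_force, "force_trace"), "`true_force` must be a force_trace")
  assert_that(inherits(modal, "modal_model"), "`modal` must be a modal_model")
  assert_that(inherits(sensor, "sensor_spec"), "`sensor` must be a sensor_spec")
  span <- diff(range(true_force$time))
  assert_that(span >= 10 * sensor$sampling_interval,
              "true_force is shorter than 10 sampling intervals")
  ts <- seq(min(true_force$time), max(true_force$time),
            by = sensor$sampling_interval)
  u <- stats::approx(true_force$time, true_force$force, ts, rule = 2)$y
  y <- modal_response(u, sensor$sampling_interval, modal)
  nch <- sensor$n_channels
  gain <- 1 / sensor$calibration_coefficient
  channels <- withr::with_seed(seed, {
    vapply(seq_len(nch), function(ch) {
      raw <- gain * (y + sensor$preload_total) / nch +
        stats::rnorm(length(y), sd = sensor$noise_rms)
      sensor$resolution * round(raw / sensor$resolution)
    }, numeric(length(y)))
  })
  structure(list(time = ts, channels = channels, sensor = sensor, modal = modal,
                 calibrated = FALSE, seed = seed),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples x %d channels @ %.4g ms, %s\n",
              length(x$time), ncol(x$channels), 1000 * x$sensor$sampling_interval,
              if (x$calibrated) "calibrated" else "raw"))
  invisible(x)
}

#' Impulse (balloon-pop) excitation recording
#'
#' Simulates the pop test used to identify the structural resonance: a train
#' of brief raised-cosine impulses with jittered timing, passed through the
#' instrument simulator.
#'
#' @inheritParams simulate_recording
#' @param n_pops Number of impulses (the identification protocol uses 5).
#' @param amplitude Impulse peak force, N.
#' @param width Impulse width, s.
#' @param spacing Nominal spacing between impulses, s.
#' @return A raw `recording`.
#' @export
pop_test <- function(modal, sensor, n_pops = 5, seed = 1L,
                     amplitude = 2, width = 2e-3, spacing = 1) {
  trace <- gen_pop_impulse(amplitude = amplitude, width = width, n_pops = n_pops,
                           spacing = spacing, seed = seed,
                           sample_rate = 4 / sensor$sampling_interval)
  simulate_recording(trace, modal, sensor, seed = seed + 1L)
}

#' Apply the linear calibration to a raw recording
#'
#' Multiplies every channel by the calibration coefficient; refuses to run
#' twice on the same recording.
#'
#' @param rec A raw `recording`.
#' @return The calibrated `recording`.
#' @export
apply_calibration <- function(rec) {
  assert_that(inherits(rec, "recording"), "`rec` must be a recording")
  if (isTRUE(rec$calibrated)) stop("calibration already applied", call. = FALSE)
  rec$channels <- rec$channels * rec$sensor$calibration_coefficient
  rec$calibrated <- TRUE
  rec
}

#' Net force trace from a recording
#'
#' Sums the channels and removes the static preload, yielding the measured
#' net fluid force as a [force_trace]. For a raw (uncalibrated) recording
#' the preload is removed on the raw scale (divided by the calibration
#' coefficient) so the operation is consistent in either state.
#'
#' @param rec A `recording`.
#' @return A [force_trace].
#' @export
recording_force <- function(rec) {
  assert_that(inherits(rec, "recording"), "`rec` must be a recording")
  preload <- rec$sensor$preload_total
  if (!isTRUE(rec$calibrated)) preload <- preload / rec$sensor$calibration_coefficient
  force_trace(rec$time, rowSums(rec$channels) - preload)
}
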