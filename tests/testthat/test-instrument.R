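# Instrument simulator: modal dynamics, channel split, quantization,
# calibration.

# noiseless high-resolution sensor for dynamics-only checks
ideal_sensor <- function(n_channels = 3, sampling_interval = 1e-3,
                         preload_total = 0) {
  sensor_spec(n_channels = n_channels, resolution = 1e-9,
              sampling_interval = sampling_interval,
              calibration_coefficient = 1, noise_rms = 0,
              preload_total = preload_total)
}

const_trace <- function(value, duration = 2, fs = 1000) {
  tt <- seq(0, duration, by = 1 / fs)
  force_trace(tt, rep(value, length(tt)))
}

test_that("DC conservation: channel sum minus preload returns the input", {
  sens <- sensor_spec(n_channels = 3, resolution = 2e-3, noise_rms = 0,
                      preload_total = 1.79 * 9.81)
  rec <- simulate_recording(const_trace(1), afp_platform_modes(), sens, seed = 1)
  f <- recording_force(rec)
  settled <- f$force[f$time > 1]
  expect_lt(max(abs(settled - 1)), sens$resolution * sens$n_channels)
  # zero input, zero noise: channels constant at quantized preload share
  rec0 <- simulate_recording(const_trace(0), afp_platform_modes(), sens, seed = 1)
  share <- sens$preload_total / sens$n_channels
  expect_true(all(abs(rec0$channels[rec0$time > 1, ] - share) <= sens$resolution))
  expect_equal(length(unique(rec0$channels[rec0$time > 1, 1])), 1L)
})

test_that("raw channels sit exactly on the quantization lattice", {
  rec <- simulate_recording(const_trace(0.731), afp_platform_modes(),
                            afp_platform_sensor(), seed = 3)
  ratio <- rec$channels / rec$sensor$resolution
  expect_lt(max(abs(ratio - round(ratio))), 1e-8)
})

test_that("recordings are seed-deterministic", {
  tr <- const_trace(0.5, duration = 0.5)
  r1 <- simulate_recording(tr, afp_platform_modes(), afp_platform_sensor(), seed = 11)
  r2 <- simulate_recording(tr, afp_platform_modes(), afp_platform_sensor(), seed = 11)
  r3 <- simulate_recording(tr, afp_platform_modes(), afp_platform_sensor(), seed = 12)
  expect_identical(r1$channels, r2$channels)
  expect_false(identical(r1$channels, r3$channels))
})

test_that("impulse ringdown matches the closed-form underdamped response", {
  f0 <- 132; zeta <- 0.03
  modal <- modal_model(f0, zeta)
  sens <- ideal_sensor(sampling_interval = 1e-4)
  dt <- 1e-4
  tt <- seq(0, 0.3, by = dt)
  u <- numeric(length(tt)); u[tt >= 0.05 & tt < 0.05 + dt] <- 1
  rec <- simulate_recording(force_trace(tt, u), modal, sens, seed = 1)
  y <- rowSums(rec$channels)
  ring <- y[rec$time > 0.052 & rec$time < 0.15]
  tr <- rec$time[rec$time > 0.052 & rec$time < 0.15]
  # zero-crossing spacing = half the damped period
  sgn <- sign(ring)
  cross <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0)
  spacing <- mean(diff(tr[cross]))
  fd <- f0 * sqrt(1 - zeta^2)
  expect_equal(spacing, 1 / (2 * fd), tolerance = 0.02)
  # envelope decay per full period: exp(-2 pi zeta / sqrt(1 - zeta^2))
  pk <- which(diff(sign(diff(ring))) == -2) + 1L
  pk <- pk[ring[pk] > 0]
  ratios <- ring[pk[-1]] / ring[pk[-length(pk)]]
  expect_equal(mean(ratios), exp(-2 * pi * zeta / sqrt(1 - zeta^2)),
               tolerance = 0.05)
})

test_that("sub-resonant sinusoids pass with small distortion and lag", {
  modal <- afp_platform_modes()
  sens <- ideal_sensor(sampling_interval = 1e-3)
  tt <- seq(0, 3, by = 1e-3)
  tr <- force_trace(tt, sin(2 * pi * 20 * tt))
  rec <- simulate_recording(tr, modal, sens, seed = 1)
  y <- rowSums(rec$channels)
  mid <- rec$time > 1 & rec$time < 2.5
  amp <- max(abs(y[mid]))
  expect_lt(abs(amp - 1), 0.03)
  lag <- afplatform:::xcorr_delay(y[mid], tr$force[mid], 1e-3, 0.02)
  expect_lt(abs(lag), 1 / 132)
})

test_that("calibration is linear, faithful and applied exactly once", {
  tr <- const_trace(1, duration = 3)
  sens1 <- sensor_spec(3, resolution = 1e-9, calibration_coefficient = 1,
                       noise_rms = 0)
  rec1 <- simulate_recording(tr, afp_platform_modes(), sens1, seed = 1)
  cal1 <- apply_calibration(rec1)
  expect_equal(cal1$channels, rec1$channels) # coefficient 1 is the identity
  expect_error(apply_calibration(cal1), "already applied")

  sens <- sensor_spec(3, resolution = 1e-9, calibration_coefficient = 0.989,
                      noise_rms = 0)
  rec <- simulate_recording(tr, afp_platform_modes(), sens, seed = 1)
  cal <- apply_calibration(rec)
  # a raw 1.000 N channel reading calibrates to 0.989 N
  expect_equal(cal$channels, 0.989 * rec$channels, tolerance = 1e-12)
  # sum-then-calibrate equals calibrate-then-sum
  expect_equal(rowSums(cal$channels), 0.989 * rowSums(rec$channels),
               tolerance = 1e-12)
  # end to end the simulated gain and the calibration cancel
  f <- recording_force(cal)
  expect_equal(mean(f$force[f$time > 2]), 1, tolerance = 1e-6)
})

test_that("pop tests excite the modal spectrum in participation order", {
  sens <- ideal_sensor(sampling_interval = 1e-3)
  rec <- pop_test(afp_platform_modes(), sens, n_pops = 5, seed = 2)
  x <- rowSums(rec$channels)
  ps <- afplatform:::welch_psd(x - mean(x), 1000, nseg = 1024)
  p_at <- function(f0) max(ps$power[abs(ps$freq - f0) < 3])
  expect_gt(p_at(132), p_at(105)) # secondary mode stays secondary
  # single pop, one mode: one dominant spectral peak
  rec1 <- pop_test(modal_model(132, 0.03), sens, n_pops = 1, seed = 3)
  expect_equal(natural_frequency(rec1), 132, tolerance = 0.02)
})
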