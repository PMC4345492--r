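# Synthetic-data generators: determinism, invariants, closed-form checks.

test_that("thrust profiles honour kind, duration and mean", {
  const <- gen_thrust_profile(thrust_profile_spec(kind = "constant",
                                                  frequency = 0.5, n_periods = 6))
  expect_true(all(const$force == 1))
  expect_equal(diff(range(const$time)), 6 / 0.5)

  semi <- gen_thrust_profile(thrust_profile_spec(frequency = 0.5, n_periods = 84,
                                                 sample_rate = 50))
  expect_equal(diff(range(semi$time)), 168) # 84 periods at 0.5 Hz
  # unclipped semi-sinusoid time-averages to the mean thrust
  expect_equal(pracma::trapz(semi$time, semi$force) / diff(range(semi$time)),
               1, tolerance = 1e-6)
  expect_true(all(semi$force >= 0))

  # thrust stays non-negative even when the modulation reaches the mean
  clip <- gen_thrust_profile(thrust_profile_spec(frequency = 0.5, n_periods = 4,
                                                 mean_thrust = 0.5,
                                                 modulation_amplitude = 0.5))
  expect_true(all(clip$force >= 0))
  rnd <- gen_thrust_profile(thrust_profile_spec(kind = "manual_random",
                                                frequency = 0.25, n_periods = 2,
                                                seed = 3))
  expect_true(all(rnd$force >= 0))
  expect_error(thrust_profile_spec(mean_thrust = 1, modulation_amplitude = 1.5),
               "exceed")
})

test_that("every generator is seed-deterministic", {
  s <- thrust_profile_spec(kind = "manual_random", frequency = 0.25,
                           n_periods = 2, seed = 4)
  expect_identical(gen_thrust_profile(s)$force, gen_thrust_profile(s)$force)
  b <- bird_flight_spec(seed = 8)
  expect_identical(gen_bird_flight(b)$trace$force, gen_bird_flight(b)$trace$force)
  expect_false(identical(gen_bird_flight(bird_flight_spec(seed = 9))$trace$force,
                         gen_bird_flight(b)$trace$force))
  expect_identical(gen_pop_impulse(seed = 2)$force, gen_pop_impulse(seed = 2)$force)
})

test_that("flight segmentation tiles the flight with alternating strokes", {
  fl <- gen_bird_flight(bird_flight_spec(n_wingbeats = 8, seed = 1))
  seg <- fl$segmentation
  fb <- attr(seg, "flight_bounds")
  expect_equal(fb, c(0, 8 / 20))
  expect_equal(seg$start[1], fb[1])
  expect_equal(seg$end[nrow(seg)], fb[2])
  expect_equal(seg$start[-1], seg$end[-nrow(seg)], tolerance = 1e-12) # no gaps
  expect_true(all(seg$phase == rep(c("downstroke", "upstroke"), 8)))
})

test_that("flight forces carry the configured stroke structure", {
  spec <- bird_flight_spec(seed = 2, amplitude_jitter = 0,
                           upstroke_support_multiple = 0,
                           takeoff_push_fraction = 0)
  fl <- gen_bird_flight(spec)
  W <- fl$body$weight
  # peak downstroke force is twice body weight before filtering
  expect_equal(max(fl$trace$force) / W, 2, tolerance = 1e-3)
  # zero upstroke support: the force vanishes in every upstroke window
  seg <- fl$segmentation
  for (i in which(seg$phase == "upstroke")) {
    idx <- fl$trace$time >= seg$start[i] & fl$trace$time < seg$end[i]
    expect_lt(max(abs(fl$trace$force[idx])), 1e-12)
  }
  expect_true(all(fl$trace$force >= 0))

  # symmetric hovering-like spec: whole-flight mean support of one
  hov <- gen_bird_flight(bird_flight_spec(downstroke_peak_multiple = pi / 2,
                                          upstroke_support_multiple = 1,
                                          downstroke_fraction = 0.5,
                                          takeoff_push_fraction = 0,
                                          amplitude_jitter = 0.05, seed = 3))
  fb <- attr(hov$segmentation, "flight_bounds")
  idx <- hov$trace$time >= fb[1] & hov$trace$time <= fb[2]
  mean_support <- pracma::trapz(hov$trace$time[idx], hov$trace$force[idx]) /
    diff(fb) / hov$body$weight
  expect_equal(mean_support, 1, tolerance = 0.05)
})

test_that("pop impulses have the closed-form count and integral", {
  fine <- gen_pop_impulse(amplitude = 3, width = 0.01, n_pops = 1,
                          spacing = 0.5, seed = 1, sample_rate = 1e5)
  expect_equal(pracma::trapz(fine$time, fine$force), 3 * 0.01 / 2,
               tolerance = 1e-4)
  train <- gen_pop_impulse(amplitude = 2, width = 0.01, n_pops = 5,
                           spacing = 1, seed = 4, sample_rate = 4000)
  y <- train$force
  maxima <- sum(diff(sign(diff(y))) == -2 & y[2:(length(y) - 1)] > 1)
  expect_identical(maxima, 5L)
  zero <- gen_pop_impulse(amplitude = 0, width = 0.01, n_pops = 3, spacing = 1)
  expect_true(all(zero$force == 0))
  expect_error(gen_pop_impulse(width = 2, spacing = 1), "smaller")
})

test_that("generated traces carry their specs for ground-truth bookkeeping", {
  s <- thrust_profile_spec(frequency = 0.25, n_periods = 2)
  expect_identical(attr(gen_thrust_profile(s), "spec"), s)
  b <- bird_flight_spec(n_wingbeats = 2)
  expect_identical(attr(gen_bird_flight(b)$trace, "spec"), b)
})
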