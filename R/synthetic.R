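# Seeded generators for every input the pipeline needs: vehicle thrust
# profiles, flapping-flight force traces with their stroke segmentations,
# and impulse excitations. Every generator attaches its spec to the output
# so parameter-recovery tests can compare against stated ground truth.

#' Thrust profile specification
#'
#' Study conditions for the validation experiments: constant and
#' semi-sinusoidal thrust profiles at modulation frequencies of 0.125, 0.25
#' and 0.5 Hz, 84 periods each, plus a smoothed hand-controlled style random
#' profile.
#'
#' "Semi-sinusoidal" means a mean-offset sinusoid clipped at zero thrust
#' (a rotor cannot pull); at the default amplitudes the clip never engages.
#'
#' @param kind `"constant"`, `"semi_sinusoid"`, or `"manual_random"`.
#' @param frequency Modulation frequency, Hz; also sets the duration of
#'   constant profiles (`n_periods / frequency`).
#' @param n_periods Number of modulation periods (default 84).
#' @param mean_thrust Mean thrust, N.
#' @param modulation_amplitude Modulation amplitude, N; must not exceed
#'   `mean_thrust` so thrust stays non-negative.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Integer seed (used by `manual_random`).
#' @return An object of class `thrust_profile_spec`.
#' @export
thrust_profile_spec <- function(kind = c("semi_sinusoid", "constant", "manual_random"),
                                frequency = 0.5, n_periods = 84,
                                mean_thrust = 1, modulation_amplitude = 0.3,
                                sample_rate = 1000, seed = 1L) {
  kind <- match.arg(kind)
  assert_scalar_pos(frequency, "frequency")
  assert_that(n_periods >= 1, "n_periods must be >= 1")
  assert_scalar_pos(mean_thrust, "mean_thrust")
  assert_scalar_pos(modulation_amplitude, "modulation_amplitude", strict = FALSE)
  assert_that(modulation_amplitude <= mean_thrust,
              "modulation_amplitude must not exceed mean_thrust")
  assert_scalar_pos(sample_rate, "sample_rate")
  structure(list(kind = kind, frequency = frequency, n_periods = n_periods,
                 mean_thrust = mean_thrust,
                 modulation_amplitude = modulation_amplitude,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "thrust_profile_spec")
}

#' Generate a thrust profile
#'
#' @param spec A [thrust_profile_spec].
#' @return A [force_trace] of duration `n_periods / frequency`, carrying the
#'   spec as an attribute.
#' @export
#' @examples
#' tr <- gen_thrust_profile(thrust_profile_spec(frequency = 0.5, n_periods = 4))
#' range(tr$force)
gen_thrust_profile <- function(spec) {
  assert_that(inherits(spec, "thrust_profile_spec"),
              "`spec` must be a thrust_profile_spec")
  duration <- spec$n_periods / spec$frequency
  tt <- seq(0, duration, by = 1 / spec$sample_rate)
  f <- switch(spec$kind,
    constant = rep(spec$mean_thrust, length(tt)),
    semi_sinusoid = pmax(0, spec$mean_thrust +
                           spec$modulation_amplitude *
                           sin(2 * pi * spec$frequency * tt)),
    manual_random = {
      x <- withr::with_seed(spec$seed, stats::rnorm(length(tt)))
      bf <- signal::butter(2, min(2, 0.4 * spec$sample_rate / 2) /
                             (spec$sample_rate / 2), type = "low")
      x <- signal::filtfilt(bf, x)
      x <- x / max(stats::sd(x), .Machine$double.eps) * spec$modulation_amplitude
      pmax(0, spec$mean_thrust + x)
    })
  force_trace(tt, f, spec = spec)
}

#' Flapping-flight force specification
#'
#' Study conditions of a short perch-to-perch flight of a small parrot
#' (28 g, 20 Hz wingbeat, perches 0.28 m apart): per wingbeat the vertical
#' force is a half-sine hump over the downstroke peaking at
#' `downstroke_peak_multiple` body weights (up to 2 at the default) and a
#' low plateau of `upstroke_support_multiple` body weights over the
#' upstroke. Brief raised-cosine pushes at take-off and landing model the
#' leg impulses on the perch. Cycle-to-cycle amplitudes jitter by +-5 per
#' cent (seeded).
#'
#' @param mass Body mass, kg (0.028 preset).
#' @param wingbeat_frequency Hz (20 preset).
#' @param downstroke_peak_multiple Downstroke peak force over body weight.
#' @param upstroke_support_multiple Upstroke force over body weight
#'   (approximately 0: the upstroke supports little weight).
#' @param downstroke_fraction Fraction of the cycle spent in downstroke.
#' @param n_wingbeats Number of wingbeats in the flight (8 preset: a
#'   0.28 m hop at 20 Hz lasts well under a second).
#' @param perch_distance Perch separation, m (metadata).
#' @param takeoff_push_fraction Peak of the take-off/landing leg-push
#'   impulse over body weight; 0 disables the pushes.
#' @param amplitude_jitter Relative cycle-to-cycle amplitude jitter.
#' @param waveform Downstroke hump shape: `"half_sine"` (default) or
#'   `"trapezoid"`.
#' @param sample_rate Sampling rate of the generated truth, Hz.
#' @param seed Integer seed.
#' @return An object of class `bird_flight_spec`.
#' @export
bird_flight_spec <- function(mass = 0.028, wingbeat_frequency = 20,
                             downstroke_peak_multiple = 2,
                             upstroke_support_multiple = 0.05,
                             downstroke_fraction = 0.55,
                             n_wingbeats = 8, perch_distance = 0.28,
                             takeoff_push_fraction = 0.5,
                             amplitude_jitter = 0.05,
                             waveform = c("half_sine", "trapezoid"),
                             sample_rate = 5000, seed = 1L) {
  waveform <- match.arg(waveform)
  assert_scalar_pos(mass, "mass")
  assert_scalar_pos(wingbeat_frequency, "wingbeat_frequency")
  assert_scalar_pos(downstroke_peak_multiple, "downstroke_peak_multiple", strict = FALSE)
  assert_scalar_pos(upstroke_support_multiple, "upstroke_support_multiple", strict = FALSE)
  assert_that(downstroke_fraction > 0 && downstroke_fraction < 1,
              "downstroke_fraction must lie in (0, 1)")
  assert_that(n_wingbeats >= 1, "n_wingbeats must be >= 1")
  assert_scalar_pos(perch_distance, "perch_distance")
  assert_scalar_pos(takeoff_push_fraction, "takeoff_push_fraction", strict = FALSE)
  assert_that(amplitude_jitter >= 0 && amplitude_jitter < 0.5,
              "amplitude_jitter must lie in [0, 0.5)")
  assert_scalar_pos(sample_rate, "sample_rate")
  structure(list(mass = mass, wingbeat_frequency = wingbeat_frequency,
                 downstroke_peak_multiple = downstroke_peak_multiple,
                 upstroke_support_multiple = upstroke_support_multiple,
                 downstroke_fraction = downstroke_fraction,
                 n_wingbeats = as.integer(n_wingbeats),
                 perch_distance = perch_distance,
                 takeoff_push_fraction = takeoff_push_fraction,
                 amplitude_jitter = amplitude_jitter, waveform = waveform,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "bird_flight_spec")
}

#' Generate a flapping-flight force trace with its stroke segmentation
#'
#' @param spec A [bird_flight_spec].
#' @return A list with elements `trace` ([force_trace], padded with 0.1 s of
#'   zero force before take-off and after landing), `segmentation`
#'   ([stroke_segmentation] with flight bounds at take-off/landing) and
#'   `body` ([body_properties]).
#' @export
#' @examples
#' fl <- gen_bird_flight(bird_flight_spec(n_wingbeats = 4, seed = 7))
#' max(fl$trace$force) / fl$body$weight
gen_bird_flight <- function(spec) {
  assert_that(inherits(spec, "bird_flight_spec"), "`spec` must be a bird_flight_spec")
  body <- body_properties(spec$mass)
  W <- body$weight
  Tw <- 1 / spec$wingbeat_frequency
  D <- spec$n_wingbeats * Tw
  pad <- 0.1
  tt <- seq(-pad, D + pad, by = 1 / spec$sample_rate)
  f <- numeric(length(tt))

  jit <- withr::with_seed(spec$seed, {
    stats::runif(2 * spec$n_wingbeats, -spec$amplitude_jitter, spec$amplitude_jitter)
  })

  starts <- (seq_len(spec$n_wingbeats) - 1L) * Tw
  dsl <- spec$downstroke_fraction * Tw
  seg_start <- seg_end <- numeric(0)
  seg_phase <- character(0)
  for (i in seq_len(spec$n_wingbeats)) {
    t0 <- starts[i]
    td <- c(t0, t0 + dsl)
    tu <- c(t0 + dsl, t0 + Tw)
    peak <- W * spec$downstroke_peak_multiple * (1 + jit[2 * i - 1L])
    idx <- tt >= td[1] & tt < td[2]
    hump <- switch(spec$waveform,
      half_sine = sin(pi * (tt[idx] - td[1]) / dsl),
      trapezoid = pmin(1, pmin(tt[idx] - td[1], td[2] - tt[idx]) / (0.2 * dsl)))
    f[idx] <- f[idx] + peak * hump
    up <- W * spec$upstroke_support_multiple * (1 + jit[2 * i])
    f[tt >= tu[1] & tt < tu[2]] <- up
    seg_start <- c(seg_start, td[1], tu[1])
    seg_end <- c(seg_end, td[2], tu[2])
    seg_phase <- c(seg_phase, "downstroke", "upstroke")
  }

  if (spec$takeoff_push_fraction > 0) {
    pw <- 0.3 * Tw
    push <- function(center) {
      idx <- abs(tt - center) <= pw / 2
      out <- numeric(length(tt))
      out[idx] <- spec$takeoff_push_fraction * W *
        0.5 * (1 + cos(2 * pi * (tt[idx] - center) / pw))
      out
    }
    f <- f + push(pw / 2) + push(D - pw / 2)
  }

  seg <- stroke_segmentation(seg_start, seg_end, seg_phase, flight_bounds = c(0, D))
  list(trace = force_trace(tt, f, spec = spec), segmentation = seg, body = body)
}

#' Generate an impulse (balloon-pop) excitation trace
#'
#' A train of raised-cosine impulses `A/2 * (1 - cos(2 pi t / width))` with
#' seeded timing jitter; one pulse integrates to `amplitude * width / 2`.
#'
#' @param amplitude Peak force of each pulse, N.
#' @param width Pulse width, s; must be smaller than `spacing`.
#' @param n_pops Number of pulses.
#' @param spacing Nominal pulse spacing, s.
#' @param seed Integer seed for the timing jitter.
#' @param sample_rate Sampling rate, Hz.
#' @return A [force_trace].
#' @export
gen_pop_impulse <- function(amplitude = 2, width = 2e-3, n_pops = 5,
                            spacing = 1, seed = 1L, sample_rate = 4000) {
  assert_scalar_pos(amplitude, "amplitude", strict = FALSE)
  assert_scalar_pos(width, "width")
  assert_that(n_pops >= 1, "n_pops must be >= 1")
  assert_scalar_pos(spacing, "spacing")
  assert_that(width < spacing, "width must be smaller than spacing")
  duration <- spacing * n_pops + spacing / 2
  tt <- seq(0, duration, by = 1 / sample_rate)
  centers <- spacing * (seq_len(n_pops) - 0.5) + spacing / 4 +
    withr::with_seed(seed, stats::runif(n_pops, -0.1, 0.1) * spacing)
  f <- numeric(length(tt))
  for (ct in centers) {
    idx <- abs(tt - ct) <= width / 2
    f[idx] <- f[idx] + amplitude * 0.5 * (1 - cos(2 * pi * (tt[idx] - (ct - width / 2)) / width))
  }
  force_trace(tt, f, spec = list(amplitude = amplitude, width = width,
                                 n_pops = n_pops, spacing = spacing,
                                 seed = seed, centers = centers))
}
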