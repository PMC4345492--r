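# End-to-end replay of the two experiments on synthetic data: the vehicle
# validation (platform vs reference beam) and the flight weight-support
# analysis.

#' Configuration for an end-to-end experiment run
#'
#' Collects the component specs with study-condition defaults. The
#' validation replays constant plus 0.125 / 0.25 / 0.5 Hz semi-sinusoidal
#' thrust profiles; `n_periods` defaults to 6 per profile (a desk-scale
#' analog of the 84-period laboratory runs) with 10 replicates.
#'
#' @param geometry A [box_geometry].
#' @param fluid A [fluid_properties].
#' @param platform_modal,platform_sensor Instrument model of the platform.
#' @param beam_modal,beam_sensor Instrument model of the reference beam.
#' @param validation_frequencies Semi-sinusoid frequencies, Hz; 0 encodes
#'   the constant profile.
#' @param n_periods Modulation periods per validation trace.
#' @param replicates Validation replicates per profile.
#' @param mean_thrust,modulation_amplitude Thrust profile parameters, N.
#' @param validation_cutoff,flight_cutoff Low-pass cut-offs, Hz.
#' @param bird A [bird_flight_spec].
#' @param seed Integer master seed.
#' @param out_dir Optional output directory; when given, runs write their
#'   reports, tables and a reproduction manifest there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(geometry = box_geometry(),
                       fluid = fluid_properties(),
                       platform_modal = afp_platform_modes(),
                       platform_sensor = afp_platform_sensor(),
                       beam_modal = beam_modes(),
                       beam_sensor = afplatform::beam_sensor(),
                       validation_frequencies = c(0, 0.125, 0.25, 0.5),
                       n_periods = 6, replicates = 10,
                       mean_thrust = 1, modulation_amplitude = 0.3,
                       validation_cutoff = 30, flight_cutoff = 60,
                       bird = bird_flight_spec(),
                       seed = 1L, out_dir = NULL) {
  structure(list(geometry = geometry, fluid = fluid,
                 platform_modal = platform_modal, platform_sensor = platform_sensor,
                 beam_modal = beam_modal, beam_sensor = beam_sensor,
                 validation_frequencies = validation_frequencies,
                 n_periods = n_periods, replicates = replicates,
                 mean_thrust = mean_thrust,
                 modulation_amplitude = modulation_amplitude,
                 validation_cutoff = validation_cutoff,
                 flight_cutoff = flight_cutoff,
                 bird = bird, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# simulate both instruments on one truth trace and return filtered forces
.measure_pair <- function(truth, config, seed) {
  afp <- apply_calibration(simulate_recording(truth, config$platform_modal,
                                              config$platform_sensor, seed = seed))
  beam <- apply_calibration(simulate_recording(truth, config$beam_modal,
                                               config$beam_sensor, seed = seed + 499L))
  fs <- filter_spec(config$validation_cutoff)
  list(afp = lowpass(afp, fs), beam = lowpass(beam, fs))
}

# drop the filter/modal start-up edges before computing metrics
.trim_trace <- function(trace, margin = 0.2) {
  keep <- trace$time >= min(trace$time) + margin & trace$time <= max(trace$time) - margin
  force_trace(trace$time[keep], trace$force[keep])
}

#' Run the validation experiment (platform versus reference beam)
#'
#' For each configured thrust profile, generates the true thrust, simulates
#' both the platform and the reference-beam recordings, calibrates, filters
#' both identically, and computes the validation metrics of the platform
#' against the beam; replicates differ only in their noise seeds. The report
#' has one row per profile with mean and standard deviation of the total
#' impulse ratio, average force ratio and delay.
#'
#' @param config A [run_config].
#' @return An object of class `validation_report`: a data frame with columns
#'   `profile`, `n`, `impulse_ratio`, `impulse_ratio_sd`, `force_ratio`,
#'   `force_ratio_sd`, `delay_ms`, `delay_ms_sd`.
#' @export
run_validation_experiment <- function(config = run_config()) {
  assert_that(inherits(config, "run_config"), "`config` must be a run_config")
  rows <- list()
  for (pi_ in seq_along(config$validation_frequencies)) {
    fmod <- config$validation_frequencies[pi_]
    kind <- if (fmod == 0) "constant" else "semi_sinusoid"
    freq <- if (fmod == 0) 0.5 else fmod
    met <- lapply(seq_len(config$replicates), function(r) {
      seed_r <- config$seed + 1000L * pi_ + r
      truth <- gen_thrust_profile(thrust_profile_spec(
        kind = kind, frequency = freq, n_periods = config$n_periods,
        mean_thrust = config$mean_thrust,
        modulation_amplitude = config$modulation_amplitude,
        sample_rate = 1 / config$platform_sensor$sampling_interval,
        seed = seed_r))
      pair <- .measure_pair(truth, config, seed_r)
      validation_metrics(.trim_trace(pair$afp), .trim_trace(pair$beam),
                         max_delay = 0.05)
    })
    imp <- vapply(met, `[[`, numeric(1), "total_impulse_ratio")
    frc <- vapply(met, `[[`, numeric(1), "average_force_ratio")
    dly <- vapply(met, `[[`, numeric(1), "delay") * 1000
    rows[[pi_]] <- data.frame(
      profile = if (fmod == 0) "constant" else sprintf("%.3f Hz", fmod),
      n = length(met),
      impulse_ratio = mean(imp), impulse_ratio_sd = stats::sd(imp),
      force_ratio = mean(frc), force_ratio_sd = stats::sd(frc),
      delay_ms = mean(dly), delay_ms_sd = stats::sd(dly))
  }
  report <- do.call(rbind, rows)
  class(report) <- c("validation_report", "data.frame")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report, file.path(config$out_dir, "validation_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_manifest(config, file.path(config$out_dir, "validation_manifest.json"))
  }
  report
}

#' Run the flight experiment (wingbeat-resolved weight support)
#'
#' Generates a flapping flight from the configured spec, simulates the
#' platform recording, calibrates, filters at the flight cut-off, and
#' computes per-stroke and wingbeat-averaged weight support against the
#' generated (ground-truth) stroke segmentation.
#'
#' @param config A [run_config].
#' @return List with `summary` ([weight_support()] result), `measured`
#'   (the filtered measured force trace), `truth` (the generator output).
#' @export
run_flight_experiment <- function(config = run_config()) {
  assert_that(inherits(config, "run_config"), "`config` must be a run_config")
  fl <- gen_bird_flight(config$bird)
  rec <- apply_calibration(simulate_recording(fl$trace, config$platform_modal,
                                              config$platform_sensor,
                                              seed = config$seed))
  measured <- lowpass(rec, filter_spec(config$flight_cutoff))
  summary <- weight_support(measured, fl$body, fl$segmentation)
  out <- list(summary = summary, measured = measured, truth = fl)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(summary$strokes,
                       file.path(config$out_dir, "stroke_support.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_force_trace(measured, file.path(config$out_dir, "measured_force.tsv"))
    write_manifest(config, file.path(config$out_dir, "flight_manifest.json"))
  }
  out
}
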