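# Measurement analysis: filtering, validation metrics, resonance
# identification, net acceleration, wingbeat-resolved weight support.

#' Low-pass filter specification
#'
#' Fourth-order Butterworth low-pass by default, applied forward-backward
#' (zero phase) so identically filtered signal pairs acquire no differential
#' delay. Cut-offs of 30 Hz (vehicle validation) and 60 Hz (flapping flight,
#' three times the wingbeat frequency) are the two working values.
#'
#' @param cutoff Cut-off frequency, Hz; must be below the Nyquist frequency
#'   of the signal it is applied to.
#' @param order Filter order (default 4).
#' @param zero_phase Apply forward-backward (`TRUE`, default) or single-pass.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff, order = 4, zero_phase = TRUE) {
  assert_scalar_pos(cutoff, "cutoff")
  assert_that(is.numeric(order) && order >= 1, "order must be >= 1")
  structure(list(cutoff = cutoff, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Butterworth low-pass filtering of a force trace
#'
#' @param trace A [force_trace] (or a `recording`, whose channel sum minus
#'   preload is filtered via [recording_force()]).
#' @param spec A [filter_spec].
#' @return A filtered [force_trace] on the same time base.
#' @export
lowpass <- function(trace, spec) {
  assert_that(inherits(spec, "filter_spec"), "`spec` must be a filter_spec")
  if (inherits(trace, "recording")) trace <- recording_force(trace)
  assert_that(inherits(trace, "force_trace"), "`trace` must be a force_trace")
  dt <- uniform_dt(trace$time)
  nyq <- 0.5 / dt
  assert_that(spec$cutoff < nyq,
              sprintf("cutoff (%.3g Hz) must be below Nyquist (%.3g Hz)",
                      spec$cutoff, nyq))
  bf <- signal::butter(spec$order, spec$cutoff / nyq, type = "low")
  # remove the mean (restored after: DC gain is exactly 1) and pad with an
  # odd reflection so the zero-state start-up transient stays out of the data
  x <- trace$force - mean(trace$force)
  n <- length(x)
  p <- min(n - 1L, ceiling(6 / (spec$cutoff * dt)))
  xp <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  yp <- if (spec$zero_phase) signal::filtfilt(bf, xp)
  else as.numeric(signal::filter(bf, xp))
  y <- yp[(p + 1L):(p + n)] + mean(trace$force)
  force_trace(trace$time, y, spec = attr(trace, "spec"))
}

#' Validation metrics between a platform and a reference measurement
#'
#' Compares two time-aligned, identically filtered force traces the way the
#' platform is validated against an independent reference: the total impulse
#' ratio (trapezoidal integrals), the average force ratio (means), and the
#' time delay of the first trace relative to the reference (cross-correlation
#' peak with parabolic sub-sample interpolation; positive when the platform
#' lags). The delay is `NA` for signals without usable fluctuation (e.g. a
#' constant thrust profile).
#'
#' @param afp [force_trace] measured by the platform.
#' @param reference [force_trace] from the independent reference, same time
#'   base.
#' @param max_delay Largest delay magnitude searched, s.
#' @return An object of class `validation_metrics` with fields
#'   `total_impulse_ratio`, `average_force_ratio`, `delay` (s).
#' @export
validation_metrics <- function(afp, reference, max_delay = 0.1) {
  assert_that(inherits(afp, "force_trace") && inherits(reference, "force_trace"),
              "inputs must be force_trace objects")
  assert_that(nrow(afp) == nrow(reference), "traces must have equal length")
  dt <- uniform_dt(afp$time)
  assert_that(abs(dt - uniform_dt(reference$time)) < 1e-12,
              "traces must share one sampling interval")
  imp_ref <- pracma::trapz(reference$time, reference$force)
  assert_that(abs(imp_ref) > .Machine$double.eps * nrow(reference),
              "reference impulse is zero; ratios undefined")
  structure(list(
    total_impulse_ratio = pracma::trapz(afp$time, afp$force) / imp_ref,
    average_force_ratio = mean(afp$force) / mean(reference$force),
    delay = xcorr_delay(afp$force, reference$force, dt, max_delay)
  ), class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf(paste0("<validation_metrics> impulse ratio %.4f, force ratio %.4f, ",
                     "delay %s\n"),
              x$total_impulse_ratio, x$average_force_ratio,
              if (is.na(x$delay)) "n/a" else sprintf("%.3f ms", 1000 * x$delay)))
  invisible(x)
}

# Hann-windowed averaged (Welch) periodogram; returns frequency grid and
# mean power. Hand-rolled because no installed package exposes one.
welch_psd <- function(x, fs, nseg = 2048, overlap = 0.5) {
  n <- length(x)
  nseg <- min(nseg, 2^floor(log2(n)))
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  pw <- rowMeans(vapply(starts, function(s) {
    seg <- (x[s:(s + nseg - 1L)] - mean(x[s:(s + nseg - 1L)])) * w
    Mod(stats::fft(seg)[seq_len(nseg %/% 2 + 1L)])^2
  }, numeric(nseg %/% 2 + 1L)))
  list(freq = fs * (0:(nseg %/% 2)) / nseg, power = pw)
}

#' Dominant structural natural frequency from an impulse recording
#'
#' Estimates the primary resonance from the ringdown of impulse (pop)
#' excitations: averaged Hann-windowed periodogram of the channel sum, peak
#' within the search band, with parabolic interpolation on log power.
#'
#' @param rec A `recording` (typically from [pop_test()]) or a [force_trace].
#' @param band Search band `c(lo, hi)` in Hz, within Nyquist.
#' @param nseg Segment length for the averaged periodogram.
#' @return Peak frequency in Hz.
#' @export
natural_frequency <- function(rec, band = c(20, 480), nseg = 2048) {
  if (inherits(rec, "recording")) {
    x <- rowSums(rec$channels)
    fs <- 1 / rec$sensor$sampling_interval
  } else {
    assert_that(inherits(rec, "force_trace"), "`rec` must be a recording or force_trace")
    x <- rec$force
    fs <- 1 / uniform_dt(rec$time)
  }
  assert_that(length(band) == 2L && band[1] > 0 && band[2] > band[1],
              "band must be increasing and positive")
  assert_that(band[2] < fs / 2, "band must lie below Nyquist")
  ps <- welch_psd(x - mean(x), fs, nseg = nseg)
  sel <- which(ps$freq >= band[1] & ps$freq <= band[2])
  assert_that(length(sel) >= 3L, "band too narrow for the spectral resolution")
  pk <- sel[which.max(ps$power[sel])]
  assert_that(ps$power[pk] > 5 * stats::median(ps$power[sel]),
              "no spectral peak above the noise floor in the band")
  fhat <- ps$freq[pk]
  if (pk > 1 && pk < length(ps$freq)) {
    lp <- log(ps$power[(pk - 1):(pk + 1)] + .Machine$double.xmin)
    den <- lp[1] - 2 * lp[2] + lp[3]
    if (abs(den) > .Machine$double.eps)
      fhat <- fhat + 0.5 * (lp[1] - lp[3]) / den * (ps$freq[2] - ps$freq[1])
  }
  fhat
}

#' Net acceleration of the body from the measured force
#'
#' `a(t) = (F(t) - W) / m`: the net measured vertical fluid force minus body
#' weight, over the associated mass. Equal weight support gives zero; zero
#' force gives free fall, -g.
#'
#' @param F_net Vertical net force [force_trace], N.
#' @param body A [body_properties].
#' @return Data frame with `time` (s) and `accel` (m/s^2).
#' @export
net_acceleration <- function(F_net, body) {
  assert_that(inherits(F_net, "force_trace"), "`F_net` must be a force_trace")
  assert_that(inherits(body, "body_properties"), "`body` must be body_properties")
  data.frame(time = F_net$time, accel = (F_net$force - body$weight) / body$mass)
}

#' Wingbeat-resolved weight support
#'
#' Per-stroke duration-weighted mean of the vertical force normalized by
#' body weight, wingbeat averages (each downstroke paired with the upstroke
#' that follows it; a trailing unpaired stroke is reported alone or dropped
#' per `terminal`), and the peak support over the airborne phase.
#'
#' @param filtered Filtered vertical force [force_trace].
#' @param body A [body_properties].
#' @param seg A [stroke_segmentation] within the trace span.
#' @param terminal How to report a trailing stroke without a partner:
#'   `"alone"` (default; its own wingbeat entry, flagged incomplete) or
#'   `"drop"`.
#' @return An object of class `weight_support_summary`: `strokes` data frame
#'   (start, end, phase, duration, mean_support), `wingbeats` data frame
#'   (start, end, mean_support, complete), `peak_support`.
#' @export
weight_support <- function(filtered, body, seg, terminal = c("alone", "drop")) {
  terminal <- match.arg(terminal)
  assert_that(inherits(filtered, "force_trace"), "`filtered` must be a force_trace")
  assert_that(inherits(body, "body_properties"), "`body` must be body_properties")
  assert_that(inherits(seg, "stroke_segmentation"), "`seg` must be a stroke_segmentation")
  W <- body$weight
  if (nrow(seg) == 0L) {
    return(structure(list(strokes = data.frame(start = numeric(0), end = numeric(0),
                                               phase = character(0),
                                               duration = numeric(0),
                                               mean_support = numeric(0)),
                          wingbeats = data.frame(start = numeric(0), end = numeric(0),
                                                 mean_support = numeric(0),
                                                 complete = logical(0)),
                          peak_support = NA_real_, body = body),
                     class = "weight_support_summary"))
  }
  tt <- filtered$time
  ff <- filtered$force
  stroke_mean <- function(s, e) {
    idx <- which(tt >= s - 1e-12 & tt <= e + 1e-12)
    assert_that(length(idx) >= 2L, "stroke interval contains fewer than 2 samples")
    pracma::trapz(tt[idx], ff[idx]) / (tt[idx[length(idx)]] - tt[idx[1]])
  }
  strokes <- data.frame(start = seg$start, end = seg$end, phase = seg$phase)
  strokes$duration <- strokes$end - strokes$start
  strokes$mean_support <- vapply(seq_len(nrow(strokes)), function(i)
    stroke_mean(strokes$start[i], strokes$end[i]) / W, numeric(1))

  wb <- list()
  i <- 1L
  while (i <= nrow(strokes)) {
    if (strokes$phase[i] == "downstroke" && i + 1L <= nrow(strokes) &&
        strokes$phase[i + 1L] == "upstroke") {
      d <- strokes[i, ]; u <- strokes[i + 1L, ]
      wb[[length(wb) + 1L]] <- data.frame(
        start = d$start, end = u$end,
        mean_support = (d$mean_support * d$duration + u$mean_support * u$duration) /
          (d$duration + u$duration),
        complete = TRUE)
      i <- i + 2L
    } else {
      if (terminal == "alone")
        wb[[length(wb) + 1L]] <- data.frame(start = strokes$start[i],
                                            end = strokes$end[i],
                                            mean_support = strokes$mean_support[i],
                                            complete = FALSE)
      i <- i + 1L
    }
  }
  wingbeats <- if (length(wb)) do.call(rbind, wb)
  else data.frame(start = numeric(0), end = numeric(0),
                  mean_support = numeric(0), complete = logical(0))
  fb <- attr(seg, "flight_bounds")
  inflight <- tt >= fb[1] & tt <= fb[2]
  structure(list(strokes = strokes, wingbeats = wingbeats,
                 peak_support = max(ff[inflight]) / W, body = body),
            class = "weight_support_summary")
}

#' @export
print.weight_support_summary <- function(x, ...) {
  cat(sprintf("<weight_support_summary> %d strokes, %d wingbeats, peak support %.3f\n",
              nrow(x$strokes), nrow(x$wingbeats), x$peak_support))
  if (nrow(x$strokes)) {
    ds <- x$strokes$mean_support[x$strokes$phase == "downstroke"]
    us <- x$strokes$mean_support[x$strokes$phase == "upstroke"]
    cat(sprintf("  mean downstroke support %.3f | mean upstroke support %.3f\n",
                mean(ds), mean(us)))
  }
  invisible(x)
}
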