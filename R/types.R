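#' Fluid properties
#'
#' Bundle of the fluid constants the control-volume analysis needs: density
#' (pressure integral), kinematic viscosity (Reynolds screening and Blasius
#' shear) and speed of sound (acoustic compactness).
#'
#' The default viscosity is the standard-air value `1.48e-5` m^2/s; air at
#' 25 degrees C is closer to `1.56e-5` m^2/s and can be requested with
#' [standard_air()]. Both are exposed because screening numbers quoted for
#' laboratory air are commonly computed with either.
#'
#' @param density Fluid density, kg/m^3.
#' @param kinematic_viscosity Kinematic viscosity, m^2/s.
#' @param sound_speed Speed of sound, m/s.
#' @return An object of class `fluid_properties`.
#' @export
#' @examples
#' air <- fluid_properties()
#' air$sound_speed
fluid_properties <- function(density = 1.204,
                             kinematic_viscosity = 1.48e-5,
                             sound_speed = 340) {
  assert_scalar_pos(density, "density")
  assert_scalar_pos(kinematic_viscosity, "kinematic_viscosity")
  assert_scalar_pos(sound_speed, "sound_speed")
  structure(list(density = density,
                 kinematic_viscosity = kinematic_viscosity,
                 sound_speed = sound_speed),
            class = "fluid_properties")
}

#' @describeIn fluid_properties Air at a given temperature (dry, sea level);
#'   linear interpolation of tabulated density and viscosity between 0 and
#'   40 degrees C.
#' @param temperature_c Air temperature in degrees Celsius.
#' @export
standard_air <- function(temperature_c = 25) {
  assert_that(is.numeric(temperature_c) && length(temperature_c) == 1L &&
                temperature_c >= -20 && temperature_c <= 60,
              "`temperature_c` must be a scalar in [-20, 60]")
  tt <- c(0, 20, 25, 40)
  rho <- c(1.293, 1.204, 1.184, 1.127)
  nu <- c(1.33e-5, 1.51e-5, 1.56e-5, 1.70e-5)
  c0 <- c(331.3, 343.2, 346.1, 354.9)
  fluid_properties(density = stats::approx(tt, rho, temperature_c, rule = 2)$y,
                   kinematic_viscosity = stats::approx(tt, nu, temperature_c, rule = 2)$y,
                   sound_speed = stats::approx(tt, c0, temperature_c, rule = 2)$y)
}

# wall bookkeeping: id -> fixed axis, in-plane axes, outward normal
.wall_table <- function(geom) {
  L <- c(geom$Lx, geom$Ly, geom$Lz)
  list(
    left   = list(axis = 1L, at = 0,    u = 2L, v = 3L, normal = c(-1, 0, 0)),
    right  = list(axis = 1L, at = L[1], u = 2L, v = 3L, normal = c(1, 0, 0)),
    front  = list(axis = 2L, at = 0,    u = 1L, v = 3L, normal = c(0, -1, 0)),
    back   = list(axis = 2L, at = L[2], u = 1L, v = 3L, normal = c(0, 1, 0)),
    bottom = list(axis = 3L, at = 0,    u = 1L, v = 2L, normal = c(0, 0, -1)),
    top    = list(axis = 3L, at = L[3], u = 1L, v = 2L, normal = c(0, 0, 1))
  )
}

wall_ids <- function() c("left", "right", "front", "back", "bottom", "top")

#' Control-volume box geometry
#'
#' Inner dimensions of the instrumented box. The coordinate frame is
#' right-handed with z vertical (positive up) and the box corner at the
#' origin: x spans the width `Lx`, y the depth `Ly`, z the height `Lz`.
#' Walls are named `left`/`right` (x = 0 / Lx), `front`/`back`
#' (y = 0 / Ly) and `bottom`/`top` (z = 0 / Lz), each with the outward
#' normal convention.
#'
#' Defaults are the inner dimensions of the first-generation platform:
#' 0.525 m wide, 0.452 m deep, 0.420 m high.
#'
#' An optional circular aperture (an uninstrumented hole, e.g. an access
#' gap in an acrylic side panel) is described by the wall it sits on, its
#' centre in that wall's (u, v) in-plane coordinates, and its diameter.
#'
#' @param Lx,Ly,Lz Inner width, depth and height in metres.
#' @param aperture `NULL`, or `list(wall =, center = c(u, v), diameter =)`.
#' @return An object of class `box_geometry`.
#' @export
#' @examples
#' geom <- box_geometry()
#' geom_holed <- box_geometry(aperture = list(wall = "front",
#'                                            center = c(0.26, 0.21),
#'                                            diameter = 0.25))
box_geometry <- function(Lx = 0.525, Ly = 0.452, Lz = 0.420, aperture = NULL) {
  assert_scalar_pos(Lx, "Lx"); assert_scalar_pos(Ly, "Ly"); assert_scalar_pos(Lz, "Lz")
  geom <- structure(list(Lx = Lx, Ly = Ly, Lz = Lz, aperture = NULL),
                    class = "box_geometry")
  if (!is.null(aperture)) {
    assert_that(is.list(aperture) &&
                  all(c("wall", "center", "diameter") %in% names(aperture)),
                "`aperture` needs fields wall, center, diameter")
    assert_that(aperture$wall %in% wall_ids(), "unknown aperture wall id")
    assert_scalar_pos(aperture$diameter, "aperture$diameter")
    w <- .wall_table(geom)[[aperture$wall]]
    L <- c(Lx, Ly, Lz)
    lu <- L[w$u]; lv <- L[w$v]
    ctr <- aperture$center
    assert_that(is.numeric(ctr) && length(ctr) == 2L, "aperture center must be length-2")
    r <- aperture$diameter / 2
    assert_that(ctr[1] - r >= 0 && ctr[1] + r <= lu &&
                  ctr[2] - r >= 0 && ctr[2] + r <= lv,
                "aperture disc must lie entirely within its wall")
    geom$aperture <- aperture
  }
  geom
}

#' @export
print.box_geometry <- function(x, ...) {
  cat(sprintf("<box_geometry> %.3f x %.3f x %.3f m (W x D x H)\n", x$Lx, x$Ly, x$Lz))
  if (!is.null(x$aperture))
    cat(sprintf("  aperture: %s wall, d = %.3f m at (%.3f, %.3f)\n",
                x$aperture$wall, x$aperture$diameter,
                x$aperture$center[1], x$aperture$center[2]))
  invisible(x)
}

#' Interior point forcing
#'
#' A concentrated force generated by an object inside the box (thrust of a
#' rotorcraft, weight support of a bird). `amplitude` is the force the
#' *object* produces; the fluid receives the reaction, and the wall-pressure
#' solver accounts for the sign so that wall integration recovers
#' `amplitude`.
#'
#' @param position 3-vector, metres; must be strictly inside the box when used.
#' @param amplitude Force 3-vector, newtons.
#' @param waveform One of `"constant"`, `"sinusoid"`, `"trace"`.
#' @param frequency Forcing frequency in Hz (sinusoid only).
#' @param trace Optional [force_trace] giving a sampled scalar modulation
#'   (multiplies `amplitude`) for `waveform = "trace"`.
#' @return An object of class `point_forcing`.
#' @export
point_forcing <- function(position, amplitude,
                          waveform = c("constant", "sinusoid", "trace"),
                          frequency = 0, trace = NULL) {
  waveform <- match.arg(waveform)
  assert_that(is.numeric(position) && length(position) == 3L, "position must be a 3-vector")
  assert_that(is.numeric(amplitude) && length(amplitude) == 3L, "amplitude must be a 3-vector")
  assert_that(is.numeric(frequency) && length(frequency) == 1L && frequency >= 0,
              "frequency must be a non-negative scalar")
  if (waveform == "sinusoid") assert_that(frequency > 0, "sinusoid needs frequency > 0")
  if (waveform == "trace")
    assert_that(inherits(trace, "force_trace"), "waveform 'trace' needs a force_trace")
  structure(list(position = position, amplitude = amplitude,
                 waveform = waveform, frequency = frequency, trace = trace),
            class = "point_forcing")
}

# instantaneous scalar modulation of the forcing at time t
forcing_value <- function(forcing, t) {
  switch(forcing$waveform,
         constant = 1,
         sinusoid = sin(2 * pi * forcing$frequency * t),
         trace = stats::approx(forcing$trace$time, forcing$trace$force, t, rule = 2)$y)
}

#' Force-vs-time trace
#'
#' A uniformly sampled scalar (vertical) force signal — the ground truth
#' F(t) that the platform is meant to recover, or any derived signal in the
#' pipeline. Stored as a two-column data frame (`time`, `force`) so it
#' writes/reads as plain delimited text.
#'
#' @param time Time stamps in seconds (uniform grid).
#' @param force Force samples in newtons.
#' @param spec Optional generating spec, kept as an attribute for
#'   ground-truth bookkeeping in parameter-recovery tests.
#' @return An object of class `force_trace` (also a data.frame).
#' @export
force_trace <- function(time, force, spec = NULL) {
  assert_that(is.numeric(time) && is.numeric(force) && length(time) == length(force),
              "time and force must be numeric vectors of equal length")
  assert_that(length(time) >= 2L, "a force trace needs at least two samples")
  uniform_dt(time)
  out <- data.frame(time = as.numeric(time), force = as.numeric(force))
  class(out) <- c("force_trace", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' @export
print.force_trace <- function(x, ...) {
  dt <- uniform_dt(x$time)
  cat(sprintf("<force_trace> %d samples @ %.6g s, span %.4g s, force in [%.4g, %.4g] N\n",
              nrow(x), dt, diff(range(x$time)), min(x$force), max(x$force)))
  invisible(x)
}

#' Body properties of the flying animal or object
#'
#' @param mass Body mass in kg.
#' @param g Gravitational acceleration, m/s^2.
#' @return An object of class `body_properties` with fields `mass`, `g` and
#'   `weight` (= mass * g, newtons).
#' @export
#' @examples
#' parrotlet <- body_properties(0.028)
#' parrotlet$weight
body_properties <- function(mass, g = 9.81) {
  assert_scalar_pos(mass, "mass")
  assert_scalar_pos(g, "g")
  structure(list(mass = mass, g = g, weight = mass * g), class = "body_properties")
}

#' Stroke segmentation of a flapping flight
#'
#' Ordered, non-overlapping downstroke/upstroke intervals delimited by the
#' wing's highest and lowest positions (stroke reversal), plus the take-off
#' and landing time marks bounding the airborne phase. Stroke markers are
#' inputs (from synchronized kinematics), not derived from force.
#'
#' @param start,end Stroke start/end times, seconds.
#' @param phase Character vector, `"downstroke"` or `"upstroke"`, alternating.
#' @param flight_bounds Length-2 numeric `(take-off, landing)` in seconds.
#' @return An object of class `stroke_segmentation` (also a data.frame).
#' @export
stroke_segmentation <- function(start, end, phase, flight_bounds = NULL) {
  assert_that(length(start) == length(end) && length(end) == length(phase),
              "start, end, phase must have equal length")
  if (length(start)) {
    assert_that(all(end > start), "every stroke must have end > start")
    assert_that(all(phase %in% c("downstroke", "upstroke")), "unknown phase label")
    if (length(start) > 1L) {
      assert_that(all(diff(start) > 0) && all(start[-1] >= end[-length(end)] - 1e-12),
                  "strokes must be time-ordered and non-overlapping")
      assert_that(all(phase[-1] != phase[-length(phase)]), "phases must alternate")
    }
  }
  if (is.null(flight_bounds))
    flight_bounds <- if (length(start)) c(min(start), max(end)) else c(NA_real_, NA_real_)
  out <- data.frame(start = as.numeric(start), end = as.numeric(end),
                    phase = as.character(phase))
  class(out) <- c("stroke_segmentation", "data.frame")
  attr(out, "flight_bounds") <- as.numeric(flight_bounds)
  out
}

#' @export
print.stroke_segmentation <- function(x, ...) {
  fb <- attr(x, "flight_bounds")
  cat(sprintf("<stroke_segmentation> %d strokes, flight [%.4g, %.4g] s\n",
              nrow(x), fb[1], fb[2]))
  invisible(x)
}
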