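#' Acoustic compactness ("AFP") number
#'
#' `f * L / c`: the enclosure length scale over the acoustic wavelength of
#' the fastest force fluctuation to resolve. When this number is much
#' smaller than one, pressure fluctuations reach the walls quasi-
#' instantaneously and the wall integral tracks the interior force with a
#' negligible phase delay; the delay expressed as a fraction of the forcing
#' period equals this number exactly (see [acoustic_delay()]).
#'
#' @param L Enclosure length scale, m.
#' @param f Highest force-fluctuation frequency of interest, Hz (may be 0).
#' @param c Speed of sound, m/s.
#' @return Dimensionless scalar.
#' @export
#' @examples
#' afp_number(0.41, 18, 340) # about 0.022
afp_number <- function(L, f, c) {
  assert_scalar_pos(L, "L")
  assert_scalar_pos(f, "f", strict = FALSE)
  assert_scalar_pos(c, "c")
  f * L / c
}

#' Acoustic transit delay across the enclosure
#'
#' Time for sound to cross the enclosure length scale, `L / c`. Multiplied
#' by the forcing frequency this is identically the compactness number of
#' [afp_number()].
#'
#' @inheritParams afp_number
#' @return Delay in seconds.
#' @export
#' @examples
#' acoustic_delay(0.41, 340) # about 1 ms
acoustic_delay <- function(L, c) {
  assert_scalar_pos(L, "L", strict = FALSE)
  assert_scalar_pos(c, "c")
  L / c
}

#' Reynolds number of the enclosure flow
#'
#' `U * L / nu`. Used to screen whether wall shear can be neglected against
#' wall pressure: for Reynolds numbers much larger than unity the viscous
#' contribution to the wall integral is subordinate.
#'
#' @param U Characteristic near-wall flow speed, m/s.
#' @param L Characteristic length (e.g. enclosure height), m.
#' @param fluid A [fluid_properties] object.
#' @return Dimensionless scalar.
#' @export
#' @examples
#' reynolds_number(0.95, 0.42, fluid_properties()) # about 27 000
reynolds_number <- function(U, L, fluid) {
  assert_scalar_pos(U, "U", strict = FALSE)
  assert_scalar_pos(L, "L")
  assert_that(inherits(fluid, "fluid_properties"), "`fluid` must be fluid_properties")
  U * L / fluid$kinematic_viscosity
}

#' Laminar flat-plate (Blasius) friction drag
#'
#' One-sided skin-friction drag of a flat plate in a uniform stream from the
#' Blasius boundary-layer solution: `D = C_f * 0.5 * rho * U^2 * A` with
#' `C_f = 1.328 / sqrt(Re_L)` and `Re_L` based on the streamwise plate
#' length. Used to bound the shear force an uninstrumented smooth panel
#' would carry, relative to the pressure force the platform measures.
#'
#' @param U Free-stream (near-wall) speed, m/s; `U = 0` returns 0.
#' @param plate_length Streamwise plate length, m.
#' @param plate_width Spanwise plate width, m.
#' @param fluid A [fluid_properties] object.
#' @return Drag force in newtons.
#' @export
#' @examples
#' blasius_shear_force(0.95, 0.420, 0.525, standard_air(25)) # about 1 mN
blasius_shear_force <- function(U, plate_length, plate_width, fluid) {
  assert_scalar_pos(U, "U", strict = FALSE)
  assert_scalar_pos(plate_length, "plate_length")
  assert_scalar_pos(plate_width, "plate_width")
  assert_that(inherits(fluid, "fluid_properties"), "`fluid` must be fluid_properties")
  if (U == 0) return(0)
  re <- U * plate_length / fluid$kinematic_viscosity
  cf <- 1.328 / sqrt(re)
  cf * 0.5 * fluid$density * U^2 * plate_length * plate_width
}

#' Pressure sensitivity of the platform
#'
#' Smallest resolvable wall-pressure change for vertical force sensing: the
#' load-cell force resolution divided by the horizontal projected wall area
#' (`Lx * Ly`). In this sense the platform is an infrasound microphone.
#'
#' @param resolution Load-cell force resolution, N.
#' @param geom A [box_geometry].
#' @return Pressure in pascals.
#' @export
#' @examples
#' pressure_sensitivity(2e-3, box_geometry()) # about 0.008 Pa
pressure_sensitivity <- function(resolution, geom) {
  assert_scalar_pos(resolution, "resolution")
  assert_that(inherits(geom, "box_geometry"), "`geom` must be box_geometry")
  resolution / (geom$Lx * geom$Ly)
}

#' Aperture-to-wall area ratio
#'
#' Fraction of a wall's area removed by its circular aperture. Because the
#' aperture sits in a vertical wall whose outward normal has no vertical
#' component, any such hole leaves the recovered vertical force unchanged in
#' the inviscid idealization, whatever this ratio is.
#'
#' @param geom A [box_geometry] with an aperture.
#' @return Dimensionless area ratio in (0, 1).
#' @export
#' @examples
#' g <- box_geometry(aperture = list(wall = "front", center = c(0.26, 0.21),
#'                                   diameter = 0.25))
#' aperture_area_ratio(g) # about 0.223
aperture_area_ratio <- function(geom) {
  assert_that(inherits(geom, "box_geometry"), "`geom` must be box_geometry")
  assert_that(!is.null(geom$aperture), "geometry has no aperture")
  w <- .wall_table(geom)[[geom$aperture$wall]]
  L <- c(geom$Lx, geom$Ly, geom$Lz)
  pi * (geom$aperture$diameter / 2)^2 / (L[w$u] * L[w$v])
}
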