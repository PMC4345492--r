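# Independent oracles used to cross-check the implementation. These stay
# deliberately separate from the package's own numerics: the image series
# solves the same boundary-value problem by reflection instead of
# eigenfunction expansion, and the boundary-layer oracle integrates the
# similarity ODE instead of using the closed-form friction law.

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# radial factor of the pressure field of a Gaussian-regularized point dipole
# in free space: p(x) = m . (x - x0) * gsig(r), with m the body force
# applied to the fluid
gauss_dipole_radial <- function(r, sigma) {
  enc <- erf_(r / (sqrt(2) * sigma)) -
    sqrt(2 / pi) * (r / sigma) * exp(-r^2 / (2 * sigma^2))
  enc / (4 * pi * r^3)
}

# method-of-images pressure of a regularized dipole in a rigid box: sum over
# the reflection lattice, flipping each moment component once per reflection
# in that axis. `pts` is an n x 3 matrix of evaluation points.
image_series_pressure <- function(pts, pos, moment, L, sigma, n_shells = 5) {
  stopifnot(is.matrix(pts), ncol(pts) == 3)
  p <- numeric(nrow(pts))
  shifts <- -n_shells:n_shells
  for (i in shifts) for (j in shifts) for (k in shifts) {
    for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
      xi <- c(2 * i * L[1] + sx * pos[1],
              2 * j * L[2] + sy * pos[2],
              2 * k * L[3] + sz * pos[3])
      m <- moment * c(sx, sy, sz)
      dx <- sweep(pts, 2, xi)
      r <- sqrt(rowSums(dx^2))
      p <- p + (dx %*% m) * gauss_dipole_radial(r, sigma)
    }
  }
  as.numeric(p)
}

# Blasius similarity solution f''' + 0.5 f f'' = 0 by shooting (deSolve),
# returning f''(0); the one-sided plate drag follows as
#   D = 2 f''(0) rho U^2 sqrt(nu L / U) W
blasius_shoot_fpp0 <- function() {
  rhs <- function(eta, y, parms) list(c(y[2], y[3], -0.5 * y[1] * y[3]))
  fprime_end <- function(a) {
    sol <- deSolve::ode(y = c(f = 0, fp = 0, fpp = a),
                        times = c(0, 12), func = rhs, parms = NULL)
    sol[nrow(sol), "fp"] - 1
  }
  stats::uniroot(fprime_end, c(0.2, 0.5), tol = 1e-10)$root
}

# squared magnitude response of an order-n Butterworth low-pass (the
# zero-phase filter applies it twice)
butter_mag2 <- function(f, cutoff, order) 1 / (1 + (f / cutoff)^(2 * order))
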