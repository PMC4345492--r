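# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

assert_scalar_pos <- function(x, name, strict = TRUE) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x),
              sprintf("`%s` must be a finite numeric scalar", name))
  if (strict) assert_that(x > 0, sprintf("`%s` must be strictly positive", name))
  else assert_that(x >= 0, sprintf("`%s` must be non-negative", name))
  invisible(TRUE)
}

# composite Simpson weights for n_points nodes (n_points odd => even interval count)
simpson_weights <- function(n_points, h) {
  assert_that(n_points >= 3 && n_points %% 2L == 1L,
              "Simpson quadrature needs an odd number of nodes")
  w <- rep(2, n_points)
  w[seq(2, n_points - 1, by = 2)] <- 4
  w[c(1, n_points)] <- 1
  w * h / 3
}

# sampling interval of a uniform time grid; errors if visibly non-uniform
uniform_dt <- function(time) {
  dt <- diff(time)
  assert_that(length(dt) >= 1 && diff(range(dt)) < 1e-9 * max(abs(dt)),
              "time base must be uniformly sampled")
  mean(dt)
}

# cross-correlation delay of x relative to y (positive = x lags y), with
# parabolic sub-sample interpolation around the integer-lag peak
xcorr_delay <- function(x, y, dt, max_delay) {
  n <- length(x)
  x <- x - mean(x)
  y <- y - mean(y)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(NA_real_)
  kmax <- min(n - 2L, max(1L, round(max_delay / dt)))
  lags <- seq.int(-kmax, kmax)
  r <- vapply(lags, function(k) {
    if (k >= 0) sum(x[(1 + k):n] * y[1:(n - k)]) else sum(x[1:(n + k)] * y[(1 - k):n])
  }, numeric(1))
  # an insignificant correlation peak (e.g. two constant signals whose
  # fluctuation is independent noise) has no meaningful delay
  if (max(r) < 0.2 * sqrt(sum(x^2) * sum(y^2))) return(NA_real_)
  i <- which.max(r)
  delta <- 0
  if (i > 1 && i < length(r)) {
    denom <- r[i - 1] - 2 * r[i] + r[i + 1]
    if (abs(denom) > .Machine$double.eps) delta <- 0.5 * (r[i - 1] - r[i + 1]) / denom
  }
  (lags[i] + delta) * dt
}
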