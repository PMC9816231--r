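#' Gamma-variate kinetic phenotype of a voxel time-activity curve
#'
#' The continuous tracer concentration follows a normalised gamma-variate
#' \deqn{c(t) = A \, u^\alpha e^{\alpha (1 - u)}, \quad u = (t - t_0)/(t_p - t_0),}
#' with \eqn{c(t) = 0} for \eqn{t \le t_0}. The curve attains its maximum
#' \eqn{A} exactly at the peak time \eqn{t_p}; the shape parameter
#' \eqn{\alpha} controls how sharp the peak is (larger is sharper, with
#' faster washout).
#'
#' @param amplitude Peak activity concentration \eqn{A} (arbitrary units,
#'   > 0).
#' @param peak_time Peak time \eqn{t_p} in minutes post-injection (> onset).
#' @param onset_time Appearance time \eqn{t_0} in minutes (>= 0).
#' @param shape Dimensionless sharpness \eqn{\alpha} (> 0).
#' @return A list of class `kinetic_phenotype`.
#' @examples
#' ph <- kinetic_phenotype(amplitude = 2, peak_time = 7)
#' tac_value(ph, t = 7) # == 2, the amplitude, exactly at the peak
#' @export
kinetic_phenotype <- function(amplitude, peak_time, onset_time = 0,
                              shape = 1) {
  if (!is.numeric(amplitude) || amplitude <= 0)
    abort("amplitude must be > 0", class = "fetrad_invalid_phenotype")
  if (onset_time < 0)
    abort("onset_time must be >= 0", class = "fetrad_invalid_phenotype")
  if (peak_time - onset_time <= 0)
    abort("peak_time must exceed onset_time",
          class = "fetrad_invalid_phenotype")
  if (shape <= 0)
    abort("shape must be > 0", class = "fetrad_invalid_phenotype")
  structure(
    list(amplitude = amplitude, peak_time = peak_time,
         onset_time = onset_time, shape = shape),
    class = "kinetic_phenotype"
  )
}

#' @export
print.kinetic_phenotype <- function(x, ...) {
  cat(sprintf(
    "<kinetic_phenotype> A = %g, peak %g min, onset %g min, shape %g\n",
    x$amplitude, x$peak_time, x$onset_time, x$shape))
  invisible(x)
}

#' Evaluate a gamma-variate curve at given times
#'
#' @param phenotype A [kinetic_phenotype()].
#' @param t Times in minutes.
#' @return Activity concentrations, 0 for `t <= onset_time`.
#' @export
tac_value <- function(phenotype, t) {
  u <- (t - phenotype$onset_time) / (phenotype$peak_time - phenotype$onset_time)
  a <- phenotype$shape
  out <- ifelse(u > 0, phenotype$amplitude * u^a * exp(a * (1 - u)), 0)
  as.numeric(out)
}

# Frame-averaged gamma-variate activity, vectorised over voxels.
# PET frames integrate activity over the frame interval, so the frame value is
# the time average of c(t). The integral has a closed form through the
# regularised incomplete gamma function:
#   int_0^x u^a exp(-a u) du = a^-(a+1) Gamma(a+1) P(a+1, a x)
# which pgamma() evaluates to machine precision.
tac_frame_means <- function(amplitude, peak_time, onset_time, shape,
                            starts, ends) {
  nf <- length(starts)
  nv <- length(amplitude)
  tp0 <- peak_time - onset_time
  # log of A * exp(a) * (tp - t0) * a^-(a+1) * Gamma(a+1)
  lg <- log(amplitude) + shape + log(tp0) - (shape + 1) * log(shape) +
    lgamma(shape + 1)
  cum <- function(tt) {
    # tt: one frame boundary per voxel (recycled); cumulative integral of c
    u <- pmax((tt - onset_time) / tp0, 0)
    exp(lg) * pgamma(shape * u, shape + 1)
  }
  out <- matrix(0, nv, nf)
  for (f in seq_len(nf)) {
    out[, f] <- (cum(ends[f]) - cum(starts[f])) / (ends[f] - starts[f])
  }
  out
}

#' Simulate a frame-sampled time-activity curve
#'
#' Frame values are the exact time averages of the continuous gamma-variate
#' curve over each frame interval (PET frames integrate activity), with
#' optional additive Gaussian noise whose standard deviation is
#' `noise_sd * amplitude`.
#'
#' @param phenotype A [kinetic_phenotype()].
#' @param schedule A [frame_schedule()].
#' @param noise_sd Relative noise level (>= 0), as a fraction of the
#'   phenotype amplitude.
#' @param seed Optional integer; fixing it makes the noise reproducible.
#' @return Numeric vector of frame activities, one per schedule frame.
#' @examples
#' tac <- simulate_tac(kinetic_phenotype(1, 7), default_schedule())
#' @export
simulate_tac <- function(phenotype, schedule, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(phenotype, "kinetic_phenotype"))
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("noise_sd must be >= 0")
  mu <- tac_frame_means(phenotype$amplitude, phenotype$peak_time,
                        phenotype$onset_time, phenotype$shape,
                        schedule$start, schedule$end)[1, ]
  if (noise_sd > 0) {
    local_seed(seed)
    mu <- mu + rnorm(length(mu), sd = noise_sd * phenotype$amplitude)
  }
  mu
}
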