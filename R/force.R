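# Force traces: sampled ground reaction force in Newtons.

#' Construct a force trace
#'
#' A `force_trace` holds a uniformly sampled ground-reaction-force signal in
#' Newtons together with its sampling rate. It is the regression target of the
#' whole pipeline.
#'
#' @param samples Numeric vector of force values (N). Must be finite.
#' @param rate Sampling frequency in Hz (> 0).
#' @return An object of class `force_trace` with fields `samples`, `rate` and
#'   `duration` (seconds, `length(samples) / rate`).
#' @export
force_trace <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) {
    stop("force_trace: samples must be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("force_trace: rate must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = samples, rate = rate, duration = length(samples) / rate),
    class = "force_trace"
  )
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf(
    "<force_trace> %d samples @ %g Hz (%.3f s), peak %.1f N\n",
    length(x$samples), x$rate, x$duration, max(x$samples)
  ))
  invisible(x)
}

#' @export
length.force_trace <- function(x) length(x$samples)

#' Simulate a maximum-voluntary-contraction force profile
#'
#' Generates the ~5 s isometric-squat force profile the pipeline assumes:
#' a trapezoid (linear ramp up, plateau at `peak`, linear ramp down) plus
#' additive Gaussian measurement noise. The trapezoid is used (rather than,
#' say, a half-sine) so that the plateau value is exactly known and testable.
#'
#' @param duration_s Total duration in seconds; must exceed `2 * ramp_s`.
#' @param rate Sampling frequency in Hz (the force plate's, nominally 1600).
#' @param peak Plateau force in Newtons (> 0).
#' @param ramp_s Ramp duration (s) for both the rise and the fall.
#' @param noise_sd Standard deviation of additive Gaussian noise (N).
#' @param seed Integer RNG seed; identical seeds give identical traces.
#' @return A [force_trace()] of length `round(rate * duration_s)`.
#' @examples
#' f <- generate_mvc_force(5, 1600, peak = 1500, ramp_s = 1, noise_sd = 0, seed = 1)
#' max(f$samples) # exactly 1500
#' @export
generate_mvc_force <- function(duration_s = 5, rate = 1600, peak = 1500,
                               ramp_s = 1, noise_sd = 20, seed = 1L) {
  if (duration_s <= 0 || rate <= 0 || peak <= 0) {
    stop("generate_mvc_force: duration_s, rate and peak must be positive",
         call. = FALSE)
  }
  if (duration_s <= 2 * ramp_s) {
    stop("generate_mvc_force: duration_s must exceed 2 * ramp_s", call. = FALSE)
  }
  n <- round(rate * duration_s)
  t <- (seq_len(n) - 1) / rate
  prof <- pmin(1, pmin(t / ramp_s, (duration_s - t) / ramp_s))
  prof <- pmax(prof, 0) * peak
  if (noise_sd > 0) {
    prof <- prof + withr::with_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  force_trace(prof, rate)
}

#' Resample a force trace to an imaging frame rate by block averaging
#'
#' The force plate samples much faster (1600 Hz) than the imaging frame rate
#' (50 Hz). Alignment is by block-mean decimation: consecutive windows of
#' `round(force_rate / frame_rate)` samples are averaged, one block per image
#' frame. Block averaging is anti-aliasing and exactly reproducible.
#'
#' @param force A [force_trace()].
#' @param frame_rate Target frame rate (Hz); `force$rate / frame_rate` should
#'   be close to an integer (1600/50 = 32).
#' @param n_frames Optional number of frames to produce; defaults to
#'   `floor(length(force) / block)`.
#' @return Numeric vector of per-frame mean forces (N).
#' @export
resample_force <- function(force, frame_rate, n_frames = NULL) {
  stopifnot(inherits(force, "force_trace"), frame_rate > 0)
  block <- round(force$rate / frame_rate)
  if (block < 1) stop("resample_force: frame_rate exceeds force rate", call. = FALSE)
  max_frames <- floor(length(force$samples) / block)
  if (is.null(n_frames)) n_frames <- max_frames
  if (n_frames > max_frames) {
    stop("resample_force: trace too short for requested frame count", call. = FALSE)
  }
  idx <- seq_len(n_frames * block)
  colMeans(matrix(force$samples[idx], nrow = block))
}
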