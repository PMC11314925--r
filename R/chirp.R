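# Frequency-sweep (FMCW) acquisition model: depth encoded as beat frequency
# in the down-mixed baseband, recovered by FFT over the sweep window.

#' Configure the frequency-sweep acquisition
#'
#' The wearable acquisition transmits a linear frequency sweep; after mixing
#' the echo with the transmit chirp, a reflector at depth `d` appears as a
#' beat tone at `sweep_rate * 2 d / c`, so shallow tissue maps to low
#' frequencies and deep tissue to high frequencies, all in the kHz band.
#'
#' The sweep bandwidth and baseband sample rate are engineering defaults
#' (2 MHz and 100 kHz): they give ~0.39 mm range bins over a 4 cm depth and a
#' Nyquist-safe kHz beat band.
#'
#' @param sweep_duration Sweep length in seconds (default 0.010).
#' @param sweep_bandwidth Swept bandwidth in Hz (default 2e6).
#' @param center_frequency Transducer centre frequency in Hz (default 4.25e6);
#'   enters only the (irrelevant-to-magnitude) phase convention.
#' @param sample_rate Baseband sampling rate in Hz (default 1e5).
#' @param sound_speed Speed of sound in m/s (default 1540).
#' @param imaging_depth Maximum imaged depth in m (default 0.04).
#' @param frame_rate Frame rate in Hz (default 50); must not exceed
#'   `1 / sweep_duration`.
#' @return An object of class `chirp_config`.
#' @export
chirp_config <- function(sweep_duration = 0.010, sweep_bandwidth = 2e6,
                         center_frequency = 4.25e6, sample_rate = 1e5,
                         sound_speed = 1540, imaging_depth = 0.04,
                         frame_rate = 50) {
  if (sweep_duration <= 0) stop("chirp_config: sweep_duration must be positive", call. = FALSE)
  if (frame_rate > 1 / sweep_duration + 1e-12) {
    stop("chirp_config: frame_rate cannot exceed 1/sweep_duration", call. = FALSE)
  }
  cfg <- structure(list(sweep_duration = sweep_duration,
                        sweep_bandwidth = sweep_bandwidth,
                        center_frequency = center_frequency,
                        sample_rate = sample_rate,
                        sound_speed = sound_speed,
                        imaging_depth = imaging_depth,
                        frame_rate = frame_rate),
                   class = "chirp_config")
  fmax <- beat_frequency(cfg, imaging_depth * (1 - 1e-12))
  if (sample_rate <= 2 * fmax) {
    stop(sprintf(
      "chirp_config: sample_rate %g Hz undersamples the %g Hz beat at full depth",
      sample_rate, fmax), call. = FALSE)
  }
  cfg
}

#' Serialize / deserialize a chirp configuration as YAML
#' @param config A [chirp_config()].
#' @param path YAML file path.
#' @return `write_chirp_config()` returns `path` invisibly;
#'   `read_chirp_config()` returns a [chirp_config()].
#' @export
write_chirp_config <- function(config, path) {
  stopifnot(inherits(config, "chirp_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_chirp_config
#' @export
read_chirp_config <- function(path) {
  do.call(chirp_config, yaml::read_yaml(path))
}

#' A discrete-reflector echo scene
#'
#' @param depths Reflector depths in m, each inside `(0, imaging_depth)`.
#' @param amplitudes Nonnegative reflector amplitudes (recycled to
#'   `length(depths)`).
#' @return An object of class `echo_scene`.
#' @export
echo_scene <- function(depths, amplitudes = 1) {
  depths <- as.numeric(depths)
  amplitudes <- rep_len(as.numeric(amplitudes), length(depths))
  if (any(amplitudes < 0)) stop("echo_scene: amplitudes must be >= 0", call. = FALSE)
  structure(list(depths = depths, amplitudes = amplitudes), class = "echo_scene")
}

#' Beat frequency of a reflector
#'
#' `beat_frequency = sweep_rate * 2 d / c` with
#' `sweep_rate = sweep_bandwidth / sweep_duration`; strictly increasing in
#' depth, which is what makes the FFT of the baseband a depth profile.
#'
#' @param config A [chirp_config()].
#' @param depth Depth in m, inside `(0, imaging_depth)`; vectorized.
#' @return Beat frequency in Hz.
#' @export
beat_frequency <- function(config, depth) {
  stopifnot(inherits(config, "chirp_config"))
  if (any(depth <= 0) || any(depth >= config$imaging_depth)) {
    stop(sprintf("beat_frequency: depth must lie in (0, %g) m",
                 config$imaging_depth), call. = FALSE)
  }
  sweep_rate <- config$sweep_bandwidth / config$sweep_duration
  sweep_rate * 2 * depth / config$sound_speed
}

#' Simulate one down-mixed sweep
#'
#' The baseband record over one sweep window is the sum over reflectors of
#' `amplitude * cos(2 pi f_b(depth) t + phi(depth))` plus white Gaussian
#' noise. The phase convention is `phi = 2 pi * center_frequency * 2 d / c`
#' (the carrier phase of the round trip); it is documented but irrelevant
#' downstream because only magnitude spectra are used.
#'
#' @param config A [chirp_config()].
#' @param scene An [echo_scene()]; an empty scene gives pure noise (or an
#'   all-zero record at `noise_sd = 0`).
#' @param noise_sd Additive noise sd in amplitude units.
#' @param seed RNG seed for the noise.
#' @return Numeric baseband record of length
#'   `round(sweep_duration * sample_rate)`.
#' @export
simulate_sweep <- function(config, scene, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(config, "chirp_config"), inherits(scene, "echo_scene"))
  n <- round(config$sweep_duration * config$sample_rate)
  t <- (seq_len(n) - 1) / config$sample_rate
  rec <- numeric(n)
  if (length(scene$depths) > 0) {
    fb <- beat_frequency(config, scene$depths)
    over <- which(fb >= config$sample_rate / 2)
    if (length(over) > 0) {
      stop(sprintf(
        "simulate_sweep: reflector %d at %.4f m aliases (beat %.0f Hz >= Nyquist %.0f Hz)",
        over[1], scene$depths[over[1]], fb[over[1]], config$sample_rate / 2),
        call. = FALSE)
    }
    phi <- 2 * pi * config$center_frequency * 2 * scene$depths / config$sound_speed
    for (j in seq_along(fb)) {
      rec <- rec + scene$amplitudes[j] * cos(2 * pi * fb[j] * t + phi[j])
    }
  }
  if (noise_sd > 0) {
    rec <- rec + withr::with_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  rec
}

#' Demodulate one sweep record into an A-line over depth
#'
#' A Hann window is applied to control spectral leakage between nearby
#' interfaces, the record is zero-padded (4x the next power of two) for a
#' smooth spectrum, and the one-sided FFT magnitude over
#' `[0, beat_frequency(imaging_depth)]` is mapped to depth through the
#' inverse of the beat-frequency relation, then linearly interpolated onto
#' `depth_px` pixel-centre depths.
#'
#' @param config A [chirp_config()].
#' @param record Baseband record from [simulate_sweep()].
#' @param depth_px Number of output depth pixels.
#' @return Nonnegative numeric A-line of length `depth_px`; the depth (cm) of
#'   pixel `p` is `(p - 0.5) * imaging_depth * 100 / depth_px`.
#' @export
demodulate_aline <- function(config, record, depth_px = 128) {
  stopifnot(inherits(config, "chirp_config"))
  n <- round(config$sweep_duration * config$sample_rate)
  if (length(record) != n) {
    stop(sprintf("demodulate_aline: record length %d != sweep samples %d",
                 length(record), n), call. = FALSE)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hann
  nfft <- 4L * 2L^ceiling(log2(n))
  spec <- Mod(stats::fft(c(record * w, numeric(nfft - n))))[seq_len(nfft %/% 2 + 1)]
  freq <- (seq_len(nfft %/% 2 + 1) - 1) * config$sample_rate / nfft
  sweep_rate <- config$sweep_bandwidth / config$sweep_duration
  depth_of_freq <- freq * config$sound_speed / (2 * sweep_rate)  # m
  pix_depth <- (seq_len(depth_px) - 0.5) * config$imaging_depth / depth_px
  out <- stats::approx(depth_of_freq, spec, xout = pix_depth, rule = 2)$y
  pmax(out, 0)
}

#' Acquire an M-mode image through the frequency-sweep path
#'
#' One sweep is simulated and demodulated per frame; the resulting A-lines
#' are stacked as columns. The depth axis follows the pixel-centre convention
#' and is reported in cm to match the rest of the package.
#'
#' @param config A [chirp_config()].
#' @param scene_sequence List of [echo_scene()], one per frame.
#' @param noise_sd Additive baseband noise sd.
#' @param seed Master seed; per-frame noise derives from it.
#' @param depth_px Depth pixels of the output image.
#' @param site Site label for the image.
#' @return An [mmode_image()] with provenance `"chirp"`.
#' @export
acquire_mmode <- function(config, scene_sequence, noise_sd = 0, seed = 1L,
                          depth_px = 128, site = "") {
  stopifnot(inherits(config, "chirp_config"), length(scene_sequence) >= 1)
  n_frames <- length(scene_sequence)
  frame_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_frames))
  cols <- vapply(seq_len(n_frames), function(i) {
    rec <- simulate_sweep(config, scene_sequence[[i]], noise_sd,
                          seed = frame_seeds[i])
    demodulate_aline(config, rec, depth_px)
  }, numeric(depth_px))
  depth_axis_cm <- (seq_len(depth_px) - 0.5) * config$imaging_depth * 100 / depth_px
  mmode_image(cols, depth_axis_cm, config$frame_rate,
              site = site, provenance = "chirp")
}

#' Build per-frame echo scenes from interface trajectories
#'
#' Convenience bridge from the phantom's kinematics (cm) to the sweep
#' simulator (m): one [echo_scene()] per frame with unit amplitudes.
#'
#' @param trajectories Frames x interfaces matrix of depths in cm.
#' @param amplitudes Per-interface amplitudes.
#' @return List of [echo_scene()], one per row of `trajectories`.
#' @export
scenes_from_trajectories <- function(trajectories, amplitudes = 1) {
  trajectories <- as.matrix(trajectories)
  lapply(seq_len(nrow(trajectories)), function(i) {
    echo_scene(trajectories[i, ] / 100, amplitudes)
  })
}
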