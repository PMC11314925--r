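# Synthetic multi-muscle contraction phantom: force -> interface kinematics
# -> speckle M-mode imagery. Everything downstream is testable against it.

SMART_SITES <- c("vl", "rf", "mh", "vmo")

#' Describe image noise for the phantom renderer
#'
#' @param speckle_contrast Contrast of the multiplicative speckle field in
#'   `[0, 1]`: 0 disables speckle, 1 is a full unit-mean Rayleigh field
#'   (the standard fully developed speckle model, spatially unsmoothed).
#' @param snr_db Additive white-noise level as a signal-to-noise ratio in dB
#'   relative to the RMS of the speckled signal; `Inf` disables it.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(speckle_contrast = 1, snr_db = 30) {
  if (speckle_contrast < 0 || speckle_contrast > 1) {
    stop("noise_spec: speckle_contrast must be in [0, 1]", call. = FALSE)
  }
  structure(list(speckle_contrast = speckle_contrast, snr_db = snr_db),
            class = "noise_spec")
}

#' Construct a multi-muscle contraction phantom
#'
#' The phantom states the generative world the analysis assumes: four
#' instrumented thigh sites (vastus lateralis, rectus femoris, medial
#' hamstring, vastus medialis), each with a few tissue interfaces whose depths
#' displace linearly with the force that site transmits, imaged at 4 cm depth.
#' Linearity of the force-displacement coupling is an assumption of the
#' phantom, not a physiological claim.
#'
#' @param site_names Character vector of sensor-site labels.
#' @param interface_rest_depths Named list (per site) of strictly increasing
#'   resting interface depths in cm, all inside `(0, imaging_depth)`.
#' @param gains Named numeric vector of displacement-per-force coefficients
#'   (cm/N), one per site; signs may differ (tissue may move toward or away
#'   from the transducer).
#' @param contribution_weights Named nonnegative weights summing to 1: each
#'   site's share of the total ground reaction force.
#' @param noise A [noise_spec()].
#' @param imaging_depth Imaging depth in cm (default 4).
#' @param band_sigma_cm Gaussian cross-section (sd, cm) of an interface's
#'   bright band in depth; 0.06 cm approximates a sub-millimetre interface.
#' @param seed Integer seed used when the phantom itself is asked to generate.
#' @return An object of class `muscle_phantom`.
#' @export
muscle_phantom <- function(site_names = SMART_SITES,
                           interface_rest_depths = list(
                             vl  = c(0.8, 1.8, 3.0),
                             rf  = c(1.0, 2.2, 3.2),
                             mh  = c(0.9, 2.0, 3.1),
                             vmo = c(1.1, 2.1, 2.9)
                           ),
                           gains = c(vl = 1.6e-3, rf = -1.2e-3,
                                     mh = 1.4e-3, vmo = 1.0e-3),
                           contribution_weights = c(vl = 0.25, rf = 0.25,
                                                    mh = 0.25, vmo = 0.25),
                           noise = noise_spec(),
                           imaging_depth = 4,
                           band_sigma_cm = 0.06,
                           seed = 1L) {
  stopifnot(length(site_names) >= 1)
  if (!setequal(names(interface_rest_depths), site_names) ||
      !setequal(names(gains), site_names) ||
      !setequal(names(contribution_weights), site_names)) {
    stop("muscle_phantom: depths, gains and weights must be named per site",
         call. = FALSE)
  }
  for (s in site_names) {
    d <- interface_rest_depths[[s]]
    if (any(diff(d) <= 0) || any(d <= 0) || any(d >= imaging_depth)) {
      stop(sprintf(
        "muscle_phantom: rest depths for site '%s' must be strictly increasing within (0, %g) cm",
        s, imaging_depth), call. = FALSE)
    }
  }
  w <- contribution_weights[site_names]
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("muscle_phantom: contribution weights must be nonnegative and sum to 1",
         call. = FALSE)
  }
  structure(list(
    site_names = site_names,
    interface_rest_depths = interface_rest_depths[site_names],
    gains = gains[site_names],
    contribution_weights = w,
    noise = noise,
    imaging_depth = imaging_depth,
    band_sigma_cm = band_sigma_cm,
    seed = as.integer(seed)
  ), class = "muscle_phantom")
}

#' Interface depth trajectories for one site
#'
#' Maps a force signal to the depth time series of each tissue interface at a
#' site: `depth_j(t) = rest_depth_j + gain_site * force(t)`.
#'
#' @param phantom A [muscle_phantom()].
#' @param site One of `phantom$site_names`.
#' @param force A [force_trace()] or plain numeric force vector (N).
#' @return Matrix of depths (cm), `length(force)` rows x one column per
#'   interface.
#' @export
interface_trajectory <- function(phantom, site, force) {
  stopifnot(inherits(phantom, "muscle_phantom"))
  if (!site %in% phantom$site_names) {
    stop(sprintf("interface_trajectory: unknown site '%s'", site), call. = FALSE)
  }
  f <- if (inherits(force, "force_trace")) force$samples else as.numeric(force)
  rest <- phantom$interface_rest_depths[[site]]
  traj <- outer(phantom$gains[[site]] * f, rep(1, length(rest))) +
    matrix(rest, nrow = length(f), ncol = length(rest), byrow = TRUE)
  bad <- which(traj <= 0 | traj >= phantom$imaging_depth, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "interface_trajectory: site '%s' leaves the imaging window at time index %d (depth %.3f cm)",
      site, bad[1, 1], traj[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  colnames(traj) <- paste0("interface_", seq_along(rest))
  traj
}

# Unit-mean Rayleigh draws: sqrt of Exp(1) is Rayleigh(sigma = 1/sqrt(2)),
# whose mean is sqrt(pi)/2; divide it out.
runit_rayleigh <- function(n) sqrt(stats::rexp(n)) / (sqrt(pi) / 2)

#' Render an M-mode image from interface trajectories
#'
#' Each frame (column) contains one bright band per interface — a Gaussian
#' cross-section in depth centred on the interface's current depth —
#' multiplied by per-pixel unit-mean multiplicative speckle and then degraded
#' by additive white noise at the requested SNR. Negative values are clipped
#' to zero so intensities stay nonnegative.
#'
#' Pixel `p` (1-based) is centred at depth `(p - 0.5) * imaging_depth /
#' depth_px` cm; this pixel-centre convention is used throughout the package.
#'
#' @param trajectories Matrix of interface depths (cm): frames x interfaces,
#'   as returned by [interface_trajectory()].
#' @param frame_rate Frame rate in Hz.
#' @param depth_px Number of depth pixels (>= 64). 256 approximates a
#'   clinical-resolution image, 128 a wearable-sensor image.
#' @param imaging_depth Imaging depth in cm.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; it controls only the noise, never the band
#'   centres.
#' @param band_sigma_cm Gaussian band sd in cm.
#' @param site,provenance Metadata stored on the image.
#' @return An [mmode_image()] of size `depth_px` x `nrow(trajectories)`.
#' @export
render_mmode <- function(trajectories, frame_rate = 50, depth_px = 128,
                         imaging_depth = 4, noise = noise_spec(), seed = 1L,
                         band_sigma_cm = 0.06, site = "", provenance = "synthetic") {
  trajectories <- as.matrix(trajectories)
  if (depth_px < 64) stop("render_mmode: depth_px must be >= 64", call. = FALSE)
  if (frame_rate <= 0) stop("render_mmode: frame_rate must be positive", call. = FALSE)
  n_frames <- nrow(trajectories)
  depth_axis <- (seq_len(depth_px) - 0.5) * imaging_depth / depth_px

  img <- matrix(0, nrow = depth_px, ncol = n_frames)
  for (j in seq_len(ncol(trajectories))) {
    # outer(depth, frame): Gaussian band around the moving centre
    img <- img + exp(-0.5 * (outer(depth_axis, trajectories[, j], "-") /
                               band_sigma_cm)^2)
  }

  withr::with_seed(seed, {
    if (noise$speckle_contrast > 0) {
      spk <- 1 + noise$speckle_contrast * (runit_rayleigh(length(img)) - 1)
      img <- img * matrix(spk, nrow = depth_px)
    }
    if (is.finite(noise$snr_db)) {
      sig_rms <- sqrt(mean(img^2))
      noise_sd <- sig_rms / 10^(noise$snr_db / 20)
      img <- img + matrix(stats::rnorm(length(img), sd = noise_sd),
                          nrow = depth_px)
    }
  })
  img[img < 0] <- 0
  mmode_image(img, depth_axis, frame_rate, site = site, provenance = provenance)
}

#' Generate a complete multi-trial dataset from a phantom
#'
#' Emulates the experiment's structure: `n_trials` repetitions of a ~5 s
#' maximal isometric contraction, each observed simultaneously by one
#' clinical-resolution M-mode on the vastus lateralis and four wearable-sensor
#' M-modes (VL, RF, MH, VMO). Per trial, the force noise and the speckle are
#' independent. The force is resampled to the frame rate by block averaging,
#' and the last trial is marked `test` with all earlier trials `train`.
#'
#' Each site's interfaces are driven by that site's share of the total force,
#' `weight_site * F(t)`, so the total force is the sum of the per-site scaled
#' profiles.
#'
#' @param phantom A [muscle_phantom()].
#' @param n_trials Number of trials (>= 2; default 3: two train + one test).
#' @param duration_s,force_rate,peak,ramp_s,force_noise_sd Passed to
#'   [generate_mvc_force()] per trial.
#' @param frame_rate Imaging frame rate (Hz).
#' @param depth_px_clinical,depth_px_smart Depth resolution of the clinical
#'   and wearable images.
#' @param subject_id Label stored on the dataset.
#' @param seed Master seed; all per-trial seeds derive from it.
#' @return A `trial_dataset`: list with `subject_id`, `site_names` and
#'   `trials`, each trial holding `index`, `role`, `images` (named list of
#'   [mmode_image()]: `clinical` plus one per wearable site) and
#'   `force_frames` (frame-rate force, N).
#' @export
generate_trial_dataset <- function(phantom = muscle_phantom(),
                                   n_trials = 3,
                                   duration_s = 5, force_rate = 1600,
                                   peak = 1500, ramp_s = 1,
                                   force_noise_sd = 20,
                                   frame_rate = 50,
                                   depth_px_clinical = 256,
                                   depth_px_smart = 128,
                                   subject_id = "phantom-01",
                                   seed = phantom$seed) {
  if (n_trials < 2) {
    stop("generate_trial_dataset: need n_trials >= 2 to form a train+test split",
         call. = FALSE)
  }
  n_streams <- length(phantom$site_names) + 1L
  sub_seeds <- withr::with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, n_trials * (n_streams + 1L)),
    nrow = n_trials))

  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    force <- generate_mvc_force(duration_s, force_rate, peak, ramp_s,
                                force_noise_sd, seed = sub_seeds[i, 1])
    n_frames <- round(frame_rate * duration_s)
    force_frames <- resample_force(force, frame_rate, n_frames)

    images <- list()
    # clinical-resolution stream on the VL
    vl_traj <- interface_trajectory(
      phantom, "vl", phantom$contribution_weights[["vl"]] * force_frames)
    images$clinical <- render_mmode(
      vl_traj, frame_rate, depth_px_clinical, phantom$imaging_depth,
      phantom$noise, seed = sub_seeds[i, 2],
      band_sigma_cm = phantom$band_sigma_cm,
      site = "vl", provenance = "clinical_scanline")
    for (k in seq_along(phantom$site_names)) {
      s <- phantom$site_names[k]
      traj <- interface_trajectory(
        phantom, s, phantom$contribution_weights[[s]] * force_frames)
      images[[s]] <- render_mmode(
        traj, frame_rate, depth_px_smart, phantom$imaging_depth,
        phantom$noise, seed = sub_seeds[i, 2 + k],
        band_sigma_cm = phantom$band_sigma_cm,
        site = s, provenance = "synthetic")
    }
    trials[[i]] <- list(
      index = i,
      role = if (i == n_trials) "test" else "train",
      images = images,
      force_frames = force_frames,
      force_trace = force
    )
  }
  structure(list(subject_id = subject_id,
                 site_names = phantom$site_names,
                 frame_rate = frame_rate,
                 trials = trials),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  roles <- vapply(x$trials, `[[`, "", "role")
  cat(sprintf("<trial_dataset> subject %s: %d trials (%s), streams: %s\n",
              x$subject_id, length(x$trials), paste(roles, collapse = ", "),
              paste(names(x$trials[[1]]$images), collapse = ", ")))
  invisible(x)
}
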