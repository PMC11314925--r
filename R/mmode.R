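# M-mode image container, B-mode -> M-mode projection, and text-based I/O.

#' Construct an M-mode image
#'
#' An M-mode image is a depth x time intensity matrix: rows are depth pixels
#' (shallow at row 1), columns are frames. The depth axis carries the physical
#' depth (cm) of each pixel centre and must be strictly increasing.
#'
#' @param intensities Nonnegative numeric matrix, `depth_px x frames`.
#' @param depth_axis Strictly increasing numeric vector of pixel depths (cm),
#'   length `nrow(intensities)`.
#' @param frame_rate Frame rate in Hz (> 0).
#' @param site Sensor-site label (e.g. `"vl"`).
#' @param provenance One of `"clinical_scanline"`, `"chirp"`, `"synthetic"`.
#' @return An object of class `mmode_image`.
#' @export
mmode_image <- function(intensities, depth_axis, frame_rate,
                        site = "", provenance = "synthetic") {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) < 1) stop("mmode_image: need >= 1 frame", call. = FALSE)
  if (any(intensities < 0) || any(!is.finite(intensities))) {
    stop("mmode_image: intensities must be finite and nonnegative", call. = FALSE)
  }
  if (length(depth_axis) != nrow(intensities) || any(diff(depth_axis) <= 0)) {
    stop("mmode_image: depth_axis must be strictly increasing with one entry per row",
         call. = FALSE)
  }
  if (frame_rate <= 0) stop("mmode_image: frame_rate must be positive", call. = FALSE)
  provenance <- match.arg(provenance, c("clinical_scanline", "chirp", "synthetic"))
  structure(list(intensities = intensities, depth_axis = as.numeric(depth_axis),
                 frame_rate = frame_rate, site = site, provenance = provenance),
            class = "mmode_image")
}

#' @export
print.mmode_image <- function(x, ...) {
  cat(sprintf("<mmode_image> %d px x %d frames @ %g Hz, depth %.2f-%.2f cm, site '%s' (%s)\n",
              nrow(x$intensities), ncol(x$intensities), x$frame_rate,
              x$depth_axis[1], x$depth_axis[length(x$depth_axis)],
              x$site, x$provenance))
  invisible(x)
}

#' @export
dim.mmode_image <- function(x) dim(x$intensities)

#' Construct a B-mode image stack
#'
#' @param frames List of 2-D matrices (`depth_px x lateral_px`), all of the
#'   same shape: the brightness-mode frames acquired over time.
#' @param depth_axis Per-row depth (cm).
#' @param frame_rate Frame rate in Hz.
#' @return An object of class `bmode_stack`.
#' @export
bmode_stack <- function(frames, depth_axis, frame_rate) {
  stopifnot(length(frames) >= 1, frame_rate > 0)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stop("bmode_stack: all frames must share one shape", call. = FALSE)
  if (length(depth_axis) != d[1]) {
    stop("bmode_stack: depth_axis length must equal frame row count", call. = FALSE)
  }
  structure(list(frames = frames, depth_axis = as.numeric(depth_axis),
                 frame_rate = frame_rate),
            class = "bmode_stack")
}

#' Collapse a B-mode stack to an M-mode image
#'
#' The clinical acquisition path: one lateral scanline, by default the centre
#' column, is extracted from every frame and the scanlines are stacked over
#' time. Column `t` of the result is the chosen column of frame `t`.
#'
#' @param stack A [bmode_stack()].
#' @param scanline_index 1-based lateral column to extract; defaults to the
#'   centre column `floor(lateral_px / 2) + 1`.
#' @param site,provenance Metadata for the resulting image.
#' @return An [mmode_image()] with one column per frame.
#' @export
bmode_to_mmode <- function(stack, scanline_index = NULL,
                           site = "", provenance = "clinical_scanline") {
  stopifnot(inherits(stack, "bmode_stack"))
  lateral_px <- ncol(stack$frames[[1]])
  if (is.null(scanline_index)) scanline_index <- floor(lateral_px / 2) + 1L
  if (scanline_index < 1 || scanline_index > lateral_px) {
    stop(sprintf("bmode_to_mmode: scanline_index %d outside 1..%d",
                 scanline_index, lateral_px), call. = FALSE)
  }
  cols <- vapply(stack$frames, function(f) f[, scanline_index],
                 numeric(nrow(stack$frames[[1]])))
  mmode_image(cols, stack$depth_axis, stack$frame_rate,
              site = site, provenance = provenance)
}

# ---- I/O ------------------------------------------------------------------
# Canonical on-disk form: a TSV of 16-bit integer codes (rows = depth,
# shallow first; columns = time) plus a JSON sidecar <path>.json holding the
# min/max scale, depth axis, frame rate, site and provenance. Quantization to
# 65535 steps of the min-max range makes round trips lossless to one step.
# An 8-bit PNG can additionally be written for visual inspection.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read an M-mode image
#'
#' `write_mmode()` stores the image as delimited text of 16-bit integer codes
#' with a JSON sidecar recording the intensity scale and metadata;
#' `read_mmode()` inverts it. The round trip is lossless to one quantization
#' step of the min-max intensity range (1/65535).
#'
#' @param image An [mmode_image()].
#' @param path Destination `.tsv` path; the sidecar is written to
#'   `<path>.json`.
#' @param png_preview Optional path to also write an 8-bit grayscale PNG
#'   (requires the `png` package; preview only, not read back).
#' @return `write_mmode()` returns `path` invisibly; `read_mmode()` returns
#'   an [mmode_image()].
#' @export
write_mmode <- function(image, path, png_preview = NULL) {
  stopifnot(inherits(image, "mmode_image"))
  lo <- min(image$intensities)
  hi <- max(image$intensities)
  scale <- if (hi > lo) 65535 / (hi - lo) else 0
  codes <- round((image$intensities - lo) * scale)
  utils::write.table(codes, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(
    format = "sonoforce-mmode-tsv16",
    depth_axis_cm = image$depth_axis,
    frame_rate_hz = image$frame_rate,
    site = image$site,
    provenance = image$provenance,
    intensity_min = lo,
    intensity_max = hi,
    orientation = "rows=depth(shallow first), cols=time"
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  if (!is.null(png_preview)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      warning("png package unavailable; skipping PNG preview")
    } else {
      png::writePNG(codes / 65535, png_preview)
    }
  }
  invisible(path)
}

#' @rdname write_mmode
#' @export
read_mmode <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop(sprintf("read_mmode: missing JSON sidecar '%s'", sc), call. = FALSE)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(meta$format, "sonoforce-mmode-tsv16")) {
    stop("read_mmode: unrecognized format tag in sidecar", call. = FALSE)
  }
  codes <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(codes) <- NULL
  if (nrow(codes) != length(meta$depth_axis_cm)) {
    stop("read_mmode: image shape does not match sidecar depth axis", call. = FALSE)
  }
  lo <- meta$intensity_min
  hi <- meta$intensity_max
  intens <- if (hi > lo) lo + codes * (hi - lo) / 65535 else
    matrix(lo, nrow(codes), ncol(codes))
  mmode_image(intens, as.numeric(meta$depth_axis_cm),
              as.numeric(meta$frame_rate_hz),
              site = meta$site, provenance = meta$provenance)
}

#' Write / read a force trace as CSV
#'
#' Two columns, `time_s` and `force_N`; values are preserved to at least six
#' significant digits.
#'
#' @param force A [force_trace()].
#' @param path CSV path.
#' @return `write_force_csv()` returns `path` invisibly; `read_force_csv()`
#'   returns a [force_trace()].
#' @export
write_force_csv <- function(force, path) {
  stopifnot(inherits(force, "force_trace"))
  t <- (seq_along(force$samples) - 1) / force$rate
  df <- data.frame(time_s = signif(t, 10), force_N = signif(force$samples, 10))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_csv
#' @export
read_force_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "force_N") %in% names(df))) {
    stop("read_force_csv: expected columns time_s, force_N", call. = FALSE)
  }
  rate <- if (nrow(df) > 1) 1 / stats::median(diff(df$time_s)) else 1
  force_trace(df$force_N, round(rate, 6))
}

#' Write / read a trial dataset on disk
#'
#' `write_trial_dataset()` lays a dataset out as one directory per trial
#' (M-mode TSVs + sidecars, force CSV) plus a YAML manifest listing every
#' file with its trial index, role and site. `read_trial_dataset()` rebuilds
#' the in-memory `trial_dataset` from the manifest.
#'
#' @param dataset A `trial_dataset` from [generate_trial_dataset()].
#' @param dir Output directory (created if needed).
#' @return `write_trial_dataset()` returns the manifest path invisibly;
#'   `read_trial_dataset()` returns a `trial_dataset`.
#' @export
write_trial_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(subject_id = dataset$subject_id,
                   site_names = as.list(dataset$site_names),
                   frame_rate = dataset$frame_rate,
                   trials = list())
  for (tr in dataset$trials) {
    tdir <- file.path(dir, sprintf("trial%02d", tr$index))
    dir.create(tdir, showWarnings = FALSE)
    entry <- list(index = tr$index, role = tr$role, images = list())
    for (stream in names(tr$images)) {
      rel <- file.path(sprintf("trial%02d", tr$index),
                       paste0(stream, ".tsv"))
      write_mmode(tr$images[[stream]], file.path(dir, rel))
      entry$images[[stream]] <- rel
    }
    rel_force <- file.path(sprintf("trial%02d", tr$index), "force.csv")
    write_force_csv(tr$force_trace, file.path(dir, rel_force))
    entry$force <- rel_force
    manifest$trials[[length(manifest$trials) + 1L]] <- entry
  }
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' @rdname write_trial_dataset
#' @param manifest_path Path to a `manifest.yaml` written by
#'   `write_trial_dataset()`.
#' @export
read_trial_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("read_trial_dataset: no manifest at '%s'", manifest_path),
         call. = FALSE)
  }
  man <- yaml::read_yaml(manifest_path)
  for (f in c("subject_id", "site_names", "frame_rate", "trials")) {
    if (is.null(man[[f]])) {
      stop(sprintf("read_trial_dataset: manifest missing field '%s'", f),
           call. = FALSE)
    }
  }
  dir <- dirname(manifest_path)
  trials <- lapply(man$trials, function(entry) {
    images <- lapply(entry$images, function(rel) read_mmode(file.path(dir, rel)))
    force <- read_force_csv(file.path(dir, entry$force))
    n_frames <- ncol(images[[1]]$intensities)
    list(index = entry$index, role = entry$role, images = images,
         force_frames = resample_force(force, man$frame_rate, n_frames),
         force_trace = force)
  })
  structure(list(subject_id = man$subject_id,
                 site_names = unlist(man$site_names),
                 frame_rate = man$frame_rate,
                 trials = trials),
            class = "trial_dataset")
}
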