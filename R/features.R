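# Feature extraction: windowed intensity-weighted mean depth per A-line,
# z-scoring, and PCA truncation at 99% explained variance.

#' Intensity-weighted mean depth of one window
#'
#' The core image feature: within a depth window, each pixel's depth `D_i` is
#' weighted by its intensity `A_i`, giving `sum(A_i D_i) / sum(A_i)` — the
#' depth where the window's echo energy is centred. It tracks a tissue
#' interface as the muscle expands or contracts.
#'
#' @param window_intensities Nonnegative intensities `A` (sum must be > 0).
#' @param window_depths Depths `D` (cm), same length as the intensities.
#' @return The weighted mean depth (cm); always within `[min(D), max(D)]`.
#' @examples
#' mean_depth(c(1, 2, 3), c(5, 6, 7)) # 38/6
#' @export
mean_depth <- function(window_intensities, window_depths) {
  if (length(window_intensities) != length(window_depths)) {
    stop("mean_depth: intensities and depths must have equal length", call. = FALSE)
  }
  if (any(window_intensities < 0)) {
    stop("mean_depth: intensities must be nonnegative", call. = FALSE)
  }
  # left-to-right double-precision accumulation: bit-for-bit the definitional
  # loop (R's sum() accumulates in extended precision and can differ by 1 ulp)
  num <- 0
  den <- 0
  for (i in seq_along(window_intensities)) {
    num <- num + window_intensities[i] * window_depths[i]
    den <- den + window_intensities[i]
  }
  if (den <= 0) {
    stop("mean_depth: degenerate window (all-zero intensities)", call. = FALSE)
  }
  num / den
}

# Start indices of full windows: stride = round(window_px * (1 - overlap)).
window_starts <- function(n_px, window_px, overlap) {
  stride <- round(window_px * (1 - overlap))
  if (stride < 1) stop("window stride must be >= 1", call. = FALSE)
  seq.int(1L, n_px - window_px + 1L, by = stride)
}

#' Per-window mean-depth features of one A-line
#'
#' Slides a depth window of `window_px` pixels along the A-line with the
#' requested overlap (stride `round(window_px * (1 - overlap))`, i.e. 12 px
#' for the 25 px / 50% defaults) and evaluates [mean_depth()] in each full
#' window; trailing partial windows are dropped, so the feature count is
#' `floor((n_px - window_px) / stride) + 1`. A window whose intensities sum
#' to zero falls back to its central depth (a uniform-intensity reading)
#' rather than propagating NaN.
#'
#' @param aline Nonnegative intensity vector (one image column).
#' @param depth_axis Per-pixel depths (cm), same length.
#' @param window_px Window length in pixels (default 25).
#' @param overlap Fractional overlap between consecutive windows (default 0.5).
#' @return Numeric vector of per-window mean depths (cm).
#' @export
extract_frame_features <- function(aline, depth_axis, window_px = 25,
                                   overlap = 0.5) {
  n <- length(aline)
  if (length(depth_axis) != n) {
    stop("extract_frame_features: aline and depth_axis lengths differ", call. = FALSE)
  }
  if (n < window_px) {
    stop("extract_frame_features: A-line shorter than one window", call. = FALSE)
  }
  starts <- window_starts(n, window_px, overlap)
  vapply(starts, function(s) {
    idx <- s:(s + window_px - 1L)
    tot <- sum(aline[idx])
    if (tot <= 0) mean(depth_axis[idx]) else
      sum(aline[idx] * depth_axis[idx]) / tot
  }, numeric(1))
}

#' Mean-depth feature matrix of an M-mode image
#'
#' Row `t` of the result holds the windowed mean-depth features of column
#' (frame) `t` of the image. Implemented with per-window column sums so a
#' 256 x 250 image reduces in a few milliseconds.
#'
#' @param image An [mmode_image()].
#' @param window_px,overlap As in [extract_frame_features()].
#' @return A `feature_matrix`: list with `values` (frames x features),
#'   `labels` (data.frame of site and window index) and `frame_rate`.
#' @export
extract_features <- function(image, window_px = 25, overlap = 0.5) {
  stopifnot(inherits(image, "mmode_image"))
  I <- image$intensities
  d <- image$depth_axis
  starts <- window_starts(nrow(I), window_px, overlap)
  vals <- matrix(NA_real_, nrow = ncol(I), ncol = length(starts))
  degenerate <- FALSE
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + window_px - 1L)
    num <- colSums(I[idx, , drop = FALSE] * d[idx])
    den <- colSums(I[idx, , drop = FALSE])
    zero <- den <= 0
    if (any(zero)) {
      degenerate <- TRUE
      num[zero] <- mean(d[idx])
      den[zero] <- 1
    }
    vals[, w] <- num / den
  }
  if (degenerate) {
    warning("extract_features: degenerate all-zero window(s) fell back to central depth")
  }
  feature_matrix(vals,
                 labels = data.frame(site = rep(image$site, length(starts)),
                                     window = seq_along(starts)),
                 frame_rate = image$frame_rate)
}

#' Construct a feature matrix
#'
#' @param values Finite numeric matrix, frames x features.
#' @param labels data.frame with one row per feature (columns `site`,
#'   `window`).
#' @param frame_rate Frame rate in Hz.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels = NULL, frame_rate = NA_real_) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) {
    stop("feature_matrix: values must be finite", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- data.frame(site = rep("", ncol(values)),
                         window = seq_len(ncol(values)))
  }
  if (nrow(labels) != ncol(values)) {
    stop("feature_matrix: one label row per feature required", call. = FALSE)
  }
  structure(list(values = values, labels = labels, frame_rate = frame_rate),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d frames x %d features (sites: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$labels$site), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Concatenate per-site feature matrices column-wise
#'
#' Used to assemble the distributed (all-sensor) input: the per-site feature
#' matrices are bound horizontally in the order given, with labels preserved.
#'
#' @param matrices List of `feature_matrix` objects with equal frame counts.
#' @return One `feature_matrix`.
#' @export
concat_sites <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  frames <- vapply(matrices, function(m) nrow(m$values), integer(1))
  if (length(unique(frames)) != 1) {
    stop(sprintf("concat_sites: frame counts differ (%s)",
                 paste(frames, collapse = ", ")), call. = FALSE)
  }
  if (length(matrices) == 1) return(matrices[[1]])
  feature_matrix(do.call(cbind, lapply(matrices, `[[`, "values")),
                 labels = do.call(rbind, lapply(matrices, `[[`, "labels")),
                 frame_rate = matrices[[1]]$frame_rate)
}

#' Fit the z-score + PCA feature transform on training rows only
#'
#' Per-feature means and standard deviations are computed on the training
#' rows; features are z-scored and a PCA of the z-scores is taken. The
#' smallest number of leading components whose cumulative explained-variance
#' ratio reaches `variance_threshold` (default 0.99) is retained. A
#' zero-variance feature gets sd 1 (it becomes a constant 0 and contributes
#' nothing). Component signs are fixed by making each component's
#' largest-magnitude loading positive, so the transform is deterministic.
#'
#' @param train A `feature_matrix` (or plain matrix) of training rows (>= 2).
#' @param variance_threshold Fraction of variance to retain, in `(0, 1]`.
#' @return A `feature_transform`: `z_means`, `z_sds`, `pca_components`
#'   (orthonormal p x m loadings), `explained_ratio`, `variance_threshold`.
#' @export
fit_feature_transform <- function(train, variance_threshold = 0.99) {
  X <- if (inherits(train, "feature_matrix")) train$values else as.matrix(train)
  if (nrow(X) < 2) {
    stop("fit_feature_transform: need >= 2 training rows", call. = FALSE)
  }
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop("fit_feature_transform: variance_threshold must be in (0, 1]", call. = FALSE)
  }
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ratio <- ev / sum(ev)
  if (variance_threshold >= 1) {
    m <- sum(ev > max(ev) * 1e-12)
  } else {
    m <- which(cumsum(ratio) >= variance_threshold - 1e-12)[1]
  }
  rot <- pc$rotation[, seq_len(m), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(z_means = mu, z_sds = sds, pca_components = rot,
                 explained_ratio = ratio[seq_len(m)],
                 variance_threshold = variance_threshold),
            class = "feature_transform")
}

#' Project a feature matrix through a fitted transform
#'
#' `((X - z_means) / z_sds) %*% pca_components`; purely deterministic, no
#' statistics are recomputed, so held-out data never leaks into the transform.
#'
#' @param transform A `feature_transform` from [fit_feature_transform()].
#' @param matrix_ A `feature_matrix` or plain matrix with matching feature
#'   count.
#' @return A `feature_matrix` of PCA scores (frames x retained components).
#' @export
apply_feature_transform <- function(transform, matrix_) {
  stopifnot(inherits(transform, "feature_transform"))
  X <- if (inherits(matrix_, "feature_matrix")) matrix_$values else as.matrix(matrix_)
  if (ncol(X) != length(transform$z_means)) {
    stop(sprintf("apply_feature_transform: %d features, transform expects %d",
                 ncol(X), length(transform$z_means)), call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, transform$z_means), 2, transform$z_sds, "/")
  scores <- Z %*% transform$pca_components
  fr <- if (inherits(matrix_, "feature_matrix")) matrix_$frame_rate else NA_real_
  feature_matrix(scores,
                 labels = data.frame(site = rep("pca", ncol(scores)),
                                     window = seq_len(ncol(scores))),
                 frame_rate = fr)
}
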