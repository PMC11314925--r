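# Closed-form ridge regression of force on image features, prediction,
# moving-average smoothing and the R^2 metric.

#' Fit a ridge regression model in closed form
#'
#' Solves the penalized least-squares problem
#' `min_{b0, b} sum_i (y_i - b0 - x_i' b)^2 + k * sum_j b_j^2`.
#' Columns of `X` and `y` are centred, `b = (Xc'Xc + kI)^{-1} Xc' yc` is
#' obtained from a stable linear solve (never an explicit inverse), and the
#' intercept is recovered as `b0 = mean(y) - colMeans(X) . b` — the standard
#' resolution that satisfies both the no-intercept normal-equation form and
#' the intercept-bearing objective. Only `b` is penalized. Features are
#' expected to arrive already z-scored / PCA-projected, so no further scaling
#' happens here (rescaling would silently change the meaning of `k`).
#'
#' With `k = 0` and collinear columns the system is singular; a minimum-norm
#' least-squares solution (SVD pseudo-inverse) is returned with a warning.
#'
#' @param X A `feature_matrix` or numeric matrix, frames x features.
#' @param y Numeric force vector (N) or [force_trace()], one value per row
#'   of `X`.
#' @param k Ridge penalty (default 5; `k >= 0`).
#' @param feature_transform Optional `feature_transform` to store with the
#'   model (applied by [predict.ridge_model()] when raw features are given).
#' @return An object of class `ridge_model` with `beta0`, `beta`, `k`,
#'   `feature_transform`.
#' @export
fit_ridge <- function(X, y, k = 5, feature_transform = NULL) {
  Xm <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  yv <- if (inherits(y, "force_trace")) y$samples else as.numeric(y)
  if (nrow(Xm) != length(yv)) {
    stop("fit_ridge: nrow(X) must equal length(y)", call. = FALSE)
  }
  if (nrow(Xm) < 2) stop("fit_ridge: need >= 2 observations", call. = FALSE)
  if (k < 0) stop("fit_ridge: k must be >= 0", call. = FALSE)
  mx <- colMeans(Xm)
  my <- mean(yv)
  Xc <- sweep(Xm, 2, mx)
  yc <- yv - my
  A <- crossprod(Xc) + k * diag(ncol(Xc))
  beta <- tryCatch(
    solve(A, crossprod(Xc, yc)),
    error = function(e) {
      warning("fit_ridge: singular system; returning minimum-norm solution")
      sv <- svd(Xc)
      pos <- sv$d > max(sv$d) * 1e-12
      drop(sv$v[, pos, drop = FALSE] %*%
             ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos]))
    })
  beta <- drop(beta)
  structure(list(beta0 = my - sum(mx * beta), beta = beta, k = k,
                 feature_transform = feature_transform),
            class = "ridge_model")
}

#' Predict force from a fitted ridge model
#'
#' @param object A `ridge_model`.
#' @param newdata A `feature_matrix` or numeric matrix. If the model stores a
#'   `feature_transform` and `newdata` has the transform's raw feature count,
#'   the transform is applied first.
#' @param ... Unused.
#' @return Numeric vector of predicted force (N), `beta0 + X %*% beta`.
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$values else as.matrix(newdata)
  tr <- object$feature_transform
  if (!is.null(tr) && ncol(X) == length(tr$z_means) &&
      ncol(X) != length(object$beta)) {
    X <- apply_feature_transform(tr, X)$values
  }
  if (ncol(X) != length(object$beta)) {
    stop(sprintf("predict.ridge_model: %d features, model expects %d",
                 ncol(X), length(object$beta)), call. = FALSE)
  }
  drop(object$beta0 + X %*% object$beta)
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("<ridge_model> %d coefficients, k = %g, beta0 = %.3f\n",
              length(x$beta), x$k, x$beta0))
  invisible(x)
}

#' Serialize / deserialize a ridge model as JSON
#' @param model A `ridge_model`.
#' @param path JSON file path.
#' @return `write_ridge_model()` returns `path` invisibly;
#'   `read_ridge_model()` returns a `ridge_model`.
#' @export
write_ridge_model <- function(model, path) {
  stopifnot(inherits(model, "ridge_model"))
  tr <- model$feature_transform
  obj <- list(beta0 = model$beta0, beta = model$beta, k = model$k,
              feature_transform = if (is.null(tr)) NULL else list(
                z_means = tr$z_means, z_sds = tr$z_sds,
                pca_components = tr$pca_components,
                explained_ratio = tr$explained_ratio,
                variance_threshold = tr$variance_threshold))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ridge_model
#' @export
read_ridge_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- NULL
  if (!is.null(obj$feature_transform)) {
    t0 <- obj$feature_transform
    tr <- structure(list(z_means = t0$z_means, z_sds = t0$z_sds,
                         pca_components = as.matrix(t0$pca_components),
                         explained_ratio = t0$explained_ratio,
                         variance_threshold = t0$variance_threshold),
                    class = "feature_transform")
  }
  structure(list(beta0 = obj$beta0, beta = obj$beta, k = obj$k,
                 feature_transform = tr),
            class = "ridge_model")
}

#' Moving-average smoothing of a predicted force trace
#'
#' Centred moving average with the window truncated (shrunk) at the edges, so
#' the output has the input's length and no phase lag. `window = 1` is the
#' identity; constant inputs pass unchanged.
#'
#' @param pred Numeric vector (predicted force, N).
#' @param window Window size in samples (default 25, >= 1).
#' @return Smoothed numeric vector, same length as `pred`.
#' @export
smooth_prediction <- function(pred, window = 25) {
  if (window < 1) stop("smooth_prediction: window must be >= 1", call. = FALSE)
  n <- length(pred)
  if (window == 1 || n == 0) return(pred)
  lo_off <- floor((window - 1) / 2)
  hi_off <- ceiling((window - 1) / 2)
  cs <- cumsum(c(0, pred))
  i <- seq_len(n)
  lo <- pmax(1L, i - lo_off)
  hi <- pmin(n, i + hi_off)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; may be negative when the prediction is worse than
#' the mean of the truth.
#'
#' @param y_true Ground-truth vector (variance must be positive).
#' @param y_pred Prediction vector, same length.
#' @return A single number (dimensionless).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    stop("r_squared: need two equal-length vectors of length >= 2", call. = FALSE)
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot <= 0) {
    stop("r_squared: undefined for zero-variance ground truth", call. = FALSE)
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}
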