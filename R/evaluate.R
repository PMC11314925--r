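# Six-model comparison protocol: 5-fold cross-validation on the training
# trials, held-out testing on the last trial, per-model R^2 tables.

#' The six model input specifications
#'
#' One entry per model: the clinical-resolution single-site image, the
#' distributed model pooling all four wearable sensors, and the four
#' single-sensor models.
#'
#' @return Named list of `model_spec` objects (`name`, `streams`): the image
#'   streams of a `trial_dataset` each model consumes.
#' @export
default_model_specs <- function() {
  mk <- function(name, streams) {
    structure(list(name = name, streams = streams), class = "model_spec")
  }
  list(
    clinical    = mk("Clinical M-mode", "clinical"),
    distributed = mk("Distributed SMART-US", c("vl", "rf", "mh", "vmo")),
    vl          = mk("SMART-US: VL", "vl"),
    rf          = mk("SMART-US: RF", "rf"),
    mh          = mk("SMART-US: MH", "mh"),
    vmo         = mk("SMART-US: VMO", "vmo")
  )
}

# Pool features + force over the requested trials for one model spec.
# Returns list(values = frames x features matrix, y, trial = frame's trial).
assemble_features <- function(dataset, spec, roles,
                              window_px = 25, overlap = 0.5) {
  stopifnot(inherits(dataset, "trial_dataset"))
  keep <- Filter(function(tr) tr$role %in% roles, dataset$trials)
  if (length(keep) == 0) {
    stop(sprintf("no trials with role(s) %s", paste(roles, collapse = "/")),
         call. = FALSE)
  }
  blocks <- lapply(keep, function(tr) {
    missing <- setdiff(spec$streams, names(tr$images))
    if (length(missing) > 0) {
      stop(sprintf("model '%s': trial %d lacks image stream(s) %s",
                   spec$name, tr$index, paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    fm <- concat_sites(lapply(spec$streams, function(s) {
      extract_features(tr$images[[s]], window_px, overlap)
    }))
    if (nrow(fm$values) != length(tr$force_frames)) {
      stop(sprintf("trial %d: %d frames but %d force samples",
                   tr$index, nrow(fm$values), length(tr$force_frames)),
           call. = FALSE)
    }
    list(values = fm$values, y = tr$force_frames,
         trial = rep(tr$index, nrow(fm$values)))
  })
  list(values = do.call(rbind, lapply(blocks, `[[`, "values")),
       y = unlist(lapply(blocks, `[[`, "y")),
       trial = unlist(lapply(blocks, `[[`, "trial")))
}

#' k-fold cross-validation of one model on the training trials
#'
#' Frames from all training trials are pooled and randomly partitioned into
#' `k_folds` near-equal subsets (sizes differ by at most one). For each fold,
#' the feature transform (z-score + PCA) and the ridge model are fitted on
#' the other folds and R^2 is evaluated on the held-out fold. Refitting the
#' transform inside every fold is the leakage-safe default;
#' `refit_transform = FALSE` fits it once on all pooled training frames
#' (the literal single-pass reading). `blocked = TRUE` replaces the random
#' partition with contiguous segments, a sterner test when adjacent frames
#' are correlated.
#'
#' @param dataset A `trial_dataset`.
#' @param spec A `model_spec` (see [default_model_specs()]).
#' @param k_folds Number of folds (default 5).
#' @param k_ridge Ridge penalty (default 5).
#' @param variance_threshold PCA retention threshold (default 0.99).
#' @param window_px,overlap Feature-extraction window parameters.
#' @param refit_transform Refit z-score/PCA inside each fold (default TRUE).
#' @param blocked Use contiguous-segment folds instead of random frames.
#' @param smooth_validation Optional moving-average window applied to fold
#'   predictions before R^2 (default `NULL`: validation predictions are not
#'   smoothed; smoothing belongs to the testing path).
#' @param seed RNG seed for the fold assignment.
#' @return Numeric vector of `k_folds` fold R^2 values, with the fold
#'   assignment attached as attribute `"folds"`.
#' @export
kfold_cv <- function(dataset, spec, k_folds = 5, k_ridge = 5,
                     variance_threshold = 0.99,
                     window_px = 25, overlap = 0.5,
                     refit_transform = TRUE, blocked = FALSE,
                     smooth_validation = NULL, seed = 1L) {
  pooled <- assemble_features(dataset, spec, roles = "train",
                              window_px = window_px, overlap = overlap)
  n <- nrow(pooled$values)
  if (n < k_folds) {
    stop(sprintf("kfold_cv: %d frames cannot form %d folds", n, k_folds),
         call. = FALSE)
  }
  folds <- if (blocked) {
    sort(rep_len(seq_len(k_folds), n))
  } else {
    withr::with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  }
  global_tr <- if (!refit_transform) {
    fit_feature_transform(pooled$values, variance_threshold)
  }
  r2 <- vapply(seq_len(k_folds), function(f) {
    tr_idx <- folds != f
    tr <- if (refit_transform) {
      fit_feature_transform(pooled$values[tr_idx, , drop = FALSE],
                            variance_threshold)
    } else global_tr
    Xtr <- apply_feature_transform(tr, pooled$values[tr_idx, , drop = FALSE])
    Xte <- apply_feature_transform(tr, pooled$values[!tr_idx, , drop = FALSE])
    model <- fit_ridge(Xtr, pooled$y[tr_idx], k_ridge)
    pred <- predict(model, Xte)
    if (!is.null(smooth_validation)) {
      pred <- smooth_prediction(pred, smooth_validation)
    }
    r_squared(pooled$y[!tr_idx], pred)
  }, numeric(1))
  attr(r2, "folds") <- folds
  r2
}

#' Train on all training trials, test on the held-out trial
#'
#' The feature transform and ridge model are fitted on every training-trial
#' frame; the test trial's frames are projected and predicted, the prediction
#' is smoothed with a centred moving average (default window 25), and R^2
#' against the test trial's force is returned, one value per test trial.
#'
#' @inheritParams kfold_cv
#' @param smooth_window Moving-average window applied to the test prediction
#'   (default 25 samples).
#' @return Named numeric vector of per-test-trial R^2 (usually length 1),
#'   with the fitted `ridge_model` attached as attribute `"model"`.
#' @export
train_test <- function(dataset, spec, k_ridge = 5, smooth_window = 25,
                       variance_threshold = 0.99,
                       window_px = 25, overlap = 0.5) {
  train <- assemble_features(dataset, spec, roles = "train",
                             window_px = window_px, overlap = overlap)
  test <- assemble_features(dataset, spec, roles = "test",
                            window_px = window_px, overlap = overlap)
  tr <- fit_feature_transform(train$values, variance_threshold)
  model <- fit_ridge(apply_feature_transform(tr, train$values), train$y,
                     k_ridge, feature_transform = tr)
  out <- vapply(unique(test$trial), function(ti) {
    sel <- test$trial == ti
    pred <- predict(model, apply_feature_transform(tr, test$values[sel, , drop = FALSE]))
    r_squared(test$y[sel], smooth_prediction(pred, smooth_window))
  }, numeric(1))
  names(out) <- paste0("trial", unique(test$trial))
  attr(out, "model") <- model
  out
}

#' Run the full six-model comparison
#'
#' Cross-validates and tests every model spec on one dataset, assembling the
#' per-model mean/sd fold R^2 and test R^2 into an `evaluation_report`. Fully
#' deterministic given `seed`.
#'
#' @inheritParams kfold_cv
#' @param specs List of `model_spec` (default [default_model_specs()]).
#' @param smooth_window Test-path smoothing window.
#' @return An `evaluation_report`: `summary` data.frame (model, cv_mean,
#'   cv_sd, test_r2), `folds` data.frame (model, fold, split, r2), `seed`,
#'   and the evaluation `config`.
#' @export
run_comparison <- function(dataset, specs = default_model_specs(), seed = 1L,
                           k_folds = 5, k_ridge = 5, variance_threshold = 0.99,
                           window_px = 25, overlap = 0.5, smooth_window = 25,
                           refit_transform = TRUE, blocked = FALSE) {
  spec_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, length(specs)))
  rows <- list()
  folds_rows <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    cv <- kfold_cv(dataset, spec, k_folds, k_ridge, variance_threshold,
                   window_px, overlap, refit_transform, blocked,
                   seed = spec_seeds[i])
    tt <- train_test(dataset, spec, k_ridge, smooth_window,
                     variance_threshold, window_px, overlap)
    rows[[i]] <- data.frame(model = spec$name,
                            cv_mean = mean(cv), cv_sd = stats::sd(cv),
                            test_r2 = mean(tt))
    folds_rows[[i]] <- rbind(
      data.frame(model = spec$name, fold = seq_along(cv),
                 split = "validation", r2 = as.numeric(cv)),
      data.frame(model = spec$name, fold = NA_integer_,
                 split = "test", r2 = as.numeric(tt)))
  }
  structure(list(
    summary = do.call(rbind, rows),
    folds = do.call(rbind, folds_rows),
    seed = seed,
    config = list(k_folds = k_folds, k_ridge = k_ridge,
                  variance_threshold = variance_threshold,
                  window_px = window_px, overlap = overlap,
                  smooth_window = smooth_window,
                  refit_transform = refit_transform, blocked = blocked)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  s <- x$summary
  s$cv <- sprintf("%.3f +/- %.3f", s$cv_mean, s$cv_sd)
  s$test <- sprintf("%.3f", s$test_r2)
  print(s[, c("model", "cv", "test")], row.names = FALSE)
  invisible(x)
}

#' Write / read an evaluation report
#'
#' The report is written as JSON (summary, per-fold values, seed, config)
#' plus a flat CSV `<stem>.csv` with columns model, fold, split, r2 — the
#' table external statistical comparisons run on.
#'
#' @param report An `evaluation_report`.
#' @param path JSON path; the CSV goes to the same stem with `.csv`.
#' @return `write_report()` returns `path` invisibly; `read_report()` returns
#'   an `evaluation_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(
    list(summary = report$summary, folds = report$folds,
         seed = report$seed, config = report$config),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  utils::write.csv(report$folds, sub("\\.json$", ".csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(summary = as.data.frame(obj$summary),
                 folds = as.data.frame(obj$folds),
                 seed = obj$seed, config = obj$config),
            class = "evaluation_report")
}
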