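## Per-voxel encoding: one ROMP model per feature layer, per-layer
## validation accuracy, and optimal-layer selection.

#' Fit one sparse model per feature layer for a single voxel
#'
#' @param reduced A `reduced_features` (or `layer_feature_set`) whose
#'   per-layer `train` matrices form the regression designs.
#' @param y_train The voxel's training responses.
#' @param sparsity,tol ROMP parameters, see [fit_romp()].
#' @return A list of `romp_fit` objects, one per layer, with `layer_id`
#'   set.
#' @export
fit_voxel_all_layers <- function(reduced, y_train, sparsity = 20, tol = 1e-4) {
  stopifnot(inherits(reduced, c("reduced_features", "layer_feature_set")))
  lapply(reduced$layer_ids, function(l) {
    fit <- fit_romp(reduced$layers[[l]]$train, y_train, sparsity, tol)
    fit$layer_id <- l
    fit
  })
}

#' Select the optimal feature layer from per-layer accuracies
#'
#' The optimal layer is the argmax of the supplied accuracies; exact ties
#' break toward the lowest layer id.  Callers decide which accuracies to
#' rank: validation-set accuracies (the default throughout the pipeline)
#' or training-set cross-validated accuracies for a leakage-free variant
#' (see [encode_study()]'s `layer_selection`).
#'
#' @param accuracies Numeric vector of per-layer accuracies, ordered by
#'   layer id (names, if present, are returned instead of positions).
#' @return The selected layer id (integer position, or name).
#' @export
select_optimal_layer <- function(accuracies) {
  if (length(accuracies) == 0) {
    abort("`accuracies` must contain at least one layer.",
          class = "voxelencode_invalid_input")
  }
  i <- which.max(accuracies)  # first maximum == lowest layer id on ties
  if (!is.null(names(accuracies))) names(accuracies)[i] else as.integer(i)
}

#' Cross-validated per-layer accuracy for one voxel
#'
#' Deterministic interleaved fold assignment; per fold a ROMP model is fit
#' on the remaining folds, held-out predictions are pooled, and accuracy is
#' the Pearson correlation between pooled predictions and the responses.
#'
#' @param X Training design for one layer.
#' @param y Voxel training responses.
#' @param sparsity,tol ROMP parameters.
#' @param folds Number of folds (default 5).
#' @return A single correlation.
#' @export
cv_accuracy <- function(X, y, sparsity = 20, tol = 1e-4, folds = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- assert_count(folds, "folds")
  fold_id <- rep_len(seq_len(folds), n)
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    fit <- fit_romp(X[!hold, , drop = FALSE], y[!hold], sparsity, tol)
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  safe_cor(y, pred)
}

#' Encode every voxel of a study against every feature layer
#'
#' The full per-voxel workflow: reduce the layer features by PCA, fit one
#' ROMP model per layer per voxel on the training split, predict the
#' validation responses, score each layer by prediction accuracy (Pearson
#' correlation), and select each voxel's optimal layer.
#'
#' @param study A `synthetic_study` (or any object with the same
#'   `subjects` structure).
#' @param features Feature set to encode with; defaults to the study's own
#'   features (the generator-matched model).  Supplying a different
#'   `layer_feature_set` encodes the same responses under an alternative
#'   feature model.
#' @param n_components PCA components per layer (see [reduce_pca()]);
#'   `Inf` skips reduction and regresses on raw layer features.
#' @param sparsity,tol ROMP parameters.
#' @param layer_selection `"validation"` (argmax of validation accuracy,
#'   the default) or `"cv"` (argmax of 5-fold training cross-validated
#'   accuracy; leakage-free).
#' @param model_name Label attached to the result.
#' @return An `encoding_result` with `accuracies` (long tibble: subject,
#'   roi, voxel, layer, accuracy), `voxels` (per-voxel tibble with
#'   `optimal_layer` and best `accuracy`), and `predicted` /`measured`
#'   validation response matrices at the optimal layer.
#' @export
encode_study <- function(study, features = NULL, n_components = 1249,
                         sparsity = 20, tol = 1e-4,
                         layer_selection = c("validation", "cv"),
                         model_name = "model") {
  layer_selection <- match.arg(layer_selection)
  features <- features %||% study$features
  reduced <- if (is.infinite(n_components)) features else
    reduce_pca(features, n_components)
  designs <- lapply(reduced$layer_ids,
                    function(l) romp_prepare(reduced$layers[[l]]$train))
  val_feats <- lapply(reduced$layer_ids, function(l) reduced$layers[[l]]$val)
  L <- length(reduced$layer_ids)

  # CV selection: fold designs are shared by every voxel, prepare them once
  n_folds <- 5L
  if (layer_selection == "cv") {
    n_tr <- nrow(reduced$layers[[1]]$train)
    fold_id <- rep_len(seq_len(n_folds), n_tr)
    cv_designs <- lapply(reduced$layer_ids, function(l) {
      lapply(seq_len(n_folds), function(f) {
        romp_prepare(reduced$layers[[l]]$train[fold_id != f, , drop = FALSE])
      })
    })
    cv_heldout <- lapply(reduced$layer_ids, function(l) {
      lapply(seq_len(n_folds), function(f) {
        reduced$layers[[l]]$train[fold_id == f, , drop = FALSE]
      })
    })
  }

  acc_rows <- list()
  vox_rows <- list()
  predicted <- list()
  measured <- list()
  for (s in names(study$subjects)) {
    predicted[[s]] <- list()
    measured[[s]] <- list()
    for (rn in names(study$subjects[[s]])) {
      ds <- study$subjects[[s]][[rn]]
      V <- ncol(ds$train)
      acc <- matrix(NA_real_, L, V)
      opt <- integer(V)
      pred_opt <- matrix(NA_real_, nrow(ds$val), V)
      for (v in seq_len(V)) {
        preds <- matrix(NA_real_, nrow(ds$val), L)
        for (l in seq_len(L)) {
          fit <- fit_romp(designs[[l]], ds$train[, v], sparsity, tol)
          preds[, l] <- predict(fit, val_feats[[l]])
          acc[l, v] <- safe_cor(ds$val[, v], preds[, l])
        }
        rank_by <- if (layer_selection == "cv") {
          vapply(seq_len(L), function(l) {
            cvp <- numeric(length(fold_id))
            for (f in seq_len(n_folds)) {
              fit <- fit_romp(cv_designs[[l]][[f]], ds$train[fold_id != f, v],
                              sparsity, tol)
              cvp[fold_id == f] <- predict(fit, cv_heldout[[l]][[f]])
            }
            safe_cor(ds$train[, v], cvp)
          }, numeric(1))
        } else {
          acc[, v]
        }
        opt[v] <- select_optimal_layer(rank_by)
        pred_opt[, v] <- preds[, opt[v]]
      }
      acc_rows[[length(acc_rows) + 1L]] <- tibble(
        subject = s, roi = rn,
        voxel = rep(seq_len(V), each = L),
        layer = rep(seq_len(L), V),
        accuracy = as.numeric(acc)
      )
      vox_rows[[length(vox_rows) + 1L]] <- tibble(
        subject = s, roi = rn, voxel = seq_len(V),
        optimal_layer = opt,
        accuracy = acc[cbind(opt, seq_len(V))]
      )
      predicted[[s]][[rn]] <- pred_opt
      measured[[s]][[rn]] <- ds$val
    }
  }
  structure(list(
    model = model_name,
    accuracies = list_rbind(acc_rows),
    voxels = list_rbind(vox_rows),
    predicted = predicted,
    measured = measured,
    params = list(n_components = n_components, sparsity = sparsity,
                  tol = tol, layer_selection = layer_selection),
    layer_ids = reduced$layer_ids
  ), class = "encoding_result")
}

#' @export
print.encoding_result <- function(x, ...) {
  cat(sprintf("<encoding_result> model '%s': %d voxels x %d layers\n",
              x$model, nrow(x$voxels), length(x$layer_ids)))
  cat(sprintf("  mean best accuracy %.3f (selection: %s)\n",
              mean(x$voxels$accuracy), x$params$layer_selection))
  invisible(x)
}

#' Tidy an encoding result
#'
#' @param x An `encoding_result`.
#' @param ... Unused.
#' @return The long per-voxel-per-layer accuracy tibble.
#' @export
tidy.encoding_result <- function(x, ...) x$accuracies

#' One-row summary of an encoding result
#'
#' @param x An `encoding_result`.
#' @param ... Unused.
#' @return A tibble with voxel counts and accuracy summaries.
#' @export
glance.encoding_result <- function(x, ...) {
  tibble(model = x$model, n_voxels = nrow(x$voxels),
         n_layers = length(x$layer_ids),
         mean_accuracy = mean(x$voxels$accuracy),
         median_accuracy = median(x$voxels$accuracy))
}

# Flatten an encoding result's optimal-layer predictions and measured
# validation responses to aligned matrices (stimuli x all voxels), with a
# key tibble describing the columns.
collect_val_matrices <- function(enc) {
  keys <- list()
  pr <- list()
  me <- list()
  for (s in names(enc$predicted)) {
    for (rn in names(enc$predicted[[s]])) {
      keys[[length(keys) + 1L]] <- tibble(
        subject = s, roi = rn, voxel = seq_len(ncol(enc$predicted[[s]][[rn]])))
      pr[[length(pr) + 1L]] <- enc$predicted[[s]][[rn]]
      me[[length(me) + 1L]] <- enc$measured[[s]][[rn]]
    }
  }
  list(key = list_rbind(keys), predicted = do.call(cbind, pr),
       measured = do.call(cbind, me))
}
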