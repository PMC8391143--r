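## Feature-space reduction: per-layer PCA fitted on the training split only,
## plus a pluggable extractor registry so real-network feature extractors can
## stand in for the built-in synthetic cascade.

#' Reduce each layer's features by PCA
#'
#' PCA is fitted per layer on the training split only (mean-centering, no
#' variance scaling); training and validation splits are then projected with
#' the training means and loadings, so no validation information leaks into
#' the design matrix.  The number of retained components per layer is
#' `min(n_components, d_layer, n_train - 1)`.  Component signs are fixed so
#' the largest-magnitude loading of each component is positive, making the
#' reduced design (and downstream regression weights) reproducible.
#'
#' @param features A `layer_feature_set`.
#' @param n_components Requested number of components (the regression
#'   design width before the constant term); default 1249.
#' @return A `reduced_features` object: per layer `train` and `val` score
#'   matrices, the training `center`, the `loadings`, and the component
#'   standard deviations.
#' @export
reduce_pca <- function(features, n_components = 1249) {
  stopifnot(inherits(features, "layer_feature_set"))
  n_components <- assert_count(n_components, "n_components")
  layers <- lapply(features$layer_ids, function(l) {
    tr <- features$layers[[l]]$train
    va <- features$layers[[l]]$val
    if (all(apply(tr, 2, sd) == 0)) {
      abort(sprintf("Layer %d has zero variance on the training split; PCA is undefined.", l),
            class = "voxelencode_degenerate_layer")
    }
    p <- min(n_components, ncol(tr), nrow(tr) - 1L)
    fit <- prcomp(tr, center = TRUE, scale. = FALSE, rank. = p)
    rot <- fit$rotation
    # deterministic sign: largest-|loading| entry of each component positive
    flip <- vapply(seq_len(ncol(rot)), function(j) {
      i <- which.max(abs(rot[, j]))
      rot[i, j] < 0
    }, logical(1))
    rot[, flip] <- -rot[, flip]
    scores_tr <- fit$x
    scores_tr[, flip] <- -scores_tr[, flip]
    scores_va <- sweep(va, 2, fit$center) %*% rot
    list(train = scores_tr, val = scores_va, center = fit$center,
         loadings = rot, sdev = fit$sdev[seq_len(p)])
  })
  structure(list(layer_ids = features$layer_ids, layers = layers,
                 stim_ids = features$stim_ids,
                 n_components = vapply(layers, function(x) ncol(x$train), integer(1))),
            class = "reduced_features")
}

#' @export
print.reduced_features <- function(x, ...) {
  cat(sprintf("<reduced_features> %d layer(s), components: %s\n",
              length(x$layer_ids),
              paste(x$n_components, collapse = ", ")))
  invisible(x)
}

## ---- extractor registry -----------------------------------------------

.extractors <- new.env(parent = emptyenv())

#' Register a feature extractor
#'
#' Extractors turn a stimulus description into a `layer_feature_set`.  The
#' built-in `"synthetic"` extractor is the random ReLU cascade
#' ([make_layer_features()]); extractors for real pretrained networks can be
#' registered under the same contract.
#'
#' @param name Extractor name.
#' @param fun A function called as `fun(stimuli, ...)` returning a
#'   `layer_feature_set`.
#' @export
register_extractor <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .extractors)
  invisible(name)
}

#' List registered extractor names
#' @export
list_extractors <- function() sort(ls(.extractors))

#' Extract layer features through a registered extractor
#'
#' @param extractor Name of a registered extractor.
#' @param stimuli Stimulus description handed to the extractor.  For the
#'   built-in `"synthetic"` extractor this is a list with `n_train`,
#'   `n_val`, `layer_dims` and `seed`.
#' @param ... Further arguments passed to the extractor.
#' @return A validated `layer_feature_set`.
#' @export
extract_layers <- function(extractor, stimuli, ...) {
  if (!is.character(extractor) || length(extractor) != 1L ||
      !exists(extractor, envir = .extractors, inherits = FALSE)) {
    abort(sprintf("Unknown extractor '%s'. Registered extractors: %s.",
                  as.character(extractor)[1],
                  paste(list_extractors(), collapse = ", ")),
          class = "voxelencode_unknown_extractor")
  }
  fun <- get(extractor, envir = .extractors)
  out <- fun(stimuli, ...)
  validate_layer_feature_set(out)
}

validate_layer_feature_set <- function(x) {
  if (!inherits(x, "layer_feature_set")) {
    abort("Extractor did not return a `layer_feature_set`.",
          class = "voxelencode_invalid_features")
  }
  ntr <- unique(vapply(x$layers, function(l) nrow(l$train), integer(1)))
  nva <- unique(vapply(x$layers, function(l) nrow(l$val), integer(1)))
  if (length(ntr) != 1L || length(nva) != 1L) {
    abort("Layer feature matrices have inconsistent row counts across layers.",
          class = "voxelencode_invalid_features")
  }
  bad <- vapply(x$layers, function(l) anyNA(l$train) || anyNA(l$val), logical(1))
  if (any(bad)) {
    abort(sprintf("Missing values in layer(s) %s.",
                  paste(which(bad), collapse = ", ")),
          class = "voxelencode_invalid_features")
  }
  x
}

# Built-in synthetic extractor: delegates to the seeded ReLU cascade.
register_extractor("synthetic", function(stimuli, ...) {
  make_layer_features(stimuli$n_train, stimuli$n_val, stimuli$layer_dims,
                      seed = stimuli$seed %||% 1L)
})
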