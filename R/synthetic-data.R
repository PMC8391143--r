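## Synthetic studies: hierarchical layer features, sparse voxel readouts,
## ROI-specific layer preferences, repeated noisy validation runs.  Every
## draw is seeded and ground truth is recorded, so recovery of generating
## layers, supports and noise levels can be checked exactly.

#' Default retinotopic-to-category ROI set
#'
#' Seven regions of interest mirroring the ventral-stream hierarchy: V1-V3
#' (lower visual cortex, LVC), V4, and LOC/PPA/FFA (higher visual cortex,
#' HVC).  Each ROI carries a discrete preference distribution over feature
#' layers: a normalised Gaussian bump whose centre moves from early layers
#' (V1) to late layers (FFA), so simulated LVC voxels read out low-level
#' features and HVC voxels high-level ones.
#'
#' @param n_layers Number of feature layers the preferences range over.
#' @param n_voxels Voxels per ROI (same for all seven).
#' @param spread Standard deviation of the preference bump, in layers.
#'   Defaults to `n_layers / 10`, a gradient comparable to optimal-layer
#'   distributions reported for human ventral stream.
#' @return A list of ROI specifications, each with `name`, `n_voxels` and
#'   `layer_preference` (a probability vector over `1:n_layers`).
#' @export
default_rois <- function(n_layers, n_voxels = 60, spread = max(0.75, n_layers / 10)) {
  n_layers <- assert_count(n_layers, "n_layers")
  n_voxels <- assert_count(n_voxels, "n_voxels")
  names <- c("V1", "V2", "V3", "V4", "LOC", "PPA", "FFA")
  fracs <- c(0.05, 0.18, 0.32, 0.50, 0.68, 0.82, 0.95)
  centers <- 1 + fracs * (n_layers - 1)
  lapply(seq_along(names), function(i) {
    pref <- dnorm(seq_len(n_layers), mean = centers[i], sd = spread)
    roi_spec(names[i], n_voxels, pref / sum(pref))
  })
}

#' Construct a single ROI specification
#'
#' @param name ROI label (e.g. "V1").
#' @param n_voxels Number of voxels.
#' @param layer_preference Probability vector over layers from which each
#'   voxel's generating layer is drawn; must sum to 1.
#' @return A `roi_spec` list.
#' @export
roi_spec <- function(name, n_voxels, layer_preference) {
  n_voxels <- assert_count(n_voxels, "n_voxels")
  if (!is.numeric(layer_preference) || any(layer_preference < 0) ||
      abs(sum(layer_preference) - 1) > 1e-8) {
    abort("`layer_preference` must be a non-negative vector summing to 1.",
          class = "voxelencode_invalid_config")
  }
  structure(list(name = as.character(name), n_voxels = n_voxels,
                 layer_preference = as.numeric(layer_preference)),
            class = "roi_spec")
}

#' Configuration of a synthetic encoding study
#'
#' Defaults follow the generic-object-decoding design the pipeline targets:
#' 5 subjects, 1200 training and 50 validation stimuli, 18 feature layers,
#' 35 repeated validation runs, and the seven-ROI ventral-stream set.
#'
#' @param n_subjects Number of subjects.
#' @param n_train,n_val Training / validation stimulus counts.
#' @param n_layers Number of feature layers in the synthetic hierarchy.
#' @param layer_dims Integer vector of layer widths (length `n_layers`).
#' @param rois List of [roi_spec()] objects; preferences must span
#'   `n_layers` layers.
#' @param k_true Support size of each voxel's sparse readout.
#' @param snr Signal-to-noise ratio (signal sd / noise sd, unitless) of the
#'   observed responses; clean responses have unit variance, so noise sd is
#'   `1/snr`.
#' @param n_runs Repeated validation runs per subject.
#' @param run_noise_sd Standard deviation of the additional per-run
#'   measurement noise (response units).
#' @param n_train_categories,n_val_categories Category labels attached to
#'   stimuli for schema fidelity; the pipeline itself never uses them.
#' @param seed Master seed; all child seeds derive from it by a fixed
#'   counter scheme.
#' @return A `study_config` list, validated.
#' @export
study_config <- function(n_subjects = 5, n_train = 1200, n_val = 50,
                         n_layers = 18, layer_dims = rep(200L, n_layers),
                         rois = default_rois(n_layers), k_true = 10,
                         snr = 2, n_runs = 35, run_noise_sd = 4,
                         n_train_categories = 150, n_val_categories = 50,
                         seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  n_train <- assert_count(n_train, "n_train")
  n_val <- assert_count(n_val, "n_val")
  n_layers <- assert_count(n_layers, "n_layers")
  n_runs <- assert_count(n_runs, "n_runs")
  k_true <- assert_count(k_true, "k_true")
  snr <- assert_positive(snr, "snr")
  if (run_noise_sd < 0) {
    abort("`run_noise_sd` must be >= 0.", class = "voxelencode_invalid_config")
  }
  layer_dims <- vapply(layer_dims, assert_count, integer(1), name = "layer_dims")
  if (length(layer_dims) != n_layers) {
    abort("`layer_dims` must have length `n_layers`.",
          class = "voxelencode_invalid_config")
  }
  if (k_true > min(layer_dims)) {
    abort("`k_true` cannot exceed the smallest layer dimension.",
          class = "voxelencode_invalid_config")
  }
  rois <- lapply(rois, function(r) {
    if (!inherits(r, "roi_spec")) r <- do.call(roi_spec, r)
    if (length(r$layer_preference) != n_layers) {
      abort(sprintf("ROI '%s': layer preference length %d != n_layers %d.",
                    r$name, length(r$layer_preference), n_layers),
            class = "voxelencode_invalid_config")
    }
    r
  })
  structure(list(n_subjects = n_subjects, n_train = n_train, n_val = n_val,
                 n_layers = n_layers, layer_dims = layer_dims, rois = rois,
                 k_true = k_true, snr = snr, n_runs = n_runs,
                 run_noise_sd = as.numeric(run_noise_sd),
                 n_train_categories = assert_count(n_train_categories, "n_train_categories"),
                 n_val_categories = assert_count(n_val_categories, "n_val_categories"),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Generate a hierarchical layer feature set
#'
#' Layer 1 is i.i.d. standard Gaussian.  Each subsequent layer is a random
#' ReLU map of the previous one: `phi(X A + b)` with `phi = max(0, .)`,
#' `A` i.i.d. Gaussian scaled by `1/sqrt(d_in)` and Gaussian bias `b`.  The
#' same map is applied to training and validation stimuli, and every
#' layer's columns are standardized (centered, unit variance) using
#' training-split statistics; near-dead columns -- ReLU units that barely
#' activate on the training split -- are centered but not rescaled, so no
#' column can blow up on held-out stimuli.  The cascade yields nested,
#' progressively transformed representations: enough hierarchical structure
#' to exercise layer assignment without any trained network.
#'
#' @param n_train,n_val Row counts of the two splits.
#' @param layer_dims Widths of the layers, in order.
#' @param seed Seed; the output is bit-identical for identical inputs.
#' @return A `layer_feature_set`: per layer a `train` and `val` matrix,
#'   plus stimulus ids.
#' @export
make_layer_features <- function(n_train, n_val, layer_dims, seed = 1L) {
  n_train <- assert_count(n_train, "n_train", min = 2L)
  n_val <- assert_count(n_val, "n_val")
  if (length(layer_dims) == 0) {
    abort("`layer_dims` must be non-empty.", class = "voxelencode_invalid_config")
  }
  layer_dims <- vapply(layer_dims, function(d) assert_count(d, "layer_dims", min = 2L),
                       integer(1))
  with_seed(seed, {
    n <- n_train + n_val
    layers <- vector("list", length(layer_dims))
    X <- matrix(rnorm(n * layer_dims[1]), n, layer_dims[1])
    X <- standardize_train(X, n_train)
    layers[[1]] <- X
    for (l in seq_along(layer_dims)[-1]) {
      A <- matrix(rnorm(layer_dims[l - 1] * layer_dims[l]), layer_dims[l - 1]) /
        sqrt(layer_dims[l - 1])
      # bias scale 0.5: pre-activations are ~N(b, 1), so every unit keeps a
      # non-degenerate activation rate; larger bias spread creates units that
      # fire on a handful of stimuli, whose standardized features are
      # ill-conditioned spikes
      b <- rnorm(layer_dims[l], sd = 0.5)
      Z <- sweep(layers[[l - 1]] %*% A, 2, -b)
      Z[Z < 0] <- 0
      layers[[l]] <- standardize_train(Z, n_train)
    }
    train_ids <- sprintf("trn%05d", seq_len(n_train))
    val_ids <- sprintf("val%05d", seq_len(n_val))
    structure(list(
      layer_ids = seq_along(layer_dims),
      layers = lapply(layers, function(M) {
        list(train = M[seq_len(n_train), , drop = FALSE],
             val = M[n_train + seq_len(n_val), , drop = FALSE])
      }),
      stim_ids = list(train = train_ids, val = val_ids),
      n_train = n_train, n_val = n_val, layer_dims = layer_dims
    ), class = "layer_feature_set")
  })
}

# Standardize each column (center and scale to unit variance) using
# statistics of the first n_train rows.  Centering keeps deep cascade
# layers well-behaved: without it the shared positive mode of ReLU outputs
# dominates the next layer's pre-activations, and units that barely
# activate on the training split blow up on validation stimuli once
# rescaled.  Near-dead columns (train sd below the floor) are left
# unscaled; they carry no usable signal either way.
standardize_train <- function(M, n_train) {
  tr <- M[seq_len(n_train), , drop = FALSE]
  mu <- colMeans(tr)
  s <- apply(tr, 2, sd)
  s[s < 1e-3 | !is.finite(s)] <- 1
  sweep(sweep(M, 2, mu), 2, s, "/")
}

#' Simulate voxel responses for one ROI
#'
#' Each voxel draws a generating layer from the ROI's layer-preference
#' distribution, a support of `k_true` feature columns uniformly without
#' replacement, and i.i.d. standard Gaussian readout weights.  The clean
#' response (support columns times weights) is standardised to zero mean
#' and unit variance using training-split statistics, then observed train
#' and validation responses add Gaussian noise of sd `1/snr`, so that
#' cor(clean, observed) has expectation `snr/sqrt(snr^2+1)`.  Each of
#' `n_runs` validation runs adds further independent Gaussian run noise of
#' sd `run_noise_sd` to the observed validation signal.
#'
#' @param features A [make_layer_features()] result.
#' @param roi A [roi_spec()].
#' @param k_true Support size per voxel.
#' @param snr Signal-to-noise ratio of observed responses.
#' @param n_runs Number of repeated validation runs.
#' @param run_noise_sd Per-run measurement noise sd.
#' @param seed Seed.
#' @return A `voxel_dataset`: `train` (n_train x V), `val` (n_val x V),
#'   `runs` (n_runs x n_val x V array) and a `truth` tibble (generating
#'   layer, support, weights, noise sd per voxel).
#' @export
make_voxel_responses <- function(features, roi, k_true, snr, n_runs = 35,
                                 run_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(features, "layer_feature_set"))
  if (!inherits(roi, "roi_spec")) roi <- do.call(roi_spec, roi)
  k_true <- assert_count(k_true, "k_true")
  snr <- assert_positive(snr, "snr")
  n_runs <- assert_count(n_runs, "n_runs")
  if (length(roi$layer_preference) != length(features$layer_ids)) {
    abort("ROI layer preference length does not match the number of layers.",
          class = "voxelencode_invalid_config")
  }
  if (k_true > min(features$layer_dims)) {
    abort("`k_true` exceeds the smallest layer dimension.",
          class = "voxelencode_invalid_config")
  }
  n_train <- features$n_train
  n_val <- features$n_val
  V <- roi$n_voxels
  noise_sd <- 1 / snr
  with_seed(seed, {
    train <- matrix(0, n_train, V)
    val <- matrix(0, n_val, V)
    clean_train <- matrix(0, n_train, V)
    clean_val <- matrix(0, n_val, V)
    gl <- integer(V)
    supports <- vector("list", V)
    weights <- vector("list", V)
    for (v in seq_len(V)) {
      gl[v] <- sample.int(length(roi$layer_preference), 1L,
                          prob = roi$layer_preference)
      d <- features$layer_dims[gl[v]]
      supports[[v]] <- sort(sample.int(d, k_true))
      weights[[v]] <- rnorm(k_true)
      ctr <- features$layers[[gl[v]]]$train[, supports[[v]], drop = FALSE] %*% weights[[v]]
      cva <- features$layers[[gl[v]]]$val[, supports[[v]], drop = FALSE] %*% weights[[v]]
      mu <- mean(ctr)
      sc <- sd(ctr)
      if (sc == 0) sc <- 1
      clean_train[, v] <- (ctr - mu) / sc
      clean_val[, v] <- (cva - mu) / sc
      train[, v] <- clean_train[, v] + rnorm(n_train, sd = noise_sd)
      val[, v] <- clean_val[, v] + rnorm(n_val, sd = noise_sd)
    }
    runs <- array(rep(val, each = n_runs), dim = c(n_runs, n_val, V))
    if (run_noise_sd > 0) {
      runs <- runs + array(rnorm(n_runs * n_val * V, sd = run_noise_sd),
                           dim = dim(runs))
    }
    truth <- tibble(
      roi = roi$name,
      voxel = seq_len(V),
      generating_layer = gl,
      support = supports,
      weights = weights,
      noise_sd = noise_sd
    )
    structure(list(roi = roi$name, train = train, val = val, runs = runs,
                   clean_train = clean_train, clean_val = clean_val,
                   truth = truth, n_runs = n_runs,
                   run_noise_sd = as.numeric(run_noise_sd)),
              class = "voxel_dataset")
  })
}

#' Generate a complete multi-subject synthetic study
#'
#' One shared [make_layer_features()] feature set; per subject and ROI an
#' independent [make_voxel_responses()] draw.  Child seeds derive from the
#' master seed by a fixed counter scheme (feature stream 1; subject `s`,
#' ROI `r` stream `100 s + r`), so adding subjects or ROIs never perturbs
#' earlier draws.  Category labels are attached to stimuli for schema
#' fidelity but are unused downstream.
#'
#' @param config A [study_config()].
#' @return A `synthetic_study`: `features`, `subjects` (list of per-ROI
#'   `voxel_dataset`s), pooled `truth` tibble, `categories`, `config`.
#' @export
make_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  features <- make_layer_features(config$n_train, config$n_val,
                                  config$layer_dims,
                                  seed = derive_seed(config$seed, 1L))
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    rois <- lapply(seq_along(config$rois), function(r) {
      make_voxel_responses(features, config$rois[[r]], config$k_true,
                           config$snr, config$n_runs, config$run_noise_sd,
                           seed = derive_seed(config$seed, 100L * s + r))
    })
    names(rois) <- vapply(config$rois, `[[`, character(1), "name")
    rois
  })
  names(subjects) <- sprintf("S%d", seq_len(config$n_subjects))
  truth <- list_rbind(lapply(names(subjects), function(s) {
    mutate(list_rbind(lapply(subjects[[s]], `[[`, "truth")), subject = s,
           .before = 1)
  }))
  categories <- list(
    train = ((seq_len(config$n_train) - 1L) %% config$n_train_categories) + 1L,
    val = ((seq_len(config$n_val) - 1L) %% config$n_val_categories) + 1L
  )
  structure(list(features = features, subjects = subjects, truth = truth,
                 categories = categories, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic_study> %d subject(s), %d ROI(s) x %s voxels, %d layers\n",
    cfg$n_subjects, length(cfg$rois),
    paste(unique(vapply(cfg$rois, `[[`, integer(1), "n_voxels")), collapse = "/"),
    cfg$n_layers))
  cat(sprintf("  %d train / %d val stimuli, %d validation runs, snr = %g\n",
              cfg$n_train, cfg$n_val, cfg$n_runs, cfg$snr))
  invisible(x)
}

#' Tidy the ground truth of a synthetic study
#'
#' @param x A `synthetic_study`.
#' @param ... Unused.
#' @return A tibble with one row per voxel: subject, roi, voxel,
#'   generating layer, support, weights, noise sd.
#' @export
tidy.synthetic_study <- function(x, ...) x$truth
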