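## Orchestration and report tables shaped like the standard figures of a
## voxel-wise encoding study: ROI accuracy summaries, model-advantage
## tables, optimal-layer distributions, per-layer accuracy curves, and
## ROI-level RSA scores.

#' Pipeline configuration
#'
#' Bundles the synthetic-study configuration, the feature models to
#' compare, and all analysis parameters.  The default study is a
#' desk-scale instance of the target design (5 subjects, 7 ROIs x 60
#' voxels, 8 layers x 200 features, 300 train / 50 validation stimuli, 35
#' runs) chosen so a full two-model run completes in minutes; all sizes
#' scale up through `study`.
#'
#' The default model pair compares the study's own generating features
#' (`"study"`) with a degraded copy (`"study_noisy"`: the same features
#' plus i.i.d. Gaussian feature noise), a controlled stand-in for two
#' network variants of different encoding quality.
#'
#' @param study A [study_config()].
#' @param models Named list of feature sources: `"study"`, a list
#'   `list(type = "study_noisy", sd = , stream = )`, or a list
#'   `list(extractor = , stimuli = )` resolved through [extract_layers()].
#' @param n_components,sparsity,tol,layer_selection Encoding parameters
#'   (see [encode_study()]).
#' @param n_perm,alpha Randomization-test parameters.
#' @param adv_alpha Advantage permutation-test level.
#' @param top_k Voxels per subject in ROI summaries and accuracy curves.
#' @param n_sim Noise-ceiling simulations.
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(study = NULL,
                            models = list(
                              modelA = "study",
                              modelB = list(type = "study_noisy", sd = 0.7,
                                            stream = 7777L)),
                            n_components = 1249, sparsity = 20, tol = 1e-4,
                            layer_selection = "validation",
                            n_perm = 1000, alpha = 0.001, adv_alpha = 0.05,
                            top_k = 100, n_sim = 1000, seed = 1L) {
  seed <- as.integer(seed)
  study <- study %||% study_config(
    n_subjects = 5, n_train = 300, n_val = 50, n_layers = 8,
    layer_dims = rep(200L, 8), rois = default_rois(8, 60),
    k_true = 10, snr = 2, n_runs = 35, run_noise_sd = 4, seed = seed)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    abort("`models` must be a named list.", class = "voxelencode_invalid_config")
  }
  if (alpha <= 0 || alpha >= 1 || adv_alpha <= 0 || adv_alpha >= 1) {
    abort("alpha levels must be in (0, 1).", class = "voxelencode_invalid_config")
  }
  structure(list(study = study, models = models,
                 n_components = n_components, sparsity = sparsity, tol = tol,
                 layer_selection = layer_selection, n_perm = n_perm,
                 alpha = alpha, adv_alpha = adv_alpha, top_k = top_k,
                 n_sim = n_sim, seed = seed),
            class = "pipeline_config")
}

# Resolve a model's feature source against the simulated study.
resolve_features <- function(source, study, seed) {
  if (identical(source, "study")) return(study$features)
  if (is.list(source) && identical(source$type, "study_noisy")) {
    return(perturb_features(study$features, sd = source$sd %||% 0.7,
                            seed = derive_seed(seed, source$stream %||% 7777L)))
  }
  if (is.list(source) && !is.null(source$extractor)) {
    return(extract_layers(source$extractor, source$stimuli))
  }
  abort("Unrecognised feature source.", class = "voxelencode_invalid_config")
}

#' Add Gaussian feature noise to a layer feature set
#'
#' Every layer matrix (train and validation) receives i.i.d. Gaussian
#' noise of the given sd, degrading its predictive value while keeping
#' the representational structure; a controlled second model for
#' advantage comparisons.
#'
#' @param features A `layer_feature_set`.
#' @param sd Noise standard deviation (features are unit variance).
#' @param seed Seed.
#' @return A perturbed `layer_feature_set`.
#' @export
perturb_features <- function(features, sd = 0.7, seed = 1L) {
  stopifnot(inherits(features, "layer_feature_set"))
  with_seed(seed, {
    out <- features
    for (l in features$layer_ids) {
      for (split in c("train", "val")) {
        M <- out$layers[[l]][[split]]
        out$layers[[l]][[split]] <- M + matrix(rnorm(length(M), sd = sd),
                                               nrow(M), ncol(M))
      }
    }
    out
  })
}

#' Significance table for an encoding result
#'
#' Applies [randomization_threshold()] to all voxels of an encoding
#' result at once (pooled across subjects and ROIs by default, matching a
#' single global cutoff).
#'
#' @param enc An `encoding_result`.
#' @param n_perm,alpha,pooling,seed See [randomization_threshold()].
#' @return A list: `result` (the `significance_result`) and `table`
#'   (tibble subject, roi, voxel, accuracy, threshold, accurate).
#' @export
study_significance <- function(enc, n_perm = 1000, alpha = 0.001,
                               pooling = "pooled", seed = 1L) {
  mats <- collect_val_matrices(enc)
  res <- randomization_threshold(mats$measured, mats$predicted,
                                 n_perm = n_perm, alpha = alpha,
                                 pooling = pooling, seed = seed)
  tbl <- mats$key
  tbl$accuracy <- res$accuracy
  tbl$threshold <- if (identical(pooling, "pooled"))
    rep(res$threshold, nrow(tbl)) else res$threshold
  tbl$accurate <- res$mask
  list(result = res, table = tbl)
}

#' Distribution of optimal feature layers per ROI
#'
#' Among accurately predicted voxels (pooled across subjects), the
#' fraction per ROI whose optimal layer is each layer.  Fractions sum to
#' 1 within an ROI; ROIs without accurate voxels are flagged empty.
#'
#' @param enc An `encoding_result`.
#' @param mask Tibble with subject, roi, voxel, accurate (from
#'   [study_significance()]`$table`); omit to use all voxels.
#' @return Tibble: roi, layer, n_accurate, fraction, empty.
#' @export
report_layer_distribution <- function(enc, mask = NULL) {
  vox <- enc$voxels
  if (!is.null(mask)) {
    vox <- left_join(vox, select(mask, "subject", "roi", "voxel", "accurate"),
                     by = c("subject", "roi", "voxel")) |>
      filter(.data$accurate)
  }
  grid <- tidyr::expand_grid(roi = unique(enc$voxels$roi),
                             layer = enc$layer_ids)
  counts <- vox |>
    group_by(.data$roi, layer = .data$optimal_layer) |>
    summarise(count = n(), .groups = "drop")
  grid |>
    left_join(counts, by = c("roi", "layer")) |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count)) |>
    group_by(.data$roi) |>
    mutate(n_accurate = sum(.data$count),
           fraction = ifelse(.data$n_accurate > 0,
                             .data$count / .data$n_accurate, NA_real_),
           empty = .data$n_accurate == 0) |>
    ungroup() |>
    select("roi", "layer", "n_accurate", "fraction", "empty") |>
    arrange(.data$roi, .data$layer)
}

#' Per-layer accuracy curves
#'
#' For each ROI and layer, the mean prediction accuracy of the `top_k`
#' voxels with the highest accuracy at that layer, per subject and pooled
#' across subjects -- the layer-by-layer encoding-ability curve.
#'
#' @param enc An `encoding_result`.
#' @param top_k Voxels per subject (default 100; ROIs with fewer use all,
#'   with a warning).
#' @return Tibble: roi, layer, n, mean_accuracy.
#' @export
report_layer_accuracy_curves <- function(enc, top_k = 100) {
  top_k <- assert_count(top_k, "top_k")
  n_vox <- enc$accuracies |>
    group_by(.data$subject, .data$roi) |>
    summarise(n = dplyr::n_distinct(.data$voxel), .groups = "drop")
  if (any(n_vox$n < top_k)) {
    warn(sprintf("Some subject-ROI groups have fewer than top_k = %d voxels; using all.",
                 top_k))
  }
  enc$accuracies |>
    group_by(.data$subject, .data$roi, .data$layer) |>
    slice_max(.data$accuracy, n = top_k, with_ties = FALSE) |>
    group_by(.data$roi, .data$layer) |>
    summarise(n = n(), mean_accuracy = mean(.data$accuracy),
              .groups = "drop")
}

#' Model-advantage table for two encoding models
#'
#' For each subject and ROI group, restricts to voxels accurately
#' predicted by both models, computes each model's advantage (percent of
#' voxels it predicts better), the permutation threshold `x`, and
#' significance flags.
#'
#' @param enc_a,enc_b `encoding_result`s of the two models over the same
#'   study.
#' @param sig_a,sig_b Matching [study_significance()] outputs.
#' @param groups Named list of ROI groupings (default `LVC + V4` =
#'   V1-V4 and `HVC` = LOC/PPA/FFA).
#' @param n_perm,alpha,seed Advantage permutation-test parameters.
#' @return Tibble: subject, group, n_common, fraction_a, fraction_b,
#'   threshold_x, significant_a, significant_b, undefined.
#' @export
advantage_table <- function(enc_a, enc_b, sig_a, sig_b,
                            groups = list(`LVC + V4` = c("V1", "V2", "V3", "V4"),
                                          HVC = c("LOC", "PPA", "FFA")),
                            n_perm = 1000, alpha = 0.05, seed = 1L) {
  key_cols <- c("subject", "roi", "voxel")
  tbl <- left_join(
    sig_a$table |> select(dplyr::all_of(key_cols), acc_a = "accuracy",
                          ok_a = "accurate"),
    sig_b$table |> select(dplyr::all_of(key_cols), acc_b = "accuracy",
                          ok_b = "accurate"),
    by = key_cols)
  rows <- list()
  subjects <- unique(tbl$subject)
  for (s in subjects) {
    for (g in names(groups)) {
      sub <- filter(tbl, .data$subject == s, .data$roi %in% groups[[g]])
      adv <- model_advantage(sub$acc_a, sub$acc_b, sub$ok_a, sub$ok_b)
      x <- if (adv$n_common > 0) {
        stream <- 200L + 10L * match(s, subjects) + match(g, names(groups))
        advantage_permutation_threshold(adv$n_common, n_perm, alpha,
                                        seed = derive_seed(seed, stream))
      } else NA_real_
      rows[[length(rows) + 1L]] <- tibble(
        subject = s, group = g, n_common = adv$n_common,
        fraction_a = adv$fraction_a, fraction_b = adv$fraction_b,
        threshold_x = x,
        significant_a = !adv$undefined & adv$fraction_a > x,
        significant_b = !adv$undefined & adv$fraction_b > x,
        undefined = adv$undefined)
    }
  }
  list_rbind(rows)
}

#' ROI-level RSA table
#'
#' For each model and ROI: per subject the best-matching model layer
#' (maximal Kendall tau between the layer RDM and the subject's ROI RDM),
#' then the mean and variance of the per-subject maxima, alongside the
#' inter-subject RDM ceiling of the ROI.
#'
#' @param study A `synthetic_study`.
#' @param model_features Named list of `layer_feature_set`s, one per
#'   model.
#' @return Tibble: model, roi, mean_tau, var_tau, modal_best_layer,
#'   inter_subject_ceiling.
#' @export
rsa_table <- function(study, model_features) {
  brains <- brain_rdms(study)
  roi_names <- names(brains[[1]])
  ceilings <- setNames(vapply(roi_names, function(rn) {
    inter_subject_ceiling(lapply(brains, `[[`, rn))
  }, numeric(1)), roi_names)
  rows <- list()
  for (m in names(model_features)) {
    mr <- model_rdms(model_features[[m]])
    for (rn in roi_names) {
      best <- lapply(brains, function(subj) best_layer_correlation(mr, subj[[rn]]))
      taus <- vapply(best, `[[`, numeric(1), "tau")
      layers <- vapply(best, `[[`, integer(1), "layer")
      rows[[length(rows) + 1L]] <- tibble(
        model = m, roi = rn, mean_tau = mean(taus), var_tau = var(taus),
        modal_best_layer = as.integer(names(sort(table(layers),
                                                 decreasing = TRUE))[1]),
        inter_subject_ceiling = ceilings[[rn]])
    }
  }
  list_rbind(rows)
}

#' Run the full encoding pipeline
#'
#' simulate -> reduce -> encode -> evaluate -> RSA -> report.  Fully
#' deterministic given the configuration: rerunning writes byte-identical
#' tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, all report
#'   tables are written as CSV plus a `provenance.json` sidecar.
#' @return An `encoding_report` bundle: the study, per-model encodings and
#'   significance, and all report tables.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- make_study(config$study)

  encodings <- list()
  significance <- list()
  for (m in names(config$models)) {
    feats <- resolve_features(config$models[[m]], study, config$seed)
    enc <- encode_study(study, features = feats,
                        n_components = config$n_components,
                        sparsity = config$sparsity, tol = config$tol,
                        layer_selection = config$layer_selection,
                        model_name = m)
    sig <- study_significance(enc, n_perm = config$n_perm,
                              alpha = config$alpha,
                              seed = derive_seed(config$seed, 31L + match(m, names(config$models))))
    encodings[[m]] <- enc
    significance[[m]] <- sig
  }

  # noise ceiling is a property of the measurements, not of a model
  ceil_rows <- list()
  for (s in names(study$subjects)) {
    for (rn in names(study$subjects[[s]])) {
      nc <- noise_ceiling(study$subjects[[s]][[rn]]$runs, n_sim = config$n_sim,
                          seed = derive_seed(config$seed, 500L + match(s, names(study$subjects))))
      ceil_rows[[length(ceil_rows) + 1L]] <-
        mutate(nc$voxels, subject = s, roi = rn, .before = 1)
    }
  }
  ceiling_tbl <- list_rbind(ceil_rows)
  roi_ceiling <- ceiling_tbl |>
    group_by(.data$roi) |>
    summarise(median_ceiling = median(.data$ceiling), .groups = "drop")

  fig2 <- list_rbind(lapply(names(encodings), function(m) {
    mutate(roi_summary(encodings[[m]]$voxels, top_k = config$top_k),
           model = m, .before = 1)
  })) |> left_join(roi_ceiling, by = "roi")

  fig5 <- list_rbind(lapply(names(encodings), function(m) {
    mutate(report_layer_distribution(encodings[[m]], significance[[m]]$table),
           model = m, .before = 1)
  }))

  fig6 <- list_rbind(lapply(names(encodings), function(m) {
    mutate(report_layer_accuracy_curves(encodings[[m]], top_k = config$top_k),
           model = m, .before = 1)
  }))

  mnames <- names(config$models)
  table1 <- if (length(mnames) >= 2) {
    advantage_table(encodings[[mnames[1]]], encodings[[mnames[2]]],
                    significance[[mnames[1]]], significance[[mnames[2]]],
                    n_perm = config$n_perm, alpha = config$adv_alpha,
                    seed = derive_seed(config$seed, 77L))
  } else NULL

  model_feats <- lapply(setNames(mnames, mnames), function(m) {
    resolve_features(config$models[[m]], study, config$seed)
  })
  fig3 <- rsa_table(study, model_feats)

  vox_acc <- list_rbind(lapply(mnames, function(m) {
    mutate(significance[[m]]$table, model = m, .before = 1)
  }))

  report <- structure(list(
    study = study, encodings = encodings, significance = significance,
    tables = list(roi_summary = fig2, rsa = fig3, advantage = table1,
                  layer_distribution = fig5, layer_accuracy = fig6,
                  voxel_accuracy = vox_acc, noise_ceiling = ceiling_tbl),
    config = config
  ), class = "encoding_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an encoding report's tables to CSV
#'
#' @param report An `encoding_report`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(roi_summary = "fig2_roi_summary.csv",
             rsa = "fig3_rsa.csv",
             advantage = "table1_advantage.csv",
             layer_distribution = "fig5_layer_distribution.csv",
             layer_accuracy = "fig6_layer_accuracy.csv",
             voxel_accuracy = "voxel_accuracy.csv",
             noise_ceiling = "noise_ceiling.csv")
  for (nm in names(files)) {
    tbl <- report$tables[[nm]]
    if (!is.null(tbl)) {
      readr::write_csv(tbl, file.path(out_dir, files[[nm]]), progress = FALSE)
    }
  }
  prov <- list(
    package = "voxelencode",
    version = as.character(utils::packageVersion("voxelencode")),
    r_version = R.version.string,
    seed = report$config$seed,
    config_hash = rlang::hash(report$config)
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.encoding_report <- function(x, ...) {
  cat(sprintf("<encoding_report> %d model(s): %s\n",
              length(x$encodings), paste(names(x$encodings), collapse = ", ")))
  cat(sprintf("  tables: %s\n", paste(names(x$tables), collapse = ", ")))
  invisible(x)
}
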