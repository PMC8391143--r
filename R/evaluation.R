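## Evaluation: prediction accuracy, randomization-test significance
## thresholds, ROI summaries, model-advantage permutation tests, and
## Monte-Carlo noise ceilings from repeated validation runs.

#' Prediction accuracy of a voxel
#'
#' Pearson correlation between measured and predicted validation
#' responses.  If either vector is constant the accuracy is defined as 0
#' (with a warning): a constant prediction carries no signal.
#'
#' @param r Measured responses.
#' @param r_hat Predicted responses.
#' @return A correlation in \[-1, 1\].
#' @export
prediction_accuracy <- function(r, r_hat) {
  if (length(r) != length(r_hat)) {
    abort("`r` and `r_hat` must have equal length.",
          class = "voxelencode_invalid_input")
  }
  if (length(r) < 3) {
    abort("At least 3 samples are required.",
          class = "voxelencode_invalid_input")
  }
  safe_cor(r, r_hat, warn_degenerate = TRUE)
}

#' Randomization-test threshold for prediction accuracy
#'
#' For each voxel the correspondence between measured and predicted
#' responses is scrambled `n_perm` times (permutation without replacement
#' of the predicted vector) and the accuracy recomputed, building an
#' empirical null of the correlation.  With `pooling = "pooled"` (default)
#' all null values are pooled into one global threshold -- the higher
#' nearest-rank `1 - alpha` quantile -- matching the single cutoff the
#' randomization test is usually quoted with; `"per-voxel"` keeps one
#' threshold per voxel.  A voxel is accurately predicted when its accuracy
#' exceeds the threshold.
#'
#' @param measured,predicted Matrices (stimuli x voxels) or vectors (one
#'   voxel) of validation responses.
#' @param n_perm Number of permutations per voxel (default 1000).
#' @param alpha Significance level (default 0.001).
#' @param pooling `"pooled"` or `"per-voxel"`.
#' @param seed Seed for the permutation stream.
#' @return A `significance_result`: `threshold` (scalar or per-voxel
#'   vector), `alpha`, `pooling`, `accuracy`, logical `mask`, and the null
#'   mean/variance (`null_mean`, `null_var`).
#' @export
randomization_threshold <- function(measured, predicted, n_perm = 1000,
                                    alpha = 0.001,
                                    pooling = c("pooled", "per-voxel"),
                                    seed = 1L) {
  pooling <- match.arg(pooling)
  n_perm <- assert_count(n_perm, "n_perm", min = 100L)
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).", class = "voxelencode_invalid_input")
  }
  measured <- as.matrix(measured)
  predicted <- as.matrix(predicted)
  stopifnot(all(dim(measured) == dim(predicted)))
  n <- nrow(measured)
  if (n < 3) {
    abort("At least 3 validation samples are required.",
          class = "voxelencode_invalid_input")
  }
  V <- ncol(measured)
  nulls <- matrix(NA_real_, n_perm, V)
  with_seed(seed, {
    for (v in seq_len(V)) {
      idx <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
      perm <- matrix(predicted[idx, v], n, n_perm)
      nulls[, v] <- col_cor(matrix(measured[, v], n, n_perm), perm)
    }
  })
  accuracy <- col_cor(measured, predicted)
  threshold <- if (pooling == "pooled") {
    nearest_rank_quantile(as.numeric(nulls), 1 - alpha)
  } else {
    apply(nulls, 2, nearest_rank_quantile, q = 1 - alpha)
  }
  structure(list(threshold = threshold, alpha = alpha, pooling = pooling,
                 accuracy = accuracy, mask = accuracy > threshold,
                 null_mean = mean(nulls), null_var = var(as.numeric(nulls)),
                 n_perm = n_perm, n_samples = n),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  thr <- if (x$pooling == "pooled") sprintf("%.3f", x$threshold) else
    sprintf("per-voxel (median %.3f)", median(x$threshold))
  cat(sprintf("<significance_result> threshold %s at alpha = %g (%s, %d perms)\n",
              thr, x$alpha, x$pooling, x$n_perm))
  cat(sprintf("  %d / %d voxels accurately predicted\n",
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Tidy a significance result
#'
#' @param x A `significance_result`.
#' @param ... Unused.
#' @return A tibble with one row per voxel: accuracy, threshold, accurate.
#' @export
tidy.significance_result <- function(x, ...) {
  tibble(voxel = seq_along(x$accuracy), accuracy = x$accuracy,
         threshold = if (x$pooling == "pooled")
           rep(x$threshold, length(x$accuracy)) else x$threshold,
         accurate = x$mask)
}

#' ROI summary of top-voxel prediction accuracy
#'
#' For each ROI the `top_k` most accurately predicted voxels of every
#' subject are pooled (k times S values for S subjects) and their mean and
#' variance reported -- the bar-plot summary of ROI-level encoding
#' performance.
#'
#' @param accuracies A data frame with columns `subject`, `roi`,
#'   `accuracy` (one row per voxel), e.g. `encoding_result$voxels`.
#' @param top_k Voxels kept per subject per ROI (default 100).  ROIs with
#'   fewer voxels use all of them, with a warning.
#' @return A tibble: roi, n (pooled voxels), mean_accuracy,
#'   var_accuracy.
#' @export
roi_summary <- function(accuracies, top_k = 100) {
  top_k <- assert_count(top_k, "top_k")
  stopifnot(all(c("subject", "roi", "accuracy") %in% names(accuracies)))
  short <- accuracies |>
    group_by(.data$subject, .data$roi) |>
    summarise(n = n(), .groups = "drop") |>
    filter(.data$n < top_k)
  if (nrow(short) > 0) {
    warn(sprintf("%d subject-ROI group(s) have fewer than top_k = %d voxels; using all.",
                 nrow(short), top_k))
  }
  accuracies |>
    group_by(.data$subject, .data$roi) |>
    slice_max(.data$accuracy, n = top_k, with_ties = FALSE) |>
    group_by(.data$roi) |>
    summarise(n = n(), mean_accuracy = mean(.data$accuracy),
              var_accuracy = var(.data$accuracy), .groups = "drop")
}

#' Advantage of one model over another on commonly accurate voxels
#'
#' Restricted to voxels accurately predicted by both models, the advantage
#' of model A is the percentage with strictly higher accuracy under A;
#' exact ties are split 50/50 (and counted), so the two fractions sum to
#' 100.
#'
#' @param acc_a,acc_b Aligned per-voxel accuracy vectors.
#' @param mask_a,mask_b Aligned accurate-voxel masks.
#' @return A one-row tibble: n_common, fraction_a, fraction_b (percent),
#'   n_ties, undefined (TRUE when no voxel passes both masks).
#' @export
model_advantage <- function(acc_a, acc_b, mask_a, mask_b) {
  n <- length(acc_a)
  stopifnot(length(acc_b) == n, length(mask_a) == n, length(mask_b) == n)
  common <- mask_a & mask_b
  if (!any(common)) {
    return(tibble(n_common = 0L, fraction_a = NA_real_, fraction_b = NA_real_,
                  n_ties = 0L, undefined = TRUE))
  }
  a <- acc_a[common]
  b <- acc_b[common]
  ties <- sum(a == b)
  if (ties > 0) {
    warn(sprintf("%d tie(s) in model advantage; split 50/50.", ties))
  }
  wins_a <- sum(a > b) + ties / 2
  tibble(n_common = sum(common),
         fraction_a = 100 * wins_a / sum(common),
         fraction_b = 100 * (1 - wins_a / sum(common)),
         n_ties = as.integer(ties), undefined = FALSE)
}

#' Permutation threshold for model advantage
#'
#' Under the null of no model difference each commonly accurate voxel's
#' winner is flipped independently with probability 0.5; the advantage is
#' recomputed `n_perm` times and the threshold `x` is the higher
#' nearest-rank `1 - alpha` quantile of the null advantages, in percent.
#' A model is significantly better when its advantage exceeds `x`.
#'
#' @param n_common_voxels Number of commonly accurate voxels.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Seed.
#' @return The threshold `x` in percent.
#' @export
advantage_permutation_threshold <- function(n_common_voxels, n_perm = 1000,
                                            alpha = 0.05, seed = 1L) {
  n_common_voxels <- assert_count(n_common_voxels, "n_common_voxels")
  n_perm <- assert_count(n_perm, "n_perm")
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).", class = "voxelencode_invalid_input")
  }
  with_seed(seed, {
    null_adv <- 100 * rbinom(n_perm, n_common_voxels, 0.5) / n_common_voxels
    nearest_rank_quantile(null_adv, 1 - alpha)
  })
}

#' Monte-Carlo noise ceiling from repeated validation runs
#'
#' Per voxel, variance components are estimated from the run stack: the
#' noise variance is the pooled squared standard error of the across-run
#' mean (the across-run sample variance divided by the number of runs,
#' averaged over stimuli), the signal mean is the grand mean of the
#' across-run mean responses, and the signal variance is the variance over
#' stimuli of the across-run mean minus the noise variance, clipped at 0.
#' `n_sim` simulations then draw a Gaussian signal and add Gaussian noise
#' with these components; the ceiling is the median correlation between
#' simulated signal and simulated measurement -- the accuracy a perfect
#' model could reach given the measurement noise.
#'
#' @param run_stack Array (runs x stimuli x voxels) or matrix (runs x
#'   stimuli, one voxel) of repeated validation responses.
#' @param n_sim Number of Monte-Carlo simulations (default 1000).
#' @param seed Seed.
#' @return A `noise_ceiling_result` whose `voxels` tibble holds
#'   signal_mean, signal_var, noise_var and ceiling per voxel.
#' @export
noise_ceiling <- function(run_stack, n_sim = 1000, seed = 1L) {
  if (is.matrix(run_stack)) {
    run_stack <- array(run_stack, dim = c(dim(run_stack), 1L))
  }
  stopifnot(length(dim(run_stack)) == 3L)
  n_runs <- dim(run_stack)[1]
  n_stim <- dim(run_stack)[2]
  V <- dim(run_stack)[3]
  if (n_runs < 2) {
    abort("At least 2 runs are required to estimate noise variance.",
          class = "voxelencode_invalid_input")
  }
  n_sim <- assert_count(n_sim, "n_sim")
  out <- tibble(voxel = seq_len(V), signal_mean = NA_real_,
                signal_var = NA_real_, noise_var = NA_real_,
                ceiling = NA_real_)
  with_seed(seed, {
    for (v in seq_len(V)) {
      runs <- run_stack[, , v, drop = TRUE]
      if (n_stim == 1L) runs <- matrix(runs, n_runs, 1L)
      stim_mean <- colMeans(runs)
      run_var <- apply(runs, 2, var)
      noise_var <- mean(run_var) / n_runs   # pooled squared standard error
      signal_var <- max(0, var(stim_mean) - noise_var)
      signal_mean <- mean(stim_mean)
      signal <- matrix(rnorm(n_stim * n_sim, signal_mean, sqrt(signal_var)),
                       n_stim, n_sim)
      meas <- signal + matrix(rnorm(n_stim * n_sim, 0, sqrt(noise_var)),
                              n_stim, n_sim)
      out$signal_mean[v] <- signal_mean
      out$signal_var[v] <- signal_var
      out$noise_var[v] <- noise_var
      out$ceiling[v] <- median(col_cor(signal, meas))
    }
  })
  structure(list(voxels = out, n_sim = n_sim, n_runs = n_runs),
            class = "noise_ceiling_result")
}

#' @export
print.noise_ceiling_result <- function(x, ...) {
  cat(sprintf("<noise_ceiling_result> %d voxel(s), %d runs, median ceiling %.3f\n",
              nrow(x$voxels), x$n_runs, median(x$voxels$ceiling)))
  invisible(x)
}

#' Tidy a noise-ceiling result
#'
#' @param x A `noise_ceiling_result`.
#' @param ... Unused.
#' @return The per-voxel tibble of variance components and ceilings.
#' @export
tidy.noise_ceiling_result <- function(x, ...) x$voxels
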