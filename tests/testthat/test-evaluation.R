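test_that("prediction accuracy is the Pearson correlation with guarded edges", {
  r <- c(0.3, -1.2, 0.5, 2.0)
  expect_equal(prediction_accuracy(r, r), 1)
  expect_equal(prediction_accuracy(r, -r), -1)
  # direct textbook-formula case
  expect_equal(prediction_accuracy(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_warning(z <- prediction_accuracy(r, rep(1, 4)), "Zero-variance")
  expect_equal(z, 0)
  expect_error(prediction_accuracy(r, r[1:3]),
               class = "voxelencode_invalid_input")
  expect_error(prediction_accuracy(1:2, 2:1),
               class = "voxelencode_invalid_input")
})

test_that("the permutation null of the correlation has mean zero and variance 1/(n-1)", {
  set.seed(5)
  n <- 50
  M <- matrix(rnorm(n * 100), n, 100)
  P <- matrix(rnorm(n * 100), n, 100)
  sig <- randomization_threshold(M, P, n_perm = 1000, alpha = 0.001, seed = 7)
  # 1e5 pooled null draws
  expect_lt(abs(sig$null_mean), 0.01)
  expect_equal(sig$null_var, 1 / (n - 1), tolerance = 0.1)
})

test_that("a symmetric null puts the alpha = 0.5 threshold near zero", {
  set.seed(6)
  M <- matrix(rnorm(50 * 100), 50, 100)
  P <- matrix(rnorm(50 * 100), 50, 100)
  sig <- randomization_threshold(M, P, n_perm = 1000, alpha = 0.5, seed = 8)
  expect_lt(abs(sig$threshold), 0.05)
})

test_that("constant predictions never pass the randomization test", {
  set.seed(9)
  M <- matrix(rnorm(20 * 10), 20, 10)
  P <- matrix(0, 20, 10)
  sig <- randomization_threshold(M, P, n_perm = 100, alpha = 0.01, seed = 1)
  expect_true(all(!sig$mask))
  expect_equal(sig$accuracy, rep(0, 10))
})

test_that("per-voxel pooling yields one threshold per voxel", {
  set.seed(10)
  M <- matrix(rnorm(30 * 8), 30, 8)
  P <- matrix(rnorm(30 * 8), 30, 8)
  sig <- randomization_threshold(M, P, n_perm = 200, alpha = 0.05,
                                 pooling = "per-voxel", seed = 2)
  expect_length(sig$threshold, 8L)
  expect_identical(sig$mask, sig$accuracy > sig$threshold)
  expect_equal(nrow(tidy(sig)), 8L)
})

test_that("randomization test enforces its preconditions", {
  M <- matrix(rnorm(4), 2, 2)
  expect_error(randomization_threshold(M, M, n_perm = 100, seed = 1),
               class = "voxelencode_invalid_input")
  M2 <- matrix(rnorm(40), 20, 2)
  expect_error(randomization_threshold(M2, M2, n_perm = 50, seed = 1),
               class = "voxelencode_invalid_config")
  expect_error(randomization_threshold(M2, M2, n_perm = 100, alpha = 1.2,
                                       seed = 1),
               class = "voxelencode_invalid_input")
})

test_that("ROI summaries pool the top voxels of every subject", {
  set.seed(11)
  acc <- tidyr::expand_grid(subject = sprintf("S%d", 1:5),
                            roi = c("V1", "FFA"), voxel = 1:120) |>
    dplyr::mutate(accuracy = runif(dplyr::n()))
  out <- roi_summary(acc, top_k = 100)
  expect_equal(out$n, c(500L, 500L))
  # oracle for one ROI: mean of the pooled per-subject top-100 sets
  pooled <- acc |>
    dplyr::filter(roi == "V1") |>
    dplyr::group_by(subject) |>
    dplyr::slice_max(accuracy, n = 100, with_ties = FALSE)
  expect_equal(out$mean_accuracy[out$roi == "V1"], mean(pooled$accuracy))
  expect_equal(out$var_accuracy[out$roi == "V1"], var(pooled$accuracy))
})

test_that("ROI summaries handle constants, top-1 and short ROIs", {
  acc <- tibble::tibble(subject = "S1", roi = "V1", voxel = 1:3,
                        accuracy = c(0.2, 0.9, 0.5))
  expect_equal(roi_summary(acc, top_k = 1)$mean_accuracy, 0.9)
  acc_const <- dplyr::mutate(acc, accuracy = 0.7)
  out <- roi_summary(acc_const, top_k = 3)
  expect_equal(out$mean_accuracy, 0.7)
  expect_equal(out$var_accuracy, 0)
  expect_warning(out2 <- roi_summary(acc, top_k = 10), "fewer than top_k")
  expect_equal(out2$n, 3L)
})

test_that("model advantage splits wins, ties and undefined cases correctly", {
  acc_b <- c(0.5, 0.6, 0.7, 0.2)
  mask <- rep(TRUE, 4)
  out <- model_advantage(acc_b + 0.1, acc_b, mask, mask)
  expect_equal(out$fraction_a, 100)
  expect_equal(out$fraction_b, 0)
  expect_warning(tie <- model_advantage(acc_b, acc_b, mask, mask), "tie")
  expect_equal(tie$fraction_a, 50)
  expect_equal(tie$fraction_b, 50)
  expect_equal(tie$fraction_a + tie$fraction_b, 100)
  none <- model_advantage(acc_b, acc_b, mask, !mask)
  expect_true(none$undefined)
  expect_equal(none$n_common, 0L)
  # only commonly accurate voxels count
  part <- model_advantage(c(1, 0, 1, 0), c(0, 1, 0, 1),
                          c(TRUE, TRUE, FALSE, FALSE),
                          c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(part$n_common, 2L)
  expect_equal(part$fraction_a, 50)
})

test_that("the advantage threshold matches the binomial closed form", {
  for (n in c(100L, 500L, 1000L)) {
    x <- advantage_permutation_threshold(n, n_perm = 1000, alpha = 0.05,
                                         seed = 3)
    closed <- 100 * qbinom(0.95, n, 0.5) / n
    expect_lte(abs(x - closed), 1)
  }
  # one voxel: null advantages are {0, 100}, so x = 100 at alpha = 0.05
  expect_equal(advantage_permutation_threshold(1, 1000, 0.05, seed = 4), 100)
})

test_that("noise ceilings hit their closed-form limits", {
  # zero across-run variance (plus a signal): ceiling ~ 1
  stack <- pinned_run_stack(1, 1e-6, seed = 2)
  nc <- noise_ceiling(stack, n_sim = 500, seed = 3)
  expect_gte(nc$voxels$ceiling, 0.999)
  # pure noise: signal variance clips to zero, ceiling ~ 0
  nc0 <- noise_ceiling(pinned_run_stack(0, 3, seed = 4), n_sim = 1000,
                       seed = 5)
  expect_equal(nc0$voxels$signal_var, 0)
  expect_lt(abs(nc0$voxels$ceiling), 0.1)
  # equal signal and noise sd: 1/sqrt(2)
  nc1 <- noise_ceiling(pinned_run_stack(1, 1, seed = 6), n_sim = 1000,
                       seed = 7)
  expect_equal(nc1$voxels$ceiling, 1 / sqrt(2), tolerance = 0.02 * sqrt(2))
})

test_that("noise ceilings track sigma_s/sqrt(sigma_s^2+sigma_n^2) across a grid", {
  for (ratio in c(0.5, 1, 2, 4)) {
    nc <- noise_ceiling(pinned_run_stack(ratio, 1, seed = 11), n_sim = 1000,
                        seed = 12)
    expect_equal(nc$voxels$signal_var, ratio^2, tolerance = 1e-6)
    expect_equal(nc$voxels$noise_var, 1, tolerance = 1e-6)
    closed <- ratio / sqrt(ratio^2 + 1)
    expect_lt(abs(nc$voxels$ceiling - closed), 0.02)
  }
})

test_that("more run noise never raises the median ceiling", {
  f <- make_layer_features(40, 50, c(30), seed = 21)
  med <- vapply(c(0.5, 2, 6), function(rs) {
    vd <- make_voxel_responses(f, roi_spec("X", 20, 1), k_true = 4, snr = 2,
                               n_runs = 12, run_noise_sd = rs, seed = 22)
    median(noise_ceiling(vd$runs, n_sim = 300, seed = 23)$voxels$ceiling)
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("noise ceiling requires repeated runs", {
  one_run <- array(rnorm(50), c(1, 50, 1))
  expect_error(noise_ceiling(one_run, 100, 1),
               class = "voxelencode_invalid_input")
})
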