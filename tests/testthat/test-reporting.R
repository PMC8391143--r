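test_that("the full pipeline emits every report table with stable schemas", {
  out <- withr::local_tempdir()
  rep <- tiny_report()
  write_report(rep, out)
  files <- c("fig2_roi_summary.csv", "fig3_rsa.csv", "table1_advantage.csv",
             "fig5_layer_distribution.csv", "fig6_layer_accuracy.csv",
             "voxel_accuracy.csv", "noise_ceiling.csv", "provenance.json")
  expect_true(all(file.exists(file.path(out, files))))
  expect_named(rep$tables$roi_summary,
               c("model", "roi", "n", "mean_accuracy", "var_accuracy",
                 "median_ceiling"))
  expect_named(rep$tables$advantage,
               c("subject", "group", "n_common", "fraction_a", "fraction_b",
                 "threshold_x", "significant_a", "significant_b", "undefined"))
  expect_named(rep$tables$rsa,
               c("model", "roi", "mean_tau", "var_tau", "modal_best_layer",
                 "inter_subject_ceiling"))
  expect_named(rep$tables$layer_distribution,
               c("model", "roi", "layer", "n_accurate", "fraction", "empty"))
  expect_named(rep$tables$layer_accuracy,
               c("model", "roi", "layer", "n", "mean_accuracy"))
})

test_that("rerunning an identical configuration is byte-identical", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  suppressWarnings(run_pipeline(tiny_pipeline_config(), out_dir = out1))
  suppressWarnings(run_pipeline(tiny_pipeline_config(), out_dir = out2))
  for (f in list.files(out1, pattern = "csv$")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("layer distributions are normalised per ROI and flag empties", {
  study <- tiny_study()
  enc <- encode_study(study, sparsity = 8)
  dist_all <- report_layer_distribution(enc)
  sums <- dist_all |>
    dplyr::group_by(roi) |>
    dplyr::summarise(s = sum(fraction))
  expect_equal(sums$s, rep(1, 2))
  # point mass: force every optimal layer to 2
  enc2 <- enc
  enc2$voxels$optimal_layer <- 2L
  d2 <- report_layer_distribution(enc2)
  expect_equal(d2$fraction[d2$layer == 2], rep(1, 2))
  expect_equal(d2$fraction[d2$layer != 2], rep(0, 4))
  # no accurate voxels: flagged empty with NA fractions
  mask <- tibble::tibble(subject = enc$voxels$subject, roi = enc$voxels$roi,
                         voxel = enc$voxels$voxel, accurate = FALSE)
  d0 <- report_layer_distribution(enc, mask)
  expect_true(all(d0$empty))
  expect_true(all(is.na(d0$fraction)))
})

test_that("layer accuracy curves use the top voxels per layer", {
  study <- tiny_study()
  enc <- encode_study(study, sparsity = 8)
  curves <- report_layer_accuracy_curves(enc, top_k = 4)
  expect_equal(nrow(curves), 2L * 3L)   # 2 ROIs x 3 layers
  expect_equal(unique(curves$n), 8L)    # 4 voxels x 2 subjects
  # oracle for one cell
  cell <- enc$accuracies |>
    dplyr::filter(roi == "early", layer == 1) |>
    dplyr::group_by(subject) |>
    dplyr::slice_max(accuracy, n = 4, with_ties = FALSE)
  expect_equal(curves$mean_accuracy[curves$roi == "early" & curves$layer == 1],
               mean(cell$accuracy))
  # oversized top_k warns and uses everything
  expect_warning(all_curves <- report_layer_accuracy_curves(enc, top_k = 50),
                 "fewer than top_k")
  expect_equal(unique(all_curves$n), 16L)
})

test_that("perturbed features are reproducible and keep the schema", {
  f <- make_layer_features(30, 10, c(12, 12), seed = 1)
  p1 <- perturb_features(f, sd = 0.5, seed = 2)
  p2 <- perturb_features(f, sd = 0.5, seed = 2)
  expect_identical(p1, p2)
  expect_false(identical(p1$layers[[1]]$train, f$layers[[1]]$train))
  expect_equal(dim(p1$layers[[2]]$val), dim(f$layers[[2]]$val))
})

test_that("the advantage table separates a strong model from a degraded one", {
  rep <- tiny_report()
  adv <- rep$tables$advantage
  expect_equal(nrow(adv), 2L * 2L)  # 2 subjects x 2 groups
  ok <- !adv$undefined
  expect_true(any(ok))
  expect_true(all(abs(adv$fraction_a[ok] + adv$fraction_b[ok] - 100) < 1e-9))
  expect_true(all(adv$threshold_x[ok] >= 50 & adv$threshold_x[ok] <= 100))
  expect_identical(adv$significant_a[ok],
                   adv$fraction_a[ok] > adv$threshold_x[ok])
})

test_that("plot helpers return ggplot objects", {
  rep <- tiny_report()
  expect_s3_class(plot_roi_summary(rep$tables$roi_summary), "ggplot")
  expect_s3_class(plot_layer_distribution(rep$tables$layer_distribution),
                  "ggplot")
  expect_s3_class(plot_layer_accuracy(rep$tables$layer_accuracy), "ggplot")
  rdm <- compute_rdm(matrix(rnorm(50), 10, 5))
  expect_s3_class(autoplot(rdm), "ggplot")
})

test_that("pipeline configurations are validated", {
  expect_error(pipeline_config(models = list("study")),
               class = "voxelencode_invalid_config")
  expect_error(pipeline_config(alpha = 2), class = "voxelencode_invalid_config")
  cfg <- pipeline_config()
  expect_equal(cfg$n_perm, 1000)
  expect_equal(cfg$alpha, 0.001)
  expect_equal(cfg$n_sim, 1000)
  expect_equal(cfg$top_k, 100)
})
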