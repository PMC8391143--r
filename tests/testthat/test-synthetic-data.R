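test_that("single-layer features have the stated shape and unit train variance", {
  f <- make_layer_features(10, 4, c(4), seed = 1)
  expect_equal(dim(f$layers[[1]]$train), c(10L, 4L))
  expect_equal(dim(f$layers[[1]]$val), c(4L, 4L))
  expect_equal(apply(f$layers[[1]]$train, 2, sd), rep(1, 4))
})

test_that("feature generation is bit-identical for identical seeds", {
  a <- make_layer_features(40, 10, c(16, 16), seed = 9)
  b <- make_layer_features(40, 10, c(16, 16), seed = 9)
  expect_identical(a, b)
  c <- make_layer_features(40, 10, c(16, 16), seed = 10)
  expect_false(identical(a$layers[[1]]$train, c$layers[[1]]$train))
})

test_that("successive cascade layers share information without being identical", {
  f <- make_layer_features(300, 10, c(100, 100), seed = 3)
  cc <- stats::cancor(f$layers[[1]]$train, f$layers[[2]]$train)
  expect_gt(mean(cc$cor), 0)
  expect_lt(mean(cc$cor), 1)
})

test_that("deep layers stay bounded on the validation split", {
  f <- make_layer_features(200, 50, rep(60L, 6), seed = 8)
  val_sds <- unlist(lapply(f$layers, function(l) apply(l$val, 2, sd)))
  expect_lt(max(val_sds), 10)
  expect_false(anyNA(unlist(lapply(f$layers, `[[`, "val"))))
})

test_that("feature generation rejects invalid dimensions", {
  expect_error(make_layer_features(10, 2, integer(0)),
               class = "voxelencode_invalid_config")
  expect_error(make_layer_features(10, 2, c(4, 0)),
               class = "voxelencode_invalid_config")
})

test_that("voxel responses match the snr calibration closed form", {
  f <- make_layer_features(1200, 50, c(100), seed = 5)
  roi <- roi_spec("V1", 50, 1)
  # noiseless limit
  vd0 <- make_voxel_responses(f, roi, k_true = 10, snr = 1e6, n_runs = 2,
                              run_noise_sd = 0, seed = 2)
  r0 <- vapply(1:50, function(v) cor(vd0$clean_train[, v], vd0$train[, v]),
               numeric(1))
  expect_true(all(r0 > 0.999))
  # snr = 1: corr = snr / sqrt(snr^2 + 1) = 1/sqrt(2)
  vd1 <- make_voxel_responses(f, roi, k_true = 10, snr = 1, n_runs = 2,
                              run_noise_sd = 0, seed = 2)
  r1 <- vapply(1:50, function(v) cor(vd1$clean_train[, v], vd1$train[, v]),
               numeric(1))
  expect_equal(mean(r1), 1 / sqrt(2), tolerance = 0.03 / (1 / sqrt(2)))
})

test_that("a point-mass layer preference pins every generating layer", {
  f <- make_layer_features(30, 5, c(10, 10, 10), seed = 4)
  vd <- make_voxel_responses(f, roi_spec("X", 12, c(0, 0, 1)), k_true = 2,
                             snr = 2, n_runs = 2, run_noise_sd = 0.1, seed = 6)
  expect_true(all(vd$truth$generating_layer == 3L))
  expect_true(all(lengths(vd$truth$support) == 2L))
})

test_that("per-run noise variance matches its nominal level", {
  f <- make_layer_features(60, 50, c(40), seed = 13)
  vd <- make_voxel_responses(f, roi_spec("X", 60, 1), k_true = 5, snr = 2,
                             n_runs = 35, run_noise_sd = 1.5, seed = 14)
  rv <- apply(vd$runs, c(2, 3), var)   # 50 stimuli x 60 voxels
  expect_equal(mean(rv), 1.5^2, tolerance = 0.1)
})

test_that("voxel simulation rejects unattainable supports", {
  f <- make_layer_features(30, 5, c(6), seed = 1)
  expect_error(make_voxel_responses(f, roi_spec("X", 3, 1), k_true = 7,
                                    snr = 1, seed = 1),
               class = "voxelencode_invalid_config")
})

test_that("a full study has consistent schema and recorded ground truth", {
  study <- tiny_study()
  cfg <- study$config
  expect_length(study$subjects, 2L)
  expect_named(study$subjects[[1]], c("early", "late"))
  ds <- study$subjects$S1$early
  expect_equal(dim(ds$train), c(cfg$n_train, 8L))
  expect_equal(dim(ds$val), c(cfg$n_val, 8L))
  expect_equal(dim(ds$runs), c(cfg$n_runs, cfg$n_val, 8L))
  expect_equal(nrow(study$truth), 2L * 2L * 8L)
  expect_true(all(study$truth$generating_layer %in% 1:3))
  expect_true(all(lengths(study$truth$support) == cfg$k_true))
  # early ROI prefers layer 1, late ROI layer 3, in expectation
  tt <- dplyr::count(study$truth, roi, generating_layer)
  expect_true(all(study$truth$generating_layer[study$truth$roi == "early"] <= 2))
  expect_true(all(study$truth$generating_layer[study$truth$roi == "late"] >= 2))
})

test_that("a minimal one-voxel study is shaped consistently", {
  cfg <- study_config(n_subjects = 1, n_train = 20, n_val = 5, n_layers = 1,
                      layer_dims = 8L, rois = list(roi_spec("solo", 1, 1)),
                      k_true = 2, snr = 1, n_runs = 2, run_noise_sd = 0,
                      seed = 3)
  study <- make_study(cfg)
  expect_equal(dim(study$subjects$S1$solo$train), c(20L, 1L))
  expect_equal(dim(study$subjects$S1$solo$runs), c(2L, 5L, 1L))
  expect_equal(nrow(study$truth), 1L)
})

test_that("different master seeds give different truths under the same schema", {
  base <- function(seed) study_config(
    n_subjects = 1, n_train = 30, n_val = 6, n_layers = 2,
    layer_dims = c(10L, 10L), rois = list(roi_spec("r", 5, c(0.5, 0.5))),
    k_true = 2, snr = 2, n_runs = 2, run_noise_sd = 0.2, seed = seed)
  s1 <- make_study(base(1))
  s2 <- make_study(base(2))
  expect_identical(names(s1$subjects), names(s2$subjects))
  expect_false(identical(s1$truth$support, s2$truth$support))
})

test_that("adding a subject leaves earlier subjects' draws untouched", {
  cfg1 <- study_config(n_subjects = 1, n_train = 30, n_val = 6, n_layers = 2,
                       layer_dims = c(10L, 10L),
                       rois = list(roi_spec("r", 5, c(0.5, 0.5))),
                       k_true = 2, snr = 2, n_runs = 2, run_noise_sd = 0.2,
                       seed = 7)
  cfg2 <- cfg1
  cfg2$n_subjects <- 2L
  s1 <- make_study(cfg1)
  s2 <- make_study(cfg2)
  expect_identical(s1$subjects$S1, s2$subjects$S1)
})

test_that("study configuration enforces its invariants", {
  expect_error(study_config(n_subjects = 0), class = "voxelencode_invalid_config")
  expect_error(study_config(snr = -1), class = "voxelencode_invalid_config")
  expect_error(study_config(n_layers = 3, layer_dims = c(10, 10)),
               class = "voxelencode_invalid_config")
  expect_error(roi_spec("x", 4, c(0.5, 0.4)), class = "voxelencode_invalid_config")
  # defaults follow the target design
  cfg <- study_config()
  expect_equal(cfg$n_train, 1200L)
  expect_equal(cfg$n_val, 50L)
  expect_equal(cfg$n_layers, 18L)
  expect_equal(cfg$n_runs, 35L)
  expect_equal(vapply(cfg$rois, `[[`, character(1), "name"),
               c("V1", "V2", "V3", "V4", "LOC", "PPA", "FFA"))
  prefs <- vapply(cfg$rois, function(r) sum(r$layer_preference), numeric(1))
  expect_equal(prefs, rep(1, 7))
})

test_that("ROI layer preferences move from early to late along the hierarchy", {
  rois <- default_rois(8)
  com <- vapply(rois, function(r) sum(seq_len(8) * r$layer_preference),
                numeric(1))
  expect_true(all(diff(com) > 0))
})
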