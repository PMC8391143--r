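# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small but non-trivial study used across unit tests: 2 subjects,
# 2 ROIs with opposite layer preferences, 3 layers.
tiny_study <- function() {
  cache_fixture("tiny_study", function() {
    cfg <- study_config(
      n_subjects = 2, n_train = 80, n_val = 25, n_layers = 3,
      layer_dims = c(30L, 30L, 30L),
      rois = list(roi_spec("early", 8, c(0.8, 0.2, 0)),
                  roi_spec("late", 8, c(0, 0.2, 0.8))),
      k_true = 4, snr = 3, n_runs = 6, run_noise_sd = 1, seed = 404)
    make_study(cfg)
  })
}

# Configuration of a minimal two-model pipeline used for orchestration and
# determinism checks.
tiny_pipeline_config <- function(seed = 11L) {
  pipeline_config(
    study = study_config(
      n_subjects = 2, n_train = 60, n_val = 20, n_layers = 3,
      layer_dims = rep(24L, 3),
      rois = list(roi_spec("V1", 6, c(0.9, 0.1, 0)),
                  roi_spec("FFA", 6, c(0, 0.1, 0.9))),
      k_true = 3, snr = 3, n_runs = 4, run_noise_sd = 1, seed = seed),
    n_perm = 200, n_sim = 200, top_k = 5, seed = seed)
}

# A cached run of the tiny pipeline for tests that only read its outputs.
tiny_report <- function() {
  cache_fixture("tiny_report", function() {
    suppressWarnings(run_pipeline(tiny_pipeline_config()))
  })
}

# The acceptance study: the pipeline's default configuration (5 subjects,
# 7 ROIs x 60 voxels, 8 layers x 200 features, 300 train / 50 validation,
# 35 runs, snr 2).  Built once; several acceptance blocks share it.
acceptance_report <- function() {
  cache_fixture("acceptance_report", function() {
    suppressWarnings(run_pipeline(pipeline_config()))
  })
}

# Run-stack fixture with exactly pinned variance components: stimulus means
# with sample variance exactly sigma_s^2 + sigma_n^2 is NOT what we want --
# we pin the signal variance and the pooled standard error separately so
# the estimator returns the intended components exactly.
pinned_run_stack <- function(sigma_s, sigma_n, n_stim = 50, n_runs = 35,
                             seed = 1) {
  set.seed(seed)
  m <- rnorm(n_stim)
  m <- (m - mean(m)) / sd(m) * sqrt(sigma_s^2 + sigma_n^2)
  runs <- matrix(0, n_runs, n_stim)
  for (i in seq_len(n_stim)) {
    e <- rnorm(n_runs)
    e <- (e - mean(e)) / sd(e) * sqrt(n_runs) * sigma_n
    runs[, i] <- m[i] + e
  }
  array(runs, dim = c(n_runs, n_stim, 1L))
}
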