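## Plain-text study container: a directory tree mirroring an array-store
## layout (features/layer{l}/{train,val}.csv, subjects/{s}/{roi}/...,
## truth.csv) with a JSON sidecar for the configuration.

mat_write <- function(M, path) {
  df <- as.data.frame(M)
  names(df) <- sprintf("c%d", seq_len(ncol(M)))
  readr::write_csv(df, path, progress = FALSE)
}

mat_read <- function(path) {
  unname(as.matrix(readr::read_csv(path, show_col_types = FALSE,
                                   progress = FALSE)))
}

num_list_chr <- function(x) vapply(x, paste, character(1), collapse = ";")
chr_num_list <- function(x) lapply(strsplit(x, ";", fixed = TRUE), as.numeric)

#' Write a synthetic study to a directory container
#'
#' @param study A `synthetic_study`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  cfg_json <- list(
    n_subjects = cfg$n_subjects, n_train = cfg$n_train, n_val = cfg$n_val,
    n_layers = cfg$n_layers, layer_dims = cfg$layer_dims,
    rois = lapply(cfg$rois, function(r) {
      list(name = r$name, n_voxels = r$n_voxels,
           layer_preference = r$layer_preference)
    }),
    k_true = cfg$k_true, snr = cfg$snr, n_runs = cfg$n_runs,
    run_noise_sd = cfg$run_noise_sd,
    n_train_categories = cfg$n_train_categories,
    n_val_categories = cfg$n_val_categories, seed = cfg$seed
  )
  jsonlite::write_json(cfg_json, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (l in study$features$layer_ids) {
    d <- file.path(dir, "features", sprintf("layer%d", l))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    mat_write(study$features$layers[[l]]$train, file.path(d, "train.csv"))
    mat_write(study$features$layers[[l]]$val, file.path(d, "val.csv"))
  }
  for (s in names(study$subjects)) {
    for (rn in names(study$subjects[[s]])) {
      ds <- study$subjects[[s]][[rn]]
      d <- file.path(dir, "subjects", s, rn)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      mat_write(ds$train, file.path(d, "train.csv"))
      mat_write(ds$val, file.path(d, "val.csv"))
      # runs flattened run-major: row (r, stim) of voxel v
      runs2d <- matrix(aperm(ds$runs, c(2, 1, 3)),
                       nrow = dim(ds$runs)[1] * dim(ds$runs)[2])
      mat_write(runs2d, file.path(d, "runs.csv"))
    }
  }
  truth <- study$truth
  truth$support <- num_list_chr(truth$support)
  truth$weights <- num_list_chr(truth$weights)
  readr::write_csv(truth, file.path(dir, "truth.csv"), progress = FALSE)
  invisible(dir)
}

#' Read a synthetic study from a directory container
#'
#' @param dir Directory written by [write_study()].
#' @return A `synthetic_study`.
#' @export
read_study <- function(dir) {
  cfg_json <- jsonlite::read_json(file.path(dir, "config.json"),
                                  simplifyVector = TRUE)
  rois <- lapply(seq_len(nrow(cfg_json$rois)), function(i) {
    roi_spec(cfg_json$rois$name[i], cfg_json$rois$n_voxels[i],
             cfg_json$rois$layer_preference[[i]])
  })
  cfg <- study_config(
    n_subjects = cfg_json$n_subjects, n_train = cfg_json$n_train,
    n_val = cfg_json$n_val, n_layers = cfg_json$n_layers,
    layer_dims = cfg_json$layer_dims, rois = rois, k_true = cfg_json$k_true,
    snr = cfg_json$snr, n_runs = cfg_json$n_runs,
    run_noise_sd = cfg_json$run_noise_sd,
    n_train_categories = cfg_json$n_train_categories,
    n_val_categories = cfg_json$n_val_categories, seed = cfg_json$seed
  )
  n_train <- cfg$n_train
  n_val <- cfg$n_val
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    d <- file.path(dir, "features", sprintf("layer%d", l))
    list(train = mat_read(file.path(d, "train.csv")),
         val = mat_read(file.path(d, "val.csv")))
  })
  features <- structure(list(
    layer_ids = seq_len(cfg$n_layers), layers = layers,
    stim_ids = list(train = sprintf("trn%05d", seq_len(n_train)),
                    val = sprintf("val%05d", seq_len(n_val))),
    n_train = n_train, n_val = n_val, layer_dims = cfg$layer_dims
  ), class = "layer_feature_set")
  truth_all <- readr::read_csv(file.path(dir, "truth.csv"),
                               show_col_types = FALSE, progress = FALSE)
  truth_all$support <- lapply(chr_num_list(truth_all$support), as.integer)
  truth_all$weights <- chr_num_list(truth_all$weights)
  truth_all <- as_tibble(truth_all)
  subjects <- lapply(sprintf("S%d", seq_len(cfg$n_subjects)), function(s) {
    rois_ds <- lapply(cfg$rois, function(r) {
      d <- file.path(dir, "subjects", s, r$name)
      runs2d <- mat_read(file.path(d, "runs.csv"))
      runs <- aperm(array(runs2d, dim = c(cfg$n_val, cfg$n_runs, r$n_voxels)),
                    c(2, 1, 3))
      structure(list(roi = r$name, train = mat_read(file.path(d, "train.csv")),
                     val = mat_read(file.path(d, "val.csv")), runs = runs,
                     clean_train = NULL, clean_val = NULL,
                     truth = filter(truth_all, .data$subject == s,
                                    .data$roi == r$name) |>
                       select(-"subject"),
                     n_runs = cfg$n_runs, run_noise_sd = cfg$run_noise_sd),
                class = "voxel_dataset")
    })
    names(rois_ds) <- vapply(cfg$rois, `[[`, character(1), "name")
    rois_ds
  })
  names(subjects) <- sprintf("S%d", seq_len(cfg$n_subjects))
  categories <- list(
    train = ((seq_len(n_train) - 1L) %% cfg$n_train_categories) + 1L,
    val = ((seq_len(n_val) - 1L) %% cfg$n_val_categories) + 1L
  )
  structure(list(features = features, subjects = subjects, truth = truth_all,
                 categories = categories, config = cfg),
            class = "synthetic_study")
}
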