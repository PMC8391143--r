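## Representational similarity analysis: correlation-distance RDMs for
## brain ROIs and model layers, compared by Kendall's tau-a.

#' Compute a representational dissimilarity matrix
#'
#' Entry (i, j) is the correlation distance `1 - Pearson(rep_i, rep_j)`
#' between the representations of stimuli i and j, giving a symmetric,
#' zero-diagonal matrix with entries in \[0, 2\].
#'
#' @param representations Matrix (stimuli x features): voxel responses of
#'   an ROI or features of a model layer.
#' @param stim_ids Stimulus ids (default: rownames or a running index).
#' @param label Source label (e.g. "V1/S1" or "model/layer3").
#' @return An `rdm` object.
#' @export
compute_rdm <- function(representations, stim_ids = NULL, label = "") {
  R <- as.matrix(representations)
  if (nrow(R) < 3) {
    abort("At least 3 stimuli are required.", class = "voxelencode_invalid_input")
  }
  if (ncol(R) < 2) {
    abort("Representations need at least 2 feature dimensions.",
          class = "voxelencode_invalid_input")
  }
  stim_ids <- stim_ids %||% rownames(R) %||% sprintf("stim%03d", seq_len(nrow(R)))
  const <- which(apply(R, 1, sd) == 0)
  if (length(const)) {
    abort(sprintf("Constant representation for stimulus %s; correlation distance is undefined.",
                  paste(stim_ids[const], collapse = ", ")),
          class = "voxelencode_degenerate_stimulus")
  }
  D <- 1 - cor(t(R))
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(stim_ids, stim_ids)
  structure(list(matrix = D, stim_ids = stim_ids, label = label),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d x %d%s, dissimilarity range [%.3f, %.3f]\n",
              nrow(x$matrix), ncol(x$matrix),
              if (nzchar(x$label)) paste0(" (", x$label, ")") else "",
              min(upper_tri(x)), max(upper_tri(x))))
  invisible(x)
}

upper_tri <- function(rdm) rdm$matrix[upper.tri(rdm$matrix)]

# Kendall's tau-a.  The concordant-minus-discordant count is obtained from
# the tau-b statistic (computed in C by stats::cor) with an exact algebraic
# tie correction; with no ties tau-a equals tau-b.
kendall_tau_a <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  n0 <- n * (n - 1) / 2
  tx <- table(x)
  ty <- table(y)
  Tx <- sum(tx * (tx - 1) / 2)
  Ty <- sum(ty * (ty - 1) / 2)
  if (Tx == n0 || Ty == n0) {
    abort("Kendall's tau is undefined for a constant vector.",
          class = "voxelencode_invalid_input")
  }
  tau_b <- cor(x, y, method = "kendall")
  (tau_b * sqrt((n0 - Tx) * (n0 - Ty))) / n0
}

#' Kendall correlation between two RDMs
#'
#' Kendall's tau-a over the strict upper triangles of the two matrices.
#' Stimulus ids must match in content and order.
#'
#' @param rdm_a,rdm_b `rdm` objects over the same stimuli.
#' @return Kendall's tau-a.
#' @export
rdm_correlation <- function(rdm_a, rdm_b) {
  stopifnot(inherits(rdm_a, "rdm"), inherits(rdm_b, "rdm"))
  if (!identical(rdm_a$stim_ids, rdm_b$stim_ids)) {
    abort("RDMs are over different stimuli (ids or order differ).",
          class = "voxelencode_invalid_input")
  }
  kendall_tau_a(upper_tri(rdm_a), upper_tri(rdm_b))
}

#' Inter-subject RDM ceiling
#'
#' The mean Kendall tau-a over all unordered pairs of subjects' brain
#' RDMs: how similar one brain's representational geometry is to
#' another's, an upper reference for model-to-brain correlations.
#'
#' @param brain_rdms List of `rdm` objects (one per subject), same
#'   stimuli.
#' @return Mean tau over the `choose(S, 2)` pairs.
#' @export
inter_subject_ceiling <- function(brain_rdms) {
  S <- length(brain_rdms)
  if (S < 2) {
    abort("At least 2 subject RDMs are required.",
          class = "voxelencode_invalid_input")
  }
  pairs <- utils::combn(S, 2)
  mean(apply(pairs, 2, function(ij) {
    rdm_correlation(brain_rdms[[ij[1]]], brain_rdms[[ij[2]]])
  }))
}

#' Best-matching model layer for a brain RDM
#'
#' Correlates every layer's model RDM with the brain RDM and returns the
#' layer with maximal tau (ties to the lowest layer id).  Averaging the
#' per-subject maxima across subjects gives the ROI-level representational
#' score.
#'
#' @param model_rdms_by_layer List of `rdm` objects, ordered by layer.
#' @param brain_rdm `rdm` of an ROI.
#' @return A list: `layer` (index), `tau` (its correlation), `taus` (all
#'   layers).
#' @export
best_layer_correlation <- function(model_rdms_by_layer, brain_rdm) {
  if (length(model_rdms_by_layer) == 0) {
    abort("`model_rdms_by_layer` must contain at least one RDM.",
          class = "voxelencode_invalid_input")
  }
  taus <- vapply(model_rdms_by_layer, rdm_correlation, numeric(1),
                 rdm_b = brain_rdm)
  i <- which.max(taus)
  list(layer = as.integer(i), tau = taus[i], taus = taus)
}

#' Brain RDMs of every subject and ROI of a study
#'
#' The representation of a stimulus in an ROI is the vector of all its
#' voxels' responses, taken from the across-run mean of the repeated
#' validation runs (falling back to the single validation response when
#' runs are absent).
#'
#' @param study A `synthetic_study`.
#' @return Nested list: `rdms[[subject]][[roi]]`, each an `rdm`.
#' @export
brain_rdms <- function(study) {
  ids <- study$features$stim_ids$val
  lapply(study$subjects, function(subj) {
    lapply(subj, function(ds) {
      rep_mat <- if (!is.null(ds$runs)) apply(ds$runs, c(2, 3), mean) else ds$val
      compute_rdm(rep_mat, stim_ids = ids, label = ds$roi)
    })
  })
}

#' Model RDMs per layer
#'
#' One RDM per feature layer from the raw (unreduced) validation-split
#' features.
#'
#' @param features A `layer_feature_set`.
#' @return List of `rdm` objects, ordered by layer.
#' @export
model_rdms <- function(features) {
  lapply(features$layer_ids, function(l) {
    compute_rdm(features$layers[[l]]$val, stim_ids = features$stim_ids$val,
                label = sprintf("layer%d", l))
  })
}
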