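## Regularized orthogonal matching pursuit (Needell & Vershynin style):
## greedy sparse regression used as the per-voxel encoding model.  At each
## iteration the s largest correlations between (unit-norm) columns and the
## current residual are regularized: among contiguous windows of comparable
## magnitude (max <= 2 * min), the window with maximal energy joins the
## support, and the model is refit by least squares.  Iteration stops when
## the support reaches 2s or the residual is negligible.

#' Precompute a ROMP design
#'
#' Centers the columns of `X` and stores unit-norm copies used for support
#' selection.  When many responses are regressed on the same design (all
#' voxels of an ROI, say), preparing once avoids repeating the O(m d) setup.
#'
#' @param X Numeric design matrix (stimuli x features), without a constant
#'   column; the intercept is handled internally.
#' @return A `romp_design` object.
#' @export
romp_prepare <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) {
    abort("`X` contains missing or non-finite values.",
          class = "voxelencode_invalid_input")
  }
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  norms <- sqrt(colSums(Xc^2))
  scale <- ifelse(norms > 0, norms, 1)
  Xn <- sweep(Xc, 2, scale, "/")
  Xn[, norms == 0] <- 0  # constant columns never compete for selection
  structure(list(Xc = Xc, Xn = Xn, center = center, norms = norms,
                 m = nrow(X), p = ncol(X)),
            class = "romp_design")
}

# Least-squares coefficients via the fast fitter, falling back to the
# NA-unpivoting lm.fit only for rank-deficient supports.
ls_coefs <- function(X, y) {
  fit <- .lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    coefs <- lm.fit(X, y)$coefficients
    coefs[is.na(coefs)] <- 0
    return(coefs)
  }
  coefs <- numeric(ncol(X))
  coefs[fit$pivot] <- fit$coefficients
  coefs
}

# Regularization step: candidates sorted by decreasing |u|; the admissible
# windows are contiguous runs whose first (largest) entry is at most twice
# the last (smallest); pick the one with maximal sum of squared u.
romp_select_window <- function(u_abs_sorted) {
  k <- length(u_abs_sorted)
  best_energy <- -Inf
  best <- c(1L, 1L)
  csq <- cumsum(u_abs_sorted^2)
  for (i in seq_len(k)) {
    # largest j with u[j] >= u[i] / 2; vector is non-increasing
    j <- i + sum(u_abs_sorted[i:k] >= u_abs_sorted[i] / 2) - 1L
    energy <- csq[j] - if (i > 1L) csq[i - 1L] else 0
    if (energy > best_energy) {
      best_energy <- energy
      best <- c(i, j)
    }
  }
  seq.int(best[1], best[2])
}

#' Fit a sparse linear model by regularized orthogonal matching pursuit
#'
#' The response and the design columns are centered, and columns are
#' rescaled to unit norm for the selection inner products only; reported
#' weights are on the original feature scale.  The returned weight vector
#' has length `ncol(X) + 1` with the intercept as the last entry,
#' mirroring a design matrix whose last column is the constant term.
#'
#' @param X Design matrix or a prepared [romp_prepare()] object.
#' @param y Response vector (one voxel's training responses).
#' @param sparsity Target sparsity level s; the support never exceeds 2s.
#' @param tol Stop when the residual norm falls below `tol * ||y||`
#'   (centered norms).
#' @return A `romp_fit`: `weights` (length p + 1, intercept last),
#'   `support` (sorted selected columns with nonzero coefficients),
#'   `residual_norm`, `residual_path` (norm after each refit), `layer_id`
#'   (filled by callers fitting per layer).
#' @export
fit_romp <- function(X, y, sparsity = 20, tol = 1e-4) {
  design <- if (inherits(X, "romp_design")) X else romp_prepare(X)
  sparsity <- assert_count(sparsity, "sparsity")
  y <- as.numeric(y)
  if (anyNA(y) || any(!is.finite(y))) {
    abort("`y` contains missing or non-finite values.",
          class = "voxelencode_invalid_input")
  }
  if (length(y) != design$m) {
    abort(sprintf("length(y) == %d but the design has %d rows.",
                  length(y), design$m),
          class = "voxelencode_invalid_input")
  }
  p <- design$p
  intercept_only <- function() {
    structure(list(weights = c(numeric(p), mean(y)), support = integer(0),
                   residual_norm = sqrt(sum((y - mean(y))^2)),
                   residual_path = numeric(0),
                   sparsity = sparsity, tol = tol, p = p, layer_id = NA_integer_),
              class = "romp_fit")
  }
  yc <- y - mean(y)
  ynorm <- sqrt(sum(yc^2))
  if (ynorm == 0) return(intercept_only())

  support <- integer(0)
  coefs <- numeric(0)
  r <- yc
  res_path <- numeric(0)
  repeat {
    u <- crossprod(design$Xn, r)[, 1]
    if (length(support)) u[support] <- 0
    au <- abs(u)
    nz <- which(au > 0)
    if (!length(nz)) break
    cand <- nz[order(au[nz], decreasing = TRUE)]
    cand <- cand[seq_len(min(sparsity, length(cand)))]
    win <- romp_select_window(au[cand])
    # never exceed the 2s support budget: keep the largest-|u| entries of
    # the window (it is ordered by decreasing |u|)
    budget <- 2L * sparsity - length(support)
    win <- win[seq_len(min(length(win), budget))]
    support <- c(support, cand[win])
    coefs <- ls_coefs(design$Xc[, support, drop = FALSE], yc)
    r <- yc - design$Xc[, support, drop = FALSE] %*% coefs
    res_path <- c(res_path, sqrt(sum(r^2)))
    if (length(support) >= 2L * sparsity || sqrt(sum(r^2)) <= tol * ynorm) break
  }
  if (!length(support)) return(intercept_only())
  # drop numerically-zero coefficients (indices selected along the way that
  # the exact least-squares solution does not use)
  keep <- abs(coefs) > 1e-10 * max(abs(coefs))
  support <- support[keep]
  coefs <- coefs[keep]
  if (!length(support)) return(intercept_only())
  ord <- order(support)
  support <- support[ord]
  coefs <- coefs[ord]
  w <- numeric(p + 1L)
  w[support] <- coefs
  w[p + 1L] <- mean(y) - sum(design$center[support] * coefs)
  structure(list(weights = w, support = support,
                 residual_norm = sqrt(sum(r^2)),
                 residual_path = res_path,
                 sparsity = sparsity, tol = tol, p = p,
                 layer_id = NA_integer_),
            class = "romp_fit")
}

#' Predict responses from a fitted sparse linear model
#'
#' @param object A `romp_fit`.
#' @param newdata Feature matrix with the same columns as the training
#'   design (no constant column).
#' @param ... Unused.
#' @return Numeric vector `newdata %*% w + intercept`.
#' @export
predict.romp_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    abort(sprintf("`newdata` has %d columns; the model expects %d.",
                  ncol(newdata), object$p),
          class = "voxelencode_invalid_input")
  }
  p <- object$p
  drop(newdata %*% object$weights[seq_len(p)]) + object$weights[p + 1L]
}

#' @export
print.romp_fit <- function(x, ...) {
  cat(sprintf("<romp_fit> %d/%d features selected (s = %d), residual norm %.4g\n",
              length(x$support), x$p, x$sparsity, x$residual_norm))
  invisible(x)
}

#' Tidy a ROMP fit
#'
#' @param x A `romp_fit`.
#' @param ... Unused.
#' @return One row per selected feature plus the intercept: `term`,
#'   `estimate`.
#' @export
tidy.romp_fit <- function(x, ...) {
  tibble(
    term = c(sprintf("x%d", x$support), "(Intercept)"),
    estimate = c(x$weights[x$support], x$weights[x$p + 1L])
  )
}

#' Summarise a ROMP fit in one row
#'
#' @param x A `romp_fit`.
#' @param ... Unused.
#' @return A one-row tibble: number of selected features, sparsity target,
#'   residual norm, design width.
#' @export
glance.romp_fit <- function(x, ...) {
  tibble(n_selected = length(x$support), sparsity = x$sparsity,
         residual_norm = x$residual_norm, p = x$p)
}
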