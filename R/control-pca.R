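# Control Probe Adjustment: PCA of control-probe intensities whose scores
# become regression covariates absorbing batch and technical variation.

#' Control-probe feature matrix
#'
#' One feature per (control probe, colour channel), excluding negative
#' controls (they measure background, not chemistry). Zero-variance
#' features are dropped with a message. Feature order is deterministic:
#' control id within channel, green before red.
#'
#' @param raw A [raw_intensities()] object.
#' @param control_manifest The control manifest.
#' @param log_transform Log-transform intensities first? Off by default.
#' @return A features x samples numeric matrix.
#' @export
control_feature_matrix <- function(raw, control_manifest,
                                   log_transform = FALSE) {
  keep <- control_manifest$category != "negative"
  if (!any(keep)) abort("no non-negative control probes available")
  ids <- control_manifest$control_id[keep]
  F <- rbind(raw$control_green[ids, , drop = FALSE],
             raw$control_red[ids, , drop = FALSE])
  rownames(F) <- c(paste0(ids, ".green"), paste0(ids, ".red"))
  F <- F[order(rownames(F)), , drop = FALSE]
  if (log_transform) F <- log(F + 1)
  v <- apply(F, 1, var)
  if (any(v == 0)) {
    inform(paste0("dropping ", sum(v == 0),
                  " zero-variance control feature(s)"))
    F <- F[v > 0, , drop = FALSE]
  }
  F
}

# Deterministic sign convention: within each component, the loading with the
# largest magnitude is made positive.
fix_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal components of control-probe features
#'
#' Features are centred and (by default) scaled to unit variance, then
#' decomposed by SVD. The sample scores of the first `k` components
#' (pipeline default 30) are used as linear covariates in all downstream
#' regressions.
#'
#' @param features Output of [control_feature_matrix()].
#' @param k Number of components to keep.
#' @param scale. Scale features to unit variance (correlation PCA, the
#'   default) or leave on the covariance scale.
#' @return A list with class `control_pcs`: `scores` (samples x k, columns
#'   `PC1`..), `loadings`, `explained` (variance fractions), `k`.
#' @export
control_pcs <- function(features, k = 30, scale. = TRUE) {
  kmax <- min(nrow(features), ncol(features)) - 1L
  if (k > kmax)
    abort(paste0("k = ", k, " exceeds the maximum of ", kmax,
                 " for ", nrow(features), " features x ", ncol(features),
                 " samples"))
  pr <- prcomp(t(features), center = TRUE, scale. = scale., rank. = k)
  fx <- fix_signs(pr$rotation, pr$x)
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- fx$scores
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- colnames(features)
  structure(list(scores = scores[, seq_len(k), drop = FALSE],
                 loadings = fx$loadings,
                 explained = expl[seq_len(k)], k = k),
            class = "control_pcs")
}

#' @export
print.control_pcs <- function(x, ...) {
  cat("<control_pcs> ", nrow(x$scores), " samples x ", x$k, " PCs; PC1 ",
      sprintf("explains %.1f%% of variance\n", 100 * x$explained[1]), sep = "")
  invisible(x)
}
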