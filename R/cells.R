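# Reference-based white blood cell deconvolution by constrained projection.

#' Estimate white-cell proportions from methylation
#'
#' Houseman-style constrained projection: for each sample, solve
#' `min_w || y - B w ||^2` subject to `w >= 0`, where `y` is the sample's
#' beta values at the reference markers present on the array and `B` the
#' cell-type reference profiles at those markers. No sum-to-one constraint
#' is imposed: the pipeline additionally adjusts for the measured total
#' white-cell count as its own covariate. Reference markers absent from the
#' data are dropped (with a count message); markers missing within a sample
#' are dropped for that sample only.
#'
#' @param beta A [beta_matrix()].
#' @param reference Numeric matrix, reference markers x cell types, with
#'   marker-id rownames.
#' @return A tibble `sample_id`, one `wbc_est_<cell>` column per cell type,
#'   and `resid_norm` (per-sample residual norm of the fit); the markers
#'   used are attached as attribute `markers_used`.
#' @export
estimate_wbc <- function(beta, reference) {
  common <- intersect(rownames(reference), rownames(beta$beta))
  if (length(common) < 2)
    abort("fewer than 2 reference markers intersect the data")
  dropped <- nrow(reference) - length(common)
  if (dropped > 0)
    inform(paste0(dropped, " reference marker(s) absent from the array; ",
                  length(common), " used"))
  B <- reference[common, , drop = FALSE]
  if (qr(B)$rank < ncol(B)) {
    warn("reference matrix is rank-deficient on the intersected markers; using pseudo-inverse least squares")
  }
  Y <- beta$beta[common, , drop = FALSE]
  K <- ncol(B)
  fit1 <- function(y) {
    ok <- !is.na(y)
    if (sum(ok) < K) return(c(rep(NA_real_, K), NA_real_))
    sol <- pracma::lsqnonneg(B[ok, , drop = FALSE], y[ok])
    c(pmax(sol$x, 0), sqrt(sol$resid.norm))
  }
  est <- apply(Y, 2, fit1)
  w <- t(est[seq_len(K), , drop = FALSE])
  colnames(w) <- paste0("wbc_est_", colnames(B))
  out <- tibble::as_tibble(w)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(Y)), out)
  out$resid_norm <- est[K + 1, ]
  attr(out, "markers_used") <- common
  out
}
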