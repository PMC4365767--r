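# Stratified quantile normalisation of intensities and beta computation.

QN_SCHEMES <- c("QN-I6", "QN-I4", "QN-I2", "QN-B3", "none")

# Category label of each (marker, role) signal under a stratification
# scheme. Type II M signals are read in the green channel and Type II U
# signals in the red channel.
signal_category <- function(manifest, role, scheme) {
  ch <- signal_channel(manifest, role)
  ty <- manifest$probe_type
  switch(scheme,
    "QN-I2" = paste0(ch),
    "QN-I4" = paste0("Type-", ty, " ", ch),
    "QN-I6" = paste0("Type-", ty, " ",
                     ifelse(ty == "II", "", paste0(role, " ")), ch),
    abort(paste0("unknown probe stratification scheme: ", scheme)))
}

#' Stratify intensity signals into normalisation categories
#'
#' Assigns every (marker, M/U role) signal to exactly one category of the
#' chosen scheme. `QN-I6` yields the six canonical categories Type-I M red,
#' Type-I U red, Type-I M green, Type-I U green, Type-II green (all Type II
#' M signals) and Type-II red (all Type II U signals); `QN-I4` collapses the
#' M/U split, `QN-I2` keeps only the colour channel.
#'
#' @param manifest The marker manifest.
#' @param scheme One of `"QN-I2"`, `"QN-I4"`, `"QN-I6"`.
#' @return A tibble `marker_id`, `role`, `category`.
#' @export
stratify <- function(manifest, scheme = "QN-I6") {
  if (!scheme %in% c("QN-I2", "QN-I4", "QN-I6"))
    abort("stratify() applies to intensity schemes QN-I2/QN-I4/QN-I6")
  dplyr::bind_rows(
    tibble::tibble(marker_id = manifest$marker_id, role = "M",
                   category = signal_category(manifest, "M", scheme)),
    tibble::tibble(marker_id = manifest$marker_id, role = "U",
                   category = signal_category(manifest, "U", scheme)))
}

#' Quantile-normalise a matrix across samples
#'
#' Each sample (column) is mapped onto the mean of the per-sample sorted
#' value distributions; missing entries stay missing, with non-missing
#' values placed by interpolated fractional ranks, and ties receive the mean
#' of their rank span. Delegates to `limma::normalizeQuantiles(ties = TRUE)`,
#' which implements exactly this behaviour.
#'
#' @param X Numeric matrix (features x samples), may contain `NA`.
#' @return The normalised matrix, same shape and dimnames.
#' @export
quantile_normalize <- function(X) {
  if (ncol(X) < 2) abort("quantile normalisation requires >= 2 samples")
  nn <- colSums(!is.na(X))
  if (any(nn < 2))
    abort(paste0("sample ", colnames(X)[which(nn < 2)[1]],
                 " has fewer than 2 non-missing values in a category"))
  out <- limma::normalizeQuantiles(X, ties = TRUE)
  dimnames(out) <- dimnames(X)
  out
}

#' Compute beta values from M and U intensities
#'
#' `beta = M / (M + U + offset)`; the offset (Illumina convention 100)
#' keeps values strictly below 1. Entries are missing wherever either
#' signal is missing.
#'
#' @param M,U Markers x samples intensity matrices.
#' @param missing Logical mask of missing entries.
#' @param offset Positive offset in the denominator.
#' @return A [beta_matrix()].
#' @export
compute_beta <- function(M, U, missing = NULL, offset = 100) {
  if (offset <= 0) abort("beta offset must be > 0")
  b <- M / (M + U + offset)
  if (!is.null(missing)) b[missing] <- NA_real_
  beta_matrix(b, offset = offset)
}

#' Normalise intensities and compute beta values
#'
#' For the intensity schemes (`QN-I2`/`QN-I4`/`QN-I6`), signals are
#' stratified, each category quantile-normalised across samples, recombined
#' and converted to beta values. `QN-B3` instead computes raw beta values
#' and quantile-normalises them within three probe categories (Type II,
#' Type I red, Type I green). `"none"` computes beta values without any
#' normalisation. Autosomal and sex-chromosome markers should be normalised
#' in separate runs (see [run_cpacor()]), which keeps their category pools
#' apart.
#'
#' @param raw QC-masked [raw_intensities()].
#' @param manifest The matching manifest.
#' @param scheme One of `"QN-I6"` (pipeline default), `"QN-I4"`, `"QN-I2"`,
#'   `"QN-B3"`, `"none"`.
#' @param offset Beta-denominator offset.
#' @return A [beta_matrix()].
#' @export
normalize_betas <- function(raw, manifest, scheme = "QN-I6", offset = 100) {
  scheme <- match.arg(scheme, QN_SCHEMES)
  if (scheme == "none")
    return(compute_beta(raw$M, raw$U, raw$missing, offset))
  if (scheme == "QN-B3") {
    b <- compute_beta(raw$M, raw$U, raw$missing, offset)$beta
    cat3 <- ifelse(manifest$probe_type == "II", "Type-II",
                   paste0("Type-I ", manifest$channel))
    for (cc in unique(cat3)) {
      idx <- cat3 == cc
      b[idx, ] <- quantile_normalize(b[idx, , drop = FALSE])
    }
    b <- pmin(b, 1 - 1e-12)  # QN of betas can touch but not exceed the bound
    return(beta_matrix(b, offset = offset))
  }
  M <- raw$M; U <- raw$U
  M[raw$missing] <- NA_real_; U[raw$missing] <- NA_real_
  cat_M <- signal_category(manifest, "M", scheme)
  cat_U <- signal_category(manifest, "U", scheme)
  for (cc in unique(c(cat_M, cat_U))) {
    im <- cat_M == cc; iu <- cat_U == cc
    X <- rbind(M[im, , drop = FALSE], U[iu, , drop = FALSE])
    X <- quantile_normalize(X)
    if (any(im)) M[im, ] <- X[seq_len(sum(im)), , drop = FALSE]
    if (any(iu)) U[iu, ] <- X[sum(im) + seq_len(sum(iu)), , drop = FALSE]
  }
  Mz <- M; Uz <- U
  Mz[raw$missing] <- 0; Uz[raw$missing] <- 0
  compute_beta(pmax(Mz, 0), pmax(Uz, 0), raw$missing, offset)
}
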