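# Quality control: background correction, detection P values, masking,
# call rates, sex checks and outlier metrics.

#' Smallest detection P value reported by the pipeline
#'
#' Detection P values are upper-tail complements (`1 - CDF`) evaluated in
#' double precision; the pipeline floors them at machine epsilon
#' (2.220446e-16) rather than letting them underflow to zero, so log-scale
#' diagnostics never divide by zero.
#' @export
DETECTION_P_FLOOR <- .Machine$double.eps

signal_channel <- function(manifest, role = c("M", "U")) {
  role <- match.arg(role)
  ifelse(manifest$probe_type == "II",
         if (role == "M") "green" else "red",
         manifest$channel)
}

negative_controls <- function(raw, control_manifest) {
  neg <- control_manifest$category == "negative"
  if (!any(neg)) abort("no negative control probes present")
  list(green = raw$control_green[control_manifest$control_id[neg], ,
                                 drop = FALSE],
       red = raw$control_red[control_manifest$control_id[neg], ,
                             drop = FALSE])
}

#' Background-correct intensities against negative controls
#'
#' For every sample and colour channel, a background level is estimated as a
#' low quantile (default the 5th percentile) of the negative-control
#' intensities in that channel, subtracted from all probe and control
#' intensities in that channel, and the result floored at `floor`.
#'
#' @param raw A [raw_intensities()] object.
#' @param manifest The marker manifest (routes M/U signals to channels).
#' @param control_manifest The control manifest (identifies negatives).
#' @param probs Quantile of the negative controls used as background.
#' @param floor Lower clamp applied after subtraction.
#' @return A background-corrected [raw_intensities()] object.
#' @export
background_correct <- function(raw, manifest, control_manifest,
                               probs = 0.05, floor = 1) {
  neg <- negative_controls(raw, control_manifest)
  bg_g <- apply(neg$green, 2, quantile, probs = probs, names = FALSE)
  bg_r <- apply(neg$red, 2, quantile, probs = probs, names = FALSE)
  corr <- function(x, bg_row) pmax(sweep(x, 2, bg_row, "-"), floor)
  ch_M <- signal_channel(manifest, "M")
  ch_U <- signal_channel(manifest, "U")
  sub_ch <- function(x, ch) {
    out <- x
    g <- ch == "green"
    out[g, ] <- corr(x[g, , drop = FALSE], bg_g)
    out[!g, ] <- corr(x[!g, , drop = FALSE], bg_r)
    out
  }
  raw_intensities(sub_ch(raw$M, ch_M), sub_ch(raw$U, ch_U),
                  corr(raw$control_green, bg_g),
                  corr(raw$control_red, bg_r),
                  raw$missing)
}

#' Detection P values from negative-control background
#'
#' The background distribution per sample and colour channel is summarised
#' by the median and the normal-consistent MAD of the negative controls. A
#' probe's total signal M+U is compared to the background of its channels:
#' Type I probes against `Normal(2*mu_c, 2*sigma_c)` of their single
#' channel, Type II probes against `Normal(mu_G + mu_R, sigma_G + sigma_R)`
#' (spreads added, not combined in quadrature, following the convention of
#' the minfi detection test). P values are the upper-tail complement
#' `1 - CDF`, floored at [DETECTION_P_FLOOR]; they are never exactly zero.
#'
#' @param raw Background-corrected intensities.
#' @param manifest The marker manifest.
#' @param control_manifest The control manifest.
#' @return A list with class `detection_p`: `p` (markers x samples matrix)
#'   and `floor`.
#' @export
detection_pvalues <- function(raw, manifest, control_manifest) {
  neg <- negative_controls(raw, control_manifest)
  mu_g <- apply(neg$green, 2, median); sd_g <- apply(neg$green, 2, mad)
  mu_r <- apply(neg$red, 2, median); sd_r <- apply(neg$red, 2, mad)
  if (any(c(sd_g, sd_r) == 0))
    abort(paste0("a negative-control MAD is zero; detection P values are ",
                 "undefined (add jitter or more negative controls)"))
  total <- raw$M + raw$U
  n <- ncol(total); m <- nrow(total)
  mu <- matrix(0, m, n); sdv <- matrix(0, m, n)
  t1 <- manifest$probe_type == "I"
  g <- manifest$channel == "green"
  fill <- function(idx, mu_row, sd_row) {
    if (!any(idx)) return(invisible())
    mu[idx, ] <<- matrix(mu_row, sum(idx), n, byrow = TRUE)
    sdv[idx, ] <<- matrix(sd_row, sum(idx), n, byrow = TRUE)
  }
  fill(t1 & g, 2 * mu_g, 2 * sd_g)
  fill(t1 & !g, 2 * mu_r, 2 * sd_r)
  fill(!t1, mu_g + mu_r, sd_g + sd_r)
  p_raw <- 1 - pnorm((total - mu) / sdv)
  p <- pmax(p_raw, DETECTION_P_FLOOR)
  dimnames(p) <- dimnames(p_raw) <- dimnames(raw$M)
  structure(list(p = p, p_raw = p_raw, floor = DETECTION_P_FLOOR),
            class = "detection_p")
}

#' Mask intensities that fail the detection test
#'
#' Entries with detection P at or above `threshold` are set to missing (the
#' comparison is inclusive: `p >= threshold` masks). Masking uses the raw
#' complement values, in which a signal overwhelmingly above background
#' underflows to exactly zero — this is what makes a threshold of `1e-16`,
#' below the double-precision floor of the reported values, meaningful: it
#' keeps exactly the entries whose detection P underflowed. Masking only
#' ever adds to the existing mask.
#'
#' @param raw A [raw_intensities()] object.
#' @param detp A `detection_p` object from [detection_pvalues()].
#' @param threshold Detection threshold in (0, 1]; the pipeline default is
#'   `1e-16`.
#' @return `raw` with an updated missingness mask.
#' @export
apply_detection_mask <- function(raw, detp, threshold = 1e-16) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  raw$missing <- raw$missing | (detp$p_raw >= threshold)
  raw
}

#' Sample and marker call rates
#'
#' @param raw A masked [raw_intensities()] object.
#' @return A list of tibbles `sample` (`sample_id`, `call_rate`) and
#'   `marker` (`marker_id`, `call_rate`): fractions of non-missing entries.
#' @export
call_rates <- function(raw) {
  list(sample = tibble::tibble(sample_id = colnames(raw$M),
                               call_rate = unname(1 - colMeans(raw$missing))),
       marker = tibble::tibble(marker_id = rownames(raw$M),
                               call_rate = unname(1 - rowMeans(raw$missing))))
}

#' Check recorded sex against Y-chromosome call rates
#'
#' Y-chromosome probes in genetic females measure only background, so their
#' call rate after stringent detection masking is near zero; a female with a
#' high Y call rate (or a male with a low one) indicates a sample swap.
#'
#' @param raw Masked intensities.
#' @param manifest The marker manifest (supplies Y markers).
#' @param covariates Covariate table with a `sex` column.
#' @param y_high Female Y call rate above this is a mismatch (default 0.5).
#' @param y_low Male Y call rate below this is a mismatch (default 0.5).
#' @return A tibble `sample_id`, `sex`, `y_call_rate`, `verdict` in
#'   `{"pass", "mismatch", "untestable"}`.
#' @export
sex_check <- function(raw, manifest, covariates, y_high = 0.5, y_low = 0.5) {
  is_y <- manifest$chromosome == "Y"
  if (!any(is_y)) {
    return(tibble::tibble(sample_id = covariates$sample_id,
                          sex = covariates$sex,
                          y_call_rate = NA_real_, verdict = "untestable"))
  }
  ycr <- unname(1 - colMeans(raw$missing[is_y, , drop = FALSE]))
  sex <- covariates$sex[match(colnames(raw$M), covariates$sample_id)]
  verdict <- ifelse(sex == "female" & ycr > y_high, "mismatch",
                    ifelse(sex == "male" & ycr < y_low, "mismatch", "pass"))
  tibble::tibble(sample_id = colnames(raw$M), sex = sex,
                 y_call_rate = ycr, verdict = verdict)
}

#' Per-marker outlier rates
#'
#' A beta value is an outlier if it falls below Q1 - 1.5*IQR or above
#' Q3 + 1.5*IQR of its marker, with quartiles by linear interpolation
#' (quantile type 7). The rate is outliers / non-missing; markers with
#' fewer than 4 non-missing values get `NA`.
#'
#' @param beta A [beta_matrix()].
#' @return A tibble `marker_id`, `n_used`, `outlier_rate`.
#' @export
outlier_rate <- function(beta) {
  b <- beta$beta
  rate <- apply(b, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 4) return(NA_real_)
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    mean(x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr)
  })
  tibble::tibble(marker_id = rownames(b),
                 n_used = rowSums(!is.na(b)),
                 outlier_rate = unname(rate))
}

#' Filter samples on call rate and sex mismatch
#'
#' Samples with call rate strictly below `sample_threshold` (default 0.98,
#' i.e. the "<98%" rule) or with a sex-check mismatch are excluded; every
#' exclusion carries a machine-readable reason code.
#'
#' @param rates Output of [call_rates()].
#' @param sex_verdicts Optional output of [sex_check()].
#' @param sample_threshold Minimum sample call rate to keep (strict `<`
#'   excludes).
#' @return A list: `kept` (character sample ids) and `excluded` (tibble
#'   `sample_id`, `reason`).
#' @export
qc_filter <- function(rates, sex_verdicts = NULL, sample_threshold = 0.98) {
  ex <- tibble::tibble(sample_id = character(0), reason = character(0))
  low <- rates$sample$sample_id[rates$sample$call_rate < sample_threshold]
  if (length(low) > 0)
    ex <- dplyr::bind_rows(ex, tibble::tibble(sample_id = low,
                                              reason = "low_call_rate"))
  if (!is.null(sex_verdicts)) {
    mm <- sex_verdicts$sample_id[sex_verdicts$verdict == "mismatch"]
    if (length(mm) > 0)
      ex <- dplyr::bind_rows(ex, tibble::tibble(sample_id = mm,
                                                reason = "sex_mismatch"))
  }
  kept <- setdiff(rates$sample$sample_id, ex$sample_id)
  if (length(kept) == 0) abort("all samples excluded by QC")
  list(kept = kept, excluded = ex)
}

#' Subset a raw-intensity object to selected samples
#'
#' @param raw A [raw_intensities()] object.
#' @param sample_ids Samples to keep, in the order given.
#' @return A [raw_intensities()] restricted to `sample_ids`.
#' @export
subset_samples <- function(raw, sample_ids) {
  raw_intensities(raw$M[, sample_ids, drop = FALSE],
                  raw$U[, sample_ids, drop = FALSE],
                  raw$control_green[, sample_ids, drop = FALSE],
                  raw$control_red[, sample_ids, drop = FALSE],
                  raw$missing[, sample_ids, drop = FALSE])
}

#' Subset a raw-intensity object to selected markers
#'
#' @param raw A [raw_intensities()] object.
#' @param marker_ids Markers to keep, in the order given.
#' @return A [raw_intensities()] restricted to `marker_ids`.
#' @export
subset_markers <- function(raw, marker_ids) {
  raw_intensities(raw$M[marker_ids, , drop = FALSE],
                  raw$U[marker_ids, , drop = FALSE],
                  raw$control_green, raw$control_red,
                  raw$missing[marker_ids, , drop = FALSE])
}
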