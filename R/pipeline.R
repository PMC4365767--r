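# End-to-end orchestration of the CPACOR workflow.

#' Pipeline configuration
#'
#' Defaults reproduce the reference pipeline settings: detection threshold
#' 1e-16 (with an optional initial 0.05 pass for top-level QC), sample
#' call-rate threshold 0.98, QN-I6 intensity normalisation, beta offset
#' 100, 30 control-probe PCs, 5 residual PCs, logistic association.
#'
#' @param detection_threshold Final detection-P threshold.
#' @param initial_threshold Optional first-pass threshold (two-pass QC);
#'   `NULL` runs a single pass at `detection_threshold`.
#' @param sample_call_rate Minimum sample call rate (strict `<` excludes).
#' @param scheme Normalisation scheme (see [normalize_betas()]).
#' @param beta_offset Beta-denominator offset.
#' @param n_control_pcs,n_residual_pcs Numbers of adjustment components.
#' @param family Association family, `"logistic"` or `"linear"`.
#' @param stream Marker stream: `"autosomal"`, `"X-male"`, `"X-female"` or
#'   `"Y-male"`; sex-chromosome streams subset samples by sex and apply
#'   their own call-rate filter.
#' @param seed Seed for any stochastic step.
#' @return A list with class `cpacor_config`.
#' @export
cpacor_config <- function(detection_threshold = 1e-16,
                          initial_threshold = NULL,
                          sample_call_rate = 0.98,
                          scheme = "QN-I6", beta_offset = 100,
                          n_control_pcs = 30, n_residual_pcs = 5,
                          family = "logistic",
                          stream = "autosomal", seed = 1L) {
  stopifnot(detection_threshold > 0, detection_threshold <= 1)
  stream <- match.arg(stream, c("autosomal", "X-male", "X-female", "Y-male"))
  structure(list(detection_threshold = detection_threshold,
                 initial_threshold = initial_threshold,
                 sample_call_rate = sample_call_rate,
                 scheme = match.arg(scheme, QN_SCHEMES),
                 beta_offset = beta_offset,
                 n_control_pcs = n_control_pcs,
                 n_residual_pcs = n_residual_pcs,
                 family = match.arg(family, c("logistic", "linear")),
                 stream = stream, seed = seed),
            class = "cpacor_config")
}

stream_markers <- function(manifest, stream) {
  switch(stream,
         "autosomal" = !manifest$chromosome %in% c("X", "Y"),
         "X-male" = , "X-female" = manifest$chromosome == "X",
         "Y-male" = manifest$chromosome == "Y")
}

stream_sex <- function(stream) {
  switch(stream, "autosomal" = c("male", "female"),
         "X-male" = , "Y-male" = "male", "X-female" = "female")
}

#' Run the full CPACOR pipeline
#'
#' Executes, in order: background correction, detection P values, masking,
#' call rates, sex check and sample filtering (optionally in two passes:
#' an initial lenient threshold followed by the final stringent one with
#' call rates recomputed), stratified quantile normalisation and beta
#' computation, control-probe PCA, cell-composition estimation, covariate
#' adjustment of betas, residual PCA, and the final per-marker regression
#' of phenotype on beta plus the full adjustment set. Every threshold and
#' exclusion is recorded in the provenance log.
#'
#' @param dataset A list with `manifest`, `control_manifest`, `raw`,
#'   `covariates` (as from [read_cpacor_dataset()] or the generator).
#' @param reference Cell-type reference beta matrix for [estimate_wbc()];
#'   `NULL` skips cell adjustment.
#' @param config A [cpacor_config()].
#' @return A list with class `cpacor_fit`: `result` (association tibble),
#'   `qc` (QC report), `beta`, `control_pcs`, `residual_pcs`,
#'   `cell_estimates`, `design`, `log` (provenance tibble).
#' @export
run_cpacor <- function(dataset, reference = NULL, config = cpacor_config()) {
  log <- list()
  note <- function(stage, detail) {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage, detail = detail)
  }
  manifest <- dataset$manifest
  raw <- dataset$raw
  covariates <- dataset$covariates

  sexes <- stream_sex(config$stream)
  keep_s <- covariates$sample_id[covariates$sex %in% sexes]
  if (length(keep_s) < nrow(covariates)) {
    raw <- subset_samples(raw, keep_s)
    covariates <- covariates[covariates$sample_id %in% keep_s, ]
    note("stream", paste0(config$stream, ": ", length(keep_s), " samples"))
  }

  raw <- background_correct(raw, manifest, dataset$control_manifest)
  note("background_correct", "5th-percentile negative-control background, floor 1")
  detp <- detection_pvalues(raw, manifest, dataset$control_manifest)

  thr1 <- config$initial_threshold %||% config$detection_threshold
  masked <- apply_detection_mask(raw, detp, thr1)
  note("detection_mask", paste0("threshold ", format(thr1)))

  sm <- stream_markers(manifest, config$stream)
  mstream <- subset_markers(masked, manifest$marker_id[sm])
  mani_s <- manifest[sm, ]

  rates <- call_rates(mstream)
  sexv <- sex_check(masked, manifest, covariates)
  filt <- qc_filter(rates, sexv, config$sample_call_rate)
  note("qc_filter", paste0(length(filt$kept), " samples kept, ",
                           nrow(filt$excluded), " excluded"))

  if (!is.null(config$initial_threshold)) {
    masked <- apply_detection_mask(raw, detp, config$detection_threshold)
    mstream <- subset_markers(masked, manifest$marker_id[sm])
    rates <- call_rates(subset_samples(mstream, filt$kept))
    filt2 <- qc_filter(rates, NULL, config$sample_call_rate)
    filt$kept <- filt2$kept
    filt$excluded <- dplyr::bind_rows(filt$excluded, filt2$excluded)
    note("detection_mask", paste0("final threshold ",
                                  format(config$detection_threshold),
                                  "; call rates recomputed; ",
                                  length(filt$kept), " samples kept"))
  }

  mstream <- subset_samples(mstream, filt$kept)
  covariates <- covariates[match(filt$kept, covariates$sample_id), ]
  rates <- call_rates(mstream)

  beta <- normalize_betas(mstream, mani_s, config$scheme, config$beta_offset)
  note("normalize", paste0("scheme ", config$scheme, ", offset ",
                           config$beta_offset))

  feats <- control_feature_matrix(mstream, dataset$control_manifest)
  cpcs <- control_pcs(feats, k = config$n_control_pcs)
  note("control_pcs", paste0(config$n_control_pcs, " PCs; PC1 explains ",
                             sprintf("%.1f%%", 100 * cpcs$explained[1])))

  cells <- NULL
  if (!is.null(reference)) {
    cells <- estimate_wbc(beta, reference)
    covariates <- dplyr::left_join(
      covariates, dplyr::select(cells, -"resid_norm"), by = "sample_id")
    note("estimate_wbc", paste0(length(attr(cells, "markers_used")),
                                " reference markers used"))
  }

  design <- build_design(covariates, control_pcs = cpcs)
  resid <- adjust_betas(beta, design)
  rpcs <- residual_pcs(resid, k = config$n_residual_pcs)
  note("residual_pcs", paste0(config$n_residual_pcs, " PCs from ",
                              rpcs$n_markers_used, " complete markers"))

  design_full <- build_design(covariates, control_pcs = cpcs,
                              residual_pcs = rpcs)
  result <- marker_regression(covariates$phenotype, beta, design_full,
                              family = config$family, manifest = mani_s,
                              call_rate = rates$marker)
  note("marker_regression", paste0(config$family, " family, ",
                                   sum(!is.na(result$p)), " markers tested"))

  structure(list(result = result,
                 qc = list(rates = rates, sex_check = sexv,
                           excluded = filt$excluded),
                 beta = beta, control_pcs = cpcs, residual_pcs = rpcs,
                 cell_estimates = cells, design = design_full,
                 covariates = covariates, config = config,
                 log = dplyr::bind_rows(log)), class = "cpacor_fit")
}

#' @export
print.cpacor_fit <- function(x, ...) {
  cat("<cpacor_fit> ", nrow(x$result), " markers, ",
      nrow(x$covariates), " samples (stream ", x$config$stream, ")\n",
      sep = "")
  lam <- tryCatch(genomic_inflation(x$result$p), error = function(e) NA)
  if (is.finite(lam)) cat(sprintf("  genomic inflation lambda = %.3f\n", lam))
  invisible(x)
}
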