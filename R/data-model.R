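#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats median mad sd cor quantile pnorm qchisq pchisq lm glm
#'   binomial coef vcov complete.cases rnorm runif rbinom rgamma setNames
#'   prcomp lm.fit model.matrix p.adjust wilcox.test var
#' @importFrom utils head tail
NULL

CHROM_LEVELS <- c(as.character(1:22), "X", "Y")

#' Build and validate a marker manifest
#'
#' A manifest describes the geometry of every methylation marker on the
#' array: genomic location, Infinium probe chemistry (Type I uses two bead
#' types read in a single colour channel; Type II uses one bead type with the
#' methylated signal read in green and the unmethylated in red), and quality
#' flags. Flagged markers (non-CpG, predicted cross-hybridising, SNP in the
#' probe sequence) are retained throughout the pipeline and echoed in all
#' outputs, never silently dropped.
#'
#' @param manifest A data frame with columns `marker_id`, `chromosome`
#'   (`"1"`..`"22"`, `"X"`, `"Y"`), `position` (1-based bp on the forward
#'   strand), `probe_type` (`"I"` or `"II"`), `channel` (`"red"`, `"green"`,
#'   or `"both"`; Type II probes always carry `"both"`), and logical flag
#'   columns `flag_non_cpg`, `flag_cross_hybridising`, `flag_snp_in_probe`.
#' @return A validated tibble with class `cpacor_manifest`.
#' @export
as_manifest <- function(manifest) {
  req <- c("marker_id", "chromosome", "position", "probe_type", "channel",
           "flag_non_cpg", "flag_cross_hybridising", "flag_snp_in_probe")
  miss <- setdiff(req, names(manifest))
  if (length(miss) > 0)
    abort(paste0("manifest is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  m <- tibble::as_tibble(manifest)
  if (anyDuplicated(m$marker_id))
    abort("manifest marker_id values must be unique")
  if (any(m$position < 1))
    abort("manifest positions must be >= 1 (1-based coordinates)")
  if (!all(m$probe_type %in% c("I", "II")))
    abort("probe_type must be 'I' or 'II'")
  if (!all(m$channel %in% c("red", "green", "both")))
    abort("channel must be 'red', 'green' or 'both'")
  bad <- (m$probe_type == "II") != (m$channel == "both")
  if (any(bad))
    abort(paste0("probe_type II must pair with channel 'both' (and only then); ",
                 "offending marker: ", m$marker_id[which(bad)[1]]))
  if (!all(m$chromosome %in% CHROM_LEVELS))
    abort("chromosome labels must be '1'..'22', 'X' or 'Y'")
  class(m) <- c("cpacor_manifest", class(tibble::tibble()))
  m
}

#' Build and validate a control-probe manifest
#'
#' Control probes monitor assay chemistry (staining, extension,
#' hybridisation, bisulfite conversion, specificity); negative controls
#' measure background fluorescence and are the basis of detection P values.
#' At least one negative control is required.
#'
#' @param controls A data frame with columns `control_id` and `category`;
#'   the category `"negative"` identifies negative controls. Any other
#'   category taxonomy is accepted.
#' @return A validated tibble with class `cpacor_control_manifest`.
#' @export
as_control_manifest <- function(controls) {
  miss <- setdiff(c("control_id", "category"), names(controls))
  if (length(miss) > 0)
    abort(paste0("control manifest is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  ct <- tibble::as_tibble(controls)
  if (anyDuplicated(ct$control_id))
    abort("control_id values must be unique")
  if (!any(ct$category == "negative"))
    abort("control manifest must contain at least one 'negative' control probe")
  class(ct) <- c("cpacor_control_manifest", class(tibble::tibble()))
  ct
}

#' Construct a raw-intensity container
#'
#' Holds per-sample methylated (M) and unmethylated (U) signal intensities
#' for every marker, control-probe intensities in both colour channels, and
#' an explicit missingness mask. The mask is the single in-band encoding of
#' missing data: intensities themselves are never replaced by sentinels, so
#' detection masking and downstream quantile normalisation interact
#' predictably.
#'
#' @param M,U Numeric matrices, markers x samples, nonnegative, with
#'   rownames = marker ids and colnames = sample ids.
#' @param control_green,control_red Numeric matrices, controls x samples.
#' @param missing Logical matrix, same shape as `M`; `TRUE` marks entries
#'   set to missing (e.g. by detection-P masking).
#' @return An object of class `raw_intensities`.
#' @export
raw_intensities <- function(M, U, control_green, control_red, missing = NULL) {
  stopifnot(is.matrix(M), is.matrix(U),
            identical(dim(M), dim(U)),
            identical(dim(control_green), dim(control_red)))
  if (is.null(missing)) {
    missing <- matrix(FALSE, nrow(M), ncol(M), dimnames = dimnames(M))
  }
  stopifnot(identical(dim(missing), dim(M)))
  for (nm in c("M", "U")) {
    x <- get(nm)
    bad <- !missing & (!is.finite(x) | x < 0)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      abort(paste0("negative or non-finite ", nm, " intensity violates the ",
                   "nonnegativity invariant (marker ", rownames(x)[idx[1]],
                   ", sample ", colnames(x)[idx[2]], ")"))
    }
  }
  if (any(control_green < 0, na.rm = TRUE) || any(control_red < 0, na.rm = TRUE))
    abort("negative control-probe intensity violates the nonnegativity invariant")
  structure(list(M = M, U = U,
                 control_green = control_green, control_red = control_red,
                 missing = missing),
            class = "raw_intensities")
}

#' @export
print.raw_intensities <- function(x, ...) {
  cat("<raw_intensities> ", nrow(x$M), " markers x ", ncol(x$M), " samples; ",
      nrow(x$control_green), " control probes; ",
      sum(x$missing), " masked entries\n", sep = "")
  invisible(x)
}

#' Construct a beta-value matrix
#'
#' Beta values are methylation fractions M / (M + U + offset); the positive
#' offset keeps every value strictly below 1 and stabilises low-intensity
#' probes. Missing entries are `NA` exactly where the intensity mask was
#' `TRUE`.
#'
#' @param beta Numeric matrix markers x samples with values in `[0, 1)` or
#'   `NA`.
#' @param offset The positive offset used in the denominator.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(beta, offset = 100) {
  stopifnot(is.matrix(beta))
  if (offset <= 0) abort("beta offset must be > 0")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] >= 1)
    abort("beta values must lie in [0, 1)")
  structure(list(beta = beta, offset = offset), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("<beta_matrix> ", nrow(x$beta), " markers x ", ncol(x$beta),
      " samples; offset ", x$offset, "; ", sum(is.na(x$beta)),
      " missing entries\n", sep = "")
  invisible(x)
}

#' Validate a sample covariate table
#'
#' @param covariates A data frame with columns `sample_id`, `phenotype`
#'   (binary 0/1 or numeric), `age`, `sex` (`"male"`/`"female"`), `wbc_tot`
#'   (measured total white-cell count); optional batch label columns (e.g.
#'   `chip`) and estimated cell-fraction columns (`wbc_est_*`, filled by
#'   [estimate_wbc()]).
#' @param sample_ids Optional character vector the table must match in
#'   content and order (normally the intensity column names).
#' @return A validated tibble.
#' @export
as_covariate_table <- function(covariates, sample_ids = NULL) {
  req <- c("sample_id", "phenotype", "age", "sex", "wbc_tot")
  miss <- setdiff(req, names(covariates))
  if (length(miss) > 0)
    abort(paste0("covariate table is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  cv <- tibble::as_tibble(covariates)
  if (anyDuplicated(cv$sample_id)) abort("sample_id values must be unique")
  if (!is.null(sample_ids)) {
    extra <- setdiff(sample_ids, cv$sample_id)
    if (length(extra) > 0)
      abort(paste0("sample present in intensities but absent from covariates: ",
                   extra[1]))
    extra2 <- setdiff(cv$sample_id, sample_ids)
    if (length(extra2) > 0)
      abort(paste0("sample present in covariates but absent from intensities: ",
                   extra2[1]))
    cv <- cv[match(sample_ids, cv$sample_id), ]
  }
  est <- grep("^wbc_est_", names(cv), value = TRUE)
  if (length(est) > 0 && any(as.matrix(cv[est]) < -1e-8, na.rm = TRUE))
    abort("estimated cell fractions must be nonnegative")
  cv
}

chrom_rank <- function(chr) match(chr, CHROM_LEVELS)

#' Write a synthetic or real dataset to tab-separated files
#'
#' Writes `manifest.tsv`, `controls.tsv`, `intensities.tsv` (wide, one
#' `<sample>.M` and one `<sample>.U` column per sample; masked entries as
#' `NA`), `control_intensities.tsv` (long in channel: `control_id`,
#' `channel`, then one column per sample) and `covariates.tsv` into `dir`.
#'
#' @param manifest,control_manifest,raw,covariates Dataset components as
#'   produced by the generator or [read_cpacor_dataset()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cpacor_dataset <- function(manifest, control_manifest, raw, covariates,
                                 dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(control_manifest, file.path(dir, "controls.tsv"))
  Mna <- raw$M; Una <- raw$U
  Mna[raw$missing] <- NA_real_
  Una[raw$missing] <- NA_real_
  samp <- colnames(raw$M)
  wide <- tibble::tibble(marker_id = rownames(raw$M))
  for (s in samp) {
    wide[[paste0(s, ".M")]] <- Mna[, s]
    wide[[paste0(s, ".U")]] <- Una[, s]
  }
  readr::write_tsv(wide, file.path(dir, "intensities.tsv"))
  ctl <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(control_id = rownames(raw$control_green),
                                    channel = "green"),
                     tibble::as_tibble(raw$control_green)),
    dplyr::bind_cols(tibble::tibble(control_id = rownames(raw$control_red),
                                    channel = "red"),
                     tibble::as_tibble(raw$control_red)))
  readr::write_tsv(ctl, file.path(dir, "control_intensities.tsv"))
  readr::write_tsv(covariates, file.path(dir, "covariates.tsv"))
  invisible(dir)
}

#' Read a dataset written by [write_cpacor_dataset()]
#'
#' Cross-references all components: sample order is taken from the intensity
#' file and imposed on the covariate table; unknown marker or control ids
#' and negative intensities are fatal.
#'
#' @param dir Directory containing the five TSV files.
#' @return A list with elements `manifest`, `control_manifest`, `raw`
#'   (`raw_intensities`), `covariates`.
#' @export
read_cpacor_dataset <- function(dir) {
  manifest <- as_manifest(readr::read_tsv(file.path(dir, "manifest.tsv"),
                                          col_types = readr::cols(
                                            chromosome = "c", position = "i",
                                            .default = readr::col_guess())))
  control_manifest <- as_control_manifest(
    readr::read_tsv(file.path(dir, "controls.tsv"), col_types = "cc"))
  wide <- readr::read_tsv(file.path(dir, "intensities.tsv"),
                          col_types = readr::cols(marker_id = "c",
                                                  .default = "d"))
  unknown <- setdiff(wide$marker_id, manifest$marker_id)
  if (length(unknown) > 0)
    abort(paste0("intensity file contains marker id absent from manifest: ",
                 unknown[1]))
  if (!identical(wide$marker_id, manifest$marker_id))
    abort("intensity file marker order must match the manifest")
  cn <- setdiff(names(wide), "marker_id")
  mcols <- grep("\\.M$", cn, value = TRUE)
  ucols <- grep("\\.U$", cn, value = TRUE)
  samp <- sub("\\.M$", "", mcols)
  if (!setequal(samp, sub("\\.U$", "", ucols)))
    abort("each sample needs both a <sample>.M and a <sample>.U column")
  M <- as.matrix(wide[paste0(samp, ".M")])
  U <- as.matrix(wide[paste0(samp, ".U")])
  dimnames(M) <- dimnames(U) <- list(wide$marker_id, samp)
  missing <- is.na(M) | is.na(U)
  M[missing] <- 0; U[missing] <- 0
  ctl <- readr::read_tsv(file.path(dir, "control_intensities.tsv"),
                         col_types = readr::cols(control_id = "c",
                                                 channel = "c",
                                                 .default = "d"))
  unknown <- setdiff(ctl$control_id, control_manifest$control_id)
  if (length(unknown) > 0)
    abort(paste0("control intensity for unknown control id: ", unknown[1]))
  grab <- function(ch) {
    sub <- ctl[ctl$channel == ch, ]
    m <- as.matrix(sub[samp])
    rownames(m) <- sub$control_id
    m[control_manifest$control_id, , drop = FALSE]
  }
  raw <- raw_intensities(M, U, grab("green"), grab("red"), missing)
  covariates <- as_covariate_table(
    readr::read_tsv(file.path(dir, "covariates.tsv"),
                    col_types = readr::cols(sample_id = "c", sex = "c",
                                            chip = readr::col_character(),
                                            .default = readr::col_guess())),
    sample_ids = samp)
  list(manifest = manifest, control_manifest = control_manifest,
       raw = raw, covariates = covariates)
}

#' Write per-marker association results
#'
#' One row per marker ordered by (chromosome, position), numeric fields
#' serialised to 12 significant digits so a read-back reproduces them.
#'
#' @param result An association result tibble (see [marker_regression()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_association <- function(result, path) {
  res <- dplyr::arrange(result, chrom_rank(.data$chromosome), .data$position)
  num <- vapply(res, is.numeric, logical(1))
  out <- res
  out[num] <- lapply(res[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.15g", x))
  })
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an association result file written by [write_association()]
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_association <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(marker_id = "c",
                                                chromosome = "c",
                                                flags = "c",
                                                .default = readr::col_guess()),
                  na = "NA")
}

flags_string <- function(manifest) {
  paste0(ifelse(manifest$flag_non_cpg, "non_cpg;", ""),
         ifelse(manifest$flag_cross_hybridising, "cross_hybridising;", ""),
         ifelse(manifest$flag_snp_in_probe, "snp_in_probe;", "")) |>
    sub(pattern = ";$", replacement = "") |>
    (\(x) ifelse(x == "", ".", x))()
}
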