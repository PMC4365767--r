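# Synthetic 450K-style data generator.
#
# The generator emulates the statistical structure the pipeline assumes:
# chip-level batch effects expressed multiplicatively per colour channel and
# carried by the control probes, Dirichlet cell mixtures driving global
# covariation, locally correlated CpG clusters, duplicate-pair designs, and
# spiked case-control effects, together with a ground-truth record.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Describe a synthetic cohort
#'
#' Bundles every tunable of the synthetic generator. Defaults describe a
#' desk-scale population study: 500 samples on chips of up to 96,
#' 2,000 markers in clustered CpG islands, six white-cell types with a
#' granulocyte-dominated Dirichlet mixture, chip batch effects of log-scale
#' SD 0.3 per colour channel, and logit-scale marker noise 0.3.
#'
#' @param n_samples,n_markers Number of samples and methylation markers.
#' @param n_controls Number of non-negative control probes (spread over at
#'   least five chemistry categories).
#' @param n_negative_controls Number of negative (background) controls.
#' @param n_chips Number of chips; samples are assigned round-robin.
#' @param n_cell_types Number of white-cell types (default 6).
#' @param dirichlet_alpha Dirichlet concentration for cell mixtures; length
#'   must equal `n_cell_types`.
#' @param batch_sd Log-scale SD of per-chip per-channel gain factors.
#' @param probe_batch_sd Logit-scale SD of probe-by-chip effects: chip-to-
#'   chip variability that hits each probe differently (probe lots, spatial
#'   hybridisation gradients). Channel gains are largely removed by rank-
#'   based quantile normalisation; this component is what control-probe
#'   adjustment removes beyond it.
#' @param noise_sd Logit-scale SD of independent per-marker noise.
#' @param cluster_sd Logit-scale SD of the shared within-cluster component
#'   that produces local correlation between neighbouring CpGs.
#' @param age_effect_frac,sex_effect_frac Fractions of markers with age and
#'   sex effects.
#' @param spike_frac,spike_magnitude Fraction of markers spiked in cases and
#'   the logit-scale effect size in units of `noise_sd`.
#' @param cell_frac Fraction of non-reference markers whose methylation
#'   depends on cell type (source of cell-mixture covariation).
#' @param cell_contrast Upper bound of the beta-scale contrast between the
#'   divergent cell type and the rest at cell-dependent markers (contrasts
#'   are drawn from Unif(0.3, cell_contrast)); large contrasts make cell
#'   composition the dominant biological variance component at those
#'   markers, as it is in whole-blood methylation.
#' @param cluster_size_bp Maximum span of a marker cluster in bp.
#' @param frac_x,frac_y Fractions of marker clusters placed on the X and Y
#'   chromosomes.
#' @param seed Integer seed; every generator call is deterministic given it.
#' @return A list with class `cohort_design`.
#' @export
cohort_design <- function(n_samples = 500, n_markers = 2000,
                          n_controls = 200, n_negative_controls = 60,
                          n_chips = max(1L, ceiling(n_samples / 12)),
                          n_cell_types = 6,
                          dirichlet_alpha = c(9.6, 2.4, 1.6, 1.0, 1.6, 0.8),
                          batch_sd = 0.3, probe_batch_sd = 0.1,
                          noise_sd = 0.15, cluster_sd = 0.15,
                          age_effect_frac = 0.05, sex_effect_frac = 0.05,
                          spike_frac = 0, spike_magnitude = 1,
                          cell_frac = 0.25, cell_contrast = 0.9,
                          cluster_size_bp = 1000,
                          frac_x = 0.03, frac_y = 0.02,
                          seed = 1L) {
  counts <- c(n_samples, n_markers, n_controls, n_negative_controls, n_chips,
              n_cell_types)
  if (any(counts < 1)) abort("all design counts must be >= 1")
  fr <- c(age_effect_frac, sex_effect_frac, spike_frac, cell_frac,
          frac_x, frac_y)
  if (any(fr < 0 | fr > 1)) abort("design fractions must lie in [0, 1]")
  if (length(dirichlet_alpha) != n_cell_types)
    abort("dirichlet_alpha must have length n_cell_types")
  if (any(dirichlet_alpha <= 0)) abort("dirichlet_alpha must be positive")
  structure(as.list(environment())[
    c("n_samples", "n_markers", "n_controls", "n_negative_controls",
      "n_chips", "n_cell_types", "dirichlet_alpha", "batch_sd",
      "probe_batch_sd", "noise_sd",
      "cluster_sd", "age_effect_frac", "sex_effect_frac", "spike_frac",
      "spike_magnitude", "cell_frac", "cell_contrast", "cluster_size_bp",
      "frac_x", "frac_y", "seed")], class = "cohort_design")
}

CELL_TYPES <- c("gran", "cd4t", "cd8t", "bcell", "mono", "nk")

#' Generate a synthetic marker and control-probe manifest
#'
#' Markers are laid out in clusters of 2-8 within `cluster_size_bp`, with
#' clusters at least 10 kb apart, mimicking the clustered placement of CpGs
#' on the array; ~72% of markers are Type II and Type I markers split evenly
#' between the red and green channels. About 1% of markers per category are
#' flagged at random. The control manifest carries five chemistry categories
#' plus negatives.
#'
#' @param design A [cohort_design()].
#' @return A list with elements `manifest` and `control_manifest`.
#' @export
generate_manifest <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, {
    n <- design$n_markers
    sizes <- integer(0)
    while (sum(sizes) < n) sizes <- c(sizes, sample(2:8, 64, replace = TRUE))
    k <- which(cumsum(sizes) >= n)[1]
    sizes <- sizes[seq_len(k)]
    sizes[k] <- sizes[k] - (sum(sizes) - n)
    if (sizes[k] == 0) sizes <- sizes[-k]
    n_clust <- length(sizes)
    if (n < n_clust) abort("n_markers smaller than number of clusters requested")
    w <- c(rep((1 - design$frac_x - design$frac_y) / 22, 22),
           design$frac_x, design$frac_y)
    chrom <- sample(CHROM_LEVELS, n_clust, replace = TRUE, prob = w)
    # clusters on a chromosome are spaced >= 10 kb apart
    pos <- integer(0); chr_out <- character(0); clust_id <- integer(0)
    for (ci in seq_len(n_clust)) {
      prev <- sum(chrom[seq_len(ci - 1)] == chrom[ci])
      # spacing guarantees >= 10 kb between cluster extents after jitter
      spacing <- 12000L + 2L * design$cluster_size_bp
      start <- 1L + prev * spacing + sample.int(2000L, 1)
      p <- start + sort(sample.int(design$cluster_size_bp + 1L,
                                   sizes[ci], replace = FALSE) - 1L)
      pos <- c(pos, p)
      chr_out <- c(chr_out, rep(chrom[ci], sizes[ci]))
      clust_id <- c(clust_id, rep(ci, sizes[ci]))
    }
    type2 <- runif(n) < 0.72
    channel <- ifelse(type2, "both",
                      ifelse(runif(n) < 0.5, "red", "green"))
    m <- tibble::tibble(
      marker_id = sprintf("cg%07d", seq_len(n)),
      chromosome = chr_out,
      position = pos,
      probe_type = ifelse(type2, "II", "I"),
      channel = channel,
      flag_non_cpg = runif(n) < 0.01,
      flag_cross_hybridising = runif(n) < 0.01,
      flag_snp_in_probe = runif(n) < 0.01,
      cluster = clust_id)
    cats <- c("bisulfite_conversion", "staining", "extension",
              "hybridization", "specificity")
    ctl <- tibble::tibble(
      control_id = c(sprintf("ctl%04d", seq_len(design$n_controls)),
                     sprintf("neg%04d", seq_len(design$n_negative_controls))),
      category = c(rep(cats, length.out = design$n_controls),
                   rep("negative", design$n_negative_controls)))
    list(manifest = as_manifest(m), control_manifest = as_control_manifest(ctl))
  })
}

#' Generate a synthetic cell-type reference matrix
#'
#' Stands in for a reference panel of CpGs informative of white blood cell
#' subpopulations: 500 markers are chosen from the manifest and given
#' cell-type-discriminative beta values (between-cell-type range at least
#' 0.3, all values inside (0.02, 0.98)). This synthetic reference is used
#' both to mix cell-type methylomes in [generate_cohort()] and as the
#' reference for [estimate_wbc()].
#'
#' @param manifest A manifest with at least 500 markers.
#' @param design A [cohort_design()].
#' @param n_ref Number of reference markers (default 500).
#' @return A numeric matrix `n_ref` x `n_cell_types` with marker-id
#'   rownames and cell-type colnames.
#' @export
generate_reference <- function(manifest, design, n_ref = 500) {
  if (nrow(manifest) < n_ref)
    abort(paste0("manifest must contain at least ", n_ref, " markers"))
  with_seed(design$seed + 1L, {
    auto <- manifest$marker_id[!manifest$chromosome %in% c("X", "Y")]
    ids <- sort(sample(auto, min(n_ref, length(auto))))
    K <- design$n_cell_types
    cells <- if (K == 6) CELL_TYPES else paste0("cell", seq_len(K))
    base <- runif(length(ids), 0.1, 0.55)
    hi <- sample.int(K, length(ids), replace = TRUE)
    B <- matrix(base + runif(length(ids) * K, 0, 0.05),
                nrow = length(ids), ncol = K,
                dimnames = list(ids, cells))
    B[cbind(seq_along(ids), hi)] <- base + runif(length(ids), 0.36, 0.42)
    pmin(pmax(B, 0.021), 0.979)
  })
}

logit <- function(p) log(p / (1 - p))

# Channel gains are hierarchical: a processing-run component shared by all
# chips generated in one call (reagent lots, scanner session) plus a
# chip-local component, each of log-scale SD batch_sd. Samples processed in
# separate runs (e.g. duplicate batches) therefore differ systematically,
# not only through chip-draw averages.
draw_gains <- function(n_chips, batch_sd) {
  run_g <- rnorm(1, 0, batch_sd); run_r <- rnorm(1, 0, batch_sd)
  tibble::tibble(chip = seq_len(n_chips),
                 g_green = run_g + rnorm(n_chips, 0, batch_sd),
                 g_red = run_r + rnorm(n_chips, 0, batch_sd))
}

# Chip-specific channel gain factor for a set of markers: gain enters
# multiplicatively on the log scale, modulated by a per-marker sensitivity so
# that batch effects perturb within-sample ranks (a pure scalar gain would be
# removed completely by rank-based quantile normalisation, unlike real dye
# and batch biases).
gain_factor <- function(g_chip, sens, chip_of_sample) {
  exp(outer(sens, g_chip[chip_of_sample]))
}

#' Generate a synthetic cohort of raw intensities, covariates and truth
#'
#' For each sample, cell proportions are drawn from a Dirichlet; each
#' marker's true methylation fraction is a logistic transform of the
#' cell-mixture logit plus covariate, spike, cluster and independent noise
#' terms. Intensities route the methylated and unmethylated signal to colour
#' channels by probe chemistry and are multiplied by chip-specific channel
#' gains, which the control probes carry too, so control-probe PCA can
#' recover the batch structure. Y-chromosome probes in females measure only
#' background. A ground-truth record (cell proportions, chip gains, spiked
#' markers, per-marker effects, true betas) is returned for validation.
#'
#' @param manifest,control_manifest From [generate_manifest()].
#' @param reference From [generate_reference()].
#' @param design A [cohort_design()].
#' @return A list with elements `raw` ([raw_intensities()]), `covariates`
#'   (tibble) and `truth` (list with class `cpacor_truth`).
#' @export
generate_cohort <- function(manifest, control_manifest, reference, design) {
  with_seed(design$seed + 2L, {
    n <- design$n_samples
    m <- nrow(manifest)
    K <- design$n_cell_types
    cells <- colnames(reference)
    sample_id <- sprintf("S%04d", seq_len(n))
    chip_of <- rep(seq_len(design$n_chips), length.out = n)

    W <- rdirichlet(n, design$dirichlet_alpha)
    colnames(W) <- cells

    # per-marker cell-type beta profiles; reference rows use the reference.
    # Cell-dependent markers look like real cell-specific CpGs: one cell
    # type strongly divergent on the beta scale (hypo- or hypermethylated
    # in that lineage), the rest near a common base. Constitutive markers
    # are bimodal (modes near 0 and 1), giving the array's marginal shape.
    B <- matrix(NA_real_, m, K, dimnames = list(manifest$marker_id, cells))
    L0 <- ifelse(runif(m) < 0.45, rnorm(m, -2.5, 0.7),
                 ifelse(runif(m) < 0.8, rnorm(m, 2.5, 0.7), rnorm(m, 0, 0.8)))
    cellful <- runif(m) < design$cell_frac
    B[] <- stats::plogis(L0)
    if (any(cellful)) {
      nc_m <- sum(cellful)
      base <- runif(nc_m, 0.05, 0.6)
      contrast <- runif(nc_m, 0.3, design$cell_contrast)
      # divergent lineages in proportion to their abundance: most
      # cell-informative CpGs separate the major (myeloid) compartment
      hi <- sample.int(K, nc_m, replace = TRUE,
                       prob = design$dirichlet_alpha)
      Bc <- matrix(base + runif(nc_m * K, 0, 0.05), nc_m, K)
      Bc[cbind(seq_len(nc_m), hi)] <- base + contrast
      B[cellful, ] <- pmin(pmax(Bc, 0.02), 0.97)
    }
    in_ref <- manifest$marker_id %in% rownames(reference)
    B[manifest$marker_id[in_ref], ] <-
      reference[manifest$marker_id[in_ref], cells]

    mix <- B %*% t(W)                      # m x n expected beta
    mix <- pmin(pmax(mix, 1e-6), 1 - 1e-6)

    age <- rnorm(n, 50, 8)
    sex <- ifelse(runif(n) < 0.5, "male", "female")
    phenotype <- rbinom(n, 1, 0.5)

    age_slope <- ifelse(runif(m) < design$age_effect_frac,
                        sample(c(-1, 1), m, TRUE) * runif(m, 0.01, 0.03), 0)
    sex_shift <- ifelse(runif(m) < design$sex_effect_frac,
                        sample(c(-1, 1), m, TRUE) * runif(m, 0.2, 0.6), 0)
    spiked <- runif(m) < design$spike_frac
    spike_dir <- ifelse(spiked, sample(c(-1, 1), m, TRUE), 0)
    spike_shift <- spike_dir * design$spike_magnitude * design$noise_sd

    eta <- logit(mix) +
      outer(age_slope, age - 50) +
      outer(sex_shift, as.numeric(sex == "male")) +
      outer(spike_shift, as.numeric(phenotype == 1))
    clust_f <- matrix(rnorm(max(manifest$cluster) * n, 0, design$cluster_sd),
                      ncol = n)
    eta <- eta + clust_f[manifest$cluster, ]
    eta <- eta + matrix(rnorm(m * n, 0, design$noise_sd), m, n)
    true_beta <- stats::plogis(eta)
    dimnames(true_beta) <- list(manifest$marker_id, sample_id)

    gains <- draw_gains(design$n_chips, design$batch_sd)
    sens <- runif(m, 0.5, 1.5)
    ctl_base <- exp(rnorm(nrow(control_manifest), log(3000), 0.4))
    ctl_base[control_manifest$category == "negative"] <- NA

    raw <- intensities_from_beta(true_beta, manifest, control_manifest,
                                 design, chip_of, gains, sens, ctl_base,
                                 female = sex == "female")
    wbc_tot <- 4 + 5 * W[, 1] + rnorm(n, 0, 0.4)
    covariates <- tibble::tibble(sample_id = sample_id,
                                 phenotype = phenotype, age = age, sex = sex,
                                 wbc_tot = wbc_tot,
                                 chip = sprintf("chip%02d", chip_of))
    truth <- structure(list(
      spiked = tibble::tibble(marker_id = manifest$marker_id[spiked],
                              direction = spike_dir[spiked],
                              logit_shift = spike_shift[spiked]),
      cell_props = dplyr::bind_cols(tibble::tibble(sample_id = sample_id),
                                    tibble::as_tibble(W)),
      chip_gains = gains,
      chip_of_sample = chip_of,
      marker_effects = tibble::tibble(marker_id = manifest$marker_id,
                                      age_slope = age_slope,
                                      sex_shift = sex_shift),
      gain_sensitivity = sens,
      control_baseline = ctl_base,
      true_beta = true_beta), class = "cpacor_truth")
    list(raw = raw, covariates = covariates, truth = truth)
  })
}

# Technical layer: true betas -> observed intensities. Used by both
# generate_cohort and generate_duplicates so duplicate pairs share their
# biology but not their technical draws. Measurement error has three parts:
# per-measurement logit-scale noise on the methylation fraction (tech_sd),
# log-normal variation of the probe's total intensity, and additive
# background fluorescence.
intensities_from_beta <- function(true_beta, manifest, control_manifest,
                                  design, chip_of, gains, sens, ctl_base,
                                  female, tech_sd = 0.1) {
  m <- nrow(true_beta); n <- ncol(true_beta)
  H <- matrix(rnorm(m * nrow(gains), 0, design$probe_batch_sd), m)
  meas_beta <- stats::plogis(logit(pmin(pmax(true_beta, 1e-8), 1 - 1e-8)) +
                               H[, chip_of, drop = FALSE] +
                               matrix(rnorm(m * n, 0, tech_sd), m, n))
  logT0 <- rnorm(m, log(2000), 0.3)
  Tm <- exp(logT0 + matrix(rnorm(m * n, 0, 0.25), m, n))
  M0 <- meas_beta * Tm
  U0 <- (1 - meas_beta) * Tm
  ch_M <- ifelse(manifest$probe_type == "II", "green", manifest$channel)
  ch_U <- ifelse(manifest$probe_type == "II", "red", manifest$channel)
  fac_g <- gain_factor(gains$g_green, sens, chip_of)
  fac_r <- gain_factor(gains$g_red, sens, chip_of)
  M <- M0 * ifelse(ch_M == "green", 1, 0) * fac_g +
       M0 * ifelse(ch_M == "red", 1, 0) * fac_r
  U <- U0 * ifelse(ch_U == "green", 1, 0) * fac_g +
       U0 * ifelse(ch_U == "red", 1, 0) * fac_r
  bg <- function() exp(matrix(rnorm(m * n, log(60), 0.4), m, n))
  M <- M + bg(); U <- U + bg()
  # Y probes in females carry background only
  is_y <- manifest$chromosome == "Y"
  if (any(is_y) && any(female)) {
    yb <- function(nr) exp(matrix(rnorm(nr * sum(female), log(60), 0.4), nr))
    M[is_y, female] <- yb(sum(is_y))
    U[is_y, female] <- yb(sum(is_y))
  }
  dimnames(M) <- dimnames(U) <- dimnames(true_beta)
  nc <- nrow(control_manifest)
  neg <- control_manifest$category == "negative"
  n_chips <- nrow(gains)
  # each control probe responds to the chip's channel gain with its own
  # sensitivity and additionally carries a control-by-chip fingerprint,
  # reflecting that the monitored chemistry steps (staining, extension,
  # bisulfite conversion, ...) vary semi-independently across chips; this
  # is what makes control-probe PCA informative about the whole chip-level
  # batch space rather than a single gain direction
  ctl_sens <- runif(nc, 0.5, 1.5)
  h_g <- matrix(rnorm(nc * n_chips, 0, 0.15), nc, n_chips)
  h_r <- matrix(rnorm(nc * n_chips, 0, 0.15), nc, n_chips)
  cg_chip <- gains$g_green[chip_of]; cr_chip <- gains$g_red[chip_of]
  cnoise <- function() exp(matrix(rnorm(nc * n, 0, 0.1), nc, n))
  base_mat <- matrix(ctl_base, nc, n)
  eff_g <- outer(ctl_sens, cg_chip) + h_g[, chip_of, drop = FALSE]
  eff_r <- outer(ctl_sens, cr_chip) + h_r[, chip_of, drop = FALSE]
  ctl_g <- base_mat * exp(eff_g) * cnoise()
  ctl_r <- base_mat * exp(eff_r) * cnoise()
  negdraw <- function() exp(matrix(rnorm(sum(neg) * n, log(60), 0.4),
                                   sum(neg), n))
  ctl_g[neg, ] <- negdraw() * exp(eff_g[neg, , drop = FALSE])
  ctl_r[neg, ] <- negdraw() * exp(eff_r[neg, , drop = FALSE])
  dimnames(ctl_g) <- dimnames(ctl_r) <-
    list(control_manifest$control_id, colnames(true_beta))
  raw_intensities(M, U, ctl_g, ctl_r)
}

#' Generate technical duplicates of a subset of cohort samples
#'
#' Re-measures `n_pairs` samples with identical true methylation but fresh
#' chip assignments (new chips, new channel-gain draws at the design's
#' `batch_sd`) and fresh technical noise, emulating duplicate samples run in
#' separate batches.
#'
#' @param cohort Output of [generate_cohort()].
#' @param manifest,control_manifest The matching manifests.
#' @param design The [cohort_design()] used for the cohort.
#' @param n_pairs Number of duplicate pairs (must not exceed `n_samples`).
#' @param seed Seed for the duplicate technical layer.
#' @return A list with elements `raw` (duplicate intensities, sample ids
#'   suffixed `_rep`), `pairing` (tibble `sample_id`, `dup_id`),
#'   `chip_gains` and `chip_of_sample` for the duplicate batch.
#' @export
generate_duplicates <- function(cohort, manifest, control_manifest, design,
                                n_pairs = 36, seed = design$seed + 9L) {
  truth <- cohort$truth
  n <- ncol(truth$true_beta)
  if (n_pairs > n) abort("n_pairs must not exceed n_samples")
  with_seed(seed, {
    sel <- sort(sample.int(n, n_pairs))
    ids <- colnames(truth$true_beta)[sel]
    tb <- truth$true_beta[, sel, drop = FALSE]
    colnames(tb) <- paste0(ids, "_rep")
    n_chips <- max(1L, ceiling(n_pairs / 12))
    gains <- draw_gains(n_chips, design$batch_sd)
    chip_of <- rep(seq_len(n_chips), length.out = n_pairs)
    female <- cohort$covariates$sex[sel] == "female"
    raw <- intensities_from_beta(tb, manifest, control_manifest, design,
                                 chip_of, gains, truth$gain_sensitivity,
                                 truth$control_baseline, female)
    list(raw = raw,
         pairing = tibble::tibble(sample_id = ids,
                                  dup_id = paste0(ids, "_rep")),
         chip_gains = gains, chip_of_sample = chip_of)
  })
}
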