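# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# A small cohort shared by many tests: 60 samples x 400 markers.
small_cohort <- function() fixture("small_cohort", function() {
  design <- cohort_design(n_samples = 60, n_markers = 400, seed = 101)
  mf <- generate_manifest(design)
  reference <- generate_reference(mf$manifest, design, n_ref = 80)
  cohort <- generate_cohort(mf$manifest, mf$control_manifest, reference,
                            design)
  list(design = design, manifest = mf$manifest,
       control_manifest = mf$control_manifest, reference = reference,
       raw = cohort$raw, covariates = cohort$covariates,
       truth = cohort$truth)
})

# The same cohort pushed through QC and normalisation.
small_processed <- function() fixture("small_processed", function() {
  sc <- small_cohort()
  bc <- background_correct(sc$raw, sc$manifest, sc$control_manifest)
  detp <- detection_pvalues(bc, sc$manifest, sc$control_manifest)
  masked <- apply_detection_mask(bc, detp, 1e-16)
  auto <- !sc$manifest$chromosome %in% c("X", "Y")
  masked_auto <- subset_markers(masked, sc$manifest$marker_id[auto])
  list(bc = bc, detp = detp, masked = masked, masked_auto = masked_auto,
       manifest_auto = sc$manifest[auto, ],
       beta = normalize_betas(masked_auto, sc$manifest[auto, ], "QN-I6"))
})

# Duplicate-pair experiment with batch effects carried by control probes.
dup_experiment <- function(seed = 11, n_markers = 1500) {
  key <- paste0("dup_", seed, "_", n_markers)
  fixture(key, function() {
    design <- cohort_design(n_samples = 36, n_markers = n_markers,
                            batch_sd = 0.3, seed = seed)
    mf <- generate_manifest(design)
    reference <- generate_reference(mf$manifest, design,
                                    n_ref = min(500, n_markers %/% 2))
    cohort <- generate_cohort(mf$manifest, mf$control_manifest, reference,
                              design)
    dup <- generate_duplicates(cohort, mf$manifest, mf$control_manifest,
                               design, n_pairs = 36)
    combined <- raw_intensities(
      cbind(cohort$raw$M, dup$raw$M), cbind(cohort$raw$U, dup$raw$U),
      cbind(cohort$raw$control_green, dup$raw$control_green),
      cbind(cohort$raw$control_red, dup$raw$control_red))
    bc <- background_correct(combined, mf$manifest, mf$control_manifest)
    masked <- apply_detection_mask(
      bc, detection_pvalues(bc, mf$manifest, mf$control_manifest), 1e-16)
    auto <- !mf$manifest$chromosome %in% c("X", "Y")
    list(design = design, manifest = mf$manifest[auto, ],
         control_manifest = mf$control_manifest,
         masked = subset_markers(masked, mf$manifest$marker_id[auto]),
         pairing = dup$pairing, cohort = cohort, dup = dup)
  })
}

# Replicate-regression inflation factors at three adjustment levels.
dup_lambdas <- function(seed = 11) {
  key <- paste0("duplam_", seed)
  fixture(key, function() {
    dx <- dup_experiment(seed)
    y <- rep(c(0, 1), each = 36)
    lam <- function(beta, design)
      genomic_inflation(marker_regression(y, beta, design,
                                          family = "linear")$p)
    int_only <- matrix(1, 72, 1)
    b_raw <- normalize_betas(dx$masked, dx$manifest, "none")
    b_qn <- normalize_betas(dx$masked, dx$manifest, "QN-I6")
    cp <- control_pcs(control_feature_matrix(dx$masked, dx$control_manifest),
                      k = 30)
    c(raw = lam(b_raw, int_only), qn = lam(b_qn, int_only),
      cp = lam(b_qn, cbind(int_only, cp$scores)))
  })
}
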