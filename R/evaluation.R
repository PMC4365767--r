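# Performance machinery: spike-in simulations, rank-recovery scoring,
# duplicate concordance and local-correlation diagnostics.

#' Plan a spike-in experiment
#'
#' Chooses `n` markers to spike and, after a seeded shuffle, assigns
#' alternate markers to have their methylated (M) or unmethylated (U)
#' intensity altered, so half the spikes act on each signal.
#'
#' @param manifest The marker manifest.
#' @param n Number of markers to spike (default 100).
#' @param magnitude Effect size as a fraction of the per-marker SD of raw
#'   beta values.
#' @param seed Integer seed.
#' @return A tibble `marker_id`, `alter` (`"M"`/`"U"`) with attributes
#'   `magnitude` and `seed`, class `spike_plan`.
#' @export
spike_plan <- function(manifest, n = 100, magnitude = 1, seed = 1L) {
  if (n > nrow(manifest)) abort("cannot spike more markers than exist")
  with_seed(seed, {
    ids <- sample(manifest$marker_id, n)
    plan <- tibble::tibble(marker_id = ids,
                           alter = rep(c("M", "U"), length.out = n))
    attr(plan, "magnitude") <- magnitude
    attr(plan, "seed") <- seed
    class(plan) <- c("spike_plan", class(plan))
    plan
  })
}

#' Spike differential methylation into raw intensities
#'
#' For each spiked marker and each case sample, the raw beta value is
#' increased by `magnitude` standard deviations of that marker's raw betas
#' (SD across all samples, denominator n-1), and intensities are recomputed
#' to express the new beta: for M-altered probes
#' `M' = beta' (U + offset) / (1 - beta')`, for U-altered probes
#' `U' = M (1 - beta') / beta' - offset`. Negative intensities are set to
#' zero; target betas at or above 1 are capped at `1 - 1e-6` (with a
#' message). When no clipping occurs the transformation is an exact
#' algebraic inverse of the beta formula.
#'
#' @param raw Raw (masked) intensities.
#' @param beta_raw The unnormalised [beta_matrix()] computed from `raw`
#'   with the same offset convention.
#' @param plan A [spike_plan()].
#' @param case Logical or 0/1 vector marking case samples.
#' @return `raw` with spiked intensities.
#' @export
spike_intensities <- function(raw, beta_raw, plan, case) {
  case <- as.logical(case)
  off <- beta_raw$offset
  magnitude <- attr(plan, "magnitude")
  M <- raw$M; U <- raw$U
  n_capped <- 0L
  for (r in seq_len(nrow(plan))) {
    id <- plan$marker_id[r]
    bv <- beta_raw$beta[id, ]
    s <- sd(bv, na.rm = TRUE)
    bprime <- bv + magnitude * s
    hi <- !is.na(bprime) & bprime >= 1
    n_capped <- n_capped + sum(hi & case)
    bprime[hi] <- 1 - 1e-6
    idx <- case & !is.na(bprime)
    if (plan$alter[r] == "M") {
      M[id, idx] <- pmax(bprime[idx] * (U[id, idx] + off) / (1 - bprime[idx]),
                         0)
    } else {
      U[id, idx] <- pmax(M[id, idx] * (1 - bprime[idx]) / bprime[idx] - off,
                         0)
    }
  }
  if (n_capped > 0)
    inform(paste0(n_capped, " spiked value(s) capped below 1"))
  raw_intensities(M, U, raw$control_green, raw$control_red, raw$missing)
}

#' Proportion of spiked markers recovered in the top ranks
#'
#' Markers are ranked by ascending P value, ties broken by descending
#' absolute coefficient and then by marker id; the score is the fraction of
#' spiked markers among the top `k`. Spiked markers with missing P are
#' unranked.
#'
#' @param result An association tibble.
#' @param plan The [spike_plan()] used.
#' @param k Size of the top list (default 100).
#' @return The recovery proportion in `[0, 1]`.
#' @export
spike_rank_score <- function(result, plan, k = 100) {
  miss <- setdiff(plan$marker_id, result$marker_id)
  if (length(miss) > 0)
    abort(paste0("result does not cover spiked marker ", miss[1]))
  ranked <- result[!is.na(result$p), ]
  ord <- order(ranked$p, -abs(ranked$coef), ranked$marker_id)
  top <- ranked$marker_id[ord][seq_len(min(k, nrow(ranked)))]
  mean(plan$marker_id %in% top)
}

#' Concordance between duplicate measurements
#'
#' Pearson correlation between paired measurements, either per marker
#' (across the duplicate pairs) or per pair (across markers), using
#' pairwise-complete observations; units with fewer than 3 complete
#' observations get `NA`.
#'
#' @param beta_a,beta_b [beta_matrix()] objects for the original and repeat
#'   measurements.
#' @param pairing Tibble `sample_id`, `dup_id` mapping columns of `beta_a`
#'   to columns of `beta_b` (must be a bijection).
#' @param level `"marker"` or `"sample"`.
#' @return A tibble of correlations (`marker_id`/`sample_id`, `r`, `n`).
#' @export
duplicate_concordance <- function(beta_a, beta_b, pairing,
                                  level = c("sample", "marker")) {
  level <- match.arg(level)
  if (anyDuplicated(pairing$sample_id) || anyDuplicated(pairing$dup_id))
    abort("pairing must be a bijection on the selected sample ids")
  A <- beta_a$beta[, pairing$sample_id, drop = FALSE]
  B <- beta_b$beta[, pairing$dup_id, drop = FALSE]
  cor3 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(c(NA_real_, sum(ok)))
    c(cor(x[ok], y[ok]), sum(ok))
  }
  if (level == "sample") {
    out <- vapply(seq_len(ncol(A)), function(j) cor3(A[, j], B[, j]),
                  numeric(2))
    tibble::tibble(sample_id = pairing$sample_id, r = out[1, ],
                   n = as.integer(out[2, ]))
  } else {
    out <- vapply(seq_len(nrow(A)), function(i) cor3(A[i, ], B[i, ]),
                  numeric(2))
    tibble::tibble(marker_id = rownames(A), r = out[1, ],
                   n = as.integer(out[2, ]))
  }
}

#' Compare two sets of concordance values by paired rank test
#'
#' Paired Wilcoxon signed-rank test of the correlation vectors produced by
#' [duplicate_concordance()] under two processing schemes.
#'
#' @param conc_a,conc_b Tibbles from [duplicate_concordance()] over the same
#'   units.
#' @param alternative Passed to [stats::wilcox.test()]; default `"less"`
#'   tests whether scheme A's concordance is lower than scheme B's.
#' @return The `htest` object.
#' @export
compare_concordance <- function(conc_a, conc_b, alternative = "less") {
  ok <- !is.na(conc_a$r) & !is.na(conc_b$r)
  wilcox.test(conc_a$r[ok], conc_b$r[ok], paired = TRUE,
              alternative = alternative)
}

#' Correlation between neighbouring markers as a function of distance
#'
#' Restricts to the `top_frac` most variable markers (by raw-beta SD),
#' forms all within-chromosome autosomal pairs up to `max_dist` bp apart
#' (boundary inclusive), computes the Pearson correlation of each pair and
#' a sliding-window mean correlation against distance.
#'
#' @param x A [beta_matrix()] or `residual_matrix` supplying the values to
#'   correlate.
#' @param manifest The marker manifest (positions, chromosomes).
#' @param beta_raw Raw betas used to select the most variable markers;
#'   defaults to `x` itself.
#' @param max_dist Maximum pair distance in bp (default 5000).
#' @param top_frac Fraction of most variable markers retained (default
#'   0.05).
#' @param window Sliding-window width in bp for the smoothed curve
#'   (default 300).
#' @return A list with class `local_correlation`: `pairs` (tibble
#'   `marker_a`, `marker_b`, `distance`, `r`) and `smoothed` (tibble
#'   `distance`, `mean_r`, `n_pairs`).
#' @export
local_correlation <- function(x, manifest, beta_raw = NULL, max_dist = 5000,
                              top_frac = 0.05, window = 300) {
  V <- if (inherits(x, "beta_matrix")) x$beta else x$residuals
  sel_src <- if (is.null(beta_raw)) V else beta_raw$beta
  auto <- !manifest$chromosome %in% c("X", "Y")
  sds <- apply(sel_src, 1, sd, na.rm = TRUE)
  n_keep <- max(2L, ceiling(top_frac * sum(auto)))
  keep_ids <- manifest$marker_id[auto][
    order(sds[manifest$marker_id[auto]], decreasing = TRUE)[seq_len(n_keep)]]
  mf <- manifest[manifest$marker_id %in% keep_ids, ]
  pairs <- list()
  for (ch in unique(mf$chromosome)) {
    sub <- mf[mf$chromosome == ch, ]
    sub <- sub[order(sub$position), ]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) {
      j <- i + 1
      while (j <= nrow(sub) && sub$position[j] - sub$position[i] <= max_dist) {
        pairs[[length(pairs) + 1]] <-
          c(i = sub$marker_id[i], j = sub$marker_id[j],
            d = sub$position[j] - sub$position[i])
        j <- j + 1
      }
    }
  }
  if (length(pairs) == 0)
    abort("no eligible marker pairs within max_dist on any chromosome")
  pr <- do.call(rbind, pairs)
  d <- as.integer(pr[, "d"])
  r <- vapply(seq_len(nrow(pr)), function(k) {
    xa <- V[pr[k, "i"], ]; xb <- V[pr[k, "j"], ]
    ok <- !is.na(xa) & !is.na(xb)
    if (sum(ok) < 3) return(NA_real_)
    cor(xa[ok], xb[ok])
  }, numeric(1))
  pt <- tibble::tibble(marker_a = pr[, "i"], marker_b = pr[, "j"],
                       distance = d, r = r)
  grid <- seq(window / 2, max_dist - window / 2, by = 50)
  sm <- purrr::map_dfr(grid, function(g) {
    inw <- abs(d - g) <= window / 2
    tibble::tibble(distance = g,
                   mean_r = mean(r[inw], na.rm = TRUE),
                   n_pairs = sum(inw))
  })
  structure(list(pairs = pt, smoothed = sm[sm$n_pairs > 0, ]),
            class = "local_correlation")
}

#' Does adjustment preferentially remove long-range correlation?
#'
#' Regresses the per-pair change in correlation between two adjustment
#' levels on genomic distance. A negative slope means the second adjustment
#' removed more correlation at larger distances — the desired behaviour,
#' since short-range (<1 kb) correlation reflects biology while long-range
#' correlation is more likely confounding.
#'
#' @param lc_before,lc_after `local_correlation` objects over the same
#'   pairs.
#' @return A tibble `slope`, `se`, `p`, `n_pairs` for the regression of
#'   `|r_after| - |r_before|` on distance.
#' @export
delta_correlation_slope <- function(lc_before, lc_after) {
  stopifnot(identical(lc_before$pairs$marker_a, lc_after$pairs$marker_a),
            identical(lc_before$pairs$marker_b, lc_after$pairs$marker_b))
  dr <- abs(lc_after$pairs$r) - abs(lc_before$pairs$r)
  d <- lc_before$pairs$distance
  ok <- !is.na(dr)
  f <- summary(lm(dr[ok] ~ d[ok]))
  tibble::tibble(slope = f$coefficients[2, 1], se = f$coefficients[2, 2],
                 p = f$coefficients[2, 4], n_pairs = sum(ok))
}

#' Spike-in benchmark across pipeline stages
#'
#' The paper-style power benchmark: generate a cohort with chip batch
#' effects and cell-mixture covariation, spike `n_spike` markers in the case
#' samples by `magnitude` standard deviations of their raw betas, and score
#' each processing stage by the fraction of spiked markers recovered among
#' the top `n_spike` association ranks. Stages are cumulative: no
#' normalisation; stratified quantile normalisation; plus control-probe PC
#' adjustment; plus biological adjustment (age, sex, estimated cell
#' fractions, measured total count and residual PCs).
#'
#' @param seeds Integer vector; one full simulation per seed.
#' @param n_samples,n_markers Cohort size per run.
#' @param n_spike Number of spiked markers (and the rank cutoff).
#' @param magnitude Spike size in per-marker raw-beta SDs.
#' @param n_control_pcs,n_residual_pcs Adjustment sizes.
#' @param batch_sd Chip batch-effect size passed to the design.
#' @return A tibble `seed`, `stage`, `score`, with `stage` an ordered
#'   factor `none < qn < qn_cp < full`.
#' @export
spike_benchmark <- function(seeds = 1:10, n_samples = 150, n_markers = 1000,
                            n_spike = 50, magnitude = 1,
                            n_control_pcs = 30, n_residual_pcs = 5,
                            batch_sd = 0.3) {
  out <- list()
  for (sd_i in seeds) {
    design <- cohort_design(n_samples = n_samples, n_markers = n_markers,
                            batch_sd = batch_sd, seed = sd_i)
    mf <- generate_manifest(design)
    reference <- generate_reference(mf$manifest, design,
                                    n_ref = min(500, n_markers %/% 4))
    coh <- generate_cohort(mf$manifest, mf$control_manifest, reference,
                           design)
    auto <- !mf$manifest$chromosome %in% c("X", "Y")
    mani <- mf$manifest[auto, ]
    raw <- subset_markers(coh$raw, mani$marker_id)
    braw <- compute_beta(raw$M, raw$U, raw$missing)
    plan <- spike_plan(mani, n = n_spike, magnitude = magnitude,
                       seed = sd_i + 1000L)
    case <- coh$covariates$phenotype == 1
    spiked <- spike_intensities(raw, braw, plan, case)
    y <- coh$covariates$phenotype
    one <- matrix(1, n_samples, 1)
    score <- function(res) spike_rank_score(res, plan, k = n_spike)

    b_none <- normalize_betas(spiked, mani, "none")
    b_qn <- normalize_betas(spiked, mani, "QN-I6")
    feats <- control_feature_matrix(spiked, mf$control_manifest)
    kcp <- min(n_control_pcs, min(dim(feats)) - 1)
    cp <- control_pcs(feats, k = kcp)
    cov <- coh$covariates
    cells <- estimate_wbc(b_qn, reference)
    cov <- dplyr::left_join(cov, dplyr::select(cells, -"resid_norm"),
                            by = "sample_id")
    des_cp <- build_design(cov, control_pcs = cp, include = character(0))
    res_cp <- adjust_betas(b_qn, des_cp)
    des_bio <- build_design(cov, control_pcs = cp)
    resid_bio <- adjust_betas(b_qn, des_bio)
    rpcs <- residual_pcs(resid_bio, k = n_residual_pcs)
    des_full <- build_design(cov, control_pcs = cp, residual_pcs = rpcs)
    res_full <- adjust_betas(b_qn, des_full)

    sc <- c(
      none = score(marker_regression(y, b_none, one, "logistic")),
      qn = score(marker_regression(y, b_qn, one, "logistic")),
      qn_cp = score(two_stage_association(res_cp, y)),
      full = score(two_stage_association(res_full, y)))
    out[[length(out) + 1]] <- tibble::tibble(
      seed = sd_i, stage = factor(names(sc),
                                  levels = c("none", "qn", "qn_cp", "full"),
                                  ordered = TRUE),
      score = unname(sc))
  }
  dplyr::bind_rows(out)
}
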