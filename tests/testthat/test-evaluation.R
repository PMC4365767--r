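test_that("spiking follows the beta -> intensity algebra exactly", {
  # beta = 0.5, SD = 0.1, magnitude 1, U = 900, offset 100:
  # beta' = 0.6, M' = 0.6 * 1000 / 0.4 = 1500
  mani <- tibble::tibble(
    marker_id = "m1", chromosome = "1", position = 100L,
    probe_type = "II", channel = "both",
    flag_non_cpg = FALSE, flag_cross_hybridising = FALSE,
    flag_snp_in_probe = FALSE)
  n <- 9
  set.seed(2)
  # betas with sample mean 0.5 and sample SD exactly 0.1
  bvals <- 0.5 + scale(rnorm(n))[, 1] * 0.1
  bvals <- pmin(pmax(bvals, 0.05), 0.95)
  U <- matrix(900, 1, n, dimnames = list("m1", paste0("s", 1:n)))
  M <- (bvals * (900 + 100)) / (1 - bvals)
  M <- matrix(M, 1, n, dimnames = dimnames(U))
  raw <- raw_intensities(M, U, matrix(1, 1, n, dimnames = list("c", NULL)),
                         matrix(1, 1, n, dimnames = list("c", NULL)))
  braw <- compute_beta(raw$M, raw$U, offset = 100)
  expect_equal(unname(braw$beta[1, ]), unname(bvals), tolerance = 1e-12)

  plan <- tibble::tibble(marker_id = "m1", alter = "M")
  attr(plan, "magnitude") <- 1
  class(plan) <- c("spike_plan", class(plan))
  case <- c(TRUE, rep(FALSE, n - 1))
  s <- sd(braw$beta[1, ])
  spiked <- spike_intensities(raw, braw, plan, case)
  bprime <- braw$beta[1, 1] + 1 * s
  expect_equal(spiked$M[1, 1], bprime * (900 + 100) / (1 - bprime),
               tolerance = 1e-12)
  expect_equal(spiked$M[1, -1], raw$M[1, -1])  # controls untouched
  # round trip: recomputed beta equals the target beta
  b2 <- compute_beta(spiked$M, spiked$U, offset = 100)
  expect_equal(b2$beta[1, 1], bprime, tolerance = 1e-12)

  # magnitude 0 leaves intensities unchanged
  plan0 <- plan; attr(plan0, "magnitude") <- 0
  s0 <- spike_intensities(raw, braw, plan0, case)
  expect_equal(s0$M, raw$M, tolerance = 1e-12)

  # U-altered probes invert through the U formula
  planU <- plan; planU$alter <- "U"
  sU <- spike_intensities(raw, braw, planU, case)
  bU <- compute_beta(sU$M, sU$U, offset = 100)
  expect_equal(bU$beta[1, 1], bprime, tolerance = 1e-12)
})

test_that("the spike plan alternates M and U over a seeded shuffle", {
  sc <- small_cohort()
  plan <- spike_plan(sc$manifest, n = 50, magnitude = 1, seed = 4)
  expect_equal(sum(plan$alter == "M"), 25)
  expect_false(anyDuplicated(plan$marker_id) > 0)
  expect_identical(plan, spike_plan(sc$manifest, n = 50, magnitude = 1,
                                    seed = 4))
})

test_that("rank scoring is exact for perfect recovery and hypergeometric under the null", {
  res <- tibble::tibble(marker_id = paste0("m", 1:200),
                        coef = rnorm(200),
                        p = c(runif(100, 0, 1e-4), runif(100, 0.1, 1)))
  plan <- tibble::tibble(marker_id = paste0("m", 1:100), alter = "M")
  class(plan) <- c("spike_plan", class(plan))
  expect_equal(spike_rank_score(res, plan, k = 100), 1.0)

  # random ranking: expected overlap k/M
  set.seed(14)
  M <- 400; k <- 40; nspike <- 40; nrep <- 200
  scores <- replicate(nrep, {
    r <- tibble::tibble(marker_id = paste0("m", 1:M), coef = rnorm(M),
                        p = runif(M))
    pl <- tibble::tibble(marker_id = sample(r$marker_id, nspike))
    class(pl) <- c("spike_plan", class(pl))
    spike_rank_score(r, pl, k = k)
  })
  exp_score <- k / M
  se <- sqrt(exp_score * (1 - exp_score) / nspike / nrep)
  expect_lt(abs(mean(scores) - exp_score), 3 * se * sqrt(nrep / nrep) + 0.01)

  # missing p on a spiked marker counts as unranked
  res_na <- res; res_na$p[1] <- NA
  expect_lt(spike_rank_score(res_na, plan, k = 100), 1.0)
})

test_that("duplicate concordance handles identity, reversal and missing data", {
  set.seed(3)
  A <- matrix(runif(200) * 0.9, 20, 10,
              dimnames = list(paste0("m", 1:20), paste0("s", 1:10)))
  B <- A; colnames(B) <- paste0("s", 1:10, "_rep")
  pairing <- tibble::tibble(sample_id = colnames(A), dup_id = colnames(B))
  r_same <- duplicate_concordance(beta_matrix(A), beta_matrix(B), pairing,
                                  "marker")
  expect_true(all(abs(r_same$r - 1) < 1e-12))
  Brev <- 0.9 - A; colnames(Brev) <- colnames(B)
  r_rev <- duplicate_concordance(beta_matrix(A), beta_matrix(Brev), pairing,
                                 "sample")
  expect_true(all(abs(r_rev$r + 1) < 1e-12))
  # fewer than 3 complete pairs -> NA
  A2 <- A; A2[1, 3:10] <- NA
  r_na <- duplicate_concordance(beta_matrix(A2), beta_matrix(B), pairing,
                                "marker")
  expect_true(is.na(r_na$r[1]))
  bad <- pairing; bad$dup_id[2] <- bad$dup_id[1]
  expect_error(duplicate_concordance(beta_matrix(A), beta_matrix(B), bad),
               "bijection")
})

test_that("local correlation respects the distance boundary and cluster structure", {
  # 3 clusters of 4 markers; within-cluster shared factor, none between
  set.seed(9)
  n <- 80
  pos <- c(1000, 1200, 1400, 1600,
           4000, 4200, 4400, 4600,
           9000, 9200, 9400, 9600)
  mani <- tibble::tibble(
    marker_id = sprintf("m%02d", 1:12), chromosome = "1",
    position = as.integer(pos), probe_type = "II", channel = "both",
    flag_non_cpg = FALSE, flag_cross_hybridising = FALSE,
    flag_snp_in_probe = FALSE)
  f <- matrix(rnorm(3 * n), 3, n)
  V <- (f[rep(1:3, each = 4), ] * 0.6 + matrix(rnorm(12 * n, 0, 0.5), 12, n))
  V <- stats::plogis(V)
  dimnames(V) <- list(mani$marker_id, paste0("s", 1:n))
  lc <- local_correlation(beta_matrix(V), mani, max_dist = 5000,
                          top_frac = 1, window = 300)
  # pair at 5000 bp (m5: 4000 -> m9: 9000) included, none at 5001
  expect_true(any(lc$pairs$distance == 5000))
  expect_true(all(lc$pairs$distance <= 5000))
  within <- lc$pairs$distance <= 600
  between <- lc$pairs$distance > 2000
  expect_gt(mean(lc$pairs$r[within]), mean(lc$pairs$r[between]) + 0.2)
  expect_true(all(lc$smoothed$mean_r >= -1 & lc$smoothed$mean_r <= 1))
})

test_that("adjustment removes long-range correlation preferentially", {
  # global confounder correlates everything; cluster factors act locally
  set.seed(15)
  n <- 100
  n_clust <- 12
  pos <- as.integer(outer(c(0, 150, 300), (0:(n_clust - 1)) * 2000, "+") + 500)
  m <- length(pos)
  mani <- tibble::tibble(
    marker_id = sprintf("m%03d", seq_len(m)), chromosome = "1",
    position = pos, probe_type = "II", channel = "both",
    flag_non_cpg = FALSE, flag_cross_hybridising = FALSE,
    flag_snp_in_probe = FALSE)
  g <- rnorm(n)                                  # shared confounder
  cl <- rep(seq_len(n_clust), each = 3)
  fc <- matrix(rnorm(n_clust * n), n_clust, n)   # local biology
  V <- outer(runif(m, 0.6, 1), g) + fc[cl, ] * 0.8 +
    matrix(rnorm(m * n, 0, 0.4), m, n)
  V <- stats::plogis(V)
  dimnames(V) <- list(mani$marker_id, paste0("s", 1:n))
  raw_b <- beta_matrix(V)
  lc_before <- local_correlation(raw_b, mani, top_frac = 1)
  adj <- adjust_betas(raw_b, cbind(1, g))
  lc_after <- local_correlation(adj, mani, beta_raw = raw_b, top_frac = 1)
  sl <- delta_correlation_slope(lc_before, lc_after)
  expect_lt(sl$slope, 0)
  expect_lt(sl$p, 0.05)
})
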