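tiny_manifest <- function(types, channels) {
  as_manifest(tibble::tibble(
    marker_id = paste0("m", seq_along(types)),
    chromosome = "1", position = seq_along(types) * 100L,
    probe_type = types, channel = channels,
    flag_non_cpg = FALSE, flag_cross_hybridising = FALSE,
    flag_snp_in_probe = FALSE))
}

test_that("background correction subtracts the negative-control quantile", {
  mani <- tiny_manifest(c("II", "I"), c("both", "red"))
  M <- matrix(150, 2, 2, dimnames = list(c("m1", "m2"), c("s1", "s2")))
  U <- matrix(150, 2, 2, dimnames = dimnames(M))
  neg <- matrix(100, 2, 3)  # all negatives equal 100 in both channels
  ctl_m <- as_control_manifest(tibble::tibble(
    control_id = c("ctl1", "neg1", "neg2", "neg3"),
    category = c("staining", "negative", "negative", "negative")))
  cg <- rbind(ctl1 = c(500, 500), matrix(100, 3, 2))
  cr <- rbind(ctl1 = c(500, 500), matrix(100, 3, 2))
  rownames(cg) <- rownames(cr) <- ctl_m$control_id
  raw <- raw_intensities(M, U, cg, cr)
  bc <- background_correct(raw, mani, ctl_m)
  expect_equal(unname(bc$M), matrix(50, 2, 2))  # 150 - 100
  expect_equal(unname(bc$control_green["ctl1", ]), c(400, 400))
  # negatives all zero: only the floor clamps
  raw0 <- raw_intensities(M, U, rbind(ctl1 = c(500, 500), matrix(0, 3, 2),
                                      deparse.level = 0) |>
                            `rownames<-`(ctl_m$control_id),
                          rbind(ctl1 = c(500, 500), matrix(0, 3, 2)) |>
                            `rownames<-`(ctl_m$control_id))
  bc0 <- background_correct(raw0, mani, ctl_m)
  expect_equal(bc0$M, M)
  # monotone: larger raw intensity never yields smaller corrected intensity
  M2 <- M; M2[1, 1] <- 250
  bc2 <- background_correct(raw_intensities(M2, U, cg, cr), mani, ctl_m)
  expect_gte(bc2$M[1, 1], bc$M[1, 1])
})

test_that("detection P values follow the negative-control normal model", {
  # negatives constructed so median = 100 and normal-consistent MAD = 10
  negv <- c(100 - 10 / 1.4826, 100, 100 + 10 / 1.4826)
  mani <- tiny_manifest(c("II", "II", "I"), c("both", "both", "green"))
  ids <- c("m1", "m2", "m3")
  M <- matrix(c(100, 150, 100), 3, 2, dimnames = list(ids, c("s1", "s2")))
  U <- matrix(c(100, 90, 100), 3, 2, dimnames = dimnames(M))
  ctl_m <- as_control_manifest(tibble::tibble(
    control_id = c("ctl1", paste0("neg", 1:3)),
    category = c("staining", rep("negative", 3))))
  cg <- rbind(c(500, 500), cbind(negv, negv))
  cr <- cg
  rownames(cg) <- rownames(cr) <- ctl_m$control_id
  raw <- raw_intensities(M, U, cg, cr)
  detp <- detection_pvalues(raw, mani, ctl_m)
  # Type II: total 240, background N(200, 20) -> z = 2 -> upper tail 0.02275
  expect_equal(detp$p["m2", "s1"], 0.02275013, tolerance = 1e-6)
  expect_equal(detp$p["m2", "s1"], pnorm(2, lower.tail = FALSE),
               tolerance = 1e-9)
  # total exactly at the background mean -> p = 0.5 by symmetry
  expect_equal(detp$p["m1", "s1"], 0.5, tolerance = 1e-12)
  # Type I green: total 200, background N(200, 20) -> 0.5
  expect_equal(detp$p["m3", "s1"], 0.5, tolerance = 1e-12)
  expect_true(all(detp$p > 0 & detp$p <= 1))
})

test_that("an extremely bright probe hits the double-precision floor", {
  sc <- small_cohort()
  sp <- small_processed()
  expect_equal(min(sp$detp$p), .Machine$double.eps)
  expect_true(all(sp$detp$p > 0))
  # the floor value corresponds to raw complements that underflowed to 0
  expect_true(any(sp$detp$p_raw == 0))
  expect_equal(min(sp$detp$p[sp$detp$p_raw > 0][
    sp$detp$p[sp$detp$p_raw > 0] > .Machine$double.eps]) > 0, TRUE)
})

test_that("masking is inclusive at the threshold and monotone in stringency", {
  sp <- small_processed()
  sc <- small_cohort()
  m_strict <- apply_detection_mask(sp$bc, sp$detp, 1e-16)
  m_loose <- apply_detection_mask(sp$bc, sp$detp, 0.05)
  expect_true(all(m_loose$missing[m_strict$missing == FALSE] == FALSE))
  expect_true(all(m_strict$missing | !m_loose$missing))

  # exact-threshold entry is masked (>= is inclusive)
  thr <- sp$detp$p_raw[which(sp$detp$p_raw > 0)[1]]
  m_at <- apply_detection_mask(sp$bc, sp$detp, thr)
  expect_true(all(m_at$missing[sp$detp$p_raw == thr]))

  # threshold 1: only p == 1 entries masked beyond the existing mask
  m_one <- apply_detection_mask(sp$bc, sp$detp, 1)
  expect_equal(unname(m_one$missing), unname(sp$detp$p_raw >= 1))
})

test_that("call rates are fractions with a double-counting identity", {
  sp <- small_processed()
  cr <- call_rates(sp$masked)
  expect_true(all(cr$sample$call_rate >= 0 & cr$sample$call_rate <= 1))
  n_mark <- nrow(sp$masked$M); n_samp <- ncol(sp$masked$M)
  miss_by_sample <- (1 - cr$sample$call_rate) * n_mark
  miss_by_marker <- (1 - cr$marker$call_rate) * n_samp
  expect_equal(sum(miss_by_sample), sum(miss_by_marker), tolerance = 1e-8)

  raw <- sp$masked
  raw$missing[] <- FALSE
  raw$missing[1, 1] <- TRUE
  cr2 <- call_rates(raw)
  expect_equal(cr2$sample$call_rate[1], 1 - 1 / n_mark)
  expect_equal(cr2$marker$call_rate[1], 1 - 1 / n_samp)
})

test_that("sex check flags mismatches by Y-chromosome call rate", {
  sc <- small_cohort()
  sp <- small_processed()
  verdicts <- sex_check(sp$masked, sc$manifest, sc$covariates)
  stopifnot(any(sc$manifest$chromosome == "Y"))
  vm <- verdicts[verdicts$sex == "male", ]
  vf <- verdicts[verdicts$sex == "female", ]
  # females measure background only on Y: their call rate sits below males
  expect_gt(mean(vm$y_call_rate), mean(vf$y_call_rate))
  expect_true(all(verdicts$verdict == "pass"))

  # a swapped label is caught
  cov_swap <- sc$covariates
  male_idx <- which(cov_swap$sex == "male")[1]
  cov_swap$sex[male_idx] <- "female"
  v2 <- sex_check(sp$masked, sc$manifest, cov_swap)
  expect_equal(v2$verdict[v2$sample_id == cov_swap$sample_id[male_idx]],
               "mismatch")

  no_y <- sc$manifest[sc$manifest$chromosome != "Y", ]
  v3 <- sex_check(subset_markers(sp$masked, no_y$marker_id), no_y,
                  sc$covariates)
  expect_true(all(v3$verdict == "untestable"))
})

test_that("outlier rates follow the interpolated-quartile fence rule", {
  b <- matrix(c(1, 2, 3, 4, 100,
                rep(0.5, 5)), 2, 5, byrow = TRUE,
              dimnames = list(c("mA", "mB"), paste0("s", 1:5)))
  # scale into [0,1) for the container, preserving the quartile geometry
  rate <- outlier_rate(beta_matrix(b / 1000))
  # {1,2,3,4,100}: Q1 = 2, Q3 = 4, IQR = 2, upper fence 7 -> one outlier
  expect_equal(rate$outlier_rate[rate$marker_id == "mA"], 0.2)
  expect_equal(rate$outlier_rate[rate$marker_id == "mB"], 0)

  # large-sample normal oracle: fences at +/-2.698 SD -> rate ~ 0.007
  set.seed(42)
  xn <- matrix(rnorm(20000) / 20 + 0.5, 1,
               dimnames = list("m", NULL))
  r <- outlier_rate(beta_matrix(xn))$outlier_rate
  expect_equal(r, 2 * pnorm(-2.697959), tolerance = 0.35)

  # fewer than 4 values -> undefined
  short <- matrix(c(0.1, 0.2, 0.3, NA, NA), 1,
                  dimnames = list("m", NULL))
  expect_true(is.na(outlier_rate(beta_matrix(short))$outlier_rate))
})

test_that("sample filtering applies the strict <98% rule with reasons", {
  rates <- list(sample = tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    call_rate = c(0.979, 0.98, 1.0, 0.5)))
  f <- qc_filter(rates)
  expect_setequal(f$kept, c("b", "c"))  # 0.98 exactly is kept (strict <)
  expect_setequal(f$excluded$sample_id, c("a", "d"))
  expect_true(all(f$excluded$reason == "low_call_rate"))

  sexv <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                         verdict = c("pass", "mismatch", "pass", "pass"))
  f2 <- qc_filter(rates, sexv)
  expect_setequal(f2$kept, "c")
  expect_true("sex_mismatch" %in% f2$excluded$reason)

  all_bad <- list(sample = tibble::tibble(sample_id = "a", call_rate = 0.1))
  expect_error(qc_filter(all_bad), "all samples excluded")
})

test_that("stricter detection thresholds lower outlier rates at weak markers", {
  sc <- small_cohort()
  sp <- small_processed()
  beta_loose <- compute_beta(sp$bc$M, sp$bc$U,
                             apply_detection_mask(sp$bc, sp$detp, 0.05)$missing)
  beta_strict <- compute_beta(sp$bc$M, sp$bc$U,
                              apply_detection_mask(sp$bc, sp$detp, 1e-16)$missing)
  # Y markers in females are the canonical weak-signal case
  yv <- sc$manifest$marker_id[sc$manifest$chromosome == "Y"]
  expect_gte(length(yv), 2)  # the fixture places clusters on Y
  or_loose <- outlier_rate(beta_matrix(beta_loose$beta[yv, , drop = FALSE]))
  or_strict <- outlier_rate(beta_matrix(beta_strict$beta[yv, , drop = FALSE]))
  expect_lte(mean(or_strict$outlier_rate, na.rm = TRUE),
             mean(or_loose$outlier_rate, na.rm = TRUE))
})
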