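test_that("bias correction averages dual-alignment counts", {
  obs <- data.frame(alignment_ref = c("ref", "alt"),
                    ref_count = c(60L, 50L), alt_count = c(40L, 50L))
  expect_equal(bias_corrected_counts(obs),
               c(ref_count = 55L, alt_count = 45L))
  same <- data.frame(alignment_ref = c("ref", "alt"),
                     ref_count = c(30L, 30L), alt_count = c(10L, 10L))
  expect_equal(bias_corrected_counts(same),
               c(ref_count = 30L, alt_count = 10L))
  expect_equal(bias_corrected_counts(obs, combine = "min"),
               c(ref_count = 50L, alt_count = 40L))
  expect_equal(bias_corrected_counts(obs, combine = "sum"),
               c(ref_count = 110L, alt_count = 90L))
  expect_error(bias_corrected_counts(obs[1, ]), "both alignment references")
})

test_that("half-up rounding is used for averaged counts", {
  obs <- data.frame(alignment_ref = c("ref", "alt"),
                    ref_count = c(3L, 4L), alt_count = c(2L, 1L))
  expect_equal(bias_corrected_counts(obs),
               c(ref_count = 4L, alt_count = 2L))  # 3.5 -> 4, 1.5 -> 2
})

test_that("Benjamini-Hochberg reproduces the hand-worked example", {
  expect_equal(benjamini_hochberg(c(0.001, 0.02, 0.03, 0.04)),
               c(0.004, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(c(0.05, 0.05)), c(0.05, 0.05))
  expect_equal(benjamini_hochberg(numeric(0)), numeric(0))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(50)
  expect_true(all(benjamini_hochberg(p) >= p))  # adjusted_p >= raw_p
})

test_that("detect_asb gates on OTFR membership and the binomial test", {
  cfg <- run_config()
  otfr <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  het <- data.frame(chrom = "chr1", pos = c(100L, 200L, 5000L),
                    id = c("rs1", NA, NA), ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  counts <- rbind(
    dual_obs("e1", "chr1", 100L, 90L, 10L),   # strong imbalance, in OTFR
    dual_obs("e1", "chr1", 200L, 52L, 48L),   # balanced, in OTFR
    dual_obs("e1", "chr1", 5000L, 90L, 10L)   # strong, but outside OTFRs
  )
  res <- detect_asb(het, counts, otfr, cfg)
  expect_setequal(res$pos, c(100L, 200L))     # step-3 gate excludes 5000
  r100 <- res[res$pos == 100L, ]
  expect_equal(r100$raw_p, binomial_two_sided(90, 100))
  expect_lt(r100$raw_p, 1e-16)
  expect_true(r100$significant)
  r200 <- res[res$pos == 200L, ]
  expect_gt(r200$raw_p, 0.7)
  expect_false(r200$significant)
  asym <- asymmetric_snps(res)
  expect_equal(asym$pos, 100L)
  expect_true(all(res$adjusted_p >= res$raw_p))
})

test_that("adjusted-p gating is available behind the config flag", {
  cfg <- run_config(asb_use_adjusted_p = TRUE)
  otfr <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  het <- data.frame(chrom = "chr1", pos = seq(10L, 2000L, by = 10L),
                    stringsAsFactors = FALSE)
  set.seed(5)
  k <- rbinom(nrow(het), 60, 0.5)
  counts <- do.call(rbind, lapply(seq_len(nrow(het)), function(i)
    dual_obs("e1", "chr1", het$pos[i], k[i], 60L - k[i])))
  res <- detect_asb(het, counts, otfr, cfg)
  expect_equal(sum(res$significant), sum(res$adjusted_p < cfg$asb_alpha))
})

test_that("null calibration matches the exact test's achieved size", {
  cfg <- run_config()
  set.seed(1)
  n_sites <- 20000L
  cov <- rep(5L * cfg$min_site_coverage, n_sites)   # coverage 50
  k <- rbinom(n_sites, cov, 0.5)
  raw_p <- binomial_two_sided(k, cov)
  observed <- mean(raw_p < cfg$asb_alpha)
  # independent oracle: enumerate the rejection region of the exact test
  ks <- 0:50
  pv <- vapply(ks, function(x) stats::binom.test(x, 50)$p.value, numeric(1))
  achieved <- sum(dbinom(ks[pv < cfg$asb_alpha], 50, 0.5))
  se <- sqrt(achieved * (1 - achieved) / n_sites)
  expect_lt(abs(observed - achieved), 3 * se)
  expect_lte(observed, cfg$asb_alpha)  # discrete exact test is conservative
})

test_that("planted-effect detection matches closed-form binomial power", {
  set.seed(2)
  n_sites <- 2000L
  cov <- 100L
  k <- rbinom(n_sites, cov, 0.7)
  raw_p <- binomial_two_sided(k, cov)
  observed <- mean(raw_p < 0.01)
  expected <- binomial_test_power(100L, 0.7, 0.01)
  se <- sqrt(expected * (1 - expected) / n_sites)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("asymmetric set is a subset of het sites inside OTFRs", {
  d <- shared_bundle_dir()
  run <- shared_run()
  otfrs <- read_intervals(file.path(d, "otfrs.bed"))
  hetk <- paste(run$het_snps$chrom, run$het_snps$pos)
  asymk <- paste(run$asymmetric$chrom, run$asymmetric$pos)
  expect_true(all(asymk %in% hetk))
  expect_true(all(in_otfr(run$asymmetric$chrom, run$asymmetric$pos, otfrs)))
})
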