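test_that("blacklist filter removes sex/mito/repeat sites", {
  sites <- data.frame(chrom = c("chrX", "chrM", "chr1", "chr1"),
                      pos = c(5L, 5L, 150L, 500L),
                      stringsAsFactors = FALSE)
  reps <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  kept <- filter_blacklist(sites, repeat_intervals = reps)
  expect_equal(kept$pos, 500L)
  expect_equal(attr(kept, "removed")$reason, rep("blacklist", 3))
})

test_that("indel-proximity distances follow the worked examples", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 100L, 104L),
                      stringsAsFactors = FALSE)
  # region covering 1-based 103..105 is 0-based [102, 105)
  near <- data.frame(chrom = "chr1", start = 102L, end = 105L)
  far <- data.frame(chrom = "chr1", start = 105L, end = 108L)
  expect_equal(nrow(filter_indel_proximity(sites[1, ], near, 5L)), 0L)
  expect_equal(nrow(filter_indel_proximity(sites[2, ], far, 5L)), 1L)
  expect_equal(nrow(filter_indel_proximity(sites[3, ], near, 5L)), 0L)
})

test_that("clustered filter follows the worked examples and is simultaneous", {
  s <- function(p) data.frame(chrom = "chr1", pos = p,
                              stringsAsFactors = FALSE)
  expect_equal(nrow(filter_clustered(s(c(100L, 105L, 109L)), 10L)), 0L)
  expect_equal(nrow(filter_clustered(s(c(100L, 105L, 300L)), 10L)), 3L)
  expect_equal(nrow(filter_clustered(s(42L), 10L)), 1L)
  expect_error(filter_clustered(s(c(7L, 7L)), 10L), "unique")
})

test_that("clustered and indel filters agree with brute-force oracles", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(10:120, 1)
    sites <- unique(data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      pos = sample.int(2000L, n, replace = TRUE),
      stringsAsFactors = FALSE))
    w <- sample(c(5L, 10L, 25L), 1)
    kept <- filter_clustered(sites, w)
    expect_equal(paste(kept$chrom, kept$pos),
                 paste(sites$chrom, sites$pos)[!oracle_clustered_removed(sites, w)])

    regions <- data.frame(
      chrom = sample(c("chr1", "chr2"), 5, replace = TRUE),
      start = sample.int(1900L, 5))
    regions$end <- regions$start + sample(1:20, 5, replace = TRUE)
    kept2 <- filter_indel_proximity(sites, regions, 5L)
    expect_equal(paste(kept2$chrom, kept2$pos),
                 paste(sites$chrom, sites$pos)[!oracle_indel_removed(sites, regions, 5L)])
  }
})

test_that("exact two-sided binomial p-values match closed forms", {
  expect_equal(binomial_two_sided(5, 10), 1)
  expect_equal(binomial_two_sided(10, 10), 2 / 1024)
  expect_equal(binomial_two_sided(0, 10), 2 / 1024)
  expect_equal(binomial_two_sided(7, 10), 2 * 176 / 1024)  # 0.34375
  expect_error(binomial_two_sided(1, 0), "n must be")
  expect_error(binomial_two_sided(5, 4), "0 <= k <= n")
})

test_that("binomial test agrees with stats::binom.test and is symmetric", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    p0 <- sample(c(0.5, 0.5, 0.3, 0.71), 1)
    expect_equal(binomial_two_sided(k, n, p0),
                 stats::binom.test(k, n, p = p0)$p.value, tolerance = 1e-12)
    expect_equal(binomial_two_sided(k, n), binomial_two_sided(n - k, n))
  }
  # monotone: p non-increasing as |k - n/2| grows
  p <- binomial_two_sided(50:100, 100)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("het calling applies coverage, support and balance rules", {
  cfg <- run_config()
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                      id = NA_character_, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  counts <- rbind(
    # site 10: strongly imbalanced in every sample -> balance failure
    dual_obs("s1", "chr1", 10L, 20L, 1L), dual_obs("s2", "chr1", 10L, 20L, 1L),
    # site 20: balanced, two samples, both references -> retained
    dual_obs("s1", "chr1", 20L, 6L, 5L), dual_obs("s2", "chr1", 20L, 5L, 6L),
    # site 30: pooled coverage 9 -> low coverage
    ac_row("s1", "ref", "chr1", 30L, 3L, 2L),
    ac_row("s1", "alt", "chr1", 30L, 2L, 2L)
  )
  het <- call_het_snps(sites, counts, cfg)
  expect_equal(het$pos, 20L)
  expect_equal(het$pooled_ref_count, 22L)  # summed over samples and alignments
  expect_equal(het$pooled_alt_count, 22L)
  rem <- attr(het, "removed")
  expect_equal(rem$reason[match(c(10L, 30L), rem$pos)],
               c("allelic_balance", "low_coverage"))
})

test_that("pooled-balance mode reproduces the single pooled test", {
  cfg <- run_config(het_balance_pooled = TRUE)
  sites <- data.frame(chrom = "chr1", pos = 10L, id = NA, ref = "A",
                      alt = "G", stringsAsFactors = FALSE)
  counts <- rbind(dual_obs("s1", "chr1", 10L, 20L, 1L),
                  dual_obs("s2", "chr1", 10L, 20L, 1L))
  het <- call_het_snps(sites, counts, cfg)
  expect_equal(nrow(het), 0L)
  expect_equal(attr(het, "removed")$reason, "allelic_balance")
  expect_equal(attr(het, "removed")$balance_p,
               binomial_two_sided(80, 84))
})

test_that("a site must be seen in two samples and both references", {
  cfg <- run_config()
  sites <- data.frame(chrom = "chr1", pos = c(1L, 2L), id = NA, ref = "A",
                      alt = "G", stringsAsFactors = FALSE)
  counts <- rbind(
    dual_obs("s1", "chr1", 1L, 8L, 7L),                 # one sample only
    ac_row("s1", "ref", "chr1", 2L, 8L, 7L),            # one reference only
    ac_row("s2", "ref", "chr1", 2L, 8L, 7L)
  )
  het <- call_het_snps(sites, counts, cfg)
  expect_equal(nrow(het), 0L)
  rem <- attr(het, "removed")
  expect_setequal(rem$reason, c("sample_support", "reference_support"))
})

test_that("blacklist and indel filters commute", {
  set.seed(23)
  sites <- data.frame(chrom = sample(c("chr1", "chrX"), 60, replace = TRUE),
                      pos = sample.int(5000L, 60),
                      stringsAsFactors = FALSE)
  sites <- unique(sites)
  regions <- data.frame(chrom = "chr1", start = c(100L, 900L),
                        end = c(200L, 950L))
  a <- filter_indel_proximity(filter_blacklist(sites), regions, 5L)
  b <- filter_blacklist(filter_indel_proximity(sites, regions, 5L))
  expect_equal(paste(a$chrom, a$pos), paste(b$chrom, b$pos))
})
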