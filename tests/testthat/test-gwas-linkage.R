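test_that("trait filtering is case-insensitive substring matching", {
  cat <- data.frame(
    rsid = paste0("rs", 1:4), chrom = "chr1", pos = 1:4,
    trait = c("Schizophrenia", "Bipolar disorder", "Height",
              "late-onset Alzheimer's disease"),
    maf = 0.2, stringsAsFactors = FALSE)
  kept <- filter_traits(cat)
  expect_setequal(kept$rsid, c("rs1", "rs2", "rs4"))
  expect_error(filter_traits(cat, character(0)), "non-empty")
})

test_that("window matching is inclusive, chromosome-aware, symmetric", {
  expect_true(window_match("chr1", 1000000L, "chr1", 1010000L, 10000L))
  expect_false(window_match("chr1", 1000000L, "chr1", 1010001L, 10000L))
  expect_false(window_match("chr2", 1000000L, "chr1", 1000000L, 10000L))
  expect_equal(window_match("chr1", 5L, "chr1", 900L, 1000L),
               window_match("chr1", 900L, "chr1", 5L, 1000L))
})

test_that("MAF linkage uses absolute differences with an inclusive bound", {
  expect_true(maf_linked(0.30, 0.40))
  expect_false(maf_linked(0.05, 0.25))
  expect_true(maf_linked(0.10, 0.25))       # boundary |diff| = 0.15
  expect_equal(maf_linked(0.2, 0.4), maf_linked(0.4, 0.2))
  expect_error(maf_linked(0.6, 0.2), "\\(0, 0.5\\]")
  expect_error(maf_linked(0.2, 0), "\\(0, 0.5\\]")
})

test_that("report building agrees with the all-pairs oracle", {
  cfg <- run_config()
  set.seed(17)
  for (rep in 1:8) {
    n_r <- sample(20:60, 1); n_i <- sample(20:60, 1)
    rsnps <- data.frame(
      chrom = sample(c("chr1", "chr2"), n_r, replace = TRUE),
      pos = sample.int(200000L, n_r),
      maf = round(runif(n_r, 0.05, 0.5), 3), stringsAsFactors = FALSE)
    rsnps$display_id <- paste0(rsnps$chrom, ":", rsnps$pos)
    rsnps$gene_id <- sample(paste0("G", 1:10), n_r, replace = TRUE)
    idx <- data.frame(
      rsid = paste0("rs", seq_len(n_i)),
      chrom = sample(c("chr1", "chr2"), n_i, replace = TRUE),
      pos = sample.int(200000L, n_i),
      trait = "cognitive decline",
      maf = round(runif(n_i, 0.05, 0.5), 3), stringsAsFactors = FALSE)
    mafs <- rsnps[, c("chrom", "pos", "maf")]
    rep_df <- build_report(rsnps, idx, mafs, cfg)
    want <- oracle_linkage(rsnps, idx, cfg$gwas_window_bp, cfg$maf_max_diff)
    got_pairs <- paste(rep_df$rsnp_id, rep_df$index_rsid)
    want_pairs <- paste(rsnps$display_id[want[, 1]], idx$rsid[want[, 2]])
    expect_setequal(got_pairs, want_pairs)
    # every row satisfies both invariants
    expect_true(all(rep_df$distance_bp <= cfg$gwas_window_bp))
    expect_true(all(abs(rep_df$maf_rsnp - rep_df$maf_index) <=
                      cfg$maf_max_diff))
  }
})

test_that("report summaries count unique identifiers order-independently", {
  rep_df <- data.frame(
    rsnp_id = c("rs1", "rs1", "chr1:5"),
    gene_id = c("GA", "GB", "GA"),
    index_rsid = c("rs9", "rs9", "rs8"),
    stringsAsFactors = FALSE)
  s <- report_summary(rep_df)
  expect_equal(s$n_rows, 3L)
  expect_equal(s$unique_rsnps, 2L)
  expect_equal(s$unique_genes, 2L)
  expect_lte(s$unique_rsnps, s$n_rows)
  perm <- rep_df[c(3, 1, 2), ]
  expect_equal(report_summary(perm)[c("unique_rsnps", "unique_genes")],
               s[c("unique_rsnps", "unique_genes")])
  expect_equal(report_summary(rep_df[0, ])$unique_rsnps, 0L)
})

test_that("one rSNP matching two indexes yields two rows", {
  cfg <- run_config()
  rsnps <- data.frame(chrom = "chr1", pos = 50000L, display_id = "rs1",
                      gene_id = "GA", stringsAsFactors = FALSE)
  idx <- data.frame(rsid = c("rsA", "rsB"), chrom = "chr1",
                    pos = c(45000L, 55000L),
                    trait = c("schizophrenia", "autism"),
                    maf = c(0.2, 0.25), stringsAsFactors = FALSE)
  mafs <- data.frame(chrom = "chr1", pos = 50000L, maf = 0.22)
  rep_df <- build_report(rsnps, idx, mafs, cfg)
  expect_equal(nrow(rep_df), 2L)
  expect_equal(report_summary(rep_df)$unique_rsnps, 1L)
})
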