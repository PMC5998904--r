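test_that("marker selection enforces gene membership and RNA depth", {
  d <- shared_bundle_dir()
  gm <- read_gene_models(file.path(d, "genes.gtf"))
  cfg <- run_config()
  g1 <- gm[["G001"]]
  cds_pos <- g1$cds$start[2] + 3L + 1L
  targets <- data.frame(chrom = g1$chrom, pos = g1$tss + 10L,
                        gene_id = "G001", relation = "promoter",
                        stringsAsFactors = FALSE)
  rna <- data.frame(
    chrom = g1$chrom,
    pos = c(cds_pos, cds_pos + 7L, gm[["G003"]]$cds$start[1] + 2L),
    ref_count = c(8L, 5L, 30L), alt_count = c(4L, 4L, 10L),
    sample = "r1", stringsAsFactors = FALSE)
  mk <- select_markers(targets, rna, gm, cfg)
  # 12 reads in G001 CDS -> marker; 9 reads -> excluded; G003 not targeted
  expect_equal(mk$pos, cds_pos)
  expect_equal(mk$rna_ref_count, 8L)
  expect_equal(mk$marker_type, "cds_marker")
  # the promoter SNP itself becomes its own marker when expressed
  rna2 <- rbind(rna, data.frame(chrom = g1$chrom, pos = g1$tss + 10L,
                                ref_count = 20L, alt_count = 5L,
                                sample = "r1"))
  mk2 <- select_markers(targets, rna2, gm, cfg)
  expect_true(any(mk2$marker_type == "own_snp" & mk2$pos == g1$tss + 10L))
})

test_that("ASE flagging needs both the ratio and the significance gate", {
  cfg <- run_config()
  mk <- data.frame(
    chrom = "chr1", pos = 1:4, gene_id = "G",
    rna_ref_count = c(30L, 12L, 15L, 40L),
    rna_alt_count = c(10L, 10L, 10L, 0L),
    stringsAsFactors = FALSE)
  res <- ase_test(mk, cfg)
  expect_equal(res$allele_ratio, c(3, 1.2, 1.5, Inf))
  expect_equal(res$raw_p[1], binomial_two_sided(30, 40))
  expect_lt(res$raw_p[1], 0.01)
  expect_true(res$flagged[1])            # ratio 3, p ~ 0.0025
  expect_false(res$flagged[2])           # ratio 1.2 fails the ratio gate
  expect_false(res$flagged[3])           # ratio exactly 1.5 is not strict
  expect_true(res$flagged[4])            # infinite ratio, tiny p
  expect_true(all(res$adjusted_p >= res$raw_p))
})

test_that("ratio and p gates are each necessary on random data", {
  cfg <- run_config()
  set.seed(13)
  n <- 400
  tot <- sample(c(10:60, 150:400), n, replace = TRUE)
  ref <- rbinom(n, tot, 0.5)
  mk <- data.frame(chrom = "chr1", pos = seq_len(n), gene_id = "G",
                   rna_ref_count = ref, rna_alt_count = tot - ref,
                   stringsAsFactors = FALSE)
  res <- ase_test(mk, cfg)
  thr <- cfg$ase_ratio_threshold
  ratio_only <- res$allele_ratio > thr | res$allele_ratio < 1 / thr
  p_only <- res$raw_p <= cfg$ase_alpha
  expect_gt(sum(ratio_only), sum(res$flagged))
  expect_gt(sum(p_only), sum(res$flagged))
  expect_equal(res$flagged, ratio_only & p_only)
})

test_that("Fisher variant tests RNA counts against pooled DNA counts", {
  cfg <- run_config(ase_test = "fisher")
  mk <- data.frame(chrom = "chr1", pos = 1L, gene_id = "G",
                   rna_ref_count = 40L, rna_alt_count = 10L,
                   stringsAsFactors = FALSE)
  dna <- data.frame(chrom = "chr1", pos = 1L,
                    pooled_ref_count = 50L, pooled_alt_count = 55L,
                    stringsAsFactors = FALSE)
  res <- ase_test(mk, cfg, dna_counts = dna)
  expect_equal(res$raw_p,
               stats::fisher.test(matrix(c(40, 10, 50, 55), 2))$p.value)
  expect_error(ase_test(mk, cfg), "DNA counts")
})

test_that("promotion requires a flagged marker in a targeted gene", {
  asnps <- data.frame(chrom = c("chr10", "chr10"),
                      pos = c(70716212L, 70720000L),
                      id = c(NA, "rs999"), stringsAsFactors = FALSE)
  targets <- data.frame(chrom = c("chr10", "chr10"),
                        pos = c(70716212L, 70720000L),
                        gene_id = c("GA", "GB"), relation = "promoter",
                        stringsAsFactors = FALSE)
  ase <- data.frame(gene_id = c("GA", "GB"), flagged = c(TRUE, FALSE),
                    stringsAsFactors = FALSE)
  rs <- promote_to_rsnp(asnps, targets, ase)
  expect_equal(nrow(rs), 1L)
  expect_equal(rs$display_id, "chr10:70716212")  # unannotated -> chrN:pos
  expect_equal(attr(rs, "rsnps")$display_id, "chr10:70716212")
  ase$flagged <- c(FALSE, TRUE)
  rs2 <- promote_to_rsnp(asnps, targets, ase)
  expect_equal(rs2$display_id, "rs999")          # annotated -> rsID
  ase$flagged <- c(FALSE, FALSE)
  expect_equal(nrow(promote_to_rsnp(asnps, targets, ase)), 0L)
})
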