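test_that("proximal targets follow promoter/intron/UTR membership", {
  d <- shared_bundle_dir()
  gm <- read_gene_models(file.path(d, "genes.gtf"))
  g1 <- gm[["G001"]]
  cfg <- run_config()
  intron_pos <- g1$introns$start[1] + 5L + 1L
  asnps <- data.frame(chrom = g1$chrom,
                      pos = c(intron_pos, g1$cds$start[2] + 3L + 1L),
                      stringsAsFactors = FALSE)
  tg <- assign_nearby_targets(asnps, gm, cfg)
  expect_true(any(tg$pos == intron_pos & tg$gene_id == "G001" &
                    tg$relation == "intron"))
  # the CDS-exonic position is far from the TSS and yields no assignment
  mid_cds <- data.frame(chrom = g1$chrom, pos = g1$cds$start[3] + 1L + 1L)
  if (abs(mid_cds$pos - g1$tss) > cfg$promoter_flank_bp) {
    expect_equal(nrow(assign_nearby_targets(mid_cds, gm, cfg)), 0L)
  }
})

test_that("effective genome size merges peaks and averages datasets", {
  expect_equal(effective_genome_size(
    data.frame(chrom = "chr1", start = c(0L, 50L), end = c(100L, 200L))), 200)
  expect_equal(effective_genome_size(list(
    data.frame(chrom = "chr1", start = 0L, end = 100L),
    data.frame(chrom = "chr1", start = 0L, end = 300L))), 200)
  expect_equal(effective_genome_size(
    data.frame(chrom = "chr1", start = c(0L, 20L), end = c(10L, 30L))), 20)
  expect_error(effective_genome_size(list()), "no peak sets")
})

test_that("contact filtering applies pair, direction and geometry rules", {
  cfg <- run_config()
  ct <- data.frame(
    chrom1 = "chr1", start1 = 0L, end1 = 1000L,
    chrom2 = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    start2 = c(50000L, 50000L, 50000L, 50000L, 500L),
    end2 = c(51000L, 51000L, 51000L, 51000L, 1500L),
    total_pairs = c(25L, 19L, 25L, 25L, 25L),
    pairs_forward = c(12L, 10L, 18L, 12L, 12L),
    pairs_reverse = c(13L, 9L, 7L, 13L, 13L),
    stringsAsFactors = FALSE
  )
  kept <- filter_contacts(ct, cfg)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$total_pairs, 25L)
  expect_setequal(attr(kept, "removed")$reason,
                  c("few_pairs", "direction_support", "interchromosomal",
                    "intersecting_anchors"))
})

test_that("contact significance is a 1-df Pearson chi-squared upper tail", {
  expect_equal(contact_significance(10, 10), 1)
  expect_lt(contact_significance(50, 10), 1e-30)   # X^2 = 160
  expect_equal(contact_significance(50, 10),
               stats::pchisq((50 - 10)^2 / 10, 1, lower.tail = FALSE))
  expect_error(contact_significance(5, 0), "positive")
  # monotone in O for O >= E
  p <- contact_significance(10:60, 10)
  expect_true(all(diff(p) <= 0))
})

test_that("distal assignment recovers an enriched cell and applies gates", {
  d <- shared_bundle_dir()
  gm <- read_gene_models(file.path(d, "genes.gtf"))
  cfg <- run_config()
  g_far <- gm[["G003"]]            # same chromosome as G001, 60 kb away
  snp_pos <- gm[["G001"]]$tss + 50L
  asnps <- data.frame(chrom = "chr1", pos = snp_pos,
                      stringsAsFactors = FALSE)
  ct <- data.frame(chrom1 = "chr1", start1 = snp_pos - 200L,
                   end1 = snp_pos + 200L,
                   chrom2 = "chr1", start2 = g_far$tss - 100L,
                   end2 = g_far$tss + 100L,
                   total_pairs = 30L, pairs_forward = 15L,
                   pairs_reverse = 15L, stringsAsFactors = FALSE)
  res <- assign_distal_targets(asnps, gm, ct, g_eff = 200000, cfg)
  expect_true(any(res$gene_id == "G003" & res$relation == "distal_chiapet"))
  expect_true(all(res$contact_p < cfg$contact_alpha))
  expect_true(all(res$contact_O > res$contact_E))
  # a contact onto the SNP's own promoter is excluded as intersecting
  own <- ct
  own$start2 <- snp_pos - 100L; own$end2 <- snp_pos + 100L
  res_own <- assign_distal_targets(asnps, gm, own, g_eff = 200000, cfg)
  expect_false("G001" %in% res_own$gene_id)
  # depleted cells are never reliable even when formally extreme
  expect_equal(nrow(assign_distal_targets(
    asnps, gm, ct[0, ], g_eff = 200000, cfg)), 0L)
  expect_error(assign_distal_targets(asnps, gm, ct, g_eff = 0, cfg),
               "positive")
})

test_that("combine_targets prefers proximal evidence and deduplicates", {
  nearby <- data.frame(chrom = "chr1", pos = 10L, gene_id = "G1",
                       relation = "promoter", stringsAsFactors = FALSE)
  distal <- data.frame(chrom = "chr1", pos = c(10L, 10L),
                       gene_id = c("G1", "G2"),
                       relation = "distal_chiapet",
                       contact_O = c(30, 25), contact_E = c(0.1, 0.1),
                       contact_p = c(1e-10, 1e-9), stringsAsFactors = FALSE)
  comb <- combine_targets(nearby, distal)
  expect_equal(nrow(comb), 2L)
  expect_equal(comb$relation[comb$gene_id == "G1"], "promoter")
  expect_equal(comb$relation[comb$gene_id == "G2"], "distal_chiapet")
})

test_that("planted loops are recovered and ligation noise is rejected", {
  d <- shared_bundle_dir()
  run <- shared_run()
  man <- read_truth_manifest(d)
  dl <- man$distal_links
  asymk <- paste(run$asymmetric$chrom, run$asymmetric$pos)
  tk <- paste(run$targets$chrom, run$targets$pos, run$targets$gene_id)
  # every planted loop whose source SNP was detected asymmetric yields the
  # distal target
  det <- paste(dl$chrom, dl$pos) %in% asymk
  expect_gt(mean(det), 0.8)
  expect_true(all(paste(dl$chrom, dl$pos, dl$gene_id)[det] %in% tk))
  # all reported distal cells are significantly enriched
  distal <- run$targets[run$targets$relation == "distal_chiapet", ]
  expect_true(all(distal$contact_p < run$config$contact_alpha))
  expect_true(all(distal$contact_O > distal$contact_E))
})
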