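test_that("identical seeds give byte-identical bundles", {
  spec <- simulation_spec(n_het_sites = 400L, n_genes = 20L, n_otfrs = 100L,
                          n_gwas_indexes = 20L, chiapet_noise_pairs = 50L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  simulate_bundle(spec, d1)
  simulate_bundle(spec, d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed changes the data
  d3 <- file.path(tempdir(), "det3")
  simulate_bundle(simulation_spec(rng_seed = 2L, n_het_sites = 400L,
                                  n_genes = 20L, n_otfrs = 100L,
                                  n_gwas_indexes = 20L,
                                  chiapet_noise_pairs = 50L), d3)
  f3 <- sort(list.files(d3, full.names = TRUE))
  expect_false(all(tools::md5sum(f1) == tools::md5sum(f3)))
})

test_that("emitted files pass their own readers without warnings", {
  d <- shared_bundle_dir()
  expect_no_warning({
    v <- read_variants(file.path(d, "variants.vcf"))
    read_intervals(file.path(d, "otfrs.bed"))
    read_intervals(file.path(d, "repeats.bed"))
    read_allele_counts(file.path(d, "chip_allele_counts.tsv"))
    read_contacts(file.path(d, "chiapet_contacts.bedpe"))
    read_rna_counts(file.path(d, "rna_allele_counts.tsv"))
    read_gwas_catalog(file.path(d, "gwas_catalog.tsv"))
    read_maf_table(file.path(d, "snp_mafs.tsv"))
    read_gene_models(file.path(d, "genes.gtf"))
  })
  man <- read_truth_manifest(d)
  expect_equal(nrow(v$snvs) - nrow(man$qc_decoys) - nrow(man$artifact_sites),
               man$n_clean_sites)
  # VCF reference alleles match the emitted genome
  genome <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  idx <- sample(nrow(v$snvs), 50)
  got <- vapply(idx, function(i) as.character(Biostrings::extractAt(
    genome[[v$snvs$chrom[i]]],
    IRanges::IRanges(v$snvs$pos[i], v$snvs$pos[i]))), character(1))
  expect_equal(got, v$snvs$ref[idx])
})

test_that("simulated coverage matches the specified mean", {
  d <- shared_bundle_dir()
  man <- read_truth_manifest(d)
  counts <- read_allele_counts(file.path(d, "chip_allele_counts.tsv"))
  ref_align <- counts[counts$alignment_ref == "ref", ]
  # under the reference alignment all true reads are present except lost
  # alternative-allele reads; reconstruct totals from the alt alignment's
  # alt counts, which are complete
  alt_align <- counts[counts$alignment_ref == "alt", ]
  tot <- ref_align$ref_count + alt_align$alt_count
  keep <- tot > 4  # exclude the low-coverage fodder
  expect_gt(sum(keep), 1000)
  expect_lt(abs(mean(tot[keep]) - man$spec$coverage_mean),
            0.05 * man$spec$coverage_mean)
})

test_that("reference bias shifts alignments oppositely and averages out", {
  d <- shared_bundle_dir()
  man <- read_truth_manifest(d)
  counts <- read_allele_counts(file.path(d, "chip_allele_counts.tsv"))
  pl <- man$planted_asymmetric
  null_keys <- setdiff(paste(counts$chrom, counts$pos),
                       paste(pl$chrom, pl$pos))
  art <- man$artifact_sites
  null_keys <- setdiff(null_keys, paste(art$chrom, art$pos))
  cc <- counts[paste(counts$chrom, counts$pos) %in% null_keys, ]
  fr_ref <- with(cc[cc$alignment_ref == "ref", ],
                 sum(ref_count) / sum(ref_count + alt_count))
  fr_alt <- with(cc[cc$alignment_ref == "alt", ],
                 sum(ref_count) / sum(ref_count + alt_count))
  expect_gt(fr_ref, 0.5 + man$spec$reference_bias / 2)
  expect_lt(fr_alt, 0.5 - man$spec$reference_bias / 2)
})

test_that("a null configuration plants nothing and calibrates near nominal", {
  spec <- simulation_spec(rng_seed = 4L, frac_asymmetric = 0,
                          n_het_sites = 600L, n_genes = 20L, n_otfrs = 100L,
                          n_gwas_indexes = 10L, chiapet_noise_pairs = 50L,
                          n_chiapet_loops = 1L)
  d <- file.path(tempdir(), "nullcfg")
  b <- simulate_bundle(spec, d)
  expect_equal(nrow(b$manifest$planted_asymmetric), 0L)
  run <- run_pipeline(d)
  frac <- mean(run$asb_tests$raw_p < run$config$asb_alpha)
  # conservative exact test: per-test rejections stay at or below nominal
  expect_lt(frac, run$config$asb_alpha + 3 * sqrt(0.01 * 0.99 /
                                                    nrow(run$asb_tests)))
})

test_that("infeasible layouts are rejected", {
  expect_error(simulate_bundle(simulation_spec(
    n_genes = 400L, n_otfrs = 2000L), tempdir()), "infeasible")
  expect_error(simulation_spec(n_otfrs = 7L), "n_otfrs")
  expect_error(simulation_spec(frac_asymmetric = 1.5), "frac_asymmetric")
  expect_error(simulation_spec(n_active_samples = 9L,
                               n_covering_samples = 5L), "n_active_samples")
})
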