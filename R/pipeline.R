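# End-to-end orchestration: heterozygous-SNP QC -> allele-specific binding
# -> target assignment -> allele-specific expression -> GWAS linkage, with
# funnel logging and per-stage outputs.

default_input_paths <- function(dir) {
  list(
    genes = file.path(dir, "genes.gtf"),
    otfrs = file.path(dir, "otfrs.bed"),
    repeats = file.path(dir, "repeats.bed"),
    variants = file.path(dir, "variants.vcf"),
    chip_counts = file.path(dir, "chip_allele_counts.tsv"),
    contacts = file.path(dir, "chiapet_contacts.bedpe"),
    peaks = Sys.glob(file.path(dir, "polII_peaks_*.bed")),
    rna_counts = file.path(dir, "rna_allele_counts.tsv"),
    gwas = file.path(dir, "gwas_catalog.tsv"),
    mafs = file.path(dir, "snp_mafs.tsv")
  )
}

#' Run the full rSNP discovery pipeline
#'
#' Executes the stages in fixed order: heterozygous-site QC, allele-specific
#' binding detection inside OTFRs, proximal and ChIA-PET distal target
#' assignment, allele-specific expression confirmation, and GWAS linkage.
#' Every filtering step is recorded in a funnel log.
#'
#' @param input Either a directory containing a standard input bundle (as
#'   written by [simulate_bundle()]) or a named list of paths with elements
#'   `genes`, `otfrs`, `variants`, `chip_counts`, `contacts`, `peaks`
#'   (character vector), `rna_counts`, `gwas`, `mafs` and optionally
#'   `repeats`.
#' @param config A [run_config()] object.
#' @param out_dir Optional directory: when given, per-stage TSV outputs, the
#'   final report and a JSON summary are written there.
#' @return An object of class `"rsnp_run"`: a list with the per-stage
#'   tables (`het_snps`, `asb_tests`, `asymmetric`, `targets`, `markers`,
#'   `ase`, `rsnp_targets`, `rsnps`, `report`), the `summary` counts and
#'   the `funnel` log.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = NULL) {
  paths <- if (is.character(input) && length(input) == 1L &&
               dir.exists(input)) default_input_paths(input) else input
  required <- c("genes", "otfrs", "variants", "chip_counts", "contacts",
                "peaks", "rna_counts", "gwas", "mafs")
  for (f in required) {
    p <- paths[[f]]
    if (is.null(p) || !length(p) || !all(file.exists(p))) {
      stop("missing input file for '", f, "': ",
           paste(p %||% "<unset>", collapse = ", "), call. = FALSE)
    }
  }
  log <- funnel_log()

  ## stage 1-2: variants and QC
  vars <- read_variants(paths$variants)
  sites <- vars$snvs
  otfrs <- read_intervals(paths$otfrs)
  repeats <- if (!is.null(paths$repeats) && file.exists(paths$repeats)) {
    read_intervals(paths$repeats)
  } else NULL
  counts <- read_allele_counts(paths$chip_counts)

  s1 <- filter_blacklist(sites, config$sex_chroms, config$mito_names,
                         repeats)
  log$add("blacklist", nrow(sites), nrow(s1), "sex/mito/repeat")
  s2 <- filter_clustered(s1, config$cluster_window_bp)
  log$add("clustered", nrow(s1), nrow(s2), "clustered_snps")
  s3 <- filter_indel_proximity(s2, vars$other_regions,
                               config$indel_exclusion_bp)
  log$add("indel_proximity", nrow(s2), nrow(s3), "near_indel")
  het <- call_het_snps(s3, counts, config)
  qc_removed <- attr(het, "removed")
  if (!is.null(qc_removed) && nrow(qc_removed)) {
    for (why in unique(qc_removed$reason)) {
      log$add("het_call", nrow(s3),
              nrow(s3) - sum(qc_removed$reason == why), why)
    }
  }
  log$add("het_call_total", nrow(s3), nrow(het))

  ## stage 3-4: allele-specific binding inside OTFRs
  asb <- detect_asb(het, counts, otfrs, config)
  asym <- asymmetric_snps(asb)
  n_in_otfr <- length(unique(paste(asb$chrom, asb$pos)))
  log$add("otfr_membership", nrow(het),
          sum(in_otfr(het$chrom, het$pos, otfrs)), "outside_otfr")
  log$add("asb_detection", sum(in_otfr(het$chrom, het$pos, otfrs)),
          nrow(asym), "no_significant_asb")

  ## stage 5: target genes
  genes <- read_gene_models(paths$genes)
  nearby <- assign_nearby_targets(asym, genes, config)
  g_eff <- effective_genome_size(lapply(paths$peaks, read_intervals))
  contacts <- read_contacts(paths$contacts)
  kept_contacts <- filter_contacts(contacts, config)
  log$add("chiapet_filter", nrow(contacts), nrow(kept_contacts),
          "pair_count/direction/interchromosomal/intersecting")
  distal <- assign_distal_targets(asym, genes, kept_contacts, g_eff, config)
  targets <- combine_targets(nearby, distal)
  log$add("target_assignment", nrow(asym),
          length(unique(paste(targets$chrom, targets$pos))), "no_target")

  ## stage 6: allele-specific expression
  rna <- read_rna_counts(paths$rna_counts)
  markers <- select_markers(targets, rna, genes, config)
  ase <- ase_test(markers, config, dna_counts = het)
  rsnp_targets <- promote_to_rsnp(asym, targets, ase)
  rsnps <- attr(rsnp_targets, "rsnps")
  log$add("ase_confirmation", length(unique(paste(targets$chrom,
                                                  targets$pos))),
          nrow(rsnps), "no_confirmed_target")

  ## stage 7: GWAS linkage
  catalog <- read_gwas_catalog(paths$gwas)
  indexes <- filter_traits(catalog, config$trait_signatures)
  log$add("gwas_trait_filter", nrow(catalog), nrow(indexes),
          "trait_signature")
  mafs <- read_maf_table(paths$mafs)
  report <- build_report(rsnp_targets, indexes, mafs, config)
  log$add("gwas_linkage", nrow(rsnps),
          length(unique(report$rsnp_id)), "no_linked_index")

  summ <- list(
    n_het = nrow(het),
    n_asymmetric = nrow(asym),
    n_targeted_snps = length(unique(paste(targets$chrom, targets$pos))),
    n_target_genes = length(unique(targets$gene_id)),
    n_rsnps = nrow(rsnps),
    n_linked_rsnps_unique = length(unique(report$rsnp_id)),
    n_linked_genes_unique = length(unique(report$gene_id))
  )
  run <- structure(list(
    config = config, het_snps = het, asb_tests = asb, asymmetric = asym,
    targets = targets, markers = markers, ase = ase,
    rsnp_targets = rsnp_targets, rsnps = rsnps, report = report,
    summary = summ, funnel = log$table()
  ), class = "rsnp_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(het, file.path(out_dir, "het_snps.tsv"))
    write_tsv(asb, file.path(out_dir, "asb_tests.tsv"))
    write_tsv(targets, file.path(out_dir, "targets.tsv"))
    write_tsv(ase, file.path(out_dir, "ase_results.tsv"))
    write_tsv(rsnp_targets, file.path(out_dir, "rsnps.tsv"))
    write_tsv(run$report, file.path(out_dir, "linked_rsnps.tsv"))
    write_tsv(run$funnel, file.path(out_dir, "funnel_log.tsv"))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.rsnp_run <- function(x, ...) {
  s <- x$summary
  cat("rSNP pipeline run\n")
  cat("  heterozygous SNPs retained :", s$n_het, "\n")
  cat("  asymmetric SNPs (ASB)      :", s$n_asymmetric, "\n")
  cat("  SNPs with target genes     :", s$n_targeted_snps,
      "(", s$n_target_genes, "genes )\n")
  cat("  confirmed rSNPs (ASE)      :", s$n_rsnps, "\n")
  cat("  GWAS-linked rSNPs          :", s$n_linked_rsnps_unique,
      "(", s$n_linked_genes_unique, "genes )\n")
  invisible(x)
}

#' @export
summary.rsnp_run <- function(object, ...) {
  out <- object$summary
  out$funnel <- object$funnel
  class(out) <- "summary.rsnp_run"
  out
}

#' @export
print.summary.rsnp_run <- function(x, ...) {
  cat("Stage funnel:\n")
  print(x$funnel)
  cat("\nCounts:\n")
  for (nm in setdiff(names(x), "funnel")) cat(" ", nm, "=", x[[nm]], "\n")
  invisible(x)
}
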