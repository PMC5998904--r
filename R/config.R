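#' Default GWAS-catalog trait signatures for cognitive disorders
#'
#' The twelve free-text query strings used to restrict a GWAS-catalog extract
#' to traits related to cognition and cognitive disorders.  Matching is
#' case-insensitive substring containment (see [filter_traits()]).
#'
#' @return Character vector of twelve trait signatures.
#' @export
default_trait_signatures <- function() {
  c(
    "Alzheimer's disease", "autism", "autism spectrum disorder",
    "antipsychotic", "anxiety", "bipolar disorder", "cognitive",
    "depression", "depressive disorder", "Parkinson's disease",
    "posttraumatic", "schizophrenia"
  )
}

#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the rSNP discovery pipeline into a
#' validated list.  Defaults reproduce the published analysis settings: sites
#' must be covered by at least 10 high-quality reads (bases with Phred <= 20
#' and alignments with mapping quality <= 25 are assumed excluded upstream of
#' count extraction), SNPs within 5 bp of indel-mapped regions or within
#' 10 bp of two other SNPs are dropped, allele-specific binding is called at
#' p < 0.01 by exact two-sided binomial test, promoters span 1.8 kb either
#' side of the TSS, ChIA-PET contacts need 20 paired reads with at least 10
#' in each direction and pass at p < 0.001 against the random-ligation
#' expectation, allele-specific expression needs 10 RNA reads, an allelic
#' ratio beyond 1.5 (or 1/1.5) and p <= 0.05, and GWAS linkage uses a
#' +/- 10 kb window with minor-allele-frequency difference <= 0.15.
#'
#' @param min_site_coverage Minimum pooled read coverage at a site (reads).
#' @param min_base_quality Phred cutoff assumed applied during pileup
#'   extraction (bases at or below it excluded); recorded for provenance.
#' @param min_mapping_quality Mapping-quality cutoff assumed applied upstream
#'   (only alignments above it retained); recorded for provenance.
#' @param indel_exclusion_bp Exclusion distance around indel-mapped regions.
#' @param cluster_window_bp Window defining clustered SNPs: a site with two
#'   or more other sites within this distance is removed.
#' @param het_balance_alpha Significance level of the heterozygosity balance
#'   test; samples (or the pooled counts, see `het_balance_pooled`) with
#'   binomial p below it are not balance-consistent.
#' @param het_balance_pooled Logical; if `TRUE` the balance test runs on
#'   counts pooled over all samples instead of per sample (see the methods
#'   vignette for why per-sample support is the default).
#' @param min_reads_per_allele Minimum pooled reads supporting each allele.
#' @param min_supporting_samples Minimum number of samples that must observe
#'   the site (and, per-sample mode, be balance-consistent).
#' @param asb_alpha Significance level for allele-specific binding.
#' @param asb_use_adjusted_p Logical; gate ASB on Benjamini-Hochberg adjusted
#'   p-values instead of raw p-values (both are always computed).
#' @param bias_combine How dual-alignment counts are combined: one of
#'   `"mean"`, `"min"`, `"sum"`.
#' @param promoter_flank_bp Promoter half-width around the TSS.
#' @param promoter_union Logical; if `TRUE`, promoter windows are taken
#'   around every annotated transcript TSS of a gene rather than the
#'   canonical (longest) transcript only.
#' @param snp_window_bp Half-width of the SNP window used as ChIA-PET
#'   contact-matrix rows.
#' @param chiapet_min_pairs Minimum total paired ChIA-PET reads per contact.
#' @param chiapet_min_per_direction Minimum reads per direction per contact.
#' @param contact_alpha Significance level for contact reliability.
#' @param contact_use_adjusted_p Logical; BH-adjust contact p-values before
#'   gating (off by default).
#' @param min_rna_reads Minimum RNA reads crossing a marker SNP.
#' @param ase_ratio_threshold Allelic expression ratio beyond which (strictly)
#'   an exon is ratio-eligible for allele-specific expression.
#' @param ase_alpha Significance level for allele-specific expression.
#' @param ase_test `"binomial"` (against 0.5) or `"fisher"` (RNA counts vs
#'   pooled DNA counts).
#' @param ase_use_adjusted_p Logical; gate ASE on BH-adjusted p-values.
#' @param gwas_window_bp Window around each GWAS index SNP.
#' @param maf_max_diff Maximum absolute minor-allele-frequency difference for
#'   two SNPs to be considered closely linked (0.15 means 15 percentage
#'   points).
#' @param trait_signatures Character vector of trait query strings.
#' @param sex_chroms,mito_names Chromosome names removed by the blacklist
#'   filter.
#' @param rng_seed Integer seed recorded with the run.
#'
#' @return A list of class `"rsnp_config"`.
#' @examples
#' cfg <- run_config()
#' cfg$asb_alpha
#' @export
run_config <- function(min_site_coverage = 10L,
                       min_base_quality = 20L,
                       min_mapping_quality = 25L,
                       indel_exclusion_bp = 5L,
                       cluster_window_bp = 10L,
                       het_balance_alpha = 0.05,
                       het_balance_pooled = FALSE,
                       min_reads_per_allele = 3L,
                       min_supporting_samples = 2L,
                       asb_alpha = 0.01,
                       asb_use_adjusted_p = FALSE,
                       bias_combine = c("mean", "min", "sum"),
                       promoter_flank_bp = 1800L,
                       promoter_union = FALSE,
                       snp_window_bp = 1000L,
                       chiapet_min_pairs = 20L,
                       chiapet_min_per_direction = 10L,
                       contact_alpha = 0.001,
                       contact_use_adjusted_p = FALSE,
                       min_rna_reads = 10L,
                       ase_ratio_threshold = 1.5,
                       ase_alpha = 0.05,
                       ase_test = c("binomial", "fisher"),
                       ase_use_adjusted_p = FALSE,
                       gwas_window_bp = 10000L,
                       maf_max_diff = 0.15,
                       trait_signatures = default_trait_signatures(),
                       sex_chroms = c("chrX", "chrY", "X", "Y"),
                       mito_names = c("chrM", "chrMT", "M", "MT"),
                       rng_seed = 1L) {
  cfg <- list(
    min_site_coverage = as.integer(min_site_coverage),
    min_base_quality = as.integer(min_base_quality),
    min_mapping_quality = as.integer(min_mapping_quality),
    indel_exclusion_bp = as.integer(indel_exclusion_bp),
    cluster_window_bp = as.integer(cluster_window_bp),
    het_balance_alpha = het_balance_alpha,
    het_balance_pooled = isTRUE(het_balance_pooled),
    min_reads_per_allele = as.integer(min_reads_per_allele),
    min_supporting_samples = as.integer(min_supporting_samples),
    asb_alpha = asb_alpha,
    asb_use_adjusted_p = isTRUE(asb_use_adjusted_p),
    bias_combine = match.arg(bias_combine),
    promoter_flank_bp = as.integer(promoter_flank_bp),
    promoter_union = isTRUE(promoter_union),
    snp_window_bp = as.integer(snp_window_bp),
    chiapet_min_pairs = as.integer(chiapet_min_pairs),
    chiapet_min_per_direction = as.integer(chiapet_min_per_direction),
    contact_alpha = contact_alpha,
    contact_use_adjusted_p = isTRUE(contact_use_adjusted_p),
    min_rna_reads = as.integer(min_rna_reads),
    ase_ratio_threshold = ase_ratio_threshold,
    ase_alpha = ase_alpha,
    ase_test = match.arg(ase_test),
    ase_use_adjusted_p = isTRUE(ase_use_adjusted_p),
    gwas_window_bp = as.integer(gwas_window_bp),
    maf_max_diff = maf_max_diff,
    trait_signatures = as.character(trait_signatures),
    sex_chroms = as.character(sex_chroms),
    mito_names = as.character(mito_names),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "rsnp_config"
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  counts <- c(
    "min_site_coverage", "min_base_quality", "min_mapping_quality",
    "cluster_window_bp", "min_reads_per_allele", "min_supporting_samples",
    "promoter_flank_bp", "snp_window_bp", "chiapet_min_pairs",
    "chiapet_min_per_direction", "min_rna_reads", "gwas_window_bp"
  )
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v <= 0L) {
      stop("config field '", f, "' must be a single positive integer", call. = FALSE)
    }
  }
  if (cfg$indel_exclusion_bp < 0L) {
    stop("config field 'indel_exclusion_bp' must be >= 0", call. = FALSE)
  }
  for (f in c("het_balance_alpha", "asb_alpha", "contact_alpha", "ase_alpha")) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v <= 0 || v >= 1) {
      stop("config field '", f, "' must lie in (0, 1)", call. = FALSE)
    }
  }
  if (cfg$maf_max_diff <= 0 || cfg$maf_max_diff > 0.5) {
    stop("config field 'maf_max_diff' must lie in (0, 0.5]", call. = FALSE)
  }
  if (cfg$ase_ratio_threshold <= 1) {
    stop("config field 'ase_ratio_threshold' must exceed 1", call. = FALSE)
  }
  if (length(cfg$trait_signatures) < 1L) {
    stop("config field 'trait_signatures' must be non-empty", call. = FALSE)
  }
  cfg
}

#' Read a run configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [run_config()]; unknown keys are an
#' error so that typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `"rsnp_config"` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @export
print.rsnp_config <- function(x, ...) {
  cat("rSNP pipeline configuration\n")
  cat("  het calling : coverage >=", x$min_site_coverage,
      "| reads/allele >=", x$min_reads_per_allele,
      "| supporting samples >=", x$min_supporting_samples,
      "| balance alpha", x$het_balance_alpha,
      if (x$het_balance_pooled) "(pooled)" else "(per sample)", "\n")
  cat("  ASB         : alpha", x$asb_alpha,
      if (x$asb_use_adjusted_p) "(BH-adjusted)" else "(raw)",
      "| bias combine:", x$bias_combine, "\n")
  cat("  targets     : promoter +/-", x$promoter_flank_bp,
      "bp | ChIA-PET >=", x$chiapet_min_pairs, "pairs, >=",
      x$chiapet_min_per_direction, "per direction | contact alpha",
      x$contact_alpha, "\n")
  cat("  ASE         :", x$ase_test, "test | ratio >", x$ase_ratio_threshold,
      "| alpha", x$ase_alpha, "| RNA reads >=", x$min_rna_reads, "\n")
  cat("  GWAS        : window +/-", x$gwas_window_bp, "bp | MAF diff <=",
      x$maf_max_diff, "|", length(x$trait_signatures), "trait signatures\n")
  invisible(x)
}
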