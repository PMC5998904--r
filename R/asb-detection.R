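# Allele-specific binding detection: reference mapping-bias correction by
# combining dual-alignment counts, exact binomial testing per ChIP
# experiment, and Benjamini-Hochberg multiple-testing adjustment.

#' Combine dual-alignment counts into bias-corrected allele counts
#'
#' Reads are aligned both to the standard reference and to the alternative
#' genome carrying the alternate alleles; the reference alignment inflates
#' the reference allele and the alternative alignment inflates the
#' alternate allele.  The default correction takes the arithmetic mean of
#' the two alignments' counts per allele (rounded half up), which cancels a
#' symmetric additive mapping bias in expectation; `"min"` and `"sum"` are
#' available as alternative symmetric combinations.
#'
#' @param obs Data frame of observations for one site and one experiment,
#'   with columns `alignment_ref` (`"ref"`/`"alt"`), `ref_count`,
#'   `alt_count`; both alignment references must be present.
#' @param combine One of `"mean"`, `"min"`, `"sum"`.
#' @return Named integer vector `c(ref_count = , alt_count = )`.
#' @examples
#' obs <- data.frame(alignment_ref = c("ref", "alt"),
#'                   ref_count = c(60, 50), alt_count = c(40, 50))
#' bias_corrected_counts(obs)  # 55, 45
#' @export
bias_corrected_counts <- function(obs, combine = c("mean", "min", "sum")) {
  combine <- match.arg(combine)
  stopifnot_cols(obs, c("alignment_ref", "ref_count", "alt_count"),
                 "observation table")
  if (!all(c("ref", "alt") %in% obs$alignment_ref)) {
    stop("bias correction requires counts under both alignment references",
         call. = FALSE)
  }
  f <- switch(combine, mean = function(x) round_half_up(mean(x)),
              min = min, sum = sum)
  c(ref_count = as.integer(f(obs$ref_count)),
    alt_count = as.integer(f(obs$alt_count)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment of a vector of p-values; input order is
#' preserved.  Delegates to `stats::p.adjust(method = "BH")`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' benjamini_hochberg(c(0.001, 0.02, 0.03, 0.04))  # 0.004 0.04 0.04 0.04
#' @export
benjamini_hochberg <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Detect asymmetric SNPs (allele-specific binding)
#'
#' For every retained heterozygous SNP lying inside an OTFR and every ChIP
#' experiment with sufficient bias-corrected coverage, the exact two-sided
#' binomial test compares the corrected reference and alternative allele
#' counts against 0.5.  P-values are Benjamini-Hochberg adjusted across all
#' (site, experiment) tests of the run.  A SNP significant in at least one
#' experiment is asymmetric.  By default significance is gated on the raw
#' p-value at `asb_alpha` (adjusted values are reported alongside); set
#' `asb_use_adjusted_p = TRUE` in the config to gate on adjusted values.
#'
#' @param het_snps Retained sites from [call_het_snps()].
#' @param counts Allele-count table as from [read_allele_counts()].
#' @param otfrs OTFR interval table (`chrom`, `start`, `end`).
#' @param config A [run_config()] object.
#' @return Data frame with one row per tested (site, experiment):
#'   `chrom`, `pos`, `id`, `ref`, `alt`, `experiment_id`, `ref_count`,
#'   `alt_count`, `allele_ratio`, `raw_p`, `adjusted_p`, `significant`,
#'   plus the per-site logical `asymmetric` replicated across its rows.
#'   The unique asymmetric site table is attached as attribute
#'   `"asymmetric_sites"`.
#' @export
detect_asb <- function(het_snps, counts, otfrs, config = run_config()) {
  stopifnot_cols(het_snps, c("chrom", "pos"), "het SNP table")
  stopifnot_cols(counts, allele_count_cols, "allele-count table")

  inside <- in_otfr(het_snps$chrom, het_snps$pos, otfrs)
  snps <- het_snps[inside, , drop = FALSE]
  empty <- data.frame(
    chrom = character(), pos = integer(), id = character(),
    ref = character(), alt = character(), experiment_id = character(),
    ref_count = integer(), alt_count = integer(), allele_ratio = numeric(),
    raw_p = numeric(), adjusted_p = numeric(), significant = logical(),
    asymmetric = logical(), stringsAsFactors = FALSE
  )
  if (!nrow(snps)) {
    attr(empty, "asymmetric_sites") <- snps
    return(empty)
  }

  skey <- paste(snps$chrom, snps$pos)
  sel <- paste(counts$chrom, counts$pos) %in% skey
  cc <- counts[sel, , drop = FALSE]
  if (!nrow(cc)) {
    attr(empty, "asymmetric_sites") <- snps[0, , drop = FALSE]
    return(empty)
  }
  grp <- paste(cc$chrom, cc$pos, cc$sample_id, sep = "\r")
  n_align <- tapply(cc$alignment_ref,  grp,
                    function(x) length(unique(x)))
  comb <- switch(config$bias_combine,
                 mean = function(x) round_half_up(mean(x)),
                 min = min, sum = sum)
  ref_c <- tapply(cc$ref_count, grp, comb)
  alt_c <- tapply(cc$alt_count, grp, comb)
  keys <- do.call(rbind, strsplit(names(ref_c), "\r", fixed = TRUE))
  tests <- data.frame(
    chrom = keys[, 1], pos = as.integer(keys[, 2]),
    experiment_id = keys[, 3],
    ref_count = as.integer(ref_c), alt_count = as.integer(alt_c),
    stringsAsFactors = FALSE
  )
  # require dual-alignment evidence and per-experiment coverage
  ok <- as.integer(n_align) == 2L &
    tests$ref_count + tests$alt_count >= config$min_site_coverage
  tests <- tests[ok, , drop = FALSE]
  if (!nrow(tests)) {
    attr(empty, "asymmetric_sites") <- snps[0, , drop = FALSE]
    return(empty)
  }

  m <- match(paste(tests$chrom, tests$pos), skey)
  col_or_na <- function(col) {
    if (is.null(snps[[col]])) rep(NA_character_, nrow(tests)) else snps[[col]][m]
  }
  tests$id <- col_or_na("id")
  tests$ref <- col_or_na("ref")
  tests$alt <- col_or_na("alt")

  tot <- tests$ref_count + tests$alt_count
  tests$allele_ratio <- ifelse(tests$alt_count == 0, Inf,
                               tests$ref_count / tests$alt_count)
  tests$raw_p <- binomial_two_sided(tests$ref_count, tot)
  tests$adjusted_p <- benjamini_hochberg(tests$raw_p)
  gate <- if (config$asb_use_adjusted_p) tests$adjusted_p else tests$raw_p
  tests$significant <- gate < config$asb_alpha

  site_key <- paste(tests$chrom, tests$pos)
  asym_keys <- unique(site_key[tests$significant])
  tests$asymmetric <- site_key %in% asym_keys
  tests <- tests[order(tests$chrom, tests$pos, tests$experiment_id),
                 c("chrom", "pos", "id", "ref", "alt", "experiment_id",
                   "ref_count", "alt_count", "allele_ratio", "raw_p",
                   "adjusted_p", "significant", "asymmetric")]
  rownames(tests) <- NULL
  attr(tests, "asymmetric_sites") <-
    snps[skey %in% asym_keys, , drop = FALSE]
  tests
}

#' Extract the unique asymmetric-SNP table from [detect_asb()] output
#' @param asb_tests Result of [detect_asb()].
#' @return Data frame of unique asymmetric sites.
#' @export
asymmetric_snps <- function(asb_tests) {
  attr(asb_tests, "asymmetric_sites")
}
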