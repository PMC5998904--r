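# Heterozygous-site calling and quality control.  Sites arrive as
# allele-count evidence; the filters below remove blacklisted, clustered and
# indel-adjacent sites, then heterozygosity is called from coverage, allele
# support, multi-sample support and allelic balance.

site_cols <- c("chrom", "pos", "id", "ref", "alt")

keep_with_removed <- function(sites, keep, reason) {
  removed <- sites[!keep, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason
  kept <- sites[keep, , drop = FALSE]
  attr(kept, "removed") <- removed
  kept
}

#' Remove blacklisted sites (sex chromosomes, mitochondria, repeats)
#'
#' @param sites Site data frame with columns `chrom`, `pos` (1-based).
#' @param sex_chroms,mito_names Chromosome names to drop.
#' @param repeat_intervals Interval data frame (`chrom`, `start`, `end`;
#'   0-based half-open) of repeat-masked regions, or `NULL`.
#' @return The retained sites; removed records (with a `reason` column) are
#'   attached as attribute `"removed"`.
#' @export
filter_blacklist <- function(sites, sex_chroms = c("chrX", "chrY"),
                             mito_names = c("chrM", "chrMT"),
                             repeat_intervals = NULL) {
  stopifnot_cols(sites, c("chrom", "pos"), "site table")
  bad <- sites$chrom %in% c(sex_chroms, mito_names)
  if (!is.null(repeat_intervals) && nrow(repeat_intervals)) {
    bad <- bad | in_otfr(sites$chrom, sites$pos, repeat_intervals)
  }
  keep_with_removed(sites, !bad, "blacklist")
}

#' Remove sites near insertion/deletion regions
#'
#' A site is removed when its distance to the nearest base of any indel
#' region is at most `max_bp` (distance 0 meaning inside the region).
#'
#' @param sites Site data frame.
#' @param indel_regions Interval data frame (0-based half-open).
#' @param max_bp Exclusion distance in bp (default 5).
#' @return Retained sites with attribute `"removed"`.
#' @export
filter_indel_proximity <- function(sites, indel_regions, max_bp = 5L) {
  stopifnot_cols(sites, c("chrom", "pos"), "site table")
  if (max_bp < 0) stop("max_bp must be >= 0", call. = FALSE)
  if (is.null(indel_regions) || !nrow(indel_regions)) {
    return(keep_with_removed(sites, rep(TRUE, nrow(sites)), "indel_proximity"))
  }
  bad <- logical(nrow(sites))
  for (cc in unique(sites$chrom)) {
    iv <- indel_regions[indel_regions$chrom == cc, , drop = FALSE]
    if (!nrow(iv)) next
    sel <- which(sites$chrom == cc)
    p0 <- sites$pos[sel] - 1L
    for (i in seq_along(sel)) {
      d <- ifelse(p0[i] < iv$start, iv$start - p0[i],
                  ifelse(p0[i] >= iv$end, p0[i] - (iv$end - 1L), 0L))
      if (min(d) <= max_bp) bad[sel[i]] <- TRUE
    }
  }
  keep_with_removed(sites, !bad, "indel_proximity")
}

#' Remove clustered sites
#'
#' A site is clustered when at least two other sites lie within `window_bp`
#' of it (inclusive) on the same chromosome.  Clustering is evaluated
#' against the full input set and removals applied simultaneously, so the
#' result does not depend on processing order.
#'
#' @param sites Site data frame, unique by `(chrom, pos)`.
#' @param window_bp Cluster window in bp (default 10).
#' @return Retained sites with attribute `"removed"`.
#' @export
filter_clustered <- function(sites, window_bp = 10L) {
  stopifnot_cols(sites, c("chrom", "pos"), "site table")
  if (anyDuplicated(sites[, c("chrom", "pos")])) {
    stop("sites must be unique by (chrom, pos)", call. = FALSE)
  }
  bad <- logical(nrow(sites))
  for (cc in unique(sites$chrom)) {
    sel <- which(sites$chrom == cc)
    p <- sites$pos[sel]
    o <- order(p)
    ps <- p[o]
    # neighbours within +/- window_bp, excluding the site itself
    lo <- findInterval(ps - window_bp - 0.5, ps)
    hi <- findInterval(ps + window_bp + 0.5, ps)
    nb <- hi - lo - 1L
    bad[sel[o]] <- nb >= 2L
  }
  keep_with_removed(sites, !bad, "clustered")
}

#' Exact two-sided binomial test p-value
#'
#' The two-sided p-value is the total probability of all outcomes whose
#' point probability under `Binomial(n, p0)` does not exceed that of the
#' observed count (the convention of `stats::binom.test`).  For `p0 = 0.5`
#' this equals `min(1, 2 * min(P(X <= k), P(X >= k)))`.  Vectorised over
#' `k` and `n`.
#'
#' @param k Observed successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param p0 Null success probability (default 0.5).
#' @return Numeric vector of p-values.
#' @examples
#' binomial_two_sided(10, 10)  # 2 / 1024
#' binomial_two_sided(7, 10)   # 0.34375
#' @export
binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (any(n < 1)) stop("binomial_two_sided: n must be >= 1", call. = FALSE)
  if (any(k < 0 | k > n)) {
    stop("binomial_two_sided: k must satisfy 0 <= k <= n", call. = FALSE)
  }
  len <- max(length(k), length(n))
  k <- rep_len(as.numeric(k), len)
  n <- rep_len(as.numeric(n), len)
  if (length(p0) == 1L && p0 == 0.5) {
    m <- pmin(k, n - k)
    return(pmin(1, 2 * stats::pbinom(m, n, 0.5)))
  }
  p0 <- rep_len(p0, len)
  vapply(seq_len(len), function(i) {
    d <- stats::dbinom(0:n[i], n[i], p0[i])
    sum(d[d <= d[k[i] + 1] * (1 + 1e-07)])
  }, numeric(1))
}

#' Call heterozygous SNPs from allele-count evidence
#'
#' Applies, in order, the coverage, per-allele read-support, multi-sample /
#' dual-reference support and allelic-balance criteria.  By default the
#' balance test runs per sample: a sample is balance-consistent when the
#' exact binomial test on its bias-corrected allele counts does not reject
#' equality at `het_balance_alpha`, and a site is heterozygous-supported
#' when at least `min_supporting_samples` samples are balance-consistent.
#' Samples in which an allele-specific signal is genuinely present are thus
#' allowed to look imbalanced, provided other samples document both alleles
#' (see the methods vignette).  With `het_balance_pooled = TRUE` the single
#' test on counts pooled over all samples is used instead.
#'
#' @param sites Site data frame (`chrom`, `pos`, `id`, `ref`, `alt`),
#'   already passed the blacklist/cluster/indel filters.
#' @param counts Allele-count table as from [read_allele_counts()].
#' @param config A [run_config()] object.
#' @return Data frame of retained heterozygous SNPs with pooled counts and
#'   support summaries; removed sites (with single `reason`) attached as
#'   attribute `"removed"`.
#' @export
call_het_snps <- function(sites, counts, config = run_config()) {
  stopifnot_cols(sites, c("chrom", "pos"), "site table")
  stopifnot_cols(counts, allele_count_cols, "allele-count table")
  key <- paste(sites$chrom, sites$pos)
  ckey <- paste(counts$chrom, counts$pos)
  idx <- split(seq_len(nrow(counts)), ckey)

  n <- nrow(sites)
  pooled_ref <- integer(n); pooled_alt <- integer(n)
  n_samp <- integer(n); n_refs <- integer(n)
  n_consistent <- integer(n); balance_p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rows <- idx[[key[i]]]
    if (is.null(rows)) next
    obs <- counts[rows, , drop = FALSE]
    pooled_ref[i] <- sum(obs$ref_count)
    pooled_alt[i] <- sum(obs$alt_count)
    with_reads <- obs$ref_count + obs$alt_count > 0
    n_samp[i] <- length(unique(obs$sample_id[with_reads]))
    n_refs[i] <- length(unique(obs$alignment_ref[with_reads]))
    if (config$het_balance_pooled) {
      tot <- pooled_ref[i] + pooled_alt[i]
      balance_p[i] <- if (tot > 0) {
        binomial_two_sided(pooled_ref[i], tot)
      } else NA_real_
    } else {
      per <- split(obs, obs$sample_id)
      cons <- vapply(per, function(o) {
        r <- round_half_up(mean(o$ref_count))
        a <- round_half_up(mean(o$alt_count))
        tot <- r + a
        tot > 0 && binomial_two_sided(r, tot) >= config$het_balance_alpha
      }, logical(1))
      n_consistent[i] <- sum(cons)
    }
  }

  coverage <- pooled_ref + pooled_alt
  reason <- rep(NA_character_, n)
  fail <- function(cond, why) {
    reason[is.na(reason) & cond] <<- why
  }
  fail(coverage < config$min_site_coverage, "low_coverage")
  fail(pooled_ref < config$min_reads_per_allele |
         pooled_alt < config$min_reads_per_allele, "allele_support")
  fail(n_samp < config$min_supporting_samples, "sample_support")
  fail(n_refs < 2L, "reference_support")
  if (config$het_balance_pooled) {
    fail(is.na(balance_p) | balance_p < config$het_balance_alpha,
         "allelic_balance")
  } else {
    fail(n_consistent < config$min_supporting_samples, "allelic_balance")
  }

  het <- sites
  het$pooled_ref_count <- pooled_ref
  het$pooled_alt_count <- pooled_alt
  het$n_supporting_samples <- n_samp
  het$n_supporting_references <- n_refs
  if (config$het_balance_pooled) {
    het$balance_p <- balance_p
  } else {
    het$n_balance_consistent <- n_consistent
  }
  removed <- het[!is.na(reason), , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!is.na(reason)]
  kept <- het[is.na(reason), , drop = FALSE]
  attr(kept, "removed") <- removed
  kept
}
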