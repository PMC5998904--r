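# Closed-form power of the pipeline's decision rules, and the per-site
# recovery prediction used to validate planted-effect recovery on synthetic
# studies.  All quantities are exact binomial tail sums (no simulation).

#' Exact power of the two-sided binomial test
#'
#' Probability that the exact two-sided binomial test (against 0.5) rejects
#' at level `alpha` when the true success fraction is `f`, computed by
#' enumerating the rejection region.
#'
#' @param n Number of trials.
#' @param f True success probability.
#' @param alpha Significance level.
#' @param strict If `TRUE` (default) rejection requires `p < alpha`, as in
#'   allele-specific binding detection; `FALSE` uses `p <= alpha`.
#' @return Rejection probability.
#' @export
binomial_test_power <- function(n, f, alpha, strict = TRUE) {
  k <- 0:n
  p <- binomial_two_sided(k, n)
  sel <- if (strict) p < alpha else p <= alpha
  sum(stats::dbinom(k[sel], n, f))
}

#' Exact probability that a marker is flagged for allele-specific expression
#'
#' A marker is flagged when its allelic ratio strictly exceeds `thr` (or is
#' strictly below `1/thr`) and the exact binomial p-value is at most
#' `alpha`; this enumerates the joint acceptance region.
#'
#' @param n Total RNA reads at the marker.
#' @param f True reference-allele expression fraction.
#' @param alpha Significance level (default 0.05).
#' @param thr Ratio threshold (default 1.5).
#' @return Flagging probability.
#' @export
ase_flag_power <- function(n, f, alpha = 0.05, thr = 1.5) {
  k <- 0:n
  p <- binomial_two_sided(k, n)
  ratio <- ifelse(n - k == 0, Inf, k / (n - k))
  sel <- (ratio > thr | ratio < 1 / thr) & p <= alpha
  sum(stats::dbinom(k[sel], n, f))
}

#' Read a synthetic-study truth manifest
#'
#' @param dir Bundle directory (or a direct path to the JSON file).
#' @return The manifest as a list with data-frame components.
#' @export
read_truth_manifest <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "truth_manifest.json") else dir
  if (!file.exists(path)) stop("truth manifest not found: ", path,
                               call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# P(at most one success) for independent Bernoulli probabilities q.
poisson_binomial_le1 <- function(q) {
  p0 <- prod(1 - q)
  p1 <- sum(vapply(seq_along(q), function(i) q[i] * prod(1 - q[-i]),
                   numeric(1)))
  p0 + p1
}

#' Closed-form recovery prediction for planted rSNPs
#'
#' For every true planted rSNP of a synthetic bundle, computes the
#' probability that the pipeline recovers it, as the product of the exact
#' per-stage probabilities at the realised coverages: (i) heterozygosity
#' support (at least `min_supporting_samples` balance-consistent
#' experiments), (ii) allele-specific binding detection in at least one
#' covering experiment at the raw threshold, and (iii) allele-specific
#' expression flagging of at least one marker of at least one regulated
#' target gene.  Everything is an exact binomial tail sum conditioned on
#' the realised per-experiment read totals; no simulation is involved.
#'
#' @param dir Bundle directory written by [simulate_bundle()].
#' @param config The [run_config()] the pipeline is run with.
#' @return A list with `per_site` (data frame of per-rSNP predicted
#'   probabilities) and `predicted_power` (their mean).
#' @export
predict_planted_recovery <- function(dir, config = run_config()) {
  man <- read_truth_manifest(dir)
  pl <- man$planted_asymmetric
  act <- man$active_experiments
  dl <- man$distal_links
  f_asb <- man$spec$asb_allele_fraction
  f_ase <- man$spec$ase_allele_fraction
  counts <- read_allele_counts(file.path(dir, "chip_allele_counts.tsv"))
  rna <- read_rna_counts(file.path(dir, "rna_allele_counts.tsv"))
  genes <- read_gene_models(file.path(dir, "genes.gtf"))

  ckey <- paste(counts$chrom, counts$pos, counts$sample_id)
  corr_r <- tapply(counts$ref_count, ckey, function(x) round_half_up(mean(x)))
  corr_a <- tapply(counts$alt_count, ckey, function(x) round_half_up(mean(x)))
  csite <- paste(counts$chrom, counts$pos)
  rna_key <- paste(rna$chrom, rna$pos)

  true_rows <- which(pl$is_rsnp)
  pred <- numeric(length(true_rows))
  for (ii in seq_along(true_rows)) {
    i <- true_rows[ii]
    sk <- paste(pl$chrom[i], pl$pos[i])
    samples <- unique(counts$sample_id[csite == sk])
    actv <- act$experiment[act$chrom == pl$chrom[i] & act$pos == pl$pos[i]]
    ns <- as.integer(corr_r[paste(sk, samples)] + corr_a[paste(sk, samples)])
    fs <- ifelse(samples %in% actv, f_asb, 0.5)
    tested <- ns >= config$min_site_coverage
    pow <- ifelse(tested,
                  mapply(binomial_test_power, ns, fs,
                         MoreArgs = list(alpha = config$asb_alpha)), 0)
    p_asb <- 1 - prod(1 - pow)
    cons <- mapply(function(n, f)
      1 - binomial_test_power(n, f, config$het_balance_alpha), ns, fs)
    p_qc <- 1 - poisson_binomial_le1(cons)
    genes_i <- unique(c(pl$host_gene[i],
                        dl$gene_id[dl$chrom == pl$chrom[i] &
                                     dl$pos == pl$pos[i]]))
    p_gene <- vapply(genes_i, function(g) {
      gg <- genes[[g]]
      if (is.null(gg)) return(0)
      in_cds <- rna$chrom == gg$chrom &
        vapply(rna$pos - 1L, function(p0) in_iv(p0, gg$cds), logical(1))
      mk <- rna[in_cds, , drop = FALSE]
      if (g == pl$host_gene[i]) {
        mk <- rbind(mk, rna[rna_key == sk, , drop = FALSE])
      }
      tots <- mk$ref_count + mk$alt_count
      tots <- tots[tots >= config$min_rna_reads]
      if (!length(tots)) return(0)
      1 - prod(1 - vapply(tots, ase_flag_power, numeric(1), f = f_ase,
                          alpha = config$ase_alpha,
                          thr = config$ase_ratio_threshold))
    }, numeric(1))
    p_ase <- 1 - prod(1 - p_gene)
    pred[ii] <- p_qc * p_asb * p_ase
  }
  list(
    per_site = data.frame(chrom = pl$chrom[true_rows],
                          pos = pl$pos[true_rows],
                          predicted = pred, stringsAsFactors = FALSE),
    predicted_power = mean(pred)
  )
}
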