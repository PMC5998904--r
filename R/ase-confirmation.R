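# Allele-specific expression confirmation: exonic heterozygous marker SNPs
# measure the allelic expression of targeted genes; asymmetric SNPs whose
# targets show significant allele-specific expression are promoted to rSNPs.

#' Select heterozygous expression marker SNPs for targeted genes
#'
#' Markers are heterozygous sites with RNA-seq allele counts that fall in
#' the coding (CDS) regions of targeted genes and are crossed by at least
#' `min_rna_reads` RNA reads (pooled over RNA samples).  Asymmetric SNPs
#' that themselves lie in a target gene's promoter or UTR and have RNA
#' coverage serve directly as their own markers.
#'
#' @param targets Target assignments from [combine_targets()].
#' @param rna_counts RNA allele counts from [read_rna_counts()].
#' @param genes A `"gene_models"` object.
#' @param config A [run_config()] object.
#' @return Data frame: `chrom`, `pos`, `gene_id`, `rna_ref_count`,
#'   `rna_alt_count`, `marker_type` (`"cds_marker"` or `"own_snp"`).
#' @export
select_markers <- function(targets, rna_counts, genes,
                           config = run_config()) {
  stopifnot_cols(targets, c("chrom", "pos", "gene_id", "relation"),
                 "target table")
  stopifnot_cols(rna_counts, c("chrom", "pos", "ref_count", "alt_count"),
                 "RNA allele-count table")
  empty <- data.frame(chrom = character(), pos = integer(),
                      gene_id = character(), rna_ref_count = integer(),
                      rna_alt_count = integer(), marker_type = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(targets) || !nrow(rna_counts)) return(empty)

  agg <- stats::aggregate(
    cbind(ref_count, alt_count) ~ chrom + pos, data = rna_counts, FUN = sum)
  agg <- agg[agg$ref_count + agg$alt_count >= config$min_rna_reads, ,
             drop = FALSE]
  if (!nrow(agg)) return(empty)
  target_genes <- unique(targets$gene_id)

  out <- list()
  # coding-region markers inside targeted genes
  for (i in seq_len(nrow(agg))) {
    pos0 <- agg$pos[i] - 1L
    for (gid in target_genes) {
      g <- genes[[gid]]
      if (is.null(g) || g$chrom != agg$chrom[i]) next
      if (in_iv(pos0, g$cds)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = agg$chrom[i], pos = agg$pos[i], gene_id = gid,
          rna_ref_count = agg$ref_count[i], rna_alt_count = agg$alt_count[i],
          marker_type = "cds_marker", stringsAsFactors = FALSE)
      }
    }
  }
  # asymmetric SNPs in promoters/UTRs acting as their own markers
  own <- targets[targets$relation %in% c("promoter", "utr5", "utr3"), ,
                 drop = FALSE]
  if (nrow(own)) {
    m <- match(paste(own$chrom, own$pos), paste(agg$chrom, agg$pos))
    hit <- which(!is.na(m))
    for (i in hit) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = own$chrom[i], pos = own$pos[i], gene_id = own$gene_id[i],
        rna_ref_count = agg$ref_count[m[i]],
        rna_alt_count = agg$alt_count[m[i]],
        marker_type = "own_snp", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- unique(do.call(rbind, out))
  res <- res[order(res$chrom, res$pos, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Test markers for allele-specific expression
#'
#' The allelic expression ratio is `rna_ref_count / rna_alt_count`
#' (infinite when the alternative allele is unseen).  The default test is
#' the exact two-sided binomial test of the reference-allele read fraction
#' against 0.5; alternatively (`ase_test = "fisher"`) Fisher's exact test
#' compares the RNA counts against the site's pooled DNA allele counts.
#' P-values are Benjamini-Hochberg adjusted across all markers of the run.
#' A marker is flagged when its ratio strictly exceeds
#' `ase_ratio_threshold` (or is strictly below its reciprocal) and its
#' p-value (raw by default, adjusted if `ase_use_adjusted_p`) is at most
#' `ase_alpha`.
#'
#' @param markers Marker table from [select_markers()].
#' @param config A [run_config()] object.
#' @param dna_counts Optional pooled DNA allele counts (`chrom`, `pos`,
#'   `pooled_ref_count`, `pooled_alt_count`), required for the Fisher
#'   variant; [call_het_snps()] output qualifies.
#' @return The marker table extended with `allele_ratio`, `raw_p`,
#'   `adjusted_p`, `flagged`.
#' @export
ase_test <- function(markers, config = run_config(), dna_counts = NULL) {
  stopifnot_cols(markers, c("chrom", "pos", "gene_id", "rna_ref_count",
                            "rna_alt_count"), "marker table")
  res <- markers
  if (!nrow(res)) {
    res$allele_ratio <- numeric(0); res$raw_p <- numeric(0)
    res$adjusted_p <- numeric(0); res$flagged <- logical(0)
    return(res)
  }
  tot <- res$rna_ref_count + res$rna_alt_count
  if (any(tot < 1)) stop("marker without RNA reads", call. = FALSE)
  res$allele_ratio <- ifelse(res$rna_alt_count == 0, Inf,
                             res$rna_ref_count / res$rna_alt_count)
  if (config$ase_test == "binomial") {
    res$raw_p <- binomial_two_sided(res$rna_ref_count, tot)
  } else {
    if (is.null(dna_counts)) {
      stop("Fisher ASE test requires pooled DNA counts", call. = FALSE)
    }
    stopifnot_cols(dna_counts, c("chrom", "pos", "pooled_ref_count",
                                 "pooled_alt_count"), "DNA count table")
    m <- match(paste(res$chrom, res$pos),
               paste(dna_counts$chrom, dna_counts$pos))
    if (anyNA(m)) {
      stop("no DNA counts for marker(s): ",
           paste(utils::head(paste0(res$chrom, ":", res$pos)[is.na(m)], 5),
                 collapse = ", "), call. = FALSE)
    }
    res$raw_p <- vapply(seq_len(nrow(res)), function(i) {
      tab <- matrix(c(res$rna_ref_count[i], res$rna_alt_count[i],
                      dna_counts$pooled_ref_count[m[i]],
                      dna_counts$pooled_alt_count[m[i]]), nrow = 2)
      stats::fisher.test(tab)$p.value
    }, numeric(1))
  }
  res$adjusted_p <- benjamini_hochberg(res$raw_p)
  thr <- config$ase_ratio_threshold
  ratio_ok <- res$allele_ratio > thr | res$allele_ratio < 1 / thr
  gate_p <- if (config$ase_use_adjusted_p) res$adjusted_p else res$raw_p
  res$flagged <- ratio_ok & gate_p <= config$ase_alpha
  res
}

#' Promote asymmetric SNPs with confirmed targets to rSNPs
#'
#' An asymmetric SNP becomes a regulatory SNP (rSNP) when at least one of
#' its targeted genes carries at least one flagged allele-specific
#' expression marker.  rSNPs are displayed by dbSNP identifier when
#' annotated and as `chrN:pos` otherwise.
#'
#' @param asnps Asymmetric SNP table (`chrom`, `pos`, optional `id`).
#' @param targets Target assignments from [combine_targets()].
#' @param ase_results Output of [ase_test()].
#' @return Data frame with one row per (rSNP, confirmed target gene):
#'   `chrom`, `pos`, `display_id`, `gene_id`; the unique rSNP table is
#'   attached as attribute `"rsnps"`.
#' @export
promote_to_rsnp <- function(asnps, targets, ase_results) {
  stopifnot_cols(asnps, c("chrom", "pos"), "asymmetric SNP table")
  empty <- data.frame(chrom = character(), pos = integer(),
                      display_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  flagged_genes <- unique(ase_results$gene_id[ase_results$flagged])
  if (!nrow(asnps) || !length(flagged_genes)) {
    attr(empty, "rsnps") <- unique(empty[, c("chrom", "pos", "display_id")])
    return(empty)
  }
  conf <- targets[targets$gene_id %in% flagged_genes, , drop = FALSE]
  akey <- paste(asnps$chrom, asnps$pos)
  conf <- conf[paste(conf$chrom, conf$pos) %in% akey, , drop = FALSE]
  if (!nrow(conf)) {
    attr(empty, "rsnps") <- unique(empty[, c("chrom", "pos", "display_id")])
    return(empty)
  }
  m <- match(paste(conf$chrom, conf$pos), akey)
  id <- if (is.null(asnps$id)) rep(NA_character_, nrow(asnps)) else asnps$id
  res <- data.frame(
    chrom = conf$chrom, pos = conf$pos,
    display_id = ifelse(is.na(id[m]) | id[m] == "",
                        paste0(conf$chrom, ":", conf$pos), id[m]),
    gene_id = conf$gene_id, stringsAsFactors = FALSE
  )
  res <- unique(res[order(res$chrom, res$pos, res$gene_id), , drop = FALSE])
  rownames(res) <- NULL
  attr(res, "rsnps") <- unique(res[, c("chrom", "pos", "display_id")])
  res
}
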