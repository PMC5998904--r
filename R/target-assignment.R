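# Target-gene assignment for asymmetric SNPs: proximal targets by
# promoter/intron/UTR membership, distal targets by ChIA-PET contacts
# between SNP windows and gene promoters tested against a random-ligation
# background scaled by the effective genome size.

#' Assign proximal target genes to asymmetric SNPs
#'
#' A SNP lying in the promoter, an intron, or a 5'/3' UTR of a gene is
#' assigned that gene as a proximal target; CDS-exonic positions yield no
#' proximal target (they remain usable as expression markers).
#'
#' @param asnps Data frame of asymmetric SNPs (`chrom`, `pos`).
#' @param genes A `"gene_models"` object.
#' @param config A [run_config()] object.
#' @return Data frame: `chrom`, `pos`, `gene_id`, `relation`.
#' @export
assign_nearby_targets <- function(asnps, genes, config = run_config()) {
  stopifnot_cols(asnps, c("chrom", "pos"), "asymmetric SNP table")
  out <- vector("list", nrow(asnps))
  for (i in seq_len(nrow(asnps))) {
    hits <- classify_position(asnps$chrom[i], asnps$pos[i], genes,
                              flank_bp = config$promoter_flank_bp,
                              union_promoters = config$promoter_union)
    if (nrow(hits)) {
      hits$chrom <- asnps$chrom[i]
      hits$pos <- asnps$pos[i]
      out[[i]] <- hits[, c("chrom", "pos", "gene_id", "relation")]
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer(),
                      gene_id = character(), relation = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Effective genome size from RNA Pol II peak sets
#'
#' The random-ligation background model for ChIA-PET contacts is scaled by
#' the effective genome size: the mean, over Pol II ChIP-seq datasets, of
#' the total merged peak length.
#'
#' @param polII_peaks A single interval data frame (`chrom`, `start`,
#'   `end`) or a list of them (one per dataset).
#' @return Effective genome size in bp.
#' @examples
#' effective_genome_size(list(
#'   data.frame(chrom = "chr1", start = c(0, 50), end = c(100, 200)),
#'   data.frame(chrom = "chr1", start = 0, end = 100)))  # (200 + 100) / 2
#' @export
effective_genome_size <- function(polII_peaks) {
  if (is.data.frame(polII_peaks)) polII_peaks <- list(polII_peaks)
  if (!length(polII_peaks)) {
    stop("effective_genome_size: no peak sets supplied", call. = FALSE)
  }
  merged_len <- vapply(polII_peaks, function(pk) {
    stopifnot_cols(pk, c("chrom", "start", "end"), "peak table")
    if (!nrow(pk)) return(0)
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end)))
    sum(as.numeric(GenomicRanges::width(gr)))
  }, numeric(1))
  mean(merged_len)
}

#' Filter ChIA-PET contacts
#'
#' Retains contacts with at least `chiapet_min_pairs` total paired tags,
#' at least `chiapet_min_per_direction` tags in each read orientation,
#' both anchors on the same chromosome, and non-intersecting anchors.
#'
#' @param contacts Contact table from [read_contacts()].
#' @param config A [run_config()] object.
#' @return The retained contacts; removed records (with `reason`) attached
#'   as attribute `"removed"`.
#' @export
filter_contacts <- function(contacts, config = run_config()) {
  stopifnot_cols(contacts, contact_cols, "contact table")
  reason <- rep(NA_character_, nrow(contacts))
  mark <- function(cond, why) reason[is.na(reason) & cond] <<- why
  mark(contacts$total_pairs < config$chiapet_min_pairs, "few_pairs")
  mark(pmin(contacts$pairs_forward, contacts$pairs_reverse) <
         config$chiapet_min_per_direction, "direction_support")
  mark(contacts$chrom1 != contacts$chrom2, "interchromosomal")
  mark(contacts$chrom1 == contacts$chrom2 &
         contacts$start1 < contacts$end2 & contacts$start2 < contacts$end1,
       "intersecting_anchors")
  kept <- contacts[is.na(reason), , drop = FALSE]
  removed <- contacts[!is.na(reason), , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!is.na(reason)]
  attr(kept, "removed") <- removed
  kept
}

#' Chi-squared reliability p-value for a contact-matrix cell
#'
#' Pearson goodness-of-fit of the observed paired-tag count against the
#' random-ligation expectation: `X^2 = (O - E)^2 / E` referred to the upper
#' tail of the chi-squared distribution with one degree of freedom.
#' Reliability additionally requires enrichment (`O > E`); this function
#' returns the p-value only.
#'
#' @param O Observed count(s).
#' @param E Expected count(s) under the random-ligation model, `> 0`.
#' @return Upper-tail p-value(s).
#' @export
contact_significance <- function(O, E) {
  if (any(E <= 0)) stop("expected count must be positive", call. = FALSE)
  x2 <- (O - E)^2 / E
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Assign distal target genes via ChIA-PET contacts
#'
#' Builds the contact matrix whose rows are +/- `snp_window_bp` windows
#' around asymmetric SNPs and whose columns are gene promoter regions,
#' accumulates filtered intrachromosomal paired-tag counts into its cells,
#' and calls a cell reliable when the Pearson chi-squared test against the
#' random-ligation expectation `E = 2 T len_row len_col / G_eff^2` rejects
#' at `contact_alpha` with enrichment (`O > E`).  Cells whose SNP window
#' intersects the gene's promoter are excluded (such genes are proximal,
#' not distal, candidates), as are interchromosomal pairings.
#'
#' @param asnps Asymmetric SNP table (`chrom`, `pos`).
#' @param genes A `"gene_models"` object.
#' @param contacts Filtered contacts from [filter_contacts()].
#' @param g_eff Effective genome size in bp (see
#'   [effective_genome_size()]).
#' @param config A [run_config()] object.
#' @return Data frame: `chrom`, `pos`, `gene_id`, `relation`
#'   (`"distal_chiapet"`), `contact_O`, `contact_E`, `contact_p`.
#' @export
assign_distal_targets <- function(asnps, genes, contacts, g_eff,
                                  config = run_config()) {
  stopifnot_cols(asnps, c("chrom", "pos"), "asymmetric SNP table")
  if (is.null(g_eff) || is.na(g_eff) || g_eff <= 0) {
    stop("effective genome size must be positive", call. = FALSE)
  }
  empty <- data.frame(chrom = character(), pos = integer(),
                      gene_id = character(), relation = character(),
                      contact_O = numeric(), contact_E = numeric(),
                      contact_p = numeric(), stringsAsFactors = FALSE)
  if (!nrow(asnps) || !nrow(contacts)) return(empty)

  w <- config$snp_window_bp
  windows <- data.frame(
    chrom = asnps$chrom, pos = asnps$pos,
    start = pmax(0L, asnps$pos - 1L - w), end = asnps$pos - 1L + w + 1L,
    stringsAsFactors = FALSE
  )
  proms <- do.call(rbind, lapply(genes, function(g) {
    span <- promoter_region(g, config$promoter_flank_bp)
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = span[["start"]] - 1L, end = span[["end"]],
               stringsAsFactors = FALSE)
  }))

  ovl <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  T_pairs <- sum(contacts$total_pairs)
  cells <- new.env(parent = emptyenv())
  add_cell <- function(wi, pj, pairs) {
    key <- paste(wi, pj)
    prev <- cells[[key]] %||% 0
    cells[[key]] <- prev + pairs
  }
  for (k in seq_len(nrow(contacts))) {
    ct <- contacts[k, ]
    wi_a <- which(windows$chrom == ct$chrom1 &
                    ovl(windows$start, windows$end, ct$start1, ct$end1))
    pj_a <- which(proms$chrom == ct$chrom2 &
                    ovl(proms$start, proms$end, ct$start2, ct$end2))
    wi_b <- which(windows$chrom == ct$chrom2 &
                    ovl(windows$start, windows$end, ct$start2, ct$end2))
    pj_b <- which(proms$chrom == ct$chrom1 &
                    ovl(proms$start, proms$end, ct$start1, ct$end1))
    for (wi in wi_a) for (pj in pj_a) add_cell(wi, pj, ct$total_pairs)
    for (wi in wi_b) for (pj in pj_b) add_cell(wi, pj, ct$total_pairs)
  }
  keys <- ls(cells)
  if (!length(keys)) return(empty)
  km <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  wi <- as.integer(km[, 1]); pj <- as.integer(km[, 2])
  O <- vapply(keys, function(k) cells[[k]], numeric(1))

  same_chrom <- windows$chrom[wi] == proms$chrom[pj]
  intersects <- ovl(windows$start[wi], windows$end[wi],
                    proms$start[pj], proms$end[pj])
  keep <- same_chrom & !intersects
  wi <- wi[keep]; pj <- pj[keep]; O <- O[keep]
  if (!length(wi)) return(empty)

  len_w <- windows$end[wi] - windows$start[wi]
  len_p <- proms$end[pj] - proms$start[pj]
  E <- 2 * T_pairs * (len_w / g_eff) * (len_p / g_eff)
  p <- contact_significance(O, E)
  gate_p <- if (config$contact_use_adjusted_p) benjamini_hochberg(p) else p
  reliable <- gate_p < config$contact_alpha & O > E
  res <- data.frame(
    chrom = windows$chrom[wi], pos = windows$pos[wi],
    gene_id = proms$gene_id[pj], relation = "distal_chiapet",
    contact_O = O, contact_E = E, contact_p = p,
    stringsAsFactors = FALSE
  )[reliable, , drop = FALSE]
  res <- res[order(res$chrom, res$pos, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Combine proximal and distal target assignments
#'
#' Union of the two assignment routes, deduplicated by (SNP, gene) with the
#' proximal relation preferred when both routes support the same pair.
#'
#' @param nearby Output of [assign_nearby_targets()].
#' @param distal Output of [assign_distal_targets()].
#' @return Data frame: `chrom`, `pos`, `gene_id`, `relation`, `contact_O`,
#'   `contact_E`, `contact_p` (contact columns `NA` for proximal rows).
#' @export
combine_targets <- function(nearby, distal) {
  nearby$contact_O <- rep(NA_real_, nrow(nearby))
  nearby$contact_E <- rep(NA_real_, nrow(nearby))
  nearby$contact_p <- rep(NA_real_, nrow(nearby))
  all_t <- rbind(
    nearby[, c("chrom", "pos", "gene_id", "relation",
               "contact_O", "contact_E", "contact_p"), drop = FALSE],
    distal[, c("chrom", "pos", "gene_id", "relation",
               "contact_O", "contact_E", "contact_p"), drop = FALSE]
  )
  if (!nrow(all_t)) return(all_t)
  # proximal first, then drop duplicate (snp, gene) pairs
  pref <- order(all_t$relation == "distal_chiapet")
  all_t <- all_t[pref, , drop = FALSE]
  dup <- duplicated(all_t[, c("chrom", "pos", "gene_id")])
  all_t <- all_t[!dup, , drop = FALSE]
  all_t <- all_t[order(all_t$chrom, all_t$pos, all_t$gene_id), , drop = FALSE]
  rownames(all_t) <- NULL
  all_t
}
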