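# Linkage of confirmed rSNPs to GWAS index SNPs for cognitive-disorder
# traits: trait-signature filtering of the catalog, +/- 10 kb window
# matching, and minor-allele-frequency similarity.

#' Filter a GWAS-catalog extract by trait signatures
#'
#' Retains catalog entries whose trait string contains any of the query
#' signatures, case-insensitively.
#'
#' @param catalog Data frame from [read_gwas_catalog()].
#' @param signatures Character vector of query strings (default: the twelve
#'   cognitive-disorder signatures, [default_trait_signatures()]).
#' @return The retained catalog rows.
#' @export
filter_traits <- function(catalog, signatures = default_trait_signatures()) {
  stopifnot_cols(catalog, "trait", "GWAS catalog extract")
  if (!length(signatures)) stop("signatures must be non-empty", call. = FALSE)
  lt <- tolower(catalog$trait)
  keep <- Reduce(`|`, lapply(signatures, function(s) {
    grepl(tolower(s), lt, fixed = TRUE)
  }))
  catalog[keep, , drop = FALSE]
}

#' Window match between an rSNP and a GWAS index SNP
#'
#' `TRUE` iff the two positions share a chromosome and lie within
#' `window_bp` of each other (inclusive; the locus spans `-window_bp` to
#' `+window_bp` around the index).
#'
#' @param rsnp_chrom,rsnp_pos rSNP coordinates (1-based).
#' @param index_chrom,index_pos Index SNP coordinates (1-based).
#' @param window_bp Window half-width (default 10000).
#' @return Logical vector.
#' @export
window_match <- function(rsnp_chrom, rsnp_pos, index_chrom, index_pos,
                         window_bp = 10000L) {
  rsnp_chrom == index_chrom & abs(rsnp_pos - index_pos) <= window_bp
}

#' Minor-allele-frequency linkage criterion
#'
#' Two SNPs are considered closely linked when their minor-allele
#' frequencies differ by at most `max_diff` in absolute frequency units
#' (0.15 meaning 15 percentage points).
#'
#' @param maf_a,maf_b Minor-allele frequencies in `(0, 0.5]`.
#' @param max_diff Maximum absolute difference (default 0.15).
#' @return Logical vector.
#' @export
maf_linked <- function(maf_a, maf_b, max_diff = 0.15) {
  if (any(maf_a <= 0 | maf_a > 0.5 | maf_b <= 0 | maf_b > 0.5,
          na.rm = TRUE)) {
    stop("MAF values must lie in (0, 0.5]", call. = FALSE)
  }
  abs(maf_a - maf_b) <= max_diff
}

#' Build the linked-rSNP report
#'
#' One report row per (rSNP, targeted gene, matched GWAS index, trait)
#' combination where the rSNP lies within the index window and the two MAFs
#' are linked.  Rows are sorted by (display id, gene, index).
#'
#' @param rsnp_targets Data frame from [promote_to_rsnp()] (`chrom`, `pos`,
#'   `display_id`, `gene_id`).
#' @param indexes Trait-filtered GWAS index table (`rsid`, `chrom`, `pos`,
#'   `trait`, `maf`).
#' @param mafs MAF lookup for candidate rSNPs (`chrom`, `pos`, `maf`), as
#'   from [read_maf_table()].
#' @param config A [run_config()] object.
#' @return Data frame: `rsnp_id`, `gene_id`, `index_rsid`, `trait`,
#'   `chrom`, `rsnp_pos`, `index_pos`, `distance_bp`, `maf_rsnp`,
#'   `maf_index`.
#' @export
build_report <- function(rsnp_targets, indexes, mafs,
                         config = run_config()) {
  empty <- data.frame(
    rsnp_id = character(), gene_id = character(), index_rsid = character(),
    trait = character(), chrom = character(), rsnp_pos = integer(),
    index_pos = integer(), distance_bp = integer(), maf_rsnp = numeric(),
    maf_index = numeric(), stringsAsFactors = FALSE
  )
  if (!nrow(rsnp_targets) || !nrow(indexes)) return(empty)
  stopifnot_cols(rsnp_targets, c("chrom", "pos", "display_id", "gene_id"),
                 "rSNP target table")
  stopifnot_cols(indexes, c("rsid", "chrom", "pos", "trait", "maf"),
                 "GWAS index table")
  stopifnot_cols(mafs, c("chrom", "pos", "maf"), "MAF table")

  m <- match(paste(rsnp_targets$chrom, rsnp_targets$pos),
             paste(mafs$chrom, mafs$pos))
  maf_rsnp <- mafs$maf[m]

  rows <- list()
  for (i in seq_len(nrow(rsnp_targets))) {
    if (is.na(maf_rsnp[i])) next   # unannotated MAF: cannot assess linkage
    sel <- which(window_match(rsnp_targets$chrom[i], rsnp_targets$pos[i],
                              indexes$chrom, indexes$pos,
                              config$gwas_window_bp) &
                   maf_linked(maf_rsnp[i], indexes$maf,
                              config$maf_max_diff))
    for (j in sel) {
      rows[[length(rows) + 1L]] <- data.frame(
        rsnp_id = rsnp_targets$display_id[i],
        gene_id = rsnp_targets$gene_id[i],
        index_rsid = indexes$rsid[j],
        trait = indexes$trait[j],
        chrom = rsnp_targets$chrom[i],
        rsnp_pos = rsnp_targets$pos[i],
        index_pos = indexes$pos[j],
        distance_bp = abs(rsnp_targets$pos[i] - indexes$pos[j]),
        maf_rsnp = maf_rsnp[i],
        maf_index = indexes$maf[j],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(empty)
  rep <- unique(do.call(rbind, rows))
  rep <- rep[order(rep$rsnp_id, rep$gene_id, rep$index_rsid, rep$trait), ,
             drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' Summarise a linked-rSNP report
#'
#' @param report A report data frame carrying rSNP and gene identifier
#'   columns (`rsnp_id`/`display_id` and `gene_id`).
#' @return List with `n_rows`, `unique_rsnps`, `unique_genes`.
#' @export
report_summary <- function(report) {
  idcol <- intersect(c("rsnp_id", "display_id"), names(report))[1]
  if (is.na(idcol) || !"gene_id" %in% names(report)) {
    stop("report must carry rSNP and gene identifier columns", call. = FALSE)
  }
  list(
    n_rows = nrow(report),
    unique_rsnps = length(unique(report[[idcol]])),
    unique_genes = length(unique(report$gene_id))
  )
}
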