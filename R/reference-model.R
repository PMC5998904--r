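# Gene-model geometry: promoter windows, intron/UTR membership, OTFR
# membership, and construction of the alternative reference genome used to
# control reference mapping bias.

#' Build gene models from a GTF/GFF annotation
#'
#' Reads an annotation via \pkg{rtracklayer} and assembles one model per
#' gene.  Exactly one canonical transcript per gene is used (the one with
#' the greatest total exon length; ties broken by transcript id); TSSs of
#' all transcripts are retained so promoter windows can optionally be taken
#' as the union over transcripts.
#'
#' Feature types used: `exon`, `CDS`, `five_prime_utr`/`5UTR`,
#' `three_prime_utr`/`3UTR`.  Introns are derived as the gaps between
#' consecutive exons of the canonical transcript.
#'
#' @param path Path to a GTF or GFF3 file.
#' @return An object of class `"gene_models"`: a named list of gene records,
#'   each with `gene_id`, `chrom`, `strand`, `tss` (1-based), `tss_all`,
#'   and interval data frames (`exons`, `cds`, `utr5`, `utr3`, `introns`;
#'   0-based half-open, sorted, non-overlapping).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  gene_id <- as.character(mc$gene_id)
  tx_id <- as.character(mc$transcript_id %||% gene_id)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type, gene_id = gene_id, tx_id = tx_id,
    stringsAsFactors = FALSE
  )
  df$type[df$type %in% c("five_prime_utr", "5UTR", "five_prime_UTR")] <- "utr5"
  df$type[df$type %in% c("three_prime_utr", "3UTR", "three_prime_UTR")] <- "utr3"
  df <- df[df$type %in% c("exon", "CDS", "utr5", "utr3"), , drop = FALSE]
  if (!nrow(df)) stop("annotation '", path, "' contains no exon features",
                      call. = FALSE)
  models <- lapply(split(df, df$gene_id), build_gene_model)
  structure(models[order(names(models))], class = "gene_models")
}

build_gene_model <- function(g) {
  exons_by_tx <- split(g[g$type == "exon", , drop = FALSE], g$tx_id[g$type == "exon"])
  exon_len <- vapply(exons_by_tx, function(e) sum(e$end - e$start), numeric(1))
  canon <- names(sort(exon_len, decreasing = TRUE))[1]
  strand <- g$strand[1]
  tss_of <- function(e) {
    if (strand == "-") max(e$end) else min(e$start) + 1L   # 1-based
  }
  iv <- function(d) {
    d <- d[order(d$start), c("start", "end"), drop = FALSE]
    rownames(d) <- NULL
    d
  }
  exons <- iv(exons_by_tx[[canon]])
  introns <- if (nrow(exons) > 1L) {
    data.frame(start = exons$end[-nrow(exons)], end = exons$start[-1])
  } else {
    data.frame(start = integer(), end = integer())
  }
  introns <- introns[introns$end > introns$start, , drop = FALSE]
  sub <- function(tp) iv(g[g$type == tp & g$tx_id == canon, , drop = FALSE])
  list(
    gene_id = g$gene_id[1],
    chrom = g$chrom[1],
    strand = strand,
    tss = tss_of(exons_by_tx[[canon]]),
    tss_all = sort(unique(vapply(exons_by_tx, tss_of, numeric(1)))),
    exons = exons,
    cds = sub("CDS"),
    utr5 = sub("utr5"),
    utr3 = sub("utr3"),
    introns = introns
  )
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x), "genes on",
      length(unique(vapply(x, `[[`, character(1), "chrom"))),
      "chromosome(s)\n")
  invisible(x)
}

#' Promoter window around a gene's TSS
#'
#' The promoter spans `flank_bp` bases upstream through `flank_bp` bases
#' downstream of the TSS, inclusive at both ends in 1-based coordinates and
#' clamped at the chromosome boundary.  Because the window is symmetric the
#' strand does not change the span.
#'
#' @param gene A gene record from [read_gene_models()].
#' @param flank_bp Positive half-width in bp (default 1800).
#' @param chrom_length Optional chromosome length for right clamping.
#' @return Numeric vector `c(start, end)` of the 1-based inclusive span.
#' @examples
#' g <- list(gene_id = "G", chrom = "chr1", strand = "+", tss = 5000)
#' promoter_region(g, 1800)  # 3200 6800
#' @export
promoter_region <- function(gene, flank_bp = 1800L, chrom_length = NULL) {
  if (length(flank_bp) != 1L || is.na(flank_bp) || flank_bp <= 0) {
    stop("flank_bp must be a single positive integer", call. = FALSE)
  }
  tss <- gene$tss
  if (tss < 1 || (!is.null(chrom_length) && tss > chrom_length)) {
    stop("TSS of gene '", gene$gene_id, "' lies outside its chromosome",
         call. = FALSE)
  }
  lo <- max(1, tss - flank_bp)
  hi <- tss + flank_bp
  if (!is.null(chrom_length)) hi <- min(hi, chrom_length)
  c(start = lo, end = hi)
}

in_iv <- function(pos0, iv) {
  nrow(iv) > 0L && any(iv$start <= pos0 & pos0 < iv$end)
}

#' Classify a genomic position against gene models
#'
#' Returns every (gene, relation) pair whose region contains the position:
#' `promoter` (within `flank_bp` of the TSS), `intron`, `utr5` or `utr3`.
#' A position may hit several genes and several relations; positions lying
#' only in CDS exons (or intergenic) yield no rows.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param genes A `"gene_models"` object.
#' @param flank_bp Promoter half-width (default 1800).
#' @param union_promoters If `TRUE`, promoter windows are taken around every
#'   annotated transcript TSS instead of the canonical one only.
#' @return Data frame with columns `gene_id`, `relation`.
#' @export
classify_position <- function(chrom, pos, genes, flank_bp = 1800L,
                              union_promoters = FALSE) {
  known <- unique(vapply(genes, `[[`, character(1), "chrom"))
  if (!chrom %in% known) {
    warning("classify_position: unknown chromosome '", chrom, "'")
    return(data.frame(gene_id = character(), relation = character(),
                      stringsAsFactors = FALSE))
  }
  pos0 <- pos - 1L
  out <- list()
  for (g in genes) {
    if (g$chrom != chrom) next
    tss <- if (union_promoters) g$tss_all else g$tss
    if (any(abs(pos - tss) <= flank_bp)) {
      out[[length(out) + 1L]] <- c(g$gene_id, "promoter")
    }
    if (in_iv(pos0, g$introns)) out[[length(out) + 1L]] <- c(g$gene_id, "intron")
    if (in_iv(pos0, g$utr5)) out[[length(out) + 1L]] <- c(g$gene_id, "utr5")
    if (in_iv(pos0, g$utr3)) out[[length(out) + 1L]] <- c(g$gene_id, "utr3")
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), relation = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  data.frame(gene_id = m[, 1], relation = m[, 2], stringsAsFactors = FALSE)
}

#' Test whether positions fall inside an OTFR
#'
#' Overlapping transcription-factor binding regions (OTFRs) are the
#' regulatory regions the pipeline restricts itself to.  A 1-based position
#' `pos` is inside a 0-based half-open interval `[start, end)` iff
#' `start <= pos - 1 < end`.
#'
#' @param chrom Chromosome name(s), recycled against `pos`.
#' @param pos 1-based position(s).
#' @param otfrs Interval data frame (`chrom`, `start`, `end`), as from
#'   [read_intervals()].
#' @return Logical vector.
#' @export
in_otfr <- function(chrom, pos, otfrs) {
  stopifnot_cols(otfrs, c("chrom", "start", "end"), "OTFR table")
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  out <- logical(n)
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    iv <- otfrs[otfrs$chrom == cc, , drop = FALSE]
    if (!nrow(iv)) next
    p0 <- pos[sel] - 1L
    out[sel] <- vapply(p0, function(x) any(iv$start <= x & x < iv$end),
                       logical(1))
  }
  out
}

#' Construct an alternative reference genome
#'
#' Replaces the reference base at each heterozygous SNP position with the
#' alternate allele, producing the alternative genome that reads are
#' realigned to for reference mapping-bias control.  Applying the operation
#' a second time with ref/alt swapped restores the original sequence.
#'
#' @param ref A [Biostrings::DNAStringSet] (or named character vector) of
#'   chromosome sequences.
#' @param snps Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; every `ref` must match the base at `pos`.
#' @return A `DNAStringSet` of identical lengths differing from the input
#'   exactly at the SNP positions.
#' @export
make_alternative_reference <- function(ref, snps) {
  if (!methods::is(ref, "DNAStringSet")) {
    ref <- Biostrings::DNAStringSet(ref)
  }
  stopifnot_cols(snps, c("chrom", "pos", "ref", "alt"), "SNP table")
  bad_chrom <- setdiff(unique(snps$chrom), names(ref))
  if (length(bad_chrom)) {
    stop("SNPs on chromosome(s) absent from the reference: ",
         paste(bad_chrom, collapse = ", "), call. = FALSE)
  }
  out <- ref
  mism <- character()
  for (cc in unique(snps$chrom)) {
    s <- snps[snps$chrom == cc, , drop = FALSE]
    bases <- as.character(Biostrings::extractAt(
      ref[[cc]], IRanges::IRanges(s$pos, s$pos)))
    off <- bases != s$ref
    if (any(off)) {
      mism <- c(mism, paste0(cc, ":", s$pos[off], " (expected ", s$ref[off],
                             ", found ", bases[off], ")"))
      next
    }
    out[[cc]] <- Biostrings::replaceLetterAt(
      ref[[cc]], s$pos, s$alt)
  }
  if (length(mism)) {
    stop("reference allele mismatch at site(s): ",
         paste(mism, collapse = "; "), call. = FALSE)
  }
  out
}
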