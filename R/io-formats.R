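# Readers and writers for the external formats consumed and produced by the
# pipeline.  Conventions: point variants are 1-based (VCF-style); intervals
# are 0-based half-open (BED-style).  A 1-based position pos lies in interval
# [start, end) iff start <= pos - 1 < end.

#' Read biallelic SNVs from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and retains biallelic SNV records.
#' Indel and multiallelic records are not discarded: their reference spans
#' are emitted on a side channel so that SNVs falling near them can later be
#' removed by the indel-proximity filter.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A list with elements `snvs` (data frame: `chrom`, `pos` (1-based),
#'   `id`, `ref`, `alt`) and `other_regions` (data frame: `chrom`, `start`,
#'   `end`, 0-based half-open spans of non-SNV records).
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  head_lines <- readLines(con, n = 10000L)
  if (!any(startsWith(head_lines, "#CHROM\t"))) {
    stop("malformed VCF '", path, "': no #CHROM header line found",
         call. = FALSE)
  }
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      stop("malformed VCF '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(list(
      snvs = data.frame(chrom = character(), pos = integer(),
                        id = character(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE),
      other_regions = data.frame(chrom = character(), start = integer(),
                                 end = integer(), stringsAsFactors = FALSE)
    ))
  }
  bad <- is.na(fix$REF) | is.na(fix$ALT) | fix$REF == "" | fix$ALT == ""
  if (any(bad)) {
    message("read_variants: rejected ", sum(bad),
            " record(s) with missing REF/ALT in ", path)
    fix <- fix[!bad, , drop = FALSE]
  }
  pos <- as.integer(fix$POS)
  is_snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  snvs <- data.frame(
    chrom = fix$CHROM[is_snv],
    pos = pos[is_snv],
    id = ifelse(is.na(fix$ID[is_snv]) | fix$ID[is_snv] == ".",
                NA_character_, fix$ID[is_snv]),
    ref = fix$REF[is_snv],
    alt = fix$ALT[is_snv],
    stringsAsFactors = FALSE
  )
  oth <- fix[!is_snv, , drop = FALSE]
  other_regions <- data.frame(
    chrom = oth$CHROM,
    start = as.integer(oth$POS) - 1L,
    end = as.integer(oth$POS) - 1L +
      pmax(nchar(oth$REF), vapply(strsplit(oth$ALT, ","), function(a)
        max(nchar(a)), integer(1))),
    stringsAsFactors = FALSE
  )
  list(snvs = snvs, other_regions = other_regions)
}

#' Read genomic intervals from a BED file
#'
#' BED3+ input parsed via \pkg{rtracklayer}; intervals are returned 0-based
#' half-open, sorted by `(chrom, start)`.  Zero-length intervals are
#' rejected.
#'
#' @param path Path to a BED file.
#' @return Data frame with columns `chrom`, `start`, `end` and, when present
#'   in the input, `name`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) {
      stop("malformed BED '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) df$name <- as.character(nm)
  if (any(df$end <= df$start)) {
    stop("BED '", path, "': interval with end <= start at line(s) ",
         paste(which(df$end <= df$start), collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write genomic intervals to a BED file
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  stopifnot_cols(intervals, c("chrom", "start", "end"), "interval table")
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
  if (!is.null(intervals$name)) S4Vectors::mcols(gr)$name <- intervals$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

contact_cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "total_pairs", "pairs_forward", "pairs_reverse")

#' Read ChIA-PET contacts from a BEDPE-with-counts file
#'
#' The file is headerless tab-separated BEDPE extended with counts: six
#' anchor coordinates (0-based half-open), the total number of paired tags
#' supporting the contact, and the tag counts in the two read orientations
#' (which partition the total).  Anchors are normalised so that anchor 1
#' precedes anchor 2 by `(chrom, start)`.
#'
#' @param path Path to the BEDPE file.
#' @return Data frame with columns `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, `total_pairs`, `pairs_forward`, `pairs_reverse`.
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) stop("BEDPE file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 9L) {
    stop("BEDPE '", path, "': expected 9 columns (6 coordinates + total + ",
         "per-direction counts), got ", ncol(df), call. = FALSE)
  }
  df <- df[, 1:9]
  names(df) <- contact_cols
  for (col in c("start1", "end1", "start2", "end2",
                "total_pairs", "pairs_forward", "pairs_reverse")) {
    df[[col]] <- as.integer(df[[col]])
  }
  neg <- df$total_pairs < 0 | df$pairs_forward < 0 | df$pairs_reverse < 0
  if (any(neg)) {
    stop("BEDPE '", path, "': negative count(s) at record(s) ",
         paste(which(neg), collapse = ", "), call. = FALSE)
  }
  mism <- df$pairs_forward + df$pairs_reverse != df$total_pairs
  if (any(mism)) {
    stop("BEDPE '", path, "': per-direction counts do not partition the ",
         "total at record(s) ", paste(which(mism), collapse = ", "),
         call. = FALSE)
  }
  swap <- df$chrom2 < df$chrom1 |
    (df$chrom2 == df$chrom1 & df$start2 < df$start1)
  if (any(swap)) {
    a <- df[swap, c("chrom2", "start2", "end2")]
    df[swap, c("chrom2", "start2", "end2")] <-
      df[swap, c("chrom1", "start1", "end1")]
    df[swap, c("chrom1", "start1", "end1")] <- a
  }
  df
}

#' Write ChIA-PET contacts to a BEDPE-with-counts file
#'
#' @param contacts Data frame as returned by [read_contacts()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  stopifnot_cols(contacts, contact_cols, "contact table")
  utils::write.table(contacts[, contact_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

allele_count_cols <- c("sample_id", "alignment_ref", "chrom", "pos",
                       "ref_count", "alt_count")

#' Read a per-site allele-count table
#'
#' The canonical evidence format of the pipeline: one row per (sample,
#' alignment reference, site) with the number of reads supporting the
#' reference and alternative alleles.  `alignment_ref` records which genome
#' the reads were aligned to: `"ref"` (standard reference) or `"alt"` (the
#' alternative genome carrying the alternate alleles), the pair enabling
#' reference mapping-bias correction.
#'
#' @param path Path to a TSV with header columns `sample_id`,
#'   `alignment_ref`, `chrom`, `pos`, `ref_count`, `alt_count`.
#' @return Data frame with those columns.
#' @export
read_allele_counts <- function(path) {
  df <- read_tsv_checked(path, allele_count_cols, "allele-count table")
  df$pos <- as.integer(df$pos)
  df$ref_count <- as.integer(df$ref_count)
  df$alt_count <- as.integer(df$alt_count)
  bad <- !df$alignment_ref %in% c("ref", "alt")
  if (any(bad)) {
    stop("allele-count table '", path, "': alignment_ref must be 'ref' or ",
         "'alt' (records ", paste(utils::head(which(bad), 5), collapse = ", "),
         ")", call. = FALSE)
  }
  if (any(df$ref_count < 0 | df$alt_count < 0)) {
    stop("allele-count table '", path, "': negative counts", call. = FALSE)
  }
  df[, allele_count_cols]
}

#' Write a per-site allele-count table
#' @param counts Data frame as returned by [read_allele_counts()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  stopifnot_cols(counts, allele_count_cols, "allele-count table")
  write_tsv(counts[, allele_count_cols], path)
}

#' Read RNA-seq allele counts at heterozygous marker positions
#'
#' @param path TSV with header columns `chrom`, `pos`, `ref_count`,
#'   `alt_count`, `sample`.
#' @return Data frame with those columns.
#' @export
read_rna_counts <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos", "ref_count", "alt_count",
                                 "sample"), "RNA allele-count table")
  df$pos <- as.integer(df$pos)
  df$ref_count <- as.integer(df$ref_count)
  df$alt_count <- as.integer(df$alt_count)
  if (any(df$ref_count < 0 | df$alt_count < 0)) {
    stop("RNA allele-count table '", path, "': negative counts",
         call. = FALSE)
  }
  df
}

#' Write RNA-seq allele counts
#' @param counts Data frame as returned by [read_rna_counts()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rna_counts <- function(counts, path) {
  stopifnot_cols(counts, c("chrom", "pos", "ref_count", "alt_count",
                           "sample"), "RNA allele-count table")
  write_tsv(counts[, c("chrom", "pos", "ref_count", "alt_count", "sample")],
            path)
}

#' Read a GWAS-catalog extract
#'
#' @param path TSV with header columns `rsid`, `chrom`, `pos` (1-based),
#'   `trait`, `maf`.
#' @return Data frame with those columns.
#' @export
read_gwas_catalog <- function(path) {
  df <- read_tsv_checked(path, c("rsid", "chrom", "pos", "trait", "maf"),
                         "GWAS catalog extract")
  df$pos <- as.integer(df$pos)
  df$maf <- as.numeric(df$maf)
  df
}

#' Write a GWAS-catalog extract
#' @param catalog Data frame as returned by [read_gwas_catalog()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gwas_catalog <- function(catalog, path) {
  stopifnot_cols(catalog, c("rsid", "chrom", "pos", "trait", "maf"),
                 "GWAS catalog extract")
  write_tsv(catalog[, c("rsid", "chrom", "pos", "trait", "maf")], path)
}

#' Read a minor-allele-frequency table
#'
#' Population MAFs for candidate SNPs, keyed by position (with the dbSNP
#' identifier where one exists).
#'
#' @param path TSV with header columns `chrom`, `pos`, `rsid`, `maf`;
#'   unannotated variants carry an empty `rsid`.
#' @return Data frame with those columns (`rsid` is `NA` when absent).
#' @export
read_maf_table <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos", "rsid", "maf"), "MAF table")
  df$pos <- as.integer(df$pos)
  df$maf <- as.numeric(df$maf)
  df$rsid <- as.character(df$rsid)
  df$rsid[is.na(df$rsid) | df$rsid %in% c("", ".")] <- NA_character_
  df
}

#' Write a minor-allele-frequency table
#' @param mafs Data frame as returned by [read_maf_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_maf_table <- function(mafs, path) {
  stopifnot_cols(mafs, c("chrom", "pos", "rsid", "maf"), "MAF table")
  out <- mafs[, c("chrom", "pos", "rsid", "maf")]
  out$rsid[is.na(out$rsid)] <- "."
  write_tsv(out, path)
}
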