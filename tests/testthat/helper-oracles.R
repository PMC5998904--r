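# Brute-force oracles and small fixture builders shared across tests.

# O(n^2) clustered-SNP oracle: a site is removed when >= 2 other sites lie
# within window_bp on the same chromosome.
oracle_clustered_removed <- function(sites, window_bp) {
  vapply(seq_len(nrow(sites)), function(i) {
    nb <- sum(sites$chrom == sites$chrom[i] &
                abs(sites$pos - sites$pos[i]) <= window_bp) - 1L
    nb >= 2L
  }, logical(1))
}

# Exhaustive indel-proximity oracle: minimum distance from a 1-based
# position to any base of any 0-based half-open region.
oracle_indel_removed <- function(sites, regions, max_bp) {
  vapply(seq_len(nrow(sites)), function(i) {
    rg <- regions[regions$chrom == sites$chrom[i], , drop = FALSE]
    if (!nrow(rg)) return(FALSE)
    p0 <- sites$pos[i] - 1L
    d <- vapply(seq_len(nrow(rg)), function(j) {
      bases <- rg$start[j]:(rg$end[j] - 1L)
      min(abs(bases - p0))
    }, numeric(1))
    min(d) <= max_bp
  }, logical(1))
}

# Exhaustive position classifier over a gene_models-like list.
oracle_classify <- function(chrom, pos, genes, flank_bp) {
  hits <- list()
  for (g in genes) {
    if (g$chrom != chrom) next
    p0 <- pos - 1L
    member <- function(iv) nrow(iv) > 0 &&
      any(vapply(seq_len(nrow(iv)), function(j)
        p0 %in% (iv$start[j]:(iv$end[j] - 1L)), logical(1)))
    if (pos %in% (g$tss - flank_bp):(g$tss + flank_bp)) {
      hits[[length(hits) + 1L]] <- c(g$gene_id, "promoter")
    }
    if (member(g$introns)) hits[[length(hits) + 1L]] <- c(g$gene_id, "intron")
    if (member(g$utr5)) hits[[length(hits) + 1L]] <- c(g$gene_id, "utr5")
    if (member(g$utr3)) hits[[length(hits) + 1L]] <- c(g$gene_id, "utr3")
  }
  if (!length(hits)) {
    return(data.frame(gene_id = character(), relation = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, hits)
  data.frame(gene_id = m[, 1], relation = m[, 2], stringsAsFactors = FALSE)
}

# All-pairs GWAS linkage oracle.
oracle_linkage <- function(rsnps, indexes, window_bp, max_diff) {
  out <- list()
  for (i in seq_len(nrow(rsnps))) {
    for (j in seq_len(nrow(indexes))) {
      if (rsnps$chrom[i] == indexes$chrom[j] &&
          abs(rsnps$pos[i] - indexes$pos[j]) <= window_bp &&
          abs(rsnps$maf[i] - indexes$maf[j]) <= max_diff) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 2))
  do.call(rbind, out)
}

# Random gene-model list (directly built, no GTF) for property tests.
random_gene_models <- function(n_genes, chrom_len = 100000L) {
  genes <- list()
  for (k in seq_len(n_genes)) {
    start <- sample.int(chrom_len - 6000L, 1)
    ne <- sample(2:4, 1)
    bounds <- sort(sample(seq(start, start + 5000L, by = 10L), 2L * ne))
    exons <- data.frame(start = bounds[seq(1, 2 * ne, 2)],
                        end = bounds[seq(2, 2 * ne, 2)])
    exons <- exons[exons$end > exons$start, , drop = FALSE]
    if (!nrow(exons)) next
    introns <- if (nrow(exons) > 1) {
      data.frame(start = exons$end[-nrow(exons)], end = exons$start[-1])
    } else data.frame(start = integer(), end = integer())
    introns <- introns[introns$end > introns$start, , drop = FALSE]
    u5len <- min(50L, exons$end[1] - exons$start[1])
    u3n <- nrow(exons)
    u3len <- min(50L, exons$end[u3n] - exons$start[u3n])
    genes[[length(genes) + 1L]] <- list(
      gene_id = paste0("RG", k), chrom = "chr1", strand = "+",
      tss = exons$start[1] + 1L,
      tss_all = exons$start[1] + 1L,
      exons = exons,
      cds = data.frame(start = exons$start[1] + u5len, end = exons$end[1]),
      utr5 = data.frame(start = exons$start[1], end = exons$start[1] + u5len),
      utr3 = data.frame(start = exons$end[u3n] - u3len, end = exons$end[u3n]),
      introns = introns
    )
  }
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  structure(genes, class = "gene_models")
}

# Minimal VCF writer for fixtures.
write_test_vcf <- function(path, body, contigs = c(chr1 = 1000000L)) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(contigs), ",length=", contigs, ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    body
  ), path)
  path
}

# Allele-count row builder.
ac_row <- function(sample, align, chrom, pos, ref, alt) {
  data.frame(sample_id = sample, alignment_ref = align, chrom = chrom,
             pos = pos, ref_count = ref, alt_count = alt,
             stringsAsFactors = FALSE)
}

# Dual-alignment observations with identical counts under both genomes.
dual_obs <- function(sample, chrom, pos, ref, alt) {
  rbind(ac_row(sample, "ref", chrom, pos, ref, alt),
        ac_row(sample, "alt", chrom, pos, ref, alt))
}

# A cached default-spec synthetic bundle shared by the heavier tests.
shared_bundle_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !file.exists(file.path(dir, "truth_manifest.json"))) {
      dir <<- file.path(tempdir(), "rsnpscout-shared-bundle")
      simulate_bundle(simulation_spec(), dir)
    }
    dir
  }
})

# A cached pipeline run over the shared bundle.
shared_run <- local({
  run <- NULL
  function() {
    if (is.null(run)) run <<- run_pipeline(shared_bundle_dir())
    run
  }
})

# Random DNA and alternative-base pickers for sequence tests.
random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
         character(1))
}
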