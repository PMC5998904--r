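# Synthetic-data generator: emits a complete, internally consistent input
# bundle (genome, annotation, OTFRs, variants, ChIP allele counts, ChIA-PET
# contacts, Pol II peaks, RNA allele counts, GWAS catalog, MAF table) with a
# planted ground-truth manifest.
#
# Genome layout: each chromosome is tiled into 30 kb slots.  A gene slot
# carries one 8 kb five-exon gene (alternating strand), five OTFRs over its
# promoter, two introns and two intergenic positions, heterozygous sites on
# a 30 bp grid inside the OTFRs plus a few outside, and quiet zones used for
# QC fodder.  The last slots of every chromosome are het-free deserts where
# window-violating GWAS decoys can be placed more than 10 kb from every
# candidate site.

# 0-based offsets of the gene structure within its 8 kb span (plus strand).
.gene_span <- 8000L
.exon_off <- rbind(c(0L, 400L), c(1500L, 2100L), c(3000L, 3800L),
                   c(5000L, 5600L), c(7000L, 8000L))
.utr5_plus <- c(0L, 200L);    .utr3_plus <- c(7400L, 8000L)
.utr5_minus <- c(7600L, 8000L); .utr3_minus <- c(0L, 200L)
.marker_off <- c(1800L, 5300L)   # inside CDS on either strand

#' Specification of a synthetic study
#'
#' Defaults define the simulated study conditions: two 1 Mb chromosomes
#' carrying 60 genes and 300 OTFRs, 2,000 heterozygous sites of which 5%
#' carry a planted allele-specific binding effect at allele fraction 0.7,
#' negative-binomially dispersed ChIP coverage around 80 reads with a 6%
#' reference mapping bias of opposite sign under the two alignment genomes,
#' twelve ChIP experiments of which six cover any given site and three carry
#' the planted effect, allele-specific expression at fraction 0.7 in the
#' targets of 80% of planted-SNP host genes, 40 planted ChIA-PET loops plus
#' random-ligation noise, and a 50-entry GWAS catalog of which 30% are
#' indexes placed near planted rSNPs with matched minor-allele frequencies
#' while the rest are decoys each violating exactly one linkage criterion.
#'
#' @param rng_seed Integer seed; the same seed yields a byte-identical
#'   bundle.
#' @param n_chroms,chrom_length_bp Autosome count and length.
#' @param n_genes Total gene count (distributed over chromosomes).
#' @param n_otfrs Total OTFR count (five per gene are laid out; must equal
#'   `5 * n_genes`).
#' @param n_het_sites Clean heterozygous sites (excludes QC fodder).
#' @param frac_asymmetric Fraction of sites carrying a planted binding
#'   effect.
#' @param asb_allele_fraction Reference-allele read fraction at planted
#'   sites in their active experiments.
#' @param coverage_mean,coverage_dispersion Negative-binomial ChIP coverage
#'   (dispersion is 1/size).
#' @param reference_bias Excess reference-allele mapping fraction under the
#'   reference alignment at a balanced site (mirrored under the alternative
#'   alignment).
#' @param n_samples,n_covering_samples,n_active_samples ChIP experiments in
#'   the study, experiments covering any one site, and covering experiments
#'   in which a planted effect manifests.
#' @param frac_targets_with_ase Fraction of planted-SNP host genes whose
#'   expression carries the planted allele-specific effect (their planted
#'   SNPs are the true rSNPs).
#' @param ase_allele_fraction RNA reference-allele fraction at markers of
#'   regulated genes.
#' @param rna_coverage_mean,rna_coverage_dispersion Negative-binomial RNA
#'   coverage at marker SNPs.
#' @param n_chiapet_loops Planted loops from true-rSNP windows to distal
#'   regulated promoters.
#' @param chiapet_noise_pairs Random-ligation noise contact records.
#' @param n_gwas_indexes GWAS catalog size.
#' @param frac_indexes_near_rsnps Fraction of catalog entries that are
#'   genuinely linked indexes; the remainder are one-violation decoys.
#' @param maf_min,maf_max Uniform population MAF range.
#' @param frac_annotated Fraction of heterozygous sites with dbSNP-style
#'   rsIDs (the rest are reported as `chrN:pos`).
#' @param frac_homozygous_artifacts Fraction (of `n_het_sites`) of
#'   additional near-homozygous artifact sites that the balance QC should
#'   remove.
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(rng_seed = 1L,
                            n_chroms = 2L,
                            chrom_length_bp = 1000000L,
                            n_genes = 60L,
                            n_otfrs = 300L,
                            n_het_sites = 2000L,
                            frac_asymmetric = 0.05,
                            asb_allele_fraction = 0.7,
                            coverage_mean = 80,
                            coverage_dispersion = 0.2,
                            reference_bias = 0.06,
                            n_samples = 12L,
                            n_covering_samples = 6L,
                            n_active_samples = 3L,
                            frac_targets_with_ase = 0.8,
                            ase_allele_fraction = 0.7,
                            rna_coverage_mean = 200,
                            rna_coverage_dispersion = 0.05,
                            n_chiapet_loops = 40L,
                            chiapet_noise_pairs = 500L,
                            n_gwas_indexes = 50L,
                            frac_indexes_near_rsnps = 0.3,
                            maf_min = 0.05,
                            maf_max = 0.5,
                            frac_annotated = 0.7,
                            frac_homozygous_artifacts = 0.02) {
  spec <- as.list(environment())
  fracs <- c("frac_asymmetric", "frac_targets_with_ase",
             "frac_indexes_near_rsnps", "frac_annotated",
             "frac_homozygous_artifacts")
  for (f in fracs) {
    if (spec[[f]] < 0 || spec[[f]] > 1) {
      stop("spec field '", f, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  counts <- c("n_chroms", "chrom_length_bp", "n_genes", "n_otfrs",
              "n_het_sites", "n_samples", "n_covering_samples",
              "n_active_samples", "n_chiapet_loops", "n_gwas_indexes")
  for (f in counts) {
    if (spec[[f]] <= 0) {
      stop("spec field '", f, "' must be positive", call. = FALSE)
    }
  }
  if (spec$n_otfrs != 5L * spec$n_genes) {
    stop("n_otfrs must equal 5 * n_genes (five OTFRs are laid out per gene)",
         call. = FALSE)
  }
  if (spec$n_active_samples > spec$n_covering_samples ||
      spec$n_covering_samples > spec$n_samples) {
    stop("need n_active_samples <= n_covering_samples <= n_samples",
         call. = FALSE)
  }
  if (spec$asb_allele_fraction <= 0.5 || spec$asb_allele_fraction >= 1 ||
      spec$ase_allele_fraction <= 0.5 || spec$ase_allele_fraction >= 1) {
    stop("planted allele fractions must lie in (0.5, 1)", call. = FALSE)
  }
  class(spec) <- "simulation_spec"
  spec
}

#' Read a simulation spec from a YAML file
#' @param path YAML file whose keys mirror [simulation_spec()] arguments.
#' @return A `"simulation_spec"` list.
#' @export
read_simulation_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  bad <- setdiff(names(vals), names(formals(simulation_spec)))
  if (length(bad)) stop("unknown spec keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(simulation_spec, vals)
}

rnb <- function(n, mu, dispersion, floor_at = 1L) {
  pmax(floor_at, stats::rnbinom(n, mu = mu, size = 1 / dispersion))
}

# Draw dual-alignment allele counts for one vector of site-sample units.
# Reads carrying the disfavoured allele are lost at rate lambda under each
# alignment, which shifts the observed reference fraction by about
# +reference_bias (ref alignment) / -reference_bias (alt alignment) at a
# balanced site; averaging the two alignments cancels the shift.
draw_dual_counts <- function(cov, f, bias) {
  lambda <- 4 * bias / (1 + 2 * bias)
  r <- stats::rbinom(length(cov), cov, f)
  a <- cov - r
  data.frame(
    ref_ref = r,
    ref_alt = stats::rbinom(length(cov), a, 1 - lambda),
    alt_ref = stats::rbinom(length(cov), r, 1 - lambda),
    alt_alt = a
  )
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
         character(1))
}

#' Generate the full synthetic input bundle
#'
#' Writes every pipeline input plus `truth_manifest.json` into `out_dir`.
#' The same `rng_seed` produces a byte-identical bundle.
#'
#' @param spec A [simulation_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and `manifest`
#'   (the ground truth, also written as JSON).
#' @export
simulate_bundle <- function(spec = simulation_spec(), out_dir) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (missing(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$rng_seed)

  slot_bp <- 30000L
  slots_per_chrom <- spec$chrom_length_bp %/% slot_bp
  genes_per_chrom <- ceiling(spec$n_genes / spec$n_chroms)
  if (genes_per_chrom + 2L > slots_per_chrom) {
    stop("infeasible placement: ", spec$n_genes, " genes do not fit on ",
         spec$n_chroms, " chromosome(s) of ", spec$chrom_length_bp,
         " bp with two desert slots reserved", call. = FALSE)
  }
  chroms <- paste0("chr", seq_len(spec$n_chroms))

  ## ---- genes -------------------------------------------------------------
  g_idx <- seq_len(spec$n_genes)
  gene <- data.frame(
    gene_id = sprintf("G%03d", g_idx),
    chrom = chroms[((g_idx - 1L) %% spec$n_chroms) + 1L],
    slot = (g_idx - 1L) %/% spec$n_chroms,
    strand = ifelse(g_idx %% 2L == 1L, "+", "-"),
    stringsAsFactors = FALSE
  )
  gene$gs <- gene$slot * slot_bp + 2000L                 # 0-based gene start
  gene$tss0 <- ifelse(gene$strand == "+", gene$gs, gene$gs + .gene_span - 1L)
  gene$tss1 <- gene$tss0 + 1L

  ## ---- OTFRs (five per gene) ----------------------------------------------
  otfr_one <- function(i) {
    gs <- gene$gs[i]
    prom <- if (gene$strand[i] == "+") c(gs - 900L, gs + 900L) else
      c(gs + .gene_span - 901L, gs + .gene_span + 899L)
    data.frame(
      chrom = gene$chrom[i],
      start = c(prom[1], gs + 500L, gs + 4000L, gs + 9000L, gs + 10100L),
      end = c(prom[2], gs + 1400L, gs + 4900L, gs + 9900L, gs + 11000L),
      gene_id = gene$gene_id[i],
      class = c("promoter", "intron", "intron", "intergenic", "intergenic"),
      stringsAsFactors = FALSE
    )
  }
  otfr <- do.call(rbind, lapply(seq_len(nrow(gene)), otfr_one))
  otfr$name <- sprintf("OTFR%04d", seq_len(nrow(otfr)))

  ## ---- heterozygous sites --------------------------------------------------
  n_outside <- round(0.15 * spec$n_het_sites)
  n_inside <- spec$n_het_sites - n_outside
  base_per <- n_inside %/% nrow(otfr)
  extra <- n_inside - base_per * nrow(otfr)
  per_otfr <- rep(base_per, nrow(otfr)) +
    c(rep(1L, extra), rep(0L, nrow(otfr) - extra))
  site_list <- lapply(seq_len(nrow(otfr)), function(j) {
    grid <- seq(otfr$start[j] + 6L, otfr$end[j] - 6L, by = 30L)
    if (length(grid) < per_otfr[j] + 1L) {
      stop("infeasible placement: OTFR ", otfr$name[j],
           " cannot host ", per_otfr[j], " sites", call. = FALSE)
    }
    pos0 <- sort(sample(grid, per_otfr[j]))
    data.frame(chrom = otfr$chrom[j], pos = pos0 + 1L,
               otfr_class = otfr$class[j], host_gene = otfr$gene_id[j],
               in_otfr = TRUE, stringsAsFactors = FALSE)
  })
  # sites outside OTFRs (zone [gs + 11200, gs + 11900) of each gene slot)
  per_gene_out <- n_outside %/% nrow(gene)
  rem_out <- n_outside - per_gene_out * nrow(gene)
  out_counts <- rep(per_gene_out, nrow(gene)) +
    c(rep(1L, rem_out), rep(0L, nrow(gene) - rem_out))
  out_list <- lapply(seq_len(nrow(gene)), function(i) {
    if (out_counts[i] == 0L) return(NULL)
    grid <- seq(gene$gs[i] + 11200L, gene$gs[i] + 11894L, by = 30L)
    pos0 <- sort(sample(grid, out_counts[i]))
    data.frame(chrom = gene$chrom[i], pos = pos0 + 1L,
               otfr_class = "none", host_gene = NA_character_,
               in_otfr = FALSE, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, c(site_list, out_list))
  sites$role <- "null"

  ## planted asymmetric sites (inside promoter/intron OTFRs only)
  n_planted <- round(spec$frac_asymmetric * spec$n_het_sites)
  eligible <- which(sites$otfr_class %in% c("promoter", "intron"))
  if (length(eligible) < n_planted) {
    stop("infeasible placement: not enough promoter/intron sites to plant ",
         n_planted, " effects", call. = FALSE)
  }
  planted_idx <- sort(sample(eligible, n_planted))
  sites$role[planted_idx] <- "planted"

  ## regulated host genes: the planted SNPs of a regulated host are true rSNPs
  host_genes <- sort(unique(sites$host_gene[planted_idx]))
  n_reg <- round(spec$frac_targets_with_ase * length(host_genes))
  regulated_hosts <- sort(sample(host_genes, n_reg))
  sites$is_rsnp <- sites$role == "planted" &
    sites$host_gene %in% regulated_hosts

  ## ---- QC fodder sites ----------------------------------------------------
  fodder <- list()
  # blacklist: chrX sites + repeat-masked sites
  fodder$chrx <- data.frame(chrom = "chrX", pos = 10000L + 50L * (1:10),
                            reason = "blacklist", stringsAsFactors = FALSE)
  chr1_genes <- which(gene$chrom == chroms[1])
  if (length(chr1_genes) < 5L) {
    stop("infeasible placement: need at least five genes on ", chroms[1],
         " for the QC fodder zones", call. = FALSE)
  }
  wrap <- function(k) chr1_genes[((k - 1L) %% length(chr1_genes)) + 1L]
  rep_slots <- wrap(1:5)
  repeats <- data.frame(chrom = gene$chrom[rep_slots],
                        start = gene$gs[rep_slots] + 11000L,
                        end = gene$gs[rep_slots] + 11150L,
                        stringsAsFactors = FALSE)
  fodder$repeat_hit <- data.frame(
    chrom = repeats$chrom, pos = repeats$start + c(30L, 60L, 90L, 50L, 70L) + 1L,
    reason = "blacklist", stringsAsFactors = FALSE)
  # indel proximity
  ind_slots <- wrap(6:10)
  indel_pos1 <- gene$gs[ind_slots] + 12100L + 1L      # 1-based indel start
  fodder$indel_near <- data.frame(
    chrom = gene$chrom[ind_slots], pos = indel_pos1 + 4L,
    reason = "indel_proximity", stringsAsFactors = FALSE)
  # clustered triplets
  cl_slots <- wrap(11:15)
  cl_base <- gene$gs[cl_slots] + 12500L + 1L
  fodder$clustered <- data.frame(
    chrom = rep(gene$chrom[cl_slots], each = 3L),
    pos = as.vector(vapply(cl_base, function(p) p + c(0L, 4L, 8L),
                           integer(3))),
    reason = "clustered", stringsAsFactors = FALSE)
  # low coverage
  lc_otfr <- which(otfr$class == "intergenic")[1:5]
  fodder$low_cov <- data.frame(
    chrom = otfr$chrom[lc_otfr], pos = otfr$end[lc_otfr] - 3L,
    reason = "low_coverage", stringsAsFactors = FALSE)
  qc_decoys <- do.call(rbind, fodder)

  # near-homozygous artifacts (balance QC should remove)
  n_artifact <- round(spec$frac_homozygous_artifacts * spec$n_het_sites)
  art_otfr <- sample(nrow(otfr), n_artifact, replace = TRUE)
  art_pos0 <- otfr$start[art_otfr] + 18L +
    30L * (sample(3L, n_artifact, replace = TRUE) - 1L)
  artifacts <- unique(data.frame(chrom = otfr$chrom[art_otfr],
                                 pos = art_pos0 + 1L,
                                 stringsAsFactors = FALSE))
  # drop artifact positions colliding with clean sites
  artifacts <- artifacts[!paste(artifacts$chrom, artifacts$pos) %in%
                           paste(sites$chrom, sites$pos), , drop = FALSE]

  ## ---- genome sequence -----------------------------------------------------
  seqs <- c(
    stats::setNames(lapply(chroms, function(x)
      random_seq(spec$chrom_length_bp)), chroms),
    list(chrX = random_seq(50000L))
  )
  genome <- Biostrings::DNAStringSet(unlist(seqs))

  all_sites <- rbind(
    sites[, c("chrom", "pos")],
    qc_decoys[, c("chrom", "pos")],
    artifacts[, c("chrom", "pos")]
  )
  all_sites$kind <- c(rep("clean", nrow(sites)),
                      rep("fodder", nrow(qc_decoys)),
                      rep("artifact", nrow(artifacts)))
  refb <- character(nrow(all_sites))
  for (cc in unique(all_sites$chrom)) {
    sel <- which(all_sites$chrom == cc)
    refb[sel] <- as.character(Biostrings::extractAt(
      genome[[cc]], IRanges::IRanges(all_sites$pos[sel], all_sites$pos[sel])))
  }
  all_sites$ref <- refb
  all_sites$alt <- other_base(refb)
  annotated <- stats::runif(nrow(all_sites)) < spec$frac_annotated
  all_sites$id <- ifelse(annotated,
                         sprintf("rs%06d", 100000L + seq_len(nrow(all_sites))),
                         NA_character_)
  all_sites$maf <- stats::runif(nrow(all_sites), spec$maf_min, spec$maf_max)

  ## ---- ChIP allele counts --------------------------------------------------
  sample_ids <- sprintf("chip%02d", seq_len(spec$n_samples))
  units <- list(); truth_active <- list()
  clean_rows <- which(all_sites$kind == "clean")
  for (i in seq_len(nrow(all_sites))) {
    kind <- all_sites$kind[i]
    if (kind == "fodder" && qc_decoys$reason[i - nrow(sites)] == "low_coverage") {
      units[[i]] <- data.frame(site = i, sample = sample_ids[1], f = 0.5,
                               cov_mu = 3, stringsAsFactors = FALSE)
      next
    }
    covering <- sort(sample(spec$n_samples, spec$n_covering_samples))
    f <- rep(0.5, length(covering))
    if (kind == "artifact") {
      f[] <- 0.97
    } else if (kind == "clean") {
      j <- i  # clean sites come first in all_sites
      if (sites$role[j] == "planted") {
        act <- sample(length(covering), spec$n_active_samples)
        f[act] <- spec$asb_allele_fraction
        truth_active[[length(truth_active) + 1L]] <- data.frame(
          chrom = sites$chrom[j], pos = sites$pos[j],
          experiment = sample_ids[covering[act]], stringsAsFactors = FALSE)
      }
    }
    units[[i]] <- data.frame(site = i, sample = sample_ids[covering], f = f,
                             cov_mu = spec$coverage_mean,
                             stringsAsFactors = FALSE)
  }
  units <- do.call(rbind, units)
  cov <- ifelse(units$cov_mu < 10, units$cov_mu,
                rnb(nrow(units), spec$coverage_mean,
                    spec$coverage_dispersion, floor_at = 4L))
  dual <- draw_dual_counts(cov, units$f, spec$reference_bias)
  chip_counts <- rbind(
    data.frame(sample_id = units$sample, alignment_ref = "ref",
               chrom = all_sites$chrom[units$site],
               pos = all_sites$pos[units$site],
               ref_count = dual$ref_ref, alt_count = dual$ref_alt,
               stringsAsFactors = FALSE),
    data.frame(sample_id = units$sample, alignment_ref = "alt",
               chrom = all_sites$chrom[units$site],
               pos = all_sites$pos[units$site],
               ref_count = dual$alt_ref, alt_count = dual$alt_alt,
               stringsAsFactors = FALSE)
  )
  chip_counts <- chip_counts[order(chip_counts$chrom, chip_counts$pos,
                                   chip_counts$sample_id,
                                   chip_counts$alignment_ref), ]

  ## ---- ChIA-PET ------------------------------------------------------------
  rsnp_rows <- which(sites$is_rsnp)
  n_loops <- min(spec$n_chiapet_loops, length(rsnp_rows))
  loop_src <- sample(rsnp_rows, n_loops)
  loops <- list(); loop_truth <- list()
  for (k in seq_len(n_loops)) {
    j <- loop_src[k]
    cand <- which(gene$gene_id %in% regulated_hosts &
                    gene$chrom == sites$chrom[j] &
                    gene$gene_id != sites$host_gene[j] &
                    abs(gene$gs - (sites$pos[j] - 1L)) > 20000L)
    if (!length(cand)) next
    gi <- cand[sample(length(cand), 1L)]
    p0 <- sites$pos[j] - 1L
    a1 <- c(p0 - 500L, p0 + 500L)
    a2 <- c(gene$tss0[gi] - 500L, gene$tss0[gi] + 500L)
    total <- 22L + stats::rpois(1, 8)
    repeat {
      fwd <- stats::rbinom(1, total, 0.5)
      if (min(fwd, total - fwd) >= 10L) break
    }
    loops[[length(loops) + 1L]] <- data.frame(
      chrom1 = sites$chrom[j], start1 = a1[1], end1 = a1[2],
      chrom2 = gene$chrom[gi], start2 = a2[1], end2 = a2[2],
      total_pairs = total, pairs_forward = fwd, pairs_reverse = total - fwd,
      stringsAsFactors = FALSE)
    loop_truth[[length(loop_truth) + 1L]] <- data.frame(
      chrom = sites$chrom[j], pos = sites$pos[j],
      gene_id = gene$gene_id[gi], stringsAsFactors = FALSE)
  }
  loops <- do.call(rbind, loops)
  # random-ligation noise (filtered out by the pair-count thresholds)
  nz <- spec$chiapet_noise_pairs
  nchr <- sample(chroms, nz, replace = TRUE)
  npos1 <- sample.int(spec$chrom_length_bp - 2000L, nz)
  npos2 <- sample.int(spec$chrom_length_bp - 2000L, nz)
  ntot <- sample(3L, nz, replace = TRUE)
  nfwd <- stats::rbinom(nz, ntot, 0.5)
  noise <- data.frame(
    chrom1 = nchr, start1 = npos1, end1 = npos1 + 1000L,
    chrom2 = sample(chroms, nz, replace = TRUE),
    start2 = npos2, end2 = npos2 + 1000L,
    total_pairs = ntot, pairs_forward = nfwd, pairs_reverse = ntot - nfwd,
    stringsAsFactors = FALSE)
  # structured rejects: direction-skewed, interchromosomal, intersecting
  g1 <- gene[gene$chrom == chroms[1], ][1:3, ]
  rejects <- data.frame(
    chrom1 = c(g1$chrom[1], g1$chrom[2], g1$chrom[3]),
    start1 = c(g1$gs[1], g1$gs[2], g1$gs[3]),
    end1 = c(g1$gs[1] + 1000L, g1$gs[2] + 1000L, g1$gs[3] + 2000L),
    chrom2 = c(g1$chrom[1], chroms[min(2L, length(chroms))], g1$chrom[3]),
    start2 = c(g1$gs[1] + 50000L, g1$gs[2] + 50000L, g1$gs[3] + 1000L),
    end2 = c(g1$gs[1] + 51000L, g1$gs[2] + 51000L, g1$gs[3] + 2500L),
    total_pairs = c(25L, 40L, 40L), pairs_forward = c(18L, 20L, 20L),
    pairs_reverse = c(7L, 20L, 20L), stringsAsFactors = FALSE)
  contacts <- rbind(loops, noise, rejects)

  ## ---- Pol II peaks --------------------------------------------------------
  prom_iv <- data.frame(chrom = gene$chrom,
                        start = pmax(0L, gene$tss0 - 1800L),
                        end = gene$tss0 + 1801L, stringsAsFactors = FALSE)
  intr_iv <- otfr[otfr$class == "intron", c("chrom", "start", "end")]
  peaks1 <- prom_iv
  peaks2 <- rbind(prom_iv, intr_iv)

  ## ---- RNA allele counts ---------------------------------------------------
  regulated_genes <- sort(unique(c(
    regulated_hosts,
    if (length(loop_truth)) do.call(rbind, loop_truth)$gene_id
  )))
  mk <- list()
  for (i in seq_len(nrow(gene))) {
    f <- if (gene$gene_id[i] %in% regulated_genes)
      spec$ase_allele_fraction else 0.5
    for (off in .marker_off) {
      mk[[length(mk) + 1L]] <- data.frame(
        chrom = gene$chrom[i], pos = gene$gs[i] + off + 1L, f = f,
        stringsAsFactors = FALSE)
    }
  }
  # planted SNPs inside transcribed UTRs serve as their own markers
  for (j in planted_idx) {
    gi <- match(sites$host_gene[j], gene$gene_id)
    off <- sites$pos[j] - 1L - gene$gs[gi]
    u5 <- if (gene$strand[gi] == "+") .utr5_plus else .utr5_minus
    u3 <- if (gene$strand[gi] == "+") .utr3_plus else .utr3_minus
    if ((off >= u5[1] && off < u5[2]) || (off >= u3[1] && off < u3[2])) {
      f <- if (sites$is_rsnp[j]) spec$ase_allele_fraction else 0.5
      mk[[length(mk) + 1L]] <- data.frame(chrom = sites$chrom[j],
                                          pos = sites$pos[j], f = f,
                                          stringsAsFactors = FALSE)
    }
  }
  mk <- do.call(rbind, mk)
  rcov <- rnb(nrow(mk), spec$rna_coverage_mean, spec$rna_coverage_dispersion)
  rref <- stats::rbinom(nrow(mk), rcov, mk$f)
  rna_counts <- data.frame(chrom = mk$chrom, pos = mk$pos,
                           ref_count = rref, alt_count = rcov - rref,
                           sample = "rna01", stringsAsFactors = FALSE)
  rna_counts <- rna_counts[order(rna_counts$chrom, rna_counts$pos), ]

  ## ---- GWAS catalog --------------------------------------------------------
  true_rsnp <- sites[sites$is_rsnp, , drop = FALSE]
  site_key <- paste(all_sites$chrom, all_sites$pos)
  tr_key <- paste(true_rsnp$chrom, true_rsnp$pos)
  n_linked <- round(spec$frac_indexes_near_rsnps * spec$n_gwas_indexes)
  n_decoy <- spec$n_gwas_indexes - n_linked
  n_trait_d <- n_decoy %/% 3L
  n_maf_d <- n_decoy %/% 3L
  n_window_d <- n_decoy - n_trait_d - n_maf_d
  if (nrow(true_rsnp) == 0L) {
    # null configuration: no planted effects, so no anchored design --
    # emit an unanchored catalog (far positions, matching traits)
    n_trait_d <- 0L; n_maf_d <- 0L; n_linked <- 0L
    n_window_d <- spec$n_gwas_indexes
  } else if (nrow(true_rsnp) < n_linked + n_trait_d + n_maf_d) {
    stop("infeasible placement: not enough true rSNPs to anchor the GWAS ",
         "catalog design", call. = FALSE)
  }
  picks <- sample(nrow(true_rsnp), n_linked + n_trait_d + n_maf_d)
  anchor_linked <- picks[seq_len(n_linked)]
  anchor_trait <- picks[n_linked + seq_len(n_trait_d)]
  anchor_maf <- picks[n_linked + n_trait_d + seq_len(n_maf_d)]

  match_traits <- c("Schizophrenia", "Bipolar disorder",
                    "Autism spectrum disorder", "Major depressive disorder",
                    "Parkinson's disease", "Alzheimer's disease (late onset)",
                    "Cognitive decline (age-related)",
                    "Depression (quantitative trait)", "Anxiety disorder",
                    "Posttraumatic stress disorder")
  nonmatch_traits <- c("Height", "Body mass index", "Type 2 diabetes",
                       "Coronary artery disease", "Crohn's disease",
                       "Rheumatoid arthritis")

  place_near <- function(rows) {
    d <- sample(1000:9000, length(rows), replace = TRUE) *
      sample(c(-1L, 1L), length(rows), replace = TRUE)
    pmax(2000L, pmin(spec$chrom_length_bp - 2000L, true_rsnp$pos[rows] + d))
  }
  maf_decoy_pos <- place_near(anchor_maf)
  # override the MAF of every candidate site near a MAF decoy to [0.35, 0.5]
  for (k in seq_along(anchor_maf)) {
    near <- which(all_sites$chrom == true_rsnp$chrom[anchor_maf[k]] &
                    abs(all_sites$pos - maf_decoy_pos[k]) <=
                      10000L + 500L)
    all_sites$maf[near] <- stats::runif(length(near), 0.35, 0.5)
  }
  final_maf <- function(rows) {
    all_sites$maf[match(tr_key[rows], site_key)]
  }
  jitter_maf <- function(m) {
    pmin(0.5, pmax(spec$maf_min, m + stats::runif(length(m), -0.08, 0.08)))
  }

  gwas <- list()
  gwas$linked <- if (n_linked > 0) data.frame(
    rsid = sprintf("rs%06d", 900000L + seq_len(n_linked)),
    chrom = true_rsnp$chrom[anchor_linked],
    pos = place_near(anchor_linked),
    trait = sample(match_traits, n_linked, replace = TRUE),
    maf = jitter_maf(final_maf(anchor_linked)),
    class = "linked",
    anchor = tr_key[anchor_linked],
    stringsAsFactors = FALSE)
  gwas$trait_decoy <- if (n_trait_d > 0) data.frame(
    rsid = sprintf("rs%06d", 910000L + seq_len(n_trait_d)),
    chrom = true_rsnp$chrom[anchor_trait],
    pos = place_near(anchor_trait),
    trait = sample(nonmatch_traits, n_trait_d, replace = TRUE),
    maf = jitter_maf(final_maf(anchor_trait)),
    class = "decoy_trait",
    anchor = tr_key[anchor_trait],
    stringsAsFactors = FALSE)
  gwas$maf_decoy <- if (n_maf_d > 0) data.frame(
    rsid = sprintf("rs%06d", 920000L + seq_len(n_maf_d)),
    chrom = true_rsnp$chrom[anchor_maf],
    pos = maf_decoy_pos,
    trait = sample(match_traits, n_maf_d, replace = TRUE),
    maf = stats::runif(n_maf_d, 0.05, 0.12),
    class = "decoy_maf",
    anchor = tr_key[anchor_maf],
    stringsAsFactors = FALSE)
  # window decoys live in the het-free desert slots
  desert_slots <- (genes_per_chrom):(slots_per_chrom - 1L)
  desert <- expand.grid(chrom = chroms, slot = desert_slots,
                        off = seq(3000L, 21000L, by = 2000L),
                        stringsAsFactors = FALSE)
  desert$pos <- desert$slot * slot_bp + desert$off
  desert <- desert[seq_len(min(n_window_d, nrow(desert))), , drop = FALSE]
  if (nrow(desert) < n_window_d) {
    stop("infeasible placement: not enough desert positions for window ",
         "decoys", call. = FALSE)
  }
  if (nrow(true_rsnp)) {
    wd_anchor <- vapply(seq_len(nrow(desert)), function(k) {
      cand <- which(true_rsnp$chrom == desert$chrom[k])
      cand[which.min(abs(true_rsnp$pos[cand] - desert$pos[k]))]
    }, integer(1))
    wd_maf <- jitter_maf(final_maf(wd_anchor))
    wd_key <- tr_key[wd_anchor]
  } else {
    wd_maf <- stats::runif(nrow(desert), spec$maf_min, spec$maf_max)
    wd_key <- rep(NA_character_, nrow(desert))
  }
  gwas$window_decoy <- if (n_window_d > 0) data.frame(
    rsid = sprintf("rs%06d", 930000L + seq_len(n_window_d)),
    chrom = desert$chrom,
    pos = desert$pos,
    trait = sample(match_traits, n_window_d, replace = TRUE),
    maf = wd_maf,
    class = "decoy_window",
    anchor = wd_key,
    stringsAsFactors = FALSE)
  gwas <- do.call(rbind, gwas[!vapply(gwas, is.null, logical(1))])
  rownames(gwas) <- NULL

  ## verify the one-violation design
  signatures <- default_trait_signatures()
  trait_ok <- vapply(gwas$trait, function(tt)
    any(vapply(signatures, function(s)
      grepl(tolower(s), tolower(tt), fixed = TRUE), logical(1))), logical(1))
  stopifnot(all(trait_ok[gwas$class != "decoy_trait"]),
            !any(trait_ok[gwas$class == "decoy_trait"]))
  for (k in which(gwas$class == "decoy_window")) {
    near <- all_sites$chrom == gwas$chrom[k] &
      abs(all_sites$pos - gwas$pos[k]) <= 10000L
    if (any(near)) stop("infeasible placement: window decoy ",
                        gwas$rsid[k], " has a candidate site within 10 kb",
                        call. = FALSE)
  }
  for (k in which(gwas$class == "decoy_maf")) {
    near <- which(all_sites$chrom == gwas$chrom[k] &
                    abs(all_sites$pos - gwas$pos[k]) <= 10000L)
    if (any(abs(all_sites$maf[near] - gwas$maf[k]) <= 0.15 + 0.02)) {
      stop("infeasible placement: MAF decoy ", gwas$rsid[k],
           " nearly matches a candidate site", call. = FALSE)
    }
  }
  lk <- gwas$class == "linked"
  am <- match(gwas$anchor[lk], site_key)
  stopifnot(all(abs(true_rsnp$pos[anchor_linked] - gwas$pos[lk]) <= 10000L),
            all(abs(all_sites$maf[am] - gwas$maf[lk]) <= 0.15))

  ## ---- write files ---------------------------------------------------------
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    genes = file.path(out_dir, "genes.gtf"),
    otfrs = file.path(out_dir, "otfrs.bed"),
    repeats = file.path(out_dir, "repeats.bed"),
    variants = file.path(out_dir, "variants.vcf"),
    chip_counts = file.path(out_dir, "chip_allele_counts.tsv"),
    contacts = file.path(out_dir, "chiapet_contacts.bedpe"),
    peaks = c(file.path(out_dir, "polII_peaks_1.bed"),
              file.path(out_dir, "polII_peaks_2.bed")),
    rna_counts = file.path(out_dir, "rna_allele_counts.tsv"),
    gwas = file.path(out_dir, "gwas_catalog.tsv"),
    mafs = file.path(out_dir, "snp_mafs.tsv"),
    manifest = file.path(out_dir, "truth_manifest.json")
  )
  Biostrings::writeXStringSet(genome, paths$genome)
  write_gtf(gene, paths$genes)
  write_intervals(otfr[, c("chrom", "start", "end", "name")], paths$otfrs)
  write_intervals(repeats, paths$repeats)
  write_vcf(all_sites, indel_pos1, gene$chrom[ind_slots], genome,
            paths$variants)
  write_allele_counts(chip_counts, paths$chip_counts)
  write_contacts(contacts, paths$contacts)
  write_intervals(peaks1, paths$peaks[1])
  write_intervals(peaks2, paths$peaks[2])
  write_rna_counts(rna_counts, paths$rna_counts)
  write_gwas_catalog(gwas, paths$gwas)
  maf_tab <- data.frame(chrom = all_sites$chrom, pos = all_sites$pos,
                        rsid = all_sites$id, maf = all_sites$maf,
                        stringsAsFactors = FALSE)
  write_maf_table(maf_tab, paths$mafs)

  truth_active <- if (length(truth_active)) do.call(rbind, truth_active) else
    data.frame(chrom = character(), pos = integer(), experiment = character())
  planted <- sites[planted_idx, , drop = FALSE]
  planted$id <- all_sites$id[match(paste(planted$chrom, planted$pos),
                                   site_key)]
  planted$display_id <- ifelse(is.na(planted$id),
                               paste0(planted$chrom, ":", planted$pos),
                               planted$id)
  manifest <- list(
    spec = unclass(spec),
    n_clean_sites = nrow(sites),
    planted_asymmetric = planted[, c("chrom", "pos", "display_id",
                                     "host_gene", "is_rsnp")],
    active_experiments = truth_active,
    regulated_genes = regulated_genes,
    distal_links = if (length(loop_truth)) do.call(rbind, loop_truth) else
      data.frame(chrom = character(), pos = integer(), gene_id = character()),
    gwas_design = gwas[, c("rsid", "chrom", "pos", "trait", "maf", "class",
                           "anchor")],
    qc_decoys = qc_decoys,
    artifact_sites = artifacts
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(list(paths = paths, manifest = manifest))
}

# GTF writer for the synthetic annotation (exon/CDS/UTR features, one
# transcript per gene), via rtracklayer; the export date comment is stripped
# so that identical seeds give byte-identical files.
write_gtf <- function(gene, path) {
  feats <- list()
  for (i in seq_len(nrow(gene))) {
    gs <- gene$gs[i]
    u5 <- if (gene$strand[i] == "+") .utr5_plus else .utr5_minus
    u3 <- if (gene$strand[i] == "+") .utr3_plus else .utr3_minus
    cds <- list()
    for (k in seq_len(nrow(.exon_off))) {
      e <- .exon_off[k, ]
      seg <- c(e[1], e[2])
      # carve UTRs out of the terminal exons
      for (u in list(u5, u3)) {
        if (u[1] >= e[1] && u[2] <= e[2]) {
          seg <- if (u[1] == e[1]) c(u[2], e[2]) else c(e[1], u[1])
        }
      }
      cds[[k]] <- seg
    }
    add <- function(type, s, e) {
      data.frame(chrom = gene$chrom[i], start = gs + s + 1L, end = gs + e,
                 strand = gene$strand[i], type = type,
                 gene_id = gene$gene_id[i],
                 transcript_id = paste0(gene$gene_id[i], ".t1"),
                 stringsAsFactors = FALSE)
    }
    feats[[length(feats) + 1L]] <- do.call(rbind, c(
      lapply(seq_len(nrow(.exon_off)), function(k)
        add("exon", .exon_off[k, 1], .exon_off[k, 2])),
      lapply(cds, function(s) add("CDS", s[1], s[2])),
      list(add("five_prime_utr", u5[1], u5[2]),
           add("three_prime_utr", u3[1], u3[2]))
    ))
  }
  ft <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    ft$chrom, IRanges::IRanges(ft$start, ft$end), strand = ft$strand,
    type = ft$type, gene_id = ft$gene_id, transcript_id = ft$transcript_id,
    phase = ifelse(ft$type == "CDS", 0L, NA_integer_))
  rtracklayer::export(gr, path, format = "gtf")
  lines <- readLines(path)
  writeLines(lines[!startsWith(lines, "##date")], path)
  invisible(path)
}

# Plain-text VCF writer for the synthetic variants (SNVs plus deletion
# records whose spans feed the indel-proximity filter).
write_vcf <- function(all_sites, indel_pos1, indel_chroms, genome, path) {
  snv <- data.frame(
    chrom = all_sites$chrom, pos = all_sites$pos,
    id = ifelse(is.na(all_sites$id), ".", all_sites$id),
    ref = all_sites$ref, alt = all_sites$alt, stringsAsFactors = FALSE)
  ind <- data.frame(
    chrom = indel_chroms, pos = indel_pos1, id = ".",
    ref = vapply(seq_along(indel_pos1), function(k)
      as.character(Biostrings::extractAt(
        genome[[indel_chroms[k]]],
        IRanges::IRanges(indel_pos1[k], indel_pos1[k] + 1L))), character(1)),
    alt = NA_character_, stringsAsFactors = FALSE)
  ind$alt <- substr(ind$ref, 1, 1)
  rec <- rbind(snv, ind)
  rec <- rec[order(rec$chrom, rec$pos), ]
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(genome), ",length=",
                  Biostrings::width(genome), ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- paste(rec$chrom, rec$pos, rec$id, rec$ref, rec$alt, ".", ".", ".",
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
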