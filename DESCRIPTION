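Package: rsnpscout
Title: Regulatory SNP Discovery from Allele-Specific Binding and Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for prioritising regulatory SNPs (rSNPs) from
    allele-count evidence at heterozygous sites in ChIP-seq data.
    Heterozygous sites are called and quality-filtered, allele-specific
    binding is detected inside overlapping transcription-factor binding
    regions with an exact two-sided binomial test and reference
    mapping-bias correction via dual-genome alignment counts, target genes
    are assigned by promoter/intron/UTR membership and by ChIA-PET chromatin
    contacts tested against a random-ligation background, regulatory effect
    is confirmed by allele-specific expression at exonic marker SNPs, and
    confirmed rSNPs are linked to GWAS index SNPs for cognitive-disorder
    traits by genomic window and minor-allele-frequency matching.  A
    synthetic-data generator emits every pipeline input with a planted
    ground-truth manifest so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    methods,
    utils,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
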