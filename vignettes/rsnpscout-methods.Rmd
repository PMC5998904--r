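---
title: "Methods: detecting regulatory SNPs from allele-specific binding and expression"
author: "rsnpscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting regulatory SNPs from allele-specific binding and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnpscout)
```

## The screening problem

A heterozygous SNP inside a bound regulatory region offers a natural,
internally controlled experiment: the two alleles sit in the same nucleus,
the same chromatin environment and the same sequencing library, so a
reproducible skew of ChIP-seq reads toward one allele (allele-specific
binding, ASB) is direct evidence that the variant perturbs protein-DNA
binding.  If the genes that the variant plausibly regulates also show
skewed allelic expression (allele-specific expression, ASE) in RNA-seq,
the variant graduates to a *regulatory SNP* (rSNP).  Finally, rSNPs that
sit inside windows around GWAS index SNPs for cognitive-disorder traits,
with similar minor-allele frequencies, are candidates for the causal
variants behind those association signals.

`rsnpscout` implements this screen as a fixed funnel:

1. heterozygous-site calling and quality control from allele-count
   evidence;
2. ASB detection inside *OTFRs* (overlapping transcription-factor binding
   regions — regions bound by two or more factors, consumed as a BED
   annotation);
3. target-gene assignment, proximal (promoter/intron/UTR membership) and
   distal (ChIA-PET chromatin contacts);
4. ASE confirmation at exonic heterozygous marker SNPs;
5. GWAS linkage by genomic window and MAF similarity.

Every stage logs its removals, so the whole funnel is auditable
(`run_pipeline()$funnel`).

## Allele-count evidence and mapping-bias control

The unit of evidence is a per-site allele-count table: one row per
(ChIP experiment, alignment genome, site) holding reference- and
alternative-allele read counts.  Reads carrying the non-reference allele
map to the standard reference slightly less efficiently, inflating the
reference allele's apparent fraction.  The pipeline therefore expects
counts obtained twice: against the standard reference and against an
*alternative genome* in which every heterozygous site carries its
alternate allele (`make_alternative_reference()`).  The two alignments
bias opposite alleles by a comparable amount, so
`bias_corrected_counts()` averages them per allele (rounded half up);
the averaged reference fraction is unbiased when the loss rate of the
disfavoured allele is the same under both genomes.  `"min"` and `"sum"`
are available as alternative symmetric combinations.

## Heterozygosity QC

Sites are first filtered by location: sex chromosomes, mitochondria and
repeat-masked regions are excluded; sites within 5 bp of a region mapped
to an insertion/deletion are excluded (alignment around indels is
unreliable); *clustered* sites — those with at least two other sites
within 10 bp — are excluded, evaluated on the full input set and removed
simultaneously so that the result is order-independent.

Heterozygosity itself is then called from the counts.  A site must have
pooled coverage of at least 10 reads, at least 3 reads supporting each
allele, and evidence from at least two experiments and both alignment
genomes (a single-sample variant is indistinguishable from a somatic or
library artifact).  The balance criterion is deliberately *per sample*:
a sample is balance-consistent when the exact two-sided binomial test on
its bias-corrected counts does not reject equality at
`het_balance_alpha = 0.05`, and the site is retained when at least
`min_supporting_samples = 2` samples are balance-consistent.  The
alternative — a single test on counts pooled over all experiments —
is available (`het_balance_pooled = TRUE`) but interacts destructively
with ASB detection: pooling hundreds of reads gives the balance test
essentially perfect power against *any* truly imbalanced site, so every
genuine ASB signal would be discarded as an unreliable genotype before
the ASB stage could test it.  Under the per-sample reading, experiments
in which the variant perturbs binding are allowed to look imbalanced,
while the remaining experiments document that both alleles are present —
which is exactly the evidence heterozygosity requires.

## ASB detection

For each retained heterozygous SNP inside an OTFR and each experiment
with at least 10 bias-corrected reads, the exact two-sided binomial test
compares the corrected reference count against a null fraction of 0.5.
The two-sided p-value is the total probability of outcomes whose point
probability does not exceed that of the observed count — the convention
of `stats::binom.test`, against which the vectorised implementation is
cross-checked.  A SNP significant in at least one experiment is
*asymmetric*.

P-values are Benjamini–Hochberg adjusted across all (site, experiment)
tests and reported, but the default significance gate is the raw
p-value at `asb_alpha = 0.01`.  This is a considered choice.  With
per-experiment testing the family easily reaches 10^4–10^6 tests of
which well under 1% carry true moderate effects; the BH step-up at 1%
then has a self-defeating fixed point (the realised cutoff falls to
~10^-5 and recall collapses toward zero for effects of allele fraction
0.7 at coverage ~80).  A fixed threshold keeps power analysable in
closed form — the per-test power is an exact binomial tail sum
(`binomial_test_power()`) — at the cost of a known per-test false-positive
rate, which the funnel reports.  Gating on adjusted values is available
via `asb_use_adjusted_p = TRUE`.

Because the exact test is discrete, its achieved size is *below* the
nominal level: averaged over coverages of 50–150 the rejection
probability at nominal 0.01 is about 0.0074.  Calibration checks in the
test suite therefore compare the empirical rejection rate against the
enumerated achieved size of the test, not against the nominal level.

## Target genes

A SNP in the promoter (±1.8 kb around the TSS, inclusive, symmetric and
hence strand-invariant), an intron, or a 5'/3' UTR of a gene is assigned
that gene as a proximal target; positions only in coding exons get no
proximal target but remain usable as ASE markers.  One canonical
transcript per gene is used (the one with the greatest exonic length);
`promoter_union = TRUE` takes promoter windows around every annotated
TSS instead.  Overlapping genes may all be assigned — no uniqueness is
forced.

Distal targets come from ChIA-PET.  Contacts are first filtered: at
least 20 paired tags in total, at least 10 in each read orientation,
anchors on one chromosome and non-intersecting.  A contact matrix is
then built over ±1 kb windows around asymmetric SNPs (rows) and gene
promoters (columns), and each non-empty cell is tested against a
random-ligation background: with `T` retained intrachromosomal pairs and
an effective genome size `G_eff` (the mean merged RNA Pol II peak area
across datasets, `effective_genome_size()`), the expected count is

$$E_{ij} = 2\,T\,\frac{\ell_i}{G_{\mathrm{eff}}}\,\frac{\ell_j}{G_{\mathrm{eff}}},$$

where the factor 2 reflects the two anchor orientations a random
ligation can take.  Reliability requires the 1-df Pearson chi-squared
statistic $(O-E)^2/E$ to reject at `contact_alpha = 0.001` *and*
enrichment ($O > E$); depleted cells are never called.  Cells whose SNP
window intersects the promoter are excluded — such genes are proximal,
not distal, candidates.  Contact p-values are not multiplicity-adjusted
by default (the thresholds above already discard sparse cells);
`contact_use_adjusted_p = TRUE` switches BH adjustment on.

## ASE confirmation

Markers are heterozygous sites with RNA-seq allele counts, at least 10
RNA reads deep (pooled over RNA samples), inside the coding regions of
targeted genes; asymmetric SNPs that themselves sit in a promoter or UTR
and are expressed serve as their own markers.  A marker is *flagged*
when its allelic ratio strictly exceeds 1.5 (or is strictly below 1/1.5
— an exactly-1.5 ratio does not qualify) and the test is significant at
`ase_alpha = 0.05`.  The default test is the exact binomial against 0.5;
Fisher's exact test of the RNA counts against the site's pooled DNA
counts is available (`ase_test = "fisher"`) for designs where the DNA
counts themselves are skewed.  BH-adjusted values are always reported;
the default gate is the raw p-value, with `ase_use_adjusted_p = TRUE`
as the alternative.  An asymmetric SNP with at least one flagged marker
in at least one targeted gene becomes an rSNP.  No haplotype phasing is
attempted: any flagged marker of a targeted gene confirms the SNP, and
direction-of-effect agreement between binding and expression is visible
in the outputs but not required.

## GWAS linkage

The GWAS catalog extract is filtered to cognitive-disorder traits by
case-insensitive substring matching against twelve query signatures
(`default_trait_signatures()`).  An rSNP is linked to an index SNP when
they share a chromosome, lie within ±10 kb (inclusive), and their minor
allele frequencies differ by at most 0.15 — an absolute difference in
frequency units, since the criterion is that the two variants could
plausibly sit in one linkage group with similar population frequencies.
MAFs are inputs (a table keyed by position); no live annotation lookup
is performed.  The report grain is one row per (rSNP, targeted gene,
index, trait); deduplicated summaries count unique rSNP identifiers and
unique target genes.  Unannotated variants are displayed as `chrN:pos`.

## The synthetic study

`simulate_bundle()` emits every input the pipeline consumes, with a
ground-truth manifest.  The defaults define the study conditions: two
1 Mb chromosomes tiled into 30 kb slots, 60 five-exon genes of
alternating strand, five OTFRs per gene (promoter, two intronic, two
intergenic), and 2,000 heterozygous sites on a 30 bp grid, 85% inside
OTFRs.  Five percent of sites carry a planted binding effect at allele
fraction 0.7.  Twelve ChIP experiments are simulated; each site is
covered by six of them and a planted effect manifests in three — in the
remaining covering experiments the site is balanced, which is what lets
it pass the per-sample heterozygosity QC, mirroring how a real
TF-specific effect appears against a background of other ChIP tracks.
The covering/active counts were chosen so that per-site recovery power
is high (~0.95); at lower power the binomial noise of ~80 planted rSNPs
would swamp a ±5-percentage-point comparison between observed and
predicted recovery.

Coverage is negative-binomially dispersed (mean 80, dispersion 0.2) —
real pileup depth is overdispersed, and the dispersion materially lowers
per-experiment power, which the closed-form prediction must track.
Mapping bias is generated mechanistically: reads carrying the
disfavoured allele are lost at rate $\lambda = 4\delta/(1+2\delta)$
under each alignment genome, producing a ±6% fraction shift of opposite
sign under the two alignments at a balanced site, which averaging
cancels.  RNA markers (two per gene, in CDS) are drawn at fraction 0.7
for regulated genes, 0.5 otherwise, at negative-binomial depth of mean
200 with modest dispersion — markers are by construction restricted to
well-expressed exons, and at this depth the ratio gate rather than the
p-value gate is the operative ASE criterion, keeping the null flag rate
low.  Eighty percent of planted-SNP host genes carry the expression
effect; their planted SNPs are the *true rSNPs*.  Forty ChIA-PET loops
connect true-rSNP windows to distal regulated promoters with balanced
orientations; 500 random-ligation noise records (1–3 pairs each) and a
few structured rejects (direction-skewed, interchromosomal,
self-intersecting) exercise the contact filters.

The GWAS catalog mixes 15 genuine indexes — placed within 9 kb of a true
rSNP, MAF within 0.10, trait drawn from the signature list — with
decoys, each violating exactly one linkage criterion *by construction*:
trait decoys carry non-matching traits; window decoys sit in reserved
het-free desert slots more than 10 kb from every candidate site; MAF
decoys sit near a true rSNP whose neighbourhood MAFs are all forced at
least 0.2 away from the decoy's.  The generator asserts all three
properties and fails rather than emit an ambiguous design, so decoy
absence from the final report is a structural guarantee, robust even to
the occasional false-positive rSNP.

QC fodder (chrX sites, repeat-masked sites, indel-adjacent sites,
clustered triplets, low-coverage sites) and ~2% near-homozygous
artifact sites (allele fraction 0.97) are added so that every filter
removes something and the manifest records why.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure, read-level errors and duplicates, motif-dependent
binding effects, isoform complexity, correlated experiments, and
population variation in MAF.  Passing the recovery tests therefore
demonstrates that the statistical machinery is correct under the model's
assumptions, not that those assumptions hold in any particular real
dataset.

## Closed-form recovery prediction

`predict_planted_recovery()` computes, per true rSNP, the probability
that the pipeline recovers it, as a product of exact binomial tail sums
conditioned on the realised per-experiment read totals: heterozygosity
support is a Poisson-binomial event over per-sample balance-consistency
probabilities; ASB detection is one minus the product of per-experiment
miss probabilities; ASE confirmation is the analogous any-marker,
any-gene event using `ase_flag_power()`.  No simulation is involved, so
agreement between observed and predicted recovery (within binomial
noise) is a genuine two-route check of the implementation.  The
prediction assumes the default raw-p ASB gate; under a BH-adjusted gate
the threshold becomes data-dependent and no fixed closed form exists.

## Numerical conventions and degenerate inputs

* Coordinates: 1-based positions for point variants (VCF convention),
  0-based half-open intervals (BED convention); a position `pos` is in
  `[start, end)` iff `start <= pos - 1 < end`.
* All interval boundaries and distance thresholds are inclusive
  (`<=`); the ASE ratio gate is strict (`>`).
* Averaged counts round half *up* (`round()` would round half to even
  and is avoided).
* `alt_count = 0` gives an infinite allelic ratio, which is
  ratio-eligible; the p-value is computed normally.
* Empty inputs flow through: an empty variant set yields an empty
  report with a zeroed funnel; empty p-value vectors adjust to empty
  vectors.
* The exact binomial test is conservative on discrete supports; its
  achieved size at nominal 0.01 is ~0.0066–0.0100 depending on `n`.
* With a fixed `rng_seed`, `simulate_bundle()` is byte-deterministic,
  and `run_pipeline()` is deterministic given its inputs.

## Problem sizes in the test suite

The test suite runs the full default study (2,000 sites, 12
experiments, ~25,000 count rows) once and shares it across tests;
calibration checks use 20,000 null sites; oracle-equivalence checks use
hundreds of random instances of up to 150 sites; the recovery check
scores ~80 planted rSNPs against the closed-form prediction.  These
sizes keep each property estimable with comfortable margins while the
whole suite completes in a few minutes.

## Known limitations

* The beta-binomial overdispersion of real ChIP allele counts is not
  modelled; sites with replicate-level variability beyond binomial will
  be over-called.  A beta-binomial ASB test is a natural extension.
* Linkage to GWAS indexes by window + MAF is a proxy; it neither
  computes LD from a reference panel nor fine-maps.
* One canonical transcript per gene; isoform-specific regulation is
  invisible.
* The Fisher ASE variant conditions on pooled DNA counts; if DNA counts
  are themselves biased the comparison inherits that bias.
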