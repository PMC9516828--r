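---
title: "Detecting false duplications in genome assemblies"
author: "falsedup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting false duplications in genome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A haploid assembly of a diploid genome should contain one copy of every
locus. Two failure modes violate this. When a locus is heterozygous enough,
an assembler may fail to collapse the two haplotypes and keep both — either
spliced into one scaffold behind an N gap or as a separate, typically small,
scaffold. We call these **heterotype** duplications: both copies are real
haplotype sequence, and each carries k-mers private to one haplotype.
Second, reads carrying sequencing errors can fail to align to their true
locus and be assembled into a spurious extra copy; these **homotype**
duplications carry excess base errors and attract almost no reads when the
read set is mapped back. Both inflate assembly size and, more damagingly,
annotation: duplicated genes are reported as gene gains, duplicated exons
corrupt gene models, and family expansions are overstated.

`falsedup` detects such duplications from the assembly and its read set,
confirms them with read-depth and read-pair evidence, classifies them as
heterotype or homotype, quantifies their effect on annotation, and measures
the heterozygosity and sequence-error signatures that distinguish them from
correctly assembled sequence. A seeded diploid-genome simulator with ground
truth makes every stage testable end to end.

## Detection model

**Candidates** come from two independent sources and their union set:

* *Cross-assembly*: alignment blocks between the assembly under test and a
  second assembly of the same individual or species. A reference interval
  covered by two or more distinct query intervals (one-to-many homology) is
  a candidate: each unordered pair of query projections of the
  multiply-covered region becomes a candidate pair. Blocks shorter than
  20 bp, or whose chained query interval is covered by alignment for less
  than 80% of its length, are discarded first (both strict inequalities).
* *Self-alignment*: the assembly is segmented at N gaps and aligned to
  itself (hits of a contig to itself excluded); homologous interval pairs
  where at least one member's mean read depth is below the half-diploid
  cutoff are candidates.

Pairs from the two sources whose members reciprocally overlap by at least
50% are merged (interval union). The built-in aligner is a deliberate
desk-scale design: exact shared 31-mers chained on a common (anti)diagonal,
with chains of at least 500 bp and anchor-density-estimated identity of at
least 0.90 becoming blocks. It assumes substitution-only divergence, which
is exactly what the simulator produces and a good approximation for
haplotype copies; for real data with indels, precomputed PAF from a
whole-genome aligner can be supplied instead and flows through the same
interfaces.

**Evidence.** Three signals confirm a candidate:

1. *Near-haploid depth*: mean coverage of a member strictly below half the
   diploid depth, where the diploid depth is the modal depth of the
   assembly-wide coverage histogram above the sequencing-error depth
   (smallest depth among tied bins, for determinism).
2. *Gap evidence*: an N gap between the two copies of a same-scaffold pair,
   or a depth gap — at least one position with zero coverage between them.
   Different-scaffold pairs have no "between"; for them the same signals
   are sought within 550 bp of the duplication-facing contig end.
3. *Discordant pairs*: a read pair is discordant when its outer insert
   exceeds 550 bp (the mean insert of the linked reads this method was
   built around) or its mates map to different scaffolds. Evidence requires
   a single 550 bp flanking window to anchor one mate of a discordant pair
   whose other mate lies in the partner copy, and one mate of a concordant
   pair whose other mate lies in the local copy.

The default policy confirms a pair when it is low-depth **and** shows at
least one of the other signals. Depth is mandatory because it is the one
criterion that applies to every candidate and is what separates false
duplications from true segmental duplications, which sit at full diploid
depth; the required count of supporting signals is configurable.

**Depth and mapping qualities.** A read that maps equally well to both
copies of a duplication carries no information about which copy it belongs
to; the mapper assigns it uniformly at random (reproducibly under the
seed) and records it with mapping quality 0, and `compute_depth()` excludes
MAPQ < 1 records, as read-depth analyses built on standard mappers
conventionally do. This matters more than it may look: if ambiguous reads
are split between copies instead, each copy of a heterotype duplication
sits at *exactly* half the diploid depth and the strict "below half" rule
becomes a coin flip against sampling noise. Excluding them puts false
copies at ~0.45–0.48 of the diploid mode — the "near-haploid" signature —
with a stable margin, while unique sequence is untouched. Duplicate-flagged
pairs are likewise excluded from depth and discordance.

## K-mer classification

Canonical k-mers (default k = 20, exact hash counting; the 2-bit encoding
caps k at 26) are counted in the assembly and in the reads. An assembly
k-mer with read multiplicity strictly below the error threshold is
**erroneous**; a non-erroneous k-mer found once in the assembly is
**single-copy**; the rest are **multi-copy**. The error-multiplicity and
heterotype-depth thresholds are dataset properties; presets carry the
published values for the zebra finch, hummingbird and platypus assemblies
(erroneous: 6/3/18 for the previous assemblies, 3/3/10 for the VGP ones;
heterotype minimum depth: 5/8/22 and 2/2/9). A confirmed pair is
**heterotype** when both members contain at least one single-copy k-mer
(k-mers fully inside the interval only) and both have mean read depth above
the heterotype minimum; otherwise **homotype**. Whether "average read
depth" should be taken over the whole interval or only over single-copy
k-mer positions is not externally fixed; the whole interval is used, which
is simpler and, at these interval sizes, almost identical.

The **k-mer duplication proportion** summarises duplication load without
calling intervals: for each non-erroneous assembly k-mer the reads imply
`round(multiplicity / haploid_peak)` copies (clamped to ≥ 1), where the
haploid peak is the primary peak of the read k-mer spectrum — the
multiplicity of sequence present once in the assembly. The proportion is
the summed excess of assembly copies over implied copies, relative to all
assembly k-mer instances. This expected-copies formula is the package's
own defined surrogate for spectrum-based duplication counting and is
labelled as such in the output.

## Annotation impact

Only the longest-CDS isoform of each gene is considered (ties broken by
isoform id). A gene qualifies for a call only when at least one coding exon
is completely contained in a confirmed duplication interval. Calls are
exclusive, with precedence by severity: **FGG** (false gene gain) when more
than 50% of the CDS length is duplicated; otherwise **FCG** (false chimeric
gain) when a completely duplicated exon's homologous partner interval lies
within a different gene's CDS span; otherwise **FEG** (false exon gain).
Exon partners landing in unannotated sequence are FEG — the chimeric label
is reserved for insertions into another gene (configurable via the
partner-containment fraction, default 0.5). Repeat elements count as
affected on any (≥ 1 bp) overlap; the complete-exon rule is specific to
genes. The "-like" scaffold screen flags small scaffolds mostly occupied
(> 50%) by a gene whose product name is an existing gene's name plus
"-like" and that align almost entirely (≥ 90%) into the original gene's
locus, optionally requiring sub-half-diploid depth.

## Statistics

The internal variant caller is a plain pileup: a site needs `min_depth`
(default 10) coverage, at least two alleles at ≥ 10% of the depth (stray
error reads below that are not part of the genotype), and every considered
allele fraction strictly between 0.25 and 0.75 — the allele-balance filter
that removes cross-duplication mismapping artefacts. Heterozygosity is
variant sites per bp. Real-data users supply a VCF; only the balance filter
is applied then.

Heterozygosity of a confirmed duplication cannot be measured in place: the
reads of the two haplotypes split between the copies, so duplicated regions
look variant-free. One member of each pair (the one without annotation,
else the lower-depth one) is therefore masked to N, the reads are remapped,
and variants are recalled over the surviving member — restoring diploid
depth and exposing the haplotype difference as heterozygous calls.

Bootstrap comparisons tile the region sets into 1 kbp units, resample units
with replacement (1000 replicates by default), recompute the metric per
replicate, and apply a two-sided Student's t-test between the two
replicate distributions. Treating replicates as independent samples makes
the test anti-conservative by construction; it is reproduced in that form
deliberately and should be read as a descriptive contrast, not a calibrated
test. Partition enrichment reports, per genomic partition (CDS, intron,
intergenic — intergenic being everything that is neither), the observed
share of duplication bases against the partition's share of the assembly;
a one-way ANOVA across partitions is run on bootstrap replicates of
(observed − expected), which is this package's own construction of the
test and is flagged as such in the output. Correction between assembly
versions uses `uncorrected = sum_H_new − (sum_H_old − FD)` over homologous
block lengths, with `uncorrected ≤ 0` meaning corrected.

## The simulator

`sim_config()` defaults encode the benchmark study conditions: a 5 Mbp
diploid genome over 5 scaffolds, background SNP heterozygosity 1% with
1.8× hotspots, 15 same-scaffold (gap-separated) and 15 different-scaffold
heterotype duplications plus 10 homotype duplications with 2% injected
substitutions, lengths 5–50 kbp; 60× diploid coverage of 150 bp pairs with
550 ± 100 bp inserts and 0.1% base error. On one CPU the full simulation
plus scan takes a few minutes.

Two generator choices deserve explanation:

* *Hotspots are the duplication-prone regions.* The mechanism that creates
  heterotype duplications is elevated local heterozygosity, so the
  generator draws the duplication source regions first and designates a
  bp-stratified 80% of duplicated bases as 1.8× hotspots (margin 500 bp).
  Stratifying by bases rather than flipping a coin per duplication keeps
  the realized hotspot share at its nominal value, and sizing hotspots to
  the duplications keeps the background at ~1× so the elevation of
  duplicated regions (~1.6×) is a stable, recoverable signal rather than
  a noisy one.
* *True segmental duplications are diverged.* The rejection control
  injects duplications present in both haplotypes at full depth. Real
  segmental duplications are diverged between loci, so the copies carry 1%
  substitutions (identical across haplotypes); reads then map uniquely and
  the copies sit at full diploid depth, which is precisely the property
  that the depth criterion uses to leave them alone. Byte-identical copies
  would instead have all-ambiguous reads — a degenerate case no real SD
  exhibits.

What the simulator does **not** emulate: linked-read barcodes (reads are
plain pairs; barcode-aware mapping would depress false-copy depth even
further), indels (substitution-only divergence and errors), repeat
families, GC or coverage bias, and assembly-pipeline artefacts beyond the
three duplication mechanisms. Passing the bundled checks therefore
demonstrates that the statistical machinery recovers the modelled signals
at realistic magnitudes; it does not certify performance on real assemblies
with indel-rich divergence or biased coverage, where the PAF/SAM/VCF input
paths and the configurable thresholds are the intended route.

## Numerical choices

* Internal coordinates are 0-based half-open everywhere; GFF3/VCF/SAM are
  converted at the boundary. Abutting intervals do not overlap.
* All boundary filters are strict: a 20 bp block and an exactly-80%
  covered interval survive; depth exactly at half-diploid is not flagged;
  insert exactly 550 bp is concordant.
* The depth histogram mode takes the smallest depth among tied bins; the
  haploid threshold is mode/2, or mean × 0.75 in Sanger mode (unimodal
  ~1× data).
* Mapper ties are broken uniformly at random under an explicit seed; every
  stochastic stage derives its own sub-seed, so whole-pipeline runs are
  bit-reproducible.
* Chains merge only when both sequences advance by at most the join
  distance (bounded diagonal drift); this is what keeps cross-assembly
  projections exact around insertion breakpoints.
* Degenerate inputs fail loudly: all-zero depth histograms, empty
  duplication sets for partition enrichment, regions shorter than k,
  fewer than two bootstrap tiles.

## Problem sizes used by the checks

The bundled test suite runs the full 5 Mbp default simulation once and
reuses it; calibration properties (true-duplication rejection, partition
neutrality) use ten 1 Mbp simulations with uniformly placed duplications;
k-mer sweep properties use 0.8 Mbp genomes. These sizes were chosen so the
whole suite exercises every stage at realistic coverage in minutes on a
single CPU while keeping binomial/bootstrap noise well inside the asserted
bands.

## Known limitations

* The anchor aligner does not model indels; supply external PAF for
  indel-rich data.
* The discordance test uses plain read pairs; barcode/molecule-level
  evidence is out of scope.
* The bootstrap t-test inherits the anti-conservative construction noted
  above.
* Exact k-mer counting holds whole hash tables in memory — ample for
  desk-scale genomes (≤ ~50 Mbp with 60× reads in a few GB), not for
  multi-gigabase assemblies.
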