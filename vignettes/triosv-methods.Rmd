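---
title: "Models and methods behind triosv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind triosv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`triosv` implements the analysis stages of a trio-based long-read
sequencing (LRS) study of structural variants (SVs) and single
nucleotide variants (SNVs): call-set matching between technologies,
Mendelian inheritance error (MIE) quantification, de novo candidate
filtering with evidence-based classification, gene-level recessive
candidate detection, cross-technology coverage partitioning, and
coverage-titration precision/recall. A seeded cohort simulator provides
ground truth for every stage. This vignette documents the models, the
parameters that matter, and the design decisions taken where the design
was genuinely open.

## Data model

SVs are deletions, insertions and inversions of at least 50 bp, the
conventional lower bound separating SVs from indels in long-read
calling. A call set (`sv_set`, `snv_set`) couples a site table with
per-sample genotype, depth (DP) and allele-support (AD) matrices, the
shape of a joint-called multi-sample VCF. All coordinates at the API
surface are 0-based half-open (BED convention); the 1-based VCF `POS`
and the 1-based closed `GRanges` used internally for interval algebra
are converted at the boundary. An insertion occupies a zero-length
reference anchor (`end == start`); wherever a footprint is required
(gene assignment, overlap queries) an insertion is treated as the 1 bp
point at its anchor, because it has no reference footprint to
intersect. Genotypes are unphased throughout, matching the callers this
pipeline models; a phased separator on input is accepted and ignored.

Region sets are reduced `GRanges` objects. Book-ended intervals are
merged (as `bedtools merge` does), so `[0,100)` plus `[100,200)` is one
200 bp interval; this matters when zero-coverage regions are assembled
from window-level tracks.

## SV call-set matching

Two SVs match when they are of the same type, their start coordinates
and end coordinates each differ by at most `refdist` (default 1000 bp),
and the smaller/larger size ratio is at least `size_ratio_min` (default
0.7). All three thresholds are inclusive, reading "at least"/"within"
inclusively. Records outside `[sizemin, sizemax]` (defaults 50 bp and
1 Mb) are removed before matching. Sequence similarity is never
computed: the call sets this models are not sequence-resolved.

`match_callsets()` assigns matches greedily 1:1, nearest first:
candidate pairs are ordered by start-coordinate distance, then by the
deviation of the size ratio from 1, then by input order. The greedy
assignment is deterministic and, on call sets whose clusters are
separated by more than twice `refdist`, provably attains the maximum
matching; the test suite verifies equality with an exhaustive
maximum-bipartite-matching oracle on 500 random cluster-separated
instances. On adversarial overlapping clusters greedy can in principle
fall short of the maximum; the greedy result is the contract. With
`multimatch = TRUE` (the titration default) a record may participate in
several pairs; recall then counts base records with at least one match
and precision counts comparison records with at least one match, each
once. Precision and recall are reported as `NA`, not 0, when their
denominator is empty.

Comparison against interval-only external SV sets
(`reciprocal_overlap_compare()`) uses 50% reciprocal overlap for
deletions and inversions. Insertions cannot reciprocally overlap a
zero-width anchor, so an insertion matches when an external insertion
interval starts within `refdist` of its anchor and the width ratio
meets the same fraction — a pragmatic extension documented here because
interval-based external comparisons do not define insertion handling.

## Mendelian inheritance

A trio genotype is consistent when the child's two alleles can be
partitioned so that one is carried by the father and the other by the
mother. Sites with any missing genotype are excluded from the
denominator (mirroring the behaviour of the standard `bcftools
+mendelian` workflow); the MIE rate is violations over fully genotyped
sites. De novo variants are violations under this definition; at
genome scale their contribution to the rate is negligible, and the
simulator's truth ledger lets tests account for them exactly. The
autosome filter accepts `chr1`–`chr22` naming with or without the
`chr` prefix.

A variant is *unique* to a sample when that sample carries a
non-reference genotype and every other sample is homozygous reference;
a missing genotype in any other sample disqualifies the site, because
missingness cannot certify absence.

## De novo filtering and classification

The de novo SV filter applies five criteria, all of which must hold:
the proband is heterozygous; the proband's alternative-read ratio lies
in `[0.3, 0.7]` (inclusive — "between" is read inclusively); every
cohort sample has depth at least 6 reads at the site; every other
cohort sample is homozygous reference; and no other sample has any
alternative-supporting read. "All samples" means the full joint-called
cohort when one is supplied, otherwise the trio. Records with missing
genotypes or read support at otherwise-passing sites are excluded with
a logged reason.

De novo SNV candidates are Mendelian-violating sites that are
loss-of-function (any quality) or missense with quality at least 30
(inclusive — a "cutoff of 30" retains 30).

`classify_candidate()` is a programmatic stand-in for the manual
re-inspection of candidate alignments: a candidate is *inherited* when
either parent shows any alternative-read support (one read suffices —
the call was likely dropped in that parent), *false positive* when the
proband's own evidence is substandard, and *putative de novo*
otherwise. The relaxed proband band `[0.2, 0.8]` and the depth floor
used here widen the strict filter bounds deliberately: the strict
filter selects candidates, the classifier asks whether the raw
evidence still supports them. The band is an implementation choice
standing in for visual inspection, which has no published threshold.

## Recessive candidates

Per gene and proband, three mechanisms are emitted: homozygous coding
SV, homozygous loss-of-function SNV, and compound heterozygous coding
SV plus LoF SNV. The LoF quality rule here is *strictly* greater than
30 ("higher than 30"), intentionally different from the inclusive de
novo missense cutoff. Parental origin is inferred from trio genotypes
when exactly one parent carries the allele; compound het pairs whose
two origins are provably identical (cis) are suppressed unless
`phase = FALSE`, which restores naive pairing for comparability with
analyses that did not phase. Origin inference from unphased trio
genotypes is an added strictness, not a full phasing.

## Coverage accessibility and GC comparison

`partition_coverage()` classifies every base of the genome by coverage
presence in two tracks into four disjoint sets — covered by both, by
LRS only, by SRS only, or by neither — whose lengths always sum to the
genome length (property-tested on random tracks). "Covered" defaults
to depth ≥ 1, because the sets are defined by absence of coverage; a
`min_depth` option allows stricter definitions. Intervals shorter than
`min_report_length` (default 1000 bp) remain part of the partition but
are flagged sub-threshold in the summary, so totals are reported both
with and without the length filter. Mapping-quality filtering (the
mapq ≥ 10 convention) happens when tracks are built from alignments,
upstream of this package; the `mapq_floor` field is metadata.

Fold-coverage summaries report the fraction of the genome at or above
each threshold twice: over the easily accessible genome (everything
outside the supplied difficult regions — assembly gaps, centromeres,
telomeres — with chrY appended automatically for cross-sex
comparability) and over the whole genome.

A gene is *poorly covered* when at least 10% of its length (inclusive)
has zero short-read depth. `gc_comparison()` then draws one
length-matched control per poorly covered gene — the nearest-length
unused well-covered gene within a ±20% relative window, widened with a
warning when empty — and compares GC fractions with Welch's two-sample
t-test. The ±20% window operationalizes "comparable length", which has
no standard definition; the seeded draw makes the control set
reproducible.

## Coverage titration

`titration_curve()` compares the call set at each reduced coverage to
the full-coverage call set as truth, with multimatch on, events of
50 bp–1 Mb, and `refdist` 1000 — the conventional settings for
titration comparisons. Subsampling operates on call sets produced by
the simulator's detection model, not on reads: read-level subsampling
is out of scope and the contract is the precision/recall computation.

## The simulator

`simulate_trio_cohort()` generates a joint-called cohort of five trios
(samples `T1P/T1F/T1M`, ...) on three 10 Mb contigs. The genome is
desk-scaled: contract verification needs the statistical structure,
not the size, of a human genome, and the full default cohort (5,000 SV
sites, 50,000 SNV sites) simulates in seconds. The acceptance tests
run at exactly this scale.

**SV sites.** Types are drawn with weights 63% insertion, 37% deletion
and 0.05% inversion, the spectrum reported for long-read trio cohorts.
Sizes follow a truncated power law (decay exponent 1.2) plus
point-mass peaks at 300 bp (weight 0.12; Alu) and 6.4 kb (weight 0.03;
LINE1), within per-type bounds of 50–5,000 bp for insertions,
50–100,000 bp for deletions and 200–5,000 bp for inversions — the
effective size ranges of long-read SV discovery. Deletion and
inversion footprints never overlap; placement collisions are retried
up to ten rounds and then skipped with a warning and a ledger record.

**Genotypes.** Each site in the founder pool is carried by each founder
independently with probability 0.35 and is homozygous in a carrier
with probability 0.2 — a simple exchangeable allele-frequency model
that gives every variant a chance of being shared across trios, which
the proband-unique counting and the "absent from all other samples"
de novo criteria need. Children receive one allele from each parent,
drawn uniformly and independently per site; linkage is not modelled
because no downstream statistic depends on it. De novo SVs are drawn
Poisson(0.2) per child — the established de novo rate for large copy
number events, the only SV class with a well-measured rate — placed as
fresh sites heterozygous in that child only.

**Errors.** Two processes corrupt called genotypes after transmission:
a genotype error replaces a call with one of the other two diploid
genotypes (uniformly) at rate `genotype_error_rate`, in any sample;
parental dropout converts a true heterozygous *parental* call to
homozygous reference at rate `parental_dropout_rate` while the
simulated reads keep supporting the variant — exactly the mechanism
that turns an inherited variant into an apparent de novo call in the
child. Both processes are recorded per event in the truth ledger.

**Read support.** Depth per sample and site is Poisson(coverage);
alternative reads are Binomial(depth, p) with p = 0, 0.5, 1 for
hom-ref, het and hom-alt true genotypes (no allelic bias by default;
`het_alt_read_prob` is the knob). A variant is detected when at least
`min_supporting_reads` (default 3) alternative reads are drawn, which
makes recall at coverage c analytically tractable: for a heterozygous
site the alternative-read count is a thinned Poisson(c/2), and the
acceptance tests check observed titration recall against this closed
form within three binomial standard errors.

**Emission.** The emitted VCF contains the sites with at least one
non-reference *called* genotype, as a joint caller would output. The
ledger keeps all sites, true and called genotype matrices, error
events and emission flags, so tests can compute exact expectations.
Because an all-homozygous-reference trio is always Mendelian
consistent, every violation occurs at an emitted site, which keeps the
expected violation count independent of the emission filter — the
acceptance suite exploits this.

**SNVs.** Substitutions are placed uniformly (duplicate positions
dropped), transitions drawn with probability 2.1/3.1 to hit the
expected whole-genome Ti/Tv of 2.1, functional classes with
probabilities 0.90/0.04/0.04/0.01/0.01 for
noncoding/synonymous/missense/LoF/other, and quality scores from a
normal(50, 20) truncated below at 1 so that quality thresholds at 30
have both sides populated.

**Coverage tracks.** Long-read depth is Poisson(coverage) per 1 kb
window. Short-read depth is Poisson with mean scaled by
`exp(-gc_bias_strength * max(0, gc - 0.5))` and drops to zero with
probability proportional to the GC excess above `gc_knee` (default
0.55), reproducing the empirical pattern that genes poorly covered by
short reads are GC-rich while long-read coverage stays uniform. Window
GC is the overlapping gene's GC fraction where a gene model overlaps
and background noise around 0.45 elsewhere.

**Reproducibility.** One global seed feeds fixed named substreams per
stage (site placement, genotypes, de novo events, errors, reads,
tracks, genes), so changing one stage's draw does not perturb the
others, and the same seed yields byte-identical VCF output.

## What the simulator does and does not show

Passing tests on simulated cohorts demonstrate that the filters,
matchers and summaries compute what they claim on data with the
assumed statistical structure: independent sites, Poisson depth,
unbiased allele sampling, genotype errors independent of genomic
context. Real long-read data violate several of these assumptions —
errors cluster in repeats, depth is not Poisson, SV breakpoints are
imprecise in caller-specific ways, and the SV size spectrum is richer
than a power law with two peaks. Results on simulation therefore
validate the *implementation*, not the field performance of the
filters. The numbers the acceptance script reports (MIE rates under
injected error, titration recall, GC contrast) are properties of the
simulator's generative model, scaled down; they are not reproductions
of any study's empirical values, which derive from ~15–40× human
whole-genome data.

## Numerical and degenerate-input choices

Ratios with zero denominators are reported as `NA`, never 0: MIE rate
with no evaluable site, precision with no comparison call, Ti/Tv with
no transversion. The proband read ratio uses `max(depth, 1)` to avoid
0/0 and a zero-depth proband fails the depth criterion anyway.
Matching tie-breaks are fully specified (distance, ratio deviation,
input order) so results are reproducible across platforms. Derived
stage seeds stay below 2^31 − 1. The control draw in `gc_comparison`
restores the caller's RNG state on exit.

## Known limitations

Only deletions, insertions and inversions are modelled; duplications
and translocations are out of scope, as are SNV–SNV compound
heterozygotes (the recessive analysis pairs SVs with SNVs and reports
homozygous events). X-chromosome inheritance is not modelled; the MIE
machinery is autosomal. Breakpoint uncertainty is not simulated: the
simulator's calls have exact coordinates, so matching tests exercise
the rules, not coordinate jitter robustness. Functional classes are
assigned independently of gene overlap in the simulator, which is
adequate for threshold tests but not a model of coding impact.
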