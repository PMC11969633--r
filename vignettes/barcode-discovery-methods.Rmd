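---
title: "Discovering intraspecific barcode loci and quantifying strains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering intraspecific barcode loci and quantifying strains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainbarcode)
```

## The problem

A panel of clonal strains of one species — say diatom isolates kept in
culture — is to be tracked through a mixed-population experiment by
amplicon sequencing of a single locus.  That locus must satisfy three
conditions at once: it must be short enough to amplify and sequence; it
must be variable enough that every strain is distinguishable; and it must
sit between conserved flanks so a single primer pair works across all
genotypes.  `strainbarcode` searches a reference genome plus per-strain
variant calls for such loci, and then uses the resulting allele catalogue
to convert amplicon-sequence-variant (ASV) counts back into relative
strain abundances.

The package operates downstream of read mapping, variant calling and
(for diploids) phasing: its inputs are a reference FASTA, one phased VCF
per strain, and one per-base depth table per strain (the three-column
`samtools depth` dialect).  ASV inference (merging, denoising, chimera
filtering) is likewise upstream of the quantifier, which consumes any
`sample / sequence / count` table.

## Coordinates

All internal coordinates are 0-based half-open, the BED convention.  VCF
and depth tables are 1-based and converted at the boundary; BED output is
written without conversion.  A single convention throughout eliminates
off-by-one drift between modules.

## Coverage masking

For each strain and contig the median depth $m$ is computed over **all**
positions, zeros included — the reference defines the positional
universe, which makes the median deterministic and robust to unmapped
tails.  For contigs with an even position count the median is the mean of
the central pair and may be fractional; since depths are integers and the
bounds are $m/2$ and $2m$, all threshold comparisons are exact in double
arithmetic.  A position is masked iff its depth is *strictly* below 50 %
or *strictly* above 200 % of $m$; values exactly at the boundary are kept,
reading the bounds literally as "less than" and "more than".  A contig
whose median is zero is masked entirely, with a warning: no position can
be called conforming against a zero baseline.

Masks are unioned across strains before window exclusion: a region
unusable in any one strain cannot host a barcode that must amplify in
every strain.  (Whether one should union or intersect is genuinely open;
union is the conservative choice and the per-strain masks are retained
for reporting.)

## The window screen

With window width $W$ and primer width $P$ (defaults 500 and 21,
matching the diploid use case; $W = 300$ suits shorter amplicons for
haploid panels), a window starting at $s$ survives iff

* flanks $[s, s+P)$ and $[s+W-P, s+W)$ contain no flank-blocking
  position, and
* the interior $[s+P, s+W-P)$ contains at least one SNP.

SNP positions always block flanks.  By default indel-affected reference
positions block them too (`flank_block = "snps+indels"`): an indel under
a primer destroys the binding site just as surely as a SNP.  This is
deliberately stricter than a SNP-only reading; `flank_block = "snps"`
restores the laxer behaviour.  Interior variability, by contrast,
requires a SNP — an indel-only interior does not qualify, keeping the
screen SNP-centric.

The step size is fixed at 1.  The implementation answers the two range
queries per start from sorted position vectors (`findInterval`), but its
contract is equality with the naive per-start enumeration, and a
brute-force oracle enforces exactly that over hundreds of random panels
in the test suite.

Overlapping surviving windows are merged transitively into maximal loci
(`[min start, max end)`).  Touching-but-not-overlapping windows stay
separate.  Merged loci may exceed $W$; no maximum length is imposed.  The
merged locus keeps conserved flanks by construction — its left flank is
the first member window's left flank, its right the last member's right.

A merged locus is then discarded if it overlaps **any single** masked
interval by ten or more bases.  The per-interval (rather than summed)
reading reflects that each masked run is one coverage anomaly; short
(< 10 bp) overlaps are tolerated because they frequently mark small,
genuinely informative indels.

## Allele cataloguing

For every surviving locus, each strain haplotype's consensus is computed
by applying its variants to the reference slice right-to-left (so
coordinates stay valid through indels).  Exact string identity over the
whole locus defines an allele — deliberately so, since amplicon
sequencing resolves exactly that.  An allele is *strain-specific* iff
its carrier set is one strain; a homozygote for a unique sequence still
counts one specific allele.  A locus is *universal* — and only then
reported — iff every strain has at least one specific allele.

Heterozygosity of a locus is the fraction of strains whose haplotype
sequences differ; haploid panels report 0 by convention and their single
haplotype enters universality directly.  Two guard rails: a deletion
straddling a locus boundary makes the consensus ill-defined, so such
loci are disqualified with a warning; and strains whose VCFs showed more
called alleles than their ploidy (a triploid signal) are catalogued but
excluded from the universality decision.

## Quantification

ASVs are matched to the allele database by exact full-length string
equality — anything else is an artefact and is reported as unmatched
(real datasets can see large unmatched fractions from chimeras and
unmerged reads, so this tally is a first-class output).  Counts of
strain-specific alleles ($a_2$) are assigned directly.  A shared
allele's count $S$ is split among its $k$ carriers proportionally to
each carrier's summed specific counts:

$$a_1 = S \cdot \frac{a_2}{a_2 + b_2 + \dots + n_2}.$$

The weights sum over *all* of a strain's specific alleles, since a
heterozygote can have two.  If every carrier has zero specific counts
the split is even ($S/k$) and flagged `zero_specific_tie` so downstream
users can drop those strains — the even split is a declared fallback,
not a principled estimate.  Relative abundance divides each strain's
$a_1 + a_2$ by the total over all alleles of all strains (the global
total, following the verbal definition of the denominator rather than
the two-strain symbol list).

Strains carrying more than two alleles contribute only their two
highest-count alleles, ties broken lexicographically by sequence for
determinism, and are flagged `polyploid_extra_allele`.  No copy-number
correction is applied to homozygotes' double gene dosage; dosage effects
are left visible rather than silently rescaled.

For diploid strains with two observed alleles the minor-allele fraction
is checked against a default threshold of 0.35: ratios near 1:1 are
expected, while ratios nearer 1:3 (fraction 0.25) suggest polyploidy,
allele-specific amplification bias, or a chimera coinciding with a real
allele (a "perfect fake").  The threshold sits midway between those two
regimes; it is a screening flag, not a test with controlled error rates.

## The synthetic truth sets

`generate_truth_set()` emulates the pipeline's input universe at desk
scale: a random genome (default 5 kb + 1.5 kb), a panel of $n \ge 2$
strains (default 4, phased diploid), constant baseline depth (default
20×), and four engineered regions on the first contig, each violating or
satisfying exactly one rule:

* a **planted universal locus** — one unique interior SNP per strain at
  spacing $P+2$, assigned round-robin to haplotypes so diploids are 100 %
  heterozygous, plus one insertion and one deletion mid-cluster for
  panels of ≥ 4 strains;
* a **shared-allele decoy** (two strains carry the identical SNP —
  universality fails);
* a **coverage decoy** (unique SNPs per strain, but one strain's depth
  is 3× baseline over a 60 bp stretch — the ≥ 10 bp exclusion fires);
* a **flank decoy** (SNPs gridded at spacing $P$ over more than $W +
  2P$ — no window can present a clean flank).

A benign 4-base depth dip inside the planted locus exercises the
< 10 bp tolerance.  The $P+2$ SNP spacing keeps the merged extent
analytically exact, $[q_1 - W + P + 1,\; q_m + W - P)$, so recovery tests
compare intervals *exactly* rather than by overlap; engineered regions
are separated by $2(W-P)$ bases, which provably prevents their windows
from merging.  Truth haplotype sequences are assembled by independent
forward string surgery, not by the package's consensus routine, keeping
the round-trip test two-sided.

What the generator does *not* emulate: read-level errors, mappability
structure, GC bias, repeat-length polymorphism, and real phasing errors.
Passing tests therefore demonstrate the correctness of the algorithms on
their stated inputs, not robustness to upstream artefacts in real data.

`synthesize_asv_counts()` draws amplicon counts multinomially from the
allele frequencies implied by given strain abundances (a strain's
abundance splits evenly across its haplotypes), with an optional
binomially-drawn chimera fraction: each chimeric read recombines two
frequency-sampled alleles at a uniform breakpoint, and chimeras that
coincide with genuine alleles are recorded as perfect-fake collisions.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` run entirely on generated
data: 200 random scan-oracle panels up to a few kilobases, 20 truth sets
for planted-locus recovery, 100 random depth arrays for the mask oracle,
and 100 quantification replicates at $N = 10^5$ reads — sizes chosen so
the whole suite completes in well under a minute on one core while
leaving each property statistically meaningful.  Count partitioning is
exact in double arithmetic (integer-weighted ratios), and conservation
of counts is asserted exactly; abundance unit-sums are checked to
$10^{-9}$.  With a universally shared reference allele the abundance
estimator reduces algebraically to the ratio of strain-specific counts,
so recovery is judged against the multinomial standard error over the
specific-count total — the correct error scale for that estimator.

## Known limitations

* Primer thermodynamics (melting temperature, GC clamp, dimers) are out
  of scope; flank conservation is a necessary, not sufficient, condition
  for a working primer pair.
* Unphased heterozygotes at ploidy 2 are a hard error by design; the
  method cannot reconstruct per-allele sequences without phasing.
* The quantifier assumes the allele database is complete for the panel;
  alleles absent from the database simply surface as unmatched counts.
* Equal-split partitioning for all-zero specific counts is arbitrary
  (and flagged); abundances for such strain groups are not identifiable
  from shared counts alone.
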