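# strainbarcode

Tools for finding **intraspecific DNA barcode loci** in whole-genome
variant data and for **quantifying strain abundances** from amplicon
counts at such a locus.

Species-level barcodes (COI, ITS, 16S/18S) cannot tell apart clonal
strains of the same species, yet tracking individual genotypes in a mixed
culture — e.g. during a selection experiment on a microalgal population —
requires exactly that resolution. `strainbarcode` addresses both halves of
the problem for panels of haploid or phased diploid strains with a
reference genome and per-strain variant calls:

1. **Discovery** (`run_scan()`): find short hypervariable loci where
   *every* strain in the panel carries at least one *strain-specific
   allele* (an allele no other strain has), flanked by conserved,
   SNP-free primer sites so one primer pair amplifies all genotypes.
2. **Quantification** (`run_quantify()`): assign denoised amplicon
   sequence variant (ASV) counts to strains via the allele catalogue and
   convert them into relative strain abundances, with diagnostics for
   skewed allelic ratios.

## The method

Discovery proceeds in six steps per strain panel:

1. **Coverage masking.** For each strain, every position with read depth
   `< 0.5·m` or `> 2·m` — where `m` is that strain's contig-wide median
   depth — is masked (boundary values are kept).  Maximal runs of masked
   positions become intervals; the union over strains defines the
   unusable part of the genome (repeat collapse, duplications,
   misassembly all inflate apparent SNPs).
2. **Variable-site compilation.** SNP positions are unioned over all
   strains and haplotypes; indel-affected reference positions are
   tracked separately as "flank-blocking" sites.
3. **Window screen.** A window of width `W` (default 500 bp) slides with
   step 1.  A window survives iff its two flanks of width `P` (default
   21 bp) contain no variable site and its interior contains at least
   one SNP.
4. **Merging.** Overlapping surviving windows are merged into maximal
   loci (merged loci may exceed `W`).
5. **Coverage exclusion.** A locus overlapping any single masked
   interval by **ten or more bases** is dropped; shorter overlaps (often
   genuine short indels) are tolerated.
6. **Allele cataloguing.** Per strain and haplotype, the variant-applied
   consensus sequence over the locus is computed; identical sequences
   are pooled into alleles.  A locus is reported iff every strain has at
   least one strain-specific allele ("universal").

Quantification uses the allele catalogue as an exact-match database.
Strain-specific ASV counts (`a2`) pass through directly; a shared
allele's count `S` is partitioned among its carriers proportionally to
their strain-specific evidence,

```
a1 = S * a2 / (a2 + b2 + ... + n2)
```

and the relative abundance of strain *a* is `(a1 + a2) / total` over all
alleles of all strains.  Strains observed with more than two alleles
(triploids in a nominally diploid panel) contribute only their two
highest-count alleles.  A minor-allele fraction below 0.35 for a diploid
strain raises an `unbalanced` flag — the signature of polyploidy,
amplification bias, or a PCR chimera masquerading as a real allele.

## Worked example

Everything below runs on synthetic data generated at run time — a 4-strain
diploid panel on a 5 kb + 1.5 kb genome with one planted universal locus
and three decoy regions:

```r
library(strainbarcode)

ts  <- generate_truth_set(n_strains = 4, ploidy = 2, seed = 11,
                          outdir = tempfile())
res <- run_scan(ts$paths$reference, ts$paths$vcf, ts$paths$depth, ploidy = 2)
#> step 1: coverage mask spans 64 of 6500 bases (conforming: 6436)
#> step 2: 35 SNP position(s), 39 flank-blocking position(s)
#> step 3: 1256 candidate window(s) of 5502 possible; step 4: 3 merged locus/loci
#> step 5: 2 locus/loci after coverage exclusion
#> step 6: 1 universal barcode locus/loci
res
#> Barcode scan (W=500, P=21, ploidy=2)
#>   possible_windows: 5502 | candidates: 1256 | merged: 3 | after_coverage: 2 | universal: 1
#>  locus_id contig start  end n_snp_positions n_alleles n_strain_specific heterozygosity
#>   Bc_C1W1   chr1    22 1048               4         5                 4              1
```

Of the three merged candidate loci, one decoy fails the ≥10 bp coverage
rule (step 5) and one fails universality because two strains share its
only variant allele (step 6).  The survivor is the planted locus: 4 SNP
positions, 5 alleles (one unique per strain plus the shared reference
haplotype), every strain heterozygous.

Simulated amplicon counts at that locus recover the true mixing
proportions (0.4/0.3/0.2/0.1):

```r
ct  <- res$catalogs[[1]]
db  <- allele_db(list(ct))
sim <- synthesize_asv_counts(ct, c(strain01 = 0.4, strain02 = 0.3,
                                   strain03 = 0.2, strain04 = 0.1),
                             n_reads = 100000, chimera_rate = 0, seed = 11)
quantify_strains(sim$table, db)
#> Strain abundance estimates (1 sample(s), 4 strain(s))
#>  sample   strain      a1    a2 abundance flags
#>      s1 strain01 19893.0 20101    0.3999
#>      s1 strain02 14761.7 14916    0.2968
#>      s1 strain03 10078.6 10184    0.2026
#>      s1 strain04  5006.7  5059    0.1007
```

`a2` are strain-specific counts, `a1` each strain's partitioned share of
the common reference allele; abundances are their normalised sums.

A thin command-line wrapper lives in `inst/cli/strainbarcode.R`
(`scan` and `quantify` subcommands over the same functions).

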