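Package: strainbarcode
Title: Discovery of Hypervariable Intraspecific Barcode Loci and
    Strain Quantification from Amplicon Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scans whole-genome variant data from a panel of clonal
    strains for short hypervariable loci suitable as intraspecific DNA
    barcodes: per-strain coverage anomalies are masked against the
    contig median, a sliding window keeps variable cores flanked by
    SNP-free primer sites, overlapping windows are merged, and
    per-strain haplotype consensus sequences are catalogued into
    alleles to find loci where every strain carries a strain-specific
    allele.  A companion quantifier assigns amplicon-sequence-variant
    counts to strains via the allele catalogue, partitions counts of
    shared alleles proportionally to strain-specific evidence, and
    reports relative strain abundances with allelic-balance
    diagnostics.  A seeded synthetic truth-set generator produces
    reference genomes, phased VCFs, depth tables and multinomial
    amplicon counts so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
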