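test_that("haplotype consensus applies SNPs, deletions and insertions", {
  expect_identical(
    haplotype_consensus("ACGTACGT", vrow("c", 1, "C", "G")), "AGGTACGT")
  expect_identical(
    haplotype_consensus("ACGTACGT", vrow("c", 4, "ACG", "A")), "ACGTAT")
  expect_identical(
    haplotype_consensus("ACGTACGT", vrow("c", 2, "G", "GTT")), "ACGTTTACGT")
  expect_identical(haplotype_consensus("ACGTACGT", NULL), "ACGTACGT")
  # combined right-to-left application keeps earlier coordinates valid
  v <- rbind(vrow("c", 1, "C", "A"), vrow("c", 3, "T", "TGG"),
             vrow("c", 5, "CG", "C"))
  expect_identical(haplotype_consensus("ACGTACGT", v), "AAGTGGACT")
})

test_that("consensus rejects overlaps, mismatches and out-of-slice variants", {
  expect_error(
    haplotype_consensus("ACGTACGT", rbind(vrow("c", 2, "GTA", "G"),
                                          vrow("c", 3, "T", "A"))),
    "overlapping")
  expect_error(haplotype_consensus("ACGTACGT", vrow("c", 1, "G", "T")),
               "reference mismatch")
  expect_error(haplotype_consensus("ACGT", vrow("c", 3, "TA", "T")),
               "outside slice")
})

test_that("allele catalogue pools identical haplotypes and finds specifics", {
  # engineered three-strain case: A:(x,y) B:(y,z) C:(w,w)
  g <- toy_genome(c1 = "AAAACCCCGGGGTTTTAAAA")
  panel <- list(
    strain_variants("A", 2, rbind(vrow("c1", 5, "C", "T", 0),     # x
                                  vrow("c1", 13, "T", "G", 1))),  # y
    strain_variants("B", 2, rbind(vrow("c1", 13, "T", "G", 0),    # y
                                  vrow("c1", 17, "A", "C", 1))),  # z
    strain_variants("C", 2, rbind(vrow("c1", 9, "G", "A", 0),
                                  vrow("c1", 9, "G", "A", 1))))   # w,w
  locus <- data.frame(contig = "c1", start = 0L, end = 20L)
  ct <- build_allele_catalog(locus, g, panel, "L1")
  expect_identical(nrow(ct$alleles), 4L)
  expect_identical(unname(ct$specific_counts), c(1L, 1L, 1L))
  expect_true(ct$universal)
  expect_equal(ct$heterozygosity, 2 / 3)
  # statistics: 4 distinct SNP positions (5, 9, 13, 17), no indels
  st <- locus_statistics(ct, panel)
  expect_identical(st$n_snp_positions, 4L)
  expect_identical(st$n_indel_positions, 0L)
  expect_identical(st$n_alleles, 4L)
  expect_identical(st$n_strain_specific, 3L)

  # two strains with identical allele pairs {ref, y}: nothing is specific
  panel2 <- list(
    strain_variants("A", 2, vrow("c1", 13, "T", "G", 1)),
    strain_variants("B", 2, vrow("c1", 13, "T", "G", 0)))
  ct2 <- build_allele_catalog(locus, g, panel2, "L2")
  expect_identical(unname(ct2$specific_counts), c(0L, 0L))
  expect_false(ct2$universal)
})

test_that("degenerate catalogues behave by convention", {
  g <- toy_genome(c1 = "ACGTACGTACGTACGTACGT")
  locus <- data.frame(contig = "c1", start = 2L, end = 18L)
  # single heterozygous strain: both alleles specific, universal
  one <- list(strain_variants("A", 2, vrow("c1", 5, "C", "T", 0)))
  ct <- build_allele_catalog(locus, g, one, "L")
  expect_identical(nrow(ct$alleles), 2L)
  expect_identical(unname(ct$specific_counts), 2L)
  expect_true(ct$universal)
  expect_equal(ct$heterozygosity, 1)
  # all strains identical to reference
  none <- lapply(c("A", "B"), function(s)
    strain_variants(s, 2, data.frame(contig = character(), pos = integer(),
                                     ref = character(), alt = character(),
                                     haplotype = integer())))
  ct0 <- build_allele_catalog(locus, g, none, "L0")
  expect_identical(nrow(ct0$alleles), 1L)
  expect_identical(unname(ct0$specific_counts), c(0L, 0L))
  expect_false(ct0$universal)
  expect_equal(ct0$heterozygosity, 0)
  # haploid: heterozygosity 0 by convention
  hap <- list(strain_variants("A", 1, vrow("c1", 5, "C", "T", 0)),
              strain_variants("B", 1, vrow("c1", 10, "G", "A", 0)))
  cth <- build_allele_catalog(locus, g, hap, "Lh")
  expect_equal(cth$heterozygosity, 0)
  expect_true(cth$universal)
})

test_that("boundary-straddling deletions disqualify the locus", {
  g <- toy_genome(c1 = "ACGTACGTACGTACGTACGT")
  bad <- list(strain_variants("A", 2, vrow("c1", 9, "GTAC", "G", 0)))
  locus <- data.frame(contig = "c1", start = 4L, end = 11L)
  expect_warning(
    expect_null(build_allele_catalog(locus, g, bad, "Lx")),
    "straddles")
})

test_that("ploidy-conflict strains are catalogued but excluded from universality", {
  g <- toy_genome(c1 = "ACGTACGTACGTACGTACGT")
  panel <- list(
    strain_variants("A", 2, vrow("c1", 5, "C", "T", 0)),
    strain_variants("B", 2, vrow("c1", 10, "G", "A", 1),
                    ploidy_conflict = TRUE))
  locus <- data.frame(contig = "c1", start = 2L, end = 18L)
  ct <- build_allele_catalog(locus, g, panel, "L")
  expect_identical(ct$excluded_strains, "B")
  # A has a specific allele; B's status is ignored
  expect_true(ct$universal)
})

test_that("catalogue agrees with brute force and shrinks monotonically", {
  set.seed(33)
  for (trial in 1:25) {
    L <- 40L
    g <- toy_genome(c1 = random_sequence(L))
    n <- sample(2:5, 1)
    panel <- lapply(seq_len(n), function(k) {
      npos <- sample(0:3, 1)
      rows <- lapply(sample(5:(L - 6), npos), function(p) {
        ref <- substr(g$seq[["c1"]], p + 1, p + 1)
        vrow("c1", p, ref, chartr("ACGT", "TGCA", ref), sample(0:1, 1))
      })
      strain_variants(paste0("s", k), 2,
                      if (npos > 0) do.call(rbind, rows) else
                        data.frame(contig = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   haplotype = integer()))
    })
    # drop strains with overlapping same-haplotype duplicates
    ok <- vapply(panel, function(sv) {
      v <- sv$variants
      !any(duplicated(v[, c("pos", "haplotype")]))
    }, logical(1))
    panel <- panel[ok]
    if (length(panel) < 2) next
    locus <- data.frame(contig = "c1", start = 0L, end = L)
    ct <- build_allele_catalog(locus, g, panel, "L")
    want <- brute_catalog(ct$haplotypes)
    expect_identical(nrow(ct$alleles), want$n_alleles)
    expect_identical(ct$specific_counts, want$specific_counts)
    expect_identical(ct$universal, want$universal)
    expect_lte(sum(ct$specific_counts), nrow(ct$alleles))
    # removing one strain can only keep or increase others' specific counts
    sub <- panel[-sample(length(panel), 1)]
    ct_sub <- build_allele_catalog(locus, g, sub, "L")
    common <- intersect(names(ct_sub$specific_counts),
                        names(ct$specific_counts))
    expect_true(all(ct_sub$specific_counts[common] >=
                      ct$specific_counts[common]))
  }
})
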