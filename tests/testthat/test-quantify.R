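make_db <- function(seqs, carriers) {
  db <- data.frame(allele_id = paste0("a", seq_along(seqs)),
                   sequence = seqs, stringsAsFactors = FALSE)
  db$carriers <- carriers
  db
}

test_that("ASV matching is exact full-length and reports unmatched", {
  db <- make_db("ACGT", list("A"))
  m <- match_asvs(c(ACGT = 100L), db)
  expect_identical(m$matched$count, 100)
  expect_length(m$unmatched, 0L)
  expect_identical(m$unmatched_fraction, 0)

  m2 <- match_asvs(c(ACGT = 100L, TTTT = 40L), db)
  expect_identical(unname(m2$unmatched), 40L)
  expect_equal(m2$unmatched_fraction, 40 / 140)
  # partial overlap does not match
  m3 <- match_asvs(c(ACG = 10L, ACGTA = 10L), db)
  expect_identical(m3$matched$count, 0)
  expect_equal(m3$unmatched_fraction, 1)
  # empty table
  m4 <- match_asvs(integer(), db)
  expect_identical(m4$matched$count, 0)
  expect_identical(m4$unmatched_fraction, 0)
  # duplicate db sequences are rejected
  expect_error(match_asvs(c(ACGT = 1L), make_db(c("ACGT", "ACGT"),
                                                list("A", "B"))),
               "duplicate")
})

test_that("shared counts split proportionally to strain-specific evidence", {
  # shared allele S=400 carried by A (a2=100) and B (b2=300)
  db <- make_db(c("AAAA", "CCCC", "GGGG"), list("A", "B", c("A", "B")))
  m <- match_asvs(c(AAAA = 100L, CCCC = 300L, GGGG = 400L), db)
  p <- partition_shared_counts(m$matched, db)
  expect_equal(unname(p$a2), c(100, 300))
  expect_equal(unname(p$a1), c(100, 300))
  # Eq. 1 limit: a2 = 0 sends the whole shared count to the other carrier
  m0 <- match_asvs(c(AAAA = 0L, CCCC = 300L, GGGG = 400L), db)
  p0 <- partition_shared_counts(m0$matched, db)
  expect_equal(unname(p0$a1), c(0, 400))
  # all-zero specific counts: equal split, flagged
  mz <- match_asvs(c(GGGG = 300L), db)
  pz <- partition_shared_counts(mz$matched, db)
  expect_equal(unname(pz$a1), c(150, 150))
  expect_true(all(vapply(pz$flags, function(f) "zero_specific_tie" %in% f,
                         logical(1))))
})

test_that("count conservation holds exactly under partitioning", {
  set.seed(19)
  for (trial in 1:20) {
    n_all <- sample(3:8, 1)
    strains <- paste0("s", 1:4)
    carriers <- lapply(seq_len(n_all), function(i)
      sort(sample(strains, sample(1:3, 1))))
    # ensure at least one specific allele exists
    carriers[[1]] <- strains[1]
    db <- make_db(vapply(seq_len(n_all), function(i)
      random_sequence(12), ""), carriers)
    counts <- setNames(as.integer(rpois(n_all, 200)), db$sequence)
    p <- partition_shared_counts(match_asvs(counts, db)$matched, db)
    expect_equal(sum(p$strain_allele_counts$count), sum(counts))
    expect_equal(sum(p$a1) + sum(p$a2), sum(counts))
  }
})

test_that("relative abundances follow the global-total rule", {
  # A: 100+100, B: 300+300, C: 200 homozygous single allele
  db <- make_db(c("AAAA", "AATA", "CCCC", "CCGC", "GGGG"),
                list("A", "A", "B", "B", "C"))
  counts <- c(AAAA = 100L, AATA = 100L, CCCC = 300L, CCGC = 300L, GGGG = 200L)
  p <- partition_shared_counts(match_asvs(counts, db)$matched, db)
  ab <- strain_relative_abundance(p, db)
  expect_equal(unname(ab$abundance), c(0.2, 0.6, 0.2))
  expect_equal(sum(ab$abundance), 1, tolerance = 1e-9)
  # single strain
  db1 <- make_db("AAAA", list("A"))
  p1 <- partition_shared_counts(match_asvs(c(AAAA = 50L), db1)$matched, db1)
  expect_equal(unname(strain_relative_abundance(p1, db1)$abundance), 1)
  # zero totals are undefined
  p0 <- partition_shared_counts(match_asvs(integer(), db1)$matched, db1)
  expect_warning(ab0 <- strain_relative_abundance(p0, db1), "zero")
  expect_true(all(is.na(ab0$abundance)))
})

test_that("triploid strains contribute only their two highest-count alleles", {
  db <- make_db(c("AAAA", "CCCC", "GGGG", "TTTT"),
                list("tri", "tri", "tri", "B"))
  counts <- c(AAAA = 50L, CCCC = 40L, GGGG = 10L, TTTT = 100L)
  p <- partition_shared_counts(match_asvs(counts, db)$matched, db)
  ab <- strain_relative_abundance(p, db)
  expect_true("polyploid_extra_allele" %in% ab$flags$tri)
  expect_equal(unname(ab$a2["tri"]), 90)             # 50 + 40, 10 dropped
  expect_equal(unname(ab$abundance["tri"]), 90 / 190)
  expect_equal(unname(ab$abundance["B"]), 100 / 190)
  # deterministic tie-break: equal counts resolved by allele sequence
  counts2 <- c(AAAA = 40L, CCCC = 40L, GGGG = 40L, TTTT = 100L)
  p2 <- partition_shared_counts(match_asvs(counts2, db)$matched, db)
  ab2 <- strain_relative_abundance(p2, db)
  used <- ab2$a2["tri"]
  expect_equal(unname(used), 80)
})

test_that("allelic balance flags unbalanced and missing alleles", {
  sac <- data.frame(strain = c("A", "A"), allele_id = c("x", "y"),
                    count = c(100, 100))
  expect_identical(allelic_balance_flags(sac)$A, character())
  sac$count <- c(100, 300)
  expect_identical(allelic_balance_flags(sac)$A, "unbalanced")
  # 0.35 is a strict lower bound on the minor fraction
  sac$count <- c(35, 65)
  expect_identical(allelic_balance_flags(sac)$A, character())
  sac$count <- c(0, 200)
  expect_identical(allelic_balance_flags(sac)$A, "missing_allele")
})

test_that("quantify_strains handles multiple samples independently", {
  db <- make_db(c("AAAA", "CCCC"), list("A", "B"))
  tab <- data.frame(sample = c("s1", "s1", "s2", "s2"),
                    sequence = c("AAAA", "CCCC", "AAAA", "CCCC"),
                    count = c(100L, 100L, 300L, 100L))
  q <- quantify_strains(tab, db)
  expect_s3_class(q, "sb_abundance")
  expect_equal(q$table$abundance[q$table$sample == "s1"], c(0.5, 0.5))
  expect_equal(q$table$abundance[q$table$sample == "s2"], c(0.75, 0.25))
  # an all-unmatched sample reports fraction 1 and undefined abundances
  tab2 <- data.frame(sample = "s3", sequence = "TTTT", count = 10L)
  q2 <- suppressWarnings(quantify_strains(tab2, db))
  expect_equal(q2$unmatched$unmatched_fraction, 1)
  expect_true(all(is.na(q2$table$abundance)))
  expect_error(quantify_strains(tab, db[0, ]), "empty")
})

test_that("abundance tables round-trip to TSV", {
  db <- make_db(c("AAAA", "CCCC"), list("A", "B"))
  tab <- data.frame(sample = "s1", sequence = c("AAAA", "CCCC"),
                    count = c(60L, 40L))
  q <- quantify_strains(tab, db)
  out <- withr::local_tempdir()
  paths <- write_abundance_tables(q, out)
  back <- read.delim(paths$abundance)
  expect_equal(back$abundance, c(0.6, 0.4))
  expect_identical(back$strain, c("A", "B"))
})
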