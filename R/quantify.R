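#' Match ASV sequences against the allele database
#'
#' Exact, full-length string matching only: an amplicon sequence variant
#' either is an allele of the database or it is an artefact.  Substantial
#' unmatched fractions are expected in real data (PCR chimeras, unmerged or
#' error-bearing reads), so the unmatched tally is part of the result.
#'
#' @param counts Named integer vector: ASV sequence -> count (one sample).
#' @param db Allele database data.frame (columns allele_id, sequence,
#'   carriers) as from [load_allele_db()] or [allele_db()].
#' @return List with `matched` (data.frame allele_id, sequence, count,
#'   including zero-count alleles), `unmatched` (named counts) and
#'   `unmatched_fraction`.
#' @export
match_asvs <- function(counts, db) {
  if (anyDuplicated(db$sequence)) stop("duplicate sequences in allele database")
  if (is.null(counts)) counts <- integer()
  hit <- match(names(counts), db$sequence)
  matched_counts <- stats::setNames(numeric(nrow(db)), db$sequence)
  matched_counts[names(counts)[!is.na(hit)]] <- counts[!is.na(hit)]
  unmatched <- counts[is.na(hit)]
  total <- sum(counts)
  list(matched = data.frame(allele_id = db$allele_id,
                            sequence = db$sequence,
                            count = unname(matched_counts),
                            stringsAsFactors = FALSE),
       unmatched = sort(unmatched, decreasing = TRUE),
       unmatched_fraction = if (total > 0) sum(unmatched) / total else 0)
}

#' Partition matched allele counts among carrier strains
#'
#' Strain-specific allele counts pass through unchanged.  A shared allele's
#' count S is divided among its k carrier strains proportionally to each
#' carrier's summed strain-specific counts a2: carrier a receives
#' S * a2 / (a2 + b2 + ... + n2).  If every carrier has zero specific
#' counts the split is equal (S/k) and the carriers are flagged
#' `zero_specific_tie`.
#'
#' @param matched Data.frame (allele_id, sequence, count) from [match_asvs()].
#' @param db Allele database with list-column `carriers` aligned to `matched`.
#' @return List with `strain_allele_counts` (data.frame strain, allele_id,
#'   count, specific), `a1`/`a2` (named per-strain totals) and `flags`
#'   (named list of character vectors per strain).
#' @export
partition_shared_counts <- function(matched, db) {
  stopifnot(identical(matched$allele_id, db$allele_id))
  carriers <- db$carriers
  strains <- sort(unique(unlist(carriers)))
  is_specific <- lengths(carriers) == 1L
  a2 <- stats::setNames(numeric(length(strains)), strains)
  for (i in which(is_specific)) {
    a2[carriers[[i]]] <- a2[carriers[[i]]] + matched$count[i]
  }
  a1 <- stats::setNames(numeric(length(strains)), strains)
  flags <- stats::setNames(vector("list", length(strains)), strains)
  rows <- list()
  for (i in seq_len(nrow(matched))) {
    cs <- carriers[[i]]
    S <- matched$count[i]
    if (is_specific[i]) {
      share <- stats::setNames(S, cs)
    } else {
      w <- a2[cs]
      if (sum(w) > 0) {
        share <- S * w / sum(w)
      } else {
        share <- stats::setNames(rep(S / length(cs), length(cs)), cs)
        for (st in cs) flags[[st]] <- union(flags[[st]], "zero_specific_tie")
      }
      a1[cs] <- a1[cs] + share
    }
    rows[[i]] <- data.frame(strain = cs, allele_id = matched$allele_id[i],
                            count = unname(share), specific = is_specific[i],
                            stringsAsFactors = FALSE)
  }
  sac <- do.call(rbind, c(rows, list(data.frame(strain = character(),
                                                allele_id = character(),
                                                count = numeric(),
                                                specific = logical()))))
  list(strain_allele_counts = sac, a1 = a1, a2 = a2, flags = flags)
}

#' Relative strain abundances from partitioned counts
#'
#' Abundance of strain a is (a1 + a2) / total, where a1 is its share of
#' shared-allele counts, a2 its summed strain-specific counts, and the
#' total runs over all alleles of all strains.  Strains carrying more than
#' two alleles (polyploids in a nominally diploid panel) contribute only
#' their two highest-count alleles — ties broken lexicographically by
#' allele sequence — and are flagged `polyploid_extra_allele`.
#'
#' @param partition Result of [partition_shared_counts()].
#' @param db Allele database (used to detect strains with > 2 alleles and
#'   to order ties by sequence).
#' @return List with `abundance` (named per-strain vector; NA with a warning
#'   if total assigned counts are zero), `a1`, `a2` (per-strain, after any
#'   polyploid top-two restriction) and `flags`.
#' @export
strain_relative_abundance <- function(partition, db) {
  sac <- partition$strain_allele_counts
  flags <- partition$flags
  seq_of <- stats::setNames(db$sequence, db$allele_id)
  strains <- names(partition$a2)
  keep <- rep(TRUE, nrow(sac))
  for (st in strains) {
    idx <- which(sac$strain == st)
    if (length(idx) > 2L) {
      flags[[st]] <- union(flags[[st]], "polyploid_extra_allele")
      o <- order(-sac$count[idx], seq_of[sac$allele_id[idx]])
      keep[idx[o[-(1:2)]]] <- FALSE
    }
  }
  used <- sac[keep, , drop = FALSE]
  a1 <- a2 <- stats::setNames(numeric(length(strains)), strains)
  for (i in seq_len(nrow(used))) {
    st <- used$strain[i]
    if (used$specific[i]) a2[st] <- a2[st] + used$count[i]
    else a1[st] <- a1[st] + used$count[i]
  }
  total <- sum(a1) + sum(a2)
  if (total > 0) {
    abundance <- (a1 + a2) / total
  } else {
    warning("total assigned counts are zero; abundances undefined")
    abundance <- stats::setNames(rep(NA_real_, length(strains)), strains)
  }
  list(abundance = abundance, a1 = a1, a2 = a2, flags = flags)
}

#' Allelic-balance diagnostics for diploid strains
#'
#' For a diploid strain with two expected distinct alleles, the minor-allele
#' fraction minor/(minor+major) should sit near 0.5 (a 1:1 ratio).  A
#' fraction below `min_minor_fraction` is flagged `unbalanced` — ratios
#' nearer 1:3 suggest polyploidy, amplification bias, or a chimera
#' masquerading as a genuine allele ("perfect fake").  An expected allele
#' observed zero times is flagged `missing_allele`.  Homozygous strains
#' (one distinct allele) are not assessed.
#'
#' @param strain_allele_counts Data.frame (strain, allele_id, count) from
#'   [partition_shared_counts()].
#' @param min_minor_fraction Threshold on the minor-allele fraction
#'   (default 0.35).
#' @return Named list of character flag vectors per strain.
#' @export
allelic_balance_flags <- function(strain_allele_counts,
                                  min_minor_fraction = 0.35) {
  flags <- list()
  for (st in unique(strain_allele_counts$strain)) {
    cnt <- strain_allele_counts$count[strain_allele_counts$strain == st]
    fl <- character()
    if (length(cnt) == 2L) {
      if (any(cnt == 0) && sum(cnt) > 0) {
        fl <- c(fl, "missing_allele")
      } else if (sum(cnt) > 0) {
        if (min(cnt) / sum(cnt) < min_minor_fraction) fl <- c(fl, "unbalanced")
      }
    }
    flags[[st]] <- fl
  }
  flags
}

#' Quantify strain abundances in one or more samples
#'
#' Full quantification for an ASV count table against an allele database:
#' exact matching, shared-count partitioning, relative abundances and
#' allelic-balance flags, independently per sample.
#'
#' @param asv_table Data.frame with columns sample, sequence, count.
#' @param db Allele database data.frame (allele_id, sequence, carriers).
#' @param min_minor_fraction Passed to [allelic_balance_flags()].
#' @return An object of class `sb_abundance`: list with `table` (data.frame
#'   sample, strain, a1, a2, abundance, flags) and `unmatched` (data.frame
#'   sample, unmatched_fraction, n_unmatched_sequences).
#' @examples
#' db <- data.frame(allele_id = c("a1", "a2"),
#'                  sequence = c("ACGT", "AGGT"), stringsAsFactors = FALSE)
#' db$carriers <- list("strainA", "strainB")
#' tab <- data.frame(sample = "s1", sequence = c("ACGT", "AGGT"),
#'                   count = c(120L, 80L))
#' quantify_strains(tab, db)
#' @export
quantify_strains <- function(asv_table, db, min_minor_fraction = 0.35) {
  if (nrow(db) == 0L) stop("empty allele database")
  rows <- list()
  unm <- list()
  for (smp in unique(asv_table$sample)) {
    sub <- asv_table[asv_table$sample == smp, , drop = FALSE]
    agg <- tapply(sub$count, sub$sequence, sum)
    counts <- stats::setNames(as.numeric(agg), names(agg))
    m <- match_asvs(counts, db)
    part <- partition_shared_counts(m$matched, db)
    ab <- strain_relative_abundance(part, db)
    bal <- allelic_balance_flags(part$strain_allele_counts, min_minor_fraction)
    strains <- names(ab$abundance)
    fl <- vapply(strains, function(st)
      paste(sort(union(ab$flags[[st]], bal[[st]])), collapse = ";"), "")
    rows[[smp]] <- data.frame(sample = smp, strain = strains,
                              a1 = unname(ab$a1), a2 = unname(ab$a2),
                              abundance = unname(ab$abundance),
                              flags = unname(fl), stringsAsFactors = FALSE)
    unm[[smp]] <- data.frame(sample = smp,
                             unmatched_fraction = m$unmatched_fraction,
                             n_unmatched_sequences = length(m$unmatched))
  }
  structure(list(table = do.call(rbind, c(rows, list(NULL))),
                 unmatched = do.call(rbind, c(unm, list(NULL)))),
            class = "sb_abundance")
}

#' @export
print.sb_abundance <- function(x, digits = 4, ...) {
  cat("Strain abundance estimates (", length(unique(x$table$sample)),
      " sample(s), ", length(unique(x$table$strain)), " strain(s))\n", sep = "")
  tab <- x$table
  tab$abundance <- round(tab$abundance, digits)
  tab$a1 <- round(tab$a1, 1)
  tab$a2 <- round(tab$a2, 1)
  print(tab, row.names = FALSE)
  if (!is.null(x$unmatched) && any(x$unmatched$unmatched_fraction > 0)) {
    cat("Unmatched ASV fraction per sample:\n")
    print(x$unmatched, row.names = FALSE)
  }
  invisible(x)
}
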