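#' Apply one haplotype's variants to a reference slice
#'
#' Reconstructs the haplotype sequence over a locus by applying SNPs,
#' insertions and deletions to the reference slice.  Variant positions are
#' 0-based offsets relative to the slice start.  A SNP substitutes one base;
#' a deletion removes `nchar(ref) - nchar(alt)` bases after the anchor; an
#' insertion appends the extra ALT suffix after the anchor base.  Variants
#' are applied right-to-left so earlier coordinates stay valid.
#'
#' @param ref_slice Reference sequence of the locus (character scalar).
#' @param variants Data.frame with columns pos (offset in slice), ref, alt;
#'   one strain-haplotype, sorted by pos, non-overlapping.
#' @return The consensus sequence (character scalar).
#' @export
haplotype_consensus <- function(ref_slice, variants) {
  if (is.null(variants) || nrow(variants) == 0L) return(ref_slice)
  v <- variants[order(variants$pos), , drop = FALSE]
  span_end <- v$pos + nchar(v$ref)
  if (nrow(v) > 1L && any(v$pos[-1] < span_end[-nrow(v)])) {
    stop("overlapping variants on one haplotype")
  }
  if (any(v$pos < 0L) || any(span_end > nchar(ref_slice))) {
    stop("variant outside slice")
  }
  seq <- ref_slice
  for (i in rev(seq_len(nrow(v)))) {
    at <- v$pos[i]
    if (substr(seq, at + 1L, at + nchar(v$ref[i])) != v$ref[i]) {
      stop("reference mismatch at offset ", at, ": expected ", v$ref[i])
    }
    seq <- paste0(substr(seq, 1L, at), v$alt[i],
                  substr(seq, at + nchar(v$ref[i]) + 1L, nchar(seq)))
  }
  seq
}

#' Build the allele catalogue of a barcode locus
#'
#' Computes the consensus sequence of every strain haplotype over the locus,
#' pools identical sequences into alleles, and derives the locus summary:
#' which alleles are strain-specific (carrier set of exactly one strain —
#' a strain homozygous for a unique sequence still counts one), whether the
#' locus is universal (every strain has at least one strain-specific
#' allele), and its heterozygosity (fraction of strains whose haplotype
#' sequences are not all identical; 0 by convention for haploid panels).
#' Strains flagged with a ploidy conflict upstream are catalogued but
#' excluded from the universality determination.  A deletion straddling a
#' locus boundary makes the consensus ill-defined; such loci are
#' disqualified (`NULL` with a warning).
#'
#' @param locus One-row data.frame (contig, start, end), 0-based half-open.
#' @param genome An `sb_genome`.
#' @param panel List of `sb_variants`, one per strain.
#' @param locus_id Identifier recorded in the catalogue.
#' @return An `sb_allele_catalog` object, or `NULL` if disqualified.
#' @export
build_allele_catalog <- function(locus, genome, panel, locus_id = "locus") {
  stopifnot(inherits(genome, "sb_genome"), nrow(locus) == 1L)
  ctg <- locus$contig
  start <- locus$start
  end <- locus$end
  ref_slice <- substr(genome$seq[[ctg]], start + 1L, end)
  strains <- vapply(panel, `[[`, "", "strain")
  stopifnot(!anyDuplicated(strains))

  haplotypes <- list()
  for (sv in panel) {
    v <- sv$variants
    v <- v[v$contig == ctg & v$pos + nchar(v$ref) > start & v$pos < end, ,
           drop = FALSE]
    if (nrow(v) > 0 && (any(v$pos < start) || any(v$pos + nchar(v$ref) > end))) {
      warning("locus ", locus_id, ": variant straddles the locus boundary in ",
              sv$strain, "; locus disqualified")
      return(NULL)
    }
    haps <- character(sv$ploidy)
    for (h in seq_len(sv$ploidy) - 1L) {
      vh <- v[v$haplotype == h, , drop = FALSE]
      vh$pos <- vh$pos - start
      haps[h + 1L] <- haplotype_consensus(ref_slice, vh)
    }
    haplotypes[[sv$strain]] <- haps
  }

  seqs <- unlist(haplotypes, use.names = FALSE)
  carrier <- rep(strains, times = vapply(panel, `[[`, 1L, "ploidy"))
  allele_seq <- unique(seqs)
  carriers <- lapply(allele_seq, function(s) sort(unique(carrier[seqs == s])))
  specific <- vapply(carriers, function(cs) length(cs) == 1L, logical(1))
  specific_counts <- vapply(strains, function(st)
    sum(specific & vapply(carriers, function(cs) identical(cs, st), logical(1))),
    integer(1))

  excluded <- strains[vapply(panel, function(sv) isTRUE(sv$ploidy_conflict),
                             logical(1))]
  eligible <- setdiff(strains, excluded)
  universal <- length(eligible) > 0L && all(specific_counts[eligible] >= 1L)

  ploidies <- vapply(panel, `[[`, 1L, "ploidy")
  if (all(ploidies == 1L)) {
    het <- 0
  } else {
    het <- mean(vapply(haplotypes, function(h) length(unique(h)) > 1L,
                       logical(1)))
  }

  structure(list(
    locus_id = locus_id, contig = ctg, start = start, end = end,
    strains = strains, haplotypes = haplotypes,
    alleles = data.frame(allele_id = sprintf("a%02d", seq_along(allele_seq)),
                         sequence = allele_seq, stringsAsFactors = FALSE),
    carriers = carriers, specific_counts = specific_counts,
    excluded_strains = excluded, universal = universal,
    heterozygosity = het), class = "sb_allele_catalog")
}

#' @export
print.sb_allele_catalog <- function(x, ...) {
  cat("Allele catalogue ", x$locus_id, " (", x$contig, ":", x$start, "-",
      x$end, ")\n", sep = "")
  cat("  strains: ", length(x$strains), "; alleles: ", nrow(x$alleles),
      "; strain-specific: ", sum(x$specific_counts),
      "; universal: ", x$universal,
      "; heterozygosity: ", signif(x$heterozygosity, 3), "\n", sep = "")
  invisible(x)
}

#' Summary statistics of a catalogued locus
#'
#' Counts distinct reference positions inside the locus carrying a SNP or
#' an indel in any strain, and packages the catalogue-level allele counts.
#'
#' @param catalog An `sb_allele_catalog`.
#' @param panel The strain panel the catalogue was built from.
#' @return A one-row data.frame: n_snp_positions, n_indel_positions,
#'   n_alleles, n_strain_specific, heterozygosity, universal.
#' @export
locus_statistics <- function(catalog, panel) {
  stopifnot(inherits(catalog, "sb_allele_catalog"))
  v <- do.call(rbind, lapply(panel, `[[`, "variants"))
  inside <- v[v$contig == catalog$contig & v$pos >= catalog$start &
                v$pos < catalog$end, , drop = FALSE]
  data.frame(
    n_snp_positions = length(unique(inside$pos[inside$vclass == "SNP"])),
    n_indel_positions = length(unique(inside$pos[inside$vclass != "SNP"])),
    n_alleles = nrow(catalog$alleles),
    n_strain_specific = sum(catalog$specific_counts),
    heterozygosity = catalog$heterozygosity,
    universal = catalog$universal)
}
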