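#' Load a reference genome from FASTA
#'
#' Reads a (possibly gzipped) FASTA file into a genome object holding one
#' uppercase sequence per contig, in file order.  Lowercase bases are
#' normalised to uppercase and any symbol outside `A`, `C`, `G`, `T`, `N`
#' (e.g. IUPAC ambiguity codes) is mapped to `N` with a warning.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `sb_genome`: a list with element `seq`, a named
#'   character vector of contig sequences in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtACGT"), fa)
#' g <- load_reference(fa)
#' contig_lengths(g)
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) {
    stop("reference FASTA not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("empty FASTA: ", path)
  }
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for contig: ",
         paste(nm[nchar(seqs) == 0L], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning(sum(bad), " contig(s) contain non-ACGTN symbols; mapped to N")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  structure(list(seq = seqs), class = "sb_genome")
}

#' Contig lengths of a genome
#'
#' @param genome An `sb_genome` object.
#' @return Named integer vector of contig lengths, in genome order.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "sb_genome"))
  stats::setNames(nchar(genome$seq), names(genome$seq))
}

#' @export
print.sb_genome <- function(x, ...) {
  L <- contig_lengths(x)
  cat("Genome:", length(L), "contig(s),", sum(L), "bp total\n")
  utils::head(data.frame(contig = names(L), length = unname(L)), 10) |>
    print(row.names = FALSE)
  invisible(x)
}

#' Load a per-base read-depth table for one strain
#'
#' Reads a 3-column tab-separated depth table in the `samtools depth`
#' dialect (contig, 1-based position, depth) into per-contig depth arrays.
#' Positions absent from the table get depth 0, so sparse output (e.g. from
#' `samtools depth` without `-a`) is accepted.
#'
#' @param path Path to the depth table (no header).
#' @param genome An `sb_genome`; defines the contig universe and lengths.
#' @param strain Strain identifier recorded in the result.
#' @return An object of class `sb_depth`: list with `strain` and `depth`,
#'   a named list of non-negative integer vectors (0-based indexing by
#'   position + 1), one per genome contig.
#' @export
load_depth_table <- function(path, genome, strain) {
  stopifnot(inherits(genome, "sb_genome"))
  lens <- contig_lengths(genome)
  depth <- lapply(lens, function(L) integer(L))
  info <- file.info(path)
  if (is.na(info$size)) stop("depth table not found: ", path)
  if (info$size > 0) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("contig", "pos", "depth"),
                             colClasses = c("character", "numeric", "character"))
    if (nrow(tab) > 0) {
      unknown <- setdiff(unique(tab$contig), names(lens))
      if (length(unknown)) {
        stop("depth table references unknown contig(s): ",
             paste(unknown, collapse = ", "))
      }
      d <- suppressWarnings(as.numeric(tab$depth))
      if (anyNA(d) || any(d != floor(d)) || any(d < 0)) {
        stop("non-integer or negative depth value in ", path)
      }
      if (any(tab$pos != floor(tab$pos)) || any(tab$pos < 1)) {
        stop("positions must be positive integers in ", path)
      }
      for (ctg in unique(tab$contig)) {
        sel <- tab$contig == ctg
        p <- tab$pos[sel]
        if (any(p > lens[[ctg]])) {
          stop("depth position beyond contig length for ", ctg)
        }
        depth[[ctg]][p] <- as.integer(d[sel])
      }
    }
  }
  structure(list(strain = strain, depth = depth), class = "sb_depth")
}

.vclass <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "SNP", ifelse(la > lr, "INS", "DEL"))
}

#' Load phased variants for one strain from a VCF file
#'
#' Converts VCF records into one variant per ALT-carrying haplotype, with
#' 0-based reference positions.  Multi-allelic records are split per ALT
#' allele before classification into SNP / INS / DEL.  Homozygous-ALT sites
#' yield one variant per haplotype.  Records with genotype `0/0` (or all-ref),
#' missing calls (`./.`), or symbolic ALT alleles (`<DEL>` etc.) are skipped
#' and counted.  At ploidy 2, heterozygous genotypes must be phased (`|`);
#' an unphased heterozygote is a hard error because per-haplotype allele
#' reconstruction would be ambiguous.  Genotypes calling more alleles than
#' the declared ploidy are skipped and counted as `ploidy_conflict`, and the
#' strain is flagged — a triploid signal relevant downstream.
#'
#' @param path Path to a VCF file (plain or gzipped) with a GT FORMAT field.
#' @param genome An `sb_genome` used to validate positions.
#' @param strain Strain identifier.
#' @param ploidy Declared ploidy (1 for haploid, 2 for phased diploid).
#' @return An object of class `sb_variants`: list with `strain`, `ploidy`,
#'   `variants` (data.frame: contig, pos, ref, alt, vclass, haplotype, sorted
#'   by contig then pos), `skipped` (named counts of skipped records) and
#'   `ploidy_conflict` (logical).
#' @export
load_strain_variants <- function(path, genome, strain, ploidy = 2L) {
  stopifnot(inherits(genome, "sb_genome"), ploidy >= 1L)
  lens <- contig_lengths(genome)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  skipped <- c(ref_only = 0L, missing = 0L, symbolic = 0L, ploidy_conflict = 0L)
  out <- list()
  if (nrow(fix) > 0) {
    if (is.null(gt) || ncol(gt) < 2L) stop("VCF has no genotype column: ", path)
    fmt <- strsplit(gt[, 1L], ":", fixed = TRUE)
    calls <- strsplit(gt[, 2L], ":", fixed = TRUE)
    for (i in seq_len(nrow(fix))) {
      gt_idx <- match("GT", fmt[[i]])
      if (is.na(gt_idx)) stop("record without GT at ", fix[i, "CHROM"], ":",
                              fix[i, "POS"], " in ", path)
      g <- calls[[i]][gt_idx]
      if (is.na(g) || grepl("\\.", g)) {
        skipped["missing"] <- skipped["missing"] + 1L
        next
      }
      phased <- !grepl("/", g, fixed = TRUE)
      al <- as.integer(strsplit(g, "[|/]")[[1]])
      if (length(al) > ploidy) {
        skipped["ploidy_conflict"] <- skipped["ploidy_conflict"] + 1L
        next
      }
      if (!phased && length(al) > 1L && length(unique(al)) > 1L) {
        stop("unphased heterozygote at ", fix[i, "CHROM"], ":", fix[i, "POS"],
             " (GT=", g, "); phased genotypes are required at ploidy ", ploidy)
      }
      if (all(al == 0L)) { skipped["ref_only"] <- skipped["ref_only"] + 1L; next }
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      if (any(grepl("[<>\\[\\]]", alts[al[al > 0L]]))) {
        skipped["symbolic"] <- skipped["symbolic"] + 1L
        next
      }
      ctg <- fix[i, "CHROM"]
      if (!ctg %in% names(lens)) stop("VCF references unknown contig: ", ctg)
      pos0 <- as.integer(fix[i, "POS"]) - 1L
      ref <- fix[i, "REF"]
      if (pos0 + nchar(ref) > lens[[ctg]]) {
        stop("variant beyond contig end at ", ctg, ":", fix[i, "POS"])
      }
      for (h in seq_along(al)) {
        if (al[h] == 0L) next
        alt <- alts[al[h]]
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, pos = pos0, ref = ref, alt = alt,
          vclass = .vclass(ref, alt), haplotype = h - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  variants <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), vclass = character(), haplotype = integer(),
               stringsAsFactors = FALSE)
  variants <- variants[order(variants$contig, variants$pos, variants$haplotype), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  if (sum(skipped) > 0) {
    message(strain, ": skipped ", sum(skipped), " VCF record(s) [",
            paste(names(skipped), skipped, sep = "=", collapse = ", "), "]")
  }
  structure(list(strain = strain, ploidy = as.integer(ploidy),
                 variants = variants, skipped = skipped,
                 ploidy_conflict = skipped[["ploidy_conflict"]] > 0L),
            class = "sb_variants")
}

#' Construct a strain-variant set programmatically
#'
#' Builds the same object [load_strain_variants()] reads from a VCF, from an
#' in-memory variant table.  Variant classes are derived from REF/ALT
#' lengths and records are sorted by (contig, pos).
#'
#' @param strain Strain identifier.
#' @param ploidy Ploidy (>= 1); every haplotype index must be below it.
#' @param variants Data.frame with columns contig, pos (0-based), ref, alt,
#'   haplotype.  May be empty.
#' @param ploidy_conflict Whether the strain showed more called alleles
#'   than its ploidy upstream (default FALSE).
#' @return An `sb_variants` object.
#' @export
strain_variants <- function(strain, ploidy, variants,
                            ploidy_conflict = FALSE) {
  stopifnot(ploidy >= 1L)
  if (nrow(variants) > 0) {
    stopifnot(all(variants$haplotype < ploidy), all(variants$haplotype >= 0))
    variants$vclass <- .vclass(variants$ref, variants$alt)
    variants <- variants[order(variants$contig, variants$pos,
                               variants$haplotype), , drop = FALSE]
  } else {
    variants <- data.frame(contig = character(), pos = integer(),
                           ref = character(), alt = character(),
                           vclass = character(), haplotype = integer(),
                           stringsAsFactors = FALSE)
  }
  rownames(variants) <- NULL
  structure(list(strain = strain, ploidy = as.integer(ploidy),
                 variants = variants,
                 skipped = c(ref_only = 0L, missing = 0L, symbolic = 0L,
                             ploidy_conflict = 0L),
                 ploidy_conflict = isTRUE(ploidy_conflict)),
            class = "sb_variants")
}

#' @export
print.sb_variants <- function(x, ...) {
  cat("Strain", x$strain, "(ploidy ", x$ploidy, "): ",
      nrow(x$variants), " variant record(s); skipped: ",
      paste(names(x$skipped), x$skipped, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read an amplicon-sequence-variant count table
#'
#' Expects a tab-separated file with header columns `sample`, `sequence`,
#' `count`.  Sequences are uppercased; counts must be non-negative integers.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns sample, sequence, count.
#' @export
load_asv_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "numeric"))
  need <- c("sample", "sequence", "count")
  if (!all(need %in% names(tab))) {
    stop("ASV table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$count < 0) || any(tab$count != floor(tab$count))) {
    stop("ASV counts must be non-negative integers")
  }
  tab$sequence <- toupper(tab$sequence)
  tab$count <- as.integer(tab$count)
  tab[, need]
}

#' Read an allele database from multi-FASTA
#'
#' Headers follow the catalogue convention
#' `>{locus_id}|{allele_id}|{carrier1,carrier2,...}`.
#'
#' @param path Path to the allele FASTA.
#' @return A data.frame with columns locus_id, allele_id, sequence, and a
#'   list-column carriers.
#' @export
load_allele_db <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty allele database: ", path)
  parts <- strsplit(names(set), "|", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("allele FASTA headers must be locus_id|allele_id|carriers")
  }
  seqs <- toupper(as.character(set))
  if (anyDuplicated(seqs)) stop("duplicate sequences in allele database")
  db <- data.frame(locus_id = vapply(parts, `[[`, "", 1L),
                   allele_id = vapply(parts, `[[`, "", 2L),
                   sequence = unname(seqs),
                   stringsAsFactors = FALSE)
  db$carriers <- lapply(parts, function(p) strsplit(p[[3L]], ",", fixed = TRUE)[[1]])
  db
}
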