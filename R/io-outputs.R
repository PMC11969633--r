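#' Assign locus identifiers in the C{contig}W{rank} style
#'
#' Loci are ranked per contig in ascending start order; the identifier is
#' `{prefix}_C{contig_index}W{rank}` with the 1-based contig index in genome
#' order (e.g. `Sm_C12W1` = first locus on the twelfth contig).
#'
#' @param loci Data.frame with columns contig, start, end.
#' @param genome An `sb_genome` (fixes contig order).
#' @param prefix Identifier prefix, typically a species abbreviation.
#' @return `loci` with a `locus_id` column, sorted by (contig order, start).
#' @export
assign_locus_ids <- function(loci, genome, prefix = "Bc") {
  ctg_index <- match(loci$contig, names(genome$seq))
  if (anyNA(ctg_index)) stop("locus on unknown contig")
  o <- order(ctg_index, loci$start)
  loci <- loci[o, , drop = FALSE]
  ctg_index <- ctg_index[o]
  rank <- stats::ave(loci$start, ctg_index, FUN = seq_along)
  loci$locus_id <- sprintf("%s_C%dW%d", prefix, ctg_index, as.integer(rank))
  rownames(loci) <- NULL
  loci
}

#' Write the scan outputs: metadata TSV, BED, per-locus multi-FASTA
#'
#' Emits (1) a tab-separated metadata table with one row per locus, (2) a
#' BED file (0-based half-open) of locus coordinates for genome-browser
#' inspection, and (3) one multi-FASTA per locus with every strain
#' haplotype sequence, headers `>{strain}_hap{h} locus={locus_id}`.
#'
#' @param catalogs List of `sb_allele_catalog` objects.
#' @param stats Data.frame of per-locus statistics aligned with `catalogs`
#'   (from [locus_statistics()]), or NULL to recompute nothing and write
#'   catalogue-level fields only.
#' @param outdir Output directory (created if needed).
#' @param prefix Basename prefix for the TSV/BED files.
#' @return Invisibly, the paths written (tsv, bed, fasta vector).
#' @export
emit_scan_outputs <- function(catalogs, stats = NULL, outdir, prefix = "barcodes") {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop("cannot create output directory: ", outdir)
  }
  tsv <- file.path(outdir, paste0(prefix, ".tsv"))
  bed <- file.path(outdir, paste0(prefix, ".bed"))
  header <- c("locus_id", "contig", "start0", "end", "length",
              "n_snp_positions", "n_indel_positions", "n_alleles",
              "n_strain_specific", "heterozygosity", "universal")
  lines <- paste(header, collapse = "\t")
  bed_lines <- character()
  fasta_paths <- character()
  for (i in seq_along(catalogs)) {
    cat_i <- catalogs[[i]]
    st <- if (is.null(stats)) {
      data.frame(n_snp_positions = NA_integer_, n_indel_positions = NA_integer_,
                 n_alleles = nrow(cat_i$alleles),
                 n_strain_specific = sum(cat_i$specific_counts),
                 heterozygosity = cat_i$heterozygosity,
                 universal = cat_i$universal)
    } else stats[i, , drop = FALSE]
    lines <- c(lines, paste(c(
      cat_i$locus_id, cat_i$contig, cat_i$start, cat_i$end,
      cat_i$end - cat_i$start,
      st$n_snp_positions, st$n_indel_positions, st$n_alleles,
      st$n_strain_specific, format(st$heterozygosity, digits = 6),
      tolower(as.character(st$universal))), collapse = "\t"))
    bed_lines <- c(bed_lines,
                   paste(cat_i$contig, cat_i$start, cat_i$end, cat_i$locus_id,
                         sep = "\t"))
    fa <- file.path(outdir, paste0(cat_i$locus_id, ".fasta"))
    seqs <- character()
    for (strain in names(cat_i$haplotypes)) {
      haps <- cat_i$haplotypes[[strain]]
      for (h in seq_along(haps)) {
        seqs[sprintf("%s_hap%d locus=%s", strain, h - 1L, cat_i$locus_id)] <-
          haps[h]
      }
    }
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), fa)
    fasta_paths <- c(fasta_paths, fa)
  }
  writeLines(lines, tsv)
  writeLines(bed_lines, bed)
  invisible(list(tsv = tsv, bed = bed, fasta = fasta_paths))
}

#' Read locus intervals back from a BED file
#'
#' @param path BED3+1 file as written by [emit_scan_outputs()].
#' @return Data.frame with columns contig, start, end, locus_id.
#' @export
read_locus_bed <- function(path) {
  info <- file.info(path)
  if (is.na(info$size)) stop("BED file not found: ", path)
  if (info$size == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), locus_id = character()))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("contig", "start", "end", "locus_id"),
                           colClasses = c("character", "integer", "integer",
                                          "character"))
  tab
}

#' Build an allele database from catalogues
#'
#' Flattens one or more allele catalogues into the database consumed by the
#' quantifier, one row per distinct allele sequence.
#'
#' @param catalogs List of `sb_allele_catalog` objects.
#' @return Data.frame with columns locus_id, allele_id, sequence and a
#'   list-column carriers.
#' @export
allele_db <- function(catalogs) {
  rows <- lapply(catalogs, function(ct) {
    df <- data.frame(locus_id = ct$locus_id,
                     allele_id = paste0(ct$locus_id, ".", ct$alleles$allele_id),
                     sequence = ct$alleles$sequence,
                     stringsAsFactors = FALSE)
    df$carriers <- ct$carriers
    df
  })
  db <- do.call(rbind, rows)
  if (anyDuplicated(db$sequence)) {
    stop("identical allele sequence shared between loci; database ambiguous")
  }
  rownames(db) <- NULL
  db
}

#' Write the allele database to multi-FASTA
#'
#' Headers follow `>{locus_id}|{allele_id}|{carrier1,carrier2,...}` so the
#' database round-trips through [load_allele_db()].
#'
#' @param db Allele database data.frame.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_allele_db <- function(db, path) {
  headers <- sprintf("%s|%s|%s", db$locus_id, db$allele_id,
                     vapply(db$carriers, paste, "", collapse = ","))
  set <- Biostrings::BStringSet(stats::setNames(db$sequence, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write quantification results to TSV
#'
#' Emits the per-sample abundance table (sample, strain, a1, a2, abundance,
#' flags) and the unmatched-ASV report.
#'
#' @param result An `sb_abundance` object from [quantify_strains()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the two paths written.
#' @export
write_abundance_tables <- function(result, outdir) {
  stopifnot(inherits(result, "sb_abundance"))
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop("cannot create output directory: ", outdir)
  }
  ab <- file.path(outdir, "abundance.tsv")
  un <- file.path(outdir, "unmatched.tsv")
  utils::write.table(result$table, ab, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$unmatched, un, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(abundance = ab, unmatched = un))
}
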