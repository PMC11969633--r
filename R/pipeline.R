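#' Run the full barcode-discovery scan
#'
#' Executes the six-step discovery pipeline over a strain panel: per-strain
#' coverage masking against the contig median, compilation of variable
#' sites, a step-1 sliding-window screen for variable cores with SNP-free
#' primer flanks, merging of overlapping windows, exclusion of loci
#' overlapping irregular coverage by ten or more bases, and allele
#' cataloguing — keeping the loci at which every strain carries at least
#' one strain-specific allele.
#'
#' @param reference An `sb_genome` or path to a reference FASTA.
#' @param vcfs Named character vector of per-strain VCF paths (names are
#'   strain identifiers), or a list of `sb_variants`.
#' @param depths Named character vector of per-strain depth-table paths, or
#'   a list of `sb_depth` (aligned with `vcfs`).
#' @param ploidy Strain ploidy used when reading VCFs (default 2).
#' @param window_size,primer_size Window width `W` (default 500) and primer
#'   flank width `P` (default 21); `2P < W`.
#' @param coverage_bounds Length-2 numeric, fractions of the contig median
#'   bounding conforming coverage (default `c(0.5, 2)`).
#' @param max_irregular Largest tolerated overlap with a single irregular-
#'   coverage interval, in bases (default 9).
#' @param flank_block `"snps+indels"` (default) or `"snps"`; whether indel
#'   positions also disqualify primer flanks.
#' @param outdir If non-NULL, scan outputs (TSV, BED, per-locus FASTA,
#'   allele database, run metadata JSON) are written there.
#' @param prefix Locus-identifier prefix (default `"Bc"`).
#' @param quiet Suppress per-step progress messages.
#' @return An object of class `sb_scan`: list with `loci` (metadata
#'   data.frame of universal loci), `catalogs` (their allele catalogues),
#'   `counts` (per-step tallies), `mask` (union coverage mask), `config`.
#' @export
run_scan <- function(reference, vcfs, depths, ploidy = 2L,
                     window_size = 500L, primer_size = 21L,
                     coverage_bounds = c(0.5, 2), max_irregular = 9L,
                     flank_block = c("snps+indels", "snps"),
                     outdir = NULL, prefix = "Bc", quiet = FALSE) {
  flank_block <- match.arg(flank_block)
  W <- as.integer(window_size); P <- as.integer(primer_size)
  if (2L * P >= W) stop("[config] primer_size must satisfy 2P < W")
  if (length(vcfs) < 1L) stop("[config] at least one strain is required")
  if (length(coverage_bounds) != 2L || coverage_bounds[1] >= 1 ||
      coverage_bounds[2] <= 1) {
    stop("[config] coverage bounds must bracket 1")
  }
  say <- function(...) if (!quiet) message(...)

  genome <- if (inherits(reference, "sb_genome")) reference else
    tryCatch(load_reference(reference),
             error = function(e) stop("[load_reference] ", conditionMessage(e)))

  strains <- names(vcfs)
  if (is.null(strains)) strains <- vapply(vcfs, `[[`, "", "strain")
  panel <- if (all(vapply(vcfs, inherits, TRUE, "sb_variants"))) vcfs else
    tryCatch(
      lapply(strains, function(st)
        load_strain_variants(vcfs[[st]], genome, st, ploidy)),
      error = function(e) stop("[load_strain_variants] ", conditionMessage(e)))
  names(panel) <- vapply(panel, `[[`, "", "strain")

  profiles <- if (all(vapply(depths, inherits, TRUE, "sb_depth"))) depths else
    tryCatch(
      lapply(names(panel), function(st)
        load_depth_table(depths[[st]], genome, st)),
      error = function(e) stop("[load_depth_table] ", conditionMessage(e)))

  # step 1: coverage masking
  masks <- tryCatch(
    lapply(profiles, irregular_intervals, genome = genome,
           low = coverage_bounds[1], high = coverage_bounds[2]),
    error = function(e) stop("[irregular_intervals] ", conditionMessage(e)))
  mask <- union_masks(masks)
  say("step 1: coverage mask spans ", sum(mask$end - mask$start), " of ",
      sum(contig_lengths(genome)), " bases (conforming: ",
      conforming_length(genome, mask), ")")

  # step 2: variable-site compilation
  index <- compile_variable_sites(panel, flank_block = flank_block)
  say("step 2: ", sum(lengths(index$snp)), " SNP position(s), ",
      sum(lengths(index$blocking)), " flank-blocking position(s)")

  # steps 3-4: window screen and merging, per contig
  lens <- contig_lengths(genome)
  possible <- count_possible_windows(genome, W)
  cand_list <- list()
  loci_list <- list()
  for (ctg in names(lens)) {
    cand <- scan_contig(lens[[ctg]],
                        if (is.null(index$snp[[ctg]])) integer() else index$snp[[ctg]],
                        if (is.null(index$blocking[[ctg]])) integer() else
                          index$blocking[[ctg]],
                        W, P)
    if (nrow(cand) > 0) {
      cand$contig <- ctg
      cand_list[[ctg]] <- cand
      m <- merge_windows(cand)
      m$contig <- ctg
      loci_list[[ctg]] <- m[, c("contig", "start", "end", "n_windows")]
    }
  }
  n_candidates <- sum(vapply(cand_list, nrow, 0L))
  merged <- do.call(rbind, c(loci_list, list(
    data.frame(contig = character(), start = integer(), end = integer(),
               n_windows = integer()))))
  rownames(merged) <- NULL
  say("step 3: ", n_candidates, " candidate window(s) of ", possible,
      " possible; step 4: ", nrow(merged), " merged locus/loci")

  # step 5: coverage exclusion
  surviving <- apply_coverage_exclusion(merged, mask, max_irregular)
  say("step 5: ", nrow(surviving), " locus/loci after coverage exclusion")

  # step 6: allele cataloguing; keep universal loci
  surviving <- assign_locus_ids(surviving, genome, prefix)
  catalogs <- list()
  stats_rows <- list()
  for (i in seq_len(nrow(surviving))) {
    ct <- build_allele_catalog(surviving[i, , drop = FALSE], genome, panel,
                               locus_id = surviving$locus_id[i])
    if (is.null(ct) || !ct$universal) next
    catalogs[[ct$locus_id]] <- ct
    stats_rows[[ct$locus_id]] <- locus_statistics(ct, panel)
  }
  stats <- do.call(rbind, c(stats_rows, list(NULL)))
  keep <- surviving[surviving$locus_id %in% names(catalogs), , drop = FALSE]
  loci <- if (nrow(keep) > 0) cbind(keep, stats, row.names = NULL) else
    cbind(keep, data.frame(n_snp_positions = integer(),
                           n_indel_positions = integer(),
                           n_alleles = integer(), n_strain_specific = integer(),
                           heterozygosity = numeric(), universal = logical()))
  say("step 6: ", nrow(loci), " universal barcode locus/loci")

  counts <- c(possible_windows = possible, candidates = n_candidates,
              merged = nrow(merged), after_coverage = nrow(surviving),
              universal = nrow(loci))
  config <- list(window_size = W, primer_size = P, ploidy = ploidy,
                 coverage_bounds = coverage_bounds,
                 max_irregular = max_irregular, flank_block = flank_block,
                 prefix = prefix)
  res <- structure(list(loci = loci, catalogs = catalogs, counts = counts,
                        mask = mask, per_strain_masks = masks,
                        config = config), class = "sb_scan")
  if (!is.null(outdir)) {
    emit_scan_outputs(catalogs, stats, outdir, prefix = "barcodes")
    if (length(catalogs) > 0) {
      write_allele_db(allele_db(catalogs), file.path(outdir, "alleles.fasta"))
    }
    meta <- list(tool = "strainbarcode",
                 version = as.character(utils::packageVersion("strainbarcode")),
                 config = config, counts = as.list(counts))
    jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' @export
print.sb_scan <- function(x, ...) {
  cat("Barcode scan (W=", x$config$window_size, ", P=", x$config$primer_size,
      ", ploidy=", x$config$ploidy, ")\n", sep = "")
  cat("  ", paste(names(x$counts), x$counts, sep = ": ", collapse = " | "),
      "\n", sep = "")
  if (nrow(x$loci) > 0) {
    print(x$loci[, c("locus_id", "contig", "start", "end", "n_snp_positions",
                     "n_alleles", "n_strain_specific", "heterozygosity")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Run the quantification workflow
#'
#' Matches an ASV count table against an allele database, partitions
#' shared-allele counts, and writes per-sample abundance and unmatched
#' reports.
#'
#' @param alleles Allele database data.frame or path to an allele FASTA
#'   written by [write_allele_db()].
#' @param counts ASV table data.frame (sample, sequence, count) or path to
#'   such a TSV.
#' @param min_minor_fraction Allelic-balance threshold (default 0.35).
#' @param outdir If non-NULL, abundance and unmatched TSVs are written there.
#' @param quiet Suppress progress messages.
#' @return An `sb_abundance` object.
#' @export
run_quantify <- function(alleles, counts, min_minor_fraction = 0.35,
                         outdir = NULL, quiet = FALSE) {
  db <- if (is.character(alleles))
    tryCatch(load_allele_db(alleles),
             error = function(e) stop("[load_allele_db] ", conditionMessage(e)))
  else alleles
  if (nrow(db) == 0L) stop("[load_allele_db] empty allele database")
  tab <- if (is.character(counts))
    tryCatch(load_asv_table(counts),
             error = function(e) stop("[load_asv_table] ", conditionMessage(e)))
  else counts
  res <- quantify_strains(tab, db, min_minor_fraction)
  if (!quiet && !is.null(res$unmatched)) {
    for (i in seq_len(nrow(res$unmatched))) {
      message("sample ", res$unmatched$sample[i], ": unmatched ASV fraction ",
              signif(res$unmatched$unmatched_fraction[i], 4))
    }
  }
  if (!is.null(outdir)) write_abundance_tables(res, outdir)
  res
}
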