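#' Generate a seeded synthetic truth set for the barcode pipeline
#'
#' Builds a random reference genome plus a panel of strains with planted
#' variation, and writes every input the scan needs: the reference FASTA,
#' one phased VCF and one depth table per strain, and a truth JSON.  The
#' first contig carries four engineered regions, each designed to exercise
#' exactly one rule of the scan:
#'
#' * a *planted universal locus*: one unique interior SNP per strain
#'   (assigned round-robin to haplotypes, so diploid strains are
#'   heterozygous), plus an insertion and a deletion on the first two
#'   strains when the panel allows, with clean primer flanks — every strain
#'   ends up with a strain-specific allele;
#' * a *shared-allele decoy*: two strains carry the identical SNP, so no
#'   strain has a strain-specific allele there (universality fails);
#' * a *coverage decoy*: per-strain unique SNPs as in the planted locus,
#'   but one strain's read depth is 3x its baseline over a stretch
#'   overlapping the region by well over ten bases (coverage exclusion
#'   fires);
#' * a *flank decoy*: SNPs gridded at primer-size spacing over more than a
#'   window length, so no window can present a SNP-free flank.
#'
#' Planted SNPs are spaced `primer_size + 2` apart, which keeps the merged
#' locus extent analytically predictable: with interior SNPs at positions
#' q1..qm the scan must return exactly `[q1 - W + P + 1, qm + W - P)`.
#' A benign 4-base coverage dip is planted inside the locus for one strain
#' to exercise the < 10-base tolerance.  Engineered regions are separated
#' by `2 (W - P)` bases so their windows can never merge.
#'
#' @param n_strains Number of strains (>= 2).
#' @param ploidy 1 (haploid) or 2 (phased diploid).
#' @param contig_lengths Named or unnamed integer vector of contig lengths;
#'   the first contig hosts the engineered regions and must be long enough
#'   (roughly `9 * window_size`... an informative error is raised if not).
#' @param window_size,primer_size Scan parameters the truth set is built
#'   for (defaults 500 and 21).
#' @param base_depth Baseline per-base read depth (default 20).
#' @param seed Integer seed; the same seed reproduces byte-identical files.
#' @param outdir Directory to write into (created if needed).
#' @return Invisibly, a list with `paths` (reference, vcf, depth, truth)
#'   and `truth` (the truth-set description, also written as JSON).
#' @export
generate_truth_set <- function(n_strains = 4L, ploidy = 2L,
                               contig_lengths = c(chr1 = 5000L, chr2 = 1500L),
                               window_size = 500L, primer_size = 21L,
                               base_depth = 20L, seed = 1L, outdir = tempfile()) {
  stopifnot(n_strains >= 2L, ploidy %in% c(1L, 2L),
            2L * primer_size < window_size, all(contig_lengths > 0))
  W <- as.integer(window_size); P <- as.integer(primer_size)
  set.seed(seed)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (is.null(names(contig_lengths))) {
    names(contig_lengths) <- paste0("chr", seq_along(contig_lengths))
  }
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(contig_lengths, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""), "")
  genome <- structure(list(seq = seqs), class = "sb_genome")
  ctg <- names(contig_lengths)[1]
  L1 <- contig_lengths[[1]]

  # region layout on contig 1
  spacing <- P + 2L
  planted_w <- (n_strains - 1L) * spacing + 8L   # room for the mid-cluster indels
  shared_w <- 1L
  cover_w <- (n_strains - 1L) * spacing + 1L
  n_grid <- (W + 2L * P) %/% P + 1L
  flank_w <- (n_grid - 1L) * P + 1L
  gap <- 2L * (W - P)
  margin <- W   # keeps merged extents clear of the contig ends
  starts <- margin + cumsum(c(0L, planted_w + gap, shared_w + gap, cover_w + gap))
  total <- starts[4] + flank_w + margin
  if (total > L1) {
    stop("first contig too short for the engineered layout: need >= ", total,
         " bp, have ", L1)
  }
  names(starts) <- c("planted", "shared", "coverage", "flank")

  base_at <- function(pos) substr(seqs[[ctg]], pos + 1L, pos + 1L)
  alt_of <- function(b) bases[match(b, bases) %% 4L + 1L]
  new_snp <- function(pos, hap) data.frame(
    contig = ctg, pos = pos, ref = base_at(pos), alt = alt_of(base_at(pos)),
    vclass = "SNP", haplotype = hap, stringsAsFactors = FALSE)

  variants <- stats::setNames(vector("list", n_strains),
                              sprintf("strain%02d", seq_len(n_strains)))
  strains <- names(variants)
  for (k in seq_len(n_strains)) variants[[k]] <- list()

  # planted universal locus: unique interior SNP per strain, round-robin haps
  p_pos <- starts["planted"] + (seq_len(n_strains) - 1L) * spacing
  hap_of <- (seq_len(n_strains) - 1L) %% ploidy
  for (k in seq_len(n_strains)) {
    variants[[k]] <- c(variants[[k]], list(new_snp(p_pos[k], hap_of[k])))
  }
  indel_pos <- integer()
  if (n_strains >= 4L && spacing >= 20L) {
    # INS for strain 1 and DEL for strain 2, tucked between the 2nd and 3rd
    # unique SNPs on the same haplotype as each strain's own SNP: mid-cluster
    # placement keeps both indels more than a primer length away from the
    # outermost SNPs, so the merged-locus extent stays analytically exact
    ins_at <- p_pos[2] + 11L
    del_at <- p_pos[2] + 15L
    variants[[1]] <- c(variants[[1]], list(data.frame(
      contig = ctg, pos = ins_at, ref = base_at(ins_at),
      alt = paste0(base_at(ins_at), "GT"), vclass = "INS",
      haplotype = hap_of[1], stringsAsFactors = FALSE)))
    variants[[2]] <- c(variants[[2]], list(data.frame(
      contig = ctg, pos = del_at,
      ref = substr(seqs[[ctg]], del_at + 1L, del_at + 3L),
      alt = base_at(del_at), vclass = "DEL",
      haplotype = hap_of[2], stringsAsFactors = FALSE)))
    indel_pos <- c(ins_at, del_at, del_at + 1L, del_at + 2L)
  }
  q1 <- min(p_pos)
  qm <- max(p_pos)
  expected_locus <- c(start = q1 - W + P + 1L, end = qm + W - P)

  # shared-allele decoy: strains 1 and 2 carry the identical SNP on hap 0
  s_pos <- starts["shared"]
  for (k in 1:2) variants[[k]] <- c(variants[[k]], list(new_snp(s_pos, 0L)))

  # coverage decoy: looks universal, but strain 1 depth is 3x baseline there
  c_pos <- starts["coverage"] + (seq_len(n_strains) - 1L) * spacing
  for (k in seq_len(n_strains)) {
    variants[[k]] <- c(variants[[k]], list(new_snp(c_pos[k], hap_of[k])))
  }
  anomaly <- c(start = starts[["coverage"]] - 10L,
               end = starts[["coverage"]] + 50L)

  # flank decoy: SNP grid at primer-size spacing over more than one window
  f_pos <- starts["flank"] + (seq_len(n_grid) - 1L) * P
  for (g in f_pos) variants[[1]] <- c(variants[[1]], list(new_snp(g, 0L)))

  panel <- lapply(strains, function(st) {
    v <- do.call(rbind, variants[[st]])
    v <- v[order(v$contig, v$pos), , drop = FALSE]
    rownames(v) <- NULL
    structure(list(strain = st, ploidy = ploidy, variants = v,
                   skipped = c(ref_only = 0L, missing = 0L, symbolic = 0L,
                               ploidy_conflict = 0L),
                   ploidy_conflict = FALSE), class = "sb_variants")
  })
  names(panel) <- strains

  # truth haplotypes over the expected locus, by direct string surgery
  ref_slice <- substr(seqs[[ctg]], expected_locus["start"] + 1L,
                      expected_locus["end"])
  surgery <- function(slice, v) {
    if (nrow(v) == 0L) return(slice)
    v <- v[order(-v$pos), , drop = FALSE]
    for (i in seq_len(nrow(v))) {
      off <- v$pos[i] - expected_locus[["start"]]
      slice <- paste0(substr(slice, 1L, off), v$alt[i],
                      substr(slice, off + nchar(v$ref[i]) + 1L, nchar(slice)))
    }
    slice
  }
  truth_haps <- lapply(panel, function(sv) {
    v <- sv$variants
    v <- v[v$contig == ctg & v$pos >= expected_locus["start"] &
             v$pos < expected_locus["end"], , drop = FALSE]
    vapply(seq_len(ploidy) - 1L, function(h)
      surgery(ref_slice, v[v$haplotype == h, , drop = FALSE]), "")
  })

  # write files
  ref_path <- file.path(outdir, "reference.fasta")
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(seqs, names(contig_lengths))),
    ref_path)
  vcf_paths <- stats::setNames(
    file.path(outdir, paste0(strains, ".vcf")), strains)
  for (st in strains) write_fixture_vcf(panel[[st]], vcf_paths[[st]])

  depth_paths <- stats::setNames(
    file.path(outdir, paste0(strains, ".depth.tsv")), strains)
  dip <- c(start = q1 + 2L, end = q1 + 6L)   # benign < 10-base anomaly
  for (k in seq_len(n_strains)) {
    lines <- character()
    for (cn in names(contig_lengths)) {
      d <- rep(base_depth, contig_lengths[[cn]])
      if (cn == ctg) {
        if (k == 1L) d[(anomaly["start"] + 1L):anomaly["end"]] <- 3L * base_depth
        if (k == 2L) d[(dip["start"] + 1L):dip["end"]] <-
            as.integer(floor(0.4 * base_depth))
      }
      lines <- c(lines, paste(cn, seq_along(d), d, sep = "\t"))
    }
    writeLines(lines, depth_paths[[k]])
  }

  truth <- list(
    seed = seed, n_strains = n_strains, ploidy = ploidy,
    window_size = W, primer_size = P, base_depth = base_depth,
    contig_lengths = as.list(contig_lengths),
    strains = strains,
    planted_locus = list(contig = ctg,
                         cluster = c(start = q1, end = qm + 1L),
                         expected = as.list(expected_locus),
                         snp_positions = as.integer(p_pos),
                         indel_positions = as.integer(indel_pos),
                         haplotypes = truth_haps,
                         expected_universal = TRUE,
                         expected_heterozygosity = if (ploidy == 2L) 1 else 0,
                         expected_n_alleles = n_strains + (ploidy == 2L)),
    decoys = list(
      shared = list(contig = ctg, pos = s_pos, strains = strains[1:2]),
      coverage = list(contig = ctg,
                      cluster = c(start = min(c_pos), end = max(c_pos) + 1L),
                      anomaly = as.list(anomaly), strain = strains[1]),
      flank = list(contig = ctg,
                   span = c(start = min(f_pos), end = max(f_pos) + 1L))),
    benign_dip = as.list(dip),
    variants = lapply(panel, `[[`, "variants"))
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)

  invisible(list(paths = list(reference = ref_path, vcf = vcf_paths,
                              depth = depth_paths, truth = truth_path),
                 truth = truth, genome = genome, panel = panel))
}

# minimal phased VCFv4.2 writer for fixture panels (not a general writer)
write_fixture_vcf <- function(sv, path) {
  v <- sv$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sv$strain))
  recs <- character()
  if (nrow(v) > 0) {
    key <- paste(v$contig, v$pos, v$ref, v$alt)
    for (k in unique(key)) {
      rows <- v[key == k, , drop = FALSE]
      gt <- rep("0", sv$ploidy)
      gt[rows$haplotype + 1L] <- "1"
      recs <- c(recs, paste(rows$contig[1], rows$pos[1] + 1L, ".", rows$ref[1],
                            rows$alt[1], ".", "PASS", ".", "GT",
                            paste(gt, collapse = "|"), sep = "\t"))
    }
    ord <- order(vapply(strsplit(recs, "\t"), `[[`, "", 1L),
                 as.integer(vapply(strsplit(recs, "\t"), `[[`, "", 2L)))
    recs <- recs[ord]
  }
  writeLines(c(hdr, recs), path)
}

#' Simulate an amplicon-sequence-variant count table from known abundances
#'
#' Draws `n_reads` amplicons multinomially from the allele frequencies
#' implied by the given strain abundances: a strain's abundance is split
#' evenly across its haplotypes, so a heterozygous diploid contributes half
#' its abundance to each allele and a homozygote all of it to one.  A
#' binomially-drawn fraction `chimera_rate` of reads is replaced by
#' left/right recombinants of two frequency-sampled alleles with a uniform
#' breakpoint; chimeras that coincide with a genuine allele ("perfect
#' fakes") are recorded in the returned truth.
#'
#' @param catalog An `sb_allele_catalog` (supplies per-strain haplotype to
#'   allele assignments).
#' @param abundances Named vector of true strain abundances, summing to 1,
#'   names matching the catalogue's strains.
#' @param n_reads Total amplicon count to draw (> 0).
#' @param chimera_rate Fraction of reads replaced by PCR chimeras, in [0, 1].
#' @param seed Integer seed.
#' @param sample_id Sample name in the output table.
#' @return List with `table` (data.frame sample, sequence, count),
#'   `expected_freq` (named by allele sequence) and `truth` (n_chimeric,
#'   perfect-fake collision counts per allele sequence).
#' @export
synthesize_asv_counts <- function(catalog, abundances, n_reads = 100000L,
                                  chimera_rate = 0, seed = 1L,
                                  sample_id = "s1") {
  stopifnot(inherits(catalog, "sb_allele_catalog"), n_reads > 0)
  if (chimera_rate < 0 || chimera_rate > 1) stop("chimera_rate must be in [0, 1]")
  if (abs(sum(abundances) - 1) > 1e-8) stop("abundances must sum to 1")
  if (!setequal(names(abundances), catalog$strains)) {
    stop("abundance names must match the catalogue strains")
  }
  set.seed(seed)
  freq <- stats::setNames(numeric(nrow(catalog$alleles)),
                          catalog$alleles$sequence)
  for (st in catalog$strains) {
    haps <- catalog$haplotypes[[st]]
    for (h in haps) freq[h] <- freq[h] + abundances[[st]] / length(haps)
  }
  n_chim <- stats::rbinom(1L, n_reads, chimera_rate)
  real <- stats::rmultinom(1L, n_reads - n_chim, freq)[, 1L]
  counts <- stats::setNames(as.integer(real), names(freq))
  collisions <- integer()
  if (n_chim > 0) {
    iA <- sample.int(length(freq), n_chim, replace = TRUE, prob = freq)
    iB <- sample.int(length(freq), n_chim, replace = TRUE, prob = freq)
    for (j in seq_len(n_chim)) {
      A <- names(freq)[iA[j]]
      B <- names(freq)[iB[j]]
      cut <- sample.int(min(nchar(A), nchar(B)) - 1L, 1L)
      chim <- paste0(substr(A, 1L, cut), substr(B, cut + 1L, nchar(B)))
      if (chim %in% names(freq)) {
        collisions[chim] <- if (chim %in% names(collisions))
          collisions[[chim]] + 1L else 1L
      }
      counts[chim] <- if (chim %in% names(counts)) counts[[chim]] + 1L else 1L
    }
  }
  counts <- counts[counts > 0L]
  list(table = data.frame(sample = sample_id, sequence = names(counts),
                          count = unname(counts), stringsAsFactors = FALSE),
       expected_freq = freq,
       truth = list(n_chimeric = n_chim, collisions = collisions))
}
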