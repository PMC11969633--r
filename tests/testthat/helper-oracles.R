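# Independent brute-force oracles and fixture builders shared across tests.
# Everything here is deliberately naive: per-position logical vectors and
# per-start loops, so the fast implementations are checked against a
# different computation path.

# genome object from named character sequences
toy_genome <- function(...) {
  structure(list(seq = toupper(c(...))), class = "sb_genome")
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# depth profile from per-contig integer vectors
toy_depth <- function(strain, ...) {
  structure(list(strain = strain, depth = list(...)), class = "sb_depth")
}

# one-strain variant table row
vrow <- function(contig, pos, ref, alt, haplotype = 0L) {
  data.frame(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
             haplotype = as.integer(haplotype), stringsAsFactors = FALSE)
}

# naive per-start window scan: the oracle scan_contig must reproduce
naive_scan <- function(contig_length, snp_pos, blocking_pos, W, P) {
  snp <- logical(contig_length)
  blk <- logical(contig_length)
  snp[snp_pos + 1L] <- TRUE
  blk[blocking_pos + 1L] <- TRUE
  keep <- integer()
  if (W <= contig_length) {
    for (s in 0:(contig_length - W)) {
      left <- blk[(s + 1):(s + P)]
      right <- blk[(s + W - P + 1):(s + W)]
      interior <- snp[(s + P + 1):(s + W - P)]
      if (!any(left) && !any(right) && any(interior)) keep <- c(keep, s)
    }
  }
  keep
}

# naive per-position coverage mask: positions with depth < low*m or > high*m
naive_mask_positions <- function(depths, low = 0.5, high = 2.0) {
  m <- stats::median(depths)
  which(depths < low * m | depths > high * m) - 1L
}

# random strain panel on a single contig, for property tests
random_panel <- function(contig, contig_length, n_strains, ploidy,
                         n_var_per_strain = 8) {
  lapply(seq_len(n_strains), function(k) {
    n <- sample.int(n_var_per_strain, 1L)
    pos <- sample.int(contig_length - 4L, n) - 1L
    rows <- lapply(pos, function(p) {
      kind <- sample(c("SNP", "INS", "DEL"), 1L, prob = c(0.7, 0.15, 0.15))
      ref1 <- "A"   # placeholder; class checks only need lengths
      if (kind == "SNP") vrow(contig, p, "A", "C", sample.int(ploidy, 1L) - 1L)
      else if (kind == "INS") vrow(contig, p, "A", "ACT",
                                   sample.int(ploidy, 1L) - 1L)
      else vrow(contig, p, "ACT", "A", sample.int(ploidy, 1L) - 1L)
    })
    strain_variants(sprintf("s%02d", k), ploidy, do.call(rbind, rows))
  })
}

# brute-force allele catalogue summary from haplotype sequence sets
brute_catalog <- function(haplotypes) {
  strains <- names(haplotypes)
  seqs <- unlist(haplotypes, use.names = FALSE)
  carrier <- rep(strains, times = lengths(haplotypes))
  alleles <- unique(seqs)
  carriers <- lapply(alleles, function(a) unique(carrier[seqs == a]))
  specific <- vapply(seq_along(alleles), function(i)
    length(carriers[[i]]) == 1L, logical(1))
  spec_count <- vapply(strains, function(st)
    sum(vapply(seq_along(alleles), function(i)
      specific[i] && carriers[[i]][1] == st, logical(1))), integer(1))
  list(n_alleles = length(alleles), specific_counts = spec_count,
       universal = all(spec_count >= 1L))
}

# write a small VCF from header + record lines
write_vcf <- function(path, records, sample = "s1") {
  writeLines(c("##fileformat=VCFv4.2",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample),
               records), path)
}

vcf_rec <- function(chrom, pos, ref, alt, gt) {
  paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gt, sep = "\t")
}
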