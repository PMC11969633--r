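#' Compile the variable-site index from a strain panel
#'
#' Unions variant positions over all strains and haplotypes into two
#' per-contig sorted position lists: `snp` (SNP positions, which make a
#' window interior variable) and `blocking` (positions that disqualify a
#' primer flank).  A SNP blocks its own position; a deletion blocks every
#' reference base it spans, `[pos, pos + nchar(ref))`; an insertion blocks
#' its anchor base.  Whether indels block flanks at all is controlled by
#' `flank_block` — the stricter `"snps+indels"` default reflects that an
#' indel under a primer destroys the binding site, while `"snps"` restricts
#' blocking to SNP positions only.
#'
#' @param panel A list of `sb_variants` objects.
#' @param flank_block `"snps+indels"` (default) or `"snps"`.
#' @return An object of class `sb_site_index`: list with per-contig sorted
#'   deduplicated integer vectors `snp` and `blocking`.
#' @export
compile_variable_sites <- function(panel, flank_block = c("snps+indels", "snps")) {
  flank_block <- match.arg(flank_block)
  stopifnot(all(vapply(panel, inherits, TRUE, "sb_variants")))
  v <- do.call(rbind, lapply(panel, `[[`, "variants"))
  snp <- list()
  blocking <- list()
  if (!is.null(v) && nrow(v) > 0) {
    for (ctg in unique(v$contig)) {
      vc <- v[v$contig == ctg, , drop = FALSE]
      s <- sort(unique(vc$pos[vc$vclass == "SNP"]))
      b <- s
      if (flank_block == "snps+indels") {
        ins <- vc[vc$vclass == "INS", , drop = FALSE]
        del <- vc[vc$vclass == "DEL", , drop = FALSE]
        b <- c(b, ins$pos)
        if (nrow(del) > 0) {
          b <- c(b, unlist(mapply(seq.int, del$pos, del$pos + nchar(del$ref) - 1L,
                                  SIMPLIFY = FALSE)))
        }
      }
      snp[[ctg]] <- s
      blocking[[ctg]] <- sort(unique(as.integer(b)))
    }
  }
  structure(list(snp = snp, blocking = blocking), class = "sb_site_index")
}

#' Number of possible windows of a given size in a genome
#'
#' Sums `max(0, L - W + 1)` over contigs, i.e. the number of start positions
#' a step-1 sliding window of width `W` can take.
#'
#' @param genome An `sb_genome`.
#' @param window_size Window width in bases (>= 1).
#' @return Integer-valued count (as double, to avoid overflow on large genomes).
#' @export
count_possible_windows <- function(genome, window_size) {
  stopifnot(window_size >= 1)
  L <- contig_lengths(genome)
  sum(pmax(0, L - window_size + 1))
}

# number of sorted positions falling in [from, to) for each (from, to) pair
.count_in <- function(sorted_pos, from, to) {
  findInterval(to - 1L, sorted_pos) - findInterval(from - 1L, sorted_pos)
}

#' Scan one contig for candidate barcode windows
#'
#' Slides a window of width `W` with step 1 over a contig and keeps a start
#' `s` iff (a) the two primer flanks `[s, s+P)` and `[s+W-P, s+W)` contain no
#' flank-blocking position, and (b) the interior `[s+P, s+W-P)` contains at
#' least one SNP position.
#'
#' @param contig_length Contig length in bases.
#' @param snp_pos Sorted SNP positions on the contig (0-based).
#' @param blocking_pos Sorted flank-blocking positions on the contig.
#' @param window_size,primer_size Window width `W` and flank width `P`;
#'   `2P < W` is required.
#' @return Data.frame of kept windows with columns start, end (0-based
#'   half-open, width exactly `W`), sorted by start.
#' @export
scan_contig <- function(contig_length, snp_pos, blocking_pos,
                        window_size, primer_size) {
  W <- as.integer(window_size)
  P <- as.integer(primer_size)
  stopifnot(2L * P < W)
  if (W > contig_length || length(snp_pos) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  s <- 0:(contig_length - W)
  left_clear <- .count_in(blocking_pos, s, s + P) == 0L
  right_clear <- .count_in(blocking_pos, s + W - P, s + W) == 0L
  interior_var <- .count_in(snp_pos, s + P, s + W - P) >= 1L
  keep <- s[left_clear & right_clear & interior_var]
  data.frame(start = keep, end = keep + W)
}

#' Merge overlapping candidate windows into barcode loci
#'
#' Takes the kept windows of one contig (sorted by start) and merges the
#' transitive closure of the strict-overlap relation into maximal intervals
#' `[min start, max end)`.  Touching-but-not-overlapping windows stay
#' separate.  The merged locus keeps conserved flanks by construction: its
#' left flank is the first window's left flank and its right flank the last
#' window's right flank.
#'
#' @param candidates Data.frame with columns start, end from [scan_contig()].
#' @return Data.frame with columns start, end, n_windows.
#' @export
merge_windows <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(data.frame(start = integer(), end = integer(), n_windows = integer()))
  }
  o <- order(candidates$start, candidates$end)
  st <- candidates$start[o]
  en <- candidates$end[o]
  grp <- cumsum(c(1L, as.integer(st[-1] >= cummax(en[-length(en)]))))
  data.frame(start = as.integer(tapply(st, grp, min)),
             end = as.integer(tapply(en, grp, max)),
             n_windows = as.integer(tapply(st, grp, length)),
             row.names = NULL)
}

#' Drop loci that overlap irregular-coverage regions
#'
#' A locus is excluded iff its overlap with any single masked interval is
#' ten bases or more; shorter overlaps (which often reflect small,
#' potentially informative indels) are tolerated.
#'
#' @param loci Data.frame with columns contig, start, end.
#' @param mask Union mask intervals (contig, start, end).
#' @param max_irregular Largest tolerated per-interval overlap in bases
#'   (default 9, i.e. exclusion at >= 10).
#' @return The surviving rows of `loci`.
#' @export
apply_coverage_exclusion <- function(loci, mask, max_irregular = 9L) {
  if (nrow(loci) == 0L || nrow(mask) == 0L) return(loci)
  excluded <- vapply(seq_len(nrow(loci)), function(i) {
    m <- mask[mask$contig == loci$contig[i], , drop = FALSE]
    if (nrow(m) == 0L) return(FALSE)
    ov <- pmin(m$end, loci$end[i]) - pmax(m$start, loci$start[i])
    any(ov > max_irregular)
  }, logical(1))
  out <- loci[!excluded, , drop = FALSE]
  rownames(out) <- NULL
  out
}
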