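#' Per-strain intervals of irregular read coverage
#'
#' Flags every position whose depth is below 50% or above 200% of the
#' contig median for that strain, and returns maximal runs of flagged
#' positions as 0-based half-open intervals.  The median is taken over all
#' positions of the contig, zeros included, with the usual mean-of-central-
#' pair rule for even lengths; depths exactly at the 50%/200% boundary are
#' kept.  A contig with median 0 is masked entirely (with a warning) since
#' no position can be called conforming against a zero baseline.
#'
#' @param profile An `sb_depth` object for one strain.
#' @param genome An `sb_genome`; every contig must be covered by the profile.
#' @param low,high Fractions of the contig median bounding conforming
#'   coverage (defaults 0.5 and 2.0; comparisons are strict).
#' @return A data.frame with columns contig, start, end (0-based half-open),
#'   sorted, non-overlapping, adjacent runs merged.
#' @export
irregular_intervals <- function(profile, genome, low = 0.5, high = 2.0) {
  stopifnot(inherits(profile, "sb_depth"), inherits(genome, "sb_genome"))
  lens <- contig_lengths(genome)
  missing <- setdiff(names(lens), names(profile$depth))
  if (length(missing)) {
    stop("depth profile missing contig(s): ", paste(missing, collapse = ", "))
  }
  res <- lapply(names(lens), function(ctg) {
    d <- profile$depth[[ctg]]
    m <- stats::median(d)
    if (m == 0) {
      warning("contig ", ctg, " has median depth 0 for strain ",
              profile$strain, "; fully masked")
      return(data.frame(contig = ctg, start = 0L, end = lens[[ctg]]))
    }
    bad <- d < low * m | d > high * m
    runs_to_intervals(bad, ctg)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# maximal runs of TRUE in a logical vector -> 0-based half-open intervals
runs_to_intervals <- function(flag, contig) {
  if (!any(flag)) {
    return(data.frame(contig = character(), start = integer(), end = integer()))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(contig = contig, start = starts[keep], end = ends[keep])
}

#' Union of per-strain coverage masks
#'
#' Merges the irregular-coverage intervals of several strains into one
#' sorted, non-overlapping interval set per contig.  A region unusable in
#' any single strain cannot host a universal barcode, so downstream window
#' exclusion runs against this union.
#'
#' @param masks A list of interval data.frames (contig, start, end) as
#'   returned by [irregular_intervals()].
#' @return One interval data.frame, the union, adjacent runs merged.
#' @export
union_masks <- function(masks) {
  stopifnot(is.list(masks))
  all <- do.call(rbind, c(masks, list(empty_intervals())))
  if (nrow(all) == 0L) return(empty_intervals())
  res <- lapply(split(all, all$contig), function(df) {
    ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
    data.frame(contig = df$contig[1L],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  })
  out <- do.call(rbind, res[order(names(res))])
  rownames(out) <- NULL
  out
}

empty_intervals <- function() {
  data.frame(contig = character(), start = integer(), end = integer())
}

#' Genome length conforming to the coverage filter
#'
#' @param genome An `sb_genome`.
#' @param mask Union mask intervals (contig, start, end).
#' @return Total genome length minus total masked bases.
#' @export
conforming_length <- function(genome, mask) {
  stopifnot(inherits(genome, "sb_genome"))
  sum(contig_lengths(genome)) - sum(mask$end - mask$start)
}
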