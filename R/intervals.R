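#' Genomic interval tibbles
#'
#' All peak and site arithmetic in m6ascape runs on plain tibbles with columns
#' `chrom`, `start`, `end`, `strand`: 0-based, half-open (`start` inclusive,
#' `end` exclusive), strand one of `"+"`/`"-"`. BED files use the same
#' convention, so rows round-trip through BED unchanged. Internally intervals
#' are lifted to [GenomicRanges::GRanges] for overlap queries.
#'
#' @param chrom,start,end,strand vectors defining the intervals.
#' @param ... further columns carried along (e.g. `peak_id`, `score`).
#' @return A tibble with at least the four interval columns.
#' @examples
#' interval_tbl("chr1", 100, 200, "+", peak_id = "p1")
#' @export
interval_tbl <- function(chrom, start, end, strand = "+", ...) {
  x <- tibble(chrom = as.character(chrom), start = as.integer(start),
              end = as.integer(end), strand = as.character(strand), ...)
  validate_intervals(x)
}

validate_intervals <- function(x, arg = "intervals") {
  need <- c("chrom", "start", "end", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s must have columns %s (missing: %s)", arg,
                  paste(need, collapse = ", "), paste(miss, collapse = ", ")))
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    abort(sprintf("%s must satisfy 0 <= start < end (half-open coordinates)", arg))
  }
  if (!all(x$strand %in% c("+", "-"))) {
    abort(sprintf("%s strand must be '+' or '-'", arg))
  }
  as_tibble(x)
}

# 0-based half-open tibble -> 1-based closed GRanges
tbl_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = x$strand
  )
}

gr_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

# index pairs (a_idx, b_idx) of >=1 bp same-strand overlaps
overlap_pairs <- function(a, b) {
  hits <- GenomicRanges::findOverlaps(tbl_to_gr(a), tbl_to_gr(b),
                                      ignore.strand = FALSE)
  tibble(a_idx = S4Vectors::queryHits(hits), b_idx = S4Vectors::subjectHits(hits))
}

# logical: does each row of a overlap any row of b (same strand by default)
overlaps_any <- function(a, b, ignore_strand = FALSE) {
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  GenomicRanges::countOverlaps(tbl_to_gr(a), tbl_to_gr(b),
                               ignore.strand = ignore_strand) > 0
}

interval_midpoint <- function(x) (x$start + x$end) %/% 2L
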