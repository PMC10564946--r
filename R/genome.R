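#' Genome sequences as named character vectors
#'
#' A genome is represented as a named character vector (or
#' [Biostrings::DNAStringSet]) of uppercase chromosome sequences over
#' `A,C,G,T,N`. Minus-strand queries return the reverse complement, so a
#' sequence fetched for an interval always reads 5'->3' on the strand of the
#' interval.
#'
#' @param genome named character vector or `DNAStringSet` of chromosomes.
#' @return A `DNAStringSet` with uppercase sequences.
#' @export
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    gs <- genome
  } else {
    if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
      abort("genome must be a named vector of chromosome sequences")
    }
    gs <- Biostrings::DNAStringSet(toupper(unlist(genome)))
  }
  if (is.null(names(gs))) abort("genome sequences must be named by chromosome")
  gs
}

#' Fetch strand-aware sequences for intervals
#'
#' @param intervals interval tibble (see [interval_tbl()]).
#' @param genome genome as accepted by [as_genome()].
#' @return Character vector of sequences, reverse-complemented on `-` strand.
#' @export
interval_seq <- function(intervals, genome) {
  intervals <- validate_intervals(intervals)
  gs <- as_genome(genome)
  bad <- !(intervals$chrom %in% names(gs))
  if (any(bad)) {
    abort(sprintf("chromosome(s) absent from genome: %s",
                  paste(unique(intervals$chrom[bad]), collapse = ", ")))
  }
  lens <- Biostrings::width(gs)[match(intervals$chrom, names(gs))]
  if (any(intervals$end > lens)) {
    abort("interval end beyond chromosome length")
  }
  views <- Biostrings::DNAStringSet(
    mapply(function(ch, s, e) Biostrings::subseq(gs[[ch]], start = s + 1L, end = e),
           intervals$chrom, intervals$start, intervals$end, SIMPLIFY = FALSE)
  )
  neg <- intervals$strand == "-"
  if (any(neg)) views[neg] <- Biostrings::reverseComplement(views[neg])
  as.character(views)
}

# single-base lookup, genome strand (no revcomp); 0-based position
base_at <- function(genome, chrom, pos) {
  gs <- as_genome(genome)
  if (!chrom %in% names(gs)) abort(sprintf("chromosome %s absent from genome", chrom))
  if (pos < 0 || pos >= length(gs[[chrom]])) {
    abort("position outside genome bounds")
  }
  as.character(Biostrings::subseq(gs[[chrom]], pos + 1L, pos + 1L))
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]
}
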