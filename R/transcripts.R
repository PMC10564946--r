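#' Transcript models
#'
#' Bundle of two tibbles describing gene annotation with one canonical
#' transcript per gene: `transcripts` with columns `gene_id`, `transcript_id`,
#' `chrom`, `start`, `end`, `strand`, `cds_start`, `cds_end` (0-based half-open
#' genomic CDS span, both `NA` for non-coding) and `is_canonical`; and `exons`
#' with `transcript_id`, `chrom`, `start`, `end`, `strand`. Exons must be
#' sorted, non-overlapping and contained in the transcript span; a coding CDS
#' must lie inside exonic space.
#'
#' @param transcripts,exons tibbles as described above.
#' @return An object of class `transcript_models`.
#' @export
transcript_models <- function(transcripts, exons) {
  transcripts <- as_tibble(transcripts)
  exons <- as_tibble(exons)
  validate_intervals(transcripts, "transcripts")
  validate_intervals(exons, "exons")
  if (!all(c("gene_id", "transcript_id", "is_canonical") %in% names(transcripts))) {
    abort("transcripts needs gene_id, transcript_id, is_canonical columns")
  }
  if (!"transcript_id" %in% names(exons)) abort("exons needs a transcript_id column")
  if (!all(c("cds_start", "cds_end") %in% names(transcripts))) {
    transcripts$cds_start <- NA_integer_
    transcripts$cds_end <- NA_integer_
  }

  dup <- transcripts |>
    filter(.data$is_canonical) |>
    count(.data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("more than one canonical transcript for gene(s): %s",
                  paste(dup$gene_id, collapse = ", ")))
  }

  # per-transcript exon structure checks
  ex_split <- split(exons, exons$transcript_id)
  for (tid in names(ex_split)) {
    ex <- arrange(ex_split[[tid]], .data$start)
    tx <- filter(transcripts, .data$transcript_id == tid)
    if (nrow(tx) == 0) abort(sprintf("exons reference unknown transcript %s", tid))
    if (any(ex$start < tx$start) || any(ex$end > tx$end)) {
      abort(sprintf("exons of %s extend beyond the transcript span", tid))
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      abort(sprintf("exons of %s overlap", tid))
    }
  }

  coding <- filter(transcripts, !is.na(.data$cds_start))
  if (any(coding$cds_start >= coding$cds_end)) {
    abort("coding transcripts must have cds_start < cds_end")
  }

  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("<transcript_models> %d transcripts (%d canonical), %d exons\n",
              nrow(x$transcripts), sum(x$transcripts$is_canonical),
              nrow(x$exons)))
  invisible(x)
}

canonical_tx <- function(tm) filter(tm$transcripts, .data$is_canonical)

tx_exons <- function(tm, tid) {
  filter(tm$exons, .data$transcript_id == tid) |> arrange(.data$start)
}

# genomic sub-intervals of the canonical transcript `tx` (one-row tibble)
# classified as 5UTR / CDS / 3UTR exonic space, NULL for non-coding
tx_regions <- function(tm, tx) {
  ex <- tx_exons(tm, tx$transcript_id)
  if (is.na(tx$cds_start)) return(NULL)
  exr <- IRanges::IRanges(ex$start + 1L, ex$end)
  cdsr <- IRanges::IRanges(tx$cds_start + 1L, tx$cds_end)
  if (tx$strand == "+") {
    utr5r <- IRanges::IRanges(tx$start + 1L, max(tx$start, tx$cds_start))
    utr3r <- IRanges::IRanges(min(tx$end, tx$cds_end + 1L), tx$end)
  } else {
    utr5r <- IRanges::IRanges(min(tx$end, tx$cds_end + 1L), tx$end)
    utr3r <- IRanges::IRanges(tx$start + 1L, max(tx$start, tx$cds_start))
  }
  as_tbl <- function(r, what) {
    r <- IRanges::intersect(r, exr)
    r <- r[IRanges::width(r) > 0]
    if (length(r) == 0) return(NULL)
    tibble(chrom = tx$chrom, start = IRanges::start(r) - 1L,
           end = IRanges::end(r), strand = tx$strand, region = what)
  }
  bind_rows(as_tbl(utr5r, "5UTR"), as_tbl(cdsr, "CDS"), as_tbl(utr3r, "3UTR"))
}

# genomic position (0-based) of the first base of the start / last base region
# of the stop codon for a coding transcript row
codon_positions <- function(tx) {
  if (tx$strand == "+") {
    list(start_codon = tx$cds_start, stop_codon = tx$cds_end - 3L)
  } else {
    list(start_codon = tx$cds_end - 3L, stop_codon = tx$cds_start)
  }
}

# map genomic position to spliced-transcript coordinate (0-based from TSS);
# NA if the position is not exonic
genomic_to_tx <- function(tm, tx, gpos) {
  ex <- tx_exons(tm, tx$transcript_id)
  cum <- cumsum(ex$end - ex$start)
  offs <- c(0L, head(cum, -1))
  hit <- which(gpos >= ex$start & gpos < ex$end)
  if (length(hit) == 0) return(NA_integer_)
  pos_plus <- offs[hit] + (gpos - ex$start[hit])
  total <- sum(ex$end - ex$start)
  if (tx$strand == "+") pos_plus else total - 1L - pos_plus
}
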