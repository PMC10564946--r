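#' Read and write 6-column BED
#'
#' BED is 0-based half-open, matching the package's interval convention, so
#' coordinates round-trip unchanged. The `name` field maps to `name` and is
#' split into `sample_id`/`caller` by [read_bed_peaks()] when it has the
#' `sample:caller` form.
#'
#' @param path file path.
#' @return Interval tibble with `name` and `score` columns.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                           "score", "strand"),
                       col_types = "ciicdc", comment = "#")
  validate_intervals(x)
}

#' @rdname read_bed
#' @param x interval tibble; missing `name`/`score` filled with `.`/`0`.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  nm <- if ("name" %in% names(x)) x$name
        else if ("peak_id" %in% names(x)) x$peak_id
        else rep(".", nrow(x))
  sc <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
  out <- tibble(chrom = x$chrom, start = x$start, end = x$end,
                name = nm, score = sc, strand = x$strand)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname read_bed
#' @export
read_bed_peaks <- function(path) {
  x <- read_bed(path)
  parts <- stringr::str_split_fixed(x$name, ":", 2)
  mutate(x, sample_id = parts[, 1],
         caller = if_else(parts[, 2] == "", NA_character_, parts[, 2]))
}

#' Write and read transcript models as GTF
#'
#' Standard 9-column GTF (1-based closed intervals on disk, converted to the
#' package's 0-based half-open convention in memory). Canonical transcripts
#' carry `tag "canonical"`; CDS features span the genomic CDS interval.
#'
#' @param tm a [transcript_models] object.
#' @param path file path.
#' @export
write_gtf <- function(tm, path) {
  tx <- tm$transcripts
  attr_str <- function(gid, tid, canonical) {
    s <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    if_else(rep_len(canonical, length(s)), paste(s, 'tag "canonical";'), s)
  }
  rows_tx <- tibble(
    seqname = tx$chrom, source = "m6ascape", feature = "transcript",
    start = tx$start + 1L, end = tx$end, score = ".", strand = tx$strand,
    frame = ".", attribute = attr_str(tx$gene_id, tx$transcript_id,
                                      tx$is_canonical)
  )
  ex <- inner_join(tm$exons,
                   select(tx, "transcript_id", "gene_id", "is_canonical"),
                   by = "transcript_id")
  rows_ex <- tibble(
    seqname = ex$chrom, source = "m6ascape", feature = "exon",
    start = ex$start + 1L, end = ex$end, score = ".", strand = ex$strand,
    frame = ".", attribute = attr_str(ex$gene_id, ex$transcript_id, FALSE)
  )
  cds <- filter(tx, !is.na(.data$cds_start))
  rows_cds <- tibble(
    seqname = cds$chrom, source = "m6ascape", feature = "CDS",
    start = cds$cds_start + 1L, end = cds$cds_end, score = ".",
    strand = cds$strand, frame = "0",
    attribute = attr_str(cds$gene_id, cds$transcript_id, FALSE)
  )
  readr::write_tsv(bind_rows(rows_tx, rows_ex, rows_cds), path,
                   col_names = FALSE, escape = "none")
  invisible(path)
}

#' @rdname write_gtf
#' @return `read_gtf()` returns a [transcript_models] object.
#' @export
read_gtf <- function(path) {
  g <- readr::read_tsv(path, col_names = c("seqname", "source", "feature",
                                           "start", "end", "score", "strand",
                                           "frame", "attribute"),
                       col_types = "ccciicccc", comment = "#")
  get_attr <- function(s, key) {
    stringr::str_match(s, sprintf('%s "([^"]*)"', key))[, 2]
  }
  g <- mutate(g, gene_id = get_attr(.data$attribute, "gene_id"),
              transcript_id = get_attr(.data$attribute, "transcript_id"))
  txf <- filter(g, .data$feature == "transcript")
  cdsf <- filter(g, .data$feature == "CDS") |>
    group_by(.data$transcript_id) |>
    summarise(cds_start = min(.data$start) - 1L, cds_end = max(.data$end),
              .groups = "drop")
  tx <- tibble(
    gene_id = txf$gene_id, transcript_id = txf$transcript_id,
    chrom = txf$seqname, start = txf$start - 1L, end = txf$end,
    strand = txf$strand,
    is_canonical = stringr::str_detect(txf$attribute, 'tag "canonical"')
  ) |>
    left_join(cdsf, by = "transcript_id")
  exf <- filter(g, .data$feature == "exon")
  ex <- tibble(transcript_id = exf$transcript_id, chrom = exf$seqname,
               start = exf$start - 1L, end = exf$end, strand = exf$strand)
  transcript_models(tx, ex)
}

#' Read and write genomes as FASTA
#'
#' @param genome genome accepted by [as_genome()].
#' @param path file path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  gs <- Biostrings::readDNAStringSet(path)
  names(gs) <- sub("\\s.*$", "", names(gs))
  gs
}

#' Read a long IP/input count table and library sizes
#'
#' @param counts_path TSV with `peak_id`, `sample_id`, `ip_count`,
#'   `input_count`, `peak_length`.
#' @param lib_path TSV with `sample_id`, `ip_lib`, `input_lib`.
#' @return List `counts`, `lib_sizes`.
#' @export
read_count_tables <- function(counts_path, lib_path) {
  list(
    counts = readr::read_tsv(counts_path, col_types = "cciii"),
    lib_sizes = readr::read_tsv(lib_path, col_types = "cdd")
  )
}
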