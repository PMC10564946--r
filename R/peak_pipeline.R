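#' Call enrichment peaks from IP and input coverage
#'
#' Internal window-based Poisson caller used to exercise the pipeline end to
#' end; real analyses may supply external peak calls instead. Coverage is
#' tiled into non-overlapping windows; a window is significant when its IP
#' count exceeds the depth-scaled input expectation under a one-sided Poisson
#' test at `p_cutoff`, and maximal runs of adjacent significant windows are
#' reported as peaks. The input is scaled to IP depth by the median
#' per-window IP/input ratio over informative windows (input > 0 and joint
#' count >= 10), which keeps the background estimate robust when enrichment
#' inflates the IP library total.
#'
#' @param ip,input numeric vectors of per-base counts over the same coordinate
#'   space (a single chromosome), or named lists of such vectors (one per
#'   chromosome).
#' @param window window size in bp (>= 10).
#' @param p_cutoff one-sided Poisson p-value cutoff.
#' @param min_input floor (reads) on the per-window input count used for the
#'   background estimate; the background cannot be estimated below sampling
#'   resolution, so windows with no input coverage are tested against this
#'   floor rather than an expectation of zero.
#' @param chrom chromosome name when `ip`/`input` are bare vectors.
#' @param sample_id,caller identifiers stamped on the output rows.
#' @return Tibble of peak calls: `chrom`, `start`, `end`, `strand` (`"+"`
#'   placeholder; MeRIP coverage is unstranded), `sample_id`, `caller`,
#'   `score` (`-log10` of the smallest window p in the run).
#' @export
call_enrichment_peaks <- function(ip, input, window = 50, p_cutoff = 1e-6,
                                  min_input = 1, chrom = "chr1",
                                  sample_id = "sample", caller = "callerA") {
  if (window < 10) abort("window must be >= 10 bp")
  if (is.list(ip) || is.list(input)) {
    if (!is.list(ip) || !is.list(input) ||
        !setequal(names(ip), names(input))) {
      abort("ip and input must cover the same chromosomes")
    }
    res <- map(names(ip), function(ch) {
      call_enrichment_peaks(ip[[ch]], input[[ch]], window, p_cutoff,
                            min_input = min_input, chrom = ch,
                            sample_id = sample_id, caller = caller)
    })
    return(arrange(list_rbind(res), .data$chrom, .data$start))
  }
  if (length(ip) != length(input)) {
    abort("ip and input tracks have different lengths (coordinate spaces differ)")
  }
  if (sum(input) == 0) abort("input track has zero depth (degenerate input)")

  n_win <- length(ip) %/% window
  if (n_win == 0) return(empty_peak_calls())
  idx <- rep(seq_len(n_win), each = window)
  used <- seq_len(n_win * window)
  ip_w <- as.numeric(tapply(ip[used], idx, sum))
  in_w <- as.numeric(tapply(input[used], idx, sum))
  # depth scaling by the median per-window IP/input ratio over informative
  # windows: robust against enrichment regions inflating the library totals
  informative <- in_w > 0 & (ip_w + in_w) >= 10
  scale <- if (any(informative)) median(ip_w[informative] / in_w[informative])
           else sum(ip) / sum(input)
  if (!is.finite(scale) || scale <= 0) scale <- sum(ip) / sum(input)
  mu <- scale * pmax(in_w, min_input)
  p <- stats::ppois(ip_w - 1, mu, lower.tail = FALSE)
  sig <- p <= p_cutoff & ip_w > mu

  if (!any(sig)) return(empty_peak_calls())
  r <- rle(sig)
  ends_w <- cumsum(r$lengths)
  starts_w <- ends_w - r$lengths + 1
  keep <- which(r$values)
  tibble(
    chrom = chrom,
    start = as.integer((starts_w[keep] - 1) * window),
    end = as.integer(ends_w[keep] * window),
    strand = "+",
    sample_id = sample_id,
    caller = caller,
    score = map_dbl(keep, function(k) {
      pm <- min(p[starts_w[k]:ends_w[k]])
      min(-log10(pmax(pm, 1e-300)), 300)
    })
  )
}

empty_peak_calls <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), sample_id = character(), caller = character(),
         score = double())
}

#' Two-caller consensus peaks for one sample
#'
#' Retains only signal supported by both callers: every pair of overlapping
#' (>= 1 bp, same strand) A/B peaks is merged to its union, and overlapping
#' unions are then collapsed. Peaks seen by a single caller are dropped.
#'
#' @param calls_a,calls_b interval tibbles of peak calls from the two callers
#'   for the same sample.
#' @return Interval tibble of consensus peaks.
#' @export
merge_consensus <- function(calls_a, calls_b) {
  if (nrow(calls_a) == 0 || nrow(calls_b) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  calls_a <- validate_intervals(calls_a, "calls_a")
  calls_b <- validate_intervals(calls_b, "calls_b")
  hits <- overlap_pairs(calls_a, calls_b)
  if (nrow(hits) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  unions <- tibble(
    chrom = calls_a$chrom[hits$a_idx],
    start = pmin(calls_a$start[hits$a_idx], calls_b$start[hits$b_idx]),
    end = pmax(calls_a$end[hits$a_idx], calls_b$end[hits$b_idx]),
    strand = calls_a$strand[hits$a_idx]
  )
  reduced <- GenomicRanges::reduce(tbl_to_gr(unions))
  arrange(gr_to_tbl(reduced), .data$chrom, .data$start)
}

#' Flag putative m6Am peaks
#'
#' m6Am (N6,2'-O-dimethyladenosine) sits on the first transcribed nucleotide
#' and cross-reacts with the m6A antibody, so 5'UTR peaks whose host
#' transcript starts with an adenosine in a BCA context (B = C/G/T immediately
#' 5' of the TSS adenosine on the transcript strand, any base 3') are flagged
#' for removal from the m6A catalogue.
#'
#' @param peaks interval tibble.
#' @param transcripts a [transcript_models] object.
#' @param genome genome accepted by [as_genome()].
#' @return `peaks` with a logical `is_m6am` column.
#' @export
flag_m6am <- function(peaks, transcripts, genome) {
  peaks <- validate_intervals(peaks, "peaks")
  gs <- as_genome(genome)
  cano <- canonical_tx(transcripts)

  tss_bca <- map_lgl(seq_len(nrow(cano)), function(i) {
    tx <- cano[i, ]
    chrlen <- Biostrings::width(gs)[match(tx$chrom, names(gs))]
    if (is.na(chrlen)) abort(sprintf("chromosome %s absent from genome", tx$chrom))
    if (tx$strand == "+") {
      tss <- tx$start
      if (tss < 1 || tss >= chrlen) abort("TSS outside genome bounds")
      a <- base_at(gs, tx$chrom, tss)
      b <- base_at(gs, tx$chrom, tss - 1)
    } else {
      tss <- tx$end - 1L
      if (tss < 0 || tss >= chrlen - 1L) abort("TSS outside genome bounds")
      a <- complement_base(base_at(gs, tx$chrom, tss))
      b <- complement_base(base_at(gs, tx$chrom, tss + 1))
    }
    a == "A" && b %in% c("C", "G", "T")
  })

  utr5 <- map(seq_len(nrow(cano)), function(i) {
    if (!tss_bca[i]) return(NULL)
    tx <- cano[i, ]
    reg <- tx_regions(transcripts, tx)
    if (is.null(reg)) return(NULL)
    filter(reg, .data$region == "5UTR")
  }) |> list_rbind()

  if (is.null(utr5) || nrow(utr5) == 0) {
    peaks$is_m6am <- rep(FALSE, nrow(peaks))
    return(peaks)
  }
  # 5'UTR membership is positional; peaks from unstranded coverage carry a
  # placeholder strand, so overlap ignores strand here
  hit <- GenomicRanges::countOverlaps(tbl_to_gr(peaks), tbl_to_gr(utr5),
                                      ignore.strand = TRUE) > 0
  peaks$is_m6am <- hit
  peaks
}

#' Retain peaks recurring in enough samples
#'
#' @param presence long tibble with columns `peak_id`, `sample_id`, `present`
#'   (logical), complete over the peak x sample grid.
#' @param min_samples minimum number of samples a peak must appear in.
#' @return Tibble `peak_id`, `recurrence`, `retained`.
#' @export
filter_recurrence <- function(presence, min_samples = 5) {
  if (min_samples < 1) abort("min_samples must be >= 1")
  if (anyNA(presence$present)) abort("presence table has missing cells")
  presence |>
    group_by(.data$peak_id) |>
    summarise(recurrence = sum(.data$present), .groups = "drop") |>
    mutate(retained = .data$recurrence >= min_samples)
}

#' Presence of catalogue peaks across per-sample peak sets
#'
#' A catalogue peak is "present" in a sample when that sample's consensus
#' peaks overlap it by >= 1 bp.
#'
#' @param catalogue interval tibble with a `peak_id` column.
#' @param sample_peaks interval tibble with a `sample_id` column (consensus
#'   peaks of each sample).
#' @return Long presence tibble for [filter_recurrence()].
#' @export
peak_presence <- function(catalogue, sample_peaks) {
  catalogue <- validate_intervals(catalogue, "catalogue")
  samples <- unique(sample_peaks$sample_id)
  grid <- tidyr::expand_grid(peak_id = catalogue$peak_id, sample_id = samples)
  hits <- map(samples, function(s) {
    sp <- filter(sample_peaks, .data$sample_id == s)
    tibble(peak_id = catalogue$peak_id, sample_id = s,
           present = overlaps_any(catalogue, sp))
  }) |> list_rbind()
  left_join(grid, hits, by = c("peak_id", "sample_id"))
}

#' Annotate peaks against canonical transcripts
#'
#' Assigns each peak a host gene and a region class using the canonical
#' transcript only. Peaks overlapping no transcript are `intergenic`; peaks on
#' non-coding transcripts are `noncoding`. For peaks straddling several
#' regions the priority is start/stop-codon vicinity (+/- `codon_flank` bp
#' around the codon) > 5'UTR/3'UTR > CDS > intron.
#'
#' @param peaks interval tibble (a `peak_id` column is added if absent).
#' @param transcripts a [transcript_models] object.
#' @param codon_flank half-width in bp of the start/stop-codon vicinity.
#' @return Tibble with `peak_id`, interval columns, `gene_id`, `region`; the
#'   output strand is the host gene's strand where a gene is assigned.
#' @export
annotate_peaks <- function(peaks, transcripts, codon_flank = 100) {
  peaks <- validate_intervals(peaks, "peaks")
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  }
  cano <- canonical_tx(transcripts)
  if (nrow(peaks) == 0) {
    return(mutate(peaks, gene_id = character(), region = character()))
  }

  hits <- GenomicRanges::findOverlaps(tbl_to_gr(peaks), tbl_to_gr(cano),
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # pick the transcript with the largest overlap per peak
  ov_w <- pmin(peaks$end[qh], cano$end[sh]) - pmax(peaks$start[qh], cano$start[sh])
  best <- tibble(peak = qh, tx = sh, w = ov_w) |>
    arrange(.data$peak, dplyr::desc(.data$w), .data$tx) |>
    distinct(.data$peak, .keep_all = TRUE)

  region <- rep("intergenic", nrow(peaks))
  gene <- rep(NA_character_, nrow(peaks))
  strand_out <- peaks$strand

  for (r in seq_len(nrow(best))) {
    i <- best$peak[r]
    tx <- cano[best$tx[r], ]
    gene[i] <- tx$gene_id
    strand_out[i] <- tx$strand
    region[i] <- classify_region(peaks[i, ], tx, transcripts, codon_flank)
  }
  peaks |>
    mutate(strand = strand_out, gene_id = gene, region = region) |>
    select("peak_id", "chrom", "start", "end", "strand", "gene_id", "region",
           dplyr::everything())
}

classify_region <- function(peak, tx, tm, codon_flank) {
  if (is.na(tx$cds_start)) return("noncoding")
  cod <- codon_positions(tx)
  sv <- c(cod$start_codon - codon_flank, cod$start_codon + 3L + codon_flank)
  pv <- c(cod$stop_codon - codon_flank, cod$stop_codon + 3L + codon_flank)
  hits_iv <- function(s, e) peak$start < e && peak$end > s
  if (hits_iv(sv[1], sv[2])) return("start_codon_vicinity")
  if (hits_iv(pv[1], pv[2])) return("stop_codon_vicinity")
  reg <- tx_regions(tm, tx)
  for (what in c("5UTR", "3UTR", "CDS")) {
    sub <- filter(reg, .data$region == what)
    if (nrow(sub) > 0 &&
        any(peak$start < sub$end & peak$end > sub$start)) return(what)
  }
  "intron"
}

#' Fraction of peaks containing a motif
#'
#' @param peaks interval tibble.
#' @param genome genome accepted by [as_genome()].
#' @param motif IUPAC motif string (default the m6A methyltransferase
#'   consensus `GGACH`, H = A/C/T).
#' @return Fraction in `[0, 1]` of peaks whose strand-aware sequence contains
#'   at least one motif match.
#' @export
motif_fraction <- function(peaks, genome, motif = "GGACH") {
  ok <- strsplit(toupper(motif), "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok)) abort(sprintf("invalid IUPAC code in motif '%s'", motif))
  if (nrow(peaks) == 0) return(0)
  seqs <- Biostrings::DNAStringSet(interval_seq(peaks, genome))
  n_hit <- Biostrings::vcountPattern(toupper(motif), seqs, fixed = FALSE)
  mean(n_hit > 0)
}

#' Metagene density of peaks along the 5'UTR/CDS/3'UTR axis
#'
#' Maps each peak midpoint to spliced-transcript coordinates of its host
#' canonical coding transcript, normalizes within the 5'UTR, CDS and 3'UTR
#' segments, and bins per region. Peaks on non-coding transcripts, without a
#' host gene, or with an intronic midpoint are skipped and tallied.
#'
#' @param peaks annotated peak tibble (from [annotate_peaks()]; needs
#'   `gene_id`).
#' @param transcripts a [transcript_models] object.
#' @param bins_per_region number of bins for each of the three regions.
#' @return Tibble `region`, `bin`, `position` (global axis in `[0, 3)`),
#'   `count`, `density`; densities sum to 1 when any peak maps. The skip tally
#'   is attached as attribute `skipped`.
#' @export
metagene_profile <- function(peaks, transcripts, bins_per_region = 30) {
  cano <- canonical_tx(transcripts)
  regions <- c("5UTR", "CDS", "3UTR")
  grid <- tidyr::expand_grid(region = factor(regions, levels = regions),
                             bin = seq_len(bins_per_region))
  skipped <- c(no_gene = 0, noncoding = 0, not_exonic = 0)
  rel <- double(0)

  for (i in seq_len(nrow(peaks))) {
    gid <- peaks$gene_id[i]
    if (is.na(gid)) { skipped["no_gene"] <- skipped["no_gene"] + 1; next }
    tx <- filter(cano, .data$gene_id == gid)
    if (nrow(tx) == 0 || is.na(tx$cds_start)) {
      skipped["noncoding"] <- skipped["noncoding"] + 1; next
    }
    mid <- (peaks$start[i] + peaks$end[i]) %/% 2L
    tpos <- genomic_to_tx(transcripts, tx, mid)
    if (is.na(tpos)) { skipped["not_exonic"] <- skipped["not_exonic"] + 1; next }
    cs <- genomic_to_tx(transcripts, tx,
                        if (tx$strand == "+") tx$cds_start else tx$cds_end - 1L)
    ce <- genomic_to_tx(transcripts, tx,
                        if (tx$strand == "+") tx$cds_end - 1L else tx$cds_start)
    ex <- tx_exons(transcripts, tx$transcript_id)
    total <- sum(ex$end - ex$start)
    # tpos in [0, cs) -> 5UTR, [cs, ce] -> CDS, (ce, total) -> 3UTR
    if (tpos < cs) {
      rel <- c(rel, tpos / max(cs, 1))
    } else if (tpos <= ce) {
      rel <- c(rel, 1 + (tpos - cs) / max(ce - cs + 1, 1))
    } else {
      rel <- c(rel, 2 + (tpos - ce - 1) / max(total - ce - 1, 1))
    }
  }

  if (length(rel) == 0) {
    warn("no peaks mapped to coding transcripts; returning an all-zero profile")
    out <- mutate(grid, position = (as.integer(.data$region) - 1) +
                    (.data$bin - 0.5) / bins_per_region,
                  count = 0L, density = 0)
    attr(out, "skipped") <- skipped
    return(out)
  }
  which_reg <- pmin(floor(rel) + 1, 3)
  frac <- rel - floor(rel)
  bin <- pmin(floor(frac * bins_per_region) + 1, bins_per_region)
  tallied <- tibble(region = factor(regions[which_reg], levels = regions),
                    bin = as.integer(bin)) |>
    count(.data$region, .data$bin, name = "count")
  out <- grid |>
    left_join(tallied, by = c("region", "bin")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L),
           position = (as.integer(.data$region) - 1) +
             (.data$bin - 0.5) / bins_per_region,
           density = .data$count / sum(.data$count)) |>
    select("region", "bin", "position", "count", "density")
  attr(out, "skipped") <- skipped
  out
}
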