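#' Call m6A residues from CIMS mutation tables
#'
#' Crosslink-induced mutation sites (CIMS) from miCLIP identify m6A residues
#' as C-to-T transitions one base 3' of the methylated adenosine. A record is
#' called when it is (i) not a known SNP, (ii) a C>T substitution on the read
#' strand, (iii) has mutation fraction `m/k <= max_mk`, and (iv) the base
#' immediately 5' in transcript orientation is an adenosine on the transcript
#' strand. The reported residue is that adenosine. Records with `k = 0` or
#' with the adenosine position outside the genome are skipped and tallied.
#'
#' @param records tibble `chrom`, `pos` (0-based position of the mutation),
#'   `strand`, `ref`, `alt` (read-strand bases), `k` (unique-tag coverage),
#'   `m` (mutation count), optional logical `is_known_snp`.
#' @param genome genome accepted by [as_genome()].
#' @param snps optional interval tibble of known SNP positions; records
#'   overlapping them are excluded in addition to the `is_known_snp` flag.
#' @param max_mk maximum mutation fraction.
#' @return Tibble of called residues: `chrom`, `pos` (0-based position of the
#'   methylated A), `strand`, `k`, `m`, `source_pos`. Skip counts are in
#'   attribute `skipped`.
#' @export
call_cims_m6a <- function(records, genome, snps = NULL, max_mk = 0.5) {
  gs <- as_genome(genome)
  if (!"is_known_snp" %in% names(records)) records$is_known_snp <- FALSE
  if (any(records$m > records$k)) abort("mutation count m exceeds coverage k")

  skipped <- c(zero_coverage = sum(records$k == 0), out_of_bounds = 0L)
  records <- filter(records, .data$k > 0)

  if (!is.null(snps) && nrow(snps) > 0) {
    rec_iv <- tibble(chrom = records$chrom, start = records$pos,
                     end = records$pos + 1L, strand = records$strand)
    in_snp <- GenomicRanges::countOverlaps(tbl_to_gr(rec_iv), tbl_to_gr(snps),
                                           ignore.strand = TRUE) > 0
    records$is_known_snp <- records$is_known_snp | in_snp
  }

  cand <- records |>
    filter(!.data$is_known_snp, .data$ref == "C", .data$alt == "T",
           .data$m / .data$k <= max_mk)
  if (nrow(cand) == 0) {
    out <- tibble(chrom = character(), pos = integer(), strand = character(),
                  k = integer(), m = integer(), source_pos = integer())
    attr(out, "skipped") <- skipped
    return(out)
  }

  # adenosine one base 5' in transcript orientation
  a_pos <- if_else(cand$strand == "+", cand$pos - 1L, cand$pos + 1L)
  chrlen <- Biostrings::width(gs)[match(cand$chrom, names(gs))]
  inb <- !is.na(chrlen) & a_pos >= 0 & a_pos < chrlen
  skipped["out_of_bounds"] <- sum(!inb)
  cand <- cand[inb, ]
  a_pos <- a_pos[inb]

  base_tx <- map_chr(seq_len(nrow(cand)), function(i) {
    b <- base_at(gs, cand$chrom[i], a_pos[i])
    if (cand$strand[i] == "-") complement_base(b) else b
  })
  keep <- base_tx == "A"
  out <- tibble(chrom = cand$chrom[keep], pos = a_pos[keep],
                strand = cand$strand[keep], k = cand$k[keep],
                m = cand$m[keep], source_pos = cand$pos[keep])
  attr(out, "skipped") <- skipped
  out
}

#' Signed distance profile between two anchor sets
#'
#' For each anchor in `a` (midpoint by default), the signed distance to the
#' nearest anchor in `b` on the same chromosome, oriented by the `a` anchor's
#' strand (positive = 3' of the anchor), kept when within `window` bp and
#' binned. Equidistant neighbors resolve toward the 3' side.
#'
#' @param a,b interval tibbles.
#' @param window maximum absolute distance in bp.
#' @param bin_width histogram bin width in bp.
#' @param anchor `"midpoint"` or `"edge"` (edge = distance between closest
#'   interval edges, signed the same way, 0 when overlapping).
#' @return Tibble `bin_start`, `bin_mid`, `count` covering
#'   `[-window, window)`; per-anchor distances in attribute `distances`.
#' @export
distance_profile <- function(a, b, window = 2000, bin_width = 50,
                             anchor = c("midpoint", "edge")) {
  anchor <- match.arg(anchor)
  if (nrow(a) == 0 || nrow(b) == 0) abort("both anchor sets must be non-empty")
  a <- validate_intervals(a, "a")
  b <- validate_intervals(b, "b")

  dists <- rep(NA_real_, nrow(a))
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    if (length(bi) == 0) next
    if (anchor == "midpoint") {
      am <- interval_midpoint(a[ai, ])
      bm <- sort(interval_midpoint(b[bi, ]))
      d <- map_dbl(seq_along(ai), function(j) {
        delta <- bm - am[j]
        dd <- delta[which.min(abs(delta))]
        # 3'-ward tie-break: prefer larger oriented distance
        tie <- delta[abs(delta) == min(abs(delta))]
        if (length(tie) > 1) {
          dd <- if (a$strand[ai[j]] == "+") max(tie) else min(tie)
        }
        dd
      })
    } else {
      d <- map_dbl(seq_along(ai), function(j) {
        s <- a$start[ai[j]]; e <- a$end[ai[j]]
        left <- b$start[bi] - e      # positive when b is right of a
        right <- s - b$end[bi]       # positive when b is left of a
        gap <- pmax(pmax(left, right), 0)
        signd <- if_else(gap == 0, 0L, if_else(left > 0, left, -right))
        dd <- signd[which.min(gap)]
        ties <- signd[gap == min(gap)]
        if (length(ties) > 1) {
          dd <- if (a$strand[ai[j]] == "+") max(ties) else min(ties)
        }
        dd
      })
    }
    neg <- a$strand[ai] == "-"
    d[neg] <- -d[neg]
    dists[ai] <- d
  }
  dists <- dists[!is.na(dists) & abs(dists) <= window]

  breaks <- seq(-window, window, by = bin_width)
  if (max(breaks) < window) breaks <- c(breaks, window)
  h <- graphics::hist(dists, breaks = breaks, plot = FALSE, right = FALSE)
  out <- tibble(bin_start = head(breaks, -1), bin_mid = h$mids,
                count = h$counts)
  attr(out, "distances") <- dists
  out
}

#' Fisher test for overlap association of two site sets over a catalogue
#'
#' Each universe peak is classified by >= 1 bp overlap (strand-ignored) with
#' `set_a` and with `set_b`; the 2x2 membership table is tested one-sided for
#' positive association.
#'
#' @param set_a,set_b interval tibbles.
#' @param universe interval tibble of catalogue peaks.
#' @return One-row tibble `n_both`, `n_a_only`, `n_b_only`, `n_neither`,
#'   `odds_ratio`, `p_value`.
#' @export
overlap_fisher <- function(set_a, set_b, universe) {
  if (nrow(universe) == 0) abort("empty universe")
  in_a <- GenomicRanges::countOverlaps(tbl_to_gr(universe), tbl_to_gr(set_a),
                                       ignore.strand = TRUE) > 0
  in_b <- GenomicRanges::countOverlaps(tbl_to_gr(universe), tbl_to_gr(set_b),
                                       ignore.strand = TRUE) > 0
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)), 2, byrow = TRUE)
  ft <- fisher.test(tab, alternative = "greater")
  tibble(n_both = tab[1, 1], n_a_only = tab[1, 2], n_b_only = tab[2, 1],
         n_neither = tab[2, 2], odds_ratio = unname(ft$estimate),
         p_value = ft$p.value)
}
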