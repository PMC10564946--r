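test_that("enrichment caller finds planted enrichment and nothing under the null", {
  set.seed(1)
  n <- 5000
  input <- rpois(n, 2)

  # null: IP identical to input
  expect_equal(nrow(call_enrichment_peaks(input, input)), 0)

  # one 200-bp region with 10x enrichment over flat background
  lam <- rep(2, n)
  lam[2001:2200] <- 20
  ip <- rpois(n, lam)
  pk <- call_enrichment_peaks(ip, input, window = 50, p_cutoff = 1e-6)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$start - 2000), 50)
  expect_lte(abs(pk$end - 2200), 50)

  # independent oracle: exact Poisson tail per window at the same scaling
  win_id <- rep(seq_len(n %/% 50), each = 50)
  ip_w <- tapply(ip, win_id, sum)
  in_w <- tapply(input, win_id, sum)
  informative <- in_w > 0 & (ip_w + in_w) >= 10
  scale <- median(ip_w[informative] / in_w[informative])
  p_oracle <- ppois(ip_w - 1, scale * pmax(in_w, 1), lower.tail = FALSE)
  sig <- which(p_oracle <= 1e-6 & ip_w > scale * pmax(in_w, 1))
  expect_equal(pk$start, (min(sig) - 1L) * 50L)
  expect_equal(pk$end, max(sig) * 50L)

  # one-sided: swapping IP and input must yield nothing
  expect_equal(nrow(call_enrichment_peaks(input, ip, window = 50)), 0)

  expect_error(call_enrichment_peaks(ip, input[-1]), "lengths")
  expect_error(call_enrichment_peaks(ip, rep(0, n)), "zero depth")
})

test_that("two-caller consensus keeps only jointly-supported signal, merged to the union", {
  iv <- function(s, e) interval_tbl("chr1", s, e, "+")
  # disjoint -> empty
  expect_equal(nrow(merge_consensus(iv(100, 200), iv(500, 600))), 0)
  # overlapping -> union
  got <- merge_consensus(iv(100, 300), iv(250, 400))
  expect_equal(got$start, 100L)
  expect_equal(got$end, 400L)
  # identical inputs -> identity (idempotent)
  ident <- merge_consensus(iv(100, 200), iv(100, 200))
  expect_equal(ident$start, 100L)
  expect_equal(ident$end, 200L)
  # different strands never merge
  a <- interval_tbl("chr1", 100, 300, "+")
  b <- interval_tbl("chr1", 250, 400, "-")
  expect_equal(nrow(merge_consensus(a, b)), 0)
})

test_that("consensus merge is commutative and matches a brute-force overlap oracle", {
  set.seed(42)
  for (rep in 1:5) {
    mk <- function(n) {
      s <- sample(0:2000, n)
      interval_tbl("chr1", s, s + sample(50:200, n, replace = TRUE), "+")
    }
    a <- mk(15); b <- mk(12)
    got <- merge_consensus(a, b)
    swapped <- merge_consensus(b, a)
    expect_equal(got, swapped)

    # oracle: all pairwise >=1bp overlaps -> union intervals -> collapse
    unions <- list()
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      if (a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        unions[[length(unions) + 1]] <- c(min(a$start[i], b$start[j]),
                                          max(a$end[i], b$end[j]))
      }
    }
    if (length(unions) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      u <- do.call(rbind, unions)
      u <- u[order(u[, 1]), , drop = FALSE]
      merged <- list(u[1, ])
      for (r in seq_len(nrow(u))[-1]) {
        last <- merged[[length(merged)]]
        if (u[r, 1] <= last[2]) {
          merged[[length(merged)]] <- c(last[1], max(last[2], u[r, 2]))
        } else merged[[length(merged) + 1]] <- u[r, ]
      }
      mo <- do.call(rbind, merged)
      expect_equal(got$start, as.integer(mo[, 1]))
      expect_equal(got$end, as.integer(mo[, 2]))
    }
  }
})

test_that("m6Am flagging needs a 5'UTR peak, TSS adenosine and BCA context", {
  g0 <- 100L
  base <- strrep("T", 2000)
  with_tss <- function(first, before) {
    s <- base
    substr(s, g0, g0) <- before       # genomic pos g0-1 (0-based)
    substr(s, g0 + 1, g0 + 1) <- first  # TSS base at 0-based g0
    toy_genome(chr1 = s)
  }
  tm <- one_gene_tm("+")
  utr_peak <- interval_tbl("chr1", g0 + 10L, g0 + 60L, "+")
  cds_peak <- interval_tbl("chr1", g0 + 600L, g0 + 700L, "+")

  expect_true(flag_m6am(utr_peak, tm, with_tss("A", "C"))$is_m6am)
  expect_false(flag_m6am(utr_peak, tm, with_tss("G", "C"))$is_m6am)  # TSS not A
  expect_false(flag_m6am(utr_peak, tm, with_tss("A", "A"))$is_m6am)  # no BCA
  expect_false(flag_m6am(cds_peak, tm, with_tss("A", "C"))$is_m6am)  # not 5'UTR
})

test_that("m6Am flags are invariant under reverse-complementing the genome", {
  g0 <- 100L
  L <- 2000L
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  substr(s, g0, g0 + 1) <- "CA"  # BCA TSS on + strand
  tm_fwd <- one_gene_tm("+", g0)
  pk_fwd <- interval_tbl("chr1", g0 + 10L, g0 + 60L, "+")
  fwd <- flag_m6am(pk_fwd, tm_fwd, toy_genome(chr1 = s))$is_m6am

  # mirror the world: position x -> L - 1 - x, complement bases, flip strands
  s_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  flip_iv <- function(st, en) c(L - en, L - st)
  tm_rc <- transcript_models(
    tibble::tibble(gene_id = "geneA", transcript_id = "txA", chrom = "chr1",
                   start = L - (g0 + 1400L), end = L - g0, strand = "-",
                   cds_start = L - (g0 + 1250L), cds_end = L - (g0 + 150L),
                   is_canonical = TRUE),
    tibble::tibble(transcript_id = "txA", chrom = "chr1",
                   start = L - (g0 + c(300L, 900L, 1400L)),
                   end = L - (g0 + c(0L, 500L, 1100L)), strand = "-")
  )
  pk_rc <- interval_tbl("chr1", L - (g0 + 60L), L - (g0 + 10L), "-")
  rc <- flag_m6am(pk_rc, tm_rc, toy_genome(chr1 = s_rc))$is_m6am
  expect_identical(fwd, rc)
  expect_true(fwd)
})

test_that("recurrence filter applies the >= min_samples rule and is monotone", {
  mk_presence <- function(n_present, n_samples = 98) {
    tibble::tibble(peak_id = "p1",
                   sample_id = paste0("s", seq_len(n_samples)),
                   present = seq_len(n_samples) <= n_present)
  }
  expect_true(filter_recurrence(mk_presence(5), 5)$retained)   # boundary
  expect_false(filter_recurrence(mk_presence(4), 5)$retained)
  expect_true(filter_recurrence(mk_presence(1), 1)$retained)
  expect_error(filter_recurrence(mk_presence(3), 0), "min_samples")

  # monotone non-increasing retained set in min_samples
  set.seed(3)
  pres <- tidyr::expand_grid(peak_id = paste0("p", 1:50),
                             sample_id = paste0("s", 1:20)) |>
    dplyr::mutate(present = runif(dplyr::n()) < 0.25)
  kept <- sapply(1:8, function(ms) sum(filter_recurrence(pres, ms)$retained))
  expect_true(all(diff(kept) <= 0))
})

test_that("peak presence means >=1 bp overlap with the sample's peaks", {
  cat <- interval_tbl("chr1", c(100, 500), c(200, 600), "+",
                      peak_id = c("a", "b"))
  sp <- interval_tbl("chr1", c(199, 700), c(250, 800), "+",
                     sample_id = c("s1", "s1"))
  pres <- peak_presence(cat, sp)
  expect_true(pres$present[pres$peak_id == "a"])
  expect_false(pres$present[pres$peak_id == "b"])
})

test_that("region annotation follows the canonical transcript and priority rules", {
  tm <- one_gene_tm("+")
  g0 <- 100L
  ann <- function(s, e) {
    annotate_peaks(interval_tbl("chr1", g0 + s, g0 + e, "+"), tm)$region
  }
  expect_equal(ann(350L, 450L), "intron")       # fully intronic
  expect_equal(ann(600L, 700L), "CDS")          # mid-CDS exon
  # straddling CDS/3'UTR near the stop codon (stop at cds_end-3 = 1247)
  expect_equal(ann(1200L, 1300L), "stop_codon_vicinity")
  expect_equal(ann(1380L, 1395L), "3UTR")
  expect_equal(ann(5L, 40L), "5UTR")
  # no gene -> intergenic
  out <- annotate_peaks(interval_tbl("chr1", 5000L, 5100L, "+"), tm)
  expect_equal(out$region, "intergenic")
  expect_true(is.na(out$gene_id))

  # exactly one region per peak: counts add up
  set.seed(4)
  s <- sample(0:2000, 40)
  peaks <- interval_tbl("chr1", s, s + 50L, "+")
  res <- annotate_peaks(peaks, tm)
  expect_equal(nrow(res), 40)
  expect_false(anyNA(res$region))
  expect_equal(sum(table(res$region)), 40)
})

test_that("motif fraction counts strand-aware IUPAC matches", {
  seqs <- strrep("T", 400)
  genome <- toy_genome(chr1 = seqs)
  peaks <- interval_tbl("chr1", (0:9) * 40L, (0:9) * 40L + 30L, "+")
  expect_equal(motif_fraction(peaks, genome), 0)

  # plant GGACA (a GGACH instance) in 7 of 10 peaks
  chars <- strsplit(seqs, "")[[1]]
  for (i in 0:6) chars[(i * 40 + 10):(i * 40 + 14)] <- c("G", "G", "A", "C", "A")
  genome2 <- toy_genome(chr1 = paste(chars, collapse = ""))
  expect_equal(motif_fraction(peaks, genome2), 0.7)

  # minus-strand peak sees the reverse complement
  rc_peak <- interval_tbl("chr1", 8L, 20L, "-")
  chars3 <- strsplit(seqs, "")[[1]]
  chars3[10:14] <- c("A", "G", "T", "C", "C")  # revcomp(GGACT)
  expect_equal(motif_fraction(rc_peak, toy_genome(chr1 = paste(chars3, collapse = ""))), 1)

  expect_error(motif_fraction(peaks, genome, motif = "GGAXH"), "IUPAC")
})

test_that("metagene profile localizes stop-codon peaks and sums to one", {
  tm <- one_gene_tm("+")
  g0 <- 100L
  # peaks centered right at the stop codon (genomic 1347 is in the last exon)
  pk <- annotate_peaks(
    interval_tbl("chr1", rep(g0 + 1220L, 20), rep(g0 + 1280L, 20), "+"), tm)
  prof <- metagene_profile(pk, tm, bins_per_region = 10)
  expect_equal(sum(prof$density), 1, tolerance = 1e-9)
  # mass concentrated at the CDS/3'UTR junction
  junction_mass <- prof |>
    dplyr::filter((region == "CDS" & bin >= 9) | (region == "3UTR" & bin <= 2)) |>
    dplyr::pull(density) |> sum()
  expect_gt(junction_mass, 0.99)

  # uniform peaks over the spliced transcript -> roughly flat
  set.seed(5)
  ex_starts <- c(0L, 500L, 1100L); ex_ends <- c(300L, 900L, 1400L)
  mids <- unlist(mapply(function(s, e) s:(e - 1), ex_starts, ex_ends))
  sel <- g0 + sample(mids, 3000, replace = TRUE)
  pku <- annotate_peaks(interval_tbl("chr1", sel, sel + 1L, "+"), tm)
  profu <- metagene_profile(pku, tm, bins_per_region = 5)
  expect_equal(sum(profu$density), 1, tolerance = 1e-9)
  # each region's mass ~ its share of transcript length (150/850, 550/850... )
  reg_mass <- profu |> dplyr::group_by(region) |>
    dplyr::summarise(m = sum(density)) |> tibble::deframe()
  expect_equal(unname(reg_mass["5UTR"]), 150 / 1000, tolerance = 0.05)
  expect_equal(unname(reg_mass["CDS"]), 700 / 1000, tolerance = 0.05)

  expect_warning(out <- metagene_profile(pk[0, ], tm), "all-zero")
  expect_equal(sum(out$density), 0)
})
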