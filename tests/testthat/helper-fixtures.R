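# shared fixtures and independent oracles used across test files

# genome from explicit chromosome strings
toy_genome <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- paste0("chr", seq_along(seqs))
  seqs
}

# one coding gene: exons/UTRs sized in genomic coords, plus strand by default
one_gene_tm <- function(strand = "+", g0 = 100L) {
  tx <- tibble::tibble(
    gene_id = "geneA", transcript_id = "txA", chrom = "chr1",
    start = g0, end = g0 + 1400L, strand = strand,
    cds_start = g0 + 150L, cds_end = g0 + 1250L, is_canonical = TRUE
  )
  ex <- tibble::tibble(
    transcript_id = "txA", chrom = "chr1",
    start = g0 + c(0L, 500L, 1100L), end = g0 + c(300L, 900L, 1400L),
    strand = strand
  )
  transcript_models(tx, ex)
}

# adjusted Rand index (closed form on the pair-counting contingency table)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_i * sum_j / n
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments,
# doubling the smaller tail as wilcox.test does
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

# exact two-sided rank-sum p by enumerating all C(n, nb) group assignments
enum_rank_sum_p <- function(xa, xb) {
  pooled <- c(xa, xb)
  r <- rank(pooled)
  nb <- length(xb)
  w_obs <- sum(r[seq_along(xb) + length(xa)])
  combs <- utils::combn(length(pooled), nb)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# brute-force nearest-signed-distance oracle (midpoint anchors)
brute_nearest_signed <- function(a_mid, b_mid, strand) {
  vapply(seq_along(a_mid), function(i) {
    delta <- b_mid - a_mid[i]
    best <- min(abs(delta))
    cand <- delta[abs(delta) == best]
    d <- if (strand[i] == "+") max(cand) else min(cand)
    if (strand[i] == "-") -d else d
  }, numeric(1))
}

# brute-force two-sample KS statistic: sup over jump points of |F1 - F2|
brute_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# textbook log-rank arithmetic for two groups, no ties beyond shared times
logrank_oracle <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# four-condition brute-force CIMS filter (explicit loop over records)
brute_cims <- function(records, genome) {
  chars <- lapply(genome, function(s) strsplit(s, "")[[1]])
  out <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$k == 0) next
    if (isTRUE(r$is_known_snp)) next
    if (!(r$ref == "C" && r$alt == "T")) next
    if (r$m / r$k > 0.5) next
    a_pos <- if (r$strand == "+") r$pos - 1L else r$pos + 1L
    if (a_pos < 0 || a_pos >= length(chars[[r$chrom]])) next
    b <- chars[[r$chrom]][a_pos + 1]
    if (r$strand == "-") b <- chartr("ACGT", "TGCA", b)
    if (b != "A") next
    out[[length(out) + 1]] <- tibble::tibble(chrom = r$chrom, pos = a_pos,
                                             strand = r$strand)
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          strand = character()))
  }
  dplyr::bind_rows(out)
}

# long level tibble from a plain matrix
levels_from_matrix <- function(m) {
  tibble::tibble(
    peak_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    m6a_level = as.vector(m)
  )
}
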