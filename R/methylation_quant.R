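#' Relative m6A levels from IP/input counts
#'
#' The relative m6A level of a peak in a sample is the ratio of IP RPKM to
#' input RPKM. Peak length cancels in the ratio, so the value reduces to
#' `(ip/input) * (input_lib/ip_lib)`; it is computed through the full RPKM
#' arithmetic regardless. Values are missing where the input count is zero.
#'
#' @param counts long tibble with columns `peak_id`, `sample_id`, `ip_count`,
#'   `input_count`, `peak_length` (bp).
#' @param lib_sizes tibble `sample_id`, `ip_lib`, `input_lib` (total mapped
#'   reads per library).
#' @return Long tibble `peak_id`, `sample_id`, `m6a_level` (NA where input
#'   count is zero).
#' @export
relative_m6a_level <- function(counts, lib_sizes) {
  if (any(lib_sizes$ip_lib <= 0) || any(lib_sizes$input_lib <= 0)) {
    abort("library sizes must be > 0")
  }
  if (any(counts$peak_length <= 0)) abort("peak lengths must be > 0")
  counts |>
    inner_join(lib_sizes, by = "sample_id") |>
    mutate(
      ip_rpkm = .data$ip_count /
        ((.data$peak_length / 1e3) * (.data$ip_lib / 1e6)),
      input_rpkm = .data$input_count /
        ((.data$peak_length / 1e3) * (.data$input_lib / 1e6)),
      m6a_level = if_else(.data$input_count == 0, NA_real_,
                          .data$ip_rpkm / .data$input_rpkm)
    ) |>
    select("peak_id", "sample_id", "m6a_level")
}

# peaks x samples matrix from a long level tibble
level_matrix <- function(levels) {
  wide <- tidyr::pivot_wider(levels, id_cols = "peak_id",
                             names_from = "sample_id",
                             values_from = "m6a_level")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$peak_id
  m
}

# vectorized two-sided signed-rank machinery for a peaks x pairs matrix of
# paired differences: zeros dropped per row, normal approximation with tie
# correction and continuity correction (the large-sample branch of
# wilcox.test). The ranks of |d| are invariant under within-pair label swaps,
# so they are computed once and each sign-flip permutation reduces to a
# masked row sum. Rows with < min_pairs usable differences get NA.
prep_signed_rank <- function(D, min_pairs = 5) {
  valid <- !is.na(D) & D != 0
  nr <- nrow(D)
  R <- matrix(0, nr, ncol(D))
  mu <- sig2 <- rep(NA_real_, nr)
  for (i in seq_len(nr)) {
    v <- valid[i, ]
    n <- sum(v)
    if (n < min_pairs) next
    r <- rank(abs(D[i, v]))
    R[i, v] <- r
    ties <- table(r)
    mu[i] <- n * (n + 1) / 4
    sig2[i] <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  }
  pos <- D > 0
  pos[is.na(pos)] <- FALSE
  list(R = R, mu = mu, sig2 = sig2, pos = pos)
}

# p-values for one sign assignment: flip[j] = -1 swaps the labels of pair j
signed_rank_p_flip <- function(prep, flip) {
  keep_pos <- sweep(prep$pos, 2, flip == 1, `==`)
  W <- rowSums(prep$R * keep_pos)
  z0 <- W - prep$mu
  z <- (z0 - sign(z0) * 0.5) / sqrt(prep$sig2)
  p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  p[!is.na(prep$sig2) & prep$sig2 <= 0] <- 1
  list(p = p, statistic = W)
}

signed_rank_p_matrix <- function(D, min_pairs = 5) {
  prep <- prep_signed_rank(D, min_pairs)
  signed_rank_p_flip(prep, rep(1, ncol(D)))
}

# exact two-sided signed-rank p over all 2^n sign assignments, ties handled
# by mid-ranks; computed by dynamic programming on doubled ranks (integers)
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r2 <- as.integer(round(2 * rank(abs(d))))
  w_obs <- sum(r2[d > 0])
  total <- sum(r2)
  cnt <- numeric(total + 1)
  cnt[1] <- 1
  for (v in r2) {
    cnt <- cnt + c(rep(0, v), cnt[seq_len(total + 1 - v)])
  }
  probs <- cnt / 2^n
  lo <- sum(probs[seq_len(w_obs + 1)])
  hi <- sum(probs[(w_obs + 1):(total + 1)])
  min(1, 2 * min(lo, hi))
}

#' Paired differential methylation (tumor vs normal)
#'
#' Two-sided Wilcoxon signed-rank test on paired tumor - normal differences
#' per peak, Benjamini-Hochberg correction across peaks. The exact null
#' distribution is used up to `exact_max` complete pairs, the normal
#' approximation with continuity and tie correction above that; zero
#' differences are dropped. Direction comes from the median paired difference
#' at the FDR cutoff.
#'
#' @param levels long level tibble (see [relative_m6a_level()]).
#' @param pairs tibble `pair_id`, `tumor`, `normal` naming the paired sample
#'   ids.
#' @param fdr_cut FDR threshold for calling a direction.
#' @param min_pairs minimum complete (both values present) pairs per peak;
#'   peaks below are reported `ns` with reason `low_pairs`.
#' @param exact_max largest number of pairs for which the exact signed-rank
#'   distribution is used.
#' @return Tibble `peak_id`, `n_pairs`, `median_diff`, `log2_fc`, `p_value`,
#'   `fdr`, `direction` (`hyper`/`hypo`/`ns`), `reason`.
#' @export
differential_paired <- function(levels, pairs, fdr_cut = 0.1, min_pairs = 5,
                                exact_max = 25) {
  m <- level_matrix(levels)
  tum <- m[, pairs$tumor, drop = FALSE]
  nor <- m[, pairs$normal, drop = FALSE]
  D <- tum - nor

  res <- map(seq_len(nrow(D)), function(i) {
    d <- D[i, ]
    ok <- !is.na(d)
    n <- sum(ok)
    lfc <- log2(mean(tum[i, ok]) / mean(nor[i, ok]))
    if (n < min_pairs) {
      return(tibble(n_pairs = n, median_diff = NA_real_, log2_fc = lfc,
                    p_value = NA_real_, reason = "low_pairs"))
    }
    d <- d[ok]
    if (all(d == 0)) {
      return(tibble(n_pairs = n, median_diff = 0, log2_fc = lfc,
                    p_value = 1, reason = "all_zero_diff"))
    }
    p <- if (n <= exact_max) {
      exact_signed_rank_p(d)
    } else {
      suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
    }
    tibble(n_pairs = n, median_diff = median(d), log2_fc = lfc,
           p_value = p, reason = NA_character_)
  }) |> list_rbind()

  res |>
    mutate(peak_id = rownames(D), .before = 1) |>
    mutate(
      fdr = p.adjust(.data$p_value, method = "BH"),
      direction = case_when(
        is.na(.data$fdr) | .data$fdr >= fdr_cut ~ "ns",
        .data$median_diff > 0 ~ "hyper",
        .data$median_diff < 0 ~ "hypo",
        TRUE ~ "ns"
      )
    )
}

#' Permutation null for the paired differential analysis
#'
#' Randomly swaps tumor/normal labels within pairs (sign flips of the paired
#' differences, preserving the pairing structure), recomputes signed-rank
#' p-values and counts significant peaks per permutation, both at the BH FDR
#' cutoff (as reported in cohort analyses) and at the raw p cutoff.
#'
#' @param levels,pairs as in [differential_paired()].
#' @param n_perm number of label permutations.
#' @param seed optional integer seed.
#' @param fdr_cut,alpha significance cutoffs for the two counts.
#' @param min_pairs minimum usable pairs per peak.
#' @return Object of class `permutation_null`: observed counts, a tibble of
#'   per-permutation counts, and their means. Both observed and permuted
#'   counts use the same vectorized normal-approximation test so the
#'   comparison is internally consistent.
#' @export
permutation_null <- function(levels, pairs, n_perm = 1000, seed = NULL,
                             fdr_cut = 0.1, alpha = 0.05, min_pairs = 5) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- level_matrix(levels)
  D <- m[, pairs$tumor, drop = FALSE] - m[, pairs$normal, drop = FALSE]
  prep <- prep_signed_rank(D, min_pairs)

  count_sig <- function(flip) {
    p <- signed_rank_p_flip(prep, flip)$p
    fdr <- p.adjust(p, method = "BH")
    c(n_fdr = sum(fdr < fdr_cut, na.rm = TRUE),
      n_p = sum(p < alpha, na.rm = TRUE))
  }
  obs <- count_sig(rep(1, ncol(D)))
  perms <- map(seq_len(n_perm), function(b) {
    flip <- sample(c(1, -1), ncol(D), replace = TRUE)
    cs <- count_sig(flip)
    tibble(perm = b, n_fdr = cs[["n_fdr"]], n_p = cs[["n_p"]])
  }) |> list_rbind()

  structure(
    list(observed = tibble(n_fdr = obs[["n_fdr"]], n_p = obs[["n_p"]]),
         permutations = perms,
         mean_fdr_count = mean(perms$n_fdr),
         mean_p_count = mean(perms$n_p),
         n_perm = n_perm, fdr_cut = fdr_cut, alpha = alpha),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> %d permutations\n  observed: %d peaks at FDR<%.2g (%d at p<%.2g)\n  permuted mean: %.2f at FDR (%.2f at p)\n",
    x$n_perm, x$observed$n_fdr, x$fdr_cut, x$observed$n_p, x$alpha,
    x$mean_fdr_count, x$mean_p_count))
  invisible(x)
}

#' Two-condition fold-change calls
#'
#' Condition means of relative m6A levels per peak; a peak is `hyper` when
#' `mean_b / mean_a` exceeds `fc_cut`, `hypo` when `mean_a / mean_b` does, and
#' `ns` otherwise. Peaks with a zero or missing condition mean are reported
#' with direction `NA`.
#'
#' @param levels_a,levels_b long level tibbles for the two conditions
#'   (replicate samples are averaged).
#' @param fc_cut fold-change cutoff (default 1.2).
#' @return Tibble `peak_id`, `mean_a`, `mean_b`, `fc` (b over a),
#'   `direction`.
#' @export
two_condition_fc <- function(levels_a, levels_b, fc_cut = 1.2) {
  ma <- levels_a |> group_by(.data$peak_id) |>
    summarise(mean_a = mean(.data$m6a_level, na.rm = TRUE), .groups = "drop")
  mb <- levels_b |> group_by(.data$peak_id) |>
    summarise(mean_b = mean(.data$m6a_level, na.rm = TRUE), .groups = "drop")
  inner_join(ma, mb, by = "peak_id") |>
    mutate(
      fc = if_else(.data$mean_a > 0, .data$mean_b / .data$mean_a, NA_real_),
      direction = case_when(
        is.na(.data$mean_a) | is.na(.data$mean_b) |
          .data$mean_a <= 0 | .data$mean_b <= 0 ~ NA_character_,
        .data$mean_b / .data$mean_a > fc_cut ~ "hyper",
        .data$mean_a / .data$mean_b > fc_cut ~ "hypo",
        TRUE ~ "ns"
      )
    )
}

#' Overlap between two peak-id sets
#'
#' @param set_x,set_y character vectors of peak ids from one catalogue.
#' @return One-row tibble with sizes, intersection count, and both directional
#'   fractions.
#' @export
overlap_sets <- function(set_x, set_y) {
  set_x <- unique(set_x)
  set_y <- unique(set_y)
  n_common <- length(intersect(set_x, set_y))
  tibble(
    n_x = length(set_x), n_y = length(set_y), n_common = n_common,
    frac_x = if (length(set_x) > 0) n_common / length(set_x) else NA_real_,
    frac_y = if (length(set_y) > 0) n_common / length(set_y) else NA_real_
  )
}

#' Cross m6A change with host-RNA change
#'
#' Classifies each differential m6A peak by the joint direction of the m6A
#' change and its host gene's RNA change: `hyper-up` (both increase),
#' `hypo-down` (both decrease), `hypo-up`, `hyper-down`, and
#' `non-significant` whenever the RNA direction is `ns`, the m6A direction is
#' `ns`, or the gene is absent from the RNA table.
#'
#' @param dm tibble `peak_id`, `gene_id`, `direction` (m6A:
#'   `hyper`/`hypo`/`ns`).
#' @param de tibble `gene_id`, `direction` (RNA: `up`/`down`/`ns`), produced
#'   by any external differential-expression method.
#' @return Tibble `gene_id`, `peak_id`, `m6a_direction`, `rna_direction`,
#'   `category`.
#' @export
integrate_rna_m6a <- function(dm, de) {
  de <- rename(de, rna_direction = "direction")
  dm |>
    rename(m6a_direction = "direction") |>
    left_join(de, by = "gene_id") |>
    mutate(
      rna_direction = dplyr::coalesce(.data$rna_direction, "ns"),
      category = case_when(
        .data$m6a_direction == "hyper" & .data$rna_direction == "up" ~ "hyper-up",
        .data$m6a_direction == "hypo" & .data$rna_direction == "down" ~ "hypo-down",
        .data$m6a_direction == "hypo" & .data$rna_direction == "up" ~ "hypo-up",
        .data$m6a_direction == "hyper" & .data$rna_direction == "down" ~ "hyper-down",
        TRUE ~ "non-significant"
      )
    ) |>
    select("gene_id", "peak_id", "m6a_direction", "rna_direction", "category")
}
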