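#' Resampling consensus clustering of samples
#'
#' Re-implementation of the resampling consensus-clustering procedure: in each
#' of `n_boot` resamples a fraction `subsample` of the samples is drawn
#' without replacement and clustered into `k` groups (agglomerative,
#' `linkage` on Euclidean distance over peaks by default; k-means optional);
#' the consensus matrix entry for a sample pair is the fraction of
#' co-sampled resamples in which the pair co-clustered. Final labels come
#' from hierarchical clustering of `1 - consensus`. Rows (peaks) are
#' standardized to zero mean / unit variance across samples beforehand unless
#' `scale_rows = FALSE`.
#'
#' @param levels long level tibble (see [relative_m6a_level()]), typically
#'   restricted to differential peaks, or a peaks x samples numeric matrix.
#' @param k number of clusters for the reported assignment.
#' @param k_range additional k values for which consensus matrices and PAC
#'   statistics are computed (for choosing k).
#' @param n_boot number of resamples.
#' @param subsample subsampling proportion in (0, 1].
#' @param seed optional integer seed.
#' @param inner inner clusterer for the resamples.
#' @param linkage linkage for the hierarchical inner/final clusterer.
#' @param scale_rows standardize peaks before clustering.
#' @return Object of class `consensus_cluster` with elements `consensus`
#'   (named list of per-k matrices), `assignment` (tibble `sample_id`,
#'   `cluster`, `silhouette`), `k`, and `metrics` (per-k PAC). Cluster labels
#'   are `S1..Sk` ordered by first occurrence in the consensus dendrogram.
#' @export
consensus_cluster <- function(levels, k = 2, k_range = k, n_boot = 1000,
                              subsample = 0.8, seed = NULL,
                              inner = c("hclust", "kmeans"),
                              linkage = "average", scale_rows = TRUE) {
  inner <- match.arg(inner)
  m <- if (is.matrix(levels)) levels else level_matrix(levels)
  n <- ncol(m)
  k_all <- sort(unique(c(k, k_range)))
  if (max(k_all) > n) abort("k exceeds the number of samples")
  if (n < 2 * max(k_all)) abort("need at least 2*k samples")
  if (subsample <= 0 || subsample > 1) abort("subsample must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)

  x <- m
  if (scale_rows) {
    keep <- apply(x, 1, function(r) sd(r, na.rm = TRUE) > 0)
    x <- t(scale(t(x[keep, , drop = FALSE])))
  }
  x[is.na(x)] <- 0
  n_draw <- ceiling(subsample * n)

  co_cluster <- lapply(k_all, function(kk) matrix(0, n, n))
  names(co_cluster) <- as.character(k_all)
  co_sample <- matrix(0, n, n)

  for (b in seq_len(n_boot)) {
    idx <- sort(sample.int(n, n_draw))
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    sub <- x[, idx, drop = FALSE]
    if (inner == "hclust") {
      hc <- hclust(dist(t(sub)), method = linkage)
      labs_k <- lapply(k_all, function(kk) cutree(hc, kk))
    } else {
      labs_k <- lapply(k_all, function(kk) {
        stats::kmeans(t(sub), centers = kk, nstart = 1)$cluster
      })
    }
    for (j in seq_along(k_all)) {
      lab <- labs_k[[j]]
      same <- outer(lab, lab, `==`) * 1
      co_cluster[[j]][idx, idx] <- co_cluster[[j]][idx, idx] + same
    }
  }

  consensus <- lapply(co_cluster, function(cc) {
    cons <- ifelse(co_sample > 0, cc / co_sample, 0)
    diag(cons) <- 1
    dimnames(cons) <- list(colnames(m), colnames(m))
    cons
  })

  pac <- map_dbl(consensus, function(cons) {
    v <- cons[upper.tri(cons)]
    mean(v > 0.1 & v < 0.9)  # proportion of ambiguous co-clustering
  })

  cons_k <- consensus[[as.character(k)]]
  hc_final <- hclust(stats::as.dist(1 - cons_k), method = linkage)
  raw_lab <- cutree(hc_final, k)
  # stable S1..Sk naming: order clusters by first sample index
  ord <- rank(map_dbl(seq_len(k), function(g) min(which(raw_lab == g))))
  cluster <- paste0("S", ord[raw_lab])
  sil <- silhouette_from_dist(1 - cons_k, raw_lab)

  structure(
    list(
      consensus = consensus,
      assignment = tibble(sample_id = colnames(m), cluster = cluster,
                          silhouette = sil),
      k = k,
      metrics = tibble(k = k_all, pac = unname(pac)),
      n_boot = n_boot, subsample = subsample
    ),
    class = "consensus_cluster"
  )
}

# plain silhouette on a distance matrix
silhouette_from_dist <- function(d, lab) {
  n <- length(lab)
  map_dbl(seq_len(n), function(i) {
    own <- lab == lab[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    bs <- map_dbl(setdiff(unique(lab), lab[i]),
                  function(g) mean(d[i, lab == g]))
    if (length(bs) == 0) return(0)
    b <- min(bs)
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  })
}

#' @export
print.consensus_cluster <- function(x, ...) {
  cat(sprintf("<consensus_cluster> k=%d, %d samples, %d resamples (%.0f%%)\n",
              x$k, nrow(x$assignment), x$n_boot, 100 * x$subsample))
  print(count(x$assignment, .data$cluster))
  invisible(x)
}

#' Differential m6A between two subtypes
#'
#' Unpaired two-sided Wilcoxon rank-sum test per peak between the `ref` and
#' `alt` clusters with BH correction; directions are relative to `alt`
#' (`hyper` = higher in `alt`).
#'
#' @param levels long level tibble or peaks x samples matrix.
#' @param assignment tibble `sample_id`, `cluster` (e.g. from
#'   [consensus_cluster()]).
#' @param ref,alt cluster labels to compare.
#' @param fdr_cut FDR threshold for direction calls.
#' @param min_group minimum samples per group.
#' @return Tibble `peak_id`, `median_ref`, `median_alt`, `log2_fc`,
#'   `p_value`, `fdr`, `direction`.
#' @export
subtype_differential <- function(levels, assignment, ref = "S1", alt = "S2",
                                 fdr_cut = 0.1, min_group = 5) {
  m <- if (is.matrix(levels)) levels else level_matrix(levels)
  s_ref <- assignment$sample_id[assignment$cluster == ref]
  s_alt <- assignment$sample_id[assignment$cluster == alt]
  if (length(s_ref) < min_group) abort(sprintf("group %s has < %d samples", ref, min_group))
  if (length(s_alt) < min_group) abort(sprintf("group %s has < %d samples", alt, min_group))
  a <- m[, s_ref, drop = FALSE]
  b <- m[, s_alt, drop = FALSE]

  res <- map(seq_len(nrow(m)), function(i) {
    xa <- a[i, !is.na(a[i, ])]
    xb <- b[i, !is.na(b[i, ])]
    if (length(xa) < min_group || length(xb) < min_group) {
      return(tibble(median_ref = NA_real_, median_alt = NA_real_,
                    log2_fc = NA_real_, p_value = NA_real_))
    }
    p <- suppressWarnings(wilcox.test(xb, xa)$p.value)
    # fold change only meaningful on a positive scale (raw relative levels);
    # on log-transformed input report the mean difference instead
    lfc <- if (mean(xa) > 0 && mean(xb) > 0) log2(mean(xb) / mean(xa))
           else mean(xb) - mean(xa)
    tibble(median_ref = median(xa), median_alt = median(xb),
           log2_fc = lfc, p_value = p)
  }) |> list_rbind()

  res |>
    mutate(peak_id = rownames(m), .before = 1) |>
    mutate(
      fdr = p.adjust(.data$p_value, method = "BH"),
      direction = case_when(
        is.na(.data$fdr) | .data$fdr >= fdr_cut ~ "ns",
        .data$median_alt > .data$median_ref ~ "hyper",
        .data$median_alt < .data$median_ref ~ "hypo",
        TRUE ~ "ns"
      )
    )
}

#' Subtype vs clinical-feature association tests
#'
#' For each categorical clinical feature, cross-tabulates it against the
#' cluster assignment (missing values excluded per feature) and tests
#' association: Fisher's exact test for 2x2 tables, chi-square otherwise,
#' falling back to Fisher when any expected cell is below 5. The odds ratio
#' is reported for 2x2 tables.
#'
#' @param assignment tibble `sample_id`, `cluster`.
#' @param clinical tibble with `sample_id` plus one column per categorical
#'   feature.
#' @return Tibble `feature`, `test`, `p_value`, `odds_ratio`, `note`.
#' @export
clinical_association <- function(assignment, clinical) {
  feats <- setdiff(names(clinical), "sample_id")
  dat <- inner_join(assignment, clinical, by = "sample_id")
  map(feats, function(f) {
    v <- dat[[f]]
    ok <- !is.na(v)
    tab <- table(dat$cluster[ok], v[ok])
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      return(tibble(feature = f, test = "none", p_value = 1,
                    odds_ratio = NA_real_, note = "constant feature"))
    }
    if (nrow(tab) == 2 && ncol(tab) == 2) {
      ft <- fisher.test(tab)
      return(tibble(feature = f, test = "fisher", p_value = ft$p.value,
                    odds_ratio = unname(ft$estimate), note = NA_character_))
    }
    expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expct < 5)) {
      ft <- fisher.test(tab, workspace = 2e6)
      tibble(feature = f, test = "fisher", p_value = ft$p.value,
             odds_ratio = NA_real_, note = "expected cell < 5")
    } else {
      ct <- suppressWarnings(chisq.test(tab))
      tibble(feature = f, test = "chisq", p_value = ct$p.value,
             odds_ratio = NA_real_, note = NA_character_)
    }
  }) |> list_rbind()
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' Product-limit estimate per cluster with the median survival taken as the
#' smallest time at which the estimated survival drops to 0.5 or below
#' (NA when never reached), and the log-rank test across groups.
#'
#' @param survival_data tibble `sample_id`, `time` (months, > 0), `event`
#'   (1 observed / 0 censored); an optional `endpoint` column is carried
#'   through when filtering is done upstream.
#' @param assignment tibble `sample_id`, `cluster`.
#' @return Object of class `km_fit` with `curves` (tibble `cluster`, `time`,
#'   `n_risk`, `n_event`, `survival`), `medians`, `chisq`, `df`, `p_value`.
#' @export
km_logrank <- function(survival_data, assignment) {
  if (any(survival_data$time <= 0)) abort("survival times must be > 0")
  dat <- inner_join(survival_data, assignment, by = "sample_id")
  if (sum(dat$event) == 0) abort("no events in any group")
  if (length(unique(dat$cluster)) < 2) abort("need at least two groups")

  sf <- survival::survfit(survival::Surv(time, event) ~ cluster, data = dat)
  strata_lab <- sub("^cluster=", "", rep(names(sf$strata), sf$strata))
  curves <- tibble(cluster = strata_lab, time = sf$time, n_risk = sf$n.risk,
                   n_event = sf$n.event, survival = sf$surv)
  medians <- curves |>
    group_by(.data$cluster) |>
    summarise(
      median_survival = {
        hit <- .data$time[.data$survival <= 0.5]
        if (length(hit) == 0) NA_real_ else min(hit)
      },
      n = first(.data$n_risk), .groups = "drop"
    )
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ cluster, data = dat)
  df <- length(sd_$n) - 1
  p <- pchisq(sd_$chisq, df, lower.tail = FALSE)

  structure(list(curves = curves, medians = medians, chisq = sd_$chisq,
                 df = df, p_value = p),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> log-rank chisq=%.3f (df=%d), p=%.3g\n",
              x$chisq, x$df, x$p_value))
  print(x$medians)
  invisible(x)
}
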