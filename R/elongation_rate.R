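#' Build TSS-anchored coverage profiles
#'
#' Extracts per-base (or binned) read depth over `[-upstream, +downstream)`
#' around each gene's TSS, oriented by strand (minus-strand profiles are
#' reversed so position increases 3'-ward), for each release time point. When
#' several replicate tracks are supplied per time, the per-base depth is their
#' 0.01-trimmed mean. Genes closer than the window to a contig edge are
#' truncated (zero-padded) and flagged.
#'
#' @param coverage named list: one element per time point (names = minutes),
#'   each a list of replicate tracks, each track a named list of per-chrom
#'   numeric depth vectors. A single track may be given directly.
#' @param genes tibble `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @param upstream,downstream window in bp around the TSS.
#' @param bin_width average depth into bins of this many bp (1 = per-base).
#' @param trim trim fraction for the replicate mean.
#' @return Tibble `gene_id`, `time_min`, `truncated`, `mean_depth`, and a
#'   list-column `profile` of depth vectors; positions for element `i` are
#'   `-upstream + (i - 0.5) * bin_width` relative to the TSS.
#' @export
build_profiles <- function(coverage, genes, upstream = 10000,
                           downstream = 120000, bin_width = 1, trim = 0.01) {
  len <- upstream + downstream
  map(names(coverage), function(tm) {
    tracks <- coverage[[tm]]
    if (!is.list(tracks[[1]])) tracks <- list(tracks)
    map(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      mats <- map(tracks, function(trk) {
        if (!g$chrom %in% names(trk)) return(NULL)
        v <- trk[[g$chrom]]
        extract_window(v, g$tss, g$strand, upstream, downstream)
      })
      mats <- mats[!map_lgl(mats, is.null)]
      if (length(mats) == 0) return(NULL)
      prof <- if (length(mats) == 1) {
        mats[[1]]$depth
      } else {
        apply(do.call(cbind, map(mats, "depth")), 1, mean, trim = trim)
      }
      if (bin_width > 1) {
        nb <- length(prof) %/% bin_width
        prof <- as.numeric(tapply(prof[seq_len(nb * bin_width)],
                                  rep(seq_len(nb), each = bin_width), mean))
      }
      tibble(gene_id = g$gene_id, time_min = as.numeric(tm),
             truncated = any(map_lgl(mats, "truncated")),
             mean_depth = mean(prof), profile = list(prof))
    }) |> list_rbind()
  }) |>
    list_rbind() |>
    structure(upstream = upstream, bin_width = bin_width)
}

extract_window <- function(v, tss, strand, upstream, downstream) {
  n <- length(v)
  if (strand == "+") {
    lo <- tss - upstream
    hi <- tss + downstream
  } else {
    lo <- tss - downstream + 1L
    hi <- tss + upstream + 1L
  }
  idx <- seq(lo, hi - 1)
  inb <- idx >= 0 & idx < n
  depth <- numeric(length(idx))
  depth[inb] <- v[idx[inb] + 1]
  if (strand == "-") depth <- rev(depth)
  list(depth = depth, truncated = any(!inb))
}

#' Smooth a profile and locate its wave peak
#'
#' Fits a cubic smoothing spline (`stats::smooth.spline`, default
#' `spar = 0.8`) to the profile and reports the wave peak: the maximum of the
#' smoothed curve over positions downstream of the TSS (>= `search_from`).
#' With tied maxima the 5'-most is reported and flagged ambiguous; an
#' all-zero profile is flagged `low_expression`.
#'
#' @param profile numeric depth vector (one row of [build_profiles()]).
#' @param upstream,bin_width geometry of the profile (bp).
#' @param spar smoothing parameter passed to `smooth.spline`.
#' @param df optional effective degrees of freedom overriding `spar`.
#' @param search_from smallest position (bp, TSS-relative) considered for the
#'   peak.
#' @return One-row tibble `peak_pos` (bp relative to TSS), `peak_height`,
#'   `ambiguous`, `flag`.
#' @export
smooth_and_peak <- function(profile, upstream = 10000, bin_width = 1,
                            spar = 0.8, df = NULL, search_from = 0) {
  pos <- -upstream + (seq_along(profile) - 0.5) * bin_width
  if (all(profile == 0)) {
    return(tibble(peak_pos = NA_real_, peak_height = NA_real_,
                  ambiguous = FALSE, flag = "low_expression"))
  }
  fit <- if (is.null(df)) {
    smooth.spline(pos, profile, spar = spar)
  } else {
    smooth.spline(pos, profile, df = df)
  }
  sm <- predict(fit, pos)$y
  in_body <- pos >= search_from
  y <- sm[in_body]
  x <- pos[in_body]
  top <- max(y)
  at <- which(y >= top - 1e-9)
  tibble(peak_pos = x[at[1]], peak_height = top, ambiguous = length(at) > 1,
         flag = NA_character_)
}

#' Wave-peak table for a set of profiles
#'
#' Runs [smooth_and_peak()] over every gene/time profile.
#'
#' @param profiles output of [build_profiles()].
#' @param ... passed to [smooth_and_peak()].
#' @return Tibble `gene_id`, `time_min`, `mean_depth`, `peak_pos`,
#'   `ambiguous`, `flag`.
#' @export
wave_peaks <- function(profiles, ...) {
  upstream <- attr(profiles, "upstream") %||% 10000
  bin_width <- attr(profiles, "bin_width") %||% 1
  profiles |>
    mutate(fit = map(.data$profile, smooth_and_peak, upstream = upstream,
                     bin_width = bin_width, ...)) |>
    select("gene_id", "time_min", "mean_depth", "fit") |>
    unnest("fit")
}

#' Filter genes for elongation-rate fitting
#'
#' Applies the wave-tracking quality filters: genes are failed when lowly
#' expressed (mean profile depth below `expr_threshold`, default the cohort's
#' 25th percentile), when any wave peak is missing, when peak positions are
#' identical across all times (`duplicate`), when the peak does not strictly
#' advance with time (`non_advancing`), or when the peak at the latest time
#' is at or before `early_cut` bp (`early_peak`).
#'
#' @param peaks tibble from [wave_peaks()] (needs >= 2 time points per gene).
#' @param expr_threshold low-expression cutoff on mean depth.
#' @param early_cut minimum peak position (bp) required at the latest time.
#' @return Tibble `gene_id`, `pass`, `reasons` (comma-joined).
#' @export
filter_genes <- function(peaks, expr_threshold = NULL, early_cut = 1000) {
  if (is.null(expr_threshold)) {
    gene_depth <- peaks |> group_by(.data$gene_id) |>
      summarise(d = mean(.data$mean_depth), .groups = "drop")
    expr_threshold <- quantile(gene_depth$d, 0.25)
  }
  peaks |>
    group_by(.data$gene_id) |>
    arrange(.data$time_min, .by_group = TRUE) |>
    summarise(
      reasons = {
        r <- character()
        if (mean(.data$mean_depth) < expr_threshold) r <- c(r, "low_expression")
        if (anyNA(.data$peak_pos)) {
          r <- c(r, "missing")
        } else {
          if (length(unique(.data$peak_pos)) == 1) r <- c(r, "duplicate")
          if (any(diff(.data$peak_pos) <= 0)) r <- c(r, "non_advancing")
          if (tail(.data$peak_pos, 1) <= early_cut) r <- c(r, "early_peak")
        }
        paste(r, collapse = ",")
      },
      .groups = "drop"
    ) |>
    mutate(pass = .data$reasons == "")
}

#' Elongation rates from wave-peak positions
#'
#' Ordinary least-squares slope of wave-peak position (kb) on release time
#' (min) per gene; with exactly two time points this is the two-point slope.
#'
#' @param peaks tibble from [wave_peaks()].
#' @param keep optional gene ids to fit (e.g. `filter_genes()` passers);
#'   default all genes with >= 2 non-missing peaks.
#' @return Tibble `gene_id`, `rate_kb_per_min`, `intercept_kb`, `n_times`.
#' @export
fit_rate <- function(peaks, keep = NULL) {
  d <- filter(peaks, !is.na(.data$peak_pos))
  if (!is.null(keep)) d <- filter(d, .data$gene_id %in% keep)
  d |>
    group_by(.data$gene_id) |>
    summarise(
      n_times = n(),
      rate_kb_per_min = ols_coef(.data$time_min, .data$peak_pos / 1000)[2],
      intercept_kb = ols_coef(.data$time_min, .data$peak_pos / 1000)[1],
      .groups = "drop"
    )
}

ols_coef <- function(x, y) {
  if (length(x) < 2) abort("need >= 2 time points per gene")
  if (length(unique(x)) < 2) abort("identical times")
  unname(coef(lm(y ~ x)))
}

#' Compare two elongation-rate distributions
#'
#' Two-sample two-sided Kolmogorov-Smirnov test on per-gene rates.
#'
#' @param rates_a,rates_b numeric vectors of rates (kb/min), >= 5 each.
#' @return One-row tibble `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_rates <- function(rates_a, rates_b) {
  if (length(rates_a) < 5 || length(rates_b) < 5) {
    abort("need >= 5 genes per sample")
  }
  kt <- suppressWarnings(ks.test(rates_a, rates_b))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n_a = length(rates_a), n_b = length(rates_b))
}

#' Elongation rate from a DRB release qPCR design
#'
#' Rate arithmetic for the amplicon-based assay: distance of the amplicon
#' from the TSS divided by the time of first pre-mRNA reappearance.
#'
#' @param distance_kb amplicon distance from the TSS in kb.
#' @param time_min release time (min) at which the pre-mRNA signal reappears.
#' @return Rate in kb/min.
#' @export
drb_qpcr_rate <- function(distance_kb, time_min) {
  if (any(time_min <= 0)) abort("time must be > 0")
  distance_kb / time_min
}
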