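#' Plot helpers
#'
#' ggplot2 figures for the package's result types. Each returns a ggplot
#' object so it can be themed or extended downstream.
#'
#' @name m6ascape-plots
NULL

#' @rdname m6ascape-plots
#' @param profile output of [metagene_profile()].
#' @export
plot_metagene <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$density,
                                        colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(1, 2), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_continuous(breaks = c(0.5, 1.5, 2.5),
                                labels = c("5'UTR", "CDS", "3'UTR")) +
    ggplot2::labs(x = NULL, y = "peak density") +
    ggplot2::theme_minimal()
}

#' @rdname m6ascape-plots
#' @param diff differential tibble (from [differential_paired()] or
#'   [subtype_differential()]).
#' @export
plot_volcano <- function(diff) {
  d <- filter(diff, !is.na(.data$p_value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(.data$p_value),
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(hyper = "firebrick",
                                            hypo = "steelblue",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' @rdname m6ascape-plots
#' @param x a `consensus_cluster`, `km_fit` or `rbp_rank` object.
#' @param ... unused.
#' @export
autoplot.consensus_cluster <- function(x, ...) {
  cons <- x$consensus[[as.character(x$k)]]
  ord <- order(x$assignment$cluster)
  m <- cons[ord, ord]
  d <- tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    consensus = as.vector(m)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus matrix (k = %d)", x$k)) +
    ggplot2::theme_minimal()
}

#' @rdname m6ascape-plots
#' @export
autoplot.km_fit <- function(x, ...) {
  # step curves starting at S(0) = 1
  d <- x$curves |>
    group_by(.data$cluster) |>
    dplyr::group_modify(~ bind_rows(tibble(time = 0, survival = 1),
                                    select(.x, "time", "survival"))) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$survival,
                                  colour = .data$cluster)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival",
                  subtitle = sprintf("log-rank p = %.3g", x$p_value)) +
    ggplot2::theme_minimal()
}

#' @rdname m6ascape-plots
#' @export
autoplot.rbp_rank <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(.data$neg_log10_fdr, .data$contribution)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::geom_point(data = dplyr::slice_min(x, .data$rank, n = 3),
                        colour = "firebrick") +
    ggplot2::geom_text(data = dplyr::slice_min(x, .data$rank, n = 3),
                       ggplot2::aes(label = .data$rbp), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(x = "-log10(FDR), correlation enrichment",
                  y = "forest contribution score") +
    ggplot2::theme_minimal()
}

#' @rdname m6ascape-plots
#' @param dp output of [distance_profile()].
#' @export
plot_distance_profile <- function(dp) {
  ggplot2::ggplot(dp, ggplot2::aes(.data$bin_mid, .data$count)) +
    ggplot2::geom_col(width = dp$bin_mid[2] - dp$bin_mid[1],
                      fill = "steelblue") +
    ggplot2::labs(x = "distance to nearest site (bp, 3' positive)",
                  y = "anchor count") +
    ggplot2::theme_minimal()
}

#' @rdname m6ascape-plots
#' @param profiles output of [build_profiles()]; `gene` a gene id.
#' @param gene gene to draw.
#' @export
plot_wave <- function(profiles, gene) {
  upstream <- attr(profiles, "upstream") %||% 10000
  bw <- attr(profiles, "bin_width") %||% 1
  d <- profiles |>
    filter(.data$gene_id == gene) |>
    mutate(pos = map(.data$profile,
                     ~ -upstream + (seq_along(.x) - 0.5) * bw)) |>
    select("time_min", "pos", "profile") |>
    unnest(c("pos", "profile"))
  ggplot2::ggplot(d, ggplot2::aes(.data$pos / 1000, .data$profile)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_smooth(method = "gam", formula = y ~ s(x, k = 50),
                         se = FALSE, colour = "firebrick") +
    ggplot2::facet_wrap(~time_min, ncol = 1) +
    ggplot2::labs(x = "position from TSS (kb)", y = "read depth") +
    ggplot2::theme_minimal()
}
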