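#' Tidy and glance methods
#'
#' broom-style summaries for the package's fitted objects.
#'
#' @param x a fitted object.
#' @param ... unused.
#' @name m6ascape-tidiers
NULL

#' @rdname m6ascape-tidiers
#' @export
tidy.contribution_forest <- function(x, ...) {
  tibble(predictor = x$predictors,
         contribution = colMeans(x$contribution)) |>
    arrange(dplyr::desc(abs(.data$contribution)))
}

#' @rdname m6ascape-tidiers
#' @export
glance.contribution_forest <- function(x, ...) {
  resid <- x$y - x$prediction
  identity_err <- max(abs(x$prediction - x$root_value -
                            rowSums(x$contribution)))
  tibble(
    n_trees = x$n_trees, mtry = x$mtry, n_samples = length(x$y),
    n_predictors = length(x$predictors),
    root_value = x$root_value,
    r_squared = if (var(x$y) > 0) 1 - sum(resid^2) / sum((x$y - mean(x$y))^2)
                else NA_real_,
    max_identity_error = identity_err
  )
}

#' @rdname m6ascape-tidiers
#' @export
tidy.consensus_cluster <- function(x, ...) x$assignment

#' @rdname m6ascape-tidiers
#' @export
glance.consensus_cluster <- function(x, ...) {
  tibble(k = x$k, n_samples = nrow(x$assignment), n_boot = x$n_boot,
         subsample = x$subsample,
         mean_silhouette = mean(x$assignment$silhouette),
         pac = x$metrics$pac[x$metrics$k == x$k])
}

#' @rdname m6ascape-tidiers
#' @export
tidy.km_fit <- function(x, ...) x$curves

#' @rdname m6ascape-tidiers
#' @export
glance.km_fit <- function(x, ...) {
  med <- x$medians |>
    select("cluster", "median_survival") |>
    tidyr::pivot_wider(names_from = "cluster",
                       values_from = "median_survival",
                       names_prefix = "median_")
  bind_cols(tibble(chisq = x$chisq, df = x$df, p_value = x$p_value), med)
}

#' @rdname m6ascape-tidiers
#' @export
tidy.permutation_null <- function(x, ...) x$permutations

#' @rdname m6ascape-tidiers
#' @export
glance.permutation_null <- function(x, ...) {
  tibble(n_perm = x$n_perm,
         observed_fdr_count = x$observed$n_fdr,
         observed_p_count = x$observed$n_p,
         mean_perm_fdr_count = x$mean_fdr_count,
         mean_perm_p_count = x$mean_p_count)
}
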