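#' Regression forest with per-prediction contribution decomposition
#'
#' Fits a random regression forest (CART trees on bootstrap samples with
#' `mtry` candidate features per split) of one peak's m6A levels on the
#' predictor matrix, and decomposes every prediction additively over
#' predictors: walking a sample's decision path, the change in node mean from
#' parent to child is credited to the split feature, so for every tree
#' `prediction = root_mean + sum of contributions` holds exactly. The
#' per-predictor contribution is the signed average over trees and samples.
#'
#' @param x data frame or matrix of predictors (samples x predictors), e.g.
#'   RBP expression plus encoded clinical covariates. Constant columns are
#'   dropped with a warning.
#' @param y numeric response (per-sample m6A level of one peak).
#' @param n_trees number of trees.
#' @param mtry candidate features per split; default `ceiling(p/3)`
#'   (regression convention).
#' @param min_node minimum samples per leaf.
#' @param max_depth maximum tree depth (0 = unlimited).
#' @param bootstrap draw a bootstrap sample per tree.
#' @param seed optional integer seed.
#' @return Object of class `contribution_forest` with the per-sample
#'   contribution matrix, predictions, root value, and the fitted trees.
#'   `tidy()` gives per-predictor mean contributions; `glance()` gives fit
#'   summaries including the maximum additive-identity error.
#' @export
fit_contribution_forest <- function(x, y, n_trees = 100, mtry = NULL,
                                    min_node = 5, max_depth = 0,
                                    bootstrap = TRUE, seed = NULL) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) abort("x and y disagree on the number of samples")
  if (n_trees < 1) abort("n_trees must be >= 1")
  keep <- apply(X, 2, function(v) length(unique(v)) > 1)
  if (!all(keep)) {
    warn(sprintf("dropping constant predictor(s): %s",
                 paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(mtry)) mtry <- max(1L, ceiling(ncol(X) / 3))
  if (!is.null(seed)) set.seed(seed)

  forest <- forest_fit_cpp(X, as.double(y), as.integer(n_trees),
                           as.integer(mtry), as.integer(min_node),
                           as.integer(max_depth), bootstrap)
  dec <- forest_contrib_cpp(forest, X)
  contrib <- dec$contribution
  dimnames(contrib) <- list(rownames(X), colnames(X))

  structure(
    list(forest = forest, predictors = colnames(X),
         contribution = contrib, prediction = dec$prediction,
         root_value = dec$root_value, y = as.double(y),
         n_trees = n_trees, mtry = mtry),
    class = "contribution_forest"
  )
}

#' @export
print.contribution_forest <- function(x, ...) {
  cat(sprintf("<contribution_forest> %d trees, %d predictors, %d samples\n",
              x$n_trees, length(x$predictors), length(x$y)))
  invisible(x)
}

#' Predict (with contributions) from a contribution forest
#'
#' @param object a `contribution_forest`.
#' @param newdata predictor matrix with the fitted predictor columns.
#' @param ... unused.
#' @return List with `prediction`, `contribution` matrix and `root_value`;
#'   `prediction = root_value + rowSums(contribution)` per construction.
#' @export
predict.contribution_forest <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$predictors, drop = FALSE]
  storage.mode(X) <- "double"
  dec <- forest_contrib_cpp(object$forest, X)
  dimnames(dec$contribution) <- list(rownames(X), object$predictors)
  dec
}

#' Fit contribution forests across peaks
#'
#' Convenience wrapper running [fit_contribution_forest()] for each peak in a
#' level matrix against a shared predictor matrix.
#'
#' @param x predictor data frame (samples x predictors) with a `sample_id`
#'   column or rownames matching the level samples.
#' @param levels long level tibble or peaks x samples matrix.
#' @param peaks peak ids to fit (default all rows).
#' @param ... passed to [fit_contribution_forest()].
#' @param seed optional seed applied once before the sweep.
#' @return Tibble `peak_id`, `predictor`, `contribution` (signed mean over
#'   trees and samples).
#' @export
contribution_sweep <- function(x, levels, peaks = NULL, seed = NULL, ...) {
  m <- if (is.matrix(levels)) levels else level_matrix(levels)
  if ("sample_id" %in% names(as.data.frame(x))) {
    xd <- as.data.frame(x)
    rownames(xd) <- xd$sample_id
    xd$sample_id <- NULL
    x <- xd
  }
  x <- x[colnames(m), , drop = FALSE]
  if (is.null(peaks)) peaks <- rownames(m)
  if (!is.null(seed)) set.seed(seed)
  map(peaks, function(p) {
    fit <- fit_contribution_forest(x, m[p, ], ...)
    tibble(peak_id = p, predictor = fit$predictors,
           contribution = colMeans(fit$contribution),
           contribution_abs = colMeans(abs(fit$contribution)))
  }) |> list_rbind()
}

#' Aggregate forest contributions over a peak set
#'
#' Mean per-predictor contribution over the given (typically hypermethylated)
#' peaks; clinical covariates can be excluded from the ranking output. Ties
#' are broken by predictor name for a stable order.
#'
#' @param records tibble `peak_id`, `predictor`, `contribution`,
#'   `contribution_abs` (from [contribution_sweep()]).
#' @param hyper_set peak ids to aggregate over (must be scored).
#' @param exclude predictors (e.g. clinical covariates) dropped from the
#'   output.
#' @param mode `"absolute"` (default) scores each predictor by the mean
#'   absolute per-sample contribution; `"signed"` uses the signed mean. Over
#'   a training cohort the signed per-sample contributions of any predictor
#'   sum to approximately zero (leaf-mean deviations cancel), so the
#'   magnitude is what measures how much the forest relies on a predictor.
#' @return Tibble `rbp`, `contribution`, sorted by decreasing contribution.
#' @export
aggregate_contributions <- function(records, hyper_set, exclude = character(),
                                    mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (length(hyper_set) == 0) abort("hyper_set is empty")
  missing_pk <- setdiff(hyper_set, unique(records$peak_id))
  if (length(missing_pk) > 0) {
    abort(sprintf("hyper_set peaks not scored: %s",
                  paste(head(missing_pk, 5), collapse = ", ")))
  }
  col <- if (mode == "absolute") "contribution_abs" else "contribution"
  records |>
    filter(.data$peak_id %in% hyper_set, !.data$predictor %in% exclude) |>
    group_by(rbp = .data$predictor) |>
    summarise(contribution = mean(.data[[col]]), .groups = "drop") |>
    arrange(dplyr::desc(.data$contribution), .data$rbp)
}

# vectorized Spearman rho + t-approximation p for matrix columns:
# x (samples x A), y (samples x B) -> list(rho, p) of A x B matrices
spearman_matrix <- function(x, y) {
  ok <- complete.cases(x) & complete.cases(y)
  x <- x[ok, , drop = FALSE]
  y <- y[ok, , drop = FALSE]
  n <- nrow(x)
  rx <- apply(x, 2, rank)
  ry <- apply(y, 2, rank)
  rho <- cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = p, n = n)
}

#' Spearman screen of RBP-m6A pairs
#'
#' Spearman correlation between each RBP's expression and each peak's m6A
#' level, computed separately within the hyper, hypo and unchanged peak
#' strata. A pair is significant when `|rho| > r_min` and `p < p_max`.
#' P-values use the t approximation on rho (tie-safe); constant vectors are
#' skipped.
#'
#' @param rbp_expr wide tibble `sample_id` + one numeric column per RBP, or a
#'   samples x RBPs matrix with rownames.
#' @param levels long level tibble or peaks x samples matrix.
#' @param strata tibble `peak_id`, `stratum` (`hyper`/`hypo`/`unchanged`).
#' @param r_min,p_max significance thresholds.
#' @return Tibble `rbp`, `peak_id`, `stratum`, `rho`, `p_value`,
#'   `significant`.
#' @export
spearman_screen <- function(rbp_expr, levels, strata, r_min = 0.25,
                            p_max = 0.05) {
  m <- if (is.matrix(levels)) levels else level_matrix(levels)
  if (is.data.frame(rbp_expr)) {
    xd <- as.data.frame(rbp_expr)
    rownames(xd) <- xd$sample_id
    xd$sample_id <- NULL
    rbp_expr <- as.matrix(xd)
  }
  rbp_expr <- rbp_expr[colnames(m), , drop = FALSE]
  keep_rbp <- apply(rbp_expr, 2, function(v) sd(v, na.rm = TRUE) > 0)
  if (!all(keep_rbp)) {
    warn(sprintf("skipping constant RBP column(s): %s",
                 paste(colnames(rbp_expr)[!keep_rbp], collapse = ", ")))
    rbp_expr <- rbp_expr[, keep_rbp, drop = FALSE]
  }
  strata <- filter(strata, .data$peak_id %in% rownames(m))

  map(split(strata$peak_id, strata$stratum), function(pids) {
    y <- t(m[pids, , drop = FALSE])
    keep_pk <- apply(y, 2, function(v) sd(v, na.rm = TRUE) > 0)
    y <- y[, keep_pk, drop = FALSE]
    if (ncol(y) == 0) return(NULL)
    sp <- spearman_matrix(rbp_expr, y)
    if (sp$n < 5) abort("need >= 5 paired observations")
    tibble(
      rbp = rep(colnames(rbp_expr), times = ncol(y)),
      peak_id = rep(colnames(y), each = ncol(rbp_expr)),
      rho = as.vector(sp$rho),
      p_value = as.vector(sp$p)
    )
  }) |>
    list_rbind(names_to = "stratum") |>
    mutate(significant = abs(.data$rho) > r_min & .data$p_value < p_max) |>
    select("rbp", "peak_id", "stratum", "rho", "p_value", "significant")
}

#' Fisher enrichment of significant pairs in the hyper stratum
#'
#' For each RBP, a 2x2 table of peaks (hyper vs background stratum) by pair
#' significance, tested one-sided for over-representation of significant
#' pairs among hypermethylated peaks; BH correction across RBPs.
#'
#' @param screen output of [spearman_screen()].
#' @param hyper_stratum,background_strata stratum labels defining the two
#'   disjoint peak pools.
#' @return Tibble `rbp`, `n_sig_hyper`, `n_hyper`, `n_sig_bg`, `n_bg`,
#'   `odds_ratio`, `p_value`, `fdr`.
#' @export
enrichment_fisher <- function(screen, hyper_stratum = "hyper",
                              background_strata = c("unchanged", "hypo")) {
  bg <- filter(screen, .data$stratum %in% background_strata)
  hy <- filter(screen, .data$stratum == hyper_stratum)
  if (nrow(bg) == 0) abort("empty background stratum")
  if (nrow(hy) == 0) abort("empty hyper stratum")

  summ <- function(d, suffix) {
    d |>
      group_by(.data$rbp) |>
      summarise("n_sig_{suffix}" := sum(.data$significant),
                "n_{suffix}" := n(), .groups = "drop")
  }
  res <- inner_join(summ(hy, "hyper"), summ(bg, "bg"), by = "rbp") |>
    mutate(pmap(list(.data$n_sig_hyper, .data$n_hyper,
                     .data$n_sig_bg, .data$n_bg),
                function(a, na, b, nb) {
                  ft <- fisher.test(matrix(c(a, na - a, b, nb - b), 2,
                                           byrow = TRUE),
                                    alternative = "greater")
                  tibble(odds_ratio = unname(ft$estimate),
                         p_value = ft$p.value)
                }) |> list_rbind())
  mutate(res, fdr = p.adjust(.data$p_value, method = "BH"))
}

#' Combine contribution scores and correlation-enrichment FDR into a ranking
#'
#' Emits the two axes of the regulator scatter (`-log10(FDR)` from the
#' correlation enrichment, mean forest contribution) and ranks RBPs by the
#' product of the min-max-standardized axes. Ties are broken by name.
#'
#' @param aggregates tibble `rbp`, `contribution` (from
#'   [aggregate_contributions()]).
#' @param enrichments tibble from [enrichment_fisher()].
#' @return Tibble `rbp`, `contribution`, `fdr`, `odds_ratio`,
#'   `neg_log10_fdr`, `score`, `rank`.
#' @export
rank_rbps <- function(aggregates, enrichments) {
  minmax <- function(v) {
    r <- range(v, finite = TRUE)
    if (diff(r) == 0) return(rep(0.5, length(v)))
    (v - r[1]) / diff(r)
  }
  res <- inner_join(aggregates,
                    select(enrichments, "rbp", "fdr", "odds_ratio"),
                    by = "rbp") |>
    mutate(neg_log10_fdr = -log10(pmax(.data$fdr, 1e-300)),
           score = minmax(.data$contribution) * minmax(.data$neg_log10_fdr)) |>
    arrange(dplyr::desc(.data$score), dplyr::desc(.data$contribution),
            .data$rbp) |>
    mutate(rank = row_number())
  structure(res, class = c("rbp_rank", class(res)))
}
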