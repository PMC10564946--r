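test_that("the additive contribution identity holds exactly for every forest", {
  set.seed(1)
  for (rep in 1:5) {
    n <- sample(20:60, 1); p <- sample(3:12, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- x %*% rnorm(p) + rnorm(n)
    f <- fit_contribution_forest(x, y, n_trees = 20, seed = rep)
    err <- max(abs(f$prediction - f$root_value - rowSums(f$contribution)))
    expect_lt(err, 1e-9)
    # identity also on new data
    xn <- matrix(rnorm(10 * p), 10, p, dimnames = list(NULL, f$predictors))
    pr <- predict(f, xn)
    expect_lt(max(abs(pr$prediction - pr$root_value -
                        rowSums(pr$contribution))), 1e-9)
  }
})

test_that("a single stump attributes exactly child-mean minus root-mean", {
  # forced split on the only informative predictor
  x <- cbind(a = c(rep(0, 10), rep(1, 10)), b = rnorm(20, sd = 1e-8))
  y <- c(rep(0, 10), rep(10, 10))
  f <- fit_contribution_forest(x, y, n_trees = 1, mtry = 2, max_depth = 1,
                               bootstrap = FALSE, min_node = 5, seed = 2)
  root_mean <- mean(y)
  expect_equal(f$root_value, root_mean)
  # left group: contribution of 'a' = 0 - 5; right: 10 - 5
  expect_equal(unname(f$contribution[1:10, "a"]), rep(0 - root_mean, 10))
  expect_equal(unname(f$contribution[11:20, "a"]), rep(10 - root_mean, 10))
  expect_equal(unname(f$contribution[, "b"]), rep(0, 20))
})

test_that("a constant response yields zero contributions and the constant root", {
  x <- matrix(rnorm(60), 20, 3)
  f <- fit_contribution_forest(x, rep(3.5, 20), n_trees = 10, seed = 3)
  expect_equal(f$root_value, 3.5)
  expect_true(all(f$contribution == 0))
  expect_true(all(f$prediction == 3.5))
})

test_that("forests are reproducible under a seed and track an informative predictor", {
  set.seed(4)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 3 * x[, 2] + rnorm(50, sd = 0.1)
  f1 <- fit_contribution_forest(x, y, n_trees = 30, seed = 11)
  f2 <- fit_contribution_forest(x, y, n_trees = 30, seed = 11)
  expect_equal(f1$contribution, f2$contribution)
  expect_equal(which.max(colMeans(abs(f1$contribution))), c(f2 = 2))
  # sanity: comparable out-of-the-box accuracy to an established forest
  skip_if_not_installed("randomForest")
  rf <- randomForest::randomForest(x, y, ntree = 100)
  expect_gt(stats::cor(f1$prediction, stats::predict(rf, x)), 0.95)
})

test_that("aggregation averages over the hyper set with stable tie order", {
  rec <- tibble::tibble(
    peak_id = rep(c("p1", "p2"), each = 3),
    predictor = rep(c("r1", "r2", "clin_age"), 2),
    contribution = c(1, 2, 5, 3, 4, 5),
    contribution_abs = c(1, 2, 5, 3, 4, 5)
  )
  one <- aggregate_contributions(rec, "p1", exclude = "clin_age")
  expect_equal(one$contribution[one$rbp == "r1"], 1)
  both <- aggregate_contributions(rec, c("p1", "p2"), exclude = "clin_age")
  expect_equal(both$contribution[both$rbp == "r2"], 3)
  expect_error(aggregate_contributions(rec, character()), "empty")
  expect_error(aggregate_contributions(rec, "nope"), "not scored")

  # equal contributions -> name-stable order
  tied <- dplyr::mutate(rec, contribution_abs = 1)
  expect_equal(aggregate_contributions(tied, c("p1", "p2"),
                                       exclude = "clin_age")$rbp,
               c("r1", "r2"))
})

test_that("spearman screen equals rank-Pearson and is monotone-invariant", {
  set.seed(5)
  n <- 30
  expr <- tibble::tibble(sample_id = paste0("s", 1:n), rbpA = rnorm(n))
  m <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("pk1", "pk2"), paste0("s", 1:n)))
  m["pk1", ] <- expr$rbpA + rnorm(n, sd = 0.3)  # correlated peak
  strata <- tibble::tibble(peak_id = c("pk1", "pk2"),
                           stratum = c("hyper", "unchanged"))
  scr <- spearman_screen(expr, m, strata)

  # oracle: rank-transform + Pearson, and cor.test's rho
  rho_oracle <- stats::cor(rank(expr$rbpA), rank(m["pk1", ]))
  expect_equal(scr$rho[scr$peak_id == "pk1"], rho_oracle, tolerance = 1e-12)
  ct <- suppressWarnings(stats::cor.test(expr$rbpA, m["pk1", ],
                                         method = "spearman"))
  expect_equal(scr$rho[scr$peak_id == "pk1"], unname(ct$estimate),
               tolerance = 1e-12)

  # strictly monotone transforms leave rho and significance unchanged
  expr2 <- dplyr::mutate(expr, rbpA = exp(rbpA))
  m2 <- m; m2["pk1", ] <- m2["pk1", ]^3
  scr2 <- spearman_screen(expr2, m2, strata)
  expect_equal(scr$rho, scr2$rho, tolerance = 1e-12)
  expect_equal(scr$significant, scr2$significant)

  # y = x gives rho 1, significant
  m3 <- m; m3["pk1", ] <- expr$rbpA
  scr3 <- spearman_screen(expr, m3, strata)
  expect_equal(scr3$rho[scr3$peak_id == "pk1"], 1)
  expect_true(scr3$significant[scr3$peak_id == "pk1"])
})

test_that("enrichment Fisher matches the hypergeometric closed form", {
  # [[8,2],[2,8]]: 8/10 significant among hyper, 2/10 among background
  screen <- tibble::tibble(
    rbp = "r1",
    peak_id = paste0("p", 1:20),
    stratum = rep(c("hyper", "unchanged"), each = 10),
    rho = 0.5, p_value = 0.01,
    significant = c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8))
  )
  got <- enrichment_fisher(screen)
  p_oracle <- sum(dhyper(8:10, 10, 10, 10))
  expect_equal(got$p_value, p_oracle, tolerance = 1e-12)
  expect_gt(got$odds_ratio, 1)

  # extreme table: all hyper significant, no background significant
  screen2 <- dplyr::mutate(screen,
                           significant = stratum == "hyper")
  got2 <- enrichment_fisher(screen2)
  expect_equal(got2$odds_ratio, Inf)
  expect_equal(got2$p_value, 1 / choose(20, 10), tolerance = 1e-12)
})

test_that("odds ratio exceeds 1 exactly when the hyper rate exceeds background", {
  set.seed(6)
  for (rep in 1:10) {
    nh <- 30; nb <- 50
    sh <- rbinom(1, nh, runif(1, 0.1, 0.9))
    sb <- rbinom(1, nb, runif(1, 0.1, 0.9))
    screen <- tibble::tibble(
      rbp = "r", peak_id = paste0("p", 1:(nh + nb)),
      stratum = rep(c("hyper", "unchanged"), c(nh, nb)),
      rho = 0, p_value = 1,
      significant = c(seq_len(nh) <= sh, seq_len(nb) <= sb)
    )
    got <- enrichment_fisher(screen)
    if (sh / nh > sb / nb) expect_gt(got$odds_ratio, 1)
    if (sh / nh < sb / nb) expect_lt(got$odds_ratio, 1)
  }
})

test_that("combined ranking puts a double-dominant RBP first, ties name-stable", {
  agg <- tibble::tibble(rbp = c("a", "b", "c"), contribution = c(5, 1, 1))
  enr <- tibble::tibble(rbp = c("a", "b", "c"), fdr = c(1e-8, 0.5, 0.5),
                        odds_ratio = c(10, 1, 1))
  rk <- rank_rbps(agg, enr)
  expect_equal(rk$rbp[rk$rank == 1], "a")
  # symmetric pair ties -> name order
  agg2 <- tibble::tibble(rbp = c("x", "y"), contribution = c(2, 2))
  enr2 <- tibble::tibble(rbp = c("x", "y"), fdr = c(0.1, 0.1),
                         odds_ratio = c(2, 2))
  rk2 <- rank_rbps(agg2, enr2)
  expect_equal(rk2$rbp, c("x", "y"))
})

test_that("a planted driver RBP is recovered end to end", {
  co <- simulate_cohort(n_peaks = 300, n_hyper = 30, n_hypo = 15, n_rbps = 12,
                        driver_effect = 0.6, seed = 55)
  m <- log2(m6ascape:::level_matrix(co$levels))
  tum <- co$samples$sample_id[co$samples$tissue == "tumor"]
  rec <- contribution_sweep(co$rbp_expr, m[, tum],
                            peaks = co$truth$hyper_peaks, n_trees = 60,
                            seed = 56)
  agg <- aggregate_contributions(rec, co$truth$hyper_peaks)
  strata <- tibble::tibble(
    peak_id = rownames(m),
    stratum = dplyr::case_when(
      rownames(m) %in% co$truth$hyper_peaks ~ "hyper",
      rownames(m) %in% co$truth$hypo_peaks ~ "hypo",
      TRUE ~ "unchanged"
    )
  )
  scr <- spearman_screen(co$rbp_expr[co$rbp_expr$sample_id %in% tum, ],
                         m[, tum], strata)
  rk <- rank_rbps(agg, enrichment_fisher(scr))
  expect_equal(rk$rbp[rk$rank == 1], co$truth$driver)
})
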