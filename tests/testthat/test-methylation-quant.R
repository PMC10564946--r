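test_that("relative m6A level follows the IP/input RPKM ratio and its invariances", {
  counts <- tibble::tibble(peak_id = "p1", sample_id = "s1",
                           ip_count = 100L, input_count = 50L,
                           peak_length = 250L)
  libs <- tibble::tibble(sample_id = "s1", ip_lib = 1e6, input_lib = 1e6)
  expect_equal(relative_m6a_level(counts, libs)$m6a_level, 2)

  # ip = input -> 1
  counts$ip_count <- 50L
  expect_equal(relative_m6a_level(counts, libs)$m6a_level, 1)

  # scale invariance: doubling both counts and both library sizes
  counts$ip_count <- 100L
  v1 <- relative_m6a_level(counts, libs)$m6a_level
  counts2 <- dplyr::mutate(counts, ip_count = ip_count * 2L,
                           input_count = input_count * 2L)
  libs2 <- dplyr::mutate(libs, ip_lib = ip_lib * 2, input_lib = input_lib * 2)
  expect_equal(relative_m6a_level(counts2, libs2)$m6a_level, v1)

  # independent library scaling cancels per the RPKM ratio
  libs3 <- dplyr::mutate(libs, ip_lib = ip_lib * 3)
  expect_equal(relative_m6a_level(counts, libs3)$m6a_level, v1 / 3)

  # input count 0 -> missing
  counts$input_count <- 0L
  expect_true(is.na(relative_m6a_level(counts, libs)$m6a_level))
  expect_error(relative_m6a_level(counts, dplyr::mutate(libs, ip_lib = 0)),
               "library")
})

test_that("paired test matches the exact signed-rank enumeration oracle", {
  d <- c(1, 2, 3, 4, 5, 6, 7, -1)
  m <- rbind(p1 = c(10 + d, 10 + numeric(8)))
  colnames(m) <- c(paste0("T", 1:8), paste0("N", 1:8))
  lv <- levels_from_matrix(m)
  pairs <- tibble::tibble(pair_id = paste0("pr", 1:8),
                          tumor = paste0("T", 1:8), normal = paste0("N", 1:8))
  got <- differential_paired(lv, pairs)
  expect_equal(got$p_value, enum_signed_rank_p(d), tolerance = 1e-12)
  expect_equal(got$median_diff, median(d))
})

test_that("identical tumor and normal columns give no calls; low pairs are flagged", {
  set.seed(7)
  m <- matrix(rlnorm(50 * 12), 50, 12,
              dimnames = list(paste0("p", 1:50),
                              c(paste0("T", 1:6), paste0("N", 1:6))))
  m[, 7:12] <- m[, 1:6]
  pairs <- tibble::tibble(pair_id = paste0("pr", 1:6),
                          tumor = paste0("T", 1:6), normal = paste0("N", 1:6))
  got <- differential_paired(levels_from_matrix(m), pairs)
  expect_true(all(got$direction == "ns"))
  expect_true(all(got$p_value == 1))

  # knock out pairs for one peak -> ns with low_pairs reason
  m2 <- m; m2[1, 1:2] <- NA
  got2 <- differential_paired(levels_from_matrix(m2), pairs, min_pairs = 5)
  expect_equal(got2$reason[1], "low_pairs")
  expect_equal(got2$direction[1], "ns")
})

test_that("planted paired effects are recovered at FDR 0.1", {
  co <- simulate_cohort(n_pairs = 33, n_extra_tumor = 0, n_peaks = 400,
                        n_hyper = 40, n_hypo = 20, subtype_effect = 1,
                        driver_effect = 0, seed = 101)
  got <- differential_paired(co$levels, co$pairs)
  called_hyper <- got$peak_id[got$direction == "hyper"]
  called_hypo <- got$peak_id[got$direction == "hypo"]
  expect_gte(mean(co$truth$hyper_peaks %in% called_hyper), 0.9)
  expect_gte(mean(co$truth$hypo_peaks %in% called_hypo), 0.9)
  # false calls controlled
  false_pos <- setdiff(c(called_hyper, called_hypo),
                       c(co$truth$hyper_peaks, co$truth$hypo_peaks))
  expect_lte(length(false_pos), 0.15 * length(c(called_hyper, called_hypo)))
})

test_that("BH significant sets are nested across FDR levels", {
  co <- simulate_cohort(n_pairs = 20, n_extra_tumor = 0, n_peaks = 300,
                        n_hyper = 30, n_hypo = 0, subtype_effect = 1,
                        driver_effect = 0, seed = 11)
  d05 <- differential_paired(co$levels, co$pairs, fdr_cut = 0.05)
  d10 <- differential_paired(co$levels, co$pairs, fdr_cut = 0.1)
  sig05 <- d05$peak_id[d05$direction != "ns"]
  sig10 <- d10$peak_id[d10$direction != "ns"]
  expect_true(all(sig05 %in% sig10))
})

test_that("vectorized signed-rank p matches wilcox.test's normal approximation", {
  set.seed(13)
  D <- matrix(rnorm(30 * 15), 30, 15)
  got <- m6ascape:::signed_rank_p_matrix(D)$p
  ref <- apply(D, 1, function(d) {
    wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
  })
  expect_equal(got, unname(ref), tolerance = 1e-10)
})

test_that("permutation null is reproducible and tracks the observed null count", {
  co <- simulate_cohort(n_pairs = 20, n_extra_tumor = 0, n_peaks = 200,
                        n_hyper = 0, n_hypo = 0, subtype_effect = 1,
                        driver_effect = 0, seed = 21)
  a <- permutation_null(co$levels, co$pairs, n_perm = 5, seed = 3)
  b <- permutation_null(co$levels, co$pairs, n_perm = 5, seed = 3)
  expect_identical(a$permutations, b$permutations)
  expect_error(permutation_null(co$levels, co$pairs, n_perm = 0), "n_perm")

  # strong planted signal: observed count far above the permutation mean
  co2 <- simulate_cohort(n_pairs = 33, n_extra_tumor = 0, n_peaks = 300,
                         n_hyper = 60, n_hypo = 0, subtype_effect = 1,
                         driver_effect = 0, seed = 22)
  pn <- permutation_null(co2$levels, co2$pairs, n_perm = 50, seed = 4)
  expect_gte(pn$observed$n_fdr, 5 * max(pn$mean_fdr_count, 1))
})

test_that("two-condition fold-change calls respect the 1.2 cutoff and antisymmetry", {
  mk <- function(vals) levels_from_matrix(
    matrix(vals, nrow = 3, ncol = 2,
           dimnames = list(paste0("p", 1:3), c("r1", "r2"))))
  a <- mk(c(1.0, 1.0, 1.25, 1.0, 1.0, 1.25))
  b <- mk(c(1.3, 1.0, 1.0, 1.3, 1.0, 1.0))
  got <- two_condition_fc(a, b)
  expect_equal(got$direction, c("hyper", "ns", "hypo"))
  # swapping conditions maps hyper <-> hypo exactly
  rev <- two_condition_fc(b, a)
  expect_equal(rev$direction, c("hypo", "ns", "hyper"))
})

test_that("set overlaps report exact counts and the printed-style fractions", {
  expect_equal(overlap_sets(letters[1:5], letters[1:5])$frac_x, 1)
  expect_equal(overlap_sets(letters[1:3], letters[10:12])$n_common, 0)
  x <- paste0("m", 1:188)
  y <- c(paste0("m", 1:122), paste0("z", 1:50))
  got <- overlap_sets(x, y)
  expect_equal(got$n_common, 122)
  expect_equal(round(100 * got$frac_x, 1), 64.9)
  expect_lte(got$n_common, min(got$n_x, got$n_y))
})

test_that("m6A/RNA integration crosses the two direction calls", {
  dm <- tibble::tibble(peak_id = paste0("p", 1:5),
                       gene_id = paste0("g", 1:5),
                       direction = c("hyper", "hypo", "hyper", "hyper", "ns"))
  de <- tibble::tibble(gene_id = paste0("g", 1:4),
                       direction = c("up", "down", "ns", "down"))
  got <- integrate_rna_m6a(dm, de)
  expect_equal(got$category,
               c("hyper-up", "hypo-down", "non-significant", "hyper-down",
                 "non-significant"))
  # empty RNA table -> everything non-significant
  got2 <- integrate_rna_m6a(dm, de[0, ])
  expect_true(all(got2$category == "non-significant"))
})
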