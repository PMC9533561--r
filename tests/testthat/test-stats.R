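# Signed-rank and rank-sum tests against enumeration oracles, plus the
# comparison battery's bookkeeping.

test_that("signed-rank handles identity, all-positive, and tiny-n cases", {
  a <- c(3.2, 1.1, 4.8, 2.0, 7.5)
  r <- signed_rank_test(a, a)
  expect_equal(r$p_two_sided, 1)
  expect_equal(r$n_effective, 0)

  r <- signed_rank_test(a, a - c(1, 2, 3, 4, 5))  # five distinct positive diffs
  expect_equal(unname(r$statistic), 15)
  expect_equal(r$p_two_sided, 2 / 2^5)
  expect_equal(r$method, "exact")

  # with three pairs the exact two-sided p can never reach 0.05
  set.seed(12)
  for (i in 1:20) {
    r <- signed_rank_test(rnorm(3), rnorm(3))
    expect_gte(r$p_two_sided, 0.25)
  }
})

test_that("rank-sum reproduces the exact small-sample distribution", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_two_sided, 2 / 20)
  expect_equal(r$method, "exact")

  v <- c(2, 9, 4.5, 7)
  expect_equal(rank_sum_test(v, sample(v))$p_two_sided, 1)

  set.seed(14)
  a <- rnorm(6); b <- rnorm(8)
  expect_equal(rank_sum_test(a, b)$p_two_sided, rank_sum_test(b, a)$p_two_sided)
})

test_that("exact p-values equal full enumeration on random untied instances", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(signed_rank_test(a, b)$p_two_sided, enum_signed_rank_p(a, b),
                 tolerance = 1e-12)
    m <- sample(3:6, 1); k <- sample(3:6, 1)
    x <- rnorm(m); y <- rnorm(k)
    expect_equal(rank_sum_test(x, y)$p_two_sided, enum_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("normal approximation stays close to the exact path at n = 20", {
  set.seed(18)
  for (i in 1:25) {
    a <- rnorm(20); b <- rnorm(20, 0.3)
    p_exact <- signed_rank_test(a, b)$p_two_sided
    p_approx <- suppressWarnings(
      wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("zero differences and missing pairs are dropped", {
  a <- c(1, 2, 3, 4, 5, NA)
  b <- c(1, 2, 5, 1, 2, 9)
  r <- signed_rank_test(a, b)
  expect_equal(r$n_effective, 3)  # two zero diffs and one NA pair dropped
  expect_error(signed_rank_test(1:3, 1:4), "equal length")
  expect_true(is.na(rank_sum_test(numeric(0), 1:5)$p_two_sided))
})

test_that("tied samples fall back to the corrected normal approximation", {
  a <- c(1, 2, 2, 3, 5, 6, 6, 8)
  b <- c(2, 2, 4, 4, 5, 5, 7, 7)
  r <- signed_rank_test(a, b)
  expect_equal(r$method, "normal_approx")
  r2 <- rank_sum_test(a, b)
  expect_equal(r2$method, "normal_approx")
  expect_true(r2$p_two_sided >= 0 && r2$p_two_sided <= 1)
})

# hand-made cohort density table: one marker, chosen per-region values
toy_densities <- function(tc_p, tf_p, tc_m = tc_p, tf_m = tf_p,
                          pt_p = tf_p / 2, pt_m = tf_m / 2, marker = "CD8") {
  n <- length(tc_p)
  ids <- sprintf("P%02d", seq_len(n))
  mk <- function(lt, rg, v)
    data.frame(patient_id = ids, lesion_type = lt, region = rg,
               phenotype = marker, count = 1, area_mm2 = 1, density = v,
               stringsAsFactors = FALSE)
  rbind(mk("primary", "TC", tc_p), mk("primary", "TF", tf_p),
        mk("primary", "PT", pt_p), mk("primary", "ALL", (tc_p + tf_p) / 2),
        mk("metastasis", "TC", tc_m), mk("metastasis", "TF", tf_m),
        mk("metastasis", "PT", pt_m), mk("metastasis", "ALL", (tc_m + tf_m) / 2))
}

test_that("the battery covers all four families with correct pairing", {
  set.seed(21)
  n <- 17
  dens <- toy_densities(tc_p = rlnorm(n, 3), tf_p = rlnorm(n, 4),
                        tc_m = rlnorm(n, 3), tf_m = rlnorm(n, 4))
  clin <- data.frame(patient_id = sprintf("P%02d", 1:n),
                     n_liver_metastases = rep(c(1L, 2L), length.out = n),
                     max_metastasis_diameter_cm = seq(1, 6, length.out = n),
                     stringsAsFactors = FALSE)
  bat <- run_comparison_battery(dens, clin)
  expect_setequal(unique(bat$family),
                  c("general", "region_contrast", "cross_lesion", "subgroup"))
  expect_equal(nrow(bat), 1 + 4 + 3 + 4)  # one marker
  expect_true(all(bat$test[bat$family == "subgroup"] == "rank_sum"))
  expect_true(all(bat$test[bat$family != "subgroup"] == "signed_rank"))
  expect_true(all(bat$n[bat$family == "general"] == 17))

  fdr <- run_comparison_battery(dens, clin, fdr = TRUE)
  expect_true("p_adj" %in% names(fdr))
  expect_true(all(fdr$p_adj >= fdr$p, na.rm = TRUE))
})

test_that("constant densities give p = 1 everywhere", {
  dens <- toy_densities(tc_p = rep(2, 8), tf_p = rep(2, 8),
                        pt_p = rep(2, 8), pt_m = rep(2, 8))
  bat <- run_comparison_battery(dens)
  expect_true(all(bat$p == 1))
  expect_false(any(bat$significant))
})

test_that("a patient without a PT region is dropped pairwise", {
  set.seed(22)
  dens <- toy_densities(tc_p = rlnorm(17), tf_p = rlnorm(17),
                        tc_m = rlnorm(17), tf_m = rlnorm(17),
                        pt_p = rlnorm(17), pt_m = rlnorm(17))
  dens$density[dens$patient_id == "P01" & dens$region == "PT"] <- NA
  bat <- run_comparison_battery(dens)
  pt_row <- bat[bat$family == "cross_lesion" & bat$stratum == "PT primary_vs_metastasis", ]
  expect_equal(pt_row$n, 16)
  all_row <- bat[bat$family == "general", ]
  expect_equal(all_row$n, 17)
})

test_that("an empty subgroup yields a missing, non-significant row", {
  set.seed(25)
  dens <- toy_densities(tc_p = rlnorm(6), tf_p = rlnorm(6))
  clin <- data.frame(patient_id = sprintf("P%02d", 1:6),
                     n_liver_metastases = rep(1L, 6),
                     max_metastasis_diameter_cm = rep(4, 6),
                     stringsAsFactors = FALSE)
  bat <- run_comparison_battery(dens, clin)
  sub <- bat[bat$family == "subgroup" & bat$stratum == "n_metastases_1_vs_gt1", ]
  expect_true(all(is.na(sub$p)))
  expect_false(any(sub$significant))
})
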