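test_that("Friedman: hand-computed and degenerate cases", {
  # perfectly consistent ordering across 3 subjects: chi2 = 6
  m <- matrix(c(1, 2, 3,
                2, 4, 6,
                1, 3, 5), 3, 3, byrow = TRUE)
  f <- friedman_test(m)
  expect_equal(f$chi2, 6)
  expect_identical(f$df, 2L)

  # opposite orderings cancel
  m2 <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(friedman_test(m2)$chi2, 0)
  expect_equal(friedman_test(m2)$p_value, 1)

  # constant matrix: statistic 0, p = 1
  m3 <- matrix(5, 4, 3)
  expect_equal(friedman_test(m3)$chi2, 0)
  expect_equal(friedman_test(m3)$p_value, 1)

  expect_error(friedman_test(matrix(1:3, 1)), "at least 2")
  expect_error(friedman_test(matrix(c(1, NA, 3, 4), 2)), "missing")
})

test_that("Friedman is invariant to monotone transforms and subject order", {
  set.seed(1)
  for (i in 1:20) {
    m <- random_rm_matrix(sample(3:8, 1), sample(2:4, 1))
    f <- friedman_test(m)
    expect_equal(friedman_test(exp(m / 500))$chi2, f$chi2)
    expect_equal(friedman_test(m[sample(nrow(m)), ])$chi2, f$chi2)
  }
})

test_that("Durbin-Conover: identical columns, antisymmetry, monotone shift", {
  m <- cbind(a = c(1, 4, 2, 6, 3, 5), b = c(1, 4, 2, 6, 3, 5),
             c = c(2, 5, 1, 7, 4, 6))
  dc <- durbin_conover(m)
  row_ab <- dc[dc$i == 1 & dc$j == 2, ]
  expect_equal(row_ab$statistic, 0)
  expect_equal(row_ab$p_raw, 1)

  # swapping conditions flips the sign
  m_sw <- m[, c(2, 1, 3)]
  dc_sw <- durbin_conover(m_sw)
  expect_equal(dc_sw$statistic[dc_sw$i == 1 & dc_sw$j == 3],
               dc$statistic[dc$i == 2 & dc$j == 3])

  # one column far above the rest separates significantly
  set.seed(2)
  base <- matrix(rnorm(20 * 2), 20, 2)
  shifted <- cbind(base, base[, 1] + 50)
  dc2 <- durbin_conover(shifted)
  expect_lt(dc2$p_raw[dc2$i == 1 & dc2$j == 3], 0.05)
  expect_lt(dc2$p_raw[dc2$i == 2 & dc2$j == 3], 0.05)
})

test_that("Bonferroni threshold matches the family alpha division", {
  expect_equal(bonferroni_threshold(0.05, 3), 0.0167)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("Spearman handles perfect, tied and degenerate inputs", {
  expect_equal(spearman(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman(1:6, -(1:6))$rho, -1)

  s <- spearman(c(1, 2, 2, 4), c(3, 1, 1, 2))
  o <- oracle_spearman(c(1, 2, 2, 4), c(3, 1, 1, 2))
  expect_equal(s$rho, o$rho, tolerance = 1e-12)
  expect_equal(s$p_value, o$p_value, tolerance = 1e-9)

  dz <- spearman(rep(1, 5), 1:5)
  expect_true(dz$undefined)
  expect_true(is.na(dz$rho))
})

test_that("Cronbach's alpha: worked examples and degenerate flagging", {
  # shifted columns are perfectly consistent
  expect_equal(cronbach_alpha(cbind(1:3, 2:4))$alpha, 1)
  expect_equal(cronbach_alpha(cbind(c(1, 2, 3), c(1, 2, 3)))$alpha, 1)
  # anti-correlated columns: zero total-score variance, flagged
  deg <- cronbach_alpha(cbind(c(1, 2, 3), c(3, 2, 1)))
  expect_true(deg$undefined)
  expect_true(is.na(deg$alpha))
  # identical subject profiles: no between-subject variance, flagged
  ideg <- icc_3k(matrix(c(1, 1, 2, 2, 3, 3), 2, byrow = FALSE))
  expect_true(ideg$undefined)
})

test_that("alpha equals ICC(3,k) on random matrices", {
  set.seed(3)
  for (i in 1:50) {
    m <- random_rm_matrix(sample(4:10, 1), sample(2:5, 1),
                          gridded = (i %% 2 == 0))
    a <- cronbach_alpha(m)
    icc <- icc_3k(m)
    if (a$undefined || icc$undefined) next
    expect_equal(a$alpha, icc$icc, tolerance = 1e-9)
  }
})

test_that("change histograms count per-subject grid differences", {
  m <- cbind(c(900, 800, 700, 600), c(800, 700, 700, 700))
  h <- change_histogram(m, 1, 2)
  expect_identical(h$count[h$change_ms == 100], 2L)
  expect_identical(h$count[h$change_ms == 0], 1L)
  expect_identical(h$count[h$change_ms == -100], 1L)
  expect_equal(sum(h$percent), 100)
  expect_equal(attr(h, "mean_change"), 25)

  same <- change_histogram(cbind(1:4 * 100, 1:4 * 100), 1, 2)
  expect_identical(nrow(same), 1L)
  expect_identical(same$change_ms, 0)
})

test_that("repeated-measures ANOVA matches its mean-squares oracle", {
  m0 <- matrix(7, 5, 3)
  expect_equal(rm_anova_oneway(m0)$F, 0)

  set.seed(4)
  m <- random_rm_matrix(51, 3)
  a <- rm_anova_oneway(m)
  expect_identical(a$df1, 2L)
  expect_identical(a$df2, 100L)
  o <- oracle_rm_anova(m)
  expect_equal(a$F, o$F, tolerance = 1e-9)
  expect_equal(a$p_value, o$p_value, tolerance = 1e-9)
})

test_that("every statistic matches its independent oracle on random matrices", {
  set.seed(10)
  for (i in 1:40) {
    n <- sample(3:8, 1); k <- sample(2:4, 1)
    m <- random_rm_matrix(n, k, gridded = (i %% 2 == 0))

    f <- friedman_test(m)
    of <- oracle_friedman(m)
    if (is.finite(of$chi2)) {
      expect_equal(f$chi2, of$chi2, tolerance = 1e-6)
      expect_equal(f$p_value, of$p_value, tolerance = 1e-6)
    }

    dc <- durbin_conover(m)
    odc <- oracle_durbin_conover(m)
    expect_equal(dc$statistic, odc$statistic, tolerance = 1e-6)
    expect_equal(dc$p_raw, odc$p_raw, tolerance = 1e-6)

    s <- spearman(m[, 1], m[, 2])
    if (!s$undefined) {
      os <- oracle_spearman(m[, 1], m[, 2])
      expect_equal(s$rho, os$rho, tolerance = 1e-6)
      expect_equal(s$p_value, os$p_value, tolerance = 1e-6)
    }

    a <- cronbach_alpha(m)
    if (!a$undefined) {
      expect_equal(a$alpha, oracle_icc3k(m), tolerance = 1e-6)
    }

    ra <- rm_anova_oneway(m)
    ora <- oracle_rm_anova(m)
    if (is.finite(ra$F)) expect_equal(ra$F, ora$F, tolerance = 1e-6)
  }
})

test_that("analyze_cohort assembles the full battery coherently", {
  coh <- simulate_cohort(cohort_design(n_participants = 12), seed = 6)
  rep <- analyze_cohort(coh)
  expect_s3_class(rep, "reliability_report")
  expect_identical(rep$n, 12L)
  expect_identical(nrow(rep$pairwise), 3L)
  expect_equal(rep$bonferroni_threshold, 0.0167)
  expect_equal(rep$cronbach_alpha$alpha, rep$icc3k$icc, tolerance = 1e-9)
  expect_true(all(vapply(rep$covariate_friedman, function(f)
    f$p_value >= 0 && f$p_value <= 1, TRUE)))
  expect_identical(nrow(rep$covariate_correlations), 15L)
  expect_identical(rep$rm_anova_time_of_day$df1, 2L)
  expect_identical(rep$rm_anova_time_of_day$df2, 22L)
  expect_false(is.null(rep$blocks_vs_change$s1_blocks_vs_change12))

  # incomplete participants are dropped listwise
  coh_cut <- coh[-1, ]
  expect_message(rep2 <- analyze_cohort(coh_cut), "dropped")
  expect_identical(rep2$n, 11L)
})

test_that("a degenerate no-learning deterministic cohort hits the flagged branches", {
  des <- cohort_design(n_participants = 6, deterministic = TRUE,
                       delta12 = c(`0` = 1), delta23 = c(`0` = 1))
  coh <- simulate_cohort(des, seed = 2)
  rep <- analyze_cohort(coh)
  expect_equal(rep$friedman$chi2, 0)
  expect_true(all(rep$spearman_sessions$rho[upper.tri(diag(3))] == 1))
  expect_equal(rep$cronbach_alpha$alpha, 1)
  expect_identical(rep$change_12$change_ms, 0)
})
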