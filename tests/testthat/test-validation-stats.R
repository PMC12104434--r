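test_that("Bland-Altman matches hand computations", {
  ba <- bland_altman(c(10, 11, 12), c(10, 12, 11))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, 1)
  expect_equal(ba$loa_lower, -1.96)
  expect_equal(ba$loa_upper, 1.96)
  expect_equal(ba$pct_within_loa, 100)
  expect_false(ba$zero_variance)

  a <- c(10, 11, 12, 13)
  same <- bland_altman(a, a)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$sd_difference, 0)
  expect_equal(same$pct_within_loa, 100)
  expect_true(same$zero_variance)

  off <- bland_altman(a, a + 0.5)
  expect_equal(off$mean_difference, -0.5)
  expect_equal(off$sd_difference, 0)
  expect_true(off$zero_variance)

  expect_error(bland_altman(1:3, 1:4), "equal length")
  expect_error(bland_altman(1:2, 1:2), "3 pairs")
})

test_that("limits of agreement capture about 95% of normal differences", {
  set.seed(21)
  cover <- replicate(60, {
    d <- rnorm(400)
    bland_altman(d, rep(0, 400))$pct_within_loa
  })
  expect_equal(mean(cover), 95, tolerance = 2 / 95)  # +/- 2 percentage points
})

test_that("ICC(2,1) matches the ANOVA oracle and penalizes offsets", {
  a <- c(9.1, 10.4, 11.9, 13.2, 14.6)
  b <- c(9.4, 10.1, 12.3, 13.0, 14.9)
  expect_equal(icc_agreement(a, b), oracle_icc21(a, b), tolerance = 1e-10)
  expect_equal(icc_agreement(a, a), 1)
  expect_lt(icc_agreement(a, a + 5), 0.5)
  expect_error(icc_agreement(rep(1, 4), rep(1, 4)), "identical")
  set.seed(22)
  for (i in 1:10) {
    x <- rnorm(20, 12, 2); y <- x + rnorm(20, 0.2, 0.5)
    expect_equal(icc_agreement(x, y), oracle_icc21(x, y), tolerance = 1e-10)
  }
})

test_that("Cohen's kappa matches hand values and the oracle", {
  expect_equal(cohen_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B")), 0)
  expect_equal(cohen_kappa(c("A", "B", "C"), c("A", "B", "C")), 1)
  expect_error(cohen_kappa(rep("A", 5), rep("A", 5)), "undefined")
  set.seed(23)
  for (i in 1:10) {
    a <- sample(c("late", "on_time", "early"), 40, replace = TRUE)
    b <- sample(c("late", "on_time", "early"), 40, replace = TRUE)
    expect_equal(cohen_kappa(a, b), oracle_kappa(a, b), tolerance = 1e-12)
  }
})

test_that("kappa of independently random labels averages near zero", {
  set.seed(24)
  ks <- replicate(300, {
    a <- sample(c("L", "O", "E"), 60, replace = TRUE, prob = c(0.2, 0.6, 0.2))
    b <- sample(c("L", "O", "E"), 60, replace = TRUE, prob = c(0.2, 0.6, 0.2))
    cohen_kappa(a, b)
  })
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("association coefficients behave and tau-b matches pair counting", {
  x <- 1:10
  expect_equal(association(x, 2 * x + 3, "pearson"), 1)
  expect_equal(association(x, exp(x), "spearman"), 1)
  expect_lt(association(x, exp(x), "pearson"), 1)
  expect_error(association(rep(1, 5), 1:5), "zero variance")
  expect_equal(association(c(1, 2, 2, 3), c(1, 2, 3, 3), "tau_b"),
               oracle_tau_b(c(1, 2, 2, 3), c(1, 2, 3, 3)), tolerance = 1e-12)
  set.seed(25)
  for (i in 1:10) {
    a <- sample(1:5, 25, replace = TRUE)
    b <- sample(1:5, 25, replace = TRUE)
    expect_equal(association(a, b, "tau_b"), oracle_tau_b(a, b), tolerance = 1e-10)
  }
})

test_that("percent agreement counts matching positions", {
  expect_equal(percent_agreement(c("A", "A", "B", "B"), c("A", "B", "A", "B")), 50)
  expect_equal(percent_agreement(letters[1:4], letters[1:4]), 100)
  expect_equal(percent_agreement(c("A", "A"), c("B", "B")), 0)
  expect_error(percent_agreement(character(0), character(0)), "empty")
})

test_that("AUC equals the exhaustive pairwise oracle", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))$auc, 0.5)
  r <- roc_auc(c(1, 2, 3, 2, 3, 4), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
               direction = "greater_is_positive")
  expect_equal(r$auc, 7 / 9)  # 6 wins + 2 half-ties over 9 pairs
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "positive and one negative")
  set.seed(26)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    sc <- sample(seq(70, 100, by = 0.5), n, replace = TRUE)
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(roc_auc(sc, pos, direction = "greater_is_positive")$auc,
                 oracle_auc(sc, pos), tolerance = 1e-12)
  }
})

test_that("auto direction orients the AUC above one half and records it", {
  sc <- c(80, 81, 82, 90, 91, 92)
  pos <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)   # positives score LOW
  r <- roc_auc(sc, pos)
  expect_equal(r$direction, "less_is_positive")
  expect_equal(r$auc, 1)
})

test_that("DeLong interval agrees with the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(27)
  for (i in 1:5) {
    sc <- c(rnorm(30, 85, 3), rnorm(20, 90, 3))
    pos <- rep(c(FALSE, TRUE), c(30, 20))
    r <- roc_auc(sc, pos, direction = "greater_is_positive")
    ref <- suppressMessages(pROC::ci.auc(pROC::roc(pos, sc, direction = "<",
                                                   quiet = TRUE), method = "delong"))
    expect_equal(r$auc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(r$auc_ci_low, max(0, as.numeric(ref[1])), tolerance = 1e-8)
    expect_equal(r$auc_ci_high, min(1, as.numeric(ref[3])), tolerance = 1e-8)
  }
})

test_that("the Youden cut-off equals exhaustive threshold search", {
  y <- youden_cutoff(c(80, 81, 85, 86, 90, 91),
                     c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                     direction = "less_is_positive")
  expect_equal(y$cutoff, 83.0)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)
  expect_equal(y$youden_j, 1)

  sep <- youden_cutoff(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE),
                       direction = "greater_is_positive")
  expect_equal(sep$cutoff, 5)
  expect_equal(sep$youden_j, 1)

  set.seed(28)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    sc <- sample(seq(70, 100, by = 0.5), n, replace = TRUE)
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    dir <- sample(c("greater_is_positive", "less_is_positive"), 1)
    got <- youden_cutoff(sc, pos, direction = dir)
    ref <- oracle_youden(sc, pos, dir)
    expect_equal(got$youden_j, ref$j, tolerance = 1e-12)
    expect_equal(got$sensitivity, ref$sens, tolerance = 1e-12)
    expect_equal(got$cutoff, ref$cutoff)
  }
})

test_that("cut-off derivation recovers known latent thresholds", {
  # Build a cohort whose maturity is driven by PAH with clean separation:
  # per age, late below t_lo, early above t_hi, wide score gaps at the
  # boundaries so the recovered midpoint threshold is pinned.
  set.seed(29)
  rows <- list()
  id <- 0
  for (a in 12:13) {
    t_lo <- 84 + (a - 12) * 2; t_hi <- 90 + (a - 12) * 2
    pah <- c(runif(12, t_lo - 4, t_lo - 1), runif(30, t_lo + 1, t_hi - 1),
             runif(12, t_hi + 1, t_hi + 4))
    status <- rep(c("late", "on_time", "early"), c(12, 30, 12))
    ca <- runif(54, a - 0.4, a + 0.4)
    sa <- ca + ifelse(status == "late", -1.5, ifelse(status == "early", 1.5, 0))
    id <- id + seq_along(pah)
    rows[[length(rows) + 1]] <- data.frame(
      athlete_id = sprintf("T%d_%02d", a, seq_along(pah)),
      decimal_age = ca, stature_cm = 150, body_mass_kg = 45,
      mother_stature_cm = NA, father_stature_cm = NA,
      observed_sa_years = sa, adult_height_tw3_cm = NA,
      pah_tw3 = pah, pah_kr = NA
    )
  }
  coh <- do.call(rbind, rows)
  class(coh) <- c("cohort_table", "data.frame")
  tab <- derive_cutoff_table(coh)
  for (i in seq_len(nrow(tab))) {
    a <- tab$age_group[i]
    t_lo <- 84 + (a - 12) * 2; t_hi <- 90 + (a - 12) * 2
    expect_lt(abs(tab$inferior_cutoff[i] - t_lo), 1)  # within the score gap
    expect_lt(abs(tab$superior_cutoff[i] - t_hi), 1)
    expect_lt(tab$inferior_cutoff[i], tab$superior_cutoff[i])
    expect_equal(tab$auc_late[i], 1)
    expect_equal(tab$sens_early[i], 1)
  }
})

test_that("an age group without early maturers leaves that side unset", {
  coh <- data.frame(
    athlete_id = sprintf("U%02d", 1:20), decimal_age = runif(20, 11.6, 12.4),
    stature_cm = 150, body_mass_kg = 45, mother_stature_cm = NA,
    father_stature_cm = NA,
    observed_sa_years = NA, adult_height_tw3_cm = NA,
    pah_tw3 = c(runif(6, 80, 83), runif(14, 85, 88)), pah_kr = NA
  )
  coh$observed_sa_years <- coh$decimal_age + rep(c(-1.5, 0), c(6, 14))
  class(coh) <- c("cohort_table", "data.frame")
  expect_warning(tab <- derive_cutoff_table(coh), "early maturers")
  expect_true(is.na(tab$superior_cutoff[tab$age_group == 12]))
  expect_false(is.na(tab$inferior_cutoff[tab$age_group == 12]))
})

test_that("repeated-measures comparison matches the aov oracle", {
  set.seed(30)
  m <- cbind(obs = rnorm(8, 13, 1))
  m <- cbind(m, tw3 = m[, 1] + rnorm(8, 0.2, 0.3), kr = m[, 1] + rnorm(8, -0.1, 0.4))
  got <- compare_methods_repeated(m)
  ref <- oracle_rm_anova(m)
  expect_equal(got$f_statistic, ref$f, tolerance = 1e-10)
  expect_equal(got$p_value, ref$p, tolerance = 1e-10)
  # pairwise paired t against stats::t.test with Bonferroni
  for (j in seq_len(nrow(got$pairs))) {
    pr <- got$pairs[j, ]
    tt <- stats::t.test(m[, pr$method_a], m[, pr$method_b], paired = TRUE)
    expect_equal(pr$t_statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(pr$p_adjusted, min(1, tt$p.value * 3), tolerance = 1e-10)
  }
})

test_that("repeated-measures handles identical and degenerate columns", {
  base <- rnorm(6, 12, 1)
  same <- cbind(a = base, b = base, c = base)
  got <- compare_methods_repeated(same)
  expect_true(all(got$pairs$mean_difference == 0))
  expect_true(all(got$pairs$p_adjusted == 1))

  shifted <- cbind(a = base, b = base + 0.7)
  got2 <- compare_methods_repeated(shifted)
  expect_true(got2$pairs$degenerate[1])
  expect_true(is.na(got2$pairs$p_adjusted[1]))
  expect_error(compare_methods_repeated(cbind(base[1:2], base[1:2])), "3 subjects")
})

test_that("agreement_report bundles numeric and categorical suites", {
  set.seed(31)
  ca <- runif(40, 11.6, 13.4)
  a <- ca + rnorm(40, 0, 0.8)
  b <- a + rnorm(40, 0.05, 0.3)
  rep <- agreement_report(a, b,
                          labels_a = classify_by_sa_difference(a, ca),
                          labels_b = classify_by_sa_difference(b, ca))
  expect_true(rep$pearson_r > 0.9)
  expect_true(rep$icc > 0.8)
  expect_true(rep$pct_agreement >= 0 && rep$pct_agreement <= 100)
  expect_true(abs(rep$kappa) <= 1 && abs(rep$tau_b) <= 1)
  expect_output(print(rep), "ICC")
})
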