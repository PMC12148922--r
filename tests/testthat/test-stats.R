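test_that("Kruskal-Wallis reproduces the hand-computed H", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p_value, stats::pchisq(7.2, 2, lower.tail = FALSE))

  same <- kruskal_wallis(list(rep(3, 4), rep(3, 4), rep(3, 4)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "length")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "at least one value")
})

test_that("H equals the tie-corrected oracle on random small samples", {
  set.seed(31)
  for (rep in 1:20) {
    samples <- lapply(1:3, function(i)
      sample(1:5, sample(2:4, 1), replace = TRUE))
    if (length(unique(unlist(samples))) == 1) next
    expect_equal(kruskal_wallis(samples)$statistic, oracle_kw_h(samples),
                 tolerance = 1e-10)
  }
})

test_that("asymptotic p approximates the exact permutation p at small n", {
  # approximation-quality check: chi-square/normal approximations against
  # exhaustive enumeration of group relabelings (total n <= 10)
  kw_cases <- list(
    list(c(1, 5, 3), c(4, 2, 6), c(8, 7, 9)),
    list(c(1.2, 3.4, 2.2), c(2.8, 4.1), c(0.5, 5.0, 3.9)))
  for (s in kw_cases) {
    expect_lt(abs(kruskal_wallis(s)$p_value - oracle_kw_perm_p(s)), 0.06)
  }
  w_cases <- list(list(c(1, 2, 3, 7), c(4, 5, 6, 8)),
                  list(c(2.5, 1.1, 6.3), c(4.2, 3.3, 5.1, 0.7)))
  for (s in w_cases) {
    got <- pairwise_wilcoxon(s)
    expect_lt(abs(got$p_value - oracle_wilcoxon_perm_p(s[[1]], s[[2]])),
              0.06)
  }
})

test_that("pairwise Wilcoxon reports rank sums, z and asymptotic p", {
  pw <- pairwise_wilcoxon(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(pw$w, 6)          # rank sum of the first group
  expect_equal(pw$group1, "a")

  # swapping group order negates z and keeps p
  pw_rev <- pairwise_wilcoxon(list(b = c(4, 5, 6), a = c(1, 2, 3)))
  expect_equal(pw_rev$z, -pw$z)
  expect_equal(pw_rev$p_value, pw$p_value)

  ident <- pairwise_wilcoxon(list(rep(2, 3), rep(2, 3)))
  expect_equal(ident$z, 0)
  expect_equal(ident$p_value, 1)

  # tie-corrected asymptotic p agrees with the standard implementation
  set.seed(8)
  x <- sample(1:6, 8, replace = TRUE); y <- sample(1:6, 9, replace = TRUE)
  ref <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))$p.value
  expect_equal(pairwise_wilcoxon(list(x, y))$p_value, ref,
               tolerance = 1e-10)

  # three groups -> three pairs; Holm never lowers a p-value
  s3 <- list(rnorm(5), rnorm(5) + 1, rnorm(5) + 2)
  p_none <- pairwise_wilcoxon(s3)$p_value
  p_holm <- pairwise_wilcoxon(s3, adjust = "holm")$p_value
  expect_equal(length(p_none), 3L)
  expect_true(all(p_holm >= p_none - 1e-12))
})

test_that("Spearman matches a brute-force rank oracle and bands correctly", {
  mono <- spearman_corr(1:10, (1:10)^3)
  expect_equal(mono$rho, 1)
  expect_equal(mono$band, "good_to_excellent")

  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    x <- sample(1:4, n, replace = TRUE)   # heavy ties
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_corr(x, y)$rho, oracle_spearman_rho(x, y),
                 tolerance = 1e-10)
  }

  # incomplete pairs are dropped
  r <- spearman_corr(c(1, 2, 3, 4, NA), c(2, 4, 6, NA, 10))
  expect_equal(r$n, 3L)

  flat <- spearman_corr(rep(1, 5), 1:5)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$rho))
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})

test_that("band assignment follows the documented boundaries", {
  expect_equal(rho_band(0.487), "fair")
  expect_equal(rho_band(0.24), "below_fair")
  expect_equal(rho_band(0.25), "fair")
  expect_equal(rho_band(0.50), "moderate_to_good")
  expect_equal(rho_band(0.75), "good_to_excellent")
  expect_equal(rho_band(-0.80), "good_to_excellent")
})

test_that("ICC is 1 with identical repetitions and matches pingouin", {
  m <- cbind(1:10, 1:10, 1:10)
  r <- icc_3_3(m)
  expect_equal(r$icc, 1)
  expect_equal(r$sem, 0)
  expect_match(r$model, "absolute agreement")

  # independent oracle: pingouin's average-measures absolute-agreement ICC
  set.seed(17)
  subj <- rnorm(12, 5, 1)
  dat <- sapply(1:3, function(j) subj + rnorm(12, 0, 0.4) + 0.1 * j)
  ours <- icc_3_3(dat)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(dat), csv, row.names = FALSE)
  script <- paste(
    "import pandas as pd, pingouin as pg, sys",
    "d = pd.read_csv(sys.argv[1])",
    "d['subj'] = range(len(d))",
    "m = d.melt(id_vars='subj', var_name='rater', value_name='y')",
    "icc = pg.intraclass_corr(m, targets='subj', raters='rater', ratings='y')",
    "row = icc[icc.Type.isin(['ICC2k', 'ICC(A,k)'])].iloc[0]",
    "ci = row[[c for c in icc.columns if c.startswith('CI95')][0]]",
    "print(row.ICC, ci[0], ci[1])",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(csv)),
                 stdout = TRUE, stderr = FALSE)
  vals <- as.numeric(strsplit(trimws(out[length(out)]), " +")[[1]])
  expect_equal(ours$icc, vals[1], tolerance = 1e-6)
  expect_equal(ours$ci95[1], vals[2], tolerance = 0.01)
  expect_equal(ours$ci95[2], vals[3], tolerance = 0.01)

  expect_error(icc_3_3(m[1, , drop = FALSE]), "at least 2")
})

test_that("ICC recovers known variance components", {
  # subject SD 1.0, error SD 0.5, k = 3: ICC(A,k) = 1 / (1 + 0.25/3)
  set.seed(23)
  n <- 200
  subj <- rnorm(n, 0, 1)
  dat <- sapply(1:3, function(j) subj + rnorm(n, 0, 0.5))
  true_icc <- 1 / (1 + 0.5^2 / 3)
  expect_lt(abs(icc_3_3(dat)$icc - true_icc), 0.05)

  # pure noise, no subject effect: the estimator centres on 0 (single draws
  # of the average-measures ICC scatter widely, so test the mean)
  null_iccs <- replicate(20, icc_3_3(matrix(rnorm(3 * n), n, 3))$icc)
  expect_lt(abs(mean(null_iccs)), 0.1)
})

test_that("the agreement CI covers the true value at its nominal rate", {
  set.seed(29)
  n <- 30; sd_s <- 1; sd_e <- 0.6
  true_icc <- sd_s^2 / (sd_s^2 + sd_e^2 / 3)
  cover <- 0
  for (i in 1:500) {
    subj <- rnorm(n, 0, sd_s)
    dat <- sapply(1:3, function(j) subj + rnorm(n, 0, sd_e))
    ci <- icc_3_3(dat)$ci95
    if (ci[1] <= true_icc && true_icc <= ci[2]) cover <- cover + 1
  }
  expect_gte(cover / 500, 0.92)
  expect_lte(cover / 500, 0.98)
})

test_that("consistency variant reduces to (MSR - MSE)/MSR", {
  set.seed(37)
  subj <- rnorm(15, 4, 0.8)
  dat <- sapply(1:3, function(j) subj + rnorm(15, 0, 0.3) + 0.2 * j)
  r <- icc_3_3(dat, type = "consistency")
  # systematic repetition shifts do not hurt consistency, do hurt agreement
  expect_gt(r$icc, icc_3_3(dat, type = "agreement")$icc)
  expect_match(r$model, "consistency")
})

test_that("ANOVA sample size search matches its defining inequality", {
  n45 <- anova_power_n(0.48, alpha = 0.05, power = 0.80, k_groups = 3)
  expect_equal(as.integer(n45), 45L)
  expect_gte(attr(n45, "achieved_power"), 0.80)
  # one fewer participant fails the target
  p44 <- 1 - stats::pf(stats::qf(0.95, 2, 41), 2, 41, ncp = 0.48^2 * 44)
  expect_lt(p44, 0.80)

  # doubling the effect shrinks the requirement
  expect_lt(anova_power_n(0.96), 45)
  expect_error(anova_power_n(0), "> 0")
})

test_that("WMW sample size uses the ARE inflation of the t-test size", {
  n38 <- wmw_power_n(effect_f = 0.48)
  expect_equal(as.integer(n38), 38L)
  expect_gte(attr(n38, "achieved_power"), 0.80)

  # ARE = 1 recovers the plain t-test requirement
  n_t <- wmw_power_n(effect_d = 0.96, are = 1)
  expect_lte(as.integer(n_t), as.integer(n38))
  # halving d roughly quadruples N (power-curve check via noncentral t)
  n_half <- wmw_power_n(effect_d = 0.48)
  ratio <- as.integer(n_half) / as.integer(n38)
  expect_gt(ratio, 3.4)
  expect_lt(ratio, 4.3)
  expect_error(wmw_power_n(), "supply")
})

test_that("null simulations keep the Kruskal-Wallis size near nominal", {
  set.seed(41)
  rejections <- 0
  for (i in 1:2000) {
    s <- list(rnorm(15), rnorm(15), rnorm(15))
    if (kruskal_wallis(s)$p_value < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / 2000
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
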