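make_table <- function(n = 41, seed = 1, beta_map = 0, beta_age = 0,
                       noise = 1) {
  set.seed(seed)
  map <- stats::rnorm(n, 95, 10)
  age <- stats::rnorm(n, 62, 9)
  sex <- stats::rbinom(n, 1, 0.5)
  y <- beta_map * scale(map)[, 1] + beta_age * scale(age)[, 1] +
    stats::rnorm(n, 0, noise)
  data.frame(subject_id = sprintf("S%03d", 1:n), y = y, map = map,
             age = age, sex_male = sex)
}

test_that("a perfectly correlated exposure gives beta_std 1 with tiny p", {
  tab <- make_table(seed = 2, noise = 1)
  tab$y <- tab$map
  # summary.lm warns about the essentially perfect fit; that is the point here
  r <- suppressWarnings(
    fit_adjusted_regression(tab, "y", "map", covariates = c("age", "sex_male")))
  expect_equal(r$beta_std, 1, tolerance = 1e-8)
  expect_lt(r$p_value, 1e-10)
  expect_equal(r$n_used, 41)
})

test_that("standardized beta recovers a planted 0.3 slope on average", {
  betas <- vapply(1:200, function(s) {
    tab <- make_table(seed = s, beta_map = 0.3, beta_age = 0.2,
                      noise = sqrt(1 - 0.3^2 - 0.2^2))
    fit_adjusted_regression(tab, "y", "map")$beta_std
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.3), 0.05)
})

test_that("standardized beta is invariant to affine rescaling of inputs", {
  tab <- make_table(seed = 9, beta_map = 0.4, noise = 0.8)
  base <- fit_adjusted_regression(tab, "y", "map")
  tab2 <- tab
  tab2$map <- tab2$map * 7.6 - 300       # mm Hg -> arbitrary affine units
  tab2$y <- tab2$y / 1000 + 2            # min^-1 -> arbitrary affine units
  tab2$age <- tab2$age / 12
  res <- fit_adjusted_regression(tab2, "y", "map")
  expect_equal(res$beta_std, base$beta_std, tolerance = 1e-10)
  expect_equal(res$p_value, base$p_value, tolerance = 1e-10)
})

test_that("missing rows are omitted and rank deficiency is named", {
  tab <- make_table(seed = 4, beta_map = 0.3)
  tab$y[c(3, 7)] <- NA
  tab$map[11] <- NA
  r <- fit_adjusted_regression(tab, "y", "map")
  expect_equal(r$n_used, 38)
  tab$map2 <- tab$map
  expect_error(fit_adjusted_regression(tab, "y", "map", rotating = "map2"),
               "collinear")
  expect_error(fit_adjusted_regression(tab, "y", "map", rotating = "map"),
               "distinct")
})

test_that("diagnostics match the leave-one-out refit oracle to 1e-10", {
  for (s in c(6, 7)) {
    tab <- make_table(n = 41, seed = s, beta_map = 0.3)
    d <- detect_subject_outliers(tab, "y", c("map", "age", "sex_male"))
    oracle <- loo_diagnostics(tab$y, tab[, c("map", "age", "sex_male")])
    expect_equal(d$rstudent, oracle$rstudent, tolerance = 1e-10)
    expect_equal(d$cooks, oracle$cooks, tolerance = 1e-10)
  }
  # small-n guard
  expect_error(detect_subject_outliers(make_table(n = 5), "y",
                                       c("map", "age", "sex_male")),
               "too few")
})

test_that("a 20-SD outcome shift at high leverage is excluded; clean data is not", {
  tab <- make_table(n = 41, seed = 8, beta_map = 0.3,
                    noise = sqrt(1 - 0.09))
  tab$map[41] <- 140                       # far outside the covariate cloud
  tab$y[41] <- tab$y[41] + 20 * stats::sd(tab$y[1:40])
  d <- detect_subject_outliers(tab, "y", c("map", "age", "sex_male"))
  expect_true(d$flagged[41])
  expect_equal(sum(d$flagged), 1)
  r <- fit_adjusted_regression(tab, "y", "map")
  expect_identical(r$excluded_ids, "S041")
  expect_equal(r$n_used, 40)
  # determinism: identical data, identical exclusion set
  r2 <- fit_adjusted_regression(tab, "y", "map")
  expect_identical(r$excluded_ids, r2$excluded_ids)
  # exclusion rate on clean simulated cohorts stays below 1%
  flags <- vapply(1:100, function(s) {
    t0 <- make_table(seed = 1000 + s, beta_map = 0.3, noise = 0.9)
    sum(detect_subject_outliers(t0, "y", c("map", "age", "sex_male"))$flagged)
  }, numeric(1))
  expect_lt(mean(flags) / 41, 0.01)
})

test_that("subgroup ANOVA and Tukey behave at the known edge cases", {
  df <- data.frame(subgroup = rep(c("CHT", "UHT_minus", "UHT_plus"), each = 4),
                   y = rep(1, 12))
  # identical groups: no between-group variance
  df$y <- rep(c(5, 6, 7, 8), 3)
  out <- subgroup_anova_tukey(df, "y")
  expect_equal(out$F, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1, tolerance = 1e-12)
  expect_true(all(out$tukey$p_adj > 0.999))
  # two groups: Tukey adjusted p equals the plain two-group ANOVA p
  df2 <- data.frame(subgroup = rep(c("CHT", "UHT_minus"), each = 6),
                    y = c(1.2, 0.8, 1.1, 0.9, 1.3, 1.0,
                          1.9, 2.2, 1.7, 2.0, 2.4, 1.8))
  out2 <- subgroup_anova_tukey(df2, "y", groups = c("CHT", "UHT_minus"))
  # analytically identical; ptukey is evaluated numerically to ~1e-8
  expect_lt(abs(out2$tukey$p_adj - out2$p_value), 1e-8)
  expect_error(subgroup_anova_tukey(
    data.frame(subgroup = c("CHT", "CHT", "UHT_minus"), y = 1:3), "y"),
    "fewer than 2")
})

test_that("a planted subgroup shift is flagged by Tukey in most replicates", {
  hits_shift <- 0
  hits_null <- 0
  for (s in 1:50) {
    set.seed(400 + s)
    df <- data.frame(
      subgroup = rep(c("CHT", "UHT_minus", "UHT_plus"), times = c(12, 5, 5)),
      y = stats::rnorm(22))
    df$y[df$subgroup == "UHT_minus"] <- df$y[df$subgroup == "UHT_minus"] + 2.5
    tk <- subgroup_anova_tukey(df, "y")$tukey
    shifted <- grepl("UHT_minus", tk$comparison)
    if (all(tk$p_adj[shifted] < 0.05)) hits_shift <- hits_shift + 1
    if (any(tk$p_adj[!shifted] < 0.05)) hits_null <- hits_null + 1
  }
  expect_gte(hits_shift / 50, 0.8)
  expect_lt(hits_null / 50, 0.15)
})

test_that("pooled UHT comparison matches a hand-computed t statistic", {
  # toy example: CHT = (1, 2, 3), pooled UHT = (4, 5, 6)
  df <- data.frame(subgroup = c("CHT", "CHT", "CHT",
                                "UHT_minus", "UHT_plus", "UHT_minus"),
                   y = c(1, 2, 3, 4, 5, 6))
  out <- pooled_uht_comparison(df, "y")
  # pooled sd = 1, se = sqrt(2/3), t = -3/se
  t_hand <- (2 - 5) / (1 * sqrt(1 / 3 + 1 / 3))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * stats::pt(t_hand, df = 4), tolerance = 1e-12)
  expect_equal(out$direction, "CHT lower")
  # identical groups: mean difference 0, p ~ 1
  df0 <- data.frame(subgroup = rep(c("CHT", "UHT_plus"), each = 4),
                    y = rep(c(1, 2, 3, 4), 2))
  out0 <- pooled_uht_comparison(df0, "y")
  expect_equal(out0$mean_diff, 0)
  expect_equal(out0$p_value, 1, tolerance = 1e-12)
  # separation by 5 SD
  set.seed(30)
  dfs <- data.frame(subgroup = rep(c("CHT", "UHT_minus"), each = 10),
                    y = c(stats::rnorm(10), stats::rnorm(10) + 5))
  outs <- pooled_uht_comparison(dfs, "y")
  expect_lt(outs$p_value, 0.001)
  expect_equal(outs$direction, "CHT lower")
  expect_error(pooled_uht_comparison(
    data.frame(subgroup = "CHT", y = 1), "y"), ">= 2")
})
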