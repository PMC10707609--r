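# Frozen expected values below come from a published 56-eye four-method
# cohort summary (see method_moments()); each was re-derived from the printed
# (n, mean, sd) with the standard formulas before being asserted.

test_that("moments-based descriptives reproduce published standard errors and CIs", {
  expect_equal(se_from_moments(56, 1.03859), 0.13879, tolerance = 1e-4)
  ci <- ci_from_moments(56, 2.8450, 1.07324)
  expect_equal(ci$ci_lo, 2.5576, tolerance = 1e-3)
  expect_equal(ci$ci_hi, 3.1324, tolerance = 1e-3)

  pooled <- pool_moments(method_moments())
  expect_equal(pooled$mean, 2.8357, tolerance = 2e-4)
  expect_equal(pooled$sd, 1.03971, tolerance = 2e-4)
})

test_that("describe handles raw vectors and degenerate inputs", {
  d <- describe(tibble::tibble(mrd1_manual = c(2, 3, 4, 5)))
  expect_equal(d$mean, 3.5)
  expect_equal(d$se, sd(2:5) / 2)
  dc <- describe(tibble::tibble(mrd1_manual = rep(2.5, 10)))
  expect_equal(dc$sd, 0)
  expect_equal(dc$ci_lo, 2.5)            # CI collapses onto the mean
  expect_equal(dc$ci_hi, 2.5)
  expect_error(describe(tibble::tibble(mrd1_manual = 1)),
               class = "mrdeye_stats_error")
})

test_that("moments ANOVA reproduces the published decomposition", {
  a <- anova_from_moments(method_moments())
  expect_equal(a$ss[1], 5.463, tolerance = 5e-4)
  expect_equal(a$ss[2], 235.601, tolerance = 5e-4)
  expect_equal(a$ms[1], 1.821, tolerance = 5e-4)
  expect_equal(a$ms[2], 1.071, tolerance = 5e-4)
  expect_equal(a$statistic[1], 1.700, tolerance = 5e-4)
  expect_equal(a$p.value[1], 0.168, tolerance = 1e-3)
})

test_that("moments-based and raw-data ANOVA agree to numerical precision", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 4)
    df <- tibble::tibble(
      mrd1_manual = rnorm(max(n)), mrd1_dl = rnorm(max(n)),
      mrd1_ir = rnorm(max(n)), mrd1_rgb = rnorm(max(n)))
    raw <- one_way_anova(df)
    mom <- anova_from_moments(describe(df))
    expect_equal(raw$ss, mom$ss, tolerance = 1e-10)
    expect_equal(raw$statistic[1], mom$statistic[1], tolerance = 1e-10)
    expect_equal(raw$p.value[1], mom$p.value[1], tolerance = 1e-10)
  }
})

test_that("identical groups give a null ANOVA and infinite F is flagged", {
  same <- tibble::tibble(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  a <- one_way_anova(same, cols = c("a", "b", "c"))
  expect_equal(a$ss[1], 0)
  expect_equal(a$statistic[1], 0)
  expect_equal(a$p.value[1], 1)
  m <- tibble::tibble(n = c(5, 5), mean = c(1, 2), sd = c(0, 0))
  expect_warning(inf <- anova_from_moments(m), "infinite")
  expect_identical(inf$statistic[1], Inf)
})

test_that("Scheffe post hoc reproduces the published pairwise table", {
  sch <- scheffe_posthoc(method_moments())
  expect_true(all(abs(sch$se - 0.19557) < 2e-4))

  mr <- sch[sch$method1 == "mrd1_manual" & sch$method2 == "mrd1_rgb", ]
  expect_equal(mr$diff, -0.43330, tolerance = 1e-4)
  expect_equal(mr$ci_lo, -0.9843, tolerance = 2e-3)
  expect_equal(mr$ci_hi, 0.1177, tolerance = 2e-3)
  expect_equal(mr$p.adj, 0.182, tolerance = 2e-3)

  md <- sch[sch$method1 == "mrd1_manual" & sch$method2 == "mrd1_dl", ]
  expect_equal(md$diff, -0.20464, tolerance = 1e-3)
  expect_equal(md$p.adj, 0.778, tolerance = 2e-3)

  di <- sch[sch$method1 == "mrd1_dl" & sch$method2 == "mrd1_ir", ]
  expect_equal(di$diff, 0.06109, tolerance = 1e-3)
  expect_equal(di$p.adj, 0.992, tolerance = 2e-3)
})

test_that("Scheffe intervals are centred on the mean difference", {
  set.seed(17)
  for (i in 1:10) {
    m <- tibble::tibble(n = sample(5:50, 3), mean = rnorm(3),
                        sd = runif(3, 0.5, 2))
    sch <- scheffe_posthoc(m)
    expect_equal((sch$ci_lo + sch$ci_hi) / 2, sch$diff, tolerance = 1e-12)
  }
  two <- tibble::tibble(n = c(8, 8), mean = c(1, 1), sd = c(0.5, 0.5))
  s2 <- scheffe_posthoc(two)
  expect_equal(s2$diff, 0)
  expect_equal(s2$p.adj, 1)
})

test_that("Pearson matrix matches a direct covariance computation", {
  expect_equal(pearson_matrix(tibble::tibble(a = 1:10, b = 2 * (1:10) + 1),
                              cols = c("a", "b"))$r[1, 2], 1)
  set.seed(4)
  df <- tibble::tibble(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  pm <- pearson_matrix(df, cols = c("a", "b", "c"))
  for (p in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    x <- df[[p[1]]]; y <- df[[p[2]]]
    r_direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pm$r[p[1], p[2]], r_direct, tolerance = 1e-12)
  }
  expect_true(isSymmetric(pm$r))
  expect_equal(unname(diag(pm$r)), rep(1, 3))

  set.seed(5)
  big <- tibble::tibble(a = rnorm(1e4), b = rnorm(1e4))
  expect_lt(abs(pearson_matrix(big, cols = c("a", "b"))$r[1, 2]), 0.05)

  cz <- tibble::tibble(a = rep(1, 10), b = rnorm(10))
  expect_warning(pz <- pearson_matrix(cz, cols = c("a", "b")), "zero variance")
  expect_true(is.na(pz$r[1, 2]))
})

test_that("Bland-Altman identities and published mean differences", {
  x <- c(1, 2, 3, 4); y <- x
  ba0 <- bland_altman(x, y)
  expect_equal(ba0$mean_diff, 0); expect_equal(ba0$delta_loa, 0)

  set.seed(9)
  a <- rnorm(40); b <- rnorm(40)
  ba <- bland_altman(a, b)
  expect_equal(ba$mean_diff, mean(a) - mean(b), tolerance = 1e-14)
  expect_equal(ba$delta_loa, 2 * 1.96 * ba$sd_diff, tolerance = 1e-14)
  expect_equal(ba$loa_hi - ba$loa_lo, ba$delta_loa, tolerance = 1e-14)

  # mean differences depend only on the method means
  mm <- method_moments()
  expect_equal(mm$mean[mm$method == "mrd1_dl"] - mm$mean[mm$method == "mrd1_ir"],
               0.0611, tolerance = 1e-4)
  expect_equal(mm$mean[mm$method == "mrd1_manual"] - mm$mean[mm$method == "mrd1_rgb"],
               -0.4333, tolerance = 1e-4)

  expect_error(bland_altman(1:3, 1:4), class = "mrdeye_stats_error")
})

test_that("linear fit: exact lines, R^2 = r^2 identity, null behaviour", {
  x <- seq(0, 5, by = 0.25)
  lf <- linear_fit(x, 0.82 * x + 1.3)
  expect_equal(lf$slope, 0.82, tolerance = 1e-12)
  expect_equal(lf$intercept, 1.3, tolerance = 1e-12)
  expect_equal(lf$r.squared, 1, tolerance = 1e-12)

  set.seed(12)
  for (i in 1:5) {
    a <- rnorm(30); b <- 0.5 * a + rnorm(30)
    expect_equal(linear_fit(a, b)$r.squared, cor(a, b)^2, tolerance = 1e-12)
  }
  set.seed(13)
  noise <- linear_fit(rnorm(1e4), rnorm(1e4))
  expect_lt(noise$r.squared, 0.01)
  expect_error(linear_fit(rep(1, 5), rnorm(5)), class = "mrdeye_stats_error")
})

test_that("exclusion rules count violations exactly, first match wins", {
  base <- function(id, manual = 3, dl = 3.1, rgb = 3.2, ir = 2.9)
    tibble::tibble(eye_id = id,
                   mrd1_manual_r1 = manual, mrd1_manual_r2 = manual,
                   mrd1_manual_r3 = manual, mrd1_manual = manual,
                   mrd1_dl = dl, mrd1_rgb = rgb, mrd1_ir = ir,
                   rgb_indistinct = FALSE, machine_failed = FALSE,
                   recent_surgery = FALSE)
  tab <- dplyr::bind_rows(
    base(1), base(2), base(3),                       # clean
    dplyr::mutate(base(4), mrd1_manual_r2 = NA),     # rule 1
    base(5, manual = 0, ir = 0.5),                   # rule 2 (also trips 4)
    base(6, manual = -1),                            # rule 2
    dplyr::mutate(base(7), rgb_indistinct = TRUE),   # rule 3
    base(8, manual = 2.0, ir = 3.2),                 # rule 4: |d| = 1.2
    dplyr::mutate(base(9), machine_failed = TRUE),   # rule 5
    dplyr::mutate(base(10), recent_surgery = TRUE))  # rule 6
  res <- apply_exclusions(tab, reference_method = "mrd1_ir")
  expect_equal(res$report$counts$n_excluded, c(1, 2, 1, 1, 1, 1))
  expect_equal(res$report$n_retained, 3)
  expect_equal(res$table$eye_id, c(1, 2, 3))
  expect_equal(res$report$n_input,
               res$report$n_retained + sum(res$report$counts$n_excluded))
  # boundary: |d| = 1.0 exactly is retained
  ok <- apply_exclusions(base(1, manual = 2.2, ir = 3.2), "mrd1_ir")
  expect_equal(ok$report$n_retained, 1)
  expect_error(apply_exclusions(tab, "mrd1_nope"),
               class = "mrdeye_format_error")
})

test_that("agreement report is internally consistent and row-order invariant", {
  tab <- generate_cohort(cohort_sim_spec(n_eyes = 60, seed = 21))
  rep1 <- agreement_report(tab)
  rep2 <- agreement_report(tab[sample(nrow(tab)), ])
  expect_equal(rep1$descriptives, rep2$descriptives)
  expect_equal(rep1$anova, rep2$anova)
  expect_equal(rep1$scheffe, rep2$scheffe)
  expect_equal(rep1$pearson$r, rep2$pearson$r)
  expect_equal(rep1$bland_altman, rep2$bland_altman)

  # cross-component identities: R^2 = r^2, BA mean diff = mean(A) - mean(B)
  for (i in seq_len(nrow(rep1$regression))) {
    r <- rep1$pearson$r[rep1$regression$response[i],
                        rep1$regression$predictor[i]]
    expect_equal(rep1$regression$r.squared[i], r^2, tolerance = 1e-12)
  }
  d <- rep1$descriptives
  for (i in seq_len(nrow(rep1$bland_altman))) {
    m1 <- d$mean[d$method == rep1$bland_altman$method1[i]]
    m2 <- d$mean[d$method == rep1$bland_altman$method2[i]]
    expect_equal(rep1$bland_altman$mean_diff[i], m1 - m2, tolerance = 1e-12)
  }

  g <- glance(rep1)
  expect_equal(g$n_methods, 4)
  expect_s3_class(tidy(rep1, "pearson"), "tbl_df")
  expect_equal(nrow(tidy(rep1, "scheffe")), 6)
})

test_that("cohort-generator biases are recovered by Bland-Altman analysis", {
  tab <- generate_cohort(cohort_sim_spec(n_eyes = 10000, seed = 3))
  rep <- agreement_report(tab)
  ba <- rep$bland_altman
  inj <- c(manual = 0, dl = 0.20, ir = 0.14, rgb = 0.43)
  for (i in seq_len(nrow(ba))) {
    m1 <- sub("mrd1_", "", ba$method1[i]); m2 <- sub("mrd1_", "", ba$method2[i])
    se <- ba$sd_diff[i] / sqrt(ba$n[i])
    expect_lt(abs(ba$mean_diff[i] - (inj[[m1]] - inj[[m2]])), 3 * se)
  }
})

test_that("agreement report serializes to parseable JSON", {
  tab <- generate_cohort(cohort_sim_spec(n_eyes = 20, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_agreement_report(agreement_report(tab), path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$anova$term, c("between", "within", "total"))
  expect_equal(nrow(j$scheffe), 6)
})
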