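#' Published per-method MRD1 summary statistics
#'
#' Sample size, mean and standard deviation (mm) of MRD1 for the four
#' measurement methods — manual penlight (three-rater average), deep-learning
#' IR, ImageJ analysis of IR photographs, ImageJ analysis of RGB
#' photographs — as printed for a 56-eye clinical validation cohort. Because
#' the moments-based routines ([anova_from_moments()], [scheffe_posthoc()],
#' [se_from_moments()], [ci_from_moments()]) need only (n, mean, sd), this
#' table suffices to reproduce the cohort's ANOVA decomposition, Scheffe
#' post hoc comparisons, standard errors, confidence intervals and
#' Bland-Altman mean differences without access to the raw patient data.
#'
#' @return A tibble: `method`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
method_moments <- function() {
  path <- system.file("extdata", "mrd1_method_moments.csv",
                      package = "mrdeye", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Pooled moments of several groups
#'
#' Combines per-group (n, mean, sd) into the overall sample's mean and
#' standard deviation: the pooled sum of squares is the within-group part
#' `sum (n_i - 1) sd_i^2` plus the between-group part
#' `sum n_i (mean_i - grand mean)^2`, divided by `N - 1`.
#'
#' @param moments Data frame with columns `n`, `mean`, `sd`.
#' @return A one-row tibble: `n`, `mean`, `sd`, `se`.
#' @export
pool_moments <- function(moments) {
  stopifnot(all(c("n", "mean", "sd") %in% names(moments)))
  n <- moments$n; m <- moments$mean; s <- moments$sd
  N <- sum(n)
  grand <- sum(n * m) / N
  ss <- sum((n - 1) * s^2) + sum(n * (m - grand)^2)
  sd_all <- sqrt(ss / (N - 1))
  tibble(n = N, mean = grand, sd = sd_all, se = sd_all / sqrt(N))
}
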