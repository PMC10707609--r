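# Method-agreement statistics for multi-method MRD1 cohorts: exclusion
# filtering, descriptives, one-way ANOVA (raw and moments-based), Scheffe
# post hoc, Pearson correlation, Bland-Altman limits of agreement and simple
# linear regression.

DEFAULT_METHODS <- c("mrd1_manual", "mrd1_dl", "mrd1_ir", "mrd1_rgb")

#' Apply the cohort exclusion rules
#'
#' Filters a multi-method cohort under six rules, applied in order with
#' first-match attribution: (1) missing manual-rater replicates, (2) manual
#' MRD1 of zero or below, (3) indistinct pupil/iris boundary in the RGB image
#' (flag column `rgb_indistinct`, or a missing RGB value), (4) manual value
#' differing from the reference method by more than `max_discrepancy_mm`,
#' (5) no machine (automated) measurement (flag column `machine_failed`, or a
#' missing DL value), (6) recent eyelid surgery (flag column
#' `recent_surgery`).
#'
#' @param table Cohort tibble with at least `mrd1_manual` and the reference
#'   column; optional flag columns as above and rater replicate columns
#'   `mrd1_manual_r<i>`.
#' @param reference_method Column name used in rule 4 (typically `"mrd1_rgb"`
#'   or `"mrd1_ir"`).
#' @param max_discrepancy_mm Rule-4 threshold (mm).
#' @return A list: `table` (retained rows) and `report`, an
#'   `exclusion_report` with per-rule counts and retained row ids.
#' @export
apply_exclusions <- function(table, reference_method = "mrd1_ir",
                             max_discrepancy_mm = 1.0) {
  table <- as_tibble(table)
  if (!"mrd1_manual" %in% names(table))
    abort("cohort table must contain mrd1_manual", class = "mrdeye_format_error")
  if (!reference_method %in% names(table))
    abort(sprintf("unknown reference method: %s", reference_method),
          class = "mrdeye_format_error")
  n <- nrow(table)
  flag_col <- function(nm) if (nm %in% names(table)) isTRUE_vec(table[[nm]]) else rep(FALSE, n)
  rep_cols <- grep("^mrd1_manual_r[0-9]+$", names(table), value = TRUE)

  r1 <- if (length(rep_cols)) rowSums(is.na(table[rep_cols])) > 0
        else is.na(table$mrd1_manual)
  r2 <- !is.na(table$mrd1_manual) & table$mrd1_manual <= 0
  r3 <- flag_col("rgb_indistinct") |
    (if ("mrd1_rgb" %in% names(table)) is.na(table$mrd1_rgb) else rep(FALSE, n))
  ref <- table[[reference_method]]
  r4 <- is.na(ref) | (!is.na(table$mrd1_manual) &
                        abs(table$mrd1_manual - ref) > max_discrepancy_mm)
  r5 <- flag_col("machine_failed") |
    (if ("mrd1_dl" %in% names(table)) is.na(table$mrd1_dl) else rep(FALSE, n))
  r6 <- flag_col("recent_surgery")

  rules <- cbind(r1, r2, r3, r4, r5, r6)
  rules[is.na(rules)] <- FALSE
  first <- apply(rules, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  retained <- is.na(first)
  report <- structure(list(
    counts = tibble(
      rule = 1:6,
      label = c("missing rater replicates", "manual MRD1 <= 0",
                "indistinct RGB boundary",
                sprintf("|manual - %s| > %.1f mm", reference_method,
                        max_discrepancy_mm),
                "no machine measurement", "recent surgery"),
      n_excluded = vapply(1:6, function(k) sum(first == k, na.rm = TRUE), numeric(1))
    ),
    n_input = n, n_retained = sum(retained),
    retained_ids = which(retained)
  ), class = "exclusion_report")
  list(table = table[retained, , drop = FALSE], report = report)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d rows in, %d retained\n", x$n_input, x$n_retained))
  print(x$counts)
  invisible(x)
}

#' Per-method descriptive statistics
#'
#' @param data Cohort data frame.
#' @param cols Character vector of measurement columns (mm).
#' @param conf Confidence level for the mean's t-interval.
#' @return A tibble with one row per method: `method`, `n`, `mean`, `sd`,
#'   `se`, `ci_lo`, `ci_hi`, `min`, `max`.
#' @export
describe <- function(data, cols = intersect(DEFAULT_METHODS, names(data)),
                     conf = 0.95) {
  purrr::map_dfr(cols, function(cl) {
    v <- data[[cl]]; v <- v[!is.na(v)]
    if (length(v) < 2)
      abort(sprintf("need n >= 2 non-missing values in %s for a variance", cl),
            class = "mrdeye_stats_error")
    ci <- ci_from_moments(length(v), mean(v), sd(v), conf)
    tibble(method = cl, n = length(v), mean = mean(v), sd = sd(v),
           se = se_from_moments(length(v), sd(v)),
           ci_lo = ci[[1]], ci_hi = ci[[2]], min = min(v), max = max(v))
  })
}

#' Standard error and confidence interval from summary moments
#'
#' `se_from_moments` gives `sd / sqrt(n)`; `ci_from_moments` the t-based
#' interval `mean +/- t_{(1+conf)/2, n-1} * se`. These let printed summary
#' tables (n, mean, sd) be re-analysed without raw data.
#'
#' @param n Sample size(s).
#' @param mean,sd Sample moments.
#' @param conf Confidence level.
#' @return `se_from_moments`: numeric; `ci_from_moments`: tibble
#'   `(ci_lo, ci_hi)`.
#' @export
se_from_moments <- function(n, sd) {
  stopifnot(all(n >= 2), all(sd >= 0))
  sd / sqrt(n)
}

#' @rdname se_from_moments
#' @export
ci_from_moments <- function(n, mean, sd, conf = 0.95) {
  se <- se_from_moments(n, sd)
  tcrit <- qt((1 + conf) / 2, n - 1)
  tibble(ci_lo = mean - tcrit * se, ci_hi = mean + tcrit * se)
}

#' One-way ANOVA across measurement methods
#'
#' `one_way_anova()` fits on raw data via [stats::lm()]; with only printed
#' group moments available, `anova_from_moments()` reconstructs the identical
#' decomposition from `SS_between = sum n_i (mean_i - grand mean)^2` and
#' `SS_within = sum (n_i - 1) sd_i^2`.
#'
#' @param data Cohort data frame (wide, one column per method).
#' @param cols Measurement columns treated as independent groups.
#' @return A tibble with rows `between`, `within`, `total` and columns
#'   `term`, `ss`, `df`, `ms`, `statistic`, `p.value`. A zero within-group
#'   variance with unequal means yields `statistic = Inf`, `p.value = 0` and
#'   a warning.
#' @export
one_way_anova <- function(data, cols = intersect(DEFAULT_METHODS, names(data))) {
  long <- tidyr::pivot_longer(dplyr::select(as_tibble(data), dplyr::all_of(cols)),
                              dplyr::everything(),
                              names_to = "method", values_to = "value")
  long <- long[!is.na(long$value), ]
  fit <- lm(value ~ method, data = long)
  a <- anova(fit)
  ss <- c(a$`Sum Sq`[1], a$`Sum Sq`[2])
  df <- c(a$Df[1], a$Df[2])
  anova_table(ss[1], df[1], ss[2], df[2])
}

#' @rdname one_way_anova
#' @param moments A data frame with columns `n`, `mean`, `sd` (one row per
#'   group), e.g. the output of [describe()].
#' @export
anova_from_moments <- function(moments) {
  stopifnot(all(c("n", "mean", "sd") %in% names(moments)), nrow(moments) >= 2,
            all(moments$n >= 2))
  n <- moments$n; m <- moments$mean; s <- moments$sd
  grand <- sum(n * m) / sum(n)
  ss_b <- sum(n * (m - grand)^2)
  ss_w <- sum((n - 1) * s^2)
  anova_table(ss_b, length(n) - 1, ss_w, sum(n) - length(n))
}

anova_table <- function(ss_b, df_b, ss_w, df_w) {
  ms_b <- ss_b / df_b; ms_w <- ss_w / df_w
  if (ms_w == 0 && ss_b > 0) {
    warn("zero within-group variance with distinct means: F is infinite")
    f <- Inf; p <- 0
  } else if (ms_w == 0) {
    f <- 0; p <- 1
  } else {
    f <- ms_b / ms_w; p <- pf(f, df_b, df_w, lower.tail = FALSE)
  }
  tibble(term = c("between", "within", "total"),
         ss = c(ss_b, ss_w, ss_b + ss_w),
         df = c(df_b, df_w, df_b + df_w),
         ms = c(ms_b, ms_w, NA_real_),
         statistic = c(f, NA_real_, NA_real_),
         p.value = c(p, NA_real_, NA_real_))
}

#' Scheffe post hoc pairwise comparisons
#'
#' For each method pair (i, j): difference of means, pooled standard error
#' `sqrt(MS_within (1/n_i + 1/n_j))`, Scheffe-adjusted p-value
#' `P(F_{k-1, df_w} >= (diff/SE)^2 / (k-1))` and simultaneous confidence
#' interval `diff +/- sqrt((k-1) F_{conf; k-1, df_w}) * SE`. Works directly
#' from group moments, so printed summary tables can be re-analysed.
#'
#' @param moments Data frame with `method` (or rownames), `n`, `mean`, `sd`.
#' @param ms_within,df_within Within-group mean square and df; computed from
#'   `moments` when omitted.
#' @param conf Simultaneous confidence level.
#' @return A tibble with one row per unordered pair: `method1`, `method2`,
#'   `diff` (mean1 - mean2), `se`, `p.adj`, `ci_lo`, `ci_hi`.
#' @export
scheffe_posthoc <- function(moments, ms_within = NULL, df_within = NULL,
                            conf = 0.95) {
  stopifnot(all(c("n", "mean", "sd") %in% names(moments)))
  k <- nrow(moments)
  stopifnot(k >= 2)
  meth <- if ("method" %in% names(moments)) moments$method
          else paste0("group", seq_len(k))
  if (is.null(ms_within) || is.null(df_within)) {
    a <- anova_from_moments(moments)
    ms_within <- a$ms[2]; df_within <- a$df[2]
  }
  if (df_within <= 0)
    abort("df_within must be positive", class = "mrdeye_stats_error")
  crit <- sqrt((k - 1) * qf(conf, k - 1, df_within))
  pairs <- utils::combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    d <- moments$mean[i] - moments$mean[j]
    se <- sqrt(ms_within * (1 / moments$n[i] + 1 / moments$n[j]))
    padj <- if (se == 0) as.numeric(d == 0) else
      pf((d / se)^2 / (k - 1), k - 1, df_within, lower.tail = FALSE)
    if (se == 0 && d == 0) padj <- 1
    tibble(method1 = meth[i], method2 = meth[j], diff = d, se = se,
           p.adj = padj, ci_lo = d - crit * se, ci_hi = d + crit * se)
  })
}

#' Pearson correlation matrix with two-tailed p-values
#'
#' @param data Cohort data frame.
#' @param cols Measurement columns (pairwise-complete observations).
#' @param flag_p Significance threshold used by the print method's flag.
#' @return A `pearson_matrix` list: `r`, `p`, `n` matrices and `flag_p`.
#'   Zero-variance columns give `NA` entries with a warning.
#' @export
pearson_matrix <- function(data, cols = intersect(DEFAULT_METHODS, names(data)),
                           flag_p = 0.005) {
  k <- length(cols)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    x <- data[[cols[i]]]; y <- data[[cols[j]]]
    keep <- complete.cases(x, y)
    nmat[i, j] <- nmat[j, i] <- sum(keep)
    if (sum(keep) < 3) next
    if (sd(x[keep]) == 0 || sd(y[keep]) == 0) {
      warn(sprintf("zero variance in %s or %s: correlation undefined",
                   cols[i], cols[j]))
      next
    }
    ct <- cor.test(x[keep], y[keep], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  diag(nmat) <- vapply(cols, function(cl) sum(!is.na(data[[cl]])), numeric(1))
  structure(list(r = r, p = p, n = nmat, flag_p = flag_p),
            class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, digits = 3, ...) {
  cat("<pearson_matrix> (", sprintf("flag: p < %g", x$flag_p), ")\n", sep = "")
  m <- round(x$r, digits)
  flag <- !is.na(x$p) & x$p < x$flag_p
  out <- matrix(paste0(format(m), ifelse(flag, " *", "  ")),
                nrow(m), dimnames = dimnames(m))
  print(out, quote = FALSE)
  invisible(x)
}

#' Bland-Altman agreement between two paired measurement series
#'
#' Differences are taken as `x - y`; limits of agreement are
#' `mean_diff +/- multiplier * sd_diff` and `delta_loa` is their width
#' (upper minus lower).
#'
#' @param x,y Paired numeric vectors (equal length, n >= 2 complete pairs).
#' @param multiplier LOA multiplier (1.96 for 95% limits).
#' @return A one-row tibble: `n`, `mean_diff`, `sd_diff`, `loa_lo`, `loa_hi`,
#'   `delta_loa`.
#' @export
bland_altman <- function(x, y, multiplier = 1.96) {
  if (length(x) != length(y))
    abort("x and y must have equal length", class = "mrdeye_stats_error")
  keep <- complete.cases(x, y)
  d <- x[keep] - y[keep]
  if (length(d) < 2)
    abort("need at least 2 complete pairs", class = "mrdeye_stats_error")
  md <- mean(d); s <- sd(d)
  tibble(n = length(d), mean_diff = md, sd_diff = s,
         loa_lo = md - multiplier * s, loa_hi = md + multiplier * s,
         delta_loa = 2 * multiplier * s)
}

#' Ordinary least-squares line through paired measurements
#'
#' @param x,y Paired numeric vectors (n >= 3 complete pairs, var(x) > 0).
#' @return A one-row tibble: `n`, `slope`, `intercept`, `r.squared`.
#' @export
linear_fit <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    abort("need at least 3 complete pairs", class = "mrdeye_stats_error")
  if (sd(x) == 0)
    abort("x has zero variance", class = "mrdeye_stats_error")
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  tibble(n = length(x), slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r.squared = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot)
}

#' Full method-agreement report
#'
#' Composes [describe()], [one_way_anova()], [scheffe_posthoc()],
#' [pearson_matrix()], [bland_altman()] and [linear_fit()] over every method
#' pair into one serializable report. The report depends only on the column
#' values, not row order.
#'
#' @param data Cohort tibble (already exclusion-filtered if desired).
#' @param cols Measurement columns.
#' @param loa_multiplier Bland-Altman LOA multiplier.
#' @param flag_p Correlation significance flag threshold.
#' @return An `agreement_report` list: `descriptives`, `anova`, `scheffe`,
#'   `pearson`, `bland_altman` (tibble, one row per ordered pair as
#'   method1 - method2), `regression` (one row per ordered pair, y ~ x with
#'   x = method2), and `settings`.
#' @export
agreement_report <- function(data, cols = intersect(DEFAULT_METHODS, names(data)),
                             loa_multiplier = 1.96, flag_p = 0.005) {
  stopifnot(length(cols) >= 2)
  desc <- describe(data, cols)
  an <- one_way_anova(data, cols)
  sch <- scheffe_posthoc(dplyr::rename(desc, method = "method"),
                         ms_within = an$ms[2], df_within = an$df[2])
  pm <- pearson_matrix(data, cols, flag_p = flag_p)
  pairs <- utils::combn(cols, 2)
  ba <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    dplyr::bind_cols(tibble(method1 = pairs[1, p], method2 = pairs[2, p]),
                     bland_altman(data[[pairs[1, p]]], data[[pairs[2, p]]],
                                  loa_multiplier))
  })
  reg <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    dplyr::bind_cols(tibble(response = pairs[1, p], predictor = pairs[2, p]),
                     linear_fit(data[[pairs[2, p]]], data[[pairs[1, p]]]))
  })
  structure(list(descriptives = desc, anova = an, scheffe = sch, pearson = pm,
                 bland_altman = ba, regression = reg,
                 settings = list(cols = cols, loa_multiplier = loa_multiplier,
                                 flag_p = flag_p)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("== Method agreement report ==\n\nDescriptives:\n")
  print(x$descriptives)
  cat("\nOne-way ANOVA:\n"); print(x$anova)
  cat("\nScheffe post hoc:\n"); print(x$scheffe)
  cat("\nPearson correlations:\n"); print(x$pearson)
  cat("\nBland-Altman (method1 - method2):\n"); print(x$bland_altman)
  cat("\nRegressions (response ~ predictor):\n"); print(x$regression)
  invisible(x)
}

#' Tidy an agreement report component
#'
#' @param x An `agreement_report`.
#' @param component One of `"descriptives"`, `"anova"`, `"scheffe"`,
#'   `"pearson"`, `"bland_altman"`, `"regression"`.
#' @param ... Unused.
#' @return A tibble; for `"pearson"` the matrix is returned in long form
#'   (`method1`, `method2`, `r`, `p.value`, `n`).
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, component = "bland_altman", ...) {
  component <- match.arg(component,
                         c("descriptives", "anova", "scheffe", "pearson",
                           "bland_altman", "regression"))
  if (component != "pearson") return(as_tibble(x[[component]]))
  cols <- rownames(x$pearson$r)
  pairs <- utils::combn(length(cols), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    tibble(method1 = cols[i], method2 = cols[j],
           r = x$pearson$r[i, j], p.value = x$pearson$p[i, j],
           n = x$pearson$n[i, j])
  })
}

#' One-row summary of an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return A one-row tibble: number of methods and eyes, the ANOVA F and p,
#'   and the best-agreeing pair (highest Pearson r) with its r and
#'   Bland-Altman LOA width.
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  r <- x$pearson$r; diag(r) <- NA
  best <- which(r == max(r, na.rm = TRUE), arr.ind = TRUE)[1, ]
  m1 <- rownames(r)[best[1]]; m2 <- colnames(r)[best[2]]
  ba <- x$bland_altman
  hit <- (ba$method1 == m1 & ba$method2 == m2) |
    (ba$method1 == m2 & ba$method2 == m1)
  tibble(n_methods = length(x$settings$cols),
         n_eyes = min(x$descriptives$n),
         anova_f = x$anova$statistic[1], anova_p = x$anova$p.value[1],
         best_pair = paste(m1, m2, sep = " ~ "),
         best_r = max(r, na.rm = TRUE),
         best_delta_loa = ba$delta_loa[hit][1])
}

#' Serialize an agreement report to JSON
#'
#' @param x An `agreement_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(x, path) {
  stopifnot(inherits(x, "agreement_report"))
  out <- list(descriptives = x$descriptives, anova = x$anova,
              scheffe = x$scheffe,
              pearson = list(methods = rownames(x$pearson$r),
                             r = x$pearson$r, p = x$pearson$p, n = x$pearson$n),
              bland_altman = x$bland_altman, regression = x$regression,
              settings = x$settings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       matrix = "rowmajor")
  invisible(path)
}
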