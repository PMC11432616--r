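#' Long-format repeated-measurement table
#'
#' Validates a long table of repeated measurements with columns `patient`,
#' `phase` (`"pre"`/`"post"`), `observer`, `repeat`, `metric`, `value`; the
#' combination of the first five must be unique and values finite.
#'
#' @param df data frame (or tibble) with the columns above.
#' @return a tibble of class `measurement_table`.
#' @export
measurement_table <- function(df) {
  need <- c("patient", "phase", "observer", "repeat", "metric", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing measurement-table columns: ", paste(miss, collapse = ", "))
  df <- tibble::as_tibble(df)
  if (!all(df$phase %in% c("pre", "post")))
    stop("phase must be 'pre' or 'post'")
  if (!all(is.finite(df$value))) stop("values must be finite")
  key <- do.call(paste, df[, c("patient", "phase", "observer", "repeat", "metric")])
  if (anyDuplicated(key))
    stop("duplicate (patient, phase, observer, repeat, metric) rows")
  class(df) <- c("measurement_table", class(df))
  df
}

#' Read a measurement table from CSV
#' @param path CSV with header `patient,phase,observer,repeat,metric,value`.
#' @return a [measurement_table()].
#' @export
read_measurement_table <- function(path) {
  measurement_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
}

#' Coefficient of variation (percent)
#'
#' The repeatability metric for repeated angle measurements: sample standard
#' deviation (n - 1 denominator) over the mean, times 100.
#'
#' @param values numeric vector (>= 2 values, non-zero mean).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (abs(m) < 1e-12) stop("mean is zero; CV undefined")
  100 * stats::sd(values) / m
}

#' Two-way random-effects intraclass correlation (absolute agreement)
#'
#' Computes the ICC under the two-way random-effects, absolute-agreement
#' model from the mean squares of the subjects-by-raters layout:
#' ICC(2,1) (`form = "single"`) for single measurements or ICC(2,k)
#' (`form = "mean_k"`) for the mean of the k raters, with the standard
#' F-based 95% confidence interval (McGraw & Wong).
#'
#' @param ratings either a numeric matrix (subjects in rows, raters in
#'   columns, complete) or a [measurement_table()] whose observers are the
#'   raters (one metric; each patient-phase combination is a subject).
#' @param form `"single"` or `"mean_k"`.
#' @param conf_level confidence level for the interval.
#' @return object of class `reliability_report`: `icc`, `icc_ci95`,
#'   `model`, `form`, `n_subjects`, `k_raters`.
#' @export
icc_two_way_random <- function(ratings, form = c("single", "mean_k"),
                               conf_level = 0.95) {
  form <- match.arg(form)
  X <- ratings_matrix(ratings)
  n <- nrow(X)
  k <- ncol(X)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  if (any(!is.finite(X))) stop("incomplete two-way layout (missing ratings)")
  g <- mean(X)
  rm_ <- rowMeans(X)
  cm <- colMeans(X)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm - g)^2) / (k - 1)
  sse <- sum((X - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  a <- k * icc1 / (n * (1 - icc1))
  b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  if (form == "single") {
    icc <- icc1; ci <- c(lo1, hi1)
  } else {
    avg <- function(r) k * r / (1 + (k - 1) * r)
    icc <- (msr - mse) / (msr + (msc - mse) / n)
    ci <- c(avg(lo1), avg(hi1))
  }
  structure(list(icc = icc, icc_ci95 = ci,
                 model = "two-way random effects, absolute agreement",
                 form = form, n_subjects = n, k_raters = k,
                 ms = c(msr = msr, msc = msc, mse = mse)),
            class = "reliability_report")
}

ratings_matrix <- function(ratings) {
  if (is.matrix(ratings)) return(ratings)
  if (inherits(ratings, "measurement_table") || is.data.frame(ratings)) {
    df <- tibble::as_tibble(ratings)
    if ("metric" %in% names(df) && length(unique(df$metric)) > 1L)
      stop("ratings table mixes metrics; filter to one metric first")
    subj <- paste(df$patient, df$phase, sep = ":")
    wide <- tapply(df$value, list(subj, df$observer), mean)
    return(unclass(wide))
  }
  stop("ratings must be a matrix or a measurement table")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> ICC(%s) = %.3f, 95%% CI [%.3f, %.3f] (%s; n = %d, k = %d)\n",
              ifelse(x$form == "single", "2,1", "2,k"), x$icc,
              x$icc_ci95[1], x$icc_ci95[2], x$model, x$n_subjects, x$k_raters))
  invisible(x)
}

#' Paired pre/post comparison
#'
#' Two-sided paired t-test on `post - pre`, with group means/SDs and the
#' percent change of the means.
#'
#' @param pre,post numeric vectors of equal length (>= 2 pairs).
#' @param metric_name label carried into the result.
#' @return object of class `paired_comparison`: `metric_name`, `n_pairs`,
#'   `mean_pre`, `sd_pre`, `mean_post`, `sd_post`, `mean_diff`, `t_stat`,
#'   `df`, `p_value`, `percent_change`.
#' @export
paired_t <- function(pre, post, metric_name = "metric") {
  if (length(pre) != length(post)) stop("pre and post must pair up")
  if (length(pre) < 2L) stop("need at least 2 pairs")
  d <- post - pre
  if (stats::sd(d) <= 0) stop("zero-variance differences; t-test undefined")
  tt <- stats::t.test(post, pre, paired = TRUE)
  structure(list(metric_name = metric_name, n_pairs = length(pre),
                 mean_pre = mean(pre), sd_pre = stats::sd(pre),
                 mean_post = mean(post), sd_post = stats::sd(post),
                 mean_diff = mean(d),
                 t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 percent_change = percent_change(mean(pre), mean(post))),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s: %.2f +/- %.2f -> %.2f +/- %.2f (n = %d), t = %.3f, df = %g, p = %.4f, change %+.2f%%\n",
              x$metric_name, x$mean_pre, x$sd_pre, x$mean_post, x$sd_post,
              x$n_pairs, x$t_stat, x$df, x$p_value, x$percent_change))
  invisible(x)
}

#' Percent change between pre- and post-treatment means
#'
#' The default (`signed_post_minus_pre`) reports `100 * (post - pre) / pre`,
#' matching the sign convention of increases printed as positive.
#' `pre_minus_post` is the literal `100 * (pre - post) / pre` variant.
#'
#' @param pre,post scalar means (`pre` non-zero).
#' @param convention `"signed_post_minus_pre"` (default) or
#'   `"pre_minus_post"`.
#' @return percent change.
#' @export
percent_change <- function(pre, post,
                           convention = c("signed_post_minus_pre",
                                          "pre_minus_post")) {
  convention <- match.arg(convention)
  if (abs(pre) < 1e-12) stop("pre-treatment mean is zero")
  if (convention == "signed_post_minus_pre") 100 * (post - pre) / pre
  else 100 * (pre - post) / pre
}

#' Cohort summary (mean and SD per group)
#'
#' Groups a long measurement table and reports per-group n, mean, and
#' sample SD (flagged `NA` for single-observation groups); optionally adds
#' paired pre/post comparisons within each metric, pairing on patient.
#'
#' @param table a [measurement_table()] or data frame with a `value`
#'   column.
#' @param group_cols character vector of grouping columns.
#' @param compare_phases logical; add paired t-tests across `phase` per
#'   metric (requires `phase` and `patient` columns).
#' @return list with `summary` (tibble) and, if requested, `comparisons`
#'   (list of [paired_t()] results per metric).
#' @export
cohort_summary <- function(table, group_cols = c("metric", "phase"),
                           compare_phases = FALSE) {
  df <- tibble::as_tibble(table)
  miss <- setdiff(group_cols, names(df))
  if (length(miss) > 0L) stop("grouping columns not found: ",
                              paste(miss, collapse = ", "))
  summary <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1L, stats::sd(.data$value),
                                 NA_real_),
                     .groups = "drop")
  if (any(summary$n == 0L)) stop("empty group in cohort summary")
  out <- list(summary = summary)
  if (compare_phases) {
    cmps <- list()
    for (m in unique(df$metric)) {
      sub <- df[df$metric == m, ]
      wide <- tapply(sub$value, list(sub$patient, sub$phase), mean)
      if (!all(c("pre", "post") %in% colnames(wide))) next
      ok <- stats::complete.cases(wide[, c("pre", "post")])
      if (sum(ok) < 2L) next
      cmps[[m]] <- paired_t(wide[ok, "pre"], wide[ok, "post"],
                            metric_name = m)
    }
    out$comparisons <- cmps
  }
  out
}
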