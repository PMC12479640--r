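# Cohort-level statistics: descriptive summaries, Shapiro-Wilk normality
# gate, Pearson correlation with Fisher-z confidence intervals, Spearman
# rank correlation, and the correlation-based sample-size calculation.

#' Descriptive summary of a numeric sample
#'
#' Mean, sample (n-1) standard deviation, median, interquartile range
#' (25th/75th percentiles, linear-interpolation quantiles), min, max, n.
#'
#' @param values numeric vector (NA removed); `n >= 1`, sd requires
#'   `n >= 2`.
#' @return one-row `data.frame` with `mean, sd, median, q25, q75, min,
#'   max, n`.
#' @export
summarize_numeric <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) sca_error("empty sample", "swallowCA_bad_parameter")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(
    mean = mean(values),
    sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
    median = q[2], q25 = q[1], q75 = q[3],
    min = min(values), max = max(values),
    n = length(values)
  )
}

#' Shapiro-Wilk normality gate
#'
#' Thin wrapper over [stats::shapiro.test()] returning the (W, p,
#' decision) triple used to choose between parametric and rank-based
#' correlation.
#'
#' @param values numeric sample, `3 <= n <= 5000`, not constant.
#' @param alpha significance level for the decision flag.
#' @return list with `statistic` (W), `p_value` and `is_normal`
#'   (`p > alpha`).
#' @export
shapiro_wilk_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000) {
    sca_error("Shapiro-Wilk requires 3 <= n <= 5000", "swallowCA_bad_parameter")
  }
  if (stats::sd(values) == 0) {
    sca_error("Shapiro-Wilk W is undefined for a constant sample", "swallowCA_degenerate")
  }
  sw <- stats::shapiro.test(values)
  list(
    statistic = unname(sw$statistic),
    p_value = sw$p.value,
    is_normal = sw$p.value > alpha
  )
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Product-moment correlation with the interval
#' `tanh(atanh(r) +/- z_(1+conf)/2 / sqrt(n - 3))`.
#'
#' @param x,y paired numeric samples, `n >= 4`, both non-constant.
#' @param confidence confidence level (default 0.95).
#' @return list with `r`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_with_ci <- function(x, y, confidence = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) sca_error("need at least 4 complete pairs", "swallowCA_bad_parameter")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    sca_error("correlation undefined for a constant variable", "swallowCA_degenerate")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    return(list(r = r, ci_low = r, ci_high = r, n = n))
  }
  z <- atanh(r)
  half <- stats::qnorm((1 + confidence) / 2) / sqrt(n - 3)
  list(r = r, ci_low = tanh(z - half), ci_high = tanh(z + half), n = n)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties get average ranks).
#'
#' @param x,y paired samples, `n >= 4`, both non-constant after ranking.
#' @return rho.
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) sca_error("need at least 4 complete pairs", "swallowCA_bad_parameter")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    sca_error("correlation undefined for a constant variable", "swallowCA_degenerate")
  }
  stats::cor(x, y, method = "spearman")
}

#' Sample size for detecting a correlation
#'
#' Fisher-z approximation:
#' `n = ceil(((z_(1-alpha/2) + z_power) / atanh(rho))^2 + 3)`.
#' At effect size 0.31 with two-sided alpha 0.05 and power 0.80 this
#' gives 80 participants.
#'
#' @param rho correlation effect size, `0 < rho < 1`.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return required sample size (integer).
#' @export
sample_size_correlation <- function(rho, alpha = 0.05, power = 0.80) {
  if (!is.finite(rho) || rho <= 0 || rho >= 1) {
    sca_error("rho must lie strictly between 0 and 1", "swallowCA_bad_parameter")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    sca_error("alpha and power must lie strictly between 0 and 1", "swallowCA_bad_parameter")
  }
  z <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / atanh(rho)
  as.integer(ceiling(z^2 + 3))
}

#' Correlation report between cohort covariates and acoustic means
#'
#' For each covariate/feature pair, runs the Shapiro-Wilk gate on both
#' variables and reports Pearson (with Fisher-z CI) when both pass,
#' Spearman otherwise — alongside the always-computed Spearman rho.
#'
#' @param cohort `data.frame` with per-neonate covariates and acoustic
#'   feature means.
#' @param covariates,features column names to pair up.
#' @param confidence confidence level for Pearson CIs.
#' @return `data.frame` `pair, method, estimate, ci_low, ci_high, n`.
#' @export
correlation_report <- function(cohort,
                               covariates = c("birth_gestation_weeks",
                                              "chronological_gestation_weeks",
                                              "n_medical_conditions"),
                               features = c("duration_s", "peak_frequency_hz",
                                            "peak_amplitude_db", "peak_power_db"),
                               confidence = 0.95) {
  rows <- list()
  for (cv in covariates) {
    for (ft in features) {
      x <- cohort[[cv]]; y <- cohort[[ft]]
      if (is.null(x) || is.null(y)) next
      normal <- tryCatch(
        shapiro_wilk_gate(x)$is_normal && shapiro_wilk_gate(y)$is_normal,
        error = function(e) FALSE
      )
      if (normal) {
        p <- pearson_with_ci(x, y, confidence)
        rows[[length(rows) + 1L]] <- data.frame(
          pair = paste(cv, ft, sep = "~"), method = "pearson",
          estimate = p$r, ci_low = p$ci_low, ci_high = p$ci_high, n = p$n,
          stringsAsFactors = FALSE
        )
      } else {
        ok <- stats::complete.cases(x, y)
        rows[[length(rows) + 1L]] <- data.frame(
          pair = paste(cv, ft, sep = "~"), method = "spearman",
          estimate = spearman_rho(x, y), ci_low = NA_real_, ci_high = NA_real_,
          n = sum(ok), stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
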