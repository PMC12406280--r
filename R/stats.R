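#' 95th-centile trial summary of per-transition peaks
#'
#' The per-trial capacity measure is the 95th centile of the per-transition
#' peaks (RP95c, VP95c), which captures near-maximal power generation while
#' protecting against outliers. Linear interpolation between the closest
#' order statistics is used (the default sample-quantile convention).
#'
#' @param values Non-empty numeric vector.
#' @param prob Centile as a probability (default 0.95).
#' @return Scalar centile.
#' @export
percentile95 <- function(values, prob = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("percentile of an empty vector is undefined")
  unname(stats::quantile(values, probs = prob, type = 7))
}

#' Standardize to zero mean and unit variance
#'
#' Population convention: the divisor is the root-mean-square deviation
#' (denominator n), so the standardized sample has population variance
#' exactly 1. Used to put RPP (rad^2/s^3) and VPP (W/kg) on a common scale
#' before agreement analysis.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Standardized vector.
#' @export
standardize <- function(values) {
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (values - m) / s
}

#' Evans strength label for a correlation coefficient
#'
#' Bands on the absolute coefficient: 0.00-0.19 very weak, 0.20-0.39 weak,
#' 0.40-0.59 moderate, 0.60-0.79 strong, 0.80-1.00 very strong.
#'
#' @param coefficient Correlation coefficient in [-1, 1] (vectorized).
#' @return Character vector of labels.
#' @export
evans_label <- function(coefficient) {
  a <- abs(coefficient)
  if (any(!is.finite(a)) || any(a > 1 + 1e-12)) {
    stop("coefficients must lie in [-1, 1]")
  }
  cut(pmin(a, 1), breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
      labels = c("very weak", "weak", "moderate", "strong", "very strong"),
      right = FALSE) |> as.character()
}

#' Normality-gated correlation with Evans label
#'
#' Pearson's r is used when both variables pass the Shapiro-Wilk normality
#' test at `alpha`; otherwise Spearman's rank correlation. The significance
#' threshold is 0.05 a priori for all tests; no multiplicity adjustment is
#' applied (each association is tested once at the a-priori level).
#'
#' @param x,y Numeric vectors of equal length >= 4 (pairs with missing values
#'   are dropped first).
#' @param alpha Normality-gate level (default 0.05).
#' @param method Force `"pearson"` or `"spearman"` instead of gating
#'   (default `"auto"`).
#' @return List of class `correlation_result`: `method`, `coefficient`,
#'   `p_value`, `strength_label`, `n`, and the two Shapiro-Wilk p-values.
#' @export
gated_correlation <- function(x, y, alpha = 0.05,
                              method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation with a constant variable is undefined")
  }
  sw <- c(x = shapiro_p(x), y = shapiro_p(y))
  if (method == "auto") {
    method <- if (all(sw > alpha)) "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  structure(list(method = method,
                 coefficient = unname(ct$estimate),
                 p_value = ct$p.value,
                 strength_label = evans_label(unname(ct$estimate)),
                 n = n,
                 shapiro_p = sw),
            class = "correlation_result")
}

shapiro_p <- function(x) {
  # Shapiro-Wilk is undefined for identical values or n outside [3, 5000]
  if (length(unique(x)) < 3L) return(0)
  stats::shapiro.test(x)$p.value
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: %.3f (%s), p = %.4g, n = %d\n",
              x$method, x$coefficient, x$strength_label, x$p_value, x$n))
  invisible(x)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1) (single measures) quantifies agreement between individual
#' standardized RPP and VPP values; ICC(2,k) (average measures) quantifies
#' agreement at trial level. Both follow the two-way random-effects,
#' absolute-agreement convention with F-based 95 percent confidence
#' intervals.
#'
#' @param ratings Numeric matrix or data frame, targets in rows and the k
#'   raters (measurement systems) in columns; at least 5 targets.
#' @param form `"2,1"` (single) or `"2,k"` (average).
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `icc_result`: `form`, `estimate`, `ci95`, mean
#'   squares, `n`, `k`.
#' @export
icc <- function(ratings, form = c("2,1", "2,k"), conf_level = 0.95) {
  form <- match.arg(form)
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  if (n < 5L) stop("need at least 5 targets for the ICC")
  if (k < 2L) stop("need at least 2 raters")
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  sse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (!is.finite(mse)) stop("degenerate mean squares")
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  est <- if (form == "2,1") icc1 else (msr - mse) / (msr + (msc - mse) / n)
  alpha <- 1 - conf_level
  # McGraw & Wong F-based interval for ICC(A,1), Satterthwaite df
  fj <- msc / mse
  a <- k * icc1 / (n * (1 - icc1))
  b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v <- (a * fj + b)^2 /
    (a^2 * fj^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
  f1 <- stats::qf(1 - alpha / 2, n - 1, v)
  f2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi1 <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  ci <- c(lo1, hi1)
  if (form == "2,k") {
    sb <- function(r) k * r / (1 + (k - 1) * r)
    ci <- sb(ci)
  }
  structure(list(form = form, estimate = est, ci95 = ci,
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.3f, 95%% CI [%.3f, %.3f], n = %d targets\n",
              x$form, x$estimate, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Clinical correlation table
#'
#' Applies the normality-gated correlation to every pairing of a trial-level
#' power capacity measure (RP95c and VP95c, per transition type) with a
#' clinical variable (#Reps, ABC, MFIS total and its physical, cognitive and
#' psychosocial sub-scores), reproducing the structure of the clinical
#' validation table.
#'
#' @param summaries Data frame with one row per subject: `subject_id`,
#'   `n_reps`, `rp95c_sist`, `rp95c_stsi`, `vp95c_sist`, `vp95c_stsi`.
#' @param scores Data frame with one row per subject: `subject_id`, `abc`,
#'   `mfis_total`, `mfis_physical`, `mfis_cognitive`, `mfis_psychosocial`
#'   (plus `age`, `gender`, ignored here).
#' @param alpha Significance/normality-gate level (default 0.05).
#' @return Data frame: `measure`, `score`, `method`, `coefficient`,
#'   `p_value`, `strength`, `significant`, `n`.
#' @export
clinical_correlations <- function(summaries, scores, alpha = 0.05) {
  d <- merge(summaries, scores, by = "subject_id")
  if (nrow(d) < 4L) stop("need at least 4 matched subjects")
  measures <- c("rp95c_sist", "rp95c_stsi", "vp95c_sist", "vp95c_stsi")
  clin <- c("n_reps", "abc", "mfis_total", "mfis_physical",
            "mfis_cognitive", "mfis_psychosocial")
  rows <- list()
  for (m in measures) {
    for (s in clin) {
      cr <- gated_correlation(d[[m]], d[[s]], alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, score = s, method = cr$method,
        coefficient = cr$coefficient, p_value = cr$p_value,
        strength = cr$strength_label,
        significant = cr$p_value < alpha, n = cr$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Confounder-screened regression of a clinical score on power capacity
#'
#' Age and gender are included as covariates only when significantly
#' correlated with the outcome (screened with the same normality-gated
#' correlation at `alpha`); the model is then an ordinary least-squares fit
#' of the score on the capacity measure plus the retained confounders.
#'
#' @param data Data frame containing all referenced columns (gender may be a
#'   factor/character; it is coded numerically for screening and fitting).
#' @param y Name of the outcome column (e.g. `"abc"`).
#' @param x Name of the capacity column (e.g. `"rp95c_sist"`).
#' @param candidates Candidate confounder column names (default age, gender).
#' @param alpha Screening level (default 0.05).
#' @return List of class `confounder_regression`: `model` (the `lm` fit),
#'   `retained`, `r_squared`, `coefficients` (matrix with estimates, SEs,
#'   p-values).
#' @export
confounder_regression <- function(data, y, x, candidates = c("age", "gender"),
                                  alpha = 0.05) {
  d <- data
  for (cc in candidates) {
    if (!is.numeric(d[[cc]])) d[[cc]] <- as.numeric(factor(d[[cc]]))
  }
  retained <- character()
  for (cc in candidates) {
    if (stats::sd(d[[cc]]) == 0) next
    cr <- gated_correlation(d[[cc]], d[[y]], alpha = alpha)
    if (cr$p_value < alpha) retained <- c(retained, cc)
  }
  fml <- stats::reformulate(c(x, retained), response = y)
  fit <- stats::lm(fml, data = d)
  if (any(!is.finite(stats::coef(fit)))) stop("collinear design matrix")
  sm <- summary(fit)
  structure(list(model = fit, retained = retained,
                 r_squared = sm$r.squared,
                 coefficients = sm$coefficients),
            class = "confounder_regression")
}

#' @export
print.confounder_regression <- function(x, ...) {
  cat(sprintf("OLS with confounders [%s]: R^2 = %.3f\n",
              paste(x$retained, collapse = ", "), x$r_squared))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' Acute-fatigue analysis over three 10-second windows
#'
#' Each trial is divided into three 10-second periods; the 95th centile of
#' the per-transition peak RP is computed per subject within each period
#' (transitions assigned by their end time). The within-task trend is then
#' assessed two ways: a linear regression of the per-subject per-window
#' RP95c on the window index (with subject intercepts, so the slope is the
#' within-subject change per window), and a two-sided paired t-test of
#' window 1 against window 3. Subjects lacking a transition in any window
#' are excluded (with a message).
#'
#' @param transitions Data frame with columns `subject_id`, `label`, `t_f`,
#'   `rpp` (one row per transition).
#' @param label Transition type to analyze: `"SI-ST"` or `"ST-SI"`.
#' @param task_end_s Task duration in seconds (default 30).
#' @param prob Centile (default 0.95).
#' @return List of class `fatigue_result`: `window_stats` (per-window mean
#'   and SE over subjects), `slope`, `slope_p`, `t_stat`, `t_df`, `t_p`,
#'   `n_subjects`, `excluded`.
#' @export
fatigue_analysis <- function(transitions, label = c("SI-ST", "ST-SI"),
                             task_end_s = 30, prob = 0.95) {
  label <- match.arg(label)
  d <- transitions[transitions$label == label, , drop = FALSE]
  d$window <- assign_window(d$t_f, task_end_s = task_end_s)
  d <- d[!is.na(d$window), , drop = FALSE]
  per <- stats::aggregate(rpp ~ subject_id + window, data = d,
                          FUN = percentile95, prob = prob)
  names(per)[names(per) == "rpp"] <- "rp95c"
  tab <- table(per$subject_id)
  complete <- names(tab)[tab == 3L]
  excluded <- setdiff(unique(as.character(d$subject_id)), complete)
  if (length(excluded) > 0L) {
    message(sprintf("fatigue_analysis: excluding %d subject(s) lacking a %s in some window",
                    length(excluded), label))
  }
  per <- per[as.character(per$subject_id) %in% complete, , drop = FALSE]
  n_sub <- length(complete)
  if (n_sub < 2L) stop("need at least 2 subjects with transitions in all windows")
  per$subject_id <- factor(per$subject_id)
  fit <- stats::lm(rp95c ~ window + subject_id, data = per)
  sm <- summary(fit)$coefficients
  w1 <- per$rp95c[per$window == 1L][order(per$subject_id[per$window == 1L])]
  w3 <- per$rp95c[per$window == 3L][order(per$subject_id[per$window == 3L])]
  tt <- stats::t.test(w1, w3, paired = TRUE, alternative = "two.sided")
  ws <- stats::aggregate(rp95c ~ window, data = per, FUN = function(v) {
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  })
  window_stats <- data.frame(window = ws$window,
                             mean = ws$rp95c[, "mean"],
                             se = ws$rp95c[, "se"])
  structure(list(window_stats = window_stats,
                 slope = sm["window", "Estimate"],
                 slope_se = sm["window", "Std. Error"],
                 slope_p = sm["window", "Pr(>|t|)"],
                 t_stat = unname(tt$statistic),
                 t_df = unname(tt$parameter),
                 t_p = tt$p.value,
                 n_subjects = n_sub,
                 excluded = excluded),
            class = "fatigue_result")
}

#' @export
print.fatigue_result <- function(x, ...) {
  cat(sprintf("fatigue trend: slope %.4g per window (p = %.4g); paired t(%d) = %.3f, p = %.4g; %d subjects\n",
              x$slope, x$slope_p, x$t_df, x$t_stat, x$t_p, x$n_subjects))
  invisible(x)
}
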