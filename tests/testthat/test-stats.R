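test_that("95th centile uses linear interpolation between order statistics", {
  expect_equal(percentile95(7), 7)
  expect_equal(percentile95(1:100), 95.05)
  set.seed(2)
  for (i in 1:10) {
    v <- rlnorm(sample(3:40, 1))
    p <- percentile95(v)
    expect_gte(p, min(v)); expect_lte(p, max(v))
  }
  expect_error(percentile95(numeric(0)), "empty")
})

test_that("standardization is population-scaled and affine invariant", {
  s <- standardize(c(1, 2, 3))
  expect_equal(mean(s), 0)
  expect_equal(mean(s^2), 1)  # population variance
  set.seed(4)
  x <- rnorm(20)
  expect_equal(standardize(3.2 * x - 7), standardize(x), tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "constant")
})

test_that("Evans labels match the published band examples", {
  expect_equal(evans_label(0.79), "strong")
  expect_equal(evans_label(0.83), "very strong")
  expect_equal(evans_label(0.59), "moderate")
  expect_equal(evans_label(c(-0.1, 0.2, -0.39, 0.4, 0.6, -1)),
               c("very weak", "weak", "weak", "moderate", "strong",
                 "very strong"))
  expect_error(evans_label(1.2), "\\[-1, 1\\]")
})

test_that("the normality gate selects Pearson or Spearman correctly", {
  set.seed(10)
  x <- rnorm(30)
  r1 <- gated_correlation(x, 2 * x + 1)
  expect_equal(r1$method, "pearson")
  expect_equal(r1$coefficient, 1, tolerance = 1e-12)

  # monotone but heavily non-normal: Spearman, rho = 1
  r2 <- gated_correlation(x, exp(4 * x))
  expect_equal(r2$method, "spearman")
  expect_equal(r2$coefficient, 1, tolerance = 1e-12)

  # forced Pearson equals the textbook covariance formula; Spearman equals
  # Pearson on ranks
  y <- rnorm(30)
  rp <- gated_correlation(x, y, method = "pearson")
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rp$coefficient, manual, tolerance = 1e-12)
  rs <- gated_correlation(x, y, method = "spearman")
  rr <- gated_correlation(rank(x), rank(y), method = "pearson")
  expect_equal(rs$coefficient, rr$coefficient, tolerance = 1e-12)

  expect_error(gated_correlation(rep(1, 10), rnorm(10)), "constant")
})

test_that("independent Gaussian pairs at n = 17 are rarely significant", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    r <- gated_correlation(rnorm(17), rnorm(17))
    r$p_value > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ICC matches the two-way ANOVA oracle and its known identities", {
  set.seed(21)
  x <- cbind(rnorm(6), rnorm(6))
  x[, 2] <- x[, 1] + 0.3 * x[, 2]
  for (form in c("2,1", "2,k")) {
    expect_equal(icc(x, form)$estimate, icc_aov_oracle(x, form),
                 tolerance = 1e-9)
  }

  # identical columns agree perfectly
  y <- cbind(rnorm(8), 0)
  y[, 2] <- y[, 1]
  expect_equal(icc(y, "2,1")$estimate, 1, tolerance = 1e-9)
  expect_equal(icc(y, "2,k")$estimate, 1, tolerance = 1e-9)

  # property sweep: random 5-20 target tables match the oracle; the
  # average-measure form dominates the single-measure form when positive
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:20, 1)
    tab <- matrix(rnorm(2 * n), n, 2) +
      matrix(rep(rnorm(n, sd = runif(1, 0, 2)), 2), n, 2)
    i1 <- icc(tab, "2,1"); ik <- icc(tab, "2,k")
    expect_equal(i1$estimate, icc_aov_oracle(tab, "2,1"), tolerance = 1e-9)
    expect_equal(ik$estimate, icc_aov_oracle(tab, "2,k"), tolerance = 1e-9)
    if (i1$estimate >= 0) expect_gte(ik$estimate, i1$estimate - 1e-12)
    expect_lte(i1$ci95[1], i1$estimate + 1e-9)
    expect_gte(i1$ci95[2], i1$estimate - 1e-9)
  }

  # null tables: |ICC| small in most seeds
  small <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    abs(icc(matrix(rnorm(100), 50, 2), "2,1")$estimate) < 0.3
  }, logical(1))
  expect_gte(mean(small), 0.9)
})

test_that("the clinical correlation table has the expected structure and nulls", {
  co <- simulate_cohort(sim_config(seed = 5))
  tab <- clinical_correlations(co$summaries, co$scores)
  expect_equal(nrow(tab), 4 * 6)
  expect_true(all(abs(tab$coefficient) <= 1))

  # capacity drives power up and fatigue impact down
  mf <- tab[tab$measure == "rp95c_sist" & tab$score == "mfis_total", ]
  expect_lt(mf$coefficient, 0)
  expect_true(mf$significant)

  # a measure against itself would be 1: sanity of the gating path
  self <- gated_correlation(co$summaries$rp95c_sist, co$summaries$rp95c_sist)
  expect_equal(self$coefficient, 1, tolerance = 1e-12)

  # shuffled scores are rarely significant
  null_ok <- vapply(1:25, function(s) {
    set.seed(s)
    sc <- co$scores
    sc$mfis_total <- sample(sc$mfis_total)
    t2 <- clinical_correlations(co$summaries, sc)
    cell <- t2[t2$measure == "rp95c_sist" & t2$score == "mfis_total", ]
    !cell$significant
  }, logical(1))
  expect_gte(mean(null_ok), 0.8)
})

test_that("confounder screening keeps only correlated covariates", {
  set.seed(30)
  n <- 40
  d <- data.frame(x = rnorm(n), age = rnorm(n, 45, 10),
                  gender = sample(c("F", "M"), n, replace = TRUE))
  # y exactly linear in x: no confounder retained, R^2 = 1
  d$y <- 2 * d$x + 1
  fit <- suppressWarnings(confounder_regression(d, "y", "x"))
  expect_equal(fit$retained, character(0))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # y depends on x and age: age retained, both coefficients within 2 SE
  d$y <- d$x + 0.5 * d$age + rnorm(n, 0, 0.5)
  fit2 <- confounder_regression(d, "y", "x")
  expect_true("age" %in% fit2$retained)
  cf <- fit2$coefficients
  expect_lt(abs(cf["x", "Estimate"] - 1), 2 * cf["x", "Std. Error"])
  expect_lt(abs(cf["age", "Estimate"] - 0.5), 2 * cf["age", "Std. Error"])
})

test_that("fatigue analysis assigns windows and reports paired-test df", {
  co <- simulate_cohort(sim_config(seed = 9))
  fr <- suppressMessages(fatigue_analysis(co$transitions, "SI-ST"))
  expect_equal(fr$t_df, fr$n_subjects - 1)
  expect_equal(nrow(fr$window_stats), 3)

  # decay 5%/rep: clearly negative within-task slope
  expect_lt(fr$slope, 0)
  expect_lt(fr$slope_p, 0.05)

  # no decay: slope within 2 SE of zero for a typical seed
  co0 <- simulate_cohort(sim_config(seed = 9, fatigue_decay = 0))
  fr0 <- suppressMessages(fatigue_analysis(co0$transitions, "SI-ST"))
  expect_lt(abs(fr0$slope), 3 * fr0$slope_se)
})
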