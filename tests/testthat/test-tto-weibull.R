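test_that("time-to-onset handles precision, order and same-day rules", {
  r <- compute_tto("20200104", "20200101")
  expect_equal(r$days, 3)
  expect_true(is.na(r$reason))

  expect_equal(compute_tto("20191231", "20200101")$reason,
               "event_before_start")
  expect_equal(compute_tto("20200104", "202001")$reason, "partial_precision")
  expect_equal(compute_tto("202001", "20200101")$reason, "partial_precision")
  expect_equal(compute_tto("", "20200101")$reason, "missing_date")
  expect_equal(compute_tto("20201340", "20200101")$reason, "invalid_date")
  # same-day onset retained as half a day for the likelihood
  expect_equal(compute_tto("20200101", "20200101")$days, 0.5)
})

test_that("TTO sample accounting reconciles exclusions with candidates", {
  demo <- demo_df(as.character(1:6),
                  event_dt = c("20200110", "20200110", "202001",
                               "", "20200110", "20200110"))
  drug <- drug_df(as.character(1:6), "X")
  reac <- reac_df(as.character(1:6), "CONSTIPATION")
  ther <- ther_df(as.character(1:6),
                  c("20200101", "20200120", "20200101", "20200101",
                    "20200101", ""))
  ds <- build_event_dataset(list(DEMO = demo, DRUG = drug, REAC = reac,
                                 THER = ther))
  s <- tto_sample(ds, "X")
  expect_equal(s$n_candidates, 6L)
  expect_equal(length(s$values) + sum(s$n_excluded_by_reason), 6L)
  expect_equal(unname(s$n_excluded_by_reason["event_before_start"]), 1L)
  expect_equal(unname(s$n_excluded_by_reason["partial_precision"]), 1L)
  expect_equal(unname(s$n_excluded_by_reason["missing_date"]), 2L)
  expect_equal(sort(s$values), c(9, 9))
})

test_that("TTO summary uses interpolated quartiles, same-day as zero", {
  s <- tto_summary(c(1, 2, 3, 4, 5))
  expect_equal(c(s$q1, s$median, s$q3), c(2, 3, 4))
  expect_equal(tto_summary(c(2, 3, 9))$median, 3)
  # quantile type 7 interpolation on [2,3,9]: q1 = 2.5, q3 = 6
  expect_equal(tto_summary(c(2, 3, 9))$q1, 2.5)
  expect_equal(tto_summary(c(2, 3, 9))$q3, 6)
  expect_equal(tto_summary(c(0.5, 0.5, 4))$median, 0)
  expect_error(tto_summary(numeric(0)), "empty")
})

test_that("Weibull MLE recovers simulated parameters", {
  set.seed(501)
  x <- rweibull(5000, shape = 0.6, scale = 50)
  fit <- weibull_fit(x)
  expect_lt(abs(fit$alpha / 50 - 1), 0.05)
  expect_lt(abs(fit$beta / 0.6 - 1), 0.05)
  expect_true(fit$alpha_lo < 50 && 50 < fit$alpha_hi)
  expect_true(fit$beta_lo < 0.6 && 0.6 < fit$beta_hi)
  expect_true(fit$alpha_lo <= fit$alpha && fit$alpha <= fit$alpha_hi)
  expect_true(fit$beta_lo <= fit$beta && fit$beta <= fit$beta_hi)
})

test_that("Weibull MLE matches an independent optimizer", {
  set.seed(502)
  x <- rweibull(800, shape = 0.7, scale = 30)
  fit <- weibull_fit(x)
  ref <- fitdistrplus::fitdist(x, "weibull")
  # fitdistrplus stops at optim's looser likelihood tolerance
  expect_equal(fit$beta, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$alpha, unname(ref$estimate["scale"]), tolerance = 1e-3)
})

test_that("exponential data give shape CI covering 1 and median alpha*ln 2", {
  set.seed(503)
  x <- rexp(4000, rate = 1 / 40) # Weibull(shape 1, scale 40)
  fit <- weibull_fit(x)
  expect_true(fit$beta_lo < 1 && 1 < fit$beta_hi)
  expect_equal(fit$alpha * log(2), median(x), tolerance = 0.1)
  expect_equal(classify_failure(fit$beta, fit$beta_lo, fit$beta_hi),
               "random")
})

test_that("degenerate and invalid samples error", {
  expect_error(weibull_fit(c(1, 1, 1)), "identical")
  expect_error(weibull_fit(c(1, 2)), "at least 3")
  expect_error(weibull_fit(c(0, 1, 2)), "positive")
})

test_that("Weibull MLE is scale-equivariant", {
  set.seed(504)
  x <- rweibull(300, shape = 0.8, scale = 20)
  f1 <- weibull_fit(x)
  f2 <- weibull_fit(x * 7)
  expect_equal(f2$alpha, 7 * f1$alpha, tolerance = 1e-7)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-7)
})

test_that("Wald CIs achieve near-nominal coverage", {
  set.seed(505)
  reps <- 200
  cover_a <- logical(reps)
  cover_b <- logical(reps)
  for (i in seq_len(reps)) {
    x <- rweibull(500, shape = 0.6, scale = 50)
    fit <- weibull_fit(x)
    cover_a[i] <- fit$alpha_lo < 50 && 50 < fit$alpha_hi
    cover_b[i] <- fit$beta_lo < 0.6 && 0.6 < fit$beta_hi
  }
  expect_gte(mean(cover_a), 0.90)
  expect_lte(mean(cover_a), 0.99)
  expect_gte(mean(cover_b), 0.90)
  expect_lte(mean(cover_b), 0.99)
})

test_that("constant-hazard truth is classified 'random' most of the time", {
  set.seed(506)
  cls <- replicate(50, {
    x <- rexp(1000, rate = 1 / 30)
    fit <- weibull_fit(x)
    classify_failure(fit$beta, fit$beta_lo, fit$beta_hi)
  })
  expect_gte(mean(cls == "random"), 0.8)
})

test_that("failure classification follows the CI position", {
  expect_equal(classify_failure(0.55, 0.52, 0.59), "early")
  expect_equal(classify_failure(1.00, 0.9, 1.1), "random")
  expect_equal(classify_failure(1.4, 1.2, 1.6), "wear-out")
  expect_equal(classify_failure(NA, NA, NA), "indeterminate")
})

test_that("bootstrap CIs are reproducible and bracket the estimate", {
  set.seed(507)
  x <- rweibull(60, shape = 0.6, scale = 20)
  f1 <- weibull_fit(x, ci = "bootstrap", boot_n = 200, seed = 9)
  f2 <- weibull_fit(x, ci = "bootstrap", boot_n = 200, seed = 9)
  expect_identical(f1[c("beta_lo", "beta_hi")], f2[c("beta_lo", "beta_hi")])
  expect_true(f1$beta_lo < f1$beta && f1$beta < f1$beta_hi)
})
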