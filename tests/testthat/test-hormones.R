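test_that("4PL fitting recovers noise-free standards exactly", {
  st <- make_standards()
  cal <- fit_4pl(st)
  expect_equal(cal$a, 0.1, tolerance = 1e-4)
  expect_equal(cal$b, 1.0, tolerance = 1e-4)
  expect_equal(cal$c, 5.0, tolerance = 1e-4)
  expect_equal(cal$d, 2.0, tolerance = 1e-4)
  # inflection identity: y(c) = (a + d) / 2
  expect_equal(forward_4pl(cal, cal$c), (cal$a + cal$d) / 2, tolerance = 1e-8)
  expect_error(fit_4pl(make_standards(conc = c(1, 2, 5, 10))), "at least 5")
  bad <- make_standards()
  bad$od[3] <- bad$od[5]  # break monotonicity
  expect_error(fit_4pl(bad), "monotone")
})

test_that("4PL inversion is the algebraic inverse", {
  cal <- fit_4pl(make_standards())
  expect_equal(invert_4pl(cal, 1.05), 5.0, tolerance = 1e-6)
  x <- c(0.7, 1.3, 4.9, 12, 33)
  expect_equal(invert_4pl(cal, forward_4pl(cal, x)), x, tolerance = 1e-9)
  expect_error(invert_4pl(cal, cal$d), "range")
  expect_error(invert_4pl(cal, cal$a - 0.01), "range")
})

test_that("beta-tail filter excludes exactly a planted extreme baseline", {
  # the planted value sits far below the 0.0005 tail even after the fitted
  # distribution adapts to its presence (MLE contamination fattens the
  # tail, so the plant must be deep in it; see the methods vignette)
  planted <- qbeta(1e-12, 2, 5)
  set.seed(31)
  vals <- rbeta(19, 2, 5)
  res <- beta_outlier_filter(c(vals, planted))
  expect_equal(res$excluded, 20L)
  expect_equal(length(res$kept), 19L)
  expect_lt(res$tail_probs[20], 5e-4)
  # well-behaved samples are all kept
  res2 <- beta_outlier_filter(vals)
  expect_equal(length(res2$excluded), 0L)
  # recovery holds across the seeded replicate set, not just one draw
  hit <- vapply(1:40, function(s) {
    set.seed(s)
    identical(beta_outlier_filter(c(rbeta(19, 2, 5), planted))$excluded, 20L)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("beta-tail filter rarely excludes on-model data", {
  # on data truly from the family, P(no exclusion) >= (1 - 2 * 5e-4)^18
  set.seed(77)
  clean <- vapply(1:200, function(i) {
    length(beta_outlier_filter(rbeta(18, 2, 5))$excluded) == 0
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})

test_that("log-ratio test handles identities and hand values", {
  mk <- function(rat, condition, pre, post)
    data.frame(rat = rat, condition = condition, phase = c("pre", "post"),
               value = c(pre, post))
  eq <- do.call(rbind, c(lapply(1:4, function(i) mk(i, "control", 5, 5)),
                         lapply(5:8, function(i) mk(i, "active", 3, 3))))
  res <- post_pre_log_ratio_test(eq)
  expect_equal(res$test$statistic, 0)
  expect_true(all(res$ratios$log_ratio == 0))
  one <- mk(1, "active", 4, 2)
  expect_equal(log(one$value[2] / one$value[1]), -0.6931472,
               tolerance = 1e-6)
  # two-day averaging precedes ratio formation
  two <- rbind(data.frame(rat = 1, condition = "active", phase = "pre",
                          value = c(2, 4), day = 1:2),
               data.frame(rat = 1, condition = "active", phase = "post",
                          value = c(6, 6), day = 1:2),
               do.call(rbind, lapply(2:4, function(i)
                 data.frame(rat = i,
                            condition = if (i == 2) "active" else "control",
                            phase = c("pre", "post"), value = c(3, 3),
                            day = 1))))
  res2 <- post_pre_log_ratio_test(two)
  expect_equal(res2$ratios$ratio[res2$ratios$rat == 1], 2)  # 6 / mean(2, 4)
  neg <- mk(1, "active", 4, -1)
  expect_error(post_pre_log_ratio_test(rbind(eq, neg)), "rat")
})

test_that("log-ratio test is invariant to rescaling all concentrations", {
  set.seed(13)
  df <- do.call(rbind, lapply(1:12, function(i)
    data.frame(rat = i, condition = if (i <= 6) "control" else "active",
               phase = c("pre", "post"),
               value = rlnorm(2, log(50), 0.3))))
  t1 <- post_pre_log_ratio_test(df)$test$statistic
  df2 <- df; df2$value <- df2$value * 123.4
  expect_equal(post_pre_log_ratio_test(df2)$test$statistic, t1,
               tolerance = 1e-9)
})

test_that("suppressed active-group ratios yield negative t in most cohorts", {
  # generator: active geometric-mean ratio 0.7, control 1.0, sigma 0.3, 9/9
  stats <- vapply(1:100, function(s) {
    set.seed(s)
    df <- do.call(rbind, lapply(1:18, function(i) {
      eff <- if (i <= 9) 1.0 else 0.7
      pre <- rlnorm(1, log(100), 0.4)
      data.frame(rat = i, condition = if (i <= 9) "control" else "active",
                 phase = c("pre", "post"),
                 value = c(pre, pre * eff * rlnorm(1, 0, 0.3)))
    }))
    post_pre_log_ratio_test(df)$test$statistic
  }, numeric(1))
  expect_lt(mean(stats), 0)
  expect_gt(mean(stats <= -2), 0.5)
})
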