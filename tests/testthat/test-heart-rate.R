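ramp_trace <- function(gap_at = NULL) {
  times <- 0:400
  bpm <- 300 + 60 * times / 400
  if (!is.null(gap_at)) bpm[gap_at] <- NA
  hr_trace(times, bpm, stim_window = c(300, 360))
}

test_that("imputation is the identity on gap-free traces and idempotent", {
  tr <- ramp_trace()
  expect_equal(impute_gaps(tr)$bpm, tr$bpm)
  gap <- ramp_trace(gap_at = 150:169)
  once <- impute_gaps(gap)
  expect_equal(attr(once, "n_imputed"), 20L)
  expect_equal(impute_gaps(once)$bpm, once$bpm)
  # observed samples never change
  obs <- !is.na(gap$bpm)
  expect_equal(once$bpm[obs], gap$bpm[obs])
})

test_that("Kalman smoothing fills a ramp gap close to linear interpolation", {
  gap <- ramp_trace(gap_at = 150:169)
  fill <- impute_gaps(gap)$bpm[150:169]
  lin <- approx(c(149, 170), c(gap$bpm[149], gap$bpm[170]), xout = 150:169)$y
  expect_lt(max(abs(fill - lin)), 2)
})

test_that("unimputable traces are rejected", {
  times <- 0:400
  bpm <- rep(350, 401)
  bpm[1:250] <- NA
  bpm[1] <- 350
  expect_error(impute_gaps(hr_trace(times, bpm, c(300, 360))), "50%")
  bpm2 <- rep(350, 401)
  bpm2[1:11] <- NA
  expect_error(impute_gaps(hr_trace(times, bpm2, c(300, 360))),
               "first or last")
})

test_that("baseline scaling normalizes the pre-stimulation mean to 1", {
  tr <- hr_trace(0:400, rep(360, 401), c(300, 360))
  sc <- scale_baseline(tr)
  expect_equal(sc$values, rep(1, 401))
  expect_equal(sc$baseline_bpm, 360)
  tr2 <- hr_trace(0:400, c(rep(300, 300), rep(330, 101)), c(300, 360))
  sc2 <- scale_baseline(tr2)
  expect_equal(mean(sc2$values[tr2$times < 300]), 1, tolerance = 1e-9)
  expect_equal(sc2$values[302], 1.1)
})

test_that("session averaging is pointwise", {
  tr <- hr_trace(0:400, rep(300, 401), c(300, 360))
  a <- scale_baseline(tr)
  expect_equal(average_sessions(list(a))$values, a$values)
  lo <- a; lo$values <- rep(0.9, 401)
  hi <- a; hi$values <- rep(1.1, 401)
  expect_equal(average_sessions(list(lo, hi))$values, rep(1, 401))
  short <- a; short$times <- 0:100; short$values <- rep(1, 101)
  expect_error(average_sessions(list(a, short)), "mismatched")
})

test_that("stimulation AUC uses an inclusive 300-360 s window", {
  tr <- hr_trace(0:400, rep(1, 401) * 300, c(300, 360))
  sc <- scale_baseline(tr)  # all values 1
  res <- auc_window(sc)
  expect_equal(res$auc, 61)
  expect_equal(res$n_samples, 61)
  # all-zero values sum to zero
  z <- sc; z$values <- rep(0, 401)
  expect_equal(auc_window(z)$auc, 0)
  # linear 0 -> 1 ramp across the window: arithmetic series sum 30.5
  r <- sc; r$values <- rep(0, 401)
  r$values[301:361] <- seq(0, 1, length.out = 61)
  expect_equal(auc_window(r)$auc, 30.5)
  expect_error(auc_window(sc, window = c(500, 600)), "empty")
})

test_that("AUC comparison recovers group means and is scale invariant", {
  set.seed(21)
  n <- 200
  df <- data.frame(auc = c(rgamma(n, shape = 100, rate = 100 / 60),
                           rgamma(n, shape = 100, rate = 100 / 66)),
                   condition = rep(c("control", "active"), each = n))
  fit <- compare_auc(df)
  expect_lt(abs(fit$group_means["control"] / 60 - 1), 0.02)
  expect_lt(abs(fit$group_means["active"] / 66 - 1), 0.02)
  # identity-link coefficient scales with the data, t does not
  df2 <- df; df2$auc <- df2$auc * 3.7
  fit2 <- compare_auc(df2)
  expect_equal(unname(fit2$coefficients[2]), 3.7 * unname(fit$coefficients[2]),
               tolerance = 1e-8)
  expect_equal(unname(fit2$t[2]), unname(fit$t[2]), tolerance = 1e-6)
  # identical groups: coefficient ~ 0
  df3 <- data.frame(auc = rep(c(55, 60, 65), 2),
                    condition = rep(c("control", "active"), each = 3))
  expect_lt(abs(fit_gamma_glm_identity(
    df3$auc, cbind(1, df3$condition == "active"))$coefficients[2]), 1e-8)
  expect_error(compare_auc(data.frame(auc = c(1, 2),
                                      condition = c("active", "active"))),
               "both conditions")
  expect_error(compare_auc(data.frame(auc = c(1, -2),
                                      condition = c("active", "control"))),
               "positive")
})

test_that("generator-encoded HR rises are detected in active rats", {
  hits <- vapply(1:20, function(s) {
    cfg <- cohort_config(n_per_condition = 20, seed = s,
                         hr = list(gap_rate = 0))
    set.seed(s)
    aucs <- c(lapply(1:20, function(i)
      auc_window(scale_baseline(gen_heart_rate(cfg, i, "control", 1)))),
      lapply(1:20, function(i)
        auc_window(scale_baseline(gen_heart_rate(cfg, i, "active", 1)))))
    df <- data.frame(auc = sapply(aucs, `[[`, "auc"),
                     condition = rep(c("control", "active"), each = 20))
    unname(compare_auc(df)$coefficients[2]) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
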