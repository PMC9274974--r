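make_rat <- function(rat = "r1", condition = "control",
                     hab = c(0.02, 0.03, 0.05, 0.04, 0.06),
                     cond = seq(0.1, 0.7, length.out = 7),
                     ext = seq(0.7, 0.2, length.out = 20),
                     rec = c(0.25, 0.2, 0.22)) {
  ph <- freezing_phases()
  data.frame(rat = rat, condition = condition,
             phase = rep(names(ph), ph),
             trial = unlist(lapply(ph, seq_len)),
             fraction = c(hab, cond, ext, rec))
}

test_that("min-max normalization and baseline scaling follow the chain", {
  df <- rbind(make_rat("r1"), make_rat("r2", "active"))
  nm <- normalize_chain(df)
  # [0, 50, 100] % pattern -> [0, 0.5, 1]
  r <- make_rat("r3", hab = c(0, 0.25, 0.5, 0.75, 1),
                cond = c(0, 0.5, 1, 0, 0.5, 1, 0.5))
  nm3 <- normalize_chain(rbind(df, r))
  got <- nm3$normalized[nm3$rat == "r3" & nm3$phase == "conditioning"]
  expect_equal(got, c(0, 0.5, 1, 0, 0.5, 1, 0.5))
  # baseline = mean of normalized habituation trials 3-5; scaled = norm / base
  hab3 <- nm3[nm3$rat == "r3" & nm3$phase == "habituation", ]
  base <- mean(hab3$normalized[hab3$trial %in% 3:5])
  ext3 <- nm3[nm3$rat == "r3" & nm3$phase == "extinction", ]
  expect_equal(ext3$scaled, pmin(1, ext3$normalized / base))
  # compressed values live strictly inside (0, 1)
  expect_true(all(nm$compressed > 0 & nm$compressed < 1))
})

test_that("chain is invariant to affine transforms of a phase's raw values", {
  df <- rbind(make_rat("r1"), make_rat("r2", "active"))
  df2 <- df
  sel <- df2$rat == "r1" & df2$phase == "extinction"
  df2$fraction[sel] <- 0.3 * df2$fraction[sel] + 0.2
  expect_equal(normalize_chain(df2)$normalized, normalize_chain(df)$normalized)
})

test_that("centered moving average shrinks windows at the ends", {
  ma <- magnetoadrenal:::moving_average3
  expect_equal(ma(c(0, 0.3, 0.6, 0.9)), c(0.15, 0.3, 0.6, 0.75))
  expect_equal(ma(c(1, 1, 1)), c(1, 1, 1))
  # smoothing preserves the per-phase mean within 1/n
  set.seed(2)
  x <- runif(20)
  expect_lt(abs(mean(ma(x)) - mean(x)), 1 / 20)
})

test_that("flat phases map to 0.5 and are flagged", {
  df <- rbind(make_rat("r1"), make_rat("r2", "active", rec = c(0.3, 0.3, 0.3)))
  nm <- normalize_chain(df)
  expect_equal(nm$normalized[nm$rat == "r2" & nm$phase == "recall"],
               rep(0.5, 3))
  expect_true(any(grepl("r2 recall", attr(nm, "flat_phases"))))
})

test_that("non-conditioner detection uses the acquisition gap rule", {
  flat <- make_rat("f", hab = rep(0.05, 5), cond = rep(0.05, 7))
  hot <- make_rat("h", hab = rep(0.05, 5),
                  cond = c(0.1, 0.2, 0.4, 0.5, 0.6, 0.6, 0.6))
  # exactly at the 0.10 threshold counts as conditioned (>= rule)
  edge <- make_rat("e", hab = rep(0.10, 5), cond = rep(0.20, 7))
  cc <- detect_nonconditioners(rbind(flat, hot, edge))
  expect_false(cc$conditioned[cc$rat == "f"])
  expect_true(cc$conditioned[cc$rat == "h"])
  expect_true(cc$conditioned[cc$rat == "e"])
})

test_that("generated non-acquirers are exactly the ones excluded", {
  for (s in 1:5) {
    cfg <- cohort_config(n_per_condition = 8, seed = s,
                         freezing = list(nonacquirer_fraction = 0.3))
    set.seed(s)
    recs <- lapply(1:16, function(i)
      gen_freezing(cfg, sprintf("r%02d", i),
                   if (i <= 8) "control" else "active"))
    truth <- vapply(recs, attr, logical(1), "nonacquirer")
    cc <- detect_nonconditioners(do.call(rbind, recs))
    expect_equal(!cc$conditioned, truth)
  }
})

test_that("freezing model design carries all interactions and rat duplication invariance", {
  df <- make_freezing_cohort(n_per = 5, seed = 4, nonacquirer_fraction = 0)
  nm <- normalize_chain(df)
  fit <- fit_freezing_model(nm)
  X <- attr(fit, "design")
  expect_equal(ncol(X), 16)  # 1 + trial + 3 phase + treat + interactions
  expect_true(fit$converged)
  # duplicating every rat leaves estimates unchanged, shrinks SEs
  dup <- nm
  dup$rat <- paste0(dup$rat, "_b")
  both <- rbind(nm, dup)
  fit2 <- fit_freezing_model(both)
  expect_equal(unname(fit2$coefficients), unname(fit$coefficients),
               tolerance = 1e-3)
  expect_true(all(fit2$se < fit$se + 1e-9))
})

test_that("faster active extinction yields a negative treatment x trial slope", {
  # control lambda 0.08 doubled in active rats: initial-slope difference
  # 0.063 per trial, and neither curve floors out within the 20 trials
  # (a linear trial:treatment summary of exponential decay reverses sign
  # once the faster curve spends most of the window at its floor)
  hits <- vapply(1:15, function(s) {
    df <- make_freezing_cohort(n_per = 12, seed = 100 + s,
                               lambda = 0.08, treatment_modifier = 2.0,
                               nonacquirer_fraction = 0)
    nm <- normalize_chain(df)
    fit <- fit_freezing_model(nm)
    b <- fit$coefficients
    # extinction-specific treatment trial slope
    unname(b["trial:treatmentactive"] +
             b["trial:phaseextinction:treatmentactive"]) < 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("extinction endpoint test reproduces hand-computed Welch values", {
  ph <- freezing_phases()
  mk <- function(rat, condition, endvals) {
    d <- make_rat(rat, condition)
    d$smoothed <- d$fraction
    d$smoothed[d$phase == "extinction" & d$trial %in% 18:20] <- endvals
    d
  }
  # per-rat endpoint means {0.2, 0.3, 0.4} vs {0.5, 0.6, 0.7}
  cohort <- rbind(mk("a1", "active", rep(0.2, 3)),
                  mk("a2", "active", rep(0.3, 3)),
                  mk("a3", "active", rep(0.4, 3)),
                  mk("c1", "control", rep(0.5, 3)),
                  mk("c2", "control", rep(0.6, 3)),
                  mk("c3", "control", rep(0.7, 3)))
  res <- extinction_endpoint_test(cohort)
  expect_equal(res$test$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(res$test$df, 4, tolerance = 1e-6)
  expect_equal(res$test$variant, "welch")
  # identical cohorts give t = 0
  same <- rbind(mk("a1", "active", rep(0.3, 3)),
                mk("a2", "active", rep(0.4, 3)),
                mk("c1", "control", rep(0.3, 3)),
                mk("c2", "control", rep(0.4, 3)))
  expect_equal(extinction_endpoint_test(same)$test$statistic, 0)
  # Welch df goes fractional when variances differ
  uneq <- rbind(mk("a1", "active", rep(0.2, 3)),
                mk("a2", "active", rep(0.7, 3)),
                mk("a3", "active", rep(0.4, 3)),
                mk("c1", "control", rep(0.50, 3)),
                mk("c2", "control", rep(0.52, 3)),
                mk("c3", "control", rep(0.54, 3)))
  df_w <- extinction_endpoint_test(uneq)$test$df
  expect_gt(abs(df_w - round(df_w)), 1e-6)
  # missing endpoint trials are rejected with the rat named
  broken <- cohort[!(cohort$rat == "a1" & cohort$phase == "extinction" &
                       cohort$trial == 19), ]
  expect_error(extinction_endpoint_test(broken), "a1")
})
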