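#' Heart-rate trace with a stimulation window
#'
#' Uniformly sampled heart-rate record (default 1 Hz) with `NA` marking
#' gaps from pulse-oximeter signal loss, and the stimulation window in
#' seconds. The standard session layout is 0-300 s pre-stimulation,
#' 300-360 s stimulation, then a post window.
#'
#' @param times Sample times in s, uniformly spaced.
#' @param bpm Heart rate in beats/min; `NA` = missing.
#' @param stim_window Two-element `[start, end]` in s (default `c(300, 360)`).
#' @param rat,day,condition Optional identifiers (`condition` is `"active"`
#'   or `"control"`).
#' @return An object of class `hr_trace`.
#' @export
hr_trace <- function(times, bpm, stim_window = c(300, 360), rat = NA,
                     day = NA, condition = NA) {
  stopifnot(length(times) == length(bpm), length(stim_window) == 2)
  d <- diff(times)
  if (length(d) && max(abs(d - d[1])) > 1e-6)
    stop("times must be uniformly spaced")
  if (stim_window[1] < min(times) || stim_window[2] > max(times))
    stop("stimulation window must lie within the record")
  if (any(bpm <= 0, na.rm = TRUE)) stop("bpm must be positive where present")
  structure(list(times = times, bpm = bpm, stim_window = stim_window,
                 rat = rat, day = day, condition = condition),
            class = "hr_trace")
}

#' Impute heart-rate gaps by Kalman smoothing
#'
#' Fills missing samples with the fixed-interval smoother of a local-level
#' Gaussian state-space model whose level and observation variances are
#' fitted by maximum likelihood ([stats::StructTS()] type `"level"`, then
#' [stats::tsSmooth()]). Observed values are left untouched. Traces with
#' more than 50% missing samples, or with no observation in the first or
#' last 10 s, are rejected as unimputable.
#'
#' @param trace An `hr_trace`.
#' @return The trace with `NA`s replaced; attribute `n_imputed` records how
#'   many samples were filled.
#' @export
impute_gaps <- function(trace) {
  y <- trace$bpm
  miss <- is.na(y)
  if (!any(miss)) {
    attr(trace, "n_imputed") <- 0L
    return(trace)
  }
  if (all(miss) || mean(miss) > 0.5)
    stop("unable to impute: more than 50% of samples are missing")
  dt <- diff(trace$times)[1]
  k <- max(1L, ceiling(10 / dt))
  if (all(miss[seq_len(k)]) || all(miss[seq(length(y) - k + 1, length(y))]))
    stop("unable to impute: no observations in the first or last 10 s")
  sm <- tryCatch({
    fit <- StructTS(ts(y), type = "level")
    as.numeric(tsSmooth(fit)[, 1])
  }, error = function(e) NULL)
  if (is.null(sm)) {
    # degenerate ML fit (e.g. near-constant trace): fall back to the same
    # smoother limit, which is linear interpolation of the level
    sm <- approx(trace$times[!miss], y[!miss], xout = trace$times,
                 rule = 2)$y
  }
  y[miss] <- sm[miss]
  trace$bpm <- y
  attr(trace, "n_imputed") <- sum(miss)
  trace
}

#' Scale a trace to its pre-stimulation baseline
#'
#' Divides every sample by the mean heart rate over `[0, stim start)`,
#' giving a dimensionless ratio-to-baseline trace whose pre-stimulation
#' mean is 1.
#'
#' @param trace A gap-free `hr_trace` (run [impute_gaps()] first).
#' @return An object of class `scaled_hr_trace` with `values` (ratios) and
#'   `baseline_bpm`.
#' @export
scale_baseline <- function(trace) {
  if (any(is.na(trace$bpm))) stop("trace contains missing values; impute first")
  pre <- trace$times < trace$stim_window[1]
  if (!any(pre)) stop("empty pre-stimulation segment")
  baseline <- mean(trace$bpm[pre])
  if (baseline <= 0) stop("non-positive baseline")
  structure(list(times = trace$times, values = trace$bpm / baseline,
                 baseline_bpm = baseline, stim_window = trace$stim_window,
                 rat = trace$rat, day = trace$day,
                 condition = trace$condition),
            class = "scaled_hr_trace")
}

#' Average scaled traces across sessions
#'
#' Pointwise mean of several baseline-scaled traces on identical time
#' bases (e.g. day 1 and day 2 of pre-conditioning stimulation).
#'
#' @param traces List of `scaled_hr_trace`s.
#' @return A single `scaled_hr_trace` (baseline_bpm = mean of baselines).
#' @export
average_sessions <- function(traces) {
  stopifnot(length(traces) >= 1)
  t0 <- traces[[1]]
  for (tr in traces[-1]) {
    if (length(tr$times) != length(t0$times) ||
        max(abs(tr$times - t0$times)) > 1e-9)
      stop("traces have mismatched time bases")
  }
  vals <- rowMeans(sapply(traces, `[[`, "values"))
  structure(list(times = t0$times, values = vals,
                 baseline_bpm = mean(sapply(traces, `[[`, "baseline_bpm")),
                 stim_window = t0$stim_window, rat = t0$rat,
                 day = paste(sapply(traces, `[[`, "day"), collapse = "+"),
                 condition = t0$condition),
            class = "scaled_hr_trace")
}

#' Stimulation-window area under the curve
#'
#' Sum of the scaled samples whose time t satisfies
#' `start <= t <= end` (both endpoints inclusive: 61 samples at 1 Hz for
#' the default 300-360 s window).
#'
#' @param trace A `scaled_hr_trace`.
#' @param window Two-element window in s; defaults to the trace's
#'   stimulation window.
#' @return An object of class `auc_result` with `auc`, `window`, `rat`,
#'   `condition`.
#' @export
auc_window <- function(trace, window = trace$stim_window) {
  sel <- trace$times >= window[1] & trace$times <= window[2]
  if (!any(sel)) stop("empty AUC window")
  structure(list(auc = sum(trace$values[sel]), window = window,
                 n_samples = sum(sel), rat = trace$rat,
                 condition = trace$condition),
            class = "auc_result")
}

#' Compare stimulation AUCs between conditions with a gamma GLM
#'
#' Fits the gamma generalized linear model with identity link
#' `auc ~ condition` (control as reference), the distribution the AUCs of
#' baseline-scaled positive traces follow.
#'
#' @param results List of `auc_result`s, or a data frame with columns
#'   `auc` and `condition`.
#' @return A `gamma_glm_fit`; the `conditionactive` coefficient is the
#'   difference in mean AUC (active - control).
#' @export
compare_auc <- function(results) {
  if (is.data.frame(results)) df <- results
  else df <- data.frame(auc = sapply(results, `[[`, "auc"),
                        condition = sapply(results, `[[`, "condition"))
  if (length(unique(df$condition)) < 2)
    stop("both conditions must be represented")
  if (any(df$auc <= 0)) stop("AUCs must be strictly positive for a gamma GLM")
  cond <- factor(df$condition, levels = c("control", "active"))
  X <- cbind("(Intercept)" = 1, conditionactive = as.numeric(cond == "active"))
  fit <- fit_gamma_glm_identity(df$auc, X)
  fit$group_means <- c(control = unname(fit$coefficients[1]),
                       active = unname(sum(fit$coefficients)))
  fit
}
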