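#' Phase structure of the conditioning paradigm
#'
#' Trial counts per phase of the 3-day tone-shock paradigm: habituation 5,
#' conditioning 7, extinction 20, recall 3 tone presentations.
#' @export
freezing_phases <- function() {
  c(habituation = 5L, conditioning = 7L, extinction = 20L, recall = 3L)
}

check_freezing_df <- function(df, full = TRUE) {
  stopifnot(all(c("rat", "condition", "phase", "trial", "fraction")
                %in% names(df)))
  if (any(df$fraction < 0 | df$fraction > 1))
    stop("freezing fractions must lie in [0, 1]")
  if (full) {
    ph <- freezing_phases()
    counts <- table(df$rat, factor(df$phase, levels = names(ph)))
    for (p in names(ph))
      if (any(counts[, p] != ph[[p]]))
        stop("every rat needs ", ph[[p]], " ", p, " trials")
  }
  invisible(df)
}

# centered moving average, window 3, windows shrunk at the ends
moving_average3 <- function(x, window = 3) {
  n <- length(x)
  half <- (window - 1) %/% 2
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Normalize per-trial freezing through the standard chain
#'
#' Per rat and phase: (1) min-max normalization `(x - min)/(max - min)`;
#' (2) division by the rat's baseline, the mean of normalized habituation
#' trials 3-5; (3) re-clipping into `[0, 1]` (baseline scaling can exceed
#' 1; the clip count is reported); (4) centered moving average with window
#' 3, windows shrunk at phase ends; (5) boundary compression
#' `(y (n - 1) + 0.5)/n` (n = total observations) so the values fit the
#' open unit interval a beta regression requires. A phase with `max = min`
#' is mapped to constant 0.5 and flagged.
#'
#' @param df Freezing data frame: `rat`, `condition`, `phase`, `trial`,
#'   `fraction` (of the 30 s tone spent freezing, in `[0, 1]`).
#' @param smooth_window Moving-average window (default 3).
#' @param baseline_trials Habituation trials defining the baseline
#'   (default 3:5).
#' @param baseline_floor Lower bound applied to the baseline before
#'   division (default 0.05) to keep the scaling bounded; floored rats are
#'   flagged.
#' @return Data frame with added columns `normalized`, `scaled`,
#'   `smoothed`, `compressed`; attributes `n_clipped`, `flat_phases`,
#'   `floored_baselines`, `compression_n`.
#' @export
normalize_chain <- function(df, smooth_window = 3, baseline_trials = 3:5,
                            baseline_floor = 0.05) {
  check_freezing_df(df)
  df <- df[order(df$rat, match(df$phase, names(freezing_phases())), df$trial), ]
  df$normalized <- NA_real_
  flat <- character(0)
  for (key in unique(paste(df$rat, df$phase))) {
    sel <- paste(df$rat, df$phase) == key
    x <- df$fraction[sel]
    if (max(x) == min(x)) {
      df$normalized[sel] <- 0.5
      flat <- c(flat, key)
    } else {
      df$normalized[sel] <- (x - min(x)) / (max(x) - min(x))
    }
  }
  floored <- character(0)
  df$scaled <- NA_real_
  for (r in unique(df$rat)) {
    sel <- df$rat == r
    hab <- df$normalized[sel & df$phase == "habituation" &
                           df$trial %in% baseline_trials]
    baseline <- mean(hab)
    if (baseline < baseline_floor) {
      baseline <- baseline_floor
      floored <- c(floored, as.character(r))
    }
    df$scaled[sel] <- df$normalized[sel] / baseline
  }
  n_clipped <- sum(df$scaled > 1 | df$scaled < 0)
  df$scaled <- pmin(1, pmax(0, df$scaled))
  df$smoothed <- NA_real_
  for (key in unique(paste(df$rat, df$phase))) {
    sel <- paste(df$rat, df$phase) == key
    df$smoothed[sel] <- moving_average3(df$scaled[sel], smooth_window)
  }
  n <- nrow(df)
  df$compressed <- (df$smoothed * (n - 1) + 0.5) / n
  attr(df, "n_clipped") <- n_clipped
  attr(df, "flat_phases") <- flat
  attr(df, "floored_baselines") <- floored
  attr(df, "compression_n") <- n
  df
}

#' Flag rats that failed to acquire conditioning
#'
#' Automated stand-in for visual inspection of the conditioning curve: a
#' rat is considered conditioned iff its mean raw freezing over the last
#' 3 conditioning trials exceeds its mean habituation freezing by at least
#' `threshold` (absolute fraction; `>=` comparison, so exactly at the
#' threshold counts as conditioned).
#'
#' @param df Freezing data frame (raw fractions).
#' @param threshold Required acquisition gap (default 0.10).
#' @return Data frame with one row per rat: `rat`, `condition`,
#'   `conditioned`, `gap` (conditioning-end minus habituation mean).
#' @export
detect_nonconditioners <- function(df, threshold = 0.10) {
  check_freezing_df(df, full = FALSE)
  rats <- unique(df$rat)
  out <- do.call(rbind, lapply(rats, function(r) {
    d <- df[df$rat == r, ]
    cond <- d[d$phase == "conditioning", ]
    last3 <- cond$fraction[cond$trial > max(cond$trial) - 3]
    hab <- d$fraction[d$phase == "habituation"]
    gap <- mean(last3) - mean(hab)
    data.frame(rat = r, condition = d$condition[1],
               conditioned = gap >= threshold, gap = gap)
  }))
  attr(out, "threshold") <- threshold
  out
}

#' Beta regression of normalized freezing
#'
#' Fits the compressed, normalized freezing values with a beta regression
#' on trial (numeric, restarting at 1 within each phase), testing phase
#' (categorical, habituation reference), and treatment (active vs
#' control), including all 2-way and 3-way interactions.
#'
#' @param norm_df Output of [normalize_chain()] (column `compressed` used).
#' @param response Column to model (default `"compressed"`).
#' @return A `beta_reg_fit` with the design column names; attribute
#'   `design` holds the model matrix.
#' @export
fit_freezing_model <- function(norm_df, response = "compressed") {
  stopifnot(response %in% names(norm_df))
  conds <- table(unique(norm_df[c("rat", "condition")])$condition)
  if (length(conds) < 2 || any(conds < 2))
    stop("need at least 2 rats per condition after exclusions")
  d <- data.frame(trial = as.numeric(norm_df$trial),
                  phase = factor(norm_df$phase,
                                 levels = names(freezing_phases())),
                  treatment = factor(norm_df$condition,
                                     levels = c("control", "active")))
  X <- model.matrix(~ trial * phase * treatment, data = d)
  fit <- fit_beta_regression(norm_df[[response]], X)
  attr(fit, "design") <- X
  fit
}

#' Endpoint comparison over the final extinction trials
#'
#' Per-rat mean over extinction trials 18-20, compared between conditions
#' with a Welch two-sample t test (active - control).
#'
#' @param norm_df Output of [normalize_chain()] (or any freezing data frame
#'   with the chosen value column).
#' @param value Column to average (default `"smoothed"`, the normalized
#'   scale before boundary compression).
#' @param trials Endpoint trials (default 18:20).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return List with `means` (per-rat endpoint means) and `test`.
#' @export
extinction_endpoint_test <- function(norm_df, value = "smoothed",
                                     trials = 18:20, variant = "welch") {
  stopifnot(value %in% names(norm_df))
  ext <- norm_df[norm_df$phase == "extinction", ]
  rats <- unique(ext$rat)
  means <- do.call(rbind, lapply(rats, function(r) {
    d <- ext[ext$rat == r & ext$trial %in% trials, ]
    if (nrow(d) < length(trials))
      stop("rat ", r, " is missing extinction trials ",
           paste(setdiff(trials, d$trial), collapse = ", "))
    data.frame(rat = r, condition = d$condition[1], mean = mean(d[[value]]))
  }))
  a <- means$mean[means$condition == "active"]
  b <- means$mean[means$condition == "control"]
  list(means = means, test = t_test(a, b, variant = variant))
}
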