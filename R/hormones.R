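#' Fit a four-parameter logistic ELISA calibration curve
#'
#' Least-squares fit of `od = d + (a - d) / (1 + (conc / c)^b)` to a plate's
#' standards (a = zero-dose asymptote, d = infinite-dose asymptote, c =
#' inflection concentration, b = slope), via [minpack.lm::nlsLM()]. The 4PL
#' is the standard immunoassay calibration family; each plate is calibrated
#' separately.
#'
#' @param standards Data frame with columns `conc` (> 0 allowed to include
#'   0 for the blank) and `od`; at least 5 standards spanning the range,
#'   with monotone mean OD in concentration.
#' @param hormone,plate Optional identifiers stored in the result.
#' @return An object of class `plate_calibration` with elements `a`, `b`,
#'   `c`, `d`, `standards`, `residuals`, `sigma`.
#' @export
fit_4pl <- function(standards, hormone = NA, plate = NA) {
  stopifnot(all(c("conc", "od") %in% names(standards)))
  standards <- standards[order(standards$conc), ]
  if (nrow(standards) < 5) stop("need at least 5 standards")
  med <- tapply(standards$od, standards$conc, mean)
  dmed <- diff(as.numeric(med))
  if (!(all(dmed > 0) || all(dmed < 0)))
    stop("standards are not monotone in concentration")
  a0 <- as.numeric(med[1])                 # response at lowest conc
  d0 <- as.numeric(med[length(med)])       # response at highest conc
  c0 <- median(standards$conc[standards$conc > 0])
  start <- list(a = a0, b = 1, c = c0, d = d0)
  fit <- minpack.lm::nlsLM(od ~ d + (a - d) / (1 + (conc / c)^b),
                           data = standards, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- as.list(coef(fit))
  if (p$c <= 0) stop("fitted inflection concentration is non-positive")
  res <- structure(list(a = p$a, b = p$b, c = p$c, d = p$d,
                        hormone = hormone, plate = plate,
                        standards = standards,
                        residuals = as.numeric(residuals(fit)),
                        sigma = sqrt(mean(residuals(fit)^2))),
                   class = "plate_calibration")
  res
}

#' Evaluate and invert a 4PL calibration curve
#'
#' `forward_4pl()` maps concentration to optical density;
#' `invert_4pl()` maps an OD strictly between the asymptotes back to
#' concentration via `c * ((a - d)/(od - d) - 1)^(1/b)`. ODs at or beyond
#' an asymptote are out of quantification range and raise an error (the
#' sample should be flagged, not clipped).
#'
#' @param cal A `plate_calibration`.
#' @param conc Concentration(s).
#' @param od Optical density value(s).
#' @return Numeric vector.
#' @export
forward_4pl <- function(cal, conc) {
  cal$d + (cal$a - cal$d) / (1 + (conc / cal$c)^cal$b)
}

#' @rdname forward_4pl
#' @export
invert_4pl <- function(cal, od) {
  lo <- min(cal$a, cal$d); hi <- max(cal$a, cal$d)
  if (any(od <= lo) || any(od >= hi))
    stop("optical density outside the open asymptote interval (",
         signif(lo, 4), ", ", signif(hi, 4), "): out of quantification range")
  cal$c * ((cal$a - cal$d) / (od - cal$d) - 1)^(1 / cal$b)
}

#' Exclude baseline outliers by a fitted beta tail rule
#'
#' Maps pre-stimulation hormone values into (0, 1) by dividing by
#' `scale_factor` times the maximum observed value, fits a beta
#' distribution by maximum likelihood to all values of that hormone, and
#' excludes samples whose tail probability under the fitted distribution is
#' below `p_cut` (default 0.0005; two-sided, so either extreme counts as
#' "extremely unlikely").
#'
#' @param pre_values Named or unnamed numeric vector of positive baseline
#'   values for one hormone (>= 4 values).
#' @param p_cut Tail probability cutoff (default 5e-4).
#' @param side `"two"` (default), `"lower"`, or `"upper"`.
#' @param scale_factor Values are divided by `scale_factor * max(pre_values)`
#'   (default 1.05) to land strictly inside (0, 1).
#' @return List with `kept`, `excluded` (indices), `tail_probs`, the
#'   fitted `beta_fit`, and the normalization constant used.
#' @export
beta_outlier_filter <- function(pre_values, p_cut = 5e-4,
                                side = c("two", "lower", "upper"),
                                scale_factor = 1.05) {
  side <- match.arg(side)
  stopifnot(length(pre_values) >= 4, all(pre_values > 0))
  denom <- scale_factor * max(pre_values)
  z <- pre_values / denom
  fit <- tryCatch(fit_beta_mle(z), error = function(e) NULL)
  if (is.null(fit)) {
    warning("degenerate beta fit; no outliers excluded")
    return(list(kept = seq_along(pre_values), excluded = integer(0),
                tail_probs = rep(NA_real_, length(pre_values)),
                fit = NULL, normalization = denom))
  }
  tp <- tail_prob(fit, z, side = side)
  excl <- which(tp < p_cut)
  list(kept = setdiff(seq_along(pre_values), excl), excluded = excl,
       tail_probs = tp, fit = fit, normalization = denom)
}

#' Compare post/pre hormone ratios between conditions
#'
#' For each rat, hormone values are averaged across collection days within
#' phase (pre / post), the post/pre ratio is formed, and the natural-log
#' ratios are compared between active and control animals with a
#' two-sample t test (`statistic = active - control`; pooled variant by
#' default, giving df `n1 + n2 - 2`).
#'
#' @param samples Data frame with columns `rat`, `condition`
#'   (`active`/`control`), `phase` (`pre`/`post`), `value` (> 0), and
#'   optionally `day`.
#' @param variant Passed to [t_test()] (default `"pooled"`).
#' @return List with `ratios` (per-rat data frame incl. `log_ratio`) and
#'   `test` (a `t_test_result`).
#' @export
post_pre_log_ratio_test <- function(samples, variant = "pooled") {
  stopifnot(all(c("rat", "condition", "phase", "value") %in% names(samples)))
  if (any(samples$value <= 0)) {
    bad <- unique(samples$rat[samples$value <= 0])
    stop("non-positive hormone values for rat(s): ",
         paste(bad, collapse = ", "))
  }
  agg <- aggregate(value ~ rat + condition + phase, data = samples, FUN = mean)
  wide <- merge(agg[agg$phase == "pre", c("rat", "condition", "value")],
                agg[agg$phase == "post", c("rat", "value")],
                by = "rat", suffixes = c("_pre", "_post"))
  if (!nrow(wide)) stop("no rats with both pre and post values")
  wide$ratio <- wide$value_post / wide$value_pre
  wide$log_ratio <- log(wide$ratio)
  a <- wide$log_ratio[wide$condition == "active"]
  b <- wide$log_ratio[wide$condition == "control"]
  if (!length(a) || !length(b)) stop("both conditions must be present")
  list(ratios = wide, test = t_test(a, b, variant = variant))
}
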