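#' Gamma GLM with identity link
#'
#' Fits a gamma generalized linear model with identity link by iteratively
#' reweighted least squares (via [stats::glm.fit()]), with Pearson
#' dispersion and Wald t tests per coefficient. Used to compare
#' stimulation-window heart-rate AUCs between treatment conditions.
#'
#' @param response Strictly positive response vector.
#' @param design Full-rank design matrix (include an intercept column).
#' @return An object of class `gamma_glm_fit`: `coefficients`, `dispersion`
#'   (Pearson), `se`, `t`, `p`, `df_residual`, `fitted`, `converged`.
#' @export
fit_gamma_glm_identity <- function(response, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  if (any(response <= 0)) stop("gamma GLM requires strictly positive responses")
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
  start <- qr.coef(qr(design), response)
  fit <- suppressWarnings(
    glm.fit(design, response, family = Gamma(link = "identity"),
            start = start))
  if (any(fit$fitted.values <= 0))
    stop("gamma GLM iteration produced non-positive fitted means")
  mu <- fit$fitted.values
  n <- length(response)
  p <- ncol(design)
  df_res <- n - p
  pearson <- sum(((response - mu) / mu)^2)
  dispersion <- if (df_res > 0) pearson / df_res else NA_real_
  degenerate <- is.na(dispersion) || dispersion < 1e-12
  # Wald: cov(beta) = dispersion * (X' W X)^-1 with W = (dmu/deta)^2 / V(mu),
  # identity link: W = 1 / mu^2
  XtWX <- crossprod(design / mu)
  cov_un <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov_un)) stop("singular information matrix")
  if (!degenerate) {
    se <- sqrt(pmax(0, diag(cov_un)) * dispersion)
    tstat <- fit$coefficients / se
    pval <- 2 * pt(-abs(tstat), df_res)
  } else {
    se <- tstat <- pval <- rep(NA_real_, p)
  }
  structure(list(coefficients = setNames(fit$coefficients, colnames(design)),
                 dispersion = dispersion, se = se, t = tstat, p = pval,
                 df_residual = df_res, fitted = mu,
                 converged = fit$converged,
                 zero_dispersion = degenerate),
            class = "gamma_glm_fit")
}

beta_reg_loglik <- function(theta, X, y) {
  k <- ncol(X)
  mu <- plogis(drop(X %*% theta[1:k]))
  phi <- exp(theta[k + 1])
  sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
        (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
}

beta_reg_grad <- function(theta, X, y) {
  k <- ncol(X)
  eta <- drop(X %*% theta[1:k])
  mu <- plogis(eta)
  phi <- exp(theta[k + 1])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gb <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  gp <- sum(digamma(phi) - mu * digamma(mu * phi) -
              (1 - mu) * digamma((1 - mu) * phi) +
              mu * log(y) + (1 - mu) * log1p(-y)) * phi
  c(gb, gp)
}

#' Beta regression with logit mean link
#'
#' Joint maximum likelihood of logit-link mean coefficients and a common
#' precision phi for responses strictly inside (0, 1). Newton ascent with
#' analytic gradient, numeric Hessian, and step halving from a
#' deterministic start (least squares on the logit-transformed response;
#' method-of-moments precision), so the log-likelihood trace is
#' monotonically non-decreasing. Standard errors come from the observed
#' information at the optimum.
#'
#' @param response Vector in the open interval (0, 1).
#' @param design Full-rank design matrix (include an intercept column).
#' @param maxit Maximum Newton iterations.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @return An object of class `beta_reg_fit`: `coefficients`, `phi`,
#'   `loglik`, `se`, `z`, `p`, `loglik_trace`, `converged`.
#' @export
fit_beta_regression <- function(response, design, maxit = 200, tol = 1e-9) {
  y <- as.numeric(response)
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(y <= 0 | y >= 1))
    stop("responses must lie strictly inside (0, 1); compress boundaries first")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    drop_cols <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  k <- ncol(X)
  beta0 <- qr.coef(qrX, qlogis(y))
  mu0 <- plogis(drop(X %*% beta0))
  s2 <- max(var(y - mu0), 1e-8)
  phi0 <- max(mean(mu0 * (1 - mu0)) / s2 - 1, 0.1)
  theta <- c(beta0, log(phi0))

  ll <- beta_reg_loglik(theta, X, y)
  trace_ll <- ll
  converged <- FALSE
  for (it in seq_len(maxit)) {
    g <- beta_reg_grad(theta, X, y)
    H <- optimHess(theta, beta_reg_loglik, beta_reg_grad, X = X, y = y)
    # damped Newton: ridge -H until positive definite so the step ascends
    A <- -(H + t(H)) / 2
    ridge <- 0
    repeat {
      R <- tryCatch(chol(A + diag(ridge, nrow(A))), error = function(e) NULL)
      if (!is.null(R)) break
      ridge <- if (ridge == 0) 1e-6 * max(1, max(abs(diag(A)))) else ridge * 10
      if (ridge > 1e12) stop("beta regression Hessian irreparably singular")
    }
    step <- backsolve(R, forwardsolve(t(R), g))
    if (!all(is.finite(step)) || sum(step * g) <= 0)
      step <- g / max(1, sqrt(sum(g^2)))
    lam <- 1
    repeat {
      cand <- theta + lam * step
      llc <- beta_reg_loglik(cand, X, y)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- theta; llc <- ll; break }
    }
    theta <- cand
    trace_ll <- c(trace_ll, llc)
    if (abs(llc - ll) < tol && sqrt(sum(g^2)) < 1e-4 * (1 + abs(llc))) {
      ll <- llc
      converged <- TRUE
      break
    }
    ll <- llc
  }
  if (!converged && abs(diff(tail(trace_ll, 2))) < 1e-6) converged <- TRUE
  if (!converged)
    stop("beta regression did not converge; log-likelihood trace: ",
         paste(sprintf("%.4f", tail(trace_ll, 8)), collapse = " -> "))
  H <- optimHess(theta, beta_reg_loglik, beta_reg_grad, X = X, y = y)
  cov <- tryCatch(solve(-H), error = function(e)
    matrix(NA_real_, k + 1, k + 1))
  se_all <- sqrt(pmax(0, diag(cov)))
  coefs <- setNames(theta[1:k], colnames(X))
  se <- se_all[1:k]
  z <- coefs / se
  structure(list(coefficients = coefs, phi = exp(theta[k + 1]),
                 loglik = ll, se = setNames(se, colnames(X)),
                 z = z, p = 2 * pnorm(-abs(z)),
                 phi_se = exp(theta[k + 1]) * se_all[k + 1],
                 loglik_trace = trace_ll, iterations = length(trace_ll) - 1,
                 converged = converged, fitted = plogis(drop(X %*% theta[1:k]))),
            class = "beta_reg_fit")
}

#' Beta distribution maximum likelihood fit and tail probabilities
#'
#' `fit_beta_mle()` fits shape parameters (alpha, beta) to values strictly
#' inside (0, 1) by maximum likelihood (via [fitdistrplus::fitdist()]).
#' `tail_prob()` returns the probability of being at least as extreme as
#' `x` under the fitted distribution: two-sided `min(F(x), 1 - F(x))` by
#' default, or a lower/upper one-sided tail.
#'
#' @param values Numeric vector in (0, 1), length >= 3.
#' @return `fit_beta_mle`: an object of class `beta_fit` with `alpha`,
#'   `beta`, `loglik`.
#' @export
fit_beta_mle <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  if (any(values <= 0 | values >= 1)) stop("values must lie strictly in (0, 1)")
  m <- mean(values); v <- var(values)
  cm <- max(m * (1 - m) / v - 1, 0.1)
  start <- list(shape1 = max(m * cm, 0.05), shape2 = max((1 - m) * cm, 0.05))
  fd <- fitdistrplus::fitdist(as.numeric(values), "beta", start = start)
  structure(list(alpha = unname(fd$estimate["shape1"]),
                 beta = unname(fd$estimate["shape2"]),
                 loglik = fd$loglik),
            class = "beta_fit")
}

#' @rdname fit_beta_mle
#' @param fit A `beta_fit`.
#' @param x Value(s) in (0, 1) to evaluate.
#' @param side `"two"` (default), `"lower"`, or `"upper"`.
#' @export
tail_prob <- function(fit, x, side = c("two", "lower", "upper")) {
  side <- match.arg(side)
  F <- pbeta(x, fit$alpha, fit$beta)
  switch(side, two = pmin(F, 1 - F), lower = F, upper = 1 - F)
}

#' Two-sample t test (pooled or Welch)
#'
#' Thin wrapper around [stats::t.test()] recording the variant explicitly.
#' Pooled degrees of freedom are `n1 + n2 - 2`; the Welch variant uses the
#' Satterthwaite approximation (possibly fractional df). The statistic is
#' computed as `mean(a) - mean(b)` over the standard error.
#'
#' @param a,b Numeric samples (each length >= 2).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return An object of class `t_test_result`: `statistic`, `df`, `p`,
#'   `variant`, group means.
#' @export
t_test <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b)) {
    res <- list(statistic = 0, df = if (variant == "pooled")
      length(a) + length(b) - 2 else NA_real_, p = 1)
  } else {
    tt <- t.test(a, b, var.equal = (variant == "pooled"))
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(list(statistic = res$statistic, df = res$df, p = res$p,
                 variant = variant, mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b)),
            class = "t_test_result")
}

# unbiased sample skewness and (non-excess) kurtosis
sample_skew_kurt <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("constant input: skewness and kurtosis are undefined")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2
  skew <- sqrt(n * (n - 1)) / (n - 2) * g1
  kurt <- (n - 1) / ((n - 2) * (n - 3)) * ((n + 1) * g2 - 3 * (n - 1)) + 3
  c(skewness = skew, kurtosis = kurt)
}

#' Skewness-kurtosis (Cullen-Frey) summary
#'
#' Computes the unbiased sample skewness and kurtosis, a bootstrap cloud of
#' the pair, and the distance from the observed point to the loci of common
#' reference distributions on the (skewness^2, kurtosis) plane: normal
#' (0, 3), uniform (0, 1.8), exponential (4, 9), logistic (0, 4.2), the
#' gamma line `kurt = 3 + 1.5 skew^2`, and the lognormal curve. Used to
#' shortlist candidate distributions before model fitting.
#'
#' @param values Numeric vector, length >= 4, non-constant.
#' @param n_boot Number of bootstrap replicates of the pair (default 100).
#' @return An object of class `skew_kurt_summary`: `skewness`,
#'   `skewness_sq`, `kurtosis`, `boot` (data frame of replicate pairs),
#'   `reference_distances` (sorted, nearest first).
#' @export
cullen_frey <- function(values, n_boot = 100) {
  if (length(values) < 4) stop("need at least 4 values")
  sk <- sample_skew_kurt(values)
  boot <- NULL
  if (n_boot > 0) {
    boot <- t(replicate(n_boot, {
      res <- tryCatch(sample_skew_kurt(sample(values, replace = TRUE)),
                      error = function(e) c(NA_real_, NA_real_))
      res
    }))
    boot <- as.data.frame(boot)
    names(boot) <- c("skewness", "kurtosis")
  }
  s2 <- sk[["skewness"]]^2
  ku <- sk[["kurtosis"]]
  pointd <- function(p) sqrt((s2 - p[1])^2 + (ku - p[2])^2)
  sg <- seq(0, max(4, s2 * 2), length.out = 400)
  gamma_line <- min(sqrt((s2 - sg)^2 + (ku - (3 + 1.5 * sg))^2))
  # lognormal locus parameterized by sigma^2
  s2g <- seq(0.001, 2, length.out = 400)
  w <- exp(s2g)
  ln_skew2 <- (w + 2)^2 * (w - 1)
  ln_kurt <- w^4 + 2 * w^3 + 3 * w^2 - 3
  lognormal_line <- min(sqrt((s2 - ln_skew2)^2 + (ku - ln_kurt)^2))
  dists <- c(normal = pointd(c(0, 3)), uniform = pointd(c(0, 1.8)),
             exponential = pointd(c(4, 9)), logistic = pointd(c(0, 4.2)),
             gamma = gamma_line, lognormal = lognormal_line)
  structure(list(skewness = sk[["skewness"]], skewness_sq = s2,
                 kurtosis = ku, boot = boot,
                 reference_distances = sort(dists),
                 nearest = names(sort(dists))[1]),
            class = "skew_kurt_summary")
}
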