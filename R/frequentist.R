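#' @title Frequentist companion tests
#' @name frequentist
#' @description The null-hypothesis-significance-testing companions to the
#'   Bayesian comparison: a Mann-Whitney U statistic built explicitly from
#'   the pairwise win/tie double sum, exact and normal-approximation
#'   p-values, a Shapiro-Wilk normality gate, and a probability-plot fit of
#'   the location-scale t with a Kolmogorov-Smirnov goodness-of-fit check.
NULL

#' Mann-Whitney U statistic
#'
#' `U = sum_i sum_j S(X_i, Y_j)` over all pairs, with `S = 0` when
#' `X_i > Y_j`, `1/2` on ties and `1` when `X_i < Y_j` — so U counts wins of
#' the second sample (plus half-ties) and `U(X, Y) + U(Y, X) = n1 * n2`.
#'
#' @param x,y Non-empty numeric vectors.
#' @return The U statistic (half-integers possible under ties).
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
}

mwu_exact_pvalue <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  N <- length(pooled)
  u_obs <- mann_whitney_u(x, y)
  centre <- n1 * (N - n1) / 2
  idx <- combn(N, n1)
  us <- apply(idx, 2, function(i) mann_whitney_u(pooled[i], pooled[-i]))
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

mwu_normal_pvalue <- function(x, y, continuity = TRUE) {
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  u_obs <- mann_whitney_u(x, y)
  mu_u <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v_u <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v_u <= 0) return(1) # all observations tied
  z <- u_obs - mu_u
  if (continuity) z <- sign(z) * max(abs(z) - 0.5, 0)
  min(1, 2 * pnorm(-abs(z) / sqrt(v_u)))
}

#' Mann-Whitney U test
#'
#' Two-sided test of identical distributions based on [mann_whitney_u()].
#' Small samples (pooled size at most `exact_threshold`) get an exact
#' p-value by full enumeration of group labelings; larger samples use the
#' normal approximation with tie correction and (by default) continuity
#' correction.
#'
#' @inheritParams mann_whitney_u
#' @param exact_threshold Pooled sample size up to which the exact
#'   enumeration is used (default 12).
#' @param continuity Apply the continuity correction in the normal
#'   approximation?
#' @return An object of class `mwu_result` with fields `u`, `p_value`,
#'   `method` (`"EXACT"` or `"NORMAL_APPROX"`), `n1`, `n2`.
#' @export
mwu_test <- function(x, y, exact_threshold = 12, continuity = TRUE) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- length(x) + length(y) <= exact_threshold
  p <- if (exact) mwu_exact_pvalue(x, y)
       else mwu_normal_pvalue(x, y, continuity)
  structure(list(u = mann_whitney_u(x, y), p_value = p,
                 method = if (exact) "EXACT" else "NORMAL_APPROX",
                 n1 = length(x), n2 = length(y)),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g, n1 = %d, n2 = %d, p = %.4g\n",
              x$method, x$u, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Screens a sample for normality before parametric testing; the Bayesian
#' route does not need this gate, the rank test is used when it fails.
#'
#' @param samples Numeric vector, 3 <= n <= 5000.
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic`, `p_value` and `is_normal`
#'   (`p_value >= alpha`).
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (length(samples) < 3) stop("Shapiro-Wilk needs at least 3 observations")
  sw <- shapiro.test(samples)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       is_normal = sw$p.value >= alpha)
}

# probability-plot correlation for a given nu: fit sorted sample against
# theoretical t quantiles by least squares; returns fit and correlation
t_probplot_fit <- function(x_sorted, nu) {
  q <- qt(ppoints(length(x_sorted)), df = nu)
  fit <- lm(x_sorted ~ q)
  list(mu = unname(coef(fit)[1]), sigma = unname(coef(fit)[2]),
       r = stats::cor(x_sorted, q))
}

#' Probability-plot fit of the location-scale t with a KS check
#'
#' Fits (mu, sigma, nu) by least-squares regression of the sample order
#' statistics on theoretical t quantiles (a QQ-plot fit): for each candidate
#' nu the regression gives mu (intercept) and sigma (slope), and nu is
#' chosen by a one-dimensional search maximizing the probability-plot
#' correlation. A two-sided Kolmogorov-Smirnov test of the sample against
#' the fitted distribution (parameters treated as fixed, hence conservative)
#' quantifies goodness of fit.
#'
#' @param samples Numeric vector, n >= 20, non-constant.
#' @param nu_range Search range for nu (default 0.5 to 500).
#' @return List of class `t_fit_result`: `mu`, `sigma`, `nu`, `r`
#'   (probability-plot correlation), `ks_statistic`, `ks_p`.
#' @export
t_fit_check <- function(samples, nu_range = c(0.5, 500)) {
  samples <- as.numeric(samples)
  if (length(samples) < 20) stop("need at least 20 observations")
  if (sd(samples) == 0) stop("zero-variance data cannot be fitted")
  xs <- sort(samples)
  obj <- function(log_nu) t_probplot_fit(xs, exp(log_nu))$r
  opt <- optimize(obj, log(nu_range), maximum = TRUE, tol = 1e-4)
  nu <- exp(opt$maximum)
  fit <- t_probplot_fit(xs, nu)
  if (fit$sigma <= 0) stop("degenerate fit: non-positive scale")
  ks <- suppressWarnings(
    ks.test(samples, function(q) pt((q - fit$mu) / fit$sigma, df = nu)))
  structure(list(mu = fit$mu, sigma = fit$sigma, nu = nu, r = fit$r,
                 ks_statistic = unname(ks$statistic), ks_p = ks$p.value),
            class = "t_fit_result")
}

#' @export
print.t_fit_result <- function(x, ...) {
  cat(sprintf(
    "t fit: mu = %.4g, sigma = %.4g, nu = %.4g (r = %.4f); KS D = %.4g, p = %.4g\n",
    x$mu, x$sigma, x$nu, x$r, x$ks_statistic, x$ks_p))
  invisible(x)
}
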