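#' @title Posterior decision quantities
#' @name inference
#' @description Turns posterior traces into the quantities decisions are made
#'   on: highest-density intervals, per-draw differences of means and scales,
#'   per-draw Cohen's d effect sizes with unequal-n pooling, credibility
#'   masses above zero, the HDI/ROPE four-way decision, and the pairwise
#'   credibility matrix for multi-group comparisons.
NULL

#' Decision configuration
#'
#' @param hdi_mass Probability mass of the highest-density interval used for
#'   decisions (default 0.95).
#' @param rope Region of practical equivalence on the effect-size scale,
#'   `c(low, high)`; effect sizes inside it are deemed practically null.
#'   The default (-0.2, 0.2) brackets small effects.
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(hdi_mass = 0.95, rope = c(-0.2, 0.2)) {
  stopifnot(length(hdi_mass) == 1, hdi_mass > 0, hdi_mass < 1,
            length(rope) == 2, rope[1] < rope[2])
  structure(list(hdi_mass = hdi_mass, rope = as.numeric(rope)),
            class = "decision_config")
}

#' Highest-density interval of a sample
#'
#' The shortest contiguous interval containing at least `mass` of the
#' sample: over the sorted draws, every window of `ceiling(mass * n)`
#' consecutive order statistics is a candidate and the narrowest one wins.
#' Assumes a unimodal underlying density (true of the posterior marginals
#' produced here); multimodality is not detected.
#'
#' @param samples Numeric vector (length >= 100).
#' @param mass Probability mass in (0, 1), default 0.95.
#' @return `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 100) stop("need at least 100 samples for a stable HDI")
  x <- sort(samples)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - k + 1)
  widths <- x[starts + k - 1] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}

group_index <- function(trace, g) {
  if (is.character(g)) {
    i <- match(g, trace$labels)
    if (is.na(i)) stop("unknown group '", g, "'")
    i
  } else {
    g <- as.integer(g)
    if (g < 1 || g > length(trace$labels)) stop("unknown group index ", g)
    g
  }
}

#' Per-draw differences of group means and scales
#'
#' Chain-concatenated draws of `mu[g1] - mu[g2]` and `sigma[g1] - sigma[g2]`,
#' preserving the pairing of draws.
#'
#' @param trace A `best_trace`.
#' @param g1,g2 Group indices or labels (must differ).
#' @return A list with vectors `mu_diff` and `sd_diff`.
#' @export
difference_draws <- function(trace, g1 = 1, g2 = 2) {
  stopifnot(inherits(trace, "best_trace"))
  i <- group_index(trace, g1)
  j <- group_index(trace, g2)
  if (i == j) stop("g1 and g2 must name different groups")
  list(mu_diff = trace_param(trace, sprintf("mu[%d]", i)) -
         trace_param(trace, sprintf("mu[%d]", j)),
       sd_diff = trace_param(trace, sprintf("sigma[%d]", i)) -
         trace_param(trace, sprintf("sigma[%d]", j)))
}

#' Pooled standard deviation with unequal sample sizes
#'
#' `sqrt(((n1-1) sigma1^2 + (n2-1) sigma2^2) / (n1 + n2 - 2))` — the
#' unequal-n pooling used in Cohen's d.
#'
#' @param sigma1,sigma2 Group scales (vectors allowed).
#' @param n1,n2 Group sample sizes, `n1 + n2 > 2`.
#' @export
pooled_sd <- function(sigma1, sigma2, n1, n2) {
  if (n1 + n2 <= 2) stop("need n1 + n2 > 2 for pooling")
  sqrt(((n1 - 1) * sigma1^2 + (n2 - 1) * sigma2^2) / (n1 + n2 - 2))
}

#' Per-draw Cohen's d effect size
#'
#' For every posterior draw, `(mu[g1] - mu[g2])` divided by the pooled
#' standard deviation of that draw's scales, giving a full posterior
#' distribution of the effect size; the reported point value is its mean.
#'
#' @inheritParams difference_draws
#' @param n1,n2 Group sample sizes; default the sizes stored in the trace.
#' @return Numeric vector of effect-size draws.
#' @export
effect_size_draws <- function(trace, g1 = 1, g2 = 2,
                              n1 = NULL, n2 = NULL) {
  stopifnot(inherits(trace, "best_trace"))
  i <- group_index(trace, g1)
  j <- group_index(trace, g2)
  if (i == j) stop("g1 and g2 must name different groups")
  if (is.null(n1)) n1 <- trace$n[i]
  if (is.null(n2)) n2 <- trace$n[j]
  mu_d <- trace_param(trace, sprintf("mu[%d]", i)) -
    trace_param(trace, sprintf("mu[%d]", j))
  sp <- pooled_sd(trace_param(trace, sprintf("sigma[%d]", i)),
                  trace_param(trace, sprintf("sigma[%d]", j)), n1, n2)
  mu_d / sp
}

#' Credibility mass above zero
#'
#' Percentage of draws strictly greater than zero (draws exactly at zero, a
#' measure-zero event, count as not above).
#'
#' @param samples Non-empty numeric vector.
#' @return A percentage in \[0, 100\].
#' @export
credibility_above_zero <- function(samples) {
  if (!length(samples)) stop("empty sample vector")
  100 * mean(samples > 0)
}

DECISIONS <- c("REJECT_H0_GROUP1_HIGHER", "REJECT_H0_GROUP2_HIGHER",
               "ACCEPT_H0", "UNDECIDED")

#' HDI/ROPE four-way decision
#'
#' The null hypothesis of equal means is rejected when the HDI of the
#' difference of means lies entirely above zero (group 1 higher) or entirely
#' below (group 2 higher). It is accepted only when the effect-size HDI lies
#' entirely inside the ROPE; the ROPE never widens the rejection rule.
#' Anything else is undecided.
#'
#' @param mu_diff_hdi HDI `c(low, high)` of the difference of means.
#' @param effect_hdi HDI `c(low, high)` of the effect size.
#' @param cfg A [decision_config()].
#' @return One of `"REJECT_H0_GROUP1_HIGHER"`, `"REJECT_H0_GROUP2_HIGHER"`,
#'   `"ACCEPT_H0"`, `"UNDECIDED"`.
#' @export
decide_hdi_rope <- function(mu_diff_hdi, effect_hdi,
                            cfg = decision_config()) {
  stopifnot(length(mu_diff_hdi) == 2, mu_diff_hdi[1] <= mu_diff_hdi[2],
            length(effect_hdi) == 2, effect_hdi[1] <= effect_hdi[2])
  if (mu_diff_hdi[1] > 0) return(DECISIONS[1])
  if (mu_diff_hdi[2] < 0) return(DECISIONS[2])
  if (effect_hdi[1] >= cfg$rope[1] && effect_hdi[2] <= cfg$rope[2]) {
    return(DECISIONS[3])
  }
  DECISIONS[4]
}

#' Full two-group comparison summary
#'
#' Posterior mean, HDI and credibility mass above zero for the difference of
#' means, the difference of standard deviations and the effect size, plus
#' the HDI/ROPE decision.
#'
#' @inheritParams difference_draws
#' @inheritParams decide_hdi_rope
#' @return An object of class `comparison_summary`.
#' @export
compare_groups <- function(trace, g1 = 1, g2 = 2, cfg = decision_config()) {
  i <- group_index(trace, g1)
  j <- group_index(trace, g2)
  d <- difference_draws(trace, i, j)
  es <- effect_size_draws(trace, i, j)
  summ <- function(x) {
    h <- hdi(x, cfg$hdi_mass)
    list(mean = mean(x), hdi_low = h[1], hdi_high = h[2],
         credibility_above_zero = credibility_above_zero(x))
  }
  s <- list(mean_diff = summ(d$mu_diff), sd_diff = summ(d$sd_diff),
            effect_size = summ(es))
  structure(list(
    group1 = trace$labels[i], group2 = trace$labels[j],
    n1 = trace$n[i], n2 = trace$n[j],
    mean_diff = s$mean_diff, sd_diff = s$sd_diff,
    effect_size = s$effect_size,
    decision = decide_hdi_rope(
      c(s$mean_diff$hdi_low, s$mean_diff$hdi_high),
      c(s$effect_size$hdi_low, s$effect_size$hdi_high), cfg),
    hdi_mass = cfg$hdi_mass, rope = cfg$rope),
    class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("Robust comparison: ", x$group1, " (n1=", x$n1, ") vs ", x$group2,
      " (n2=", x$n2, ")\n", sep = "")
  row <- function(lab, s) {
    cat(sprintf("  %-12s mean %8.3g  %.0f%% HDI (%.3g, %.3g)  P(>0) = %.1f%%\n",
                lab, s$mean, 100 * x$hdi_mass, s$hdi_low, s$hdi_high,
                s$credibility_above_zero))
  }
  row("mean diff", x$mean_diff)
  row("sd diff", x$sd_diff)
  row("effect size", x$effect_size)
  cat("  decision:", x$decision, "\n")
  invisible(x)
}

#' Pairwise credibility matrix for multi-group comparisons
#'
#' Entry (i, j) is the credibility (in percent) that group i's mean exceeds
#' group j's, computed from the per-draw differences `mu[i] - mu[j]`; the
#' diagonal is `NA`. This is the data behind a multi-group or multi-period
#' heatmap.
#'
#' @param trace A `best_trace` over G >= 2 groups.
#' @return A G x G matrix of percentages with group labels as dimnames.
#' @export
pairwise_credibility_matrix <- function(trace) {
  stopifnot(inherits(trace, "best_trace"))
  G <- length(trace$labels)
  mu <- sapply(sprintf("mu[%d]", seq_len(G)),
               function(p) trace_param(trace, p))
  out <- matrix(NA_real_, G, G, dimnames = list(trace$labels, trace$labels))
  for (i in seq_len(G)) {
    for (j in seq_len(G)) {
      if (i != j) out[i, j] <- credibility_above_zero(mu[, i] - mu[, j])
    }
  }
  out
}
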