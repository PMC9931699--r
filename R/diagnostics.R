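#' @title Convergence diagnostics and predictive checks
#' @name diagnostics
#' @description Split-chain potential scale reduction factor (PSRF), effective
#'   sample size (ESS), and prior/posterior predictive checks, following the
#'   Bayesian Analysis Reporting Guidelines: every fit should come with
#'   evidence that the chains converged and that the model can capture the
#'   observed data.
NULL

# split-chain PSRF for one parameter given a list of per-chain vectors
split_psrf_one <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n2 <- floor(length(x) / 2)
    list(x[seq_len(n2)], x[seq(length(x) - n2 + 1, length(x))])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  m <- length(halves)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B_over_n <- var(means)           # = B/n in the usual notation
  if (W == 0) return(1)
  sqrt((n - 1) / n + B_over_n / W)
}

#' Convergence diagnostics for a posterior trace
#'
#' Computes, for every scalar parameter, the split-chain potential scale
#' reduction factor (each chain is split in half, so stationarity within
#' chains is penalized as well as disagreement between chains; values near 1
#' indicate convergence) and the effective sample size (sum over chains of
#' the autocorrelation-adjusted sample size).
#'
#' @param trace A `best_trace` from [sample_posterior()], or a
#'   [coda::mcmc.list].
#' @return A data frame with columns `parameter`, `psrf`, `ess`.
#' @export
convergence_diagnostics <- function(trace) {
  ml <- if (inherits(trace, "best_trace")) trace$samples else trace
  if (!inherits(ml, "mcmc.list")) stop("need a best_trace or mcmc.list")
  if (length(ml) < 2) stop("need at least 2 chains for the PSRF")
  nm <- colnames(ml[[1]])
  psrf <- vapply(nm, function(p) {
    split_psrf_one(lapply(ml, function(m) as.numeric(m[, p])))
  }, 0)
  ess <- vapply(nm, function(p) {
    sum(vapply(ml, function(m) as.numeric(coda::effectiveSize(m[, p])), 0))
  }, 0)
  data.frame(parameter = nm, psrf = unname(psrf), ess = unname(ess),
             row.names = NULL)
}

draw_prior_params <- function(prior, G, reps) {
  list(mu = matrix(rnorm(reps * G, prior$M, prior$S), reps, G),
       sigma = matrix(runif(reps * G, prior$L, prior$H), reps, G),
       nu = prior$nu_offset + rexp(reps, rate = 1 / prior$nu_mean))
}

draw_posterior_params <- function(trace, G, reps) {
  all_mu <- sapply(sprintf("mu[%d]", seq_len(G)),
                   function(p) trace_param(trace, p))
  all_sigma <- sapply(sprintf("sigma[%d]", seq_len(G)),
                      function(p) trace_param(trace, p))
  all_nu <- trace_param(trace, "nu")
  idx <- sample.int(length(all_nu), reps, replace = reps > length(all_nu))
  list(mu = all_mu[idx, , drop = FALSE],
       sigma = all_sigma[idx, , drop = FALSE],
       nu = all_nu[idx])
}

#' Prior and posterior predictive checks
#'
#' Draws parameter sets (from the prior when `trace` is `NULL`, otherwise
#' from the posterior), simulates replicate datasets of exactly the observed
#' group sizes from the location-scale t likelihood, and reports where each
#' observed group mean and standard deviation falls within the replicate
#' distribution. An observed statistic far outside the central interval of
#' its replicates signals model (or prior) misfit.
#'
#' @param model A [best_model()].
#' @param trace A `best_trace` for a posterior predictive check, or `NULL`
#'   for a prior predictive check.
#' @param reps Number of replicate datasets (>= 100).
#' @param seed Integer seed.
#' @param prob Central replicate interval mass (default 0.95).
#' @return A data frame, one row per group and statistic (`mean`, `sd`):
#'   observed value, replicate interval bounds, tail quantile of the
#'   observation among replicates, and whether it lies inside the interval.
#' @export
predictive_check <- function(model, trace = NULL, reps = 1000, seed = 1,
                             prob = 0.95) {
  stopifnot(inherits(model, "best_model"))
  if (reps < 100) stop("need reps >= 100")
  G <- length(model$groups)
  set.seed(as.integer(seed))
  par <- if (is.null(trace)) draw_prior_params(model$prior, G, reps)
         else draw_posterior_params(trace, G, reps)
  alpha <- (1 - prob) / 2
  out <- vector("list", 2 * G)
  for (g in seq_len(G)) {
    y <- model$groups[[g]]$values
    n <- length(y)
    rep_mean <- numeric(reps)
    rep_sd <- numeric(reps)
    for (r in seq_len(reps)) {
      yr <- rt_ls(n, par$mu[r, g], par$sigma[r, g], par$nu[r])
      rep_mean[r] <- mean(yr)
      rep_sd[r] <- sd(yr)
    }
    for (stat in c("mean", "sd")) {
      obs <- if (stat == "mean") mean(y) else sd(y)
      repv <- if (stat == "mean") rep_mean else rep_sd
      qs <- quantile(repv, c(alpha, 1 - alpha), names = FALSE)
      out[[(g - 1) * 2 + (stat == "sd") + 1]] <- data.frame(
        group = model$groups[[g]]$label, statistic = stat,
        observed = obs, lower = qs[1], upper = qs[2],
        quantile = mean(repv <= obs),
        inside = obs >= qs[1] & obs <= qs[2])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
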