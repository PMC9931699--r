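#' @title Robust Bayesian group comparison (BEST)
#' @name robust_bayes
#' @description The robust model at the core of the package: each group's
#'   analysis values are described by a location-scale Student-t with its own
#'   mean and scale and a tail (normality) parameter shared across all
#'   groups. Priors are derived from the pooled data; the posterior is
#'   explored by a coordinate-wise slice sampler implemented in C++.
NULL

#' Location-scale Student-t density
#'
#' Density of `mu + sigma * T(nu)`: the heavy-tailed likelihood family used
#' for citation counts. For large `nu` it approaches the normal density.
#'
#' @param x Quantiles.
#' @param mu Location.
#' @param sigma Scale (> 0).
#' @param nu Shape / normality parameter (> 0); small values mean heavy tails.
#' @param log Return the log density?
#' @export
dt_ls <- function(x, mu = 0, sigma = 1, nu = 30, log = FALSE) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(nu <= 0)) stop("nu must be > 0")
  out <- dt((x - mu) / sigma, df = nu, log = TRUE) - base::log(sigma)
  if (log) out else exp(out)
}

#' Quantiles and random draws of the location-scale t
#'
#' @inheritParams dt_ls
#' @param p Probabilities.
#' @param n Number of draws.
#' @export
qt_ls <- function(p, mu = 0, sigma = 1, nu = 30) mu + sigma * qt(p, df = nu)

#' @rdname qt_ls
#' @export
rt_ls <- function(n, mu = 0, sigma = 1, nu = 30) mu + sigma * rt(n, df = nu)

#' Prior specification derived from the pooled data
#'
#' @param M Prior mean of the normal prior on each group mean.
#' @param S Prior standard deviation of that normal (> 0).
#' @param L,H Lower and upper bound of the uniform prior on each group scale
#'   (0 < L < H).
#' @param nu_offset Lower bound of the shape parameter (default 1, so the
#'   likelihood always has a finite mean's heavier-tailed regime excluded at
#'   nu < 1).
#' @param nu_mean Mean of the exponential prior on `nu - nu_offset`
#'   (default 29, balancing heavy-tailed and near-normal regimes).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(M, S, L, H, nu_offset = 1, nu_mean = 29) {
  stopifnot(is.finite(M), S > 0, L > 0, H > L, nu_offset >= 0, nu_mean > 0)
  structure(list(M = M, S = S, L = L, H = H,
                 nu_offset = nu_offset, nu_mean = nu_mean),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Priors: mu ~ N(", signif(x$M, 4), ", ", signif(x$S, 4), "^2),",
      " sigma ~ U(", signif(x$L, 4), ", ", signif(x$H, 4), "),",
      " nu ~ ", x$nu_offset, " + Exp(mean ", x$nu_mean, ")\n", sep = "")
  invisible(x)
}

#' Pooled-data priors for the robust comparison
#'
#' The prior on every group mean is normal with the pooled-data mean and 10
#' times the pooled standard deviation; the prior on every group scale is
#' uniform between 1/100 and 100 times the pooled standard deviation. These
#' scalings keep the prior on the order of magnitude of the data while
#' staying vague enough not to drive the posterior. `"sensitivity"` widens
#' them by a further factor (1000x pooled SD for the normal SD and the
#' uniform bounds) for prior-sensitivity analysis.
#'
#' @param groups List of [group_dataset()] objects (G >= 2), or a single one.
#' @param mode `"default"` or `"sensitivity"`.
#' @inheritParams prior_spec
#' @return A [prior_spec()].
#' @export
pooled_prior_spec <- function(groups, mode = c("default", "sensitivity"),
                              nu_offset = 1, nu_mean = 29) {
  mode <- match.arg(mode)
  groups <- as_group_list(groups)
  pooled <- unlist(lapply(groups, `[[`, "values"))
  m <- mean(pooled)
  s <- sd(pooled)
  if (!is.finite(s) || s == 0) {
    stop("degenerate data: pooled standard deviation is zero")
  }
  if (mode == "default") {
    prior_spec(M = m, S = 10 * s, L = s / 100, H = 100 * s,
               nu_offset = nu_offset, nu_mean = nu_mean)
  } else {
    prior_spec(M = m, S = 1000 * s, L = s / 1000, H = 1000 * s,
               nu_offset = nu_offset, nu_mean = nu_mean)
  }
}

as_group_list <- function(groups) {
  if (inherits(groups, "group_dataset")) groups <- list(groups)
  if (!length(groups) || !all(vapply(groups, inherits, TRUE, "group_dataset"))) {
    stop("`groups` must be a list of group_dataset objects")
  }
  groups
}

#' Model specification for the robust comparison
#'
#' @param groups List of [group_dataset()] (G >= 2).
#' @param prior A [prior_spec()]; defaults to [pooled_prior_spec()] of the
#'   groups.
#' @param prior_mode Passed to [pooled_prior_spec()] when `prior` is absent.
#' @return An object of class `best_model`.
#' @export
best_model <- function(groups, prior = NULL,
                       prior_mode = c("default", "sensitivity")) {
  groups <- as_group_list(groups)
  if (length(groups) < 2) stop("need at least two groups")
  if (is.null(prior)) prior <- pooled_prior_spec(groups, match.arg(prior_mode))
  stopifnot(inherits(prior, "prior_spec"))
  structure(list(groups = groups, prior = prior, shared_nu = TRUE),
            class = "best_model")
}

#' Joint log-likelihood of the robust model
#'
#' Sum over groups and data points of the log location-scale t density,
#' assuming independent observations: group g uses `(mu[g], sigma[g], nu)`.
#'
#' @param mu,sigma Numeric vectors, one entry per group.
#' @param nu Shared shape parameter (> 0).
#' @param groups List of [group_dataset()].
#' @return The log-likelihood value.
#' @export
log_likelihood <- function(mu, sigma, nu, groups) {
  groups <- as_group_list(groups)
  G <- length(groups)
  stopifnot(length(mu) == G, length(sigma) == G, length(nu) == 1)
  if (any(sigma <= 0) || nu <= 0) stop("sigma and nu must be > 0")
  ll <- 0
  for (g in seq_len(G)) {
    y <- groups[[g]]$values
    if (!all(is.finite(y))) stop("non-finite data in group ", g)
    ll <- ll + sum(dt_ls(y, mu[g], sigma[g], nu, log = TRUE))
  }
  ll
}

best_par_names <- function(G) {
  c(sprintf("mu[%d]", seq_len(G)), sprintf("sigma[%d]", seq_len(G)), "nu")
}

#' Sample the posterior of the robust comparison model
#'
#' Runs independent MCMC chains (coordinate-wise slice sampling) with
#' overdispersed initial values and discards `warmup` iterations per chain.
#' `draws` counts retained draws in total across chains, so the default
#' 100,000 draws with 4 chains keeps 25,000 per chain. Fully deterministic
#' given `seed`.
#'
#' @param model A [best_model()].
#' @param draws Total retained draws across chains (>= 1000).
#' @param chains Number of chains (>= 2, required for PSRF).
#' @param warmup Discarded iterations per chain.
#' @param seed Integer seed.
#' @return A `best_trace`: list with `samples` (a [coda::mcmc.list] with
#'   parameters `mu[g]`, `sigma[g]`, `nu`), the model, group labels/sizes,
#'   and the sampling settings.
#' @export
sample_posterior <- function(model, draws = 100000, chains = 4,
                             warmup = 1000, seed = 1) {
  stopifnot(inherits(model, "best_model"))
  if (draws < 1000) stop("need draws >= 1000")
  if (chains < 2) stop("need chains >= 2 (required for convergence checks)")
  G <- length(model$groups)
  pr <- model$prior
  per_chain <- ceiling(draws / chains)
  ys <- lapply(model$groups, `[[`, "values")
  for (y in ys) if (!all(is.finite(y))) stop("non-finite data")

  set.seed(as.integer(seed))
  chains_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    init <- numeric(2 * G + 1)
    for (g in seq_len(G)) {
      y <- ys[[g]]
      init[g] <- median(y) + rnorm(1, 0, max(sd(y), 1e-8) / sqrt(length(y)))
      s0 <- min(max(sd(y), pr$L * 1.01), pr$H * 0.99)
      init[G + g] <- min(max(s0 * exp(rnorm(1, 0, 0.3)), pr$L * 1.001),
                         pr$H * 0.999)
    }
    init[2 * G + 1] <- pr$nu_offset + exp(runif(1, log(1), log(30)))
    m <- .best_slice_chain(ys, init, pr$M, pr$S, pr$L, pr$H,
                           pr$nu_offset, pr$nu_mean,
                           as.integer(per_chain), as.integer(warmup))
    colnames(m) <- best_par_names(G)
    chains_out[[ch]] <- coda::mcmc(m, start = warmup + 1)
  }
  structure(list(samples = coda::as.mcmc.list(chains_out),
                 model = model,
                 labels = vapply(model$groups, `[[`, "", "label"),
                 n = vapply(model$groups, `[[`, 0L, "n"),
                 chains = chains, draws_per_chain = per_chain,
                 warmup = warmup, seed = as.integer(seed)),
            class = "best_trace")
}

#' @export
print.best_trace <- function(x, ...) {
  cat("Robust comparison posterior: ", length(x$labels), " groups (",
      paste(x$labels, collapse = ", "), "), ", x$chains, " chains x ",
      x$draws_per_chain, " draws\n", sep = "")
  print(signif(trace_means(x), 4))
  invisible(x)
}

#' Fit the robust comparison in one call
#'
#' Builds pooled-data priors for the supplied groups and samples the
#' posterior.
#'
#' @inheritParams best_model
#' @inheritParams sample_posterior
#' @export
best_fit <- function(groups, draws = 100000, chains = 4, warmup = 1000,
                     seed = 1, prior = NULL,
                     prior_mode = c("default", "sensitivity")) {
  sample_posterior(best_model(groups, prior, prior_mode),
                   draws = draws, chains = chains, warmup = warmup,
                   seed = seed)
}

# draws of one parameter, chains concatenated
trace_param <- function(trace, name) {
  unlist(lapply(trace$samples, function(m) as.numeric(m[, name])),
         use.names = FALSE)
}

trace_means <- function(trace) {
  nm <- colnames(trace$samples[[1]])
  setNames(vapply(nm, function(p) mean(trace_param(trace, p)), 0), nm)
}

#' Export a posterior trace as a tidy table
#'
#' @param trace A `best_trace`.
#' @return A data frame with columns `chain`, `draw`, `parameter`, `value`.
#' @export
trace_as_table <- function(trace) {
  stopifnot(inherits(trace, "best_trace"))
  nm <- colnames(trace$samples[[1]])
  do.call(rbind, lapply(seq_along(trace$samples), function(ch) {
    m <- trace$samples[[ch]]
    data.frame(chain = ch,
               draw = rep(seq_len(nrow(m)), times = length(nm)),
               parameter = rep(nm, each = nrow(m)),
               value = as.numeric(m))
  }))
}
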