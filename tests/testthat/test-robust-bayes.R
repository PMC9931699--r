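test_that("pooled priors scale with the pooled data moments", {
  # two groups engineered to pooled mean 10, pooled sd exactly 2
  vals <- c(8, 8, 12, 12)
  sd0 <- sd(vals)
  g <- list(group_dataset("a", vals[1:2] + c(-0.0, 0.0)),
            group_dataset("b", vals[3:4]))
  pr <- pooled_prior_spec(g)
  expect_equal(pr$M, 10)
  expect_equal(pr$S, 10 * sd0)
  expect_equal(pr$L, sd0 / 100)
  expect_equal(pr$H, 100 * sd0)

  prs <- pooled_prior_spec(g, "sensitivity")
  expect_equal(prs$S, 1000 * sd0)
  expect_equal(prs$L, sd0 / 1000)
  expect_equal(prs$H, 1000 * sd0)

  degen <- list(group_dataset("a", c(3, 3)), group_dataset("b", c(3, 3)))
  expect_error(pooled_prior_spec(degen), "degenerate")
})

test_that("log-likelihood matches closed forms and is additive over groups", {
  g1 <- group_dataset("a", c(5, 7, 9))
  g2 <- group_dataset("b", c(1, 2))

  # symmetry of the t density around the location
  la <- log_likelihood(6, 2, 4, list(group_dataset("x", c(6 + 1.3, 6 + 1.3))))
  lb <- log_likelihood(6, 2, 4, list(group_dataset("x", c(6 - 1.3, 6 - 1.3))))
  expect_equal(la, lb)

  # closed-form t density at the mode: f(mu) = Gamma((nu+1)/2) /
  # (Gamma(nu/2) sqrt(nu pi) sigma)
  nu <- 3.7; sigma <- 2.2
  expect_equal(
    log_likelihood(5, sigma, nu, list(group_dataset("x", c(5, 5)))),
    2 * (lgamma((nu + 1) / 2) - lgamma(nu / 2) -
           0.5 * log(nu * pi) - log(sigma)))

  # normal limit at large nu, per-point error below 1e-4
  x <- seq(-3, 3, length.out = 21)
  gl <- group_dataset("x", x)
  expect_lt(max(abs(dt_ls(x, 0, 1, 1e6, log = TRUE) -
                      dnorm(x, 0, 1, log = TRUE))), 1e-4)

  # additivity: one concatenated group with shared parameters
  both <- group_dataset("ab", c(g1$values, g2$values))
  expect_equal(log_likelihood(c(4, 4), c(3, 3), 5, list(g1, g2)),
               log_likelihood(4, 3, 5, list(both)))

  expect_error(log_likelihood(0, -1, 5, list(g1)), "sigma")
})

test_that("posterior sampling is deterministic given the seed", {
  set.seed(99)
  g <- list(group_dataset("a", rt_ls(30, 10, 3, 5)),
            group_dataset("b", rt_ls(30, 8, 3, 5)))
  t1 <- best_fit(g, draws = 2000, chains = 2, warmup = 200, seed = 5)
  t2 <- best_fit(g, draws = 2000, chains = 2, warmup = 200, seed = 5)
  expect_identical(t1$samples, t2$samples)
  t3 <- best_fit(g, draws = 2000, chains = 2, warmup = 200, seed = 6)
  expect_false(identical(t1$samples, t3$samples))
})

test_that("posterior draws respect the prior support", {
  set.seed(2)
  g <- list(group_dataset("a", rt_ls(40, 10, 3, 5)),
            group_dataset("b", rt_ls(40, 9, 3, 5)))
  m <- best_model(g)
  tr <- sample_posterior(m, draws = 4000, chains = 2, warmup = 300, seed = 3)
  for (ch in tr$samples) {
    for (gi in 1:2) {
      s <- as.numeric(ch[, sprintf("sigma[%d]", gi)])
      expect_true(all(s >= m$prior$L & s <= m$prior$H))
    }
    expect_true(all(as.numeric(ch[, "nu"]) >= m$prior$nu_offset))
  }
})

test_that("with almost no data the posterior mean tracks the prior", {
  g <- list(group_dataset("a", c(9.9, 10.1)),
            group_dataset("b", c(9.8, 10.2)))
  pr <- prior_spec(M = 50, S = 2, L = 0.001, H = 2000)
  tr <- sample_posterior(best_model(g, prior = pr), draws = 8000,
                         chains = 2, warmup = 500, seed = 4)
  post_mu <- mean(c(sapply(tr$samples, function(m) mean(m[, "mu[1]"]))))
  # the tiny dataset cannot overcome a tight prior far away: the posterior
  # of mu is pulled most of the way towards M = 50
  expect_gt(post_mu, 25)
})

test_that("posterior means recover simulation truth within 3 posterior SDs", {
  set.seed(314)
  g <- list(group_dataset("a", rt_ls(250, 20, 5, 5)),
            group_dataset("b", rt_ls(250, 10, 5, 5)))
  tr <- best_fit(g, draws = 8000, chains = 4, warmup = 500, seed = 1)
  for (p in c("mu[1]", "mu[2]")) {
    draws <- unlist(lapply(tr$samples, function(m) as.numeric(m[, p])))
    truth <- if (p == "mu[1]") 20 else 10
    expect_lt(abs(mean(draws) - truth), 3 * sd(draws))
  }
})

test_that("default and sensitivity priors agree on informative data", {
  set.seed(7)
  g <- list(group_dataset("a", rt_ls(120, 14, 6, 4)),
            group_dataset("b", rt_ls(120, 10, 6, 4)))
  t_def <- best_fit(g, draws = 6000, chains = 2, warmup = 500, seed = 2,
                    prior_mode = "default")
  t_sen <- best_fit(g, draws = 6000, chains = 2, warmup = 500, seed = 2,
                    prior_mode = "sensitivity")
  d_def <- difference_draws(t_def)$mu_diff
  d_sen <- difference_draws(t_sen)$mu_diff
  expect_lt(abs(mean(d_def) - mean(d_sen)), 0.5 * sd(d_def))
})

test_that("the slice sampler agrees with an independent MCMC engine", {
  # the same model written in the JAGS language is the cross-check oracle
  library(rjags)
  set.seed(123)
  y1 <- rt_ls(80, 18, 5, 5)
  y2 <- rt_ls(60, 11, 5, 5)
  g <- list(group_dataset("a", y1), group_dataset("b", y2))
  pr <- pooled_prior_spec(g)

  tr <- best_fit(g, draws = 12000, chains = 2, warmup = 1000, seed = 9)

  jm <- "model{
    for (i in 1:N) { y[i] ~ dt(mu[grp[i]], tau[grp[i]], nu) }
    for (j in 1:2) {
      mu[j] ~ dnorm(M, pow(S, -2))
      sigma[j] ~ dunif(L, H)
      tau[j] <- pow(sigma[j], -2)
    }
    nu <- 1 + numin
    numin ~ dexp(1/29)
  }"
  jags <- jags.model(textConnection(jm),
                     data = list(y = c(y1, y2),
                                 grp = rep(1:2, c(80, 60)), N = 140,
                                 M = pr$M, S = pr$S, L = pr$L, H = pr$H),
                     n.chains = 2, n.adapt = 500, quiet = TRUE)
  update(jags, 500, progress.bar = "none")
  js <- coda.samples(jags, c("mu", "sigma", "nu"), n.iter = 6000,
                     progress.bar = "none")
  jmean <- summary(js)$statistics[, "Mean"]

  ours <- sapply(c("mu[1]", "mu[2]", "sigma[1]", "sigma[2]", "nu"),
                 function(p) {
                   mean(unlist(lapply(tr$samples,
                                      function(m) as.numeric(m[, p]))))
                 })
  for (p in names(ours)) {
    draws <- unlist(lapply(tr$samples, function(m) as.numeric(m[, p])))
    expect_lt(abs(ours[[p]] - jmean[[p]]), 0.15 * sd(draws) + 0.02)
  }
})

test_that("trace tables are tidy and complete", {
  set.seed(5)
  g <- list(group_dataset("a", rt_ls(20, 10, 3, 5)),
            group_dataset("b", rt_ls(20, 9, 3, 5)))
  tr <- best_fit(g, draws = 2000, chains = 2, warmup = 100, seed = 1)
  tab <- trace_as_table(tr)
  expect_named(tab, c("chain", "draw", "parameter", "value"))
  expect_equal(nrow(tab), 2 * 1000 * 5)
  expect_setequal(unique(tab$parameter),
                  c("mu[1]", "mu[2]", "sigma[1]", "sigma[2]", "nu"))
})
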