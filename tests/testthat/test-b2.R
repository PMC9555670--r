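# fake posterior with given gamma draws, for summary arithmetic tests
fake_fit <- function(gamma_draws) {
  structure(list(mu = matrix(0, length(gamma_draws), 1),
                 gamma = array(gamma_draws, c(length(gamma_draws), 1, 1),
                               dimnames = list(NULL, "g", NULL)),
                 sigma_a = matrix(0, length(gamma_draws), 1),
                 covariate_names = "g",
                 spec = b2_spec(n_chains = 1)),
            class = "b2_fit")
}

test_that("simulate_b2_network matches closed-form densities", {
  # log-odds -> -Inf limit: no edges
  net_lo <- simulate_b2_network(mu = -20, n_actors = 50, seed = 1)
  expect_equal(sum(net_lo$adjacency), 0)

  # mu = 0: density ~ Bernoulli(0.5) over 19900 dyads
  net_half <- simulate_b2_network(mu = 0, n_actors = 200, seed = 2)
  d <- mean(net_half$adjacency[upper.tri(net_half$adjacency)])
  se <- sqrt(0.25 / choose(200, 2))
  expect_lt(abs(d - 0.5), 3 * se)

  # covariate enters as x_i + x_j: gamma = log 2, x = 1 for all actors
  # -> density logistic(2 log 2) = 0.8
  x <- matrix(1, 200, 1, dimnames = list(NULL, "z"))
  net_cov <- simulate_b2_network(mu = 0, gamma = log(2), covariates = x,
                                 n_actors = 200, seed = 3)
  dc <- mean(net_cov$adjacency[upper.tri(net_cov$adjacency)])
  p <- plogis(2 * log(2))
  expect_lt(abs(dc - p), 3 * sqrt(p * (1 - p) / choose(200, 2)))

  expect_error(simulate_b2_network(mu = Inf, n_actors = 10), "finite")

  # determinism
  n1 <- simulate_b2_network(mu = -1, sigma_a = 0.5, n_actors = 40, seed = 9)
  n2 <- simulate_b2_network(mu = -1, sigma_a = 0.5, n_actors = 40, seed = 9)
  expect_identical(n1$adjacency, n2$adjacency)
})

test_that("logistic MLE oracle solves the intercept-only model in closed
          form and agrees with glm", {
  net <- simulate_b2_network(mu = -1, n_actors = 60, seed = 4)
  d <- mean(net$adjacency[upper.tri(net$adjacency)])
  mle <- logistic_mle_oracle(net)
  expect_true(mle$converged)
  expect_equal(mle$mu_hat, qlogis(d), tolerance = 1e-8)

  x <- matrix(rep(c(0, 1), each = 30), ncol = 1, dimnames = list(NULL, "z"))
  net2 <- simulate_b2_network(mu = -1, gamma = 0.8, covariates = x,
                              n_actors = 60, seed = 5)
  mle2 <- logistic_mle_oracle(net2)
  dy <- proxnet:::eligible_dyads(net2)
  ref <- glm(dy$y ~ dy$Z, family = binomial())
  expect_equal(mle2$mu_hat, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(unname(mle2$gamma_hat), unname(coef(ref)[2]),
               tolerance = 1e-6)
})

test_that("MLE oracle flags perfect separation", {
  # dummy that perfectly separates edges from non-edges
  net <- build_network(c("A", "B", "C", "D"),
                       data.frame(participant_a = "A", participant_b = "B",
                                  contact_seconds = 1L, first_s = 1L,
                                  last_s = 1L),
                       covariates = matrix(c(10, 10, -10, -10), ncol = 1,
                                           dimnames = list(NULL, "sep")))
  mle <- logistic_mle_oracle(net)
  expect_false(mle$converged)
})

test_that("the dyadic likelihood is invariant under actor relabeling", {
  set.seed(12)
  x <- matrix(rbinom(40, 1, 0.5), ncol = 1, dimnames = list(NULL, "z"))
  net <- simulate_b2_network(mu = -1, gamma = 0.5, covariates = x,
                             n_actors = 40, seed = 6)
  perm <- sample(40)
  net_p <- net
  net_p$actors <- net$actors[perm]
  net_p$adjacency <- net$adjacency[perm, perm]
  net_p$weights <- net$weights[perm, perm]
  net_p$covariates <- net$covariates[perm, , drop = FALSE]
  net_p$dyad_mask <- net$dyad_mask[perm, perm]
  m1 <- logistic_mle_oracle(net)
  m2 <- logistic_mle_oracle(net_p)
  expect_equal(m1$mu_hat, m2$mu_hat, tolerance = 1e-6)
  expect_equal(m1$gamma_hat, m2$gamma_hat, tolerance = 1e-6)
})

test_that("fit_b2 is deterministic given a seed", {
  net <- simulate_b2_network(mu = -1.5, sigma_a = 0.4, n_actors = 30,
                             seed = 21)
  spec <- b2_spec(n_chains = 2, n_burnin = 200, n_iter = 300, seed = 77)
  f1 <- fit_b2(net, spec)
  f2 <- fit_b2(net, spec)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$sigma_a, f2$sigma_a)
  expect_identical(f1$actor_effects, f2$actor_effects)
  f3 <- fit_b2(net, b2_spec(n_chains = 2, n_burnin = 200, n_iter = 300,
                            seed = 78))
  expect_false(identical(f1$mu, f3$mu))
})

test_that("an edgeless network warns and leaves the OR uninformative", {
  net <- simulate_b2_network(mu = -20, n_actors = 20, seed = 8)
  net$covariates <- matrix(rep(c(0, 1), each = 10), ncol = 1,
                           dimnames = list(net$actors, "cond"))
  expect_warning(fit <- fit_b2(net, b2_spec(n_chains = 2, n_burnin = 300,
                                            n_iter = 500, seed = 2)),
                 "no edges")
  # density below 1/n_dyads: posterior mass of mu in the far-left tail
  expect_lt(mean(fit$mu), qlogis(1 / choose(20, 2)))
  or <- summarize_or(fit, "cond")
  expect_true(or$ci_low <= 1 && or$ci_high >= 1)
})

test_that("summarize_or follows the lognormal closed form", {
  # degenerate posteriors
  expect_equal(summarize_or(fake_fit(rep(0, 100)))$or_point, 1)
  expect_equal(summarize_or(fake_fit(rep(log(2), 100)))$or_point, 2)
  f0 <- summarize_or(fake_fit(rep(0, 100)))
  expect_equal(c(f0$ci_low, f0$ci_high), c(1, 1))
  expect_equal(f0$formatted, "OR = 1.00, 95% CI [1.00, 1.00]")

  # draws ~ N(0, 0.1^2): OR ~ exp(0.005), CI ~ exp(+-1.96 * 0.1)
  set.seed(123)
  g <- rnorm(20000, 0, 0.1)
  s <- summarize_or(fake_fit(g))
  expect_equal(s$or_point, exp(0.005), tolerance = 0.01)
  expect_equal(s$ci_low, exp(-0.196), tolerance = 0.02)
  expect_equal(s$ci_high, exp(0.196), tolerance = 0.02)

  expect_error(summarize_or(fake_fit(0), "nope"), "unknown covariate")
})

test_that("diagnostics separate mixed from unmixed chains", {
  set.seed(42)
  good <- structure(list(mu = matrix(rnorm(2000), 1000, 2),
                         gamma = array(0, c(1000, 0, 2)),
                         sigma_a = matrix(abs(rnorm(2000)) + 1, 1000, 2),
                         covariate_names = character(0),
                         spec = b2_spec(n_chains = 2)),
                    class = "b2_fit")
  dg <- b2_diagnostics(good, warn = FALSE)
  expect_lt(dg$rhat[dg$parameter == "mu"], 1.02)
  expect_gt(dg$ess[dg$parameter == "mu"], 500)

  bad <- good
  bad$mu <- cbind(rnorm(1000, -5), rnorm(1000, 5))
  expect_warning(db <- b2_diagnostics(bad), "R-hat")
  expect_gt(db$rhat[db$parameter == "mu"], 1.1)

  flat <- good
  flat$mu <- matrix(1, 1000, 2)
  expect_warning(df <- b2_diagnostics(flat), "degenerate")
  expect_true(is.na(df$ess[df$parameter == "mu"]))
})

test_that("single-chain fits report ESS but no R-hat", {
  one <- structure(list(mu = matrix(rnorm(1000), 1000, 1),
                        gamma = array(0, c(1000, 0, 1)),
                        sigma_a = matrix(1 + abs(rnorm(1000)), 1000, 1),
                        covariate_names = character(0),
                        spec = b2_spec(n_chains = 1)),
                   class = "b2_fit")
  d <- b2_diagnostics(one, warn = FALSE)
  expect_true(is.na(d$rhat[d$parameter == "mu"]))
  expect_gt(d$ess[d$parameter == "mu"], 100)
})

test_that("doubling the actors shrinks the credible interval for gamma", {
  widths <- sapply(c(40, 80), function(n) {
    x <- matrix(rep(c(0, 1), each = n / 2), ncol = 1,
                dimnames = list(NULL, "z"))
    ws <- sapply(1:2, function(r) {
      net <- simulate_b2_network(mu = -1.5, gamma = -0.3, sigma_a = 0.3,
                                 covariates = x, n_actors = n,
                                 seed = 100 + r)
      fit <- fit_b2(net, b2_spec(n_chains = 2, n_burnin = 400, n_iter = 800,
                                 seed = r))
      q <- quantile(as.vector(fit$gamma[, 1, ]), c(0.025, 0.975))
      diff(q)
    })
    mean(ws)
  })
  expect_lt(widths[2], widths[1])
})

test_that("fit methods expose probabilities, residuals and simulations", {
  x <- matrix(rep(c(0, 1), each = 15), ncol = 1, dimnames = list(NULL, "z"))
  net <- simulate_b2_network(mu = -1, gamma = 0.4, sigma_a = 0.3,
                             covariates = x, n_actors = 30, seed = 55)
  fit <- fit_b2(net, b2_spec(n_chains = 2, n_burnin = 200, n_iter = 400,
                             seed = 5))
  f <- fitted(fit)
  expect_true(all(f$p > 0 & f$p < 1))
  expect_equal(nrow(f), choose(30, 2))
  r <- residuals(fit)
  expect_equal(length(r), choose(30, 2))
  expect_true(all(abs(r) <= 1))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  for (s in sims) {
    expect_true(isSymmetric(s))
    expect_true(all(diag(s) == 0))
  }
  expect_output(print(fit), "b2 dyadic network model")
  expect_output(print(summary(fit)), "Odds ratios")
})
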