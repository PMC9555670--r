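#' MCMC specification for the b2 model
#'
#' Priors and sampler settings. The defaults are the conventional diffuse
#' choices for the p2 model family: Normal(0, `prior_sd_fixed`^2) on the
#' density intercept and each covariate effect, and
#' Inverse-Gamma(`prior_a`, `prior_b`) on the actor-effect variance.
#'
#' @param prior_sd_fixed prior SD for the intercept and covariate effects
#'   (log-odds scale, default 10).
#' @param prior_a,prior_b shape and scale of the Inverse-Gamma prior on the
#'   actor-effect variance (default 0.001 each).
#' @param n_chains number of MCMC chains (default 4).
#' @param n_burnin burn-in iterations per chain (default 2000); proposal
#'   scales adapt only during burn-in.
#' @param n_iter post-burn-in iterations per chain (default 10000).
#' @param thin thinning interval (default 1).
#' @param sigma_fixed optional: hold the actor-effect SD fixed at this value
#'   instead of sampling it; `0` pins all actor effects at zero, reducing the
#'   model to plain dyadic logistic regression. `NULL` (default) samples it.
#' @param store_actor_effects keep the per-actor random-effect draws
#'   (default `TRUE`).
#' @param seed integer seed; all chains derive their streams from it.
#' @return an object of class `b2_spec`.
#' @export
b2_spec <- function(prior_sd_fixed = 10, prior_a = 0.001, prior_b = 0.001,
                    n_chains = 4, n_burnin = 2000, n_iter = 10000, thin = 1,
                    sigma_fixed = NULL, store_actor_effects = TRUE,
                    seed = 1) {
  stopifnot(prior_sd_fixed > 0, prior_a > 0, prior_b > 0,
            n_chains >= 1, n_burnin >= 1, n_iter >= 1, thin >= 1,
            is.null(sigma_fixed) || sigma_fixed >= 0)
  structure(list(prior_sd_fixed = prior_sd_fixed, prior_a = prior_a,
                 prior_b = prior_b, n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_iter = as.integer(n_iter), thin = as.integer(thin),
                 sigma_fixed = sigma_fixed,
                 store_actor_effects = isTRUE(store_actor_effects),
                 seed = as.integer(seed)),
            class = "b2_spec")
}

# eligible upper-triangle dyads of a contact_network, with dyad covariates
# z_ijk = x_ik + x_jk
eligible_dyads <- function(network) {
  n <- length(network$actors)
  ut <- which(upper.tri(network$dyad_mask) & network$dyad_mask,
              arr.ind = TRUE)
  X <- network$covariates
  K <- ncol(X)
  Z <- matrix(0, nrow(ut), K)
  if (K > 0) Z <- X[ut[, 1], , drop = FALSE] + X[ut[, 2], , drop = FALSE]
  colnames(Z) <- colnames(X)
  list(i = ut[, 1], j = ut[, 2], y = network$adjacency[ut], Z = Z, n = n)
}

#' Fit the b2 Bayesian dyadic network model
#'
#' The b2 model is an undirected, unweighted reduction of the multilevel p2
#' model: it omits reciprocity, dyadic predictors and network-level random
#' effects, and gives each actor one random effect shared by its sender and
#' receiver roles. For each eligible dyad (i, j),
#' \deqn{y_{ij} \sim \mathrm{Bernoulli}\!\big(\mathrm{logit}^{-1}(\mu +
#'   \textstyle\sum_k \gamma_k (x_{ik} + x_{jk}) + A_i + A_j)\big),\quad
#'   A_i \sim N(0, \sigma_A^2).}
#' Estimation is Metropolis-within-Gibbs: random-walk proposals for
#' \eqn{\mu}, each \eqn{\gamma_k} and each \eqn{A_i}, a conjugate
#' inverse-gamma draw for \eqn{\sigma_A^2}, proposal scales adapted during
#' burn-in toward 20--50\% acceptance and frozen afterwards, and actor
#' effects re-centred each sweep with their mean absorbed into \eqn{\mu}.
#'
#' An actor-level condition dummy enters a dyad through the sum
#' \eqn{x_i + x_j}; the odds ratio reported by [summarize_or()] is
#' \eqn{\exp(\gamma_k)}, the per-actor convention.
#'
#' @param network a `contact_network` with at least 2 actors and 1 eligible
#'   dyad.
#' @param spec a [b2_spec()].
#' @return an object of class `b2_fit` with posterior draws (`mu`:
#'   iterations x chains; `gamma`: iterations x covariates x chains;
#'   `sigma_a`; optionally `actor_effects`), per-chain acceptance rates, the
#'   network and the spec. Methods: `print`, `summary`, `coef`, `plot`,
#'   `simulate`, `fitted`, `residuals`.
#' @seealso [summarize_or()], [b2_diagnostics()], [logistic_mle_oracle()]
#' @export
fit_b2 <- function(network, spec = b2_spec()) {
  stopifnot(inherits(network, "contact_network"), inherits(spec, "b2_spec"))
  dy <- eligible_dyads(network)
  if (dy$n < 2 || length(dy$y) < 1) {
    stop("network must have at least 2 actors and 1 eligible dyad")
  }
  if (!all(is.finite(network$covariates))) stop("non-finite covariates")
  dens <- mean(dy$y)
  if (dens == 0 || dens == 1) {
    warning("network has ", if (dens == 0) "no" else "all",
            " edges: density intercept is weakly identified")
  }
  sigma_fixed <- if (is.null(spec$sigma_fixed)) -1 else spec$sigma_fixed
  K <- ncol(dy$Z)
  n_keep <- spec$n_iter %/% spec$thin

  set.seed(spec$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_chains)
  mu <- matrix(NA_real_, n_keep, spec$n_chains)
  sigma_a <- matrix(NA_real_, n_keep, spec$n_chains)
  gamma <- array(NA_real_, c(n_keep, K, spec$n_chains),
                 dimnames = list(NULL, colnames(dy$Z), NULL))
  actor <- if (spec$store_actor_effects) {
    array(NA_real_, c(n_keep, dy$n, spec$n_chains),
          dimnames = list(NULL, network$actors, NULL))
  }
  accept <- matrix(NA_real_, 3, spec$n_chains,
                   dimnames = list(c("mu", "gamma", "actor"), NULL))
  for (ch in seq_len(spec$n_chains)) {
    set.seed(chain_seeds[ch])
    res <- b2_mcmc_chain(as.integer(dy$i - 1L), as.integer(dy$j - 1L),
                         as.integer(dy$y), dy$Z, dy$n,
                         spec$n_burnin, spec$n_iter, spec$thin,
                         spec$prior_sd_fixed, spec$prior_a, spec$prior_b,
                         sigma_fixed, spec$store_actor_effects)
    if (any(!is.finite(res$mu))) stop("non-finite posterior draws")
    mu[, ch] <- res$mu
    sigma_a[, ch] <- res$sigma_a
    if (K > 0) gamma[, , ch] <- res$gamma
    if (spec$store_actor_effects) actor[, , ch] <- res$actor_effects
    accept[, ch] <- res$accept
  }
  structure(list(mu = mu, gamma = gamma, sigma_a = sigma_a,
                 actor_effects = actor, accept = accept,
                 covariate_names = colnames(dy$Z),
                 network = network, spec = spec),
            class = "b2_fit")
}

#' @export
coef.b2_fit <- function(object, ...) {
  out <- c(mu = mean(object$mu))
  for (k in seq_along(object$covariate_names)) {
    out[object$covariate_names[k]] <- mean(object$gamma[, k, ])
  }
  c(out, sigma_a = mean(object$sigma_a))
}

#' @export
print.b2_fit <- function(x, ...) {
  cat("b2 dyadic network model fit\n")
  cat("  actors:", length(x$network$actors),
      " eligible dyads:", sum(x$network$dyad_mask[upper.tri(x$network$dyad_mask)]),
      "\n")
  cat("  chains:", x$spec$n_chains, " kept draws/chain:", nrow(x$mu), "\n")
  cat("  posterior means:\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' Odds-ratio summary for a covariate effect
#'
#' The point estimate is the posterior mean of `exp(gamma_k)`; the interval
#' is the central 95\% percentile credible interval of `exp(gamma_k)`.
#'
#' @param fit a [fit_b2()] result.
#' @param covariate covariate name (default: the first).
#' @param level credible level (default 0.95).
#' @return data frame `covariate`, `or_point`, `ci_low`, `ci_high`, plus a
#'   `formatted` column in the conventional two-decimal reporting style.
#' @export
summarize_or <- function(fit, covariate = NULL, level = 0.95) {
  stopifnot(inherits(fit, "b2_fit"))
  if (length(fit$covariate_names) == 0) stop("model has no covariates")
  if (is.null(covariate)) covariate <- fit$covariate_names[1]
  k <- match(covariate, fit$covariate_names)
  if (is.na(k)) stop("unknown covariate: ", covariate)
  draws <- exp(as.vector(fit$gamma[, k, ]))
  alpha <- (1 - level) / 2
  ci <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE)
  data.frame(covariate = covariate, or_point = mean(draws),
             ci_low = ci[1], ci_high = ci[2],
             formatted = sprintf("OR = %.2f, 95%% CI [%.2f, %.2f]",
                                 mean(draws), ci[1], ci[2]),
             stringsAsFactors = FALSE)
}

#' @export
summary.b2_fit <- function(object, ...) {
  pars <- param_draws(object)
  tab <- t(vapply(pars, function(m) {
    v <- as.vector(m)
    c(mean = mean(v), sd = stats::sd(v),
      `2.5%` = unname(stats::quantile(v, 0.025)),
      `97.5%` = unname(stats::quantile(v, 0.975)))
  }, numeric(4)))
  diag <- b2_diagnostics(object, warn = FALSE)
  tab <- cbind(tab, rhat = diag$rhat, ess = diag$ess)
  ors <- if (length(object$covariate_names)) {
    do.call(rbind, lapply(object$covariate_names,
                          function(nm) summarize_or(object, nm)))
  }
  structure(list(table = tab, or = ors, accept = rowMeans(object$accept),
                 spec = object$spec), class = "summary.b2_fit")
}

#' @export
print.summary.b2_fit <- function(x, ...) {
  cat("b2 model posterior summary\n\n")
  print(round(x$table, 3))
  if (!is.null(x$or)) {
    cat("\nOdds ratios (posterior mean, central 95% credible interval):\n")
    for (i in seq_len(nrow(x$or))) {
      cat(" ", x$or$covariate[i], ": ", x$or$formatted[i], "\n", sep = "")
    }
  }
  cat("\nMean acceptance rates: ",
      paste(names(x$accept), round(x$accept, 2), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# named list of draw matrices (iterations x chains) for scalar parameters
param_draws <- function(fit) {
  pars <- list(mu = fit$mu)
  for (k in seq_along(fit$covariate_names)) {
    pars[[fit$covariate_names[k]]] <- fit$gamma[, k, , drop = TRUE]
    if (is.null(dim(pars[[fit$covariate_names[k]]]))) {
      pars[[fit$covariate_names[k]]] <- matrix(pars[[fit$covariate_names[k]]],
                                               ncol = fit$spec$n_chains)
    }
  }
  pars$sigma_a <- fit$sigma_a
  pars
}

#' @export
fitted.b2_fit <- function(object, ...) {
  dy <- eligible_dyads(object$network)
  mu_hat <- mean(object$mu)
  g_hat <- vapply(seq_along(object$covariate_names),
                  function(k) mean(object$gamma[, k, ]), 0)
  eta <- mu_hat + if (length(g_hat)) drop(dy$Z %*% g_hat) else 0
  if (!is.null(object$actor_effects)) {
    a_hat <- apply(object$actor_effects, 2, mean)
    eta <- eta + a_hat[dy$i] + a_hat[dy$j]
  }
  p <- stats::plogis(eta)
  data.frame(actor_a = object$network$actors[dy$i],
             actor_b = object$network$actors[dy$j],
             y = dy$y, p = p, stringsAsFactors = FALSE)
}

#' @export
residuals.b2_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  f <- fitted(object)
  r <- f$y - f$p
  if (type == "pearson") r <- r / sqrt(f$p * (1 - f$p))
  r
}

#' @export
plot.b2_fit <- function(x, ...) {
  pars <- param_draws(x)
  op <- graphics::par(mfrow = c(length(pars), 1),
                      mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (nm in names(pars)) {
    m <- pars[[nm]]
    graphics::matplot(m, type = "l", lty = 1, ylab = nm,
                      main = paste("trace:", nm), ...)
  }
  invisible(x)
}

#' Simulate networks from the posterior (or from fixed parameters)
#'
#' Draws adjacency matrices from the model, one per posterior draw sampled
#' at random.
#'
#' @param object a `b2_fit`.
#' @param nsim number of networks.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of symmetric 0/1 adjacency matrices.
#' @export
simulate.b2_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dy <- eligible_dyads(object$network)
  S <- nrow(object$mu) * object$spec$n_chains
  picks <- sample.int(S, nsim, replace = nsim > S)
  n <- dy$n
  lapply(picks, function(s) {
    it <- (s - 1) %% nrow(object$mu) + 1
    ch <- (s - 1) %/% nrow(object$mu) + 1
    eta <- object$mu[it, ch]
    for (k in seq_along(object$covariate_names)) {
      eta <- eta + object$gamma[it, k, ch] * dy$Z[, k]
    }
    if (!is.null(object$actor_effects)) {
      a <- object$actor_effects[it, , ch]
      eta <- eta + a[dy$i] + a[dy$j]
    } else {
      a <- stats::rnorm(n, 0, object$sigma_a[it, ch])
      eta <- eta + a[dy$i] + a[dy$j]
    }
    y <- stats::rbinom(length(eta), 1, stats::plogis(eta))
    adj <- matrix(0L, n, n,
                  dimnames = list(object$network$actors,
                                  object$network$actors))
    adj[cbind(dy$i, dy$j)] <- y
    adj[cbind(dy$j, dy$i)] <- y
    adj
  })
}

#' Newton maximum-likelihood oracle for the no-random-effects limit
#'
#' With the actor-effect SD at zero the b2 model is plain logistic
#' regression of the dyad indicators on `(1, x_i + x_j)`. This fits that
#' regression by Newton-Raphson on the dyadic log-likelihood, converging
#' when the gradient norm falls below `tol`. Used as an independent check of
#' the MCMC sampler.
#'
#' @param network a `contact_network`.
#' @param tol gradient-norm convergence tolerance (default 1e-8).
#' @param max_iter maximum Newton steps (default 100).
#' @return list with `mu_hat`, `gamma_hat` (named), `converged` (logical;
#'   `FALSE` under separation).
#' @export
logistic_mle_oracle <- function(network, tol = 1e-8, max_iter = 100) {
  dy <- eligible_dyads(network)
  X <- cbind(`(Intercept)` = 1, dy$Z)
  y <- dy$y
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(X, y - p))
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    beta <- beta + step
    if (max(abs(beta)) > 50) break  # separation: estimates diverging
  }
  if (converged && max(abs(drop(X %*% beta))) > 12) {
    # fitted log-odds this extreme mean some dyads are fit perfectly:
    # (quasi-)separation, where the gradient vanishes but the MLE does
    # not exist
    converged <- FALSE
  }
  list(mu_hat = unname(beta[1]),
       gamma_hat = stats::setNames(beta[-1], colnames(dy$Z)),
       converged = converged)
}
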