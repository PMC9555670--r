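#' Simulate an undirected network from the b2 generative model
#'
#' Draws each unordered dyad independently as Bernoulli with log-odds
#' `mu + sum_k gamma_k (x_ik + x_jk) + A_i + A_j`, where the actor effects
#' `A_i` are Normal(0, `sigma_a`^2) (or supplied). The generative
#' counterpart of [fit_b2()], used for estimator validation.
#'
#' @param mu density intercept, log-odds scale.
#' @param gamma numeric vector of actor-covariate effects (log-odds per
#'   actor; may be empty).
#' @param sigma_a actor random-effect SD, `>= 0`.
#' @param covariates n-by-k numeric matrix (k = `length(gamma)`); may be
#'   `NULL` when `gamma` is empty.
#' @param n_actors number of actors.
#' @param actor_effects optional fixed actor effects (length `n_actors`);
#'   drawn if `NULL`.
#' @param seed integer seed.
#' @return a `contact_network` whose adjacency was drawn from the model,
#'   with the realized truth attached as attribute `"truth"` (list `mu`,
#'   `gamma`, `sigma_a`, `actor_effects`).
#' @export
simulate_b2_network <- function(mu, gamma = numeric(0), sigma_a = 0,
                                covariates = NULL, n_actors,
                                actor_effects = NULL, seed = 1) {
  if (!all(is.finite(c(mu, gamma, sigma_a)))) {
    stop("model parameters must be finite")
  }
  stopifnot(sigma_a >= 0, n_actors >= 2)
  k <- length(gamma)
  if (k > 0) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n_actors, ncol(covariates) == k)
  } else {
    covariates <- matrix(numeric(0), n_actors, 0)
  }
  set.seed(seed)
  if (is.null(actor_effects)) {
    actor_effects <- stats::rnorm(n_actors, 0, sigma_a)
  }
  stopifnot(length(actor_effects) == n_actors)
  actors <- sprintf("a%03d", seq_len(n_actors))
  ut <- which(upper.tri(matrix(0, n_actors, n_actors)), arr.ind = TRUE)
  eta <- mu + actor_effects[ut[, 1]] + actor_effects[ut[, 2]]
  if (k > 0) {
    Z <- covariates[ut[, 1], , drop = FALSE] + covariates[ut[, 2], , drop = FALSE]
    eta <- eta + drop(Z %*% gamma)
  }
  y <- stats::rbinom(length(eta), 1, stats::plogis(eta))
  adj <- matrix(0L, n_actors, n_actors, dimnames = list(actors, actors))
  adj[ut] <- y
  adj[ut[, c(2, 1)]] <- y
  net <- build_network(actors, data.frame(participant_a = character(),
                                          participant_b = character(),
                                          contact_seconds = integer(),
                                          first_s = integer(),
                                          last_s = integer()),
                       if (k > 0) covariates else NULL)
  net$adjacency <- adj
  net$weights <- adj
  attr(net, "truth") <- list(mu = mu, gamma = gamma, sigma_a = sigma_a,
                             actor_effects = actor_effects)
  net
}
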