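# split-R-hat for a draws matrix (iterations x chains); returns NA for a
# single chain or degenerate draws
split_rhat <- function(m) {
  n <- nrow(m)
  if (ncol(m) < 2 || n < 4) return(NA_real_)
  half <- n %/% 2
  sp <- cbind(m[seq_len(half), , drop = FALSE],
              m[(n - half + 1):n, , drop = FALSE])
  if (stats::sd(as.vector(sp)) == 0) return(NA_real_)
  nn <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size via averaged autocorrelations with Geyer's initial
# monotone positive-pair truncation, on split chains
ess_basic <- function(m) {
  n <- nrow(m)
  if (n < 4) return(NA_real_)
  half <- n %/% 2
  sp <- cbind(m[seq_len(half), , drop = FALSE],
              m[(n - half + 1):n, , drop = FALSE])
  nn <- nrow(sp)
  nc <- ncol(sp)
  if (stats::sd(as.vector(sp)) == 0) return(NA_real_)
  lag_max <- min(nn - 1L, 500L)
  acov <- vapply(seq_len(nc), function(c) {
    stats::acf(sp[, c], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(lag_max + 1L))
  vars <- acov[1, ] * nn / (nn - 1)
  W <- mean(vars)
  var_plus <- (nn - 1) / nn * W + stats::var(colMeans(sp))
  rho <- 1 - (W - rowMeans(acov)) / var_plus  # rho[1] corresponds to lag 0
  # Geyer: sum consecutive pairs while positive and non-increasing
  tau <- 0
  prev <- Inf
  t <- 2L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + pair
    prev <- pair
    t <- t + 2L
  }
  ess <- nn * nc / (1 + 2 * tau)
  min(ess, nn * nc)
}

#' Convergence diagnostics for a b2 fit
#'
#' Split-R-hat and effective sample size for the density intercept, each
#' covariate effect and the actor-effect SD. R-hat requires at least two
#' chains; ESS is computed from averaged split-chain autocorrelations with
#' Geyer's initial-monotone truncation. Degenerate (constant) draws yield
#' `NA` and are flagged.
#'
#' @param fit a [fit_b2()] result.
#' @param warn emit a warning when any R-hat exceeds 1.05 (default `TRUE`).
#' @return data frame `parameter`, `rhat`, `ess`.
#' @export
b2_diagnostics <- function(fit, warn = TRUE) {
  stopifnot(inherits(fit, "b2_fit"))
  pars <- param_draws(fit)
  res <- data.frame(parameter = names(pars),
                    rhat = vapply(pars, split_rhat, 0),
                    ess = vapply(pars, ess_basic, 0),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (warn && any(res$rhat > 1.05, na.rm = TRUE)) {
    bad <- res$parameter[which(res$rhat > 1.05)]
    warning("R-hat > 1.05 for: ", paste(bad, collapse = ", "),
            " - chains may not have mixed")
  }
  if (warn && any(is.na(res$ess))) {
    warning("degenerate (constant) draws for: ",
            paste(res$parameter[is.na(res$ess)], collapse = ", "))
  }
  res
}
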