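# exact null counts of the Mann-Whitney statistic without ties: the number
# of interleavings of n1 x's and n2 y's with U = u is the coefficient of
# q^u in the Gaussian binomial [n1 + n2 choose n1]_q, built by sequential
# multiplication with (1 - q^(n2+i)) / (1 - q^i), i = 1..n1
mwu_count_dist <- function(n1, n2) {
  max_u <- n1 * n2
  coef <- numeric(max_u + 1)
  coef[1] <- 1
  for (i in seq_len(n1)) {
    s <- n2 + i
    if (s <= max_u) {
      coef[(s + 1):(max_u + 1)] <- coef[(s + 1):(max_u + 1)] -
        coef[1:(max_u + 1 - s)]
    }
    if (i <= max_u) {
      for (u in i:max_u) coef[u + 1] <- coef[u + 1] + coef[u + 1 - i]
    }
  }
  coef
}

#' Mann-Whitney U test
#'
#' The statistic counts pairs with `x_i < y_j`, with half credit for ties:
#' `U = #\{(i,j): x_i < y_j\} + 0.5 #\{x_i = y_j\}`. Exact mode evaluates
#' the permutation null distribution (by the classical count recurrence when
#' the pooled sample has no ties, by full enumeration of group assignments
#' otherwise); normal mode uses the tie-corrected normal approximation with
#' continuity correction. Two-sided p-values throughout, defined as the null
#' probability of a statistic at least as far from `n1 n2 / 2` as observed.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"auto"` (exact when feasible, else normal), `"exact"` or
#'   `"normal"`. Auto switches to the approximation when `n1 * n2 > 10000`
#'   or when ties make full enumeration infeasible.
#' @return list of class `htest` with `statistic` (U), `p.value`, `method`,
#'   and sample sizes `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  u <- sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0

  use_exact <- switch(mode,
    exact = TRUE,
    normal = FALSE,
    auto = n1 * n2 <= 10000 &&
      (!has_ties || choose(n1 + n2, n1) <= 2e5))

  if (use_exact && has_ties && choose(n1 + n2, n1) > 2e5) {
    warning("too many tied arrangements for exact enumeration; ",
            "falling back to the normal approximation")
    use_exact <- FALSE
  }

  mid <- n1 * n2 / 2
  if (use_exact) {
    if (!has_ties) {
      cnt <- mwu_count_dist(n1, n2)
      uu <- 0:(n1 * n2)
      p <- sum(cnt[abs(uu - mid) >= abs(u - mid) - 1e-9]) / sum(cnt)
    } else {
      idx <- utils::combn(n1 + n2, n1)
      us <- apply(idx, 2, function(ii) {
        xs <- pooled[ii]; ys <- pooled[-ii]
        sum(outer(xs, ys, "<")) + 0.5 * sum(outer(xs, ys, "=="))
      })
      p <- mean(abs(us - mid) >= abs(u - mid) - 1e-9)
    }
    method <- "Mann-Whitney U test (exact)"
  } else {
    n <- n1 + n2
    t_tab <- table(pooled)
    tie_term <- sum(t_tab^3 - t_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mid) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  structure(list(statistic = c(U = u), parameter = NULL, p.value = p,
                 method = method, data.name = "x and y",
                 n1 = n1, n2 = n2),
            class = "htest")
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. With zero variance in both samples and equal
#' means, `t = 0` and `p = 1`; an infinite statistic is flagged with a
#' warning.
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return list of class `htest` with `statistic` (t), `parameter` (df),
#'   `p.value`, and sample sizes.
#' @export
#' @examples
#' welch_t(c(1, 2, 3, 4), c(2, 4, 6, 8))
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 observations")
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    d <- mean(x) - mean(y)
    if (d == 0) {
      t_stat <- 0; df <- n1 + n2 - 2; p <- 1
    } else {
      warning("zero variance with unequal means: statistic is infinite")
      t_stat <- sign(d) * Inf; df <- n1 + n2 - 2; p <- 0
    }
  } else {
    t_stat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(statistic = c(t = t_stat), parameter = c(df = df),
                 p.value = p, method = "Welch two-sample t test",
                 data.name = "x and y", n1 = n1, n2 = n2),
            class = "htest")
}

#' Simple linear regression with F test
#'
#' Ordinary least squares of `y` on a single predictor `x`, reporting slope,
#' intercept, the overall F statistic on (1, n - 2) degrees of freedom, its
#' p-value and the coefficient of determination.
#'
#' @param x predictor (not constant), `y` response, both length `n >= 3`.
#' @param y response.
#' @return list of class `proxnet_linreg`: `slope`, `intercept`,
#'   `f_statistic`, `df1`, `df2`, `p_value`, `r_squared`, `n`.
#' @export
#' @examples
#' simple_linreg(c(1, 2, 3), c(2, 4, 6))
simple_linreg <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0) stop("predictor is constant")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - intercept - slope * x)^2)
  if (sst == 0) {
    r2 <- 0; f_stat <- 0; p <- 1
  } else {
    r2 <- 1 - sse / sst
    if (sse <= .Machine$double.eps * sst) {
      r2 <- 1; f_stat <- Inf; p <- 0
    } else {
      f_stat <- (r2 / (1 - r2)) * (n - 2)
      p <- stats::pf(f_stat, 1, n - 2, lower.tail = FALSE)
    }
  }
  structure(list(slope = slope, intercept = intercept, f_statistic = f_stat,
                 df1 = 1L, df2 = n - 2L, p_value = p, r_squared = r2, n = n),
            class = "proxnet_linreg")
}

#' @export
print.proxnet_linreg <- function(x, ...) {
  cat(sprintf("Simple linear regression (n = %d)\n", x$n))
  cat(sprintf("  y = %.4g + %.4g x\n", x$intercept, x$slope))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.4g, R2 = %.2f\n",
              x$df1, x$df2, x$f_statistic, x$p_value, x$r_squared))
  invisible(x)
}
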