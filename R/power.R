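#' Wilcoxon power for a lognormal expression difference
#'
#' Monte-Carlo power of a two-sided Wilcoxon test to detect a log2 fold
#' change between two lognormal expression distributions. Each group is drawn
#' as `exp(N(mu, sigma2))`, with the underlying normal means separated by
#' `|mu1 - mu2| = ln(2) * l2fc`, so the separation is expressed in log2-fold
#' units while the spread of the underlying normal is held at `sigma2`.
#'
#' Two test variants are available. `"signed-rank"` (the default) pairs the
#' i-th observation of each group and applies the one-sample Wilcoxon
#' signed-rank test to the differences, using the exact null distribution for
#' `s <= 50` (no ties occur with continuous draws) and the normal
#' approximation beyond. This variant reproduces the published per-group
#' sample-size thresholds for this simulation (s = 158, 42, 20 at l2fc 0.5,
#' 1.0, 1.5). `"rank-sum"` applies the two-sample Wilcoxon rank-sum test via
#' its normal approximation; it crosses 80% power at somewhat smaller s
#' (about 140, 36, 18). See the package vignette for the full discussion.
#'
#' @param l2fc Log2 fold change separating the two groups (non-negative).
#' @param s Per-group sample size (number of nuclei), `s >= 2`.
#' @param alpha Two-sided test level.
#' @param sigma2 Variance of the underlying normal distribution.
#' @param iterations Number of Monte-Carlo iterations.
#' @param seed Integer seed.
#' @param test `"signed-rank"` (default) or `"rank-sum"`.
#' @return Estimated power (scalar in `[0, 1]`), with attributes `se`
#'   (binomial standard error) and `iterations`.
#' @export
wilcoxon_power_lognormal <- function(l2fc, s, alpha = 0.05, sigma2 = 1,
                                     iterations = 10000, seed = 1,
                                     test = c("signed-rank", "rank-sum")) {
  test <- match.arg(test)
  if (s < 2) stop_config("per-group sample size s must be >= 2 (got %s)", s)
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  if (sigma2 <= 0) stop_config("sigma2 must be positive")
  set_seed_strict(seed)
  p <- wilcoxon_sim_pvalues(l2fc, s, sigma2, iterations, test)
  pow <- mean(p < alpha)
  structure(pow, se = sqrt(pow * (1 - pow) / iterations),
            iterations = iterations)
}

# Draws both groups and returns the vector of two-sided p-values.
# Uses the current RNG stream (caller seeds it).
wilcoxon_sim_pvalues <- function(l2fc, s, sigma2, iterations, test,
                                 lognormal = TRUE) {
  delta <- log(2) * l2fc
  sdv <- sqrt(sigma2)
  x <- matrix(rnorm(iterations * s, 0, sdv), nrow = iterations)
  y <- matrix(rnorm(iterations * s, delta, sdv), nrow = iterations)
  if (lognormal) {
    x <- exp(x)
    y <- exp(y)
  }
  if (test == "signed-rank") {
    signed_rank_pvalues(y - x)
  } else {
    rank_sum_pvalues(x, y)
  }
}

# Vectorized two-sided Wilcoxon signed-rank p-values, one per row of the
# difference matrix d. Exact (psignrank) for n <= 50; normal approximation
# without continuity correction otherwise. Ties/zeros have probability zero
# for continuous data and are not corrected for.
signed_rank_pvalues <- function(d) {
  n <- ncol(d)
  r <- row_ranks(abs(d))
  w <- rowSums(r * (d > 0))
  if (n <= 50) {
    lower <- psignrank(w, n)
    upper <- psignrank(w - 1, n, lower.tail = FALSE)
    pmin(1, 2 * pmin(lower, upper))
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    2 * pnorm(-abs((w - mu) / sigma))
  }
}

# Vectorized two-sided Wilcoxon rank-sum p-values (normal approximation,
# no continuity correction); rows of x and y are paired simulations.
rank_sum_pvalues <- function(x, y) {
  n1 <- ncol(x)
  n2 <- ncol(y)
  r <- row_ranks(cbind(x, y))
  w1 <- rowSums(r[, seq_len(n1), drop = FALSE])
  mu <- n1 * (n1 + n2 + 1) / 2
  sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  2 * pnorm(-abs((w1 - mu) / sigma))
}

#' Sample-size search for the lognormal Wilcoxon power simulation
#'
#' Increments the per-group sample size `s` from `s0` in steps of `step`,
#' estimating power at each `s` with [wilcoxon_power_lognormal()], and stops
#' at the first `s` whose estimated power reaches `target_power`.
#'
#' @inheritParams wilcoxon_power_lognormal
#' @param target_power Required power (default 0.8).
#' @param s0 Starting per-group sample size (default 10).
#' @param step Increment (default 2).
#' @param s_max Upper bound; exceeding it raises an error carrying the curve
#'   computed so far in its `data` field.
#' @return An object of class `sn_power_search`: a list with `s` (selected
#'   sample size), `power` (its estimated power), `curve` (data frame of all
#'   evaluated sizes and power estimates), and the call parameters.
#' @export
sample_size_search <- function(l2fc, alpha = 0.05, target_power = 0.8,
                               iterations = 10000, s0 = 10, step = 2,
                               s_max = 2000, sigma2 = 1, seed = 1,
                               test = c("signed-rank", "rank-sum")) {
  test <- match.arg(test)
  if (target_power <= 0 || target_power >= 1) {
    stop_config("target_power must be in (0, 1)")
  }
  if (step < 1) stop_config("step must be >= 1")
  set_seed_strict(seed)
  s <- s0
  sizes <- integer(0)
  powers <- numeric(0)
  repeat {
    p <- wilcoxon_sim_pvalues(l2fc, s, sigma2, iterations, test)
    pow <- mean(p < alpha)
    sizes <- c(sizes, s)
    powers <- c(powers, pow)
    if (pow >= target_power) break
    s <- s + step
    if (s > s_max) {
      cond <- structure(
        class = c("sn_power_no_convergence", "error", "condition"),
        list(message = sprintf(
          "power %.3f at s = %d did not reach target %.2f by s_max = %d",
          pow, s - step, target_power, s_max),
          call = sys.call(-1),
          data = data.frame(s = sizes, power = powers)))
      stop(cond)
    }
  }
  structure(list(s = s, power = pow,
                 curve = data.frame(s = sizes, power = powers),
                 l2fc = l2fc, alpha = alpha, target_power = target_power,
                 iterations = iterations, sigma2 = sigma2, test = test,
                 seed = seed),
            class = "sn_power_search")
}

#' @export
print.sn_power_search <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon (%s) power search: l2fc = %g, alpha = %g, %d iterations\n",
    x$test, x$l2fc, x$alpha, x$iterations))
  cat(sprintf("selected s = %d per group (estimated power %.3f >= %.2f)\n",
              x$s, x$power, x$target_power))
  invisible(x)
}

#' Detection power for distinguishing-HVG calling on log1p-scale data
#'
#' Power of a two-sided Wilcoxon test to separate `N(1, sigma2)` from
#' `N(2^l2fc, sigma2)`, the normal-scale analogue used to size the
#' cluster-vs-rest distinguishing-HVG detection (log1p pre-processed data is
#' approximately normal, so the group means are placed at 1 and `2^l2fc`).
#'
#' @inheritParams wilcoxon_power_lognormal
#' @export
distinguishing_power_normal <- function(l2fc, s, alpha = 0.01, sigma2 = 1,
                                        iterations = 10000, seed = 1,
                                        test = c("signed-rank", "rank-sum")) {
  test <- match.arg(test)
  if (s < 2) stop_config("per-group sample size s must be >= 2 (got %s)", s)
  set_seed_strict(seed)
  delta <- 2^l2fc - 1
  sdv <- sqrt(sigma2)
  x <- matrix(rnorm(iterations * s, 1, sdv), nrow = iterations)
  y <- matrix(rnorm(iterations * s, 1 + delta, sdv), nrow = iterations)
  p <- if (test == "signed-rank") signed_rank_pvalues(y - x) else
    rank_sum_pvalues(x, y)
  pow <- mean(p < alpha)
  structure(pow, se = sqrt(pow * (1 - pow) / iterations),
            iterations = iterations)
}

#' Select the number of cross-validation folds k
#'
#' Starting from k = 2 and incrementing by 1, returns the smallest k such
#' that every cluster still meets the powered minimum after one of its k
#' folds is removed, i.e. `floor(size * (k - 1) / k) >= min_powered_n` for
#' every cluster; optionally the result is bumped by 1 to put each
#' fold-removed subset further above the power threshold.
#'
#' @param cluster_sizes Named or unnamed integer vector of cluster sizes.
#' @param min_powered_n Minimum powered sample size per cluster.
#' @param bump If `TRUE` (default), add 1 to the selected k.
#' @param k_max Safety bound on the search.
#' @return Selected k (integer).
#' @export
select_k <- function(cluster_sizes, min_powered_n, bump = TRUE, k_max = 100) {
  if (length(cluster_sizes) == 0) stop_config("cluster_sizes is empty")
  smallest <- which.min(cluster_sizes)
  name <- names(cluster_sizes)[smallest] %||% as.character(smallest)
  if (min(cluster_sizes) < min_powered_n) {
    stop_config(paste0(
      "cluster '%s' (%d nuclei) is below the powered minimum %d; ",
      "no k can satisfy the fold-removed requirement"),
      name, min(cluster_sizes), min_powered_n)
  }
  for (k in 2:k_max) {
    if (all(floor(cluster_sizes * (k - 1) / k) >= min_powered_n)) {
      return(if (bump) k + 1L else as.integer(k))
    }
  }
  stop_config(paste0(
    "no k <= %d leaves cluster '%s' (%d nuclei) above the powered minimum ",
    "%d after removing one fold"),
    k_max, name, min(cluster_sizes), min_powered_n)
}
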