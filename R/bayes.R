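#' Bayesian interface frequency estimation
#'
#' Relative interface frequencies are modelled by the multinomial-Poisson
#' trick: `X_j ~ Poisson(lambda_j)` with `p_j = lambda_j / sum(lambda)`,
#' and normal uninformative priors (sd 100) on `gamma_j = log(lambda_j)`.
#' The posterior is sampled with an adaptive random-walk Metropolis
#' sampler (coordinates are conditionally independent, so each is updated
#' with its own adapted step); the reported fractions are the posterior
#' draws of `p_j`, which sum to 1 by construction. Convergence is
#' enforced with split R-hat on every `p_j` (< 1.05) across 4 chains.
#'
#' @param counts Named integer vector of observed dimer counts per
#'   interface.
#' @param n_iter Post-warmup iterations per chain (default 1000).
#' @param n_warmup Warmup (adaptation) iterations (default 500).
#' @param n_chains Number of chains (default 4).
#' @param level Credible-interval level (default 0.95, equal-tailed).
#' @param prior_sd Prior standard deviation on gamma (default 100).
#' @param seed Integer seed.
#' @return Object of class `interface_freq_posterior` with the draws of
#'   `p_j`, posterior means, credible bounds and diagnostics; see
#'   [tidy.interface_freq_posterior()].
#' @export
interface_frequencies <- function(counts, n_iter = 1000L, n_warmup = 500L,
                                  n_chains = 4L, level = 0.95,
                                  prior_sd = 100, seed = 1L) {
  if (any(counts != round(counts)) || any(counts < 0)) {
    abort("interface_frequencies(): counts must be non-negative integers")
  }
  if (sum(counts) == 0) {
    abort("interface_frequencies(): need at least one positive count")
  }
  J <- length(counts)
  labels <- names(counts) %||% paste0("interface_", seq_len(J))
  set.seed(seed)
  X <- matrix(rep(as.numeric(counts), each = n_chains), n_chains, J)
  G <- log(X + 0.5) + matrix(rnorm(n_chains * J, 0, 0.5), n_chains, J)
  step <- matrix(0.5, n_chains, J)
  logpost <- function(G) X * G - exp(G) - G^2 / (2 * prior_sd^2)
  lp <- logpost(G)
  draws <- array(NA_real_, c(n_iter, n_chains, J))
  acc <- matrix(0, n_chains, J)
  adapt_block <- 50L
  for (it in seq_len(n_warmup + n_iter)) {
    prop <- G + step * matrix(rnorm(n_chains * J), n_chains, J)
    lp_prop <- logpost(prop)
    ok <- log(matrix(runif(n_chains * J), n_chains, J)) < (lp_prop - lp)
    G[ok] <- prop[ok]
    lp[ok] <- lp_prop[ok]
    acc <- acc + ok
    if (it <= n_warmup && it %% adapt_block == 0L) {
      rate <- acc / adapt_block
      step <- step * exp(rate - 0.44)
      acc[] <- 0
    }
    if (it > n_warmup) {
      P <- exp(G) / rowSums(exp(G))
      draws[it - n_warmup, , ] <- P
    }
  }
  rhat <- vapply(seq_len(J), function(j) split_rhat(draws[, , j]),
                 numeric(1))
  if (any(rhat > 1.05)) {
    abort(paste0("interface_frequencies(): convergence failure, ",
                 "max split R-hat = ", signif(max(rhat), 4),
                 " for ", labels[which.max(rhat)]))
  }
  flat <- matrix(draws, n_iter * n_chains, J)
  a <- (1 - level) / 2
  structure(
    list(draws = flat, labels = labels, counts = as.integer(counts),
         n = sum(counts), level = level,
         mean = colMeans(flat),
         lower = apply(flat, 2, quantile, probs = a),
         upper = apply(flat, 2, quantile, probs = 1 - a),
         rhat = rhat, seed = seed),
    class = "interface_freq_posterior")
}

# split R-hat over an iterations x chains matrix
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  seqs <- cbind(x[seq_len(half), , drop = FALSE],
                x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(seqs)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2, var)
  B <- half * var(means)
  W <- mean(vars)
  if (W < 1e-300) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.interface_freq_posterior <- function(x, ...) {
  cat("<interface_freq_posterior> ", length(x$labels), " interfaces, n = ",
      x$n, " dimers, ", nrow(x$draws), " draws; max split R-hat ",
      signif(max(x$rhat), 4), "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy interface frequency posterior
#'
#' @param x An `interface_freq_posterior`.
#' @param ... Unused.
#' @return Tibble with `interface`, `count`, `estimate` (posterior mean),
#'   `conf.low`, `conf.high` (equal-tailed credible bounds) and `rhat`.
#' @method tidy interface_freq_posterior
#' @export
tidy.interface_freq_posterior <- function(x, ...) {
  tibble(interface = x$labels, count = x$counts, estimate = x$mean,
         conf.low = as.numeric(x$lower), conf.high = as.numeric(x$upper),
         rhat = x$rhat)
}

#' @rdname tidy.interface_freq_posterior
#' @method glance interface_freq_posterior
#' @export
glance.interface_freq_posterior <- function(x, ...) {
  tibble(n = x$n, n_interfaces = length(x$labels),
         n_draws = nrow(x$draws), level = x$level,
         max_rhat = max(x$rhat))
}
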