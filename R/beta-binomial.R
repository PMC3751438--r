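# Core beta-binomial machinery. Everything is computed in natural-log space
# and combined with log-sum-exp so that pileups with thousands of trials do
# not underflow.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp over a matrix of log-likelihood columns.
row_log_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- mx[!is.finite(mx)]
  out
}

check_bb_args <- function(n, k, alpha, beta) {
  if (any(!is.finite(n)) || any(!is.finite(k)) || any(n < 0) || any(k < 0) || any(k > n)) {
    rlang::abort("beta-binomial requires 0 <= k <= n")
  }
  if (any(!is.finite(alpha)) || any(!is.finite(beta)) || any(alpha <= 0) || any(beta <= 0)) {
    rlang::abort("beta-binomial hyperparameters must be strictly positive")
  }
  invisible(NULL)
}

#' Beta-binomial probability mass function
#'
#' Probability of observing `k` successes in `n` Bernoulli trials when the
#' success proportion is itself beta-distributed with hyperparameters
#' `alpha` and `beta`:
#' \deqn{P(k \mid n, \alpha, \beta) = \binom{n}{k}
#'   \frac{B(k + \alpha,\; n - k + \beta)}{B(\alpha, \beta)}}
#' where \eqn{B} is the beta function. This is the evidence model used by all
#' detectors: the beta layer absorbs the uncertainty in the true
#' variant-evidence proportion (sequencing error rate, mappability, allele
#' fraction). Computation is in log space via `lchoose()`/`lbeta()`.
#'
#' All arguments are vectorised and recycled.
#'
#' @param n Number of trials (non-negative integers).
#' @param k Number of successes, `0 <= k <= n`.
#' @param alpha,beta Strictly positive beta hyperparameters.
#' @param log If `TRUE`, return log probabilities.
#' @return Numeric vector of (log) probabilities.
#' @examples
#' beta_binomial_pmf(10, 3, 1, 1) # uniform beta: every k equally likely, 1/11
#' beta_binomial_pmf(30, 2, 1, 700) # error-skewed reference model
#' @export
beta_binomial_pmf <- function(n, k, alpha, beta, log = FALSE) {
  check_bb_args(n, k, alpha, beta)
  lp <- lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
  if (log) lp else exp(lp)
}

#' Conjugate update of a beta distribution by observed counts
#'
#' Adds the observed success count to `alpha` and the failure count to `beta`.
#' This is how evidence from the normal sample sharpens the expected
#' variant-evidence proportion before the tumor sample is scored: with enough
#' normal coverage the data virtually overrides the prior beta shape.
#'
#' @param alpha,beta Strictly positive hyperparameters (vectorised).
#' @param pileup A data frame with columns `n_trials` and `k_successes`
#'   (see [pileup_summary()]).
#' @return A tibble with columns `alpha` and `beta` holding the updated
#'   hyperparameters.
#' @examples
#' conjugate_update(1, 700, pileup_summary(40, 0)) # -> (1, 740)
#' @export
conjugate_update <- function(alpha, beta, pileup) {
  stopifnot(is.data.frame(pileup), all(c("n_trials", "k_successes") %in% names(pileup)))
  n <- pileup$n_trials
  k <- pileup$k_successes
  check_bb_args(n, k, alpha, beta)
  tibble::tibble(alpha = alpha + k, beta = beta + (n - k))
}

# Log-likelihood of (n, k) under each diploid germline genotype class.
# Returns a 3-column matrix (ref, het, var).
germline_loglik <- function(n, k, priors) {
  cbind(
    ref = beta_binomial_pmf(n, k, priors$alpha_ref, priors$beta_ref, log = TRUE),
    het = beta_binomial_pmf(n, k, priors$alpha_nonhom, priors$beta_nonhom, log = TRUE),
    var = beta_binomial_pmf(n, k, priors$alpha_var, priors$beta_var, log = TRUE)
  )
}

#' Posterior over the three diploid germline genotype classes
#'
#' Applies Bayes' theorem over the three genotype classes a diploid normal
#' genome can take at a locus — reference-homozygous, heterozygous,
#' variant-homozygous — given the pileup's trial counts:
#' \deqn{P(i \mid D) = \frac{\pi_i \, P(D \mid i)}{\sum_j \pi_j \, P(D \mid j)}}
#' with each class likelihood a [beta_binomial_pmf()] under that class's
#' hyperparameters. Likelihoods are combined in log space, so the posterior is
#' well defined even at very deep pileups.
#'
#' @param data A data frame with columns `n_trials` and `k_successes`, one row
#'   per locus (see [pileup_summary()]).
#' @param priors A [pair_priors()] object.
#' @return The input tibble with columns `p_ref`, `p_het`, `p_var` appended;
#'   each row sums to 1.
#' @examples
#' germline_posterior(pileup_summary(c(30, 30), c(0, 15)), pair_priors())
#' @export
germline_posterior <- function(data, priors = pair_priors()) {
  stopifnot(is.data.frame(data), all(c("n_trials", "k_successes") %in% names(data)))
  stopifnot(inherits(priors, "pair_priors"))
  n <- data$n_trials
  k <- data$k_successes
  if (length(n) == 0L) {
    return(dplyr::mutate(tibble::as_tibble(data),
      p_ref = numeric(0), p_het = numeric(0), p_var = numeric(0)
    ))
  }
  ll <- germline_loglik(n, k, priors)
  lw <- sweep(ll, 2L, log(c(priors$pi_ref, priors$pi_het, priors$pi_var)), `+`)
  lz <- row_log_sum_exp(lw)
  post <- exp(lw - lz)
  dplyr::mutate(tibble::as_tibble(data),
    p_ref = post[, "ref"], p_het = post[, "het"], p_var = post[, "var"]
  )
}
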